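#' Grouped cooperator/cheater records
#'
#' A `group_records` object is a validated data frame with one row per
#' interaction group and columns `initial_size`, `initial_cooperators`,
#' `final_size`, `final_cooperators`. It is the unit of Price-equation
#' accounting: a group with initial cooperator frequency \eqn{P =
#' initial\_cooperators/initial\_size} ends with final size \eqn{\pi =
#' final\_size} and final cooperator frequency \eqn{P' =
#' final\_cooperators/final\_size}.
#'
#' @param initial_size,initial_cooperators,final_size,final_cooperators
#'   equal-length non-negative numeric vectors; `initial_size` must be
#'   positive and cooperator counts may not exceed the corresponding sizes.
#'   Alternatively a single data frame with these columns may be passed as
#'   the first argument.
#' @return A data frame of class `group_records`.
#' @examples
#' # the two-group worked example: groups of 6 with 1 and 5 cooperators
#' group_records(c(6, 6), c(1, 5), c(16, 32), c(1, 25))
#' @seealso [price_decompose()]
#' @export
group_records <- function(initial_size, initial_cooperators = NULL,
                          final_size = NULL, final_cooperators = NULL) {
  if (is.data.frame(initial_size)) {
    df <- initial_size
    need <- c("initial_size", "initial_cooperators",
              "final_size", "final_cooperators")
    if (!all(need %in% names(df)))
      stop("group table must have columns: ", paste(need, collapse = ", "))
    df <- df[need]
  } else {
    df <- data.frame(initial_size = initial_size,
                     initial_cooperators = initial_cooperators,
                     final_size = final_size,
                     final_cooperators = final_cooperators)
  }
  if (nrow(df) < 1L) stop("at least one group is required")
  with(df, {
    if (any(initial_size <= 0))
      stop("initial_size must be positive (initial frequency must be defined)")
    if (any(initial_cooperators < 0) || any(initial_cooperators > initial_size))
      stop("need 0 <= initial_cooperators <= initial_size")
    if (any(final_size < 0) || any(final_cooperators < 0) ||
        any(final_cooperators > final_size))
      stop("need 0 <= final_cooperators <= final_size")
  })
  class(df) <- c("group_records", "data.frame")
  df
}

#' Read a group table from delimited text
#'
#' Reads CSV or TSV with header columns `initial_size`,
#' `initial_cooperators`, `final_size`, `final_cooperators` and validates
#' them into a [group_records] object.
#'
#' @param path file path; `sep` is inferred from the extension
#'   (`.tsv`/`.txt` = tab, otherwise comma) unless given.
#' @param sep field separator override.
#' @return A [group_records] data frame.
#' @export
read_group_table <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  group_records(read.table(path, header = TRUE, sep = sep))
}

#' Price-equation decomposition of grouped cooperator dynamics
#'
#' Partitions the change in community-wide cooperator frequency into a
#' between-group covariance term and a within-group change term, the Price
#' identity
#' \deqn{\bar\pi\,\Delta\bar P = \mathrm{Cov}(\pi, P) + \mathrm{Ave}(\pi\,\Delta P),}
#' where \eqn{\pi} is final group size, \eqn{P} initial group cooperator
#' frequency, and \eqn{\Delta P = P' - P} the within-group frequency change.
#' The covariance term is the between-group component (it may be rewritten
#' as \eqn{\beta\,\mathrm{Var}(P)}); the expectation term carries the
#' within-group decline of cooperators. Community-wide cooperator frequency
#' rises only when the covariance term outweighs the (typically negative)
#' expectation term.
#'
#' Two weighting conventions are supported. `"uniform"` weights every group
#' 1/G (population covariance), matching the 0.5-per-group weights of the
#' two-group worked example; under this convention the initial community
#' frequency entering the identity is the equally weighted mean of group
#' frequencies, which coincides with the pooled frequency whenever all
#' groups start at the same size (as in the worked examples). `"size"`
#' weights groups by initial size \eqn{n_i/N} and uses per-capita fitness
#' \eqn{w_i = \pi_i/n_i}; the identity then holds with fully pooled
#' (sum-of-cooperators over sum-of-sizes) community frequencies for
#' arbitrary unequal group sizes. Both are algebraic identities: the
#' residual is zero to rounding in floating point and exactly zero in the
#' rational mode.
#'
#' A group with `final_size` 0 contributes \eqn{\pi = 0}; its
#' \eqn{\pi\Delta P} term is computed as \eqn{k' - \pi P} (hence 0) so the
#' undefined final frequency never enters, and its covariance contribution
#' is kept.
#'
#' @param groups a [group_records] object (or coercible data frame).
#' @param weights `"uniform"` (default, the worked-example convention) or
#'   `"size"`.
#' @param exact logical; if `TRUE` all terms are computed in exact reduced
#'   rational arithmetic (integer inputs required) and the residual is exact.
#' @param center constant at which \eqn{P} is centred inside the covariance;
#'   defaults to the weighted mean of \eqn{P}. Because \eqn{\pi} is centred
#'   at its own mean the choice is mathematically immaterial; the argument
#'   exists to make that robustness testable.
#' @return An object of class `price_decomposition`: a list with
#'   `n_groups`, `weights`, `mean_final_size` (\eqn{\bar\pi}),
#'   `fitness_mean` (the multiplier in the identity: \eqn{\bar\pi} under
#'   uniform weights, mean per-capita fitness under size weights),
#'   `community_initial_freq` (\eqn{\bar P} as defined by the weighting),
#'   `pooled_initial_freq`, `community_final_freq` (\eqn{\bar P'}, pooled
#'   over offspring), `delta_p` (\eqn{\Delta\bar P}), `covariance_term`,
#'   `expectation_term`, `variance_p`, `beta`
#'   (\eqn{\mathrm{Cov}/\mathrm{Var}}, `NA` when `variance_p` is 0) and
#'   `residual` (\eqn{\bar\pi\Delta\bar P - \mathrm{Cov} - \mathrm{Ave}}).
#' @examples
#' g <- group_records(c(6, 6), c(1, 5), c(16, 32), c(1, 25))
#' pd <- price_decompose(g)
#' pd$covariance_term   # 8/3  ~  2.67
#' pd$expectation_term  # -5/3 ~ -1.67
#' pd$mean_final_size   # 24
#' pd$delta_p           # 1/24 ~ 0.042
#' @export
price_decompose <- function(groups, weights = c("uniform", "size"),
                            exact = FALSE, center = NULL) {
  groups <- if (inherits(groups, "group_records")) groups else group_records(groups)
  weights <- match.arg(weights)
  n  <- groups$initial_size
  k  <- groups$initial_cooperators
  pi_ <- groups$final_size
  kf <- groups$final_cooperators
  G  <- length(n)
  if (exact && any(c(n, k, pi_, kf) != round(c(n, k, pi_, kf))))
    stop("exact mode requires integer counts")

  if (exact) {
    out <- .price_exact(n, k, pi_, kf, weights, center)
  } else {
    out <- .price_float(n, k, pi_, kf, weights, center)
  }
  out$n_groups <- G
  out$weights <- weights
  out$exact <- exact
  structure(out, class = "price_decomposition")
}

.price_float <- function(n, k, pi_, kf, weights, center) {
  G <- length(n); N <- sum(n); Npost <- sum(pi_)
  P <- k / n
  pooled0 <- sum(k) / N
  pfin <- if (Npost > 0) sum(kf) / Npost else NA_real_
  if (weights == "uniform") {
    pibar <- mean(pi_)
    pbar  <- mean(P)
    ctr   <- if (is.null(center)) pbar else center
    cov_t <- mean((pi_ - pibar) * (P - ctr))
    ave_t <- mean(kf - pi_ * P)          # pi * (P' - P), safe when pi = 0
    var_p <- mean((P - pbar)^2)
    fmean <- pibar
  } else {
    q     <- n / N
    w     <- pi_ / n
    wbar  <- Npost / N
    pbar  <- pooled0
    ctr   <- if (is.null(center)) pbar else center
    cov_t <- sum(q * (w - wbar) * (P - ctr))
    ave_t <- sum(kf - pi_ * P) / N
    var_p <- sum(q * (P - pbar)^2)
    pibar <- mean(pi_)
    fmean <- wbar
  }
  delta <- pfin - pbar
  list(mean_final_size = pibar, fitness_mean = fmean,
       community_initial_freq = pbar, pooled_initial_freq = pooled0,
       community_final_freq = pfin, delta_p = delta,
       covariance_term = cov_t, expectation_term = ave_t,
       variance_p = var_p,
       beta = if (var_p > 0) cov_t / var_p else NA_real_,
       residual = if (is.na(delta)) NA_real_ else fmean * delta - cov_t - ave_t)
}

.price_exact <- function(n, k, pi_, kf, weights, center) {
  G <- length(n); N <- sum(n); Npost <- sum(pi_)
  P  <- rat(k, n)
  Pi <- rat(pi_)
  Kf <- rat(kf)
  rg <- rat(rep(1, G), G)                       # 1/G
  pooled0 <- rat(sum(k), N)
  pfin <- if (Npost > 0) rat(sum(kf), Npost) else NULL
  one_vec <- function(x) rat(rep(x$num, G), rep(x$den, G))
  if (weights == "uniform") {
    pibar <- rat_div(rat_sum(Pi), rat(G))
    pbar  <- rat_div(rat_sum(P), rat(G))
    ctr   <- if (is.null(center)) pbar else rat(center * 10^9, 10^9)
    dev_pi <- rat_sub(Pi, one_vec(pibar))
    dev_p  <- rat_sub(P, one_vec(ctr))
    cov_t <- rat_div(rat_sum(rat_mul(dev_pi, dev_p)), rat(G))
    ave_t <- rat_div(rat_sum(rat_sub(Kf, rat_mul(Pi, P))), rat(G))
    dev0  <- rat_sub(P, one_vec(pbar))
    var_p <- rat_div(rat_sum(rat_mul(dev0, dev0)), rat(G))
    fmean <- pibar
  } else {
    q     <- rat(n, N)
    w     <- rat(pi_, n)
    wbar  <- rat(Npost, N)
    pbar  <- pooled0
    ctr   <- if (is.null(center)) pbar else rat(center * 10^9, 10^9)
    dev_w <- rat_sub(w, one_vec(wbar))
    dev_p <- rat_sub(P, one_vec(ctr))
    cov_t <- rat_sum(rat_mul(q, rat_mul(dev_w, dev_p)))
    ave_t <- rat_div(rat_sum(rat_sub(Kf, rat_mul(Pi, P))), rat(N))
    dev0  <- rat_sub(P, one_vec(pbar))
    var_p <- rat_sum(rat_mul(q, rat_mul(dev0, dev0)))
    pibar <- rat_div(rat_sum(Pi), rat(G))
    fmean <- wbar
  }
  if (is.null(pfin)) {
    delta <- NULL; res <- NULL
  } else {
    delta <- rat_sub(pfin, pbar)
    res <- rat_sub(rat_sub(rat_mul(fmean, delta), cov_t), ave_t)
  }
  vp <- rat_num(var_p)
  list(mean_final_size = rat_num(pibar), fitness_mean = rat_num(fmean),
       community_initial_freq = rat_num(pbar),
       pooled_initial_freq = rat_num(pooled0),
       community_final_freq = if (is.null(pfin)) NA_real_ else rat_num(pfin),
       delta_p = if (is.null(delta)) NA_real_ else rat_num(delta),
       covariance_term = rat_num(cov_t), expectation_term = rat_num(ave_t),
       variance_p = vp,
       beta = if (vp > 0) rat_num(rat_div(cov_t, var_p)) else NA_real_,
       residual = if (is.null(res)) NA_real_ else rat_num(res),
       residual_exact = if (is.null(res)) NULL else res)
}

#' Signed residual of the Price identity
#'
#' Computes \eqn{\bar\pi\Delta\bar P - \mathrm{Cov}(\pi,P) -
#' \mathrm{Ave}(\pi\Delta P)} for a set of group records. The identity is
#' algebraic, so the residual is 0 up to floating-point rounding, and
#' exactly 0 (a rational with numerator 0) when `exact = TRUE`. Exposed as a
#' diagnostic surface: any nonzero exact residual indicates corrupted input
#' accounting rather than biology.
#'
#' @inheritParams price_decompose
#' @return The numeric residual (exactly 0 in exact mode).
#' @examples
#' g <- group_records(c(6, 6), c(1, 5), c(16, 32), c(1, 25))
#' price_identity_residual(g, exact = TRUE)  # 0
#' @export
price_identity_residual <- function(groups, weights = c("uniform", "size"),
                                    exact = FALSE) {
  price_decompose(groups, weights = match.arg(weights), exact = exact)$residual
}

#' @export
print.price_decomposition <- function(x, digits = 4, ...) {
  cat("Price decomposition over", x$n_groups, "groups (",
      x$weights, "weights", if (x$exact) ", exact arithmetic" else "", ")\n")
  cat("  mean final group size (pi-bar): ", signif(x$mean_final_size, digits), "\n")
  cat("  community cooperator frequency:", signif(x$community_initial_freq, digits),
      "->", signif(x$community_final_freq, digits),
      " (delta =", signif(x$delta_p, digits), ")\n")
  cat("  Cov(pi, P)     :", signif(x$covariance_term, digits), "\n")
  cat("  Ave(pi deltaP) :", signif(x$expectation_term, digits), "\n")
  cat("  Var(P)         :", signif(x$variance_p, digits),
      "  beta:", signif(x$beta, digits), "\n")
  cat("  identity residual:", format(x$residual), "\n")
  invisible(x)
}

#' @export
as.data.frame.price_decomposition <- function(x, ...) {
  keep <- c("n_groups", "weights", "mean_final_size", "fitness_mean",
            "community_initial_freq", "pooled_initial_freq",
            "community_final_freq", "delta_p", "covariance_term",
            "expectation_term", "variance_p", "beta", "residual")
  data.frame(x[keep], stringsAsFactors = FALSE)
}
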