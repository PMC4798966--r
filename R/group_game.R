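#' Deterministic within-group reproduction rule
#'
#' One generation of the group-reproduction game. Each cooperator gives
#' birth to one cooperator and additionally helps every *other* group member
#' sire one extra offspring before dying; each cheater gives birth to two
#' cheaters and helps nobody. Generations do not overlap (all parents die).
#' In closed form a group with `c` cooperators and `d` cheaters produces
#' \deqn{c' = c + c(c-1) = c^2, \qquad d' = 2d + cd = d(2 + c).}
#' Cooperators therefore always decline in frequency *within* a mixed group
#' (cheaters get the help without paying for it), while cooperator-rich
#' groups grow larger — the tension the Price decomposition accounts for.
#'
#' @param cooperators,cheaters non-negative integer vectors (recycled);
#'   every group needs at least one member.
#' @return A data frame with columns `cooperators` and `cheaters`, one row
#'   per input group.
#' @examples
#' reproduce_group(1, 5)   # -> (1, 15): final size 16, frequency 1/16
#' reproduce_group(5, 1)   # -> (25, 7): final size 32, frequency 25/32
#' @export
reproduce_group <- function(cooperators, cheaters) {
  n <- max(length(cooperators), length(cheaters))
  cc <- rep_len(cooperators, n); dd <- rep_len(cheaters, n)
  stopifnot(all(cc >= 0), all(dd >= 0))
  if (any(cc + dd < 1)) stop("every group needs at least one member")
  data.frame(cooperators = cc^2, cheaters = dd * (2 + cc))
}

#' Partition a population into interaction groups
#'
#' Splits `total_cooperators` cooperators and `total_cheaters` cheaters into
#' groups, conserving individuals exactly. Schemes control the across-group
#' variance in cooperator frequency, the quantity the covariance term of the
#' Price identity feeds on:
#' \describe{
#'   \item{`"random"`}{individuals are shuffled and chunked into groups of
#'     `group_size`; each group's cooperator count is then a multivariate
#'     hypergeometric draw (sampling without replacement). Individuals left
#'     over form a final smaller group.}
#'   \item{`"fixed-counts"`}{`counts` gives each group's cooperator count
#'     explicitly; every group has exactly `group_size` members. The counts
#'     must account for all individuals.}
#'   \item{`"perfect-segregation"`}{cooperators and cheaters are packed into
#'     separate pure groups of up to `group_size` (maximal assortment).}
#' }
#'
#' @param total_cooperators,total_cheaters non-negative totals.
#' @param scheme assortment scheme, see Details.
#' @param group_size members per group (>= 1).
#' @param counts integer vector of per-group cooperator counts
#'   (`"fixed-counts"` only).
#' @param seed optional integer seed (mandatory in practice for the random
#'   scheme if reproducibility matters).
#' @return A data frame with columns `cooperators`, `cheaters`.
#' @examples
#' form_groups(6, 6, "fixed-counts", group_size = 6, counts = c(1, 5))
#' form_groups(12, 6, "perfect-segregation", group_size = 6)
#' @export
form_groups <- function(total_cooperators, total_cheaters,
                        scheme = c("random", "fixed-counts",
                                   "perfect-segregation"),
                        group_size, counts = NULL, seed = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(total_cooperators >= 0, total_cheaters >= 0, group_size >= 1)
  tot <- total_cooperators + total_cheaters
  if (tot < 1) stop("population is empty")
  if (group_size > tot) stop("group_size larger than population")
  if (scheme == "random") {
    .maybe_seed(seed)
    members <- sample(rep(c(1L, 0L), c(total_cooperators, total_cheaters)))
    idx <- ceiling(seq_along(members) / group_size)
    co <- as.vector(tapply(members, idx, sum))
    sz <- as.vector(tapply(members, idx, length))
    data.frame(cooperators = co, cheaters = sz - co)
  } else if (scheme == "fixed-counts") {
    if (is.null(counts)) stop("fixed-counts scheme requires `counts`")
    if (any(counts < 0) || any(counts > group_size))
      stop("counts must lie in [0, group_size]")
    if (sum(counts) != total_cooperators ||
        length(counts) * group_size - sum(counts) != total_cheaters)
      stop("counts do not account for the stated totals")
    data.frame(cooperators = as.integer(counts),
               cheaters = as.integer(group_size - counts))
  } else {
    split_pure <- function(n) if (n == 0) integer(0) else
      diff(unique(c(seq(0L, n, by = group_size), n)))
    co <- split_pure(total_cooperators)
    ch <- split_pure(total_cheaters)
    data.frame(cooperators = c(co, rep(0L, length(ch))),
               cheaters = c(rep(0L, length(co)), ch))
  }
}

#' Remove groups below a cooperator-frequency threshold
#'
#' The group-culling operator abstracted from selective abortion of
#' cheater-dominated flowers: groups whose *initial* cooperator frequency is
#' strictly below `min_cooperator_freq` are eliminated (all members die);
#' survivors are unchanged. The same mechanism reads as partner choice at
#' the whole-community level (the higher-level entity discriminates among
#' its spatially equivalent groups) and as partner fidelity feedback at the
#' group level (cheater-dominated groups perish with their occupants); see
#' [mechanism_annotations()].
#'
#' @param groups data frame with columns `cooperators`, `cheaters`.
#' @param min_cooperator_freq threshold in \[0, 1\]; 0 keeps every group.
#' @return The surviving subset of `groups`.
#' @examples
#' cull_groups(data.frame(cooperators = c(1, 5), cheaters = c(5, 1)), 0.5)
#' @export
cull_groups <- function(groups, min_cooperator_freq) {
  stopifnot(min_cooperator_freq >= 0, min_cooperator_freq <= 1)
  freq <- groups$cooperators / (groups$cooperators + groups$cheaters)
  groups[freq >= min_cooperator_freq, , drop = FALSE]
}

#' Multi-generation community dynamics of the group game
#'
#' Runs the trait-group lifecycle: partition the community into groups
#' ([form_groups()]), optionally cull cheater-dominated groups
#' ([cull_groups()]), let every surviving group reproduce under the
#' deterministic rule ([reproduce_group()]), pool all offspring, and repeat.
#' Each generation emits the community cooperator frequency and the full
#' Price decomposition of that generation's group records (culled groups are
#' kept in the accounting as groups of final size 0). All stochasticity
#' lives in group formation; given a seed the run is deterministic.
#'
#' The reproduction rule is specified for a single generation; pooling all
#' offspring before groups re-form is the standard trait-group lifecycle and
#' makes the across-group variance freshly manipulable each generation
#' through the scheme.
#'
#' @inheritParams form_groups
#' @param n_generations number of generations (>= 1).
#' @param min_cooperator_freq culling threshold applied to freshly formed
#'   groups each generation (default 0 = no culling).
#' @return An object of class `group_game_run`: a list with `summary` (data
#'   frame: generation, cooperators, cheaters, community_freq, delta_p,
#'   cov_term, ave_term, var_p), `decompositions` (list of
#'   [price_decompose()] results), and `status` (`"ok"` or `"extinct"`).
#'   Extinction is reported, not raised.
#' @examples
#' run <- run_generations(6, 6, "fixed-counts", group_size = 6,
#'                        counts = c(1, 5), n_generations = 1)
#' run$summary$community_freq  # 26/48, up from 6/12
#' @export
run_generations <- function(total_cooperators, total_cheaters,
                            scheme = c("random", "fixed-counts",
                                       "perfect-segregation"),
                            group_size, counts = NULL, n_generations = 1,
                            min_cooperator_freq = 0, seed = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(n_generations >= 1)
  .maybe_seed(seed)
  co <- total_cooperators; ch <- total_cheaters
  rows <- list(); decs <- list(); status <- "ok"
  for (gen in seq_len(n_generations)) {
    if (co + ch < 1) { status <- "extinct"; break }
    g <- form_groups(co, ch, scheme, group_size, counts)
    freq0 <- g$cooperators / (g$cooperators + g$cheaters)
    keep <- freq0 >= min_cooperator_freq
    off <- data.frame(cooperators = numeric(nrow(g)),
                      cheaters = numeric(nrow(g)))
    if (any(keep))
      off[keep, ] <- reproduce_group(g$cooperators[keep], g$cheaters[keep])
    rec <- group_records(g$cooperators + g$cheaters, g$cooperators,
                         off$cooperators + off$cheaters, off$cooperators)
    dec <- price_decompose(rec)
    co <- sum(off$cooperators); ch <- sum(off$cheaters)
    rows[[gen]] <- data.frame(
      generation = gen,
      cooperators = co, cheaters = ch,
      community_freq = if (co + ch > 0) co / (co + ch) else NA_real_,
      delta_p = dec$delta_p, cov_term = dec$covariance_term,
      ave_term = dec$expectation_term, var_p = dec$variance_p)
    decs[[gen]] <- dec
  }
  structure(list(summary = do.call(rbind, rows), decompositions = decs,
                 status = status),
            class = "group_game_run")
}

#' @export
print.group_game_run <- function(x, ...) {
  cat("Group-game run,", nrow(x$summary), "generation(s), status:",
      x$status, "\n")
  print(head(x$summary, 10), row.names = FALSE)
  if (nrow(x$summary) > 10) cat("  ...\n")
  invisible(x)
}

#' @export
plot.group_game_run <- function(x, ...) {
  s <- x$summary
  plot(s$generation, s$community_freq, type = "b", pch = 16,
       xlab = "generation", ylab = "community cooperator frequency",
       ylim = c(0, 1), ...)
  invisible(x)
}
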