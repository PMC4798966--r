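#' mtDNA pool of a mitochondrion or germ line
#'
#' A two-type pool of mitochondrial genomes. "Dysfunctional" is binary:
#' a dysfunctional mtDNA replicates at least as well as a functional one in
#' the same heteroplasmic mixture but delivers less or no benefit to its
#' host. The heteroplasmy of a pool is the dysfunctional fraction
#' \eqn{h = d / (f + d)}.
#'
#' @param functional,dysfunctional non-negative integer counts.
#' @return A list of class `mt_pool` with elements `functional`,
#'   `dysfunctional`.
#' @examples
#' p <- mt_pool(50, 50)
#' heteroplasmy(p)  # 0.5
#' @export
mt_pool <- function(functional, dysfunctional) {
  stopifnot(functional >= 0, dysfunctional >= 0,
            functional == round(functional),
            dysfunctional == round(dysfunctional))
  structure(list(functional = as.integer(functional),
                 dysfunctional = as.integer(dysfunctional)),
            class = "mt_pool")
}

#' @export
print.mt_pool <- function(x, ...) {
  cat(sprintf("mtDNA pool: %d functional + %d dysfunctional (h = %s)\n",
              x$functional, x$dysfunctional,
              format(heteroplasmy(x), digits = 3)))
  invisible(x)
}

#' Heteroplasmy (dysfunctional mtDNA fraction)
#'
#' @param x an [mt_pool], a cell (see [cell_state()]), or a list of cells.
#' @return Dysfunctional fraction in \[0, 1\] (`NaN` for an empty pool).
#' @export
heteroplasmy <- function(x) UseMethod("heteroplasmy")

#' @export
heteroplasmy.mt_pool <- function(x)
  x$dysfunctional / (x$functional + x$dysfunctional)

#' @export
heteroplasmy.cell_state <- function(x) {
  tot <- colSums(x$mitos)
  tot[["dysfunctional"]] / sum(tot)
}

#' @export
heteroplasmy.list <- function(x) vapply(x, heteroplasmy, numeric(1))

#' Replicate an mtDNA pool with a per-copy advantage for dysfunctional mtDNA
#'
#' Grows the pool to `target` copies by sequential draws: each new copy
#' duplicates an existing molecule chosen with per-copy weight 1
#' (functional) versus `1 + delta` (dysfunctional). `delta > 0` encodes the
#' replication advantage dysfunctional genomes can gain by skipping
#' host-serving transcription; with `delta = 0` replication is neutral and
#' expected heteroplasmy is unchanged (only drift operates). The all-
#' functional and all-dysfunctional states are absorbing (no mutation).
#'
#' @param pool an [mt_pool] with at least one molecule.
#' @param delta per-copy replication bonus of dysfunctional mtDNA (>= 0).
#' @param target final copy number (>= current pool size).
#' @param seed optional integer seed.
#' @return The grown [mt_pool].
#' @examples
#' replicate_mtdna(mt_pool(50, 50), delta = 1, target = 200, seed = 1)
#' @export
replicate_mtdna <- function(pool, delta = 0, target, seed = NULL) {
  stopifnot(inherits(pool, "mt_pool"), delta >= 0)
  .maybe_seed(seed)
  res <- urn_fill(pool$functional, pool$dysfunctional, delta,
                  as.integer(target))
  mt_pool(res[1], res[2])
}

#' A cell holding a population of mitochondria
#'
#' A cell is a collection of mitochondria, each with its own two-type mtDNA
#' pool; a dead cell takes no further part in dynamics. A mitochondrion is
#' classified functional when at least half of its mtDNAs are functional
#' (the binary classification used by the organelle-level partner-choice
#' operators).
#'
#' @param mitos a 2-column matrix (`functional`, `dysfunctional`), one row
#'   per mitochondrion, or a list of [mt_pool]s.
#' @param alive logical.
#' @return A list of class `cell_state` with elements `mitos` (matrix) and
#'   `alive`.
#' @examples
#' cell_state(rbind(c(10, 0), c(2, 8)))
#' @export
cell_state <- function(mitos, alive = TRUE) {
  if (is.list(mitos) && !is.matrix(mitos))
    mitos <- do.call(rbind, lapply(mitos, function(p)
      c(p$functional, p$dysfunctional)))
  mitos <- matrix(as.integer(mitos), ncol = 2,
                  dimnames = list(NULL, c("functional", "dysfunctional")))
  stopifnot(all(mitos >= 0))
  structure(list(mitos = mitos, alive = isTRUE(alive)), class = "cell_state")
}

#' @export
print.cell_state <- function(x, ...) {
  cat(sprintf("cell: %d mitochondria, %d mtDNAs, h = %s%s\n",
              nrow(x$mitos), sum(x$mitos),
              format(heteroplasmy(x), digits = 3),
              if (x$alive) "" else " (dead)"))
  invisible(x)
}

.mito_ffrac <- function(m) {
  tot <- rowSums(m)
  ifelse(tot > 0, m[, 1] / tot, 0)
}

#' Fitness-dependent mitochondrial division
#'
#' Each mitochondrion divides with probability
#' `mito_fitness(functional_fraction)`; `mito_fitness` must be a
#' non-decreasing map into \[0, 1\], so organelles dominated by functional
#' mtDNAs proliferate faster — a feedback between a mitochondrion and its
#' genomes (dysfunctional mtDNAs harm the replication of their own
#' carrier). A dividing mitochondrion first replicates its pool to twice
#' its copy number (with replication advantage `delta`, see
#' [replicate_mtdna()]), then partitions the molecules binomially between
#' two daughters. If the cell ends above `capacity` mitochondria, excess
#' organelles are removed uniformly at random.
#'
#' @param cell a [cell_state].
#' @param mito_fitness function mapping functional fraction to division
#'   probability.
#' @param delta per-copy replication bonus of dysfunctional mtDNA.
#' @param capacity maximum mitochondria per cell (default `Inf`).
#' @param seed optional integer seed.
#' @return The updated [cell_state].
#' @examples
#' cl <- cell_state(rbind(matrix(c(10, 0), 5, 2, byrow = TRUE),
#'                        matrix(c(0, 10), 5, 2, byrow = TRUE)))
#' divide_mitochondria(cl, function(f) 0.2 + 0.6 * f, seed = 1)
#' @export
divide_mitochondria <- function(cell, mito_fitness, delta = 0,
                                capacity = Inf, seed = NULL) {
  stopifnot(inherits(cell, "cell_state"), is.function(mito_fitness))
  if (!cell$alive) return(cell)
  .maybe_seed(seed)
  m <- cell$mitos
  if (nrow(m) == 0) return(cell)
  p <- vapply(.mito_ffrac(m), mito_fitness, numeric(1))
  stopifnot(all(p >= 0), all(p <= 1))
  divide <- runif(nrow(m)) < p
  keep <- m[!divide, , drop = FALSE]
  new_rows <- list()
  if (any(divide)) {
    tot <- rowSums(m[divide, , drop = FALSE])
    grown <- urn_fill_many(m[divide, 1], m[divide, 2], delta,
                           as.integer(2 * max(tot)))
    # grow each pool only to twice its own size, not the shared max:
    # redo per-row targets where sizes differ
    if (length(unique(tot)) > 1L) {
      grown <- t(mapply(function(f, d, tg) urn_fill(f, d, delta, tg),
                        m[divide, 1], m[divide, 2], as.integer(2 * tot)))
    }
    d1f <- rbinom(nrow(grown), grown[, 1], 0.5)
    d1d <- rbinom(nrow(grown), grown[, 2], 0.5)
    new_rows <- rbind(cbind(d1f, d1d),
                      cbind(grown[, 1] - d1f, grown[, 2] - d1d))
  }
  out <- rbind(keep, new_rows)
  out <- out[rowSums(out) > 0, , drop = FALSE]
  if (nrow(out) > capacity)
    out <- out[sample(nrow(out), capacity), , drop = FALSE]
  cell_state(out, cell$alive)
}

#' Selective mitophagy
#'
#' Each mitochondrion is destroyed with a probability whose *odds* are the
#' baseline turnover odds `rate / (1 - rate)` multiplied by
#' `1 + selectivity * (1 - functional_fraction) * weight`: the more
#' dysfunctional the organelle, the higher its destruction odds. With
#' `selectivity = 0` every mitochondrion faces the same unbiased turnover
#' `rate` and expected heteroplasmy is unchanged; with positive selectivity
#' the cell preferentially digests dysfunctional organelles — partner
#' choice by the cell among its spatially equivalent mitochondria.
#'
#' @param cell a [cell_state].
#' @param selectivity in \[0, 1\]; 0 = unbiased turnover.
#' @param rate baseline destruction probability in \[0, 1).
#' @param weight odds multiplier scale (default 1); documented knob for how
#'   strongly a fully dysfunctional organelle is disfavoured
#'   (odds ratio `1 + selectivity * weight`).
#' @param seed optional integer seed.
#' @return The updated [cell_state] (destroyed mitochondria removed).
#' @examples
#' cl <- cell_state(rbind(c(10, 0), c(0, 10)))
#' mitophagy(cl, selectivity = 1, rate = 0.5, seed = 1)
#' @export
mitophagy <- function(cell, selectivity, rate, weight = 1, seed = NULL) {
  stopifnot(inherits(cell, "cell_state"),
            selectivity >= 0, selectivity <= 1, rate >= 0, rate < 1)
  if (!cell$alive || rate == 0) return(cell)
  .maybe_seed(seed)
  m <- cell$mitos
  odds <- rate / (1 - rate) *
    (1 + selectivity * (1 - .mito_ffrac(m)) * weight)
  p_destroy <- odds / (1 + odds)
  keep <- runif(nrow(m)) >= p_destroy
  cell_state(m[keep, , drop = FALSE], cell$alive)
}

#' Asymmetric segregation of mitochondria at cell division
#'
#' Splits a cell into two daughters. Each functional mitochondrion (>= half
#' functional mtDNAs) goes to the favoured daughter with probability
#' `0.5 + bias / 2`, each dysfunctional one with probability
#' `0.5 - bias / 2`. `bias = 0` is a symmetric binomial split; `bias = 1`
#' deterministically hands the favoured daughter every functional
#' mitochondrion. This is the cell discriminating among spatially
#' equivalent organelles at inheritance — partner choice — as when a young
#' daughter cell preferentially receives young, functional mitochondria.
#'
#' @param cell a [cell_state].
#' @param bias segregation bias in \[0, 1\].
#' @param seed optional integer seed.
#' @return A list of two [cell_state]s: `favored`, `other`. mtDNA molecules
#'   are conserved: the two daughters partition the mother's pool exactly.
#' @examples
#' cl <- cell_state(rbind(c(10, 0), c(0, 10)))
#' asymmetric_inheritance(cl, bias = 1, seed = 1)
#' @export
asymmetric_inheritance <- function(cell, bias, seed = NULL) {
  stopifnot(inherits(cell, "cell_state"), bias >= 0, bias <= 1)
  .maybe_seed(seed)
  m <- cell$mitos
  functional_mito <- .mito_ffrac(m) >= 0.5
  p_fav <- ifelse(functional_mito, 0.5 + bias / 2, 0.5 - bias / 2)
  to_fav <- runif(nrow(m)) < p_fav
  list(favored = cell_state(m[to_fav, , drop = FALSE]),
       other = cell_state(m[!to_fav, , drop = FALSE]))
}

#' Apoptotic filtering of cells by dysfunctional load
#'
#' Each cell dies with probability `apoptosis_rule(h)`, where `h` is the
#' cell's heteroplasmy and the rule is non-decreasing — cells dominated by
#' dysfunctional mtDNA are more likely to undergo programmed death (or its
#' modelling equivalents, cell-cycle arrest and fertilisation failure).
#' Because the rule loads death onto high-`h` cells, the survivors' mean
#' heteroplasmy cannot exceed the pre-filter mean in expectation. This is
#' feedback between a cell and its own genomes: the cell perishes *with*
#' its cargo.
#'
#' @param cells list of [cell_state]s.
#' @param apoptosis_rule function mapping heteroplasmy to death probability
#'   in \[0, 1\], non-decreasing.
#' @param seed optional integer seed.
#' @return The list of surviving cells.
#' @examples
#' cells <- list(cell_state(rbind(c(8, 2))), cell_state(rbind(c(1, 9))))
#' apoptosis_filter(cells, function(h) as.numeric(h > 0.6), seed = 1)
#' @export
apoptosis_filter <- function(cells, apoptosis_rule, seed = NULL) {
  stopifnot(is.list(cells), is.function(apoptosis_rule))
  .maybe_seed(seed)
  h <- vapply(cells, heteroplasmy, numeric(1))
  p <- vapply(h, apoptosis_rule, numeric(1))
  stopifnot(all(p >= 0), all(p <= 1))
  cells[runif(length(cells)) >= p]
}

#' Germline transmission through an mtDNA bottleneck
#'
#' Each offspring's founding pool is a draw of `bottleneck_size` molecules
#' without replacement from the mother's pool (hypergeometric; a binomial
#' large-pool approximation is available), then amplified back to
#' `adult_size` copies by [replicate_mtdna()] with replication advantage
#' `delta` (neutral when `delta = 0`). A small bottleneck inflates the
#' across-offspring variance of founder heteroplasmy — approximately
#' `h (1 - h) / bottleneck_size` for a large maternal pool (exactly the
#' hypergeometric variance times the finite-pool correction) — which is the
#' raw material organism-level selection needs. `import_bias > 0` weights
#' the draw toward functional molecules (selective transport into the
#' oocyte), a partner-choice filter acting at the same step.
#'
#' @param mother_pool an [mt_pool].
#' @param bottleneck_size founder molecules per offspring (1 to pool size).
#' @param n_offspring number of offspring pools to generate.
#' @param adult_size copy number after post-bottleneck amplification, or
#'   `NULL` (default) to return founder pools only.
#' @param delta replication advantage during amplification.
#' @param import_bias relative weight advantage of functional molecules in
#'   the founder draw (>= 0; 0 = unbiased).
#' @param sampling `"hypergeometric"` (default) or `"binomial"`.
#' @param seed optional integer seed.
#' @return A list with `founders` (2-column matrix of founder counts),
#'   `founder_h` (numeric vector), and `adults` (matrix of amplified
#'   counts, or `NULL`).
#' @examples
#' tr <- germline_transmission(mt_pool(5000, 5000), bottleneck_size = 10,
#'                             n_offspring = 1000, adult_size = NULL,
#'                             seed = 1)
#' var(tr$founder_h)  # ~ 0.5 * 0.5 / 10
#' @export
germline_transmission <- function(mother_pool, bottleneck_size, n_offspring,
                                  adult_size = NULL, delta = 0,
                                  import_bias = 0,
                                  sampling = c("hypergeometric", "binomial"),
                                  seed = NULL) {
  stopifnot(inherits(mother_pool, "mt_pool"), bottleneck_size >= 1,
            n_offspring >= 1, import_bias >= 0)
  sampling <- match.arg(sampling)
  M <- mother_pool$functional + mother_pool$dysfunctional
  if (bottleneck_size > M)
    stop("bottleneck_size exceeds the maternal pool size")
  .maybe_seed(seed)
  h <- heteroplasmy(mother_pool)
  if (import_bias > 0) {
    founders <- t(vapply(seq_len(n_offspring), function(i)
      as.integer(biased_draw(mother_pool$functional,
                             mother_pool$dysfunctional, import_bias,
                             as.integer(bottleneck_size))),
      integer(2)))
    dys <- founders[, 2]
  } else if (sampling == "hypergeometric") {
    dys <- rhyper(n_offspring, m = mother_pool$dysfunctional,
                  n = mother_pool$functional, k = bottleneck_size)
  } else {
    dys <- rbinom(n_offspring, bottleneck_size, h)
  }
  founders <- cbind(functional = as.integer(bottleneck_size - dys),
                    dysfunctional = as.integer(dys))
  adults <- NULL
  if (!is.null(adult_size)) {
    stopifnot(adult_size >= bottleneck_size)
    adults <- urn_fill_many(founders[, 1], founders[, 2], delta,
                            as.integer(adult_size))
    colnames(adults) <- c("functional", "dysfunctional")
  }
  list(founders = founders,
       founder_h = founders[, 2] / bottleneck_size,
       adults = adults)
}
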