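#' Classification of every mechanism as partner choice or fidelity feedback
#'
#' Fixed metadata table: each toggleable operator of the hierarchy, the
#' entity levels it couples, and whether it is partner choice (PC: a focal
#' entity directs benefits or survival preferentially among spatially
#' equivalent partner entities) or partner fidelity feedback (PFF: lasting
#' association makes an entity's fate ride on its partners'). The same
#' physical mechanism can read as PFF at a lower level and PC one level up
#' (the group-culling operator of [cull_groups()] carries both readings),
#' so the table names the level at which each classification applies.
#'
#' @return A data frame with columns `mechanism`, `level`,
#'   `classification`.
#' @examples
#' mechanism_annotations()
#' @export
mechanism_annotations <- function() {
  data.frame(
    mechanism = c("replication_advantage", "mito_fitness",
                  "import_selectivity", "segregation_bias",
                  "mitophagy_selectivity", "apoptosis_rule",
                  "bottleneck", "organism_fecundity",
                  "group_culling (community reading)",
                  "group_culling (group reading)"),
    level = c("mtDNA within mitochondrion",
              "mitochondrion vs its mtDNAs",
              "cell vs mitochondria", "cell vs mitochondria",
              "cell vs mitochondria", "cell vs its mtDNAs",
              "organism to offspring (variance source)",
              "organism vs its mtDNAs",
              "community vs groups", "group vs its members"),
    classification = c("cheater advantage (what the filters oppose)",
                       "PFF", "PC", "PC", "PC", "PFF",
                       "PFF enabler", "PFF", "PC", "PFF"),
    stringsAsFactors = FALSE)
}

#' Mechanism configuration for the nested mtDNA simulator
#'
#' Bundles every toggleable operator of the mtDNA -> mitochondrion -> cell
#' -> organism hierarchy with its rates, plus the carrying capacities that
#' set the scale of the hierarchy. Defaults switch every filter *off* and
#' give dysfunctional mtDNA no advantage, so the default model is pure
#' neutral drift. Range invariants are enforced here (and again by
#' [load_config()] for file-based configuration).
#'
#' @param delta per-copy replication advantage of dysfunctional mtDNA
#'   (>= 0; 0 = off).
#' @param mito_fitness non-decreasing function from a mitochondrion's
#'   functional fraction to its division probability; default `function(f)
#'   1` (all divide, no feedback).
#' @param import_selectivity,segregation_bias,mitophagy_selectivity each in
#'   \[0, 1\], 0 = off.
#' @param mitophagy_rate baseline organelle turnover probability in
#'   \[0, 1).
#' @param apoptosis_rule non-decreasing function from cell heteroplasmy to
#'   death probability; default `function(h) 0` (off).
#' @param bottleneck_size founder mtDNAs per offspring (>= 1).
#' @param organism_fecundity non-increasing function from organism mean
#'   heteroplasmy to expected offspring count; default `function(h) 3`
#'   (no organism-level selection).
#' @param copies_per_mito,mitos_per_cell,cells_per_organism,n_organisms
#'   carrying capacities of the hierarchy (defaults 10, 8, 4, 20 — scale
#'   choices, not biological estimates).
#' @param sampling bottleneck sampling mode, see
#'   [germline_transmission()].
#' @return A list of class `mechanism_config`; its `annotations` element
#'   carries the [mechanism_annotations()] rows for the enabled operators.
#' @examples
#' cfg <- mechanism_config(delta = 0.5, bottleneck_size = 4,
#'                         apoptosis_rule = function(h) h^2)
#' cfg$annotations
#' @export
mechanism_config <- function(delta = 0,
                             mito_fitness = NULL,
                             import_selectivity = 0,
                             segregation_bias = 0,
                             mitophagy_selectivity = 0,
                             mitophagy_rate = 0,
                             apoptosis_rule = NULL,
                             bottleneck_size = 5,
                             organism_fecundity = NULL,
                             copies_per_mito = 10,
                             mitos_per_cell = 8,
                             cells_per_organism = 4,
                             n_organisms = 20,
                             sampling = c("hypergeometric", "binomial")) {
  stopifnot(delta >= 0,
            import_selectivity >= 0, import_selectivity <= 1,
            segregation_bias >= 0, segregation_bias <= 1,
            mitophagy_selectivity >= 0, mitophagy_selectivity <= 1,
            mitophagy_rate >= 0, mitophagy_rate < 1,
            bottleneck_size >= 1, copies_per_mito >= 1,
            mitos_per_cell >= 1, cells_per_organism >= 1, n_organisms >= 1)
  adult_size <- copies_per_mito * mitos_per_cell * cells_per_organism
  if (bottleneck_size > adult_size)
    stop("bottleneck_size exceeds the adult germline copy number")
  enabled <- c(
    replication_advantage = delta > 0,
    mito_fitness = !is.null(mito_fitness),
    import_selectivity = import_selectivity > 0,
    segregation_bias = segregation_bias > 0,
    mitophagy_selectivity = mitophagy_rate > 0,
    apoptosis_rule = !is.null(apoptosis_rule),
    bottleneck = bottleneck_size < adult_size,
    organism_fecundity = !is.null(organism_fecundity))
  ann <- mechanism_annotations()
  structure(list(
    delta = delta,
    mito_fitness = if (is.null(mito_fitness)) function(f) 1 else mito_fitness,
    import_selectivity = import_selectivity,
    segregation_bias = segregation_bias,
    mitophagy_selectivity = mitophagy_selectivity,
    mitophagy_rate = mitophagy_rate,
    apoptosis_rule = if (is.null(apoptosis_rule)) function(h) 0
                     else apoptosis_rule,
    bottleneck_size = bottleneck_size,
    organism_fecundity = if (is.null(organism_fecundity)) function(h) 3
                         else organism_fecundity,
    copies_per_mito = copies_per_mito,
    mitos_per_cell = mitos_per_cell,
    cells_per_organism = cells_per_organism,
    n_organisms = n_organisms,
    adult_size = adult_size,
    sampling = match.arg(sampling),
    enabled = enabled,
    annotations = ann[ann$mechanism %in% names(enabled)[enabled], ]),
    class = "mechanism_config")
}

#' @export
print.mechanism_config <- function(x, ...) {
  cat("Mechanism configuration (hierarchy:",
      x$copies_per_mito, "mtDNA/mito,", x$mitos_per_cell, "mito/cell,",
      x$cells_per_organism, "cells/organism,", x$n_organisms,
      "organisms)\n")
  on <- names(x$enabled)[x$enabled]
  cat("enabled mechanisms:",
      if (length(on)) paste(on, collapse = ", ") else "none (neutral drift)",
      "\n")
  if (nrow(x$annotations)) {
    cat("annotations:\n")
    print(x$annotations, row.names = FALSE)
  }
  invisible(x)
}

#' Found a population of heteroplasmic organisms
#'
#' Builds `n_organisms` organisms, each with `cells_per_organism` germline
#' cells of `mitos_per_cell` mitochondria holding `copies_per_mito` mtDNAs;
#' every molecule is independently dysfunctional with probability `h0`.
#'
#' @param config a [mechanism_config] (provides the capacities).
#' @param h0 founding heteroplasmy in \[0, 1\].
#' @param seed optional integer seed.
#' @return A list of organisms; an organism is a list of [cell_state]s.
#' @export
init_population <- function(config, h0, seed = NULL) {
  stopifnot(inherits(config, "mechanism_config"), h0 >= 0, h0 <= 1)
  .maybe_seed(seed)
  lapply(seq_len(config$n_organisms), function(i)
    lapply(seq_len(config$cells_per_organism), function(j) {
      dys <- rbinom(config$mitos_per_cell, config$copies_per_mito, h0)
      cell_state(cbind(config$copies_per_mito - dys, dys))
    }))
}

.organism_pool <- function(org) {
  tot <- Reduce(`+`, lapply(org, function(cl) colSums(cl$mitos)))
  mt_pool(tot[["functional"]], tot[["dysfunctional"]])
}

#' Run the nested multilevel simulation
#'
#' Executes, per generation and in fixed order, the lifecycle of the
#' hierarchy: (1) fitness-dependent mitochondrial division with
#' replication advantage ([divide_mitochondria()]); (2) selective mitophagy
#' ([mitophagy()]); (3) germ-cell division with biased organelle
#' segregation ([asymmetric_inheritance()]), capped at the cell capacity;
#' (4) apoptotic filtering of germ cells ([apoptosis_filter()]); (5)
#' reproduction — each surviving organism leaves
#' `round(organism_fecundity(h))` offspring, each founded through the
#' germline bottleneck with optional selective import
#' ([germline_transmission()]) and amplified to the adult copy number with
#' replication advantage `delta`; (6) the next generation is capped at
#' `n_organisms` by uniform sampling. The bottom-up order mirrors the
#' narrative from organelle to organism; all randomness derives from
#' `seed`.
#'
#' Each generation also performs Price accounting with organisms as groups
#' of mtDNAs: a group's initial size/cooperators are the organism's adult
#' mtDNA counts (functional = cooperator), its final size/cooperators the
#' mtDNAs it transmits through offspring founders, so the group fitness
#' \eqn{\pi} is proportional to realised offspring number. The Price
#' identity of [price_decompose()] holds exactly for these records.
#'
#' @param config a [mechanism_config].
#' @param h0 founding heteroplasmy.
#' @param n_generations generations to simulate (>= 1).
#' @param seed integer seed (one seed drives the whole run via
#'   [derive_seed()] streams).
#' @return An object of class `multilevel_run`: list with `summary` (data
#'   frame per generation: `generation`, `mean_h`, `oocyte_h_var` (variance
#'   of founder heteroplasmy across that generation's offspring),
#'   `n_organisms`, `cov_term`, `ave_term`, `delta_p`), `price` (list of
#'   [price_decompose()] objects), `config`, and `status` (`"ok"` or
#'   `"extinct"`).
#' @examples
#' cfg <- mechanism_config(n_organisms = 6, cells_per_organism = 2,
#'                         mitos_per_cell = 4, bottleneck_size = 4)
#' run_multilevel(cfg, h0 = 0.3, n_generations = 3, seed = 1)
#' @export
run_multilevel <- function(config, h0, n_generations, seed = NULL) {
  stopifnot(inherits(config, "mechanism_config"), n_generations >= 1)
  if (!is.null(seed)) set.seed(derive_seed(seed, "multilevel"))
  pop <- init_population(config, h0)
  rows <- list(); price <- list(); status <- "ok"
  for (gen in seq_len(n_generations)) {
    # --- organelle and cell level, within each organism ---
    pop <- lapply(pop, function(org) {
      org <- lapply(org, function(cl) {
        cl <- divide_mitochondria(cl, config$mito_fitness, config$delta,
                                  capacity = config$mitos_per_cell)
        if (config$mitophagy_rate > 0)
          cl <- mitophagy(cl, config$mitophagy_selectivity,
                          config$mitophagy_rate)
        cl
      })
      org <- org[vapply(org, function(cl) sum(cl$mitos) > 0, logical(1))]
      if (!length(org)) return(org)
      # germ-cell division with (possibly biased) organelle segregation
      daughters <- unlist(lapply(org, function(cl)
        asymmetric_inheritance(cl, config$segregation_bias)),
        recursive = FALSE)
      daughters <- daughters[vapply(daughters,
                                    function(cl) sum(cl$mitos) > 0,
                                    logical(1))]
      if (length(daughters) > config$cells_per_organism)
        daughters <- daughters[sample(length(daughters),
                                      config$cells_per_organism)]
      apoptosis_filter(daughters, config$apoptosis_rule)
    })
    pop <- pop[vapply(pop, length, integer(1)) > 0]
    if (!length(pop)) { status <- "extinct"; break }
    # --- organism level: fecundity, bottleneck, founding ---
    pools <- lapply(pop, .organism_pool)
    org_h <- vapply(pools, heteroplasmy, numeric(1))
    n_off <- vapply(org_h, function(h)
      max(0, round(config$organism_fecundity(h))), numeric(1))
    nb <- config$bottleneck_size
    rec <- NULL; founder_h <- numeric(0); offspring <- list()
    for (i in seq_along(pop)) {
      psize <- pools[[i]]$functional + pools[[i]]$dysfunctional
      k_off <- if (psize >= nb) n_off[i] else 0
      if (k_off > 0) {
        tr <- germline_transmission(
          pools[[i]], nb, k_off, adult_size = config$adult_size,
          delta = config$delta, import_bias = config$import_selectivity,
          sampling = config$sampling)
        founder_h <- c(founder_h, tr$founder_h)
        for (j in seq_len(k_off))
          offspring[[length(offspring) + 1L]] <-
            .found_organism(tr$adults[j, ], config)
        fin_size <- k_off * nb
        fin_coop <- sum(tr$founders[, "functional"])
      } else {
        fin_size <- 0; fin_coop <- 0
      }
      rec <- rbind(rec, c(psize, pools[[i]]$functional, fin_size, fin_coop))
    }
    dec <- if (nrow(rec) >= 1)
      price_decompose(group_records(rec[, 1], rec[, 2], rec[, 3], rec[, 4]))
    else NULL
    if (length(offspring) > config$n_organisms)
      offspring <- offspring[sample(length(offspring), config$n_organisms)]
    rows[[gen]] <- data.frame(
      generation = gen,
      mean_h = sum(vapply(pools, function(p) p$dysfunctional, numeric(1))) /
        sum(vapply(pools, function(p) p$functional + p$dysfunctional,
                   numeric(1))),
      oocyte_h_var = if (length(founder_h) > 1) var(founder_h) else NA_real_,
      n_organisms = length(pop),
      cov_term = if (is.null(dec)) NA_real_ else dec$covariance_term,
      ave_term = if (is.null(dec)) NA_real_ else dec$expectation_term,
      delta_p = if (is.null(dec)) NA_real_ else dec$delta_p)
    price[[gen]] <- dec
    if (!length(offspring)) { status <- "extinct"; break }
    pop <- offspring
  }
  structure(list(summary = do.call(rbind, rows), price = price,
                 config = config, status = status),
            class = "multilevel_run")
}

# distribute an amplified founder pool into the nested cell/mito structure
# by an exact random partition (molecules conserved)
.found_organism <- function(adult_counts, config) {
  f <- adult_counts[[1]]; d <- adult_counts[[2]]
  mol <- sample(rep(c(0L, 1L), c(f, d)))   # 1 = dysfunctional
  per_mito <- config$copies_per_mito
  n_mito <- config$mitos_per_cell * config$cells_per_organism
  idx <- rep(seq_len(n_mito), each = per_mito)[seq_along(mol)]
  dys <- vapply(split(mol, idx), sum, integer(1))
  tot <- vapply(split(mol, idx), length, integer(1))
  mitos <- cbind(tot - dys, dys)
  cell_idx <- rep(seq_len(config$cells_per_organism),
                  each = config$mitos_per_cell)[seq_len(nrow(mitos))]
  lapply(split(seq_len(nrow(mitos)), cell_idx), function(rows)
    cell_state(mitos[rows, , drop = FALSE]))
}

#' @export
print.multilevel_run <- function(x, ...) {
  cat("Multilevel run,", nrow(x$summary), "generation(s), status:",
      x$status, "\n")
  print(head(x$summary, 10), row.names = FALSE, digits = 4)
  if (nrow(x$summary) > 10) cat("  ...\n")
  invisible(x)
}

#' @export
plot.multilevel_run <- function(x, ...) {
  s <- x$summary
  plot(s$generation, s$mean_h, type = "b", pch = 16, ylim = c(0, 1),
       xlab = "generation", ylab = "population mean heteroplasmy", ...)
  invisible(x)
}
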