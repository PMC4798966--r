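#' Load and validate a model configuration file
#'
#' Reads a YAML or JSON configuration describing one run of a model in this
#' package, fills defaults, and enforces the range invariants of the target
#' module at load time, so an invalid file fails immediately with a
#' field-level message rather than mid-simulation.
#'
#' The file must contain a `model` field (`"price"`, `"group_game"`,
#' `"toxin"`, `"ptft"` or `"mito"`) plus that model's parameters; see the
#' corresponding functions ([price_decompose()], [run_generations()],
#' [well_mixed_trajectory()], [iterated_group_game()],
#' [run_multilevel()] / [mechanism_config()]) for meanings and defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated named list with class `mlsel_config`; the `model`
#'   element selects the module.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(cfg$model))
    stop("config error: missing required field `model`")
  models <- c("price", "group_game", "toxin", "ptft", "mito")
  if (!cfg$model %in% models)
    stop("config error: `model` must be one of ",
         paste(models, collapse = ", "))
  chk <- function(field, ok, msg) {
    if (!is.null(cfg[[field]]) && !ok(cfg[[field]]))
      stop("config error in field `", field, "`: ", msg, call. = FALSE)
  }
  frac <- function(x) is.numeric(x) && all(x >= 0) && all(x <= 1)
  pos  <- function(x) is.numeric(x) && all(x > 0)
  nonneg <- function(x) is.numeric(x) && all(x >= 0)
  switch(cfg$model,
    price = {
      chk("weights", function(x) x %in% c("uniform", "size"),
          "must be 'uniform' or 'size'")
    },
    group_game = {
      chk("group_size", pos, "must be positive")
      chk("n_generations", pos, "must be positive")
      chk("min_cooperator_freq", frac, "must lie in [0, 1]")
      chk("counts", nonneg, "must be non-negative")
    },
    toxin = {
      chk("suicide_fraction", frac, "must lie in [0, 1]")
      chk("kill_coefficient", nonneg, "must be non-negative")
      chk("density_threshold", pos, "must be positive")
      chk("growth_cost", frac, "must lie in [0, 1]")
      chk("cooperators", nonneg, "must be non-negative")
      chk("cheaters", nonneg, "must be non-negative")
    },
    ptft = {
      chk("rounds", pos, "must be positive")
      chk("b", pos, "must be positive")
      chk("cost", pos, "must be positive")
    },
    mito = {
      chk("delta", nonneg, "must be non-negative")
      for (f in c("import_selectivity", "segregation_bias",
                  "mitophagy_selectivity", "mitophagy_rate", "h0"))
        chk(f, frac, "must lie in [0, 1]")
      chk("bottleneck_size", pos, "must be positive")
      chk("n_generations", pos, "must be positive")
    })
  structure(cfg, class = "mlsel_config")
}

# worked-example printed precision: two decimals for magnitudes >= 0.1,
# two significant digits below (0.04166 -> "0.042", 8/3 -> "2.67", 24 -> "24")
.printed <- function(x) {
  vapply(x, function(v) {
    if (!is.finite(v)) return(NA_character_)
    out <- if (abs(v) >= 0.1 || v == 0) round(v, 2) else signif(v, 2)
    format(out, scientific = FALSE, trim = TRUE)
  }, character(1))
}

#' Write simulation results to delimited text or JSON
#'
#' Writes a data frame (or a [price_decompose()] object, which is converted
#' with its `as.data.frame` method) as headered CSV/TSV or as JSON. Numeric
#' columns are written at full precision; for CSV/TSV each numeric column
#' additionally gets a `<name>_printed` companion rounded the way the
#' worked examples print their numbers (two decimals, two significant
#' digits below 0.1), so files are comparable against the printed values at
#' a glance. An empty record set produces a header-only file.
#'
#' @param records data frame or `price_decomposition`.
#' @param path output file path.
#' @param format `"csv"`, `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @examples
#' g <- group_records(c(6, 6), c(1, 5), c(16, 32), c(1, 25))
#' f <- tempfile(fileext = ".csv")
#' write_results(price_decompose(g), f)
#' @export
write_results <- function(records, path, format = c("csv", "tsv", "json")) {
  format <- match.arg(format)
  if (inherits(records, "price_decomposition"))
    records <- as.data.frame(records)
  stopifnot(is.data.frame(records))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  if (format == "json") {
    jsonlite::write_json(records, path, auto_unbox = FALSE, digits = NA,
                         na = "null")
    return(invisible(path))
  }
  out <- records
  for (nm in names(records)) {
    if (is.numeric(records[[nm]]))
      out[[paste0(nm, "_printed")]] <- .printed(records[[nm]])
  }
  sep <- if (format == "csv") "," else "\t"
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Record a reproducible run manifest
#'
#' Captures everything needed to reproduce a stochastic run bit-for-bit:
#' model name, the full parameter set, the seed, the package version, the
#' PC/PFF annotation of every enabled mechanism, and the output files
#' written. Written as JSON next to the outputs.
#'
#' @param model model name.
#' @param params named list of parameters (functions are recorded by their
#'   deparsed body).
#' @param seed integer seed of the run.
#' @param outputs character vector of output file paths.
#' @param annotations optional data frame of mechanism annotations
#'   (defaults to the full [mechanism_annotations()] table filtered by the
#'   caller).
#' @param path file to write (`NULL` = do not write).
#' @return The manifest as a named list, invisibly if written.
#' @export
run_manifest <- function(model, params, seed, outputs = character(0),
                         annotations = NULL, path = NULL) {
  flat <- lapply(params, function(p)
    if (is.function(p)) paste(deparse(p), collapse = " ") else p)
  man <- list(model = model, parameters = flat, seed = seed,
              package_version = as.character(utils::packageVersion("mlsel")),
              annotations = annotations, outputs = outputs)
  if (!is.null(path)) {
    dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    return(invisible(man))
  }
  man
}
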