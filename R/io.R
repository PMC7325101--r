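# Configuration loading and result serialisation. Configs are YAML with a
# strict schema (unknown keys rejected, defaults applied); results are
# written as CSVs with stable column order plus a JSON run manifest.

CONFIG_SCHEMA <- list(
  seed        = list(default = 1L,     check = function(x) is.finite(x)),
  scale       = list(default = 1,      check = function(x) is.finite(x) && x > 0),
  horizon     = list(default = 7L,     check = function(x) x >= 1),
  base_year   = list(default = 2010L,  check = function(x) x >= 1900),
  tol         = list(default = 0.01,   check = function(x) x > 0),
  max_iter    = list(default = 100L,   check = function(x) x >= 1),
  damping     = list(default = 1.0,    check = function(x) x > 0 && x <= 1),
  n_draws     = list(default = 1000L,  check = function(x) x >= 2),
  base_scenario = list(default = "constant-2006",
                       check = function(x) is.character(x) && nzchar(x)),
  alt_scenario  = list(default = "constant-2012",
                       check = function(x) is.character(x) && nzchar(x)),
  outdir      = list(default = "results", check = function(x) is.character(x)),
  verbose     = list(default = FALSE,  check = function(x) is.logical(x)),
  pi_table    = list(default = NA_character_,
                     check = function(x) is.na(x) || file.exists(x))
)

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, rejects unknown keys, type-checks every
#' value and fills documented defaults for absent ones.
#'
#' @param path YAML file path.
#' @return a named list of settings (class `cvd_config`).
#' @export
load_config <- function(path) {
  abort_if(!file.exists(path), sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), names(CONFIG_SCHEMA))
  abort_if(length(unknown) > 0,
           sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  cfg <- lapply(names(CONFIG_SCHEMA), function(k) {
    spec <- CONFIG_SCHEMA[[k]]
    v <- if (k %in% names(raw)) raw[[k]] else spec$default
    abort_if(!isTRUE(spec$check(v)),
             sprintf("invalid value for config key '%s'", k))
    v
  })
  names(cfg) <- names(CONFIG_SCHEMA)
  structure(cfg, class = "cvd_config")
}

#' Write the default configuration to a YAML file
#'
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_default_config <- function(path) {
  defaults <- lapply(CONFIG_SCHEMA, `[[`, "default")
  defaults <- defaults[!vapply(defaults, function(v) is.na(v)[1], logical(1))]
  yaml::write_yaml(defaults, path)
  invisible(path)
}

#' Write results to disk
#'
#' Serialises a simulation result, an outcome-delta table or a Monte Carlo
#' summary as CSV(s) with stable column order, alongside a JSON manifest
#' recording the package version and any seed carried by the object.
#' Counts are stored unrounded; delta tables additionally carry a
#' `increase_rounded` column (nearest 100, the published convention) for
#' human-readable summaries.
#'
#' @param result a `cvd_sim_result`, `cvd_outcome_delta` or
#'   `cvd_mc_summary`.
#' @param outdir output directory (created if absent).
#' @param stem file-name stem (defaults per result class).
#' @return character vector of paths written, invisibly.
#' @export
write_results <- function(result, outdir, stem = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  abort_if(!dir.exists(outdir), sprintf("cannot create directory: %s", outdir))
  paths <- character(0)
  if (inherits(result, "cvd_sim_result")) {
    stem <- stem %||na% "simulation"
    p <- file.path(outdir, paste0(stem, "_counts.csv"))
    utils::write.csv(result$counts[, c("outcome", "year", "sex", "age_band",
                                       "count")], p, row.names = FALSE)
    paths <- c(paths, p)
    p2 <- file.path(outdir, paste0(stem, "_cumulative.csv"))
    utils::write.csv(data.frame(outcome = names(result$cumulative),
                                count = unname(result$cumulative),
                                count_rounded =
                                  round_to_hundred(unname(result$cumulative))),
                     p2, row.names = FALSE)
    paths <- c(paths, p2)
    seed <- NA
  } else if (inherits(result, "cvd_outcome_delta")) {
    stem <- stem %||na% "deltas"
    df <- as.data.frame(result)
    df$increase_rounded <- round_to_hundred(df$increase)
    df <- df[, c("outcome", "base_count", "alt_count", "increase",
                 "increase_rounded", "percent_change")]
    p <- file.path(outdir, paste0(stem, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
    seed <- NA
  } else if (inherits(result, "cvd_mc_summary")) {
    stem <- stem %||na% "montecarlo"
    df <- as.data.frame(result)[, c("outcome", "mean_increase", "se",
                                    "n_draws", "seed")]
    p <- file.path(outdir, paste0(stem, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
    seed <- result$seed[1]
  } else {
    stop("unsupported result type", call. = FALSE)
  }
  manifest <- file.path(outdir, paste0(stem, "_manifest.json"))
  jsonlite::write_json(
    list(package = "cvdpimex",
         version = as.character(utils::packageVersion("cvdpimex")),
         seed = seed, files = basename(paths)),
    manifest, auto_unbox = TRUE, pretty = TRUE, na = "null")
  paths <- c(paths, manifest)
  invisible(paths)
}

`%||na%` <- function(a, b) if (is.null(a)) b else a

#' Render an outcome-delta table in the published layout
#'
#' Counts rounded to the nearest 100 and percent difference change to one
#' decimal, matching the projection table's columns.
#'
#' @param delta a `cvd_outcome_delta`.
#' @return data frame with `outcome`, `base_count`, `increase`,
#'   `percent_change` (rounded per convention).
#' @export
format_delta_table <- function(delta) {
  data.frame(outcome = delta$outcome,
             base_count = round_to_hundred(delta$base_count),
             increase = round_to_hundred(delta$increase),
             percent_change = delta$percent_change,
             stringsAsFactors = FALSE)
}
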