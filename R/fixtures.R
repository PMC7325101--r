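#' Load the packaged physical-inactivity prevalence table
#'
#' Reads the transcription of the ENSANUT 2006/2012 physical-inactivity
#' prevalence table (adults 35-64, by 10-year age band plus the pooled
#' total). Prevalences are printed as percentages with 95% confidence
#' intervals; they are converted to proportions on load, so all downstream
#' code works on the 0-1 scale.
#'
#' @param path optional path to an alternative CSV with the same columns;
#'   defaults to the fixture shipped with the package.
#' @return a `pi_prevalence` data frame with columns `sex`, `age_band`,
#'   `year`, `survey_n`, `population_n`, `prevalence`, `ci_low`, `ci_high`
#'   (the last three as proportions).
#' @export
load_table2_fixture <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table2_pi_prevalence.csv",
                        package = "cvdpimex")
  }
  abort_if(!nzchar(path) || !file.exists(path),
           "physical-inactivity prevalence fixture not found")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sex", "age_band", "year", "survey_n", "population_n",
            "prevalence_pct", "ci_low_pct", "ci_high_pct")
  abort_if(!all(need %in% names(raw)),
           "prevalence fixture is corrupt: missing columns")
  out <- data.frame(
    sex          = raw$sex,
    age_band     = raw$age_band,
    year         = as.integer(raw$year),
    survey_n     = as.integer(raw$survey_n),
    population_n = as.numeric(raw$population_n),
    prevalence   = raw$prevalence_pct / 100,
    ci_low       = raw$ci_low_pct / 100,
    ci_high      = raw$ci_high_pct / 100,
    stringsAsFactors = FALSE
  )
  validate_pi_prevalence(out)
  class(out) <- c("pi_prevalence", "data.frame")
  out
}

#' Validate a physical-inactivity prevalence table
#'
#' Checks the structural invariants of a prevalence table: proportions in
#' [0, 1], confidence bounds bracketing the point estimate, and every
#' (sex, age band) combination present for every year.
#'
#' @param x a data frame with prevalence columns as proportions.
#' @return `x` invisibly, or an error.
#' @export
validate_pi_prevalence <- function(x) {
  abort_if(!all(c("sex", "age_band", "year", "prevalence",
                  "ci_low", "ci_high") %in% names(x)),
           "prevalence table missing required columns")
  ok <- x$ci_low >= 0 & x$ci_low <= x$prevalence &
    x$prevalence <= x$ci_high & x$ci_high <= 1
  abort_if(!all(ok), "prevalence table violates 0 <= ci_low <= p <= ci_high <= 1")
  combos <- unique(x[, c("sex", "age_band")])
  for (yr in unique(x$year)) {
    sub <- x[x$year == yr, c("sex", "age_band")]
    miss <- !make_key(combos$sex, combos$age_band) %in% make_key(sub$sex, sub$age_band)
    abort_if(any(miss),
             sprintf("prevalence table incomplete for year %s", yr))
  }
  invisible(x)
}

#' Look up one prevalence entry
#'
#' @param table a `pi_prevalence` table.
#' @param sex,age_band,year row key (`age_band` may be `"total"`).
#' @return one-row data frame.
#' @export
pi_prevalence_entry <- function(table, sex, age_band, year) {
  row <- table[table$sex == sex & table$age_band == age_band &
                 table$year == year, , drop = FALSE]
  abort_if(nrow(row) != 1L, "prevalence entry not found")
  row
}

#' Load the packaged 7-year projected case-count table
#'
#' Reads the transcription of the published 7-year accumulated case
#' projections for adults 35-64: base-case counts under the 2006
#' physical-inactivity prevalence, and the increases under the unadjusted
#' and accelerometer-adjusted 2012 prevalences, with Monte Carlo standard
#' errors and percent-difference columns as printed (counts rounded to the
#' nearest 100).
#'
#' @param path optional path to an alternative CSV; defaults to the packaged
#'   fixture.
#' @return a data frame keyed by `outcome` (`chd_incidence`,
#'   `stroke_incidence`, `t2d_incidence`, `total_mi`, `chd_mortality`,
#'   `stroke_mortality`) with columns `base_count`, `base_se`,
#'   `unadjusted_increase`, `unadjusted_se`, `unadjusted_pct`,
#'   `adjusted_increase`, `adjusted_se`, `adjusted_pct`.
#' @export
load_table3_fixture <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table3_projected_cases.csv",
                        package = "cvdpimex")
  }
  abort_if(!nzchar(path) || !file.exists(path),
           "projected case-count fixture not found")
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("outcome", "base_count", "base_se", "unadjusted_increase",
            "unadjusted_se", "unadjusted_pct", "adjusted_increase",
            "adjusted_se", "adjusted_pct")
  abort_if(!all(need %in% names(x)), "case-count fixture is corrupt")
  abort_if(!setequal(x$outcome, OUTCOMES),
           "case-count fixture must cover the six reported outcomes")
  abort_if(any(x$base_count < 0 | x$unadjusted_increase < 0 |
                 x$adjusted_increase < 0), "counts must be non-negative")
  x[match(OUTCOMES, x$outcome), , drop = FALSE]
}
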