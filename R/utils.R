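#' @keywords internal
"_PACKAGE"

# Canonical orderings used throughout the model
AGE_BANDS <- c("35-44", "45-54", "55-64", "65-74", "75-84", "85-94")
REPORTING_BANDS <- c("35-44", "45-54", "55-64")
SEXES <- c("male", "female")
HEALTH_STATES <- c("no_cvd", "post_chd", "post_stroke", "post_both")
OUTCOMES <- c("t2d_incidence", "chd_incidence", "stroke_incidence",
              "total_mi", "chd_mortality", "stroke_mortality")
INCIDENCE_OUTCOMES <- c("t2d", "chd", "stroke", "non_cvd_death")
CALIB_STREAMS <- c("chd_events", "stroke_events", "chd_deaths", "stroke_deaths")

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as opposed to the IEC round-half-even rule
#' used by [round()]. Reported percentages and counts in the published tables
#' follow the half-up convention.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (may be negative).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Round counts to the nearest hundred
#'
#' The published projection tables report all counts rounded to the nearest
#' 100; this helper applies that convention (half-up).
#'
#' @param x numeric vector of counts.
#' @return counts rounded to the nearest 100.
#' @export
round_to_hundred <- function(x) round_half_up(x / 100) * 100

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# assert helper: stop with a clear message
abort_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

# key helper for fast lookups
make_key <- function(...) do.call(paste, c(list(...), sep = "\r"))
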