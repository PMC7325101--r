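# Rate and risk mathematics: inverse-variance pooling of log relative risks,
# decomposition of a population-average rate into active/inactive stratum
# rates, and logistic risk functions over categorical risk-factor profiles.

#' Pool relative risks on the log scale by inverse variance
#'
#' Combines relative-risk estimates from several exposure strata into a
#' single active-vs-inactive relative risk by weighting the natural logs of
#' the component RRs by the inverse of their variances:
#' `exp( sum(w_i * log(rr_i)) / sum(w_i) )` with `w_i = 1 / var_i`.
#'
#' @param rr numeric vector of component relative risks (> 0).
#' @param ln_rr_variance numeric vector of variances of `log(rr)` (> 0),
#'   same length as `rr`.
#' @return the pooled relative risk (scalar). The pooled value always lies
#'   within `[min(rr), max(rr)]`.
#' @examples
#' pool_log_rr(c(0.7, 0.9), c(0.01, 0.04))
#' @export
pool_log_rr <- function(rr, ln_rr_variance) {
  abort_if(length(rr) == 0L, "at least one stratum is required")
  abort_if(length(rr) != length(ln_rr_variance),
           "rr and ln_rr_variance must have equal length")
  abort_if(any(!is.finite(rr)) || any(rr <= 0), "all rr must be positive")
  abort_if(any(!is.finite(ln_rr_variance)) || any(ln_rr_variance <= 0),
           "all variances must be positive")
  w <- 1 / ln_rr_variance
  exp(sum(w * log(rr)) / sum(w))
}

#' Split a population-average rate into inactive and active stratum rates
#'
#' Given an overall (population-average) annual event rate, the proportion
#' physically inactive, and the relative risk of the event in active versus
#' inactive persons, returns the stratum-specific rates that reproduce the
#' overall rate as their prevalence-weighted mixture:
#' \deqn{\lambda_{inactive} = \lambda / (p + (1 - p) RR), \quad
#'       \lambda_{active} = RR \cdot \lambda_{inactive}.}
#' This is the standard attributable-fraction decomposition; it guarantees
#' `p * lambda_inactive + (1 - p) * lambda_active == lambda` at the
#' prevalence used for the split, which is what keeps calibrated
#' population-average rates intact at baseline.
#'
#' @param overall_rate annual events per person-year (>= 0).
#' @param p_inactive proportion physically inactive, in [0, 1].
#' @param rr relative risk, active vs inactive (> 0; < 1 means activity is
#'   protective).
#' @return named numeric vector `c(active = ..., inactive = ...)`.
#' @examples
#' decompose_rate(0.010, 0.121, 0.78)
#' @export
decompose_rate <- function(overall_rate, p_inactive, rr) {
  abort_if(any(overall_rate < 0), "overall_rate must be non-negative")
  abort_if(any(p_inactive < 0 | p_inactive > 1),
           "p_inactive must lie in [0, 1]")
  abort_if(any(rr <= 0), "rr must be positive")
  inactive <- overall_rate / (p_inactive + (1 - p_inactive) * rr)
  c(active = unname(rr * inactive), inactive = unname(inactive))
}

# Vectorised internal variant used by the simulation loop.
decompose_rate_vec <- function(overall_rate, p_inactive, rr) {
  inactive <- overall_rate / (p_inactive + (1 - p_inactive) * rr)
  list(active = rr * inactive, inactive = inactive)
}

#' Annual event probability from a logistic risk function
#'
#' Evaluates a logistic (inverse-logit) risk function for one risk-factor
#' profile: the linear predictor is the outcome/sex-specific intercept, plus
#' an age-band term, plus one coefficient per non-reference risk-factor
#' level present in the profile. Reference levels carry coefficient 0.
#'
#' @param stratum named list or one-row data frame of risk-factor levels
#'   (e.g. `smoking = "yes"`, `sbp_band = "high"`, ...).
#' @param sex `"male"` or `"female"`.
#' @param age_band one of the model's 10-year bands (`"35-44"` ...).
#' @param coeffs a coefficient set as produced by
#'   [default_risk_coefficients()]: per outcome and sex an `intercept`, an
#'   `age` vector named by band, and a `levels` vector named
#'   `"factor=level"`.
#' @param outcome one of `"t2d"`, `"chd"`, `"stroke"`, `"non_cvd_death"`.
#' @return annual event probability, strictly inside (0, 1).
#' @export
annual_risk <- function(stratum, sex, age_band, coeffs, outcome) {
  cf <- coeffs[[outcome]][[sex]]
  abort_if(is.null(cf), sprintf("no coefficients for outcome '%s', sex '%s'",
                                outcome, sex))
  lp <- cf$intercept
  if (!is.null(cf$age)) {
    abort_if(!age_band %in% names(cf$age),
             sprintf("no age coefficient for band '%s'", age_band))
    lp <- lp + cf$age[[age_band]]
  }
  stratum <- as.list(stratum)
  for (f in names(stratum)) {
    key <- paste0(f, "=", as.character(stratum[[f]]))
    if (key %in% names(cf$levels)) {
      lp <- lp + cf$levels[[key]]
    } else if (!is.null(cf$required) && f %in% cf$required) {
      stop(sprintf("missing coefficient for level '%s'", key), call. = FALSE)
    }
  }
  stats::plogis(lp)
}

#' Convert an instantaneous rate to an annual probability
#'
#' `1 - exp(-rate)`. The simulation treats small annual probabilities as
#' rates directly (all model rates are well below 0.2/year, where the
#' difference is second order); this utility is provided for callers who
#' prefer the exact exponential conversion.
#'
#' @param rate non-negative instantaneous annual rate.
#' @return annual probability in [0, 1).
#' @export
rate_to_prob <- function(rate) {
  abort_if(any(rate < 0), "rate must be non-negative")
  1 - exp(-rate)
}

#' @rdname rate_to_prob
#' @param prob annual probability in [0, 1).
#' @export
prob_to_rate <- function(prob) {
  abort_if(any(prob < 0 | prob >= 1), "prob must lie in [0, 1)")
  -log(1 - prob)
}

# Look up the relative risk for an outcome/sex from a bundle's RR table.
# Entries with sex == "both" apply to either sex.
lookup_rr <- function(rr_table, outcome, sex) {
  hit <- rr_table[rr_table$outcome == outcome &
                    (rr_table$sex == sex | rr_table$sex == "both"), , drop = FALSE]
  abort_if(nrow(hit) == 0L,
           sprintf("no relative risk for outcome '%s', sex '%s'", outcome, sex))
  # sex-specific entry wins over a pooled "both" entry
  if (any(hit$sex == sex)) hit <- hit[hit$sex == sex, , drop = FALSE]
  hit$rr[[1L]]
}
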