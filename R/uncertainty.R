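# Monte Carlo propagation of input uncertainty. Per draw, the log relative
# risks and the logit-scale scenario prevalences are perturbed by
# standard-normal multiples of their standard errors, the paired scenario
# comparison is re-run, and the per-outcome deltas are summarised as mean
# and standard error. Sampling on the log/logit scales guarantees positive
# relative risks and prevalences inside (0, 1) in every draw.

#' Standard error from a 95% confidence interval
#'
#' `se = (g(ci_high) - g(ci_low)) / (2 * 1.96)` with `g` the identity, log
#' or logit transform — the usual back-calculation of a sampling standard
#' deviation from printed interval bounds.
#'
#' @param ci_low,ci_high interval bounds (`ci_low < ci_high`; transformed
#'   bounds must be finite).
#' @param scale `"natural"`, `"log"`, or `"logit"`.
#' @return standard error on the transformed scale.
#' @examples
#' ci_to_se(0.113, 0.129, "natural")
#' @export
ci_to_se <- function(ci_low, ci_high, scale = c("natural", "log", "logit")) {
  scale <- match.arg(scale)
  abort_if(any(ci_low >= ci_high), "ci_low must be strictly below ci_high")
  g <- switch(scale, natural = identity, log = log, logit = stats::qlogis)
  lo <- g(ci_low); hi <- g(ci_high)
  abort_if(any(!is.finite(lo)) || any(!is.finite(hi)),
           "transformed interval bounds must be finite")
  (hi - lo) / (2 * 1.96)
}

# Perturb a scenario's whole trajectory by a logit-scale shift per band.
perturb_scenario <- function(scenario, z_by_band) {
  se <- scenario$prevalence_se
  abort_if(is.null(se), paste0(
    "scenario '", scenario$name, "' carries no prevalence standard errors"))
  shift <- stats::setNames(se$se_logit, se$age_band)
  tr <- scenario$trajectory
  z <- z_by_band[tr$age_band]
  tr$prevalence <- stats::plogis(stats::qlogis(tr$prevalence) +
                                   z * shift[tr$age_band])
  scenario$trajectory <- tr
  scenario
}

#' Monte Carlo uncertainty for a scenario comparison
#'
#' Repeats [compare_scenarios()] under random perturbation of the model's
#' uncertain inputs: each relative risk on the log scale (using the
#' bundle's `ln_rr_se`) and each scenario's per-band prevalence trajectory
#' on the logit scale (using the standard errors derived from the survey
#' confidence intervals). All draws for a run are generated up front from
#' the single seed, so results are bit-identical across repeats and
#' independent of evaluation order.
#'
#' @param bundle a `cvd_bundle` whose `relative_risks` carry `ln_rr_se`.
#' @param base,alt `cvd_scenario` objects carrying `prevalence_se`.
#' @param horizon years simulated per draw.
#' @param n_draws number of Monte Carlo draws (>= 2; the published analysis
#'   used 1000).
#' @param seed integer seed (required).
#' @param se_of_mean if `TRUE` (default), report the standard error of the
#'   mean (draw SD / sqrt(n)), mirroring the published "mean +/- SE"
#'   presentation; if `FALSE`, report the draw SD itself.
#' @return a `cvd_mc_summary` data frame: `outcome`, `mean_increase`,
#'   `se`, `n_draws`, `seed`; the per-draw increases are attached as
#'   attribute `"draws"` (draws x outcomes matrix).
#' @export
run_monte_carlo <- function(bundle, base, alt,
                            horizon = min(base$horizon, alt$horizon),
                            n_draws = 1000, seed, se_of_mean = TRUE) {
  abort_if(n_draws < 2, "n_draws must be at least 2")
  abort_if(missing(seed) || !is.finite(seed), "a seed must be supplied")
  rr <- bundle$relative_risks
  abort_if(is.null(rr$ln_rr_se) || anyNA(rr$ln_rr_se),
           paste("missing log-RR standard errors for:",
                 paste(rr$outcome[is.na(rr$ln_rr_se)], collapse = ", ")))
  for (sc in list(base, alt)) {
    abort_if(is.null(sc$prevalence_se),
             paste0("scenario '", sc$name,
                    "' carries no prevalence standard errors"))
  }
  bands_b <- base$prevalence_se$age_band
  bands_a <- alt$prevalence_se$age_band
  n_par <- nrow(rr) + length(bands_b) + length(bands_a)
  Z <- with_seed(seed,
                 matrix(stats::rnorm(n_draws * n_par), nrow = n_draws))
  draws <- matrix(NA_real_, n_draws, length(OUTCOMES),
                  dimnames = list(NULL, OUTCOMES))
  for (d in seq_len(n_draws)) {
    z <- Z[d, ]
    b <- bundle
    b$relative_risks$rr <- exp(log(rr$rr) + z[seq_len(nrow(rr))] * rr$ln_rr_se)
    zb <- stats::setNames(z[nrow(rr) + seq_along(bands_b)], bands_b)
    za <- stats::setNames(z[nrow(rr) + length(bands_b) + seq_along(bands_a)],
                          bands_a)
    delta <- compare_scenarios(b, perturb_scenario(base, zb),
                               perturb_scenario(alt, za), horizon)
    draws[d, delta$outcome] <- delta$increase
  }
  mu <- colMeans(draws)
  sdv <- apply(draws, 2, stats::sd)
  out <- data.frame(outcome = OUTCOMES, mean_increase = unname(mu[OUTCOMES]),
                    se = unname(if (se_of_mean) sdv[OUTCOMES] / sqrt(n_draws)
                                else sdv[OUTCOMES]),
                    n_draws = n_draws, seed = seed, stringsAsFactors = FALSE)
  attr(out, "draws") <- draws
  class(out) <- c("cvd_mc_summary", "data.frame")
  out
}
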