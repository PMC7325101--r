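# Scenario construction and counterfactual comparison: constant-prevalence
# scenarios from a survey year, WHO-style linear relative-reduction
# trajectories, paired simulation runs with outcome deltas and percent
# changes, and the accelerometer-adjustment substitution used in the
# one-way sensitivity analysis.

#' Constant physical-inactivity scenario from a prevalence table
#'
#' Builds a scenario whose inactive share is held at the prevalences a
#' survey year reports for each 10-year band (35-64), for every simulated
#' year.
#'
#' @param pi_table a `pi_prevalence` table.
#' @param year survey year to take prevalences from.
#' @param start_year first simulated calendar year.
#' @param horizon number of years covered.
#' @param name scenario label.
#' @return a `cvd_scenario`: list with `name`, `start_year`, `horizon`,
#'   `trajectory` (data frame `year`, `age_band`, `prevalence`) and
#'   `prevalence_se` (per band, on the logit scale, from the table's CIs).
#' @export
constant_scenario <- function(pi_table, year, start_year = 2010,
                              horizon = 7,
                              name = sprintf("constant-%d", year)) {
  bands <- REPORTING_BANDS
  p <- vapply(bands, function(b)
    pi_prevalence_entry(pi_table, "both", b, year)$prevalence, numeric(1))
  se <- vapply(bands, function(b) {
    row <- pi_prevalence_entry(pi_table, "both", b, year)
    ci_to_se(row$ci_low, row$ci_high, scale = "logit")
  }, numeric(1))
  years <- start_year + seq_len(horizon) - 1L
  traj <- expand.grid(year = years, age_band = bands,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  traj$prevalence <- p[traj$age_band]
  structure(list(name = name, start_year = start_year, horizon = horizon,
                 trajectory = traj,
                 prevalence_se = data.frame(age_band = bands,
                                            se_logit = unname(se),
                                            stringsAsFactors = FALSE)),
            class = "cvd_scenario")
}

#' WHO relative-reduction trajectory
#'
#' Builds the physical-inactivity trajectory implied by the WHO global
#' targets: a `mid_reduction` (default 10%) relative reduction by
#' `mid_year` (2025) and an `end_reduction` (default 15%, inclusive of the
#' first phase) by `end_year` (2030), with gradual linear decreases in
#' prevalence between the anchor years and a flat level before
#' `start_year`.
#'
#' @param p_start named numeric vector of starting prevalences per age band
#'   (or a `pi_prevalence` table with a `from_year` to read them from).
#' @param start_year,mid_year,end_year anchor years (2016, 2025, 2030).
#' @param mid_reduction,end_reduction relative reductions at the anchors,
#'   each in [0, 1); `end_reduction` is the total reduction from
#'   `p_start`.
#' @param from_year survey year used when `p_start` is a prevalence table
#'   (default 2012: the most recent cycle, used unchanged for 2016).
#' @param name scenario label.
#' @param se_logit optional named per-band logit-scale standard errors for
#'   Monte Carlo perturbation.
#' @return a `cvd_scenario` covering `start_year` ... `end_year`.
#' @export
who_trajectory <- function(p_start, start_year = 2016, mid_year = 2025,
                           end_year = 2030, mid_reduction = 0.10,
                           end_reduction = 0.15, from_year = 2012,
                           name = "who-targets", se_logit = NULL) {
  abort_if(mid_reduction < 0 || mid_reduction >= 1 ||
             end_reduction < 0 || end_reduction >= 1,
           "reductions must lie in [0, 1)")
  abort_if(!(start_year < mid_year && mid_year < end_year),
           "anchor years must satisfy start < mid < end")
  if (inherits(p_start, "pi_prevalence") || is.data.frame(p_start)) {
    tab <- p_start
    p_start <- vapply(REPORTING_BANDS, function(b)
      pi_prevalence_entry(tab, "both", b, from_year)$prevalence, numeric(1))
    if (is.null(se_logit)) {
      se_logit <- vapply(REPORTING_BANDS, function(b) {
        row <- pi_prevalence_entry(tab, "both", b, from_year)
        ci_to_se(row$ci_low, row$ci_high, scale = "logit")
      }, numeric(1))
    }
  }
  abort_if(is.null(names(p_start)), "p_start must be named by age band")
  years <- start_year:end_year
  # piecewise-linear in prevalence: anchors at start (p), mid (p*(1-r1)),
  # end (p*(1-r2))
  frac <- function(y) {
    ifelse(y <= mid_year,
           mid_reduction * (y - start_year) / (mid_year - start_year),
           mid_reduction + (end_reduction - mid_reduction) *
             (y - mid_year) / (end_year - mid_year))
  }
  traj <- expand.grid(year = years, age_band = names(p_start),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  traj$prevalence <- p_start[traj$age_band] * (1 - frac(traj$year))
  se_df <- if (is.null(se_logit)) NULL else
    data.frame(age_band = names(p_start),
               se_logit = unname(se_logit[names(p_start)]),
               stringsAsFactors = FALSE)
  structure(list(name = name, start_year = start_year,
                 horizon = length(years), trajectory = traj,
                 prevalence_se = se_df),
            class = "cvd_scenario")
}

#' Percent difference change, published convention
#'
#' `100 * increase / base`, rounded half-up to one decimal, as in the
#' projection table's "percent difference change" column.
#'
#' @param increase outcome delta (alt minus base count).
#' @param base base-case count (> 0).
#' @return percent, one decimal.
#' @export
percent_difference_change <- function(increase, base) {
  abort_if(any(base <= 0), "base count must be positive")
  round_half_up(100 * increase / base, 1)
}

#' Relative prevalence change, published convention
#'
#' `100 * (p_new - p_old) / p_old`, rounded half-up to the nearest integer,
#' as in the prevalence table's "% change" column.
#'
#' @param p_old,p_new prevalences (proportions or percents, consistently).
#' @return percent change, nearest integer.
#' @export
relative_prevalence_change <- function(p_old, p_new) {
  abort_if(any(p_old <= 0), "p_old must be positive")
  round_half_up(100 * (p_new - p_old) / p_old, 0)
}

#' Run paired counterfactual simulations and compute outcome deltas
#'
#' Runs [run_simulation()] twice on identical inputs except the
#' physical-inactivity trajectory and returns, per reported outcome, the
#' cumulative base and alternative counts, the increase (alt minus base)
#' and the percent difference change (computed from unrounded counts).
#'
#' @param bundle a `cvd_bundle`.
#' @param base,alt `cvd_scenario` objects with equal start years.
#' @param horizon years simulated (both trajectories must cover it).
#' @return a `cvd_outcome_delta` data frame: `outcome`, `base_count`,
#'   `alt_count`, `increase`, `percent_change`.
#' @export
compare_scenarios <- function(bundle, base, alt,
                              horizon = min(base$horizon, alt$horizon)) {
  abort_if(base$start_year != alt$start_year,
           "scenarios must share a start year")
  abort_if(horizon > base$horizon || horizon > alt$horizon,
           "a scenario trajectory is shorter than the horizon")
  rb <- run_simulation(bundle, base, horizon)
  ra <- run_simulation(bundle, alt, horizon)
  b <- cumulative_counts(rb)
  a <- cumulative_counts(ra)
  out <- data.frame(outcome = OUTCOMES, base_count = unname(b[OUTCOMES]),
                    alt_count = unname(a[OUTCOMES]),
                    increase = unname(a[OUTCOMES] - b[OUTCOMES]),
                    stringsAsFactors = FALSE)
  out$percent_change <- ifelse(out$base_count > 0,
                               round_half_up(100 * out$increase /
                                               out$base_count, 1), 0)
  class(out) <- c("cvd_outcome_delta", "data.frame")
  out
}

#' Substitute accelerometer-adjusted prevalences
#'
#' One-way sensitivity analysis input swap: replaces the self-reported
#' prevalences in a table with supplied accelerometer-adjusted values.
#' The adjusted table must cover every (sex, age band, year) of the
#' original; all downstream scenario machinery is reused unchanged.
#'
#' @param table the self-report `pi_prevalence` table.
#' @param adjusted a `pi_prevalence` table of adjusted values.
#' @return the adjusted table, validated, in the original's row order.
#' @export
apply_accelerometer_adjustment <- function(table, adjusted) {
  validate_pi_prevalence(adjusted)
  key_t <- make_key(table$sex, table$age_band, table$year)
  key_a <- make_key(adjusted$sex, adjusted$age_band, adjusted$year)
  miss <- !key_t %in% key_a
  abort_if(any(miss),
           sprintf("adjusted table does not cover: %s",
                   paste(gsub("\r", "/", key_t[miss]), collapse = ", ")))
  out <- adjusted[match(key_t, key_a), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pi_prevalence", "data.frame")
  out
}
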