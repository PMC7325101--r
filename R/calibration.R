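# Iterative proportional calibration. The model's base-year event and death
# counts are brought within a relative tolerance of national-style targets,
# per sex and age band, by multiplicative scaling of four streams: CHD
# events, stroke events, CHD deaths, stroke deaths. Event-stream factors
# scale first-event and recurrent rates; death-stream factors scale 30-day
# case fatality and history CVD death rates. After each factor update the
# base year is re-simulated, so the population at risk implied by the new
# rates feeds the next iteration.

#' Calibrate model rates to base-year event and death targets
#'
#' Fixed-point iteration `factor <- factor * (target / simulated)^damping`,
#' re-simulating the base year after every update, until every stream in
#' every sex x age band is within `tol` (relative) of its target.
#'
#' Event counts respond linearly to the event factors and deaths linearly
#' to the death factors (given events), so undamped iteration converges in
#' a handful of steps; `damping < 1` is available for oscillatory
#' configurations.
#'
#' @param bundle a `cvd_bundle`.
#' @param targets a `calibration_targets` frame (columns `sex`, `age_band`,
#'   `stream`, `count`), e.g. from [generate_calibration_targets()].
#' @param tol relative tolerance on every stream (default 0.01, i.e. all
#'   simulated base-year counts within 1% of targets).
#' @param max_iter iteration cap.
#' @param damping exponent on the ratio update, in (0, 1].
#' @return a `cvd_calibration` list: `factors` (data frame `sex`,
#'   `age_band`, `stream`, `factor`), `converged`, `iterations`,
#'   `max_residual`, and `trace` (per-iteration worst residual).
#' @export
calibrate <- function(bundle, targets, tol = 0.01, max_iter = 100,
                      damping = 1.0) {
  abort_if(tol <= 0, "tol must be positive")
  abort_if(damping <= 0 || damping > 1, "damping must lie in (0, 1]")
  abort_if(!all(c("sex", "age_band", "stream", "count") %in% names(targets)),
           "targets must have sex, age_band, stream, count")
  abort_if(any(targets$count < 0), "targets must be non-negative")

  fac <- as_factor_frame(bundle, 1)
  tkey <- make_key(targets$sex, targets$age_band, targets$stream)
  trace <- numeric(0)
  for (it in 0:max_iter) {
    sim <- simulate_base_year(bundle, fac)
    skey <- make_key(sim$sex, sim$age_band, sim$stream)
    t_at <- targets$count[match(skey, tkey)]
    live <- !is.na(t_at) & t_at > 0
    abort_if(any(!is.na(t_at) & t_at > 0 & sim$count == 0),
             "structurally infeasible: zero simulated count for a positive target")
    resid <- abs(sim$count[live] - t_at[live]) / t_at[live]
    worst <- if (length(resid)) max(resid) else 0
    trace <- c(trace, worst)
    if (worst <= tol) {
      return(structure(list(factors = fac, converged = TRUE,
                            iterations = it, max_residual = worst,
                            trace = trace),
                       class = "cvd_calibration"))
    }
    if (it == max_iter) break
    ratio <- rep(1, nrow(sim))
    ratio[live] <- (t_at[live] / sim$count[live])^damping
    fkey <- make_key(fac$sex, fac$age_band, fac$stream)
    fac$factor <- fac$factor * ratio[match(fkey, skey)]
    fac$factor[is.na(fac$factor)] <- 1
  }
  stop(sprintf(
    "calibration did not converge in %d iterations (worst residual %.3g)",
    max_iter, trace[length(trace)]), call. = FALSE)
}

#' @export
print.cvd_calibration <- function(x, ...) {
  cat(sprintf("Calibration %s after %d iteration(s); worst residual %.3g\n",
              if (x$converged) "converged" else "FAILED", x$iterations,
              x$max_residual))
  invisible(x)
}

#' Attach calibration factors to a bundle
#'
#' Returns a copy of the bundle carrying the factors so that
#' [run_simulation()] applies them to every cycle.
#'
#' @param bundle a `cvd_bundle`.
#' @param calibration a `cvd_calibration` or bare factor frame.
#' @return the bundle with `calibration_factors` set.
#' @export
apply_calibration <- function(bundle, calibration) {
  fac <- if (inherits(calibration, "cvd_calibration")) calibration$factors
  else calibration
  abort_if(any(fac$factor <= 0), "factors must be positive")
  bundle$calibration_factors <- fac
  bundle
}
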