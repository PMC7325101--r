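# Synthetic model inputs. The national sources behind the real model
# (population census and projections, vital statistics, social-security
# hospital registers, health-and-nutrition surveys) are not published as
# machine-readable inputs, so this module generates complete input bundles
# with the statistical structure the simulation assumes: population counts
# by sex and 10-year band, a joint risk-factor stratum distribution built
# from independent marginals, annual base rates that rise with age, bridge
# (30-day) and disease-history parameters, and the packaged prevalence
# fixture as the default physical-inactivity table. Everything is
# deterministic given a seed.

#' Default risk-factor ontology
#'
#' The categorical levels over which the no-CVD population is stratified.
#' Physical-inactivity status (`pi_status`) and diabetes are mandatory; the
#' remaining factors may be dropped or re-levelled to shrink or refine the
#' stratification.
#'
#' @param compact if `TRUE`, return the minimal ontology (only `pi_status`
#'   and `diabetes`), convenient for small test cohorts.
#' @return named list of character level vectors; the first level of each
#'   factor is the reference level.
#' @export
default_ontology <- function(compact = FALSE) {
  base <- list(
    pi_status = c("active", "inactive"),
    diabetes  = c("no", "yes")
  )
  if (compact) return(base)
  c(base, list(
    smoking  = c("no", "yes"),
    sbp_band = c("normal", "elevated", "high"),
    hdl_band = c("normal", "low"),
    ldl_band = c("normal", "high"),
    bmi_band = c("normal", "overweight", "obese")
  ))
}

# Cartesian stratum table for an ontology, with two twin maps: for each
# stratum, the id of the stratum identical except diabetes = "yes"
# (incident T2D moves people along this map) and the id of the stratum
# identical except with pi_status flipped (PI rebalancing pairs counts
# along this map).
build_strata <- function(ontology) {
  abort_if(!all(c("pi_status", "diabetes") %in% names(ontology)),
           "ontology must include pi_status and diabetes")
  grid <- expand.grid(ontology, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid$stratum_id <- seq_len(nrow(grid))
  # diabetic twin: same profile with diabetes = "yes"
  other <- setdiff(names(ontology), "diabetes")
  key <- make_key(do.call(paste, grid[other]))
  diab_key <- key[grid$diabetes == "yes"]
  diab_id <- grid$stratum_id[grid$diabetes == "yes"]
  grid$diabetic_twin <- diab_id[match(key, diab_key)]
  # PI twin: same profile with pi_status flipped
  other_pi <- setdiff(names(ontology), "pi_status")
  key_pi <- make_key(do.call(paste, grid[other_pi]), grid$pi_status)
  flip <- ifelse(grid$pi_status == "inactive", "active", "inactive")
  grid$pi_twin <- grid$stratum_id[match(
    make_key(do.call(paste, grid[other_pi]), flip), key_pi)]
  grid
}

#' Synthetic risk-function coefficients
#'
#' Logistic risk-function coefficients on the log-odds scale for the four
#' first-event outcomes, per sex, with an age gradient over the model's
#' 10-year bands and modest positive coefficients for adverse risk-factor
#' levels. Magnitudes are chosen so that implied annual probabilities fall
#' in the range national incidence and mortality statistics report for a
#' middle-income adult population (CHD and stroke incidence a few per
#' thousand per year at 35-44 rising roughly tenfold by 85-94; non-CVD
#' death steeper still).
#'
#' @param jitter optional named numeric vector of intercept perturbations
#'   (per outcome) applied on the log-odds scale.
#' @return nested coefficient list, `coeffs[[outcome]][[sex]]`.
#' @export
default_risk_coefficients <- function(jitter = NULL) {
  age_grad <- function(step) stats::setNames((seq_along(AGE_BANDS) - 1) * step,
                                             AGE_BANDS)
  lev <- c("smoking=yes" = 0.45, "sbp_band=elevated" = 0.25,
           "sbp_band=high" = 0.55, "hdl_band=low" = 0.25,
           "ldl_band=high" = 0.30, "bmi_band=overweight" = 0.15,
           "bmi_band=obese" = 0.35, "diabetes=yes" = 0.60)
  base <- list(
    t2d           = list(intercept = -4.9, step = 0.15,
                         levels = c("bmi_band=overweight" = 0.45,
                                    "bmi_band=obese" = 1.0)),
    chd           = list(intercept = -6.3, step = 0.45, levels = lev),
    stroke        = list(intercept = -7.0, step = 0.50, levels = lev),
    non_cvd_death = list(intercept = -6.2, step = 0.75,
                         levels = c("smoking=yes" = 0.35,
                                    "diabetes=yes" = 0.45,
                                    "bmi_band=obese" = 0.20))
  )
  out <- list()
  for (oc in names(base)) {
    b <- base[[oc]]
    jit <- if (!is.null(jitter) && oc %in% names(jitter)) jitter[[oc]] else 0
    per_sex <- list()
    for (sx in SEXES) {
      # women have lower premature CVD risk; small fixed sex offset
      off <- if (sx == "female" && oc %in% c("chd", "stroke")) -0.35 else 0
      per_sex[[sx]] <- list(intercept = b$intercept + jit + off,
                            age = age_grad(b$step),
                            levels = b$levels)
    }
    out[[oc]] <- per_sex
  }
  out
}

#' Default relative risks of activity on incident disease
#'
#' The active-vs-inactive relative risks used as model inputs: incident
#' T2D 0.78 and stroke 0.80 (same for both sexes), CHD 0.86 for men and
#' 0.76 for women, all from published meta-analyses of total physical
#' activity classified against the < 600 MET-minute/week threshold. The
#' log-RR standard errors are synthetic defaults (the source meta-analyses'
#' pooled variances are not part of the packaged inputs) sized to give CI
#' widths typical of such pooled estimates.
#'
#' @return data frame with columns `outcome`, `sex`, `rr`, `ln_rr_se`,
#'   `source`.
#' @export
default_relative_risks <- function() {
  data.frame(
    outcome  = c("t2d", "stroke", "chd", "chd"),
    sex      = c("both", "both", "male", "female"),
    rr       = c(0.78, 0.80, 0.86, 0.76),
    ln_rr_se = c(0.035, 0.040, 0.040, 0.045),
    source   = c("GBD meta-analysis", "GBD meta-analysis",
                 "CHD meta-analysis (men)", "CHD meta-analysis (women)"),
    stringsAsFactors = FALSE
  )
}

# Mean population sizes (persons, both sexes) by band, around the magnitudes
# the 2010-2012 national figures imply for 35-64 (~30-36M total) with a
# declining tail above 65.
POP_MEANS <- c("35-44" = 15.0e6, "45-54" = 11.0e6, "55-64" = 7.8e6,
               "65-74" = 4.8e6, "75-84" = 2.3e6, "85-94" = 0.55e6)

#' Generate a complete synthetic model input bundle
#'
#' Builds every input the cohort simulation needs, deterministically for a
#' given seed: population counts by sex and age band (scaled by `scale`),
#' a joint risk-factor stratum distribution assembled from independent
#' Dirichlet-sampled marginals, annual base rates derived from the logistic
#' risk functions averaged over the stratum distribution (hence increasing
#' with age), bridge and history parameters, relative risks, and the
#' packaged prevalence fixture as the physical-inactivity table.
#'
#' @param seed integer RNG seed; the same seed always yields an identical
#'   bundle.
#' @param scale positive multiplier on population counts (rates are
#'   unaffected); `scale = 0.01` gives a cohort 1% of national size, handy
#'   for fast experiments.
#' @param ontology risk-factor ontology, see [default_ontology()].
#' @param age_bands subset of the model's 10-year bands to include
#'   (contiguous, starting at "35-44").
#' @param pi_table physical-inactivity prevalence table used both as the
#'   bundle's baseline (its `baseline_year` entries seed the stratum
#'   distribution) and as the default source for scenario trajectories.
#' @param baseline_year year of `pi_table` defining the baseline inactive
#'   share (default 2006, the base-case survey cycle).
#' @return an object of class `cvd_bundle`; see Details.
#' @details The bundle is a list with elements `base_year` (2010),
#'   `age_bands`, `strata`, `population`, `stratum_distribution`,
#'   `base_rates`, `relative_risks`, `pi_prevalence`, `pi_baseline`,
#'   `cvd_prevalence`, `bridge_params`, `history_params`, `coeffs`.
#' @export
generate_inputs <- function(seed, scale = 1, ontology = default_ontology(),
                            age_bands = AGE_BANDS,
                            pi_table = load_table2_fixture(),
                            baseline_year = 2006) {
  abort_if(missing(seed) || !is.finite(seed), "a seed must be supplied")
  abort_if(!is.finite(scale) || scale <= 0, "scale must be positive")
  abort_if(!all(age_bands %in% AGE_BANDS) ||
             !identical(age_bands, AGE_BANDS[seq_along(age_bands)]),
           "age_bands must be a contiguous prefix of the model bands")
  with_seed(seed, {
    strata <- build_strata(ontology)
    nb <- length(age_bands)

    # population: lognormal jitter around national-scale means; scale applied
    # last so counts are exactly proportional across scales at equal seed
    pop <- expand.grid(sex = SEXES, age_band = age_bands,
                       stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    jit <- exp(stats::rnorm(nrow(pop), 0, 0.05))
    sex_share <- ifelse(pop$sex == "female", 0.52, 0.48)
    pop$count <- scale * POP_MEANS[pop$age_band] * sex_share * jit

    # baseline inactive share per band from the prevalence table (bands above
    # 55-64 carry the 55-64 value; the table is pooled over sex)
    p_base <- vapply(age_bands, function(b) {
      bb <- if (b %in% c("35-44", "45-54", "55-64")) b else "55-64"
      pi_prevalence_entry(pi_table, "both", bb, baseline_year)$prevalence
    }, numeric(1))

    # stratum distribution: independent marginals per factor, Dirichlet-style
    # (normalised gamma draws around prior weights), per sex x band; the
    # pi_status marginal is pinned to the baseline prevalence
    marg_prior <- list(
      smoking  = c(no = 0.80, yes = 0.20),
      sbp_band = c(normal = 0.55, elevated = 0.25, high = 0.20),
      hdl_band = c(normal = 0.60, low = 0.40),
      ldl_band = c(normal = 0.65, high = 0.35),
      bmi_band = c(normal = 0.30, overweight = 0.40, obese = 0.30),
      diabetes = c(no = 0.86, yes = 0.14)
    )
    dist <- vector("list", nrow(pop))
    for (i in seq_len(nrow(pop))) {
      prop <- rep(1, nrow(strata))
      for (f in names(ontology)) {
        levs <- ontology[[f]]
        if (f == "pi_status") {
          m <- stats::setNames(c(1 - p_base[[pop$age_band[i]]],
                                 p_base[[pop$age_band[i]]]),
                               c("active", "inactive"))[levs]
        } else {
          prior <- marg_prior[[f]][levs]
          if (anyNA(prior)) prior <- stats::setNames(rep(1, length(levs)), levs)
          g <- stats::rgamma(length(levs), shape = 60 * prior, rate = 1)
          m <- stats::setNames(g / sum(g), levs)
        }
        prop <- prop * m[strata[[f]]]
      }
      dist[[i]] <- data.frame(sex = pop$sex[i], age_band = pop$age_band[i],
                              stratum_id = strata$stratum_id,
                              prop = unname(prop / sum(prop)),
                              stringsAsFactors = FALSE)
    }
    dist <- do.call(rbind, dist)

    # base rates: stratum-distribution-weighted mean of the logistic risk
    # functions (so rates inherit the age gradient and the seed's jitter);
    # the T2D rate is the rate among the non-diabetic, its population at risk
    jitter <- stats::setNames(stats::rnorm(4, 0, 0.08),
                              c("t2d", "chd", "stroke", "non_cvd_death"))
    coeffs <- default_risk_coefficients(jitter)
    rates <- expand.grid(sex = SEXES, age_band = age_bands,
                         outcome = INCIDENCE_OUTCOMES,
                         stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    rates$rate <- NA_real_
    for (i in seq_len(nrow(rates))) {
      d <- dist[dist$sex == rates$sex[i] & dist$age_band == rates$age_band[i], ]
      s <- strata[match(d$stratum_id, strata$stratum_id), ]
      p <- vapply(seq_len(nrow(s)), function(j)
        annual_risk(s[j, names(ontology), drop = FALSE], rates$sex[i],
                    rates$age_band[i], coeffs, rates$outcome[i]), numeric(1))
      w <- d$prop
      if (rates$outcome[i] == "t2d") {
        at_risk <- s$diabetes == "no"
        rates$rate[i] <- if (sum(w[at_risk]) > 0)
          sum(w[at_risk] * p[at_risk]) / sum(w[at_risk]) else 0
      } else {
        rates$rate[i] <- sum(w * p)
      }
    }

    # prior-CVD prevalence by band (drives initial post-event compartments)
    cvd_prev <- expand.grid(sex = SEXES, age_band = age_bands,
                            stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    cvd_prev$prevalence <- pmin(0.25, 0.004 * 2^(match(cvd_prev$age_band,
                                                       AGE_BANDS) - 1) *
                                  ifelse(cvd_prev$sex == "male", 1.25, 0.9))

    # bridge: incident-CHD event-type split, 30-day case fatality, arrest
    # survival; fatality rises with age
    bridge <- expand.grid(sex = SEXES, age_band = age_bands,
                          stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    split <- matrix(stats::rgamma(3 * nrow(bridge),
                                  shape = 80 * c(0.10, 0.45, 0.45)),
                    ncol = 3, byrow = TRUE)
    split <- split / rowSums(split)
    bridge$p_arrest <- split[, 1]; bridge$p_mi <- split[, 2]
    bridge$p_angina <- split[, 3]
    agei <- match(bridge$age_band, AGE_BANDS)
    bridge$arrest_survival <- pmax(0.05, 0.35 - 0.03 * (agei - 1))
    bridge$cf_mi <- pmin(0.5, 0.08 * 1.25^(agei - 1))
    bridge$cf_angina <- pmin(0.2, 0.01 * 1.25^(agei - 1))
    bridge$cf_stroke <- pmin(0.6, 0.12 * 1.22^(agei - 1))

    # disease-history: annual recurrence, revascularisation and death rates
    history <- expand.grid(sex = SEXES, age_band = age_bands,
                           health_state = c("post_chd", "post_stroke",
                                            "post_both"),
                           stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    agei <- match(history$age_band, AGE_BANDS)
    st <- history$health_state
    history$recurrent_chd_rate <- ifelse(st == "post_stroke", 0.015, 0.045) *
      1.10^(agei - 1)
    history$recurrent_stroke_rate <- ifelse(st == "post_chd", 0.010, 0.040) *
      1.12^(agei - 1)
    history$revasc_rate <- ifelse(st == "post_stroke", 0.005, 0.04)
    history$cvd_death_rate <- (0.02 + 0.01 * (st == "post_both")) *
      1.35^(agei - 1)
    history$non_cvd_death_rate <- rates$rate[match(
      make_key(history$sex, history$age_band, "non_cvd_death"),
      make_key(rates$sex, rates$age_band, rates$outcome))] * 1.2

    bundle <- structure(list(
      base_year = 2010L,
      age_bands = age_bands,
      ontology = ontology,
      strata = strata,
      population = pop,
      stratum_distribution = dist,
      base_rates = rates,
      relative_risks = default_relative_risks(),
      pi_prevalence = pi_table,
      pi_baseline = data.frame(age_band = age_bands,
                               prevalence = unname(p_base),
                               stringsAsFactors = FALSE),
      cvd_prevalence = cvd_prev,
      bridge_params = bridge,
      history_params = history,
      coeffs = coeffs
    ), class = "cvd_bundle")
    validate_bundle(bundle)
    bundle
  })
}

#' Validate an input bundle
#'
#' Checks the structural invariants of a `cvd_bundle`: non-negative counts
#' and rates, stratum proportions summing to one within each sex and age
#' band, probabilities in [0, 1], and bridge splits summing to one.
#'
#' @param bundle a `cvd_bundle`.
#' @return the bundle, invisibly, or an error.
#' @export
validate_bundle <- function(bundle) {
  abort_if(any(bundle$population$count < 0), "population counts must be >= 0")
  abort_if(any(bundle$base_rates$rate < 0), "base rates must be >= 0")
  sums <- tapply(bundle$stratum_distribution$prop,
                 make_key(bundle$stratum_distribution$sex,
                          bundle$stratum_distribution$age_band), sum)
  abort_if(any(abs(sums - 1) > 1e-9),
           "stratum proportions must sum to 1 per sex and age band")
  b <- bundle$bridge_params
  abort_if(any(abs(b$p_arrest + b$p_mi + b$p_angina - 1) > 1e-9),
           "incident-CHD event-type split must sum to 1")
  probs <- c(b$arrest_survival, b$cf_mi, b$cf_angina, b$cf_stroke)
  abort_if(any(probs < 0 | probs > 1), "bridge probabilities must be in [0, 1]")
  h <- bundle$history_params
  abort_if(any(h$recurrent_chd_rate < 0 | h$recurrent_stroke_rate < 0 |
                 h$cvd_death_rate < 0 | h$non_cvd_death_rate < 0),
           "history rates must be >= 0")
  abort_if(any(h$recurrent_chd_rate + h$recurrent_stroke_rate +
                 h$cvd_death_rate + h$non_cvd_death_rate > 1),
           "implied annual exit probability exceeds 1 in history states")
  abort_if(any(bundle$relative_risks$rr <= 0), "relative risks must be > 0")
  invisible(bundle)
}

#' Generate calibration targets from known rate multipliers
#'
#' Runs one base-year cycle of the cohort model with event and death rates
#' scaled by the supplied per-stream multipliers and records the resulting
#' event/death counts as a calibration target set. Because the targets are
#' produced by the model itself, they give an exact parameter-recovery
#' oracle for [calibrate()].
#'
#' @param bundle a `cvd_bundle`.
#' @param true_factors either a single positive number, a named vector over
#'   streams (`chd_events`, `stroke_events`, `chd_deaths`, `stroke_deaths`),
#'   or a full factor data frame with columns `sex`, `age_band`, `stream`,
#'   `factor`.
#' @return a `calibration_targets` data frame with columns `sex`,
#'   `age_band`, `stream`, `count` and attribute `reference_year`.
#' @export
generate_calibration_targets <- function(bundle, true_factors = 1) {
  fac <- as_factor_frame(bundle, true_factors)
  abort_if(any(fac$factor <= 0), "multipliers must be positive")
  counts <- simulate_base_year(bundle, fac)
  structure(counts, reference_year = bundle$base_year,
            class = c("calibration_targets", "data.frame"))
}

# Normalise the accepted multiplier shapes into a full factor frame.
as_factor_frame <- function(bundle, factors) {
  grid <- expand.grid(sex = SEXES, age_band = bundle$age_bands,
                      stream = CALIB_STREAMS,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  if (is.data.frame(factors)) {
    abort_if(!all(c("sex", "age_band", "stream", "factor") %in% names(factors)),
             "factor frame must have sex, age_band, stream, factor")
    idx <- match(make_key(grid$sex, grid$age_band, grid$stream),
                 make_key(factors$sex, factors$age_band, factors$stream))
    abort_if(anyNA(idx), "factor frame does not cover all strata and streams")
    grid$factor <- factors$factor[idx]
  } else if (!is.null(names(factors))) {
    abort_if(!all(names(factors) %in% CALIB_STREAMS),
             "named multipliers must use the four calibration streams")
    grid$factor <- 1
    for (s in names(factors)) grid$factor[grid$stream == s] <- factors[[s]]
  } else {
    abort_if(length(factors) != 1L, "supply one multiplier, a named vector, or a frame")
    grid$factor <- factors
  }
  grid
}
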