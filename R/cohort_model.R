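# The Markov engine. Three submodels advance in annual cycles:
#   * demographic-epidemiological: annual first-event incidence of T2D, CHD,
#     stroke, and non-CVD death among the no-CVD population, stratified by
#     sex, 10-year age band and risk-factor profile;
#   * bridge: the 30 days after an incident coronary or stroke event,
#     resolving the event type (cardiac arrest / MI / angina for the CHD
#     stream) and early case fatality;
#   * disease history: annual recurrence, revascularisation and death among
#     people with prior CVD, held in post-CHD / post-stroke / post-both
#     compartments per sex and age band.
# Propagation is expected-value (deterministic compartments), not
# microsimulation. Within a cycle, CVD events and deaths are computed on
# start-of-year counts; incident T2D then converts the event-free remainder
# of the non-diabetic strata; aging moves 1/10 of every band up at the end
# of the cycle.

#' Build the starting cohort for a bundle
#'
#' Expands the bundle's population, prior-CVD prevalence and stratum
#' distribution into the model's compartment table: one row per sex x age
#' band x risk stratum for the no-CVD population, plus one row per sex x
#' age band for each prior-CVD health state (post-CVD compartments are not
#' risk-stratified).
#'
#' @param bundle a `cvd_bundle`.
#' @return a `cvd_cells` data frame with columns `sex`, `age_band`,
#'   `stratum_id` (NA for post-CVD rows), `pi_status`, `diabetes`,
#'   `diabetic_twin`, `pi_twin`, `health_state`, `count`.
#' @export
new_cohort <- function(bundle) {
  pop <- bundle$population
  prev <- bundle$cvd_prevalence
  key <- make_key(pop$sex, pop$age_band)
  cvd_share <- prev$prevalence[match(key, make_key(prev$sex, prev$age_band))]
  cvd_share[is.na(cvd_share)] <- 0

  d <- bundle$stratum_distribution
  s <- bundle$strata
  i <- match(make_key(d$sex, d$age_band), key)
  j <- match(d$stratum_id, s$stratum_id)
  free <- data.frame(
    sex = d$sex, age_band = d$age_band, stratum_id = d$stratum_id,
    pi_status = s$pi_status[j], diabetes = s$diabetes[j],
    diabetic_twin = s$diabetic_twin[j], pi_twin = s$pi_twin[j],
    health_state = "no_cvd",
    count = pop$count[i] * (1 - cvd_share[i]) * d$prop,
    stringsAsFactors = FALSE
  )
  # prior-CVD split across history states: mostly single-territory disease
  post_share <- c(post_chd = 0.60, post_stroke = 0.30, post_both = 0.10)
  post <- do.call(rbind, lapply(names(post_share), function(st) {
    data.frame(sex = pop$sex, age_band = pop$age_band, stratum_id = NA_integer_,
               pi_status = NA_character_, diabetes = NA_character_,
               diabetic_twin = NA_integer_, pi_twin = NA_integer_,
               health_state = st,
               count = pop$count * cvd_share * post_share[[st]],
               stringsAsFactors = FALSE)
  }))
  cells <- rbind(free, post)
  class(cells) <- c("cvd_cells", "data.frame")
  cells
}

# rate lookup: cell-specific PI status first, then an "all" row, else 0
.rate_for <- function(rates, sex, band, outcome, pi_status) {
  map <- stats::setNames(rates$rate, make_key(rates$sex, rates$age_band,
                                              rates$outcome, rates$pi_status))
  r <- map[make_key(sex, band, outcome, pi_status)]
  fall <- map[make_key(sex, band, outcome, "all")]
  r[is.na(r)] <- fall[is.na(r)]
  r[is.na(r)] <- 0
  unname(r)
}

#' Advance the cohort one annual cycle
#'
#' Applies one year of model dynamics to a compartment table: first events
#' and non-CVD death among the no-CVD population, the 30-day bridge for
#' incident and recurrent CHD/stroke events, disease-history recurrence and
#' death, and incident-T2D stratum conversion. Aging is a separate step
#' ([age_cohort()]).
#'
#' Person conservation (counts in = counts out + deaths) is asserted to
#' 1e-9 relative tolerance on every call.
#'
#' @param cells a `cvd_cells` table.
#' @param rates data frame with columns `sex`, `age_band`, `outcome`
#'   (`t2d`, `chd`, `stroke`, `non_cvd_death`), `pi_status` (`active`,
#'   `inactive`, or `all` for rates applying to every stratum) and `rate`.
#'   Missing outcome rows are treated as rate 0.
#' @param bridge bridge-submodel parameters (see [generate_inputs()]).
#' @param history disease-history parameters.
#' @return list with elements `cells` (end-of-cycle compartments, deaths
#'   removed) and `tallies` (long data frame per sex x age band: event,
#'   case and death counts for the cycle).
#' @export
advance_year <- function(cells, rates, bridge, history) {
  abort_if(any(cells$count < 0), "malformed cells: negative counts")
  abort_if(any(rates$rate < 0), "negative rate supplied")
  total_in <- sum(cells$count)

  bkey <- make_key(bridge$sex, bridge$age_band)
  bmap <- function(col) stats::setNames(bridge[[col]], bkey)
  # 30-day death fraction of one CHD-stream event, by sex x band
  chd_cf <- pmin(bmap("p_arrest") * (1 - bmap("arrest_survival")) +
                   bmap("p_mi") * pmin(bmap("cf_mi"), 1) +
                   bmap("p_angina") * pmin(bmap("cf_angina"), 1), 1)
  p_mi <- bmap("p_mi")
  stroke_cf <- pmin(bmap("cf_stroke"), 1)

  is_free <- cells$health_state == "no_cvd"
  fc <- cells[is_free, , drop = FALSE]
  post <- cells[!is_free, , drop = FALSE]
  fkey <- make_key(fc$sex, fc$age_band)
  post_sex <- post$sex; post_band <- post$age_band
  post_key2 <- make_key(post_sex, post_band)

  r_chd <- .rate_for(rates, fc$sex, fc$age_band, "chd", fc$pi_status)
  r_str <- .rate_for(rates, fc$sex, fc$age_band, "stroke", fc$pi_status)
  r_t2d <- .rate_for(rates, fc$sex, fc$age_band, "t2d", fc$pi_status)
  r_nd  <- .rate_for(rates, fc$sex, fc$age_band, "non_cvd_death", fc$pi_status)
  r_t2d[fc$diabetes %in% "yes"] <- 0
  abort_if(any(r_chd + r_str + r_nd > 1 + 1e-12),
           "annual exit probability exceeds 1 in a no-CVD cell")

  n <- fc$count
  ev_chd <- n * r_chd
  ev_str <- n * r_str
  d_ncvd <- n * r_nd
  n_left <- n - ev_chd - ev_str - d_ncvd
  t2d_cases <- n_left * r_t2d

  # bridge on first events
  d_chd_first <- ev_chd * chd_cf[fkey]
  d_str_first <- ev_str * stroke_cf[fkey]
  mi_first <- ev_chd * p_mi[fkey]
  surv_chd <- ev_chd - d_chd_first
  surv_str <- ev_str - d_str_first

  # T2D conversion: move cases from non-diabetic strata to the diabetic twin
  fc$count <- n_left - t2d_cases
  mv <- which(t2d_cases > 0)
  if (length(mv)) {
    self_key <- make_key(fc$sex, fc$age_band, fc$stratum_id)
    tgt <- match(make_key(fc$sex, fc$age_band, fc$diabetic_twin), self_key)
    abort_if(anyNA(tgt[mv]), "diabetic twin stratum missing from cells")
    agg <- rowsum(t2d_cases[mv], tgt[mv])
    add <- numeric(nrow(fc))
    add[as.integer(rownames(agg))] <- agg[, 1L]
    fc$count <- fc$count + add
  }

  # disease-history dynamics
  hkey <- make_key(history$sex, history$age_band, history$health_state)
  hmap <- function(col) stats::setNames(history[[col]], hkey)
  pkey <- make_key(post_sex, post_band, post$health_state)
  m <- post$count
  rc <- hmap("recurrent_chd_rate")[pkey];    rc[is.na(rc)] <- 0
  rs <- hmap("recurrent_stroke_rate")[pkey]; rs[is.na(rs)] <- 0
  dc <- hmap("cvd_death_rate")[pkey];        dc[is.na(dc)] <- 0
  dn <- hmap("non_cvd_death_rate")[pkey];    dn[is.na(dn)] <- 0
  abort_if(any(rc + rs + dc + dn > 1 + 1e-12),
           "annual exit probability exceeds 1 in a history cell")
  rec_chd <- m * rc
  rec_str <- m * rs
  d_hist_cvd <- m * dc
  d_hist_ncvd <- m * dn
  d_chd_rec <- rec_chd * chd_cf[post_key2]
  d_str_rec <- rec_str * stroke_cf[post_key2]
  mi_rec <- rec_chd * p_mi[post_key2]
  surv_chd_rec <- rec_chd - d_chd_rec
  surv_str_rec <- rec_str - d_str_rec

  # state flows among survivors of recurrent events: an event in a new
  # territory moves the person to post_both; same-territory recurrence does
  # not change state
  is_pchd <- post$health_state == "post_chd"
  is_pstr <- post$health_state == "post_stroke"
  is_pboth <- post$health_state == "post_both"
  to_both <- numeric(nrow(post))
  to_both[is_pchd] <- surv_str_rec[is_pchd]
  to_both[is_pstr] <- surv_chd_rec[is_pstr]
  post$count <- m - d_hist_cvd - d_hist_ncvd - d_chd_rec - d_str_rec - to_both

  # inflows into history states (first-event survivors + cross recurrences)
  scatter <- function(df, state, key_sex, key_band, amount) {
    keep <- amount > 0
    if (!any(keep)) return(df)
    agg <- rowsum(amount[keep], make_key(key_sex[keep], key_band[keep], state))
    idx <- match(rownames(agg), make_key(df$sex, df$age_band, df$health_state))
    if (anyNA(idx)) {
      miss <- is.na(idx)
      parts <- strsplit(rownames(agg)[miss], "\r", fixed = TRUE)
      df <- rbind(df, data.frame(
        sex = vapply(parts, `[[`, "", 1L),
        age_band = vapply(parts, `[[`, "", 2L),
        stratum_id = NA_integer_, pi_status = NA_character_,
        diabetes = NA_character_, diabetic_twin = NA_integer_,
        pi_twin = NA_integer_, health_state = state, count = 0,
        stringsAsFactors = FALSE))
      idx <- match(rownames(agg), make_key(df$sex, df$age_band, df$health_state))
    }
    df$count[idx] <- df$count[idx] + agg[, 1L]
    df
  }
  post <- scatter(post, "post_chd", fc$sex, fc$age_band, surv_chd)
  post <- scatter(post, "post_stroke", fc$sex, fc$age_band, surv_str)
  post <- scatter(post, "post_both", post_sex, post_band, to_both)

  # tallies per sex x age band; history CVD deaths are attributed to the
  # stream of the compartment, post_both deaths split evenly
  d_pchd <- d_hist_cvd * is_pchd
  d_pstr <- d_hist_cvd * is_pstr
  d_both <- d_hist_cvd * is_pboth
  tally <- function(key_sex, key_band, value) {
    agg <- rowsum(value, make_key(key_sex, key_band))
    data.frame(key = rownames(agg), count = agg[, 1L],
               stringsAsFactors = FALSE)
  }
  measures <- list(
    t2d_incidence    = tally(fc$sex, fc$age_band, t2d_cases),
    chd_incidence    = tally(fc$sex, fc$age_band, ev_chd),
    stroke_incidence = tally(fc$sex, fc$age_band, ev_str),
    chd_events       = rbind(tally(fc$sex, fc$age_band, ev_chd),
                             tally(post_sex, post_band, rec_chd)),
    stroke_events    = rbind(tally(fc$sex, fc$age_band, ev_str),
                             tally(post_sex, post_band, rec_str)),
    total_mi         = rbind(tally(fc$sex, fc$age_band, mi_first),
                             tally(post_sex, post_band, mi_rec)),
    chd_mortality    = rbind(tally(fc$sex, fc$age_band, d_chd_first),
                             tally(post_sex, post_band,
                                   d_chd_rec + d_pchd + 0.5 * d_both)),
    stroke_mortality = rbind(tally(fc$sex, fc$age_band, d_str_first),
                             tally(post_sex, post_band,
                                   d_str_rec + d_pstr + 0.5 * d_both)),
    non_cvd_deaths   = rbind(tally(fc$sex, fc$age_band, d_ncvd),
                             tally(post_sex, post_band, d_hist_ncvd))
  )
  tallies <- do.call(rbind, lapply(names(measures), function(nm) {
    x <- measures[[nm]]
    agg <- rowsum(x$count, x$key)
    parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
    data.frame(measure = nm,
               sex = vapply(parts, `[[`, "", 1L),
               age_band = vapply(parts, `[[`, "", 2L),
               count = agg[, 1L], stringsAsFactors = FALSE)
  }))
  rownames(tallies) <- NULL

  out <- rbind(fc, post)
  deaths <- sum(d_ncvd) + sum(d_chd_first) + sum(d_str_first) +
    sum(d_hist_cvd) + sum(d_hist_ncvd) + sum(d_chd_rec) + sum(d_str_rec)
  abort_if(abs(total_in - sum(out$count) - deaths) >
             1e-9 * max(1, total_in),
           "person conservation violated in advance_year")
  abort_if(any(out$count < -1e-9 * max(1, total_in)),
           "negative compartment produced in advance_year")
  out$count <- pmax(out$count, 0)
  class(out) <- c("cvd_cells", "data.frame")
  list(cells = out, tallies = tallies)
}

#' Age the cohort by one year
#'
#' Moves 1/10 of every 10-year band's count into the next band; the top
#' band's outflow leaves the model. Total population is conserved up to the
#' top-band exit.
#'
#' @param cells a `cvd_cells` table.
#' @return the aged table, with the number of persons who aged out of the
#'   top band attached as attribute `"top_exit"`.
#' @export
age_cohort <- function(cells) {
  if (nrow(cells) == 0L) {
    attr(cells, "top_exit") <- 0
    return(cells)
  }
  bands <- AGE_BANDS[AGE_BANDS %in% unique(cells$age_band)]
  bi <- match(cells$age_band, bands)
  out <- cells$count / 10
  # inflow: match each row to its same-identity row one band below
  ident <- make_key(cells$sex, ifelse(is.na(cells$stratum_id), "-",
                                      cells$stratum_id), cells$health_state)
  src <- match(make_key(ident, bi - 1L), make_key(ident, bi))
  inflow <- ifelse(is.na(src), 0, out[src])
  top_exit <- sum(out[bi == length(bands)])
  total_before <- sum(cells$count)
  cells$count <- cells$count - out + inflow
  abort_if(abs(total_before - sum(cells$count) - top_exit) >
             1e-9 * max(1, total_before),
           "population not conserved during aging")
  attr(cells, "top_exit") <- top_exit
  cells
}

#' Rebalance the physical-inactivity split to a target prevalence
#'
#' Within each sex x age band of the no-CVD population, moves counts
#' between the inactive and active strata so the inactive share equals the
#' target exactly, proportionally across all other risk-factor levels: each
#' active/inactive twin pair keeps its total, so every non-PI marginal is
#' preserved. Post-CVD compartments (not risk-stratified) are untouched.
#'
#' @param cells a `cvd_cells` table.
#' @param target data frame with columns `age_band` and `prevalence`
#'   (optionally `sex`; without it, or with `sex == "both"`, the target
#'   applies to both sexes). Bands absent from `target` are left alone.
#' @return the rebalanced table.
#' @export
rebalance_pi <- function(cells, target) {
  abort_if(any(target$prevalence < 0 | target$prevalence > 1),
           "target prevalence must lie in [0, 1]")
  has_sex <- "sex" %in% names(target)
  free <- which(cells$health_state == "no_cvd")
  fc <- cells[free, , drop = FALSE]
  groups <- unique(data.frame(sex = fc$sex, age_band = fc$age_band,
                              stringsAsFactors = FALSE))
  for (g in seq_len(nrow(groups))) {
    sx <- groups$sex[g]; bd <- groups$age_band[g]
    sex_ok <- if (has_sex) target$sex %in% c(sx, "both") else TRUE
    hit <- target$age_band == bd & sex_ok
    if (!any(hit)) next
    tgt <- target$prevalence[which(hit)[1L]]
    idx <- which(fc$sex == sx & fc$age_band == bd)
    sub_cnt <- fc$count[idx]
    tot <- sum(sub_cnt)
    if (tot == 0) next
    twin <- match(fc$pi_twin[idx], fc$stratum_id[idx])
    abort_if(anyNA(twin), "cannot pair active/inactive twin strata")
    inact <- fc$pi_status[idx] == "inactive"
    p_cur <- sum(sub_cnt[inact]) / tot
    pair_tot <- sub_cnt + sub_cnt[twin]
    if (p_cur > 0) {
      new_in <- sub_cnt * (tgt / p_cur)  # meaningful for inactive rows
      feasible <- all(new_in[inact] <= pair_tot[inact] + 1e-12)
    } else feasible <- FALSE
    if (!feasible) new_in <- pair_tot * tgt
    cnt <- numeric(length(idx))
    cnt[inact] <- new_in[inact]
    cnt[!inact] <- pair_tot[!inact] - new_in[twin[!inact]]
    fc$count[idx] <- cnt
  }
  cells$count[free] <- fc$count
  cells
}

# Per-cycle rate table: the bundle's population-average first-event rates,
# decomposed into active/inactive rates at the bundle's *baseline* PI
# prevalence using the outcome/sex relative risks. The stratum rates are
# fixed properties of the population; scenarios change only the mix of
# people across the two strata.
build_cycle_rates <- function(bundle, factors = NULL) {
  br <- bundle$base_rates
  if (!is.null(factors)) {
    fmap <- stats::setNames(factors$factor,
                            make_key(factors$sex, factors$age_band,
                                     factors$stream))
    for (pair in list(c("chd", "chd_events"), c("stroke", "stroke_events"))) {
      i <- br$outcome == pair[[1L]]
      f <- fmap[make_key(br$sex[i], br$age_band[i], pair[[2L]])]
      f[is.na(f)] <- 1
      br$rate[i] <- br$rate[i] * f
    }
  }
  base_p <- stats::setNames(bundle$pi_baseline$prevalence,
                            bundle$pi_baseline$age_band)
  rows <- list()
  for (oc in c("t2d", "chd", "stroke")) {
    i <- which(br$outcome == oc)
    rr <- vapply(br$sex[i], function(sx)
      lookup_rr(bundle$relative_risks, oc, sx), numeric(1))
    p <- base_p[br$age_band[i]]
    abort_if(anyNA(p), "bundle baseline prevalence does not cover all bands")
    dec <- decompose_rate_vec(br$rate[i], p, rr)
    rows[[length(rows) + 1L]] <- data.frame(
      sex = rep(br$sex[i], 2L), age_band = rep(br$age_band[i], 2L),
      outcome = oc,
      pi_status = rep(c("active", "inactive"), each = length(i)),
      rate = c(dec$active, dec$inactive), stringsAsFactors = FALSE)
  }
  i <- which(br$outcome == "non_cvd_death")
  rows[[length(rows) + 1L]] <- data.frame(
    sex = br$sex[i], age_band = br$age_band[i], outcome = "non_cvd_death",
    pi_status = "all", rate = br$rate[i], stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Apply calibration factors to bridge/history parameters: death-stream
# factors scale 30-day case fatality and history CVD death rates (post_both
# split evenly between the two streams); event-stream factors also scale
# recurrent event rates so first and recurrent events move together.
scale_death_params <- function(bundle, factors) {
  bridge <- bundle$bridge_params
  history <- bundle$history_params
  if (is.null(factors)) return(list(bridge = bridge, history = history))
  fmap <- stats::setNames(factors$factor,
                          make_key(factors$sex, factors$age_band,
                                   factors$stream))
  g_chd <- fmap[make_key(bridge$sex, bridge$age_band, "chd_deaths")]
  g_str <- fmap[make_key(bridge$sex, bridge$age_band, "stroke_deaths")]
  g_chd[is.na(g_chd)] <- 1; g_str[is.na(g_str)] <- 1
  bridge$arrest_survival <- 1 - pmin(1, (1 - bridge$arrest_survival) * g_chd)
  bridge$cf_mi <- pmin(1, bridge$cf_mi * g_chd)
  bridge$cf_angina <- pmin(1, bridge$cf_angina * g_chd)
  bridge$cf_stroke <- pmin(1, bridge$cf_stroke * g_str)
  f_chd <- fmap[make_key(history$sex, history$age_band, "chd_events")]
  f_str <- fmap[make_key(history$sex, history$age_band, "stroke_events")]
  f_chd[is.na(f_chd)] <- 1; f_str[is.na(f_str)] <- 1
  history$recurrent_chd_rate <- history$recurrent_chd_rate * f_chd
  history$recurrent_stroke_rate <- history$recurrent_stroke_rate * f_str
  h_chd <- fmap[make_key(history$sex, history$age_band, "chd_deaths")]
  h_str <- fmap[make_key(history$sex, history$age_band, "stroke_deaths")]
  h_chd[is.na(h_chd)] <- 1; h_str[is.na(h_str)] <- 1
  g <- ifelse(history$health_state == "post_chd", h_chd,
              ifelse(history$health_state == "post_stroke", h_str,
                     (h_chd + h_str) / 2))
  history$cvd_death_rate <- history$cvd_death_rate * g
  list(bridge = bridge, history = history)
}

# One base-year cycle under given calibration factors; returns counts per
# sex x age band for the four calibration streams.
simulate_base_year <- function(bundle, factors = NULL) {
  cells <- new_cohort(bundle)
  rates <- build_cycle_rates(bundle, factors)
  dp <- scale_death_params(bundle, factors)
  res <- advance_year(cells, rates, dp$bridge, dp$history)
  t <- res$tallies
  map <- c(chd_events = "chd_events", stroke_events = "stroke_events",
           chd_deaths = "chd_mortality", stroke_deaths = "stroke_mortality")
  out <- do.call(rbind, lapply(names(map), function(s) {
    x <- t[t$measure == map[[s]], c("sex", "age_band", "count")]
    x$stream <- s
    x
  }))
  rownames(out) <- NULL
  out[, c("sex", "age_band", "stream", "count")]
}

#' Run a full scenario simulation
#'
#' Advances the cohort over the horizon, applying per year: the scenario's
#' physical-inactivity prevalence (via [rebalance_pi()]), the PI-decomposed
#' annual rates, one cycle of model dynamics ([advance_year()]) and aging
#' ([age_cohort()]). The cohort is closed (no new 35-year-old entrants).
#'
#' @param bundle a `cvd_bundle`, optionally carrying calibration factors in
#'   `bundle$calibration_factors`.
#' @param scenario a `cvd_scenario` (see [constant_scenario()],
#'   [who_trajectory()]).
#' @param horizon number of annual cycles (>= 1); the scenario trajectory
#'   must cover every simulated year.
#' @return a `cvd_sim_result`: list with `counts` (long data frame:
#'   `outcome`, `year`, `sex`, `age_band`, `count`), `cumulative` (totals
#'   over the horizon for the reporting bands 35-64), `scenario`,
#'   `start_year`, `horizon`.
#' @export
run_simulation <- function(bundle, scenario, horizon = scenario$horizon) {
  abort_if(horizon < 1, "horizon must be at least 1")
  years <- scenario$start_year + seq_len(horizon) - 1L
  abort_if(!all(years %in% scenario$trajectory$year),
           "scenario trajectory does not cover the simulation horizon")
  factors <- bundle$calibration_factors
  rates <- build_cycle_rates(bundle, factors)
  dp <- scale_death_params(bundle, factors)
  cells <- new_cohort(bundle)
  acc <- vector("list", horizon)
  for (k in seq_len(horizon)) {
    tr <- scenario$trajectory[scenario$trajectory$year == years[k], ,
                              drop = FALSE]
    cells <- rebalance_pi(cells, tr)
    step <- advance_year(cells, rates, dp$bridge, dp$history)
    cells <- age_cohort(step$cells)
    t <- step$tallies
    t$year <- years[k]
    acc[[k]] <- t
  }
  counts <- do.call(rbind, acc)
  names(counts)[names(counts) == "measure"] <- "outcome"
  counts <- counts[, c("outcome", "year", "sex", "age_band", "count")]
  keep <- counts$outcome %in% OUTCOMES & counts$age_band %in% REPORTING_BANDS
  cum <- tapply(counts$count[keep], counts$outcome[keep], sum)
  cum <- stats::setNames(as.numeric(cum[OUTCOMES]), OUTCOMES)
  structure(list(counts = counts, cumulative = cum,
                 scenario = scenario$name, start_year = scenario$start_year,
                 horizon = horizon),
            class = "cvd_sim_result")
}

#' @export
print.cvd_sim_result <- function(x, ...) {
  cat(sprintf("Cohort simulation: scenario '%s', %d year(s) from %d\n",
              x$scenario, x$horizon, x$start_year))
  cat("Cumulative counts, ages 35-64 (rounded to nearest 100):\n")
  print(round_to_hundred(x$cumulative))
  invisible(x)
}

#' Cumulative outcome counts from a simulation result
#'
#' @param result a `cvd_sim_result`.
#' @param age_bands bands to include (default the reporting bands 35-64).
#' @param rounded round to the nearest 100, the published convention.
#' @return named numeric vector over the six reported outcomes.
#' @export
cumulative_counts <- function(result, age_bands = REPORTING_BANDS,
                              rounded = FALSE) {
  cc <- result$counts
  keep <- cc$outcome %in% OUTCOMES & cc$age_band %in% age_bands
  out <- tapply(cc$count[keep], cc$outcome[keep], sum)
  out <- stats::setNames(as.numeric(out[OUTCOMES]), OUTCOMES)
  if (rounded) round_to_hundred(out) else out
}
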