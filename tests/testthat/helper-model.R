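# Shared fixtures and the independent expected-value oracle.

tiny_bundle <- function(seed = 42, bands = c("35-44", "45-54"),
                        scale = 1e-4) {
  generate_inputs(seed = seed, scale = scale,
                  ontology = default_ontology(compact = TRUE),
                  age_bands = bands)
}

table2 <- function() load_table2_fixture()
table3 <- function() load_table3_fixture()

# Hand-built minimal compartment table over the compact ontology
# (strata 1: active/no-diab, 2: inactive/no-diab, 3: active/diab,
#  4: inactive/diab), one sex, one band, with optional post-CVD counts.
micro_cells <- function(counts = c(100, 50, 20, 10),
                        post = c(post_chd = 0, post_stroke = 0,
                                 post_both = 0),
                        sex = "male", band = "35-44") {
  free <- data.frame(
    sex = sex, age_band = band, stratum_id = 1:4,
    pi_status = c("active", "inactive", "active", "inactive"),
    diabetes = c("no", "no", "yes", "yes"),
    diabetic_twin = c(3L, 4L, 3L, 4L), pi_twin = c(2L, 1L, 4L, 3L),
    health_state = "no_cvd", count = counts, stringsAsFactors = FALSE)
  hist <- data.frame(
    sex = sex, age_band = band, stratum_id = NA_integer_,
    pi_status = NA_character_, diabetes = NA_character_,
    diabetic_twin = NA_integer_, pi_twin = NA_integer_,
    health_state = names(post), count = unname(post),
    stringsAsFactors = FALSE)
  out <- rbind(free, hist)
  class(out) <- c("cvd_cells", "data.frame")
  out
}

micro_rates <- function(chd = 0, stroke = 0, t2d = 0, ncvd = 0,
                        sex = "male", band = "35-44") {
  data.frame(sex = sex, age_band = band,
             outcome = c("chd", "stroke", "t2d", "non_cvd_death"),
             pi_status = "all", rate = c(chd, stroke, t2d, ncvd),
             stringsAsFactors = FALSE)
}

micro_bridge <- function(p_arrest = 0.1, p_mi = 0.5, p_angina = 0.4,
                         arrest_survival = 0.3, cf_mi = 0.2,
                         cf_angina = 0.02, cf_stroke = 0.25,
                         sex = "male", band = "35-44") {
  data.frame(sex = sex, age_band = band, p_arrest = p_arrest, p_mi = p_mi,
             p_angina = p_angina, arrest_survival = arrest_survival,
             cf_mi = cf_mi, cf_angina = cf_angina, cf_stroke = cf_stroke,
             stringsAsFactors = FALSE)
}

micro_history <- function(rec_chd = 0, rec_stroke = 0, revasc = 0,
                          cvd_death = 0, ncvd_death = 0,
                          sex = "male", band = "35-44") {
  expand.grid(sex = sex, age_band = band,
              health_state = c("post_chd", "post_stroke", "post_both"),
              stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE) |>
    transform(recurrent_chd_rate = rec_chd,
              recurrent_stroke_rate = rec_stroke, revasc_rate = revasc,
              cvd_death_rate = cvd_death, non_cvd_death_rate = ncvd_death)
}

# Independent expected-value recursion: scalar loops and explicit formulas,
# no shared code with advance_year(). Follows the documented within-cycle
# convention: CVD events and non-CVD deaths on start-of-year counts, T2D
# conversion on the event-free remainder, recurrent events through the
# bridge, cross-territory recurrence survivors to post_both.
oracle_advance <- function(cells, rates, bridge, history) {
  get_rate <- function(sex, band, outcome) {
    r <- rates[rates$sex == sex & rates$age_band == band &
                 rates$outcome == outcome, ]
    if (nrow(r) == 0) 0 else r$rate[1]
  }
  newc <- cells
  tall <- list(t2d_incidence = 0, chd_incidence = 0, stroke_incidence = 0,
               chd_events = 0, stroke_events = 0, total_mi = 0,
               chd_mortality = 0, stroke_mortality = 0, non_cvd_deaths = 0)
  # stash inflows to apply after all rows are processed
  inflow <- c(post_chd = 0, post_stroke = 0, post_both = 0)
  t2d_in <- numeric(nrow(cells))
  b <- bridge[1, ]
  chd_cf <- b$p_arrest * (1 - b$arrest_survival) + b$p_mi * b$cf_mi +
    b$p_angina * b$cf_angina
  for (i in seq_len(nrow(cells))) {
    row <- cells[i, ]
    n <- row$count
    if (row$health_state == "no_cvd") {
      r_chd <- get_rate(row$sex, row$age_band, "chd")
      r_str <- get_rate(row$sex, row$age_band, "stroke")
      r_nd <- get_rate(row$sex, row$age_band, "non_cvd_death")
      r_t2d <- if (identical(row$diabetes, "yes")) 0 else
        get_rate(row$sex, row$age_band, "t2d")
      ev_c <- n * r_chd; ev_s <- n * r_str; d_n <- n * r_nd
      left <- n - ev_c - ev_s - d_n
      cases <- left * r_t2d
      d_c <- ev_c * chd_cf; d_s <- ev_s * b$cf_stroke
      tall$chd_incidence <- tall$chd_incidence + ev_c
      tall$stroke_incidence <- tall$stroke_incidence + ev_s
      tall$chd_events <- tall$chd_events + ev_c
      tall$stroke_events <- tall$stroke_events + ev_s
      tall$t2d_incidence <- tall$t2d_incidence + cases
      tall$total_mi <- tall$total_mi + ev_c * b$p_mi
      tall$chd_mortality <- tall$chd_mortality + d_c
      tall$stroke_mortality <- tall$stroke_mortality + d_s
      tall$non_cvd_deaths <- tall$non_cvd_deaths + d_n
      newc$count[i] <- left - cases
      # T2D movers land in the diabetic twin (applied after the loop)
      j <- which(cells$health_state == "no_cvd" &
                   cells$sex == row$sex & cells$age_band == row$age_band &
                   cells$stratum_id == row$diabetic_twin)
      t2d_in[j] <- t2d_in[j] + cases
      inflow["post_chd"] <- inflow[["post_chd"]] + (ev_c - d_c)
      inflow["post_stroke"] <- inflow[["post_stroke"]] + (ev_s - d_s)
    } else {
      h <- history[history$sex == row$sex &
                     history$age_band == row$age_band &
                     history$health_state == row$health_state, ]
      rec_c <- n * h$recurrent_chd_rate
      rec_s <- n * h$recurrent_stroke_rate
      d_cvd <- n * h$cvd_death_rate
      d_n <- n * h$non_cvd_death_rate
      d_rc <- rec_c * chd_cf; d_rs <- rec_s * b$cf_stroke
      tall$chd_events <- tall$chd_events + rec_c
      tall$stroke_events <- tall$stroke_events + rec_s
      tall$total_mi <- tall$total_mi + rec_c * b$p_mi
      tall$non_cvd_deaths <- tall$non_cvd_deaths + d_n
      attrib_c <- switch(row$health_state, post_chd = d_cvd,
                         post_both = d_cvd / 2, 0)
      attrib_s <- switch(row$health_state, post_stroke = d_cvd,
                         post_both = d_cvd / 2, 0)
      tall$chd_mortality <- tall$chd_mortality + d_rc + attrib_c
      tall$stroke_mortality <- tall$stroke_mortality + d_rs + attrib_s
      cross <- switch(row$health_state,
                      post_chd = rec_s - d_rs,
                      post_stroke = rec_c - d_rc, 0)
      newc$count[i] <- n - d_cvd - d_n - d_rc - d_rs - cross
      inflow["post_both"] <- inflow[["post_both"]] + cross
    }
  }
  newc$count <- newc$count + t2d_in
  for (st in names(inflow)) {
    j <- which(newc$health_state == st)
    if (length(j)) newc$count[j] <- newc$count[j] + inflow[[st]]
  }
  list(cells = newc, tallies = tall)
}

# Pull one tally value from advance_year() output, summed over strata.
tally_of <- function(step, measure) {
  sum(step$tallies$count[step$tallies$measure == measure])
}
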