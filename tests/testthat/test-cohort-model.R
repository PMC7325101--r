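test_that("null dynamics leave the cohort unchanged with zero tallies", {
  cells <- micro_cells(post = c(post_chd = 5, post_stroke = 3, post_both = 1))
  step <- advance_year(cells, micro_rates(), micro_bridge(), micro_history())
  expect_equal(step$cells$count, cells$count)
  expect_equal(sum(step$tallies$count), 0)
})

test_that("a single incidence rate gives the one-step expectation exactly", {
  cells <- micro_cells(counts = c(200, 0, 0, 0))
  step <- advance_year(cells, micro_rates(t2d = 0.03), micro_bridge(),
                       micro_history())
  expect_equal(tally_of(step, "t2d_incidence"), 200 * 0.03)
  # cases moved to the diabetic twin stratum
  expect_equal(step$cells$count[step$cells$stratum_id %in% 3], 6)
  step2 <- advance_year(cells, micro_rates(chd = 0.02), micro_bridge(),
                        micro_history())
  expect_equal(tally_of(step2, "chd_incidence"), 4)
})

test_that("advance_year matches the independent expected-value recursion", {
  cells <- micro_cells(counts = c(120, 40, 25, 8),
                       post = c(post_chd = 30, post_stroke = 12,
                                post_both = 4))
  rates <- micro_rates(chd = 0.015, stroke = 0.008, t2d = 0.04, ncvd = 0.01)
  bridge <- micro_bridge()
  history <- micro_history(rec_chd = 0.05, rec_stroke = 0.03,
                           cvd_death = 0.06, ncvd_death = 0.02)
  got <- advance_year(cells, rates, bridge, history)
  want <- oracle_advance(cells, rates, bridge, history)
  # compartments agree row by row
  key <- function(d) paste(d$sex, d$age_band, d$stratum_id, d$health_state)
  expect_equal(got$cells$count[order(key(got$cells))],
               want$cells$count[order(key(want$cells))], tolerance = 1e-12)
  for (m in names(want$tallies)) {
    expect_equal(tally_of(got, m), want$tallies[[m]], tolerance = 1e-12,
                 info = m)
  }
})

test_that("persons are conserved and compartments stay non-negative", {
  set.seed(21)
  for (k in 1:20) {
    cells <- micro_cells(counts = runif(4, 0, 500),
                         post = c(post_chd = runif(1, 0, 50),
                                  post_stroke = runif(1, 0, 50),
                                  post_both = runif(1, 0, 20)))
    rates <- micro_rates(chd = runif(1, 0, 0.05), stroke = runif(1, 0, 0.05),
                         t2d = runif(1, 0, 0.08), ncvd = runif(1, 0, 0.05))
    history <- micro_history(rec_chd = runif(1, 0, 0.08),
                             rec_stroke = runif(1, 0, 0.08),
                             cvd_death = runif(1, 0, 0.1),
                             ncvd_death = runif(1, 0, 0.05))
    step <- advance_year(cells, rates, micro_bridge(), history)
    deaths <- tally_of(step, "non_cvd_deaths") +
      tally_of(step, "chd_mortality") + tally_of(step, "stroke_mortality")
    expect_equal(sum(cells$count), sum(step$cells$count) + deaths,
                 tolerance = 1e-9)
    expect_true(all(step$cells$count >= 0))
  }
})

test_that("aging moves one tenth up per band and conserves the rest", {
  cells <- do.call(rbind, lapply(
    c("35-44", "45-54", "55-64"),
    function(b) { x <- micro_cells(counts = c(0, 0, 0, 0), band = b); x }))
  cells$count[which(cells$stratum_id == 1)] <- c(100, 50, 20)
  aged <- age_cohort(cells)
  got <- aged$count[which(aged$stratum_id == 1)]
  expect_equal(got, c(90, 55, 23))
  expect_equal(attr(aged, "top_exit"), 2)
  # empty cohort is a fixed point
  empty <- cells[0, ]
  expect_equal(nrow(age_cohort(empty)), 0L)
  # single band: 10 leave, 90 remain
  one <- micro_cells(counts = c(100, 0, 0, 0))
  aged1 <- age_cohort(one)
  expect_equal(sum(aged1$count), 90)
  expect_equal(attr(aged1, "top_exit"), 10)
})

test_that("PI rebalance hits the target exactly and preserves marginals", {
  cells <- micro_cells(counts = c(0.879 * 150, 0.121 * 150,
                                  0.879 * 50, 0.121 * 50))
  # fixed point: target equal to the current share
  same <- rebalance_pi(cells, data.frame(age_band = "35-44",
                                         prevalence = 0.121))
  expect_equal(same$count, cells$count, tolerance = 1e-12)
  # published example: 200 persons at 12.1% moved to 15.9% -> 31.8 inactive
  up <- rebalance_pi(cells, data.frame(age_band = "35-44",
                                       prevalence = 0.159))
  expect_equal(sum(up$count[up$pi_status %in% "inactive"]), 200 * 0.159)
  # non-PI marginal (diabetes) unchanged
  expect_equal(sum(up$count[up$diabetes %in% "yes"]), 50, tolerance = 1e-9)
  expect_equal(sum(up$count), 200, tolerance = 1e-9)
  # boundary: target zero empties the inactive strata
  zero <- rebalance_pi(cells, data.frame(age_band = "35-44", prevalence = 0))
  expect_equal(sum(zero$count[zero$pi_status %in% "inactive"]), 0)
  expect_equal(sum(zero$count), 200, tolerance = 1e-9)
  expect_error(rebalance_pi(cells, data.frame(age_band = "35-44",
                                              prevalence = 1.2)),
               "\\[0, 1\\]")
})

test_that("simulation is deterministic and composes with manual stepping", {
  b <- tiny_bundle()
  t2 <- table2()
  sc <- constant_scenario(t2, 2006, start_year = 2010, horizon = 3)
  r1 <- run_simulation(b, sc, 3)
  r2 <- run_simulation(b, sc, 3)
  expect_identical(r1, r2)
  # horizon 1 equals one manual rebalance + advance + age
  r <- run_simulation(b, sc, 1)
  cells <- new_cohort(b)
  cells <- rebalance_pi(cells, sc$trajectory[sc$trajectory$year == 2010, ])
  step <- advance_year(cells, cvdpimex:::build_cycle_rates(b, NULL),
                       b$bridge_params, b$history_params)
  expect_equal(cumulative_counts(r)[["chd_incidence"]],
               sum(step$tallies$count[step$tallies$measure == "chd_incidence" &
                                        step$tallies$age_band %in%
                                        c("35-44", "45-54", "55-64")]))
  # cumulative totals equal the sum of yearly counts
  r3 <- run_simulation(b, sc, 3)
  expect_equal(unname(r3$cumulative),
               unname(cumulative_counts(r3)))
  expect_error(run_simulation(b, sc, 10), "does not cover")
})

test_that("a lower-PI trajectory never produces more cumulative events", {
  b <- tiny_bundle()
  t2 <- table2()
  lo <- constant_scenario(t2, 2006, horizon = 5)
  hi <- constant_scenario(t2, 2012, horizon = 5)
  rl <- run_simulation(b, lo, 5)
  rh <- run_simulation(b, hi, 5)
  # per-year cumulative ordering for the three incidence outcomes
  for (oc in c("t2d_incidence", "chd_incidence", "stroke_incidence")) {
    cl <- with(subset(rl$counts, outcome == oc), tapply(count, year, sum))
    ch <- with(subset(rh$counts, outcome == oc), tapply(count, year, sum))
    expect_true(all(cumsum(cl) <= cumsum(ch) + 1e-9), info = oc)
  }
})

test_that("with all relative risks at 1 the PI trajectory is irrelevant", {
  b <- tiny_bundle()
  b$relative_risks$rr <- 1
  t2 <- table2()
  r06 <- run_simulation(b, constant_scenario(t2, 2006, horizon = 4), 4)
  r12 <- run_simulation(b, constant_scenario(t2, 2012, horizon = 4), 4)
  expect_equal(r06$counts$count, r12$counts$count, tolerance = 1e-12)
})
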