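test_that("WHO trajectory hits the published anchor reductions", {
  p <- c("35-44" = 0.159)
  sc <- who_trajectory(p)
  tr <- sc$trajectory
  at <- function(y) tr$prevalence[tr$year == y & tr$age_band == "35-44"]
  expect_equal(at(2016), 0.159)
  expect_equal(at(2025), 0.159 * 0.90)   # 0.1431
  expect_equal(at(2030), 0.159 * 0.85)   # 0.13515
  # piecewise linear: second differences vanish within each segment
  v <- vapply(2016:2030, at, numeric(1))
  d2 <- diff(diff(v))
  expect_equal(d2[1:8], rep(0, 8), tolerance = 1e-15)    # 2016-2025 segment
  expect_equal(d2[11:13], rep(0, 3), tolerance = 1e-15)  # 2026-2030 segment
  # zero mid-reduction keeps the trajectory flat through 2025
  flat <- who_trajectory(p, mid_reduction = 0, end_reduction = 0)
  expect_equal(unique(flat$trajectory$prevalence), 0.159)
  expect_error(who_trajectory(p, mid_reduction = 1.2), "\\[0, 1\\)")
})

test_that("percent arithmetic follows the published rounding conventions", {
  expect_equal(percent_difference_change(10300, 1267400), 0.8)
  expect_equal(percent_difference_change(27100, 2586300), 1.0)
  expect_equal(percent_difference_change(0, 5), 0.0)
  expect_error(percent_difference_change(1, 0), "positive")
  expect_equal(relative_prevalence_change(0.121, 0.159), 31)
  expect_equal(relative_prevalence_change(0.108, 0.163), 51)
  expect_equal(relative_prevalence_change(0.2, 0.2), 0)
  expect_error(relative_prevalence_change(0, 0.1), "positive")
  # exact rational agreement on integer inputs (half-up, not banker's)
  expect_equal(percent_difference_change(25, 2000), 1.3)  # 1.25 rounds up
  expect_equal(relative_prevalence_change(200, 203), 2)   # 1.5 rounds up
})

test_that("identical scenarios give zero deltas; swapping negates them", {
  b <- tiny_bundle()
  t2 <- table2()
  s06 <- constant_scenario(t2, 2006, horizon = 4)
  s12 <- constant_scenario(t2, 2012, horizon = 4)
  same <- compare_scenarios(b, s06, s06, 4)
  expect_equal(same$increase, rep(0, 6))
  expect_equal(same$percent_change, rep(0, 6))
  fwd <- compare_scenarios(b, s06, s12, 4)
  rev <- compare_scenarios(b, s12, s06, 4)
  expect_equal(fwd$increase, -rev$increase, tolerance = 1e-12)
})

test_that("the 2006 vs 2012 counterfactual raises all six outcomes", {
  b <- tiny_bundle(bands = c("35-44", "45-54", "55-64"))
  t2 <- table2()
  d <- compare_scenarios(b, constant_scenario(t2, 2006, horizon = 7),
                         constant_scenario(t2, 2012, horizon = 7), 7)
  expect_true(all(d$increase > 0))
  expect_true(all(d$percent_change > 0))
  expect_equal(d$increase, d$alt_count - d$base_count)
})

test_that("accelerometer adjustment substitutes tables and scales deltas", {
  t2 <- table2()
  # identity substitution changes nothing downstream
  same <- apply_accelerometer_adjustment(t2, t2)
  expect_equal(same$prevalence, t2$prevalence)
  # uniformly higher adjusted prevalences enlarge the counterfactual delta
  adj <- t2
  adj$prevalence <- pmin(0.95, t2$prevalence * 1.5)
  adj$ci_low <- pmin(adj$prevalence, t2$ci_low * 1.5)
  adj$ci_high <- pmin(0.99, t2$ci_high * 1.5)
  adj <- apply_accelerometer_adjustment(t2, adj)
  b <- tiny_bundle()
  d_un <- compare_scenarios(b, constant_scenario(t2, 2006, horizon = 4),
                            constant_scenario(t2, 2012, horizon = 4), 4)
  d_ad <- compare_scenarios(b, constant_scenario(adj, 2006, horizon = 4),
                            constant_scenario(adj, 2012, horizon = 4), 4)
  expect_true(all(d_ad$increase >= d_un$increase - 1e-9))
  # missing stratum in the adjusted table raises a coverage error
  expect_error(apply_accelerometer_adjustment(t2, adj[-1, ]),
               "does not cover|incomplete")
})

test_that("WHO-target runs avert events relative to the status quo", {
  b <- tiny_bundle()
  t2 <- table2()
  p12 <- sapply(c("35-44", "45-54"), function(bd)
    pi_prevalence_entry(t2, "both", bd, 2012)$prevalence)
  status_quo <- who_trajectory(p12, mid_reduction = 0, end_reduction = 0,
                               name = "status-quo")
  who <- who_trajectory(p12)
  d <- compare_scenarios(b, status_quo, who, 15)
  expect_true(all(d$increase <= 0))
  expect_true(any(d$increase < 0))
})
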