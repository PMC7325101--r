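test_that("CI-to-SE conversion matches hand arithmetic on each scale", {
  expect_equal(ci_to_se(0.113, 0.129, "natural"), (0.129 - 0.113) / 3.92)
  expect_equal(ci_to_se(0.113, 0.129, "natural"), 0.004082, tolerance = 1e-4)
  expect_equal(ci_to_se(0.7, 0.9, "log"), (log(0.9) - log(0.7)) / 3.92)
  expect_equal(ci_to_se(0.1, 0.2, "logit"),
               (qlogis(0.2) - qlogis(0.1)) / 3.92)
  # symmetric interval recovers its midpoint on the chosen scale
  se <- ci_to_se(0.78 * exp(-1.96 * 0.05), 0.78 * exp(1.96 * 0.05), "log")
  expect_equal(se, 0.05)
  expect_error(ci_to_se(0.5, 0.5), "strictly below")
  expect_error(ci_to_se(0, 0.5, "log"), "finite")
})

test_that("Monte Carlo is reproducible and degenerate with zero SEs", {
  b <- tiny_bundle(bands = "35-44")
  t2 <- table2()
  base <- constant_scenario(t2, 2006, horizon = 2)
  alt <- constant_scenario(t2, 2012, horizon = 2)
  m1 <- run_monte_carlo(b, base, alt, horizon = 2, n_draws = 15, seed = 9)
  m2 <- run_monte_carlo(b, base, alt, horizon = 2, n_draws = 15, seed = 9)
  expect_identical(m1, m2)
  m3 <- run_monte_carlo(b, base, alt, horizon = 2, n_draws = 15, seed = 10)
  expect_false(identical(m1$mean_increase, m3$mean_increase))

  # all SEs zero: every draw equals the deterministic delta
  b0 <- b
  b0$relative_risks$ln_rr_se <- 0
  base0 <- base; alt0 <- alt
  base0$prevalence_se$se_logit <- 0
  alt0$prevalence_se$se_logit <- 0
  m0 <- run_monte_carlo(b0, base0, alt0, horizon = 2, n_draws = 5, seed = 1)
  det <- compare_scenarios(b0, base0, alt0, 2)
  expect_equal(m0$se, rep(0, 6))
  expect_equal(m0$mean_increase, det$increase, tolerance = 1e-12)

  # missing SEs are a configuration error naming the gap
  bna <- b
  bna$relative_risks$ln_rr_se <- NA_real_
  expect_error(run_monte_carlo(bna, base, alt, horizon = 2, n_draws = 5,
                               seed = 1), "missing log-RR")
  sc_no_se <- base; sc_no_se$prevalence_se <- NULL
  expect_error(run_monte_carlo(b, sc_no_se, alt, horizon = 2, n_draws = 5,
                               seed = 1), "no prevalence standard errors")
})

test_that("draw-level inputs always stay positive and inside (0, 1)", {
  b <- tiny_bundle(bands = "35-44")
  b$relative_risks$ln_rr_se <- 0.5   # deliberately wide
  t2 <- table2()
  base <- constant_scenario(t2, 2006, horizon = 1)
  sc <- base
  sc$prevalence_se$se_logit <- 2
  set.seed(4)
  for (z in rnorm(20, 0, 3)) {
    p <- cvdpimex:::perturb_scenario(sc, setNames(rep(z, 3),
                                                  sc$prevalence_se$age_band))
    expect_true(all(p$trajectory$prevalence > 0 &
                      p$trajectory$prevalence < 1))
  }
  expect_true(all(exp(log(b$relative_risks$rr) +
                        3 * b$relative_risks$ln_rr_se) > 0))
})

test_that("empirical SE matches linear propagation and 1/sqrt(n) scaling", {
  # toy configuration where only the T2D log-RR is uncertain, so the draw
  # SD of the T2D delta follows from the delta's derivative in log RR
  b <- tiny_bundle(bands = "35-44")
  b$relative_risks$ln_rr_se <- 0
  s <- 0.03
  b$relative_risks$ln_rr_se[b$relative_risks$outcome == "t2d"] <- s
  t2 <- table2()
  base <- constant_scenario(t2, 2006, horizon = 2)
  alt <- constant_scenario(t2, 2012, horizon = 2)
  base$prevalence_se$se_logit <- 0
  alt$prevalence_se$se_logit <- 0

  delta_at <- function(lrr_shift) {
    bb <- b
    i <- bb$relative_risks$outcome == "t2d"
    bb$relative_risks$rr[i] <- exp(log(b$relative_risks$rr[i]) + lrr_shift)
    compare_scenarios(bb, base, alt, 2)$increase[
      compare_scenarios(bb, base, alt, 2)$outcome == "t2d_incidence"]
  }
  slope <- (delta_at(1e-4) - delta_at(-1e-4)) / 2e-4
  analytic_sd <- abs(slope) * s

  n_big <- 400
  m_big <- run_monte_carlo(b, base, alt, horizon = 2, n_draws = n_big,
                           seed = 31, se_of_mean = FALSE)
  sd_big <- m_big$se[m_big$outcome == "t2d_incidence"]
  # sampling error of an SD estimate is about sd / sqrt(2 (n - 1))
  expect_lt(abs(sd_big - analytic_sd), 3 * analytic_sd / sqrt(2 * (n_big - 1)))

  # SE of the mean scales as 1/sqrt(n): quarter the draws, double the SE
  m_small <- run_monte_carlo(b, base, alt, horizon = 2, n_draws = n_big / 4,
                             seed = 57)
  m_big_se <- run_monte_carlo(b, base, alt, horizon = 2, n_draws = n_big,
                              seed = 31)
  ratio <- m_small$se[m_small$outcome == "t2d_incidence"] /
    m_big_se$se[m_big_se$outcome == "t2d_incidence"]
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.8)
})
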