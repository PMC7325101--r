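test_that("log-RR pooling matches hand computation and identities", {
  # single stratum is the identity
  expect_equal(pool_log_rr(0.8, 0.04), 0.8)
  # equal inputs pool to themselves regardless of variances
  expect_equal(pool_log_rr(c(0.8, 0.8), c(0.01, 0.25)), 0.8)
  # hand-computed two-stratum case:
  # (log 0.7 / 0.01 + log 0.9 / 0.04) / (100 + 25), exponentiated
  hand <- exp((log(0.7) / 0.01 + log(0.9) / 0.04) / (1 / 0.01 + 1 / 0.04))
  expect_equal(pool_log_rr(c(0.7, 0.9), c(0.01, 0.04)), hand)
  expect_equal(hand, 0.7361, tolerance = 1e-4)
  # brute-force weighted mean agrees
  rr <- c(0.6, 0.85, 1.1); v <- c(0.02, 0.05, 0.1)
  expect_equal(pool_log_rr(rr, v),
               exp(weighted.mean(log(rr), 1 / v)))
})

test_that("pooling is order-invariant, scale-invariant and bracketed", {
  set.seed(7)
  for (k in 1:25) {
    n <- sample(2:6, 1)
    rr <- exp(rnorm(n, 0, 0.4)); v <- runif(n, 0.005, 0.2)
    p <- pool_log_rr(rr, v)
    o <- sample(n)
    expect_equal(pool_log_rr(rr[o], v[o]), p)
    expect_equal(pool_log_rr(rr, v * 13.7), p)
    expect_gte(p, min(rr) - 1e-12)
    expect_lte(p, max(rr) + 1e-12)
  }
  expect_error(pool_log_rr(numeric(0), numeric(0)), "at least one")
  expect_error(pool_log_rr(-0.5, 0.1), "positive")
  expect_error(pool_log_rr(0.8, 0), "positive")
})

test_that("rate decomposition matches the closed form and mixture identity", {
  d <- decompose_rate(0.010, 0.121, 0.78)
  expect_equal(d[["inactive"]], 0.010 / (0.121 + 0.879 * 0.78))
  expect_equal(d[["inactive"]], 0.012397, tolerance = 1e-4)
  expect_equal(d[["active"]], 0.009670, tolerance = 1e-4)
  # no effect when rr = 1
  expect_equal(decompose_rate(0.02, 0.3, 1), c(active = 0.02, inactive = 0.02))
  # whole population inactive: inactive rate equals the overall rate
  expect_equal(decompose_rate(0.015, 1, 0.7)[["inactive"]], 0.015)
  expect_error(decompose_rate(0.01, 1.2, 0.8), "\\[0, 1\\]")
  expect_error(decompose_rate(0.01, 0.5, 0), "positive")
})

test_that("mixture identity and rate ordering hold over random inputs", {
  set.seed(11)
  for (k in 1:200) {
    lam <- runif(1, 0, 0.5); p <- runif(1); rr <- exp(rnorm(1, 0, 0.7))
    d <- decompose_rate(lam, p, rr)
    expect_equal(p * d[["inactive"]] + (1 - p) * d[["active"]], lam,
                 tolerance = 1e-12)
    if (rr < 1) {
      expect_lte(d[["active"]], lam + 1e-15)
      expect_gte(d[["inactive"]], lam - 1e-15)
    } else if (rr > 1) {
      expect_gte(d[["active"]], lam - 1e-15)
      expect_lte(d[["inactive"]], lam + 1e-15)
    }
  }
})

test_that("logistic risk function evaluates and stays inside (0, 1)", {
  coeffs <- list(chd = list(male = list(
    intercept = -3, age = c("35-44" = 0),
    levels = c("smoking=yes" = 0.5))))
  s_smoker <- list(smoking = "yes")
  expect_equal(annual_risk(s_smoker, "male", "35-44", coeffs, "chd"),
               plogis(-2.5))
  expect_equal(plogis(-2.5), 0.0759, tolerance = 1e-3)
  # all-zero coefficients give probability one half
  c0 <- list(chd = list(male = list(intercept = 0, age = c("35-44" = 0),
                                    levels = c())))
  expect_equal(annual_risk(list(smoking = "no"), "male", "35-44", c0, "chd"),
               0.5)
  # logistic limit toward zero with a very negative intercept
  cneg <- list(chd = list(male = list(intercept = -40, age = c("35-44" = 0),
                                      levels = c())))
  expect_lt(annual_risk(list(), "male", "35-44", cneg, "chd"), 1e-15)
  # bounded for wild but finite coefficients
  set.seed(3)
  for (k in 1:50) {
    cf <- list(chd = list(male = list(intercept = rnorm(1, 0, 10),
                                      age = c("35-44" = rnorm(1, 0, 5)),
                                      levels = c("smoking=yes" = rnorm(1, 0, 5)))))
    p <- annual_risk(s_smoker, "male", "35-44", cf, "chd")
    expect_true(p > 0 && p < 1)
  }
  expect_error(annual_risk(list(), "female", "35-44", coeffs, "chd"),
               "no coefficients")
})

test_that("rate/probability conversions are exact inverses", {
  r <- c(0, 0.01, 0.2, 1.5)
  expect_equal(prob_to_rate(rate_to_prob(r)), r)
  expect_error(rate_to_prob(-1), "non-negative")
  expect_error(prob_to_rate(1), "\\[0, 1\\)")
})
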