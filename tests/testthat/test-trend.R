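fixed_trend <- function() {
  # five survey waves on a rising logit-linear path with small wiggles
  trend_data(c(1993, 1998, 2003, 2008, 2014),
             c(0.42, 0.50, 0.61, 0.68, 0.78))
}

test_that("logit transforms round-trip and hit known values", {
  expect_equal(logit(0.5), 0)
  expect_equal(logit(0.8), log(4), tolerance = 1e-12)
  expect_equal(inv_logit(logit(0.849)), 0.849, tolerance = 1e-12)
  expect_error(logit(0), "strictly inside")
  expect_error(logit(1.2), "strictly inside")
  expect_equal(adjust_boundary(c(0, 0.3, 1), c(99, 99, 99)),
               c(0.005, 0.3, 0.995))
})

test_that("exact-line data recover slope and intercept with floored variance", {
  td <- trend_data(2000 + 0:3, inv_logit(c(-1, -0.5, 0, 0.5)))
  expect_warning(fit <- fit_trend_conjugate(td, n_draws = 500, seed = 4),
                 "near-zero residual")
  expect_equal(mean(fit$draws$beta), 0.5, tolerance = 1e-2)
  expect_equal(mean(fit$draws$alpha), -1, tolerance = 1e-2)

  flat <- trend_data(2000 + 0:4, rep(0.37, 5) + c(0, 1e-6, -1e-6, 0, 0))
  fit2 <- suppressWarnings(fit_trend_conjugate(flat, n_draws = 500, seed = 4))
  expect_lt(abs(mean(fit2$draws$beta)), 1e-4)
})

test_that("conjugate posterior centres on the least-squares solution", {
  td <- fixed_trend()
  fit <- fit_trend_conjugate(td, n_draws = 8000, seed = 10)
  ls <- stats::lm(td$y ~ I(td$year - min(td$year)))
  expect_equal(mean(fit$draws$alpha), unname(stats::coef(ls)[1]),
               tolerance = 0.02)
  expect_equal(mean(fit$draws$beta), unname(stats::coef(ls)[2]),
               tolerance = 0.005)
  # sigma2 posterior mean: scaled-inv-chi2 with n-2 = 3 df around s2
  s2 <- sum(stats::resid(ls)^2) / 3
  expect_lt(abs(mean(fit$draws$sigma2) - 3 * s2), 2 * s2)
})

test_that("the Gibbs sampler is deterministic and matches the oracle", {
  td <- fixed_trend()
  f1 <- fit_trend_mcmc(td, seed = 3)
  f2 <- fit_trend_mcmc(td, seed = 3)
  expect_identical(f1$draws, f2$draws)
  expect_false(identical(f1$draws, fit_trend_mcmc(td, seed = 4)$draws))
  expect_true(f1$converged)
  expect_lte(max(psrf(f1)), 1.02)

  fc <- fit_trend_conjugate(td, n_draws = 4000, seed = 5)
  for (par in c("alpha", "beta")) {
    mc <- f1$draws[[par]]; or <- fc$draws[[par]]
    se <- sqrt(stats::var(mc) / length(mc) + stats::var(or) / length(or))
    expect_lt(abs(mean(mc) - mean(or)), 3 * se)
  }
})

test_that("overdispersed chain starts still converge on clean data", {
  td <- fixed_trend()
  fit <- fit_trend_mcmc(td, seed = 6, burn_in = 2000)
  expect_true(fit$converged)
  expect_true(all(psrf(fit) <= 1.02))
  expect_equal(nrow(fit$draws), 1000L)
  expect_equal(length(unique(fit$draws$chain)), 2L)
})

test_that("PSRF follows its closed form and detects gross nonconvergence", {
  withr::with_seed(14, x <- stats::rnorm(1000))
  expect_equal(psrf(cbind(x, x)), sqrt(999 / 1000), tolerance = 1e-12)
  expect_gt(psrf(cbind(x, x + 100)), 1.02)
  withr::with_seed(15, {
    y <- matrix(stats::rnorm(10000), ncol = 2)
  })
  v <- psrf(y)
  expect_gt(v, 0.99)
  expect_lt(v, 1.02)
  expect_equal(psrf(cbind(rep(1, 10), rep(1, 10))), 1)
})

test_that("DIC deviance is additive in the data", {
  d <- delta_draws(alpha = -0.2, beta = 0.05, t0 = 2000, sigma2 = 0.04)
  base <- dic(d)
  d2 <- d
  d2$X <- rbind(d$X, d$X)
  d2$y <- c(d$y, d$y)
  expect_equal(dic(d2)$Dbar, 2 * base$Dbar, tolerance = 1e-9)
  expect_equal(base$pD, 0, tolerance = 1e-9)   # delta posterior: no spread
})

test_that("projections, probabilities and rates behave on delta posteriors", {
  d0 <- delta_draws(alpha = 0, beta = 0, t0 = 2000)
  pr <- project(d0, c(2010, 2030))
  expect_equal(pr$mean, c(50, 50))
  expect_equal(pr$ci_lo, pr$ci_hi)
  expect_equal(prob_target_coverage(d0, 2030, target = 0), 1)
  expect_equal(annual_rate_of_change(d0, 1995, 2030)$rate_mean, 0)

  up <- delta_draws(alpha = -1, beta = 0.08, t0 = 2000)
  pru <- project(up, 2000:2035)
  expect_true(all(diff(pru$mean) > 0))
  expect_true(all(pru$mean > 0 & pru$mean < 100))
})

test_that("the endpoint geometric rate matches the vaccination trajectory", {
  # degenerate posterior passing through 84.9% in 1995 and 99.2% in 2030
  beta <- (logit(0.992) - logit(0.849)) / 35
  d <- delta_draws(alpha = logit(0.849), beta = beta, t0 = 1995)
  r <- annual_rate_of_change(d, 1995, 2030)
  expect_equal(r$rate_mean, 100 * ((0.992 / 0.849)^(1 / 35) - 1),
               tolerance = 1e-9)
  expect_lt(abs(r$rate_mean - 0.45), 0.005)
})

test_that("target probabilities count draws above the threshold", {
  d <- delta_draws(alpha = 0, beta = 0, t0 = 2000, n = 4L)
  d$draws$alpha <- logit(c(0.9, 0.9, 0.7, 0.7))
  expect_equal(prob_target_coverage(d, 2030, 0.8), 0.5)
  d$draws$alpha <- rep(logit(0.95), 4)
  expect_equal(prob_target_coverage(d, 2030, 0.8), 1)

  h <- delta_draws(alpha = logit(0.002), beta = 0, t0 = 2000, n = 3L)
  expect_equal(prob_financial_protection(h, 2030), 1)
  h$draws$alpha <- rep(logit(0.05), 3)
  expect_equal(prob_financial_protection(h, 2030), 0)
  expect_equal(prob_financial_protection(h, 2030, epsilon = 1), 1)
})

test_that("projection intervals widen with extrapolation distance", {
  fit <- fit_trend_conjugate(fixed_trend(), n_draws = 4000, seed = 30)
  pr <- project(fit, c(2015, 2020, 2025, 2030))
  # width on the logit scale grows monotonically away from the data
  w <- logit(pr$ci_hi / 100) - logit(pr$ci_lo / 100)
  expect_true(all(diff(w) > 0))
})

test_that("grouped fits recover null group effects and nest the simple model", {
  yrs <- c(1995, 2000, 2005, 2010, 2015)
  withr::with_seed(40, {
    y <- inv_logit(-0.5 + 0.06 * (rep(yrs, 2) - 1995) +
                     stats::rnorm(10, 0, 0.08))
  })
  td <- trend_data(rep(yrs, 2), y, group = rep(c("A", "B"), each = 5))
  fit <- fit_grouped_trend(td, method = "conjugate", retained = 4000, seed = 41)
  off <- fit$draws$g_B
  expect_lt(abs(mean(off)), 2 * stats::sd(off))

  # single group: identical design, identical posterior
  td1 <- trend_data(yrs, y[1:5], group = rep("A", 5))
  f_grp <- fit_grouped_trend(td1, method = "conjugate", retained = 500, seed = 42)
  f_plain <- fit_trend_conjugate(trend_data(yrs, y[1:5]), n_draws = 500,
                                 seed = 42)
  expect_equal(f_grp$draws$alpha, f_plain$draws$alpha)
  expect_equal(f_grp$draws$beta, f_plain$draws$beta)

  expect_error(fit_grouped_trend(trend_data(c(1995, 2000, 2005),
                                            c(0.5, 0.52, 0.54),
                                            group = c("A", "A", "B")),
                                 method = "conjugate"),
               "single observation")
})

test_that("DIC model selection reports both candidates", {
  yrs <- c(1995, 2000, 2005, 2010, 2015)
  withr::with_seed(44, {
    y <- inv_logit(-0.5 + 0.05 * (rep(yrs, 2) - 1995) +
                     rep(c(0, 0.4), each = 5) + stats::rnorm(10, 0, 0.1))
  })
  td <- trend_data(rep(yrs, 2), y, group = rep(c("A", "B"), each = 5))
  sel <- select_model_by_dic(td, method = "conjugate", retained = 1000,
                             seed = 45)
  expect_named(sel$dic, c("no_interaction", "interaction"))
  expect_true(all(is.finite(sel$dic)))
  expect_s3_class(sel$model, "uhc_draws")
  expect_identical(sel$interaction, unname(sel$dic["interaction"] <
                                             sel$dic["no_interaction"]))
})
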