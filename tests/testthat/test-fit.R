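test_that("link transforms are bijective to high precision", {
  for (v in c(1e-3, 0.7, 250, 9000)) {
    for (nm in c("mu", "sigma", "sigma_w"))
      expect_equal(intervalmix:::from_link(intervalmix:::to_link(v, nm), nm), v,
                   tolerance = 1e-10)
  }
  for (v in c(1e-4, 0.05, 0.5, 0.93)) {
    for (nm in c("p", "f"))
      expect_equal(intervalmix:::from_link(intervalmix:::to_link(v, nm), nm), v,
                   tolerance = 1e-10)
  }
})

test_that("fitting data without thinning drives the missed-event estimate to zero", {
  set.seed(5)
  x <- rgamma(2000, shape = 25, scale = 10)
  fit <- fit_intervals(x, spec = interval_spec())
  expect_true(fit$converged)
  expect_lt(fit$params$p, 0.02)
})

test_that("large-sample fit recovers the generating parameters", {
  dat <- scenario_data(n = 10000, seed = 55)
  fit <- fit_intervals(dat$interval, spec = interval_spec(trunc = 900))
  expect_true(fit$converged)
  expect_equal(fit$params$mu, 250, tolerance = 0.02)
  expect_equal(fit$params$sigma, 50, tolerance = 0.05)
  expect_lt(abs(fit$params$p - 0.3), 0.03)
  expect_equal(fit$n_param, 3)
  expect_equal(fit$n_obs, 10000)
})

test_that("fixed parameters are held and reduce the free count", {
  dat <- scenario_data(n = 300, seed = 9)
  fit <- fit_intervals(dat$interval,
                       spec = interval_spec(trunc = 900,
                                            fixed = list(p = 0.3, f = 0)))
  expect_identical(fit$params$p, 0.3)
  expect_equal(fit$n_param, 2)
})

test_that("time rescaling rescales scale parameters and leaves p unchanged", {
  dat <- scenario_data(n = 400, seed = 21)
  k <- 60
  f1 <- fit_intervals(dat$interval, spec = interval_spec(trunc = 900))
  f2 <- fit_intervals(dat$interval * k, spec = interval_spec(trunc = 900 * k))
  expect_equal(f2$params$mu / f1$params$mu, k, tolerance = 1e-3)
  expect_equal(f2$params$sigma / f1$params$sigma, k, tolerance = 1e-3)
  expect_equal(f2$params$p, f1$params$p, tolerance = 1e-3)
})

test_that("standard errors are returned on request and are positive", {
  dat <- scenario_data(n = 500, seed = 31)
  fit <- fit_intervals(dat$interval, spec = interval_spec(trunc = 900),
                       se = TRUE)
  expect_named(fit$se, fit$spec$free)
  expect_true(all(fit$se > 0))
  # rough sanity: mu's SE at n = 500 should be a few seconds
  expect_lt(fit$se[["mu"]], 30)
})

test_that("degenerate or invalid data are rejected", {
  expect_error(fit_intervals(rep(100, 50)), "degenerate")
  expect_error(fit_intervals(c(100)), "at least 2")
  expect_error(fit_intervals(c(100, -5, 200)), "positive")
  expect_error(fit_intervals(c(100, 950), spec = interval_spec(trunc = 900)),
               "trunc")
})

test_that("deviance test follows the chi-squared convention", {
  f1 <- make_fit(250, 50, p = 0.3, loglik = -500,
                 spec = interval_spec(trunc = 900))
  f0 <- make_fit(280, 70, loglik = -500,
                 spec = interval_spec(trunc = 900, fixed = list(p = 0, f = 0)))
  # identical likelihoods: deviance 0, p-value 1
  d0 <- deviance_test(f1, f0)
  expect_equal(d0$deviance, 0)
  expect_equal(d0$p_value, 1)
  expect_equal(d0$df, 1)
  # deviance 3.84 at df 1 sits at the 5% point
  f1b <- make_fit(250, 50, p = 0.3, loglik = -500 + 3.84 / 2,
                  spec = interval_spec(trunc = 900))
  expect_equal(deviance_test(f1b, f0)$p_value, 0.05, tolerance = 0.002)
  # non-nested and negative-deviance errors
  expect_error(deviance_test(f0, f1), "nested")
  f_worse <- make_fit(250, 50, p = 0.3, loglik = -505,
                      spec = interval_spec(trunc = 900))
  expect_error(deviance_test(f_worse, f0), "refit")
  f0b <- make_fit(280, 70, loglik = -500, n_obs = 80,
                  spec = interval_spec(trunc = 900, fixed = list(p = 0, f = 0)))
  expect_error(deviance_test(f1, f0b), "different numbers")
})

test_that("observer-effect test has power at moderate thinning", {
  # at p = 0.3 and n = 500 the likelihood-ratio test should reject the
  # no-missed-events model at alpha = 0.001 in essentially every run
  n_rej <- 0L
  for (k in 1:20) {
    dat <- scenario_data(n = 500, seed = 4000 + k)
    full <- fit_intervals(dat$interval, spec = interval_spec(trunc = 900))
    red <- fit_intervals(dat$interval,
                         spec = interval_spec(trunc = 900,
                                              fixed = list(p = 0, f = 0)))
    dt <- deviance_test(full, red)
    expect_gte(dt$deviance, 0) # freeing p can never fit worse
    if (dt$p_value < 0.001) n_rej <- n_rej + 1L
  }
  expect_gte(n_rej, 19)
})

test_that("AIC table ranks models and is pure arithmetic", {
  f2 <- make_fit(250, 50, loglik = -500,
                 spec = interval_spec(fixed = list(p = 0, f = 0)))
  f3 <- make_fit(250, 50, p = 0.3, loglik = -500, spec = interval_spec())
  tab <- aic_table(reduced = f2, full = f3)
  expect_equal(tab$dAIC[tab$model == "full"], 2)
  expect_equal(tab$dAIC[tab$model == "reduced"], 0)
  # one model: dAIC 0
  expect_equal(aic_table(f2)$dAIC, 0)
  # raising loglik by 7 at the cost of one parameter lowers AIC by 12
  f3b <- make_fit(250, 50, p = 0.3, loglik = -493, spec = interval_spec())
  tab2 <- aic_table(f2, f3b)
  expect_equal(diff(range(tab2$AIC)), 12)
  f_other <- make_fit(250, 50, loglik = -400, n_obs = 60,
                      spec = interval_spec(fixed = list(p = 0, f = 0)))
  expect_error(aic_table(f2, f_other), "different numbers")
})

test_that("iterative within-subject fit recovers sigma_w ~ sigma when subjects are identical", {
  # sigma_w = sigma means no between-subject spread
  dat <- scenario_data(n = 200, seed = 61, sigma_w = 50)
  fw <- fit_intervals_within(dat$interval, dat$subject,
                             spec = interval_spec(trunc = 900))
  expect_true(fw$converged)
  expect_gt(fw$params$sigma_w / fw$params$sigma, 0.8)
  expect_true(is.finite(fw$partition$s_w))
})

test_that("within-subject fit demands repeated measures", {
  expect_error(
    fit_intervals_within(c(100, 200, 300), c("a", "b", "c"),
                         spec = interval_spec()),
    "unidentifiable")
  dat <- scenario_data(n = 200, seed = 62, sigma_w = 40)
  expect_error(fit_intervals_within(dat$interval, NULL), "required")
})
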