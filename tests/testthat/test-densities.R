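test_that("gamma mean/SD parameterization maps to shape and scale", {
  # mu = 250, sigma = 50 corresponds to shape 25, scale 10
  x <- c(100, 250, 420)
  expect_equal(dgamma_musigma(x, 250, 50), dgamma(x, shape = 25, scale = 10))
  # round-trip: shape*scale = mu, sqrt(shape)*scale = sigma
  shape <- 250^2 / 50^2; scale <- 50^2 / 250
  expect_equal(shape * scale, 250)
  expect_equal(sqrt(shape) * scale, 50)
  # exponential limit when sigma = mu: density -> 1/mu at the origin
  expect_equal(dgamma_musigma(1e-9, 100, 100), 0.01, tolerance = 1e-6)
  # proper density (quadrature oracle)
  expect_equal(integrate(dgamma_musigma, 0, Inf, mu = 200, sigma = 40,
                         rel.tol = 1e-9)$value, 1, tolerance = 1e-6)
  expect_error(dgamma_musigma(1, -1, 10), "mu")
  expect_error(dgamma_musigma(1, 10, 0), "sigma")
})

test_that("normal component family matches closed form and the high-shape gamma limit", {
  expect_equal(dnorm_musigma(200, 200, 40), 1 / (40 * sqrt(2 * pi)))
  d <- 13.7
  expect_equal(dnorm_musigma(200 - d, 200, 40), dnorm_musigma(200 + d, 200, 40))
  # gamma with shape 1e6 (sigma = mu/1000) agrees with the normal at x = mu
  mu <- 300; sigma <- mu / 1000
  expect_equal(dgamma_musigma(mu, mu, sigma) / dnorm_musigma(mu, mu, sigma), 1,
               tolerance = 1e-4)
})

test_that("mixing weights follow the geometric missed-event law", {
  expect_equal(as.numeric(mixture_weights(0, 4)), c(1, 0, 0, 0, 0))
  expect_equal(as.numeric(mixture_weights(0.5, 2, renormalize = FALSE)),
               c(0.5, 0.25, 0.125))
  # renormalized weights sum to one; raw partial sum is 1 - p^(i_max+1)
  for (p in c(0.1, 0.3, 0.6, 0.9)) {
    expect_equal(sum(mixture_weights(p, 5)), 1)
    expect_equal(sum(mixture_weights(p, 5, renormalize = FALSE)), 1 - p^6)
    # partial sums approach 1 as the cap grows (full series sums to one)
    expect_equal(sum(mixture_weights(p, 200, renormalize = FALSE)), 1,
                 tolerance = 1e-9)
  }
  # strict monotone decay for p < 0.5
  for (p in c(0.05, 0.2, 0.45)) {
    w <- mixture_weights(p, 5)
    expect_true(all(diff(w) < 0))
  }
  expect_error(mixture_weights(1, 5), "p")
  expect_error(mixture_weights(-0.1, 5), "p")
})

test_that("observed pdf collapses to a single gamma when p = 0 and f = 0", {
  x <- seq(5, 800, by = 7)
  expect_equal(dinterval(x, 250, 50), dgamma_musigma(x, 250, 50))
})

test_that("within/between form equals the pooled form when sigma_w = sigma", {
  x <- seq(10, 1500, by = 13)
  expect_equal(dinterval(x, 250, 50, p = 0.3, sigma_w = 50),
               dinterval(x, 250, 50, p = 0.3))
  # and with truncation and background
  expect_equal(
    dinterval(x, 250, 50, p = 0.3, f = 0.1, sigma_w = 50, trunc = 900),
    dinterval(x, 250, 50, p = 0.3, f = 0.1, trunc = 900))
})

test_that("observed pdf integrates to one across random parameter draws", {
  set.seed(42)
  for (k in 1:8) {
    mu <- runif(1, 50, 500)
    sigma <- runif(1, 0.1 * mu, mu)
    p <- runif(1, 0, 0.6)
    bg <- runif(1, 0, 0.3)
    sw <- if (k %% 2 == 0) runif(1, 0.2 * sigma, sigma) else NULL
    # untruncated, renormalized weights
    int1 <- integrate(function(t)
      dinterval(t, mu, sigma, p = p, f = bg, sigma_w = sw),
      0, Inf, rel.tol = 1e-8, abs.tol = 1e-10)$value
    expect_equal(int1, 1, tolerance = 1e-4)
    # truncated at 4*mu/(1-p): renormalized on (0, trunc]
    tr <- 4 * mu / (1 - p)
    int2 <- integrate(function(t)
      dinterval(t, mu, sigma, p = p, f = bg, sigma_w = sw, trunc = tr),
      0, tr, rel.tol = 1e-8, abs.tol = 1e-10)$value
    expect_equal(int2, 1, tolerance = 1e-4)
  }
})

test_that("normal-family mixture renormalizes on (0, trunc] when truncated", {
  int <- integrate(dinterval, 0, 900, mu = 250, sigma = 80, p = 0.4,
                   family = "normal", trunc = 900, rel.tol = 1e-8)$value
  expect_equal(int, 1, tolerance = 1e-4)
  expect_identical(dinterval(1000, 250, 80, p = 0.4, family = "normal",
                             trunc = 900), 0)
})

test_that("untruncated observed mean equals mu/(1-p)", {
  # geometric-series closed form checked by quadrature; a large cap makes the
  # renormalized capped series indistinguishable from the full one
  set.seed(7)
  cases <- rbind(c(250, 50, 0.3), c(100, 30, 0.5), c(400, 120, 0.1),
                 c(60, 40, 0.45), c(320, 60, 0.2))
  for (r in seq_len(nrow(cases))) {
    mu <- cases[r, 1]; sigma <- cases[r, 2]; p <- cases[r, 3]
    m <- integrate(function(x) x * dinterval(x, mu, sigma, p = p, i_max = 80),
                   0, Inf, rel.tol = 1e-9, abs.tol = 1e-10)$value
    expect_equal(m, mu / (1 - p), tolerance = 1e-4)
  }
})

test_that("truncation zeroes the density beyond the bound", {
  expect_identical(dinterval(c(901, 1500), 250, 50, p = 0.3, trunc = 900),
                   c(0, 0))
  expect_gt(dinterval(899, 250, 50, p = 0.3, trunc = 900), 0)
})

test_that("component areas follow (1 - f) * pi_i", {
  # at mu = 200, sigma = 40, p = 0.5, f = 0.2 the fundamental component holds
  # (1 - 0.2) * (0.5 - 0.25) ... component 0 area = 0.8 * 0.5 = 0.4
  a0 <- integrate(function(x)
    0.8 * partial_likelihoods(x, 200, 40, p = 0.5, renormalize = FALSE)[, 1],
    0, Inf, rel.tol = 1e-8)$value
  expect_equal(a0, 0.4, tolerance = 1e-6)
})

test_that("log-likelihood sums per-point log densities", {
  expect_equal(loglik_intervals(333, 250, 50, p = 0.3),
               log(dinterval(333, 250, 50, p = 0.3)))
  set.seed(11)
  x <- rgamma(50, 25, scale = 10)
  # independent loop oracle
  brute <- 0
  for (xi in x) brute <- brute + log(dinterval(xi, 250, 50, p = 0.3, f = 0.1,
                                               trunc = 900))
  expect_equal(loglik_intervals(x, 250, 50, p = 0.3, f = 0.1, trunc = 900),
               brute)
  # additivity: duplicating the data doubles the log-likelihood
  expect_equal(loglik_intervals(c(x, x), 250, 50, p = 0.3),
               2 * loglik_intervals(x, 250, 50, p = 0.3))
})

test_that("log-likelihood error and -Inf conventions", {
  expect_error(loglik_intervals(numeric(0), 250, 50), "no interval")
  expect_error(loglik_intervals(c(100, -3), 250, 50), "positive")
  expect_error(loglik_intervals(c(100, 950), 250, 50, trunc = 900), "trunc")
  # underflowing density reported as -Inf, not an error
  expect_identical(loglik_intervals(1e-300, 250, 50), -Inf)
})

test_that("model specification validates its structure", {
  s <- interval_spec(trunc = 900)
  expect_setequal(s$free, c("mu", "sigma", "p"))
  expect_equal(s$fixed$f, 0)
  s2 <- interval_spec(fixed = list(p = 0.2, f = 0))
  expect_setequal(s2$free, c("mu", "sigma"))
  expect_error(interval_spec(free = c("mu", "sigma"), fixed = list(f = 0)),
               "free or fixed")
  expect_error(interval_spec(fixed = list(p = 0.2, f = 0),
                             free = c("mu", "sigma", "p")), "both free and fixed")
  expect_error(interval_spec(i_max = 0), "i_max")
  expect_error(interval_spec(fundamental_threshold = 0.4), "threshold")
  expect_error(interval_spec(fixed = list(p = 1.2, f = 0)), "p")
})
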