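# Construct an interval_fit from known parameter values, for operations that
# only consume the estimates (comparison, rate conversion, classification).
make_fit <- function(mu, sigma, p = 0, f = 0, sigma_w = NULL, n_obs = 100,
                     loglik = -500, spec = NULL, x = NULL, subject = NULL) {
  if (is.null(spec)) {
    fixed <- list(f = f)
    if (p == 0) fixed$p <- 0
    spec <- interval_spec(fixed = fixed)
  }
  structure(list(params = list(mu = mu, sigma = sigma, p = p, f = f,
                               sigma_w = sigma_w),
                 loglik = loglik, n_param = length(spec$free),
                 n_obs = n_obs, converged = TRUE, spec = spec,
                 se = NULL, x = x, subject = subject, optim = NULL),
            class = "interval_fit")
}

# One simulated run of the base recovery scenario (mean 250 s, SD 50 s,
# missed-event probability 0.3, 900 s bouts).
scenario_data <- function(n = 100, seed = 1, sigma_w = NULL, p = 0.3) {
  cfg <- sim_config(sigma_w = sigma_w, p = p, n_intervals = n,
                    n_runs = 1, seed = seed)
  set.seed(cfg$seed + 1)
  simulate_observed_intervals(cfg)
}

# sample with exact first two moments, for textbook-test oracles
exact_moments <- function(n, mean, sd, seed) {
  set.seed(seed)
  z <- stats::rnorm(n)
  z <- (z - mean(z)) / stats::sd(z)
  mean + sd * z
}
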