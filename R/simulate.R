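#' Define a simulation scenario for a recovery study
#'
#' Collects the true parameter values and design of a Bernoulli-thinned
#' arrival-process simulation: gamma inter-arrival times (optionally with a
#' between-subject spread of subject means), a per-arrival missed-detection
#' probability, and discarding of observed intervals longer than the
#' observation bout.
#'
#' @param mu true mean fundamental interval (seconds).
#' @param sigma true total interval SD (seconds).
#' @param sigma_w true within-subject SD (seconds), or `NULL` for a single
#'   pooled process (no subject structure).
#' @param p per-arrival missed-detection probability, in `[0, 1)`.
#' @param f random background fraction of arrivals (default 0); when
#'   positive, each true interval is drawn from the exponential-limit
#'   construction with probability `f`.
#' @param n_intervals observed intervals collected per run (default 100).
#' @param n_subjects number of subjects when `sigma_w` is set (default 10).
#' @param bout_length observation bout length in seconds (default 900);
#'   observed intervals longer than this are discarded, and the fitted model
#'   should be truncated at the same bound.
#' @param n_runs number of simulation runs (default 1000).
#' @param seed root seed; run `k` uses seed `seed + k` so any run is
#'   reproducible in isolation.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(mu = 250, sigma = 50, sigma_w = NULL, p = 0.3, f = 0,
                       n_intervals = 100L, n_subjects = 10L,
                       bout_length = 900, n_runs = 1000L, seed = 1L) {
  check_params(mu, sigma, p, f, sigma_w)
  if (!is.numeric(n_intervals) || n_intervals < 10)
    stop("`n_intervals` must be at least 10", call. = FALSE)
  if (!is.numeric(bout_length) || bout_length <= mu)
    stop("`bout_length` must exceed `mu`", call. = FALSE)
  if (!is.null(sigma_w)) {
    if (n_subjects < 2) stop("need at least 2 subjects", call. = FALSE)
    if (n_intervals %% n_subjects != 0)
      stop("`n_intervals` must be a multiple of `n_subjects`", call. = FALSE)
  }
  structure(list(mu = mu, sigma = sigma, sigma_w = sigma_w, p = p, f = f,
                 n_intervals = as.integer(n_intervals),
                 n_subjects = as.integer(n_subjects),
                 per_subject = if (is.null(sigma_w)) NULL
                               else as.integer(n_intervals / n_subjects),
                 bout_length = bout_length, n_runs = as.integer(n_runs),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate true (fully observed) inter-arrival intervals
#'
#' Without subject structure, draws i.i.d. gamma intervals with mean `mu` and
#' SD `sigma`. With subject structure, each subject's mean is drawn from a
#' normal with mean `mu` and SD `sqrt(sigma^2 - sigma_w^2)` (redrawn if not
#' positive), and that subject's intervals are gamma with the subject mean
#' and SD `sigma_w`, composing the total variance `sigma^2`.
#'
#' @param n number of intervals (without subjects) or intervals per subject
#'   (with subjects).
#' @param mu,sigma,sigma_w true values as in [sim_config()].
#' @param n_subjects number of subjects when `sigma_w` is set.
#' @param f background fraction: each interval is replaced by a draw from the
#'   exponential-limit gamma (SD `mu`) with probability `f`.
#' @return A data frame with columns `interval` and `subject`.
#' @export
simulate_true_intervals <- function(n, mu, sigma, sigma_w = NULL,
                                    n_subjects = 10L, f = 0) {
  check_params(mu, sigma, p = 0, f = f, sigma_w = sigma_w)
  draw <- function(k, m, s) {
    x <- stats::rgamma(k, shape = m^2 / s^2, scale = s^2 / m)
    if (f > 0) {
      bg <- stats::runif(k) < f
      x[bg] <- stats::rgamma(sum(bg), shape = 1, scale = mu)
    }
    x
  }
  if (is.null(sigma_w)) {
    return(data.frame(interval = draw(n, mu, sigma), subject = "s1"))
  }
  sigma_b <- sqrt(sigma^2 - sigma_w^2)
  out <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    m_s <- if (sigma_b == 0) mu else {
      v <- stats::rnorm(1, mu, sigma_b)
      while (v <= 0) v <- stats::rnorm(1, mu, sigma_b)
      v
    }
    out[[s]] <- data.frame(interval = draw(n, m_s, sigma_w),
                           subject = sprintf("s%d", s))
  }
  do.call(rbind, out)
}

#' Thin a sequence of arrivals by Bernoulli missed detections
#'
#' Given cumulative arrival times of one observation series, marks each
#' interior arrival as missed independently with probability `p` (the first
#' and last arrivals bracket the series and are treated as detected) and
#' returns the intervals between consecutive detected arrivals. An interval
#' spanning `i` missed arrivals is the sum of `i + 1` true intervals.
#'
#' @param arrival_times sorted vector of arrival times (seconds).
#' @param p per-arrival missed-detection probability, in `[0, 1)`.
#' @return Numeric vector of observed intervals with attribute `"n_missed"`
#'   giving the number of missed arrivals inside each observed interval.
#' @export
thin_arrivals <- function(arrival_times, p) {
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p >= 1)
    stop("`p` must lie in [0, 1)", call. = FALSE)
  n <- length(arrival_times)
  if (n < 2L) return(structure(numeric(0), n_missed = integer(0)))
  if (is.unsorted(arrival_times))
    stop("`arrival_times` must be sorted", call. = FALSE)
  detected <- rep(TRUE, n)
  if (n > 2L && p > 0)
    detected[2:(n - 1L)] <- stats::runif(n - 2L) >= p
  idx <- which(detected)
  structure(diff(arrival_times[idx]), n_missed = diff(idx) - 1L)
}

# Observed intervals for one subject: generate arrival batches, thin, and
# discard intervals longer than the bout, until `n_obs` intervals collected.
observe_subject <- function(n_obs, mu_s, sigma_s, p, bout_length, f, mu_pop) {
  out <- numeric(0)
  missed <- integer(0)
  while (length(out) < n_obs) {
    k <- max(50L, ceiling(2 * n_obs / (1 - p)))
    x <- stats::rgamma(k, shape = mu_s^2 / sigma_s^2, scale = sigma_s^2 / mu_s)
    if (f > 0) {
      bg <- stats::runif(k) < f
      x[bg] <- stats::rgamma(sum(bg), shape = 1, scale = mu_pop)
    }
    obs <- thin_arrivals(cumsum(x), p)
    keep <- obs <= bout_length
    out <- c(out, obs[keep])
    missed <- c(missed, attr(obs, "n_missed")[keep])
  }
  structure(out[seq_len(n_obs)], n_missed = missed[seq_len(n_obs)])
}

#' Simulate one run of observed intervals under missed detections
#'
#' Generates true gamma arrival series per [simulate_true_intervals()],
#' thins interior arrivals with probability `p` via [thin_arrivals()], and
#' discards observed intervals exceeding `bout_length` (the observer never
#' watches one individual longer than a bout), collecting exactly
#' `n_intervals` observed intervals.
#'
#' @param config a [sim_config()].
#' @return A data frame with columns `interval`, `subject` and `n_missed`.
#' @export
simulate_observed_intervals <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("`config` must be a sim_config", call. = FALSE)
  if (is.null(config$sigma_w)) {
    obs <- observe_subject(config$n_intervals, config$mu, config$sigma,
                           config$p, config$bout_length, config$f, config$mu)
    return(data.frame(interval = as.numeric(obs), subject = "s1",
                      n_missed = attr(obs, "n_missed")))
  }
  sigma_b <- sqrt(config$sigma^2 - config$sigma_w^2)
  out <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    m_s <- if (sigma_b == 0) config$mu else {
      v <- stats::rnorm(1, config$mu, sigma_b)
      while (v <= 0) v <- stats::rnorm(1, config$mu, sigma_b)
      v
    }
    obs <- observe_subject(config$per_subject, m_s, config$sigma_w,
                           config$p, config$bout_length, config$f, config$mu)
    out[[s]] <- data.frame(interval = as.numeric(obs),
                           subject = sprintf("s%d", s),
                           n_missed = attr(obs, "n_missed"))
  }
  do.call(rbind, out)
}

# uncorrected subject-centered SD, same estimator as estimate_sigma_w but on
# all observed intervals
uncorrected_sigma_w <- function(interval, subject) {
  counts <- table(subject)
  keep <- names(counts)[counts >= 2L]
  sel <- subject %in% keep
  centered <- interval[sel] - stats::ave(interval[sel], subject[sel])
  s_w <- sqrt(mean(centered^2))
  n_ind <- sum(sel) / length(keep)
  s_w * sqrt(n_ind / (n_ind + 1))
}

#' Run a parameter-recovery simulation study
#'
#' For each run, simulates `n_intervals` observed intervals under the
#' scenario in `config`, records the uncorrected sample mean and SD, and fits
#' the matching observed-interval model (pooled when `sigma_w` is `NULL`,
#' otherwise the iterative within/between fit) truncated at the bout length.
#' Estimates are aggregated into means and SDs across runs. Runs whose fit
#' fails or does not converge are excluded and counted.
#'
#' @param config a [sim_config()].
#' @param lrt also run the observer-effect deviance test (`p` free vs 0) per
#'   run and report the rejection rate at `alpha`? Default `FALSE` (doubles
#'   the fitting cost).
#' @param alpha significance level for the rejection rate.
#' @return A list of class `"recovery_summary"`: `corrected` and
#'   `uncorrected` matrices of per-parameter means and SDs across runs,
#'   `estimates` (per-run corrected estimates), `n_runs`, `n_failed`,
#'   `rejection_rate` (when `lrt`), and `config`.
#' @export
run_recovery_study <- function(config, lrt = FALSE, alpha = 0.001) {
  if (!inherits(config, "sim_config"))
    stop("`config` must be a sim_config", call. = FALSE)
  within <- !is.null(config$sigma_w)
  cols <- c("mu", "sigma", if (within) "sigma_w", "p",
            "unc_mean", "unc_sd", if (within) "unc_sigma_w")
  est <- matrix(NA_real_, nrow = config$n_runs, ncol = length(cols),
                dimnames = list(NULL, cols))
  reject <- rep(NA, config$n_runs)
  n_failed <- 0L
  base_spec <- interval_spec(trunc = config$bout_length,
                             fixed = list(f = 0))
  for (k in seq_len(config$n_runs)) {
    set.seed(config$seed + k)
    dat <- simulate_observed_intervals(config)
    est[k, "unc_mean"] <- mean(dat$interval)
    est[k, "unc_sd"] <- stats::sd(dat$interval)
    if (within)
      est[k, "unc_sigma_w"] <- uncorrected_sigma_w(dat$interval, dat$subject)
    fit <- tryCatch({
      if (within) {
        fit_intervals_within(dat$interval, dat$subject, spec = base_spec)
      } else {
        fit_intervals(dat$interval, spec = base_spec)
      }
    }, error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      n_failed <- n_failed + 1L
      next
    }
    est[k, "mu"] <- fit$params$mu
    est[k, "sigma"] <- fit$params$sigma
    est[k, "p"] <- fit$params$p
    if (within) est[k, "sigma_w"] <- fit$params$sigma_w
    if (lrt) {
      red <- tryCatch(
        fit_intervals(dat$interval,
                      spec = interval_spec(trunc = config$bout_length,
                                           fixed = list(p = 0, f = 0))),
        error = function(e) NULL)
      if (!is.null(red) && red$converged)
        reject[k] <- deviance_test(fit, red)$p_value < alpha
    }
  }
  ok <- !is.na(est[, "mu"])
  summarize <- function(cols) {
    rbind(mean = colMeans(est[ok, cols, drop = FALSE]),
          sd = apply(est[ok, cols, drop = FALSE], 2, stats::sd))
  }
  structure(list(
    corrected = summarize(c("mu", "sigma", if (within) "sigma_w", "p")),
    uncorrected = summarize(c("unc_mean", "unc_sd", if (within) "unc_sigma_w")),
    estimates = est, n_runs = config$n_runs, n_failed = n_failed,
    rejection_rate = if (lrt) mean(reject, na.rm = TRUE) else NULL,
    config = config), class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("Parameter recovery over %d runs (%d excluded)\n",
              x$n_runs, x$n_failed))
  cat("Corrected (model) estimates, mean (SD) across runs:\n")
  for (nm in colnames(x$corrected))
    cat(sprintf("  %-8s %8.4g (%.3g)\n", nm,
                x$corrected["mean", nm], x$corrected["sd", nm]))
  cat("Uncorrected sample statistics, mean (SD) across runs:\n")
  for (nm in colnames(x$uncorrected))
    cat(sprintf("  %-12s %8.4g (%.3g)\n", nm,
                x$uncorrected["mean", nm], x$uncorrected["sd", nm]))
  if (!is.null(x$rejection_rate))
    cat(sprintf("LRT rejection rate for p: %.3f\n", x$rejection_rate))
  invisible(x)
}

#' Write a recovery summary to CSV
#'
#' One row per parameter with the across-run mean and SD of corrected and
#' (where applicable) uncorrected estimates.
#'
#' @param summary a `"recovery_summary"`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recovery_summary <- function(summary, path) {
  rows <- rbind(
    data.frame(kind = "corrected", param = colnames(summary$corrected),
               mean = summary$corrected["mean", ],
               sd = summary$corrected["sd", ]),
    data.frame(kind = "uncorrected", param = colnames(summary$uncorrected),
               mean = summary$uncorrected["mean", ],
               sd = summary$uncorrected["sd", ]))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
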