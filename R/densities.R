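#' Gamma density in mean/standard-deviation parameterization
#'
#' Density of the gamma distribution expressed through its mean \code{mu} and
#' standard deviation \code{sigma}, i.e. shape \code{mu^2/sigma^2} and scale
#' \code{sigma^2/mu}. When \code{sigma == mu} this is the exponential density
#' with mean \code{mu}; when \code{mu >> sigma} it approaches the normal
#' density with the same mean and SD.
#'
#' @param x vector of quantiles (seconds); the density is zero for `x <= 0`.
#' @param mu mean of the distribution, positive (seconds).
#' @param sigma standard deviation, positive (seconds).
#' @return Numeric vector of densities.
#' @examples
#' dgamma_musigma(250, mu = 250, sigma = 50)
#' @export
dgamma_musigma <- function(x, mu, sigma) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0)
    stop("`mu` must be a positive number", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("`sigma` must be a positive number", call. = FALSE)
  stats::dgamma(x, shape = mu^2 / sigma^2, scale = sigma^2 / mu)
}

#' Normal density in mean/standard-deviation parameterization
#'
#' Thin wrapper around [stats::dnorm()] used as the component family for
#' arrival processes where intervals vary symmetrically around the mean
#' (the large-shape limit of the gamma family). Mass on the negative half-line
#' is expected to be negligible when `mu >> sigma`.
#'
#' @inheritParams dgamma_musigma
#' @return Numeric vector of densities.
#' @export
dnorm_musigma <- function(x, mu, sigma) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0)
    stop("`mu` must be a positive number", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("`sigma` must be a positive number", call. = FALSE)
  stats::dnorm(x, mean = mu, sd = sigma)
}

#' Geometric mixing weights over missed-event counts
#'
#' Probability that an observed interval spans exactly `i` consecutively
#' missed arrivals, `pi_i = p^i - p^(i+1)`, for `i = 0 ... i_max`. The full
#' (infinite) series sums to one; the capped series sums to
#' `1 - p^(i_max + 1)` and is divided by that factor when
#' `renormalize = TRUE` so the capped mixture remains a proper density.
#'
#' @param p missed-event probability, in `[0, 1)`.
#' @param i_max largest missed-event count retained (cap of the series).
#' @param renormalize divide the capped weights by their sum?
#' @return Numeric vector of length `i_max + 1` with attribute
#'   `"renormalized"`.
#' @examples
#' mixture_weights(0.5, i_max = 2, renormalize = FALSE) # 0.5 0.25 0.125
#' @export
mixture_weights <- function(p, i_max = 5L, renormalize = TRUE) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 0 || p >= 1)
    stop("`p` must lie in [0, 1)", call. = FALSE)
  if (!is.numeric(i_max) || length(i_max) != 1L || i_max < 0 || i_max != round(i_max))
    stop("`i_max` must be a nonnegative integer", call. = FALSE)
  i <- 0:i_max
  w <- p^i - p^(i + 1)
  if (renormalize) w <- w / (1 - p^(i_max + 1))
  structure(w, renormalized = renormalize)
}

# SD of mixture component i: sqrt(i+1)*sigma when no within/between split,
# sqrt(i*sigma_w^2 + sigma^2) when sigma_w is given (uncertainty propagation
# over the i+1 summed intervals, only one of which carries between-subject
# spread).
component_sd <- function(i, sigma, sigma_w = NULL) {
  if (is.null(sigma_w)) sqrt(i + 1) * sigma else sqrt(i * sigma_w^2 + sigma^2)
}

family_pdf <- function(x, mean, sd, family) {
  if (family == "gamma") {
    stats::dgamma(x, shape = mean^2 / sd^2, scale = sd^2 / mean)
  } else {
    stats::dnorm(x, mean = mean, sd = sd)
  }
}

family_cdf <- function(q, mean, sd, family) {
  if (family == "gamma") {
    stats::pgamma(q, shape = mean^2 / sd^2, scale = sd^2 / mean)
  } else {
    stats::pnorm(q, mean = mean, sd = sd)
  }
}

# Unnormalized mixture density / cdf over missed-event components.
mixture_pdf_raw <- function(x, mu, sigma, p, sigma_w, family, i_max, renormalize) {
  w <- mixture_weights(p, i_max, renormalize)
  d <- numeric(length(x))
  for (i in 0:i_max) {
    d <- d + w[i + 1L] *
      family_pdf(x, (i + 1) * mu, component_sd(i, sigma, sigma_w), family)
  }
  d
}

mixture_cdf_raw <- function(q, mu, sigma, p, sigma_w, family, i_max, renormalize) {
  w <- mixture_weights(p, i_max, renormalize)
  d <- numeric(length(q))
  for (i in 0:i_max) {
    d <- d + w[i + 1L] *
      family_cdf(q, (i + 1) * mu, component_sd(i, sigma, sigma_w), family)
  }
  d
}

check_params <- function(mu, sigma, p, f, sigma_w) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0)
    stop("`mu` must be a positive number", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("`sigma` must be a positive number", call. = FALSE)
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 0 || p >= 1)
    stop("`p` must lie in [0, 1)", call. = FALSE)
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f < 0 || f > 1)
    stop("`f` must lie in [0, 1]", call. = FALSE)
  if (!is.null(sigma_w)) {
    if (!is.numeric(sigma_w) || length(sigma_w) != 1L || !is.finite(sigma_w) ||
        sigma_w < 0 || sigma_w > sigma)
      stop("`sigma_w` must lie in [0, sigma]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Density of observed inter-arrival intervals under missed detections
#'
#' The observed-interval density is a constrained mixture over the number of
#' consecutively missed arrivals `i = 0 ... i_max`: component `i` has mean
#' `(i+1)*mu`, SD `sqrt(i+1)*sigma` (or `sqrt(i*sigma_w^2 + sigma^2)` when the
#' within-subject SD `sigma_w` is supplied), and geometric weight
#' `pi_i = p^i - p^(i+1)`. A fraction `f` of arrivals may stem from a random
#' Poisson background; that fraction follows the same construction with
#' `sigma` replaced by `mu` (the exponential limit of the gamma family) and
#' shares the same `mu` and `p`, so the overall mean interval is unchanged.
#' When `trunc` is set (the observation bout length), the whole mixture is
#' renormalized by its own cumulative mass on `(0, trunc]` and the density is
#' zero beyond `trunc`.
#'
#' @inheritParams dgamma_musigma
#' @param p missed-event probability, in `[0, 1)`.
#' @param f random background fraction, in `[0, 1]`.
#' @param sigma_w within-subject SD (seconds), `NULL` to use the pooled form.
#' @param family component family, `"gamma"` (default) or `"normal"`.
#' @param i_max cap of the missed-event sum (default 5).
#' @param trunc truncation bound in seconds (e.g. a 900 s observation bout),
#'   or `NULL` for no truncation.
#' @param renormalize renormalize the capped mixing weights (see
#'   [mixture_weights()]).
#' @return Numeric vector of densities.
#' @examples
#' dinterval(500, mu = 250, sigma = 50, p = 0.3)
#' @export
dinterval <- function(x, mu, sigma, p = 0, f = 0, sigma_w = NULL,
                      family = c("gamma", "normal"), i_max = 5L,
                      trunc = NULL, renormalize = TRUE) {
  family <- match.arg(family)
  check_params(mu, sigma, p, f, sigma_w)
  if (!is.null(trunc) && (!is.numeric(trunc) || length(trunc) != 1L || trunc <= 0))
    stop("`trunc` must be a positive number or NULL", call. = FALSE)

  d <- (1 - f) * mixture_pdf_raw(x, mu, sigma, p, sigma_w, family, i_max, renormalize)
  if (f > 0) {
    # Poisson background: exponential-limit construction, same mu and p.
    d <- d + f * mixture_pdf_raw(x, mu, mu, p, NULL, "gamma", i_max, renormalize)
  }
  if (!is.null(trunc)) {
    z <- (1 - f) * trunc_mass(mu, sigma, p, sigma_w, family, i_max, renormalize, trunc)
    if (f > 0) z <- z + f * trunc_mass(mu, mu, p, NULL, "gamma", i_max, renormalize, trunc)
    d <- ifelse(x > trunc | x <= 0, 0, d / z)
  }
  d
}

# mixture mass on (0, trunc]
trunc_mass <- function(mu, sigma, p, sigma_w, family, i_max, renormalize, trunc) {
  m <- mixture_cdf_raw(trunc, mu, sigma, p, sigma_w, family, i_max, renormalize)
  if (family == "normal")
    m <- m - mixture_cdf_raw(0, mu, sigma, p, sigma_w, family, i_max, renormalize)
  m
}

#' Log-likelihood of interval data under the observed-interval model
#'
#' Sum of log densities of [dinterval()] over the observations. Returns
#' `-Inf` when any observation has zero density (e.g. beyond truncation the
#' data/model combination is inconsistent and an error is raised instead).
#'
#' @param x vector of observed intervals (seconds), all positive.
#' @inheritParams dinterval
#' @return A single number, the log-likelihood.
#' @export
loglik_intervals <- function(x, mu, sigma, p = 0, f = 0, sigma_w = NULL,
                             family = c("gamma", "normal"), i_max = 5L,
                             trunc = NULL, renormalize = TRUE) {
  family <- match.arg(family)
  if (length(x) == 0L) stop("no interval observations supplied", call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("all intervals must be positive and finite", call. = FALSE)
  if (!is.null(trunc) && any(x > trunc))
    stop("intervals exceed the truncation bound `trunc`; data and model disagree",
         call. = FALSE)
  d <- dinterval(x, mu, sigma, p = p, f = f, sigma_w = sigma_w, family = family,
                 i_max = i_max, trunc = trunc, renormalize = renormalize)
  if (any(d == 0)) return(-Inf)
  sum(log(d))
}
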