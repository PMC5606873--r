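f_adjusted_n <- function(fit) {
  f <- if (is.null(fit$params$f)) 0 else fit$params$f
  n_eff <- round((1 - f) * fit$n_obs)
  if (n_eff < 2)
    stop("effective sample size below 2 after background adjustment", call. = FALSE)
  n_eff
}

check_comparable <- function(a, b) {
  if (!inherits(a, "interval_fit") || !inherits(b, "interval_fit"))
    stop("both arguments must be interval_fit objects", call. = FALSE)
  if (!a$converged || !b$converged)
    stop("both model fits must have converged", call. = FALSE)
}

#' Compare fitted interval means between two groups
#'
#' Two-sample t test on the model-estimated means, using each group's fitted
#' mean `mu`, SD `sigma` and an effective sample size `(1 - f) * n_obs`
#' (the information carried by random-background intervals is discounted).
#' Welch's unequal-variance form is the default; a pooled-variance form is
#' available with `pooled = TRUE`.
#'
#' @param a,b converged `"interval_fit"` objects for the two groups.
#' @param pooled use the pooled-variance t test instead of Welch's.
#' @return An object of class `"interval_comparison"` with elements
#'   `statistic`, `df`, `p_value`, `estimate` (the two means), `kind`.
#' @export
compare_means <- function(a, b, pooled = FALSE) {
  check_comparable(a, b)
  m1 <- a$params$mu; s1 <- a$params$sigma; n1 <- f_adjusted_n(a)
  m2 <- b$params$mu; s2 <- b$params$sigma; n2 <- f_adjusted_n(b)
  if (pooled) {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t_stat <- (m1 - m2) / se
  structure(list(statistic = t_stat, df = df,
                 p_value = 2 * stats::pt(-abs(t_stat), df = df),
                 estimate = c(mean_a = m1, mean_b = m2),
                 n_eff = c(n1, n2), kind = "mean_t"),
            class = "interval_comparison")
}

#' Compare fitted interval variances between two groups
#'
#' F test on the ratio of model-estimated variances `sigma_a^2 / sigma_b^2`
#' with background-adjusted degrees of freedom `(1 - f) * n_obs - 1` per
#' group; the p value is two-sided.
#'
#' @inheritParams compare_means
#' @return An `"interval_comparison"` with `kind = "var_F"` and `df` a vector
#'   of the two degrees of freedom.
#' @export
compare_variances <- function(a, b) {
  check_comparable(a, b)
  s1 <- a$params$sigma; n1 <- f_adjusted_n(a)
  s2 <- b$params$sigma; n2 <- f_adjusted_n(b)
  f_stat <- s1^2 / s2^2
  df <- c(n1 - 1, n2 - 1)
  lower <- stats::pf(f_stat, df[1], df[2])
  structure(list(statistic = f_stat, df = df,
                 p_value = min(1, 2 * min(lower, 1 - lower)),
                 estimate = c(sd_a = s1, sd_b = s2),
                 n_eff = c(n1, n2), kind = "var_F"),
            class = "interval_comparison")
}

#' @export
print.interval_comparison <- function(x, ...) {
  if (x$kind == "mean_t") {
    cat(sprintf("t test of fitted means: t = %.4g, df = %.4g, p = %.4g (means %.4g vs %.4g)\n",
                x$statistic, x$df, x$p_value, x$estimate[1], x$estimate[2]))
  } else {
    cat(sprintf("F test of fitted variances: F = %.4g, df = (%g, %g), p = %.4g (SDs %.4g vs %.4g)\n",
                x$statistic, x$df[1], x$df[2], x$p_value,
                x$estimate[1], x$estimate[2]))
  }
  invisible(x)
}

#' Convert fitted interval parameters to event-rate parameters
#'
#' The event rate per `time_unit` seconds is `time_unit / mu`; its SD follows
#' by the delta method as `time_unit * sigma / mu^2`.
#'
#' @param model a converged `"interval_fit"`.
#' @param time_unit seconds per reporting unit (3600 for events per hour).
#' @return A list with `rate`, `rate_sd` and `time_unit`.
#' @examples
#' \dontrun{interval_to_rate(fit, time_unit = 3600) # events per hour}
#' @export
interval_to_rate <- function(model, time_unit = 3600) {
  if (!inherits(model, "interval_fit"))
    stop("`model` must be an interval_fit", call. = FALSE)
  if (!model$converged) stop("model fit did not converge", call. = FALSE)
  if (!is.numeric(time_unit) || length(time_unit) != 1L || time_unit <= 0)
    stop("`time_unit` must be a positive number of seconds", call. = FALSE)
  mu <- model$params$mu; sigma <- model$params$sigma
  list(rate = time_unit / mu, rate_sd = time_unit * sigma / mu^2,
       time_unit = time_unit)
}
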