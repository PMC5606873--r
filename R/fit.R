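# Link functions keep every parameter in its natural domain during
# unconstrained quasi-Newton optimization: log for the positive scale
# parameters, logit (binomial link) for the probabilities p and f.
to_link <- function(value, name) {
  switch(name,
         mu = , sigma = , sigma_w = log(value),
         p = , f = stats::qlogis(value))
}

from_link <- function(theta, name) {
  switch(name,
         mu = , sigma = , sigma_w = exp(theta),
         p = , f = stats::plogis(theta))
}

# assemble the full natural-scale parameter list from the free vector + spec
assemble_params <- function(theta, spec) {
  params <- list(mu = NULL, sigma = NULL, p = 0, f = 0, sigma_w = NULL)
  params[names(spec$fixed)] <- spec$fixed
  for (k in seq_along(spec$free))
    params[[spec$free[k]]] <- unname(from_link(theta[k], spec$free[k]))
  lapply(params, function(v) if (is.null(v)) v else unname(v))
}

default_start <- function(x, spec) {
  p0 <- if ("p" %in% names(spec$fixed)) spec$fixed$p else 0.2
  mu0 <- mean(x) / (1 + p0)
  sigma0 <- stats::sd(x) / (1 + p0)
  starts <- list(mu = mu0, sigma = sigma0, p = max(p0, 0.05), f = 0.05,
                 sigma_w = sigma0 / 2)
  vapply(spec$free, function(nm) to_link(starts[[nm]], nm), numeric(1))
}

neg_loglik_factory <- function(x, spec) {
  function(theta) {
    params <- assemble_params(theta, spec)
    sw <- params$sigma_w
    if (!is.null(sw)) sw <- min(sw, params$sigma) # enforce sigma_w <= sigma
    d <- suppressWarnings(tryCatch(
      dinterval(x, params$mu, params$sigma, p = params$p, f = params$f,
                sigma_w = sw, family = spec$family, i_max = spec$i_max,
                trunc = spec$trunc, renormalize = spec$renormalize),
      error = function(e) rep(0, length(x))))
    # zap overflow NaNs from extreme trial parameters and floor zero
    # densities so gradients stay finite inside the optimizer; the public
    # log-likelihood reports -Inf honestly
    d[!is.finite(d)] <- 0
    -sum(log(pmax(d, 1e-300)))
  }
}

#' Fit an observed-interval model by maximum likelihood
#'
#' Maximizes the observed-interval log-likelihood over the free parameters of
#' `spec` using BFGS on link-transformed coordinates (log link for `mu`,
#' `sigma`, `sigma_w`; logit link for `p` and `f`), so estimates satisfy
#' their domain constraints by construction. On non-convergence the fit is
#' restarted from deterministically jittered starting points before being
#' reported as non-converged.
#'
#' @param x numeric vector of observed intervals (seconds), or a data frame
#'   as returned by [read_intervals()] with columns `interval` and `subject`.
#' @param subject optional vector of subject identifiers, recycled against
#'   `x`; carried along for classification and variance partitioning.
#' @param spec an [interval_spec()].
#' @param start optional named list of natural-scale starting values for
#'   (some of) the free parameters.
#' @param se compute standard errors from the inverse numerical Hessian on
#'   the link scale (delta-method back-transform)? Default `FALSE`.
#' @return An object of class `"interval_fit"`: a list with elements
#'   `params` (list `mu`, `sigma`, `p`, `f`, `sigma_w`), `loglik`, `n_param`,
#'   `n_obs`, `converged`, `spec`, `se`, `x`, `subject` and optimizer
#'   diagnostics.
#' @examples
#' set.seed(1)
#' x <- rgamma(200, shape = 25, scale = 10) # mean 250, sd 50
#' fit_intervals(x, spec = interval_spec(fixed = list(p = 0, f = 0)))
#' @export
fit_intervals <- function(x, subject = NULL, spec = interval_spec(),
                          start = NULL, se = FALSE) {
  if (is.data.frame(x)) {
    if (is.null(subject) && "subject" %in% names(x)) subject <- x$subject
    x <- x$interval
  }
  if (!inherits(spec, "interval_spec")) stop("`spec` must be an interval_spec",
                                             call. = FALSE)
  if (length(x) < 2L) stop("need at least 2 interval observations", call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("all intervals must be positive and finite", call. = FALSE)
  if (length(unique(x)) < 2L)
    stop("degenerate data: all interval values identical", call. = FALSE)
  if (!is.null(spec$trunc) && any(x > spec$trunc))
    stop("intervals exceed `spec$trunc`; data and model disagree", call. = FALSE)
  if (!is.null(subject) && length(subject) != length(x))
    stop("`subject` must match `x` in length", call. = FALSE)

  theta0 <- default_start(x, spec)
  if (!is.null(start)) {
    for (nm in names(start)) {
      if (nm %in% spec$free)
        theta0[match(nm, spec$free)] <- to_link(start[[nm]], nm)
    }
  }
  nll <- neg_loglik_factory(x, spec)

  # deterministic jitter patterns for restarts (no RNG consumed)
  jitters <- list(0, 0.4, -0.4, c(0.4, -0.4))
  best <- NULL
  for (j in jitters) {
    th <- theta0 + rep_len(j, length(theta0))
    opt <- tryCatch(
      stats::optim(th, nll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
    if (opt$convergence == 0 && is.finite(opt$value)) { best <- opt; break }
  }
  if (is.null(best))
    stop("optimization failed from all starting points", call. = FALSE)

  params <- assemble_params(best$par, spec)
  if (!is.null(params$sigma_w)) params$sigma_w <- min(params$sigma_w, params$sigma)
  converged <- best$convergence == 0 && is.finite(best$value)

  se_out <- NULL
  if (se && converged && length(spec$free)) {
    H <- tryCatch(stats::optimHess(best$par, nll), error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(V)) {
        # delta method: d(natural)/d(link) = exp(theta) for log links,
        # plogis'(theta) for logit links
        grad <- vapply(seq_along(spec$free), function(k) {
          nm <- spec$free[k]
          if (nm %in% c("p", "f")) stats::dlogis(best$par[k]) else exp(best$par[k])
        }, numeric(1))
        se_out <- sqrt(pmax(diag(V), 0)) * abs(grad)
        names(se_out) <- spec$free
      }
    }
  }

  structure(list(params = params, loglik = -best$value,
                 n_param = length(spec$free), n_obs = length(x),
                 converged = converged, spec = spec, se = se_out,
                 x = x, subject = subject,
                 optim = list(convergence = best$convergence,
                              counts = best$counts, message = best$message)),
            class = "interval_fit")
}

#' @export
print.interval_fit <- function(x, ...) {
  cat("Observed-interval model fit (", x$spec$family, " family)\n", sep = "")
  est <- unlist(x$params[!vapply(x$params, is.null, logical(1))])
  lab <- names(est)
  flag <- ifelse(lab %in% x$spec$free, "",
                 ifelse(lab %in% names(x$spec$fixed), " (fixed)", " (profiled)"))
  for (k in seq_along(est)) {
    se_txt <- if (!is.null(x$se) && lab[k] %in% names(x$se))
      sprintf(" (se %.3g)", x$se[[lab[k]]]) else ""
    cat(sprintf("  %-8s %10.4g%s%s\n", lab[k], est[k], se_txt, flag[k]))
  }
  cat(sprintf("  log-likelihood %.3f on %d observations (%d free parameters)\n",
              x$loglik, x$n_obs, x$n_param))
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  invisible(x)
}

#' @export
logLik.interval_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_param, nobs = object$n_obs,
            class = "logLik")
}

#' @export
coef.interval_fit <- function(object, ...) {
  unlist(object$params[!vapply(object$params, is.null, logical(1))])
}

#' Fit the within/between-subject model with iteratively updated sigma_w
#'
#' Alternates between (a) maximizing the observed-interval likelihood with
#' the within-subject SD `sigma_w` held at its current value and (b)
#' re-estimating `sigma_w` from the subject-centered fundamental intervals
#' (see [classify_intervals()] and [estimate_sigma_w()]), until the relative
#' change in `sigma_w` drops below `tol`.
#'
#' @inheritParams fit_intervals
#' @param subject vector of subject identifiers; at least two subjects with
#'   two or more intervals each are required for `sigma_w` to be identifiable.
#' @param sigma_w0 starting value for `sigma_w`; default half the heuristic
#'   starting SD.
#' @param tol relative-change convergence tolerance for `sigma_w`.
#' @param max_iter maximum number of alternations.
#' @return An `"interval_fit"` whose `params$sigma_w` holds the converged
#'   within-subject SD, with an extra `partition` element (`s_w`, `n_ind`,
#'   `n_fundamental`, `iterations`, `sigma_w_converged`).
#' @export
fit_intervals_within <- function(x, subject, spec = interval_spec(),
                                 sigma_w0 = NULL, tol = 1e-3, max_iter = 25L,
                                 start = NULL) {
  if (is.data.frame(x)) {
    if (missing(subject) && "subject" %in% names(x)) subject <- x$subject
    x <- x$interval
  }
  if (is.null(subject) || length(subject) != length(x))
    stop("`subject` labels matching `x` are required", call. = FALSE)
  counts <- table(subject)
  if (sum(counts >= 2L) < 2L)
    stop("sigma_w is unidentifiable: need at least 2 subjects with >= 2 intervals each",
         call. = FALSE)
  if ("sigma_w" %in% spec$free || "sigma_w" %in% names(spec$fixed))
    spec$free <- setdiff(spec$free, "sigma_w")

  sigma_w <- if (is.null(sigma_w0)) stats::sd(x) / (1 + 0.2) / 2 else sigma_w0
  fit <- NULL
  sw_converged <- FALSE
  it <- 0L
  part <- NULL
  history <- numeric(0)
  while (it < max_iter) {
    it <- it + 1L
    spec_i <- spec
    spec_i$fixed$sigma_w <- sigma_w
    fit <- fit_intervals(x, subject = subject, spec = spec_i, start = start)
    cls <- classify_intervals(fit)
    part <- estimate_sigma_w(cls)
    new_sw <- min(part$sigma_w, fit$params$sigma)
    # convergence, or return to an earlier iterate: the discrete fundamental
    # set can cycle between two states, in which case we accept the last value
    delta <- min(abs(new_sw - c(sigma_w, history))) / max(sigma_w, 1e-8)
    history <- c(history, sigma_w)
    sigma_w <- new_sw
    if (delta < tol) { sw_converged <- TRUE; break }
  }
  # final maximization at the accepted sigma_w so the reported likelihood and
  # estimates are mutually consistent
  spec_i <- spec
  spec_i$fixed$sigma_w <- sigma_w
  fit <- fit_intervals(x, subject = subject, spec = spec_i, start = start)
  fit$params$sigma_w <- sigma_w
  fit$partition <- list(s_w = part$s_w, n_ind = part$n_ind,
                        n_fundamental = part$n_fundamental,
                        iterations = it, sigma_w_converged = sw_converged)
  fit
}

#' Likelihood-ratio (deviance) test between nested interval models
#'
#' Compares two models fitted on the same data via the deviance
#' `2 * (loglik_full - loglik_reduced)`, referred to a chi-squared
#' distribution with degrees of freedom equal to the difference in free
#' parameter counts. Used e.g. to test for observer effects (`p` free versus
#' `p` fixed at 0).
#'
#' @param full,reduced `"interval_fit"` objects on the same data with nested
#'   free-parameter sets.
#' @return An object of class `"deviance_test"` with elements `deviance`,
#'   `df` and `p_value`.
#' @export
deviance_test <- function(full, reduced) {
  if (!inherits(full, "interval_fit") || !inherits(reduced, "interval_fit"))
    stop("both arguments must be interval_fit objects", call. = FALSE)
  if (full$n_obs != reduced$n_obs)
    stop("models were fitted on different numbers of observations", call. = FALSE)
  if (!all(reduced$spec$free %in% full$spec$free))
    stop("models are not nested: reduced free parameters must be a subset of the full model's",
         call. = FALSE)
  df <- full$n_param - reduced$n_param
  if (df <= 0)
    stop("models are not nested: the full model must have more free parameters",
         call. = FALSE)
  dev <- 2 * (full$loglik - reduced$loglik)
  if (dev < -1e-6)
    stop("negative deviance: the full model fits worse than the reduced one; ",
         "refit the full model from better starting values", call. = FALSE)
  dev <- max(dev, 0)
  structure(list(deviance = dev, df = df,
                 p_value = stats::pchisq(dev, df = df, lower.tail = FALSE)),
            class = "deviance_test")
}

#' @export
print.deviance_test <- function(x, ...) {
  cat(sprintf("Deviance test: D = %.3f, df = %d, p = %.4g\n",
              x$deviance, x$df, x$p_value))
  invisible(x)
}

#' AIC comparison table for interval models fitted on the same data
#'
#' @param ... `"interval_fit"` objects, or a single list of them.
#' @return A data frame with columns `model`, `loglik`, `n_param`, `AIC` and
#'   `dAIC`, sorted by increasing AIC.
#' @export
aic_table <- function(...) {
  models <- list(...)
  if (length(models) == 1L && is.list(models[[1]]) &&
      !inherits(models[[1]], "interval_fit"))
    models <- models[[1]]
  if (!length(models)) stop("no models supplied", call. = FALSE)
  if (!all(vapply(models, inherits, logical(1), "interval_fit")))
    stop("all models must be interval_fit objects", call. = FALSE)
  n_obs <- vapply(models, `[[`, numeric(1), "n_obs")
  if (length(unique(n_obs)) != 1L)
    stop("models were fitted on different numbers of observations", call. = FALSE)
  nm <- names(models)
  if (is.null(nm) || any(nm == ""))
    nm <- paste0("model", seq_along(models))
  ll <- vapply(models, `[[`, numeric(1), "loglik")
  k <- vapply(models, `[[`, numeric(1), "n_param")
  aic <- 2 * k - 2 * ll
  out <- data.frame(model = nm, loglik = ll, n_param = k, AIC = aic,
                    dAIC = aic - min(aic), row.names = NULL)
  out[order(out$AIC), , drop = FALSE]
}
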