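#' Partial likelihoods of an interval over missed-event counts
#'
#' Decomposes the observed-interval density at `x` into the contributions of
#' the missed-event components `i = 0 ... i_max`: element `i+1` is
#' `pi_i * family_pdf(x | (i+1)*mu, width_i)`. The decomposition uses the
#' main (non-background) construction only — random background arrivals carry
#' no information on missed counts — and omits the truncation constant, which
#' cancels in any confidence ratio. Row sums therefore equal the observed
#' density before background scaling and truncation renormalization.
#'
#' @inheritParams dinterval
#' @return A matrix with `length(x)` rows and `i_max + 1` columns.
#' @export
partial_likelihoods <- function(x, mu, sigma, p = 0, sigma_w = NULL,
                                family = c("gamma", "normal"), i_max = 5L,
                                renormalize = TRUE) {
  family <- match.arg(family)
  check_params(mu, sigma, p, 0, sigma_w)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("all intervals must be positive and finite", call. = FALSE)
  w <- mixture_weights(p, i_max, renormalize)
  out <- matrix(0, nrow = length(x), ncol = i_max + 1L,
                dimnames = list(NULL, paste0("i", 0:i_max)))
  for (i in 0:i_max) {
    out[, i + 1L] <- w[i + 1L] *
      family_pdf(x, (i + 1) * mu, component_sd(i, sigma, sigma_w), family)
  }
  out
}

#' Classify intervals by missed-event count and fold them back
#'
#' For each observed interval, computes the partial likelihoods over missed
#' counts, the most likely count `i_star`, the confidence that the interval is
#' fundamental (contains no missed event), and the folded value
#' `interval / (i_star + 1)` — the most likely fundamental interval it
#' represents. An interval is flagged fundamental when the `i = 0` partial
#' likelihood is at least `spec$fundamental_threshold` of the total.
#'
#' Classification always scores intervals against the pooled construction
#' `phi(x, i | mu, sigma, p)` — component widths `sqrt(i+1)*sigma` — even for
#' a model fitted with a within/between split: the pooled widths reflect the
#' full spread of summed intervals (a doubled interval accumulates the
#' between-subject deviation twice), which the split form understates for
#' `i >= 1`. The background fraction `f` is likewise ignored here, as random
#' background arrivals carry no missed-count information.
#'
#' @param model a converged `"interval_fit"`.
#' @param x intervals to classify; defaults to the data the model was fitted
#'   on. May be a data frame with columns `interval` and `subject`.
#' @param subject optional subject labels matching `x`.
#' @return A data frame of class `"interval_classification"` with columns
#'   `interval`, `subject`, `i_star`, `confidence`, `fundamental`,
#'   `folded_value`.
#' @export
classify_intervals <- function(model, x = NULL, subject = NULL) {
  if (!inherits(model, "interval_fit"))
    stop("`model` must be an interval_fit", call. = FALSE)
  if (!model$converged)
    stop("cannot classify with a non-converged model fit", call. = FALSE)
  if (is.null(x)) {
    x <- model$x
    subject <- model$subject
  } else if (is.data.frame(x)) {
    if (is.null(subject) && "subject" %in% names(x)) subject <- x$subject
    x <- x$interval
  }
  if (is.null(subject)) subject <- rep(NA_character_, length(x))
  prm <- model$params
  pl <- partial_likelihoods(x, prm$mu, prm$sigma, p = prm$p,
                            sigma_w = NULL, family = model$spec$family,
                            i_max = model$spec$i_max,
                            renormalize = model$spec$renormalize)
  tot <- rowSums(pl)
  conf <- ifelse(tot > 0, pl[, 1L] / tot, 0)
  i_star <- max.col(pl, ties.method = "first") - 1L
  out <- data.frame(interval = x, subject = subject, i_star = i_star,
                    confidence = conf,
                    fundamental = conf >= model$spec$fundamental_threshold,
                    folded_value = x / (i_star + 1L))
  class(out) <- c("interval_classification", "data.frame")
  out
}

#' Estimate the within-subject SD from classified fundamental intervals
#'
#' Centers the fundamental intervals by their subject means and computes the
#' within-subject SD as `sigma_w = s_w * sqrt(n_ind / (n_ind + 1))`, where
#' `s_w` is the uncorrected (denominator `n`) sample SD of the centered
#' values and `n_ind` the average number of fundamental intervals per
#' retained subject. Subjects contributing fewer than two fundamental
#' intervals are dropped with a warning, as they carry no within-subject
#' information.
#'
#' @param assignments an `"interval_classification"` data frame from
#'   [classify_intervals()], or any data frame with columns `interval` (or
#'   `folded_value`), `subject` and `fundamental`.
#' @return A list of class `"sigma_w_estimate"`: `sigma_w`, `s_w`, `n_ind`,
#'   `n_fundamental`, `n_subjects`.
#' @examples
#' cls <- data.frame(interval = c(240, 260), subject = c("a", "a"),
#'                   fundamental = TRUE)
#' estimate_sigma_w(cls)$sigma_w # 10 * sqrt(2/3)
#' @export
estimate_sigma_w <- function(assignments) {
  if (!is.data.frame(assignments) ||
      !all(c("interval", "subject", "fundamental") %in% names(assignments)))
    stop("`assignments` must have columns interval, subject, fundamental",
         call. = FALSE)
  fund <- assignments[assignments$fundamental, , drop = FALSE]
  if (!nrow(fund))
    stop("no fundamental intervals: sigma_w cannot be estimated", call. = FALSE)
  counts <- table(fund$subject)
  keep <- names(counts)[counts >= 2L]
  if (!length(keep))
    stop("no subject has >= 2 fundamental intervals: sigma_w cannot be estimated",
         call. = FALSE)
  if (length(keep) < length(counts))
    warning(sprintf("dropping %d subject(s) with < 2 fundamental intervals",
                    length(counts) - length(keep)), call. = FALSE)
  fund <- fund[fund$subject %in% keep, , drop = FALSE]
  centered <- fund$interval - stats::ave(fund$interval, fund$subject)
  s_w <- sqrt(mean(centered^2))
  n_ind <- nrow(fund) / length(keep)
  structure(list(sigma_w = s_w * sqrt(n_ind / (n_ind + 1)), s_w = s_w,
                 n_ind = n_ind, n_fundamental = nrow(fund),
                 n_subjects = length(keep)),
            class = "sigma_w_estimate")
}

#' @export
print.sigma_w_estimate <- function(x, ...) {
  cat(sprintf(
    "Within-subject SD: %.4g s (s_w = %.4g, %d fundamental intervals, %.3g per subject over %d subjects)\n",
    x$sigma_w, x$s_w, x$n_fundamental, x$n_ind, x$n_subjects))
  invisible(x)
}

#' Write an interval classification to CSV
#'
#' @param assignments an `"interval_classification"` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_classification <- function(assignments, path) {
  utils::write.csv(as.data.frame(assignments), path, row.names = FALSE)
  invisible(path)
}
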