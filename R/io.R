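#' Read interval observations from a CSV file
#'
#' Reads a headed CSV of interval observations, validates the interval
#' column, and drops rows with missing or nonpositive intervals, reporting
#' each rejected row by line number.
#'
#' @param path path to a CSV file with a header row.
#' @param interval_col name of the interval column (seconds).
#' @param subject_col name of the subject-identifier column, or `NULL` if the
#'   data carry no subject structure.
#' @param group_col optional name of a group-label column.
#' @param unit `"s"` (default) or `"min"`; intervals given in minutes are
#'   converted to seconds.
#' @return A data frame with columns `interval`, `subject` and (optionally)
#'   `group`, with attributes `source` (the path) and `parse_log` (messages
#'   for rejected rows).
#' @export
read_intervals <- function(path, interval_col = "interval",
                           subject_col = "subject", group_col = NULL,
                           unit = c("s", "min")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(raw)) stop("empty interval file: ", path, call. = FALSE)
  if (!interval_col %in% names(raw))
    stop("missing required column `", interval_col, "` in ", path, call. = FALSE)
  if (!is.null(subject_col) && !subject_col %in% names(raw)) subject_col <- NULL
  if (!is.null(group_col) && !group_col %in% names(raw))
    stop("missing column `", group_col, "` in ", path, call. = FALSE)

  interval <- suppressWarnings(as.numeric(raw[[interval_col]]))
  bad <- !is.finite(interval) | interval <= 0
  log <- character(0)
  if (any(bad)) {
    # +1 for the header row, so numbers refer to file lines
    log <- sprintf("line %d: rejected interval value '%s'",
                   which(bad) + 1L, as.character(raw[[interval_col]][bad]))
    for (msg in log) message(msg)
  }
  keep <- !bad
  if (!any(keep)) stop("no valid interval rows in ", path, call. = FALSE)
  out <- data.frame(
    interval = interval[keep] * if (unit == "min") 60 else 1,
    subject = if (is.null(subject_col)) "s1"
              else as.character(raw[[subject_col]][keep]))
  if (any(!nzchar(out$subject)) || anyNA(out$subject))
    stop("subject identifiers must be non-empty", call. = FALSE)
  if (!is.null(group_col)) out$group <- as.character(raw[[group_col]][keep])
  attr(out, "source") <- path
  attr(out, "parse_log") <- log
  out
}

#' Serialize a fitted interval model to JSON
#'
#' Writes the estimates, log-likelihood, sample size and model structure so a
#' fit can be reloaded (e.g. for a later group comparison). The raw data are
#' not stored.
#'
#' @param fit an `"interval_fit"`.
#' @param path output path, or `NULL` to return the JSON string.
#' @return `path` (or the JSON string), invisibly.
#' @export
write_fit_json <- function(fit, path = NULL) {
  if (!inherits(fit, "interval_fit"))
    stop("`fit` must be an interval_fit", call. = FALSE)
  obj <- list(
    params = fit$params[!vapply(fit$params, is.null, logical(1))],
    loglik = fit$loglik, n_param = fit$n_param, n_obs = fit$n_obs,
    converged = fit$converged,
    se = as.list(fit$se),
    spec = list(family = fit$spec$family, free = fit$spec$free,
                fixed = fit$spec$fixed, i_max = fit$spec$i_max,
                trunc = fit$spec$trunc,
                fundamental_threshold = fit$spec$fundamental_threshold,
                renormalize = fit$spec$renormalize))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(invisible(as.character(json)))
  writeLines(json, path)
  invisible(path)
}

#' Reload a fitted interval model from JSON
#'
#' Inverse of [write_fit_json()]. The returned object supports comparison and
#' rate conversion; operations that need the raw data (classification,
#' deviance tests against refits) require the original fit.
#'
#' @param path path to a JSON file written by [write_fit_json()].
#' @return An `"interval_fit"` (without data).
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  spec <- interval_spec(
    family = obj$spec$family, free = obj$spec$free,
    fixed = as.list(obj$spec$fixed),
    i_max = obj$spec$i_max,
    trunc = obj$spec$trunc,
    fundamental_threshold = obj$spec$fundamental_threshold,
    renormalize = isTRUE(obj$spec$renormalize))
  params <- list(mu = NULL, sigma = NULL, p = 0, f = 0, sigma_w = NULL)
  params[names(obj$params)] <- obj$params
  structure(list(params = params, loglik = obj$loglik, n_param = obj$n_param,
                 n_obs = obj$n_obs, converged = isTRUE(obj$converged),
                 spec = spec, se = if (length(obj$se)) unlist(obj$se) else NULL,
                 x = NULL, subject = NULL, optim = NULL),
            class = "interval_fit")
}
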