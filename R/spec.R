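ALL_PARAMS <- c("mu", "sigma", "p", "f", "sigma_w")

#' Specify the structure of an observed-interval model
#'
#' Collects the structural choices of an observed-interval model: the
#' component family, which parameters are estimated and which are held fixed
#' (e.g. `p` fixed from a device duty cycle, or `f = 0` to exclude the random
#' background), the cap of the missed-event sum, the truncation bound
#' (observation bout length), and the confidence threshold used to classify
#' intervals as fundamental.
#'
#' The five model parameters are `mu`, `sigma`, `p`, `f` and (optionally)
#' `sigma_w`. `mu`, `sigma`, `p` and `f` must each be either free or fixed;
#' by default `mu`, `sigma` and `p` are free and `f` is fixed at 0.
#' `sigma_w` enters only when listed in `free` or `fixed`; the usual route
#' for estimating it is [fit_intervals_within()], which holds it fixed during
#' each maximization and updates it from the fundamental subset.
#'
#' @param family component family, `"gamma"` (default) or `"normal"`.
#' @param free character vector of parameters estimated by maximum
#'   likelihood; `NULL` (default) frees every parameter of
#'   `c("mu", "sigma", "p", "f")` not named in `fixed`.
#' @param fixed named list of parameters held at fixed values.
#' @param i_max cap of the missed-event sum (default 5).
#' @param trunc truncation bound in seconds, or `NULL`.
#' @param fundamental_threshold confidence level above which an interval is
#'   classified as fundamental (default 0.9), in `(0.5, 1)`.
#' @param renormalize renormalize the capped mixing weights.
#' @return An object of class `"interval_spec"`.
#' @examples
#' interval_spec(trunc = 900)                      # free mu, sigma, p; f = 0
#' interval_spec(fixed = list(p = 0, f = 0))       # plain gamma fit
#' interval_spec(fixed = list())                   # frees f as well
#' @export
interval_spec <- function(family = c("gamma", "normal"), free = NULL,
                          fixed = list(f = 0), i_max = 5L, trunc = NULL,
                          fundamental_threshold = 0.9, renormalize = TRUE) {
  family <- match.arg(family)
  if (!is.list(fixed)) stop("`fixed` must be a named list", call. = FALSE)
  if (length(fixed) && (is.null(names(fixed)) || any(names(fixed) == "")))
    stop("`fixed` must be a named list", call. = FALSE)
  if (!all(names(fixed) %in% ALL_PARAMS))
    stop("unknown parameter in `fixed`: ",
         paste(setdiff(names(fixed), ALL_PARAMS), collapse = ", "), call. = FALSE)
  if (is.null(free))
    free <- setdiff(c("mu", "sigma", "p", "f"), names(fixed))
  if (!all(free %in% ALL_PARAMS))
    stop("unknown parameter in `free`: ",
         paste(setdiff(free, ALL_PARAMS), collapse = ", "), call. = FALSE)
  if (length(intersect(free, names(fixed))))
    stop("parameters cannot be both free and fixed: ",
         paste(intersect(free, names(fixed)), collapse = ", "), call. = FALSE)
  core <- c("mu", "sigma", "p", "f")
  missing <- setdiff(core, union(free, names(fixed)))
  if (length(missing))
    stop("each of mu, sigma, p, f must be free or fixed; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!all(c("mu", "sigma") %in% union(free, names(fixed))))
    stop("mu and sigma must always be present", call. = FALSE)
  if (!is.numeric(i_max) || length(i_max) != 1L || i_max < 0 || i_max != round(i_max))
    stop("`i_max` must be a nonnegative integer", call. = FALSE)
  if ("p" %in% free && i_max < 1)
    stop("`i_max` must be >= 1 when p is free (the likelihood otherwise carries no information on p)",
         call. = FALSE)
  if (!is.null(trunc) && (!is.numeric(trunc) || length(trunc) != 1L || trunc <= 0))
    stop("`trunc` must be a positive number or NULL", call. = FALSE)
  if (!is.numeric(fundamental_threshold) || length(fundamental_threshold) != 1L ||
      fundamental_threshold <= 0.5 || fundamental_threshold > 1)
    stop("`fundamental_threshold` must lie in (0.5, 1]", call. = FALSE)
  # validate fixed values through the shared checker
  with_defaults <- utils::modifyList(
    list(mu = 1, sigma = 1, p = 0, f = 0, sigma_w = NULL), fixed)
  # a fixed sigma_w must respect 0 <= sigma_w; the sigma_w <= sigma bound is
  # enforced against the running sigma estimate at evaluation time
  if (!is.null(with_defaults$sigma_w) &&
      (with_defaults$sigma_w < 0 || !is.finite(with_defaults$sigma_w)))
    stop("fixed `sigma_w` must be nonnegative", call. = FALSE)
  check_params(with_defaults$mu, with_defaults$sigma, with_defaults$p,
               with_defaults$f, NULL)

  structure(list(family = family, free = free, fixed = fixed,
                 i_max = as.integer(i_max), trunc = trunc,
                 fundamental_threshold = fundamental_threshold,
                 renormalize = renormalize),
            class = "interval_spec")
}

#' @export
print.interval_spec <- function(x, ...) {
  cat("Observed-interval model specification\n")
  cat("  family:", x$family, "\n")
  cat("  free:  ", paste(x$free, collapse = ", "), "\n")
  if (length(x$fixed))
    cat("  fixed: ", paste(sprintf("%s = %g", names(x$fixed), unlist(x$fixed)),
                           collapse = ", "), "\n")
  cat("  i_max: ", x$i_max, "\n")
  cat("  trunc: ", if (is.null(x$trunc)) "none" else paste0(x$trunc, " s"), "\n")
  cat("  fundamental threshold:", x$fundamental_threshold, "\n")
  invisible(x)
}

# does sigma_w participate in this spec at all?
spec_has_sigma_w <- function(spec) {
  "sigma_w" %in% spec$free || "sigma_w" %in% names(spec$fixed)
}
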