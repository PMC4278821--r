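#' Clench (saturating) accumulation model
#'
#' `S(t) = a t / (1 + b t)`: `a` is the accumulation rate at the start of
#' sampling (taxa per night), `b` controls how quickly new taxa stop
#' appearing, and the asymptote `a / b` is the estimated total richness.
#' Appropriate when the probability of adding a new taxon falls as the
#' inventory grows but keeps increasing with time spent.
#'
#' @param a,b model parameters, both positive for a meaningful curve.
#' @param t sampling effort in nights, nonnegative (vectorised).
#' @return predicted richness at each `t`.
#' @export
clench_predict <- function(a, b, t) {
  if (any(t < 0)) abort("effort `t` must be nonnegative")
  a * t / (1 + b * t)
}

#' Fit the Clench model to an accumulation curve
#'
#' Nonlinear least squares (Levenberg-Marquardt) of mean richness against
#' effort. Start values: `a0` = richness after the first night, `b0 = a0 /
#' S_max`, so the initial asymptote equals the observed maximum. The fit is
#' to the permutation-mean curve, unweighted by default; pass
#' `weights = 1 / curve$sd_richness^2` style vectors to change that.
#'
#' @param curve data frame with columns `effort` and `mean_richness`
#'   (an `accumulation_curve`), at least 3 effort levels, nonzero final
#'   richness.
#' @param weights optional nonnegative observation weights.
#' @param strict error (rather than flag) on non-convergence.
#' @return object of class `clench_fit`: list with `a`, `b`, `asymptote`,
#'   `residual_sse`, `converged`, `n_points`.
#' @export
fit_clench <- function(curve, weights = NULL, strict = FALSE) {
  if (nrow(curve) < 3) abort("need at least 3 effort levels to fit")
  s_max <- curve$mean_richness[nrow(curve)]
  if (s_max <= 0) abort("cannot fit an all-zero accumulation curve")
  a0 <- max(curve$mean_richness[1], 1e-6)
  b0 <- a0 / s_max
  dat <- data.frame(effort = curve$effort, S = curve$mean_richness)
  args <- list(
    S ~ a * effort / (1 + b * effort), data = dat,
    start = list(a = a0, b = b0),
    lower = c(1e-10, 1e-10),
    control = minpack.lm::nls.lm.control(
      maxiter = 1000, ftol = 1e-15, ptol = 1e-15, gtol = 0
    )
  )
  if (!is.null(weights)) args$weights <- weights
  fit <- tryCatch(do.call(minpack.lm::nlsLM, args), error = function(e) NULL)
  if (is.null(fit)) {
    if (strict) abort("Clench fit failed to converge")
    out <- list(a = NA_real_, b = NA_real_, asymptote = NA_real_,
                residual_sse = NA_real_, converged = FALSE,
                n_points = nrow(curve))
    class(out) <- "clench_fit"
    return(out)
  }
  cf <- stats::coef(fit)
  info <- fit$convInfo
  converged <- isTRUE(info$isConv) || (!is.null(info$stopCode) && info$stopCode %in% 1:4)
  if (!converged && strict) abort("Clench fit did not converge (%s)", info$stopMessage)
  out <- list(a = unname(cf["a"]), b = unname(cf["b"]),
              asymptote = unname(cf["a"] / cf["b"]),
              residual_sse = sum(stats::residuals(fit)^2),
              converged = converged, n_points = nrow(curve))
  class(out) <- "clench_fit"
  out
}

#' @export
print.clench_fit <- function(x, ...) {
  cat(sprintf("Clench fit: a = %.4g, b = %.4g, asymptote a/b = %.4g (%s)\n",
              x$a, x$b, x$asymptote,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' Effort needed to reach a fraction of asymptotic richness
#'
#' Solving `S(t) = q a / b` gives the closed form `t_q = q / ((1 - q) b)`;
#' for the conventional 90% completeness target, `t_0.9 = 9 / b`. Effort is
#' reported both raw and rounded up to whole nights, since nights are
#' integral effort units.
#'
#' @param fit a [fit_clench()] result (or any list with a positive `b`).
#' @param q target fraction of the asymptote, in (0, 1).
#' @return list with `effort` (exact) and `nights` (`ceiling(effort)`).
#' @export
effort_to_fraction <- function(fit, q = 0.9) {
  if (q <= 0 || q >= 1) abort("`q` must lie strictly between 0 and 1")
  b <- fit$b
  if (is.na(b) || b <= 0) abort("invalid fit: b must be positive")
  t_q <- q / ((1 - q) * b)
  list(effort = t_q, nights = ceiling(t_q - 1e-9))
}

#' Average Clench fits across sampling units
#'
#' Scheme-level curves are summarised by arithmetically averaging the
#' fitted parameters across units (`mean(a)`, `mean(b)`), then reading the
#' asymptote and effort targets off the averaged parameters. Note that
#' `mean(a) / mean(b)` is generally *not* the mean of the per-unit
#' asymptotes; see the package vignette.
#'
#' @param fits list of converged `clench_fit` objects.
#' @return a `clench_fit` with averaged parameters (`residual_sse` unset).
#' @export
average_fits <- function(fits) {
  stopifnot(length(fits) >= 1)
  bad <- which(!vapply(fits, function(f) isTRUE(f$converged), logical(1)))
  if (length(bad) > 0) {
    labs <- names(fits) %||% as.character(seq_along(fits))
    abort("cannot average non-converged fits (unit(s): %s)",
          paste(labs[bad], collapse = ", "))
  }
  a <- mean(vapply(fits, `[[`, numeric(1), "a"))
  b <- mean(vapply(fits, `[[`, numeric(1), "b"))
  out <- list(a = a, b = b, asymptote = a / b, residual_sse = NA_real_,
              converged = TRUE, n_points = NA_integer_)
  class(out) <- "clench_fit"
  out
}
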