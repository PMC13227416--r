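#' Fit the exponential closure model to a luminal area series
#'
#' Fits `a(t) = A * exp(-k * t)` to registered luminal areas by
#' Levenberg-Marquardt nonlinear least squares, initialised from the
#' log-linear regression of `log(a)` on `t`. `A` is a free amplitude (um^2)
#' and the closure rate constant `k` is constrained non-negative and reported
#' in hr^-1 regardless of the input time unit. A failure of the optimiser
#' returns the log-linear initial estimates with `converged = FALSE` rather
#' than raising.
#'
#' @param t Time points (post-registration, `t >= 0`).
#' @param area Luminal areas in um^2, all positive.
#' @param time_unit Unit of `t`: `"min"` (default), `"hr"`, or `"s"`.
#' @return An object of class `closure_fit`: a list with elements `A`, `k`,
#'   `rmse`, `n_frames_fit`, `converged`, `embryo_id`, and the fitted data.
#' @export
fit_closure <- function(t, area, time_unit = c("min", "hr", "s")) {
  time_unit <- match.arg(time_unit)
  keep <- is.finite(t) & is.finite(area)
  t <- t[keep]; area <- area[keep]
  if (length(t) < 3L) abort_insufficient("Need at least 3 (t, area) points to fit the closure model.")
  if (any(area <= 0)) abort_validation("All areas must be positive.")
  t_hr <- switch(time_unit, min = t / 60, hr = t, s = t / 3600)

  init <- stats::lm(log(area) ~ t_hr)
  k0 <- max(-unname(coef(init)[2]), 0)
  A0 <- exp(unname(coef(init)[1]))

  fit <- tryCatch(
    minpack.lm::nlsLM(
      area ~ A * exp(-k * t_hr),
      start = list(A = A0, k = k0),
      lower = c(A = 1e-9, k = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    A <- A0; k <- k0; converged <- FALSE
    rmse <- sqrt(mean((area - A * exp(-k * t_hr))^2))
  } else {
    cf <- coef(fit)
    A <- unname(cf["A"]); k <- unname(cf["k"])
    converged <- isTRUE(fit$convInfo$isConv)
    rmse <- sqrt(mean(resid(fit)^2))
  }
  structure(
    list(A = A, k = k, rmse = rmse, n_frames_fit = length(t),
         converged = converged, embryo_id = NA_character_,
         data = tibble::tibble(t_hr = t_hr, area = area)),
    class = "closure_fit"
  )
}

#' Closure rate constant from a lumen series
#'
#' Full closure-kinetics pipeline for one embryo: register the time origin by
#' the 80 um ML-extent rule, compute per-frame luminal areas, and fit the
#' decaying exponential to the frames with registered time `t >= 0`. When no
#' frame exceeds the threshold the fit spans all frames (with a fallback
#' warning from the registration step).
#'
#' @param series A [lumen_series()] object.
#' @param config A [run_config()].
#' @return A `closure_fit` object carrying the embryo id.
#' @export
closure_rate_pipeline <- function(series, config = run_config()) {
  metrics <- compute_lumen_metrics(series, config)
  sel <- metrics$t_min >= 0
  if (sum(sel) < 3L) {
    abort_insufficient("Fewer than 3 frames at or after the registered time origin.")
  }
  fit <- fit_closure(metrics$t_min[sel], metrics$area_um2[sel], time_unit = "min")
  fit$embryo_id <- series_meta(series)$embryo_id
  fit
}

#' @export
print.closure_fit <- function(x, ...) {
  cat(sprintf(
    "<closure_fit>%s A = %.4g um^2, k = %.4g hr^-1 (rmse %.3g, %d frames%s)\n",
    if (is.na(x$embryo_id)) "" else paste0(" ", x$embryo_id, ":"),
    x$A, x$k, x$rmse, x$n_frames_fit,
    if (x$converged) "" else ", NOT converged"))
  invisible(x)
}
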