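#' Tidy a closure fit
#'
#' @param x A `closure_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per model parameter (`A`, `k`).
#' @method tidy closure_fit
#' @export
tidy.closure_fit <- function(x, ...) {
  tibble::tibble(term = c("A", "k"),
                 estimate = c(x$A, x$k),
                 unit = c("um^2", "hr^-1"))
}

#' One-row summary of a closure fit
#'
#' @param x A `closure_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `A_um2`, `k_per_hr`, `rmse`, `n_frames_fit`,
#'   `converged`.
#' @method glance closure_fit
#' @export
glance.closure_fit <- function(x, ...) {
  tibble::tibble(A_um2 = x$A, k_per_hr = x$k, rmse = x$rmse,
                 n_frames_fit = x$n_frames_fit, converged = x$converged)
}
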