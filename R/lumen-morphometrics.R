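#' Polygon area (shoelace)
#'
#' Absolute shoelace area of a simple closed polygon, independent of vertex
#' orientation.
#'
#' @param vertices Two-column matrix or data frame (`x`, `y`) of vertices in
#'   outline order; the polygon is closed implicitly.
#' @return Area in um^2.
#' @export
polygon_area <- function(vertices) {
  m <- as_vertex_matrix(vertices)
  n <- nrow(m)
  if (n < 3L) abort_validation("A polygon needs at least 3 vertices.")
  j <- c(2:n, 1L)
  a <- abs(sum(m[, 1] * m[j, 2] - m[j, 1] * m[, 2])) / 2
  if (a < 1e-12) abort_validation("Degenerate polygon: area is zero.")
  a
}

#' Polygon perimeter
#'
#' Closed-contour length, including the edge from the last vertex back to the
#' first.
#'
#' @inheritParams polygon_area
#' @return Perimeter in um.
#' @export
polygon_perimeter <- function(vertices) {
  m <- as_vertex_matrix(vertices)
  n <- nrow(m)
  if (n < 3L) abort_validation("A polygon needs at least 3 vertices.")
  j <- c(2:n, 1L)
  p <- sum(sqrt((m[j, 1] - m[, 1])^2 + (m[j, 2] - m[, 2])^2))
  if (p < 1e-12) abort_validation("Degenerate polygon: perimeter is zero.")
  p
}

#' Circularity
#'
#' `c = 4 * pi * area / perimeter^2`: 1 for a circle, smaller for any other
#' shape (isoperimetric inequality).
#'
#' @param area Area in um^2 (> 0).
#' @param perimeter Perimeter in um (> 0).
#' @return Dimensionless circularity in (0, 1].
#' @export
circularity <- function(area, perimeter) {
  if (any(!is.finite(area)) || any(area <= 0)) abort_validation("`area` must be positive.")
  if (any(!is.finite(perimeter)) || any(perimeter <= 0)) abort_validation("`perimeter` must be positive.")
  4 * pi * area / perimeter^2
}

#' Maximum AP and ML luminal lengths
#'
#' Rotates the outline about its centroid so that its longest axis (the
#' maximum caliper diameter, i.e. the farthest pair of convex-hull vertices)
#' is vertical, then measures the y-extent (AP length, equal to the caliper
#' diameter) and x-extent (ML length). Invariant to rigid rotation of the
#' input.
#'
#' @inheritParams polygon_area
#' @return Named numeric vector `c(ap_length, ml_length)` in um, with
#'   `ap_length >= ml_length` by construction.
#' @export
max_axis_lengths <- function(vertices) {
  m <- as_vertex_matrix(vertices)
  if (nrow(m) < 3L) abort_validation("A polygon needs at least 3 vertices.")
  hull <- m[grDevices::chull(m), , drop = FALSE]
  h <- nrow(hull)
  if (h < 2L) abort_validation("Degenerate polygon: all vertices coincide.")
  # farthest pair of hull vertices = longest axis
  dx <- outer(hull[, 1], hull[, 1], "-")
  dy <- outer(hull[, 2], hull[, 2], "-")
  d2 <- dx^2 + dy^2
  ij <- arrayInd(which.max(d2), dim(d2))
  if (d2[ij] < 1e-24) abort_validation("Degenerate polygon: zero diameter.")
  u <- c(hull[ij[1], 1] - hull[ij[2], 1], hull[ij[1], 2] - hull[ij[2], 2])
  theta <- pi / 2 - atan2(u[2], u[1]) # rotation making the long axis vertical
  ctr <- colMeans(m)
  xc <- m[, 1] - ctr[1]; yc <- m[, 2] - ctr[2]
  xr <- xc * cos(theta) - yc * sin(theta)
  yr <- xc * sin(theta) + yc * cos(theta)
  c(ap_length = max(yr) - min(yr), ml_length = max(xr) - min(xr))
}

#' Medial-lateral extent in embryo coordinates
#'
#' The ML (cable-to-cable) width of the outline in the native, unrotated
#' frame: maximum minus minimum x-coordinate. This is the quantity compared
#' against the 80 um registration threshold.
#'
#' @inheritParams polygon_area
#' @return ML extent in um.
#' @export
ml_extent <- function(vertices) {
  m <- as_vertex_matrix(vertices)
  if (nrow(m) < 3L) abort_validation("A polygon needs at least 3 vertices.")
  max(m[, 1]) - min(m[, 1])
}

# Split a lumen_series into a named list of vertex matrices, one per frame.
lumen_frame_list <- function(series) {
  parts <- split(series[, c("x", "y")], series$frame)
  lapply(parts, function(d) cbind(x = d$x, y = d$y))
}

#' Register the closure time origin from luminal outlines
#'
#' The time origin t0 is the last frame at which the ML extent of the lumen
#' exceeds `cable_threshold`. If no frame exceeds the threshold the first
#' frame is used and a fallback warning is emitted.
#'
#' @param series A [lumen_series()] object.
#' @param cable_threshold Threshold in um (default 80).
#' @return The t0 frame index (a value of `series$frame`).
#' @export
register_lumen_time <- function(series, cable_threshold = 80) {
  if (!inherits(series, "lumen_series")) abort_validation("`series` must be a `lumen_series`.")
  frames <- lumen_frame_list(series)
  ext <- vapply(frames, ml_extent, numeric(1))
  idx <- which(ext > cable_threshold)
  fr <- as.integer(names(frames))
  if (!length(idx)) {
    warn_fallback(sprintf(
      "No frame has ML extent > %g um; using the first frame as t0.", cable_threshold))
    return(fr[1])
  }
  fr[max(idx)]
}

#' Per-frame luminal morphometrics
#'
#' Computes, for every frame of a lumen series: area, perimeter, circularity,
#' maximum AP and ML axis lengths, the native ML extent, and the registered
#' time in minutes (negative before the t0 origin set by the 80 um rule).
#'
#' @param series A [lumen_series()] object.
#' @param config A [run_config()]; `cable_threshold` and the frame interval in
#'   the series metadata determine the registered time.
#' @return A tibble of class `lumen_metrics` with columns `embryo_id`,
#'   `frame`, `t_min`, `area_um2`, `perimeter_um`, `circularity`,
#'   `ap_len_um`, `ml_len_um`, `ml_extent_um`; attribute `t0`.
#' @export
compute_lumen_metrics <- function(series, config = run_config()) {
  meta <- series_meta(series)
  t0 <- register_lumen_time(series, config$cable_threshold)
  frames <- lumen_frame_list(series)
  fr <- as.integer(names(frames))
  res <- purrr::map2_dfr(frames, fr, function(m, f) {
    a <- tryCatch(polygon_area(m), error = function(e) {
      abort_validation(sprintf("Frame %d: %s", f, conditionMessage(e)))
    })
    p <- polygon_perimeter(m)
    ax <- max_axis_lengths(m)
    tibble::tibble(
      frame = f,
      area_um2 = a,
      perimeter_um = p,
      circularity = circularity(a, p),
      ap_len_um = ax[["ap_length"]],
      ml_len_um = ax[["ml_length"]],
      ml_extent_um = ml_extent(m)
    )
  })
  res <- dplyr::mutate(res,
    embryo_id = meta$embryo_id,
    t_min = (.data$frame - t0) * meta$frame_interval / 60,
    .before = 1
  )
  structure(res, meta = meta, t0 = t0,
            class = c("lumen_metrics", class(tibble::tibble())))
}
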