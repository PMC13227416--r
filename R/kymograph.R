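#' Render synthetic objects into an image stack
#'
#' Draws either nuclear tracks (one Gaussian spot per nucleus per frame) or a
#' luminal outline (Gaussian splats along the polygon edges) on a zero
#' background. Intensity is geometric only: there is no camera-noise model,
#' because the rendered stacks exist to test kymograph geometry.
#'
#' @param x An [embryo_tracks()] or [lumen_series()] object, in um.
#' @param image_size `c(height, width)` in pixels.
#' @param pixel_size um per pixel (default 1).
#' @param psf_sd Gaussian spot sd in um (default 1).
#' @param origin um coordinates `c(x, y)` mapped to pixel (1, 1).
#' @param frames Frame indices to render; defaults to the frames present in
#'   `x`. Required when `x` has no samples.
#' @return Numeric array `(frames, height, width)`.
#' @export
render_stack <- function(x, image_size = c(64, 64), pixel_size = 1,
                         psf_sd = 1, origin = c(0, 0), frames = NULL) {
  h <- image_size[1]; w <- image_size[2]
  if (is.null(frames)) {
    frames <- sort(unique(x$frame))
    if (!length(frames)) abort_validation("`x` has no frames; supply `frames` explicitly.")
  }
  stack <- array(0, dim = c(length(frames), h, w))
  if (!nrow(x)) return(stack)

  pts_for_frame <- function(d) {
    if (inherits(x, "lumen_series")) {
      # densify the outline so edges render as continuous curves
      m <- cbind(d$x, d$y)
      n <- nrow(m)
      j <- c(2:n, 1L)
      out <- vector("list", n)
      for (i in seq_len(n)) {
        len <- sqrt(sum((m[j[i], ] - m[i, ])^2))
        k <- max(1L, ceiling(len / (0.5 * pixel_size)))
        f <- seq(0, 1, length.out = k + 1L)[-(k + 1L)]
        out[[i]] <- cbind(m[i, 1] + f * (m[j[i], 1] - m[i, 1]),
                          m[i, 2] + f * (m[j[i], 2] - m[i, 2]))
      }
      do.call(rbind, out)
    } else {
      cbind(d$x, d$y)
    }
  }

  sigma_px <- psf_sd / pixel_size
  col_grid <- seq_len(w)
  row_grid <- seq_len(h)
  for (fi in seq_along(frames)) {
    d <- x[x$frame == frames[fi], ]
    if (!nrow(d)) next
    pts <- pts_for_frame(d)
    cx <- (pts[, 1] - origin[1]) / pixel_size + 1
    cy <- (pts[, 2] - origin[2]) / pixel_size + 1
    if (any(cx < 1 | cx > w | cy < 1 | cy > h)) {
      abort_validation(sprintf("Frame %d: object outside the field of view.", frames[fi]))
    }
    img <- matrix(0, h, w)
    for (k in seq_along(cx)) {
      gx <- exp(-(col_grid - cx[k])^2 / (2 * sigma_px^2))
      gy <- exp(-(row_grid - cy[k])^2 / (2 * sigma_px^2))
      img <- img + outer(gy, gx)
    }
    stack[fi, , ] <- img
  }
  stack
}

#' Build a kymograph from an image stack
#'
#' For each frame, the rectangular region is projected to a one-dimensional
#' profile by maximum intensity across the dimension perpendicular to `axis`;
#' profiles are stacked over time. The result has one row per frame and one
#' column per spatial position along the chosen axis.
#'
#' @param stack Numeric array `(frames, height, width)`.
#' @param rect `c(x0, y0, width, height)` in 1-based pixel coordinates
#'   (x = column, y = row).
#' @param axis `"horizontal"` (profile along x, max over y) or `"vertical"`
#'   (profile along y, max over x).
#' @param frame_interval Seconds between frames, stored for plotting.
#' @return A matrix of class `kymograph`, frames x space.
#' @export
kymograph <- function(stack, rect, axis = c("horizontal", "vertical"),
                      frame_interval = 15) {
  axis <- match.arg(axis)
  if (length(dim(stack)) != 3L) abort_validation("`stack` must be a 3-D array (frames, height, width).")
  if (length(rect) != 4L) abort_validation("`rect` must be c(x0, y0, width, height).")
  x0 <- rect[1]; y0 <- rect[2]; rw <- rect[3]; rh <- rect[4]
  h <- dim(stack)[2]; w <- dim(stack)[3]
  if (rw < 1 || rh < 1 || x0 < 1 || y0 < 1 || x0 + rw - 1 > w || y0 + rh - 1 > h) {
    abort_validation(sprintf(
      "Rect [%g, %g, %g, %g] is outside the %d x %d image.", x0, y0, rw, rh, h, w))
  }
  sub <- stack[, y0:(y0 + rh - 1), x0:(x0 + rw - 1), drop = FALSE]
  out <- if (axis == "horizontal") apply(sub, c(1, 3), max) else apply(sub, c(1, 2), max)
  out <- matrix(out, nrow = dim(sub)[1]) # guard against dropped dims
  structure(out, axis = axis, rect = rect, frame_interval = frame_interval,
            class = c("kymograph", "matrix", "array"))
}
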