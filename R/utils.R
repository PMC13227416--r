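# Internal helpers shared across modules.

abort_format <- function(msg, ...) {
  rlang::abort(msg, class = "cardiomorph_format_error", ...)
}

abort_validation <- function(msg, ...) {
  rlang::abort(msg, class = "cardiomorph_validation_error", ...)
}

abort_insufficient <- function(msg, ...) {
  rlang::abort(msg, class = "cardiomorph_insufficient_data_error", ...)
}

warn_fallback <- function(msg) {
  rlang::warn(msg, class = "cardiomorph_fallback_warning")
}

# Coerce polygon vertices (two-column matrix or data frame with x/y) to a
# numeric matrix, dropping a repeated closing vertex if present.
as_vertex_matrix <- function(vertices) {
  if (is.matrix(vertices)) {
    if (ncol(vertices) != 2) {
      abort_validation("`vertices` matrix must have exactly two columns (x, y).")
    }
    m <- cbind(x = as.numeric(vertices[, 1]), y = as.numeric(vertices[, 2]))
  } else if (is.data.frame(vertices)) {
    if (!all(c("x", "y") %in% names(vertices))) {
      abort_validation("`vertices` must contain columns `x` and `y`.")
    }
    m <- cbind(x = as.numeric(vertices$x), y = as.numeric(vertices$y))
  } else {
    abort_validation("`vertices` must be a two-column matrix or a data frame with `x` and `y`.")
  }
  if (anyNA(m)) abort_validation("Polygon vertices contain missing values.")
  n <- nrow(m)
  if (n >= 2 && all(abs(m[n, ] - m[1, ]) < 1e-12)) m <- m[-n, , drop = FALSE]
  m
}

# Centered moving average with shrinking windows at the boundaries, so the
# smoothed series has the same length and no NA padding.
moving_average <- function(x, window) {
  window <- as.integer(window)
  if (window <= 1L) return(x)
  n <- length(x)
  half <- window %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# TRUE when the closed polygon has no proper self-intersection between
# non-adjacent edges. O(n^2) segment test, vectorised over the inner edge;
# used only at validation time.
is_simple_polygon <- function(m) {
  n <- nrow(m)
  if (n < 3L) return(FALSE)
  px <- m[, 1]; py <- m[, 2]
  nx <- c(2:n, 1L)
  qx <- px[nx]; qy <- py[nx]
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    j <- (i + 2L):n
    if (i == 1L) j <- j[j != n] # wrap-around pair shares a vertex
    if (!length(j)) next
    d1 <- cross(px[i], py[i], qx[i], qy[i], px[j], py[j])
    d2 <- cross(px[i], py[i], qx[i], qy[i], qx[j], qy[j])
    d3 <- cross(px[j], py[j], qx[j], qy[j], px[i], py[i])
    d4 <- cross(px[j], py[j], qx[j], qy[j], qx[i], qy[i])
    hit <- ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
           ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
    if (any(hit)) return(FALSE)
  }
  TRUE
}
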