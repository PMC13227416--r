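# Fixtures and independent oracles used across the suite. The oracles are
# deliberately naive (grid searches, full enumeration) so they stay
# independent of the implementation paths they check.

meta_fixture <- function(id = "e1", sex = "unknown", frame_interval = 15) {
  embryo_meta(id, sex, frame_interval = frame_interval)
}

unit_square <- function() data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))

regular_polygon <- function(n, r = 1, cx = 0, cy = 0) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  data.frame(x = cx + r * cos(th), y = cy + r * sin(th))
}

ellipse_vertices <- function(a, b, n = 64, angle = 0, cx = 0, cy = 0) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  x0 <- a * cos(th); y0 <- b * sin(th)
  data.frame(x = cx + x0 * cos(angle) - y0 * sin(angle),
             y = cy + x0 * sin(angle) + y0 * cos(angle))
}

rotate_vertices <- function(v, angle) {
  data.frame(x = v$x * cos(angle) - v$y * sin(angle),
             y = v$x * sin(angle) + v$y * cos(angle))
}

# Random convex polygon: points on an ellipse at sorted random angles.
random_convex_polygon <- function(n = 12, a = NULL, b = NULL) {
  if (is.null(a)) a <- runif(1, 1, 10)
  if (is.null(b)) b <- runif(1, 1, 10)
  th <- sort(runif(n, 0, 2 * pi))
  ang <- runif(1, 0, pi)
  rotate_vertices(data.frame(x = a * cos(th), y = b * sin(th)), ang)
}

# Brute-force longest-axis oracle: scan rotation angles on a fine grid and
# take the angle maximising the vertical extent; report (max y-extent,
# x-extent at that angle).
brute_force_axis_lengths <- function(v, step_deg = 0.01) {
  th <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  X <- outer(sin(th), v$x) # y' = x sin(th) + y cos(th) under rotation by th
  Y <- outer(cos(th), v$y)
  yr <- X + Y
  ext <- do.call(pmax, as.data.frame(yr)) - do.call(pmin, as.data.frame(yr))
  best <- which.max(ext)
  xr <- outer(cos(th[best]), v$x) - outer(sin(th[best]), v$y)
  c(ap_length = ext[best], ml_length = max(xr) - min(xr))
}

# Full-enumeration two-sided Mann-Whitney p-value (tie-free data): every
# C(n1 + n2, n1) assignment of the pooled values to group 1.
mw_enum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pool <- c(x, y)
  u_of <- function(ix) {
    r <- rank(pool)
    sum(r[ix]) - n1 * (n1 + 1) / 2
  }
  obs <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  cmb <- utils::combn(n1 + n2, n1)
  us <- apply(cmb, 2, u_of)
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# A single simulated nucleus track as a plain tibble.
sim_track <- function(t_min, x, y = 0, frame_interval = 15) {
  tibble::tibble(frame = seq_along(t_min), x = x,
                 y = if (length(y) == 1L) rep(y, length(t_min)) else y)
}
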