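test_that("area, perimeter and circularity match hand calculations", {
  sq <- unit_square()
  expect_equal(polygon_area(sq), 1)
  expect_equal(polygon_perimeter(sq), 4)
  expect_equal(circularity(polygon_area(sq), polygon_perimeter(sq)), pi / 4)
  tri <- data.frame(x = c(0, 1, 0), y = c(0, 0, 1))
  expect_equal(polygon_area(tri), 0.5)
  expect_equal(polygon_perimeter(data.frame(x = c(0, 3, 0), y = c(0, 0, 4))), 12)
  # orientation invariance
  expect_equal(polygon_area(sq[4:1, ]), 1)
  # translation invariance
  shifted <- data.frame(x = sq$x + 100, y = sq$y - 7)
  expect_equal(polygon_perimeter(shifted), 4)
  expect_equal(ml_extent(sq), 1)
  expect_equal(ml_extent(shifted), 1)
  # thin rectangle: c = 4*pi*1 / 20.2^2
  rect <- data.frame(x = c(0, 10, 10, 0), y = c(0, 0, 0.1, 0.1))
  expect_equal(circularity(polygon_area(rect), polygon_perimeter(rect)),
               4 * pi / 20.2^2, tolerance = 1e-12)
  expect_error(polygon_area(data.frame(x = c(0, 1, 2), y = c(0, 1, 2))),
               class = "cardiomorph_validation_error") # collinear
})

test_that("a fine regular polygon approaches the circle's circularity of 1", {
  v <- regular_polygon(360)
  cc <- circularity(polygon_area(v), polygon_perimeter(v))
  expect_gte(cc, 0.99995)
  expect_lte(cc, 1 + 1e-9)
})

test_that("longest-axis lengths match analytic shapes at any input rotation", {
  for (ang in c(0, 0.4, 1.2, 2.9)) {
    ax <- max_axis_lengths(ellipse_vertices(3, 1, n = 64, angle = ang))
    expect_equal(unname(ax["ap_length"]), 6, tolerance = 2e-3)
    expect_equal(unname(ax["ml_length"]), 2, tolerance = 2e-2)
    expect_gte(ax[["ap_length"]], ax[["ml_length"]])
  }
  circ <- regular_polygon(256, r = 5)
  ax <- max_axis_lengths(circ)
  expect_equal(unname(ax["ap_length"]), 10, tolerance = 1e-2)
  expect_equal(unname(ax["ml_length"]), 10, tolerance = 1e-2)
  # 4 x 2 rectangle: long axis is the diagonal
  rect <- data.frame(x = c(0, 4, 4, 0), y = c(0, 0, 2, 2))
  ax <- max_axis_lengths(rect)
  expect_equal(unname(ax["ap_length"]), sqrt(20), tolerance = 1e-9)
  expect_equal(unname(ax["ml_length"]), 8 / sqrt(5), tolerance = 1e-9)
})

test_that("scaling scales area by s^2, perimeter by s, circularity not at all", {
  withr::local_seed(11)
  for (i in 1:20) {
    v <- random_convex_polygon(n = sample(6:20, 1))
    s <- runif(1, 0.2, 5)
    vs <- data.frame(x = v$x * s, y = v$y * s)
    expect_equal(polygon_area(vs), s^2 * polygon_area(v), tolerance = 1e-9)
    expect_equal(polygon_perimeter(vs), s * polygon_perimeter(v), tolerance = 1e-9)
    c1 <- circularity(polygon_area(v), polygon_perimeter(v))
    c2 <- circularity(polygon_area(vs), polygon_perimeter(vs))
    expect_equal(c1, c2, tolerance = 1e-9)
    expect_lte(c1, 1 + 1e-9)
  }
})

test_that("metrics are invariant under rigid rotation of the input", {
  withr::local_seed(12)
  for (i in 1:10) {
    v <- random_convex_polygon(n = 15)
    ang <- runif(1, 0, 2 * pi)
    vr <- rotate_vertices(v, ang)
    expect_equal(polygon_area(vr), polygon_area(v), tolerance = 1e-6)
    expect_equal(polygon_perimeter(vr), polygon_perimeter(v), tolerance = 1e-6)
    a1 <- max_axis_lengths(v); a2 <- max_axis_lengths(vr)
    expect_equal(unname(a2["ap_length"]), unname(a1["ap_length"]), tolerance = 1e-6)
    expect_equal(unname(a2["ml_length"]), unname(a1["ml_length"]), tolerance = 1e-6)
  }
})

test_that("longest-axis lengths agree with the rotation grid-search oracle", {
  withr::local_seed(13)
  for (i in 1:10) {
    v <- random_convex_polygon(n = sample(8:16, 1))
    got <- max_axis_lengths(v)
    ref <- brute_force_axis_lengths(v)
    expect_equal(unname(got["ap_length"]), unname(ref["ap_length"]),
                 tolerance = 1e-3)
    expect_equal(unname(got["ml_length"]), unname(ref["ml_length"]),
                 tolerance = 1e-3)
  }
})

test_that("time registration takes the last threshold exceedance", {
  mk <- function(widths) {
    tbl <- do.call(rbind, lapply(seq_along(widths), function(i) {
      v <- ellipse_vertices(widths[i] / 2, 10, n = 32)
      cbind(frame = i - 1, v)
    }))
    lumen_series(tbl, meta_fixture())
  }
  s <- mk(c(90, 85, 81, 78, 60))
  expect_identical(register_lumen_time(s, 80), 2L)
  expect_identical(register_lumen_time(mk(c(90, 85, 82)), 80), 2L) # all above -> last
  expect_warning(t0 <- register_lumen_time(mk(c(70, 60, 50)), 80),
                 class = "cardiomorph_fallback_warning")
  expect_identical(t0, 0L)
})

test_that("per-frame metrics compose correctly and carry registered time", {
  sq <- cbind(frame = 1, unit_square())
  m <- suppressWarnings(compute_lumen_metrics(lumen_series(sq, meta_fixture())))
  expect_equal(m$area_um2, 1)
  expect_equal(m$perimeter_um, 4)
  expect_equal(m$circularity, pi / 4)
  # shrinking ellipse with constant aspect ratio: circularity constant
  tbl <- do.call(rbind, lapply(1:5, function(i) {
    s <- 0.8^i
    cbind(frame = i, ellipse_vertices(30 * s, 10 * s, n = 64))
  }))
  ms <- suppressWarnings(compute_lumen_metrics(lumen_series(tbl, meta_fixture())))
  expect_lt(diff(range(ms$circularity)), 1e-9)
  # registered time steps by the frame interval in minutes
  expect_equal(diff(ms$t_min), rep(0.25, 4))
})
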