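test_that("metadata and configuration reject invalid values", {
  expect_s3_class(embryo_meta("e1", "female"), "embryo_meta")
  expect_error(embryo_meta("e1", frame_interval = 0), class = "cardiomorph_validation_error")
  expect_error(embryo_meta("e1", pixel_size = -1), class = "cardiomorph_validation_error")
  cfg <- run_config()
  expect_equal(cfg$cable_threshold, 80)
  expect_equal(cfg$nuclei_threshold, 65)
  expect_error(run_config(cable_threshold = -5), class = "cardiomorph_validation_error")
  expect_error(run_config(max_autocorr_lag_fraction = 1.5), class = "cardiomorph_validation_error")
})

test_that("config files fill in defaults and reject unknown fields", {
  path <- withr::local_tempfile(fileext = ".yml")
  writeLines("nuclei_threshold: 60\nseed: 7", path)
  cfg <- read_run_config(path)
  expect_equal(cfg$nuclei_threshold, 60)
  expect_equal(cfg$seed, 7L)
  expect_equal(cfg$cable_threshold, 80) # default preserved
  writeLines("nuclei_thresold: 60", path)
  expect_error(read_run_config(path), class = "cardiomorph_format_error")
})

test_that("track tables round-trip losslessly and are sorted by frame", {
  tbl <- tibble::tibble(
    cardioblast_id = rep(c("a", "b"), each = 3),
    row = rep(c("left", "right"), each = 3),
    frame = c(3L, 1L, 2L, 1L, 2L, 3L),
    x = c(-30.1, -30.5, -30.3, 30.2, 30.1, 30.05),
    y = c(5, 5.1, 5.05, 5, 5.2, 5.1)
  )
  tr <- embryo_tracks(tbl, meta_fixture())
  expect_equal(tr$frame[tr$cardioblast_id == "a"], 1:3) # re-sorted ascending
  expect_equal(tr$x[tr$cardioblast_id == "a"], c(-30.5, -30.3, -30.1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks(tr, path)
  back <- read_tracks(path, meta_fixture())
  expect_equal(as.data.frame(back), as.data.frame(tr), tolerance = 1e-12)
})

test_that("track readers reject structural problems by name", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(cardioblast_id = "a", frame = 1, x = 0, y = 0), path)
  expect_error(read_tracks(path, meta_fixture()), "row",
               class = "cardiomorph_format_error")
  dup <- tibble::tibble(cardioblast_id = "a", row = "left",
                        frame = c(1, 1), x = c(0, 1), y = c(0, 0))
  expect_error(embryo_tracks(dup, meta_fixture()), "duplicated frame",
               class = "cardiomorph_validation_error")
  bad_row <- tibble::tibble(cardioblast_id = "a", row = "center",
                            frame = 1, x = 0, y = 0)
  expect_error(embryo_tracks(bad_row, meta_fixture()), class = "cardiomorph_validation_error")
})

test_that("lumen annotations round-trip to below 1e-9 um", {
  v <- regular_polygon(17, r = 40.123456789)
  tbl <- rbind(cbind(frame = 1, v), cbind(frame = 2, v * 0.5))
  series <- lumen_series(tbl, meta_fixture())
  path <- withr::local_tempfile(fileext = ".json")
  write_lumen_annotations(series, path)
  back <- read_lumen_annotations(path, meta_fixture())
  expect_equal(nrow(back), nrow(series))
  expect_lt(max(abs(back$x - series$x)), 1e-9)
  expect_lt(max(abs(back$y - series$y)), 1e-9)
})

test_that("lumen validation rejects bad polygons and names the frame", {
  two <- data.frame(frame = 1, x = c(0, 1), y = c(0, 0))
  expect_error(lumen_series(two, meta_fixture()), "fewer than 3",
               class = "cardiomorph_validation_error")
  bow <- data.frame(frame = 4, x = c(0, 1, 1, 0), y = c(0, 1, 0, 1))
  expect_error(lumen_series(bow, meta_fixture()), "Frame 4",
               class = "cardiomorph_validation_error")
  # a repeated closing vertex is deduplicated, not an error
  sq <- data.frame(frame = 1, x = c(0, 1, 1, 0, 0), y = c(0, 0, 1, 1, 0))
  s <- lumen_series(sq, meta_fixture())
  expect_equal(nrow(s), 4L)
})

test_that("image stacks round-trip with the expected shape", {
  tr <- gen_tracks(track_sim_params(n_per_row = 1, n_frames = 5,
                                    position_noise_sd = 0, seed = 1))
  stack <- render_stack(tr, image_size = c(32, 48), pixel_size = 2,
                        origin = c(-45, -5))
  expect_equal(dim(stack), c(5, 32, 48))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(stack, path)
  back <- read_stack(path)
  expect_equal(dim(back), c(5, 32, 48))
  expect_equal(back, stack / max(stack), tolerance = 1e-6)
  # single frame
  write_stack(stack[1, , , drop = FALSE], path)
  expect_equal(dim(read_stack(path))[1], 1L)
})

test_that("unreadable stack files raise a format error", {
  path <- withr::local_tempfile(fileext = ".tif")
  writeLines("this is not a tiff", path)
  expect_error(read_stack(path), class = "cardiomorph_format_error")
  expect_error(read_stack(file.path(tempdir(), "absent.tif")),
               class = "cardiomorph_format_error")
})
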