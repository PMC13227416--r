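two_row_tracks <- function(n_per_row = 3, frames = 1:10, sep = 70,
                           shuffle = FALSE) {
  rows <- purrr::map_dfr(seq_len(n_per_row), function(j) {
    dplyr::bind_rows(
      tibble::tibble(cardioblast_id = sprintf("L%d", j), row = "left",
                     frame = frames, x = -sep / 2, y = 5 * j),
      tibble::tibble(cardioblast_id = sprintf("R%d", j), row = "right",
                     frame = frames, x = sep / 2, y = 5 * j))
  })
  if (shuffle) rows <- rows[sample(nrow(rows)), ]
  embryo_tracks(rows, meta_fixture())
}

test_that("contralateral pairing is by AP rank and order-free", {
  tr <- two_row_tracks(3)
  p <- pair_contralateral(tr)
  expect_equal(nrow(p), 3L)
  expect_equal(p$left_id, c("L1", "L2", "L3"))
  expect_equal(p$right_id, c("R1", "R2", "R3"))
  withr::local_seed(4)
  p2 <- pair_contralateral(two_row_tracks(3, shuffle = TRUE))
  expect_equal(p2, p)
  # surplus tracks on one side are unpaired and reported
  tr4 <- two_row_tracks(4)
  tr4 <- embryo_tracks(tr4[tr4$cardioblast_id != "R4", ], meta_fixture())
  expect_message(p3 <- pair_contralateral(tr4), "L4")
  expect_equal(nrow(p3), 3L)
  one_row <- embryo_tracks(tr[tr$row == "left", ], meta_fixture())
  expect_error(pair_contralateral(one_row), class = "cardiomorph_validation_error")
})

test_that("pair distances are Euclidean, per frame, with mean across pairs", {
  tr <- two_row_tracks(3, sep = 70)
  pd <- contralateral_distance(tr)
  expect_true(all(pd$distance == 70))
  ms <- mean_pair_distance(pd)
  expect_true(all(ms$mean_distance == 70))
  expect_true(all(ms$n_pairs == 3))
  # single 3-4-5 pair
  tbl <- dplyr::bind_rows(
    tibble::tibble(cardioblast_id = "L1", row = "left", frame = 1, x = 0, y = 0),
    tibble::tibble(cardioblast_id = "R1", row = "right", frame = 1, x = 3, y = 4))
  expect_equal(contralateral_distance(embryo_tracks(tbl, meta_fixture()))$distance, 5)
  # no common frames is an error
  tbl2 <- dplyr::bind_rows(
    tibble::tibble(cardioblast_id = "L1", row = "left", frame = 1:2, x = 0, y = 0),
    tibble::tibble(cardioblast_id = "R1", row = "right", frame = 3:4, x = 3, y = 4))
  expect_error(contralateral_distance(embryo_tracks(tbl2, meta_fixture())),
               class = "cardiomorph_validation_error")
})

test_that("synthetic converging rows give a decreasing distance series", {
  # pure drift: strictly monotone
  tr <- gen_tracks(track_sim_params(mode = "drift_sinusoid", sin_amplitude = 0,
                                    n_per_row = 5, position_noise_sd = 0,
                                    n_frames = 61, seed = 1))
  ms <- mean_pair_distance(contralateral_distance(tr))
  expect_true(all(diff(ms$mean_distance) <= 1e-9))
  # ratchet: retreat phases oscillate, but the trend is convergence
  tr2 <- gen_tracks(track_sim_params(mode = "ratchet", n_per_row = 5,
                                     position_noise_sd = 0.2, n_frames = 121,
                                     seed = 2))
  ms2 <- mean_pair_distance(contralateral_distance(tr2))
  expect_lt(ms2$mean_distance[nrow(ms2)], ms2$mean_distance[1] - 10)
})

test_that("track registration takes the last frame above the nuclei threshold", {
  s <- tibble::tibble(frame = 0:4, mean_distance = c(80, 70, 66, 64, 50))
  expect_identical(register_tracks_time(s, 65), 2L)
  expect_identical(register_tracks_time(
    tibble::tibble(frame = 0:2, mean_distance = c(80, 75, 70)), 65), 2L)
  expect_warning(
    t0 <- register_tracks_time(
      tibble::tibble(frame = 0:2, mean_distance = c(60, 55, 50)), 65),
    class = "cardiomorph_fallback_warning")
  expect_identical(t0, 0L)
})

test_that("migration speed is the OLS slope of displacement over time", {
  t_min <- seq(0, 60, by = 0.25)
  tr <- sim_track(t_min, x = 40 - 23.0 / 60 * t_min)
  expect_equal(migration_speed(tr), 23.0, tolerance = 1e-9)
  expect_equal(migration_speed(sim_track(t_min, x = rep(12, length(t_min)))), 0,
               tolerance = 1e-9)
  expect_error(migration_speed(sim_track(c(0, 1), x = c(0, 1))),
               class = "cardiomorph_insufficient_data_error")
})

test_that("speed is insensitive to the oscillatory component", {
  withr::local_seed(31)
  errs <- replicate(50, {
    t_min <- seq(0, 60, by = 0.25)
    x <- 40 - (22.4 / 60 * t_min + 1 * sin(2 * pi * t_min / 1.4)) +
      rnorm(length(t_min), 0, 0.2)
    migration_speed(sim_track(t_min, x = x)) - 22.4
  })
  expect_true(all(abs(errs) <= 0.05 * 22.4))
})

test_that("medial velocity is positive toward the midline for either row", {
  right <- sim_track(c(0, 1), x = c(40, 30))
  right$frame <- c(1L, 5L) # 4 frames * 15 s = 1 min
  v <- medial_velocity(right, midline_x = 0)
  expect_equal(v$velocity, 10)
  left <- sim_track(c(0, 1), x = c(-40, -30))
  left$frame <- c(1L, 5L)
  expect_equal(medial_velocity(left, midline_x = 0)$velocity, 10)
  still <- sim_track(seq(0, 5, 0.25), x = 7)
  expect_true(all(medial_velocity(still, 0)$velocity == 0))
})

test_that("oscillation period is read off the first autocorrelation peak", {
  t_min <- seq(0, 40, by = 0.25)
  v_on <- sin(2 * pi * t_min / 2.0)
  expect_equal(oscillation_period(v_on), 2.0, tolerance = 0.01)
  v_off <- sin(2 * pi * t_min / 1.7)
  expect_equal(oscillation_period(v_off), 1.7, tolerance = 0.05)
  expect_error(oscillation_period(rnorm(5)), class = "cardiomorph_insufficient_data_error")
  expect_true(is.na(oscillation_period(rep(0, 50))))
})

test_that("white-noise velocity yields no period in at least 90% of seeds", {
  miss <- vapply(1:50, function(i) {
    withr::with_seed(i, is.na(oscillation_period(rnorm(160))))
  }, logical(1))
  expect_gte(mean(miss), 0.9)
})

test_that("period recovery tolerates 20% velocity noise across periods", {
  for (period in c(1.0, 1.4, 1.7, 2.5)) {
    errs <- vapply(1:50, function(i) {
      withr::with_seed(1000 * period + i, {
        t_min <- seq(0, 40, by = 0.25)
        v <- sin(2 * pi * t_min / period) + rnorm(length(t_min), 0, 0.2)
        abs(oscillation_period(v) - period)
      })
    }, numeric(1))
    expect_lte(median(errs, na.rm = TRUE), 0.1)
  }
})

test_that("step decomposition recovers a noiseless ratchet exactly", {
  tr <- gen_tracks(track_sim_params(
    mode = "ratchet", n_per_row = 1, medial_step = 1.9, lateral_step = 0.8,
    period = 1.7, position_noise_sd = 0, n_frames = 121, seed = 1))
  mid <- estimate_midline(tr)
  st <- step_decomposition(tr[tr$cardioblast_id == "L01", ], mid)
  expect_equal(st$medial_amp, 1.9, tolerance = 1e-9)
  expect_equal(st$lateral_amp, 0.8, tolerance = 1e-9)
  expect_identical(st$net_medial_step, st$medial_amp - st$lateral_amp)
})

test_that("step amplitudes survive small positional noise", {
  withr::local_seed(41)
  res <- purrr::map_dfr(1:10, function(i) {
    tr <- gen_tracks(track_sim_params(
      mode = "ratchet", n_per_row = 1, medial_step = 1.9, lateral_step = 0.8,
      period = 1.7, position_noise_sd = 0.1, n_frames = 241, seed = i))
    step_decomposition(tr[tr$cardioblast_id == "R01", ], estimate_midline(tr))
  })
  expect_lt(abs(mean(res$medial_amp) - 1.9), 0.1)
  expect_lt(abs(mean(res$lateral_amp) - 0.8), 0.1)
})

test_that("a pure sinusoid has symmetric steps of twice the amplitude", {
  t_min <- seq(0, 30, by = 0.25)
  tr <- sim_track(t_min, x = 40 + 1.5 * sin(2 * pi * t_min / 2))
  st <- step_decomposition(tr, midline_x = 0)
  expect_equal(st$medial_amp, 3, tolerance = 1e-6)
  expect_equal(st$lateral_amp, 3, tolerance = 1e-6)
  expect_equal(st$net_medial_step, 0, tolerance = 1e-6)
})

test_that("degenerate trajectories obey the step contracts", {
  t_min <- seq(0, 10, by = 0.25)
  mono <- sim_track(t_min, x = 40 - 0.5 * t_min)
  st <- step_decomposition(mono, midline_x = 0)
  expect_equal(st$n_medial_steps, 1L)
  expect_equal(st$n_lateral_steps, 0L)
  expect_equal(st$medial_amp, 5, tolerance = 1e-9)
  expect_equal(st$lateral_amp, 0)
  flat <- sim_track(t_min, x = 40)
  expect_warning(st2 <- step_decomposition(flat, midline_x = 0),
                 class = "cardiomorph_fallback_warning")
  expect_true(is.na(st2$medial_amp))
  expect_error(step_decomposition(sim_track(1:3, x = 1:3), 0),
               class = "cardiomorph_insufficient_data_error")
})

test_that("net medial step is the exact amplitude difference on random tracks", {
  withr::local_seed(51)
  for (i in 1:15) {
    t_min <- seq(0, 30, by = 0.25)
    x <- 40 - cumsum(rnorm(length(t_min), 0.05, 0.5))
    st <- suppressWarnings(step_decomposition(sim_track(t_min, x = x), 0))
    if (!is.na(st$medial_amp)) {
      expect_identical(st$net_medial_step, st$medial_amp - st$lateral_amp)
    }
  }
})

test_that("all metrics are mirror symmetric about the midline", {
  tr <- gen_tracks(track_sim_params(mode = "ratchet", n_per_row = 2,
                                    position_noise_sd = 0.1, n_frames = 121, seed = 9))
  mirrored <- tr
  mirrored$x <- -mirrored$x
  mirrored$row <- ifelse(mirrored$row == "left", "right", "left")
  m1 <- cardioblast_metrics(tr)
  m2 <- cardioblast_metrics(embryo_tracks(mirrored, meta_fixture()))
  for (col in c("speed_um_hr", "period_min", "medial_amp_um",
                "lateral_amp_um", "net_medial_step_um")) {
    expect_equal(m2[[col]], m1[[col]], tolerance = 1e-9)
  }
})

test_that("embryo summaries average per-cardioblast metrics", {
  tr <- gen_tracks(track_sim_params(mode = "ratchet", n_per_row = 1,
                                    position_noise_sd = 0, n_frames = 121, seed = 1))
  cm <- cardioblast_metrics(tr)
  expect_equal(nrow(cm), 2L)
  sm <- embryo_oscillation_summary(tr)
  # both tracks are generated identically, so the mean equals the track value
  expect_equal(sm$medial_amp_um, cm$medial_amp_um[1], tolerance = 1e-9)
  expect_equal(sm$speed_um_hr, mean(cm$speed_um_hr), tolerance = 1e-12)
  expect_equal(sm$n_cardioblasts, 2L)
})
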