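#' Parameters for the synthetic lumen generator
#'
#' The generated lumen is an elliptical polygon whose anterior-posterior
#' extent stays fixed while the medial-lateral width carries the closure, so
#' the luminal area decays as `A0 * exp(-k_true * t)` and the ML extent
#' crosses the 80 um registration threshold at the last plateau frame. The
#' decay-onset ML width defaults to `plateau_ml` (just above the threshold)
#' unless an `aspect_ratio` (AP/ML at onset) is given explicitly.
#'
#' @param A0 Luminal area at decay onset, um^2.
#' @param k_true Generating closure rate constant, hr^-1.
#' @param plateau_frames Frames held at the onset shape before decay; the
#'   last of them is the true registration origin.
#' @param n_frames Total frames (plateau + decay).
#' @param frame_interval Seconds between frames (default 15).
#' @param vertex_count Polygon vertices per frame (default 100).
#' @param vertex_noise_sd Gaussian jitter per vertex coordinate, um.
#' @param area_noise_frac Multiplicative area noise (sd of the per-frame
#'   area factor), applied as an isotropic scale.
#' @param plateau_ml ML extent at decay onset, um; must exceed 80 so the
#'   plateau is above the registration threshold (default 80.3).
#' @param aspect_ratio Optional AP/ML ratio at onset; overrides `plateau_ml`
#'   as the shape constraint.
#' @param seed Integer seed; the generator is a pure function of its
#'   parameters.
#' @param embryo_id,sex Metadata for the generated embryo.
#' @return A list of class `lumen_sim_params`.
#' @export
lumen_sim_params <- function(A0 = 1000, k_true = 1.4, plateau_frames = 10,
                             n_frames = 250, frame_interval = 15,
                             vertex_count = 100, vertex_noise_sd = 0.1,
                             area_noise_frac = 0.05, plateau_ml = 80.3,
                             aspect_ratio = NULL, seed = 1L,
                             embryo_id = "sim_lumen", sex = "unknown") {
  if (A0 <= 0 || k_true < 0 || n_frames < 1 || frame_interval <= 0 ||
      vertex_count < 8 || vertex_noise_sd < 0 || area_noise_frac < 0 ||
      plateau_frames < 0 || plateau_frames >= n_frames) {
    abort_validation("Invalid lumen simulation parameters.")
  }
  if (is.null(aspect_ratio) && plateau_ml <= 80) {
    abort_validation("`plateau_ml` must exceed the 80 um registration threshold.")
  }
  structure(as.list(environment()), class = "lumen_sim_params")
}

# Elliptical polygon with exact target area and ML extent.
ellipse_polygon_exact <- function(area, ml_width, n) {
  theta <- 2 * pi * (seq_len(n) - 1) / n
  ex <- max(cos(theta)) - min(cos(theta)) # extent factor of the unit circle
  a <- ml_width / ex
  b <- 2 * area / (n * a * sin(2 * pi / n))
  cbind(x = a * cos(theta), y = b * sin(theta))
}

#' Generate a synthetic closing-lumen polygon series
#'
#' `plateau_frames` frames hold the decay-onset shape (ML extent
#' `plateau_ml` > 80 um), then the area follows `A0 * exp(-k_true * t)` with
#' `t` measured from the last plateau frame. Without noise the polygon area
#' matches the exponential exactly and [register_lumen_time()] returns the
#' last plateau frame.
#'
#' @param params A [lumen_sim_params()] object.
#' @return A [lumen_series()] object.
#' @export
gen_lumen_series <- function(params = lumen_sim_params()) {
  if (!inherits(params, "lumen_sim_params")) {
    abort_validation("`params` must come from `lumen_sim_params()`.")
  }
  p <- params
  ml0 <- if (is.null(p$aspect_ratio)) p$plateau_ml else sqrt(4 * p$A0 / (pi * p$aspect_ratio))
  withr::with_seed(p$seed, {
    tbl <- purrr::map_dfr(seq_len(p$n_frames), function(i) {
      t_hr <- max(0, i - p$plateau_frames) * p$frame_interval / 3600
      decay <- exp(-p$k_true * t_hr)
      m <- ellipse_polygon_exact(p$A0 * decay, ml0 * decay, p$vertex_count)
      if (p$area_noise_frac > 0) {
        g <- max(0.1, 1 + stats::rnorm(1, 0, p$area_noise_frac))
        m <- m * sqrt(g)
      }
      if (p$vertex_noise_sd > 0) {
        m <- m + stats::rnorm(length(m), 0, p$vertex_noise_sd)
      }
      tibble::tibble(frame = i, x = m[, 1], y = m[, 2])
    })
  })
  meta <- embryo_meta(p$embryo_id, p$sex, frame_interval = p$frame_interval)
  lumen_series(tbl, meta, validate = FALSE)
}

#' Parameters for the synthetic cardioblast track generator
#'
#' Two contralateral rows of nuclei start at `x = +/- initial_separation/2`
#' and advance toward the midline following one of two medial waveforms:
#' `drift_sinusoid` (`m(t) = v t + B sin(2 pi t / T)`) or `ratchet`
#' (repeated linear advance of `medial_step` then retreat of `lateral_step`).
#' Ratchet phases are quantised to an integer number of frames
#' (`round(period / (2 * frame_interval))`) so that the waveform extrema lie
#' on the sampling grid and the step amplitudes are exactly recoverable.
#'
#' @param mode `"drift_sinusoid"` or `"ratchet"`.
#' @param n_per_row Nuclei per row (default 52).
#' @param initial_separation Starting row separation, um (default 75).
#' @param drift_speed Drift toward the midline, um/hr (drift_sinusoid mode).
#' @param period Oscillation period, minutes.
#' @param sin_amplitude Sinusoid amplitude, um (drift_sinusoid mode).
#' @param medial_step,lateral_step Per-cycle advance/retreat, um (ratchet).
#' @param position_noise_sd Gaussian noise per coordinate sample, um.
#' @param n_frames Number of frames.
#' @param frame_interval Seconds between frames (default 15).
#' @param row_spacing_ap AP spacing between adjacent nuclei, um.
#' @param seed Integer seed.
#' @param embryo_id,sex Metadata for the generated embryo.
#' @return A list of class `track_sim_params`.
#' @export
track_sim_params <- function(mode = c("drift_sinusoid", "ratchet"),
                             n_per_row = 52, initial_separation = 75,
                             drift_speed = 23, period = 1.7,
                             sin_amplitude = 1, medial_step = 1.9,
                             lateral_step = 0.8, position_noise_sd = 0.2,
                             n_frames = 241, frame_interval = 15,
                             row_spacing_ap = 5, seed = 1L,
                             embryo_id = "sim_tracks", sex = "unknown") {
  mode <- match.arg(mode)
  if (n_per_row < 1 || initial_separation <= 0 || n_frames < 2 ||
      frame_interval <= 0 || period <= 0 || position_noise_sd < 0 ||
      row_spacing_ap <= 0) {
    abort_validation("Invalid track simulation parameters.")
  }
  if (mode == "ratchet" && (medial_step <= 0 || lateral_step < 0)) {
    abort_validation("Ratchet mode needs `medial_step` > 0 and `lateral_step` >= 0.")
  }
  structure(as.list(environment()), class = "track_sim_params")
}

# Medial waveform shared by every nucleus of an embryo (um, per frame).
medial_waveform <- function(p) {
  i <- 0:(p$n_frames - 1L)
  t_min <- i * p$frame_interval / 60
  if (p$mode == "drift_sinusoid") {
    p$drift_speed / 60 * t_min + p$sin_amplitude * sin(2 * pi * t_min / p$period)
  } else {
    n_half <- max(1L, as.integer(round(p$period * 60 / (2 * p$frame_interval))))
    cyc <- i %/% (2L * n_half)
    pos <- i %% (2L * n_half)
    base <- cyc * (p$medial_step - p$lateral_step)
    adv <- pmin(pos, n_half) / n_half * p$medial_step
    ret <- pmax(pos - n_half, 0L) / n_half * p$lateral_step
    base + adv - ret
  }
}

#' Generate synthetic contralateral cardioblast tracks
#'
#' @param params A [track_sim_params()] object.
#' @return An [embryo_tracks()] object with `2 * n_per_row` tracks.
#' @export
gen_tracks <- function(params = track_sim_params()) {
  if (!inherits(params, "track_sim_params")) {
    abort_validation("`params` must come from `track_sim_params()`.")
  }
  p <- params
  m <- medial_waveform(p)
  frames <- seq_len(p$n_frames)
  half <- p$initial_separation / 2
  withr::with_seed(p$seed, {
    tbl <- purrr::map_dfr(seq_len(p$n_per_row), function(j) {
      y0 <- j * p$row_spacing_ap
      noise <- function(n) if (p$position_noise_sd > 0) stats::rnorm(n, 0, p$position_noise_sd) else 0
      dplyr::bind_rows(
        tibble::tibble(cardioblast_id = sprintf("L%02d", j), row = "left",
                       frame = frames, x = -half + m + noise(p$n_frames),
                       y = y0 + noise(p$n_frames)),
        tibble::tibble(cardioblast_id = sprintf("R%02d", j), row = "right",
                       frame = frames, x = half - m + noise(p$n_frames),
                       y = y0 + noise(p$n_frames))
      )
    })
  })
  meta <- embryo_meta(p$embryo_id, p$sex, frame_interval = p$frame_interval)
  embryo_tracks(tbl, meta)
}

#' Parameters for a two-group synthetic cohort
#'
#' Defaults mirror the study design: 7 female and 8 male lumen embryos, 6 and
#' 6 track embryos, 52 cardioblasts per row, and group means/SDs at the
#' reported values (closure rate 1.4 vs 1.2 hr^-1, SD 0.1; oscillation period
#' 1.7 vs 1.4 min, SD 0.8; medial step 1.9 vs 2.0 um; lateral step 0.8 vs
#' 0.7 um). Per-embryo parameters are drawn from the group mean with the
#' between-embryo SD (mildly truncated to stay physical).
#'
#' @param n_female_lumen,n_male_lumen Lumen embryos per group (7, 8).
#' @param n_female_tracks,n_male_tracks Track embryos per group (6, 6).
#' @param female,male Named lists of group means and SDs: `k`, `k_sd`,
#'   `period`, `period_sd`, `medial`, `medial_sd`, `lateral`, `lateral_sd`.
#' @param n_per_row Nuclei per row in track embryos (default 52).
#' @param lumen_frames,track_frames Frames per lumen / track embryo.
#' @param frame_interval Seconds between frames.
#' @param position_noise_sd,area_noise_frac,vertex_noise_sd Noise levels
#'   passed to the per-embryo generators.
#' @param seed Integer seed.
#' @return A list of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_female_lumen = 7, n_male_lumen = 8,
                              n_female_tracks = 6, n_male_tracks = 6,
                              female = list(k = 1.4, k_sd = 0.1,
                                            period = 1.7, period_sd = 0.8,
                                            medial = 1.9, medial_sd = 0.1,
                                            lateral = 0.8, lateral_sd = 0.1),
                              male = list(k = 1.2, k_sd = 0.1,
                                          period = 1.4, period_sd = 0.8,
                                          medial = 2.0, medial_sd = 0.2,
                                          lateral = 0.7, lateral_sd = 0.1),
                              n_per_row = 52, lumen_frames = 250,
                              track_frames = 121, frame_interval = 15,
                              position_noise_sd = 0.2, area_noise_frac = 0.05,
                              vertex_noise_sd = 0.1, seed = 1L) {
  if (n_female_lumen < 1 || n_male_lumen < 1 || n_female_tracks < 1 ||
      n_male_tracks < 1) {
    abort_validation("Each group needs at least one embryo of each modality.")
  }
  structure(as.list(environment()), class = "cohort_sim_params")
}

# Draw the per-embryo generating parameters for one group.
draw_embryo_params <- function(g, n, sex, modality, id_prefix) {
  if (!n) return(tibble::tibble())
  tibble::tibble(
    embryo_id = sprintf("%s%02d", id_prefix, seq_len(n)),
    sex = sex,
    modality = modality,
    k_true = pmax(0.2, stats::rnorm(n, g$k, g$k_sd)),
    period_true = pmax(0.6, stats::rnorm(n, g$period, g$period_sd)),
    medial_true = pmax(0.4, stats::rnorm(n, g$medial, g$medial_sd)),
    lateral_true = pmax(0.05, stats::rnorm(n, g$lateral, g$lateral_sd))
  ) |>
    dplyr::mutate(lateral_true = pmin(.data$lateral_true, 0.9 * .data$medial_true),
                  net_true = .data$medial_true - .data$lateral_true)
}

#' Generate a two-group synthetic cohort with ground truth
#'
#' Draws per-embryo parameters from the group distributions, then (unless
#' `simulate_data = FALSE`) generates the lumen series and ratchet-mode track
#' tables for every embryo. The returned ground-truth table records the
#' generating parameters for recovery tests; with identical `female` and
#' `male` parameter lists the cohort is a null cohort.
#'
#' @param params A [cohort_sim_params()] object.
#' @param simulate_data If `FALSE`, return only the ground-truth draw (fast
#'   path for calibration studies at the embryo level).
#' @return A list of class `cohort_sim`: `truth` (tibble), `lumens` (named
#'   list of [lumen_series()]), `tracks` (named list of [embryo_tracks()]),
#'   and `params`.
#' @export
gen_cohort <- function(params = cohort_sim_params(), simulate_data = TRUE) {
  if (!inherits(params, "cohort_sim_params")) {
    abort_validation("`params` must come from `cohort_sim_params()`.")
  }
  p <- params
  truth <- withr::with_seed(p$seed, dplyr::bind_rows(
    draw_embryo_params(p$female, p$n_female_lumen, "female", "lumen", "FL"),
    draw_embryo_params(p$male, p$n_male_lumen, "male", "lumen", "ML"),
    draw_embryo_params(p$female, p$n_female_tracks, "female", "tracks", "FT"),
    draw_embryo_params(p$male, p$n_male_tracks, "male", "tracks", "MT")
  ))
  truth$embryo_seed <- p$seed * 10000L + seq_len(nrow(truth))
  lumens <- list(); tracks <- list()
  if (simulate_data) {
    for (i in seq_len(nrow(truth))) {
      row <- truth[i, ]
      if (row$modality == "lumen") {
        lumens[[row$embryo_id]] <- gen_lumen_series(lumen_sim_params(
          k_true = row$k_true, n_frames = p$lumen_frames,
          frame_interval = p$frame_interval,
          vertex_noise_sd = p$vertex_noise_sd,
          area_noise_frac = p$area_noise_frac,
          seed = row$embryo_seed, embryo_id = row$embryo_id, sex = row$sex))
      } else {
        tracks[[row$embryo_id]] <- gen_tracks(track_sim_params(
          mode = "ratchet", n_per_row = p$n_per_row,
          period = row$period_true, medial_step = row$medial_true,
          lateral_step = row$lateral_true,
          position_noise_sd = p$position_noise_sd,
          n_frames = p$track_frames, frame_interval = p$frame_interval,
          seed = row$embryo_seed, embryo_id = row$embryo_id, sex = row$sex))
      }
    }
  }
  structure(list(truth = truth, lumens = lumens, tracks = tracks, params = p),
            class = "cohort_sim")
}
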