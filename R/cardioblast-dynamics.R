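#' Estimate the dorsal midline position
#'
#' The midline x-coordinate is the mean, over frames, of the midpoint between
#' the left-row and right-row mean x positions. No absolute coordinate
#' reference exists in the annotations, so the midline is always inferred
#' from the data.
#'
#' @param tracks An [embryo_tracks()] object.
#' @return Midline x in um.
#' @export
estimate_midline <- function(tracks) {
  both <- tracks |>
    dplyr::group_by(.data$frame, .data$row) |>
    dplyr::summarise(mx = mean(.data$x), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "row", values_from = "mx")
  if (!all(c("left", "right") %in% names(both))) {
    abort_validation("Both a left and a right row are needed to estimate the midline.")
  }
  both <- dplyr::filter(both, !is.na(.data$left), !is.na(.data$right))
  if (!nrow(both)) abort_validation("Left and right rows share no frames.")
  mean((both$left + both$right) / 2)
}

#' Pair contralateral cardioblasts by anterior-posterior rank
#'
#' Left-row and right-row tracks are each sorted by mean AP (y) position and
#' paired by rank; surplus tracks on the longer row are left unpaired and
#' reported. Rank pairing reflects that cardioblast rows are ordered
#' collectives with preserved neighbour relationships.
#'
#' @param tracks An [embryo_tracks()] object with at least one track per row.
#' @return A tibble with columns `pair`, `left_id`, `right_id`.
#' @export
pair_contralateral <- function(tracks) {
  ranks <- tracks |>
    dplyr::group_by(.data$cardioblast_id, .data$row) |>
    dplyr::summarise(mean_y = mean(.data$y), .groups = "drop")
  left <- ranks |> dplyr::filter(.data$row == "left") |> dplyr::arrange(.data$mean_y)
  right <- ranks |> dplyr::filter(.data$row == "right") |> dplyr::arrange(.data$mean_y)
  if (!nrow(left) || !nrow(right)) {
    abort_validation("Pairing requires at least one track in each row.")
  }
  k <- min(nrow(left), nrow(right))
  if (nrow(left) != nrow(right)) {
    surplus <- if (nrow(left) > k) left$cardioblast_id[(k + 1):nrow(left)]
               else right$cardioblast_id[(k + 1):nrow(right)]
    rlang::inform(sprintf("Unpaired cardioblast(s): %s", paste(surplus, collapse = ", ")))
  }
  tibble::tibble(pair = seq_len(k),
                 left_id = left$cardioblast_id[seq_len(k)],
                 right_id = right$cardioblast_id[seq_len(k)])
}

#' Per-frame distance between contralateral cardioblast pairs
#'
#' Euclidean distance between the members of each contralateral pair at every
#' frame both members were sampled; frames where one member is missing are
#' skipped for that pair.
#'
#' @param tracks An [embryo_tracks()] object.
#' @param pairs Pairing table from [pair_contralateral()]; computed if
#'   omitted.
#' @return A tibble of class `paired_distance` with columns `frame`, `pair`,
#'   `left_id`, `right_id`, `distance`.
#' @export
contralateral_distance <- function(tracks, pairs = pair_contralateral(tracks)) {
  out <- purrr::pmap_dfr(pairs, function(pair, left_id, right_id) {
    l <- tracks[tracks$cardioblast_id == left_id, ]
    r <- tracks[tracks$cardioblast_id == right_id, ]
    common <- intersect(l$frame, r$frame)
    if (!length(common)) {
      abort_validation(sprintf("Pair %s/%s shares no frames.", left_id, right_id))
    }
    l <- l[match(common, l$frame), ]
    r <- r[match(common, r$frame), ]
    tibble::tibble(frame = as.integer(common), pair = pair,
                   left_id = left_id, right_id = right_id,
                   distance = sqrt((l$x - r$x)^2 + (l$y - r$y)^2))
  })
  out <- dplyr::arrange(out, .data$frame, .data$pair)
  structure(out, class = c("paired_distance", class(tibble::tibble())))
}

#' Mean contralateral distance per frame
#'
#' @param distances Output of [contralateral_distance()].
#' @return A tibble with columns `frame`, `mean_distance`, `n_pairs`.
#' @export
mean_pair_distance <- function(distances) {
  distances |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(mean_distance = mean(.data$distance),
                     n_pairs = dplyr::n(), .groups = "drop")
}

#' Register the migration time origin from nuclear distances
#'
#' t0 is the last frame at which the mean contralateral nuclear distance
#' exceeds `nuclei_threshold`; if no frame does, the first frame is used with
#' a fallback warning.
#'
#' @param series Either a [contralateral_distance()] table or a data frame
#'   with columns `frame` and `mean_distance`.
#' @param nuclei_threshold Threshold in um (default 65).
#' @return The t0 frame index.
#' @export
register_tracks_time <- function(series, nuclei_threshold = 65) {
  if (!is.data.frame(series) || !nrow(series)) {
    abort_validation("`series` must be a non-empty distance table.")
  }
  if ("mean_distance" %in% names(series)) {
    ms <- series[, c("frame", "mean_distance")]
  } else if ("distance" %in% names(series)) {
    ms <- mean_pair_distance(series)
  } else {
    abort_validation("`series` needs a `distance` or `mean_distance` column.")
  }
  ms <- dplyr::arrange(ms, .data$frame)
  idx <- which(ms$mean_distance > nuclei_threshold)
  if (!length(idx)) {
    warn_fallback(sprintf(
      "No frame has mean nuclear distance > %g um; using the first frame as t0.",
      nuclei_threshold))
    return(as.integer(ms$frame[1]))
  }
  as.integer(ms$frame[max(idx)])
}

#' Cardioblast migration speed
#'
#' Ordinary least-squares slope of the distance travelled by a nucleus --
#' its Euclidean displacement from the track's first position -- against
#' time, in um/hr. Displacement (not cumulative path length) is used so that
#' the oscillatory component averages out of the net migration rate.
#'
#' @param track A data frame with columns `frame`, `x`, `y` for one nucleus
#'   (at least 3 samples), sorted by frame.
#' @param frame_interval Seconds between frames (default 15).
#' @return Speed in um/hr.
#' @export
migration_speed <- function(track, frame_interval = 15) {
  if (nrow(track) < 3L) abort_insufficient("Need at least 3 samples to fit a migration speed.")
  d <- sqrt((track$x - track$x[1])^2 + (track$y - track$y[1])^2)
  t_hr <- (track$frame - track$frame[1]) * frame_interval / 3600
  unname(coef(stats::lm(d ~ t_hr))[2])
}

# Signed medial position: positive displacement = movement toward the
# midline, for either row. The reference side is the track's first sample.
signed_medial_position <- function(x, midline_x) {
  s <- sign(x[1] - midline_x)
  if (s == 0) s <- 1
  -s * (x - midline_x)
}

#' Medial velocity of a cardioblast nucleus
#'
#' Finite-difference velocity of the signed medial position, in um/min.
#' Positive velocity means movement toward the dorsal midline for either row.
#'
#' @param track A data frame with columns `frame`, `x`, `y` (>= 2 samples).
#' @param midline_x Midline x-coordinate in um (see [estimate_midline()]).
#' @param frame_interval Seconds between frames (default 15).
#' @return A tibble with columns `frame` (the later frame of each difference)
#'   and `velocity` (um/min).
#' @export
medial_velocity <- function(track, midline_x, frame_interval = 15) {
  if (nrow(track) < 2L) abort_insufficient("Need at least 2 samples for a velocity.")
  m <- signed_medial_position(track$x, midline_x)
  dt_min <- diff(track$frame) * frame_interval / 60
  tibble::tibble(frame = track$frame[-1], velocity = diff(m) / dt_min)
}

#' Oscillation period from a velocity trace
#'
#' The period is the time lag of the first peak of the mean-subtracted,
#' variance-normalised (biased) autocorrelation of the velocity curve,
#' searched from lag 2 up to `max_lag_fraction` of the series length and
#' refined by 3-point parabolic interpolation. The first local maximum must
#' exceed the 95% white-noise confidence bound `1.96/sqrt(n)`; otherwise no
#' period is reported (`NA`), so noise-only traces rarely yield a spurious
#' period.
#'
#' @param velocity Numeric velocity series (um/min), uniformly sampled;
#'   at least 8 samples.
#' @param frame_interval Seconds between samples (default 15).
#' @param max_lag_fraction Maximum lag as a fraction of the series length
#'   (default 0.5).
#' @return Period in minutes, or `NA_real_` if no qualifying peak exists.
#' @export
oscillation_period <- function(velocity, frame_interval = 15, max_lag_fraction = 0.5) {
  velocity <- velocity[is.finite(velocity)]
  n <- length(velocity)
  if (n < 8L) abort_insufficient("Need at least 8 velocity samples to estimate a period.")
  if (stats::var(velocity) == 0) return(NA_real_)
  lag_max <- max(3L, floor(max_lag_fraction * n))
  r <- as.numeric(stats::acf(velocity, lag.max = lag_max, plot = FALSE,
                             demean = TRUE)$acf) # r[1] is lag 0
  gate <- stats::qnorm(0.975) / sqrt(n)
  # first local maximum at lag >= 2 (skip the zero-lag shoulder)
  for (l in 2:(lag_max - 1L)) {
    v <- r[l + 1L]
    if (v >= r[l] && v >= r[l + 2L]) {
      if (v <= gate) return(NA_real_)
      denom <- r[l] - 2 * v + r[l + 2L]
      delta <- if (abs(denom) > 1e-12) 0.5 * (r[l] - r[l + 2L]) / denom else 0
      delta <- max(min(delta, 0.5), -0.5)
      return((l + delta) * frame_interval / 60)
    }
  }
  NA_real_
}

# --- step decomposition internals -------------------------------------------

# Turning points of a series: indices of alternating local extrema, always
# including the endpoints. Returns a data frame with idx and type ("min"/"max").
find_turning_points <- function(s) {
  n <- length(s)
  d <- diff(s)
  sgn <- sign(d)
  # propagate the previous non-zero sign through flat runs
  nz <- which(sgn != 0)
  if (!length(nz)) return(NULL) # constant series
  filled <- sgn
  last <- sgn[nz[1]]
  for (i in seq_along(filled)) {
    if (filled[i] == 0) filled[i] <- last else last <- filled[i]
  }
  turns <- which(diff(filled) != 0) + 1L
  idx <- c(1L, turns, n)
  # type from the direction of the following (or preceding) segment
  first_dir <- filled[1]
  types <- character(length(idx))
  types[1] <- if (first_dir > 0) "min" else "max"
  for (i in seq_along(idx)[-1]) {
    types[i] <- if (types[i - 1] == "min") "max" else "min"
  }
  data.frame(idx = idx, type = types,
             boundary = c(TRUE, rep(FALSE, length(turns)), TRUE),
             stringsAsFactors = FALSE)
}

# Snap each smoothed-trace extremum to the raw trace within +/- half frames.
refine_extrema <- function(m, ext, half) {
  n <- length(m)
  for (i in seq_len(nrow(ext))) {
    lo <- max(1L, ext$idx[i] - half)
    hi <- min(n, ext$idx[i] + half)
    win <- lo:hi
    j <- if (ext$type[i] == "max") win[which.max(m[win])] else win[which.min(m[win])]
    ext$idx[i] <- j
  }
  # keep indices strictly increasing; on conflict keep the first occurrence
  keep <- c(TRUE, diff(ext$idx) > 0)
  ext[keep, , drop = FALSE]
}

# Merge consecutive same-type extrema, keeping the more extreme one.
enforce_alternation <- function(m, ext) {
  repeat {
    k <- nrow(ext)
    if (k < 2L) return(ext)
    same <- which(ext$type[-k] == ext$type[-1])
    if (!length(same)) return(ext)
    i <- same[1]
    a <- ext$idx[i]; b <- ext$idx[i + 1]
    drop <- if (ext$type[i] == "max") {
      if (m[a] >= m[b]) i + 1L else i
    } else {
      if (m[a] <= m[b]) i + 1L else i
    }
    ext <- ext[-drop, , drop = FALSE]
  }
}

# Remove excursions smaller than `prominence` (measured on the raw trace),
# smallest first, protecting the series endpoints.
prune_extrema <- function(m, ext, prominence) {
  repeat {
    ext <- enforce_alternation(m, ext)
    k <- nrow(ext)
    if (k < 2L) return(ext)
    exc <- abs(diff(m[ext$idx]))
    j <- which.min(exc)
    if (exc[j] >= prominence) return(ext)
    interior <- c(j, j + 1L)
    interior <- interior[interior != 1L & interior != k]
    if (!length(interior)) {
      # only the two endpoints remain and their excursion is sub-threshold
      return(ext[0, , drop = FALSE])
    }
    ext <- ext[-interior, , drop = FALSE]
  }
}

#' Decompose a cardioblast trajectory into medial and lateral steps
#'
#' The signed medial position (positive toward the midline) is smoothed by a
#' centred moving average; alternating local extrema are located on the
#' smoothed trace, snapped back to the raw trace within the smoothing
#' half-window, and excursions smaller than `step_prominence` are pruned. A
#' medial step is the excursion from a local minimum to the next local
#' maximum; a lateral step is the reverse excursion. Amplitudes are the means
#' of the respective excursion magnitudes measured on the raw trace, and the
#' net medial step is exactly `medial_amp - lateral_amp`. Excursions
#' truncated by the start or end of the observation window are excluded
#' whenever at least one complete interior excursion exists, so partial
#' boundary steps do not dilute the amplitudes.
#'
#' @param track A data frame with columns `frame`, `x`, `y` (>= 8 samples).
#' @param midline_x Midline x-coordinate in um.
#' @param config A [run_config()]; uses `smoothing_window` and
#'   `step_prominence`.
#' @return A one-row tibble: `medial_amp`, `lateral_amp`, `net_medial_step`
#'   (um), `n_medial_steps`, `n_lateral_steps`. When no steps are detected
#'   the amplitudes are `NA` and a warning is emitted; when only one kind of
#'   step is present the absent kind has amplitude 0 (and count 0).
#' @export
step_decomposition <- function(track, midline_x, config = run_config()) {
  if (nrow(track) < 8L) abort_insufficient("Need at least 8 samples for step decomposition.")
  m <- signed_medial_position(track$x, midline_x)
  s <- moving_average(m, config$smoothing_window)
  ext <- find_turning_points(s)
  empty <- tibble::tibble(medial_amp = NA_real_, lateral_amp = NA_real_,
                          net_medial_step = NA_real_,
                          n_medial_steps = 0L, n_lateral_steps = 0L)
  if (is.null(ext)) {
    warn_fallback("No steps detected: the trajectory is constant.")
    return(empty)
  }
  ext <- refine_extrema(m, ext, half = config$smoothing_window %/% 2L)
  ext <- prune_extrema(m, ext, config$step_prominence)
  if (nrow(ext) < 2L) {
    warn_fallback("No steps detected above the prominence threshold.")
    return(empty)
  }
  delta <- diff(m[ext$idx])
  # an excursion truncated by the observation window is not a complete step:
  # use only excursions between interior extrema when any exist
  interior <- !ext$boundary[-nrow(ext)] & !ext$boundary[-1]
  if (any(interior)) delta <- delta[interior]
  medial <- delta[delta > 0]
  lateral <- -delta[delta < 0]
  medial_amp <- if (length(medial)) mean(medial) else 0
  lateral_amp <- if (length(lateral)) mean(lateral) else 0
  tibble::tibble(
    medial_amp = medial_amp,
    lateral_amp = lateral_amp,
    net_medial_step = medial_amp - lateral_amp,
    n_medial_steps = length(medial),
    n_lateral_steps = length(lateral)
  )
}

#' Per-cardioblast oscillation and migration metrics
#'
#' Computes, for every analyzable track in an embryo: migration speed,
#' oscillation period (from the medial-velocity autocorrelation), and the
#' medial/lateral step decomposition. Tracks with too few samples for a given
#' metric receive `NA` for that metric.
#'
#' @param tracks An [embryo_tracks()] object.
#' @param config A [run_config()].
#' @return A tibble with one row per cardioblast: `cardioblast_id`, `row`,
#'   `n_frames`, `speed_um_hr`, `period_min`, `medial_amp_um`,
#'   `lateral_amp_um`, `net_medial_step_um`, `n_medial_steps`,
#'   `n_lateral_steps`.
#' @export
cardioblast_metrics <- function(tracks, config = run_config()) {
  meta <- series_meta(tracks)
  midline <- estimate_midline(tracks)
  ids <- unique(tracks$cardioblast_id)
  purrr::map_dfr(ids, function(id) {
    tr <- tracks[tracks$cardioblast_id == id, ]
    n <- nrow(tr)
    speed <- if (n >= 3L) migration_speed(tr, meta$frame_interval) else NA_real_
    period <- NA_real_
    steps <- tibble::tibble(medial_amp = NA_real_, lateral_amp = NA_real_,
                            net_medial_step = NA_real_,
                            n_medial_steps = NA_integer_, n_lateral_steps = NA_integer_)
    if (n >= 8L) {
      v <- medial_velocity(tr, midline, meta$frame_interval)$velocity
      period <- oscillation_period(v, meta$frame_interval,
                                   config$max_autocorr_lag_fraction)
      steps <- withCallingHandlers(
        step_decomposition(tr, midline, config),
        cardiomorph_fallback_warning = function(w) {
          rlang::cnd_muffle(w)
        }
      )
    }
    tibble::tibble(
      cardioblast_id = id, row = tr$row[1], n_frames = n,
      speed_um_hr = speed, period_min = period,
      medial_amp_um = steps$medial_amp, lateral_amp_um = steps$lateral_amp,
      net_medial_step_um = steps$net_medial_step,
      n_medial_steps = steps$n_medial_steps,
      n_lateral_steps = steps$n_lateral_steps
    )
  })
}

#' Embryo-level means of the oscillation metrics
#'
#' Per-cardioblast metrics are computed and then averaged within the embryo,
#' the aggregation level at which groups are compared. Cardioblasts with a
#' missing period are excluded from the period mean only.
#'
#' @param tracks An [embryo_tracks()] object.
#' @param config A [run_config()].
#' @return A one-row tibble: `embryo_id`, `sex`, `n_cardioblasts`,
#'   `speed_um_hr`, `period_min`, `medial_amp_um`, `lateral_amp_um`,
#'   `net_medial_step_um`.
#' @export
embryo_oscillation_summary <- function(tracks, config = run_config()) {
  meta <- series_meta(tracks)
  cm <- cardioblast_metrics(tracks, config)
  if (!nrow(cm) || all(is.na(cm$speed_um_hr) & is.na(cm$period_min))) {
    abort_insufficient(sprintf("Embryo %s has no analyzable tracks.", meta$embryo_id))
  }
  tibble::tibble(
    embryo_id = meta$embryo_id,
    sex = meta$sex,
    n_cardioblasts = nrow(cm),
    speed_um_hr = mean(cm$speed_um_hr, na.rm = TRUE),
    period_min = mean(cm$period_min, na.rm = TRUE),
    medial_amp_um = mean(cm$medial_amp_um, na.rm = TRUE),
    lateral_amp_um = mean(cm$lateral_amp_um, na.rm = TRUE),
    net_medial_step_um = mean(cm$net_medial_step_um, na.rm = TRUE)
  )
}
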