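#' Embryo metadata
#'
#' Describes one imaged embryo: its identifier, sex label, and the acquisition
#' frame interval. Physical time is always `frame_index * frame_interval`;
#' coordinates are in micrometres with x along the medial-lateral (ML) axis and
#' y along the anterior-posterior (AP) axis. The origin is arbitrary per
#' embryo; all downstream computations use differences only.
#'
#' @param embryo_id Character scalar identifying the embryo.
#' @param sex One of `"female"`, `"male"`, `"unknown"`. Embryos left
#'   `"unknown"` are loaded normally and simply excluded from group
#'   comparisons, mirroring post-hoc sexing.
#' @param frame_interval Seconds between frames (default 15).
#' @param pixel_size Micrometres per pixel; only needed when converting
#'   pixel-space inputs, may be `NULL`.
#' @return A list of class `embryo_meta`.
#' @export
embryo_meta <- function(embryo_id, sex = c("unknown", "female", "male"),
                        frame_interval = 15, pixel_size = NULL) {
  sex <- match.arg(sex)
  if (!is.character(embryo_id) || length(embryo_id) != 1L || is.na(embryo_id)) {
    abort_validation("`embryo_id` must be a single string.")
  }
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      !is.finite(frame_interval) || frame_interval <= 0) {
    abort_validation("`frame_interval` must be a positive number of seconds.")
  }
  if (!is.null(pixel_size)) {
    if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
      abort_validation("`pixel_size` must be positive when supplied.")
    }
  }
  structure(
    list(embryo_id = embryo_id, sex = sex,
         frame_interval = as.numeric(frame_interval),
         pixel_size = pixel_size),
    class = "embryo_meta"
  )
}

#' Analysis configuration
#'
#' Bundles the tunable parameters of the pipeline. The two registration
#' thresholds come from the measurement protocol: the closure time origin is
#' the last frame at which the ML cable-to-cable extent exceeds 80 um, or the
#' last frame at which the mean contralateral nuclear distance exceeds 65 um.
#' The remaining fields control step detection and the statistics.
#'
#' @param cable_threshold ML luminal extent threshold in um (default 80).
#' @param nuclei_threshold Mean contralateral nuclear distance threshold in um
#'   (default 65).
#' @param smoothing_window Frames of centred moving average applied to the
#'   medial-position trace before extremum detection (default 3, i.e. 45 s at
#'   the default cadence).
#' @param step_prominence Minimum excursion in um for a medial/lateral step to
#'   be retained (default 0.3).
#' @param max_autocorr_lag_fraction Fraction of the series length used as the
#'   maximum autocorrelation lag in period estimation (default 0.5).
#' @param mann_whitney_exact_max_n Largest group size for which the exact
#'   Mann-Whitney p-value is used (default 10); ties always force the
#'   corrected normal approximation.
#' @param seed Integer seed recorded with pipeline outputs.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cable_threshold = 80, nuclei_threshold = 65,
                       smoothing_window = 3, step_prominence = 0.3,
                       max_autocorr_lag_fraction = 0.5,
                       mann_whitney_exact_max_n = 10, seed = 1L) {
  num1 <- function(x, nm, lo = 0) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= lo) {
      abort_validation(sprintf("`%s` must be a single number > %s.", nm, lo))
    }
    as.numeric(x)
  }
  cfg <- list(
    cable_threshold = num1(cable_threshold, "cable_threshold"),
    nuclei_threshold = num1(nuclei_threshold, "nuclei_threshold"),
    smoothing_window = as.integer(num1(smoothing_window, "smoothing_window")),
    step_prominence = num1(step_prominence, "step_prominence"),
    max_autocorr_lag_fraction = num1(max_autocorr_lag_fraction, "max_autocorr_lag_fraction"),
    mann_whitney_exact_max_n = as.integer(num1(mann_whitney_exact_max_n, "mann_whitney_exact_max_n")),
    seed = as.integer(seed)
  )
  if (cfg$max_autocorr_lag_fraction > 1) {
    abort_validation("`max_autocorr_lag_fraction` must be in (0, 1].")
  }
  structure(cfg, class = "run_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Every field is optional and falls back to the [run_config()] default.
#' Unknown fields are rejected so that typos do not silently revert to
#' defaults.
#'
#' @param path Path to a YAML file whose keys mirror [run_config()] arguments.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("Config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    abort_format(sprintf("Unknown config field(s): %s", paste(bad, collapse = ", ")))
  }
  do.call(run_config, vals)
}

#' Time-indexed luminal outline series
#'
#' Stores one heart lumen as an ordered set of closed polygons, one per frame,
#' in embryo coordinates (x = ML, y = AP, um). Polygons are implicitly closed:
#' the last vertex connects back to the first, and a repeated final vertex is
#' deduplicated on construction.
#'
#' @param frames A data frame with columns `frame` (integer), `x`, `y` (um),
#'   in vertex order within each frame.
#' @param meta An [embryo_meta()] object.
#' @param validate If `TRUE` (default) check that every polygon has at least
#'   three vertices and is simple (no self-intersection).
#' @return A tibble of class `lumen_series` with columns `frame`, `x`, `y` and
#'   a `meta` attribute.
#' @export
lumen_series <- function(frames, meta, validate = TRUE) {
  if (!inherits(meta, "embryo_meta")) abort_validation("`meta` must be an `embryo_meta` object.")
  if (!is.data.frame(frames) || !all(c("frame", "x", "y") %in% names(frames))) {
    abort_validation("`frames` must have columns `frame`, `x`, `y`.")
  }
  tbl <- tibble::tibble(
    frame = as.integer(frames$frame),
    x = as.numeric(frames$x),
    y = as.numeric(frames$y)
  )
  if (nrow(tbl) == 0L) abort_validation("Lumen series is empty.")
  tbl <- dplyr::arrange(tbl, .data$frame) # stable: vertex order kept per frame
  parts <- split(tbl, tbl$frame)
  out <- dplyr::bind_rows(lapply(parts, function(d) {
    m <- as_vertex_matrix(d[, c("x", "y")])
    if (nrow(m) < 3L) {
      abort_validation(sprintf("Frame %d: polygon has fewer than 3 vertices.", d$frame[1]))
    }
    if (validate && !is_simple_polygon(m)) {
      abort_validation(sprintf("Frame %d: polygon is self-intersecting.", d$frame[1]))
    }
    tibble::tibble(frame = d$frame[1], x = m[, 1], y = m[, 2])
  }))
  structure(out, meta = meta, class = c("lumen_series", class(tibble::tibble())))
}

#' Cardioblast nuclear track table
#'
#' Holds the centroid trajectories of cardioblast nuclei for one embryo: two
#' contralateral rows (`left`, `right`) converging on the dorsal midline.
#'
#' @param samples A data frame with columns `cardioblast_id`, `row`
#'   (`"left"`/`"right"`), `frame` (integer), `x`, `y` (um).
#' @param meta An [embryo_meta()] object.
#' @param t0_index Optional registered time-origin frame index.
#' @return A tibble of class `embryo_tracks` with `meta` and `t0_index`
#'   attributes; samples sorted by cardioblast and frame.
#' @export
embryo_tracks <- function(samples, meta, t0_index = NULL) {
  if (!inherits(meta, "embryo_meta")) abort_validation("`meta` must be an `embryo_meta` object.")
  req <- c("cardioblast_id", "row", "frame", "x", "y")
  missing_cols <- setdiff(req, names(samples))
  if (length(missing_cols)) {
    abort_format(sprintf("Track table is missing column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  tbl <- tibble::tibble(
    cardioblast_id = as.character(samples$cardioblast_id),
    row = as.character(samples$row),
    frame = as.integer(samples$frame),
    x = as.numeric(samples$x),
    y = as.numeric(samples$y)
  )
  bad_row <- setdiff(unique(tbl$row), c("left", "right"))
  if (length(bad_row)) {
    abort_validation(sprintf("`row` must be 'left' or 'right'; found: %s",
                             paste(bad_row, collapse = ", ")))
  }
  tbl <- dplyr::arrange(tbl, .data$cardioblast_id, .data$frame)
  dup <- tbl |>
    dplyr::group_by(.data$cardioblast_id) |>
    dplyr::filter(duplicated(.data$frame)) |>
    dplyr::ungroup()
  if (nrow(dup)) {
    abort_validation(sprintf(
      "Track '%s' has duplicated frame %d; frames must be strictly increasing.",
      dup$cardioblast_id[1], dup$frame[1]))
  }
  structure(tbl, meta = meta, t0_index = t0_index,
            class = c("embryo_tracks", class(tibble::tibble())))
}

#' @export
print.embryo_meta <- function(x, ...) {
  cat(sprintf("<embryo_meta> %s (%s), frame interval %g s\n",
              x$embryo_id, x$sex, x$frame_interval))
  invisible(x)
}

# Accessor used throughout: metadata attached to a series/track object.
series_meta <- function(x) {
  m <- attr(x, "meta")
  if (is.null(m)) abort_validation("Object has no `meta` attribute.")
  m
}
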