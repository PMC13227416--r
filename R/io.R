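#' Read cardioblast nuclear tracks from a delimited table
#'
#' The file must be a comma-separated table with header columns
#' `cardioblast_id,row,frame,x,y`; coordinates in micrometres. Rows may appear
#' in any order; samples are sorted by frame within each track. A duplicated
#' frame within a track is rejected.
#'
#' @param path Path to the CSV file.
#' @param meta An [embryo_meta()] object describing the embryo.
#' @return An [embryo_tracks()] tibble.
#' @export
read_tracks <- function(path, meta) {
  if (!file.exists(path)) abort_format(sprintf("Track file not found: %s", path))
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("cardioblast_id", "row", "frame", "x", "y")
  missing_cols <- setdiff(req, names(tbl))
  if (length(missing_cols)) {
    abort_format(sprintf("Track table %s is missing column(s): %s",
                         basename(path), paste(missing_cols, collapse = ", ")))
  }
  embryo_tracks(tbl, meta)
}

#' Write cardioblast tracks to a delimited table
#'
#' @param tracks An [embryo_tracks()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  readr::write_csv(tracks[, c("cardioblast_id", "row", "frame", "x", "y")], path)
  invisible(path)
}

#' Read luminal outline annotations
#'
#' Annotations are stored as JSON: an object with a `frames` array, one record
#' per frame, each holding the integer `frame` index and parallel `x`/`y`
#' vertex arrays in micrometres (vertex order defines the outline; the polygon
#' is closed implicitly). Polygons with fewer than three vertices or with
#' self-intersections are rejected, naming the offending frame.
#'
#' @param path Path to the JSON annotation file.
#' @param meta An [embryo_meta()] object.
#' @return A [lumen_series()] tibble.
#' @export
read_lumen_annotations <- function(path, meta) {
  if (!file.exists(path)) abort_format(sprintf("Annotation file not found: %s", path))
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) abort_format(sprintf(
                    "Cannot parse %s as JSON: %s", basename(path), conditionMessage(e))))
  if (is.null(doc$frames) || !length(doc$frames)) {
    abort_format(sprintf("%s has no `frames` records.", basename(path)))
  }
  tbl <- purrr::map_dfr(doc$frames, function(rec) {
    if (is.null(rec$frame) || is.null(rec$x) || is.null(rec$y)) {
      abort_format("Each frame record needs `frame`, `x` and `y` fields.")
    }
    x <- as.numeric(unlist(rec$x)); y <- as.numeric(unlist(rec$y))
    if (length(x) != length(y)) {
      abort_format(sprintf("Frame %s: `x` and `y` differ in length.", rec$frame))
    }
    tibble::tibble(frame = as.integer(rec$frame), x = x, y = y)
  })
  lumen_series(tbl, meta, validate = TRUE)
}

#' Write luminal outline annotations
#'
#' Inverse of [read_lumen_annotations()]; coordinates are written at full
#' double precision so a write/read round trip is lossless to well below
#' 1e-9 um.
#'
#' @param series A [lumen_series()] object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_lumen_annotations <- function(series, path) {
  recs <- lapply(split(series, series$frame), function(d) {
    list(frame = d$frame[1], x = d$x, y = d$y)
  })
  names(recs) <- NULL
  jsonlite::write_json(list(frames = recs), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a grayscale multi-frame TIFF stack
#'
#' @param path Path to a TIFF file.
#' @return A numeric array of dimension `(frames, height, width)` with
#'   intensities in `[0, 1]`.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("Stack file not found: %s", path))
  frames <- tryCatch(tiff::readTIFF(path, all = TRUE),
                     error = function(e) abort_format(sprintf(
                       "Cannot read %s as TIFF: %s", basename(path), conditionMessage(e))))
  if (!is.list(frames)) frames <- list(frames)
  if (any(vapply(frames, function(f) length(dim(f)) != 2L, logical(1)))) {
    abort_format(sprintf("%s is not a grayscale stack.", basename(path)))
  }
  dims <- vapply(frames, dim, integer(2))
  if (!all(dims[1, ] == dims[1, 1]) || !all(dims[2, ] == dims[2, 1])) {
    abort_format(sprintf("%s has frames of differing size.", basename(path)))
  }
  out <- array(0, dim = c(length(frames), dims[1, 1], dims[2, 1]))
  for (i in seq_along(frames)) out[i, , ] <- frames[[i]]
  out
}

#' Write a grayscale stack as a multi-frame TIFF
#'
#' Intensities are rescaled to `[0, 1]` (by the stack maximum when positive)
#' and written as 32-bit float, one TIFF directory per frame.
#'
#' @param stack Numeric array `(frames, height, width)`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  if (length(dim(stack)) != 3L) abort_validation("`stack` must be a 3-D array (frames, height, width).")
  mx <- max(stack)
  if (mx > 0) stack <- stack / mx
  stack[stack < 0] <- 0
  frames <- lapply(seq_len(dim(stack)[1]), function(i) stack[i, , ])
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  invisible(path)
}
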