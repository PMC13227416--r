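# Pipeline orchestration: simulate -> quantify -> compare, plus kymograph
# export. Each stage writes plain delimited tables and exactly one JSON
# manifest into its output directory.

collect_warnings <- function(expr) {
  msgs <- character()
  val <- withCallingHandlers(expr, warning = function(w) {
    msgs <<- c(msgs, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  list(value = val, warnings = msgs)
}

write_manifest <- function(out_dir, stage, config, inputs, seed, timings, warnings) {
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("cardiomorph")),
    seed = seed,
    config = config,
    inputs = lapply(inputs, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    }),
    timings_sec = timings,
    warnings = if (length(warnings)) warnings else list()
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

resolve_config <- function(config) {
  if (is.null(config)) run_config()
  else if (inherits(config, "run_config")) config
  else if (is.character(config)) read_run_config(config)
  else if (is.list(config)) do.call(run_config, config)
  else abort_validation("`config` must be NULL, a path, a list, or a run_config.")
}

#' Simulate a cohort to disk
#'
#' Generates a two-group cohort with [gen_cohort()] and writes it in the
#' package's exchange formats: one track CSV per track embryo, one lumen
#' annotation JSON per lumen embryo, an `embryos.csv` index, the
#' `ground_truth.csv` table, and a run manifest. Rerunning with the same seed
#' reproduces identical files.
#'
#' @param config `NULL`, a [run_config()], a list of its fields, or a YAML
#'   path; supplies the seed.
#' @param out_dir Output directory (created if needed).
#' @param cohort A [cohort_sim_params()] object; defaults to the study
#'   design, with its seed taken from `config` unless set explicitly.
#' @return Invisibly, the cohort index tibble.
#' @export
cmd_simulate <- function(config = NULL, out_dir, cohort = NULL) {
  t_start <- proc.time()[["elapsed"]]
  cfg <- resolve_config(config)
  if (is.null(cohort)) cohort <- cohort_sim_params(seed = cfg$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- collect_warnings(gen_cohort(cohort))
  sim <- res$value
  index <- dplyr::mutate(
    sim$truth[, c("embryo_id", "sex", "modality")],
    file = ifelse(.data$modality == "lumen",
                  paste0("lumen_", .data$embryo_id, ".json"),
                  paste0("tracks_", .data$embryo_id, ".csv")))
  for (i in seq_len(nrow(index))) {
    path <- file.path(out_dir, index$file[i])
    id <- index$embryo_id[i]
    if (index$modality[i] == "lumen") write_lumen_annotations(sim$lumens[[id]], path)
    else write_tracks(sim$tracks[[id]], path)
  }
  readr::write_csv(index, file.path(out_dir, "embryos.csv"))
  readr::write_csv(sim$truth, file.path(out_dir, "ground_truth.csv"))
  elapsed <- proc.time()[["elapsed"]] - t_start
  write_manifest(out_dir, "simulate", unclass(cfg),
                 file.path(out_dir, c(index$file, "embryos.csv", "ground_truth.csv")),
                 cohort$seed, list(simulate = elapsed), res$warnings)
  invisible(index)
}

#' Quantify a cohort directory
#'
#' Reads every embryo listed in `embryos.csv`, computes per-frame lumen
#' metrics and closure fits for lumen embryos, and per-cardioblast plus
#' per-embryo oscillation summaries for track embryos. Unreadable or
#' unanalyzable embryos are logged, skipped, and recorded in the manifest.
#'
#' @param data_dir Directory produced by [cmd_simulate()] (or hand-built with
#'   the same layout).
#' @param config Configuration as in [cmd_simulate()].
#' @param out_dir Output directory for the metric tables.
#' @return Invisibly, a list of the four output tibbles.
#' @export
cmd_quantify <- function(data_dir, config = NULL, out_dir) {
  t_start <- proc.time()[["elapsed"]]
  cfg <- resolve_config(config)
  index_path <- file.path(data_dir, "embryos.csv")
  if (!file.exists(index_path)) abort_format(sprintf("No embryos found in %s.", data_dir))
  index <- readr::read_csv(index_path, show_col_types = FALSE)
  if (!nrow(index)) abort_format(sprintf("No embryos found in %s.", data_dir))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  lumen_metrics <- list(); fits <- list()
  cb_metrics <- list(); summaries <- list()
  skipped <- character(); warns <- character()
  for (i in seq_len(nrow(index))) {
    id <- index$embryo_id[i]
    meta <- embryo_meta(id, index$sex[i])
    res <- tryCatch(collect_warnings({
      path <- file.path(data_dir, index$file[i])
      if (index$modality[i] == "lumen") {
        series <- read_lumen_annotations(path, meta)
        lm_tbl <- compute_lumen_metrics(series, cfg)
        fit <- fit_closure(lm_tbl$t_min[lm_tbl$t_min >= 0],
                           lm_tbl$area_um2[lm_tbl$t_min >= 0])
        list(metrics = tibble::as_tibble(lm_tbl),
             fit = tibble::tibble(embryo_id = id, sex = meta$sex,
                                  A_um2 = fit$A, k_per_hr = fit$k,
                                  rmse = fit$rmse, n_frames_fit = fit$n_frames_fit,
                                  converged = fit$converged))
      } else {
        tracks <- read_tracks(path, meta)
        list(cb = dplyr::mutate(cardioblast_metrics(tracks, cfg),
                                embryo_id = id, sex = meta$sex, .before = 1),
             summary = embryo_oscillation_summary(tracks, cfg))
      }
    }), error = function(e) e)
    if (inherits(res, "error")) {
      warns <- c(warns, sprintf("Skipped embryo %s: %s", id, conditionMessage(res)))
      skipped <- c(skipped, id)
      next
    }
    warns <- c(warns, res$warnings)
    v <- res$value
    if (!is.null(v$metrics)) {
      lumen_metrics[[id]] <- v$metrics
      fits[[id]] <- v$fit
    } else {
      cb_metrics[[id]] <- v$cb
      summaries[[id]] <- v$summary
    }
  }
  out <- list(
    lumen_metrics = dplyr::bind_rows(lumen_metrics),
    closure_fits = dplyr::bind_rows(fits),
    cardioblast_metrics = dplyr::bind_rows(cb_metrics),
    embryo_summary = dplyr::bind_rows(summaries)
  )
  files <- character()
  for (nm in names(out)) {
    if (nrow(out[[nm]])) {
      f <- file.path(out_dir, paste0(nm, ".csv"))
      readr::write_csv(out[[nm]], f)
      files <- c(files, f)
    }
  }
  if (length(skipped)) {
    rlang::inform(sprintf("Skipped %d embryo(s): %s", length(skipped),
                          paste(skipped, collapse = ", ")))
  }
  elapsed <- proc.time()[["elapsed"]] - t_start
  manifest <- write_manifest(out_dir, "quantify", unclass(cfg), files, cfg$seed,
                             list(quantify = elapsed), warns)
  jsonlite::write_json(
    c(manifest, list(skipped_embryos = skipped)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

#' Compare female and male embryos across all metrics
#'
#' Builds the per-embryo metric table from a [cmd_quantify()] output
#' directory (closure rate constant; circularity and AP/ML lengths at the
#' registered origin; speed, period, and step amplitudes) and runs
#' [compare_all_metrics()].
#'
#' @param metrics_dir Directory produced by [cmd_quantify()].
#' @param out_dir Output directory for `comparisons.csv`.
#' @param config Configuration as in [cmd_simulate()].
#' @return Invisibly, the `group_comparison` tibble.
#' @export
cmd_compare <- function(metrics_dir, out_dir, config = NULL) {
  t_start <- proc.time()[["elapsed"]]
  cfg <- resolve_config(config)
  per_embryo <- list()
  fit_path <- file.path(metrics_dir, "closure_fits.csv")
  lm_path <- file.path(metrics_dir, "lumen_metrics.csv")
  sum_path <- file.path(metrics_dir, "embryo_summary.csv")
  if (file.exists(fit_path)) {
    fits <- readr::read_csv(fit_path, show_col_types = FALSE)
    lumen_tbl <- fits[, c("embryo_id", "sex", "k_per_hr")]
    if (file.exists(lm_path)) {
      lm_tbl <- readr::read_csv(lm_path, show_col_types = FALSE)
      at0 <- lm_tbl |>
        dplyr::filter(.data$t_min == 0) |>
        dplyr::select("embryo_id", "circularity", "ap_len_um", "ml_len_um")
      lumen_tbl <- dplyr::left_join(lumen_tbl, at0, by = "embryo_id")
    }
    per_embryo$lumen <- lumen_tbl
  }
  if (file.exists(sum_path)) {
    per_embryo$tracks <- readr::read_csv(sum_path, show_col_types = FALSE) |>
      dplyr::select(-"n_cardioblasts")
  }
  if (!length(per_embryo)) abort_format(sprintf("No metric tables found in %s.", metrics_dir))
  tbl <- dplyr::bind_rows(per_embryo)
  if (!any(tbl$sex == "female") || !any(tbl$sex == "male")) {
    abort_validation("Need labelled embryos in both groups to compare.")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- collect_warnings(compare_all_metrics(tbl, config = cfg))
  comparisons <- res$value
  f <- file.path(out_dir, "comparisons.csv")
  readr::write_csv(comparisons, f)
  elapsed <- proc.time()[["elapsed"]] - t_start
  write_manifest(out_dir, "compare", unclass(cfg), f, cfg$seed,
                 list(compare = elapsed), res$warnings)
  invisible(comparisons)
}

#' Export a kymograph from an image stack on disk
#'
#' @param stack_path Path to a grayscale multi-frame TIFF.
#' @param rect `c(x0, y0, width, height)` in pixels.
#' @param axis `"horizontal"` or `"vertical"`.
#' @param out_path Output TIFF path for the frames x space kymograph image.
#' @return Invisibly, the [kymograph()] matrix.
#' @export
cmd_kymograph <- function(stack_path, rect, axis = c("horizontal", "vertical"),
                          out_path) {
  axis <- match.arg(axis)
  stack <- read_stack(stack_path)
  km <- kymograph(stack, rect, axis)
  img <- unclass(km)
  mx <- max(img)
  if (mx > 0) img <- img / mx
  tiff::writeTIFF(img, out_path, bits.per.sample = 32L)
  invisible(km)
}
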