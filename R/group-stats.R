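#' Mann-Whitney U test for two groups
#'
#' Rank-sum (Wilcoxon rank-sum / Mann-Whitney) comparison of two samples. The
#' exact two-sided p-value is used when both groups are no larger than
#' `exact_max_n` and the pooled data contain no ties; otherwise the normal
#' approximation with tie and continuity corrections is used and the method
#' switch is reported in the output.
#'
#' @param x,y Numeric vectors, each non-empty.
#' @param exact_max_n Largest group size for which the exact p-value is
#'   computed (default 10).
#' @return A one-row tibble: `U` (statistic for `x`), `p_value` (two-sided),
#'   `method` (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney_u <- function(x, y, exact_max_n = 10) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y)) abort_validation("Both groups must be non-empty.")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && max(length(x), length(y)) <= exact_max_n
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  tibble::tibble(
    U = unname(wt$statistic),
    p_value = wt$p.value,
    method = if (exact) "exact" else "normal_approx"
  )
}

#' Group summary statistics
#'
#' Sample mean, standard deviation (n - 1 denominator) and standard error of
#' the mean, the quantities shown as the line, bars and box of the study's
#' box summaries.
#'
#' @param values Numeric vector (length >= 1; sd and sem require >= 2).
#' @return A one-row tibble: `n`, `mean`, `sd`, `sem`.
#' @export
summarize_group <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (!n) abort_validation("Cannot summarise an empty group.")
  s <- if (n >= 2L) stats::sd(values) else NA_real_
  tibble::tibble(n = n, mean = mean(values), sd = s, sem = s / sqrt(n))
}

#' Compare all per-embryo metrics between females and males
#'
#' For each metric column, embryos with a missing value are excluded from
#' that metric only; embryos of unknown sex are excluded from every
#' comparison (with a note). A metric whose female or male group is empty
#' yields an error record (NA statistics, `method = "error"`) and the run
#' continues.
#'
#' @param per_embryo A data frame with columns `embryo_id`, `sex`, and one
#'   numeric column per metric.
#' @param metrics Character vector of metric column names; defaults to every
#'   numeric column other than `embryo_id`/`sex`.
#' @param config A [run_config()]; supplies `mann_whitney_exact_max_n`.
#' @return A tibble of class `group_comparison`, one row per metric:
#'   `metric`, `n_female`, `n_male`, `mean_f`, `sd_f`, `sem_f`, `mean_m`,
#'   `sd_m`, `sem_m`, `U`, `p_value`, `method`.
#' @export
compare_all_metrics <- function(per_embryo, metrics = NULL, config = run_config()) {
  if (!all(c("embryo_id", "sex") %in% names(per_embryo))) {
    abort_validation("`per_embryo` must have `embryo_id` and `sex` columns.")
  }
  if (is.null(metrics)) {
    metrics <- names(per_embryo)[vapply(per_embryo, is.numeric, logical(1))]
    metrics <- setdiff(metrics, c("n_cardioblasts", "n_frames_fit"))
  }
  unknown <- unique(per_embryo$embryo_id[!per_embryo$sex %in% c("female", "male")])
  if (length(unknown)) {
    rlang::inform(sprintf("Excluding embryo(s) of unknown sex: %s",
                          paste(unknown, collapse = ", ")))
    per_embryo <- per_embryo[per_embryo$sex %in% c("female", "male"), ]
  }
  out <- purrr::map_dfr(metrics, function(mname) {
    f <- per_embryo[[mname]][per_embryo$sex == "female"]
    m <- per_embryo[[mname]][per_embryo$sex == "male"]
    f <- f[is.finite(f)]; m <- m[is.finite(m)]
    base <- tibble::tibble(metric = mname,
                           n_female = length(f), n_male = length(m))
    if (!length(f) || !length(m)) {
      rlang::inform(sprintf("Metric '%s': empty %s group; comparison skipped.",
                            mname, if (length(f)) "male" else "female"))
      return(dplyr::mutate(base, mean_f = NA_real_, sd_f = NA_real_, sem_f = NA_real_,
                           mean_m = NA_real_, sd_m = NA_real_, sem_m = NA_real_,
                           U = NA_real_, p_value = NA_real_, method = "error"))
    }
    sf <- summarize_group(f); sm <- summarize_group(m)
    mw <- mann_whitney_u(f, m, config$mann_whitney_exact_max_n)
    dplyr::mutate(base,
                  mean_f = sf$mean, sd_f = sf$sd, sem_f = sf$sem,
                  mean_m = sm$mean, sd_m = sm$sd, sem_m = sm$sem,
                  U = mw$U, p_value = mw$p_value, method = mw$method)
  })
  structure(out, class = c("group_comparison", class(tibble::tibble())))
}
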