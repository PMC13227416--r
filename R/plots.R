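# ggplot2 displays for each result type.

#' Plot per-frame luminal metrics
#'
#' Faceted time courses of area, circularity and the AP/ML axis lengths
#' against registered time.
#'
#' @param object A `lumen_metrics` tibble from [compute_lumen_metrics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lumen_metrics
#' @export
autoplot.lumen_metrics <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("t_min", "area_um2", "circularity",
                                  "ap_len_um", "ml_len_um")],
    -"t_min", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_min, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Registered time (min)", y = NULL)
}

#' Plot a closure fit over its data
#'
#' @param object A `closure_fit` object.
#' @param ... Unused.
#' @return A ggplot object showing the area series and the fitted
#'   exponential.
#' @method autoplot closure_fit
#' @export
autoplot.closure_fit <- function(object, ...) {
  d <- object$data
  curve <- tibble::tibble(
    t_hr = seq(min(d$t_hr), max(d$t_hr), length.out = 200))
  curve$area <- object$A * exp(-object$k * curve$t_hr)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_hr * 60, y = .data$area)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(data = curve, colour = "firebrick") +
    ggplot2::labs(x = "Registered time (min)", y = expression(Luminal~area~(mu*m^2)),
                  subtitle = sprintf("k = %.2f hr^-1", object$k))
}

#' Plot a two-group comparison in the box-summary style
#'
#' For each metric, the line marks the group mean, the box spans mean +/-
#' s.e.m., and the whiskers span mean +/- s.d.
#'
#' @param object A `group_comparison` tibble from [compare_all_metrics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot group_comparison
#' @export
autoplot.group_comparison <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("mean_f", "sd_f", "sem_f", "mean_m", "sd_m", "sem_m"),
                        names_to = c("stat", "group"), names_sep = "_") |>
    tidyr::pivot_wider(names_from = "stat", values_from = "value") |>
    dplyr::mutate(group = ifelse(.data$group == "f", "female", "male"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, colour = .data$group)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd), width = 0.2) +
    ggplot2::geom_crossbar(ggplot2::aes(y = .data$mean,
                                        ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem), width = 0.4) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Plot a kymograph
#'
#' @param object A [kymograph()] matrix.
#' @param ... Unused.
#' @return A ggplot raster with space on x and time (minutes) running down y.
#' @method autoplot kymograph
#' @export
autoplot.kymograph <- function(object, ...) {
  dt_min <- attr(object, "frame_interval") / 60
  d <- expand.grid(frame = seq_len(nrow(object)), pos = seq_len(ncol(object)))
  d$intensity <- as.vector(unclass(object))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$frame * dt_min,
                                  fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::labs(x = "Position (px)", y = "Time (min)", fill = "I")
}
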