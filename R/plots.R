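#' Tidiers for rapidsfdi objects
#'
#' `tidy()` methods return long tibbles (one row per pixel or grid node) for
#' map-like objects, following the broom convention.
#'
#' @param x A rapidsfdi object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy.rapidsfdi
NULL

#' Plot a per-pixel map
#'
#' @param map Numeric matrix (e.g. `mua`, `musp`, `sto2`).
#' @param title Plot title.
#' @param legend Fill legend label.
#' @return A ggplot object.
#' @export
plot_map <- function(map, title = NULL, legend = "value") {
  df <- tibble::tibble(row = as.integer(row(map)), col = as.integer(col(map)),
                       value = as.numeric(map))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(name = legend, na.value = "grey80") +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot ROI percent-change time courses
#'
#' @param series Long tibble with `time_s`, `quantity`, `pct` (and optional
#'   `pct_sd` ribbon).
#' @return A ggplot object.
#' @export
plot_roi_series <- function(series) {
  p <- ggplot2::ggplot(series, ggplot2::aes(x = .data$time_s / 60,
                                            y = .data$pct,
                                            colour = .data$quantity))
  if ("pct_sd" %in% names(series)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$pct - .data$pct_sd,
                   ymax = .data$pct + .data$pct_sd,
                   fill = .data$quantity),
      alpha = 0.15, colour = NA)
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "% change from baseline",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot sfdi_result
#' @export
autoplot.sfdi_result <- function(object, ...) {
  plot_roi_series(object$roi_series)
}

#' Plot an extracted heart-rate series
#'
#' @param hr Tibble from [heart_rate_fft()]; unreliable windows are drawn
#'   hollow.
#' @param reference Optional tibble with `t_center_s`, `hr_bpm` reference.
#' @return A ggplot object.
#' @export
plot_heart_rate <- function(hr, reference = NULL) {
  p <- ggplot2::ggplot(hr, ggplot2::aes(x = .data$t_center_s / 60,
                                        y = .data$hr_bpm)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$reliable), colour = "red") +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = "reliable")
  if (!is.null(reference)) {
    p <- p + ggplot2::geom_point(data = reference, shape = 21,
                                 colour = "blue")
  }
  p + ggplot2::labs(x = "time (min)", y = "heart rate (bpm)") +
    ggplot2::theme_minimal()
}

#' @method glance sfdi_result
#' @export
glance.sfdi_result <- function(x, ...) {
  tibble::tibble(
    n_cycles = length(x$times_s),
    duration_s = diff(range(x$times_s)),
    mean_valid_frac = mean(x$validity),
    n_quantities = length(unique(x$roi_series$quantity))
  )
}
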