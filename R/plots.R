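#' Spatio-temporal motility map heatmap
#'
#' Diameter versus node position and time -- the standard motility-map view
#' in which propagating contractions appear as diagonal stripes.
#'
#' @param object A `diameter_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot diameter_map
#' @export
autoplot.diameter_map <- function(object, ...) {
  d <- tidy(object)
  if (!is.na(object$frame_dt_s))
    d$frame <- (d$frame - 1) * object$frame_dt_s
  ggplot2::ggplot(d, ggplot2::aes(.data$frame, .data$s_mm,
                                  fill = .data$diameter_mm)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "diameter (mm)") +
    ggplot2::labs(x = if (is.na(object$frame_dt_s)) "frame" else "time (s)",
                  y = "axis position (mm)") +
    ggplot2::theme_minimal()
}

#' Pressure trace plot
#'
#' @param object A `pressure_traces` object.
#' @param ports Port numbers to show (default: in-antrum ports).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pressure_traces
#' @export
autoplot.pressure_traces <- function(object, ports = NULL, ...) {
  ports <- ports %||% object$ports$port[object$ports$in_antrum]
  d <- dplyr::filter(tidy(object), .data$port %in% ports)
  ggplot2::ggplot(d, ggplot2::aes(.data$time_s, .data$pressure_mmHg)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$port)) +
    ggplot2::labs(x = "time (s)", y = "pressure (mmHg)") +
    ggplot2::theme_minimal()
}

#' Per-subject mean agreement plot
#'
#' Manometry versus MRI per-subject mean AUC with SEM error bars.
#'
#' @param report A `validation_report` (or the `means` tibble from
#'   [subject_mean_correlation()]).
#' @return A ggplot.
#' @export
plot_subject_agreement <- function(report) {
  means <- if (inherits(report, "validation_report")) report$subject_means else report
  ggplot2::ggplot(means, ggplot2::aes(.data$mri_mean, .data$mano_mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mano_mean - .data$mano_sem,
                                        ymax = .data$mano_mean + .data$mano_sem),
                           width = 0, na.rm = TRUE) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$mri_mean - .data$mri_sem,
                                         xmax = .data$mri_mean + .data$mri_sem),
                            height = 0, na.rm = TRUE) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "mean MRI AUC (mm s)", y = "mean manometry AUC (mmHg s)") +
    ggplot2::theme_minimal()
}

#' Pooled block agreement plot
#'
#' Every block's manometry AUC against its MRI AUC, with the spline
#' conditional mean when a report with fits is given.
#'
#' @param tbl Study table with `mri_auc`, `mano_auc`.
#' @return A ggplot.
#' @export
plot_block_agreement <- function(tbl) {
  ggplot2::ggplot(tbl, ggplot2::aes(.data$mano_auc, .data$mri_auc)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ splines::ns(x, 4),
                         se = FALSE, linewidth = 0.5) +
    ggplot2::labs(x = "manometry AUC (mmHg s)", y = "MRI AUC (mm s)") +
    ggplot2::theme_minimal()
}

#' Study time-course plot
#'
#' Mean +/- SD of both modalities at consecutive within-visit time points,
#' each modality scaled by its study mean so the shapes are comparable.
#'
#' @param timecourse Tibble from [aggregate_timecourse()].
#' @return A ggplot.
#' @export
plot_timecourse <- function(timecourse) {
  d <- timecourse |>
    dplyr::group_by(.data$modality) |>
    dplyr::mutate(scale = mean(.data$mean),
                  m = .data$mean / .data$scale, s = .data$sd / .data$scale) |>
    dplyr::ungroup()
  ggplot2::ggplot(d, ggplot2::aes(.data$time_index, .data$m,
                                  colour = .data$modality,
                                  linetype = .data$modality)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$m - .data$s,
                                      ymax = .data$m + .data$s,
                                      fill = .data$modality),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "block time index", y = "AUC (study-mean scaled)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
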