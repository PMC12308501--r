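# Plotting: connectivity heatmaps, metric-by-condition summaries, residualized
# trait scatter plots, and model diagnostics.

#' Heatmap of a connectivity matrix
#'
#' @param x A `connectivity_matrix`.
#' @return A ggplot.
#' @export
plot_connectivity <- function(x) {
  stopifnot(inherits(x, "connectivity_matrix"))
  df <- as_tibble(x$values, rownames = "roi_i") |>
    tidyr::pivot_longer(-"roi_i", names_to = "roi_j", values_to = "pli") |>
    dplyr::mutate(roi_i = factor(.data$roi_i, levels = x$labels),
                  roi_j = factor(.data$roi_j, levels = x$labels))
  ggplot2::ggplot(df, ggplot2::aes(.data$roi_j, .data$roi_i,
                                   fill = .data$pli)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "PLI") +
    ggplot2::labs(
      title = sprintf("%s / %s / %s (%d epochs)", x$participant_id,
                      x$condition, x$band %||% "broadband",
                      x$n_epochs_averaged),
      x = NULL, y = NULL
    ) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Metric by condition and group
#'
#' Paired per-participant values with group means, one panel per band.
#'
#' @param metrics A long metrics tibble.
#' @param metric Which metric to plot (default `"SW"`).
#' @return A ggplot.
#' @export
plot_metric_by_condition <- function(metrics, metric = "SW") {
  d <- dplyr::filter(metrics, .data$metric == !!metric)
  ggplot2::ggplot(d, ggplot2::aes(.data$condition, .data$value,
                                  colour = .data$diagnosis,
                                  group = .data$participant_id)) +
    ggplot2::geom_line(alpha = 0.35) +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::stat_summary(ggplot2::aes(group = .data$diagnosis),
                          fun = mean, geom = "line", linewidth = 1.1) +
    ggplot2::facet_wrap(~band, scales = "free_y") +
    ggplot2::labs(y = metric, x = NULL, colour = NULL) +
    ggplot2::theme_bw()
}

#' Adjusted trait score versus adjusted change score
#'
#' Residualizes both the SRS total and the change score on age and sex within
#' group, then plots the adjusted values with per-group least-squares lines —
#' the standard visualization of a group-specific trait association.
#'
#' @param delta A change-score tibble from [compute_delta()] (one metric and
#'   band).
#' @return A ggplot.
#' @export
plot_delta_srs <- function(delta) {
  d <- delta |>
    residualize("srs_raw_total", by_group = TRUE) |>
    residualize("delta", by_group = TRUE)
  ggplot2::ggplot(d, ggplot2::aes(.data$delta_adj, .data$srs_raw_total_adj,
                                  colour = .data$diagnosis)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "adjusted change score (EO - DR)",
                  y = "adjusted SRS raw total", colour = NULL) +
    ggplot2::theme_bw()
}

#' Diagnostic panels for a fitted model
#'
#' Residual histogram, residuals versus fitted values, and (for mixed models)
#' the random-intercept histogram, combined side by side.
#'
#' @param x A `plinet_diagnostics` from [model_diagnostics()].
#' @return A patchwork of ggplots.
#' @export
plot_diagnostics <- function(x) {
  stopifnot(inherits(x, "plinet_diagnostics"))
  df <- tibble(residual = x$residuals, fitted = x$fitted)
  p1 <- ggplot2::ggplot(df, ggplot2::aes(.data$residual)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey35") +
    ggplot2::labs(title = "residuals") +
    ggplot2::theme_bw()
  p2 <- ggplot2::ggplot(df, ggplot2::aes(.data$fitted, .data$residual)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(title = "residuals vs fitted") +
    ggplot2::theme_bw()
  panels <- list(p1, p2)
  if (length(x$ranef) > 0) {
    panels[[3]] <- ggplot2::ggplot(tibble(u = x$ranef), ggplot2::aes(.data$u)) +
      ggplot2::geom_histogram(bins = 15, fill = "grey35") +
      ggplot2::labs(title = "random intercepts") +
      ggplot2::theme_bw()
  }
  patchwork::wrap_plots(panels, nrow = 1) +
    patchwork::plot_annotation(title = x$model_id)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname plot_diagnostics
#' @param object A `plinet_diagnostics`.
#' @param ... Unused.
#' @method autoplot plinet_diagnostics
#' @export
autoplot.plinet_diagnostics <- function(object, ...) plot_diagnostics(object)

#' @rdname plot_diagnostics
#' @method autoplot plinet_fit
#' @export
autoplot.plinet_fit <- function(object, ...) {
  plot_diagnostics(model_diagnostics(object))
}
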