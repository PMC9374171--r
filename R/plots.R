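#' Plot the autoencoder grid search
#'
#' Validation RMSE (mean +/- SD across folds) against the bottleneck
#' width, the scree used to judge reconstruction capacity.
#'
#' @param object An `ae_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ae_grid <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(x = .data$J, y = .data$val_rmse_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$val_rmse_mean - .data$val_rmse_sd,
      ymax = .data$val_rmse_mean + .data$val_rmse_sd), alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = s$J) +
    ggplot2::labs(x = "bottleneck width J", y = "validation RMSE",
                  title = "Cross-validated reconstruction error") +
    ggplot2::theme_minimal()
}

#' Plot the internal-validity selection grid
#'
#' Calinski-Harabasz index and silhouette coefficient against k, one
#' line per feature set.
#'
#' @param object A `selection_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.selection_grid <- function(object, ...) {
  long <- object |>
    dplyr::filter(.data$k >= 2) |>
    tidyr::pivot_longer(c("ch_index", "silhouette"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value,
                                     colour = .data$feature_set)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "number of clusters k", y = NULL,
                  colour = "features") +
    ggplot2::theme_minimal()
}

#' Elbow plot of the WCSS curve
#'
#' @param wcss_curve A tibble with `k` and `wcss` columns (e.g. the
#'   `wcss_curve` element of a `pi_run`).
#' @param k Optional selected k to mark.
#' @return A ggplot object.
#' @export
plot_elbow <- function(wcss_curve, k = NULL) {
  p <- ggplot2::ggplot(wcss_curve, ggplot2::aes(x = .data$k, y = .data$wcss)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = wcss_curve$k) +
    ggplot2::labs(x = "number of clusters k", y = "WCSS",
                  title = "Elbow curve") +
    ggplot2::theme_minimal()
  if (!is.null(k)) {
    p <- p + ggplot2::geom_vline(xintercept = k, linetype = "dashed")
  }
  p
}

#' Plot a pipeline run's clusters in score space
#'
#' Scatter of the external-validation coordinates (GSRS against PSQI)
#' coloured by assigned cluster, faceted by partition.
#'
#' @param object A `pi_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pi_run <- function(object, ...) {
  ggplot2::ggplot(object$coordinates,
                  ggplot2::aes(x = .data$psqi, y = .data$gsrs,
                               colour = .data$cluster)) +
    ggplot2::geom_jitter(width = 0.25, height = 0.25, alpha = 0.5, size = 0.8) +
    ggplot2::facet_wrap(~partition) +
    ggplot2::labs(x = "PSQI global", y = "GSRS total", colour = "cluster") +
    ggplot2::theme_minimal()
}
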