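#' Tidy the autoencoder grid-search table
#'
#' @param x An `ae_grid`.
#' @param ... Unused.
#' @return A tibble with one row per bottleneck width `J`: mean and SD
#'   of the final training and validation RMSE across folds.
#' @export
tidy.ae_grid <- function(x, ...) x$summary

#' @rdname tidy.ae_grid
#' @export
glance.ae_grid <- function(x, ...) {
  best <- x$summary[which.min(x$summary$val_rmse_mean), ]
  tibble::tibble(n_grid = nrow(x$summary), folds = x$folds,
                 epochs = x$config$epochs,
                 best_J = best$J, best_val_rmse = best$val_rmse_mean)
}

#' Tidy a cluster solution
#'
#' @param x A `cluster_solution`.
#' @param ... Unused.
#' @return A tibble with one row per cluster: size and centroid
#'   coordinates.
#' @export
tidy.cluster_solution <- function(x, ...) {
  cent <- tibble::as_tibble(x$centroids, .name_repair = function(nm) {
    paste0("dim", seq_along(nm))
  })
  dplyr::bind_cols(tibble::tibble(cluster = seq_len(x$k), size = x$sizes),
                   cent)
}

#' @rdname tidy.cluster_solution
#' @export
glance.cluster_solution <- function(x, ...) {
  tibble::tibble(k = x$k, wcss = x$wcss, ch_index = x$ch_index,
                 silhouette = x$silhouette)
}

#' Tidy a one-way ANOVA
#'
#' @param x An `anova_oneway`.
#' @param ... Unused.
#' @return One-row tibble with the F statistic, degrees of freedom and
#'   p-value.
#' @export
tidy.anova_oneway <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df1 = x$df[1], df2 = x$df[2],
                 msw = x$msw, p.value = x$p.value)
}

#' Tidy an external validation report
#'
#' @param x A `validation_report`.
#' @param ... Unused.
#' @return The per-score test rows (omnibus + pairwise contrasts).
#' @export
tidy.validation_report <- function(x, ...) x$tests

#' @rdname tidy.validation_report
#' @export
glance.validation_report <- function(x, ...) {
  tibble::tibble(partition = x$partition %||% NA_character_,
                 scores = length(unique(x$tests$score)),
                 significant = sum(x$tests$p.value < 0.05 &
                                     x$tests$comparison == "omnibus"))
}

#' Tidy a pipeline run
#'
#' @param x A `pi_run`.
#' @param ... Unused.
#' @return The internal-validity selection grid.
#' @export
tidy.pi_run <- function(x, ...) x$selection_grid

#' @rdname tidy.pi_run
#' @export
glance.pi_run <- function(x, ...) {
  tibble::tibble(n_train = x$n$train, n_test = x$n$test,
                 feature_set = x$feature_set, k = x$k,
                 wcss = x$solution$wcss,
                 ch_index = x$solution$ch_index,
                 silhouette = x$solution$silhouette)
}
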