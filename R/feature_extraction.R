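#' Symmetric autoencoder architecture
#'
#' The feature extractor is a symmetric fully-connected autoencoder with
#' layer widths `[d, 8J, J, 8J, d]`: a bottleneck of `J` nodes flanked by
#' hidden layers of `8 * J` nodes, ReLU activations on the hidden layers
#' and a linear output layer trained to reconstruct its standardized
#' input (root-mean-squared reconstruction error, Adam optimizer).
#'
#' @param d Input width (number of encoded feature columns), >= 1.
#' @param J Bottleneck width, >= 1.
#' @return An untrained `autoencoder` object holding the architecture.
#' @export
#' @examples
#' build_autoencoder(d = 60, J = 2)$widths  # 60 16 2 16 60
build_autoencoder <- function(d, J) {
  if (length(J) != 1 || is.na(J) || J < 1) abort("'J' must be >= 1")
  if (length(d) != 1 || is.na(d) || d < 1) abort("'d' must be >= 1")
  structure(list(J = as.integer(J), d = as.integer(d),
                 widths = as.integer(c(d, 8 * J, J, 8 * J, d)),
                 weights = NULL, trained = FALSE),
            class = "autoencoder")
}

#' @export
print.autoencoder <- function(x, ...) {
  cat(sprintf("<autoencoder> widths %s (%s)\n",
              paste(x$widths, collapse = "-"),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Root-mean-squared reconstruction error
#'
#' @param x,xhat Numeric matrices of identical shape.
#' @return `sqrt(mean((x - xhat)^2))` over all entries.
#' @export
rmse <- function(x, xhat) {
  x <- as.matrix(x); xhat <- as.matrix(xhat)
  if (!all(dim(x) == dim(xhat))) {
    abort(sprintf("rmse: shape mismatch (%dx%d vs %dx%d)",
                  nrow(x), ncol(x), nrow(xhat), ncol(xhat)))
  }
  sqrt(mean((x - xhat)^2))
}

#' Train the autoencoder
#'
#' Minibatch Adam training of the symmetric autoencoder on a
#' standardized feature matrix. Training is deterministic given the seed
#' (single-threaded, seeded initialization and epoch shuffling).
#'
#' @param X Numeric training matrix (n x d), or a `feature_matrix` whose
#'   `train` component is used.
#' @param J Bottleneck width.
#' @param epochs Training epochs (default 100).
#' @param batch Minibatch size (default 64).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param validation Optional held-out matrix; its RMSE is tracked per
#'   epoch.
#' @param seed Optional RNG seed.
#' @param restarts Number of independent training runs. With 1 (the
#'   default) the single run is returned. With more, the run to keep is
#'   chosen by `select_by`.
#' @param select_by Restart selection rule: `"loss"` keeps the lowest
#'   final training RMSE; `"clustering"` keeps the run whose
#'   standardized bottleneck features score the highest mean
#'   Calinski-Harabasz index over `k_focus` — reconstruction error
#'   barely distinguishes embeddings that chart the data manifold
#'   cleanly from sheared ones, while internal cluster validity does,
#'   mirroring how the architecture itself is selected.
#' @param k_focus Cluster counts for the `"clustering"` rule.
#' @return A trained `autoencoder` with `weights`, `train_rmse` /
#'   `val_rmse` per-epoch curves and `final_rmse`.
#' @export
fit_autoencoder <- function(X, J, epochs = 100, batch = 64,
                            learning_rate = 1e-3, validation = NULL,
                            seed = NULL, restarts = 1,
                            select_by = c("loss", "clustering"),
                            k_focus = 2:4) {
  select_by <- match.arg(select_by)
  if (inherits(X, "feature_matrix")) X <- X$train
  X <- as.matrix(X)
  if (!is.null(seed)) set.seed(seed)
  Xval <- if (is.null(validation)) matrix(0, 0, ncol(X)) else as.matrix(validation)

  train_once <- function() {
    model <- build_autoencoder(ncol(X), J)
    fit <- ae_train_cpp(X, Xval, model$J, epochs, batch, learning_rate,
                        !is.null(validation))
    model$weights <- fit[c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")]
    model$train_rmse <- as.numeric(fit$train_rmse)
    model$val_rmse <- if (is.null(validation)) NULL else as.numeric(fit$val_rmse)
    model$final_rmse <- model$train_rmse[length(model$train_rmse)]
    model$config <- list(epochs = epochs, batch = batch,
                         learning_rate = learning_rate)
    model$trained <- TRUE
    model
  }

  if (restarts <= 1) return(train_once())
  fits <- purrr::map(seq_len(restarts), function(i) train_once())
  score <- purrr::map_dbl(fits, function(m) {
    if (select_by == "loss") return(-m$final_rmse)
    Z <- whiten_codes(encode(m, X))
    mean(purrr::map_dbl(k_focus, function(k) {
      sol <- fit_kmeans(Z, k, restarts = 5, compute_metrics = FALSE)
      calinski_harabasz(Z, sol$labels)
    }))
  })
  fits[[which.max(score)]]
}

#' Bottleneck features
#'
#' Activations of the bottleneck layer, the extracted features used for
#' clustering.
#'
#' @param model A trained `autoencoder`.
#' @param X Matrix with the model's input width.
#' @return An n x J matrix of bottleneck activations.
#' @export
encode <- function(model, X) {
  stopifnot(inherits(model, "autoencoder"))
  if (!model$trained) abort("encode: model is untrained")
  X <- as.matrix(X)
  if (ncol(X) != model$d) {
    abort(sprintf("encode: input width %d does not match model width %d",
                  ncol(X), model$d))
  }
  w <- model$weights
  ae_encode_cpp(X, w$W1, w$b1, w$W2, w$b2)
}

#' Reconstruct inputs through the autoencoder
#'
#' @inheritParams encode
#' @return An n x d matrix of reconstructions.
#' @export
reconstruct <- function(model, X) {
  stopifnot(inherits(model, "autoencoder"), model$trained)
  X <- as.matrix(X)
  if (ncol(X) != model$d) abort("reconstruct: input width mismatch")
  w <- model$weights
  ae_reconstruct_cpp(X, w$W1, w$b1, w$W2, w$b2, w$W3, w$b3, w$W4, w$b4)
}

#' Whiten bottleneck codes
#'
#' An autoencoder's code space is only defined up to an affine
#' reparametrization: independent training runs of the same model
#' produce rotated, sheared and rescaled versions of the same chart.
#' Whitening (centering and transforming to unit covariance, fitted on
#' training rows) canonicalizes the codes so that distance-based
#' clustering and the WCSS elbow are invariant to that arbitrary
#' parametrization.
#'
#' @param Z Code matrix to transform.
#' @param whitener Optional whitener fitted by [code_whitener()]; when
#'   omitted, one is fitted on `Z` itself.
#' @return The whitened matrix.
#' @export
whiten_codes <- function(Z, whitener = NULL) {
  Z <- as.matrix(Z)
  if (is.null(whitener)) whitener <- code_whitener(Z)
  sweep(Z, 2, whitener$center) %*% whitener$transform
}

#' @rdname whiten_codes
#' @export
code_whitener <- function(Z) {
  Z <- as.matrix(Z)
  ctr <- colMeans(Z)
  S <- crossprod(sweep(Z, 2, ctr)) / max(nrow(Z) - 1, 1)
  e <- eigen(S, symmetric = TRUE)
  list(center = ctr,
       transform = e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)),
                                      length(e$values)))
}

#' Cross-validated bottleneck grid search
#'
#' For each candidate bottleneck width `J`, performs k-fold
#' cross-validation: each fold trains the autoencoder on the remaining
#' folds and evaluates reconstruction RMSE on the held-out fold.
#' Reports the across-fold mean and SD of the final training and
#' validation RMSE plus the per-epoch validation curves averaged across
#' folds.
#'
#' @param X Training matrix or `feature_matrix`.
#' @param J_grid Candidate bottleneck widths (default 1:10).
#' @param folds Number of CV folds (default 10).
#' @inheritParams fit_autoencoder
#' @return An `ae_grid` object; `tidy()` gives the per-J summary table.
#' @export
ae_grid_search <- function(X, J_grid = 1:10, folds = 10, epochs = 100,
                           batch = 64, learning_rate = 1e-3, seed = NULL) {
  if (inherits(X, "feature_matrix")) X <- X$train
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < folds) abort(sprintf("ae_grid_search: n = %d < folds = %d", n, folds))
  if (any(J_grid < 1)) abort("ae_grid_search: all J must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  fold_id <- sample(rep(seq_len(folds), length.out = n))
  results <- list(); curves <- list()
  for (J in J_grid) {
    tr <- numeric(folds); va <- numeric(folds)
    cv <- matrix(NA_real_, epochs, folds)
    for (f in seq_len(folds)) {
      hold <- fold_id == f
      fit <- fit_autoencoder(X[!hold, , drop = FALSE], J, epochs = epochs,
                             batch = batch, learning_rate = learning_rate,
                             validation = X[hold, , drop = FALSE])
      tr[f] <- fit$final_rmse
      va[f] <- fit$val_rmse[epochs]
      cv[, f] <- fit$val_rmse
    }
    results[[as.character(J)]] <- tibble::tibble(
      J = J,
      train_rmse_mean = mean(tr), train_rmse_sd = sd(tr),
      val_rmse_mean = mean(va), val_rmse_sd = sd(va))
    curves[[as.character(J)]] <- tibble::tibble(
      J = J, epoch = seq_len(epochs),
      val_rmse_mean = rowMeans(cv),
      val_rmse_sd = apply(cv, 1, sd))
  }
  structure(list(summary = dplyr::bind_rows(results),
                 curves = dplyr::bind_rows(curves),
                 folds = folds,
                 config = list(epochs = epochs, batch = batch,
                               learning_rate = learning_rate)),
            class = "ae_grid")
}

#' @export
print.ae_grid <- function(x, ...) {
  cat(sprintf("<ae_grid> %d bottleneck widths, %d-fold CV\n",
              nrow(x$summary), x$folds))
  print(x$summary)
  invisible(x)
}

#' Principal component feature extraction
#'
#' Fits PCA on the (already standardized) training matrix. With
#' `n_components = "auto"` the count is chosen by a scree-elbow rule:
#' the component index `j` maximizing the second difference
#' `ev(j) - 2 ev(j+1) + ev(j+2)` of the explained-variance sequence,
#' i.e. the last component before the variance flattens.
#'
#' @param X Training matrix or `feature_matrix`.
#' @param n_components `"auto"` or an integer count.
#' @return A `pca_fit` with `rotation`, `center`, `explained_variance`,
#'   `n_components` and the projected training scores `scores`.
#' @export
fit_pca <- function(X, n_components = "auto") {
  if (inherits(X, "feature_matrix")) X <- X$train
  X <- as.matrix(X)
  if (ncol(X) == 0) abort("fit_pca: zero-width input")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  if (identical(n_components, "auto")) {
    if (length(ev) < 3) {
      n_components <- length(ev)
    } else {
      j <- seq_len(length(ev) - 2)
      d2 <- ev[j] - 2 * ev[j + 1] + ev[j + 2]
      n_components <- which.max(d2)
    }
  }
  n_components <- as.integer(n_components)
  structure(list(rotation = pc$rotation, center = pc$center,
                 explained_variance = ev,
                 n_components = n_components,
                 scores = pc$x[, seq_len(n_components), drop = FALSE]),
            class = "pca_fit")
}

#' Project new rows onto fitted principal components
#'
#' @param object A `pca_fit`.
#' @param newdata Matrix with the training width.
#' @param ... Unused.
#' @return Scores on the retained components.
#' @export
predict.pca_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  sweep(newdata, 2, object$center) %*%
    object$rotation[, seq_len(object$n_components), drop = FALSE]
}

#' @export
print.pca_fit <- function(x, ...) {
  cat(sprintf("<pca_fit> %d components retained of %d\n",
              x$n_components, length(x$explained_variance)))
  invisible(x)
}
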