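sq_dist_to <- function(Z, C) {
  # n x k matrix of squared Euclidean distances to centroids C
  matrix(rowSums(Z^2), nrow(Z), nrow(C)) -
    2 * Z %*% t(C) +
    matrix(rowSums(C^2), nrow(Z), nrow(C), byrow = TRUE)
}

lloyd_once <- function(Z, centers, max_iter) {
  n <- nrow(Z); k <- nrow(centers)
  labels_prev <- rep(0L, n)
  for (it in seq_len(max_iter)) {
    D <- sq_dist_to(Z, centers)
    labels <- max.col(-D, ties.method = "first")
    # empty-cluster repair: reseed to the point farthest from its centroid
    empty <- setdiff(seq_len(k), unique(labels))
    if (length(empty) > 0) {
      d_own <- D[cbind(seq_len(n), labels)]
      for (e in empty) {
        far <- which.max(d_own)
        centers[e, ] <- Z[far, ]
        labels[far] <- e
        d_own[far] <- -Inf
      }
    }
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(Z[labels == j, , drop = FALSE])
    }
    if (identical(labels, labels_prev)) break
    labels_prev <- labels
  }
  D <- sq_dist_to(Z, centers)
  labels <- max.col(-D, ties.method = "first")
  wcss <- sum(D[cbind(seq_len(n), labels)])
  list(centers = centers, labels = labels, wcss = wcss, iter = it)
}

#' k-means clustering with restarts
#'
#' Lloyd's assign/update iterations minimizing the within-cluster sum of
#' squares, run to convergence or `max_iter` from each of `restarts`
#' seeded random initializations (plus any user-supplied initial
#' centroid matrices); the solution with the lowest WCSS is kept.
#' Assignment ties break to the lowest cluster index; an emptied cluster
#' is reseeded to the point farthest from its centroid.
#'
#' @param Z Numeric feature matrix (n x J).
#' @param k Number of clusters, `1 <= k <= n`.
#' @param max_iter Maximum Lloyd iterations per start (default 300).
#' @param restarts Number of random initializations (default 10).
#' @param init Optional list of k x J matrices used as additional
#'   initializations (e.g. warm starts from a smaller k).
#' @param seed Optional RNG seed.
#' @param compute_metrics Also compute the Calinski-Harabasz index and
#'   mean silhouette (k >= 2 only).
#' @return A `cluster_solution`: `k`, `centroids`, `labels`, `wcss`,
#'   `ch_index`, `silhouette`, `sizes`.
#' @export
#' @examples
#' z <- matrix(c(0, 1, 10, 11), ncol = 1)
#' fit_kmeans(z, k = 2, seed = 1)$wcss  # 1
fit_kmeans <- function(Z, k, max_iter = 300, restarts = 10, init = NULL,
                       seed = NULL, compute_metrics = TRUE) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (k > n) abort(sprintf("fit_kmeans: k = %d exceeds n = %d", k, n))
  if (k < 1) abort("fit_kmeans: k must be >= 1")
  if (!all(is.finite(Z))) abort("fit_kmeans: Z must be finite")
  if (!is.null(seed)) set.seed(seed)

  starts <- purrr::map(seq_len(restarts), function(i) {
    Z[sample.int(n, k), , drop = FALSE]
  })
  starts <- c(starts, init)

  best <- NULL
  for (s in starts) {
    res <- lloyd_once(Z, as.matrix(s), max_iter)
    if (is.null(best) || res$wcss < best$wcss) best <- res
  }

  sol <- structure(list(
    k = as.integer(k), centroids = best$centers, labels = best$labels,
    wcss = best$wcss, sizes = tabulate(best$labels, k),
    ch_index = NA_real_, silhouette = NA_real_), class = "cluster_solution")
  if (compute_metrics && k >= 2) {
    sol$ch_index <- calinski_harabasz(Z, best$labels)
    sol$silhouette <- silhouette_coef(Z, best$labels)
  }
  sol
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> k = %d, sizes = %s, WCSS = %.4g\n",
              x$k, paste(x$sizes, collapse = "/"), x$wcss))
  if (!is.na(x$ch_index)) {
    cat(sprintf("  CH = %.4g, silhouette = %.4g\n", x$ch_index, x$silhouette))
  }
  invisible(x)
}

#' Calinski-Harabasz index
#'
#' Ratio of between- to within-cluster dispersion, each scaled by its
#' degrees of freedom: `(B / (k - 1)) / (W / (n - k))` with
#' `B = sum_i n_i ||mu_i - mu||^2` and `W` the within-cluster sum of
#' squares. A zero `W` (perfectly collapsed clusters) returns a large
#' finite sentinel.
#'
#' @param Z Feature matrix.
#' @param labels Integer cluster labels; every cluster must be
#'   non-empty.
#' @return The index (larger is better).
#' @export
calinski_harabasz <- function(Z, labels) {
  Z <- as.matrix(Z)
  labs <- unique(labels)
  k <- length(labs)
  n <- nrow(Z)
  if (k < 2) abort("calinski_harabasz: need at least 2 clusters")
  if (any(tabulate(match(labels, labs), k) == 0)) {
    abort("calinski_harabasz: empty cluster")
  }
  mu <- colMeans(Z)
  B <- 0; W <- 0
  for (l in labs) {
    zi <- Z[labels == l, , drop = FALSE]
    mi <- colMeans(zi)
    B <- B + nrow(zi) * sum((mi - mu)^2)
    W <- W + sum(sweep(zi, 2, mi)^2)
  }
  if (W == 0) return(.Machine$double.xmax / 1e10)
  (B / (k - 1)) / (W / (n - k))
}

#' Mean silhouette coefficient
#'
#' For each point, `a` is its mean distance to the other members of its
#' own cluster and `b` the smallest mean distance to any other cluster;
#' its silhouette is `(b - a) / max(a, b)`, with the convention that a
#' singleton cluster's point scores 0. Returns the mean over all points
#' (Euclidean distances).
#'
#' @inheritParams calinski_harabasz
#' @return Mean silhouette in `[-1, 1]`.
#' @export
silhouette_coef <- function(Z, labels) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (n < 2) abort("silhouette_coef: need at least 2 points")
  labs <- sort(unique(labels))
  if (length(labs) < 2) abort("silhouette_coef: need at least 2 clusters")
  D <- as.matrix(dist(Z))
  sizes <- table(factor(labels, levels = labs))
  # mean distance from every point to each cluster
  M <- sapply(labs, function(l) {
    rowSums(D[, labels == l, drop = FALSE]) / sum(labels == l)
  })
  s <- numeric(n)
  for (i in seq_len(n)) {
    li <- match(labels[i], labs)
    ni <- sizes[[li]]
    if (ni == 1) { s[i] <- 0; next }
    a <- M[i, li] * ni / (ni - 1)  # exclude self from own-cluster mean
    b <- min(M[i, -li])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Elbow selection on a WCSS curve
#'
#' Picks the cluster count at the point of maximum curvature of the
#' WCSS-versus-k curve: the interior k maximizing the discrete second
#' difference `wcss(k-1) - 2 wcss(k) + wcss(k+1)`; ties break to the
#' smallest k. A near-linear curve (maximum second difference below
#' `tol` times the curve's range) has no elbow: the smallest interior k
#' is returned with attribute `no_elbow = TRUE` and a warning.
#'
#' @param wcss Named numeric vector of WCSS values; names are
#'   consecutive integer k values.
#' @param tol Relative curvature tolerance for the no-elbow flag.
#' @return The selected k (integer) with attribute `no_elbow`.
#' @export
#' @examples
#' elbow_select(c(`1` = 100, `2` = 20, `3` = 18, `4` = 17, `5` = 16))  # 2
elbow_select <- function(wcss, tol = 0.01) {
  ks <- as.integer(names(wcss))
  if (length(wcss) < 3) abort("elbow_select: need at least 3 consecutive k values")
  if (any(diff(ks) != 1)) abort("elbow_select: k values must be consecutive")
  v <- as.numeric(wcss)
  inner <- 2:(length(v) - 1)
  d2 <- v[inner - 1] - 2 * v[inner] + v[inner + 1]
  rng <- max(v) - min(v)
  no_elbow <- max(d2) < tol * max(rng, .Machine$double.eps)
  k_star <- if (no_elbow) ks[inner[1]] else ks[inner[which.max(d2)]]
  if (no_elbow) {
    warn("elbow_select: WCSS curve is near-linear (no elbow); returning the smallest candidate")
  }
  structure(as.integer(k_star), no_elbow = no_elbow)
}

#' Internal-validity grid over feature sets and cluster counts
#'
#' Runs k-means for every combination of candidate feature set and k,
#' recording WCSS (from k = 1, for the elbow curve) and the
#' Calinski-Harabasz index and silhouette coefficient (from k = 2).
#'
#' @param features Named list of feature matrices (e.g. `raw`, `pca`,
#'   `dae_J2`), all with the same number of rows.
#' @param k_range Candidate cluster counts for the validity indices.
#' @param restarts,max_iter,seed Passed to [fit_kmeans()].
#' @return A `selection_grid` tibble: `feature_set`, `k`, `wcss`,
#'   `ch_index`, `silhouette`.
#' @export
cluster_selection_grid <- function(features, k_range = 2:10, restarts = 10,
                                   max_iter = 300, seed = NULL) {
  stopifnot(is.list(features), !is.null(names(features)))
  if (!is.null(seed)) set.seed(seed)
  ks <- sort(unique(c(1L, as.integer(k_range))))
  grid <- purrr::map_dfr(names(features), function(fs) {
    Z <- as.matrix(features[[fs]])
    purrr::map_dfr(ks, function(k) {
      sol <- fit_kmeans(Z, k, max_iter = max_iter, restarts = restarts,
                        compute_metrics = k >= 2)
      tibble::tibble(feature_set = fs, k = k, wcss = sol$wcss,
                     ch_index = sol$ch_index, silhouette = sol$silhouette)
    })
  })
  class(grid) <- c("selection_grid", class(grid))
  grid
}

#' Select the best feature-extraction method
#'
#' For each feature set, the Calinski-Harabasz index and silhouette
#' coefficient are min-max normalized across feature sets within each
#' focal k, then averaged over both metrics and all focal k; the feature
#' set with the highest normalized mean wins (ties to the first listed).
#'
#' @param grid A [cluster_selection_grid()] result with no missing cells
#'   over `k_focus`.
#' @param k_focus Cluster counts over which to compare (default 2:4, the
#'   clinically plausible small-k regime).
#' @return The winning feature-set name, with the full ranking tibble in
#'   attribute `ranking`.
#' @export
select_feature_set <- function(grid, k_focus = 2:4) {
  sub <- grid[grid$k %in% k_focus, , drop = FALSE]
  need <- length(unique(grid$feature_set)) * length(k_focus)
  if (nrow(sub) < need || anyNA(sub$ch_index) || anyNA(sub$silhouette)) {
    abort("select_feature_set: grid has missing cells over k_focus")
  }
  norm01 <- function(x) {
    r <- max(x) - min(x)
    if (r == 0) rep(0.5, length(x)) else (x - min(x)) / r
  }
  sub <- sub |>
    dplyr::group_by(.data$k) |>
    dplyr::mutate(ch_n = norm01(.data$ch_index),
                  sil_n = norm01(.data$silhouette)) |>
    dplyr::ungroup()
  ranking <- sub |>
    dplyr::group_by(.data$feature_set) |>
    dplyr::summarise(score = mean(c(.data$ch_n, .data$sil_n)),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$score))
  best <- ranking$feature_set[1]
  attr(best, "ranking") <- ranking
  best
}

#' Assign new rows to fitted clusters
#'
#' Nearest-centroid assignment under squared Euclidean distance; ties
#' break to the lowest cluster index.
#'
#' @param solution A `cluster_solution`.
#' @param Z_new Matrix with the solution's feature width.
#' @return Integer labels.
#' @export
assign_clusters <- function(solution, Z_new) {
  stopifnot(inherits(solution, "cluster_solution"))
  Z_new <- as.matrix(Z_new)
  if (ncol(Z_new) != ncol(solution$centroids)) {
    abort(sprintf("assign_clusters: width %d does not match centroids (%d)",
                  ncol(Z_new), ncol(solution$centroids)))
  }
  if (nrow(Z_new) == 0) return(integer(0))
  D <- sq_dist_to(Z_new, solution$centroids)
  max.col(-D, ties.method = "first")
}
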