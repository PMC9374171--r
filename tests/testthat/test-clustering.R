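test_that("k-means closed forms on hand-computable inputs", {
  b <- blob_1d()
  one <- fit_kmeans(b$z, k = 1, seed = 1)
  expect_equal(as.numeric(one$centroids), mean(b$z))
  expect_equal(one$wcss, sum((b$z - mean(b$z))^2))

  two <- fit_kmeans(b$z, k = 2, seed = 2)
  expect_equal(sort(as.numeric(two$centroids)), c(0.5, 10.5))
  expect_equal(two$wcss, 1.0)
  expect_equal(length(unique(two$labels[1:2])), 1)
  expect_equal(length(unique(two$labels[3:4])), 1)

  # duplicating all points doubles WCSS, same centroids
  dup <- fit_kmeans(rbind(b$z, b$z), k = 2, seed = 3)
  expect_equal(dup$wcss, 2.0)
  expect_equal(sort(as.numeric(dup$centroids)), c(0.5, 10.5))

  expect_error(fit_kmeans(b$z, k = 5), "exceeds")
})

test_that("k-means agrees with the stock implementation on random data", {
  set.seed(44)
  Z <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 4), 30, 2))
  ours <- fit_kmeans(Z, 3, restarts = 20, seed = 45)
  ref <- kmeans(Z, 3, nstart = 20, iter.max = 300)
  expect_equal(ours$wcss, ref$tot.withinss, tolerance = 1e-6)
})

test_that("nested initialization makes WCSS non-increasing in k", {
  set.seed(46)
  Z <- matrix(rnorm(200 * 3), 200, 3)
  prev <- fit_kmeans(Z, 1, seed = 47)
  wcss <- prev$wcss
  for (k in 2:7) {
    d_own <- apply(Z, 1, function(p) {
      min(colSums((t(prev$centroids) - p)^2))
    })
    split_init <- rbind(prev$centroids, Z[which.max(d_own), , drop = FALSE])
    sol <- fit_kmeans(Z, k, restarts = 5, init = list(split_init),
                      seed = 40 + k)
    expect_lte(sol$wcss, wcss + 1e-8)
    wcss <- sol$wcss
    prev <- sol
  }
})

test_that("Calinski-Harabasz matches hand value and brute force", {
  b <- blob_1d()
  expect_equal(calinski_harabasz(b$z, b$labels), 200)
  # label names are irrelevant
  expect_equal(calinski_harabasz(b$z, c(7, 7, 2, 2)), 200)

  set.seed(48)
  for (i in 1:5) {
    Z <- matrix(rnorm(120 * 2), 120, 2)
    labels <- sample(1:4, 120, replace = TRUE)
    expect_equal(calinski_harabasz(Z, labels), ch_brute(Z, labels),
                 tolerance = 1e-9)
  }
  expect_error(calinski_harabasz(b$z, rep(1, 4)), "clusters")
})

test_that("random labels on isotropic noise give CH near 1", {
  set.seed(49)
  vals <- vapply(1:20, function(i) {
    Z <- matrix(rnorm(300 * 3), 300, 3)
    calinski_harabasz(Z, sample(1:3, 300, replace = TRUE))
  }, numeric(1))
  expect_equal(mean(vals), 1, tolerance = 0.15)
})

test_that("silhouette matches hand value, brute force and stock oracle", {
  b <- blob_1d()
  expect_equal(silhouette_coef(b$z, b$labels), 0.8997494, tolerance = 1e-6)

  set.seed(50)
  for (i in 1:4) {
    Z <- matrix(rnorm(80 * 2), 80, 2)
    labels <- sample(1:3, 80, replace = TRUE)
    ours <- silhouette_coef(Z, labels)
    expect_equal(ours, silhouette_brute(Z, labels), tolerance = 1e-9)
    ref <- mean(cluster::silhouette(labels, dist(Z))[, "sil_width"])
    expect_equal(ours, ref, tolerance = 1e-9)
    expect_true(ours >= -1 && ours <= 1)
  }

  # singleton clusters score zero by convention
  z3 <- matrix(c(0, 5, 10), 3, 1)
  expect_equal(silhouette_coef(z3, c(1, 2, 3)), 0)
})

test_that("elbow picks the maximum-curvature k and flags linear curves", {
  wcss <- c(`1` = 100, `2` = 20, `3` = 18, `4` = 17, `5` = 16)
  expect_equal(as.integer(elbow_select(wcss)), 2L)

  lin <- setNames(seq(100, 20, length.out = 8), 1:8)
  expect_warning(k <- elbow_select(lin), "no elbow")
  expect_true(attr(k, "no_elbow"))
  expect_equal(as.integer(k), 2L)

  # three well-separated equal blobs recover k = 3
  set.seed(51)
  Z <- rbind(matrix(rnorm(120, 0, 0.3), 60, 2),
             matrix(rnorm(120, 5, 0.3), 60, 2),
             cbind(rnorm(60, 0, 0.3), rnorm(60, 5, 0.3)))
  wc <- vapply(1:8, function(k) {
    fit_kmeans(Z, k, seed = 50 + k, compute_metrics = FALSE)$wcss
  }, numeric(1))
  names(wc) <- 1:8
  expect_equal(as.integer(elbow_select(wc)), 3L)

  expect_error(elbow_select(c(`1` = 3, `2` = 2)), "3 consecutive")
})

test_that("feature-set selection follows the normalized-mean rule", {
  mk <- function(fs, ch, sil) {
    tibble::tibble(feature_set = fs, k = rep(2:4, each = length(unique(fs))),
                   wcss = 1, ch_index = ch, silhouette = sil)
  }
  # dae_J2 dominates both metrics at every focal k
  grid <- tibble::tibble(
    feature_set = rep(c("raw", "pca", "dae_J2"), times = 3),
    k = rep(2:4, each = 3),
    wcss = 1,
    ch_index = c(10, 50, 90, 12, 48, 95, 11, 52, 88),
    silhouette = c(.1, .4, .8, .12, .42, .82, .09, .38, .78))
  best <- select_feature_set(grid)
  expect_equal(as.character(best), "dae_J2")
  ranking <- attr(best, "ranking")
  expect_equal(ranking$feature_set[1], "dae_J2")

  single <- grid[grid$feature_set == "pca", ]
  expect_equal(as.character(select_feature_set(single)), "pca")

  # swapped dominance: brute-force the defined rule independently
  grid2 <- tibble::tibble(
    feature_set = rep(c("x", "y"), times = 3),
    k = rep(2:4, each = 2), wcss = 1,
    ch_index = c(100, 10, 90, 20, 95, 15),
    silhouette = c(.2, .9, .25, .85, .15, .95))
  by_hand <- local({
    scores <- c(x = 0, y = 0)
    for (k in 2:4) {
      sub <- grid2[grid2$k == k, ]
      for (m in c("ch_index", "silhouette")) {
        v <- sub[[m]]
        nv <- (v - min(v)) / (max(v) - min(v))
        scores <- scores + setNames(nv, sub$feature_set)[names(scores)]
      }
    }
    names(which.max(scores))
  })
  expect_equal(as.character(select_feature_set(grid2)), by_hand)

  expect_error(select_feature_set(grid[grid$k != 3, ]), "missing")
})

test_that("assignment uses nearest centroid with low-index ties", {
  b <- blob_1d()
  sol <- fit_kmeans(b$z, 2, seed = 52)
  expect_equal(assign_clusters(sol, b$z), sol$labels)

  # order centroids so we can reason about indices
  ord <- order(sol$centroids[, 1])
  sol$centroids <- sol$centroids[ord, , drop = FALSE]
  expect_equal(assign_clusters(sol, matrix(4)), 1L)       # nearer 0.5
  expect_equal(assign_clusters(sol, matrix(5.5)), 1L)     # equidistant -> low
  expect_equal(assign_clusters(sol, matrix(9)), 2L)
  expect_error(assign_clusters(sol, matrix(0, 1, 2)), "width")
})
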