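test_that("configuration validation names the offending field", {
  expect_error(synthetic_config(n_respondents = -1), "n_respondents")
  expect_error(synthetic_config(cluster_weights = c(0.6, 0.3, 0.2)),
               "cluster_weights")
  expect_error(synthetic_config(cluster_weights = c(-0.1, 0.6, 0.5)),
               "cluster_weights")
  expect_error(synthetic_config(artifact_rates = c(duplicate = 1.2,
                                                   incomplete = 0,
                                                   outlier = 0)),
               "artifact_rates")
  expect_error(synthetic_config(separation = -0.5), "separation")
})

test_that("empty cohort keeps the full column schema", {
  x <- simulate_survey(n = 0, seed = 1)
  expect_equal(nrow(x), 0)
  expect_setequal(names(x), c(survey_dictionary()$column, ".true_cluster"))
})

test_that("generation is deterministic given config and seed", {
  a <- simulate_survey(n = 150, seed = 99)
  b <- simulate_survey(n = 150, seed = 99)
  expect_identical(a, b)
  c <- simulate_survey(n = 150, seed = 100)
  expect_false(identical(a, c))
})

test_that("latent cluster proportions match the cohort composition", {
  x <- simulate_survey(n = 10000, seed = 2)
  prop <- table(x$.true_cluster) / nrow(x)
  target <- c(A = 1396, B = 98, C = 569) / 2063
  expect_true(all(abs(prop[names(target)] - target) <= 0.02))
})

test_that("per-cluster instrument score means hit the configured targets", {
  x <- simulate_survey(n = 5000, seed = 1)
  sc <- score_survey(x)
  agg <- sc |>
    dplyr::group_by(.data$.true_cluster) |>
    dplyr::summarise(gsrs = mean(.data$gsrs_total),
                     psqi = mean(.data$psqi_global), .groups = "drop")
  gsrs_target <- c(A = 2.18, B = 17.94, C = 6.39)
  psqi_target <- c(A = 8.33, B = 11.57, C = 9.96)
  expect_true(all(abs(agg$gsrs - gsrs_target[agg$.true_cluster]) <= 0.5))
  expect_true(all(abs(agg$psqi - psqi_target[agg$.true_cluster]) <= 0.5))
})

test_that("score calibration error shrinks with n (Monte-Carlo property)", {
  err_at <- function(n, seed) {
    sc <- score_gsrs(simulate_survey(n = n, seed = seed))
    m <- mean(sc$gsrs_total[sc$.true_cluster == "A"])
    abs(m - 2.18)
  }
  small <- mean(vapply(1:3, function(i) err_at(300, i), numeric(1)))
  large <- mean(vapply(1:3, function(i) err_at(4000, 10 + i), numeric(1)))
  expect_lt(large, small + 0.05)
})

test_that("artifact injection is manifest-faithful and rate 0 is identity", {
  x <- simulate_survey(n = 400, seed = 5)
  same <- inject_artifacts(x, rates = c(duplicate = 0, incomplete = 0,
                                        outlier = 0))
  expect_equal(nrow(same), nrow(x))
  expect_equal(nrow(artifact_manifest(same)), 0)

  rates <- c(duplicate = 0.02, incomplete = 0.03, outlier = 0.02)
  y <- inject_artifacts(x, rates = rates, seed = 6)
  man <- artifact_manifest(y)
  expect_true(all(man$artifact %in% c("duplicate", "incomplete", "outlier")))

  dup_ids <- man$respondent_id[man$artifact == "duplicate"]
  expect_equal(sort(unique(y$respondent_id[duplicated(y$respondent_id)])),
               sort(dup_ids))

  # every outlier-flagged row violates at least one preprocessing bound
  out_ids <- man$respondent_id[man$artifact == "outlier"]
  bounds <- outlier_bounds()
  for (id in out_ids) {
    row <- y[y$respondent_id == id, ]
    hit <- any(vapply(names(bounds), function(f) {
      any(row[[f]] < bounds[[f]][1] | row[[f]] > bounds[[f]][2])
    }, logical(1)))
    expect_true(hit)
  }

  # incomplete-flagged rows have blanked trailing sections
  inc_ids <- man$respondent_id[man$artifact == "incomplete"]
  for (id in inc_ids) {
    row <- y[y$respondent_id == id, ][1, ]
    expect_true(anyNA(row[survey_columns(c("gsrs", "bss"))]))
  }

  expect_error(inject_artifacts(x, rates = c(duplicate = 2, incomplete = 0,
                                             outlier = 0)), "rates")
})

test_that("duplicate counts are binomial draws reproducible under a seed", {
  x <- simulate_survey(n = 1000, seed = 8)
  y1 <- inject_artifacts(x, rates = c(duplicate = 0.01, incomplete = 0,
                                      outlier = 0), seed = 9)
  y2 <- inject_artifacts(x, rates = c(duplicate = 0.01, incomplete = 0,
                                      outlier = 0), seed = 9)
  m1 <- artifact_manifest(y1)
  expect_identical(m1, artifact_manifest(y2))
  # about 10 expected; allow generous binomial spread
  expect_gt(nrow(m1), 1)
  expect_lt(nrow(m1), 25)
})

test_that("cleaning chain removes exactly the manifest-flagged rows", {
  x <- simulate_survey(n = 600, seed = 11)
  y <- inject_artifacts(x, rates = c(duplicate = 0.02, incomplete = 0.03,
                                     outlier = 0.02), seed = 12)
  man <- artifact_manifest(y)
  cleaned <- y |> dedupe_responders() |> filter_eligible() |>
    drop_outlier_rows()
  removed_ids <- setdiff(y$respondent_id, cleaned$respondent_id)
  expect_setequal(removed_ids, unique(man$respondent_id))

  log <- stage_log(cleaned)
  expect_equal(log$rows_in - log$rows_removed, log$rows_out)
  expect_equal(nrow(cleaned) + sum(log$rows_removed), nrow(y))
})

test_that("separation scalar interpolates the cluster signal", {
  sep0 <- synthetic_config(separation = 0)
  x0 <- simulate_survey(n = 1500, seed = 13, config = sep0)
  x1 <- simulate_survey(n = 1500, seed = 13)
  gap <- function(x) {
    m <- tapply(as.numeric(x$bss), x$.true_cluster, mean)
    max(m) - min(m)
  }
  expect_lt(gap(x0), gap(x1))
  expect_lt(gap(x0), 0.25)
})
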