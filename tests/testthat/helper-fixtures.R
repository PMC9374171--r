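# A single complete survey row with benign defaults; scoring tests
# override the fields they exercise.
blank_respondent <- function(n = 1) {
  dict <- survey_dictionary()
  out <- list(respondent_id = sprintf("T%04d", seq_len(n)),
              consent = rep(TRUE, n))
  defaults <- list(
    age = 21, height_cm = 175, weight_kg = 70, rank = "corporal",
    education = 3L, smoking_status = "never",
    smoking_packs_per_day = 0, smoking_years = 0,
    alcohol_freq = 2L, coffee_freq = 2L, energy_drink_freq = 2L,
    exercise_freq = 2L, physical_grade = 2L,
    sleep_disorder_present = "none", sleep_disorder_past = "none",
    gi_disorder_present = "none", gi_disorder_past = "none",
    general_disease = "none", bp_history = FALSE,
    med_sleep = FALSE, med_digestive = FALSE,
    night_shift_dutyoff_freq = 1L, night_shift_dutyoff_fatigue = 3L,
    night_shift_no_dutyoff_freq = 1L, night_shift_no_dutyoff_fatigue = 3L,
    stress = 3L,
    psqi_bedtime = 23, psqi_latency_min = 10, psqi_waketime = 7,
    psqi_sleep_hours = 7.5,
    psqi_cant_sleep_30min = 0L, psqi_quality = 0L, psqi_medication = 0L,
    psqi_sleepy = 0L, psqi_enthusiasm = 0L, psqi_other_desc = "none",
    berlin_drive_freq = 0L, bss = 4L
  )
  for (nm in paste0("psqi_", c("wake_night", "bathroom", "breathe", "snore",
                               "cold", "hot", "bad_dreams", "pain",
                               "other_disturb"))) defaults[[nm]] <- 0L
  for (nm in paste0("berlin_c1_", 1:5)) defaults[[nm]] <- 0L
  for (nm in paste0("berlin_c2_", 1:4)) defaults[[nm]] <- 0L
  for (nm in survey_columns("sleep_env")) defaults[[nm]] <- 3L
  for (nm in survey_columns("diet")) defaults[[nm]] <- 4L
  for (nm in survey_columns("nq")) defaults[[nm]] <- 3L
  for (nm in survey_columns("gsrs")) defaults[[nm]] <- 1L
  for (nm in names(defaults)) out[[nm]] <- rep(defaults[[nm]], n)
  tibble::as_tibble(out)[, c(dict$column)] |>
    dplyr::mutate(respondent_id = out$respondent_id)
}

# two tight 1-D blobs used by the hand-computed clustering examples
blob_1d <- function() {
  list(z = matrix(c(0, 1, 10, 11), ncol = 1), labels = c(1L, 1L, 2L, 2L))
}

# small standardized cohort feature matrix for extraction tests
small_cohort_features <- function(n = 400, seed = 101) {
  x <- simulate_survey(n = n, seed = seed)
  s <- score_survey(x) |> filter_disturbed() |>
    split_train_test(0.8, seed = seed + 1)
  list(fm = build_feature_matrix(s),
       truth = s$.true_cluster[s$.partition == "train"])
}

# brute-force silhouette: literal per-point definition
silhouette_brute <- function(Z, labels) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  s <- numeric(n)
  for (i in seq_len(n)) {
    di <- sqrt(rowSums(sweep(Z, 2, Z[i, ])^2))
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(di[setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(di[labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# brute-force Calinski-Harabasz from the definition
ch_brute <- function(Z, labels) {
  Z <- as.matrix(Z)
  mu <- colMeans(Z)
  labs <- unique(labels)
  B <- sum(vapply(labs, function(l) {
    zi <- Z[labels == l, , drop = FALSE]
    nrow(zi) * sum((colMeans(zi) - mu)^2)
  }, numeric(1)))
  W <- sum(vapply(labs, function(l) {
    zi <- Z[labels == l, , drop = FALSE]
    sum(sweep(zi, 2, colMeans(zi))^2)
  }, numeric(1)))
  (B / (length(labs) - 1)) / (W / (nrow(Z) - length(labs)))
}

# brute-force Pearson chi-squared from the E-table definition
chi2_brute <- function(counts) {
  counts <- as.matrix(counts)
  E <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  sum((counts - E)^2 / E)
}
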