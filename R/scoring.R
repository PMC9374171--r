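#' PSQI component band definitions
#'
#' The component algorithms of the Pittsburgh Sleep Quality Index are
#' band-based; the cut points are carried as data so variants can be
#' tested. Values are the published convention: latency minutes banded at
#' 15/30/60; sleep duration at 7/6/5 hours; habitual efficiency at
#' 85/75/65 percent; the 9-item disturbance sum at 0/9/18/27; two-item
#' sums (latency, daytime dysfunction) re-banded at 0, 1-2, 3-4, 5-6.
#'
#' @return A named list of numeric cut points consumed by [score_psqi()].
#' @export
psqi_bands <- function() {
  list(
    latency_min    = c(15, 30, 60),   # upper bounds for bands 0,1,2
    duration_hours = c(7, 6, 5),      # lower bounds for bands 0,1,2
    efficiency_pct = c(85, 75, 65),   # lower bounds for bands 0,1,2
    disturb_sum    = c(0, 9, 18),     # upper bounds for bands 0,1,2
    pair_sum       = c(0, 2, 4)       # upper bounds for bands 0,1,2
  )
}

band_upper <- function(x, cuts) {
  # band 0 if x <= cuts[1], 1 if <= cuts[2], 2 if <= cuts[3], else 3
  findInterval(x, cuts, left.open = TRUE)
}

band_lower <- function(x, cuts) {
  # band 0 if x >= cuts[1], 1 if >= cuts[2], 2 if >= cuts[3], else 3
  3L - findInterval(x, rev(cuts))
}

check_complete <- function(data, cols, what) {
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s scoring requires missing column(s): %s",
                  what, paste(missing_cols, collapse = ", ")))
  }
  for (cl in cols) {
    if (anyNA(data[[cl]])) {
      abort(sprintf("%s scoring: item '%s' has missing responses (row %d); no imputation is performed",
                    what, cl, which(is.na(data[[cl]]))[1]))
    }
  }
  invisible(TRUE)
}

#' Score the Pittsburgh Sleep Quality Index
#'
#' Computes the seven PSQI components (each 0-3), the global score (their
#' sum, 0-21) and the sleep-disturbance flag (global > 5) from the 19
#' item-level responses. Time in bed is derived from the bed-time and
#' wake-time clock hours (wrapping past midnight); habitual sleep
#' efficiency is sleep hours divided by time in bed.
#'
#' @param data A data frame containing the PSQI item columns of
#'   [survey_dictionary()].
#' @param bands Band cut points, see [psqi_bands()].
#' @return `data` with columns `psqi_c1` .. `psqi_c7`, `psqi_global` and
#'   `psqi_disturbed` appended.
#' @export
#' @examples
#' x <- simulate_survey(n = 5, seed = 1)
#' score_psqi(x)[, c("psqi_global", "psqi_disturbed")]
score_psqi <- function(data, bands = psqi_bands()) {
  items <- survey_columns("psqi")
  check_complete(data, items, "PSQI")

  disturb_items <- paste0("psqi_", c("wake_night", "bathroom", "breathe",
                                     "snore", "cold", "hot", "bad_dreams",
                                     "pain", "other_disturb"))

  c1 <- as.integer(data$psqi_quality)
  lat_band <- band_upper(data$psqi_latency_min, bands$latency_min)
  c2 <- band_upper(lat_band + data$psqi_cant_sleep_30min, bands$pair_sum)
  c3 <- band_lower(data$psqi_sleep_hours, bands$duration_hours)

  tib <- (data$psqi_waketime - data$psqi_bedtime) %% 24
  tib[tib == 0] <- 24
  eff <- 100 * data$psqi_sleep_hours / tib
  c4 <- band_lower(eff, bands$efficiency_pct)

  dsum <- rowSums(as.matrix(data[disturb_items]))
  c5 <- band_upper(dsum, bands$disturb_sum)
  c6 <- as.integer(data$psqi_medication)
  c7 <- band_upper(data$psqi_sleepy + data$psqi_enthusiasm, bands$pair_sum)

  data$psqi_c1 <- as.integer(c1); data$psqi_c2 <- as.integer(c2)
  data$psqi_c3 <- as.integer(c3); data$psqi_c4 <- as.integer(c4)
  data$psqi_c5 <- as.integer(c5); data$psqi_c6 <- as.integer(c6)
  data$psqi_c7 <- as.integer(c7)
  data$psqi_global <- as.integer(c1 + c2 + c3 + c4 + c5 + c6 + c7)
  data$psqi_disturbed <- data$psqi_global > 5L
  tibble::as_tibble(data)
}

#' Score the Berlin questionnaire
#'
#' Category 1 (five snoring/apnea items) and category 2 (four daytime
#' sleepiness items) are positive with at least two positive responses in
#' the category; category 3 is positive with a self-reported history of
#' high blood pressure and/or a body-mass index above 30 kg/m^2. A
#' respondent is at high risk of obstructive sleep apnea when at least
#' two of the three categories are positive.
#'
#' @param data A data frame with the Berlin item columns, `bp_history`,
#'   `height_cm` and `weight_kg`.
#' @return `data` with `bmi`, `berlin_cat1`, `berlin_cat2`, `berlin_cat3`
#'   (logical) and `berlin_risk` (factor `low`/`high`) appended.
#' @export
score_berlin <- function(data) {
  c1_items <- paste0("berlin_c1_", 1:5)
  c2_items <- paste0("berlin_c2_", 1:4)
  check_complete(data, c(c1_items, c2_items,
                         "bp_history", "height_cm", "weight_kg"), "Berlin")

  bmi <- data$weight_kg / (data$height_cm / 100)^2
  cat1 <- rowSums(as.matrix(data[c1_items])) >= 2
  cat2 <- rowSums(as.matrix(data[c2_items])) >= 2
  cat3 <- data$bp_history | bmi > 30

  data$bmi <- bmi
  data$berlin_cat1 <- cat1
  data$berlin_cat2 <- cat2
  data$berlin_cat3 <- cat3
  data$berlin_risk <- factor(ifelse(cat1 + cat2 + cat3 >= 2, "high", "low"),
                             levels = c("low", "high"))
  tibble::as_tibble(data)
}

#' Score the Gastrointestinal Symptom Rating Scale
#'
#' Each of the 15 items is rated on a 7-point discomfort Likert scale.
#' The default aggregation (`"sum0"`) is a 0-based total: level 1 ("no
#' discomfort") contributes 0 points, level 7 contributes 6, so the total
#' ranges over 0-90. `"sum1"` keeps the raw 1-based sum (15-105) and
#' `"mean"` averages the raw levels.
#'
#' @param data A data frame with the `gsrs_01` .. `gsrs_15` columns.
#' @param convention Aggregation convention, see Details.
#' @return `data` with `gsrs_total` appended.
#' @export
score_gsrs <- function(data, convention = c("sum0", "sum1", "mean")) {
  convention <- match.arg(convention)
  items <- survey_columns("gsrs")
  check_complete(data, items, "GSRS")
  m <- as.matrix(data[items])
  if (any(m < 1 | m > 7)) {
    bad <- which(m < 1 | m > 7, arr.ind = TRUE)[1, ]
    abort(sprintf("GSRS scoring: item '%s' (row %d) outside the 7-point level set",
                  items[bad[2]], bad[1]))
  }
  data$gsrs_total <- switch(convention,
    sum0 = rowSums(m - 1),
    sum1 = rowSums(m),
    mean = rowMeans(m))
  tibble::as_tibble(data)
}

#' Default Nutrition Quotient weight table
#'
#' The NQ is scored from a published weighting of 21 checklist items into
#' four factors (balance, diversity, moderation, behavior) plus a global
#' score; the exact published weights are proprietary to the instrument,
#' so this default is a synthetic stand-in with the instrument's
#' structure: an item-to-factor map (5/5/6/5 items), linear per-level
#' point vectors per item, and factor-to-global weights calibrated so
#' factor and global scores fall on the instrument's reported scale
#' (global around 40-45, "good" at 58+).
#'
#' @return A tibble with columns `item`, `factor`, `points` (list-column
#'   of per-level point vectors, levels 1-5) and an attribute
#'   `factor_weights` used to combine factors into the global score.
#' @export
nq_default_weights <- function() {
  fac <- c(rep("balance", 5), rep("diversity", 5),
           rep("moderation", 6), rep("behavior", 5))
  step <- c(rep(2.5, 5), rep(1.0, 5), rep(1.0, 6), rep(1.25, 5))
  w <- tibble::tibble(
    item = sprintf("nq_%02d", 1:21),
    factor = fac,
    points = purrr::map(step, function(s) s * (0:4))
  )
  attr(w, "factor_weights") <- c(balance = 0.61, diversity = 0.61,
                                 moderation = 0.61, behavior = 0.61)
  w
}

#' Score the Nutrition Quotient
#'
#' Each factor score is the sum, over the items mapped to that factor, of
#' the per-level points for the observed response level; the global score
#' is the weighted combination of the four factor scores. The grade is
#' `"good"` when the global score is at least 58 and `"monitoring"`
#' otherwise.
#'
#' @param data A data frame with the NQ item columns.
#' @param weights A weight table in the layout of [nq_default_weights()].
#' @return `data` with `nq_balance`, `nq_diversity`, `nq_moderation`,
#'   `nq_behavior`, `nq_global` and `nq_grade` appended.
#' @export
score_nq <- function(data, weights = nq_default_weights()) {
  missing_items <- setdiff(weights$item, names(data))
  if (length(missing_items) > 0) {
    abort(sprintf("NQ weight table maps item(s) absent from the data: %s",
                  paste(missing_items, collapse = ", ")))
  }
  check_complete(data, weights$item, "NQ")

  item_points <- purrr::map2(weights$item, weights$points, function(it, pts) {
    lev <- data[[it]]
    if (any(lev < 1 | lev > length(pts))) {
      abort(sprintf("NQ scoring: item '%s' has a level outside 1..%d",
                    it, length(pts)))
    }
    pts[lev]
  })
  pm <- do.call(cbind, item_points)

  fw <- attr(weights, "factor_weights", exact = TRUE)
  if (is.null(fw)) abort("NQ weight table lacks the 'factor_weights' attribute")

  for (f in unique(weights$factor)) {
    cols <- which(weights$factor == f)
    data[[paste0("nq_", f)]] <- rowSums(pm[, cols, drop = FALSE])
  }
  data$nq_global <- Reduce(`+`, purrr::map(names(fw), function(f) {
    fw[[f]] * data[[paste0("nq_", f)]]
  }))
  data$nq_grade <- factor(ifelse(data$nq_global >= 58, "good", "monitoring"),
                          levels = c("good", "monitoring"))
  tibble::as_tibble(data)
}

#' Score all instruments of a survey table
#'
#' Convenience wrapper applying [score_psqi()], [score_berlin()],
#' [score_gsrs()] and [score_nq()] in sequence; the Bristol stool scale
#' item (`bss`) is already a score and passes through unchanged.
#'
#' @inheritParams score_psqi
#' @inheritParams score_gsrs
#' @param nq_weights NQ weight table, see [nq_default_weights()].
#' @return A scored tibble with all instrument score columns appended.
#' @export
#' @examples
#' scored <- score_survey(simulate_survey(n = 20, seed = 1))
#' dplyr::select(scored, psqi_global, gsrs_total, nq_global, berlin_risk)
score_survey <- function(data, bands = psqi_bands(),
                         convention = "sum0",
                         nq_weights = nq_default_weights()) {
  data |>
    score_psqi(bands = bands) |>
    score_berlin() |>
    score_gsrs(convention = convention) |>
    score_nq(weights = nq_weights)
}

#' Finite-population sample size for a proportion
#'
#' Cochran's sample size for estimating a proportion with margin of error
#' `margin` at the given confidence, corrected for a finite population of
#' size `N`: with `n0 = z^2 p (1 - p) / e^2`, the required number of
#' completed questionnaires is `ceiling(n0 / (1 + n0 / N))`. `N = Inf`
#' drops the finite-population correction.
#'
#' @param N Population size (may be `Inf`).
#' @param margin Margin of error, a proportion in (0, 1).
#' @param confidence Confidence level in (0, 1); mapped to a normal
#'   quantile (0.95 gives z of about 1.96).
#' @param p Anticipated proportion in (0, 1); 0.5 is the conservative
#'   default.
#' @return Integer number of completed responses required.
#' @export
#' @examples
#' sample_size(N = 300000, margin = 0.03)  # 1064
sample_size <- function(N, margin, confidence = 0.95, p = 0.5) {
  if (!is.finite(margin) || margin <= 0 || margin >= 1) {
    abort("'margin' must be a proportion in (0, 1)")
  }
  if (p <= 0 || p >= 1) abort("'p' must be in (0, 1)")
  if (N <= 0) abort("'N' must be positive")
  if (confidence <= 0 || confidence >= 1) abort("'confidence' must be in (0, 1)")
  z <- qnorm(1 - (1 - confidence) / 2)
  n0 <- z^2 * p * (1 - p) / margin^2
  as.integer(ceiling(n0 / (1 + n0 / N)))
}

#' Invitations needed for a target number of completes
#'
#' @param completes Required number of completed questionnaires.
#' @param response_rate Anticipated response rate in (0, 1].
#' @return Integer number of invitations, `ceiling(completes / rate)`.
#' @export
#' @examples
#' required_invitations(1064, 0.03)  # 35467
required_invitations <- function(completes, response_rate) {
  if (response_rate <= 0 || response_rate > 1) {
    abort("'response_rate' must be in (0, 1]")
  }
  as.integer(ceiling(completes / response_rate))
}
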