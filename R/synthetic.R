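#' Default per-cluster generating profiles
#'
#' Target distributions for the three latent respondent subtypes the
#' generator emulates: a large mild-sleep-disturbance / low-GI-symptom
#' cluster (A), a small severe cluster with pronounced gastrointestinal
#' symptoms (B), and an intermediate, lifestyle/environment-driven
#' cluster (C). Instrument-score targets (PSQI global, GSRS total, NQ
#' factors, Berlin high-risk probability) are means/SDs the scoring
#' module reproduces exactly through item allocation.
#'
#' The clustering signal lives in two latent respondent traits:
#' `trait_g`, a gastrointestinal/dietary severity axis, and `trait_f`,
#' an environmental/behavioral sleep-disruption axis. Each trait loads
#' on many non-instrument items (dietary habits, sleeping environment,
#' Bristol stool scale, duty fatigue, stress), which yields the
#' correlated item blocks real questionnaires show and places the
#' between-cluster structure in the leading variance directions that
#' low-dimensional feature extraction can retain.
#'
#' @return A named list of three cluster profiles (`A`, `B`, `C`).
#' @export
cluster_profiles <- function() {
  list(
    A = list(
      psqi = c(mean = 8.33, sd = 2.20),
      gsrs = c(mean = 2.18, sd = 2.15),
      nq = list(balance = c(35.44, 14.33), diversity = c(12.67, 4.21),
                moderation = c(8.65, 4.18), behavior = c(11.38, 3.46)),
      berlin_high = 0.119,
      age = c(20.8, 1.2), height = c(174.6, 5.6), weight = c(72.2, 9.2),
      smoking = c(never = 0.529, past = 0.060, active = 0.411),
      rank = c(0.057, 0.434, 0.401, 0.108),
      sleep_disorder = c(none = 0.936, insomnia = 0.027,
                         narcolepsy = 0.021, other = 0.016),
      gi_disorder = c(none = 0.958, reflux = 0.016, ibs = 0.026),
      general_disease = c(none = 0.947, hypertension = 0.047, other = 0.006),
      bp_history = 0.05, med_sleep = 0.009, med_digestive = 0.022,
      trait_g = c(mean = -0.70, sd = 0.25),
      trait_f = c(mean = -0.35, sd = 0.30)
    ),
    B = list(
      psqi = c(mean = 11.57, sd = 3.31),
      gsrs = c(mean = 17.94, sd = 7.38),
      nq = list(balance = c(33.25, 15.37), diversity = c(11.95, 4.54),
                moderation = c(12.90, 5.85), behavior = c(9.67, 3.74)),
      berlin_high = 0.357,
      age = c(21.2, 1.6), height = c(175.2, 6.0), weight = c(75.1, 11.1),
      smoking = c(never = 0.541, past = 0.041, active = 0.418),
      rank = c(0.020, 0.388, 0.459, 0.133),
      sleep_disorder = c(none = 0.663, insomnia = 0.163,
                         narcolepsy = 0.113, other = 0.061),
      gi_disorder = c(none = 0.660, reflux = 0.190, ibs = 0.150),
      general_disease = c(none = 0.867, hypertension = 0.122, other = 0.011),
      bp_history = 0.122, med_sleep = 0.092, med_digestive = 0.133,
      trait_g = c(mean = 3.30, sd = 0.30),
      trait_f = c(mean = -2.90, sd = 0.35)
    ),
    C = list(
      psqi = c(mean = 9.96, sd = 2.81),
      gsrs = c(mean = 6.39, sd = 4.09),
      nq = list(balance = c(33.24, 16.73), diversity = c(12.83, 4.55),
                moderation = c(11.12, 4.91), behavior = c(9.90, 3.66)),
      berlin_high = 0.313,
      age = c(21.1, 1.4), height = c(174.8, 5.6), weight = c(73.8, 11.1),
      smoking = c(never = 0.429, past = 0.077, active = 0.494),
      rank = c(0.026, 0.371, 0.441, 0.162),
      sleep_disorder = c(none = 0.826, insomnia = 0.088,
                         narcolepsy = 0.047, other = 0.039),
      gi_disorder = c(none = 0.856, reflux = 0.072, ibs = 0.072),
      general_disease = c(none = 0.926, hypertension = 0.060, other = 0.014),
      bp_history = 0.06, med_sleep = 0.026, med_digestive = 0.058,
      trait_g = c(mean = 0.55, sd = 0.25),
      trait_f = c(mean = 1.70, sd = 0.30)
    )
  )
}

# Shared item loadings on the latent structure. Signs alternate so the
# dietary blocks are not a single sum score; magnitudes keep item means
# inside the Likert range for the default trait spans.
#
# Three layers of structure:
#  - two cluster-bearing traits (g, f) load the diet/env/bss/duty items;
#  - a curvature coordinate u = curv * ((g^2 + f^2)/3 - 1), the
#    daytime-consequence response to overall severity, bends the
#    response manifold so it is 2-dimensional but not linear;
#  - two cluster-independent "response style" factors (r1 consumption
#    habits, r2 fitness/activity) add the correlated-but-uninformative
#    item blocks real questionnaires carry.
trait_loadings <- function() {
  list(
    diet_g = c(0.70, -0.60, 0.70, -0.65, 0.60, 0.70, -0.60, 0.65, 0.70,
               -0.60, 0.65, 0.70, -0.60),             # diet_01..diet_13
    diet_f = c(0.55, -0.50, 0.55, -0.52, 0.55, 0.50, -0.55, 0.52, 0.55,
               -0.50, 0.55, 0.52),                    # diet_14..diet_25
    env_f = 0.70, bss_g = 0.45, fatigue_f = 0.55, stress_f = 0.50,
    curv = 0.5,
    curv_load = c(0.50, -0.55, 0.45, -0.50, 0.55, -0.45),  # recycled over 31 items
    diet_r1 = c(2, 6, 18:21), diet_r2 = c(4, 9, 22:25), diet_r_load = 0.6,
    fatigue_r2 = 0.45, stress_r2 = 0.50,
    diet_base = 3.5, env_base = 3, bss_base = 4.2, fatigue_base = 3.4,
    stress_base = 3.1, diet_sd = 0.8, env_sd = 0.6, bss_sd = 0.7
  )
}

#' Synthetic cohort configuration
#'
#' @param n_respondents Number of respondents to generate (>= 0).
#' @param cluster_weights Non-negative latent cluster probabilities
#'   summing to 1. The default is the training-cohort composition
#'   1396/98/569 normalized.
#' @param profiles Per-cluster target profiles, see [cluster_profiles()].
#' @param separation Scalar in `[0, +)` interpolating the cluster-signal
#'   features (dietary, sleeping-environment, stool-scale, medical and
#'   military items) between the mixture grand mean (0) and the full
#'   profiles (1). Instrument-score targets are not affected, so external
#'   validation contrasts survive even when the clustering signal is
#'   weakened.
#' @param artifact_rates Named rates in `[0, 1]` for `duplicate`,
#'   `incomplete` and `outlier` data-quality artifacts, consumed by
#'   [inject_artifacts()].
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_respondents = 4869,
                             cluster_weights = c(1396, 98, 569) / 2063,
                             profiles = cluster_profiles(),
                             separation = 1,
                             artifact_rates = c(duplicate = 0.007,
                                                incomplete = 0.020,
                                                outlier = 0.004)) {
  if (length(n_respondents) != 1 || is.na(n_respondents) || n_respondents < 0) {
    abort("synthetic_config: 'n_respondents' must be a single count >= 0")
  }
  if (any(cluster_weights < 0)) {
    abort("synthetic_config: 'cluster_weights' must be non-negative")
  }
  if (abs(sum(cluster_weights) - 1) > 1e-9) {
    abort("synthetic_config: 'cluster_weights' must sum to 1 (within 1e-9)")
  }
  if (length(cluster_weights) != length(profiles)) {
    abort("synthetic_config: 'cluster_weights' and 'profiles' lengths differ")
  }
  req <- c("duplicate", "incomplete", "outlier")
  if (!all(req %in% names(artifact_rates))) {
    abort("synthetic_config: 'artifact_rates' must name duplicate, incomplete and outlier")
  }
  if (any(artifact_rates < 0 | artifact_rates > 1)) {
    abort("synthetic_config: 'artifact_rates' must lie in [0, 1]")
  }
  if (length(separation) != 1 || separation < 0) {
    abort("synthetic_config: 'separation' must be a single non-negative scalar")
  }
  structure(list(n_respondents = as.integer(n_respondents),
                 cluster_weights = cluster_weights,
                 profiles = profiles, separation = separation,
                 artifact_rates = artifact_rates[req]),
            class = "synthetic_config")
}

# ---- low-level samplers ----------------------------------------------------

# truncated normal whose *truncated* mean equals `target` (the latent mean
# is moment-matched by root finding, so boundary clusters are not biased)
rtrunc_match <- function(n, target, sd, lo, hi) {
  if (n == 0) return(numeric(0))
  if (sd <= 0) return(rep(target, n))
  tmean <- function(mu) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    z <- pnorm(b) - pnorm(a)
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
  }
  mu <- tryCatch(
    uniroot(function(m) tmean(m) - target,
            lower = lo - 8 * sd, upper = hi + 8 * sd, tol = 1e-8)$root,
    error = function(e) target)
  a <- pnorm((lo - mu) / sd); b <- pnorm((hi - mu) / sd)
  qnorm(a + runif(n) * (b - a)) * sd + mu
}

# ordinal Likert draw: rounded truncated normal on 1..k
r_likert <- function(n, mean, sd, k) {
  pmin(pmax(round(rtrunc_match(n, mean, sd, 0.5, k + 0.5)), 1), k)
}

# Likert response around a per-respondent latent mean (clip + round)
r_likert_at <- function(mu, sd, k, lo = 1) {
  as.integer(pmin(pmax(round(mu + rnorm(length(mu), 0, sd)), lo), k))
}

r_cat <- function(n, levels, prob) {
  prob <- prob / sum(prob)
  levels[sample.int(length(levels), n, replace = TRUE, prob = prob)]
}

# randomly allocate `total` integer units over n_items slots capped at `cap`
allocate_capped <- function(total, n_items, cap) {
  total <- min(max(round(total), 0), n_items * cap)
  alloc <- integer(n_items)
  rem <- total
  while (rem > 0) {
    free <- cap - alloc
    add <- as.vector(stats::rmultinom(1, rem, prob = pmax(free, 0)))
    add <- pmin(add, free)
    alloc <- alloc + add
    rem <- total - sum(alloc)
  }
  alloc
}

# random split of integer s into two parts each in 0..3
split_pair <- function(s) {
  lo <- max(0L, s - 3L); hi <- min(3L, s)
  a <- if (hi > lo) sample(lo:hi, 1) else lo
  c(a, s - a)
}

# ---- section generators (vectorized over respondents of one cluster) ------

gen_psqi_items <- function(globals) {
  n <- length(globals)
  numeric_cols <- setdiff(survey_columns("psqi"), "psqi_other_desc")
  out <- matrix(0, n, length(numeric_cols))
  colnames(out) <- numeric_cols
  lat_rng <- list(c(5, 15), c(16, 30), c(31, 60), c(61, 120))
  dur_rng <- list(c(7, 9), c(6, 6.9), c(5, 5.9), c(3.5, 4.9))
  eff_rng <- list(c(85, 97), c(75, 84.9), c(65, 74.9), c(48, 64.9))
  sum_sets <- list(0L, 1:2, 3:4, 5:6)
  for (i in seq_len(n)) {
    comp <- allocate_capped(globals[i], 7, 3)
    # C1 quality, C6 medication are direct item ratings
    quality <- comp[1]; medication <- comp[6]
    # C2: latency band + frequency item, re-banded
    s2 <- sum_sets[[comp[2] + 1]]
    s2 <- if (length(s2) > 1) sample(s2, 1) else s2
    pair2 <- split_pair(s2)
    latency_min <- round(runif(1, lat_rng[[pair2[1] + 1]][1],
                               lat_rng[[pair2[1] + 1]][2]))
    # C3 duration band
    sleep_h <- round(runif(1, dur_rng[[comp[3] + 1]][1],
                           dur_rng[[comp[3] + 1]][2]), 1)
    # C4 efficiency band -> time in bed from clock items
    eff <- runif(1, eff_rng[[comp[4] + 1]][1], eff_rng[[comp[4] + 1]][2])
    tib <- sleep_h / (eff / 100)
    bedtime <- round(runif(1, 21, 24), 1) %% 24
    waketime <- round((bedtime + tib) %% 24, 2)
    # C5 disturbance sum over 9 items
    s5 <- switch(comp[5] + 1, 0L, sample(1:9, 1), sample(10:18, 1),
                 sample(19:27, 1))
    disturb <- allocate_capped(s5, 9, 3)
    # C7 two-item sum
    s7 <- sum_sets[[comp[7] + 1]]
    s7 <- if (length(s7) > 1) sample(s7, 1) else s7
    pair7 <- split_pair(s7)
    out[i, ] <- c(bedtime, latency_min, waketime, sleep_h, pair2[2], disturb,
                  quality, medication, pair7[1], pair7[2])
  }
  out
}

gen_nq_items <- function(n, nq_profile, weights = nq_default_weights()) {
  out <- matrix(1L, n, 21)
  colnames(out) <- survey_columns("nq")
  for (f in names(nq_profile)) {
    idx <- which(weights$factor == f)
    step <- weights$points[[idx[1]]][2] - weights$points[[idx[1]]][1]
    maxsc <- length(idx) * 4 * step
    target <- rtrunc_match(n, nq_profile[[f]][1], nq_profile[[f]][2], 0, maxsc)
    units <- round(target / step)
    for (i in seq_len(n)) {
      out[i, idx] <- allocate_capped(units[i], length(idx), 4) + 1L
    }
  }
  out
}

gen_gsrs_items <- function(totals) {
  n <- length(totals)
  out <- matrix(1L, n, 15)
  colnames(out) <- survey_columns("gsrs")
  for (i in seq_len(n)) out[i, ] <- allocate_capped(totals[i], 15, 6) + 1L
  out
}

# Berlin items consistent with a target high/low risk flag; cat3 may come
# from BMI alone, in which case a "low" respondent gets no other positives
gen_berlin_items <- function(high, bmi_pos) {
  n <- length(high)
  c1 <- matrix(0L, n, 5); c2 <- matrix(0L, n, 4)
  bp <- logical(n)
  for (i in seq_len(n)) {
    if (high[i]) {
      pos <- c(TRUE, TRUE, FALSE)[sample(3)]
      if (stats::runif(1) < 0.3) pos <- c(TRUE, TRUE, TRUE)
      if (bmi_pos[i]) pos[3] <- TRUE
      if (sum(pos) < 2) pos[sample(which(!pos), 1)] <- TRUE
      if (pos[1]) c1[i, sample(5, sample(2:4, 1))] <- 1L
      else if (runif(1) < 0.3) c1[i, sample(5, 1)] <- 1L
      if (pos[2]) c2[i, sample(4, sample(2:3, 1))] <- 1L
      else if (runif(1) < 0.3) c2[i, sample(4, 1)] <- 1L
      bp[i] <- pos[3] && !bmi_pos[i]
    } else {
      which_pos <- if (bmi_pos[i]) 3L else sample(0:3, 1, prob = c(.6, .15, .15, .1))
      if (which_pos == 1) c1[i, sample(5, sample(2:3, 1))] <- 1L
      else if (runif(1) < 0.4) c1[i, sample(5, 1)] <- 1L
      if (which_pos == 2) c2[i, sample(4, 2)] <- 1L
      else if (runif(1) < 0.4) c2[i, sample(4, 1)] <- 1L
      bp[i] <- which_pos == 3 && !bmi_pos[i]
    }
  }
  list(c1 = c1, c2 = c2, bp = bp)
}

# interpolate a probability vector toward a reference by `sep`
mix_prob <- function(p, ref, sep) {
  q <- ref + sep * (p - ref)
  q / sum(q)
}

# ---- main generator --------------------------------------------------------

#' Simulate an item-level survey cohort
#'
#' Generates `n` respondents from a latent mixture of the configured
#' cluster profiles. Instrument scores are drawn first from
#' moment-matched truncated normals and then allocated down to item
#' responses under each item's cap, so that [score_survey()] applied to
#' the generated table reproduces the target per-cluster score
#' distributions. The latent assignment is carried in the side column
#' `.true_cluster`, which no pipeline stage consumes; it exists only for
#' recovery checks.
#'
#' @param n Number of respondents; defaults to the configured
#'   `n_respondents`.
#' @param config A [synthetic_config()].
#' @param seed Integer RNG seed; the table is fully reproducible given
#'   the same configuration and seed.
#' @return A tibble with one row per respondent and all dictionary
#'   columns, plus `.true_cluster`.
#' @export
#' @examples
#' x <- simulate_survey(n = 50, seed = 7)
#' table(x$.true_cluster)
simulate_survey <- function(n = NULL, config = synthetic_config(),
                            seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(n)) n <- config$n_respondents
  if (!is.null(seed)) set.seed(seed)

  dict <- survey_dictionary()
  cl_names <- names(config$profiles)
  assignment <- if (n > 0) {
    cl_names[sample.int(length(cl_names), n, replace = TRUE,
                        prob = config$cluster_weights)]
  } else character(0)

  ids <- sprintf("R%06d", seq_len(n))
  rows <- vector("list", length(cl_names))
  names(rows) <- cl_names
  for (cl in cl_names) {
    idx <- which(assignment == cl)
    rows[[cl]] <- generate_cluster_rows(length(idx), ids[idx], cl, config)
  }
  out <- dplyr::bind_rows(rows)
  if (n > 0) {
    out <- out[order(match(out$respondent_id, ids)), , drop = FALSE]
  } else {
    out <- empty_survey_table()
  }
  tibble::as_tibble(out)
}

empty_survey_table <- function() {
  dict <- survey_dictionary()
  cols <- purrr::map(seq_len(nrow(dict)), function(i) {
    switch(dict$type[i],
           id = character(0), logical = logical(0), numeric = numeric(0),
           ordinal = integer(0), nominal = character(0))
  })
  names(cols) <- dict$column
  out <- tibble::as_tibble(cols)
  out$.true_cluster <- character(0)
  out
}

generate_cluster_rows <- function(n, ids, cl, config) {
  if (n == 0) return(NULL)
  p <- config$profiles[[cl]]
  sep <- config$separation
  w <- config$cluster_weights

  # mixture grand means for the separation interpolation
  mix <- function(get) {
    Reduce(`+`, purrr::map2(config$profiles, as.list(w),
                            function(pr, wt) wt * get(pr)))
  }
  g_bar <- mix(function(x) x$trait_g[["mean"]])
  f_bar <- mix(function(x) x$trait_f[["mean"]])
  # latent respondent traits carrying the cluster signal
  g <- rnorm(n, g_bar + sep * (p$trait_g[["mean"]] - g_bar),
             p$trait_g[["sd"]])
  f <- rnorm(n, f_bar + sep * (p$trait_f[["mean"]] - f_bar),
             p$trait_f[["sd"]])
  ld <- trait_loadings()
  # daytime-consequence curvature of the response surface
  u <- ld$curv * ((g^2 + f^2) / 3 - 1)
  lu <- rep(ld$curv_load, length.out = 31)  # diet 25, env 5, bss
  # cluster-independent response-style factors
  r1 <- rnorm(n); r2 <- rnorm(n)

  out <- list()
  out$respondent_id <- ids
  out$consent <- rep(TRUE, n)
  out$age <- round(rtrunc_match(n, p$age[1], p$age[2], 19, 32))
  out$height_cm <- round(rtrunc_match(n, p$height[1], p$height[2], 150, 199.5), 1)
  out$weight_kg <- round(rtrunc_match(n, p$weight[1], p$weight[2], 45, 159.5), 1)
  out$rank <- r_cat(n, c("private", "private_first_class", "corporal",
                         "sergeant"), p$rank)
  out$education <- r_cat(n, 1:4, c(0.001, 0.004, 0.93, 0.065))
  out$smoking_status <- r_cat(n, names(p$smoking), p$smoking)
  smoker <- out$smoking_status != "never"
  out$smoking_packs_per_day <- ifelse(
    smoker, round(rtrunc_match(n, 0.55, 0.4, 0.05, 4.5), 2), 0)
  out$smoking_years <- ifelse(
    smoker, round(rtrunc_match(n, 2.5, 1.8, 0.1, 15), 1), 0)
  out$alcohol_freq <- r_likert_at(2.4 + 0.7 * r1, 0.8, 4)
  out$coffee_freq <- r_likert_at(2.6 + 1.0 * r1, 0.7, 6)
  out$energy_drink_freq <- r_likert_at(2.2 + 1.0 * r1, 0.7, 6)
  out$exercise_freq <- r_likert_at(2.5 + 0.8 * r2, 0.7, 4)
  out$physical_grade <- r_likert_at(2.2 + 0.8 * r2, 0.6, 5)

  sd_bar <- mix(function(x) x$sleep_disorder)
  gi_bar <- mix(function(x) x$gi_disorder)
  gd_bar <- mix(function(x) x$general_disease)
  out$sleep_disorder_present <- r_cat(n, names(p$sleep_disorder),
                                      mix_prob(p$sleep_disorder, sd_bar, sep))
  out$sleep_disorder_past <- r_cat(n, names(p$sleep_disorder),
                                   mix_prob(p$sleep_disorder, sd_bar, sep))
  out$gi_disorder_present <- r_cat(n, names(p$gi_disorder),
                                   mix_prob(p$gi_disorder, gi_bar, sep))
  out$gi_disorder_past <- r_cat(n, names(p$gi_disorder),
                                mix_prob(p$gi_disorder, gi_bar, sep))
  out$general_disease <- r_cat(n, names(p$general_disease),
                               mix_prob(p$general_disease, gd_bar, sep))
  out$med_sleep <- runif(n) < p$med_sleep
  out$med_digestive <- runif(n) < p$med_digestive

  out$night_shift_dutyoff_freq <- r_likert_at(2.5 + 0.9 * r1, 0.9, 5, lo = 0)
  out$night_shift_dutyoff_fatigue <-
    r_likert_at(ld$fatigue_base + ld$fatigue_f * f + ld$fatigue_r2 * r2,
                0.8, 5)
  out$night_shift_no_dutyoff_freq <- r_likert_at(3.0 + 0.9 * r1, 0.9, 5,
                                                 lo = 0)
  out$night_shift_no_dutyoff_fatigue <-
    r_likert_at(ld$fatigue_base + 0.15 + ld$fatigue_f * f +
                  ld$fatigue_r2 * r2, 0.8, 5)
  out$stress <- r_likert_at(ld$stress_base + ld$stress_f * f +
                              ld$stress_r2 * r2, 0.9, 5)

  env_cols <- survey_columns("sleep_env")
  for (j in seq_along(env_cols)) {
    out[[env_cols[j]]] <- r_likert_at(ld$env_base + ld$env_f * f +
                                        lu[25 + j] * u, ld$env_sd, 5)
  }

  # PSQI: integer global targets, allocated to items
  psqi_target <- pmin(pmax(round(rtrunc_match(n, p$psqi[1], p$psqi[2], 0, 21)), 0), 21)
  psqi_m <- gen_psqi_items(psqi_target)
  for (cn in colnames(psqi_m)) out[[cn]] <- psqi_m[, cn]
  out$psqi_other_desc <- ifelse(
    psqi_m[, "psqi_other_disturb"] > 0,
    r_cat(n, c("noise", "stress", "pain", "other"), c(.3, .3, .2, .2)),
    "none")

  # Berlin: risk flag target, cat3 partly determined by generated BMI
  bmi <- out$weight_kg / (out$height_cm / 100)^2
  high <- runif(n) < p$berlin_high
  berlin <- gen_berlin_items(high, bmi > 30)
  for (j in 1:5) out[[paste0("berlin_c1_", j)]] <- berlin$c1[, j]
  for (j in 1:4) out[[paste0("berlin_c2_", j)]] <- berlin$c2[, j]
  out$berlin_drive_freq <- r_likert(n, 1.3, 0.8, 4) - 1L
  out$bp_history <- berlin$bp | (runif(n) < p$bp_history & !high)

  diet_cols <- survey_columns("diet")
  lam <- c(ld$diet_g, ld$diet_f)
  trait <- cbind(matrix(g, n, length(ld$diet_g)),
                 matrix(f, n, length(ld$diet_f)))
  for (j in seq_along(diet_cols)) {
    mu <- ld$diet_base + lam[j] * trait[, j] + lu[j] * u
    if (j %in% ld$diet_r1) mu <- mu + ld$diet_r_load * r1
    if (j %in% ld$diet_r2) mu <- mu + ld$diet_r_load * r2
    out[[diet_cols[j]]] <- r_likert_at(mu, ld$diet_sd, 7)
  }

  nq_m <- gen_nq_items(n, p$nq)
  for (cn in colnames(nq_m)) out[[cn]] <- nq_m[, cn]

  gsrs_target <- pmin(pmax(round(rtrunc_match(n, p$gsrs[1], p$gsrs[2], 0, 90)), 0), 90)
  gsrs_m <- gen_gsrs_items(gsrs_target)
  for (cn in colnames(gsrs_m)) out[[cn]] <- gsrs_m[, cn]

  out$bss <- r_likert_at(ld$bss_base + ld$bss_g * g + lu[31] * u,
                         ld$bss_sd, 7)
  out$.true_cluster <- rep(cl, n)

  tibble::as_tibble(out)[, c(survey_dictionary()$column, ".true_cluster")]
}

#' Inject data-quality artifacts into a survey table
#'
#' Emulates the defects a real survey export carries so the cleaning
#' chain can be exercised: duplicated respondents (the same identifier
#' submitted again with freshly drawn answers), incomplete responses
#' (a trailing block of sections blanked), and out-of-range open-item
#' entries (height, weight, smoking amount/duration overwritten with
#' values violating the preprocessing bounds).
#'
#' @param data A survey table with unique `respondent_id`.
#' @param rates Named rates in `[0, 1]`: `duplicate`, `incomplete`,
#'   `outlier`. Each respondent is flagged for at most one artifact.
#' @param config The [synthetic_config()] whose profiles are used to
#'   redraw answers for duplicated respondents.
#' @param seed Optional RNG seed.
#' @return The augmented tibble, with the manifest of altered rows in
#'   attribute `"artifact_manifest"` (see [artifact_manifest()]).
#' @export
inject_artifacts <- function(data,
                             rates = c(duplicate = 0.007,
                                       incomplete = 0.020,
                                       outlier = 0.004),
                             config = synthetic_config(), seed = NULL) {
  if (any(rates < 0 | rates > 1)) abort("artifact rates must lie in [0, 1]")
  if (anyDuplicated(data$respondent_id)) {
    abort("inject_artifacts: input table must have unique respondent_id")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data)
  manifest <- tibble::tibble(respondent_id = character(0),
                             artifact = character(0), detail = character(0))
  if (n == 0 || all(rates == 0)) {
    attr(data, "artifact_manifest") <- manifest
    return(tibble::as_tibble(data))
  }

  flags <- c("duplicate", "incomplete", "outlier")
  pick <- sample.int(n)  # shuffled row order; disjoint artifact groups
  counts <- sapply(flags, function(f) rbinom(1, n, rates[[f]]))
  idx <- list()
  used <- 0
  for (f in flags) {
    k <- min(counts[[f]], n - used)
    idx[[f]] <- pick[seq_len(k) + used]
    used <- used + k
  }

  out <- data
  # duplicates: same id, answers redrawn from the respondent's own cluster
  if (length(idx$duplicate) > 0) {
    dup_rows <- purrr::map_dfr(idx$duplicate, function(i) {
      generate_cluster_rows(1, data$respondent_id[i],
                            data$.true_cluster[i], config)
    })
    out <- dplyr::bind_rows(out, dup_rows)
    manifest <- dplyr::bind_rows(manifest, tibble::tibble(
      respondent_id = data$respondent_id[idx$duplicate],
      artifact = "duplicate", detail = "second submission appended"))
  }
  # incomplete: blank one trailing block of sections
  if (length(idx$incomplete) > 0) {
    section_tail <- list(
      c("diet", "nq", "gsrs", "bss"), c("nq", "gsrs", "bss"),
      c("gsrs", "bss"))
    for (i in idx$incomplete) {
      secs <- section_tail[[sample(3, 1)]]
      cols <- survey_columns(secs)
      out[out$respondent_id == data$respondent_id[i], cols] <- NA
      manifest <- dplyr::bind_rows(manifest, tibble::tibble(
        respondent_id = data$respondent_id[i], artifact = "incomplete",
        detail = paste("blanked from section", secs[1])))
    }
  }
  # outliers: overwrite open items with out-of-bound values
  if (length(idx$outlier) > 0) {
    for (i in idx$outlier) {
      field <- sample(c("height_cm", "weight_kg",
                        "smoking_packs_per_day", "smoking_years"), 1)
      val <- switch(field,
        height_cm = sample(c(runif(1, 80, 109), runif(1, 201, 240)), 1),
        weight_kg = sample(c(runif(1, 20, 39), runif(1, 161, 250)), 1),
        smoking_packs_per_day = runif(1, 5.1, 12),
        smoking_years = runif(1, 20.5, 45))
      out[out$respondent_id == data$respondent_id[i], field] <- round(val, 1)
      manifest <- dplyr::bind_rows(manifest, tibble::tibble(
        respondent_id = data$respondent_id[i], artifact = "outlier",
        detail = sprintf("%s set to %.1f", field, val)))
    }
  }
  attr(out, "artifact_manifest") <- manifest
  tibble::as_tibble(out)
}

#' Retrieve the artifact manifest of a table
#'
#' @param data A table returned by [inject_artifacts()].
#' @return The manifest tibble (`respondent_id`, `artifact`, `detail`).
#' @export
artifact_manifest <- function(data) {
  m <- attr(data, "artifact_manifest", exact = TRUE)
  m %||% tibble::tibble(respondent_id = character(0),
                        artifact = character(0), detail = character(0))
}
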