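test_that("PSQI floor, threshold and hand-scored component examples", {
  base <- blank_respondent()
  best <- score_psqi(base)
  expect_equal(unlist(best[paste0("psqi_c", 1:7)], use.names = FALSE),
               rep(0L, 7))
  expect_equal(best$psqi_global, 0L)
  expect_false(best$psqi_disturbed)

  # latency 45 min + frequency 1-2x/week; 5.5 h sleep in 8 h bed time
  row <- base
  row$psqi_latency_min <- 45
  row$psqi_cant_sleep_30min <- 1L
  row$psqi_sleep_hours <- 5.5
  row$psqi_bedtime <- 23
  row$psqi_waketime <- 7
  sc <- score_psqi(row)
  expect_equal(sc$psqi_c2, 2L)  # band(45) = 2, +1 -> 3 -> re-band 2
  expect_equal(sc$psqi_c3, 2L)  # 5.5 h
  expect_equal(sc$psqi_c4, 2L)  # efficiency 68.75 %

  # disturbance flag flips strictly above 5
  row5 <- base
  row5$psqi_quality <- 3L; row5$psqi_medication <- 2L
  expect_equal(score_psqi(row5)$psqi_global, 5L)
  expect_false(score_psqi(row5)$psqi_disturbed)
  row6 <- row5; row6$psqi_sleepy <- 1L  # C7 contributes 1 -> global 6
  expect_equal(score_psqi(row6)$psqi_global, 6L)
  expect_true(score_psqi(row6)$psqi_disturbed)
})

test_that("PSQI global stays in range and is monotone in item severity", {
  set.seed(14)
  x <- simulate_survey(n = 60, seed = 14)
  sc <- score_psqi(x)
  expect_true(all(sc$psqi_global >= 0 & sc$psqi_global <= 21))
  expect_equal(sc$psqi_global,
               as.integer(rowSums(sc[paste0("psqi_c", 1:7)])))

  # worsening any single rating item never decreases the global score
  rating_items <- c("psqi_cant_sleep_30min", "psqi_quality",
                    "psqi_medication", "psqi_sleepy", "psqi_enthusiasm",
                    "psqi_wake_night", "psqi_pain")
  for (i in 1:15) {
    row <- x[sample(nrow(x), 1), ]
    item <- sample(rating_items, 1)
    worse <- row
    worse[[item]] <- min(worse[[item]] + 1L, 3L)
    expect_gte(score_psqi(worse)$psqi_global, score_psqi(row)$psqi_global)
  }

  # missing items fail loudly, no imputation
  bad <- x[1, ]; bad$psqi_quality <- NA
  expect_error(score_psqi(bad), "psqi_quality")
})

test_that("Berlin category rules and risk threshold", {
  base <- blank_respondent()
  neg <- score_berlin(base)
  expect_false(neg$berlin_cat1 | neg$berlin_cat2 | neg$berlin_cat3)
  expect_equal(as.character(neg$berlin_risk), "low")

  two <- base
  two$berlin_c1_1 <- 1L; two$berlin_c1_3 <- 1L
  two$berlin_c2_2 <- 1L; two$berlin_c2_4 <- 1L
  sc <- score_berlin(two)
  expect_true(sc$berlin_cat1 && sc$berlin_cat2 && !sc$berlin_cat3)
  expect_equal(as.character(sc$berlin_risk), "high")

  # BMI above 30 alone sets category 3 but not high risk
  obese <- base
  obese$height_cm <- 170; obese$weight_kg <- 90   # BMI 31.1
  sc2 <- score_berlin(obese)
  expect_true(sc2$berlin_cat3)
  expect_equal(as.character(sc2$berlin_risk), "low")

  # category positivity is invariant to which items are positive
  perm <- base
  perm$berlin_c1_4 <- 1L; perm$berlin_c1_5 <- 1L
  expect_true(score_berlin(perm)$berlin_cat1)
})

test_that("GSRS totals match a per-item summation oracle", {
  base <- blank_respondent()
  expect_equal(score_gsrs(base)$gsrs_total, 0)
  worst <- base
  worst[survey_columns("gsrs")] <- 7L
  expect_equal(score_gsrs(worst)$gsrs_total, 90)

  mixed <- base
  mixed$gsrs_01 <- 3L; mixed$gsrs_07 <- 5L
  expect_equal(score_gsrs(mixed)$gsrs_total, 6)  # (3-1) + (5-1)

  set.seed(7)
  x <- simulate_survey(n = 40, seed = 7)
  items <- as.matrix(x[survey_columns("gsrs")])
  expect_equal(score_gsrs(x)$gsrs_total, rowSums(items - 1))
  expect_equal(score_gsrs(x, convention = "sum1")$gsrs_total, rowSums(items))
  expect_equal(score_gsrs(x, convention = "mean")$gsrs_total, rowMeans(items))

  oob <- base; oob$gsrs_02 <- 9L
  expect_error(score_gsrs(oob), "gsrs_02")
})

test_that("NQ weighting, grade threshold and toy weight table", {
  base <- blank_respondent()
  # hand toy: two items, per-level points (10,20) and (5,15), both level 2
  w <- tibble::tibble(item = c("nq_01", "nq_02"),
                      factor = c("balance", "balance"),
                      points = list(c(10, 20), c(5, 15)))
  attr(w, "factor_weights") <- c(balance = 1)
  toy <- base; toy$nq_01 <- 2L; toy$nq_02 <- 2L
  expect_equal(score_nq(toy, weights = w)$nq_balance, 35)
  expect_equal(score_nq(toy, weights = w)$nq_global, 35)

  # grade boundary at exactly 58
  attr(w, "factor_weights") <- c(balance = 58 / 35)
  expect_equal(as.character(score_nq(toy, weights = w)$nq_grade), "good")
  attr(w, "factor_weights") <- c(balance = 57.99 / 35)
  expect_equal(as.character(score_nq(toy, weights = w)$nq_grade),
               "monitoring")

  # all-zero weights: zero scores, monitoring grade
  w0 <- nq_default_weights()
  w0$points <- purrr::map(w0$points, function(p) p * 0)
  z <- score_nq(base, weights = w0)
  expect_equal(z$nq_global, 0)
  expect_equal(as.character(z$nq_grade), "monitoring")

  # weight table naming an absent item is a configuration error
  wbad <- nq_default_weights()
  wbad$item[1] <- "nq_99"
  expect_error(score_nq(base, weights = wbad), "nq_99")
})

test_that("finite-population sample size reproduces the design numbers", {
  expect_identical(sample_size(N = 300000, margin = 0.03), 1064L)
  expect_identical(sample_size(N = Inf, margin = 0.03), 1068L)
  expect_identical(sample_size(N = 300000, margin = 0.05), 384L)
  expect_identical(required_invitations(1064, 0.03), 35467L)
  expect_identical(required_invitations(100, 1.0), 100L)
  expect_identical(required_invitations(100, 0.5), 200L)

  # monotonicity: non-increasing in margin, non-decreasing in N, confidence
  margins <- c(0.01, 0.02, 0.03, 0.05, 0.1)
  sizes <- vapply(margins, function(e) sample_size(3e5, e), integer(1))
  expect_true(all(diff(sizes) <= 0))
  Ns <- c(1e3, 1e4, 1e5, 1e6, Inf)
  sizes_n <- vapply(Ns, function(N) sample_size(N, 0.03), integer(1))
  expect_true(all(diff(sizes_n) >= 0))
  confs <- c(0.8, 0.9, 0.95, 0.99)
  sizes_c <- vapply(confs, function(cf) sample_size(3e5, 0.03, cf), integer(1))
  expect_true(all(diff(sizes_c) >= 0))

  expect_error(sample_size(3e5, 0), "margin")
  expect_error(sample_size(3e5, 0.03, p = 1.2), "p")
  expect_error(required_invitations(100, 0), "response_rate")
})
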