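test_that("one-way ANOVA: degenerate, algebraic and oracle checks", {
  flat <- data.frame(group = rep(c("a", "b", "c"), each = 4), value = 5)
  expect_equal(anova_oneway(flat)$statistic, 0)

  # two groups: F equals the square of the pooled-variance t statistic
  set.seed(61)
  d2 <- data.frame(group = rep(c("a", "b"), c(12, 17)),
                   value = c(rnorm(12, 1), rnorm(17, 2)))
  f <- anova_oneway(d2)$statistic
  t2 <- t.test(value ~ group, data = d2, var.equal = TRUE)$statistic^2
  expect_equal(f, unname(t2), tolerance = 1e-9)

  # raw mode equals aov, and summary mode equals raw mode exactly
  d3 <- data.frame(group = rep(c("a", "b", "c"), c(8, 12, 10)),
                   value = rnorm(30))
  fit <- anova_oneway(d3)
  ref <- summary(aov(value ~ group, data = d3))[[1]]
  expect_equal(fit$statistic, ref[["F value"]][1], tolerance = 1e-9)
  expect_equal(fit$p.value, ref[["Pr(>F)"]][1], tolerance = 1e-9)
  summ <- d3 |>
    dplyr::group_by(group) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(value), sd = sd(value))
  fit_s <- anova_oneway(summ)
  expect_equal(fit_s$statistic, fit$statistic, tolerance = 1e-12)
  expect_equal(fit_s$msw, fit$msw, tolerance = 1e-12)

  expect_error(anova_oneway(data.frame(group = "a", value = 1)), "group")
  expect_error(anova_oneway(
    data.frame(group = c("a", "b"), n = c(1, 5), mean = 0, sd = 1)), "n >= 2")
})

test_that("Tukey-Kramer agrees with the stock post-hoc on balanced data", {
  set.seed(62)
  d <- data.frame(group = rep(c("g1", "g2", "g3"), each = 10),
                  value = c(rnorm(10, 0), rnorm(10, 1), rnorm(10, 3)))
  fit <- anova_oneway(d)
  tk <- tukey_kramer(fit)
  ref <- TukeyHSD(aov(value ~ group, data = d))$group
  # align pair order (ours: g1-g2, g1-g3, g2-g3; TukeyHSD: g2-g1, ...)
  expect_equal(-tk$diff, unname(ref[, "diff"]), tolerance = 1e-9)
  expect_equal(-tk$conf.low, unname(ref[, "upr"]), tolerance = 1e-9)
  expect_equal(tk$p.adj, unname(ref[, "p adj"]), tolerance = 1e-9)

  # equal-n df = 27: interval half-width = q(0.05; 3, 27) * SE, q = 3.506
  se <- sqrt(fit$msw / 2 * (1 / 10 + 1 / 10))
  expect_equal((tk$conf.high[1] - tk$conf.low[1]) / 2, 3.506 * se,
               tolerance = 1e-3)

  same <- data.frame(group = rep(c("a", "b"), each = 6),
                     value = rep(c(1, 2, 3), 4))
  tk0 <- tukey_kramer(anova_oneway(same))
  expect_equal(tk0$diff, 0)
  expect_gt(tk0$p.adj, 0.99)
})

test_that("chi-squared tests reproduce the published contingency values", {
  train <- rbind(c(1230, 166), c(63, 35), c(391, 178))
  expect_equal(round(chi_squared(train)$statistic, 2), 122.00)
  expect_equal(chi_squared(train)$df, 2)

  test_tab <- rbind(c(305, 47), c(14, 8), c(100, 42))
  expect_equal(round(chi_squared(test_tab)$statistic, 2), 22.09)

  ab <- rbind(c(1230, 166), c(63, 35))
  expect_equal(round(chi_squared_yates(ab)$statistic, 2), 42.61)
  ac <- rbind(c(1230, 166), c(391, 178))
  expect_equal(round(chi_squared_yates(ac)$statistic, 2), 103.92)

  balanced <- rbind(c(10, 10), c(10, 10))
  expect_equal(chi_squared_yates(balanced)$statistic, 0)

  # proportional table has statistic zero; brute-force E-table agreement
  prop <- outer(c(20, 30), c(2, 3, 5))
  expect_equal(chi_squared(prop)$statistic, 0, tolerance = 1e-9)
  set.seed(63)
  for (i in 1:5) {
    tab <- matrix(rpois(6, 40) + 1, 2)
    expect_equal(chi_squared(tab)$statistic, chi2_brute(tab),
                 tolerance = 1e-9)
  }

  expect_error(chi_squared(rbind(c(0, 0), c(3, 4))), "margin")
  expect_error(chi_squared_yates(rbind(c(1, 2, 3), c(4, 5, 6))), "2 x 2")
})

test_that("odds ratios reproduce the published pairwise values", {
  ab <- rbind(c(1230, 166), c(63, 35))
  or <- odds_ratio(ab)
  expect_equal(round(or$estimate, 2), 0.24)
  expect_equal(round(or$conf.low, 2), 0.16)
  expect_equal(round(or$conf.high, 2), 0.38)

  bc <- rbind(c(63, 35), c(391, 178))
  expect_equal(round(odds_ratio(bc)$estimate, 2), 1.22)
  expect_equal(round(odds_ratio(bc)$conf.low, 2), 0.78)
  expect_equal(round(odds_ratio(bc)$conf.high, 2), 1.91)

  sym <- rbind(c(40, 40), c(25, 25))
  expect_equal(odds_ratio(sym)$estimate, 1)

  # swapping both rows and columns preserves OR; one row inverts it
  set.seed(64)
  tab <- matrix(rpois(4, 30) + 1, 2)
  expect_equal(odds_ratio(tab[2:1, 2:1])$estimate,
               odds_ratio(tab)$estimate, tolerance = 1e-12)
  expect_equal(odds_ratio(tab[2:1, ])$estimate,
               1 / odds_ratio(tab)$estimate, tolerance = 1e-12)

  expect_warning(odds_ratio(rbind(c(10, 0), c(5, 5))), "Haldane")
})

test_that("validation report structure and degenerate inputs", {
  x <- score_survey(simulate_survey(n = 240, seed = 65))
  labels <- x$.true_cluster
  rep_ <- validation_report(x, labels, partition = "train")

  expect_equal(length(unique(rep_$tests$score)), 8)  # 7 continuous + Berlin
  counts <- table(rep_$tests$score)
  expect_true(all(counts == 4))  # omnibus + 3 pairwise per score

  # cluster with highest GSRS also has highest PSQI (profile construction)
  sums <- rep_$summaries
  g <- sums[sums$score == "gsrs_total", ]
  p <- sums[sums$score == "psqi_global", ]
  expect_equal(g$group[which.max(g$mean)], p$group[which.max(p$mean)])

  # three identical clusters: all F = 0, all OR = 1
  idx <- c(which(x$berlin_risk == "low")[1:8],
           which(x$berlin_risk == "high")[1:2])
  flat <- x[rep(idx, 3), ]
  flat_lab <- rep(c("A", "B", "C"), each = 10)
  rep0 <- validation_report(flat, flat_lab)
  expect_true(all(rep0$tests$statistic[rep0$tests$test == "anova_f"] == 0))
  ors <- rep0$tests$estimate[rep0$tests$test == "odds_ratio_yates"]
  expect_true(all(ors == 1))

  expect_warning(tiny <- validation_report(x[1:5, ],
                                           c("A", "A", "A", "A", "B")),
                 "fewer than 2")
  expect_equal(nrow(tiny$tests), 0)
})

test_that("tidiers return the documented shapes", {
  x <- score_survey(simulate_survey(n = 150, seed = 66))
  rep_ <- validation_report(x, x$.true_cluster, partition = "train")
  td <- tidy(rep_)
  expect_true(all(c("score", "comparison", "estimate", "p.value") %in%
                    names(td)))
  gl <- glance(rep_)
  expect_equal(gl$partition, "train")

  sol <- fit_kmeans(matrix(rnorm(60), 30, 2), 3, seed = 2)
  expect_equal(nrow(tidy(sol)), 3)
  expect_equal(glance(sol)$k, 3)
})
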