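#' One-way ANOVA from raw vectors or group summaries
#'
#' Classical fixed-effects one-way analysis of variance. Two input
#' forms are accepted: a data frame with `value` and `group` columns
#' (raw mode), or a data frame with `group`, `n`, `mean`, `sd` columns
#' (summary mode, using the exact sum-of-squares decomposition
#' `MSB = sum n_i (m_i - m)^2 / (k - 1)`,
#' `MSW = sum (n_i - 1) s_i^2 / (N - k)`). Raw and summary mode agree
#' exactly when the summaries are computed from the raw vectors.
#'
#' @param data A data frame in one of the two layouts above.
#' @return An `anova_oneway` object: `statistic` (F), `p.value`, `msw`,
#'   `df` (numerator, denominator) and the per-group summary.
#' @export
#' @examples
#' anova_oneway(data.frame(group = c("a", "a", "b", "b"),
#'                         value = c(1, 2, 4, 6)))
anova_oneway <- function(data) {
  if (all(c("value", "group") %in% names(data))) {
    groups <- data |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                       sd = sd(.data$value), .groups = "drop")
  } else if (all(c("group", "n", "mean", "sd") %in% names(data))) {
    groups <- tibble::as_tibble(data[, c("group", "n", "mean", "sd")])
  } else {
    abort("anova_oneway: need columns (value, group) or (group, n, mean, sd)")
  }
  if (nrow(groups) < 2) abort("anova_oneway: need at least 2 groups")
  if (any(groups$n < 2)) abort("anova_oneway: every group needs n >= 2")

  k <- nrow(groups); N <- sum(groups$n)
  gm <- sum(groups$n * groups$mean) / N
  msb <- sum(groups$n * (groups$mean - gm)^2) / (k - 1)
  msw <- sum((groups$n - 1) * groups$sd^2) / (N - k)
  f <- if (msw == 0) { if (msb == 0) 0 else Inf } else msb / msw
  p <- pf(f, k - 1, N - k, lower.tail = FALSE)
  structure(list(statistic = f, p.value = p, msw = msw,
                 df = c(k - 1, N - k), groups = groups),
            class = "anova_oneway")
}

#' @export
print.anova_oneway <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$statistic, x$p.value))
  invisible(x)
}

#' Tukey-Kramer post-hoc comparisons
#'
#' All pairwise mean differences after a one-way ANOVA, using the
#' studentized-range distribution with the Kramer adjustment for
#' unequal group sizes: `SE = sqrt(MSW / 2 * (1/n_i + 1/n_j))`,
#' confidence interval `diff +/- q(conf; k, df) * SE`, and adjusted p
#' from the studentized range.
#'
#' @param fit An [anova_oneway()] result.
#' @param conf Confidence level (default 0.95).
#' @return A tibble with one row per group pair: `diff`, `conf.low`,
#'   `conf.high`, `p.adj`.
#' @export
tukey_kramer <- function(fit, conf = 0.95) {
  stopifnot(inherits(fit, "anova_oneway"))
  g <- fit$groups
  k <- nrow(g); df <- fit$df[2]
  q_crit <- qtukey(conf, k, df)
  pairs <- utils::combn(seq_len(k), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    d <- g$mean[i1] - g$mean[i2]
    se <- sqrt(fit$msw / 2 * (1 / g$n[i1] + 1 / g$n[i2]))
    qs <- if (se == 0) { if (d == 0) 0 else Inf } else abs(d) / se
    tibble::tibble(
      group1 = as.character(g$group[i1]), group2 = as.character(g$group[i2]),
      diff = d, conf.low = d - q_crit * se, conf.high = d + q_crit * se,
      p.adj = ptukey(qs, k, df, lower.tail = FALSE))
  })
}

check_counts <- function(counts, what) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort(sprintf("%s: counts must be non-negative", what))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort(sprintf("%s: every row and column margin must be positive", what))
  }
  counts
}

#' Pearson chi-squared test for an R x C table
#'
#' Uncorrected Pearson statistic `sum (O - E)^2 / E` with
#' `df = (R - 1)(C - 1)`, as used for the omnibus cluster-by-category
#' comparison.
#'
#' @param counts Non-negative count matrix with positive margins.
#' @return A list with `statistic`, `df`, `p.value`.
#' @export
#' @examples
#' chi_squared(rbind(c(1230, 166), c(63, 35), c(391, 178)))$statistic
chi_squared <- function(counts) {
  counts <- check_counts(counts, "chi_squared")
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = unname(ct$p.value))
}

#' Yates-corrected chi-squared test for a 2 x 2 table
#'
#' Continuity-corrected Pearson statistic,
#' `N (|ad - bc| - N/2)^2 / ((a+b)(c+d)(a+c)(b+d))`, clamped at zero
#' when `|ad - bc| < N/2`; used for pairwise cluster comparisons of a
#' binary outcome.
#'
#' @param counts A 2 x 2 non-negative count matrix with positive
#'   margins.
#' @return A list with `statistic`, `df`, `p.value`.
#' @export
chi_squared_yates <- function(counts) {
  counts <- check_counts(counts, "chi_squared_yates")
  if (!all(dim(counts) == c(2, 2))) {
    abort("chi_squared_yates: counts must be 2 x 2")
  }
  ct <- suppressWarnings(chisq.test(counts, correct = TRUE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = unname(ct$p.value))
}

#' Odds ratio with normal-approximation confidence interval
#'
#' Rows are the two groups, columns the outcome in (negative, positive)
#' order; the odds ratio is the first group's positive odds over the
#' second group's. A zero cell triggers the Haldane-Anscombe +0.5
#' adjustment (logged via a warning). The confidence interval is the
#' log-OR normal approximation with `SE = sqrt(sum 1/cell)`.
#'
#' @param counts A 2 x 2 count matrix, rows = groups, columns =
#'   (negative, positive).
#' @param conf Confidence level.
#' @return A list with `estimate`, `conf.low`, `conf.high`.
#' @export
#' @examples
#' odds_ratio(rbind(c(1230, 166), c(63, 35)))$estimate  # about 0.24
odds_ratio <- function(counts, conf = 0.95) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2)) || any(counts < 0)) {
    abort("odds_ratio: counts must be a non-negative 2 x 2 matrix")
  }
  if (all(counts == 0)) abort("odds_ratio: all-zero table")
  if (any(counts == 0)) {
    warn("odds_ratio: zero cell; applying Haldane-Anscombe +0.5 adjustment")
    counts <- counts + 0.5
  }
  counts <- unname(counts)
  or <- (counts[1, 2] / counts[1, 1]) / (counts[2, 2] / counts[2, 1])
  se <- sqrt(sum(1 / counts))
  z <- qnorm(1 - (1 - conf) / 2)
  list(estimate = or, conf.low = exp(log(or) - z * se),
       conf.high = exp(log(or) + z * se))
}

#' External cluster validation report
#'
#' Compares the derived instrument scores across clusters: one-way ANOVA
#' with Tukey-Kramer post-hoc pairwise contrasts for the continuous
#' scores (PSQI global, GSRS total, NQ global and its four factors), and
#' for the binary Berlin risk an uncorrected omnibus chi-squared over
#' all clusters plus Yates-corrected pairwise chi-squared tests with
#' odds ratios (odds of high risk, first-listed cluster over second).
#' The asymmetric correction choice — omnibus uncorrected, pairwise
#' corrected — is deliberate and noted in the report.
#'
#' @param data A scored table.
#' @param labels Cluster labels aligned to `data` rows (any atomic
#'   vector; reported in sorted unique order).
#' @param partition Optional tag (e.g. `"train"`/`"test"`) stored on the
#'   report.
#' @param scores Character vector of continuous score columns to
#'   compare.
#' @return A `validation_report`: tibbles `summaries` (per cluster n,
#'   mean, sd or low/high counts) and `tests` (omnibus + pairwise rows
#'   per score).
#' @export
validation_report <- function(data, labels, partition = NULL,
                              scores = c("psqi_global", "gsrs_total",
                                         "nq_global", "nq_balance",
                                         "nq_diversity", "nq_moderation",
                                         "nq_behavior")) {
  stopifnot(length(labels) == nrow(data))
  labs <- sort(unique(labels))
  sizes <- table(factor(labels, levels = labs))
  if (any(sizes < 2)) {
    warn("validation_report: a cluster has fewer than 2 members; tests skipped")
    return(structure(list(summaries = tibble::tibble(),
                          tests = tibble::tibble(),
                          partition = partition), class = "validation_report"))
  }

  summaries <- list(); tests <- list()
  for (sc in scores) {
    if (!sc %in% names(data)) abort(sprintf("score column '%s' absent", sc))
    df <- tibble::tibble(value = data[[sc]], group = as.character(labels))
    fit <- anova_oneway(df)
    summaries[[sc]] <- dplyr::mutate(fit$groups, score = sc, .before = 1)
    post <- tukey_kramer(fit)
    tests[[sc]] <- dplyr::bind_rows(
      tibble::tibble(score = sc, comparison = "omnibus", test = "anova_f",
                     estimate = NA_real_, conf.low = NA_real_,
                     conf.high = NA_real_, statistic = fit$statistic,
                     p.value = fit$p.value),
      tibble::tibble(score = sc,
                     comparison = paste(post$group1, "vs", post$group2),
                     test = "tukey_kramer", estimate = post$diff,
                     conf.low = post$conf.low, conf.high = post$conf.high,
                     statistic = NA_real_, p.value = post$p.adj))
  }

  if ("berlin_risk" %in% names(data)) {
    tab <- table(factor(as.character(labels), levels = as.character(labs)),
                 data$berlin_risk)
    counts <- as.matrix(tab)[, c("low", "high"), drop = FALSE]
    summaries[["berlin_risk"]] <- tibble::tibble(
      score = "berlin_risk", group = rownames(counts),
      n = as.integer(rowSums(counts)),
      low = as.integer(counts[, "low"]), high = as.integer(counts[, "high"]))
    omni <- chi_squared(counts)
    pair_rows <- purrr::map_dfr(utils::combn(nrow(counts), 2,
                                             simplify = FALSE), function(pr) {
      sub <- counts[pr, , drop = FALSE]
      or <- odds_ratio(sub)
      x2 <- chi_squared_yates(sub)
      tibble::tibble(score = "berlin_risk",
                     comparison = paste(rownames(counts)[pr[1]], "vs",
                                        rownames(counts)[pr[2]]),
                     test = "odds_ratio_yates", estimate = or$estimate,
                     conf.low = or$conf.low, conf.high = or$conf.high,
                     statistic = x2$statistic, p.value = x2$p.value)
    })
    tests[["berlin_risk"]] <- dplyr::bind_rows(
      tibble::tibble(score = "berlin_risk", comparison = "omnibus",
                     test = "chi_squared", estimate = NA_real_,
                     conf.low = NA_real_, conf.high = NA_real_,
                     statistic = omni$statistic, p.value = omni$p.value),
      pair_rows)
  }

  structure(list(summaries = dplyr::bind_rows(summaries),
                 tests = dplyr::bind_rows(tests),
                 partition = partition,
                 note = paste("omnibus chi-squared uncorrected;",
                              "pairwise 2x2 with Yates continuity correction")),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  tag <- if (is.null(x$partition)) "" else sprintf(" (%s)", x$partition)
  cat(sprintf("<validation_report>%s: %d scores, %d test rows\n", tag,
              length(unique(x$tests$score)), nrow(x$tests)))
  print(format_p(x$tests))
  invisible(x)
}

# Table-style p formatting: 3 dp with a "<0.001" floor
format_p <- function(tests) {
  dplyr::mutate(tests, p = ifelse(.data$p.value < 0.001, "<0.001",
                                  sprintf("%.3f", .data$p.value)))
}
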