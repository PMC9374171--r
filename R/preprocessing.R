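append_log <- function(data, stage, rows_in, removed) {
  log <- attr(data, "stage_log", exact = TRUE) %||%
    tibble::tibble(stage = character(0), rows_in = integer(0),
                   rows_removed = integer(0), rows_out = integer(0))
  attr(data, "stage_log") <- dplyr::bind_rows(log, tibble::tibble(
    stage = stage, rows_in = as.integer(rows_in),
    rows_removed = as.integer(removed),
    rows_out = as.integer(rows_in - removed)))
  data
}

#' Per-stage filtering log
#'
#' The cleaning functions record how many rows entered and left each
#' stage; the log is carried on the table as an attribute and survives
#' chaining, mirroring a cohort flow chart. Row conservation
#' (`rows_in = rows_out + rows_removed`) holds for every stage.
#'
#' @param data A table that passed through the cleaning chain.
#' @return A tibble with `stage`, `rows_in`, `rows_removed`, `rows_out`.
#' @export
stage_log <- function(data) {
  attr(data, "stage_log", exact = TRUE) %||%
    tibble::tibble(stage = character(0), rows_in = integer(0),
                   rows_removed = integer(0), rows_out = integer(0))
}

#' Remove multiple responders
#'
#' A respondent identifier appearing more than once marks an unreliable
#' participant; all of that participant's rows are removed (the
#' participant is eliminated, not just the surplus submissions).
#'
#' @param data A survey table with a `respondent_id` column.
#' @return The deduplicated tibble; the stage log records the removal.
#' @export
dedupe_responders <- function(data) {
  n_in <- nrow(data)
  dup_ids <- unique(data$respondent_id[duplicated(data$respondent_id)])
  out <- data[!data$respondent_id %in% dup_ids, , drop = FALSE]
  out <- preserve_attrs(out, data)
  append_log(out, "multiple_responders", n_in, n_in - nrow(out))
}

#' Apply inclusion criteria and completeness
#'
#' Keeps respondents aged at least `min_age`, holding one of the four
#' eligible enlisted ranks, who consented, and whose required items are
#' all answered (no imputation is performed anywhere downstream, so
#' incomplete responses must leave here).
#'
#' @param data A survey table.
#' @param min_age Minimum age in years (default 19).
#' @param eligible_ranks Character vector of admissible ranks.
#' @return The filtered tibble, with two stage-log entries (inclusion
#'   criteria, then completeness).
#' @export
filter_eligible <- function(data, min_age = 19,
                            eligible_ranks = c("private",
                                               "private_first_class",
                                               "corporal", "sergeant")) {
  n_in <- nrow(data)
  keep <- !is.na(data$age) & data$age >= min_age &
    !is.na(data$rank) & data$rank %in% eligible_ranks &
    !is.na(data$consent) & data$consent
  out <- data[keep, , drop = FALSE]
  out <- preserve_attrs(out, data)
  out <- append_log(out, "inclusion_criteria", n_in, n_in - nrow(out))

  n_mid <- nrow(out)
  req <- intersect(required_item_columns(), names(out))
  complete <- complete.cases(out[req])
  out2 <- out[complete, , drop = FALSE]
  out2 <- preserve_attrs(out2, out)
  append_log(out2, "incomplete_responses", n_mid, n_mid - nrow(out2))
}

#' Default out-of-range bounds for open items
#'
#' Height below 110 cm or above 200 cm, weight below 40 kg or above
#' 160 kg, smoking amount above five packs per day, and smoking duration
#' above 20 years are treated as miswritten open-question entries. All
#' bounds are exclusive: a value exactly on a bound is kept.
#'
#' @return A named list of `c(lower, upper)` bounds.
#' @export
outlier_bounds <- function() {
  list(height_cm = c(110, 200), weight_kg = c(40, 160),
       smoking_packs_per_day = c(-Inf, 5), smoking_years = c(-Inf, 20))
}

#' Remove rows violating open-item bounds
#'
#' @param data A survey table.
#' @param bounds Bounds configuration, see [outlier_bounds()].
#' @return The filtered tibble with a stage-log entry.
#' @export
drop_outlier_rows <- function(data, bounds = outlier_bounds()) {
  n_in <- nrow(data)
  if (n_in == 0) return(append_log(data, "outlier_values", 0, 0))
  bad <- rep(FALSE, n_in)
  for (field in names(bounds)) {
    v <- data[[field]]
    bad <- bad | (!is.na(v) & (v < bounds[[field]][1] | v > bounds[[field]][2]))
  }
  out <- data[!bad, , drop = FALSE]
  out <- preserve_attrs(out, data)
  append_log(out, "outlier_values", n_in, sum(bad))
}

#' Keep the sleep-disturbed subset
#'
#' Retains respondents whose PSQI global score exceeds 5 (that is, 6 and
#' above), the conventional threshold for significant sleep disturbance.
#'
#' @param data A scored table with `psqi_global`.
#' @return The filtered tibble with a stage-log entry.
#' @export
filter_disturbed <- function(data) {
  n_in <- nrow(data)
  out <- data[!is.na(data$psqi_global) & data$psqi_global > 5, , drop = FALSE]
  out <- preserve_attrs(out, data)
  append_log(out, "psqi_gt5_filter", n_in, n_in - nrow(out))
}

preserve_attrs <- function(out, data) {
  attr(out, "stage_log") <- attr(data, "stage_log", exact = TRUE)
  attr(out, "artifact_manifest") <- attr(data, "artifact_manifest", exact = TRUE)
  out
}

#' Random train/test partition
#'
#' Uniformly random split with `floor(fraction * n)` training rows; the
#' partition is recorded in a `.partition` column (factor with levels
#' `train`, `test`) and is reproducible given the seed.
#'
#' @param data A table.
#' @param fraction Training fraction in (0, 1].
#' @param seed Optional RNG seed.
#' @return `data` with `.partition` appended.
#' @export
#' @examples
#' x <- split_train_test(tibble::tibble(i = 1:10), fraction = 0.8, seed = 1)
#' table(x$.partition)
split_train_test <- function(data, fraction = 0.8, seed = NULL) {
  if (fraction <= 0 || fraction > 1) abort("'fraction' must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data)
  n_train <- floor(fraction * n)
  train_idx <- sample.int(n, n_train)
  part <- rep("test", n)
  part[train_idx] <- "train"
  data$.partition <- factor(part, levels = c("train", "test"))
  preserve_attrs(tibble::as_tibble(data), data)
}

#' Feature schema for the clustering input matrix
#'
#' Declares which columns enter the numeric feature matrix and how each
#' is encoded. By default the input feature set is demographics, medical
#' history, military duty, sleeping environment, the dietary-habit items
#' and the Bristol stool scale — the four scored instruments (PSQI,
#' Berlin, NQ, GSRS items) and all derived scores are excluded, keeping
#' the external-validation variables strictly outside the clustering
#' input. Setting `include_scored_instrument_items = TRUE` restores the
#' alternative reading in which the raw instrument items are inputs too.
#'
#' Encodings: `numeric` and `ordinal` columns are standardized (the
#' scaler is fitted on training rows only); `onehot` expands a nominal
#' item into one indicator column per declared level.
#'
#' @param include_scored_instrument_items Include raw PSQI/Berlin/NQ/GSRS
#'   items as features.
#' @return A tibble with `column`, `encoding`, `levels`.
#' @export
feature_schema <- function(include_scored_instrument_items = FALSE) {
  dict <- survey_dictionary()
  sections <- c("demographics", "medical", "military", "sleep_env",
                "diet", "bss")
  if (include_scored_instrument_items) {
    sections <- c(sections, "psqi", "berlin", "nq", "gsrs")
  }
  dict <- dict[dict$section %in% sections, , drop = FALSE]
  tibble::tibble(
    column = dict$column,
    encoding = dplyr::case_when(
      dict$type == "numeric" ~ "numeric",
      dict$type == "ordinal" ~ "ordinal",
      dict$type == "logical" ~ "ordinal",
      dict$type == "nominal" ~ "onehot"),
    levels = dict$levels)
}

#' Build standardized train/test feature matrices
#'
#' Encodes the scored table into the numeric matrix `X` used by feature
#' extraction and clustering. Nominal items are one-hot expanded;
#' numeric/ordinal items are standardized to zero mean and unit variance
#' using location/scale fitted on the *training* rows only and applied
#' to both partitions (no leakage). A categorical level seen in test but
#' absent from training maps to an all-zero indicator block.
#'
#' @param data A scored table carrying the `.partition` column from
#'   [split_train_test()].
#' @param schema Encoding schema, see [feature_schema()].
#' @return An object of class `feature_matrix`: a list with `train` and
#'   `test` numeric matrices, `row_ids`, `column_meta`, and the fitted
#'   `scaler` (per-column center/scale).
#' @export
build_feature_matrix <- function(data, schema = feature_schema()) {
  if (!".partition" %in% names(data)) {
    abort("build_feature_matrix: run split_train_test() first (missing .partition)")
  }
  is_train <- data$.partition == "train"

  blocks <- list(); meta <- list()
  for (i in seq_len(nrow(schema))) {
    cl <- schema$column[i]; enc <- schema$encoding[i]
    v <- data[[cl]]
    if (is.null(v)) abort(sprintf("feature column '%s' absent from data", cl))
    if (enc %in% c("numeric", "ordinal")) {
      x <- as.numeric(v)
      blocks[[cl]] <- matrix(x, ncol = 1,
                             dimnames = list(NULL, cl))
      meta[[cl]] <- tibble::tibble(column = cl, source = cl,
                                   encoding = enc, level = NA_character_)
    } else {
      levs <- as.character(schema$levels[[i]])
      m <- sapply(levs, function(lv) as.numeric(as.character(v) == lv))
      if (nrow(data) == 1) m <- matrix(m, nrow = 1)
      colnames(m) <- paste0(cl, "=", levs)
      blocks[[cl]] <- m
      meta[[cl]] <- tibble::tibble(column = colnames(m), source = cl,
                                   encoding = "onehot", level = levs)
    }
  }
  X <- do.call(cbind, blocks)
  meta <- dplyr::bind_rows(meta)

  scale_cols <- meta$column[meta$encoding != "onehot"]
  center <- setNames(numeric(length(scale_cols)), scale_cols)
  scale_ <- setNames(numeric(length(scale_cols)), scale_cols)
  for (cn in scale_cols) {
    mu <- mean(X[is_train, cn]); s <- sd(X[is_train, cn])
    if (!is.finite(s) || s == 0) s <- 1
    center[cn] <- mu; scale_[cn] <- s
    X[, cn] <- (X[, cn] - mu) / s
  }

  structure(list(
    train = X[is_train, , drop = FALSE],
    test = X[!is_train, , drop = FALSE],
    row_ids = list(train = data$respondent_id[is_train],
                   test = data$respondent_id[!is_train]),
    column_meta = meta,
    scaler = tibble::tibble(column = scale_cols, center = unname(center),
                            scale = unname(scale_))),
    class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d train / %d test rows, %d encoded columns\n",
              nrow(x$train), nrow(x$test), ncol(x$train)))
  invisible(x)
}
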