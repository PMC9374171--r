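#' Pipeline configuration
#'
#' Bundles every stage's options into one resolved, seeded
#' configuration: cohort generation (or a user-supplied table),
#' artifact injection, scoring conventions, the cleaning bounds, split
#' fraction, autoencoder grid and training settings, clustering grid,
#' and output directory.
#'
#' @param synthetic A [synthetic_config()] describing the cohort to
#'   generate; ignored when `data` is supplied.
#' @param data Optional pre-existing survey table (bypasses generation
#'   and artifact injection).
#' @param inject Inject data-quality artifacts before cleaning.
#' @param gsrs_convention GSRS aggregation convention.
#' @param include_scored_instrument_items Feature-schema switch, see
#'   [feature_schema()].
#' @param fraction Training fraction.
#' @param J_grid,folds,epochs,batch,learning_rate Autoencoder grid and
#'   training settings.
#' @param k_range Candidate cluster counts for the validity indices.
#' @param k_focus Small-k regime over which feature sets are compared.
#' @param restarts k-means restarts.
#' @param ae_restarts Training restarts per final autoencoder; the run
#'   with the lowest final training RMSE is kept.
#' @param feature_set Optional override (e.g. `"dae_J2"`, `"pca"`,
#'   `"raw"`): fixes the feature set used for the elbow and the final
#'   clustering instead of the internal-validity selection. The
#'   selection grid and ranking are still computed and reported.
#' @param seed Master seed; all stage randomness flows from it.
#' @param out_dir Optional directory for persisted stage outputs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            data = NULL,
                            inject = TRUE,
                            gsrs_convention = "sum0",
                            include_scored_instrument_items = FALSE,
                            fraction = 0.8,
                            J_grid = 1:10, folds = 10, epochs = 100,
                            batch = 64, learning_rate = 1e-3,
                            k_range = 2:10, k_focus = 2:4, restarts = 10,
                            ae_restarts = 5, feature_set = NULL,
                            seed = 2021, out_dir = NULL) {
  structure(list(synthetic = synthetic, data = data, inject = inject,
                 gsrs_convention = gsrs_convention,
                 include_scored_instrument_items = include_scored_instrument_items,
                 fraction = fraction, J_grid = J_grid, folds = folds,
                 epochs = epochs, batch = batch,
                 learning_rate = learning_rate, k_range = k_range,
                 k_focus = k_focus, restarts = restarts,
                 ae_restarts = ae_restarts, feature_set = feature_set,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full subtyping pipeline
#'
#' Executes, in order: cohort simulation (unless a table is supplied),
#' artifact injection, the cleaning chain (multiple responders,
#' inclusion/completeness, out-of-range open items), instrument
#' scoring, the sleep-disturbance filter, the train/test split, feature
#' encoding, cross-validated autoencoder grid search, PCA, the
#' internal-validity grid over feature sets, feature-set selection,
#' elbow selection of k, the final k-means fit, test-set assignment,
#' and external validation reports for both partitions.
#'
#' @param config A [pipeline_config()].
#' @param dry_run Validate the configuration and return the resolved
#'   stage plan without computing.
#' @return A `pi_run` record containing every stage output: `stage_log`,
#'   `ae_grid`, `pca`, `selection_grid`, `feature_set`, `wcss_curve`,
#'   `k`, `solution`, `labels`, `reports`, `coordinates`, `scored`.
#' @export
run_pipeline <- function(config = pipeline_config(), dry_run = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  plan <- c("simulate", if (config$inject) "inject_artifacts",
            "clean", "score", "filter_disturbed", "split",
            "encode_features", "ae_grid_search", "pca",
            "selection_grid", "select_feature_set", "elbow", "final_fit",
            "assign_test", "validate")
  if (dry_run) return(structure(list(plan = plan, config = config),
                                class = "pi_plan"))
  set.seed(config$seed)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e)))
    })
  }

  data <- run_stage("simulate", {
    if (!is.null(config$data)) config$data
    else simulate_survey(config = config$synthetic)
  })
  if (is.null(config$data) && config$inject) {
    data <- run_stage("inject_artifacts", inject_artifacts(
      data, rates = config$synthetic$artifact_rates,
      config = config$synthetic))
  }

  cleaned <- run_stage("clean", {
    data |> dedupe_responders() |> filter_eligible() |> drop_outlier_rows()
  })
  scored <- run_stage("score", score_survey(
    cleaned, convention = config$gsrs_convention))
  scored <- preserve_attrs(scored, cleaned)
  disturbed <- run_stage("filter_disturbed", filter_disturbed(scored))
  split <- run_stage("split", split_train_test(disturbed, config$fraction))
  fm <- run_stage("encode_features", build_feature_matrix(
    split, feature_schema(config$include_scored_instrument_items)))

  grid <- run_stage("ae_grid_search", ae_grid_search(
    fm, J_grid = config$J_grid, folds = config$folds,
    epochs = config$epochs, batch = config$batch,
    learning_rate = config$learning_rate))

  models <- run_stage("final_autoencoders", {
    purrr::map(setNames(config$J_grid, paste0("dae_J", config$J_grid)),
               function(J) fit_autoencoder(
                 fm, J, epochs = config$epochs, batch = config$batch,
                 learning_rate = config$learning_rate,
                 restarts = config$ae_restarts, select_by = "loss"))
  })
  pca <- run_stage("pca", fit_pca(fm))

  # bottleneck codes are defined only up to an affine reparametrization,
  # so they are whitened (train-fitted) before clustering; PCA scores
  # keep their natural variance ordering
  code_whiteners <- purrr::map(models, function(m) {
    code_whitener(encode(m, fm$train))
  })
  features_train <- c(
    list(raw = fm$train, pca = pca$scores),
    purrr::map2(models, code_whiteners,
                function(m, wh) whiten_codes(encode(m, fm$train), wh)))
  sel_grid <- run_stage("selection_grid", cluster_selection_grid(
    features_train, k_range = config$k_range, restarts = config$restarts))
  selected <- run_stage("select_feature_set",
                        select_feature_set(sel_grid, config$k_focus))
  feature_set <- config$feature_set %||% selected
  if (!feature_set %in% names(features_train)) {
    abort(sprintf("unknown feature_set override '%s'", feature_set))
  }

  wcss_curve <- sel_grid[sel_grid$feature_set == feature_set, ]
  wcss_by_k <- setNames(wcss_curve$wcss, wcss_curve$k)
  k_star <- run_stage("elbow", elbow_select(wcss_by_k))

  Z_train <- features_train[[feature_set]]
  solution <- run_stage("final_fit", fit_kmeans(
    Z_train, k_star, restarts = config$restarts))

  Z_test <- run_stage("encode_test", {
    if (feature_set == "raw") fm$test
    else if (feature_set == "pca") predict(pca, fm$test)
    else whiten_codes(encode(models[[feature_set]], fm$test),
                      code_whiteners[[feature_set]])
  })
  test_labels <- run_stage("assign_test", assign_clusters(solution, Z_test))

  # canonical cluster letters, largest first
  ord <- order(solution$sizes, decreasing = TRUE)
  relabel <- setNames(LETTERS[seq_len(solution$k)], ord)
  train_lab <- unname(relabel[as.character(solution$labels)])
  test_lab <- unname(relabel[as.character(test_labels)])

  is_train <- split$.partition == "train"
  reports <- run_stage("validate", list(
    train = validation_report(split[is_train, ], train_lab, "train"),
    test = validation_report(split[!is_train, ], test_lab, "test")))

  coords <- dplyr::bind_rows(
    tibble::tibble(respondent_id = split$respondent_id[is_train],
                   partition = "train", cluster = train_lab,
                   psqi = split$psqi_global[is_train],
                   gsrs = split$gsrs_total[is_train],
                   nq_moderation = split$nq_moderation[is_train],
                   berlin_high = as.integer(split$berlin_risk[is_train] == "high")),
    tibble::tibble(respondent_id = split$respondent_id[!is_train],
                   partition = "test", cluster = test_lab,
                   psqi = split$psqi_global[!is_train],
                   gsrs = split$gsrs_total[!is_train],
                   nq_moderation = split$nq_moderation[!is_train],
                   berlin_high = as.integer(split$berlin_risk[!is_train] == "high")))

  run <- structure(list(
    config = config, plan = plan,
    stage_log = stage_log(split),
    n = list(train = sum(is_train), test = sum(!is_train)),
    ae_grid = grid, pca = pca, models = models,
    selection_grid = sel_grid, feature_set = as.character(feature_set),
    selected_feature_set = as.character(selected),
    feature_ranking = attr(selected, "ranking"),
    wcss_curve = wcss_curve, k = as.integer(k_star),
    no_elbow = isTRUE(attr(k_star, "no_elbow")),
    solution = solution,
    labels = list(train = train_lab, test = test_lab),
    reports = reports, coordinates = coords,
    scored = split), class = "pi_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

#' @export
print.pi_run <- function(x, ...) {
  cat("<pi_run>\n")
  cat(sprintf("  rows: %d train / %d test after filtering\n",
              x$n$train, x$n$test))
  cat(sprintf("  selected feature set: %s; k = %d\n", x$feature_set, x$k))
  cat(sprintf("  cluster sizes (train): %s\n",
              paste(sort(table(x$labels$train), decreasing = TRUE),
                    collapse = "/")))
  invisible(x)
}

#' @export
print.pi_plan <- function(x, ...) {
  cat("<pi_plan> stages:\n")
  cat(paste(" -", x$plan, collapse = "\n"), "\n")
  invisible(x)
}

#' Persist a pipeline run as plain-text artifacts
#'
#' Writes the stage-count log, the autoencoder grid table, the
#' internal-validity grid, the WCSS curve, train/test cluster labels,
#' both validation reports, the 3-D coordinate export and a JSON
#' manifest (seed, selections, sizes) into `dir`.
#'
#' @param run A `pi_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  wr(run$stage_log, "stage_counts.csv")
  wr(run$ae_grid$summary, "ae_grid.csv")
  wr(run$ae_grid$curves, "ae_curves.csv")
  wr(as.data.frame(run$selection_grid), "selection_grid.csv")
  wr(run$wcss_curve, "wcss_curve.csv")
  part <- as.character(run$scored$.partition)
  lab <- character(length(part))
  lab[part == "train"] <- run$labels$train
  lab[part == "test"] <- run$labels$test
  wr(tibble::tibble(respondent_id = run$scored$respondent_id,
                    partition = part, cluster = lab), "cluster_labels.csv")
  wr(run$reports$train$tests, "validation_train.csv")
  wr(run$reports$test$tests, "validation_test.csv")
  wr(run$coordinates, "cluster_coordinates.csv")
  manifest <- list(seed = run$config$seed, feature_set = run$feature_set,
                   k = run$k, n_train = run$n$train, n_test = run$n$test,
                   stage_log = run$stage_log)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
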