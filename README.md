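# somnotype

Unsupervised subtyping of sleep-disturbance survey cohorts: a tested,
reproducible R implementation of the full pipeline

> simulate (or ingest) an item-level survey → score the clinical
> instruments → clean and filter → extract low-dimensional features
> (PCA and a symmetric deep autoencoder) → k-means with internal model
> selection → external cluster validation.

It is aimed at biostatisticians and epidemiologists who want to subtype
questionnaire cohorts — here, soldiers screening positive for sleep
disturbance — and validate the subtypes against clinical scores that
were deliberately kept out of the clustering input.

## The model in brief

Respondents answer six survey sections (demographics, medical history,
military duty, sleep, diet/nutrition, gastrointestinal). Instrument
scores are computed once and reserved for validation:

- **PSQI** — 19 items → 7 components (0–3) → global 0–21; global > 5
  flags significant sleep disturbance and defines the analysis cohort;
- **Berlin questionnaire** — three categories; ≥ 2 positive categories
  = high risk of obstructive sleep apnea;
- **NQ** — global nutrition score + 4 factors; ≥ 58 graded "good";
- **GSRS** — 15-item gastrointestinal symptom total (0–90);
- **Bristol stool scale** — stool form 1–7.

The clustering input X (n × d, d ≈ 70 encoded columns) holds the
*remaining* responses, standardized on training rows. A symmetric deep
autoencoder with widths [d, 8J, J, 8J, d] (ReLU wide layers, linear
bottleneck, Adam, batch 64, 100 epochs) is compared over a bottleneck
grid 1 ≤ J ≤ 10 with 10-fold cross-validation against PCA and raw
features. k-means (Lloyd, 300 iterations, 10 restarts) partitions each
feature set for k = 2..10; the Calinski–Harabasz index and silhouette
coefficient pick the feature set, the elbow (max second difference) of
the WCSS curve picks k, and the held-out 20 % test partition is
assigned by nearest centroid. Cluster differences in PSQI/GSRS/NQ are
tested by one-way ANOVA + Tukey–Kramer contrasts; the binary Berlin
risk by χ² tests and odds ratios.

Because no survey data are distributable, the package ships a
first-class synthetic cohort generator (`simulate_survey()`) with a
calibrated three-cluster latent structure, data-quality artifacts
(duplicates, incomplete rows, out-of-range entries) and a manifest for
exact-removal checks. See the methods vignette
(`vignettes/sleep-subtyping-methods.Rmd`) for what it does and does not
emulate.

## Worked example

```r
library(somnotype)

cohort <- simulate_survey(n = 2000, seed = 42)
cfg <- pipeline_config(
  data = inject_artifacts(cohort, seed = 43),
  feature_set = "dae_J2",   # pin the published final architecture
  seed = 2021)
run <- run_pipeline(cfg)
run
#> <pi_run>
#>   rows: 1420 train / 356 test after filtering
#>   selected feature set: dae_J2; k = 3
#>   cluster sizes (train): 948/410/62

run$stage_log
#> # A tibble: 5 × 4
#>   stage                rows_in rows_removed rows_out
#>   <chr>                  <int>        <int>    <int>
#> 1 multiple_responders     2013           26     1987
#> 2 inclusion_criteria      1987            0     1987
#> 3 incomplete_responses    1987           37     1950
#> 4 outlier_values          1950            6     1944
#> 5 psqi_gt5_filter         1944          168     1776

glance(run)
#> # A tibble: 1 × 7
#>   n_train n_test feature_set     k  wcss ch_index silhouette
#>     <int>  <int> <chr>       <int> <dbl>    <dbl>      <dbl>
#> 1    1420    356 dae_J2          3  605.    2615.      0.590
```

Reading this: 2,000 simulated respondents (plus 26 injected duplicate
rows) enter the cleaning chain; the multiple responders, 37 incomplete
responses and 6 out-of-range entries are removed; the PSQI > 5 filter
keeps 1,776 sleep-disturbed respondents, split 80/20. Clustering the
two-node autoencoder codes finds k = 3 subtypes via the elbow: one
large mild cluster, one intermediate, and a small severe cluster of 62
trainees. The external validation report contrasts the held-out scores
across the subtypes:

```r
dplyr::filter(tidy(run$reports$train), comparison == "omnibus")
#> # A tibble: 8 × 8
#>   score         comparison test        statistic   p.value
#>   <chr>         <chr>      <chr>           <dbl>     <dbl>
#> 1 psqi_global   omnibus    anova_f         86.4  3.79e- 36
#> 2 gsrs_total    omnibus    anova_f       1228.   3.65e-310
#> 3 nq_global     omnibus    anova_f          5.66 3.55e-  3
#> 4 nq_moderation omnibus    anova_f         63.9  2.68e- 27
#> ...
#> 8 berlin_risk   omnibus    chi_squared    105.   1.54e- 23
```

The cluster with the highest GSRS total also carries the highest PSQI
and Berlin risk — the severe gastrointestinal/sleep subtype; the
assigned labels agree with the generator's latent clusters at an
adjusted Rand index of 0.978 on the training partition. `autoplot(run)`
draws the clusters in score space; `autoplot(run$ae_grid)` shows the
cross-validated reconstruction error over the bottleneck grid.

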