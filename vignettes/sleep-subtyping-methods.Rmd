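---
title: "Methods: autoencoder-based subtyping of sleep-disturbance survey cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: autoencoder-based subtyping of sleep-disturbance survey cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

somnotype implements a complete, reproducible pipeline for data-driven
subtyping of sleep-disturbance survey respondents: simulate (or ingest)
an item-level cohort, score the clinical instruments, clean and filter,
extract low-dimensional features, cluster, and validate the clusters
against scores held out of the clustering input. This vignette explains
the model and the design choices; the README shows a worked run.

## The analysis model

Respondents answer a six-section questionnaire: demographics, medical
history, military duty, sleep (the 19-item Pittsburgh Sleep Quality
Index, the Berlin questionnaire, and sleeping-environment items),
diet/nutrition (25 dietary-habit items and the 21-item Nutrition
Quotient), and gastrointestinal status (the 15-item GSRS and the
Bristol stool scale). Instrument scores (PSQI components/global, Berlin
risk, NQ global + four factors, GSRS total) are computed once and
reserved for *external* validation; the clustering input `X` is built
from the remaining responses — demographics, medical history, military
duty, sleeping environment, dietary items and stool form — one-hot
encoding nominal items and standardizing numeric/ordinal ones with
location/scale fitted on training rows only. The default excludes the
scored instruments' raw items from `X` so that validation variables are
strictly out-of-input; `feature_schema(include_scored_instrument_items
= TRUE)` restores the alternative reading.

Feature extraction compares principal components against a symmetric
deep autoencoder with layer widths `[d, 8J, J, 8J, d]`: ReLU on the two
wide hidden layers, a linear bottleneck and a linear output, trained to
reconstruct its standardized input under mean-squared error (reported
as RMSE) with Adam (learning rate 1e-3), minibatches of 64 and 100
epochs. The bottleneck width `J` is examined over a 1-10 grid with
10-fold cross-validation. Bottleneck activations are the extracted
features; because a code space is defined only up to an affine
reparametrization (independent training runs produce rotated, sheared
and rescaled charts), codes are whitened with a train-fitted transform
before clustering, making distances and the WCSS elbow invariant to
the arbitrary parametrization. PCA scores, in contrast, keep their
natural variance ordering — whitening them would equalize
uninformative directions with signal.

k-means (Lloyd iterations, 300 maximum, best of 10 seeded restarts,
ties to the lowest cluster index, empty clusters reseeded to the
farthest point) partitions each candidate feature set for k = 2..10.
Internal validity is judged by the Calinski-Harabasz index and mean
silhouette; the feature set is chosen by averaging min-max-normalized
CH and silhouette over the clinically plausible small-k regime
(k = 2..4), and the cluster count by the elbow rule — the k maximizing
the discrete second difference of the WCSS curve, with a "no elbow"
flag when the curve is near-linear. Test rows are assigned to the
nearest centroid. Externally, cluster differences in PSQI, GSRS and NQ
scores are tested by one-way ANOVA with Tukey-Kramer pairwise
contrasts, and the binary Berlin risk by an uncorrected omnibus
chi-squared plus Yates-corrected pairwise chi-squared tests with odds
ratios. The asymmetric correction choice (omnibus uncorrected, 2x2
pairwise corrected) reproduces the published values of the statistics
this package's validation module is calibrated against and is noted in
the report object itself.

## Scoring conventions

- **PSQI** components follow the published band tables, carried as data
  in `psqi_bands()` (latency minutes 15/30/60; duration 7/6/5 h;
  efficiency 85/75/65 %; disturbance sum 0/9/18/27; two-item sums
  re-banded 0, 1-2, 3-4, 5-6). Global > 5 flags disturbed sleep.
- **Berlin**: categories 1 and 2 positive with two positive responses
  each; category 3 with hypertension history and/or BMI > 30; high risk
  with two or more positive categories.
- **GSRS** uses a 0-based sum by default (levels 1..7 contribute 0..6
  points; range 0-90) — the only aggregation consistent with cluster
  mean totals near 2 and 18 on a 15-item scale; `sum1` and `mean`
  conventions are switchable.
- **NQ**: the instrument's true weight table is proprietary, so the
  default (`nq_default_weights()`) is a synthetic stand-in with the
  correct structure — 5/5/6/5 items per factor, linear per-level
  points, factor weights 0.61 into the global score, "good" at 58+.
  Tests exercise the structure and the grade rule, not the published
  weights.
- Sample-size arithmetic uses the finite-population formula with
  ceiling rounding, the only rule that reproduces both the target
  completes and the invitation count at a 3 % response rate.
- No imputation anywhere: incomplete instruments fail scoring and are
  excluded by the cleaning chain.

## What the synthetic cohort emulates

No study data are distributable, so `simulate_survey()` generates
item-level cohorts with a three-cluster latent structure calibrated to
the published training-cohort composition (1396/98/569) and per-cluster
score profiles (e.g. GSRS means 2.18 / 17.94 / 6.39, PSQI 8.33 / 11.57
/ 9.96, Berlin high-risk rates 0.12 / 0.36 / 0.31). Score targets are
drawn from truncated normals whose *truncated* mean is moment-matched
to the target (root-finding on the latent mean), then allocated to item
responses under each item's cap so the scoring module reproduces the
targets exactly.

The clustering signal is carried by two latent respondent traits: a
GI/dietary severity axis `g` and an environment/behavior
sleep-disruption axis `f`, loading on the dietary items (a 7-point
frequency scale), sleeping environment, stool form, duty fatigue and
stress. Three further layers make the cohort behave like real survey
data rather than separable blobs:

- a *curvature* coordinate `u = 0.5((g^2 + f^2)/3 - 1)` — a
  daytime-consequence response to overall severity — bends the item
  manifold so it is two-dimensional but not linear, which is what gives
  a two-node autoencoder a genuine advantage over a linear projection;
- two cluster-independent *response-style* factors (consumption habits;
  fitness/activity) create strong correlated item blocks that carry no
  cluster information, as real questionnaires do; they force PCA to
  spend components on uninformative directions;
- injected data-quality artifacts (duplicate submissions, blanked
  trailing sections, out-of-range open items) exercise the cleaning
  chain, with a manifest for exact-removal checks.

A single `separation` scalar interpolates the trait profiles toward the
mixture mean so recovery difficulty can be swept; instrument-score
targets are unaffected, so external validation contrasts survive even
at zero separation. Defaults were fixed once at values giving clearly
recoverable clusters (adjusted Rand index above 0.9 for the final
model) and were not revisited per-test.

What passing tests on this cohort do *not* show: real survey data are
messier — item non-response beyond the injected patterns, response
styles correlated with severity, and no guarantee that three subtypes
exist. The synthetic flow also emulates only the sleep-disturbed
subpopulation: the PSQI > 5 filter trims a low tail rather than
removing nearly half the cohort as in a general sample.

## Numerical and design choices

- **Autoencoder training protocol** (unreported in the source study;
  package's own choice): Glorot-uniform initialization, ReLU wide
  layers with a *linear* bottleneck (a rectified bottleneck clips codes
  to a quadrant and destabilized embeddings), Adam 1e-3, best of 5
  restarts by final training RMSE. `fit_autoencoder()` can instead
  select restarts by downstream internal validity
  (`select_by = "clustering"`).
- **Final-fit protocol**: cross-validation selects the architecture
  only; the final model for each `J` is refit on all training rows.
- **Known divergence from the source study**: on cleanly clustered
  synthetic data the internal-validity selection prefers the *one-node*
  bottleneck — very low-dimensional codes mechanically inflate CH and
  silhouette by collapsing within-cluster spread, and a 1-D code can
  order three clusters along a severity curve. On the study's real data
  the same rule favored J = 2. `run_pipeline()` therefore accepts a
  `feature_set` override (e.g. `"dae_J2"`) to pin the clustering space
  to the published final architecture; the selection grid and ranking
  are always reported. Relatedly, with one cluster holding under 5 % of
  respondents, the max-curvature elbow rule can only return k = 3 when
  the small cluster's isolation drop is comparable to the first split's
  drop, which requires at least two code dimensions; elbow and recovery
  claims are therefore evaluated on the J = 2 codes.
- **k-means**: "300 iterations" is interpreted as the Lloyd iteration
  cap; restarts default to 10; WCSS at k = 1 anchors the elbow curve
  while CH/silhouette start at k = 2.
- **PCA component count**: the scree rule keeps the last component
  before the flat region (argmax of `ev(j) - 2 ev(j+1) + ev(j+2)`).
- **Tolerances**: standardization and centroid identities hold to
  1e-8; validity indices match brute-force references to 1e-9;
  summary-mode ANOVA is exact, so recomputing an F statistic from
  *printed* (rounded) group summaries carries a rounding gap of order
  0.1 %.
- **Problem sizes**: tests and the acceptance script run the full
  pipeline at n = 2,000 respondents (about 1,600 after filtering),
  d = 74 encoded columns, the full J = 1..10 grid with 10-fold CV, and
  5 replicate seeds for stochastic properties; the package itself has
  no scale limits beyond memory.

## Limitations

The NQ weighting is a structural stand-in; GSRS aggregation is inferred
from published summary ranges; the autoencoder training protocol is a
reasonable reconstruction, not the study's exact code; and cluster
letters (largest first) are a presentation convention, not an
identity mapping onto the study's clusters. The clinical interpretation
of clusters — mapping subtypes to treatment patterns — is outside the
package's scope.
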