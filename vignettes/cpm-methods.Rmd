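---
title: "Connectome-based predictive modeling: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome-based predictive modeling: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpmr)
```

## The model

CPM predicts a scalar behavioral score from a subject's functional
connectome. The connectome is a symmetric K × K matrix of Fisher-z edge
weights; `cpmr` builds it from node time series by partial correlation
(`partial_correlation()`, the default, which isolates direct node-to-node
coupling by inverting the column correlation matrix) or plain Pearson
correlation, followed by `fisher_z()`. Matrices are flattened to
E = K(K−1)/2 edges in a fixed row-major upper-triangle order
(`edge_pairs()`), which every file the package writes records in a sidecar.

Training proceeds in three steps (`cpm()`):

* **Selection.** Every edge is correlated with the behavior
  (`correlate_edges()`; with covariates, both sides are residualized on the
  covariate matrix first and the t test uses n − 2 − c degrees of freedom).
  Edges with two-sided p below the threshold are split by the sign of r into
  a positive and a negative predictive network. The two masks are disjoint
  by construction.
* **Summary.** A subject's per-network score is the plain sum of their
  selected edge weights (`summary_score()`), in summed Fisher-z units.
* **Model.** Behavior is regressed on the summary score by ordinary least
  squares, independently per network. The two tails are never combined into
  one model; they are reported side by side.

Prediction for a new subject is `intercept + slope × score`
(`predict.cpm()`).

## Cross-validation and inference

Familial similarity of both connectomes and behavior makes random CV folds
leaky, so evaluation is leave-one-family-out (`family_folds()`,
`cpm_cv()`): one fold per family, selection and model fitting repeated
inside each training fold, every subject predicted exactly once by models
that never saw their family. With all-singleton families this reduces to
leave-one-subject-out. Performance is the Pearson correlation between
actual and predicted scores per tail.

Significance comes from a permutation test (`cpm_permtest()`): the behavior
vector is shuffled uniformly across all subjects and the *entire*
cross-validated pipeline — including within-fold selection — is rerun per
shuffle. The empirical p is `#(null r ≥ observed r) / m`, ties counting
toward the numerator; `smooth = TRUE` gives the (count+1)/(m+1) variant,
which never returns exactly zero. Shuffles whose prediction correlation is
undefined (every fold degenerate) are excluded from numerator and
denominator and reported. A family-restricted shuffle is deliberately *not*
the default: the null hypothesis exchanges behavior across the whole

sample, matching how the test is ordinarily run.

Internally the permutation engine caches per-fold standardized training
edges and evaluates all shuffles of a fold with single matrix products;
the test suite asserts bit-level agreement with a naive per-shuffle,
per-fold fit-and-predict loop, so the speed path cannot drift from the
definition.

## Tunable parameters

| parameter | default | units / range | why |
|---|---|---|---|
| `threshold` | 0.01 | selection p-value | main operating point; 0.05 and 0.001 standard sensitivity settings |
| `ridge` | 0.01 | fraction of mean covariance diagonal | stabilizes the K ≤ 300 precision inverse; 0 gives the raw estimator |
| `n_perm` | 1000 | count | 5000 in the original design; p resolution is 1/m |
| `alpha`, `l1_ratio` | 1.0, 0.5 | elastic-net penalty and mixing | the conventional fixed baseline hyperparameters |
| `min_degree`, `top_n` | 4, 20 | node degree / count | hub cutoff (6 for very dense networks) and hub-summary size |

Two-sided selection p-values with sign splitting are the default (a
one-sided convention would shift the effective per-tail rate); the choice
matters only at the margins of the threshold.

## Degenerate inputs and numerical choices

* Zero-variance edges get undefined r and are never selectable; constant
  behavior is a hard error.
* A training fold that selects no edges yields a constant summary score;
  the per-tail model then falls back to intercept = training mean,
  slope = 0 ("degenerate", counted in the fold diagnostics) rather than
  aborting, which keeps strict thresholds usable on small cohorts.
* Correlations with |r| ≥ 1 − 1e−7 are clamped before the Fisher transform
  (with a message) so duplicate-signal toys run end to end.
* Partial correlation standardizes columns first, adds
  `ridge × mean(diag(C))` to the diagonal, and inverts by Cholesky; a
  singular matrix raises an error naming the ridge parameter.
* Ties in the hub ranking (top-`n` boundary) break by ascending node id, so
  anatomy summaries are deterministic.
* Elastic-net features are standardized with training-fold statistics only;
  the `alpha = 0` limit is computed as exact OLS.

## What the synthetic generator emulates

`simulate_cohort()` produces a family-structured sample with an integer
behavior score (Gaussian, rounded, clipped to the 0–48 range of a 12-item
0–4 Likert factor total; defaults mean 32, SD 6 — conventions, since no
target distribution is published for such totals) plus age (uniform 22–37
years), binary gender, an intelligence count-correct (0–24) and a
log-normal head-motion scalar (mm). `simulate_edges()` plants signal:

    edge_e(s) = μ_e + β_e · z(behavior_s) + family_offset + ε,

with β_e = ±β on the planted positive/negative edge sets, baseline means
μ_e ~ N(0, 0.3) mimicking the spread of Fisher-z partial correlations, and
independent N(0, noise_sd²) edge noise. The family offset (default 0) is a
per-family, per-edge Gaussian shared by siblings; switching it on creates
exactly the dependence that makes family-aware CV necessary, which is how
the leakage tests exercise the fold logic. One user seed fans out to
per-stage sub-seeds through a fixed affine counter scheme, so all
generators are pure functions of their arguments.

What the generator does **not** emulate: voxel-level acquisition, scanner
artifacts, motion time courses, spatially structured edge covariance, or
heritability of behavior. Passing tests therefore demonstrate statistical
correctness of the pipeline — calibration, power against a linear edge
signal, leakage-freedom — not performance on real neuroimaging data.

## Calibrating the planted effect size

`beta_for_prediction_r()` answers "which β makes the pipeline's prediction
correlation come out near a target?" analytically: it models per-edge
selection power with the Fisher-z normal approximation, takes the expected
selected network (true positives plus threshold-rate false positives per
tail) and solves the population correlation of the summed score,
r = k₁b / sqrt((k₁b)² + k₁ + k₀), for β. Because this ignores fold-to-fold
heterogeneity of the masks, the realized cross-validated r runs some
10–20% below the analytic target; `tune_beta_cv()` therefore refines β by
simulating a handful of cohorts and rescaling along the analytic response
curve until the *realized* CV correlation matches the target. Both are
deterministic given a seed.

Verification sizes used by the test suite and `scripts/acceptance.R` —
chosen as desk-scale study conditions: type-I calibration over 200 null
cohorts (n = 60, 20 families of 3, K = 20, m = 200 permutations), power
over 20 cohorts (n = 200, K = 50, 30 + 30 planted edges, β tuned for CV
r ≈ 0.3), oracle checks on randomized instances with K ≤ 8 and n ≤ 40.

## Known statistical properties and limitations

* **Null CV correlations are not centered at zero in sparse regimes.**
  When folds select (almost) no edges, predictions collapse to the
  training-fold mean, which anti-correlates with the left-out family's
  scores; the null CV r then drifts markedly negative (we measure ≈ −0.26
  at E = 105, threshold 0.01, n = 60). With routine selection the center
  is near zero. The permutation test is calibrated either way — it reruns
  the same procedure on shuffled data — and our measured null rejection
  rate at 0.05 is 0.035–0.07.
* **The permutation null of the CV correlation is wide.** Under the null,
  a fold's predictions live in the span of a handful of accidentally
  selected edge scores, so the null r has spread on the order of
  sqrt(selected edges)/sqrt(n) rather than 1/sqrt(n) (≈ 0.18 at n = 200,
  K = 50, threshold 0.01). Consequently a true prediction r ≈ 0.3 at
  n = 200 is detected at the 0.05 level only ~50–60% of the time; reliable
  detection of such effect sizes needs the sample sizes of the large
  cohorts this method is normally applied to.
* Full-sample edge selection (`full_sample_networks()`) is for describing
  network anatomy only; using it before cross-validation is the classic
  CPM leakage bug, and the package ships that variant solely as a negative
  control (`leak_full_sample_selection = TRUE`), where it inflates the
  null rejection rate to ≈ 0.5–0.8.
* No multiple-comparison correction is applied across factors or tails by
  default (significance is reported at P < 0.05 per test); a Bonferroni
  adjustment over a 5-factor × 2-tail family is a one-line wrapper left to
  the analyst.
* The NEO-FFI item key (factor membership and reverse-coded items) is a
  required input — the real key is copyrighted; `synthetic_neo_key()` only
  builds structurally valid stand-ins for testing.
* The exact ridge used by published partial-correlation netmats and the
  exact head-motion summary used alongside them are not standardized;
  both are explicit parameters/columns here and recorded in reports.
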