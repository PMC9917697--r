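---
title: "Scoring mitral valve lesion complexity and modelling the repair-or-replace decision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring mitral valve lesion complexity and modelling the repair-or-replace decision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvscore)
```

## The clinical problem

Severe mitral valve disease is treated surgically by either repairing the
native valve or replacing it with a prosthesis. Repair preserves left
ventricular function and avoids prosthesis-related complications, so it is
the preferred option — but attempting repair on an unsuitable valve risks a
second bypass run and recurrent regurgitation. The decision hinges on the
anatomy of the valve apparatus as seen on preoperative (trans-esophageal)
echocardiography: which leaflet segments prolapse, whether chordae are
ruptured, how the leaflets move, and whether tissue quality is compromised
by thickening, calcification, commissural fusion, vegetations, or
perforations and clefts.

`mvscore` implements a quantitative workflow around that decision:

1. a **lesion complexity score** — a weighted sum over categorical
   echocardiographic findings — with simple / intermediate / complex strata;
2. a **surgical technique score** counting the principal maneuvers used in a
   repair;
3. a **synthetic cohort generator** that emulates the statistical structure
   of a 143-patient surgical cohort, so the downstream machinery is testable
   although the original patient-level data are not shareable;
4. **ROC analysis** of the complexity score as a predictor of the surgical
   approach, with a bootstrap confidence interval and Youden-optimal cutoff;
5. a seeded, cross-validated **gradient-boosted classifier** of repair vs.
   replacement with per-fold and aggregated feature importance.

## The complexity score

Each lesion category carries a small integer weight and the score is the
sum over the lesions present (`complexity_score()`, weights in
`default_weights()`):

| category | values and weights |
|---|---|
| posterior segment prolapse | P1, P2, P3: 1 each |
| anterior segment prolapse | A1, A2, A3: 2 each |
| commissural prolapse | anterolateral, posteromedial: 2 each |
| ruptured chordae tendineae | 1 |
| leaflet morphology | normal 0, thickening 1, redundant 3 |
| calcification (additive sites) | leaflet 1, annulus 3, chordae 3 |
| commissural fusion | 2 |
| perforation or cleft | one 1, two or more 2 |
| vegetation | one 1, two or more 2 |
| leaflet motion (scored once) | normal 0, excessive 1, restriction 2 |

Strata: **simple** 1–4, **intermediate** 5–8, **complex** ≥ 9
(`assign_stratum()`). Three design points deserve comment.

* **Pooled-lesion variant.** An alternative reading of the scoring rules
  pools vegetation, perforation and cleft into one category scored 1 for a
  single lesion and 4 for more than one. The default scores the two
  categories separately (capped at 2 each), which is the normative weight
  table; `default_weights(pooled_lesion_variant = TRUE)` activates the
  pooled rule.
* **Motion is patient-level.** Restriction or hypermobility is scored once
  regardless of how many segments are involved; a profile cannot report
  both (the constructor enforces one motion value), and restriction — the
  clinically and numerically dominant finding — is the value to record when
  both are seen.
* **Score 0.** The strata are defined from score 1 upward. A profile with
  no scored lesion maps to the simple stratum with a warning rather than an
  error: such valves exist (pure annular dilatation) and are the easiest
  repairs.

The weights are deliberately configuration-loadable (`load_weights()`):
they are assigned judgements, not estimates, and a centre may wish to
re-weight. The defaults are locked by golden tests.

```{r}
complexity_score(echo_features(prolapse_a2 = TRUE, prolapse_a3 = TRUE,
                               prolapse_posteromedial_commissure = TRUE,
                               leaflet_morphology = "redundant"))
```

The **technique score** (`technique_score()`) adds one point per principal
repair maneuver — annuloplasty, cleft closure, leaflet resection,
vegetation removal, commissurotomy — with chordal replacement counted per
segment resuspended, plus one point for a re-repair and one more if the
ring is revised. A commissurotomy counts 1 per commissure incised by
default; the weight is configurable to 2 because counting the bilateral
incision of a fused commissure as two maneuvers is an equally defensible
convention.

## The synthetic cohort generator

The original cohort cannot be redistributed, so `generate_cohort()` draws
patients from a generative model whose free parameters were set to emulate
its published structure:

* **Etiology mix**: mitral valve prolapse 55, infective endocarditis 24,
  rheumatic heart disease 39, atrial mitral regurgitation 16, Barlow's
  syndrome 4, other 5 — of 143.
* **Features given etiology**: every echocardiographic field has an
  etiology-specific Bernoulli or categorical parameter
  (`default_cohort_config()$feature_freqs`). The values encode the
  group-conditional signatures of the published tables: rheumatic valves
  concentrate thickening, restriction, leaflet/chordal calcification and
  commissural fusion (hence the complex stratum, where ~70% of patients
  are rheumatic); degenerative prolapse concentrates P2-dominant segmental
  prolapse with excessive motion and frequent chordal rupture (the
  intermediate stratum); atrial mitral regurgitation leaves the leaflets
  near-normal (the simple stratum); endocarditis carries vegetations and
  perforations.
* **Outcome**: the log-odds of replacement are
  `intercept + slope × score`, **plus fixed emphasis terms** for restricted
  motion (+1.2), leaflet calcification (+0.9) and each perforation/cleft
  lesion (+0.6). The emphasis terms encode that leaflet-quality lesions
  compromise repairability beyond their contribution to the summed score —
  the reason a learned classifier can out-predict any single score cutoff,
  and the package's own design choice after finding that a pure
  logistic-in-score link makes the optimal decision rule exactly a score
  threshold, which no feature-based classifier can beat and which
  contradicts what is observed clinically. The link remains monotone in
  the score and in every individual lesion. With the emphasis terms fixed,
  `(intercept, slope) = (−2.06, 0.15)` were calibrated by grid search
  against two targets: score-vs-label concordance (AUC) ≈ 0.75 on a large
  cohort, and a replacement fraction of 57/143.
* **Adverse events** after repair are Bernoulli with stratum-specific
  rates 0.12 / 0.13 / 0.56 (the published unsuccessful-repair fractions
  4/33, 6/45, 5/9).
* **Repair maneuvers** for repaired valves are generated from the lesions
  (prolapsed segments are resuspended, clefts closed, vegetations removed,
  fused commissures incised, nearly every repair receives a ring), so the
  technique score correlates with the complexity score as an emergent
  property (r ≈ 0.6 on large cohorts) rather than by construction.
  Re-repair never occurs because prior valve surgery is an exclusion
  criterion of the emulated cohort.
* **Demographics** (age ~ N(52, 13²) clamped to 18–90, male fraction
  88/143) are sampled but never used by the models, mirroring their
  classification as ineffective variables.

Randomness uses one root seed with a per-patient substream
(`seed + i × 1000003 mod 2³¹−1`), so cohorts are byte-identical given
`(config, seed)` and a cohort's first *m* patients do not change when *n*
grows.

**What the simulator does not emulate.** Features are independent within
etiology — only the published marginal frequencies are modelled, not
patient-level joint dependence (no copula; the large-*n* stratum mix is
≈ 33/41/26% against the published 26.6/42.6/30.8%, with the complex group
slightly under-filled because co-occurrence of rheumatic lesions is
underdispersed). Passing tests on synthetic cohorts therefore demonstrate
that the machinery is correct and that the published effect directions are
recoverable under the emulated conditions; they do not validate the
classifier on real patients.

## ROC analysis

`roc_curve()` treats replacement as the positive class — the score measures
lesion complexity, and more complex valves are less repairable. Thresholds
sit at the midpoints between consecutive distinct scores (the convention
that produces half-integer cutoffs such as 8.5 from an integer-valued
score), plus ±∞ endpoints. The trapezoidal AUC then equals the
Mann–Whitney concordance probability with ties counted ½, a property the
test suite checks by exhaustive pair counting. The confidence interval
(`auc_ci()`) is a stratified percentile bootstrap (resampling positives and
negatives separately, preserving class sizes; 2,000 replicates by default,
seeded): distribution-free and reproducible. `youden_cutoff()` maximizes
J = sensitivity + specificity − 1 over finite thresholds and breaks ties
toward the lower threshold, favouring sensitivity as appropriate for a
screening-style decision.

## The boosted classifier

`encode_features()` maps each patient to a 17-coordinate numeric vector:
the effective variables (chordal rupture; morphology and motion as ordinal
0/1/2 by clinical severity; vegetation and perforation/cleft count
classes; four calcification/fusion indicators) followed by the eight
uncertain prolapse indicators. Sex, age and diagnosis never enter. The
encoding map is versioned (`encoding_version` attribute) so a persisted
importance table can be matched to its coordinates.

`kfold_split()` shuffles indices with a seeded permutation and cuts
consecutive blocks, the first `n mod k` folds taking one extra case — 143
patients in 3 folds gives sizes 48/48/47. Folds are simple random by
default (stratified splitting by flag). `train_eval()` trains xgboost
(binary logistic objective) per fold at the reference hyperparameters —
15 rounds, learning rate 0.3, maximum depth 2, all other settings at
library defaults — predicts held-out folds at probability 0.5, and reports
per-fold confusion matrices (rows = true class, columns = predicted,
repair first), per-fold accuracy (TP+TN)/(TP+FN+FP+TN), their unweighted
mean (with pooled-prediction accuracy alongside, since the two differ when
fold sizes differ), and importance. Importance uses xgboost's **gain**
(configurable), normalized to percentages per fold;
`aggregate_importance()` superposes folds by elementwise sum and
renormalizes, with a stable sort so ties keep the declared feature order.

The natural baseline is `cutoff_classifier_cv()`: select the
Youden-optimal score cutoff on each training split and threshold the
held-out scores. On default synthetic cohorts of n = 600 the boosted
classifier out-predicts this baseline in ~19/20 seeded replicates and
ranks leaflet motion restriction among its top features essentially
always — the qualitative pattern expected when leaflet-quality lesions
carry decision signal beyond the summed score.

## Numerical and degenerate-input conventions

* Validation errors always name the offending field (and row, for tables);
  table validation collects row errors instead of failing fast.
* ROC construction refuses single-class labels; `auc_ci()` requires ≥ 100
  bootstrap replicates; correlation requires ≥ 3 complete pairs and
  nonzero variance in both scores.
* A single-class *training split* in cross-validation is an explicit error
  advising a re-seed or larger cohort, since accuracy would be undefined
  on the fold and xgboost would train a degenerate booster.
* All RNG consumption (cohort generation, fold splitting, bootstrap,
  xgboost) is seeded and restores the caller's RNG state.

## Problem sizes used by the shipped checks

The test suite exercises generator calibration at n = 50,000 (4 binomial
standard errors per parameter), concordance calibration at n = 10,000
(AUC within 0.75 ± 0.03), and the classifier comparisons on 20 replicate
cohorts of n = 600 — sizes at which the Monte-Carlo noise of each check is
comfortably below its decision margin while the whole suite stays quick to
run. The acceptance script recomputes the worked single-patient score
examples, which are exact.

## Known limitations

* The weight table is a clinical judgement, not a fitted model; the package
  treats it as configuration.
* Within-etiology feature independence underdisperses lesion co-occurrence
  (see above).
* The published fold accuracies, empirical AUC and score-technique
  correlation of the original cohort are functions of unavailable raw data;
  the package reproduces the *procedures* and the calibrated synthetic
  regime, not those exact numbers.
* No survival or time-to-event follow-up is modelled; the adverse-event
  label is a per-stratum Bernoulli.
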