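---
title: "Phenotyping oral chemesthesis sensitivity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping oral chemesthesis sensitivity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemsens)
```

## The problem

Chemesthesis is the chemically triggered somatosensory side of flavor —
the astringency of alum, the burn of capsaicin, the cooling of menthol —
carried by touch, pain and thermal receptors rather than by taste buds.
People differ widely in how intensely they perceive these stimuli, and
those differences plausibly shape food behavior the way taste sensitivity
does. `chemsens` implements a complete phenotyping pipeline for this kind
of data: panelists rate ascending concentration series of one prototypic
compound per modality on a 0–10 line scale, and the analysis turns those
ratings into ordered sensitivity groups, a composite sensitivity score,
and interaction models between modalities.

The pipeline has five computational stages, each exposed as ordinary
functions:

1. **Preprocessing** — completeness filtering per modality and removal of
   the water "zero" sample.
2. **Clustering** — agglomerative hierarchical clustering of each
   subject's five-concentration intensity profile, squared Euclidean
   distance with Ward's method, cut at *k* = 3, clusters relabeled in
   ascending intensity (1 = least sensitive … 3 = most sensitive).
3. **Scoring** — the Chemesthesis Sensitivity Score (CSS), the mean of
   the three modality cluster labels; with five taste modalities the same
   operator yields a Taste Sensitivity Score (TSS).
4. **Group statistics** — one-way MANOVA over the five-sample profile
   plus per-concentration Tukey HSD with compact letter displays.
5. **Interactions** — baseline-category multinomial logistic regression
   with forward/backward stepwise selection, Wald odds ratios, and a
   Pearson correlation matrix of groups and scores.

Because panel-study raw data are rarely public, the package also ships a
**synthetic cohort generator** whose defaults encode the published
summary statistics of a 205-subject study (per-cluster means, SDs and
sizes for all three modalities, and its 8/6/7 per-modality exclusion
counts). Every downstream stage is tested against cohorts from this
generator.

## Clustering conventions

Distances are squared Euclidean over the five concentration samples,
`d(i,j) = Σₛ (xᵢₛ − xⱼₛ)²`. Agglomeration follows Ward's criterion via the
Lance–Williams recurrence

```
d(k, i∪j) = [ (nᵢ+nₖ) d(k,i) + (nⱼ+nₖ) d(k,j) − nₖ d(i,j) ] / (nᵢ+nⱼ+nₖ),
```

applied directly to the squared distances — the classical "Ward on
squared distances" convention, under which merge heights equal twice the
increase in within-cluster sum of squares. `ward_agglomerate()` is this
package's own implementation; its heights and *k* = 3 partitions are
verified in the test suite against `stats::hclust(method = "ward.D")` on
more than a hundred random instances (agreement to 1e−6 or better).

Two deterministic conventions are pinned down where the mathematics is
silent:

* **Merge ties** are broken by the lexicographically smallest pair of
  cluster indices. Ties have measure zero for continuous ratings but the
  rule makes re-runs and row permutations reproducible.
* **Cluster ordering** uses the *grand mean* — the average of a cluster's
  five per-sample means — rather than any single sample. This matters:
  in the reference astringency solution the semi-sensitive cluster
  out-rates the most-sensitive cluster on the strongest sample (8.63 vs
  8.18), so ordering by the top concentration alone would mislabel the
  groups, while grand means (2.83 < 4.43 < 5.70) give the intended
  ordering. Remaining ties fall back to the strongest-sample mean, then
  the smaller raw label.

The number of clusters is a parameter defaulting to 3; the package makes
no attempt to automate cluster-count selection.

## The sensitivity score

With three modality labels in {1, 2, 3}, the mean takes exactly seven
values: 1.00, 1.33, 1.67, 2.00, 2.33, 2.67, 3.00 (`enumerate_lattice()`
verifies this by brute force over all 27 triples). Categories are
Hyposensitive (≤ 1.33), Semi-sensitive (1.67–2.33) and Hypersensitive
(≥ 2.67). Internally scores are kept as exact means; rounding to the
two-decimal lattice is **half-up** (4/3 → 1.33, 5/3 → 1.67), pinned
explicitly because IEEE round-half-even could differ across platforms on
exactly representable halves. Subjects missing any required modality
label are dropped from the composite score (with a warning) but stay in
all per-modality outputs. The TSS over five labels lands on the analogous
11-value lattice {1.0, 1.2, …, 3.0}; its category boundaries default to
hypo ≤ 1.4 < semi ≤ 2.4 < hyper, a configurable tertile-style convention.

## MANOVA and post hocs

`manova_one_way()` forms between- and within-group SSCP matrices
directly and reports all four classical statistics from the eigenvalues
of `W⁻¹B`: Pillai's trace, Wilks' Λ (= det W / det(W+B); Rao's F
approximation), Hotelling–Lawley trace, and Roy's largest root (whose F
is an upper bound). The multivariate effect size is reported as partial
η² = 1 − Λ^(1/s), s = min(g−1, p) — the convention used by the major
commercial packages, so published values of this form are directly
comparable. Box's M is computed as a diagnostic only: heterogeneous
covariances trigger a warning, never a refusal, since cluster solutions
routinely violate homogeneity by construction (the most sensitive cluster
is usually the most variable).

Per-concentration comparisons use the studentized-range test with the
Tukey–Kramer adjustment for unequal cluster sizes, at α = 0.05 by
default, and are summarized as compact letter displays built by
insertion–absorption; a round-trip property test confirms that letters
reconstruct the pairwise significance relation exactly. A cluster of one
subject is an error here (no within-group variance), and single-subject
confidence intervals in the summary tables are flagged as undefined.

## Interaction models

`fit_baseline_multinomial()` maximizes the baseline-category logit
likelihood by full Newton–Raphson (analytic gradient and block Hessian),
converging when the log-likelihood changes by < 1e−8, with a 200-iteration
cap. Conventions:

* The **reference outcome** is the largest cluster; each categorical
  predictor is likewise dummy-coded against its own largest cluster. The
  dependent-side convention is standard in this literature; extending it
  to predictors is this package's choice and is recorded here.
* **Stepwise selection** alternates a forward phase (add the candidate
  with the smallest likelihood-ratio p ≤ 0.05) and a backward phase
  (drop any term whose LR p has risen above 0.05) to a fixed point, 50
  steps maximum. Likelihood-ratio tests drive selection; Wald z tests
  only star individual odds ratios (* ≤ 0.05, ** ≤ 0.01, *** ≤ 0.001).
* **Odds ratios below 1** are re-expressed by the reciprocal rule: the
  factor belongs 1/OR times more likely to the reference group.
  Reciprocals are taken of unrounded estimates; reciprocals of *rounded*
  ORs can differ in the last digit, which explains occasional one-digit
  discrepancies between printed tables and prose in published reports.
* **Sparse cells**: an empty outcome × predictor-level cell makes the
  corresponding coefficient drift to ±∞; the fit warns and bounds such
  coefficients at ±30 on the log-odds scale rather than failing. True
  complete separation (a predictor that determines the outcome) is an
  error naming the predictor.
* Taste predictors enter **one taste modality at a time** alongside the
  chemesthesis base model, and taste outcomes take one chemesthetic
  predictor at a time — separate small models rather than one joint
  model, matching how such tables are built at N ≈ 190 to keep cells
  populated.

Correlations between groups and scores treat the 1–3 cluster labels as
numeric scores (ordinal-as-numeric, as is conventional for these
matrices) with listwise deletion.

## The synthetic cohort generator

The generator's job is to emulate the statistical structure the analysis
assumes, under the published study conditions:

* **Cohort**: 205 subjects; per-modality completeness 197/199/198; 196
  subjects complete for all three chemesthetic modalities; 189 complete
  for both chemesthesis and taste. The published counts constrain the
  missingness pattern only marginally; the shipped pattern (5 subjects
  missing everything, plus 4 subjects missing specific combinations) is
  one consistent choice and is configurable.
* **Memberships**: one standard-normal latent trait *z* per subject;
  each modality ranks subjects on `√ρ·z + √(1−ρ)·ε` and cuts the ranking
  into quota groups equal to the published cluster sizes. Quota cutting
  reproduces marginal sizes *exactly* for every seed — a property the
  acceptance checks rely on — while ρ tunes cross-modality association.
* **ρ calibration**: the published cross-modality signal is a CSS–TSS
  Pearson correlation of +0.56, measured on cluster labels estimated
  *from the data*. Reclustering attenuates the latent association, so ρ
  is calibrated through the full pipeline (generate → recluster → score
  → correlate), giving ρ = 0.43; on latent truth labels the same cohorts
  correlate somewhat higher. The calibration is a one-time design choice,
  not a fitted parameter.
* **Ratings**: given a cluster, the five concentration ratings are
  independent Gaussians with that cluster's published means and SDs,
  clipped to [0, 10]. Clipping (rather than truncated-normal resampling)
  mimics line-scale ceiling behavior; it shrinks extreme-cluster means
  slightly toward the interior, which is visible in, e.g., pungency's
  most-sensitive cluster (mean 8.75, SD 1.10 near the 10 bound). The
  published tables contain no within-subject covariance across
  concentrations, so none is modeled.
* **Zero samples** are Gaussian(0.3, 0.4) clipped, independent of
  cluster — they only exist to exercise the exclusion step, matching the
  published rationale that they were rated inconsistently and dropped.
* **Taste block**: the five taste modalities' per-cluster profiles are
  *synthetic stand-ins* (the companion taste study's table is not
  reproduced here); they have the same 3-group ascending structure but
  are not estimates of any real panel. Functions and files carrying them
  say `synthetic` in their names.

What the generator deliberately does **not** emulate: serving order and
carry-over/desensitization effects, rater scale-use bias, demographic
covariates, and any within-subject correlation across concentrations.
Passing tests therefore show that the analysis machinery is correct and
that the published summary structure is recoverable — not that real
panel data are this well behaved.

## Numerical and testing choices

* Seeds: one master integer seed; per-modality streams derive from it by
  a small polynomial string hash, so adding a modality never perturbs
  another modality's draws. All derived seeds stay below 2³¹.
* Cohorts regenerate byte-identically for a fixed configuration and
  seed; the pipeline is deterministic end to end.
* Reference-implementation equivalence (Ward linkage vs `stats::hclust`,
  MANOVA vs `summary.manova`, Tukey vs `TukeyHSD`, multinomial logits vs
  `nnet::multinom`) is tested on ~100 random instances with N ≤ 50 for
  clustering and N ≤ 400 for regression; multinomial parameter recovery
  uses n = 2000. Cluster-proportion recovery simulations average 20–50
  replicate cohorts of ~200 subjects; a full run of the suite takes
  well under a minute on one core.
* The simulate-and-recluster protocol has a small inherent bias: cluster
  boundaries estimated from overlapping Gaussian profiles misassign some
  subjects, so recovered shares sit 1–3 percentage points off the
  generating shares (e.g. the least-sensitive astringency share centers
  near 45% against a generating 46%). This is a property of the
  protocol, not a defect of the clustering, and the tolerances in the
  recovery tests reflect it.

## Limitations

The package takes *k* = 3 as given and implements no cluster-count
selection criterion. It fits no ordinal (proportional-odds) models, no
repeated-measures MANOVA, applies no multiple-testing correction across
the OR tables, and does no imputation — subjects with incomplete series
are excluded per modality, which is the only exclusion rule implemented.
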