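---
title: "Senescence scoring: method, design choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Senescence scoring: method, design choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senescore)
```

## The scoring model

Senescence involves the convergence of many pathways; no single marker
captures it. `senescore` treats senescence signalling as a directional
multi-marker readout: two curated signatures — 12 DNA damage-associated
(DAS) markers and 16 modified secretory senescence (mSS) markers — each
gene annotated with its expected expression direction in senescence
(most rise; MKI67, IGF1, IGF2 and WNT2 fall).

Given a genes × samples matrix of positive expression values from one
experiment, each gene is divided by its median across all arrays of that
experiment (`median_normalize()`). A marker *signals senescent* in a
sample when its normalized value lies strictly on its pro-senescence
side of 1. The sample's score for a signature is the percentage of the
signature's *expressed* (non-missing) markers signalling senescent
(`score_sample()`, `score_dataset()`).

The model's assumptions, made explicit:

- **Cohort relativity.** "Up" and "down" are relative to the cohort
  median, so scores are comparable only within the set of arrays
  normalized together. Comparing scores across experiments requires
  renormalizing the pooled matrix. A consequence worth remembering: if
  nearly every sample in a cohort is senescent, the median itself is
  senescent-like and scores compress toward 50.
- **Equal marker weighting.** Every expressed marker contributes one
  count; magnitudes beyond the median side are ignored. This is what
  makes the score invariant to per-gene monotone transforms (verified in
  the test suite with per-gene cubing and scaling), hence robust to
  probe-level calibration differences.
- **Missing = not expressed.** Markers missing in a sample drop out of
  that sample's denominator, following the "percentage of genes
  expressed" definition; no imputation is attempted.

## Tunable parameters

| Parameter | Where | Default | Rationale |
|---|---|---|---|
| `ties` | `score_sample()` | `"non-senescent"` | A value exactly at the cohort median carries no directional evidence; the strict reading is conservative. Configurable because the convention is a genuine choice. |
| `median_scope` | `score_dataset()` | `"filtered"` | Medians are per gene, so filtering to signature genes before or after normalizing gives identical marker ratios; both orders are exposed and tested equal. |
| `alpha`, `min_lines`, `adjust` | `screen_compounds()` | 0.05, 30, `"none"` | Raw p < 0.05 mirrors a plain regression screen; compounds tested on fewer than 30 lines are unreliable and skipped. BH correction is available but off by default so the raw-screen behaviour is the reference. |
| `min_leaf`, `cp` | `train_activity_tree()` | 5, 0 | CART with Gini impurity, grown fully subject to a minimum leaf size; resubstitution accuracy is the reported metric, cross-validation is available via `xval`. |
| `merge_threshold` | `cluster_samples()` | 0.01 | Width (on the similarity scale 1 − distance) within which branches near the dendrogram root count as one split; see below. |
| `deflection`, `noise_sd` | `generate_expression()` | 2, 0 | A two-fold deflection is a realistic strong marker response on linear-scale microarray intensities; zero default noise keeps planted-recovery tests sharp. |

GI50 values are consumed on whatever consistent scale the user supplies;
the packaged generator uses −log10(GI50 molar), the conventional potency
scale for 60-line tumour panels, with intercept 5 (10 µM).

## Numerical and algorithmic choices

- **Rank correlations** are implemented literally as rank-then-Pearson
  (`rank_within_group()`, `correlate_rankings()`), with average ranks for
  ties and a two-sided t-based p-value on n − 2 degrees of freedom,
  rather than being relabelled Spearman — this preserves the tie and
  p-value behaviour of a Pearson test applied to rankings. A permutation
  test would be the alternative; t-based was chosen as the standard
  default.
- **Clustering** uses distance 1 − Spearman ρ with average linkage on
  both axes. "First-level clusters" are the children of the root after
  collapsing near-ties: internal merges whose similarity is within
  `merge_threshold` of the root's are treated as the same split,
  implemented as a flat cut at (root height − threshold). Gene-axis
  groups are invariant to per-gene monotone transforms (ranks within a
  gene are preserved); sample-axis groups are invariant to global
  monotone transforms, but not to arbitrary per-gene ones, since a
  sample profile's internal ranking mixes genes.
- **Survival**: Kaplan–Meier per group, log-rank across groups, and a
  Cox model `group + age + sex` with the Efron tie approximation. The
  adjusted group p-value is a joint Wald test of the group coefficients,
  so it is well defined for more than two groups. Groups with zero
  events stay in the KM plot but are excluded from the Cox fit;
  constant adjustment covariates are dropped as inestimable.
- **OLS screen**: complete-case per compound; a constant score vector or
  fewer than 3 pairs is a degenerate regression and the compound is
  skipped with a report rather than silently classified.
- **Descriptors**: the historical 2D descriptor sets behind activity
  modelling are proprietary, so the package defines its own fixed list
  of 50 open-formula descriptors spanning the classic families
  (composition, Wiener/Harary/Zagreb/Platt/Balaban/Petitjean topology,
  Kier–Hall simple and valence chi, kappa shape, GCUT eigenvalues over
  formal charge, electronegativity and polarisability, fragment-additive
  TPSA and additive van der Waals surface/volume). This reproduces the
  method class, not bit-exact values from any particular software. TPSA
  uses hydrogen-count/bond-order fragment rules only; surface/volume
  terms are additive atomic spheres (hydrogens at 60 % weight) with no
  pairwise overlap correction. The physiological-pH preparation is
  deliberately minimal rule-based chemistry: largest-fragment selection,
  carboxylic acid deprotonation, non-amide amine protonation — no pKa
  model.
- **Split ties in the tree** follow the CART convention of the fitted
  threshold (strictly below goes left); training is deterministic given
  the data, so repeated fits predict identically.

## What the synthetic generators emulate

`generate_expression()` plants a known per-sample fraction of the 28
markers in the pro-senescence direction on a log-normal baseline
(meanlog 6, sdlog 1), deflecting the remaining markers the opposite way
so no marker sits at baseline. Two design details matter for sharp
validation:

- **Complementary pairing.** Samples whose planted fractions sum to 1
  receive complementary marker subsets. In a fully paired cohort every
  marker is pro-deflected in exactly half the samples, so each gene's
  cohort median falls strictly between the deflected levels and, at zero
  noise, every score equals 100 × its planted fraction *exactly*. This
  is what makes exact parameter-recovery tests possible despite the
  score being cohort-relative.
- **Balanced allocation and per-value jitter.** Unpaired samples are
  planted greedily onto the currently least-planted markers, and
  deflection magnitudes are jittered per value, so in odd or unbalanced
  cohorts the only loss mechanism is a cohort median landing on or
  beyond a sample's own value — the deviation is exactly the miscounted
  genes, which the test suite verifies as an identity.

`generate_gi50()` plants linear score dependence in a chosen number of
compounds with Gaussian residuals (`noise_sd_for_power()` calibrates the
residual SD to a target slope-test power from the exact non-central t
distribution). `generate_survival()` uses exponential event times with a
planted group hazard ratio and independent exponential censoring
calibrated to a target censored fraction. `generate_molecule_set()`
emits paths, rings, stars and singly-branched trees of 4–8 heavy atoms
with valence-safe N/O/S decoration, carrying byte-stable SMILES.

None of the generators attempt platform effects, batch effects,
probe-level noise structure, dose–response shapes or realistic
chemistry. Passing tests therefore demonstrate that the implementation
computes the intended quantities and recovers planted structure under
clean conditions — not that the signatures themselves generalise to any
particular real cohort.

## Problem sizes used in validation

The test suite validates scoring against a brute-force transliteration
on 1,000 random 6-gene × 5-sample matrices; drug-screen calibration on a
null panel of 1,000 compounds × 60 lines (expecting a 5 % ± 1.5 %
significant fraction) and power on 100 compounds with 10 planted at
slope −3 under 80 %-power noise (expecting ≥ 70 % recovered into the
correct unique-significant set); descriptor oracles on all paths, stars
and cycles up to 8 atoms; enrichment nulls on 100 random subsets of 200
from 1,000 compounds; and survival recovery at a planted hazard ratio of
3 with 100 subjects per group (Cox coefficient within 2 SE of log 3).

## Known limitations

- Scores are cohort-relative; absolute cross-study comparison is
  undefined without joint normalization.
- The tie convention (median value = non-senescent) can matter on
  discrete or heavily rounded data; it is configurable and documented.
- Reproducing archived microarray results depends on the probe-to-gene
  mapping, which upstream descriptions leave unstated; `collapse_probes()`
  offers median and max-mean rules, and results can be sensitive to the
  choice.
- The packaged mesothelioma gene-group table reproduces its published
  source exactly, including two markers listed in both groups (CXCR2 and
  EEF1A1); rows carry a `duplicated_across_groups` flag so users can
  decide how to handle them.
- The activity model's accuracy is reported on the training set
  (resubstitution), which flatters it; use `xval` for honest estimates.
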