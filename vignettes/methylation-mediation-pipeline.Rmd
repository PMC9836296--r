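---
title: "Candidate-gene methylation mediation and moderation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-gene methylation mediation and moderation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpgmediate)
```

## The analysis problem

`cpgmediate` implements a candidate-gene DNA-methylation pipeline for
cohorts in which a continuous childhood-adversity exposure (a CTQ-SF total,
range 25–125), a continuous depressive-symptom outcome (a BDI-II total,
range 0–63) and percent methylation at a panel of EpiTYPER-style CpG units
are measured on the same participants. Two complementary questions are
asked of every unit *j* with methylation $M_j$:

* **Mediation** — does methylation transmit part of the exposure effect?
  Two linear models are fitted,
  $M_j = i_1 + a X + \gamma' Z + \varepsilon$ and
  $Y = i_2 + c' X + b M_j + \delta' Z + \eta$
  (with covariates $Z$), and the indirect effect is the product $a \cdot b$
  (the ACME), the direct effect is $c'$, the total effect is $ab + c'$, and
  the proportion mediated is $ab / (ab + c')$.
* **Moderation** — does methylation change the strength of the exposure
  effect? One model is fitted on mean-centred predictors,
  $Y = i + \beta_X X_c + \beta_M M_{j,c} + \omega X_c M_{j,c} + \delta' Z + \eta$,
  and the conditional exposure slope at moderator level $m$ is
  $\beta_X + \omega\,(m - \bar M_j)$, reported at $\bar M_j \pm 1\,SD$
  (simple slopes).

Because per-unit effects in candidate-gene panels are small, both analyses
are aggregated over units with two cumulative indices: a summed mediator
index over the screening-gated units, and a tertile-coded methylation risk
score over the moderating units.

## Pipeline order and screening gates

`run_pipeline()` executes the stages in a fixed order: winsorization of the
two questionnaire totals; unit-level quality control; perfect-duplicate
collapse; region grouping; data-driven confounder selection; unadjusted and
covariate-adjusted per-unit screens of methylation on the exposure and on
the outcome with Benjamini–Hochberg correction; mediation restricted to
units significant on *both* screens (this gating keeps the number of
mediation tests, and hence false positives, down); per-unit moderation; the
risk score over significant interactions; and cumulative moderation. Every
stage logs its row counts, and the identity
`units_in = removed_missingness + removed_zero_inflated + merged_away +
retained` is asserted on every run.

## Preprocessing rules

* **Winsorization** (`winsorize_scores`). Bounds are $\bar v \pm k\,SD$
  with $k = 3$, moments computed once on the input. The default
  `"observed"` variant replaces an out-of-bound score with the most extreme
  observation still inside the bound; the `"boundary"` variant substitutes
  the bound itself. Both are exposed because the two readings cannot be
  distinguished from summary statistics alone: reported post-winsorization
  maxima in this literature sometimes exceed $\bar v + 3 SD$ computed from
  the printed moments, which is only consistent with moments taken before
  winsorization or with the observed-value variant. Winsorization is
  applied to the questionnaire totals only; methylation extremes are
  handled by the hard [0, 100] domain check.
* **Quality control** (`qc_filter_units`). Units with more than 20%
  missing values are removed first; among survivors, units whose non-missing
  values are more than 80% exactly zero are removed. The order is fixed, so
  a unit failing both is reported under missingness.
* **Duplicate collapse** (`collapse_perfect_duplicates`). Within a gene,
  units with pairwise Pearson $r \ge 1 - 10^{-9}$ (pairwise-complete) are
  merged transitively; the tolerance exists because the floating-point
  correlation of exact duplicates can miss 1.0 by a few ulps. The merged
  value is the per-participant mean — symmetric in the members, and the
  same convention used for regions. Pairs with fewer than three complete
  observations are skipped with a warning rather than guessed.
* **Region grouping** (`group_regions`). Within a gene, units sorted by
  first coordinate are chained when adjacent units are within 500 bp
  (nearest coordinates) *and* correlate at $r \ge 0.50$; regions are
  maximal chains. Chaining was chosen over all-pairs cliques because
  promoter tilings are naturally sequential; a clique rule would mostly
  split long tiles at their weakest internal pair while leaving short
  regions unchanged. Region values are available-case means. Region-level
  tests form their own FDR family and are never mixed with unit-level
  tests.

## Confounder selection and multiplicity

A candidate covariate (age, drug use, smoking, alcohol, BMI) is retained
when a simple-regression association at $p < 0.10$ exists with the
exposure, the outcome, or at least one methylation unit; retained
covariates enter every adjusted model. Note that with hundreds of units the
unit clause will retain a null covariate quite often — the rule is
deliberately inclusive, since the cost of adjusting for an irrelevant
covariate is small relative to residual confounding.

FDR correction uses step-up Benjamini–Hochberg within one family per
screen (exposure-side units, outcome-side units, moderation interactions),
matching per-analysis reporting; a global family across screens is a
stricter alternative but changes the meaning of the threshold and is not
the default. Under a global null, BH leaves all tests unrejected with
probability exactly $1 - q$ (Simes), which the test suite checks at
$q = 0.20$.

## The mediation estimator

`fit_mediation()` uses quasi-Bayesian Monte-Carlo intervals: `n_sims`
(default 1,000) coefficient vectors are drawn from the multivariate-normal
sampling distribution of each fitted model's estimates, and per draw the
indirect, direct and total effects are recomputed. Percentile 95% intervals
and a two-sided Monte-Carlo p-value are taken from the draws; point
estimates come from the fitted coefficients, so the identity
$\widehat{ACME} = \hat a \hat b$ holds to machine precision and
$total = ACME + ADE$ exactly (the outcome model carries no
exposure–mediator interaction). Coefficient simulation was preferred over
case-resampling because it is deterministic by seed and orders of magnitude
faster at equal draw counts; a nonparametric bootstrap mode
(`method = "bootstrap"`) is provided for sensitivity. Draws with
$|total| < 10^{-8}$ are excluded from the proportion-mediated interval and
counted in the run summary, since the ratio is unstable near a zero total
effect.

The cumulative mediator index defaults to a **sign-aligned** sum,
$\sum_j s_j M_j$ with $s_j$ the sign of unit *j*'s exposure association. A
literal sum of units whose exposure associations have opposite signs
partially cancels, which can leave the index uncorrelated with the exposure
even when every component mediates; aligning signs preserves each unit's
contribution. The literal mode is implemented (`index_mode = "literal"`)
and the choice is recorded in the run summary.

## The moderation estimator and risk score

Exposure and moderator are centred on the analysis sample and the product
is formed after centring, so the interaction coefficient is
centring-invariant (checked to $10^{-10}$) and the exposure main effect is
the slope at the average moderator level. Simple-slope standard errors come
from the coefficient covariance,
$SE(m)^2 = V_{XX} + m_c^2 V_{\omega\omega} + 2 m_c V_{X\omega}$, which the
tests verify against a re-centring refit oracle.

The risk score codes each moderating unit −1/0/+1 by empirical tertile
(quantiles at 1/3 and 2/3 with linear interpolation; ties go to the lower
tertile, making the coding deterministic, order-independent and invariant
to monotone transformations of a unit's values), oriented so that a
positive interaction sign puts the top tertile at +1. Scores sum over units
with available values; a missing unit contributes 0 and is counted.
Membership uses adjusted-model interaction significance at $p < 0.05$ by
default (with an unadjusted option). Cumulative moderation refits the
interaction model with the score as moderator and reports conditional
slopes at the mean score of each score tertile ("three equal groups" of
the score — tertiles of predicted methylation would be an alternative
reading, but the score is the quantity the analysis constructs).
Johnson–Neyman regions are deliberately out of scope; simple slopes are
the reported decomposition.

## What the synthetic generator emulates — and what it does not

`simulation_truth()` defaults to the study conditions: 156 participants, a
191-unit panel over nine stress-axis candidate genes (COMT, FKBP5, IL6,
IL10, MAOA, NR3C1, OXTR, SLC6A3, SLC6A4) with GRCh37 promoter coordinates;
exposure drawn as $25 + \Gamma$ with the gamma matched to mean 37.43 and SD
11.04 (CTQ totals are right-skewed with a hard floor); outcome residuals
from a centred gamma (shape 2) so that the BDI floor at 0 clips only a few
percent of the sample — floor heaping is a real feature of depression
inventories; unit baselines spread over 10–70% methylation with residual SD
3 (per-unit exposure slopes of ~0.04 %/point then yield the 2–5% explained
variance typical of candidate-gene screens); a direct effect of 0.25 BDI
points per CTQ point; and age/drug effects on a subset of units and on the
outcome. Structural slopes `a`, `b`, `omega` are zero by default and are
planted per analysis; duplicates, latent-factor region blocks and MCAR
missingness are injected per explicit maps.

The generator does **not** emulate: cell-type composition and its
confounding, batch/plate effects, assay heteroscedasticity across the
methylation range, non-MCAR missingness, or integer questionnaire scoring
(a rounding toggle exists but is off, since the estimators target OLS).
Passing tests therefore demonstrate correctness of the estimators and the
pipeline logic under the stated generative model — not robustness of the
scientific conclusions to the artefacts listed above.

## Numerical choices and degenerate inputs

* Complete-case analysis per model; per-row `n` is reported because
  missingness varies by unit. No imputation.
* Two-sided t-tests throughout; `fdr_adjust` validates its domain and
  preserves input order.
* Zero-variance responses and aliased designs raise typed
  `collinear_design` errors; screens record these per row instead of
  failing the run.
* Winsorization with zero SD is a warned no-op; fewer than three values is
  an error.
* All pipeline randomness derives from one seed through deterministic
  per-stage child seeds (a string-hash fold), so adding a stage never
  perturbs the draws of earlier stages, and identical seeds give
  byte-identical run directories.

## Problem sizes used by the test suite

Parameter recovery uses 200 replicates at $n = 500$ on single-gene panels
with clipping-free truths (Gaussian residuals, raised outcome intercept,
no missingness), so that OLS unbiasedness holds exactly and three
Monte-Carlo standard errors form a sharp band. Error calibration uses 500
replicates at $n = 156$ with an 8-unit null panel, pooling roughly 4,000
unit-level tests so the binomial standard error (≈0.003) makes the
[0.03, 0.07] acceptance band on the type-I error informative. Determinism
is checked on the full 156 × 191 default cohort.

## Known limitations

The mediation intervals assume the normal approximation to the coefficient
sampling distribution; at very small n the bootstrap mode is preferable.
Sequential-ignorability sensitivity analysis, multiple-mediator
path-specific effects, robust/sandwich errors and genomic-control style
inflation diagnostics are out of scope. The confounder rule's unit clause
is anti-conservative by design (see above). Region chaining can join two
units correlated only through a shared neighbour; the all-pairs reading
would prevent this at the cost of splitting long promoter tiles.
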