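---
title: "Methods: group contrasts and PLS phenotyping of CRP in stratified depression cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: group contrasts and PLS phenotyping of CRP in stratified depression cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crpls)
```

## The analysis this package implements

High-sensitivity C-reactive protein (CRP, mg/L) is a peripheral inflammation
marker repeatedly associated with major depressive disorder, and more strongly
with treatment-resistant illness. `crpls` implements, as tested and
reproducible code, the statistical pipeline of a four-group case–control
design — treatment-resistant, treatment-responsive and untreated depression
versus healthy volunteers (default sizes 102/48/48/54) — with two arms:

1. **Planned group contrasts** of CRP: non-parametric tests on the raw scale,
   Student's *t*-tests after log10 transformation, *t*-tests and Cohen's *d*
   on BMI-corrected CRP, and likelihood-ratio tests of the proportion above
   the clinically elevated 3 mg/L threshold.
2. **An exploratory multivariate arm**: univariate-response partial least
   squares (PLS) regression of CRP on 139 predictors (gender, age, BMI,
   education and 135 questionnaire items from HAM-D, CFS, BDI, CTQ, STAI and
   SHAPS), with a two-step variable-selection procedure, leave-one-out PRESS
   factor selection, bootstrap coefficient inference and a resampling null
   for the percentage of variance explained.

Because no participant-level data are distributed, the package ships a
seeded synthetic-cohort generator that reproduces the statistical structure
the analyses assume; every downstream stage is exercised against it.

## The synthetic cohort generator

`generate_cohort()` simulates one participant table from a latent-factor
model. Its defaults are the study conditions and are not meant to be tuned
per analysis; `cohort_config()` exposes them for sensitivity studies.

**Latent structure.** Each participant carries three latent variables:

* `S`, a *group-severity* factor shared by all 135 questionnaire items. Its
  group means are chosen so that HAM-D totals respect the eligibility
  thresholds (resistant > 13, untreated > 17, responsive and healthy < 7,
  items scored 0–4). The thresholds are enforced exactly by rejection
  sampling (bounded by `max_attempts`), which is equivalent to sampling the
  truncated distribution.
* `F1`, an *inflamed severity* factor. Twelve designated items (five HAM-D
  vegetative/sleep items, three BDI work/sleep/fatigue items, two CTQ
  childhood-adversity items, two STAI state-anxiety items) load on it; its
  group means decrease from resistant through untreated and responsive to
  healthy, which is what makes first-component scores rank the groups.
  Within groups `F1` is right-skewed (a standardised skew-normal): the upper
  tail of CRP belongs to genuinely inflamed participants whose symptom items
  are elevated, not to arbitrary outliers. We first tried a gamma-distributed
  factor here and rejected it: exponentiating an exponential-tailed factor
  produces a power-law CRP tail whose raw-scale variance is dominated by one
  or two points, destroying every correlation the analysis is supposed to
  find.
* `F2`, a second, CRP-negative factor loading the CTQ/STAI items, giving the
  planted structure its two-dimensional character.

**CRP model.** On the log10 scale,

\[
\log_{10}\mathrm{CRP} = a\,z_{\mathrm{BMI}} + b_1 F_1 - b_2 F_2 +
\varepsilon + \text{contamination},
\]

where \(z_{\mathrm{BMI}}\) is standardised log10 BMI, \(\varepsilon\) is
Gaussian, and the contamination term is a rare (≈0.2%) additional elevation
of about one log10 unit whose probability is tilted toward high within-group
`F1` (an acutely inflamed fringe). The constants were fixed once, by
simulation, so that at the default configuration the raw-scale moment
skewness of CRP sits near its target 5.08, the Spearman correlation between
BMI and log10 CRP near 0.56, and the BMI-corrected group effect sizes near
Cohen's *d* = 0.47/0.29/0.18 (resistant/responsive/untreated versus healthy,
scaled proportionally by `effect_size_d`). Because the HAM-D eligibility
rejection conditions on `F1` through the informative HAM-D items, it biases
the realised effect sizes; a simulation-measured correction is subtracted
when solving the `F2` group means, and the correction scales with the
F1-loading mass on HAM-D items so that it vanishes in null mode.

**Items.** Item latents are unit-variance Gaussians
(severity + factor loadings + idiosyncratic noise) discretised through fixed
cumulative cut-points per instrument (HAM-D 0–4, CFS/BDI 0–3, CTQ 1–5,
STAI/SHAPS 1–4). BMI is a shifted lognormal (skewness ≈ 1), ages are uniform
on 25–50 years, and missingness is applied last and completely at random: a
2% item rate plus exactly 12 missing BMI values, which reproduces the
degrees-of-freedom drop of the BMI-corrected contrasts (250 → 238/236).

**What the generator does not emulate.** Informative missingness,
longitudinal structure, site effects, medication classes (only a
failed-treatment count is carried), and item-specific response styles.
Passing tests therefore demonstrate that the pipeline recovers structure of
this planted form at these sample sizes — not that it would behave
identically on any real cohort.

**Null mode.** Setting `effect_size_d = 0` and empty `latent_loadings`
removes every planted CRP–predictor and CRP–group link while preserving the
eligibility thresholds; the test suite uses it to verify that each test in
the contrast battery rejects at its nominal level.

## Conventions in the contrast battery

* Raw-scale comparisons use the Wilcoxon–Mann–Whitney rank-sum test with
  midranks; the reported `Z` uses the tie-corrected normal approximation
  without continuity correction, with exact enumeration of the p-value when
  the pooled sample size is at most 10 and untied.
* Log10 and BMI-corrected comparisons use Student's (equal-variance)
  *t*-tests. Post hoc pairwise contrasts are Fisher-LSD style: they use the
  pooled within-group mean square of the one-way ANOVA across *all* groups,
  so their degrees of freedom are `N - k` (248 for log10 CRP among 252
  participants in 4 groups; 236 after dropping the 12 missing-BMI rows).
  That is what makes the battery's df arithmetic reproduce the design's.
* BMI correction regresses log10 CRP on log10 BMI by ordinary least squares
  over complete pairs and analyses the residuals; rows with missing BMI are
  excluded (complete-case), never imputed.
* The clinically elevated threshold is strict (`> 3` mg/L) and the
  contingency tests are likelihood-ratio G-tests,
  \(G^2 = 2\sum O\log(O/E)\) over non-zero cells.
* Pairwise post hoc tests are only emitted when the corresponding omnibus
  test (Kruskal–Wallis, ANOVA, or the 2×4 G-test) is significant at
  `alpha = 0.05`; no multiple-testing correction is applied. Both choices
  are recorded in the result table's metadata, and `gate_posthoc = FALSE`
  disables the gating for calibration studies.

## The PLS engine

For a univariate response the NIPALS inner iteration converges in a single
step, so each component is computed in closed form: after autoscaling X and
y (mean 0, SD 1, denominator *n* − 1; constant columns are zeroed and
flagged), component *a* takes the unit-norm weight vector
\(w_a \propto X_{a-1}' f_{a-1}\), score \(t_a = X_{a-1} w_a\), X-loading
\(p_a = X_{a-1}'t_a / t_a't_a\) and y-loading
\(q_a = f_{a-1}'t_a / t_a't_a\), then deflates both X and the y residual by
the rank-one fit. Components are oriented so the largest-magnitude weight
entry is positive — component signs are otherwise arbitrary, and predictions
and regression coefficients are invariant to them. Extraction halts early
when the residual carries no further variance (tolerance 1e−12 on the weight
norm and score sum of squares), returning the achieved number of components
with a warning.

Standardised coefficients are \(B = W(P'W)^{-1}q\); per-component X- and
Y-variance fractions come from the deflation sums of squares relative to the
total centred sums of squares, so they are non-negative and sum to at most 1.
Variable importance in projection is

\[
\mathrm{VIP}_j = \sqrt{p \, \frac{\sum_a \mathrm{SSY}_a \, w_{ja}^2}
                              {\sum_a \mathrm{SSY}_a}},
\]

with \(\mathrm{SSY}_a\) the Y variance explained by component *a*; the mean
of VIP² is exactly 1 for every fit, which the suite asserts to 1e−10.

**Cross-validation.** `loo_press()` re-estimates the entire model — mean
imputation of missing predictor entries, autoscaling, and the NIPALS
extraction — inside every leave-one-out fold (no leakage; fold-wise constant
columns fall under the autoscale degenerate policy). PRESS is accumulated on
the raw response scale and `choose_components()` takes the plain minimum,
breaking ties toward the smaller factor count. Two points were genuinely
open and are decided here: imputation is nested within cross-validation
rather than applied once up front, and factor counts are chosen by the plain
PRESS minimum (the van der Voet randomisation test offered by some
commercial implementations is not implemented).

## Two-step selection and inference

`run_pls_workflow()` chains the stages: initial fit of all predictors at the
PRESS-selected factor count; a screen that **discards** a predictor only when
VIP < 0.8 *and* |standardised coefficient| < 0.05 (the conjunction — an
`"or"` rule is available behind a flag); percentile bootstrap confidence
intervals (default 1000 row resamples, 95%) for the standardised coefficients
of the screened set, excluding predictors whose interval includes zero; a
final refit of the survivors with fresh PRESS selection; a resampling null
for the percentage of X and Y variance explained; and per-group component
score summaries with one-way ANOVA. An empty set after either step is
reported as "no significant multivariate structure", not an error.

Decisions worth stating:

* The factor count is held fixed across bootstrap replicates and null
  iterations (re-selection per replicate would confound coefficient
  variability with model-order variability and multiply the cost).
* Because the deterministic orientation rule pins component signs and the
  coefficients are sign-invariant, bootstrap replicates need no further
  alignment before aggregation; replicates whose rank collapses below the
  requested factor count are skipped and counted, with more than 10% skips
  an error.
* The null decouples y from X either by permuting y (default: both marginals
  preserved exactly) or by resampling y with replacement; both
  interpretations of a resampling null are implemented and the mode is
  recorded in every report. Empirical p-values use the add-one rule
  \((1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(n_{\mathrm{iter}} + 1)\),
  so they are never zero.
* All seeds, thresholds, modes and counts are carried in the report, and
  `workflow_report_json()` serialises them; two runs with the same inputs
  and seeds are bit-identical.

**A caution on the procedure itself.** Our simulations show that the screen
and the bootstrap reuse the same sample: predictors that pass the screen
because sampling noise inflated their importance tend to keep confidence
intervals away from zero under row resampling, so the second step removes
far fewer noise predictors than a fresh-data analysis would, and the extra
survivors in turn inflate the PRESS-selected factor count of the final
model. With 139 predictors, 252 participants and a response this
heavy-tailed, the final variable set should be read as enriched for signal
rather than as a controlled-error selection. This is a property of the
two-step heuristic, faithfully implemented, not of this implementation.

## Numerical and testing notes

Degenerate inputs have explicit policies rather than NaNs: constant columns
are zeroed and flagged by `autoscale()`; a numerically-zero within-group
mean square yields F = ∞, p = 0 with a note; an all-one-sided threshold
table yields G² = 0 with a note; all-tied rank data are an error. Classed
conditions (`crpls_config_error`, `crpls_schema_error`,
`crpls_degenerate_error`) map to distinct exit codes in the command-line
pipeline (2/3/4).

The test suite checks the engine against independent oracles — an
eigendecomposition-based PLS, a brute-force per-fold PRESS double loop,
closed-form least squares, and the OLS limit at full rank — and runs
property checks (score orthogonality, VIP normalisation, screening
monotonicity, bootstrap coverage, type-I calibration of the null tests and
of the whole contrast battery in null mode). Stochastic checks use fixed
seeds and problem sizes chosen once: 100 random instances (n ≤ 30, p ≤ 10)
for oracle equivalence, 20 default-sized cohorts for generator calibration
and selection recovery, 200 replicates at 99 null iterations for type-I
calibration; simultaneous binomial checks across the eight battery tests use
Bonferroni-adjusted binomial bounds so the family-wise level matches the
per-test intent.
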