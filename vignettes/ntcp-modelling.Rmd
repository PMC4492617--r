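---
title: "Building NTCP models for symptomatic radiation pneumonitis"
author: "srpNTCP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building NTCP models for symptomatic radiation pneumonitis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srpNTCP)
```

## The problem

Symptomatic radiation pneumonitis (SRP) is the most common pulmonary
complication of breast irradiation. Its risk depends jointly on how much of
the ipsilateral lung is exposed — summarized by dose–volume histogram (DVH)
metrics such as the relative volume receiving at least 20 Gy (IV20) — and on
patient-level factors such as age and body-mass index. `srpNTCP` implements
a complete normal tissue complication probability (NTCP) model-building
chain for a binary SRP endpoint:

1. reduce each patient's cumulative ipsilateral-lung DVH to 19 dosimetric
   factors (mean lung dose, IV5–IV50 in %, AIV5–AIV50 in cc);
2. derive the SRP endpoint from CT density-change and symptom grades;
3. rank 31 candidate factors (19 dosimetric + 12 clinical) with an
   L1-penalized logistic regression path;
4. choose the number of factors by discrimination (AUC) subject to
   calibration (Hosmer–Lemeshow);
5. refit the chosen model unpenalized, report odds ratios and a performance
   battery; and
6. fit a univariate dose–response curve in IV20 (or AIV20) and invert it to
   tolerance volumes TV50 and TV20 that can be used as planning constraints.

## The model

The NTCP model is logistic:

$$\mathrm{NTCP} = \frac{1}{1 + e^{-S}}, \qquad
S = \beta_0 + \sum_i \beta_i x_i,$$

where the $x_i$ are the selected risk factors in their natural units (%,
years, kg/m², indicator levels). The reference five-factor model shipped
with the package (`reference_srp_model()`) uses IV20, radiation energy
(reference 6 MV), age, BMI and T stage (reference T0/T1), with
$\beta_0 = -6.868$.

### The endpoint

A patient is an SRP case iff the CT density-change grade is $\ge 1$ **and**
the symptom grade is $\ge 1$. The conjunction is forced by the arithmetic of
the reference cohort: 45 patients had density changes, 43 had symptoms, but
only 31 met the endpoint — consistent only with an intersection rule
(`derive_srp()`).

### Variable selection

Selection minimizes the penalized logistic objective
$-\tfrac1n \ell(\beta_0, \beta) + \lambda \lVert\beta\rVert_1$ with an
unpenalized intercept, on columns standardized to zero mean and unit
(population) variance. The solver is cyclic coordinate descent with
soft-thresholding (in compiled code): each coordinate takes a
soft-thresholded Newton step using the exact one-dimensional curvature,
safeguarded so that a step is only accepted if the penalized objective does
not increase (otherwise the step from the global curvature bound
$p(1-p) \le 1/4$ is taken, which decreases the objective by construction).
The recorded objective sequence is therefore non-increasing, and at
convergence (maximum coefficient change below $10^{-7}$ per sweep) the KKT
conditions hold to high precision; unit tests verify both, plus agreement
with glmnet to ~$10^{-12}$ and with an independent proximal-gradient solver
to $10^{-6}$ in objective value.

The path runs over 100 log-spaced penalties from the data-derived
$\lambda_{\max}$ (every penalized coefficient exactly zero) down to
$10^{-3}\lambda_{\max}$, with warm starts. Factors are **ranked by entry
order**: the penalty at which a factor first becomes nonzero, largest first.
A multi-level factor (Energy, T stage, N stage) is grouped over its
indicator columns and enters with its first-entering indicator; this lets
the ranking speak of "Energy" while the fitted model reports per-level
coefficients. Ties at a grid point are broken by the absolute standardized
coefficient at the cross-validated penalty, then by candidate-list order.
The penalty itself is tuned by stratified 10-fold cross-validation on
out-of-fold binomial deviance with a mandatory seed; the reference analysis
software's exact cross-validation procedure is not documented, so a
conventional, fully specified default was fixed here.

### Model size

For each $k$, the top-$k$ ranked factors are refit **unpenalized**
(maximum likelihood via IRLS) and scored: AUC with a Hanley–McNeil 95% CI,
Nagelkerke $R^2$, the omnibus likelihood-ratio $p$, the Hosmer–Lemeshow
$p$ (deciles of risk, ties share a group, $\chi^2$ with $g-2$ df) and the
Brier score. The chosen size maximizes AUC rounded to two decimals among
sizes with Hosmer–Lemeshow $p \ge 0.05$, preferring the smaller size on
ties: a factor that improves apparent discrimination while destroying
calibration is rejected. LASSO is selection-only; all reported coefficients,
odds ratios ($e^\beta$ with Wald 95% intervals $e^{\beta \pm 1.96\,SE}$) and
performance numbers come from the unpenalized refit. The Wald form is
assumed for intervals; it is the default of the statistical software used
for the reference analysis.

### Dose–response inversion

The univariate curve $\mathrm{NTCP}(v) = \mathrm{logit}^{-1}(b_0 + b_1 v)$
in IV20 (%) or AIV20 (cc) is inverted in closed form:
$TV_p = (\mathrm{logit}(p) - b_0)/b_1$, defined only for $b_1 > 0$. TV50 and
TV20 are reported, and `dose_response_from_tolerances()` reconstructs the
unique logistic curve through two published (volume, probability) pairs —
useful because reference analyses print tolerance volumes, not coefficients.
The forward curve and the inversion are exact mutual inverses (tested to
$10^{-9}$). Per-patient compliance with planning constraints (default
IV20 < 37%, AIV20 < 310 cc, the published limits targeting <20% SRP
incidence) uses a strict "<": a value exactly at the limit is a failure.

## The synthetic cohort generator

No patient-level data are distributed with the reference analysis, so the
generator (`generate_cohort()`) emulates the study's statistical structure
and every pipeline stage is exercised against a known truth:

* **Clinical factors** are drawn independently from published marginals:
  truncated normals for age (mean 54.6, range 35–92), BMI (24.6,
  17.3–40.3), lung depth and total depth; published frequencies for site,
  chemotherapy, energy (3/13/77 of 93), IMN, SCF, surgery, T and N stage.
  The true joint distribution is unknown; independence is an explicit
  simplification.
* **Dosimetric factors**: the nine IV values are drawn from per-threshold
  truncated normals (published medians and ranges) coupled by a latent
  Gaussian factor at rank correlation 0.8, then made monotone by a running
  minimum across thresholds. Thresholds up to 20 Gy share IV20's lower
  bound so the monotone pass cannot push IV20 outside its published range
  (the published per-column ranges are marginal extremes and are jointly
  unsatisfiable under monotonicity, e.g. the IV10 minimum exceeds the IV5
  minimum). Each patient's DVH is the piecewise-linear cumulative curve
  through those IV knots, falling to zero at 55 Gy (prescription 50.4 Gy
  plus scatter tail): it reproduces the sampled IVs exactly, its mean dose
  is the closed-form trapezoid, and AIV = IV × total volume / 100 by
  construction. A smooth low-parameter curve family was deliberately *not*
  used: with all metrics driven by one or two shape parameters the IV
  thresholds become ~0.99 correlated, which neither matches the observed
  structure (IV20 correlates strongly but not perfectly with MLD and its
  neighbours) nor leaves variable selection a well-posed problem.
* **Outcomes** are Bernoulli draws from a configurable generating logistic
  model; the default is the published five-factor model. Grades are then
  constructed so `derive_srp()` reproduces the drawn event exactly, with
  grade patterns mixed in the published conditional proportions.
* Everything is a pure function of the seed; fixtures written by
  `write_fixture()` are byte-identical across regenerations.

What passing tests on this generator do **not** show: robustness to
correlated clinical factors, to missing data (the pipeline is
complete-case by design), to DVHs whose shape departs from a monotone
interpolant of nine knots, or to model misspecification of the outcome —
real cohorts guarantee none of these.

### The recovery scenario

The parameter-recovery simulations use a documented 5-active-of-31 truth
(`recovery_true_model()`): IV20 +0.15 per %, age +0.09 per year, BMI −0.20
per kg/m², chemotherapy +1.4, SCF +1.5, intercept −8.2 (prevalence ≈ 1/3).
These are moderate-to-strong standardized effects (≈0.7–1.4 SD of the
linear predictor each), chosen once so the active set is identifiable at
n = 500. The published model itself is not a useful recovery target at that
size: its energy factor has a 3% reference level and its age/BMI effects
are ≈0.4 SD, well below what top-5 rank recovery against 26 competitors can
resolve.

## Numerical choices and degenerate inputs

* Coordinate descent: coefficient-change tolerance $10^{-7}$; weights
  floored at $10^{-6}$ in the IRLS approximation; step-halving safeguard on
  the true penalized objective. Iteration also stops once an outer step
  lowers the objective by less than $10^{-11}$: near-degenerate fits (e.g.
  quasi-separated data at tiny penalties) can otherwise shuffle weight
  among strongly correlated columns indefinitely with the objective already
  flat.
* Unpenalized fits: `stats::glm.fit` (IRLS); separation is detected as any
  standardized coefficient exceeding 50 and raised as a dedicated error
  condition (`srp_separation_error`) — the model-size scan records such
  sizes as non-converged and skips them with a warning.
* Hosmer–Lemeshow: groups with zero expected events (or non-events) are
  merged into a neighbour, reducing the degrees of freedom; fewer than
  three groups (e.g. constant scores) makes the test degenerate and the
  p-value `NA`, with a warning.
* DVH evaluation between bin edges uses linear interpolation; at 0.01 Gy
  export resolution the choice is numerically immaterial but is fixed for
  determinism. Volumes at doses beyond the last edge are 0. The mean dose
  places each differential bin's volume at the bin midpoint, plus a point
  mass at the last edge for any residual volume.
* Zero-variance factor columns (e.g. a rare categorical level absent from a
  small cohort) are dropped by the pipeline with a warning before
  selection; inside cross-validation folds a level absent from a training
  split standardizes to an all-zero column and simply cannot be selected in
  that fold.
* Volumes `v_dose` at `threshold = 0` return the total volume; thresholds
  above the last edge return 0 rather than erroring.

## Problem sizes used by the test-suite simulations

Simulation-based checks use cohorts of n = 500 (100 replicates for ranking
and model-size recovery, 500 for interval coverage and null calibration)
and n = 2000–4000 for dose–response recovery; these sizes give Monte-Carlo
error comfortably below the margins being asserted while keeping the whole
suite quick to run. The end-to-end pipeline examples use the study-sized
n = 93.

## Known limitations

* Apparent (in-sample) performance only, as in the reference analysis: no
  optimism correction, cross-validated performance, or external validation.
* The ranking below the first few entrants is unstable by nature (the
  reference analysis's own ordering below rank 5 cannot be treated as
  ground truth), so only the top of the ranking is an acceptance surface.
* Complete-case handling only; records with any missing requested factor
  are rejected with a report.
* The logistic family is fixed; Lyman–Kutcher–Burman or probit NTCP
  variants are out of scope.
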