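---
title: "Methods: constructing and validating an individual social vulnerability index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constructing and validating an individual social vulnerability index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svindex)
```

## The scientific problem

Socially disadvantaged patients often lack the self-efficacy needed to
navigate a complex, fragmented health system. Because social
characteristics also drive health status, naive regressions of negative
healthcare events on social characteristics adjusted for health are hard
to interpret: the same variables sit on both causal paths. The approach
implemented here separates the two ideas with latent-variable machinery:
a multidimensional *social vulnerability* construct formed by social
indicators, related to a unidimensional *healthcare self-efficacy*
construct reflected by survey items, and then a simple, generalizable
index — the unweighted sum of asset/deficit codes — validated directly
against subsequent-year events.

## Coding the indicators

Each social indicator is collapsed from its raw survey scale into three
ordinal categories scored as a social asset (−1), neutral (0), or deficit
(+1); confidant support has no protective category and is scored 0/+1/+2,
and the minority-language flag 0/+1. The cut points on the 8-point
education and 7-point financial scales are configurable
(`indicator_spec()`), because only the category labels of the published
coding are fixed, not the raw-scale mapping. `search_cutpoints()`
implements the selection principle used to fix them: refit the
measurement model per candidate binning and keep the binning with the
highest explained variance of the downstream latent (PLS) or the best CFI
(MIMIC). The search is exhaustive up to 256 combinations and
coordinate-wise greedy beyond; candidates whose refit fails to converge
are skipped and logged rather than silently dropped.

## PLS path modelling

`fit_pls_path()` is a from-scratch implementation of the classic
alternating (Wold) algorithm for a two-block model: indicators are
standardized, outer weights start equal, and the algorithm alternates
outer proxies, inner proxies, and outer-weight updates — multiple
regression of the inner proxy on the block for the formative (Mode B)
block, simple correlations for the reflective (Mode A) block — until the
largest weight change falls below `tol` (default 1e-6, cap 300
iterations; non-convergence flags the result instead of raising). The
default inner scheme is the centroid scheme; for a single path the
centroid, factorial and path schemes coincide up to sign handling, and a
test documents that centroid and factorial agree on |beta| to 0.01 on
well-separated synthetic data. Latent signs are fixed by per-block anchor
indicators (default: the education code and the first efficacy item), so
the vulnerability latent loads positively on education-vulnerability and
the path against self-efficacy comes out negative. Coded ordinal
indicators are treated as numeric after recoding; that mirrors the
transform-then-refit practice the coding stage implies.

PLS assumes the formative indicators carry *all* construct variance (no
construct-level error) — the reason a complementary estimator with a
disturbance term is fitted as well. No bootstrap standard errors are
computed, since the index derivation uses only the point estimates.

## MIMIC modelling

`fit_mimic()` estimates the single-construct model
`eta = gamma' x + zeta`, `y = lambda eta + eps` by minimizing the
normal-theory discrepancy
`F = log|Sigma(theta)| + tr(S Sigma^{-1}) − log|S| − p`
with an analytic gradient under L-BFGS-B, variance parameters bounded at
zero (a Heywood case is returned at the bound with a warning).
Identification fixes the first loading to 1 — the common MIMIC convention
— rather than the latent variance; the choice is switchable in effect by
rescaling, and a test verifies the implied-covariance invariance under
rescaling of the anchor item. The cause covariance Phi is left free, so
misfit concentrates in the cause–indicator and indicator–indicator
structure. Start values: gamma from OLS of the first indicator on the
causes, loadings from covariance ratios, psi and the residual variances
at 10% of the observed variances. Convergence requires a projected
gradient max-norm below 1e-4 at the optimum (observed values are
typically below 1e-7), and `chi_square = (n−1) F`.

Fit statistics follow the standard definitions: CFI against the
closed-form independence baseline (all covariances zero), and
`AIC = −2 logLik + 2q`. AIC dialects differ across SEM software; only
AIC *differences* between models on the same data are meaningful here.
Ordinal inputs are treated as continuous in the ML fit (the common
LISREL-style first step); polychoric alternatives are out of scope and
noted as a limitation. Factor scores use the regression method on the
fitted covariance, standardized to unit variance.

The no-disturbance variant (`disturbance = FALSE`) fixes psi = 0,
reproducing the PLS assumption; on shared synthetic data its latent
scores correlate above 0.99 with the PLS scores, which is the package's
operational statement of "the two methods agree".

## From model weights to a bedside index

`fixed_weights()` collapses model weights of similar magnitude to unit
weights: if `max|w| / min|w| <= 1.75` every indicator gets weight 1,
otherwise integers `round(|w|/min|w|)`. The 1.75 default is chosen so
that a spread like 0.51 vs 0.33 (ratio ≈ 1.55) — the kind of spread the
fitted models produce — still collapses to units, while a genuine 2:1
spread does not; it is configurable. `weight_equivalence()` reports the
Pearson correlation between the model-weighted and unit-weight index on
whatever table it is given (no hidden reference data); on calibrated
synthetic cohorts it is about 0.99.

The scored index sums five indicators by default: the four modelled ones
plus the binary language deficit, which is excluded from model *fitting*
(at ~1% prevalence there is no power to estimate its weight) but kept in
*scoring* on conceptual grounds. This reconciles a five-indicator bedside
score with a four-indicator measurement model; both switches are exposed
(`include_language` in scoring and `formative_indicators()` in specs).
With unit weights the theoretical index range is −3..5 (−3..6 with
language); the full range is always reported even when extreme categories
are empty in a given sample.

## Outcome validation

`fit_outcome_logistic()` regresses each binary twelve-month event flag on
the vulnerability flag `I(Index >= 2)` and the chronic-disease count
(entering linearly, i.e. an odds ratio per additional chronic condition),
optionally with their interaction (Wald test) and extra covariates — the
functional-decline outcome controls for the baseline SF-12 score. Wald
95% intervals are reported; complete separation raises an error naming
the predictor. No multiple-testing correction is applied across the eight
outcomes, and the output is a per-outcome table; users who need
family-wise control should apply `p.adjust` downstream.

`detect_threshold()` reports two diagnostics side by side: the candidate
`k` minimizing AIC of `event ~ I(Index >= k) + chronic_count` (returned
only if it beats the no-threshold model), and the smallest index level
whose prevalence exceeds the overall rate by a configurable relative
margin (default 20%). Both pick `k = 2` under the default calibration.

## What the synthetic generator emulates — and what it does not

`generator_params()` encodes the study conditions the analysis assumes:

* **Indicator marginals** equal the published category distributions of
  the analytic sample (education 24.5/55.7/19.8%, financial
  31.0/60.1/8.9%, instrumental 49.4/33.1/17.5%, confidant
  73.4/21.5/5.1%, language 1%). The within-bin splits of the 8- and
  7-point raw scales are not published; the defaults spread mass
  plausibly and only matter for the cut-point search.
* **Dependence** among indicators uses a Gaussian copula with a single
  exchangeable correlation, default 0.2 — inter-indicator correlations
  are not published, and 0.2 yields a vulnerable share
  (`Index >= 2`) near the published ~14%.
* **Construct**: `eta` is the weighted sum of standardized coded
  indicators with weights (0.42, 0.38, 0.33, 0.51) plus a disturbance,
  standardized to unit variance so weights and loadings are comparable
  across parameter sets.
* **Items**: the four Likert items load negatively on `eta`. Default
  loadings come from a least-squares one-factor fit to the published
  item rank-correlation matrix, inflated by each item's discretization
  attenuation so that the *observed* item correlations land on the
  published values; item cut-offs are solved so the discretized means
  and SDs match the published 3.78/4.04/4.29/4.09 (1.09/0.92/0.87/0.92).
* **Disturbance calibration**: the published path coefficient (−0.38) is
  a property of observable, coded-and-discretized data. The generator
  therefore solves the disturbance variance so that the population PLS
  path on the observable scale equals the target, by monotone
  root-finding against a large fixed-seed calibration draw with common
  random numbers — the same logic `solve_intercept()` uses to hit a
  target marginal prevalence through the nonlinear logistic mixture.
* **Chronic burden**: Poisson with log-mean linear in `eta` (slope
  0.25), intercept solved so 25.5% of participants have 3+ of the 14
  listed conditions; counts truncated at 14. This builds in the
  confounding path the validation models must overcome.
* **Outcomes**: Bernoulli with
  `logit = alpha + log(OR_v) I(Index>=2) + log(OR_c) chronic (+ log(OR_b)(SF12−50))`,
  with the odds ratios and marginal prevalences of the published
  regression table and `alpha` solved per outcome.
* **Attrition**: `apply_attrition()` marks records incomplete with
  category-dependent probabilities (defaults: higher dropout for poor
  and low-educated categories, overall retention near 81%).

The generator does *not* attempt the full joint distribution of any real
cohort: real data have raw-scale heaping, item missingness patterns,
regional structure, and outcome dependence beyond the two modelled
covariates. Passing tests therefore demonstrate that the estimators
recover the published structure *when the model's assumptions hold at the
published effect sizes* — not that the index generalizes to a new
population.

## Numerical choices and degenerate inputs

Constant columns make rank correlations undefined; they are reported as
undefined, never coerced to 0. A singular formative block names the
collinear indicators. Missing indicators yield an explicitly missing
index, never 0. Attrition chi-squares compare completers with
non-completers (baseline minus completers) without continuity
correction — the construction that reproduces the published statistics
exactly; the education attrition row is internally inconsistent in its
source and is not used as a reference value. Logistic fits tighten the
IRLS tolerance to 1e-12 so they agree with a Newton oracle to 1e-8.
YAML configs treat bare `y`/`n` keys as strings (the cohort-size key `n`
would otherwise parse as a boolean).

## Problem sizes

The test suite and the acceptance script use 200 replicates at the
published sample sizes (1769 / 1368 / 2039) for odds-ratio and path
recovery, 100 planted-threshold replicates at n = 4000, 20-seed recovery
studies for the MIMIC parameters, and single draws of 50k–500k records
for marginal and calibration checks. These sizes put Monte-Carlo error
well inside the tolerances being asserted while keeping the default
suite under a few minutes.

## Known limitations

* Continuous-ML treatment of ordinal indicators biases MIMIC parameters
  relative to polychoric approaches; the bias is shared by the
  calibration and the recovery studies, so it cancels there, but
  absolute parameter values should not be over-interpreted.
* The mean of estimated odds ratios is upward-biased in rare-outcome
  regimes (Jensen's inequality on `exp`), visible in the
  admission-through-ER scenario (~64 events per cohort); the package
  reports the conventional mean-of-OR anyway, as that is the quantity
  the recovery protocol defines.
* No survey weighting, no time-to-event modelling, no multi-latent
  structural models, and no second-year outcome window beyond the
  parameterized outcome columns.
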