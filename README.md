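# svindex

Construction and validation of an **Individual Social Vulnerability
Index**: a pragmatic, fixed-weight sum of coded social indicators that
flags primary-care patients at increased risk of negative healthcare
events (repeat emergency-department use, unplanned admission, feeling
abandoned by the system, ...) independently of their chronic-disease
burden.

The package is aimed at health-services and health-equity researchers who
want to (a) reproduce the latent-variable derivation of such an index on
their own cohort data, or (b) study its statistical behaviour under
controlled synthetic conditions.

## The model

Social vulnerability is treated as a *formative* latent construct
composed by coded ordinal indicators (education, self-perceived financial
status, instrumental and confidant social support; each scored as asset
−1 / neutral 0 / deficit +1, confidant support 0/+1/+2), while limited
healthcare self-efficacy is a *reflective* construct measured by four
Likert items. Two complementary structural-equation approaches link them:

* **PLS path modelling** (two blocks, Mode B formative / Mode A
  reflective, classic Wold alternating algorithm): the vulnerability
  latent is an exact weighted sum `xi = sum_j w_j x_j` and the inner path
  `beta` measures its association with self-efficacy.
* **MIMIC modelling** (maximum-likelihood covariance fitting): a single
  latent `eta = gamma' x + zeta` with reflective indicators
  `y = lambda eta + eps`, estimated with and without the disturbance
  `zeta`, with chi-square, CFI and AIC fit statistics.

Because the fitted weights are approximately equal, they collapse to
**fixed unit weights**; the index is then just the sum of the indicator
codes, and `Index >= 2` (two or more net social deficits) defines the
vulnerability flag. Validation fits per-outcome logistic models

```
logit P(event) = alpha + log(OR_v) * I(Index >= 2) + log(OR_c) * chronic_count
```

and locates the risk threshold by AIC comparison across candidate
cut-offs plus a prevalence-curve diagnostic.

A calibrated **synthetic cohort generator** (Gaussian copula over the
ordinal indicators, latent construct with calibrated disturbance, Likert
discretization matched to published item moments, Poisson chronic burden,
odds-ratio-specified Bernoulli outcomes) makes the whole chain testable
without access to any cohort data.

## Worked example

```r
library(svindex)

params <- solve_intercepts(generator_params(n = 2039, seed = 1))
cohort <- generate_cohort(params)

pls <- fit_pls_path(cohort)
pls
#> PLS path model fit (n = 2039, 4 iterations)
#>   block 'vulnerability' (B): weights education_code=0.392,
#>     financial_code=0.328, instrumental_code=0.349, confidant_code=0.562
#>   block 'efficacy' (A): weights efficacy_info=0.259, efficacy_health=0.298,
#>     selfmgmt_between=0.404, selfmgmt_nohelp=0.400
#>   path coefficient beta = -0.354 (R^2 = 0.126)

w <- weight_equivalence(cohort, fixed_weights(pls$w$vulnerability))
w
#> Index weights
#>          indicator model fixed
#>     education_code 0.392     1
#>     financial_code 0.328     1
#>  instrumental_code 0.349     1
#>     confidant_code 0.562     1
#>   base value 0.328; equivalence r = 0.988

fit_outcome_logistic(cohort, "ed_visits_2plus")
#> Logistic model for 'ed_visits_2plus' (n = 2039)
#>           term    or or_lower or_upper  p_value
#>    (Intercept) 0.077    0.061    0.098 2.64e-95
#>     vulnerable 2.260    1.610    3.172 2.42e-06
#>  chronic_count 1.185    1.081    1.298 2.80e-04

detect_threshold(cohort, "ed_visits_2plus")
#> Threshold detection for 'ed_visits_2plus'
#>  k      aic status
#>  1 1398.717     ok
#>  2 1381.585     ok
#>  3 1391.627     ok
#>  4 1401.521     ok
#>   no-threshold AIC 1399.7; AIC choice k = 2; curve choice k = 2
```

Reading the output: the four model weights are of similar magnitude, so
the fixed-weight simplification loses almost nothing (correlation 0.988
between the model-weighted and unit-weight index). Vulnerable
participants (`Index >= 2`, about 14% of the cohort) have roughly
2.3-fold odds of two or more emergency-department visits in the following
year, after adjusting for chronic-disease burden (about 1.19 per
additional chronic condition), and the AIC comparison places the risk
threshold at an index of 2.

The whole chain — generate/load, recode, screen, fit both models, derive
weights, score, validate — can also be run as one pipeline:

```r
run_pipeline(run_config(input = params, outdir = "run1", seed = 1))
```

or from a shell via `inst/scripts/svindex-cli.R` (verbs `generate` and
`run-all`, YAML configuration as in `inst/extdata/example_config.yml`).

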