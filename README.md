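# miattrition

Estimation of the cumulative occurrence rate of an event observed at a few
discrete follow-up time points, in cohorts that lose subjects to attrition —
and a simulation framework for measuring how badly the standard analysis
breaks when drop-out is informative.

The motivating setting is IVF: the event is a delivery, a "time point" is a
treatment attempt, and drop-out is treatment interruption, which is linked
to a poor prognosis. Treating drop-out as non-informative censoring then
biases the cumulative success rate. The same structure appears in any
cohort with repeated visits where the result of a visit influences whether
the subject returns.

## What it implements

**Generative model** (`simulate_complete_cohort()`, `apply_attrition()`): a
Gaussian AR(1) covariate with drift, X₁ ~ N(0, 10),
Xₜ = 1 + Xₜ₋₁ + ε, ε ~ N(0, 10) (variances), splits subjects at each time
point into two categories at the threshold 0.014; events are Bernoulli with
category-specific per-time-point probability p ∈ {10%, 30%, 60%}, and
drop-out after each of the first T−1 time points is Bernoulli with
category-specific probability r ∈ {10%, 60%}, restricted to event-free
subjects (monotone missingness). Equal r's give MCAR attrition, unequal r's
give MAR. `default_scenarios()` returns the eight canonical scenarios.

**Estimators of P(E) = 1 − S(T):**

* `km_estimate()` — discrete-time Kaplan-Meier with drop-out as censoring:
  S(T) = Π (1 − dₜ/nₜ), Greenwood variance
  S(T)² Σ dₜ/(nₜ(nₜ−dₜ)), plain or log(−log) confidence intervals.
* `mi_estimate()` — sequential monotone multiple imputation: at each time
  point, a linear model imputes Xₜ from Xₜ₋₁ and a logistic model imputes
  Eₜ from Xₜ, for drop-outs still event-free; m = 5 proper-imputation
  chains (posterior parameter draws) are pooled by Rubin's rules
  (W + (1+1/m)B total variance, t interval with
  ν = (m−1)(1 + W/((1+1/m)B))² degrees of freedom).

**Evaluation harness** (`evaluation_design()`, `evaluate_scenario()`,
`reproduce_tables()`): per scenario, a 100 000-subject reference cohort
fixes the truth; 500 samples of 2000 subjects are analysed by both methods
and summarised as mean estimate, mean SE, bias (percentage points) and 95%
CI coverage. Fully deterministic given one root seed.

Cohorts can be exchanged as long-format CSV (`write_cohort_csv()` /
`read_cohort_csv()`), and scenario sets as YAML/JSON (`read_scenarios()`;
the eight canonical scenarios ship in `inst/extdata/scenarios.yaml`).

## Worked example

```r
library(miattrition)

sc <- default_scenarios()[["5"]]        # MAR: p = 10%/30%, r = 10%/60%
cohort <- simulate_complete_cohort(sc, 100000, seed = 11)
100 * true_occurrence_rate(cohort)
#> [1] 61.627
attr_cohort <- apply_attrition(cohort, sc, seed = 12)
100 * total_dropout_rate(attr_cohort)
#> [1] 45.714

smp <- draw_sample(attr_cohort, 2000, seed = 13)
km_estimate(smp)
#> KM estimate of P(E): 0.574 (se 0.0157, 95% CI [0.544, 0.605])
mi_estimate(smp, m = 5, seed = 14)
#> MI estimate of P(E): 0.619 (se 0.0269, 95% CI [0.553, 0.686])
#>   df = 5.7
```

The true rate is 61.6%. Kaplan-Meier, censoring the (mostly
high-prognosis-category) drop-outs, lands at 57.4% with a CI that excludes
the truth; multiple imputation recovers 61.9% with an honestly wider
interval. Over 500 such replications (`evaluate_scenario()`), KM shows a
bias of about −5 percentage points with ~10% CI coverage, MI a bias near 0
with ~95% coverage.

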