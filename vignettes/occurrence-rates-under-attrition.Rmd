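---
title: "Estimating a cumulative occurrence rate under cohort attrition: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating a cumulative occurrence rate under cohort attrition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Longitudinal cohorts with a short series of discrete follow-up time points —
the motivating case is couples undergoing successive IVF attempts, where the
event is a delivery and a "time point" is an attempt — lose subjects along
the way. When the probability of dropping out is linked to a covariate that
also predicts the event (in IVF, a woman's age predicts both success and
treatment interruption), the usual Kaplan-Meier treatment of drop-out as
non-informative censoring is violated: drop-outs do *not* have the same
subsequent event probability as subjects who stay, and the estimated
cumulative occurrence rate \(P(E)\) at the end of follow-up is biased.

`miattrition` implements, end to end, a simulation framework for studying
this problem and the two estimators it compares:

* discrete-time **Kaplan-Meier** with drop-out as censoring, and
* **sequential monotone multiple imputation** of the covariate and outcome
  trajectories of drop-outs, pooled by Rubin's rules,

together with a replication harness that measures bias and 95%
confidence-interval coverage of each method under configurable attrition
scenarios.

## The generative model

A cohort of \(n\) subjects is followed over \(T = 4\) time points. A
continuous covariate evolves as a Gaussian random walk with drift,

\[
X_{i1} \sim N(0, 10), \qquad
X_{it} = 1 + X_{i,t-1} + \varepsilon_{it}, \qquad
\varepsilon_{it} \sim N(0, 10),
\]

where both 10s are **variances**. At every time point a subject belongs to
category C1 if \(X_{it} < 0.014\) (the population median of \(X_1\); ties go
to C2) and to C2 otherwise. The event indicator is Bernoulli with a
category-specific probability \(p_{it} \in \{0.1, 0.3, 0.6\}\), constant
over time within a category. Only the first event matters: the endpoint
\(E_i\) records whether any \(E_{it} = 1\), and nothing after a subject's
first event is ever read downstream.

Attrition is superimposed after each of the first \(T-1\) time points:
subjects still observed and event-free draw a drop-out indicator with
category-specific probability \(r_{it} \in \{0.1, 0.6\}\), and a drop-out
after time \(t\) erases all later observations (a *monotone* pattern;
everyone is observed at \(t = 1\)). Because the category is a deterministic
function of the *observed* covariate at the drop-out time, equal
\(r\)-values produce MCAR attrition and unequal values produce MAR
attrition — never NMAR, which is out of scope here.

The eight canonical scenarios cross these probabilities
(`default_scenarios()`): scenarios 1–3 are MCAR, 4–8 MAR, with scenario 8
the most adversarial (the high-event category has the *low* drop-out rate).

```{r}
library(miattrition)
sc <- default_scenarios()[["5"]]     # p = 10%/30%, r = 10%/60% (MAR)
cohort <- simulate_complete_cohort(sc, 100000, seed = 11)
true_occurrence_rate(cohort)         # the target quantity
attr_cohort <- apply_attrition(cohort, sc, seed = 12)
total_dropout_rate(attr_cohort)
```

## The two estimators

**Kaplan-Meier.** `build_risk_table()` reduces each subject to one event or
one censoring: first observed event time, otherwise censoring at the last
observed time (drop-outs in \((t, t+1]\) were event-free at \(t\) and stay
in the risk set there; event-free completers are censored after \(T\)).
`km_cumulative_rate()` then computes \(1 - S(T)\) with
\(S(T) = \prod_t (1 - d_t/n_t)\) and Greenwood's variance. The paper trail
for the interval is thinner than for the point estimate, so the default CI
is the plain symmetric one, `estimate ± 1.96·se` — the simplest reading of
a "95% confidence interval", and the coverage conclusions below are driven
by bias, not by CI flavour. A `conf_type = "loglog"` variant (interval on
\(\log(-\log S)\), always inside \([0,1]\)) is available for sensitivity
analyses.

**Multiple imputation.** Imputation proceeds time point by time point
(`impute_chain()`), exploiting the monotone pattern:

1. at each \(t = 2..T\), a linear model of \(X_t\) on \(X_{t-1}\) and a
   logistic model of \(E_t\) on \(X_t\) (linear in \(X_t\): the imputer is
   *not* told about the 0.014 threshold, mimicking practical use) are
   fitted on the observed *continuers* — subjects observed at \(t\) and
   event-free through \(t-1\);
2. each of the \(m = 5\) chains draws fresh parameters from their posterior
   (*proper* imputation: exact normal–inverse-\(\chi^2\) for the linear
   step under the noninformative prior, asymptotic normal around the MLE
   for the logistic step), then imputes \(X_t\) and \(E_t\) for drop-outs
   whose observed-or-imputed event history is still all-zero; an imputed
   event stops further imputation for that subject;
3. each completed dataset is analysed by the simple proportion
   \(\hat p = \bar E_i\) with variance \(\hat p(1-\hat p)/n\), and the five
   results are pooled by Rubin's rules (`rubin_pool()`): total variance
   \(W + (1 + 1/m)B\) and a \(t\) interval with
   \(\nu = (m-1)(1 + W/((1+1/m)B))^2\) degrees of freedom.

```{r}
sample_2000 <- draw_sample(attr_cohort, 2000, seed = 13)
km_estimate(sample_2000)
mi_estimate(sample_2000, m = 5, seed = 14)
```

### Design choices in the imputation engine

Several points are open to interpretation in a sequential monotone
procedure; the package resolves them as follows.

* **Fit population.** Models at time \(t\) use observed continuers only.
  Because every continuer has \(E_{t-1} = 0\), the \(E_{t-1}\) predictor of
  the covariate step is constant in every fit sample and is dropped (the
  fit records this). Subjects with an earlier event are excluded even when
  their later covariate values exist in a simulated cohort — in a real
  cohort they would not exist at all. We also checked the alternative
  empirically: fitting on everyone observed at \(t\) regardless of event
  history degrades the estimator badly in the adversarial scenarios
  (scenario 8: bias 2.9 points and coverage 43% instead of 1.5 points and
  87%), because post-event trajectories follow a different conditional law
  than the event-free drop-outs being imputed.
* **Chain structure.** "m imputations at each time point" is read as
  \(m\) independent chains, each carrying its own imputed values forward
  through \(t = 2, 3, 4\) — the standard monotone-MI semantics, yielding
  exactly \(m\) completed datasets. Since fits use observed data only, all
  chains share one set of fits and differ only in their posterior draws.
* **Degrees of freedom.** Rubin's original \(\nu\) by default; with
  \(n = 2000\) and \(m = 5\) the Barnard–Rubin small-sample adjustment
  (available via `df_rule = "barnard-rubin"`) changes nothing of substance.
* **Numerical guards.** The residual variance of the covariate step is
  floored at \(10^{-12}\) so degenerate noise-free inputs cannot produce a
  zero-variance posterior draw. A separated or non-converged logistic fit
  is refitted with two half-weight pseudo-observations per class at the
  sample covariate mean (a mild data-augmentation ridge); a single-class
  fit sample imputes Bernoulli draws at the class rate. Both fallbacks are
  recorded on the fit objects and surfaced as the `"fallbacks"` attribute
  of `mi_estimate()` results. They essentially never trigger at
  \(n = 2000\) and remain rare at \(n = 500\).
* **What the logistic step can and cannot recover.** The true event model
  is a 10%/60% step function of \(X_t\); a logistic curve fitted to it
  saturates to 0 and 1 in the tails rather than to the step levels, and its
  within-category mean fitted probabilities land near, but not exactly at,
  the category rates (about 0.19 and 0.52 at large \(n\)). This
  misspecification is intentional — it is exactly the situation of applied
  use, where the threshold is unknown — and the evaluation shows it is
  benign for the *marginal* occurrence rate.

## The evaluation harness

`evaluation_design()` fixes the study conditions: for each scenario a
reference cohort of 100 000 subjects is simulated once (its complete-data
occurrence rate is the truth), attrition is applied, and 500 samples of
2000 subjects are drawn; each sample is analysed by both methods on exactly
the same subjects. Bias is the mean estimate minus the truth (percentage
points); coverage is the percent of 95% CIs containing the truth. A
`sample_size = 500` preset reproduces the small-sample side experiment, and
`sampling_mode = "fresh-cohort"` offers the methodological variant where
every replication simulates a new cohort. The mean of the per-replication
standard errors is what the summary reports ("mean SE"); the empirical SD
of the estimates is reported alongside for comparison.

Every random draw descends from one root seed through
`child_seed(root, scenario, replication, stream)`, so any replication (or
any single imputation chain) can be replayed in isolation and execution
order is irrelevant.

```{r}
design <- evaluation_design(replications = 500, root_seed = 1)
res <- evaluate_scenario(default_scenarios()[["5"]], design)
res$summary
# or the full eight-scenario reports + manifest:
# reproduce_tables(design, out_dir = "reports")
```

Under this design the MCAR scenarios show both methods essentially
unbiased with near-nominal coverage; in the MAR scenarios Kaplan-Meier
acquires a bias of roughly 5–7 percentage points (negative when the
high-event category drops out more, positive in the inverse case) and its
coverage collapses below 15% — the estimator is *precise around the wrong
value* — while multiple imputation keeps the bias under 2 points at the
cost of a larger standard error, except in scenario 6 where the two SEs are
essentially tied, and retains coverage above 80%.

## What the simulations do and do not show

The generator matches the evaluation design exactly, which is its purpose
and its limit. Real cohorts differ in ways the tests cannot vouch for:

* attrition here is fully explained by the observed covariate (MAR by
  construction); NMAR mechanisms are untested and would require sensitivity
  analyses;
* the imputation model sees the same variables that drive drop-out — with
  observational data the imputation model is always misspecified to some
  degree;
* time points are exchangeable attempts with no notion of elapsed time,
  no competing risks and no continuous event times;
* two latent subject classes with a fixed threshold is the simplest
  contrast structure; richer heterogeneity may behave differently.

## Problem sizes used by the test suite

The packaged tests reproduce the full design (500 replications of
\(n = 2000\)) for the scenarios whose published performance figures serve
as anchors (1, 3, 5, 8), use 150 replications for the remaining scenarios
where only the qualitative structure is asserted, and 200 replications at
\(n = 500\) for the small-sample experiment; cohort-level rates are always
checked at \(n = 100\,000\). Closed-form oracles (the no-censoring identity
between Kaplan-Meier and the empirical proportion, the analytic occurrence
and drop-out rates when the two categories are indistinguishable, the
hand-worked Rubin pooling example) and an independent product-limit
implementation from the `survival` package guard the estimators at small
\(n\).
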