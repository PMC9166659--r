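---
title: "Evaluating an integrated record viewer's effect on duplicate imaging: models, simulation design, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating an integrated record viewer's effect on duplicate imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupimaging)
library(dplyr)
```

## The scientific problem

When patients transition between health care systems — here, service
members moving from one system (which performed their imaging studies)
into another (where they receive primary care) — the receiving provider
often cannot see the originating system's records. An integrated,
read-only record viewer closes that gap, and one hoped-for benefit is
fewer *duplicate* imaging studies: a new order with the same imaging mode
and the same body part as a study performed shortly before in the other
system.

Estimating that benefit from administrative data is confounded:
unobserved patient complexity plausibly drives both the provider's
decision to open the viewer during a visit and the decision to order
imaging. `dupimaging` implements the full observational analysis as a
reusable, tested pipeline — cohort rules, variable construction, and an
instrumental-variable estimation suite — together with a synthetic
two-system EHR generator whose ground truth makes every estimator
testable.

## Exposures, instrument, outcome

Three binary variables sit at the centre:

* **Viewer encounter** (`jlv_encounter`, \(X_e\)): a viewer audit links
  the visit's provider and patient on the visit date. Endogenous — the
  same unobserved complexity \(U\) that triggers viewer use also raises
  duplicate ordering.
* **Viewer provider** (`jlv_provider`, \(W\)): the provider has at least
  one viewer audit, for any patient, in the 183 days before the visit
  (half-open window; the visit day itself is excluded). Because patients
  are assigned to primary care providers essentially arbitrarily, this
  history flag reflects the provider's propensity to use the viewer and
  is independent of the index patient's characteristics — it serves both
  as a quasi-exogenous exposure and as the instrument for \(X_e\).
* **Duplicate image** (\(Y\)): any imaging order at the visit matching
  any qualifying prior-system study on both mode and body part. A study
  qualifies when it precedes the visit by 1–90 days and its primary
  diagnosis is not cancer (repeat imaging in cancer care is usually
  indicated).

The exogenous covariate block \(X_o\) comprises the provider's
imaging-ordering rate over the prior 183 days (quartiles), provider type
(physician vs PA/NP), patient gender, age band (<30 / 30–39 / 40–49 /
50+), race (White / Black / Other), Elixhauser comorbidity bin
(0 / 1 / 2 / 3+), fiscal month (October = month 1), and facility.
Reference levels are quartile 1, physician, female, <30, White, 0, and
month 1.

## The estimation suite

**Primary model.** A logistic regression of \(Y\) on \(W\) and \(X_o\),
with fiscal-month fixed effects and facility random intercepts
(`fit_primary_logistic()`, lme4 Laplace fit; fixed-effects and
no-facility fallbacks are available and flagged on the result — the
random-intercept choice matters little at the default facility SD of
0.25 log-odds).

**Two-stage residual inclusion (2SRI).** For the endogenous exposure
\(X_e\), `fit_2sri()` fits a logistic first stage
\(X_e \sim W + X_o\), forms Anscombe residuals from the fitted
probabilities, and includes them as a regressor in the logistic second
stage \(Y \sim X_e + X_o + \hat r\). The instrument is excluded from the
second stage; both stages share one covariate block. The Anscombe
transform

\[ A(u) = \int_0^u t^{-1/3} (1-t)^{-1/3}\,dt
       = B(\tfrac23, \tfrac23)\, I_u(\tfrac23, \tfrac23) \]

is evaluated through the regularised incomplete beta function (`pbeta`),
not by quadrature; the test suite pins the implementation against
adaptive quadrature of the defining integral at 1e-8. The residual for a
binary observation is \((A(y) - A(\mu)) / (\mu(1-\mu))^{1/6}\); this
variance-stabilised form behaves better than raw or deviance residuals
when the outcome is rare, which is exactly the regime here (~8%
duplicate rate).

**Numerical safeguards.** First-stage fitted probabilities are clipped
to \([10^{-6}, 1-10^{-6}]\) before the residual transform (the scaling
factor diverges at the boundary); clip counts are recorded on the result
and in the run manifest. Logistic fits converge on relative
log-likelihood change below 1e-8 with at most 100 iterations; the
compiled IRLS used in replicate-heavy paths adds deviance step-halving
near separation. A perfectly predictive first stage aborts with an
instrument diagnostic; (quasi-)separation and non-convergence are
flagged, never silent.

**Inference.** Because the second stage contains a generated regressor,
model-based standard errors are anti-conservative. The package's
canonical inference for 2SRI is therefore a nonparametric bootstrap
(`bootstrap_inference()`, and `boot_reps` in `fit_2sri()`): the *full*
two-stage procedure — residuals included — is rerun on every resample.
Encounter-level resampling is the default; a provider-cluster bootstrap
is available since exposure varies at the provider level. Both
percentile and normal-approximation intervals are reported; 500
replicates is the default (200 in the replicate-heavy validation
experiments below). Replicates where the estimator fails are logged and
excluded; more than 20% failures is a hard error.

**Diagnostics and effect scales.** `cragg_donald_f()` fits the *linear*
first stage and reports the Cragg–Donald Wald F for the excluded
instrument (with one instrument, exactly the squared t statistic;
F > 10 is the conventional strength threshold). Odds ratios are always
`exp()` of stored coefficients. `average_incremental_effect()` reports
the probability-scale effect: the mean difference in predicted outcome
probability with the target flag toggled, all other covariates (and, for
2SRI, the computed residual) held at observed values.

**Linear robustness models.** `fit_ols()` (linear probability model of
\(Y\) on \(W + X_o\), HC1 robust SEs) and `fit_2sls()` (linear IV of
\(Y\) on \(X_e\) instrumented by \(W\)). No installed package provides
IV regression, so 2SLS is implemented directly by projection, with
sandwich SEs built from the structural residuals; with no covariates it
reduces (tested to 1e-10) to the classical Wald ratio
\(\frac{E[Y|W{=}1]-E[Y|W{=}0]}{E[X_e|W{=}1]-E[X_e|W{=}0]}\).

## The synthetic EHR generator

`simulate_ehr()` emits the five linked event tables the pipeline
consumes — prior-system imaging studies, receiving-system visits and
imaging orders, viewer audit logs, and patient/provider attributes —
from an explicitly endogenous data-generating process:

\[
\mathrm{logit}\,P(X_e{=}1) = \alpha_0 + \alpha_z Z_j + \alpha_u U_i,
\qquad
\mathrm{logit}\,P(Y{=}1) = \beta_0 + \beta_e X_e + \beta_u U_i +
\gamma' x_{o} + b_{f},
\]

with \(U_i \sim N(0,1)\) latent patient complexity (never emitted into
the event tables), \(Z_j\) a Bernoulli provider viewer-propensity class,
and \(b_f \sim N(0, \sigma^2_{\mathrm{fac}})\) facility intercepts.
Event emission is constructed to be exactly invertible by the pipeline's
own rules:

* an audit row (provider, patient, visit date) exists iff \(X_e = 1\);
* when \(Y = 1\) the emitted order matches a qualifying prior study on
  mode and body part; when \(Y = 0\) any emitted order (probability 0.10)
  is drawn from the mode × body-part combinations *not* in the visit's
  qualifying set;
* viewer-propensity providers (\(Z_j = 1\)) receive background audits
  every ~30 days from the start of the 183-day pre-period, attached to
  patients outside their panel, so every one of their visits carries the
  history flag and the flag evaluated at the study-window opening
  recovers \(Z_j\) exactly.

One point deserves care: the per-visit history flag \(W\) is *measured
from audits*, so a \(Z_j = 0\) provider who uses the viewer at one
encounter acquires audits that legitimately set \(W = 1\) at that
provider's later visits. This is a feature of audit-based measurement,
not a bug; it leaves \(W\) exogenous to the index patient (with one
visit per patient, all prior audits involve *other* patients' visits)
while making \(W\) and \(Z_j\) deliberately distinct quantities. The
round-trip guarantee is therefore stated at the provider level via
pre-period audits (`provider_history_flags()` at the window opening),
while \(X_e\) and \(Y\) reconstruct exactly per encounter.

The generator also emits realistic nuisance events that exercise every
filter: cancer-flagged studies (1–90 days back), stale studies (91–180
days), same-day studies, compensation-and-pension exams (secondary stop
code 450 + matching appointment type), non-primary-care visits (stop
code 502), and per-provider background visit histories (mean 30 visits
over 18 months, carrying orders at the provider's ordering propensity
\(\rho_j \sim \mathrm{Beta}(2, 9.4)\), mean 0.175) from a dedicated
history-patient pool, which support the ordering-rate covariate without
ever entering the cohort.

### Default parameter choices

Defaults were fixed once, to emulate the observed marginals of the
fiscal-year study population the package is designed around, and are not
revisited by any test:

| parameter | default | rationale |
|---|---|---|
| `n_patients` | 892 | analytic encounters in the reference population (one eligible visit per patient) |
| `p_instrument` | 0.66 | share of encounters with a viewer-history provider |
| `alpha0`, `alpha_z` | −3.5, 4.5 | providers without recent viewer history rarely open it at a visit (~4% averaged over \(U\)); propensity-class providers ~60–65%; marginal visit-level use ≈ 47% |
| `alpha_u`, `beta_u` | 1, 1 | a one-SD complexity shift moves both logits by 1 — strong, deliberately worst-case confounding |
| `beta_e` | log(0.44) | the provider-level odds ratio the reference analysis reports, used as the generative effect |
| `beta0` | −2.94 | calibrated once by simulation (n = 60,000) to the ~8% marginal duplicate rate; the marginal rate's drivers are not published, so this is a package tuning choice |
| covariate effects | Table-2-style | ordering-rate slope 5 per unit \(\rho\); Elixhauser bins −0.82/−0.92/−1.90; age bands +0.78/−0.25/+0.24; race +0.09/+0.49; male +0.52; PA/NP +0.28 |
| `sigma_facility` | 0.25 | modest between-facility heterogeneity |
| demographics | mixture/Poisson | age mixture mean 34.3 (truncated at 19), 65.9% male, race 57.4/25.6/17.0%, Elixhauser Poisson(1.22) |

What the generator does *not* emulate: real procedure coding (the
taxonomy is a synthetic mode × body-part vocabulary; the real
CPT-to-category mapping is unpublished), visit scheduling structure,
disease progression, or clinical appropriateness of repeats. Passing
tests therefore demonstrate that the estimators recover known effects
under the *stated* generative model — confounding of the stated form and
magnitude — not that the clinical findings generalise.

## Validation experiments

**Parameter recovery** (`recovery_experiment()`): 50 datasets of 20,000
encounters (600 providers, 40 facilities) with confounding on
(\(\alpha_u = \beta_u = 1\)) and true effect \(\beta_e = \log 0.44\).
Per dataset: the naive single-stage logistic of \(Y\) on \(X_e + X_o\),
the 2SRI estimate, and a 200-replicate percentile bootstrap interval.
The acceptance suite requires the naive estimate to be systematically
biased (it is, by roughly +0.5 on the log-odds scale — more than half
the true effect), the 2SRI mean to land within ±0.1 of the truth, and
the 95% interval to cover the truth in at least 90% of replicates.

**Null calibration** (`null_calibration()`): 200 datasets of 5,000
encounters with \(\beta_e = 0\) and confounding still on. The naive
model rejects the null nearly always (its exposure coefficient centres
on +0.4 log-odds under the null). 2SRI removes most, but not all, of
that distortion: in a binary-endogenous/binary-outcome model,
residual inclusion is an approximation rather than an exactly
consistent estimator, and under these conditions the Anscombe-residual
second stage retains a systematic bias of roughly −0.2 log-odds at the
null. With a sampling SD near 0.3 at n = 5,000, that bias inflates the
type-I error of the bootstrap-SE z-test to about three times the
nominal 5% — far better than the naive model's near-certain rejection,
but not nominal. This is a known property of residual inclusion with a
binary endogenous regressor (the control-function assumption holds only
approximately), not a consequence of how the instrument is measured.
The recovery experiment shows the flip side: at the study's actual
effect size the same approximation error happens to be negligible.
`fit_2sri()` exposes `residual_kind = "raw"` and `"deviance"` alongside
the default `"anscombe"` for sensitivity analysis of exactly this
approximation.

Problem sizes throughout (20,000-encounter recovery datasets, 200
calibration replicates, 200 bootstrap draws) are the package's chosen
validation scale: large enough that approximation bias, not sampling
noise, dominates the comparisons.

## Design choices where the design was open

* **Window boundaries.** "Within 90 days" is read as
  \(1 \le \Delta \le 90\): the prior study must strictly precede the
  visit (exposure before outcome), and day 90 is included. Same-day
  studies never qualify.
* **Six months** is 183 days, as a half-open window
  \([\,\mathrm{visit}-183, \mathrm{visit})\) everywhere (history flag,
  ordering rate, pre-period length).
* **Multiple qualifying studies** attach to one encounter (one row per
  eligible visit carrying all its studies); a duplicate means matching
  *any* of them.
* **Quartile ties** go to the lower quartile; cutpoints are sample
  quantiles of the encounter-level rates, recomputed on the analytic
  sample after drops.
* **Undefined ordering rates** (provider with no prior primary-care
  visit in the window) drop the encounter, with the count logged and
  carried in the run manifest.
* **Bootstrap unit** defaults to encounters, with provider-cluster
  resampling available — which unit the reference analysis used is not
  stated.
* **First stages.** The logistic first stage feeds the residual; the
  linear first stage exists only for the Cragg–Donald diagnostic.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
out <- run_pipeline(cfg, boot_reps = 200, facility = "random")

out$descriptives                       # stratified Table-1-style summary
tidy(out$fits$primary, exponentiate = TRUE)
glance(out$fits$tsri)                  # Cragg-Donald F, AIE, clip counts
out$fits$tsri$bootstrap                # percentile + normal CIs
out$manifest                           # counts, seeds, warnings
autoplot(out$fits$tsri)
```

## Known limitations

* 2SRI with a binary endogenous regressor is an approximation; its
  small residual bias is measured, reported by the recovery experiment,
  and inherited by the calibration results — it is not removed.
* The facility random-intercept model is fit by Laplace approximation;
  replicate-heavy experiments omit the facility term for tractability
  (attenuation at \(\sigma_{\mathrm{fac}} = 0.25\) is ~1% of the
  effect).
* The generator's one-visit-per-patient default makes the instrument
  exactly exogenous; with multiple visits per patient a patient's own
  earlier viewer-triggering visit can contribute to their provider's
  history flag, a (realistic) minor exclusion-restriction violation.
* Elixhauser scores are taken as given; computing them from diagnosis
  codes is out of scope.
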