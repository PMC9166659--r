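# dupimaging

Does giving primary care providers an integrated, read-only viewer of a
patient's records from *another* health care system reduce duplicate
medical imaging? `dupimaging` implements the full observational analysis
behind that question as a tested, reusable R pipeline, for health
services researchers working with linked administrative event tables
(visits, imaging studies, imaging orders, viewer audit logs): cohort
construction, duplicate-image detection, and a causal-inference suite
built around two-stage residual inclusion (2SRI). Because the real
two-system data are restricted, the package ships a synthetic EHR
generator with a known endogenous data-generating process, so every
estimator is validated against ground truth.

## The model

An encounter is an eligible primary care visit (stop codes 322/323/350,
physicians and PA/NPs, compensation-and-pension exams excluded) within
90 days after a non-cancer imaging study in the originating system. The
outcome Y flags a *duplicate image*: an order at the visit with the same
mode and body part as a qualifying prior study. Two exposures are
measured from viewer audit logs: the endogenous visit-level flag X_e
(audit linking provider and patient on the visit date) and the
provider-history flag W (any audit by the provider in the prior 183
days), which is exogenous to the individual patient because patients are
arbitrarily assigned to providers.

The primary model is a mixed-effects logistic regression

    logit P(Y = 1) = b_w W + Xo' g + month effects + facility intercepts,

and the endogenous exposure is handled by 2SRI with W as instrument:

    stage 1:  logit P(X_e = 1) = a_w W + Xo' a
    stage 2:  logit P(Y = 1)  = b_e X_e + Xo' g + b_r r̂ + ...

where r̂ are Anscombe residuals from stage 1,
r = (A(y) − A(mu)) / (mu(1−mu))^(1/6) with
A(u) = B(2/3, 2/3) I_u(2/3, 2/3), the variance-stabilising transform
preferred for rare binary outcomes. Inference is by nonparametric
bootstrap of the full two-stage procedure; instrument strength is
checked with the Cragg–Donald Wald F from a linear first stage; effects
are reported as odds ratios and as average incremental effects
(probability-scale differences). OLS and 2SLS linear models provide
robustness checks.

## Worked example

```r
library(dupimaging)

cfg <- sim_config(seed = 1)            # 892-encounter study population
out <- run_pipeline(cfg, boot_reps = 200, facility = "random")

out$fits$tsri
#> <dup2sri> n = 892, instrument: jlv_provider, exposure: jlv_encounter
#>   Cragg-Donald F = 382.67 (strong instrument)
#>   jlv_encounter: OR 0.562 (Wald 0.181-1.749)
#>   bootstrap (200 reps): OR 0.191-2.153 (percentile)
#>   average incremental effect = -0.0320; 0 clipped stage-1 prob(s)

tidy(out$fits$primary, exponentiate = TRUE) |> head(3)
#> # A tibble: 3 × 7
#>   term                 estimate std.error statistic   p.value conf.low conf.high
#>   <chr>                   <dbl>     <dbl>     <dbl>     <dbl>    <dbl>     <dbl>
#> 1 (Intercept)            0.0620     0.698     -3.99 0.0000671   0.0158     0.243
#> 2 jlv_provider           0.681      0.305     -1.26 0.207       0.374      1.24
#> 3 order_rate_quartile2   1.84       0.441      1.38 0.168       0.774      4.35

glance(out$fits$tsri)
autoplot(out$fits$tsri)
```

Reading the output: the Cragg–Donald F far above 10 says the
provider-history instrument strongly predicts visit-level viewer use;
the 2SRI odds ratio below 1 estimates that viewer use at the visit
reduces the odds of a duplicate order (the generative value in this
simulation is OR 0.44); the average incremental effect translates this
to about a 3-percentage-point lower duplicate probability. At n = 892 a
single draw is noisy and the intervals are wide — the validation
experiments below use larger simulated populations where recovery can
be judged precisely.

Ground-truth validation of the estimators:

```r
rec <- recovery_experiment(n_reps = 50, boot_reps = 200)  # ~10-15 min
glance(rec)     # naive vs 2SRI bias, bootstrap coverage
autoplot(rec)

nc <- null_calibration(n_reps = 200)                      # ~10 min
glance(nc)      # type-I error of 2SRI vs the naive model
```

A thin CLI wrapper (`inst/scripts/run-pipeline.R`) exposes `simulate`
and `run-all` subcommands over the same functions for shell use.

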