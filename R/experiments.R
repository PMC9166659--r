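#' Parameter-recovery experiment for the two-stage estimator
#'
#' Repeatedly simulates event bundles with unobserved confounding, runs
#' the full pipeline (cohort, variables, estimation) on each, and compares
#' the naive single-stage logistic estimate of the visit-level viewer-use
#' effect with the two-stage residual-inclusion estimate against the known
#' generative value. For each replicate a percentile bootstrap interval
#' for the 2SRI coefficient is computed by rerunning the full two-stage
#' procedure on resampled encounters.
#'
#' The default conditions are the package's headline validation scenario:
#' 20,000 encounters, latent-complexity effects of 1 on both viewer use
#' and duplicate ordering, and a true exposure effect of `log(0.44)`.
#'
#' @param n_reps Number of replicate datasets.
#' @param config A [sim_config()]; the default scales the study population
#'   to 20,000 encounters (600 providers, 40 facilities).
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @param boot_reps Bootstrap replicates per dataset.
#' @param resample_unit Bootstrap resampling unit.
#' @param conf_level Level of the bootstrap interval used for coverage.
#' @param progress Print a line per replicate.
#' @return A tibble of class `recovery_experiment` with one row per
#'   replicate (naive and 2SRI estimates, bootstrap interval, coverage
#'   indicator, Cragg-Donald F). `glance()` summarises bias, coverage and
#'   the share of replicates where 2SRI is closer to the truth.
#' @export
recovery_experiment <- function(n_reps = 50,
                                config = sim_config(n_patients = 20000,
                                                    n_providers = 600,
                                                    n_facilities = 40),
                                seed = 20180930,
                                boot_reps = 200,
                                resample_unit = "encounter",
                                conf_level = 0.95,
                                progress = FALSE) {
  truth <- config$beta_e
  rows <- purrr::map_dfr(seq_len(n_reps), function(r) {
    cfg <- config
    sim <- simulate_ehr(cfg, seed = child_seed(seed, r))
    recs <- build_analytic(sim$bundle, quiet = TRUE)
    mats <- analytic_matrices(recs)

    naive_fit <- fast_logit(cbind(mats$X_exog, jlv_encounter = mats$x_e),
                            mats$y)
    naive <- unname(naive_fit$coefficients["jlv_encounter"])

    ts <- two_stage_core(mats$X_exog, mats$w, mats$x_e, mats$y)
    boot <- boot_two_stage(mats, n_reps = boot_reps,
                           seed = child_seed(seed, 100000 + r),
                           resample_unit = resample_unit,
                           conf_level = conf_level)
    ci <- boot[boot$term == "jlv_encounter", ]
    cd <- cragg_donald_f(recs)
    if (progress) {
      inform(sprintf("replicate %d/%d: naive %.3f, 2SRI %.3f [%.3f, %.3f]",
                     r, n_reps, naive, ts$beta_e, ci$conf.low, ci$conf.high))
    }
    tibble(
      replicate = r, seed = child_seed(seed, r),
      n = length(mats$y),
      naive_estimate = naive,
      tsri_estimate = ts$beta_e,
      resid_coef = ts$beta_resid,
      conf.low = ci$conf.low, conf.high = ci$conf.high,
      covered = truth >= ci$conf.low & truth <= ci$conf.high,
      tsri_closer = abs(ts$beta_e - truth) < abs(naive - truth),
      cragg_donald_f = cd$statistic
    )
  })
  structure(rows, truth = truth, config = config, boot_reps = boot_reps,
            conf_level = conf_level,
            class = c("recovery_experiment", class(tibble())))
}

#' Null-calibration experiment for the two-stage estimator
#'
#' Simulates datasets in which the true visit-level viewer-use effect is
#' zero while the unobserved confounding channel stays on, and records how
#' often the naive single-stage logistic model and the 2SRI model reject
#' the null for the exposure at level `alpha` (Wald tests). A
#' well-calibrated 2SRI should reject at about `alpha`; the naive model
#' over-rejects because confounding biases its exposure coefficient.
#'
#' @param n_reps Number of replicate datasets.
#' @param config A [sim_config()] with `beta_e = 0`; the default scales
#'   the population to 5,000 encounters.
#' @param seed Master seed.
#' @param alpha Nominal test level.
#' @param test Inference for the 2SRI exposure coefficient:
#'   `"bootstrap"` (default; z-test with the bootstrap standard error —
#'   the second stage contains a generated regressor, so model-based SEs
#'   understate the variance) or `"wald"` (naive information-matrix SE).
#' @param boot_reps Bootstrap replicates per dataset when
#'   `test = "bootstrap"` (standard-error estimation needs far fewer
#'   replicates than percentile quantiles).
#' @return A tibble of class `null_calibration` with per-replicate
#'   estimates and p-values; `glance()` reports both rejection rates.
#' @export
null_calibration <- function(n_reps = 200,
                             config = sim_config(n_patients = 5000,
                                                 n_providers = 150,
                                                 n_facilities = 20,
                                                 beta_e = 0),
                             seed = 20171001,
                             alpha = 0.05,
                             test = c("bootstrap", "wald"),
                             boot_reps = 100) {
  test <- rlang::arg_match(test)
  if (abs(config$beta_e) > 1e-12) {
    abort("null_calibration() requires a config with beta_e = 0")
  }
  rows <- purrr::map_dfr(seq_len(n_reps), function(r) {
    sim <- simulate_ehr(config, seed = child_seed(seed, r))
    recs <- build_analytic(sim$bundle, quiet = TRUE)
    mats <- analytic_matrices(recs)

    Xn <- cbind(mats$X_exog, jlv_encounter = mats$x_e)
    naive_fit <- fast_logit(Xn, mats$y)
    naive_se <- fast_logit_se(Xn, naive_fit$fitted, naive_fit$kept)
    naive_z <- naive_fit$coefficients["jlv_encounter"] /
      naive_se["jlv_encounter"]

    ts <- two_stage_core(mats$X_exog, mats$w, mats$x_e, mats$y)
    ts_se <- if (test == "bootstrap") {
      b <- boot_two_stage(mats, n_reps = boot_reps,
                          seed = child_seed(seed, 500000 + r))
      b$std.error[b$term == "jlv_encounter"]
    } else {
      fast_logit_se(ts$X2, ts$stage2$fitted,
                    ts$stage2$kept)[["jlv_encounter"]]
    }
    ts_z <- ts$beta_e / ts_se

    tibble(
      replicate = r,
      naive_estimate = unname(naive_fit$coefficients["jlv_encounter"]),
      naive_p = unname(2 * pnorm(-abs(naive_z))),
      tsri_estimate = ts$beta_e,
      tsri_se = unname(ts_se),
      tsri_p = unname(2 * pnorm(-abs(ts_z)))
    )
  })
  structure(rows, config = config, alpha = alpha, test = test,
            class = c("null_calibration", class(tibble())))
}
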