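#' Two-stage residual inclusion (2SRI) with Anscombe residuals
#'
#' Estimates the effect of visit-level viewer use (`jlv_encounter`, an
#' endogenous exposure) on duplicate imaging, using the provider-history
#' flag (`jlv_provider`) as an instrument. Stage 1 is a logistic model of
#' the endogenous exposure on the instrument plus the exogenous covariate
#' block; its Anscombe residuals (see [anscombe_residual()]) then enter the
#' stage-2 logistic outcome model alongside the exposure, absorbing the
#' unobserved confounding channel. The instrument is excluded from stage 2
#' (exclusion restriction); both stages use the same covariate block.
#'
#' Stage-1 fitted probabilities are clipped to
#' `[clip_eps, 1 - clip_eps]` before the residual transform; the number of
#' clipped values is recorded on the result. A perfectly predictive first
#' stage aborts with an instrument diagnostic. Weak-instrument strength is
#' always reported via the Cragg-Donald F statistic from a linear first
#' stage (see [cragg_donald_f()]).
#'
#' @inheritParams fit_primary_logistic
#' @param exposure Name of the endogenous binary exposure column.
#' @param instrument Name of the binary instrument column.
#' @param residual_kind First-stage residual entering stage 2:
#'   `"anscombe"` (default), `"deviance"` or `"raw"`. The residual column
#'   and coefficient are named `<kind>_resid`.
#' @param boot_reps Number of bootstrap replicates for the second-stage
#'   coefficients (0 to skip). Replicates rerun the full two-stage
#'   procedure, residuals recomputed each time.
#' @param resample_unit `"encounter"` (rows) or `"provider"` (cluster
#'   bootstrap over providers).
#' @param seed Seed for the bootstrap.
#' @param clip_eps Clipping bound for stage-1 fitted probabilities.
#' @return An object of class `dup2sri` with components `first_stage` and
#'   `second_stage` (both `dupfit`), `residuals`, `n_clipped`,
#'   `cragg_donald`, `aie` (average incremental effect of the exposure) and
#'   `bootstrap` (a `boot_ci` tibble, or `NULL`).
#' @export
fit_2sri <- function(data,
                     exposure = "jlv_encounter",
                     instrument = "jlv_provider",
                     covariates = default_covariates(),
                     outcome = "duplicate_image",
                     facility = c("none", "random", "fixed"),
                     residual_kind = c("anscombe", "deviance", "raw"),
                     boot_reps = 0,
                     resample_unit = c("encounter", "provider"),
                     seed = 1L,
                     conf_level = 0.95,
                     clip_eps = 1e-6) {
  facility <- rlang::arg_match(facility)
  resample_unit <- rlang::arg_match(resample_unit)
  residual_kind <- rlang::arg_match(residual_kind)
  assert_columns(data, c(outcome, exposure, instrument, covariates), "data")
  df <- droplevels(as.data.frame(data))
  if (length(unique(df[[outcome]])) < 2) {
    abort(glue::glue("outcome `{outcome}` is constant; the model is unidentified"))
  }

  # stage 1: logistic of the endogenous exposure on instrument + covariates
  stage1 <- fit_primary_logistic(df, exposure = instrument,
                                 covariates = covariates,
                                 outcome = exposure, facility = "none",
                                 conf_level = conf_level)
  mu1 <- fitted(stage1$model)
  if (stage1$model$deviance < 1e-6) {
    cd <- try(cragg_donald_f(df, exposure = exposure,
                             instrument = instrument,
                             covariates = covariates), silent = TRUE)
    abort(paste0(
      "first stage exhibits perfect prediction of the exposure; ",
      "two-stage model cannot be identified",
      if (!inherits(cd, "try-error"))
        glue::glue(" (Cragg-Donald F = {round(cd$statistic, 2)})" ) else ""
    ))
  }
  mu1 <- clip_probs(mu1, clip_eps)
  n_clipped <- attr(mu1, "n_clipped")
  mu1 <- as.vector(mu1)
  resid_term <- paste0(residual_kind, "_resid")
  df[[resid_term]] <- stage1_residual(residual_kind, df[[exposure]], mu1)

  # stage 2: outcome on exposure + covariates + stage-1 residual
  stage2 <- fit_primary_logistic(df, exposure = exposure,
                                 covariates = c(covariates, resid_term),
                                 outcome = outcome, facility = facility,
                                 conf_level = conf_level)

  cd <- cragg_donald_f(df, exposure = exposure, instrument = instrument,
                       covariates = covariates)

  out <- structure(
    list(first_stage = stage1, second_stage = stage2,
         residuals = df[[resid_term]], resid_term = resid_term,
         residual_kind = residual_kind, n_clipped = n_clipped,
         cragg_donald = cd, exposure = exposure, instrument = instrument,
         outcome = outcome, covariates = covariates, n = nrow(df),
         bootstrap = NULL, boot_reps = 0),
    class = "dup2sri"
  )
  out$aie <- average_incremental_effect(stage2, df, target = exposure)

  if (boot_reps > 0) {
    mats <- analytic_matrices(df, covariates)
    out$bootstrap <- boot_two_stage(mats, n_reps = boot_reps, seed = seed,
                                    resample_unit = resample_unit,
                                    conf_level = conf_level,
                                    clip_eps = clip_eps,
                                    residual = residual_kind)
    out$boot_reps <- boot_reps
  }
  out
}

#' @export
print.dup2sri <- function(x, ...) {
  cat(sprintf("<dup2sri> n = %d, instrument: %s, exposure: %s\n",
              x$n, x$instrument, x$exposure))
  cat(sprintf("  Cragg-Donald F = %.2f (%s instrument)\n",
              x$cragg_donald$statistic,
              if (x$cragg_donald$strong) "strong" else "weak"))
  row <- x$second_stage$coefficients
  row <- row[row$term == x$exposure, ]
  if (nrow(row) == 1) {
    cat(sprintf("  %s: OR %.3f (Wald %.3f-%.3f)\n", x$exposure,
                exp(row$estimate), exp(row$conf.low), exp(row$conf.high)))
  }
  if (!is.null(x$bootstrap)) {
    b <- x$bootstrap[x$bootstrap$term == x$exposure, ]
    cat(sprintf("  bootstrap (%d reps): OR %.3f-%.3f (percentile)\n",
                attr(x$bootstrap, "n_reps"), exp(b$conf.low), exp(b$conf.high)))
  }
  cat(sprintf("  average incremental effect = %.4f; %d clipped stage-1 prob(s)\n",
              x$aie, x$n_clipped))
  invisible(x)
}

# Fast bootstrap of the full two-stage procedure on prebuilt matrices.
boot_two_stage <- function(mats, n_reps, seed, resample_unit = "encounter",
                           conf_level = 0.95, clip_eps = 1e-6,
                           residual = "anscombe") {
  set.seed(seed)
  n <- length(mats$y)
  prov_rows <- if (resample_unit == "provider") {
    split(seq_len(n), mats$provider)
  } else NULL
  full <- two_stage_core(mats$X_exog, mats$w, mats$x_e, mats$y, clip_eps,
                         residual = residual)
  init1 <- full$stage1$coefficients
  init2 <- full$stage2$coefficients
  draws <- matrix(NA_real_, n_reps, 2,
                  dimnames = list(NULL, c("jlv_encounter", full$resid_term)))
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    idx <- if (is.null(prov_rows)) {
      sample.int(n, n, replace = TRUE)
    } else {
      unlist(prov_rows[sample.int(length(prov_rows), length(prov_rows),
                                  replace = TRUE)], use.names = FALSE)
    }
    rep_fit <- tryCatch(
      two_stage_core(mats$X_exog[idx, , drop = FALSE], mats$w[idx],
                     mats$x_e[idx], mats$y[idx], clip_eps,
                     init1 = init1, init2 = init2, residual = residual),
      error = function(e) NULL
    )
    if (is.null(rep_fit) || is.na(rep_fit$beta_e)) {
      n_failed <- n_failed + 1L
    } else {
      draws[r, ] <- c(rep_fit$beta_e, rep_fit$beta_resid)
    }
  }
  if (n_failed > 0.2 * n_reps) {
    abort(glue::glue(
      "{n_failed} of {n_reps} bootstrap replicates failed (> 20%); ",
      "the estimator is unstable on these data"
    ))
  }
  estimates <- setNames(c(full$beta_e, full$beta_resid),
                        c("jlv_encounter", full$resid_term))
  boot_ci_table(
    estimates = estimates,
    draws = draws, conf_level = conf_level, n_failed = n_failed,
    n_reps = n_reps, resample_unit = resample_unit
  )
}
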