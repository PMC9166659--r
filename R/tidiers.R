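#' Tidy methods for fitted objects
#'
#' Broom-style accessors: `tidy()` returns one row per coefficient,
#' `glance()` a one-row model summary.
#'
#' @param x A fitted object from this package.
#' @param exponentiate Report odds ratios instead of log-odds.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

exp_tidy <- function(tbl, exponentiate) {
  if (!exponentiate) return(tbl)
  mutate(tbl, across(dplyr::any_of(c("estimate", "conf.low", "conf.high",
                                     "conf.low.norm", "conf.high.norm")),
                     exp))
}

#' @rdname tidiers
#' @export
tidy.dupfit <- function(x, exponentiate = FALSE, ...) {
  exp_tidy(x$coefficients, exponentiate)
}

#' @rdname tidiers
#' @export
glance.dupfit <- function(x, ...) {
  tibble(
    n = x$n, engine = x$engine, facility = x$facility,
    converged = x$converged, separation = x$separation,
    deviance = if (x$engine == "glm") x$model$deviance else
      as.numeric(deviance(x$model))
  )
}

#' @rdname tidiers
#' @param stage `"second"` (default) or `"first"`.
#' @export
tidy.dup2sri <- function(x, stage = c("second", "first"),
                         exponentiate = FALSE, ...) {
  stage <- rlang::arg_match(stage)
  fit <- if (stage == "second") x$second_stage else x$first_stage
  exp_tidy(fit$coefficients, exponentiate)
}

#' @rdname tidiers
#' @export
glance.dup2sri <- function(x, ...) {
  tibble(
    n = x$n,
    cragg_donald_f = x$cragg_donald$statistic,
    instrument_strong = x$cragg_donald$strong,
    aie = x$aie,
    n_clipped = x$n_clipped,
    boot_reps = x$boot_reps,
    converged = x$first_stage$converged && x$second_stage$converged
  )
}

#' @rdname tidiers
#' @export
tidy.duplin <- function(x, ...) x$coefficients

#' @rdname tidiers
#' @export
glance.duplin <- function(x, ...) {
  tibble(n = x$n, method = x$method, se = x$se)
}

#' @rdname tidiers
#' @export
tidy.boot_ci <- function(x, exponentiate = FALSE, ...) {
  exp_tidy(as_tibble(x), exponentiate)
}

#' @rdname tidiers
#' @export
glance.recovery_experiment <- function(x, ...) {
  truth <- attr(x, "truth")
  tibble(
    n_reps = nrow(x),
    truth = truth,
    naive_mean = mean(x$naive_estimate),
    tsri_mean = mean(x$tsri_estimate),
    naive_bias = mean(x$naive_estimate) - truth,
    tsri_bias = mean(x$tsri_estimate) - truth,
    coverage = mean(x$covered),
    tsri_closer_share = mean(x$tsri_closer),
    mean_cragg_donald_f = mean(x$cragg_donald_f)
  )
}

#' @rdname tidiers
#' @export
glance.null_calibration <- function(x, ...) {
  alpha <- attr(x, "alpha")
  tibble(
    n_reps = nrow(x),
    alpha = alpha,
    tsri_type1 = mean(x$tsri_p < alpha),
    naive_type1 = mean(x$naive_p < alpha),
    tsri_mean = mean(x$tsri_estimate),
    naive_mean = mean(x$naive_estimate)
  )
}
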