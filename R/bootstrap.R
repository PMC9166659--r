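# Shared assembly of a bootstrap CI table (percentile + normal).
boot_ci_table <- function(estimates, draws, conf_level, n_failed, n_reps,
                          resample_unit) {
  a <- (1 - conf_level) / 2
  zq <- qnorm(1 - a)
  ok <- stats::complete.cases(draws)
  out <- purrr::imap_dfr(estimates, function(est, term) {
    d <- draws[ok, term]
    tibble(
      term = term,
      estimate = est,
      std.error = sd(d),
      conf.low = quantile(d, a, names = FALSE),
      conf.high = quantile(d, 1 - a, names = FALSE),
      conf.low.norm = est - zq * sd(d),
      conf.high.norm = est + zq * sd(d)
    )
  })
  structure(out, n_failed = n_failed, n_reps = n_reps,
            resample_unit = resample_unit, replicates = draws,
            conf_level = conf_level,
            class = c("boot_ci", class(tibble())))
}

#' Bootstrap confidence intervals for an estimator
#'
#' Nonparametric bootstrap of an arbitrary estimator of the analytic
#' table: the full estimation procedure is rerun on every resample (for
#' two-stage estimators this means first-stage residuals are recomputed in
#' every replicate). Resampling is at the encounter level or as a cluster
#' bootstrap over providers. Both percentile and normal-approximation
#' intervals are returned. Replicates in which the estimator fails are
#' logged and excluded; more than 20% failures is a hard error.
#'
#' @param data A data frame (typically `encounter_records`).
#' @param estimator Function taking a resampled data frame and returning a
#'   named numeric vector of coefficients.
#' @param n_reps Number of bootstrap replicates (>= 200 recommended; the
#'   default follows the package's standard of 500).
#' @param seed Integer seed; fixed seed gives identical intervals.
#' @param resample_unit `"encounter"` or `"provider"`.
#' @param conf_level Confidence level.
#' @return A tibble of class `boot_ci` with columns `term`, `estimate`
#'   (full-sample), `std.error` (bootstrap SE), `conf.low`/`conf.high`
#'   (percentile) and `conf.low.norm`/`conf.high.norm`; attributes carry
#'   the replicate matrix and failure count.
#' @export
#' @examples
#' d <- tibble::tibble(x = rnorm(100))
#' bootstrap_inference(d, function(df) c(mean = mean(df$x)),
#'                     n_reps = 200, seed = 1)
bootstrap_inference <- function(data, estimator, n_reps = 500, seed = 1L,
                                resample_unit = c("encounter", "provider"),
                                conf_level = 0.95) {
  resample_unit <- rlang::arg_match(resample_unit)
  if (n_reps < 2) abort("n_reps must be at least 2")
  est0 <- estimator(data)
  if (is.null(names(est0))) {
    names(est0) <- paste0("stat", seq_along(est0))
  }
  set.seed(seed)
  n <- nrow(data)
  prov_rows <- if (resample_unit == "provider") {
    split(seq_len(n), data$provider_id)
  } else NULL
  draws <- matrix(NA_real_, n_reps, length(est0),
                  dimnames = list(NULL, names(est0)))
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    idx <- if (is.null(prov_rows)) {
      sample.int(n, n, replace = TRUE)
    } else {
      unlist(prov_rows[sample.int(length(prov_rows), length(prov_rows),
                                  replace = TRUE)], use.names = FALSE)
    }
    val <- tryCatch(estimator(data[idx, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(val) || anyNA(val)) {
      n_failed <- n_failed + 1L
    } else {
      draws[r, ] <- val[names(est0)]
    }
  }
  if (n_failed > 0.2 * n_reps) {
    abort(glue::glue(
      "{n_failed} of {n_reps} bootstrap replicates failed (> 20%); ",
      "the estimator is unstable on these data"
    ))
  }
  boot_ci_table(est0, draws, conf_level, n_failed, n_reps, resample_unit)
}

#' @export
print.boot_ci <- function(x, ...) {
  cat(sprintf("Bootstrap CIs: %d replicates (%d failed), %s resampling, %.0f%% level\n",
              attr(x, "n_reps"), attr(x, "n_failed"),
              attr(x, "resample_unit"), 100 * attr(x, "conf_level")))
  NextMethod()
}
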