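#' Run the full analysis pipeline end-to-end
#'
#' Orchestrates simulation (optional), cohort construction, variable
#' building, estimation under all requested specifications, and table
#' rendering, producing a run manifest with row counts at every filter
#' step and all warnings (dropped encounters, clipped probabilities,
#' failed bootstrap replicates). The run is deterministic given the seeds.
#'
#' @param config A [sim_config()] used to simulate an event bundle, or
#'   `NULL` when `bundle` is supplied.
#' @param bundle An existing `event_bundle` (skips simulation).
#' @param cohort_cfg A [cohort_config()]; defaults to the bundle's window.
#' @param estimators Character subset of
#'   `c("primary", "2sri", "ols", "2sls")`.
#' @param facility Facility-effect treatment for the logistic models.
#' @param boot_reps Bootstrap replicates for the 2SRI fit (0 to skip).
#' @param seed Seed (simulation uses `config$seed` unless overridden).
#' @param quiet Suppress progress messages.
#' @return A list of class `dup_pipeline`: `bundle`, `truth` (when
#'   simulated), `records`, `descriptives`, `fits` (named list),
#'   `tables` (rendered), and `manifest` (class `run_manifest`).
#' @export
run_pipeline <- function(config = sim_config(),
                         bundle = NULL,
                         cohort_cfg = NULL,
                         estimators = c("primary", "2sri", "ols", "2sls"),
                         facility = c("random", "fixed", "none"),
                         boot_reps = 0,
                         seed = NULL,
                         quiet = FALSE) {
  facility <- rlang::arg_match(facility)
  estimators <- match.arg(estimators, c("primary", "2sri", "ols", "2sls"),
                          several.ok = TRUE)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(glue::glue("{name} stage failed: {conditionMessage(e)}"),
            parent = e)
    })
  }

  truth <- NULL
  if (is.null(bundle)) {
    sim <- stage("simulate", simulate_ehr(config, seed = seed))
    bundle <- sim$bundle
    truth <- sim$truth
    used_seed <- if (is.null(seed)) config$seed else as.integer(seed)
  } else {
    used_seed <- as.integer(seed %||% 1L)
  }
  cohort_cfg <- cohort_cfg %||% cohort_config_for(bundle)

  records <- stage("cohort/variables",
                   build_analytic(bundle, cohort_cfg, quiet = quiet))
  descriptives <- stage("descriptives", descriptive_table(records))

  fits <- list()
  if ("primary" %in% estimators) {
    fits$primary <- stage("estimate",
                          fit_primary_logistic(records, facility = facility))
  }
  if ("2sri" %in% estimators) {
    fits$tsri <- stage("estimate",
                       fit_2sri(records, facility = facility,
                                boot_reps = boot_reps,
                                seed = child_seed(used_seed, 77L)))
  }
  if ("ols" %in% estimators) {
    fits$ols <- stage("estimate", fit_ols(records))
  }
  if ("2sls" %in% estimators) {
    fits$tsls <- stage("estimate", fit_2sls(records))
  }
  tables <- stage("render", render_tables(records, fits,
                                          descriptives = descriptives))

  counts <- attr(records, "counts")
  manifest <- structure(
    list(
      package_version = as.character(utils::packageVersion("dupimaging")),
      config_hash = rlang::hash(list(config = if (is.null(truth)) NULL else
        truth$config, cohort = cohort_cfg)),
      seeds = c(master = used_seed,
                bootstrap = if (boot_reps > 0) child_seed(used_seed, 77L)
                else NA_integer_),
      counts = counts,
      warnings = list(
        dropped_no_history = unname(counts["dropped_no_history"]),
        clipped_probs = if (!is.null(fits$tsri)) fits$tsri$n_clipped else 0L,
        failed_boot_reps = if (!is.null(fits$tsri$bootstrap))
          attr(fits$tsri$bootstrap, "n_failed") else 0L,
        nonconverged = names(Filter(
          function(f) inherits(f, "dupfit") && !f$converged, fits))
      ),
      estimators = estimators,
      elapsed_secs = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    ),
    class = "run_manifest"
  )

  structure(
    list(bundle = bundle, truth = truth, records = records,
         descriptives = descriptives, fits = fits, tables = tables,
         manifest = manifest),
    class = "dup_pipeline"
  )
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>\n")
  cat("  config hash:", x$config_hash, "\n")
  cat("  seeds:", paste(names(x$seeds), x$seeds, sep = "=", collapse = ", "),
      "\n")
  cat("  counts:\n")
  for (nm in names(x$counts)) {
    cat(sprintf("    %-22s %d\n", nm, x$counts[[nm]]))
  }
  cat(sprintf("  warnings: %d dropped, %d clipped, %d failed bootstrap reps\n",
              x$warnings$dropped_no_history, x$warnings$clipped_probs,
              x$warnings$failed_boot_reps))
  cat(sprintf("  elapsed: %.1f s\n", x$elapsed_secs))
  invisible(x)
}

#' @export
print.dup_pipeline <- function(x, ...) {
  cat("<dup_pipeline>\n")
  cat(sprintf("  %d analytic encounters; estimators: %s\n",
              nrow(x$records), paste(names(x$fits), collapse = ", ")))
  print(x$manifest)
  invisible(x)
}
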