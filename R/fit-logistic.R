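# The default exogenous covariate block used across every specification:
# ordering-rate quartile, provider type, gender, age band, race, Elixhauser
# bin and fiscal month (all factors with fixed reference levels).
default_covariates <- function(month = TRUE) {
  c("order_rate_quartile", "provider_type", "gender", "age_band", "race",
    "elix_bin", if (month) "fiscal_month")
}

# Shared formula builder. `facility` adds random intercepts (lme4), fixed
# effects, or nothing.
build_formula <- function(outcome, rhs_terms, facility) {
  rhs <- if (length(rhs_terms) == 0) "1" else paste(rhs_terms, collapse = " + ")
  rhs <- switch(facility,
    random = paste(rhs, "+ (1 | facility_id)"),
    fixed = paste(rhs, "+ facility_id"),
    none = rhs
  )
  as.formula(paste(outcome, "~", rhs))
}

new_dupfit <- function(model, coefficients, engine, outcome, exposure,
                       facility, n, converged, separation, formula) {
  structure(
    list(model = model, coefficients = coefficients, engine = engine,
         outcome = outcome, exposure = exposure, facility = facility,
         n = n, converged = converged, separation = separation,
         formula = formula),
    class = "dupfit"
  )
}

coef_table <- function(est, se, conf_level = 0.95) {
  zq <- qnorm(1 - (1 - conf_level) / 2)
  tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(est / se),
    p.value = 2 * pnorm(-abs(est / se)),
    conf.low = unname(est - zq * se),
    conf.high = unname(est + zq * se)
  )
}

#' Logistic regression of duplicate imaging on a viewer-use exposure
#'
#' The primary specification: a logistic model of the duplicate-imaging
#' outcome on a viewer-use exposure (by default the provider-history flag
#' `jlv_provider`, whose assignment is plausibly exogenous to the
#' individual patient) plus the exogenous covariate block, fiscal-month
#' effects and facility random intercepts.
#'
#' Facility heterogeneity can be modelled as random intercepts (lme4
#' Laplace fit, the default), as fixed effects, or omitted; single-facility
#' data fall back to `"none"` automatically. Non-convergence and
#' (quasi-)complete separation are detected and flagged on the returned
#' object, never silently ignored.
#'
#' @param data An `encounter_records` tibble (or any data frame with the
#'   referenced columns).
#' @param exposure Name of the binary exposure column.
#' @param covariates Character vector of exogenous covariate columns;
#'   `NULL` for an exposure-only model.
#' @param outcome Name of the binary outcome column.
#' @param facility `"random"`, `"fixed"` or `"none"`.
#' @param conf_level Confidence level for Wald intervals.
#' @return An object of class `dupfit`. Use [tidy()] (optionally with
#'   `exponentiate = TRUE` for odds ratios), [glance()], and
#'   [average_incremental_effect()].
#' @export
fit_primary_logistic <- function(data,
                                 exposure = "jlv_provider",
                                 covariates = default_covariates(),
                                 outcome = "duplicate_image",
                                 facility = c("random", "fixed", "none"),
                                 conf_level = 0.95) {
  facility <- rlang::arg_match(facility)
  assert_columns(data, c(outcome, exposure, covariates), "data")
  if (facility != "none") {
    if (!"facility_id" %in% names(data) ||
        dplyr::n_distinct(data$facility_id) < 2) {
      facility <- "none"
    }
  }
  df <- droplevels(as.data.frame(data))
  y <- df[[outcome]]
  if (length(unique(y)) < 2) {
    abort(glue::glue("outcome `{outcome}` is constant; the model is unidentified"))
  }
  fml <- build_formula(outcome, c(exposure, covariates), facility)

  converged <- TRUE
  if (facility == "random") {
    model <- withCallingHandlers(
      lme4::glmer(fml, data = df, family = binomial(),
                  control = lme4::glmerControl(calc.derivs = FALSE)),
      warning = function(w) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    )
    if (length(model@optinfo$conv$lme4) > 0) converged <- FALSE
    est <- lme4::fixef(model)
    se <- sqrt(diag(as.matrix(vcov(model))))
    mu <- fitted(model)
  } else {
    model <- suppressWarnings(glm(fml, data = df, family = binomial()))
    converged <- model$converged
    est <- coef(model)
    keep <- !is.na(est)
    est <- est[keep]
    se <- sqrt(diag(vcov(model)))[names(est)]
    mu <- fitted(model)
  }
  separation <- any(abs(est) > 15) || any(mu < 1e-8) || any(mu > 1 - 1e-8)
  if (separation) {
    warn("possible (quasi-)complete separation detected; estimates flagged")
  }
  new_dupfit(model, coef_table(est, se, conf_level), engine =
               if (facility == "random") "glmer" else "glm",
             outcome = outcome, exposure = exposure, facility = facility,
             n = nrow(df), converged = converged, separation = separation,
             formula = fml)
}

#' @export
print.dupfit <- function(x, ...) {
  cat(sprintf("<dupfit> %s, n = %d, facility: %s\n", x$engine, x$n, x$facility))
  if (!x$converged) cat("  ! convergence not attained\n")
  if (x$separation) cat("  ! possible separation\n")
  exp_terms <- grep(x$exposure, x$coefficients$term, value = TRUE)
  row <- x$coefficients[x$coefficients$term %in% exp_terms, ]
  if (nrow(row) > 0) {
    cat(sprintf("  %s: OR %.3f (%.3f-%.3f), p = %.3g\n", row$term[1],
                exp(row$estimate[1]), exp(row$conf.low[1]),
                exp(row$conf.high[1]), row$p.value[1]))
  }
  invisible(x)
}
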