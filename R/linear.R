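#' Cragg-Donald weak-instrument F statistic
#'
#' Fits the linear version of the first stage (least squares of the
#' endogenous exposure on the instrument plus the exogenous block) and
#' tests the excluded instrument. With a single instrument the statistic
#' equals the squared t statistic of the instrument's coefficient under
#' homoskedasticity. An F above 10 is conventionally read as a strong
#' instrument.
#'
#' @inheritParams fit_2sri
#' @return A list of class `cragg_donald`: `statistic`, `df1`, `df2`,
#'   `p.value`, `strong` (F > 10), `t` (instrument t statistic) and
#'   `unbounded` (TRUE when the first stage is essentially noiseless and F
#'   is reported as a very large number).
#' @export
cragg_donald_f <- function(data,
                           exposure = "jlv_encounter",
                           instrument = "jlv_provider",
                           covariates = default_covariates()) {
  assert_columns(data, c(exposure, instrument, covariates), "data")
  df <- droplevels(as.data.frame(data))
  fml <- build_formula(exposure, c(instrument, covariates), "none")
  fit <- lm(fml, data = df)
  cf <- coef(fit)
  if (anyNA(cf)) {
    abort(glue::glue(
      "collinear design: coefficient(s) not estimable for ",
      "{paste(names(cf)[is.na(cf)], collapse = ', ')}"
    ))
  }
  sm <- summary(fit)
  tt <- sm$coefficients[instrument, "t value"]
  f <- tt^2
  df2 <- fit$df.residual
  unbounded <- !is.finite(f) || f > 1e12
  if (unbounded) f <- 1e12
  structure(
    list(statistic = f, df1 = 1L, df2 = df2,
         p.value = pf(f, 1, df2, lower.tail = FALSE),
         strong = f > 10, t = tt, unbounded = unbounded),
    class = "cragg_donald"
  )
}

#' @export
print.cragg_donald <- function(x, ...) {
  cat(sprintf("Cragg-Donald Wald F = %.2f on (%d, %d) df, p = %.3g -> %s instrument%s\n",
              x$statistic, x$df1, x$df2, x$p.value,
              if (x$strong) "strong" else "weak",
              if (x$unbounded) " (noiseless first stage; F unbounded)" else ""))
  invisible(x)
}

#' Linear probability model of duplicate imaging (OLS robustness check)
#'
#' Ordinary least squares of the binary outcome on the provider-history
#' exposure and the exogenous block, with heteroskedasticity-robust (HC1)
#' standard errors.
#'
#' @inheritParams fit_primary_logistic
#' @param se `"HC1"` (robust, default) or `"classical"`.
#' @return A `duplin` object (linear fit wrapper with a `coefficients`
#'   tibble); works with [tidy()] and [glance()].
#' @export
fit_ols <- function(data,
                    exposure = "jlv_provider",
                    covariates = default_covariates(),
                    outcome = "duplicate_image",
                    se = c("HC1", "classical"),
                    conf_level = 0.95) {
  se <- rlang::arg_match(se)
  assert_columns(data, c(outcome, exposure, covariates), "data")
  df <- droplevels(as.data.frame(data))
  fml <- build_formula(outcome, c(exposure, covariates), "none")
  fit <- lm(fml, data = df)
  if (anyNA(coef(fit))) {
    abort(glue::glue(
      "rank-deficient design: {paste(names(coef(fit))[is.na(coef(fit))],
                                     collapse = ', ')}"
    ))
  }
  V <- if (se == "HC1") sandwich::vcovHC(fit, type = "HC1") else vcov(fit)
  ct <- lmtest::coeftest(fit, vcov. = V)
  structure(
    list(model = fit,
         coefficients = coef_table(ct[, 1], ct[, 2], conf_level),
         engine = "lm", se = se, outcome = outcome, exposure = exposure,
         n = nrow(df), method = "ols"),
    class = "duplin"
  )
}

#' Linear two-stage least squares (2SLS robustness check)
#'
#' Instrumental-variable linear model of the binary outcome on the
#' endogenous visit-level exposure, instrumenting with the
#' provider-history flag. Estimated by projection ("generalised" 2SLS)
#' with heteroskedasticity-robust sandwich standard errors computed from
#' the structural residuals. With no covariates and binary instrument and
#' exposure the estimate reduces to the classical Wald IV ratio.
#'
#' @inheritParams fit_2sri
#' @param se `"HC1"` or `"classical"`.
#' @return A `duplin` object.
#' @export
fit_2sls <- function(data,
                     exposure = "jlv_encounter",
                     instrument = "jlv_provider",
                     covariates = default_covariates(),
                     outcome = "duplicate_image",
                     se = c("HC1", "classical"),
                     conf_level = 0.95) {
  se <- rlang::arg_match(se)
  assert_columns(data, c(outcome, exposure, instrument, covariates), "data")
  df <- droplevels(as.data.frame(data))
  y <- df[[outcome]]
  exog <- if (length(covariates) == 0) {
    matrix(1, nrow(df), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    model.matrix(reformulate(covariates), data = df)
  }
  X <- cbind(matrix(df[[exposure]], ncol = 1,
                    dimnames = list(NULL, exposure)), exog)
  Z <- cbind(matrix(df[[instrument]], ncol = 1,
                    dimnames = list(NULL, instrument)), exog)
  qrZ <- qr(Z)
  if (qrZ$rank < ncol(Z)) {
    abort(glue::glue("rank-deficient instrument block ",
                     "(rank {qrZ$rank} < {ncol(Z)} columns)"))
  }
  Xhat <- qr.fitted(qrZ, X)
  A <- crossprod(Xhat)
  if (qr(A)$rank < ncol(X)) {
    abort("rank-deficient projected design; 2SLS not identified")
  }
  beta <- drop(solve(A, crossprod(Xhat, y)))
  names(beta) <- colnames(X)
  u <- y - drop(X %*% beta)      # structural residuals (original exposure)
  n <- nrow(X)
  k <- ncol(X)
  V <- if (se == "HC1") {
    meat <- crossprod(Xhat * u)
    n / (n - k) * solve(A, t(solve(A, t(meat))))
  } else {
    sum(u^2) / (n - k) * solve(A)
  }
  structure(
    list(model = list(beta = beta, vcov = V, residuals = u, Xhat = Xhat),
         coefficients = coef_table(beta, sqrt(diag(V)), conf_level),
         engine = "iv", se = se, outcome = outcome, exposure = exposure,
         instrument = instrument, n = n, method = "2sls"),
    class = "duplin"
  )
}

#' @export
print.duplin <- function(x, ...) {
  cat(sprintf("<duplin> %s, n = %d, %s SEs\n", toupper(x$method), x$n, x$se))
  row <- x$coefficients[x$coefficients$term == x$exposure, ]
  if (nrow(row) == 1) {
    cat(sprintf("  %s: %.4f (%.4f-%.4f), p = %.3g\n", x$exposure,
                row$estimate, row$conf.low, row$conf.high, row$p.value))
  }
  invisible(x)
}
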