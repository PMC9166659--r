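# Thin wrappers around the compiled IRLS solver. These operate on dense
# model matrices and are used wherever thousands of refits are needed
# (bootstrap replicates, recovery/calibration experiments). Zero-variance
# columns (e.g. factor levels lost in a bootstrap resample) are dropped
# before solving and reported back as NA coefficients.

fast_logit <- function(X, y, tol = 1e-8, max_iter = 100L, init = NULL) {
  keep <- c(TRUE, matrixStats_colsd_nonzero(X[, -1, drop = FALSE]))
  if (!is.null(init)) init <- init[keep]
  fit <- .logit_irls(X[, keep, drop = FALSE], y, tol, max_iter,
                     init = if (is.null(init) || anyNA(init)) NULL else init)
  if (isTRUE(fit$singular)) {
    abort("singular system in logistic fit (collinear design)")
  }
  beta <- rep(NA_real_, ncol(X))
  beta[keep] <- as.vector(fit$coefficients)
  names(beta) <- colnames(X)
  list(coefficients = beta, fitted = as.vector(fit$fitted),
       converged = isTRUE(fit$converged), deviance = fit$deviance,
       kept = keep)
}

# TRUE for columns with any variation (cheap, avoids matrixStats dep)
matrixStats_colsd_nonzero <- function(X) {
  if (ncol(X) == 0) return(logical(0))
  rng_lo <- apply(X, 2, min)
  rng_hi <- apply(X, 2, max)
  rng_hi > rng_lo
}

# Naive (information-matrix) standard errors for a fast logistic fit.
fast_logit_se <- function(X, fitted, kept) {
  Xk <- X[, kept, drop = FALSE]
  w <- fitted * (1 - fitted)
  V <- solve(crossprod(Xk * sqrt(w)))
  se <- rep(NA_real_, ncol(X))
  se[kept] <- sqrt(diag(V))
  names(se) <- colnames(X)
  se
}

# Build the pieces of the estimation design from an analytic table:
# exogenous block (with intercept), outcome, endogenous exposure and
# instrument, plus cluster ids for provider-level resampling.
analytic_matrices <- function(records, covariates = default_covariates()) {
  df <- droplevels(as.data.frame(records))
  X <- if (length(covariates) == 0) {
    matrix(1, nrow(df), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    model.matrix(reformulate(covariates), data = df)
  }
  list(
    X_exog = X,
    y = df$duplicate_image,
    x_e = df$jlv_encounter,
    w = df$jlv_provider,
    provider = df$provider_id
  )
}

# One full two-stage residual-inclusion pass on matrices: logistic first
# stage of x_e on (instrument + exogenous block), Anscombe residuals from
# clipped fitted probabilities, logistic second stage of y on
# (x_e + exogenous block + residual). Returns the coefficients of interest
# and the ingredients needed for Wald SEs.
two_stage_core <- function(X_exog, w, x_e, y, clip_eps = 1e-6,
                           init1 = NULL, init2 = NULL,
                           residual = "anscombe") {
  X1 <- cbind(X_exog, instrument = w)
  f1 <- fast_logit(X1, x_e, init = init1)
  if (f1$deviance < 1e-6) {
    abort(paste("first stage exhibits perfect prediction;",
                "two-stage model cannot be identified"))
  }
  mu <- clip_probs(f1$fitted, clip_eps)
  n_clipped <- attr(mu, "n_clipped")
  mu <- as.vector(mu)
  resid <- stage1_residual(residual, x_e, mu)
  rname <- paste0(residual, "_resid")
  X2 <- cbind(X_exog, jlv_encounter = x_e, resid)
  colnames(X2)[ncol(X2)] <- rname
  f2 <- fast_logit(X2, y, init = init2)
  list(
    beta_e = unname(f2$coefficients["jlv_encounter"]),
    beta_resid = unname(f2$coefficients[rname]),
    stage1 = f1, stage2 = f2, X1 = X1, X2 = X2, resid_term = rname,
    residuals = resid, n_clipped = n_clipped
  )
}
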