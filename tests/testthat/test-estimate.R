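# Independent quadrature oracle for the Anscombe transform, built on the
# defining integral rather than the incomplete-beta identity used by the
# implementation.
anscombe_quad <- function(u) {
  vapply(u, function(ui) {
    integrate(function(t) t^(-1 / 3) * (1 - t)^(-1 / 3), 0, ui,
              rel.tol = 1e-12)$value
  }, numeric(1))
}

test_that("the Anscombe transform matches adaptive quadrature", {
  set.seed(42)
  u <- runif(40, 0.01, 0.99)
  expect_equal(anscombe_transform(u), anscombe_quad(u), tolerance = 1e-10)
  # symmetry of the integrand about 1/2
  expect_equal(anscombe_transform(0.5), anscombe_transform(1) / 2,
               tolerance = 1e-12)
  # monotone increasing on (0, 1)
  g <- anscombe_transform(seq(0.001, 0.999, length.out = 200))
  expect_true(all(diff(g) > 0))
})

test_that("Anscombe residuals have the right sign, limits and guards", {
  mu <- c(0.1, 0.5, 0.9)
  expect_true(all(anscombe_residual(rep(1, 3), mu) > 0))
  expect_true(all(anscombe_residual(rep(0, 3), mu) < 0))
  # perfect-fit limits
  expect_lt(abs(anscombe_residual(1, 1 - 1e-9)), 1e-4)
  expect_lt(abs(anscombe_residual(0, 1e-9)), 1e-4)
  # the oracle value at (y = 1, mu = 1/2)
  want <- (anscombe_quad(1) - anscombe_quad(0.5)) / (0.25)^(1 / 6)
  expect_equal(anscombe_residual(1, 0.5), want, tolerance = 1e-10)
  expect_error(anscombe_residual(1, 1), "strictly inside")
  expect_error(anscombe_residual(0, 0), "strictly inside")
  expect_error(anscombe_residual(2, 0.5), "binary")
})

test_that("saturated logistic odds ratio equals the cross-product ratio", {
  # group counts: exposed 36 events / 587, unexposed 34 / 305
  d <- tibble::tibble(
    duplicate_image = c(rep(1L, 36), rep(0L, 551), rep(1L, 34), rep(0L, 271)),
    jlv_provider = rep(c(1L, 0L), c(587, 305))
  )
  fit <- fit_primary_logistic(d, covariates = NULL, facility = "none")
  or <- exp(fit$coefficients$estimate[fit$coefficients$term == "jlv_provider"])
  expect_equal(or, (36 * 271) / (551 * 34), tolerance = 1e-8)
})

test_that("single-instrument Cragg-Donald F equals the squared t statistic", {
  sim <- simulate_ehr(mid_config(seed = 3))
  recs <- build_analytic(sim$bundle, quiet = TRUE)
  cd <- cragg_donald_f(recs)
  fml <- dupimaging:::build_formula("jlv_encounter",
                                    c("jlv_provider", default_covariates()),
                                    "none")
  tt <- summary(lm(fml, data = recs))$coefficients["jlv_provider", "t value"]
  expect_equal(cd$statistic, tt^2, tolerance = 1e-8)
  expect_true(cd$strong)
})

test_that("a null instrument yields F with the nominal rejection rate", {
  set.seed(99)
  rejections <- vapply(1:500, function(i) {
    d <- tibble::tibble(
      jlv_encounter = rbinom(200, 1, 0.4),
      jlv_provider = rbinom(200, 1, 0.5)
    )
    cragg_donald_f(d, covariates = character(0))$p.value < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.02)
  expect_lt(mean(rejections), 0.09)
})

test_that("a noiseless first stage reports an unbounded F with a flag", {
  d <- tibble::tibble(
    jlv_provider = rep(c(0L, 1L), each = 50),
    jlv_encounter = rep(c(0L, 1L), each = 50)
  )
  cd <- suppressWarnings(cragg_donald_f(d, covariates = character(0)))
  expect_true(cd$unbounded)
  expect_true(cd$strong)
  expect_gte(cd$statistic, 1e12)
})

test_that("collinear designs raise a hard error naming the columns", {
  sim <- simulate_ehr(small_config(seed = 5))
  recs <- build_analytic(sim$bundle, quiet = TRUE)
  recs$copy_of_w <- recs$jlv_provider
  expect_error(
    cragg_donald_f(recs, covariates = c("copy_of_w")),
    "collinear"
  )
})

test_that("covariate-free 2SLS equals the closed-form Wald IV estimator", {
  set.seed(7)
  n <- 600
  w <- rbinom(n, 1, 0.5)
  x <- rbinom(n, 1, plogis(-1 + 2 * w))
  y <- rbinom(n, 1, plogis(-1.5 + 0.8 * x))
  d <- tibble::tibble(duplicate_image = y, jlv_encounter = x,
                      jlv_provider = w)
  fit <- fit_2sls(d, covariates = character(0))
  b <- fit$coefficients$estimate[fit$coefficients$term == "jlv_encounter"]
  wald <- (mean(y[w == 1]) - mean(y[w == 0])) /
    (mean(x[w == 1]) - mean(x[w == 0]))
  expect_equal(b, wald, tolerance = 1e-10)
})

test_that("with the exposure as its own instrument, 2SLS collapses to OLS", {
  sim <- simulate_ehr(small_config(seed = 11))
  recs <- build_analytic(sim$bundle, quiet = TRUE)
  recs$self <- recs$jlv_encounter
  iv <- fit_2sls(recs, exposure = "jlv_encounter", instrument = "self")
  ols <- lm(dupimaging:::build_formula("duplicate_image",
                                       c("jlv_encounter",
                                         default_covariates()), "none"),
            data = droplevels(recs))
  expect_equal(
    iv$coefficients$estimate[iv$coefficients$term == "jlv_encounter"],
    unname(coef(ols)["jlv_encounter"]),
    tolerance = 1e-8
  )
})

test_that("the average incremental effect matches direct computation", {
  sim <- simulate_ehr(mid_config(seed = 19))
  recs <- build_analytic(sim$bundle, quiet = TRUE)
  fit <- fit_primary_logistic(recs, facility = "none")
  aie <- average_incremental_effect(fit, recs)
  # independent recomputation from the coefficient vector and model matrix
  df1 <- df0 <- droplevels(as.data.frame(recs))
  df1$jlv_provider <- 1
  df0$jlv_provider <- 0
  X1 <- model.matrix(stats::delete.response(stats::terms(fit$model)), df1)
  X0 <- model.matrix(stats::delete.response(stats::terms(fit$model)), df0)
  bhat <- coef(fit$model)
  want <- mean(plogis(X1 %*% bhat) - plogis(X0 %*% bhat))
  expect_equal(aie, want, tolerance = 1e-10)
  expect_gt(aie, -1)
  expect_lt(aie, 1)
})

test_that("AIE has closed form in the intercept-plus-target model", {
  # large-sample fit of a model whose true coefficients are (0, 1)
  set.seed(12)
  n <- 200000
  x <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(0 + 1 * x))
  d <- tibble::tibble(duplicate_image = y, jlv_provider = x)
  fit <- fit_primary_logistic(d, covariates = NULL, facility = "none")
  aie <- average_incremental_effect(fit, d)
  expect_equal(aie, plogis(1) - 0.5, tolerance = 0.03)
  # and a literally zero coefficient gives a literally zero AIE
  fit0 <- fit
  fit0$model$coefficients["jlv_provider"] <- 0
  expect_equal(average_incremental_effect(fit0, d), 0, tolerance = 1e-12)
})

test_that("bootstrap of a sample mean recovers the analytic standard error", {
  set.seed(3)
  d <- tibble::tibble(x = rnorm(500, 2, 3))
  b <- bootstrap_inference(d, function(df) c(mean = mean(df$x)),
                           n_reps = 500, seed = 21)
  analytic <- sd(d$x) / sqrt(500)
  expect_lt(abs(b$std.error - analytic) / analytic, 0.15)
  # determinism: identical CI on rerun with the same seed
  b2 <- bootstrap_inference(d, function(df) c(mean = mean(df$x)),
                            n_reps = 500, seed = 21)
  expect_identical(as.data.frame(b), as.data.frame(b2))
})

test_that("an estimator failing in every replicate is a hard error", {
  d <- tibble::tibble(y = rep(0, 60))
  est <- function(df) {
    if (var(df$y) == 0) stop("constant outcome")
    c(mean = mean(df$y))
  }
  expect_error(bootstrap_inference(d, est, n_reps = 20, seed = 1),
               "constant outcome|replicates failed")
})

test_that("a constant outcome aborts the two-stage model", {
  sim <- simulate_ehr(small_config(seed = 41))
  recs <- build_analytic(sim$bundle, quiet = TRUE)
  recs$duplicate_image <- 0L
  expect_error(fit_2sri(recs), "constant")
})

test_that("under exogeneity the residual is uninformative and 2SRI tracks the naive fit", {
  cfg <- mid_config(n_patients = 6000, n_providers = 180, seed = 29,
                    alpha_u = 0, beta_u = 0)
  recs <- build_analytic(simulate_ehr(cfg)$bundle, quiet = TRUE)
  ts <- fit_2sri(recs, boot_reps = 200, seed = 5)
  naive <- fit_primary_logistic(recs, exposure = "jlv_encounter",
                                facility = "none")
  b_ts <- ts$second_stage$coefficients
  b_ts <- b_ts[b_ts$term == "jlv_encounter", ]
  b_nv <- naive$coefficients[naive$coefficients$term == "jlv_encounter", ]
  se_boot <- ts$bootstrap$std.error[ts$bootstrap$term == "jlv_encounter"]
  expect_lt(abs(b_ts$estimate - b_nv$estimate), 2 * se_boot)
  resid_row <- ts$bootstrap[ts$bootstrap$term == "anscombe_resid", ]
  expect_lt(resid_row$conf.low, 0)
  expect_gt(resid_row$conf.high, 0)
})

test_that("with confounding on, the residual coefficient is positive", {
  cfg <- mid_config(n_patients = 20000, n_providers = 600, seed = 37)
  recs <- build_analytic(simulate_ehr(cfg)$bundle, quiet = TRUE)
  ts <- fit_2sri(recs)
  row <- ts$second_stage$coefficients
  row <- row[row$term == "anscombe_resid", ]
  expect_gt(row$estimate, 0)
  expect_gt(row$statistic, 1.64)   # significantly > 0, one-sided 5%
})

test_that("one-stage logistic recovers a provider-level effect without confounding", {
  # visit-level use pinned to the provider class; beta_u = alpha_u = 0
  ests <- vapply(1:10, function(i) {
    cfg <- provider_effect_config(n_patients = 6000, n_providers = 180,
                                  seed = 100 + i)
    recs <- build_analytic(simulate_ehr(cfg)$bundle, quiet = TRUE)
    fit <- fit_primary_logistic(recs, facility = "none")
    fit$coefficients$estimate[fit$coefficients$term == "jlv_provider"]
  }, numeric(1))
  expect_lt(abs(mean(ests) - log(0.44)), 0.12)
})

test_that("alternative first-stage residual kinds follow their formulas", {
  sim <- simulate_ehr(small_config(n_patients = 600, n_providers = 25,
                                   seed = 53))
  recs <- build_analytic(simulate_ehr(small_config(n_patients = 600,
                                                   n_providers = 25,
                                                   seed = 53))$bundle,
                         quiet = TRUE)
  for (kind in c("anscombe", "deviance", "raw")) {
    ts <- fit_2sri(recs, residual_kind = kind)
    expect_equal(ts$resid_term, paste0(kind, "_resid"))
    expect_true(ts$resid_term %in% ts$second_stage$coefficients$term)
    # residual recomputed independently from the stored first stage
    mu <- fitted(ts$first_stage$model)
    mu <- pmin(pmax(mu, 1e-6), 1 - 1e-6)
    x <- recs$jlv_encounter
    want <- switch(kind,
      anscombe = anscombe_residual(x, mu),
      deviance = sign(x - mu) *
        sqrt(-2 * (x * log(mu) + (1 - x) * log(1 - mu))),
      raw = x - mu
    )
    expect_equal(unname(ts$residuals), unname(want), tolerance = 1e-12)
    # residual sign always matches the sign of (x - mu)
    expect_true(all(sign(ts$residuals) == sign(x - mu)))
  }
})

test_that("tidy and glance expose coefficients and diagnostics", {
  sim <- simulate_ehr(small_config(n_patients = 600, n_providers = 25,
                                   seed = 43))
  recs <- build_analytic(sim$bundle, quiet = TRUE)
  fit <- fit_primary_logistic(recs, facility = "none")
  td <- tidy(fit, exponentiate = TRUE)
  expect_true(all(c("term", "estimate", "conf.low", "conf.high",
                    "p.value") %in% names(td)))
  expect_equal(td$estimate,
               exp(tidy(fit)$estimate))
  ts <- fit_2sri(recs)
  g <- glance(ts)
  expect_equal(g$n, nrow(recs))
  expect_true(is.finite(g$cragg_donald_f))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(ts), "ggplot")
})
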