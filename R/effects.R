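#' Average incremental effect of a binary covariate
#'
#' The mean, over the analytic sample, of the difference in predicted
#' outcome probability when the target covariate is switched from 0 to 1
#' while every other covariate keeps its observed value. In a logistic
#' model this is a nonlinear function of all coefficients and covariate
#' values, and is the probability-scale companion to the odds ratio. For a
#' two-stage residual-inclusion fit the first-stage residual is held at
#' its computed value.
#'
#' @param fit A `dupfit`, `dup2sri` or `duplin` object.
#' @param data The data the fit was estimated on (defaults to the model
#'   frame stored in the fit where available).
#' @param target Name of the binary covariate to toggle; defaults to the
#'   fit's exposure of interest.
#' @return A single number in (-1, 1).
#' @export
average_incremental_effect <- function(fit, data = NULL, target = NULL) {
  UseMethod("average_incremental_effect")
}

#' @export
average_incremental_effect.dup2sri <- function(fit, data = NULL,
                                               target = NULL) {
  target <- target %||% fit$exposure
  rname <- fit$resid_term %||% "anscombe_resid"
  if (!is.null(data) && is.null(data[[rname]])) {
    data[[rname]] <- fit$residuals
  }
  average_incremental_effect(fit$second_stage, data, target)
}

#' @export
average_incremental_effect.dupfit <- function(fit, data = NULL,
                                              target = NULL) {
  target <- target %||% fit$exposure
  data <- data %||% model_frame_of(fit)
  d1 <- d0 <- as.data.frame(data)
  d1[[target]] <- 1
  d0[[target]] <- 0
  p1 <- predict_response(fit, d1)
  p0 <- predict_response(fit, d0)
  mean(p1 - p0)
}

#' @export
average_incremental_effect.duplin <- function(fit, data = NULL,
                                              target = NULL) {
  # linear model: the AIE is the coefficient itself
  target <- target %||% fit$exposure
  fit$coefficients$estimate[fit$coefficients$term == target]
}

model_frame_of <- function(fit) {
  if (fit$engine == "glmer") {
    stats::model.frame(fit$model)
  } else {
    fit$model$data %||% stats::model.frame(fit$model)
  }
}

predict_response <- function(fit, newdata) {
  if (fit$engine == "glmer") {
    predict(fit$model, newdata = newdata, type = "response",
            allow.new.levels = TRUE)
  } else {
    predict(fit$model, newdata = newdata, type = "response")
  }
}
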