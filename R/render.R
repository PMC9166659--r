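# Factor levels used by a fitted model, by variable (for Ref-row layout).
get_xlevels <- function(fit) {
  if (fit$engine == "glmer") {
    mf <- stats::model.frame(fit$model)
    Filter(Negate(is.null), lapply(mf, levels))
  } else {
    fit$model$xlevels %||% list()
  }
}

#' Render a fitted model as an odds-ratio table
#'
#' Formats a logistic fit the way study reports lay out regression tables:
#' one row per term, factor reference levels marked `Ref`, odds ratios and
#' confidence bounds to two decimals. No quantity is recomputed here; the
#' odds-ratio column is the exponential of the stored coefficient.
#'
#' @param fit A `dupfit` (or the `second_stage`/`first_stage` of a
#'   `dup2sri`).
#' @return A tibble with columns `variable`, `level`, `ref`, `estimate`,
#'   `odds_ratio`, `display` and `p.value`.
#' @export
render_or_table <- function(fit) {
  cf <- fit$coefficients
  xlv <- get_xlevels(fit)
  rows <- list()
  done <- character()
  for (i in seq_len(nrow(cf))) {
    term <- cf$term[i]
    matched <- FALSE
    for (v in names(xlv)) {
      lv <- xlv[[v]]
      hit <- lv[paste0(v, lv) == term]
      if (length(hit) == 1) {
        if (!v %in% done) {
          rows[[length(rows) + 1]] <- tibble(
            variable = v, level = lv[1], ref = TRUE, estimate = 0,
            odds_ratio = NA_real_, display = "Ref", p.value = NA_real_
          )
          done <- c(done, v)
        }
        rows[[length(rows) + 1]] <- tibble(
          variable = v, level = hit, ref = FALSE, estimate = cf$estimate[i],
          odds_ratio = round(exp(cf$estimate[i]), 2),
          display = sprintf("%.2f (%.2f-%.2f)", exp(cf$estimate[i]),
                            exp(cf$conf.low[i]), exp(cf$conf.high[i])),
          p.value = cf$p.value[i]
        )
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      rows[[length(rows) + 1]] <- tibble(
        variable = term, level = NA_character_, ref = FALSE,
        estimate = cf$estimate[i],
        odds_ratio = round(exp(cf$estimate[i]), 2),
        display = sprintf("%.2f (%.2f-%.2f)", exp(cf$estimate[i]),
                          exp(cf$conf.low[i]), exp(cf$conf.high[i])),
        p.value = cf$p.value[i]
      )
    }
  }
  bind_rows(rows)
}

#' Render the pipeline's result tables
#'
#' Produces the three report-style tables from already-computed results:
#' the stratified descriptive table, the primary-model odds-ratio table,
#' and (when a two-stage fit is present) the first- and second-stage
#' tables. Percentages carry one decimal, odds ratios two.
#'
#' @param records The analytic `encounter_records`.
#' @param fits Named list of fitted models (as built by [run_pipeline()]).
#' @param descriptives Optional precomputed [descriptive_table()].
#' @return A named list of tibbles.
#' @export
render_tables <- function(records, fits = list(), descriptives = NULL) {
  out <- list(
    descriptive = descriptives %||% descriptive_table(records)
  )
  if (!is.null(fits$primary)) {
    out$primary <- render_or_table(fits$primary)
  }
  if (!is.null(fits$tsri)) {
    out$first_stage <- render_or_table(fits$tsri$first_stage)
    out$second_stage <- render_or_table(fits$tsri$second_stage)
  }
  if (!is.null(fits$ols)) {
    out$ols <- fits$ols$coefficients
  }
  if (!is.null(fits$tsls)) {
    out$tsls <- fits$tsls$coefficients
  }
  out
}
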