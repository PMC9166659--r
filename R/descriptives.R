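#' Stratified descriptive statistics for the analytic sample
#'
#' Summarises the analytic encounter table overall and within the four
#' exposure strata (visit-level viewer use yes/no, provider-history viewer
#' use yes/no): group sizes, duplicate-imaging rates, gender, race and
#' provider-type percentages, and means of age, Elixhauser score and the
#' provider ordering rate. Percentages are reported to one decimal.
#'
#' @param records An `encounter_records` tibble (needs at least the
#'   outcome, the two exposures and the covariate columns; extra columns
#'   are ignored).
#' @return A tibble of class `descriptive_table` with columns `stratum`,
#'   `variable`, `level`, `n` (group size), `count` (numerator, where the
#'   statistic is a percentage), `pct` (one decimal) and `mean`.
#' @export
#' @examples
#' sim <- simulate_ehr(sim_config(n_patients = 300, n_providers = 15, seed = 2))
#' recs <- build_analytic(sim$bundle, quiet = TRUE)
#' descriptive_table(recs)
descriptive_table <- function(records) {
  if (nrow(records) == 0) abort("descriptive_table() needs at least one record")
  strata <- list(
    "Overall" = rep(TRUE, nrow(records)),
    "Non-JLV encounter" = records$jlv_encounter == 0,
    "JLV encounter" = records$jlv_encounter == 1,
    "Non-JLV provider" = records$jlv_provider == 0,
    "JLV provider" = records$jlv_provider == 1
  )
  purrr::imap_dfr(strata, function(keep, nm) {
    g <- records[keep, , drop = FALSE]
    n <- nrow(g)
    if (n == 0) {
      return(tibble(stratum = nm, variable = "n", level = NA_character_,
                    n = 0L, count = NA_integer_, pct = NA_real_,
                    mean = NA_real_))
    }
    pct_row <- function(variable, level, count) {
      tibble(stratum = nm, variable = variable, level = level, n = n,
             count = as.integer(count),
             pct = round(100 * count / n, 1), mean = NA_real_)
    }
    mean_row <- function(variable, value) {
      tibble(stratum = nm, variable = variable, level = NA_character_,
             n = n, count = NA_integer_, pct = NA_real_, mean = value)
    }
    bind_rows(
      tibble(stratum = nm, variable = "n", level = NA_character_, n = n,
             count = NA_integer_, pct = NA_real_, mean = NA_real_),
      pct_row("duplicate_image", "yes", sum(g$duplicate_image)),
      pct_row("gender", "Male", sum(g$gender == "Male")),
      pct_row("gender", "Female", sum(g$gender == "Female")),
      pct_row("race", "White", sum(g$race == "White")),
      pct_row("race", "Black", sum(g$race == "Black")),
      pct_row("race", "Other", sum(g$race == "Other")),
      pct_row("provider_type", "physician",
              sum(g$provider_type == "physician")),
      pct_row("provider_type", "pa_np", sum(g$provider_type == "pa_np")),
      mean_row("age", mean(g$age)),
      mean_row("elixhauser_score", mean(g$elixhauser_score)),
      mean_row("provider_order_rate", mean(g$provider_order_rate))
    )
  }) -> out
  class(out) <- c("descriptive_table", class(tibble()))
  out
}

#' @export
print.descriptive_table <- function(x, ...) {
  cat("Descriptive statistics by viewer-use stratum\n")
  wide <- x |>
    mutate(shown = dplyr::case_when(
      .data$variable == "n" ~ format(.data$n),
      !is.na(.data$pct) ~ sprintf("%d (%.1f%%)", .data$count, .data$pct),
      TRUE ~ sprintf("%.2f", .data$mean)
    ),
    row = ifelse(is.na(.data$level), .data$variable,
                 paste0(.data$variable, ": ", .data$level))) |>
    select("row", "stratum", "shown") |>
    tidyr::pivot_wider(names_from = "stratum", values_from = "shown")
  print(as.data.frame(wide), row.names = FALSE, right = FALSE)
  invisible(x)
}
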