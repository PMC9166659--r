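#' Flag duplicate imaging at index visits
#'
#' An encounter is a duplicate when any VA imaging order placed at the
#' visit matches any of the visit's qualifying DoD studies on both mode and
#' body part (exact vocabulary match).
#'
#' @param pairs An `index_pairs` tibble from [build_index_pairs()].
#' @param va_imaging_orders VA imaging-order table (`visit_id`, `mode`,
#'   `body_part`).
#' @param taxonomy List with character vectors `modes` and `body_parts`; an
#'   order using a label outside the taxonomy is a hard error.
#' @return `pairs` with an integer column `duplicate_image`.
#' @export
flag_duplicate <- function(pairs, va_imaging_orders, taxonomy) {
  assert_columns(va_imaging_orders, c("visit_id", "mode", "body_part"),
                 "va_imaging_orders")
  if (nrow(pairs) == 0) {
    return(mutate(pairs, duplicate_image = integer(0)))
  }
  orders <- va_imaging_orders |>
    as_tibble() |>
    filter(.data$visit_id %in% pairs$visit_id)
  bad <- !(orders$mode %in% taxonomy$modes) |
    !(orders$body_part %in% taxonomy$body_parts)
  if (any(bad)) {
    off <- orders[bad, , drop = FALSE]
    abort(glue::glue(
      "VA imaging order(s) outside the taxonomy: ",
      "{paste(head(paste0(off$visit_id, ':', off$mode, '/', off$body_part), 5),
              collapse = '; ')}"
    ))
  }
  studies <- pairs |>
    select("visit_id", "dod_studies") |>
    tidyr::unnest("dod_studies")
  hits <- inner_join(orders, studies, by = c("visit_id", "mode", "body_part"),
                     relationship = "many-to-many") |>
    distinct(.data$visit_id)
  mutate(pairs, duplicate_image = as.integer(.data$visit_id %in% hits$visit_id))
}

#' Flag visit-level viewer use ("JLV encounter")
#'
#' The endogenous exposure: 1 when a viewer audit links this visit's
#' provider and patient on the visit date.
#'
#' @param pairs An `index_pairs` tibble.
#' @param jlv_audits Audit-log table (`provider_id`, `patient_id`,
#'   `audit_date`).
#' @return `pairs` with an integer column `jlv_encounter`.
#' @export
flag_jlv_encounter <- function(pairs, jlv_audits) {
  assert_columns(jlv_audits, c("provider_id", "patient_id", "audit_date"),
                 "jlv_audits")
  hits <- pairs |>
    select("visit_id", "provider_id", "patient_id", "visit_date") |>
    inner_join(as_tibble(jlv_audits),
               by = c("provider_id", "patient_id",
                      "visit_date" = "audit_date"),
               relationship = "many-to-many") |>
    distinct(.data$visit_id)
  mutate(pairs, jlv_encounter = as.integer(.data$visit_id %in% hits$visit_id))
}

#' Flag provider viewer-use history ("JLV provider")
#'
#' The provider-level exposure / instrument: 1 when the visit's provider
#' has at least one viewer audit (for any patient) in the `lookback_days`
#' before the visit date. The window is half-open: audits on the visit date
#' itself do not count.
#'
#' @param pairs An `index_pairs` tibble.
#' @param jlv_audits Audit-log table.
#' @param lookback_days Length of the history window (days, default 183,
#'   i.e. six months).
#' @return `pairs` with an integer column `jlv_provider`.
#' @export
flag_jlv_provider <- function(pairs, jlv_audits, lookback_days = 183L) {
  assert_columns(jlv_audits, c("provider_id", "audit_date"), "jlv_audits")
  hits <- pairs |>
    select("visit_id", "provider_id", "visit_date") |>
    inner_join(select(as_tibble(jlv_audits), "provider_id", "audit_date"),
               by = "provider_id", relationship = "many-to-many") |>
    filter(.data$audit_date < .data$visit_date,
           .data$audit_date >= .data$visit_date - lookback_days) |>
    distinct(.data$visit_id)
  mutate(pairs, jlv_provider = as.integer(.data$visit_id %in% hits$visit_id))
}

#' Provider viewer-history flags at a fixed reference date
#'
#' Evaluates the same half-open lookback rule as [flag_jlv_provider()] but
#' at one common reference date for every provider (typically the study
#' window opening). On simulated bundles this recovers the generator's
#' provider viewer-propensity class exactly, because viewer-using providers
#' receive pre-period audits and others have none before the window opens.
#'
#' @param jlv_audits Audit-log table.
#' @param provider_ids Providers to evaluate.
#' @param at Reference date.
#' @param lookback_days History window length in days.
#' @return A tibble with `provider_id` and integer `jlv_provider`.
#' @export
provider_history_flags <- function(jlv_audits, provider_ids, at,
                                   lookback_days = 183L) {
  at <- as.Date(at)
  active <- jlv_audits |>
    as_tibble() |>
    filter(.data$audit_date < at, .data$audit_date >= at - lookback_days) |>
    distinct(.data$provider_id)
  tibble(provider_id = provider_ids,
         jlv_provider = as.integer(provider_ids %in% active$provider_id))
}

#' Provider imaging-order rate over the prior six months
#'
#' For each encounter, the share of the provider's prior primary care
#' visits (half-open window `[visit - lookback_days, visit)`, visits of the
#' index patient excluded) that carried at least one imaging order.
#' Encounters whose provider has no qualifying prior visit get `NA` and are
#' dropped (with a logged count) when the analytic table is assembled.
#' Quartiles are assigned from the sample quantiles of the non-missing
#' encounter-level rates; values tied with a cutpoint fall in the lower
#' quartile.
#'
#' @param pairs An `index_pairs` tibble.
#' @param va_visits Full VA visit table (pre-period visits included).
#' @param va_imaging_orders VA imaging-order table.
#' @param providers Provider attribute table.
#' @param config A [cohort_config()]; supplies the primary-care and C&P
#'   rules used to decide which prior visits count.
#' @param lookback_days History window length in days.
#' @return `pairs` with numeric `provider_order_rate`, integer
#'   `n_prior_visits` and integer `order_rate_quartile` columns.
#' @export
provider_order_rate <- function(pairs, va_visits, va_imaging_orders,
                                providers, config = cohort_config(),
                                lookback_days = 183L) {
  eligible <- va_visits |>
    as_tibble() |>
    left_join(select(providers, "provider_id", "provider_type"),
              by = "provider_id") |>
    filter(
      .data$primary_stop_code %in% config$primary_care_stop_codes,
      .data$provider_type %in% config$allowed_provider_types,
      !(!is.na(.data$secondary_stop_code) &
          .data$secondary_stop_code == config$cp_exam_stop_code &
          .data$appointment_type == config$cp_appointment_type)
    ) |>
    mutate(has_order = .data$visit_id %in% unique(va_imaging_orders$visit_id)) |>
    select(prior_visit_id = "visit_id", "provider_id",
           prior_patient_id = "patient_id", prior_date = "visit_date",
           "has_order")

  rates <- pairs |>
    select("visit_id", "provider_id", "patient_id", "visit_date") |>
    inner_join(eligible, by = "provider_id",
               relationship = "many-to-many") |>
    filter(.data$prior_date < .data$visit_date,
           .data$prior_date >= .data$visit_date - lookback_days,
           .data$prior_patient_id != .data$patient_id) |>
    group_by(.data$visit_id) |>
    summarise(provider_order_rate = mean(.data$has_order),
              n_prior_visits = dplyr::n(), .groups = "drop")

  out <- pairs |>
    left_join(rates, by = "visit_id") |>
    mutate(n_prior_visits = dplyr::coalesce(.data$n_prior_visits, 0L))
  out$order_rate_quartile <- assign_quartiles(out$provider_order_rate)
  out
}

# Sample-quartile assignment; ties at a cutpoint go to the lower quartile.
assign_quartiles <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  ifelse(is.na(x), NA_integer_,
         1L + (x > q[1]) + (x > q[2]) + (x > q[3]))
}

#' Attach and bin patient / provider covariates
#'
#' Joins patient demographics and provider type onto the encounter rows and
#' produces the categorical covariates used in the models: age bands
#' `<30 / 30-39 / 40-49 / 50+`, Elixhauser bins `0 / 1 / 2 / 3+` and race
#' `White / Black / Other`. Negative Elixhauser scores are a hard error.
#'
#' @param pairs An `index_pairs` tibble (any stage).
#' @param patients Patient attribute table.
#' @param providers Provider attribute table.
#' @return `pairs` with `age`, `age_band`, `gender`, `race`,
#'   `elixhauser_score`, `elix_bin` and `provider_type` columns.
#' @export
bin_covariates <- function(pairs, patients, providers) {
  assert_columns(patients, c("patient_id", "age", "gender", "race",
                             "elixhauser_score"), "patients")
  pairs |>
    left_join(select(patients, "patient_id", "age", "gender", "race",
                     "elixhauser_score"),
              by = "patient_id") |>
    left_join(select(providers, "provider_id", "provider_type"),
              by = "provider_id") |>
    mutate(
      age_band = fct_age_band(.data$age),
      elix_bin = fct_elix_bin(.data$elixhauser_score),
      gender = fct_gender(.data$gender),
      race = fct_race(.data$race),
      provider_type = fct_provider_type(.data$provider_type)
    )
}

#' Build the analytic encounter table from an event bundle
#'
#' Runs the cohort rules and all variable constructions, yielding one row
#' per eligible encounter: outcome (`duplicate_image`), exposures
#' (`jlv_encounter`, `jlv_provider`), the provider ordering-rate covariate
#' and its quartile, and binned patient/provider covariates, with reference
#' levels fixed (quartile 1, physician, female, `<30`, White, Elixhauser 0,
#' fiscal month 1). Encounters whose provider has no prior primary care
#' visit in the lookback window are dropped; the count is reported via a
#' message and stored in the `dropped_no_history` attribute.
#'
#' @param bundle An `event_bundle`.
#' @param config A [cohort_config()]; defaults to the bundle's window.
#' @param lookback_days Provider-history window (days).
#' @param quiet Suppress the dropped-encounter message.
#' @return A tibble of class `encounter_records`; filter-step counts are in
#'   the `counts` attribute.
#' @export
build_analytic <- function(bundle, config = cohort_config_for(bundle),
                           lookback_days = 183L, quiet = FALSE) {
  pairs <- build_cohort(bundle, config)
  tax <- attr(bundle, "taxonomy")
  rec <- pairs |>
    flag_duplicate(bundle$va_imaging_orders, tax) |>
    flag_jlv_encounter(bundle$jlv_audits) |>
    flag_jlv_provider(bundle$jlv_audits, lookback_days) |>
    provider_order_rate(bundle$va_visits, bundle$va_imaging_orders,
                        bundle$providers, config, lookback_days) |>
    bin_covariates(bundle$patients, bundle$providers)

  undefined <- is.na(rec$provider_order_rate)
  n_drop <- sum(undefined)
  if (n_drop > 0 && !quiet) {
    inform(glue::glue(
      "dropped {n_drop} encounter(s) whose provider had no prior primary ",
      "care visit in the {lookback_days}-day lookback"
    ))
  }
  rec <- rec[!undefined, , drop = FALSE]
  # quartile cutpoints re-computed on the retained analytic sample
  rec$order_rate_quartile <- assign_quartiles(rec$provider_order_rate)

  out <- rec |>
    mutate(
      order_rate_quartile = fct_quartile(.data$order_rate_quartile),
      fiscal_month = fct_fiscal_month(.data$fiscal_month)
    ) |>
    select("visit_id", "patient_id", "provider_id", "facility_id",
           "visit_date", "fiscal_month", "duplicate_image", "jlv_encounter",
           "jlv_provider", "provider_order_rate", "n_prior_visits",
           "order_rate_quartile", "provider_type", "age", "age_band",
           "gender", "race", "elixhauser_score", "elix_bin")
  counts <- c(attr(pairs, "counts"),
              dropped_no_history = n_drop,
              encounters = nrow(out))
  structure(out, counts = counts, dropped_no_history = n_drop,
            class = c("encounter_records", class(tibble())))
}
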