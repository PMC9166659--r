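#' Cohort eligibility configuration
#'
#' Holds the eligibility and exclusion rules used to build the analytic
#' cohort: which clinic stop codes identify primary care, how
#' compensation-and-pension (C&P) exams are recognised and excluded, which
#' provider types are eligible, and the imaging lookback window.
#'
#' @param primary_care_stop_codes Integer stop codes identifying outpatient
#'   primary care visits.
#' @param cp_exam_stop_code Secondary stop code marking C&P exams.
#' @param cp_appointment_type Appointment-type label marking C&P exams; a
#'   visit is dropped only when both the secondary stop code and the
#'   appointment type match.
#' @param allowed_provider_types Provider types eligible for the cohort.
#' @param window_days Imaging lookback window: a DoD study qualifies when it
#'   precedes the visit by 1 to `window_days` days (same-day studies are not
#'   prior imaging and do not qualify).
#' @param study_start,study_end Bounds of the study window (dates).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(primary_care_stop_codes = c(322L, 323L, 350L),
                          cp_exam_stop_code = 450L,
                          cp_appointment_type = "Compensation and Pension",
                          allowed_provider_types = c("physician", "pa_np"),
                          window_days = 90L,
                          study_start = as.Date("2017-10-01"),
                          study_end = as.Date("2018-09-30")) {
  if (window_days <= 0) abort("window_days must be positive")
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  if (study_start >= study_end) abort("study_start must precede study_end")
  structure(
    list(primary_care_stop_codes = as.integer(primary_care_stop_codes),
         cp_exam_stop_code = as.integer(cp_exam_stop_code),
         cp_appointment_type = cp_appointment_type,
         allowed_provider_types = allowed_provider_types,
         window_days = as.integer(window_days),
         study_start = study_start,
         study_end = study_end),
    class = "cohort_config"
  )
}

#' Cohort configuration matching an event bundle's study window
#'
#' Convenience constructor taking the study window from the bundle's
#' metadata and all rules from their defaults.
#'
#' @param bundle An `event_bundle`.
#' @param ... Overrides passed to [cohort_config()].
#' @export
cohort_config_for <- function(bundle, ...) {
  args <- list(...)
  if (is.null(args$study_start)) args$study_start <- attr(bundle, "study_start")
  if (is.null(args$study_end)) args$study_end <- attr(bundle, "study_end")
  do.call(cohort_config, args)
}

#' Select eligible primary care visits
#'
#' Keeps visits whose primary stop code identifies outpatient primary care,
#' whose date falls inside the study window, and whose provider is of an
#' allowed type; drops compensation-and-pension exams (secondary stop code
#' and appointment type both matching).
#'
#' @param va_visits Visit-level event table (one row per visit).
#' @param providers Provider attribute table with `provider_id`,
#'   `provider_type`.
#' @param config A [cohort_config()].
#' @return The eligible subset of `va_visits`, with `provider_type` joined
#'   on, as a tibble.
#' @export
select_primary_care_visits <- function(va_visits, providers,
                                       config = cohort_config()) {
  assert_columns(va_visits, c("visit_id", "patient_id", "provider_id",
                              "visit_date", "primary_stop_code",
                              "secondary_stop_code", "appointment_type"),
                 "va_visits")
  assert_columns(providers, c("provider_id", "provider_type"), "providers")
  known_types <- c("physician", "pa_np")
  bad <- !providers$provider_type %in% known_types
  if (any(bad)) {
    abort(glue::glue(
      "unknown provider_type value(s) in providers table: ",
      "{paste(unique(providers$provider_type[bad]), collapse = ', ')} ",
      "(rows {paste(head(which(bad), 5), collapse = ', ')})"
    ))
  }
  va_visits |>
    as_tibble() |>
    left_join(select(providers, "provider_id", "provider_type"),
              by = "provider_id") |>
    filter(
      .data$primary_stop_code %in% config$primary_care_stop_codes,
      .data$visit_date >= config$study_start,
      .data$visit_date <= config$study_end,
      .data$provider_type %in% config$allowed_provider_types,
      !(!is.na(.data$secondary_stop_code) &
          .data$secondary_stop_code == config$cp_exam_stop_code &
          .data$appointment_type == config$cp_appointment_type)
    )
}

#' Exclude cancer-indication imaging studies
#'
#' Removes DoD imaging studies whose primary diagnosis is cancer; repeat
#' imaging for cancer care is typically clinically indicated, so such
#' studies never anchor a duplicate.
#'
#' @param dod_imaging DoD imaging-study table with logical column
#'   `cancer_primary_dx`.
#' @return The non-cancer subset, original order preserved.
#' @export
exclude_cancer_images <- function(dod_imaging) {
  if (!"cancer_primary_dx" %in% names(dod_imaging)) {
    abort("dod_imaging lacks the required `cancer_primary_dx` flag column")
  }
  filter(as_tibble(dod_imaging), !.data$cancer_primary_dx)
}

#' Build index (visit, prior-imaging) pairs
#'
#' For each eligible visit, attaches every DoD imaging study of the same
#' patient performed 1 to `window_days` days before the visit date. Visits
#' with no qualifying study are excluded. Inputs should already have passed
#' [select_primary_care_visits()] and [exclude_cancer_images()].
#'
#' @param visits Eligible visit table.
#' @param dod_imaging Non-cancer DoD imaging-study table.
#' @param config A [cohort_config()].
#' @return A tibble of class `index_pairs`, one row per eligible visit,
#'   with a list-column `dod_studies` of qualifying studies
#'   (`study_id`, `mode`, `body_part`, `study_date`).
#' @export
build_index_pairs <- function(visits, dod_imaging,
                              config = cohort_config()) {
  assert_columns(dod_imaging, c("study_id", "patient_id", "study_date",
                                "mode", "body_part"), "dod_imaging")
  if (nrow(visits) == 0) {
    return(structure(
      tibble(visit_id = character(), patient_id = character(),
             provider_id = character(), facility_id = character(),
             visit_date = as.Date(character()),
             fiscal_month = integer(),
             dod_studies = list()),
      class = c("index_pairs", class(tibble()))
    ))
  }
  matched <- visits |>
    select("visit_id", "patient_id", "provider_id", "facility_id",
           "visit_date", "fiscal_month") |>
    inner_join(select(dod_imaging, "study_id", "patient_id", "study_date",
                      "mode", "body_part"),
               by = "patient_id", relationship = "many-to-many") |>
    filter(
      as.numeric(.data$visit_date - .data$study_date) >= 1,
      as.numeric(.data$visit_date - .data$study_date) <= config$window_days
    )
  out <- matched |>
    tidyr::nest(dod_studies = c("study_id", "mode", "body_part",
                                "study_date")) |>
    arrange(.data$visit_id)
  class(out) <- c("index_pairs", class(tibble()))
  out
}

#' Assemble the full cohort from an event bundle
#'
#' Runs the three cohort operations in sequence: primary care visit
#' selection, cancer-study exclusion, and window matching.
#'
#' @param bundle An `event_bundle`.
#' @param config A [cohort_config()]; defaults to one matching the
#'   bundle's study window.
#' @return An `index_pairs` tibble (see [build_index_pairs()]), with
#'   filter-step row counts in the `counts` attribute.
#' @export
build_cohort <- function(bundle, config = cohort_config_for(bundle)) {
  if (length(config$primary_care_stop_codes) == 0) {
    abort("cohort stage: primary_care_stop_codes is empty; no visit can qualify")
  }
  visits <- select_primary_care_visits(bundle$va_visits, bundle$providers,
                                       config)
  images <- exclude_cancer_images(bundle$dod_imaging)
  pairs <- build_index_pairs(visits, images, config)
  attr(pairs, "counts") <- c(
    va_visits = nrow(bundle$va_visits),
    primary_care_visits = nrow(visits),
    dod_studies = nrow(bundle$dod_imaging),
    non_cancer_studies = nrow(images),
    index_pairs = nrow(pairs)
  )
  attr(pairs, "config") <- config
  pairs
}
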