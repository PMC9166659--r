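# Analytic-table fixture reconstructing the published stratified
# descriptive margins of the fiscal-year 2018 study population (892
# encounters; four overlapping viewer-use strata). Only the margins are
# published; the 2x2 joint cell allocation below is one consistent
# completion of them (cells indexed by encounter-flag x provider-flag).
# All margin checks: each cell vector sums to the published counts in
# every stratum.
table1_fixture <- function() {
  cells <- tibble::tibble(
    enc = c(1L, 1L, 0L, 0L),
    prov = c(1L, 0L, 1L, 0L),
    n = c(400L, 57L, 187L, 248L),
    dup = c(20L, 16L, 16L, 18L),
    male = c(240L, 50L, 140L, 158L),
    white = c(240L, 29L, 108L, 135L),
    black = c(100L, 14L, 43L, 71L),
    physician = c(150L, 17L, 48L, 121L),
    age_mean = c(13680, 2013.38, 6355.3, 8521.32) / c(400, 57, 187, 248),
    elix_mean = c(450, 135.4, 270.95, 233.65) / c(400, 57, 187, 248),
    rate_mean = c(6900, 977, 3230, 4513) / c(400, 57, 187, 248) / 100
  )
  purrr::pmap_dfr(cells, function(enc, prov, n, dup, male, white, black,
                                  physician, age_mean, elix_mean,
                                  rate_mean) {
    other <- n - white - black
    tibble::tibble(
      jlv_encounter = enc,
      jlv_provider = prov,
      duplicate_image = rep(c(1L, 0L), c(dup, n - dup)),
      gender = factor(rep(c("Male", "Female"), c(male, n - male)),
                      levels = c("Female", "Male")),
      race = factor(rep(c("White", "Black", "Other"),
                        c(white, black, other)),
                    levels = c("White", "Black", "Other")),
      provider_type = factor(rep(c("physician", "pa_np"),
                                 c(physician, n - physician)),
                             levels = c("physician", "pa_np")),
      age = rep(age_mean, n),
      elixhauser_score = rep(elix_mean, n),
      provider_order_rate = rep(rate_mean, n)
    )
  })
}

# Pull one descriptive-table value by stratum/variable/level.
desc_value <- function(tab, stratum, variable, level = NA, what = "pct") {
  row <- tab[tab$stratum == stratum & tab$variable == variable &
               (is.na(level) & is.na(tab$level) |
                  !is.na(level) & !is.na(tab$level) & tab$level == level), ]
  row[[what]]
}

# Hand-built micro event tables for cohort/variables unit tests.
micro_taxonomy <- function() {
  list(modes = c("XR", "CT", "MR"), body_parts = c("lumbar spine", "chest"))
}

micro_visits <- function(...) {
  defaults <- tibble::tibble(
    visit_id = "v1", patient_id = "p1", provider_id = "d1",
    facility_id = "f1", visit_date = as.Date("2018-03-01"),
    primary_stop_code = 322L, secondary_stop_code = NA_integer_,
    appointment_type = "Routine", fiscal_month = 6L
  )
  over <- tibble::tibble(...)
  if (nrow(over) == 0) return(defaults)
  for (nm in setdiff(names(defaults), names(over))) {
    over[[nm]] <- rep(defaults[[nm]], length.out = nrow(over))
  }
  over[names(defaults)]
}

micro_providers <- function(ids = "d1", type = "physician") {
  tibble::tibble(provider_id = ids,
                 provider_type = rep(type, length.out = length(ids)))
}

micro_studies <- function(...) {
  defaults <- tibble::tibble(
    study_id = "s1", patient_id = "p1",
    study_date = as.Date("2018-02-01"), mode = "CT",
    body_part = "lumbar spine", cancer_primary_dx = FALSE
  )
  over <- tibble::tibble(...)
  if (nrow(over) == 0) return(defaults)
  for (nm in setdiff(names(defaults), names(over))) {
    over[[nm]] <- rep(defaults[[nm]], length.out = nrow(over))
  }
  over[names(defaults)]
}
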