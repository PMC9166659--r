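cfg <- cohort_config()

test_that("primary care selection applies stop-code, window and C&P rules", {
  visits <- micro_visits(
    visit_id = c("v1", "v2", "v3", "v4", "v5"),
    primary_stop_code = c(322L, 322L, 502L, 350L, 323L),
    secondary_stop_code = c(NA, 450L, NA, 450L, NA),
    appointment_type = c("Routine", "Compensation and Pension", "Routine",
                         "Routine", "Routine"),
    visit_date = as.Date(c("2018-03-01", "2018-03-01", "2018-03-01",
                           "2018-03-01", "2016-01-01"))
  )
  kept <- select_primary_care_visits(visits, micro_providers(), cfg)
  # v1: primary care, kept; v2: C&P exam (code + type), dropped;
  # v3: wrong stop code; v4: code 450 but not a C&P appointment, kept;
  # v5: outside the study window
  expect_setequal(kept$visit_id, c("v1", "v4"))
})

test_that("unknown provider types are a hard error naming the offender", {
  visits <- micro_visits(visit_id = "v1")
  expect_error(
    select_primary_care_visits(visits, micro_providers(type = "resident"),
                               cfg),
    "resident"
  )
})

test_that("empty inputs flow through without error", {
  empty <- micro_visits()[0, ]
  out <- select_primary_care_visits(empty, micro_providers(), cfg)
  expect_equal(nrow(out), 0)
  pairs <- build_index_pairs(out, micro_studies(), cfg)
  expect_equal(nrow(pairs), 0)
})

test_that("cancer-indication studies are removed, others kept in order", {
  studies <- micro_studies(
    study_id = sprintf("s%d", 1:10),
    cancer_primary_dx = rep(c(TRUE, FALSE), c(3, 7))
  )
  kept <- exclude_cancer_images(studies)
  expect_equal(nrow(kept), 7)
  expect_identical(kept$study_id, sprintf("s%d", 4:10))
  expect_equal(nrow(exclude_cancer_images(
    micro_studies(cancer_primary_dx = TRUE))), 0)
  none <- micro_studies(study_id = c("s1", "s2"))
  expect_identical(exclude_cancer_images(none), none)
  expect_error(exclude_cancer_images(none[, -6]), "cancer_primary_dx")
})

test_that("the 90-day window is inclusive at 90 and excludes same-day studies", {
  visit <- micro_visits(visit_id = "v1",
                        visit_date = as.Date("2018-03-31"))
  studies <- micro_studies(
    study_id = c("s90", "s91", "s0", "s1"),
    study_date = as.Date("2018-03-31") - c(90, 91, 0, 1)
  )
  pairs <- build_index_pairs(visit, studies, cfg)
  got <- pairs$dod_studies[[1]]$study_id
  expect_setequal(got, c("s90", "s1"))   # boundary in; 91 days and same-day out
})

test_that("window matching equals a brute-force double loop on random instances", {
  brute_force_pairs <- function(visits, studies, window) {
    out <- list()
    for (i in seq_len(nrow(visits))) {
      hits <- character()
      for (j in seq_len(nrow(studies))) {
        dd <- as.numeric(visits$visit_date[i] - studies$study_date[j])
        if (studies$patient_id[j] == visits$patient_id[i] &&
            dd >= 1 && dd <= window) {
          hits <- c(hits, studies$study_id[j])
        }
      }
      if (length(hits) > 0) {
        out[[visits$visit_id[i]]] <- sort(hits)
      }
    }
    out
  }
  for (k in 1:30) {
    set.seed(1000 + k)
    nv <- sample(1:60, 1)
    ns <- sample(1:140, 1)
    pats <- sprintf("p%d", 1:8)
    visits <- micro_visits(
      visit_id = sprintf("v%d", seq_len(nv)),
      patient_id = sample(pats, nv, replace = TRUE),
      visit_date = as.Date("2018-01-01") + sample(0:250, nv, replace = TRUE)
    )
    studies <- micro_studies(
      study_id = sprintf("s%d", seq_len(ns)),
      patient_id = sample(pats, ns, replace = TRUE),
      study_date = as.Date("2017-10-01") + sample(0:340, ns, replace = TRUE)
    )
    pairs <- build_index_pairs(visits, studies, cfg)
    got <- setNames(
      lapply(pairs$dod_studies, function(d) sort(d$study_id)),
      pairs$visit_id
    )
    bf <- brute_force_pairs(visits, studies, 90)
    expect_identical(got[sort(names(got))], bf[sort(names(bf))])
  }
})

test_that("cancer exclusion before matching equals pruning after matching", {
  sim <- simulate_ehr(small_config(seed = 17))
  b <- sim$bundle
  ccfg <- cohort_config_for(b)
  visits <- select_primary_care_visits(b$va_visits, b$providers, ccfg)

  before <- build_index_pairs(visits, exclude_cancer_images(b$dod_imaging),
                              ccfg)

  cancer_ids <- b$dod_imaging$study_id[b$dod_imaging$cancer_primary_dx]
  after <- build_index_pairs(visits, b$dod_imaging, ccfg)
  after$dod_studies <- lapply(after$dod_studies, function(d) {
    d[!d$study_id %in% cancer_ids, , drop = FALSE]
  })
  after <- after[vapply(after$dod_studies, nrow, 0L) > 0, ]

  expect_identical(before$visit_id, after$visit_id)
  expect_identical(
    lapply(before$dod_studies, function(d) sort(d$study_id)),
    lapply(after$dod_studies, function(d) sort(d$study_id))
  )
  # and no pair references a patient missing from the attribute table
  expect_true(all(before$patient_id %in% b$patients$patient_id))
})

test_that("an empty stop-code rule is rejected with a cohort-stage error", {
  sim <- simulate_ehr(small_config(seed = 2))
  bad <- cohort_config_for(sim$bundle, primary_care_stop_codes = integer(0))
  expect_error(build_cohort(sim$bundle, bad), "no visit can qualify")
})
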