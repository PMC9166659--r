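tax <- micro_taxonomy()

pairs_one <- function(study_mode = "CT", study_part = "lumbar spine",
                      lag = 30) {
  visits <- micro_visits(visit_id = "v1",
                         visit_date = as.Date("2018-03-01"))
  studies <- micro_studies(mode = study_mode, body_part = study_part,
                           study_date = as.Date("2018-03-01") - lag)
  build_index_pairs(visits, studies, cohort_config())
}

test_that("duplicate flag requires an exact mode and body-part match", {
  orders_ct <- tibble::tibble(visit_id = "v1", mode = "CT",
                              body_part = "lumbar spine")
  orders_mr <- tibble::tibble(visit_id = "v1", mode = "MR",
                              body_part = "lumbar spine")
  p <- pairs_one()
  expect_equal(flag_duplicate(p, orders_ct, tax)$duplicate_image, 1L)
  expect_equal(flag_duplicate(p, orders_mr, tax)$duplicate_image, 0L)
  expect_equal(flag_duplicate(p, orders_ct[0, ], tax)$duplicate_image, 0L)
})

test_that("orders outside the taxonomy are a hard error", {
  bad <- tibble::tibble(visit_id = "v1", mode = "PET", body_part = "chest")
  expect_error(flag_duplicate(pairs_one(), bad, tax), "taxonomy")
})

test_that("viewer-encounter flag needs provider, patient and exact date", {
  p <- pairs_one()
  hit <- tibble::tibble(provider_id = "d1", patient_id = "p1",
                        audit_date = as.Date("2018-03-01"))
  other_pat <- tibble::tibble(provider_id = "d1", patient_id = "p9",
                              audit_date = as.Date("2018-03-01"))
  day_off <- tibble::tibble(provider_id = "d1", patient_id = "p1",
                            audit_date = as.Date("2018-02-28"))
  expect_equal(flag_jlv_encounter(p, hit)$jlv_encounter, 1L)
  expect_equal(flag_jlv_encounter(p, other_pat)$jlv_encounter, 0L)
  expect_equal(flag_jlv_encounter(p, day_off)$jlv_encounter, 0L)
})

test_that("provider-history flag uses a strict half-open 183-day window", {
  p <- pairs_one()
  mk <- function(days_before) {
    tibble::tibble(provider_id = "d1", patient_id = "p9",
                   audit_date = as.Date("2018-03-01") - days_before)
  }
  expect_equal(flag_jlv_provider(p, mk(100))$jlv_provider, 1L)
  expect_equal(flag_jlv_provider(p, mk(0))$jlv_provider, 0L)   # visit day itself
  expect_equal(flag_jlv_provider(p, mk(200))$jlv_provider, 0L)
  expect_equal(flag_jlv_provider(p, mk(183))$jlv_provider, 1L) # boundary in
})

test_that("provider order rate is the share of prior visits with an order", {
  visits <- micro_visits(
    visit_id = sprintf("v%d", 1:5),
    patient_id = c("p1", "p2", "p3", "p4", "p5"),
    visit_date = as.Date("2018-03-01") - c(0, 10, 20, 30, 40)
  )
  orders <- tibble::tibble(visit_id = "v3", mode = "CT",
                           body_part = "chest")
  studies <- micro_studies(study_date = as.Date("2018-02-20"))
  p <- build_index_pairs(visits[1, ], studies, cohort_config())
  out <- provider_order_rate(p, visits, orders, micro_providers(),
                             cohort_config())
  expect_equal(out$provider_order_rate, 0.25)   # 4 prior visits, 1 with order
  expect_equal(out$n_prior_visits, 4L)
})

test_that("prior visits of the index patient are excluded from the rate", {
  visits <- micro_visits(
    visit_id = c("v1", "v2", "v3"),
    patient_id = c("p1", "p1", "p1"),
    visit_date = as.Date("2018-03-01") - c(0, 10, 20)
  )
  studies <- micro_studies(study_date = as.Date("2018-02-20"))
  p <- build_index_pairs(visits[1, ], studies, cohort_config())
  no_orders <- tibble::tibble(visit_id = character(), mode = character(),
                              body_part = character())
  out <- provider_order_rate(p, visits, no_orders, micro_providers(),
                             cohort_config())
  expect_true(is.na(out$provider_order_rate))
  expect_equal(out$n_prior_visits, 0L)
})

test_that("quartile assignment partitions the sample evenly up to ties", {
  set.seed(4)
  x <- runif(403)   # all distinct
  q <- dupimaging:::assign_quartiles(x)
  expect_true(all(abs(table(q) - length(x) / 4) <= 1))
  # tied values at a cutpoint fall in the lower quartile
  xt <- rep(c(1, 2, 3, 4), each = 25)
  qt <- dupimaging:::assign_quartiles(xt)
  expect_true(all(qt[xt == 2] == 2))
  expect_equal(unname(table(qt)[["1"]]), 25)
})

test_that("covariates are binned exactly as reported", {
  pats <- tibble::tibble(
    patient_id = c("p1", "p2", "p3", "p4"),
    age = c(29.99, 30, 49.5, 67),
    gender = c("Male", "Female", "Male", "Female"),
    race = c("White", "Black", "Other", "White"),
    elixhauser_score = c(0L, 1L, 5L, 2L)
  )
  visits <- micro_visits(visit_id = sprintf("v%d", 1:4),
                         patient_id = pats$patient_id,
                         visit_date = as.Date("2018-03-01"))
  studies <- micro_studies(study_id = sprintf("s%d", 1:4),
                           patient_id = pats$patient_id,
                           study_date = as.Date("2018-02-01"))
  p <- build_index_pairs(visits, studies, cohort_config())
  out <- bin_covariates(p, pats, micro_providers())
  expect_equal(as.character(out$age_band), c("<30", "30-39", "40-49", "50+"))
  expect_equal(as.character(out$elix_bin), c("0", "1", "3+", "2"))
  pats_bad <- pats
  pats_bad$elixhauser_score[1] <- -1L
  expect_error(bin_covariates(p, pats_bad, micro_providers()), "negative")
})

test_that("pipeline variables reconstruct the generator's latent flags", {
  sim <- simulate_ehr(small_config(n_patients = 800, n_providers = 30,
                                   seed = 23))
  recs <- build_analytic(sim$bundle, quiet = TRUE)
  m <- dplyr::inner_join(
    recs, sim$truth$encounters,
    by = c("visit_id", "patient_id", "provider_id")
  )
  expect_equal(nrow(m), nrow(recs))
  expect_identical(m$jlv_encounter, m$viewer_use)
  expect_identical(m$duplicate_image, m$duplicate)
  ph <- provider_history_flags(sim$bundle$jlv_audits,
                               sim$truth$providers$provider_id,
                               at = attr(sim$bundle, "study_start"))
  expect_identical(ph$jlv_provider, sim$truth$providers$z)
})

test_that("descriptive strata are conserved and degenerate cases behave", {
  sim <- simulate_ehr(small_config(seed = 31))
  recs <- build_analytic(sim$bundle, quiet = TRUE)
  tab <- descriptive_table(recs)
  n_overall <- tab$n[tab$stratum == "Overall"][1]
  enc_ns <- vapply(c("Non-JLV encounter", "JLV encounter"),
                   function(s) tab$n[tab$stratum == s][1], 0L)
  prov_ns <- vapply(c("Non-JLV provider", "JLV provider"),
                    function(s) tab$n[tab$stratum == s][1], 0L)
  expect_equal(sum(enc_ns), n_overall)
  expect_equal(sum(prov_ns), n_overall)
  # gender rows sum to the group n in every stratum
  g <- tab[tab$variable == "gender", ]
  sums <- tapply(g$count, g$stratum, sum)
  ns <- tapply(g$n, g$stratum, function(x) x[1])
  expect_equal(unname(sums[names(ns)]), unname(ns))

  single <- recs[1, ]
  tab1 <- descriptive_table(single)
  expect_true(all(tab1$pct[!is.na(tab1$pct)] %in% c(0, 100)))
})
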