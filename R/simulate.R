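#' Configuration for the synthetic two-system EHR generator
#'
#' Builds the parameter set for [simulate_ehr()]. The generator emulates the
#' event tables produced when patients transition between two health care
#' systems: an originating system that performs imaging studies (the "DoD
#' side"), and a receiving system (the "VA side") whose primary care
#' providers may or may not consult an integrated record viewer before
#' ordering images. The data-generating process is deliberately endogenous:
#' a latent patient-complexity score `U` drives both visit-level viewer use
#' and duplicate ordering, while a provider-level viewer-use propensity
#' `Z` shifts viewer use only, making it usable as an instrument downstream.
#'
#' Visit-level viewer use is drawn with
#' `logit P(X_e = 1) = alpha0 + alpha_z * Z + alpha_u * U`, and the
#' duplicate-order outcome with
#' `logit P(Y = 1) = beta0 + beta_e * X_e + beta_u * U + covariate terms +
#' facility intercept`.
#'
#' Default values reproduce the headline marginals of the fiscal-year study
#' population the package is designed around: roughly half of encounters
#' have visit-level viewer use, about two thirds of encounters belong to
#' viewer-using providers, and the marginal duplicate-imaging rate is near
#' 8%. `beta_e` defaults to `log(0.44)`, an odds ratio of 0.44 for viewer
#' use on duplicate ordering.
#'
#' @param n_patients Number of eligible patients (one analytic encounter per
#'   patient by default).
#' @param n_providers Number of primary care providers.
#' @param n_facilities Number of facilities (random-intercept clusters).
#' @param n_months Length of the study window in fiscal months (month 1 =
#'   October). The window opens on `study_start`.
#' @param study_start First day of the study window (a `Date` or string).
#' @param p_instrument Probability a provider is a viewer user (`Z = 1`).
#' @param alpha0,alpha_z,alpha_u Log-odds intercept, instrument effect and
#'   latent-complexity effect in the visit-level viewer-use model.
#' @param beta0,beta_e,beta_u Log-odds intercept, causal viewer-use effect
#'   and latent-complexity effect in the duplicate-ordering model.
#' @param sigma_facility SD of facility random intercepts (log-odds scale).
#' @param gamma_rate Slope on the provider's ordering propensity
#'   (centred at `rate_center`) in the outcome model.
#' @param rate_center Centring constant for the ordering-propensity slope.
#' @param gamma_elix Log-odds effects for Elixhauser bins 1, 2 and 3+
#'   (reference bin 0).
#' @param gamma_age Log-odds effects for age bands 30-39, 40-49 and 50+
#'   (reference `<30`).
#' @param gamma_race Log-odds effects for Black and Other race (reference
#'   White).
#' @param gamma_male Log-odds effect of male gender.
#' @param gamma_panp Log-odds effect of physician-assistant/nurse-practitioner
#'   provider type (reference physician).
#' @param month_effects Numeric vector of 12 fiscal-month log-odds offsets.
#' @param visits_per_patient Eligible visits contributed by each patient.
#' @param p_physician Probability a provider is a physician (vs PA/NP).
#' @param provider_rate_shape Beta shape parameters for the provider
#'   ordering propensity (default mean 0.175).
#' @param elix_mean Mean of the Poisson Elixhauser score.
#' @param p_male Probability a patient is male.
#' @param race_probs Probabilities for White / Black / Other race.
#' @param age_weights,age_means,age_sds,age_min Normal-mixture parameters
#'   for patient age (years), truncated below at `age_min`.
#' @param modes,body_parts Character vocabularies of imaging modes and body
#'   parts (the synthetic taxonomy used for duplicate matching).
#' @param p_order_nondup Probability that a non-duplicate encounter still
#'   emits a VA imaging order (one that fails the duplicate-match rule).
#' @param p_cancer_study,p_stale_study,p_same_day_study Per-patient
#'   probabilities of noise DoD studies: cancer-flagged (excluded by the
#'   cohort rules), stale (91-180 days before the visit) and same-day.
#' @param p_cp_visit,p_other_stop_visit Per-patient probabilities of noise
#'   VA visits: compensation-and-pension exams and non-primary-care visits.
#' @param history_visits_mean Mean number of background primary care visits
#'   per provider (drives the provider ordering-rate covariate).
#' @param pre_period_days Length of the pre-period before `study_start`
#'   (provider-history lookback support).
#' @param seed Integer seed; the same seed yields byte-identical output.
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_ehr()]
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 200, n_providers = 10, seed = 1)
#' sim <- simulate_ehr(cfg)
#' names(sim$bundle)
sim_config <- function(n_patients = 892,
                       n_providers = 60,
                       n_facilities = 8,
                       n_months = 12,
                       study_start = as.Date("2017-10-01"),
                       p_instrument = 0.66,
                       alpha0 = -3.5,
                       alpha_z = 4.5,
                       alpha_u = 1.0,
                       beta0 = -2.94,
                       beta_e = log(0.44),
                       beta_u = 1.0,
                       sigma_facility = 0.25,
                       gamma_rate = 5,
                       rate_center = 0.175,
                       gamma_elix = c(-0.82, -0.92, -1.90),
                       gamma_age = c(0.78, -0.25, 0.24),
                       gamma_race = c(0.09, 0.49),
                       gamma_male = 0.52,
                       gamma_panp = 0.28,
                       month_effects = rep(0, 12),
                       visits_per_patient = 1,
                       p_physician = 0.377,
                       provider_rate_shape = c(2, 9.4),
                       elix_mean = 1.22,
                       p_male = 0.659,
                       race_probs = c(White = 0.574, Black = 0.256, Other = 0.17),
                       age_weights = c(0.45, 0.32, 0.15, 0.08),
                       age_means = c(27, 35, 44, 55),
                       age_sds = c(3, 4, 4, 5),
                       age_min = 19,
                       modes = c("XR", "CT", "MR", "US"),
                       body_parts = c("head", "cervical spine", "lumbar spine",
                                      "chest", "abdomen", "pelvis", "knee",
                                      "shoulder"),
                       p_order_nondup = 0.10,
                       p_cancer_study = 0.08,
                       p_stale_study = 0.15,
                       p_same_day_study = 0.05,
                       p_cp_visit = 0.05,
                       p_other_stop_visit = 0.05,
                       history_visits_mean = 30,
                       pre_period_days = 183,
                       seed = 1L) {
  cfg <- list(
    n_patients = n_patients, n_providers = n_providers,
    n_facilities = n_facilities, n_months = n_months,
    study_start = as.Date(study_start),
    p_instrument = p_instrument,
    alpha0 = alpha0, alpha_z = alpha_z, alpha_u = alpha_u,
    beta0 = beta0, beta_e = beta_e, beta_u = beta_u,
    sigma_facility = sigma_facility,
    gamma_rate = gamma_rate, rate_center = rate_center,
    gamma_elix = gamma_elix, gamma_age = gamma_age, gamma_race = gamma_race,
    gamma_male = gamma_male, gamma_panp = gamma_panp,
    month_effects = month_effects,
    visits_per_patient = visits_per_patient,
    p_physician = p_physician,
    provider_rate_shape = provider_rate_shape,
    elix_mean = elix_mean, p_male = p_male,
    race_probs = race_probs,
    age_weights = age_weights, age_means = age_means, age_sds = age_sds,
    age_min = age_min,
    modes = modes, body_parts = body_parts,
    p_order_nondup = p_order_nondup,
    p_cancer_study = p_cancer_study, p_stale_study = p_stale_study,
    p_same_day_study = p_same_day_study,
    p_cp_visit = p_cp_visit, p_other_stop_visit = p_other_stop_visit,
    history_visits_mean = history_visits_mean,
    pre_period_days = pre_period_days,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c(n_patients = cfg$n_patients, n_providers = cfg$n_providers,
              n_facilities = cfg$n_facilities, n_months = cfg$n_months,
              visits_per_patient = cfg$visits_per_patient)
  bad <- counts < 1
  if (any(bad)) {
    abort(glue::glue("counts must be >= 1; offending: ",
                     "{paste(names(counts)[bad], collapse = ', ')}"))
  }
  probs <- c(p_instrument = cfg$p_instrument, p_physician = cfg$p_physician,
             p_male = cfg$p_male, p_order_nondup = cfg$p_order_nondup,
             p_cancer_study = cfg$p_cancer_study,
             p_stale_study = cfg$p_stale_study,
             p_same_day_study = cfg$p_same_day_study,
             p_cp_visit = cfg$p_cp_visit,
             p_other_stop_visit = cfg$p_other_stop_visit, cfg$race_probs)
  if (any(probs < 0 | probs > 1)) {
    abort("all probability parameters must lie in [0, 1]")
  }
  if (abs(sum(cfg$race_probs) - 1) > 1e-8) abort("race_probs must sum to 1")
  if (cfg$sigma_facility < 0) abort("sigma_facility must be >= 0")
  if (length(cfg$month_effects) != 12) abort("month_effects must have length 12")
  if (length(cfg$modes) < 1 || length(cfg$body_parts) < 1) {
    abort("taxonomy must contain at least one mode and one body part")
  }
  n_enc <- cfg$n_patients * cfg$visits_per_patient
  n_days <- study_window_days(cfg)
  if (n_enc < 1 || n_days < 1) {
    abort("configuration implies zero eligible encounters")
  }
  if (cfg$visits_per_patient > n_days) {
    abort("visits_per_patient exceeds the number of days in the study window")
  }
  invisible(cfg)
}

study_window_days <- function(cfg) {
  as.integer(study_end_date(cfg) - cfg$study_start) + 1L
}

study_end_date <- function(cfg) {
  seq(cfg$study_start, by = "month", length.out = cfg$n_months + 1)[cfg$n_months + 1] - 1
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d patients, %d providers, %d facilities, %d fiscal months\n",
              x$n_patients, x$n_providers, x$n_facilities, x$n_months))
  cat(sprintf("  window %s .. %s (+%d-day pre-period)\n",
              format(x$study_start), format(study_end_date(x)),
              x$pre_period_days))
  cat(sprintf("  viewer use: alpha0 = %.2f, alpha_z = %.2f, alpha_u = %.2f\n",
              x$alpha0, x$alpha_z, x$alpha_u))
  cat(sprintf("  duplicates: beta0 = %.2f, beta_e = %.3f (OR %.2f), beta_u = %.2f\n",
              x$beta0, x$beta_e, exp(x$beta_e), x$beta_u))
  cat(sprintf("  taxonomy: %d modes x %d body parts; seed %d\n",
              length(x$modes), length(x$body_parts), x$seed))
  invisible(x)
}

#' Uniform-at-random assignment of patients to providers
#'
#' Patients are assigned to primary care providers uniformly at random,
#' independently of all patient attributes including the latent complexity
#' score. This arbitrary-assignment structure is what justifies treating a
#' provider-level exposure as exogenous to the individual patient.
#'
#' @param patient_ids Character vector of patient ids.
#' @param provider_ids Character vector of provider ids.
#' @return A tibble with columns `patient_id`, `provider_id`.
#' @export
#' @examples
#' assign_patients(c("p1", "p2", "p3"), c("d1", "d2"))
assign_patients <- function(patient_ids, provider_ids) {
  if (length(patient_ids) < 1 || length(provider_ids) < 1) {
    abort("need at least one patient and one provider")
  }
  tibble(
    patient_id = patient_ids,
    provider_id = sample(provider_ids, length(patient_ids), replace = TRUE)
  )
}

#' Generate a synthetic two-system EHR event bundle
#'
#' Draws a complete set of linked event tables (DoD-side imaging studies, VA
#' visits, VA imaging orders, viewer audit logs, patient and provider
#' attributes) from the data-generating process described in
#' [sim_config()], together with the simulation ground truth needed for
#' parameter-recovery testing.
#'
#' Event emission is invertible by the cohort/variables rules: a viewer
#' audit row `(provider, patient, visit date)` exists exactly when
#' visit-level viewer use `X_e = 1`; when the duplicate outcome `Y = 1` the
#' emitted VA order matches a qualifying DoD study (same mode and body
#' part, 1-90 days before the visit, not cancer-flagged), and when `Y = 0`
#' any emitted order fails the match rule against every qualifying study.
#' Viewer-using providers (`Z = 1`) additionally receive background audit
#' rows every ~30 days from the start of the pre-period, so the
#' provider-history flag evaluated at the study-window opening recovers `Z`
#' exactly.
#'
#' All random draws are consumed in a fixed, documented order from a single
#' seeded generator, so equal configurations produce byte-identical output.
#'
#' @param config A [sim_config()] object.
#' @param seed Optional integer overriding `config$seed`.
#' @return A list with elements `bundle` (class `event_bundle`: tibbles
#'   `dod_imaging`, `va_visits`, `va_imaging_orders`, `jlv_audits`,
#'   `patients`, `providers`, plus a `taxonomy` attribute) and `truth`
#'   (class `simulation_truth`: per-encounter latent states and
#'   probabilities, provider/facility parameters, generative coefficients).
#' @export
simulate_ehr <- function(config = sim_config(), seed = NULL) {
  cfg <- config
  validate_sim_config(cfg)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  set.seed(cfg$seed)

  study_start <- cfg$study_start
  study_end <- study_end_date(cfg)
  n_days <- study_window_days(cfg)
  pre_start <- study_start - cfg$pre_period_days

  ## -- 1. facilities ---------------------------------------------------
  facilities <- tibble(
    facility_id = sprintf("f%02d", seq_len(cfg$n_facilities)),
    intercept = rnorm(cfg$n_facilities, 0, cfg$sigma_facility)
  )

  ## -- 2. providers ----------------------------------------------------
  providers <- tibble(
    provider_id = sprintf("d%04d", seq_len(cfg$n_providers)),
    provider_type = sample(c("physician", "pa_np"), cfg$n_providers,
                           replace = TRUE,
                           prob = c(cfg$p_physician, 1 - cfg$p_physician)),
    z = rbinom(cfg$n_providers, 1, cfg$p_instrument),
    rho = stats::rbeta(cfg$n_providers, cfg$provider_rate_shape[1],
                       cfg$provider_rate_shape[2]),
    facility_id = sample(facilities$facility_id, cfg$n_providers,
                         replace = TRUE)
  )

  ## -- 3. patients (analytic cohort + history-only pool) ----------------
  n_hist <- max(3L, ceiling(cfg$n_providers * 1.5))
  n_all <- cfg$n_patients + n_hist
  mix <- sample.int(length(cfg$age_weights), n_all, replace = TRUE,
                    prob = cfg$age_weights)
  patients <- tibble(
    patient_id = sprintf("p%06d", seq_len(n_all)),
    age = pmax(cfg$age_min,
               rnorm(n_all, cfg$age_means[mix], cfg$age_sds[mix])),
    gender = sample(c("Male", "Female"), n_all, replace = TRUE,
                    prob = c(cfg$p_male, 1 - cfg$p_male)),
    race = sample(c("White", "Black", "Other"), n_all, replace = TRUE,
                  prob = cfg$race_probs),
    elixhauser_score = rpois(n_all, cfg$elix_mean),
    u = rnorm(n_all),
    history_pool = seq_len(n_all) > cfg$n_patients
  )
  analytic_patients <- patients[!patients$history_pool, ]
  history_patients <- patients[patients$history_pool, ]

  ## -- 4. panel assignment ----------------------------------------------
  assignment <- assign_patients(analytic_patients$patient_id,
                                providers$provider_id)

  ## -- 5. index visits ---------------------------------------------------
  vpp <- cfg$visits_per_patient
  if (vpp == 1L) {
    offsets <- sample.int(n_days, cfg$n_patients, replace = TRUE) - 1L
    idx_patient <- analytic_patients$patient_id
  } else {
    offsets <- as.vector(vapply(
      seq_len(cfg$n_patients),
      function(i) sort(sample.int(n_days, vpp) - 1L),
      integer(vpp)
    ))
    idx_patient <- rep(analytic_patients$patient_id, each = vpp)
  }
  n_enc <- length(idx_patient)
  visits <- tibble(
    visit_id = sprintf("v%07d", seq_len(n_enc)),
    patient_id = idx_patient,
    visit_date = study_start + offsets,
    primary_stop_code = sample(c(322L, 323L, 350L), n_enc, replace = TRUE),
    secondary_stop_code = NA_integer_,
    appointment_type = "Routine"
  ) |>
    left_join(assignment, by = "patient_id") |>
    left_join(select(providers, "provider_id", "facility_id", "z", "rho",
                     "provider_type"),
              by = "provider_id") |>
    left_join(select(patients, "patient_id", "u", "age", "gender", "race",
                     "elixhauser_score"),
              by = "patient_id") |>
    mutate(fiscal_month = fiscal_month(.data$visit_date))

  ## -- 6. visit-level viewer use ----------------------------------------
  p_xe <- plogis(cfg$alpha0 + cfg$alpha_z * visits$z + cfg$alpha_u * visits$u)
  x_e <- rbinom(n_enc, 1, p_xe)

  ## -- 7. DoD imaging studies -------------------------------------------
  # anchor studies guarantee every index visit has >= 1 qualifying study
  n_anchor <- 1L + rbinom(n_enc, 2, 0.3)
  anchor <- tibble(
    patient_id = rep(visits$patient_id, n_anchor),
    visit_date = rep(visits$visit_date, n_anchor)
  )
  anchor$study_date <- anchor$visit_date -
    sample.int(90L, nrow(anchor), replace = TRUE)
  anchor$mode <- sample(cfg$modes, nrow(anchor), replace = TRUE)
  anchor$body_part <- sample(cfg$body_parts, nrow(anchor), replace = TRUE)
  anchor$cancer_primary_dx <- FALSE

  noise_study <- function(p, lag_min, lag_max, cancer) {
    keep <- runif(n_enc) < p
    k <- sum(keep)
    if (k == 0) return(NULL)
    lag <- if (lag_max > lag_min) {
      sample.int(lag_max - lag_min + 1L, k, replace = TRUE) + lag_min - 1L
    } else rep(lag_min, k)
    tibble(
      patient_id = visits$patient_id[keep],
      visit_date = visits$visit_date[keep],
      study_date = visits$visit_date[keep] - lag,
      mode = sample(cfg$modes, k, replace = TRUE),
      body_part = sample(cfg$body_parts, k, replace = TRUE),
      cancer_primary_dx = cancer
    )
  }
  dod_imaging <- bind_rows(
    anchor,
    noise_study(cfg$p_cancer_study, 1L, 90L, TRUE),
    noise_study(cfg$p_stale_study, 91L, 180L, FALSE),
    noise_study(cfg$p_same_day_study, 0L, 0L, FALSE)
  ) |>
    select(-"visit_date") |>
    arrange(.data$patient_id, .data$study_date, .data$mode, .data$body_part) |>
    mutate(study_id = sprintf("s%07d", row_number())) |>
    select("study_id", "patient_id", "study_date", "mode", "body_part",
           "cancer_primary_dx")

  ## -- 8. qualifying study sets (mirrors the cohort matching rule) -------
  qual <- visits |>
    select("visit_id", "patient_id", "visit_date") |>
    inner_join(filter(dod_imaging, !.data$cancer_primary_dx),
               by = "patient_id", relationship = "many-to-many") |>
    filter(.data$visit_date - .data$study_date >= 1,
           .data$visit_date - .data$study_date <= 90) |>
    mutate(combo = paste(.data$mode, .data$body_part, sep = "\r"))
  qual_combos <- qual |>
    group_by(.data$visit_id) |>
    summarise(combos = list(unique(.data$combo)), .groups = "drop")

  ## -- 9. duplicate-order outcome ----------------------------------------
  elix_bin <- pmin(visits$elixhauser_score, 3L)
  age_band <- as.integer(fct_age_band(visits$age))        # 1..4
  race_i <- match(visits$race, c("White", "Black", "Other"))
  lin <- cfg$beta0 + cfg$beta_e * x_e + cfg$beta_u * visits$u +
    cfg$gamma_rate * (visits$rho - cfg$rate_center) +
    c(0, cfg$gamma_elix)[elix_bin + 1L] +
    c(0, cfg$gamma_age)[age_band] +
    c(0, cfg$gamma_race)[race_i] +
    cfg$gamma_male * (visits$gender == "Male") +
    cfg$gamma_panp * (visits$provider_type == "pa_np") +
    cfg$month_effects[visits$fiscal_month] +
    facilities$intercept[match(visits$facility_id, facilities$facility_id)]
  p_y <- plogis(lin)
  y <- rbinom(n_enc, 1, p_y)

  ## -- 10. VA imaging orders at index visits -----------------------------
  all_combos <- as.vector(outer(cfg$modes, cfg$body_parts, paste, sep = "\r"))
  combo_of <- qual_combos$combos[match(visits$visit_id, qual_combos$visit_id)]
  emit_nondup <- y == 0 & runif(n_enc) < cfg$p_order_nondup
  pick_match <- runif(n_enc)     # consumed for every row to keep draw order fixed
  pick_nonmatch <- runif(n_enc)
  order_combo <- rep(NA_character_, n_enc)
  for (i in seq_len(n_enc)) {
    cs <- combo_of[[i]]
    if (y[i] == 1L) {
      # qualifying set is non-empty by construction (anchor studies)
      order_combo[i] <- cs[1L + floor(pick_match[i] * length(cs))]
    } else if (emit_nondup[i]) {
      pool <- setdiff(all_combos, cs)
      if (length(pool) > 0) {
        order_combo[i] <- pool[1L + floor(pick_nonmatch[i] * length(pool))]
      }
    }
  }
  has_order <- !is.na(order_combo)
  idx_orders <- tibble(
    visit_id = visits$visit_id[has_order],
    mode = vapply(strsplit(order_combo[has_order], "\r"), `[`, "", 1L),
    body_part = vapply(strsplit(order_combo[has_order], "\r"), `[`, "", 2L)
  )

  ## -- 11. noise VA visits (C&P exams, non-primary-care stop codes) ------
  cp_keep <- runif(cfg$n_patients) < cfg$p_cp_visit
  cp_visits <- if (any(cp_keep)) {
    pid <- analytic_patients$patient_id[cp_keep]
    tibble(
      patient_id = pid,
      visit_date = study_start + (sample.int(n_days, length(pid), replace = TRUE) - 1L),
      primary_stop_code = sample(c(322L, 323L, 350L), length(pid), replace = TRUE),
      secondary_stop_code = 450L,
      appointment_type = "Compensation and Pension"
    ) |>
      left_join(assignment, by = "patient_id")
  } else NULL
  oth_keep <- runif(cfg$n_patients) < cfg$p_other_stop_visit
  oth_visits <- if (any(oth_keep)) {
    pid <- analytic_patients$patient_id[oth_keep]
    tibble(
      patient_id = pid,
      visit_date = study_start + (sample.int(n_days, length(pid), replace = TRUE) - 1L),
      primary_stop_code = 502L,
      secondary_stop_code = NA_integer_,
      appointment_type = "Routine"
    ) |>
      left_join(assignment, by = "patient_id")
  } else NULL

  ## -- 12. provider history visits (ordering-rate covariate support) -----
  m_hist <- pmax(5L, rpois(cfg$n_providers, cfg$history_visits_mean))
  hist_span <- as.integer(study_end - pre_start) + 1L
  hist_visits <- tibble(
    provider_id = rep(providers$provider_id, m_hist),
    rho = rep(providers$rho, m_hist)
  )
  nh <- nrow(hist_visits)
  hist_visits$patient_id <- sample(history_patients$patient_id, nh,
                                   replace = TRUE)
  hist_visits$visit_date <- pre_start +
    (sample.int(hist_span, nh, replace = TRUE) - 1L)
  hist_visits$primary_stop_code <- sample(c(322L, 323L, 350L), nh,
                                          replace = TRUE)
  hist_visits$secondary_stop_code <- NA_integer_
  hist_visits$appointment_type <- "Routine"
  hist_has_order <- runif(nh) < hist_visits$rho

  ## -- 13. assemble the VA visit table -----------------------------------
  va_visits <- bind_rows(
    select(visits, "patient_id", "provider_id", "visit_date",
           "primary_stop_code", "secondary_stop_code", "appointment_type"),
    cp_visits,
    oth_visits,
    select(hist_visits, "patient_id", "provider_id", "visit_date",
           "primary_stop_code", "secondary_stop_code", "appointment_type")
  ) |>
    left_join(select(providers, "provider_id", "facility_id"),
              by = "provider_id") |>
    mutate(fiscal_month = fiscal_month(.data$visit_date))

  # re-key all visits with final ids; index visits keep their original ids
  extra_n <- nrow(va_visits) - n_enc
  va_visits$visit_id <- c(visits$visit_id,
                          sprintf("x%07d", seq_len(extra_n)))
  va_visits <- select(va_visits, "visit_id", "patient_id", "provider_id",
                      "facility_id", "visit_date", "primary_stop_code",
                      "secondary_stop_code", "appointment_type",
                      "fiscal_month")

  hist_orders <- tibble(
    visit_id = va_visits$visit_id[(nrow(va_visits) - nh + 1L):nrow(va_visits)][hist_has_order],
    mode = sample(cfg$modes, sum(hist_has_order), replace = TRUE),
    body_part = sample(cfg$body_parts, sum(hist_has_order), replace = TRUE)
  )
  va_imaging_orders <- bind_rows(idx_orders, hist_orders)

  ## -- 14. viewer audit log ----------------------------------------------
  enc_audits <- tibble(
    provider_id = visits$provider_id[x_e == 1L],
    patient_id = visits$patient_id[x_e == 1L],
    audit_date = visits$visit_date[x_e == 1L]
  )
  z1 <- providers$provider_id[providers$z == 1L]
  bg_audits <- if (length(z1) > 0) {
    jitter <- sample.int(14L, length(z1), replace = TRUE) - 1L
    purrr::map2_dfr(z1, jitter, function(pid, j) {
      dates <- seq(pre_start + j, study_end, by = 30L)
      tibble(
        provider_id = pid,
        patient_id = sample(history_patients$patient_id, length(dates),
                            replace = TRUE),
        audit_date = dates
      )
    })
  } else NULL
  jlv_audits <- bind_rows(enc_audits, bg_audits) |>
    arrange(.data$provider_id, .data$audit_date, .data$patient_id)

  ## -- 15. outputs --------------------------------------------------------
  bundle <- structure(
    list(
      dod_imaging = dod_imaging,
      va_visits = va_visits,
      va_imaging_orders = va_imaging_orders,
      jlv_audits = jlv_audits,
      patients = select(patients, "patient_id", "age", "gender", "race",
                        "elixhauser_score"),
      providers = select(providers, "provider_id", "provider_type")
    ),
    taxonomy = list(modes = cfg$modes, body_parts = cfg$body_parts),
    study_start = study_start,
    study_end = study_end,
    class = "event_bundle"
  )

  truth <- structure(
    list(
      encounters = tibble(
        visit_id = visits$visit_id,
        patient_id = visits$patient_id,
        provider_id = visits$provider_id,
        facility_id = visits$facility_id,
        visit_date = visits$visit_date,
        z = visits$z,
        u = visits$u,
        p_viewer_use = p_xe,
        viewer_use = x_e,
        p_duplicate = p_y,
        duplicate = y
      ),
      providers = select(providers, "provider_id", "provider_type", "z",
                         "rho", "facility_id"),
      facilities = facilities,
      patients = select(patients, "patient_id", "u", "history_pool"),
      coefficients = cfg[c("alpha0", "alpha_z", "alpha_u", "beta0", "beta_e",
                           "beta_u", "sigma_facility", "gamma_rate",
                           "rate_center", "gamma_elix", "gamma_age",
                           "gamma_race", "gamma_male", "gamma_panp")],
      config = cfg
    ),
    class = "simulation_truth"
  )

  list(bundle = bundle, truth = truth)
}

#' @export
print.event_bundle <- function(x, ...) {
  cat("<event_bundle>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-18s %8d rows\n", nm, nrow(x[[nm]])))
  }
  tax <- attr(x, "taxonomy")
  cat(sprintf("  taxonomy: %d modes x %d body parts; window %s .. %s\n",
              length(tax$modes), length(tax$body_parts),
              format(attr(x, "study_start")), format(attr(x, "study_end"))))
  invisible(x)
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("<simulation_truth>\n")
  cat(sprintf("  %d encounters, %d providers, %d facilities\n",
              nrow(x$encounters), nrow(x$providers), nrow(x$facilities)))
  cat(sprintf("  beta_e = %.3f (OR %.2f); marginal duplicate rate %.3f\n",
              x$coefficients$beta_e, exp(x$coefficients$beta_e),
              mean(x$encounters$duplicate)))
  invisible(x)
}

#' Write / read an event bundle as delimited text
#'
#' The six tables are written as comma-separated text with one header row
#' and ISO-8601 dates, one file per table, so a bundle can be exchanged
#' with any downstream tool.
#'
#' @param bundle An `event_bundle`.
#' @param dir Directory to write into (created if needed).
#' @return `write_event_bundle()` returns the directory invisibly;
#'   `read_event_bundle()` returns an `event_bundle`.
#' @export
write_event_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(bundle)) {
    utils::write.csv(bundle[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  tax <- attr(bundle, "taxonomy")
  meta <- data.frame(
    key = c("study_start", "study_end", "modes", "body_parts"),
    value = c(format(attr(bundle, "study_start")),
              format(attr(bundle, "study_end")),
              paste(tax$modes, collapse = ";"),
              paste(tax$body_parts, collapse = ";"))
  )
  utils::write.csv(meta, file.path(dir, "bundle_meta.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_event_bundle
#' @export
read_event_bundle <- function(dir) {
  tabs <- c("dod_imaging", "va_visits", "va_imaging_orders", "jlv_audits",
            "patients", "providers")
  out <- lapply(tabs, function(nm) {
    df <- utils::read.csv(file.path(dir, paste0(nm, ".csv")),
                          stringsAsFactors = FALSE)
    for (col in intersect(c("study_date", "visit_date", "audit_date"),
                          names(df))) {
      df[[col]] <- as.Date(df[[col]])
    }
    if ("secondary_stop_code" %in% names(df)) {
      df$secondary_stop_code <- as.integer(df$secondary_stop_code)
    }
    as_tibble(df)
  })
  names(out) <- tabs
  meta <- utils::read.csv(file.path(dir, "bundle_meta.csv"),
                          stringsAsFactors = FALSE)
  val <- function(k) meta$value[meta$key == k]
  structure(out,
            taxonomy = list(modes = strsplit(val("modes"), ";")[[1]],
                            body_parts = strsplit(val("body_parts"), ";")[[1]]),
            study_start = as.Date(val("study_start")),
            study_end = as.Date(val("study_end")),
            class = "event_bundle")
}
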