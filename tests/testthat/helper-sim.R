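# Small simulation configurations used across tests (kept small so the
# default suite stays fast; the acceptance tests use the full sizes).

small_config <- function(n_patients = 250, n_providers = 12,
                         n_facilities = 4, seed = 1L, ...) {
  sim_config(n_patients = n_patients, n_providers = n_providers,
             n_facilities = n_facilities, seed = seed, ...)
}

mid_config <- function(n_patients = 4000, n_providers = 120,
                       n_facilities = 10, seed = 1L, ...) {
  sim_config(n_patients = n_patients, n_providers = n_providers,
             n_facilities = n_facilities, seed = seed, ...)
}

# A provider-level-exposure scenario: visit-level viewer use is forced to
# coincide with the provider's propensity class (alpha0 very negative,
# alpha_z overwhelming), so the provider-history flag, the visit-level
# flag and the generative exposure all agree and the outcome model's
# exposure effect is identified by a one-stage logistic on either flag.
provider_effect_config <- function(n_patients, n_providers, seed, ...) {
  sim_config(n_patients = n_patients, n_providers = n_providers,
             n_facilities = 6, alpha0 = -8, alpha_z = 16, alpha_u = 0,
             beta_u = 0, seed = seed, ...)
}
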