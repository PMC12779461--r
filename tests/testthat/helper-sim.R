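# Shared simulation fixtures, all generated in code at test time.

# Small multi-site configuration for fast unit tests.
small_config <- function(n_sites = 4, pps = 8, direct = 0, mult = 1, ...) {
  sim_config(n_sites = n_sites, patients_per_site_per_week = pps,
             study_start = as.Date("2016-01-01"),
             study_end = as.Date("2018-12-31"),
             direct_effect_log_odds = direct,
             los_effect_multiplier = mult, ...)
}

# Scaled-down 17-site study used by the estimator simulation studies:
# three covariates, one-month implementation stagger, ~2-year window.
# The baseline intercept is solved once so the marginal pre-period event
# risk is 0.6%; solutions are memoized per (pps-independent) key.
.study_env <- new.env(parent = emptyenv())

scaled_study_config <- function(pps = 30, direct = 0, mult = 1) {
  prev <- c(age_ge75 = 0.35, copd = 0.25, icu_ward = 0.16)
  lor <- c(age_ge75 = 0.40, copd = 0.55, icu_ward = 0.40)
  make <- function(b, d, m) sim_config(
    n_sites = 17, patients_per_site_per_week = pps,
    study_start = as.Date("2017-01-01"),
    study_end = as.Date("2019-01-31"),
    implementation_dates = as.Date("2018-01-01") +
      round(seq(0, 30, length.out = 17)),
    covariate_prevalences = prev, covariate_log_odds_nvhap = lor,
    baseline_nvhap_log_odds = b,
    direct_effect_log_odds = d, los_effect_multiplier = m,
    los_hurdle_params = list(p_los1 = 0.18, nb_mean = 4.9,
                             nb_dispersion = 1.2, hurdle_coefs = NULL,
                             mean_coefs = c(age_ge75 = 0.05, copd = 0.08,
                                            icu_ward = 0.30)),
    mortality_params = c(intercept = -3.31, age_ge75 = 0.5, event = 1))
  if (is.null(.study_env$baseline)) {
    .study_env$baseline <- uniroot(
      function(b) ground_truth_effects(make(b, 0, 1))$risk_pre - 0.006,
      c(-8, -5), tol = 1e-6)$root
  }
  make(.study_env$baseline, direct, mult)
}

# direct effect giving a prescribed true marginal risk difference under
# the scaled study conditions
direct_effect_for_rd <- function(target_rd, pps = 30) {
  key <- paste0("d_", target_rd)
  if (is.null(.study_env[[key]])) {
    .study_env[[key]] <- uniroot(function(d)
      ground_truth_effects(scaled_study_config(pps, direct = d))$rd -
        target_rd,
      c(-1, 0.5), tol = 1e-6)$root
  }
  .study_env[[key]]
}

# run the scaled pre/post analysis on the true event indicator; the
# reduced-scale design drops site indicators and the calendar-year term
# (the scaled generator has neither site effects nor secular trends) and
# uses the stabilized binomial variance
scaled_evaluate <- function(cohort, config) {
  pp <- prepost_config(config$implementation_dates)
  evaluate_effect(cohort, pp, "nvhap_truth",
                  covariates = names(config$covariate_prevalences),
                  use_site = FALSE, use_year = FALSE,
                  stabilize_binomial = TRUE)
}

# A fully quiet single-hospitalization record: room air, flat SpO2,
# afebrile, normal WBC, no imaging, no ventilation, no antibiotics.
quiet_record <- function(los, hid = 1L) {
  days <- data.table::data.table(
    hospitalization_id = hid, day = seq_len(los),
    spo2_min = 96L, o2_device_rank = 0L,
    temp_max = 36.8, wbc_max = 7.5,
    chest_imaging = FALSE, ventilated = FALSE)
  abx <- data.table::data.table(hospitalization_id = integer(),
                                day = integer(),
                                drug_class = character())
  list(days = days, abx = abx)
}

# plant a full signature by hand (independent of plant_event_signature):
# SpO2-drop worsening, fever on onset day, imaging on onset day, a new
# 3-day antibiotic course starting at onset
manual_signature <- function(los, d, hid = 1L) {
  r <- quiet_record(los, hid)
  r$days[d, spo2_min := 92L]
  r$days[d + 1L, spo2_min := 88L]
  r$days[d, temp_max := 38.6]
  r$days[d, chest_imaging := TRUE]
  r$abx <- data.table::data.table(hospitalization_id = hid,
                                  day = d:(d + 2L),
                                  drug_class = "abx_test")
  r
}

expect_within_3se <- function(est, truth, se) {
  expect_lt(abs(est - truth), 3 * se + 1e-12)
}
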