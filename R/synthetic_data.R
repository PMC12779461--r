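# Synthetic multi-site cohort generator
#
# Emulates the data structures an integrated hospital system's EHR yields for
# NV-HAP surveillance: a hospitalization table, a patient-day table of vital
# sign / laboratory / imaging / ventilation observations, a medication-
# administration table, and a discharge-diagnosis table, together with the
# generative ground truth needed to validate the downstream estimators.

#' Simulation configuration for a multi-site NV-HAP cohort
#'
#' Parameterizes the generative model: admissions arrive as a site-week
#' Poisson process; admission covariates are independent Bernoulli flags;
#' length of stay follows a hurdle model (point mass at one day, zero-
#' truncated negative binomial above it) whose count mean is multiplied by
#' `los_effect_multiplier` after a site's implementation date; the true
#' NV-HAP event is Bernoulli on the logit scale with additive covariate,
#' length-of-stay, seasonal and (post-implementation) direct intervention
#' effects; discharge pneumonia coding is an imperfect classifier of the
#' true event with optional secular drift on the log-odds scale.
#'
#' Default values emulate a 17-site hospital system observed October 2015
#' through December 2019 with staggered roll-out of a prevention initiative,
#' a marginal NV-HAP risk near 0.6% of hospitalizations, mean length of
#' stay near 6 days, 30-day mortality near 5%, and no intervention effect
#' (both `direct_effect_log_odds = 0` and `los_effect_multiplier = 1`), so
#' that non-null effects are always an explicit choice.
#'
#' @param n_sites number of facilities.
#' @param patients_per_site_per_week Poisson mean of weekly admissions per
#'   site.
#' @param study_start,study_end study window (`Date`).
#' @param implementation_dates vector of per-site roll-out start dates;
#'   defaults to dates evenly staggered so that every site has a full year
#'   of data on each side of its own date.
#' @param covariate_prevalences named vector of Bernoulli prevalences for
#'   the binary admission flags (comorbidities, admission vital/laboratory
#'   abnormality flags, ICU ward).
#' @param covariate_log_odds_nvhap per-covariate log-odds effects on the
#'   true event; names must match `covariate_prevalences`.
#' @param baseline_nvhap_log_odds intercept of the event logit.
#' @param los_per_day_log_odds_nvhap increase in event log-odds per in-stay
#'   day (the mediating pathway of the intervention).
#' @param direct_effect_log_odds additive post-implementation effect on the
#'   event logit (0 = null).
#' @param los_hurdle_params list with `p_los1` (probability of a one-day
#'   stay), `nb_mean` and `nb_dispersion` (mean/dispersion of the
#'   untruncated negative binomial for LOS - 1 on longer stays; variance =
#'   mu + mu^2/dispersion), and optional named vectors `hurdle_coefs` and
#'   `mean_coefs` of covariate effects on the hurdle logit and log count
#'   mean.
#' @param los_effect_multiplier multiplicative post-implementation effect on
#'   the negative-binomial mean (1 = null).
#' @param coding_sensitivity,coding_specificity probability that a true
#'   event is coded / a non-event is left uncoded.
#' @param coding_trend_per_year log-odds drift per year of code assignment,
#'   emulating secular coding practice change independent of true risk.
#' @param seasonal_amplitude amplitude of the annual sinusoid on the event
#'   logit.
#' @param seasonal_amplitude_los amplitude of the annual sinusoid on the
#'   log LOS mean.
#' @param mortality_params named vector: `intercept` on the logit scale,
#'   `event` effect of a true NV-HAP event, remaining names matched to
#'   covariate flags.
#' @param seed default RNG seed used when `generate_cohort` is not given
#'   one explicitly.
#'
#' @return an object of class `nvhap_sim_config` (a validated list).
#' @export
sim_config <- function(n_sites = 17L,
                       patients_per_site_per_week = 88,
                       study_start = as.Date("2015-10-01"),
                       study_end = as.Date("2019-12-31"),
                       implementation_dates = NULL,
                       covariate_prevalences = c(
                         age_ge75 = 0.35, male = 0.95, copd = 0.25,
                         chf = 0.20, dementia = 0.10, abn_temp = 0.08,
                         abn_wbc = 0.20, hypoxemia = 0.12, icu_ward = 0.16),
                       covariate_log_odds_nvhap = c(
                         age_ge75 = 0.40, male = 0.10, copd = 0.55,
                         chf = 0.35, dementia = 0.45, abn_temp = 0.30,
                         abn_wbc = 0.35, hypoxemia = 0.50, icu_ward = 0.40),
                       baseline_nvhap_log_odds = -6.379,
                       los_per_day_log_odds_nvhap = 0.06,
                       direct_effect_log_odds = 0,
                       los_hurdle_params = list(
                         p_los1 = 0.18, nb_mean = 4.9, nb_dispersion = 1.2,
                         hurdle_coefs = NULL,
                         mean_coefs = c(age_ge75 = 0.05, copd = 0.08,
                                        chf = 0.05, icu_ward = 0.30)),
                       los_effect_multiplier = 1,
                       coding_sensitivity = 0.55,
                       coding_specificity = 0.996,
                       coding_trend_per_year = -0.18,
                       seasonal_amplitude = 0.10,
                       seasonal_amplitude_los = 0.03,
                       mortality_params = c(intercept = -3.31,
                                            age_ge75 = 0.50, chf = 0.40,
                                            event = 1.00),
                       seed = 20151001L) {
  stop_if_not_scalar_date(study_start, "study_start")
  stop_if_not_scalar_date(study_end, "study_end")
  if (study_end <= study_start) stop("study_end must follow study_start")
  n_sites <- as.integer(n_sites)
  if (is.na(n_sites) || n_sites < 1L) stop("n_sites must be >= 1")
  if (patients_per_site_per_week <= 0)
    stop("patients_per_site_per_week must be positive")
  if (is.null(implementation_dates)) {
    lo <- study_start + 365
    hi <- study_end - 365
    implementation_dates <- lo + round(seq(0, as.numeric(hi - lo),
                                           length.out = n_sites))
    implementation_dates <- as.Date(implementation_dates,
                                    origin = "1970-01-01")
  }
  implementation_dates <- as.Date(implementation_dates)
  if (length(implementation_dates) != n_sites)
    stop("implementation_dates must have one date per site")
  if (any(implementation_dates < study_start |
          implementation_dates > study_end))
    stop("implementation dates must lie within [study_start, study_end]")
  probs <- c(covariate_prevalences, coding_sensitivity, coding_specificity,
             los_hurdle_params$p_los1)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must be in [0,1]")
  if (!identical(sort(names(covariate_prevalences)),
                 sort(names(covariate_log_odds_nvhap))))
    stop("covariate prevalence and effect names must match")
  if (los_hurdle_params$nb_dispersion <= 0)
    stop("NB dispersion must be positive")
  if (los_hurdle_params$nb_mean <= 0) stop("NB mean must be positive")
  if (los_effect_multiplier <= 0)
    stop("los_effect_multiplier must be positive")
  cfg <- list(
    n_sites = n_sites,
    patients_per_site_per_week = patients_per_site_per_week,
    study_start = study_start, study_end = study_end,
    implementation_dates = implementation_dates,
    covariate_prevalences = covariate_prevalences,
    covariate_log_odds_nvhap =
      covariate_log_odds_nvhap[names(covariate_prevalences)],
    baseline_nvhap_log_odds = baseline_nvhap_log_odds,
    los_per_day_log_odds_nvhap = los_per_day_log_odds_nvhap,
    direct_effect_log_odds = direct_effect_log_odds,
    los_hurdle_params = los_hurdle_params,
    los_effect_multiplier = los_effect_multiplier,
    coding_sensitivity = coding_sensitivity,
    coding_specificity = coding_specificity,
    coding_trend_per_year = coding_trend_per_year,
    seasonal_amplitude = seasonal_amplitude,
    seasonal_amplitude_los = seasonal_amplitude_los,
    mortality_params = mortality_params,
    seed = seed)
  class(cfg) <- "nvhap_sim_config"
  cfg
}

# annual sinusoid evaluated at a Date (peak in early January by phase 0)
season_term <- function(dates) sin(2 * pi * (as.POSIXlt(dates)$yday / 365.25))

# years since study start as a numeric
years_since <- function(dates, origin) as.numeric(dates - origin) / 365.25

# covariate linear predictor from a named coefficient vector; names not
# matching a flag column are ignored so effect defaults can reference the
# full default flag set under reduced custom configurations
flag_lp <- function(dt, coefs) {
  out <- rep(0, nrow(dt))
  if (is.null(coefs)) return(out)
  for (nm in intersect(names(coefs), names(dt)))
    out <- out + coefs[[nm]] * dt[[nm]]
  out
}

# Zero-truncated draw of the count component: LOS = 1 + Y, Y >= 1 from an
# NB(mu, theta) conditioned on Y >= 1, by inverse-CDF on the truncated tail.
rztnb <- function(n, mu, theta) {
  p0 <- (theta / (theta + mu))^theta
  u <- p0 + runif(n) * (1 - p0)
  # guard against u numerically hitting 1
  u <- pmin(u, 1 - 1e-12)
  qnbinom(u, size = theta, mu = mu)
}

# per-patient event logit at a given LOS vector and post indicator
event_logit <- function(cfg, lp_cov, los, post, seas) {
  cfg$baseline_nvhap_log_odds + lp_cov +
    cfg$los_per_day_log_odds_nvhap * los +
    cfg$direct_effect_log_odds * post +
    cfg$seasonal_amplitude * seas
}

#' Generate a synthetic multi-site cohort
#'
#' Draws a full cohort from the generative model described in
#' [sim_config()]: admissions, covariate flags, hurdle-NB length of stay,
#' true NV-HAP events with in-stay onset days, quiet daily observations
#' with planted event signatures (see [plant_event_signature()]),
#' background and qualifying antibiotic courses, discharge pneumonia
#' diagnoses with imperfect sensitivity/specificity, and 30-day mortality.
#'
#' The `truth` table records, per hospitalization, the true event
#' indicator, the planted onset day (`NA` when the stay is too short or
#' ventilated to carry a detectable signature), and the closed-form
#' counterfactual event probability obtained from the generative logits
#' with all post-implementation indicators set to zero and length of stay
#' integrated out.
#'
#' @param config an [sim_config()] object.
#' @param seed integer seed; required (the generator refuses to run
#'   unseeded so every cohort is reproducible).
#' @param include_clinical if `FALSE`, skip the patient-day, antibiotic and
#'   diagnosis tables and return only hospitalizations + truth (used by
#'   large estimator simulation studies where day-level data are not
#'   consumed).
#' @param include_truth_cf if `FALSE`, skip the closed-form per-patient
#'   counterfactual probability in the truth table (it integrates the
#'   generative model over the length-of-stay support, the most expensive
#'   part of generation; replicate studies that only need the event
#'   indicator can drop it).
#' @return an object of class `nvhap_cohort`: a list of `data.table`s
#'   `hospitalizations`, `patient_days`, `antibiotic_days`, `diagnoses`,
#'   `truth`, plus the generating `config`.
#' @export
generate_cohort <- function(config, seed = config$seed,
                            include_clinical = TRUE,
                            include_truth_cf = TRUE) {
  stopifnot(inherits(config, "nvhap_sim_config"))
  if (is.null(seed) || is.na(seed))
    stop("a seed is required for cohort generation")
  cfg <- config

  hosp <- with_stream(seed, "admissions", {
    week_starts <- seq(cfg$study_start, cfg$study_end, by = 7L)
    grid <- CJ(site = seq_len(cfg$n_sites), week = seq_along(week_starts))
    grid[, n := rpois(.N, cfg$patients_per_site_per_week)]
    grid <- grid[n > 0L]
    h <- grid[rep(seq_len(.N), n)]
    h[, admit_date := week_starts[week] + sample(0:6, .N, replace = TRUE)]
    h <- h[admit_date <= cfg$study_end]
    setorder(h, site, admit_date)
    h[, hospitalization_id := seq_len(.N)]
    h[, c("week", "n") := NULL]
    h
  })

  with_stream(seed, "covariates", {
    for (nm in names(cfg$covariate_prevalences)) {
      hosp[, (nm) := rbinom(.N, 1L, cfg$covariate_prevalences[[nm]])]
    }
  })

  hosp[, impl_date := cfg$implementation_dates[site]]
  hosp[, post := as.integer(admit_date >= impl_date)]
  hosp[, seas := season_term(admit_date)]

  lhp <- cfg$los_hurdle_params
  with_stream(seed, "los", {
    hurdle_lp <- qlogis(lhp$p_los1) + flag_lp(hosp, lhp$hurdle_coefs)
    one_day <- rbinom(nrow(hosp), 1L, plogis(hurdle_lp)) == 1L
    mu <- exp(log(lhp$nb_mean) + flag_lp(hosp, lhp$mean_coefs) +
                cfg$seasonal_amplitude_los * hosp$seas +
                log(cfg$los_effect_multiplier) * hosp$post)
    los <- rep(1L, nrow(hosp))
    idx <- which(!one_day)
    los[idx] <- 1L + rztnb(length(idx), mu[idx], lhp$nb_dispersion)
    hosp[, los := los]
  })
  hosp[, discharge_date := admit_date + los]

  lp_cov <- flag_lp(hosp, cfg$covariate_log_odds_nvhap)
  with_stream(seed, "events", {
    p_event <- plogis(event_logit(cfg, lp_cov, hosp$los, hosp$post,
                                  hosp$seas))
    hosp[, true_event := rbinom(.N, 1L, p_event)]
  })

  # which stays can carry the planted 4-day signature (needs >= 2 baseline
  # days, 2 worsening days, and a 3-day antibiotic course inside the stay)
  with_stream(seed, "event_days", {
    hosp[, ventilated_stay := 0L]
    icu_idx <- which(hosp$icu_ward == 1L & hosp$true_event == 0L)
    hosp[icu_idx, ventilated_stay := rbinom(length(icu_idx), 1L, 0.3)]
    hosp[, detectable := true_event == 1L & los >= 5L &
             ventilated_stay == 0L]
    hosp[, true_event_day := NA_integer_]
    det <- which(hosp$detectable)
    if (length(det)) {
      # onset on {3, ..., LOS-2}: two baseline days before, a worsening
      # pair and a 3-day antibiotic course fitting inside the stay
      hosp[det, true_event_day :=
               3L + floor(runif(length(det)) * (los - 4L))]
    }
  })

  with_stream(seed, "mortality", {
    mp <- cfg$mortality_params
    lp <- mp[["intercept"]] + mp[["event"]] * hosp$true_event +
      flag_lp(hosp, mp[setdiff(names(mp), c("intercept", "event"))])
    hosp[, death30 := rbinom(.N, 1L, plogis(lp))]
  })

  truth <- hosp[, .(hospitalization_id, true_event, true_event_day,
                    detectable = as.integer(detectable))]
  truth[, true_counterfactual := if (include_truth_cf)
            counterfactual_truth_prob(cfg, lp_cov, hosp) else NA_real_]

  out <- list(hospitalizations = NULL, patient_days = NULL,
              antibiotic_days = NULL, diagnoses = NULL, truth = truth,
              config = cfg)

  # diagnoses are hospitalization-level and always drawn; the day-level
  # tables are the expensive part gated by include_clinical
  out$diagnoses <- with_stream(seed, "diagnoses",
                               draw_diagnoses(cfg, hosp))
  if (include_clinical) {
    pd <- with_stream(seed, "patient_days",
                      quiet_patient_days(hosp))
    abx <- with_stream(seed, "antibiotics",
                       background_antibiotics(hosp))
    planted <- with_stream(seed, "signatures",
                           plant_all_signatures(hosp, pd, abx, seed))
    out$patient_days <- planted$patient_days
    out$antibiotic_days <- planted$antibiotic_days
  }

  keep <- c("hospitalization_id", "site", "admit_date", "discharge_date",
            "los", "impl_date", "post", "death30",
            names(cfg$covariate_prevalences))
  out$hospitalizations <- hosp[, keep, with = FALSE]
  class(out) <- "nvhap_cohort"
  out
}

# Closed-form counterfactual probability for each hospitalization: the
# event probability with every post indicator set to 0 and length of stay
# integrated over its (post = 0) hurdle-NB distribution.
counterfactual_truth_prob <- function(cfg, lp_cov, hosp) {
  lhp <- cfg$los_hurdle_params
  theta <- lhp$nb_dispersion
  mu <- exp(log(lhp$nb_mean) + flag_lp(hosp, lhp$mean_coefs) +
              cfg$seasonal_amplitude_los * hosp$seas)
  p1 <- plogis(qlogis(lhp$p_los1) + flag_lp(hosp, lhp$hurdle_coefs))
  lmax <- min(500L, max(10L, qnbinom(1 - 1e-12, size = theta,
                                     mu = max(mu)) + 1L))
  base_lp <- cfg$baseline_nvhap_log_odds + lp_cov +
    cfg$seasonal_amplitude * hosp$seas
  n <- nrow(hosp)
  res <- numeric(n)
  chunk <- 20000L
  for (st in seq(1L, n, by = chunk)) {
    en <- min(st + chunk - 1L, n)
    i <- st:en
    p0 <- (theta / (theta + mu[i]))^theta
    Q <- nb_pmf_cols(mu[i], theta, lmax - 1L) / (1 - p0)
    P <- plogis(outer(base_lp[i],
                      cfg$los_per_day_log_odds_nvhap * (2:lmax), `+`))
    res[i] <- p1[i] * plogis(base_lp[i] + cfg$los_per_day_log_odds_nvhap) +
      (1 - p1[i]) * rowSums(Q * P)
  }
  res
}

# Quiet daily observations: stable oxygenation (jitter never reaches the
# 3-point drop), afebrile, normal WBC, no imaging; device rank constant per
# stay; ventilated stays carry rank 5 all days.
quiet_patient_days <- function(hosp) {
  n_days <- hosp$los
  pd <- data.table(
    hospitalization_id = rep(hosp$hospitalization_id, n_days),
    day = sequence(n_days))
  nrow_pd <- nrow(pd)
  base_spo2 <- rep(sample(93:97, nrow(hosp), replace = TRUE), n_days)
  pd[, spo2_min := base_spo2 + sample(c(-1L, 0L, 1L), nrow_pd,
                                      replace = TRUE)]
  rank_stay <- rep(ifelse(hosp$ventilated_stay == 1L, 5L,
                          rbinom(nrow(hosp), 1L, 0.15)), n_days)
  pd[, o2_device_rank := rank_stay]
  pd[, temp_max := round(runif(nrow_pd, 36.2, 37.6), 1)]
  pd[, wbc_max := round(runif(nrow_pd, 4.0, 10.9), 1)]
  pd[, chest_imaging := runif(nrow_pd) < 0.03]
  pd[, ventilated := o2_device_rank == 5L]
  # missingness, imputed-as-normal downstream
  pd[runif(nrow_pd) < 0.05, spo2_min := NA_integer_]
  pd[runif(nrow_pd) < 0.10, temp_max := NA_real_]
  pd[runif(nrow_pd) < 0.30, wbc_max := NA_real_]
  pd
}

ABX_CLASSES <- paste0("class_", LETTERS[1:8])
BACKGROUND_ABX <- ABX_CLASSES[1:6]   # classes G/H reserved for planted courses
PLANTED_ABX <- ABX_CLASSES[7:8]

# sporadic non-qualifying antibiotic exposure on quiet stays
background_antibiotics <- function(hosp) {
  treated <- hosp[runif(.N) < 0.20 & los >= 2L,
                  .(hospitalization_id, los)]
  if (nrow(treated) == 0L)
    return(data.table(hospitalization_id = integer(), day = integer(),
                      drug_class = character()))
  treated[, start := 1L + floor(runif(.N) * los)]
  treated[, len := pmin(1L + floor(runif(.N) * 4), los - start + 1L)]
  treated[, drug_class := sample(BACKGROUND_ABX, .N, replace = TRUE)]
  ab <- treated[rep(seq_len(.N), len)]
  ab[, day := start + sequence(treated$len) - 1L]
  ab[, .(hospitalization_id, day, drug_class)]
}

# Insert the full detectable signature for every event hospitalization.
plant_all_signatures <- function(hosp, pd, abx, seed) {
  det <- hosp[detectable == TRUE,
              .(hospitalization_id, true_event_day, los)]
  if (nrow(det) == 0L)
    return(list(patient_days = pd, antibiotic_days = abx))
  setkey(pd, hospitalization_id, day)
  new_abx <- vector("list", nrow(det))
  for (k in seq_len(nrow(det))) {
    hid <- det$hospitalization_id[k]
    d <- det$true_event_day[k]
    rows <- pd[.(hid)]
    planted <- plant_event_signature(
      rows, abx[hospitalization_id == hid], d,
      seed = child_seed(seed, paste0("sig", hid)))
    vcols <- setdiff(names(pd), c("hospitalization_id", "day"))
    pd[.(hid), (vcols) := planted$days[, vcols, with = FALSE]]
    new_abx[[k]] <- planted$abx[!abx[hospitalization_id == hid],
                                on = c("hospitalization_id", "day",
                                       "drug_class")]
  }
  abx <- rbind(abx, rbindlist(new_abx))
  setorder(abx, hospitalization_id, day, drug_class)
  list(patient_days = pd, antibiotic_days = abx)
}

#' Plant an electronic NV-HAP event signature into a quiet record
#'
#' Rewrites one hospitalization's patient-day rows so that the electronic
#' surveillance definition fires exactly once at `event_day`: two
#' stable/improving baseline days, two worsening days (device-rank
#' escalation or a >= 3-point drop in daily minimum SpO2), fever or
#' leukocytosis concurrent with onset, chest imaging, a new antibiotic
#' class administered three consecutive days starting on the onset day,
#' and no ventilation on the onset day or the two days before it.
#'
#' @param days `data.table` of this hospitalization's patient-day rows
#'   (one per in-stay day, columns as in the cohort `patient_days` table).
#' @param abx `data.table` of this hospitalization's antibiotic-day rows.
#' @param event_day onset day; must satisfy `event_day >= 3` and
#'   `event_day + 2 <= LOS` (the qualifying antibiotic course must fit
#'   inside the stay).
#' @param seed integer seed controlling the worsening mode (oxygen-device
#'   escalation vs SpO2 drop) and the fever-vs-leukocytosis choice.
#' @return list with modified `days` and `abx` tables.
#' @export
plant_event_signature <- function(days, abx, event_day, seed = 1L) {
  days <- copy(as.data.table(days))
  abx <- copy(as.data.table(abx))
  setorder(days, day)
  los <- nrow(days)
  if (event_day < 3L)
    stop("event_day must be >= 3 (two stable baseline days are required)")
  if (event_day + 2L > los)
    stop("event_day + 2 must not exceed the length of stay (two worsening ",
         "days plus a 3-day antibiotic course starting at onset are ",
         "required)")
  hid <- days$hospitalization_id[1L]
  set.seed(seed)
  d <- event_day
  w <- (d - 2L):(d + 1L)

  # baseline: constant rank, flat SpO2, not ventilated around onset
  base_rank <- min(days$o2_device_rank[d - 1L], 3L)
  days[w, o2_device_rank := base_rank]
  days[w, ventilated := FALSE]
  base_spo2 <- 96L
  days[(d - 2L):(d - 1L), spo2_min := base_spo2]

  if (runif(1) < 0.5 && base_rank <= 3L) {
    # escalation of supplemental-oxygen device on both worsening days
    days[d, o2_device_rank := base_rank + 1L]
    days[d + 1L, o2_device_rank := min(base_rank + 2L, 4L)]
    days[d:(d + 1L), spo2_min := base_spo2]
  } else {
    days[d, spo2_min := base_spo2 - 4L]
    days[d + 1L, spo2_min := base_spo2 - 7L]
  }

  if (runif(1) < 0.6) days[d, temp_max := 38.6]
  else days[d, wbc_max := 14.2]
  days[d, chest_imaging := TRUE]

  cls <- sample(PLANTED_ABX, 1L)
  course <- data.table(hospitalization_id = hid,
                       day = d:(d + 2L), drug_class = cls)
  abx <- rbind(abx, course)
  setorder(abx, day, drug_class)
  list(days = days[], abx = abx[])
}

# Discharge diagnoses: a pneumonia code (uniform over the qualifying set,
# dotted dialect, POA = N) emitted with probability
# plogis(qlogis(sens or 1 - spec) + trend * years); community-acquired
# pneumonia codes (POA = Y) and non-pneumonia noise codes added on top.
draw_diagnoses <- function(cfg, hosp) {
  t_years <- years_since(hosp$admit_date, cfg$study_start)
  base <- ifelse(hosp$true_event == 1L, cfg$coding_sensitivity,
                 1 - cfg$coding_specificity)
  # clamp away from 0/1 so the secular drift stays defined
  base <- pmin(pmax(base, 1e-8), 1 - 1e-8)
  p_code <- plogis(qlogis(base) + cfg$coding_trend_per_year * t_years)
  coded <- rbinom(nrow(hosp), 1L, p_code) == 1L
  pneu_codes <- c("J13", "J15.9", "J15.8", "J16.8", "J17", "J18.9",
                  "J18.1", "B95.3", "B96.0", "J84.111", "J85.1", "J85.2")
  dx_event <- data.table(
    hospitalization_id = hosp$hospitalization_id[coded],
    icd10_code = sample(pneu_codes, sum(coded), replace = TRUE),
    position = sample(c("primary", "secondary"), sum(coded),
                      replace = TRUE, prob = c(0.3, 0.7)),
    poa = "N")
  cap <- runif(nrow(hosp)) < 0.02   # community-acquired, present on admission
  dx_cap <- data.table(
    hospitalization_id = hosp$hospitalization_id[cap],
    icd10_code = sample(pneu_codes, sum(cap), replace = TRUE),
    position = "primary", poa = "Y")
  noise_codes <- c("I50.9", "E11.9", "J44.1", "N17.9", "I10", "F03.90",
                   "J96.01", "A41.9")
  nn <- rbinom(nrow(hosp), 2L, 0.6)
  dx_noise <- data.table(
    hospitalization_id = rep(hosp$hospitalization_id, nn),
    icd10_code = sample(noise_codes, sum(nn), replace = TRUE),
    position = "secondary",
    poa = sample(c("Y", "N", "U"), sum(nn), replace = TRUE,
                 prob = c(0.85, 0.10, 0.05)))
  dx <- rbind(dx_event, dx_cap, dx_noise)
  setorder(dx, hospitalization_id, icd10_code)
  dx[]
}

#' Closed-form marginal risks and true risk difference under a configuration
#'
#' Integrates the generative event logit over the covariate distribution
#' (exact enumeration of the binary flags), the annual seasonal cycle
#' (monthly quadrature), and the hurdle-NB length-of-stay distribution
#' (summation over the support, tail truncated below 1e-12 mass), with the
#' post-implementation indicator set to 0 (pre) and 1 (post).
#'
#' @param config an [sim_config()] object.
#' @return list with `risk_pre`, `risk_post` and `rd = risk_post -
#'   risk_pre`, all on the probability scale.
#' @export
ground_truth_effects <- function(config) {
  cfg <- config
  prev <- cfg$covariate_prevalences
  k <- length(prev)
  combos <- as.matrix(do.call(CJ, rep(list(0:1), k)))
  colnames(combos) <- names(prev)
  w_cov <- apply(combos, 1L, function(x)
    prod(ifelse(x == 1, prev, 1 - prev)))
  lp_cov <- as.numeric(combos %*% cfg$covariate_log_odds_nvhap)
  lhp <- cfg$los_hurdle_params
  mean_coefs <- lhp$mean_coefs
  lp_mu <- if (is.null(mean_coefs)) rep(0, nrow(combos)) else
    as.numeric(combos[, names(mean_coefs), drop = FALSE] %*% mean_coefs)
  lp_h <- if (is.null(lhp$hurdle_coefs)) rep(0, nrow(combos)) else
    as.numeric(combos[, names(lhp$hurdle_coefs), drop = FALSE] %*%
                 lhp$hurdle_coefs)
  seas_pts <- sin(2 * pi * ((1:12 - 0.5) / 12))
  theta <- lhp$nb_dispersion
  risk <- function(post) {
    mult <- if (post) cfg$los_effect_multiplier else 1
    total <- 0
    for (s in seas_pts) {
      mu <- exp(log(lhp$nb_mean) + lp_mu + cfg$seasonal_amplitude_los * s +
                  log(mult))
      p1 <- plogis(qlogis(lhp$p_los1) + lp_h)
      p0 <- (theta / (theta + mu))^theta
      lmax <- min(500L, qnbinom(1 - 1e-12, size = theta, mu = max(mu)) + 1L)
      base_lp <- cfg$baseline_nvhap_log_odds + lp_cov +
        cfg$seasonal_amplitude * s + cfg$direct_effect_log_odds * post
      acc <- p1 * plogis(base_lp + cfg$los_per_day_log_odds_nvhap)
      for (l in 2:lmax) {
        m <- (1 - p1) * dnbinom(l - 1L, size = theta, mu = mu) / (1 - p0)
        acc <- acc + m * plogis(base_lp + cfg$los_per_day_log_odds_nvhap * l)
      }
      total <- total + sum(w_cov * acc)
    }
    total / length(seas_pts)
  }
  pre <- risk(FALSE)
  post <- risk(TRUE)
  list(risk_pre = pre, risk_post = post, rd = post - pre)
}

#' Write cohort tables as CSV files
#'
#' Writes `hospitalizations.csv`, `patient_days.csv`,
#' `antibiotic_days.csv`, `diagnoses.csv` and `truth.csv` with ISO-8601
#' dates and 1-based in-stay day indices.
#'
#' @param cohort an `nvhap_cohort` object.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "nvhap_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("hospitalizations", "patient_days", "antibiotic_days",
               "diagnoses", "truth")) {
    tab <- cohort[[nm]]
    if (!is.null(tab))
      data.table::fwrite(tab, file.path(dir, paste0(nm, ".csv")))
  }
  invisible(dir)
}

#' Read cohort tables written by [write_cohort()]
#'
#' @param dir directory containing the CSV tables.
#' @return an `nvhap_cohort` list (without the generating config).
#' @export
read_cohort <- function(dir) {
  rd <- function(nm) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (file.exists(f)) data.table::fread(f) else NULL
  }
  out <- list(hospitalizations = rd("hospitalizations"),
              patient_days = rd("patient_days"),
              antibiotic_days = rd("antibiotic_days"),
              diagnoses = rd("diagnoses"),
              truth = rd("truth"),
              config = NULL)
  if (!is.null(out$hospitalizations)) {
    for (cc in intersect(c("admit_date", "discharge_date", "impl_date"),
                         names(out$hospitalizations)))
      out$hospitalizations[, (cc) := as.Date(get(cc))]
  }
  class(out) <- "nvhap_cohort"
  out
}
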