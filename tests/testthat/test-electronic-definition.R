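library(data.table)

make_days <- function(rank, spo2 = rep(96L, length(rank)), hid = 1L) {
  data.table(hospitalization_id = hid, day = seq_along(rank),
             spo2_min = spo2, o2_device_rank = rank,
             temp_max = 36.8, wbc_max = 7.5,
             chest_imaging = FALSE, ventilated = rank == 5L)
}

test_that("oxygenation labels follow the escalation and desaturation rules", {
  expect_equal(daily_oxygenation_status(make_days(c(0L, 0L, 1L))),
               c("undefined", "stable_or_improving", "worsening"))
  # 3-point SpO2 drop at unchanged rank is worsening
  expect_equal(daily_oxygenation_status(
    make_days(c(0L, 0L), spo2 = c(96L, 92L)))[2], "worsening")
  expect_equal(daily_oxygenation_status(
    make_days(c(0L, 0L), spo2 = c(96L, 93L)))[2], "worsening")
  expect_equal(daily_oxygenation_status(
    make_days(c(0L, 0L), spo2 = c(96L, 95L)))[2], "stable_or_improving")
  # missing SpO2 at unchanged rank never creates worsening
  expect_equal(daily_oxygenation_status(
    make_days(c(0L, 0L), spo2 = c(96L, NA)))[2], "stable_or_improving")
  # de-escalation is stable/improving even with an SpO2 drop
  expect_equal(daily_oxygenation_status(
    make_days(c(2L, 1L), spo2 = c(96L, 90L)))[2], "stable_or_improving")
  d <- make_days(c(0L, 0L))
  d$day <- c(1L, 1L)
  expect_error(daily_oxygenation_status(d), "duplicate")
})

test_that("candidate onsets require two worsening after two stable days", {
  lab <- function(x) ifelse(strsplit(x, "")[[1]] == "W", "worsening",
                            "stable_or_improving")
  l1 <- lab("SSWW"); l1[1] <- "undefined"
  expect_equal(find_candidate_onsets(l1), 3L)
  l2 <- lab("SSSWW"); l2[1] <- "undefined"
  expect_equal(find_candidate_onsets(l2), 4L)
  # a worsening day at d - 2 breaks the two-day stable baseline
  l3 <- lab("SWSWW"); l3[1] <- "undefined"
  expect_equal(find_candidate_onsets(l3), integer())
  expect_equal(find_candidate_onsets(lab("SSSSS")), integer())

  # exhaustive check over all 2^10 worsening patterns of a 10-day stay
  # against a first-principles window enumeration
  oracle <- function(labels) {
    n <- length(labels)
    out <- integer()
    for (d in 3:(n - 1)) {
      base_ok <- all(labels[c(d - 1, d - 2)] %in%
                       c("stable_or_improving", "undefined"))
      if (labels[d] == "worsening" && labels[d + 1] == "worsening" &&
            base_ok)
        out <- c(out, d)
    }
    out
  }
  for (bits in 0:1023) {
    w <- as.logical(bitwAnd(bits, 2^(0:9)))
    labels <- ifelse(w, "worsening", "stable_or_improving")
    labels[1] <- "undefined"
    expect_identical(find_candidate_onsets(labels), oracle(labels))
  }
})

test_that("adjudication enforces every criterion and its window", {
  base <- manual_signature(los = 12, d = 6)
  expect_equal(nrow(detect_nvhap(base$days, base$abx)), 1L)

  tweak <- function(mod_days = NULL, abx = base$abx) {
    d2 <- copy(base$days)
    if (!is.null(mod_days)) mod_days(d2)
    detect_nvhap(d2, abx)
  }
  # fever/leukocytosis window [d-1, d+1]
  expect_equal(nrow(tweak(function(d2) {
    d2[6, temp_max := 36.8]; d2[5, temp_max := 38.2] })), 1L)
  expect_equal(nrow(tweak(function(d2) {
    d2[6, temp_max := 36.8]; d2[7, wbc_max := 13.0] })), 1L)
  expect_equal(nrow(tweak(function(d2) {
    d2[6, temp_max := 36.8]; d2[4, temp_max := 39.0] })), 0L)
  # imaging window [d-1, d+2]
  expect_equal(nrow(tweak(function(d2) {
    d2[6, chest_imaging := FALSE]; d2[8, chest_imaging := TRUE] })), 1L)
  expect_equal(nrow(tweak(function(d2) {
    d2[6, chest_imaging := FALSE]; d2[9, chest_imaging := TRUE] })), 0L)
  # ventilation on [d-2, d] excludes
  expect_equal(nrow(tweak(function(d2) d2[4, ventilated := TRUE])), 0L)
  expect_equal(nrow(tweak(function(d2) d2[7, ventilated := TRUE])), 1L)

  # antibiotic rules: class present in the lookback is not new
  ab_look <- rbind(base$abx,
                   data.table(hospitalization_id = 1L, day = 4L,
                              drug_class = "abx_test"))
  expect_equal(nrow(detect_nvhap(base$days, ab_look)), 0L)
  # a different class in the lookback does not block the new course
  ab_other <- rbind(base$abx,
                    data.table(hospitalization_id = 1L, day = 4L,
                               drug_class = "abx_old"))
  expect_equal(nrow(detect_nvhap(base$days, ab_other)), 1L)
  # start at d+1 qualifies; course must still fit 3 consecutive days
  ab_late <- data.table(hospitalization_id = 1L, day = 7:9,
                        drug_class = "abx_test")
  expect_equal(nrow(detect_nvhap(base$days, ab_late)), 1L)
  # discharge truncation disqualifies: same signature near end of stay
  short <- manual_signature(los = 7, d = 6)
  short$abx <- short$abx[day <= 7]
  expect_equal(nrow(detect_nvhap(short$days, short$abx)), 0L)
  # a 2-day gapped course never qualifies
  ab_gap <- data.table(hospitalization_id = 1L, day = c(6L, 7L, 9L),
                       drug_class = "abx_test")
  expect_equal(nrow(detect_nvhap(base$days, ab_gap)), 0L)
})

test_that("first event only, row-order invariance, no short-stay events", {
  # two full signatures at days 5 and 15: only the first is kept
  r <- quiet_record(20)
  p1 <- plant_event_signature(r$days, r$abx, event_day = 5, seed = 1)
  p2 <- plant_event_signature(p1$days, p1$abx, event_day = 15, seed = 2)
  ev <- detect_nvhap(p2$days, p2$abx)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$event_day, 5L)

  # shuffled row order detects identically
  set.seed(1)
  shuf <- p2$days[sample(.N)]
  ev2 <- detect_nvhap(shuf, p2$abx)
  expect_equal(as.data.frame(ev2), as.data.frame(ev))

  # cohort-level: no onset before day 3, no events in stays < 5 days,
  # and detection matches the planted truth exactly
  co <- generate_cohort(small_config(n_sites = 3, pps = 10), seed = 11)
  evc <- detect_nvhap(co)
  h <- co$hospitalizations
  expect_true(all(evc$event_day >= 3L))
  los_of <- h$los[match(evc$hospitalization_id, h$hospitalization_id)]
  expect_true(all(los_of >= 5L))
  planted <- co$truth[detectable == 1L]
  m <- merge(planted, evc, by = "hospitalization_id", all = TRUE)
  expect_true(all(!is.na(m$event_day)))
  expect_true(all(m$event_day == m$true_event_day))

  # referential integrity errors carry the offending id
  bad_abx <- data.table(hospitalization_id = 999999L, day = 1L,
                        drug_class = "x")
  expect_error(detect_nvhap(co$patient_days, bad_abx), "999999")
})

test_that("each single criterion ablation suppresses a planted detection", {
  base <- manual_signature(los = 12, d = 6)
  expect_equal(nrow(detect_nvhap(base$days, base$abx)), 1L)
  ablate <- list(
    fever_leuko = function(r) { r$days[5:7, `:=`(temp_max = 36.8,
                                                 wbc_max = 7.5)]; r },
    imaging = function(r) { r$days[, chest_imaging := FALSE]; r },
    new_abx = function(r) { r$abx <- r$abx[0]; r },
    oxygenation = function(r) { r$days[, spo2_min := 96L]; r },
    nonventilated = function(r) { r$days[6, ventilated := TRUE]; r })
  for (nm in names(ablate)) {
    r <- list(days = copy(base$days), abx = copy(base$abx))
    r <- ablate[[nm]](r)
    expect_equal(nrow(detect_nvhap(r$days, r$abx)), 0L, label = nm)
  }
})
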