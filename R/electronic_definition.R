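# Electronic clinical-data NV-HAP surveillance definition
#
# A hospitalization qualifies when a non-ventilated patient shows new
# respiratory deterioration -- at least 2 days of worsening oxygenation
# (device escalation or SpO2 drop) after at least 2 days of stable or
# improving oxygenation -- together with concurrent fever or leukocytosis,
# chest imaging, and a new antibiotic class given on at least 3 consecutive
# days.  All thresholds and concurrency windows are explicit in
# detection_rules() and recorded on the detector output.

#' Detection rule settings for the electronic NV-HAP definition
#'
#' @param spo2_drop minimum drop in daily minimum SpO2 (percentage points,
#'   at unchanged device rank) counted as worsening oxygenation.
#' @param fever_temp fever threshold, degrees C, on daily maximum.
#' @param leukocytosis_wbc leukocytosis threshold, 10^3 cells/uL, on daily
#'   maximum.
#' @param fever_window days relative to onset day `d` in which fever or
#'   leukocytosis qualifies as concurrent.
#' @param imaging_window days relative to `d` in which chest imaging
#'   qualifies.
#' @param abx_start_window days relative to `d` in which a qualifying new
#'   antibiotic course may start.
#' @param abx_min_days required consecutive days of the new class; courses
#'   cut short by discharge do not qualify.
#' @param abx_lookback days before `d` that must be free of the class for
#'   it to count as new.
#' @param vent_exclusion_days days up to and including `d` that must be
#'   ventilation-free.
#' @return a list of class `nvhap_rules`.
#' @export
detection_rules <- function(spo2_drop = 3,
                            fever_temp = 38.0,
                            leukocytosis_wbc = 12.0,
                            fever_window = c(-1L, 1L),
                            imaging_window = c(-1L, 2L),
                            abx_start_window = c(-1L, 1L),
                            abx_min_days = 3L,
                            abx_lookback = 2L,
                            vent_exclusion_days = 2L) {
  rules <- list(spo2_drop = spo2_drop, fever_temp = fever_temp,
                leukocytosis_wbc = leukocytosis_wbc,
                fever_window = as.integer(fever_window),
                imaging_window = as.integer(imaging_window),
                abx_start_window = as.integer(abx_start_window),
                abx_min_days = as.integer(abx_min_days),
                abx_lookback = as.integer(abx_lookback),
                vent_exclusion_days = as.integer(vent_exclusion_days))
  class(rules) <- "nvhap_rules"
  rules
}

#' Label each in-stay day's oxygenation trajectory
#'
#' Day `d >= 2` is `worsening` when the supplemental-oxygen device rank
#' increased from the previous day, or the rank is unchanged and the daily
#' minimum SpO2 fell by at least `spo2_drop` points (both values present).
#' Day 1 is `undefined`.  Missing values never create worsening: a day
#' whose SpO2 is missing at unchanged rank is `stable_or_improving`.
#'
#' @param days one hospitalization's patient-day rows (columns `day`,
#'   `spo2_min`, `o2_device_rank`), any row order; duplicate day indices
#'   are an error.
#' @param rules a [detection_rules()] object.
#' @return character vector of labels, one per day in day order:
#'   `"undefined"`, `"worsening"` or `"stable_or_improving"`.
#' @export
daily_oxygenation_status <- function(days, rules = detection_rules()) {
  days <- as.data.table(days)
  if (anyDuplicated(days$day))
    stop("duplicate day index for hospitalization")
  setorder(days, day)
  n <- nrow(days)
  rank <- days$o2_device_rank
  spo2 <- days$spo2_min
  lab <- rep("stable_or_improving", n)
  if (n >= 2L) {
    i <- 2:n
    esc <- rank[i] > rank[i - 1L]
    drop <- rank[i] == rank[i - 1L] &
      !is.na(spo2[i]) & !is.na(spo2[i - 1L]) &
      spo2[i] <= spo2[i - 1L] - rules$spo2_drop
    lab[i][esc | drop] <- "worsening"
  }
  lab[1L] <- "undefined"
  lab
}

#' Find candidate NV-HAP onset days from oxygenation labels
#'
#' Day `d` is a candidate onset when `d >= 3`, days `d` and `d + 1` are
#' worsening, and days `d - 1` and `d - 2` are stable or improving (day
#' 1's `undefined` label counts as stable for the baseline requirement).
#'
#' @param labels labels from [daily_oxygenation_status()].
#' @return integer vector of candidate onset days (possibly empty).
#' @export
find_candidate_onsets <- function(labels) {
  n <- length(labels)
  if (n < 4L) return(integer())
  ok_base <- labels %in% c("stable_or_improving", "undefined")
  wors <- labels == "worsening"
  d <- 3:(n - 1L)
  d[wors[d] & wors[d + 1L] & ok_base[d - 1L] & ok_base[d - 2L]]
}

#' Adjudicate one candidate onset against the full criterion set
#'
#' Emits an event call only when all of the following hold, windows
#' clipped to the stay: fever or leukocytosis within the concurrency
#' window; chest imaging within the imaging window; some antibiotic class
#' absent during the lookback days, first administered within the start
#' window and given on the required number of consecutive days (discharge
#' truncation disqualifies); and no ventilation on the onset day or the
#' exclusion days before it.
#'
#' @param candidate_day candidate onset day `d`.
#' @param days this hospitalization's patient-day rows, day-sorted.
#' @param abx this hospitalization's antibiotic-day rows (columns `day`,
#'   `drug_class`).
#' @param rules a [detection_rules()] object.
#' @return a one-row `data.table` event call, or `NULL` when any
#'   criterion fails.
#' @export
adjudicate_event <- function(candidate_day, days, abx,
                             rules = detection_rules()) {
  d <- as.integer(candidate_day)
  days <- as.data.table(days)
  setorder(days, day)
  los <- max(days$day)
  win <- function(w) max(1L, d + w[1L]):min(los, d + w[2L])

  fw <- win(rules$fever_window)
  fsub <- days[day %in% fw]
  fever <- any(!is.na(fsub$temp_max) & fsub$temp_max >= rules$fever_temp)
  leuko <- any(!is.na(fsub$wbc_max) &
                 fsub$wbc_max >= rules$leukocytosis_wbc)

  isub <- days[day %in% win(rules$imaging_window)]
  imaging <- any(isub$chest_imaging %in% TRUE)

  vw <- max(1L, d - rules$vent_exclusion_days):d
  vsub <- days[day %in% vw]
  nonvent <- !any(vsub$ventilated %in% TRUE)

  qualifying <- NA_character_
  if (!is.null(abx) && nrow(abx) > 0L) {
    lookback <- max(1L, d - rules$abx_lookback):(d - 1L)
    start_win <- win(rules$abx_start_window)
    for (cls in unique(abx$drug_class)) {
      cdays <- sort(unique(abx[drug_class == cls]$day))
      if (any(cdays %in% lookback)) next
      starts <- intersect(cdays, start_win)
      for (s in starts) {
        need <- s:(s + rules$abx_min_days - 1L)
        if (max(need) <= los && all(need %in% cdays)) {
          qualifying <- cls
          break
        }
      }
      if (!is.na(qualifying)) break
    }
  }
  new_abx <- !is.na(qualifying)

  if ((fever || leuko) && imaging && new_abx && nonvent) {
    data.table(hospitalization_id = days$hospitalization_id[1L],
               event_day = d,
               fever_met = fever, leukocytosis_met = leuko,
               imaging_met = imaging, new_abx_met = new_abx,
               nonventilated_met = nonvent,
               qualifying_abx_class = qualifying)
  } else NULL
}

#' Detect NV-HAP events across a cohort
#'
#' Applies the full electronic definition to every hospitalization,
#' evaluating candidate onsets in ascending day order and keeping only the
#' first adjudicated event per hospitalization.
#'
#' @param patient_days patient-day table (or an `nvhap_cohort`, in which
#'   case `antibiotic_days` is taken from it too).
#' @param antibiotic_days antibiotic-day table.
#' @param rules a [detection_rules()] object.
#' @return `data.table` of event calls, at most one row per
#'   hospitalization, with the rule settings attached as attribute
#'   `"rules"`.
#' @export
detect_nvhap <- function(patient_days, antibiotic_days = NULL,
                         rules = detection_rules()) {
  if (inherits(patient_days, "nvhap_cohort")) {
    antibiotic_days <- patient_days$antibiotic_days
    patient_days <- patient_days$patient_days
  }
  pd <- as.data.table(patient_days)
  abx <- if (is.null(antibiotic_days))
    data.table(hospitalization_id = integer(), day = integer(),
               drug_class = character())
  else as.data.table(antibiotic_days)
  if (nrow(abx) > 0L) {
    orphan <- setdiff(abx$hospitalization_id, pd$hospitalization_id)
    if (length(orphan))
      stop("antibiotic_days reference unknown hospitalizations: ",
           paste(head(orphan, 5L), collapse = ", "))
  }
  setorder(pd, hospitalization_id, day)
  if (anyDuplicated(pd, by = c("hospitalization_id", "day")))
    stop("duplicate (hospitalization_id, day) rows in patient_days")

  # vectorized oxygenation labelling across the whole table
  pd[, `:=`(prev_rank = shift(o2_device_rank),
            prev_spo2 = shift(spo2_min)),
     by = hospitalization_id]
  pd[, worsening := (o2_device_rank > prev_rank) |
        (o2_device_rank == prev_rank & !is.na(spo2_min) &
           !is.na(prev_spo2) & spo2_min <= prev_spo2 - rules$spo2_drop)]
  pd[is.na(worsening), worsening := FALSE]
  pd[, day_idx := seq_len(.N), by = hospitalization_id]
  pd[day_idx == 1L, worsening := FALSE]
  # candidate: d >= 3, worsening at d and d+1, baseline at d-1 and d-2
  pd[, `:=`(w_next = shift(worsening, type = "lead"),
            w_m1 = shift(worsening, n = 1L),
            w_m2 = shift(worsening, n = 2L)),
     by = hospitalization_id]
  cands <- pd[day_idx >= 3L & worsening %in% TRUE & w_next %in% TRUE &
                !(w_m1 %in% TRUE) & !(w_m2 %in% TRUE),
              .(hospitalization_id, day)]
  pd[, c("prev_rank", "prev_spo2", "worsening", "day_idx", "w_next",
         "w_m1", "w_m2") := NULL]
  if (nrow(cands) == 0L) {
    out <- data.table(hospitalization_id = integer(), event_day = integer(),
                      fever_met = logical(), leukocytosis_met = logical(),
                      imaging_met = logical(), new_abx_met = logical(),
                      nonventilated_met = logical(),
                      qualifying_abx_class = character())
    setattr(out, "rules", rules)
    return(out)
  }
  setorder(cands, hospitalization_id, day)
  setkey(pd, hospitalization_id)
  setkey(abx, hospitalization_id)
  calls <- vector("list", length(unique(cands$hospitalization_id)))
  k <- 0L
  for (hid in unique(cands$hospitalization_id)) {
    drec <- pd[.(hid)]
    arec <- if (nrow(abx)) abx[.(hid), nomatch = 0L] else abx
    for (d in cands[hospitalization_id == hid]$day) {
      call <- adjudicate_event(d, drec, arec, rules)
      if (!is.null(call)) {
        k <- k + 1L
        calls[[k]] <- call
        break   # only the first event per hospitalization is counted
      }
    }
  }
  out <- if (k > 0L) rbindlist(calls[seq_len(k)]) else
    data.table(hospitalization_id = integer(), event_day = integer(),
               fever_met = logical(), leukocytosis_met = logical(),
               imaging_met = logical(), new_abx_met = logical(),
               nonventilated_met = logical(),
               qualifying_abx_class = character())
  setattr(out, "rules", rules)
  out[]
}

#' Per-hospitalization event indicator from detector output
#'
#' @param hospitalizations hospitalization table (needs
#'   `hospitalization_id`).
#' @param events detector output from [detect_nvhap()].
#' @return integer 0/1 vector aligned with `hospitalizations` rows.
#' @export
event_indicator <- function(hospitalizations, events) {
  as.integer(hospitalizations$hospitalization_id %in%
               events$hospitalization_id)
}
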