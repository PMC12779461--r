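# Diagnostic-coding NV-HAP definition: a primary or secondary discharge
# diagnosis code for pneumonia that was not present on admission.

# exact qualifying codes (normalized, undotted)
NVHAP_EXACT_CODES <- c("B953", "B960", "J13", "J84111", "J84116",
                       "J84117", "J842", "J851", "J852")
# code families: the 3-character root and any extension qualify
NVHAP_FAMILY_PREFIXES <- c("J15", "J16", "J17", "J18")

#' Normalize an ICD-10 code
#'
#' Uppercases and strips periods and whitespace, so the dotted and
#' undotted dialects compare equal (`"J15.9"` and `"j159 "` both become
#' `"J159"`).  Idempotent.
#'
#' @param raw character vector of raw codes.
#' @return canonical codes.
#' @export
normalize_code <- function(raw) {
  out <- toupper(gsub("[.[:space:]]", "", as.character(raw)))
  if (any(!nzchar(out) | is.na(out)))
    stop("ICD-10 code empty after normalization")
  out
}

#' Does a canonical code qualify as an NV-HAP pneumonia code?
#'
#' True for the exact codes B95.3, B96.0, J13, J84.111, J84.116, J84.117,
#' J84.2, J85.1, J85.2 and for any member of the J15, J16, J17 or J18
#' families (the 3-character root with or without further characters).
#'
#' @param code canonical code(s) from [normalize_code()].
#' @return logical vector.
#' @export
matches_nvhap_code <- function(code) {
  exact <- code %in% NVHAP_EXACT_CODES
  fam <- substr(code, 1L, 3L) %in% NVHAP_FAMILY_PREFIXES
  exact | fam
}

#' Classify one hospitalization's diagnosis records
#'
#' `TRUE` iff some primary or secondary record carries a qualifying
#' pneumonia code with an explicit present-on-admission flag of `"N"`.
#' POA values `Y`, `U`, `W` or missing never qualify: hospital onset must
#' be affirmatively documented.
#'
#' @param records `data.table`/data.frame of this hospitalization's
#'   diagnosis rows (columns `icd10_code`, `poa`; `position` is accepted
#'   but both positions qualify).
#' @return logical scalar.
#' @export
classify_hospitalization <- function(records) {
  records <- as.data.table(records)
  if (nrow(records) == 0L) return(FALSE)
  ok <- matches_nvhap_code(normalize_code(records$icd10_code))
  any(ok & records$poa %in% "N")
}

#' Coding-definition NV-HAP calls for a whole cohort
#'
#' @param diagnoses diagnosis table (or an `nvhap_cohort`).
#' @return `data.table` with `hospitalization_id` and logical
#'   `nvhap_coding` for every hospitalization appearing in the table.
#' @export
classify_coding <- function(diagnoses) {
  if (inherits(diagnoses, "nvhap_cohort")) diagnoses <- diagnoses$diagnoses
  dx <- as.data.table(diagnoses)
  if (nrow(dx) == 0L)
    return(data.table(hospitalization_id = integer(),
                      nvhap_coding = logical()))
  dx[, .(nvhap_coding = any(matches_nvhap_code(normalize_code(icd10_code)) &
                              poa %in% "N")),
     by = hospitalization_id]
}

#' Per-hospitalization coding indicator
#'
#' @param hospitalizations hospitalization table.
#' @param coding_calls output of [classify_coding()].
#' @return integer 0/1 vector aligned with `hospitalizations` rows.
#' @export
coding_indicator <- function(hospitalizations, coding_calls) {
  pos <- coding_calls[nvhap_coding == TRUE]$hospitalization_id
  as.integer(hospitalizations$hospitalization_id %in% pos)
}
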