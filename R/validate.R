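# Dataset-level invariant checking. Violations are returned as data, never
# thrown: downstream engines decide what to do with an inconsistent extract.

issue_row <- function(severity, table, row, message) {
  data.frame(severity = severity, table = table, row = as.integer(row),
             message = message, stringsAsFactors = FALSE)
}

empty_issue_list <- function() {
  data.frame(severity = character(0), table = character(0),
             row = integer(0), message = character(0), stringsAsFactors = FALSE)
}

#' Validate a CDM dataset
#'
#' Checks every model invariant — identifier uniqueness, referential
#' integrity of `patient_id` across tables, ICD-10 / ATC code formats,
#' chronology of date pairs, finiteness of laboratory values, adult age at
#' diagnosis, non-empty report text, one registry record per
#' (patient, tumor group, year) — and returns all violations as an issue
#' list. An empty issue list means the dataset is internally consistent.
#' The dataset is never mutated.
#'
#' @param ds a [cdm_dataset()].
#' @return a data.frame with columns `severity` ("error" or "warning"),
#'   `table`, `row`, `message`.
#' @export
validate_dataset <- function(ds) {
  issues <- list()
  add <- function(...) issues[[length(issues) + 1]] <<- issue_row(...)
  pats <- ds$patients

  dup <- which(duplicated(pats$patient_id))
  for (i in dup) add("error", "patients", i, sprintf(
    "duplicate patient_id '%s'", pats$patient_id[i]))

  known <- pats$patient_id
  for (tab in setdiff(cdm_table_names(), "patients")) {
    bad <- which(!(ds[[tab]]$patient_id %in% known))
    for (i in bad) add("error", tab, i, sprintf(
      "patient_id '%s' does not resolve to a patient", ds[[tab]]$patient_id[i]))
  }

  trj <- ds$trajectories
  for (i in which(is.na(trj$start_date)))
    add("error", "trajectories", i, "start_date is missing")
  for (i in which(!is.na(trj$tumor_group) & !(trj$tumor_group %in% tumor_groups())))
    add("error", "trajectories", i, sprintf(
      "unknown tumor_group '%s'", trj$tumor_group[i]))

  dx <- ds$diagnoses
  for (i in which(!is.na(dx$icd10_code) & !is_valid_icd10(dx$icd10_code)))
    add("error", "diagnoses", i, sprintf(
      "icd10_code '%s' is not a valid ICD-10 code", dx$icd10_code[i]))
  for (i in which(is.na(dx$date))) add("error", "diagnoses", i, "date is missing")
  for (i in which(!is.na(dx$status) & !(dx$status %in% c("preliminary", "confirmed"))))
    add("error", "diagnoses", i, sprintf("unknown status '%s'", dx$status[i]))

  # adult registry scope: age >= 18 at every diagnosis date
  if (nrow(dx) > 0 && nrow(pats) > 0) {
    by <- pats$birth_year[match(dx$patient_id, pats$patient_id)]
    dx_year <- as.integer(format(dx$date, "%Y"))
    for (i in which(!is.na(by) & !is.na(dx_year) & dx_year - by < 18))
      add("error", "diagnoses", i, sprintf(
        "patient '%s' younger than 18 at diagnosis", dx$patient_id[i]))
  }

  rx <- ds$prescriptions
  for (i in which(!is.na(rx$atc_code) & !is_valid_atc(rx$atc_code)))
    add("error", "prescriptions", i, sprintf(
      "atc_code '%s' is not a valid ATC code", rx$atc_code[i]))
  for (i in which(!is.na(rx$end_date) & rx$end_date < rx$start_date))
    add("error", "prescriptions", i, "end_date precedes start_date")
  for (i in which(!is.na(rx$dose_mg_per_day) & rx$dose_mg_per_day < 0))
    add("error", "prescriptions", i, "negative dose_mg_per_day")

  labs <- ds$labs
  for (i in which(!is.finite(labs$value)))
    add("error", "labs", i, "lab value is not finite")
  for (i in which(is.na(labs$loinc_code) | labs$loinc_code == ""))
    add("error", "labs", i, "loinc_code is empty")

  adm <- ds$admissions
  for (i in which(!is.na(adm$discharge_date) & adm$discharge_date < adm$admit_date))
    add("error", "admissions", i, "discharge_date precedes admit_date")
  if (nrow(adm) > 0) {
    all_codes <- split_codes(adm$secondary_icd10)
    for (i in seq_len(nrow(adm))) {
      codes <- c(adm$main_icd10[i], all_codes[[i]])
      codes <- codes[!is.na(codes) & codes != ""]
      bad <- codes[!is_valid_icd10(codes)]
      if (length(bad) > 0) add("error", "admissions", i, sprintf(
        "invalid ICD-10 admission code '%s'", bad[1]))
    }
  }

  rep <- ds$reports
  for (i in which(is.na(rep$text) | rep$text == ""))
    add("error", "reports", i, "report text is empty")

  sct <- ds$sct
  for (i in which(is.na(sct$date))) add("error", "sct", i, "date is missing")
  for (i in which(!is.na(sct$kind) & !(sct$kind %in% c("auto", "allo"))))
    add("error", "sct", i, sprintf("unknown transplant kind '%s'", sct$kind[i]))

  reg <- ds$registry
  if (nrow(reg) > 0) {
    key <- paste(reg$patient_id, reg$tumor_group, reg$diagnosis_year)
    for (i in which(duplicated(key)))
      add("error", "registry", i, "duplicate (patient_id, tumor_group, diagnosis_year)")
  }

  if (length(issues) == 0) empty_issue_list() else do.call(rbind, issues)
}
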