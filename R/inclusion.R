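# New-diagnosis inclusion decisions (prospective) and registry
# cross-matching (retrospective).
#
# A candidate case surfaces once its first hospital contact (the earliest
# care-trajectory start for that patient and tumor group) is at least 28
# days old — four weeks of maturation so the diagnostic work-up is complete.
# Inclusion requires a new oncological diagnosis plus Dutch residency;
# exclusion reasons are evaluated in a fixed precedence (residency, then
# relapsed/refractory trajectory, then preliminary-only diagnosis) so each
# decision carries exactly one reason.

exclusion_reasons <- function() {
  c("NONE", "NON_RESIDENT", "RELAPSE_TRAJECTORY", "PRELIMINARY_DIAGNOSIS")
}

#' Detect candidate cases for registry inclusion
#'
#' One candidate per (patient, tumor group) whose earliest trajectory start
#' satisfies the 28-day maturation rule at `as_of` (closed boundary: a first
#' contact exactly 28 days old is surfaced).
#'
#' @param ds a [cdm_dataset()].
#' @param as_of evaluation date.
#' @return data.frame with `patient_id`, `tumor_group`, `first_contact_date`,
#'   sorted by (first_contact_date, patient_id).
#' @export
detect_candidates <- function(ds, as_of) {
  as_of <- as.Date(as_of)
  trj <- ds$trajectories
  if (nrow(trj) == 0) {
    return(data.frame(patient_id = character(0), tumor_group = character(0),
                      first_contact_date = as.Date(character(0)),
                      stringsAsFactors = FALSE))
  }
  key <- paste(trj$patient_id, trj$tumor_group, sep = "\r")
  first <- tapply(as.integer(trj$start_date), key, min)
  parts <- strsplit(names(first), "\r", fixed = TRUE)
  out <- data.frame(
    patient_id = vapply(parts, `[`, character(1), 1),
    tumor_group = vapply(parts, `[`, character(1), 2),
    first_contact_date = as.Date(as.integer(first), origin = "1970-01-01"),
    stringsAsFactors = FALSE
  )
  out <- out[out$first_contact_date + 28 <= as_of, , drop = FALSE]
  out <- out[order(out$first_contact_date, out$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify candidate cases against registry inclusion criteria
#'
#' Applies the exclusion reasons in precedence order: `NON_RESIDENT` when
#' the patient is not a Dutch resident; `RELAPSE_TRAJECTORY` when a
#' confirmed diagnosis of the same tumor group predates the trajectory
#' start (the new trajectory is for relapsed or refractory disease, not a
#' new diagnosis); `PRELIMINARY_DIAGNOSIS` when the only triggering
#' diagnosis rows by `as_of` are preliminary; otherwise include.
#'
#' @param candidates data.frame from [detect_candidates()] (or a single row).
#' @param ds a [cdm_dataset()].
#' @param as_of evaluation date; defaults to the latest data in `ds`.
#' @return data.frame with `patient_id`, `tumor_group`, `decision`
#'   ("include"/"exclude") and `reason` (`NONE` iff included).
#' @export
classify_inclusion <- function(candidates, ds, as_of = NULL) {
  if (is.null(as_of)) {
    as_of <- max(c(ds$trajectories$start_date, ds$diagnoses$date)) + 28
  }
  as_of <- as.Date(as_of)
  pats <- ds$patients
  dx <- ds$diagnoses
  n <- nrow(candidates)
  decision <- character(n)
  reason <- character(n)
  for (i in seq_len(n)) {
    pid <- candidates$patient_id[i]
    grp <- candidates$tumor_group[i]
    p <- match(pid, pats$patient_id)
    if (is.na(p)) stopf("reference error: candidate '%s' not in dataset", pid)
    start <- candidates$first_contact_date[i]
    pdx <- dx[dx$patient_id == pid & dx$tumor_group == grp &
                !is.na(dx$date) & dx$date <= as_of, , drop = FALSE]
    if (!isTRUE(pats$resident_nl[p])) {
      reason[i] <- "NON_RESIDENT"
    } else if (any(pdx$status == "confirmed" & pdx$date < start)) {
      reason[i] <- "RELAPSE_TRAJECTORY"
    } else if (nrow(pdx) > 0 && all(pdx$status == "preliminary")) {
      reason[i] <- "PRELIMINARY_DIAGNOSIS"
    } else {
      reason[i] <- "NONE"
    }
    decision[i] <- if (reason[i] == "NONE") "include" else "exclude"
  }
  data.frame(patient_id = candidates$patient_id,
             tumor_group = candidates$tumor_group,
             decision = decision, reason = reason, stringsAsFactors = FALSE)
}

#' Cross-match a registry extract against the CDM
#'
#' For each registry record, looks for care trajectories of the same
#' patient: `matched_same_year` when a trajectory of the same tumor group
#' starts in the registry's diagnosis year; `year_mismatch` when patient and
#' tumor group exist but only in other years; `diagnosis_mismatch` when the
#' patient only has trajectories of a different tumor group. A registry
#' patient wholly absent from the CDM is flagged `absent` — the engines can
#' retrieve every generated patient, but a real extract might not.
#'
#' @param registry the registry table (or a [cdm_dataset()]'s `$registry`).
#' @param ds a [cdm_dataset()].
#' @return data.frame with one row per registry record (`patient_id`,
#'   `tumor_group`, `diagnosis_year`, `category`); the categories partition
#'   the registry records.
#' @export
retrospective_match <- function(registry, ds) {
  trj <- ds$trajectories
  trj_year <- as.integer(format(trj$start_date, "%Y"))
  n <- nrow(registry)
  category <- character(n)
  for (i in seq_len(n)) {
    pid <- registry$patient_id[i]
    sel <- trj$patient_id == pid
    if (!any(sel)) {
      category[i] <- "absent"
      next
    }
    same_group <- sel & trj$tumor_group == registry$tumor_group[i]
    if (any(same_group & trj_year == registry$diagnosis_year[i])) {
      category[i] <- "matched_same_year"
    } else if (any(same_group)) {
      category[i] <- "year_mismatch"
    } else {
      category[i] <- "diagnosis_mismatch"
    }
  }
  data.frame(patient_id = registry$patient_id,
             tumor_group = registry$tumor_group,
             diagnosis_year = registry$diagnosis_year,
             category = category, stringsAsFactors = FALSE)
}
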