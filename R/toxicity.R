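# CTCAE treatment-toxicity signaling across four evidence channels.
#
# Toxicity is attributed to treatment only inside the attribution window:
# from the first day of treatment to 30 days after the last day, truncated
# to the day before a stem-cell transplantation. Four channels can raise a
# signal: laboratory indicators (absolute thresholds at CTCAE grade
# boundaries, or excursions relative to a pre-treatment baseline),
# indicator drug orders (trigger sets of ATC codes started within 3 days of
# each other), case-insensitive whole-word keywords in imaging reports
# (deliberately negation-blind), and ICD-10-coded admission diagnoses
# (main or secondary) overlapping the window. ICU admission is its own
# category, fired by the admission ICU flag.

toxicity_categories <- function() {
  c("acute_renal_failure", "hemorrhage", "hepatic_toxicity", "icu_admission",
    "invasive_aspergillosis", "invasive_candidiasis", "pulmonary_toxicity",
    "sepsis", "typhlitis", "venous_thrombosis")
}

#' Load toxicity indicator rules
#'
#' Reads a YAML rules file with one block per CTCAE category (see the
#' shipped `ctcae_rules.yaml` for the format). Each category must define at
#' least one channel: `labs`, `drugs`, `keywords`, `admission_codes` or
#' `icu_flag`.
#'
#' @param path YAML rules file; default is the shipped reconstruction.
#' @return named list of rules plus the attribute `baseline_lookback_days`.
#' @export
load_toxicity_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ctcae_rules.yaml", package = "oncocdm",
                        mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  lookback <- raw$baseline_lookback_days %||% 90
  raw$baseline_lookback_days <- NULL
  for (cat in names(raw)) {
    rule <- raw[[cat]]
    has_channel <- length(rule$labs %||% list()) > 0 ||
      length(rule$drugs %||% list()) > 0 ||
      length(rule$keywords %||% character(0)) > 0 ||
      length(rule$admission_codes %||% character(0)) > 0 ||
      isTRUE(rule$icu_flag)
    if (!has_channel) stopf("toxicity rule '%s' defines no channel", cat)
  }
  structure(raw, baseline_lookback_days = lookback)
}

#' @rdname load_toxicity_rules
#' @export
default_toxicity_rules <- function() load_toxicity_rules()

#' Attribution window for one patient's treatment course
#'
#' @param assignments regimen assignments for one patient (data.frame from
#'   [derive_sequence()]); transplant rows (category `HSCT`) are treatment
#'   events but do not extend the drug-treatment window.
#' @param sct_date date of the first stem-cell transplantation, or `NULL`.
#' @return list with `start` and `end` dates; `end` may precede `start`
#'   (empty window) when the transplant precedes the treatment end.
#' @export
attribution_window <- function(assignments, sct_date = NULL) {
  drug <- assignments[assignments$category != "HSCT", , drop = FALSE]
  if (nrow(drug) == 0) {
    stopf("contract violation: no drug-treatment assignments for window")
  }
  start <- min(drug$start_date)
  end <- max(drug$end_date) + 30
  if (!is.null(sct_date) && length(sct_date) > 0 && !all(is.na(sct_date))) {
    end <- min(end, min(sct_date, na.rm = TRUE) - 1)
  }
  list(start = start, end = end)
}

in_window <- function(d, window) {
  !is.na(d) & d >= window$start & d <= window$end
}

signal_row <- function(patient_id, category, date, channel, evidence) {
  data.frame(patient_id = patient_id, category = category,
             date = as.Date(date), channel = channel,
             evidence = evidence, stringsAsFactors = FALSE)
}

empty_signal_table <- function() {
  data.frame(patient_id = character(0), category = character(0),
             date = as.Date(character(0)), channel = character(0),
             evidence = character(0), stringsAsFactors = FALSE)
}

#' Evaluate a laboratory indicator rule within a window
#'
#' Emits one signal at the first in-window timestamp where the rule fires.
#' Rules with `relative_to_baseline: true` compare against the most recent
#' pre-window value of the same analyte within the baseline lookback; with
#' no baseline available the rule is skipped. A lab row whose unit differs
#' from the rule's unit is an evaluation error naming the row.
#'
#' @param labs lab rows of one patient.
#' @param rule one category's rule (list with `labs`).
#' @param window attribution window from [attribution_window()].
#' @param category category label for the emitted signal.
#' @param baseline_lookback_days how far before the window a baseline may lie.
#' @return signal data.frame (zero or one row per lab sub-rule).
#' @export
eval_lab_indicator <- function(labs, rule, window, category = "lab_rule",
                               baseline_lookback_days = 90) {
  out <- list()
  for (lr in rule$labs %||% list()) {
    rows <- which(labs$loinc_code == lr$loinc)
    if (length(rows) == 0) next
    mismatch <- rows[labs$unit[rows] != lr$unit]
    if (length(mismatch) > 0) {
      stopf("evaluation error: lab row %d (%s) has unit '%s', rule expects '%s'",
            mismatch[1], labs$loinc_code[mismatch[1]],
            labs$unit[mismatch[1]], lr$unit)
    }
    d <- as.Date(labs$datetime[rows])
    threshold <- lr$threshold
    if (isTRUE(lr$relative_to_baseline)) {
      pre <- rows[d < window$start & d >= window$start - baseline_lookback_days]
      if (length(pre) == 0) next  # no baseline -> rule skipped
      baseline <- labs$value[pre[which.max(labs$datetime[pre])]]
      threshold <- lr$threshold * baseline
    }
    inside <- rows[in_window(d, window)]
    fired <- switch(lr$comparator,
      ">" = inside[labs$value[inside] > threshold],
      "<" = inside[labs$value[inside] < threshold],
      ">=" = inside[labs$value[inside] >= threshold],
      "<=" = inside[labs$value[inside] <= threshold],
      stopf("unknown comparator '%s'", lr$comparator))
    if (length(fired) > 0) {
      first <- fired[which.min(labs$datetime[fired])]
      out[[length(out) + 1]] <- signal_row(
        labs$patient_id[first], category, as.Date(labs$datetime[first]),
        "lab", sprintf("loinc %s value %s", lr$loinc, labs$value[first]))
    }
  }
  if (length(out) == 0) empty_signal_table() else do.call(rbind, out)
}

#' Evaluate an indicator-drug rule within a window
#'
#' A trigger set fires at the first in-window start where every member ATC
#' code of the set has a prescription starting within 3 days of the others.
#' Trigger codes match by ATC prefix, so class-level codes cover all their
#' substances.
#'
#' @inheritParams eval_lab_indicator
#' @param prescriptions prescription rows of one patient.
#' @export
eval_drug_indicator <- function(prescriptions, rule, window,
                                category = "drug_rule") {
  out <- list()
  rx <- prescriptions
  for (set in rule$drugs %||% list()) {
    set <- unlist(set)
    starts_per_code <- lapply(set, function(code) {
      sel <- startsWith(rx$atc_code, code)
      sort(rx$start_date[sel])
    })
    if (any(vapply(starts_per_code, length, integer(1)) == 0)) next
    # candidate anchors: starts of the first member inside the window
    anchors <- starts_per_code[[1]]
    fired_date <- NULL
    for (a in sort(anchors)) {
      a <- as.Date(a, origin = "1970-01-01")
      complete <- all(vapply(starts_per_code, function(s) {
        any(abs(as.integer(s - a)) <= 3)
      }, logical(1)))
      if (!complete) next
      member_starts <- lapply(starts_per_code, function(s) {
        s[abs(as.integer(s - a)) <= 3]
      })
      d <- min(as.Date(unlist(lapply(member_starts, min)),
                       origin = "1970-01-01"))
      if (in_window(d, window)) {
        fired_date <- d
        break
      }
    }
    if (!is.null(fired_date)) {
      out[[length(out) + 1]] <- signal_row(
        rx$patient_id[1], category, fired_date, "drug",
        sprintf("atc %s", paste(set, collapse = "+")))
    }
  }
  if (length(out) == 0) empty_signal_table() else do.call(rbind, out)
}

#' Scan imaging reports for toxicity keywords
#'
#' Case-insensitive whole-word match of any rule keyword in report text
#' with an in-window timestamp. No negation handling: "no evidence of
#' aspergillosis" still signals — the channel is deliberately naive.
#'
#' @inheritParams eval_lab_indicator
#' @param reports imaging-report rows of one patient.
#' @export
scan_reports <- function(reports, rule, window, category = "keyword_rule") {
  kws <- rule$keywords %||% character(0)
  if (length(kws) == 0 || nrow(reports) == 0) return(empty_signal_table())
  d <- as.Date(reports$datetime)
  inside <- which(in_window(d, window))
  out <- list()
  hit_rows <- integer(0)
  for (kw in kws) {
    pattern <- paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", kw), "\\b")
    hits <- inside[grepl(pattern, reports$text[inside], ignore.case = TRUE, perl = TRUE)]
    hit_rows <- union(hit_rows, hits)
  }
  if (length(hit_rows) > 0) {
    first <- hit_rows[which.min(reports$datetime[hit_rows])]
    out[[1]] <- signal_row(reports$patient_id[first], category,
                           as.Date(reports$datetime[first]), "keyword",
                           sprintf("report row %d", first))
  }
  if (length(out) == 0) empty_signal_table() else do.call(rbind, out)
}

#' Map admission diagnoses to toxicity signals
#'
#' Signals when an admission overlapping the window carries a listed ICD-10
#' code as main or secondary diagnosis (prefix match). For the ICU category
#' (`icu_flag` rules) any in-window ICU admission fires. Signal date is the
#' later of admission date and window start.
#'
#' @inheritParams eval_lab_indicator
#' @param admissions admission rows of one patient.
#' @export
map_admissions <- function(admissions, rule, window,
                           category = "admission_rule") {
  adm <- admissions
  if (nrow(adm) == 0) return(empty_signal_table())
  adm_end <- as.Date(ifelse(is.na(adm$discharge_date),
                            as.integer(adm$admit_date),
                            as.integer(adm$discharge_date)),
                     origin = "1970-01-01")
  overlaps <- adm$admit_date <= window$end & adm_end >= window$start
  codes <- rule$admission_codes %||% character(0)
  hits <- logical(nrow(adm))
  if (length(codes) > 0) {
    sec <- split_codes(adm$secondary_icd10)
    for (i in which(overlaps)) {
      all_codes <- c(adm$main_icd10[i], sec[[i]])
      all_codes <- all_codes[!is.na(all_codes) & all_codes != ""]
      hits[i] <- any(vapply(codes, function(code) {
        any(startsWith(all_codes, code))
      }, logical(1)))
    }
  }
  if (isTRUE(rule$icu_flag)) {
    hits <- hits | (overlaps & adm$icu %in% TRUE)
  }
  idx <- which(hits)
  if (length(idx) == 0) return(empty_signal_table())
  first <- idx[which.min(adm$admit_date[idx])]
  signal_row(adm$patient_id[first], category,
             max(adm$admit_date[first], window$start), "admission",
             sprintf("admission row %d", first))
}

#' Combine signals into per-patient findings
#'
#' Groups signals by (patient, category), keeps the earliest date and the
#' union of evidence channels. Idempotent and invariant to signal order.
#'
#' @param signals signal data.frame (any number of patients/categories).
#' @return data.frame with `patient_id`, `category`, `first_date`,
#'   `channels` (semicolon-joined, sorted).
#' @export
combine_findings <- function(signals) {
  if (nrow(signals) == 0) {
    return(data.frame(patient_id = character(0), category = character(0),
                      first_date = as.Date(character(0)),
                      channels = character(0), stringsAsFactors = FALSE))
  }
  key <- paste(signals$patient_id, signals$category, sep = "\r")
  out <- lapply(sort(unique(key)), function(k) {
    g <- signals[key == k, , drop = FALSE]
    data.frame(patient_id = g$patient_id[1], category = g$category[1],
               first_date = min(g$date),
               channels = paste(sort(unique(g$channel)), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$patient_id, res$category), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Run the full toxicity engine over a dataset
#'
#' Derives per-patient attribution windows from the regimen sequence
#' (overlapping courses merge into one window per patient), evaluates every
#' rule channel inside the window, and combines signals into findings.
#' Patients with no drug treatment have no window and can never signal.
#'
#' @param ds a [cdm_dataset()].
#' @param rules from [load_toxicity_rules()].
#' @param catalog,drug_map passed to [derive_sequence()].
#' @return list with `signals`, `findings` and `windows` (per patient).
#' @export
detect_toxicity <- function(ds, rules = default_toxicity_rules(),
                            catalog = mm_regimen_catalog(),
                            drug_map = default_drug_map()) {
  assignments <- derive_sequence(ds, catalog, drug_map)
  lookback <- attr(rules, "baseline_lookback_days") %||% 90
  signals <- list()
  windows <- list()
  treated <- unique(assignments$patient_id[assignments$category != "HSCT"])
  for (pid in treated) {
    a <- assignments[assignments$patient_id == pid, , drop = FALSE]
    sct_dates <- ds$sct$date[ds$sct$patient_id == pid]
    win <- attribution_window(a, if (length(sct_dates) > 0) min(sct_dates) else NULL)
    windows[[pid]] <- win
    if (win$end < win$start) next  # transplant preceded treatment end
    labs <- ds$labs[ds$labs$patient_id == pid, , drop = FALSE]
    rx <- ds$prescriptions[ds$prescriptions$patient_id == pid, , drop = FALSE]
    rep <- ds$reports[ds$reports$patient_id == pid, , drop = FALSE]
    adm <- ds$admissions[ds$admissions$patient_id == pid, , drop = FALSE]
    for (cat in names(rules)) {
      rule <- rules[[cat]]
      signals[[length(signals) + 1]] <-
        eval_lab_indicator(labs, rule, win, cat, lookback)
      signals[[length(signals) + 1]] <- eval_drug_indicator(rx, rule, win, cat)
      signals[[length(signals) + 1]] <- scan_reports(rep, rule, win, cat)
      signals[[length(signals) + 1]] <- map_admissions(adm, rule, win, cat)
    }
  }
  signals <- if (length(signals) > 0) do.call(rbind, signals) else empty_signal_table()
  signals <- signals[order(signals$patient_id, signals$category, signals$date,
                           signals$channel), , drop = FALSE]
  rownames(signals) <- NULL
  list(signals = signals, findings = combine_findings(signals),
       windows = windows)
}
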