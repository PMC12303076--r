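# Treatment-regimen inference from ATC-coded prescription streams.
#
# The engine works in three steps: (1) normalize prescriptions to drug
# classes and group them into episodes — drugs co-started within the same
# week (a 7-day half-open window anchored at the earliest unassigned
# prescription, not a calendar week); (2) match each episode's class set
# against the regimen catalog by largest-subset search, with a dose-based
# disambiguation between lenalidomide maintenance and Rd; (3) order
# assignments per patient, merge re-prescriptions of the same regimen
# across gaps of at most 60 days, and interleave event-based transplant
# assignments.

#' Build drug episodes from prescriptions
#'
#' Greedy anchor algorithm: the earliest unassigned oncology-class
#' prescription anchors a new episode; every prescription of the same
#' patient starting within `[anchor, anchor + window_days)` joins it.
#' Prescriptions whose ATC code is outside the drug-class mapping are
#' ignored. Row order of the input never affects the result.
#'
#' @param prescriptions the CDM prescriptions table (one or many patients).
#' @param drug_map mapping from [load_drug_map()].
#' @param window_days width of the same-week window (default 7).
#' @return list of episodes; each episode is a list with `patient_id`,
#'   `anchor`, `start`, `end`, `classes` (character vector) and `max_dose`
#'   (named numeric, maximum daily dose seen per class).
#' @export
build_episodes <- function(prescriptions, drug_map = default_drug_map(),
                           window_days = 7) {
  rx <- prescriptions
  if (nrow(rx) == 0) return(list())
  rx$drug_class <- normalize_drug(rx$atc_code, drug_map)
  rx <- rx[!is.na(rx$drug_class) & !is.na(rx$start_date), , drop = FALSE]
  if (nrow(rx) == 0) return(list())
  # canonical order makes the algorithm permutation-invariant
  rx <- rx[order(rx$patient_id, rx$start_date, rx$atc_code, rx$drug_name), ,
           drop = FALSE]
  episodes <- list()
  for (pid in unique(rx$patient_id)) {
    p <- rx[rx$patient_id == pid, , drop = FALSE]
    assigned <- rep(FALSE, nrow(p))
    while (!all(assigned)) {
      anchor_idx <- which(!assigned)[1]
      anchor <- p$start_date[anchor_idx]
      member <- !assigned & p$start_date >= anchor &
        p$start_date < anchor + window_days
      rows <- p[member, , drop = FALSE]
      assigned[member] <- TRUE
      ends <- ifelse(is.na(rows$end_date), as.integer(rows$start_date),
                     as.integer(rows$end_date))
      max_dose <- tapply(ifelse(is.na(rows$dose_mg_per_day), 0,
                                rows$dose_mg_per_day),
                         rows$drug_class, max)
      episodes[[length(episodes) + 1]] <- list(
        patient_id = pid,
        anchor = anchor,
        start = min(rows$start_date),
        end = as.Date(max(ends), origin = "1970-01-01"),
        classes = sort(unique(rows$drug_class)),
        max_dose = max_dose
      )
    }
  }
  episodes
}

#' Match one episode against the regimen catalog
#'
#' Assigns the catalog entry whose drug-class set is the largest subset of
#' the episode's class set; ties are broken by larger set size, then by
#' catalog order. Episodes whose only anti-myeloma class is lenalidomide
#' are disambiguated by dose: lenalidomide maintenance if the daily dose is
#' at most `maintenance_max_dose` mg and no corticosteroid co-occurs,
#' otherwise Rd (which is how a 15 mg maintenance prescription ends up
#' labelled Rd). `UNMATCHED` when no catalog entry is a subset.
#'
#' @param episode one episode from [build_episodes()].
#' @param catalog regimen catalog from [load_regimen_catalog()].
#' @param maintenance_max_dose maintenance dose ceiling in mg/day (default 10).
#' @return list with `patient_id`, `regimen`, `category`, `start_date`,
#'   `end_date`.
#' @export
match_regimen <- function(episode, catalog = mm_regimen_catalog(),
                          maintenance_max_dose = 10) {
  if (length(episode$classes) == 0) {
    stopf("contract violation: episode has no drug classes")
  }
  classes <- episode$classes
  res <- list(patient_id = episode$patient_id, regimen = "UNMATCHED",
              category = "Unmatched", start_date = episode$start,
              end_date = episode$end)
  anti_myeloma <- setdiff(classes, "corticosteroid")
  if (identical(anti_myeloma, "lenalidomide") &&
      any(c("Rd", "Lenalidomide maintenance") %in% catalog$name)) {
    len_dose <- unname(episode$max_dose["lenalidomide"])
    maintenance <- !is.na(len_dose) && len_dose <= maintenance_max_dose &&
      !("corticosteroid" %in% classes)
    name <- if (maintenance) "Lenalidomide maintenance" else "Rd"
    hit <- match(name, catalog$name)
    res$regimen <- name
    res$category <- catalog$category[hit]
    return(res)
  }
  drug_entries <- which(catalog$event == "")
  sizes <- vapply(catalog$classes[drug_entries], length, integer(1))
  subset_of <- vapply(catalog$classes[drug_entries], function(cl) {
    length(cl) > 0 && all(cl %in% classes)
  }, logical(1))
  if (!any(subset_of)) return(res)
  candidates <- drug_entries[subset_of]
  best <- candidates[order(-sizes[subset_of], candidates)][1]
  res$regimen <- catalog$name[best]
  res$category <- catalog$category[best]
  res
}

empty_assignment_table <- function() {
  data.frame(patient_id = character(0), regimen = character(0),
             category = character(0),
             start_date = as.Date(character(0)),
             end_date = as.Date(character(0)), stringsAsFactors = FALSE)
}

#' Derive the per-patient regimen sequence
#'
#' Runs episode building and catalog matching over a whole dataset, orders
#' assignments per patient by start date, merges consecutive assignments
#' with the same regimen name separated by at most `merge_gap_days`
#' (re-prescription of the same regimen is one treatment course), and emits
#' event-based transplant assignments (Auto-SCT / Allo-SCT, start = end =
#' transplant date) from the sct table.
#'
#' @param ds a [cdm_dataset()].
#' @param catalog regimen catalog.
#' @param drug_map ATC drug-class mapping.
#' @param window_days same-week window width (default 7).
#' @param merge_gap_days maximum gap merged into one course (default 60).
#' @param maintenance_max_dose see [match_regimen()].
#' @return data.frame with columns `patient_id`, `regimen`, `category`,
#'   `start_date`, `end_date`, ordered by patient and start date.
#' @export
derive_sequence <- function(ds, catalog = mm_regimen_catalog(),
                            drug_map = default_drug_map(), window_days = 7,
                            merge_gap_days = 60, maintenance_max_dose = 10) {
  episodes <- build_episodes(ds$prescriptions, drug_map, window_days)
  rows <- lapply(episodes, function(e) {
    a <- match_regimen(e, catalog, maintenance_max_dose)
    data.frame(patient_id = a$patient_id, regimen = a$regimen,
               category = a$category, start_date = a$start_date,
               end_date = a$end_date, stringsAsFactors = FALSE)
  })
  drug_assign <- if (length(rows) > 0) do.call(rbind, rows) else empty_assignment_table()

  merged <- list()
  for (pid in unique(drug_assign$patient_id)) {
    p <- drug_assign[drug_assign$patient_id == pid, , drop = FALSE]
    p <- p[order(p$start_date, p$regimen), , drop = FALSE]
    keep <- p[1, , drop = FALSE]
    if (nrow(p) > 1) {
      for (i in 2:nrow(p)) {
        last <- nrow(keep)
        gap <- as.integer(p$start_date[i] - keep$end_date[last])
        if (p$regimen[i] == keep$regimen[last] && gap <= merge_gap_days) {
          keep$end_date[last] <- max(keep$end_date[last], p$end_date[i])
        } else {
          keep <- rbind(keep, p[i, , drop = FALSE])
        }
      }
    }
    merged[[length(merged) + 1]] <- keep
  }
  out <- if (length(merged) > 0) do.call(rbind, merged) else empty_assignment_table()

  # transplants are events, not prescriptions
  sct <- ds$sct
  if (nrow(sct) > 0) {
    sct_names <- ifelse(sct$kind == "auto", "Auto-SCT", "Allo-SCT")
    sct_cat <- catalog$category[match(sct_names, catalog$name)]
    sct_rows <- data.frame(patient_id = sct$patient_id, regimen = sct_names,
                           category = ifelse(is.na(sct_cat), "HSCT", sct_cat),
                           start_date = sct$date, end_date = sct$date,
                           stringsAsFactors = FALSE)
    out <- rbind(out, sct_rows)
  }
  out <- out[order(out$patient_id, out$start_date, out$regimen), , drop = FALSE]
  rownames(out) <- NULL
  out
}
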