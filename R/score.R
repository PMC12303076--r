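# Scoring engines against ground truth, with registry accuracy semantics:
# the "accuracy" printed in every table is a positive predictive value —
# correct predictions over all predictions — rounded half-up to a whole
# percent; a stratum with zero predictions prints a blank (NA) accuracy,
# never 0%.

#' Score inclusion decisions against ground truth
#'
#' @param decisions data.frame from [classify_inclusion()].
#' @param truth the generator's inclusion truth (same columns).
#' @return list: `n_candidates`, `accuracy_pct` (decision+reason agreement
#'   with truth), `include_share_pct` (share of candidates meeting the
#'   inclusion criteria), `n_excluded`, and `reasons` — the frequency table
#'   over exclusion reasons with whole-percent shares.
#' @export
score_inclusion <- function(decisions, truth) {
  if (nrow(decisions) == 0) {
    return(list(n_candidates = 0L, accuracy_pct = NA_real_,
                include_share_pct = NA_real_, n_excluded = 0L,
                reasons = data.frame(reason = character(0), n = integer(0),
                                     pct = numeric(0))))
  }
  m <- match(decisions$patient_id, truth$patient_id)
  if (any(is.na(m))) {
    stopf("scoring error: decision for patient '%s' outside truth universe",
          decisions$patient_id[which(is.na(m))[1]])
  }
  agree <- decisions$decision == truth$decision[m] &
    decisions$reason == truth$reason[m]
  excl <- decisions[decisions$decision == "exclude", , drop = FALSE]
  reasons <- c("NON_RESIDENT", "RELAPSE_TRAJECTORY", "PRELIMINARY_DIAGNOSIS")
  n_r <- vapply(reasons, function(r) sum(excl$reason == r), integer(1))
  reason_tab <- data.frame(
    reason = reasons, n = unname(n_r),
    pct = unname(accuracy_pct(n_r, rep(nrow(excl), length(reasons)))),
    stringsAsFactors = FALSE
  )
  list(
    n_candidates = nrow(decisions),
    accuracy_pct = accuracy_pct(sum(agree), nrow(decisions)),
    include_share_pct = accuracy_pct(sum(decisions$decision == "include"),
                                     nrow(decisions)),
    n_excluded = nrow(excl),
    reasons = reason_tab
  )
}

# one-to-one matching of predictions to truth regimens on name and dates
match_assignments <- function(assignments, truth, date_tol = 3) {
  truth$used <- FALSE
  matched <- logical(nrow(assignments))
  truth_hit <- rep(NA_integer_, nrow(assignments))
  ord <- order(assignments$patient_id, assignments$start_date)
  for (i in ord) {
    cand <- which(!truth$used &
                    truth$patient_id == assignments$patient_id[i] &
                    truth$regimen == assignments$regimen[i] &
                    abs(as.integer(truth$start_date - assignments$start_date[i])) <= date_tol &
                    abs(as.integer(truth$end_date - assignments$end_date[i])) <= date_tol)
    if (length(cand) > 0) {
      j <- cand[order(abs(as.integer(truth$start_date[cand] -
                                       assignments$start_date[i])))][1]
      truth$used[j] <- TRUE
      matched[i] <- TRUE
      truth_hit[i] <- j
    }
  }
  list(matched = matched, truth_recovered = truth$used)
}

#' Score derived regimens against planted truth
#'
#' Predictions and truth regimens are matched one-to-one within a patient
#' on regimen name with both dates within `date_tol` days. Two tables are
#' returned, because the accuracy denominator can be read two ways: `ppv`
#' strata are the *predicted* regimens by catalog category (correct
#' predictions over predictions — the printed accuracy semantics; spurious
#' predictions count against their own category), and `recall` strata are
#' the *truth* regimens (recovered truths over planted truths).
#'
#' @param assignments data.frame from [derive_sequence()].
#' @param truth the generator's regimen truth (`patient_id`, `regimen`,
#'   `category`, `start_date`, `end_date`).
#' @param catalog regimen catalog (fixes the category display order).
#' @param date_tol date tolerance in days (default 3).
#' @return list with `ppv`, `recall` (data.frames with per-category and
#'   overall rows: `n`, `n_correct`, `accuracy_pct`), and the row subsets
#'   `wrong_predictions`, `missed_truths`.
#' @export
score_regimens <- function(assignments, truth, catalog = mm_regimen_catalog(),
                           date_tol = 3) {
  mm <- match_assignments(assignments, truth, date_tol)
  cat_order <- unique(catalog$category)

  strata_table <- function(groups, correct, order_hint) {
    cats <- unique(c(order_hint[order_hint %in% groups], sort(unique(groups))))
    rows <- lapply(cats, function(cc) {
      sel <- groups == cc
      data.frame(category = cc, n = sum(sel),
                 n_correct = sum(correct[sel]),
                 accuracy_pct = accuracy_pct(sum(correct[sel]), sum(sel)),
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, c(rows, list(data.frame(
      category = "Total", n = length(groups), n_correct = sum(correct),
      accuracy_pct = accuracy_pct(sum(correct), length(groups)),
      stringsAsFactors = FALSE))))
    rownames(tab) <- NULL
    tab
  }

  ppv <- strata_table(assignments$category, mm$matched, cat_order)
  recall <- strata_table(truth$category, mm$truth_recovered, cat_order)
  list(
    ppv = ppv,
    recall = recall,
    wrong_predictions = assignments[!mm$matched, , drop = FALSE],
    missed_truths = truth[!mm$truth_recovered, , drop = FALSE]
  )
}

#' Score toxicity signals against planted truth
#'
#' Builds the accuracy table per category with a total row (patients
#' signaled by any channel) and one sub-row per evidence-channel group:
#' `indicator` (lab, drug or keyword) and `admission`. A signaled patient
#' counts as correct when the truth holds an event of that category for the
#' patient. Sub-rows may overlap: a patient signaled through both channel
#' groups appears in both.
#'
#' @param signals signal data.frame from [detect_toxicity()].
#' @param truth the generator's toxicity truth (`patient_id`, `category`,
#'   `date`, `channel`).
#' @return data.frame with `category`, `group` ("total"/"indicator"/
#'   "admission"), `n_predicted`, `n_correct`, `accuracy_pct`.
#' @export
score_toxicity <- function(signals, truth) {
  groups <- list(total = c("lab", "drug", "keyword", "admission"),
                 indicator = c("lab", "drug", "keyword"),
                 admission = "admission")
  rows <- list()
  for (cat in toxicity_categories()) {
    truth_pat <- unique(truth$patient_id[truth$category == cat])
    for (g in names(groups)) {
      sel <- signals$category == cat & signals$channel %in% groups[[g]]
      pred_pat <- unique(signals$patient_id[sel])
      if (g != "total" && length(pred_pat) == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        category = cat, group = g,
        n_predicted = length(pred_pat),
        n_correct = sum(pred_pat %in% truth_pat),
        accuracy_pct = accuracy_pct(sum(pred_pat %in% truth_pat),
                                    length(pred_pat)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize a retrospective match report
#'
#' @param match_report data.frame from [retrospective_match()].
#' @param truth optional generator truth (`patient_id`, `category`) to
#'   score category agreement.
#' @return list: `n_registry`, per-category counts, `matched_pct` (share of
#'   registry records matched in the same year), and among the mismatches
#'   the whole-percent split between `year_mismatch` and
#'   `diagnosis_mismatch`; plus `accuracy_pct` when truth is given.
#' @export
score_retrospective <- function(match_report, truth = NULL) {
  n <- nrow(match_report)
  cnt <- function(cc) sum(match_report$category == cc)
  n_matched <- cnt("matched_same_year")
  n_year <- cnt("year_mismatch")
  n_diag <- cnt("diagnosis_mismatch")
  n_mis <- n_year + n_diag
  out <- list(
    n_registry = n,
    n_matched = n_matched,
    n_year_mismatch = n_year,
    n_diagnosis_mismatch = n_diag,
    n_absent = cnt("absent"),
    matched_pct = accuracy_pct(n_matched, n),
    year_mismatch_pct_of_mismatch = accuracy_pct(n_year, n_mis),
    diagnosis_mismatch_pct_of_mismatch = accuracy_pct(n_diag, n_mis)
  )
  if (!is.null(truth)) {
    m <- match(match_report$patient_id, truth$patient_id)
    out$accuracy_pct <- accuracy_pct(
      sum(match_report$category == truth$category[m]), n)
  }
  out
}
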