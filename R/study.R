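# End-to-end validation study: synthesize each sub-cohort at the scale of
# the original multi-hospital validation, run every engine, and score it
# against ground truth. This is the computation behind `oncocdm report`
# and scripts/acceptance.R.

#' The multiple-myeloma regimen study plan
#'
#' 198 predicted regimens once derived: per reporting category the clean
#' instances below plus the six misclassification scenarios (two 15 mg
#' maintenance/Rd confusions, a lenalidomide-prednisone and a
#' melphalan-prednisone catalog gap, one same-week D-mono+Rd merge, one
#' maintenance/D-Rd continuation split).
#'
#' @return a regimen plan data.frame for [generator_config()].
#' @export
mm_study_plan <- function() {
  clean <- rbind(
    regimen_plan("D-VRd", 8), regimen_plan("D-VTd", 4),
    regimen_plan("D-VCd", 4), regimen_plan("D-VMP", 3),
    regimen_plan("D-Vd", 6), regimen_plan("D-Rd", 12),
    regimen_plan("D-Pd", 4), regimen_plan("D-mono", 6),
    regimen_plan("Isa-KRd", 2), regimen_plan("Isa-Kd", 2),
    regimen_plan("Isa-Pd", 2),
    regimen_plan("VRd", 8), regimen_plan("VTd", 4), regimen_plan("VCd", 5),
    regimen_plan("Pom-Vd", 2), regimen_plan("IRd", 3),
    regimen_plan("Vd", 8), regimen_plan("KRd", 5), regimen_plan("Kd", 3),
    regimen_plan("PCd", 3), regimen_plan("Rd", 14), regimen_plan("Pd", 6),
    regimen_plan("P-mono", 3), regimen_plan("Lenalidomide maintenance", 6),
    regimen_plan("Iberdomide maintenance", 1),
    regimen_plan("Tal-PD", 4), regimen_plan("Tec", 8), regimen_plan("Elr", 4),
    regimen_plan("Trial medication", 1),
    regimen_plan("CAR-T", 5),
    regimen_plan("EPd", 2), regimen_plan("ERd", 3),
    regimen_plan("Melphalan", 2), regimen_plan("Bridging", 2),
    regimen_plan("Auto-SCT", 30), regimen_plan("Allo-SCT", 6)
  )
  failures <- rbind(
    regimen_plan("", 2, "rd_vs_len15"),
    regimen_plan("", 1, "len_pred"),
    regimen_plan("", 1, "mel_pred"),
    regimen_plan("", 1, "drd_merge"),
    regimen_plan("", 1, "maint_dmono_vs_drd")
  )
  rbind(failures, clean)
}

#' The AML regimen study plan
#'
#' 254 treated patients, one regimen each, all clean (the concordance
#' study: every derived regimen must equal its planted truth).
#'
#' @return a regimen plan data.frame for [generator_config()].
#' @export
aml_study_plan <- function() {
  rbind(
    regimen_plan("7+3", 90), regimen_plan("7+3-midostaurin", 30),
    regimen_plan("AZA-VEN", 80), regimen_plan("AZA-mono", 30),
    regimen_plan("Gilteritinib", 10), regimen_plan("Hydroxycarbamide", 8),
    regimen_plan("Allo-SCT", 6)
  )
}

#' The AML toxicity study plan
#'
#' Planted CTCAE events across the ten categories and their observed
#' evidence channels (laboratory indicators, indicator drug orders,
#' imaging-report keywords, admission diagnoses).
#'
#' @return a toxicity plan data.frame for [generator_config()].
#' @export
aml_toxicity_plan <- function() {
  rbind(
    toxicity_plan("acute_renal_failure", 17, "lab"),
    toxicity_plan("hepatic_toxicity", 40, "lab"),
    toxicity_plan("icu_admission", 44, "admission"),
    toxicity_plan("sepsis", 33, "drug"),
    toxicity_plan("sepsis", 10, "admission"),
    toxicity_plan("invasive_aspergillosis", 4, "keyword"),
    toxicity_plan("invasive_aspergillosis", 8, "admission"),
    toxicity_plan("invasive_candidiasis", 2, "drug"),
    toxicity_plan("invasive_candidiasis", 3, "admission"),
    toxicity_plan("typhlitis", 12, "drug"),
    toxicity_plan("typhlitis", 10, "admission"),
    toxicity_plan("hemorrhage", 3, "keyword"),
    toxicity_plan("hemorrhage", 10, "admission"),
    toxicity_plan("pulmonary_toxicity", 1, "keyword"),
    toxicity_plan("pulmonary_toxicity", 7, "admission"),
    toxicity_plan("venous_thrombosis", 11, "drug")
  )
}

#' Run the full validation study
#'
#' Synthesizes five sub-cohorts and scores each engine against its ground
#' truth: (1) prospective new-diagnosis inclusion over 1,287 AML and
#' lung-cancer candidates with 68 planted exclusions (11 non-resident, 27
#' relapsed/refractory trajectories, 30 preliminary-only diagnoses);
#' (2) retrospective matching of a 384-record registry extract (342 same
#' year, 14 other year, 28 other tumor group); (3) the multiple-myeloma
#' regimen study (117 patients, [mm_study_plan()]); (4) the AML regimen
#' concordance study (254 patients, all clean) with the toxicity plan and
#' background noise on; (5) laboratory cross-validation of 1,689 items
#' against a manual copy carrying 7 injected typos.
#'
#' @param seed integer seed driving all sub-cohorts.
#' @return named list of sub-study results (`prospective`, `retrospective`,
#'   `mm_regimens`, `aml_regimens`, `toxicity`, `labs`), each holding the
#'   relevant score tables.
#' @export
run_validation_study <- function(seed = 1L) {
  seed <- as.integer(seed) %% 100000L
  out <- list()

  # (1) prospective inclusion
  cfg <- generator_config(
    n_patients = c(AML = 349, lung = 938),
    exclusion_scenarios = c(non_resident = 11, relapse_trajectory = 27,
                            preliminary_diagnosis = 30),
    noise = FALSE, routine_labs_per_patient = 0, seed = seed * 10L + 1L)
  g <- generate_cohort(cfg)
  as_of <- max(g$dataset$trajectories$start_date) + 28
  cands <- detect_candidates(g$dataset, as_of)
  decisions <- classify_inclusion(cands, g$dataset, as_of)
  out$prospective <- score_inclusion(decisions, g$truth$inclusion)

  # (2) retrospective registry matching
  cfg <- generator_config(
    n_patients = c(AML = 168, lung = 216),
    registry_plan = c(matched = 342, year_mismatch = 14,
                      diagnosis_mismatch = 28),
    noise = FALSE, routine_labs_per_patient = 0, seed = seed * 10L + 2L)
  g <- generate_cohort(cfg)
  report <- retrospective_match(g$dataset$registry, g$dataset)
  out$retrospective <- score_retrospective(report, g$truth$retrospective)

  # (3) MM regimens at printed scale
  cfg <- generator_config(
    n_patients = c(MM = 117), regimen_plan = mm_study_plan(),
    noise = FALSE, routine_labs_per_patient = 0, seed = seed * 10L + 3L)
  g <- generate_cohort(cfg)
  mm_cat <- mm_regimen_catalog()
  assignments <- derive_sequence(g$dataset, mm_cat)
  out$mm_regimens <- score_regimens(assignments, g$truth$regimens, mm_cat)

  # (4) AML regimens + toxicity, with background noise
  cfg <- generator_config(
    n_patients = c(AML = 254), regimen_plan = aml_study_plan(),
    toxicity_plan = aml_toxicity_plan(), regimen_tumor_group = "AML",
    noise = TRUE, seed = seed * 10L + 4L)
  aml_cat <- aml_regimen_catalog()
  g <- generate_cohort(cfg, catalog = aml_cat)
  assignments <- derive_sequence(g$dataset, aml_cat)
  out$aml_regimens <- score_regimens(assignments, g$truth$regimens, aml_cat)
  tox <- detect_toxicity(g$dataset, catalog = aml_cat)
  out$toxicity <- list(
    table = score_toxicity(tox$signals, g$truth$toxicity),
    n_events_planted = nrow(g$truth$toxicity),
    n_events_signaled = sum(
      paste(g$truth$toxicity$patient_id, g$truth$toxicity$category) %in%
        paste(tox$findings$patient_id, tox$findings$category)),
    n_fp_planted = nrow(g$truth$fp)
  )
  out$toxicity$sensitivity_pct <- accuracy_pct(
    out$toxicity$n_events_signaled, out$toxicity$n_events_planted)

  # (5) laboratory cross-validation
  cfg <- generator_config(
    n_patients = c(breast = 16), routine_labs_per_patient = 106,
    noise = FALSE, seed = seed * 10L + 5L)
  g <- generate_cohort(cfg)
  auto <- g$dataset$labs[seq_len(1689), , drop = FALSE]
  corrupted <- corrupt_manual_labs(auto, n_typos = 7, seed = seed * 10L + 6L)
  cmp <- compare_pairs(pair_items(auto, corrupted$manual))
  out$labs <- list(n_pairs = cmp$n_pairs, n_mismatch = cmp$n_mismatch,
                   pct_exact = cmp$pct_exact, pct_2dec = cmp$pct_2dec,
                   pct_display = cmp$pct_display,
                   typo_rows = corrupted$typo_rows,
                   mismatch_rows = which(cmp$verdicts$verdict == "value_mismatch"))
  out
}
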