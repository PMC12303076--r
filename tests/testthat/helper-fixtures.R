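# Fixtures are built in code; nothing is read from disk except the
# package's own shipped catalog/rules files.

`%||%` <- function(a, b) if (is.null(a)) b else a

cdm_table_set <- c("patients", "trajectories", "diagnoses", "prescriptions",
                   "labs", "admissions", "reports", "sct", "registry")

# minimal hand-built dataset: two patients, one AML trajectory each
tiny_dataset <- function() {
  cdm_dataset(
    patients = data.frame(
      patient_id = c("P1", "P2"), birth_year = c(1960L, 1955L),
      sex = c("female", "male"), resident_nl = c(TRUE, TRUE)),
    trajectories = data.frame(
      trajectory_id = c("T1", "T2"), patient_id = c("P1", "P2"),
      hospital_id = "H1", start_date = as.Date(c("2022-03-01", "2022-06-01")),
      tumor_group = c("AML", "AML")),
    diagnoses = data.frame(
      patient_id = c("P1", "P2"), icd10_code = "C92.0",
      date = as.Date(c("2022-03-03", "2022-06-02")),
      status = "confirmed", tumor_group = "AML")
  )
}

rx <- function(pid, atc, name, dose, start, end = NA) {
  data.frame(patient_id = pid, atc_code = atc, drug_name = name,
             dose_mg_per_day = dose, start_date = as.Date(start),
             end_date = as.Date(end), stringsAsFactors = FALSE)
}

# a small generated cohort with clean planted MM regimens
small_clean_cohort <- function(seed = 42L, noise = FALSE) {
  plan <- rbind(
    regimen_plan("D-Rd", 3), regimen_plan("VRd", 2), regimen_plan("Vd", 2),
    regimen_plan("Rd", 2), regimen_plan("Lenalidomide maintenance", 2),
    regimen_plan("Melphalan", 1), regimen_plan("Tec", 1),
    regimen_plan("Auto-SCT", 2)
  )
  cfg <- generator_config(n_patients = c(MM = 10), regimen_plan = plan,
                          noise = noise, seed = seed)
  generate_cohort(cfg)
}

expect_tables_equal <- function(a, b) {
  for (nm in cdm_table_set) {
    expect_equal(a[[nm]], b[[nm]], info = paste("table", nm))
  }
}

# exhaustive catalog search: the independent oracle for match_regimen on
# generic (non lenalidomide-only) episodes
brute_force_match <- function(classes, catalog) {
  best <- NULL
  best_size <- -1L
  for (i in seq_len(nrow(catalog))) {
    if (catalog$event[i] != "") next
    cl <- catalog$classes[[i]]
    if (length(cl) == 0 || !all(cl %in% classes)) next
    if (length(cl) > best_size) {
      best <- catalog$name[i]
      best_size <- length(cl)
    }
  }
  best %||% "UNMATCHED"
}
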