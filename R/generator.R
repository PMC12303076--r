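# Seeded synthetic EHR cohort generator with complete ground truth.
#
# The generator emulates a Dutch-hospital EHR extract harmonized into the
# CDM: ICD-10 coded diagnoses, ATC coded prescriptions, LOINC coded labs.
# Cohort composition defaults to the validated case mix (four tumor groups
# with their sex and age-band distributions). Every planted fact — the
# inclusion status of each candidate, each treatment regimen realized as
# co-started prescriptions, each toxicity event realized through one
# evidence channel — is recorded in a GroundTruth object against which the
# engines are scored. Five named failure modes reproduce, by construction,
# the regimen misclassification scenarios the engine's rules are known to
# produce.

failure_modes <- function() {
  c("rd_vs_len15", "len_pred", "mel_pred", "drd_merge", "maint_dmono_vs_drd")
}

# per-group demographics: share of females and of the 18-65 age band
group_demographics <- function() {
  data.frame(
    tumor_group = c("AML", "lung", "MM", "breast"),
    female_pct = c(42.4, 44.4, 47.0, 100.0),
    age_18_65_pct = c(40.8, 24.7, 53.0, 75.0),
    icd10 = c("C92.0", "C34.9", "C90.0", "C50.9"),
    stringsAsFactors = FALSE
  )
}

#' Build a regimen plan table
#'
#' @param name catalog regimen name (ignored for failure-mode rows).
#' @param count number of instances to plant.
#' @param failure_mode `""` for a clean regimen, or one of
#'   `r paste(failure_modes(), collapse = ", ")`.
#' @return data.frame usable as `regimen_plan` in [generator_config()].
#' @export
regimen_plan <- function(name, count = 1, failure_mode = "") {
  data.frame(name = name, count = as.integer(count),
             failure_mode = failure_mode, stringsAsFactors = FALSE)
}

#' Build a toxicity plan table
#'
#' @param category CTCAE category (see [toxicity_categories()]).
#' @param count number of events to plant.
#' @param channel evidence channel realizing each event: `"lab"`,
#'   `"drug"`, `"keyword"` or `"admission"`.
#' @return data.frame usable as `toxicity_plan` in [generator_config()].
#' @export
toxicity_plan <- function(category, count = 1, channel = "lab") {
  data.frame(category = category, count = as.integer(count),
             channel = channel, stringsAsFactors = FALSE)
}

#' Generator configuration
#'
#' Defines the cohort to synthesize: patients per tumor group (defaults are
#' the validated case mix), counts of the three exclusion scenarios among
#' new-diagnosis candidates, the regimen plan (instances per catalog entry,
#' optionally carrying a failure mode), the toxicity plan (events per CTCAE
#' category and evidence channel), the retrospective registry plan, and
#' background-noise settings. Everything is deterministic given `seed`.
#'
#' @param n_patients named counts per tumor group (AML, lung, MM, breast).
#' @param exclusion_scenarios named counts for `non_resident`,
#'   `relapse_trajectory`, `preliminary_diagnosis`.
#' @param regimen_plan data.frame from [regimen_plan()], or `NULL`.
#' @param toxicity_plan data.frame from [toxicity_plan()], or `NULL`.
#' @param registry_plan named counts for `matched`, `year_mismatch`,
#'   `diagnosis_mismatch` registry records.
#' @param regimen_tumor_group tumor group receiving the planted regimens.
#' @param routine_labs_per_patient background laboratory rows per patient.
#' @param noise add benign background prescriptions and a low rate of
#'   false-positive toxicity triggers (exercises the engines'
#'   false-positive paths).
#' @param noise_fp_rate share of treated patients receiving a spurious
#'   indicator trigger when `noise` is on.
#' @param seed RNG seed.
#' @return a `generator_config` list, validated.
#' @export
generator_config <- function(n_patients = c(AML = 517, lung = 1154, MM = 117,
                                            breast = 16),
                             exclusion_scenarios = c(non_resident = 0,
                                                     relapse_trajectory = 0,
                                                     preliminary_diagnosis = 0),
                             regimen_plan = NULL,
                             toxicity_plan = NULL,
                             registry_plan = c(matched = 0, year_mismatch = 0,
                                               diagnosis_mismatch = 0),
                             regimen_tumor_group = "MM",
                             routine_labs_per_patient = 3,
                             noise = TRUE,
                             noise_fp_rate = 0.02,
                             seed = 1L) {
  np <- stats::setNames(rep(0L, 4), tumor_groups())
  np[names(n_patients)] <- as.integer(n_patients)
  ex <- c(non_resident = 0L, relapse_trajectory = 0L, preliminary_diagnosis = 0L)
  ex[names(exclusion_scenarios)] <- as.integer(exclusion_scenarios)
  rp <- c(matched = 0L, year_mismatch = 0L, diagnosis_mismatch = 0L)
  rp[names(registry_plan)] <- as.integer(registry_plan)
  if (any(np < 0) || any(ex < 0) || any(rp < 0)) {
    stopf("config error: counts must be nonnegative")
  }
  if (sum(ex) > np["AML"] + np["lung"]) {
    stopf("config error: more exclusion scenarios than AML+lung patients")
  }
  if (sum(rp) > np["AML"] + np["lung"]) {
    stopf("config error: more registry records than AML+lung patients")
  }
  if (!is.null(regimen_plan)) {
    bad <- setdiff(regimen_plan$failure_mode, c("", failure_modes()))
    if (length(bad) > 0) stopf("config error: unknown failure_mode '%s'", bad[1])
    if (any(regimen_plan$count < 0)) stopf("config error: negative regimen count")
  }
  if (!is.null(toxicity_plan)) {
    bad <- setdiff(toxicity_plan$category, toxicity_categories())
    if (length(bad) > 0) stopf("config error: unknown toxicity category '%s'", bad[1])
    bad <- setdiff(toxicity_plan$channel, c("lab", "drug", "keyword", "admission"))
    if (length(bad) > 0) stopf("config error: unknown evidence channel '%s'", bad[1])
    if (is.null(regimen_plan) && sum(toxicity_plan$count) > 0) {
      stopf("config error: toxicity planted but no treatment plan (no attribution window)")
    }
  }
  structure(list(
    n_patients = np, exclusion_scenarios = ex, regimen_plan = regimen_plan,
    toxicity_plan = toxicity_plan, registry_plan = rp,
    regimen_tumor_group = regimen_tumor_group,
    routine_labs_per_patient = as.integer(routine_labs_per_patient),
    noise = isTRUE(noise), noise_fp_rate = noise_fp_rate,
    seed = as.integer(seed)
  ), class = "generator_config")
}

rx_row <- function(pid, atc, name, dose, start, end) {
  data.frame(patient_id = pid, atc_code = atc, drug_name = name,
             dose_mg_per_day = dose, start_date = as.Date(start),
             end_date = as.Date(end), stringsAsFactors = FALSE)
}

truth_regimen_row <- function(pid, regimen, category, start, end) {
  data.frame(patient_id = pid, regimen = regimen, category = category,
             start_date = as.Date(start), end_date = as.Date(end),
             stringsAsFactors = FALSE)
}

# one clean catalog regimen as co-started prescriptions (day offsets 0,1,2,...
# inside the same-week window); maintenance entries run long at low dose
realize_clean_regimen <- function(pid, entry, drug_map, slot_start) {
  if (entry$event != "") {
    sct <- data.frame(patient_id = pid, date = slot_start, kind = entry$event,
                      stringsAsFactors = FALSE)
    return(list(rx = NULL, sct = sct,
                truth = truth_regimen_row(pid, entry$name, entry$category,
                                          slot_start, slot_start),
                next_free = slot_start + 75))
  }
  classes <- entry$classes[[1]]
  duration <- if (isTRUE(entry$maintenance_flag)) 179L else 20L
  rx <- list()
  for (j in seq_along(classes)) {
    hit <- which(drug_map$drug_class == classes[j])[1]
    if (is.na(hit)) stopf("config error: no ATC mapping for drug class '%s'",
                          classes[j])
    dose <- drug_map$default_dose_mg[hit]
    if (classes[j] == "lenalidomide" && isTRUE(entry$maintenance_flag)) dose <- 10
    start <- slot_start + (j - 1)
    rx[[j]] <- rx_row(pid, drug_map$atc_code[hit], drug_map$drug_name[hit],
                      dose, start, start + duration)
  }
  rx <- do.call(rbind, rx)
  list(rx = rx, sct = NULL,
       truth = truth_regimen_row(pid, entry$name, entry$category,
                                 min(rx$start_date), max(rx$end_date)),
       next_free = max(rx$end_date) + 75)
}

# the five narrated misclassification scenarios; truth holds what the
# patient actually received, the prescriptions are laid out so the engine's
# documented rules produce the misreading
realize_failure <- function(pid, mode, slot_start) {
  s <- slot_start
  out <- switch(mode,
    rd_vs_len15 = list(
      rx = rx_row(pid, "L04AX04", "lenalidomide", 15, s, s + 179),
      truth = truth_regimen_row(pid, "Lenalidomide maintenance", "IMID",
                                s, s + 179)),
    len_pred = list(
      rx = rbind(rx_row(pid, "L04AX04", "lenalidomide", 25, s, s + 20),
                 rx_row(pid, "H02AB07", "prednisone", 60, s + 1, s + 21)),
      truth = truth_regimen_row(pid, "Lenalidomide-prednisone", "IMID",
                                s, s + 21)),
    mel_pred = list(
      rx = rbind(rx_row(pid, "L01AA03", "melphalan", 16, s, s + 3),
                 rx_row(pid, "H02AB07", "prednisone", 60, s + 1, s + 21)),
      truth = truth_regimen_row(pid, "Melphalan-prednisone", "Other",
                                s, s + 21)),
    drd_merge = list(
      rx = rbind(rx_row(pid, "L01FC01", "daratumumab", 1800, s, NA),
                 rx_row(pid, "L04AX04", "lenalidomide", 25, s + 3, s + 23),
                 rx_row(pid, "H02AB02", "dexamethasone", 40, s + 3, s + 23)),
      truth = rbind(
        truth_regimen_row(pid, "D-mono", "Anti-CD38", s, s),
        truth_regimen_row(pid, "Rd", "IMID", s + 3, s + 23))),
    maint_dmono_vs_drd = list(
      rx = rbind(rx_row(pid, "L04AX04", "lenalidomide", 10, s, s + 99),
                 rx_row(pid, "L01FC01", "daratumumab", 1800, s + 100, s + 160),
                 rx_row(pid, "H02AB02", "dexamethasone", 40, s + 101, s + 160)),
      truth = rbind(
        truth_regimen_row(pid, "Lenalidomide maintenance", "IMID", s, s + 99),
        truth_regimen_row(pid, "D-Rd", "Anti-CD38", s + 100, s + 160))),
    stopf("config error: unknown failure_mode '%s'", mode)
  )
  out$sct <- NULL
  out$next_free <- max(out$truth$end_date) + 75
  out
}

lab_panel <- function() {
  data.frame(
    loinc = c("718-7", "6690-2", "777-3", "2160-0", "1975-2", "1742-6",
              "2951-2", "6298-4", "17861-6"),
    analyte = c("hemoglobin", "leukocytes", "platelets", "creatinine",
                "total bilirubin", "alanine aminotransferase", "sodium",
                "potassium", "calcium"),
    unit = c("mmol/L", "10*9/L", "10*9/L", "umol/L", "umol/L", "U/L",
             "mmol/L", "mmol/L", "mmol/L"),
    mean = c(8.5, 6, 250, 75, 9, 25, 140, 4.2, 2.35),
    sd = c(0.6, 1.5, 40, 2.5, 2, 6, 2, 0.3, 0.08),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic CDM cohort with ground truth
#'
#' Deterministic given the config seed: the same config produces
#' byte-identical datasets. The output always passes [validate_dataset()].
#'
#' @param config a [generator_config()].
#' @param catalog regimen catalog realizing the regimen plan (default MM).
#' @param drug_map ATC drug-class mapping.
#' @param rules toxicity rules realizing the toxicity plan.
#' @return list with `dataset` (a [cdm_dataset()]) and `truth` (class
#'   `cdm_truth`: data.frames `inclusion`, `regimens`, `toxicity`,
#'   `retrospective`, `fp`).
#' @export
generate_cohort <- function(config, catalog = mm_regimen_catalog(),
                            drug_map = default_drug_map(),
                            rules = default_toxicity_rules()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  demo <- group_demographics()
  day0 <- as.Date("2021-01-01")
  day_span <- as.integer(as.Date("2023-06-30") - day0)

  # ---- patients, trajectories, diagnoses -------------------------------
  n_total <- sum(config$n_patients)
  groups <- rep(names(config$n_patients), config$n_patients)
  pats <- trjs <- dxs <- NULL
  if (n_total > 0) {
    pid <- sprintf("P%05d", seq_len(n_total))
    d <- demo[match(groups, demo$tumor_group), ]
    sex <- ifelse(stats::runif(n_total) * 100 < d$female_pct, "female", "male")
    start <- day0 + sample.int(day_span + 1, n_total, replace = TRUE) - 1
    young <- stats::runif(n_total) * 100 < d$age_18_65_pct
    age <- ifelse(young, sample(25:64, n_total, replace = TRUE),
                  sample(66:88, n_total, replace = TRUE))
    birth_year <- as.integer(format(start, "%Y")) - age
    pats <- data.frame(patient_id = pid, birth_year = birth_year, sex = sex,
                       resident_nl = TRUE, stringsAsFactors = FALSE)
    trjs <- data.frame(trajectory_id = sprintf("T%05d", seq_len(n_total)),
                       patient_id = pid,
                       hospital_id = sprintf("H%d", 1 + (seq_len(n_total) %% 3)),
                       start_date = start, tumor_group = groups,
                       stringsAsFactors = FALSE)
    dxs <- data.frame(patient_id = pid, icd10_code = d$icd10,
                      date = start + sample(0:7, n_total, replace = TRUE),
                      status = "confirmed", tumor_group = groups,
                      stringsAsFactors = FALSE)
  }

  truth_incl <- if (n_total > 0) {
    data.frame(patient_id = pats$patient_id, tumor_group = groups,
               decision = "include", reason = "NONE", stringsAsFactors = FALSE)
  } else {
    data.frame(patient_id = character(0), tumor_group = character(0),
               decision = character(0), reason = character(0))
  }

  # ---- exclusion scenarios --------------------------------------------
  extra_dx <- list()
  elig <- which(groups %in% c("AML", "lung"))
  n_ex <- sum(config$exclusion_scenarios)
  if (n_ex > 0) {
    chosen <- elig[sample.int(length(elig), n_ex)]
    idx <- 0
    take <- function(k) chosen[idx + seq_len(k)]
    for (i in take(config$exclusion_scenarios["non_resident"])) {
      pats$resident_nl[i] <- FALSE
      truth_incl$decision[i] <- "exclude"
      truth_incl$reason[i] <- "NON_RESIDENT"
    }
    idx <- idx + config$exclusion_scenarios["non_resident"]
    for (i in take(config$exclusion_scenarios["relapse_trajectory"])) {
      extra_dx[[length(extra_dx) + 1]] <- data.frame(
        patient_id = pats$patient_id[i], icd10_code = dxs$icd10_code[i],
        date = trjs$start_date[i] - sample(400:1000, 1), status = "confirmed",
        tumor_group = groups[i], stringsAsFactors = FALSE)
      truth_incl$decision[i] <- "exclude"
      truth_incl$reason[i] <- "RELAPSE_TRAJECTORY"
    }
    idx <- idx + config$exclusion_scenarios["relapse_trajectory"]
    for (i in take(config$exclusion_scenarios["preliminary_diagnosis"])) {
      dxs$status[i] <- "preliminary"
      truth_incl$decision[i] <- "exclude"
      truth_incl$reason[i] <- "PRELIMINARY_DIAGNOSIS"
    }
  }
  dxs <- bind_cdm_rows(c(list(dxs), extra_dx), "diagnoses")

  # ---- regimen plan ----------------------------------------------------
  rx_rows <- list()
  sct_rows <- list()
  truth_reg <- list()
  plan <- config$regimen_plan
  if (!is.null(plan) && sum(plan$count) > 0) {
    target <- which(groups == config$regimen_tumor_group)
    if (length(target) == 0) {
      stopf("config error: regimen plan targets tumor group '%s' but no such patients",
            config$regimen_tumor_group)
    }
    instances <- plan[rep(seq_len(nrow(plan)), plan$count), , drop = FALSE]
    fail_inst <- instances[instances$failure_mode != "", , drop = FALSE]
    clean_inst <- instances[instances$failure_mode == "", , drop = FALSE]
    if (nrow(fail_inst) > length(target)) {
      stopf("config error: more failure scenarios than target patients")
    }
    next_free <- trjs$start_date + 14
    # failure scenarios get dedicated patients so each narrative stays clean
    fail_pat <- target[seq_len(nrow(fail_inst))]
    clean_pool <- if (nrow(clean_inst) > 0 &&
                      length(target) > nrow(fail_inst)) {
      setdiff(target, fail_pat)
    } else {
      target
    }
    for (k in seq_len(nrow(fail_inst))) {
      i <- fail_pat[k]
      r <- realize_failure(pats$patient_id[i], fail_inst$failure_mode[k],
                           next_free[i])
      next_free[i] <- r$next_free
      rx_rows[[length(rx_rows) + 1]] <- r$rx
      truth_reg[[length(truth_reg) + 1]] <- r$truth
    }
    if (nrow(clean_inst) > 0) {
      cat_idx <- match(clean_inst$name, catalog$name)
      if (any(is.na(cat_idx))) {
        stopf("config error: regimen '%s' not in catalog",
              clean_inst$name[which(is.na(cat_idx))[1]])
      }
      for (k in seq_len(nrow(clean_inst))) {
        i <- clean_pool[1 + (k - 1) %% length(clean_pool)]
        entry <- catalog[cat_idx[k], , drop = FALSE]
        r <- realize_clean_regimen(pats$patient_id[i], entry, drug_map,
                                   next_free[i])
        next_free[i] <- r$next_free
        rx_rows[[length(rx_rows) + 1]] <- r$rx
        sct_rows[[length(sct_rows) + 1]] <- r$sct
        truth_reg[[length(truth_reg) + 1]] <- r$truth
      }
    }
  }
  truth_reg <- if (length(truth_reg) > 0) do.call(rbind, truth_reg) else
    truth_regimen_row(character(0), character(0), character(0),
                      as.Date(character(0)), as.Date(character(0)))

  # ---- toxicity plan ---------------------------------------------------
  lab_rows <- list()
  adm_rows <- list()
  rep_rows <- list()
  truth_tox <- list()
  tplan <- config$toxicity_plan
  sct_pats <- unique(unlist(lapply(sct_rows, function(x) x$patient_id)))
  drug_truth <- truth_reg[truth_reg$category != "HSCT", , drop = FALSE]
  treated <- setdiff(unique(drug_truth$patient_id), sct_pats)
  tox_assigned <- character(0)
  if (!is.null(tplan) && sum(tplan$count) > 0) {
    events <- tplan[rep(seq_len(nrow(tplan)), tplan$count), , drop = FALSE]
    if (nrow(events) > length(treated)) {
      stopf("config error: toxicity plan needs %d treated patients, only %d available",
            nrow(events), length(treated))
    }
    for (k in seq_len(nrow(events))) {
      pid <- treated[k]
      tox_assigned <- c(tox_assigned, pid)
      tw <- drug_truth[drug_truth$patient_id == pid, , drop = FALSE]
      ws <- min(tw$start_date)
      we <- max(tw$end_date) + 30
      event <- min(ws + 10 + (k %% 15), we)
      cat <- events$category[k]
      channel <- events$channel[k]
      rule <- rules[[cat]]
      if (channel == "lab") {
        lr <- (rule$labs %||% list())[[1]]
        if (is.null(lr)) stopf("config error: category '%s' has no lab channel", cat)
        if (isTRUE(lr$relative_to_baseline)) {
          base_val <- 70
          lab_rows[[length(lab_rows) + 1]] <- data.frame(
            patient_id = pid, loinc_code = lr$loinc, analyte_name = lr$analyte,
            value = base_val, unit = lr$unit,
            datetime = as.POSIXct(paste(ws - 10, "08:00:00"), tz = "UTC"),
            stringsAsFactors = FALSE)
          val <- round(base_val * lr$threshold * 1.3, 1)
        } else {
          val <- round(lr$threshold * 1.3, 1)
        }
        lab_rows[[length(lab_rows) + 1]] <- data.frame(
          patient_id = pid, loinc_code = lr$loinc, analyte_name = lr$analyte,
          value = val, unit = lr$unit,
          datetime = as.POSIXct(paste(event, "08:00:00"), tz = "UTC"),
          stringsAsFactors = FALSE)
      } else if (channel == "drug") {
        set <- unlist((rule$drugs %||% list())[[1]])
        if (is.null(set)) stopf("config error: category '%s' has no drug channel", cat)
        for (j in seq_along(set)) {
          rx_rows[[length(rx_rows) + 1]] <- rx_row(
            pid, set[j], "indicator drug", 1, event + (j - 1), event + 7)
        }
      } else if (channel == "keyword") {
        kw <- (rule$keywords %||% character(0))[1]
        if (is.na(kw)) stopf("config error: category '%s' has no keyword channel", cat)
        rep_rows[[length(rep_rows) + 1]] <- data.frame(
          patient_id = pid,
          datetime = as.POSIXct(paste(event, "10:00:00"), tz = "UTC"),
          modality = "CT",
          text = sprintf("CT thorax/abdomen: findings consistent with %s.", kw),
          stringsAsFactors = FALSE)
      } else {  # admission
        icu <- isTRUE(rule$icu_flag)
        main <- if (icu) "Z51.1" else (rule$admission_codes %||% character(0))[1]
        if (is.na(main)) stopf("config error: category '%s' has no admission channel", cat)
        adm_rows[[length(adm_rows) + 1]] <- data.frame(
          patient_id = pid, admit_date = event, discharge_date = event + 7,
          main_icd10 = main, secondary_icd10 = "", icu = icu,
          stringsAsFactors = FALSE)
      }
      truth_tox[[length(truth_tox) + 1]] <- data.frame(
        patient_id = pid, category = cat, date = event, channel = channel,
        stringsAsFactors = FALSE)
    }
  }
  truth_tox <- if (length(truth_tox) > 0) do.call(rbind, truth_tox) else
    data.frame(patient_id = character(0), category = character(0),
               date = as.Date(character(0)), channel = character(0))

  # ---- background noise ------------------------------------------------
  truth_fp <- data.frame(patient_id = character(0), category = character(0),
                         channel = character(0), stringsAsFactors = FALSE)
  if (config$noise && n_total > 0) {
    benign <- data.frame(atc = c("C09AA02", "A02BC02", "N02BE01"),
                         name = c("enalapril", "pantoprazole", "paracetamol"),
                         dose = c(10, 40, 1000), stringsAsFactors = FALSE)
    who <- which(stats::runif(n_total) < 0.5)
    if (length(who) > 0) {
      pick <- sample.int(3, length(who), replace = TRUE)
      starts <- trjs$start_date[who] + sample(0:200, length(who), replace = TRUE)
      rx_rows[[length(rx_rows) + 1]] <- data.frame(
        patient_id = pats$patient_id[who], atc_code = benign$atc[pick],
        drug_name = benign$name[pick], dose_mg_per_day = benign$dose[pick],
        start_date = starts, end_date = starts + 30, stringsAsFactors = FALSE)
    }
    # spurious indicator triggers in-window for a small share of treated
    # patients: drug orders for other indications, and a negated keyword
    fp_pool <- setdiff(treated, tox_assigned)
    n_fp <- min(length(fp_pool), floor(config$noise_fp_rate * length(treated)))
    if (n_fp > 0) {
      fp_kinds <- c("sepsis", "venous_thrombosis", "invasive_aspergillosis")
      for (k in seq_len(n_fp)) {
        pid <- fp_pool[k]
        tw <- drug_truth[drug_truth$patient_id == pid, , drop = FALSE]
        d <- min(tw$start_date) + 5
        kind <- fp_kinds[1 + (k - 1) %% 3]
        if (kind == "sepsis") {
          rx_rows[[length(rx_rows) + 1]] <- rx_row(
            pid, "J01DH02", "meropenem", 3, d, d + 7)
        } else if (kind == "venous_thrombosis") {
          rx_rows[[length(rx_rows) + 1]] <- rx_row(
            pid, "B01AB05", "enoxaparin", 80, d, d + 30)
        } else {
          rep_rows[[length(rep_rows) + 1]] <- data.frame(
            patient_id = pid,
            datetime = as.POSIXct(paste(d, "11:00:00"), tz = "UTC"),
            modality = "CT",
            text = "CT thorax: no evidence of aspergillosis.",
            stringsAsFactors = FALSE)
        }
        truth_fp <- rbind(truth_fp, data.frame(
          patient_id = pid, category = kind,
          channel = if (kind == "invasive_aspergillosis") "keyword" else "drug",
          stringsAsFactors = FALSE))
      }
    }
  }

  # ---- routine labs ----------------------------------------------------
  if (config$routine_labs_per_patient > 0 && n_total > 0) {
    panel <- lab_panel()
    m <- config$routine_labs_per_patient
    j <- rep(seq_len(m), times = n_total)
    pidx <- rep(seq_len(n_total), each = m)
    a <- 1 + (j - 1) %% nrow(panel)
    week <- (j - 1) %/% nrow(panel)
    val <- stats::rnorm(length(j), panel$mean[a], panel$sd[a])
    val <- round(pmin(pmax(val, panel$mean[a] - 2 * panel$sd[a]),
                      panel$mean[a] + 2 * panel$sd[a]), 1)
    lab_rows[[length(lab_rows) + 1]] <- data.frame(
      patient_id = pats$patient_id[pidx],
      loinc_code = panel$loinc[a], analyte_name = panel$analyte[a],
      value = val, unit = panel$unit[a],
      datetime = as.POSIXct(paste0(trjs$start_date[pidx] + week * 7,
                                   sprintf(" 09:%02d:00", a)), tz = "UTC"),
      stringsAsFactors = FALSE)
  }

  # ---- registry extract (retrospective) -------------------------------
  reg_rows <- NULL
  truth_retro <- data.frame(patient_id = character(0), category = character(0),
                            stringsAsFactors = FALSE)
  if (sum(config$registry_plan) > 0) {
    n_reg <- sum(config$registry_plan)
    reg_pat <- elig[seq_len(n_reg)]
    category <- rep(c("matched_same_year", "year_mismatch", "diagnosis_mismatch"),
                    config$registry_plan)
    year <- as.integer(format(trjs$start_date[reg_pat], "%Y"))
    reg_group <- groups[reg_pat]
    year[category == "year_mismatch"] <- year[category == "year_mismatch"] - 1L
    flip <- category == "diagnosis_mismatch"
    reg_group[flip] <- ifelse(groups[reg_pat][flip] == "AML", "lung", "AML")
    reg_rows <- data.frame(patient_id = pats$patient_id[reg_pat],
                           tumor_group = reg_group, diagnosis_year = year,
                           hospital_id = trjs$hospital_id[reg_pat],
                           stringsAsFactors = FALSE)
    truth_retro <- data.frame(patient_id = reg_rows$patient_id,
                              category = category, stringsAsFactors = FALSE)
  }

  # ---- assemble --------------------------------------------------------
  prescriptions <- bind_cdm_rows(rx_rows, "prescriptions")
  if (nrow(prescriptions) > 0) {
    prescriptions <- prescriptions[order(prescriptions$patient_id,
                                         prescriptions$start_date,
                                         prescriptions$atc_code), , drop = FALSE]
  }
  labs <- bind_cdm_rows(lab_rows, "labs")
  if (nrow(labs) > 0) {
    labs <- labs[order(labs$patient_id, labs$datetime, labs$loinc_code), ,
                 drop = FALSE]
  }
  cfg_file <- tempfile()
  writeLines(utils::capture.output(utils::str(config)), cfg_file)
  digest <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  ds <- cdm_dataset(
    patients = pats %||% empty_cdm_table("patients"),
    trajectories = trjs %||% empty_cdm_table("trajectories"),
    diagnoses = dxs,
    prescriptions = prescriptions,
    labs = labs,
    admissions = bind_cdm_rows(adm_rows, "admissions"),
    reports = bind_cdm_rows(rep_rows, "reports"),
    sct = bind_cdm_rows(sct_rows, "sct"),
    registry = if (is.null(reg_rows)) empty_cdm_table("registry") else reg_rows,
    provenance = list(seed = config$seed, config_digest = digest)
  )
  truth <- structure(list(inclusion = truth_incl, regimens = truth_reg,
                          toxicity = truth_tox, retrospective = truth_retro,
                          fp = truth_fp), class = "cdm_truth")
  list(dataset = ds, truth = truth)
}

#' Build the regimen misclassification fixture
#'
#' One dedicated patient per scenario instance; prescriptions are laid out
#' so the regimen engine produces the narrated misreading while the ground
#' truth records what was actually received. An empty scenario list yields
#' an empty fixture.
#'
#' @param scenarios character vector of failure modes (repeats allowed);
#'   see [failure_modes()].
#' @param seed RNG seed.
#' @return list with `dataset` and `truth`, as [generate_cohort()].
#' @export
make_failure_fixture <- function(scenarios, seed = 1L) {
  bad <- setdiff(scenarios, failure_modes())
  if (length(bad) > 0) stopf("config error: unknown scenario '%s'", bad[1])
  if (length(scenarios) == 0) {
    cfg <- generator_config(n_patients = c(MM = 0), noise = FALSE,
                            routine_labs_per_patient = 0, seed = seed)
    return(generate_cohort(cfg))
  }
  cfg <- generator_config(
    n_patients = c(MM = length(scenarios)),
    regimen_plan = regimen_plan(name = "", count = 1,
                                failure_mode = scenarios),
    noise = FALSE, routine_labs_per_patient = 0, seed = seed)
  generate_cohort(cfg)
}

#' Corrupt a lab table with manual-registration typos
#'
#' Emulates a manually registered copy of an automatically extracted lab
#' table: exactly `n_typos` rows differ from the source, each by a
#' single-digit substitution or a decimal shift in the value; all other
#' rows are identical. Deterministic per seed.
#'
#' @param labs a CDM labs table (the automatic source).
#' @param n_typos number of rows to perturb.
#' @param seed RNG seed.
#' @return list with `manual` (the corrupted copy) and `typo_rows`
#'   (integer indices of the perturbed rows).
#' @export
corrupt_manual_labs <- function(labs, n_typos, seed = 1L) {
  if (n_typos > nrow(labs)) {
    stopf("config error: n_typos (%d) exceeds number of lab rows (%d)",
          n_typos, nrow(labs))
  }
  set.seed(seed)
  manual <- labs
  rows <- if (n_typos > 0) sort(sample.int(nrow(labs), n_typos)) else integer(0)
  for (i in rows) {
    v <- manual$value[i]
    if (stats::runif(1) < 0.5) {
      manual$value[i] <- if (stats::runif(1) < 0.5) v * 10 else v / 10
    } else {
      s <- format(v, trim = TRUE, scientific = FALSE)
      digits_at <- which(strsplit(s, "")[[1]] %in% as.character(0:9))
      pos <- digits_at[sample.int(length(digits_at), 1)]
      old <- substr(s, pos, pos)
      new <- sample(setdiff(as.character(0:9), old), 1)
      substr(s, pos, pos) <- new
      manual$value[i] <- as.numeric(s)
    }
    if (manual$value[i] == labs$value[i]) manual$value[i] <- v + 1  # safety net
  }
  list(manual = manual, typo_rows = rows)
}
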