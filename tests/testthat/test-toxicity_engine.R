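rules <- default_toxicity_rules()

assign_row <- function(start, end, category = "IMID") {
  data.frame(patient_id = "P1", regimen = "Rd", category = category,
             start_date = as.Date(start), end_date = as.Date(end),
             stringsAsFactors = FALSE)
}

test_that("attribution window runs to 30 days after treatment, or the day before SCT", {
  a <- assign_row("2021-01-01", "2021-02-01")
  w <- attribution_window(a)
  expect_equal(w$start, as.Date("2021-01-01"))
  expect_equal(w$end, as.Date("2021-03-03"))

  w2 <- attribution_window(a, sct_date = as.Date("2021-02-15"))
  expect_equal(w2$end, as.Date("2021-02-14"))

  # transplant rows themselves never extend the window
  both <- rbind(a, data.frame(patient_id = "P1", regimen = "Auto-SCT",
                              category = "HSCT",
                              start_date = as.Date("2021-06-01"),
                              end_date = as.Date("2021-06-01")))
  expect_equal(attribution_window(both)$end, as.Date("2021-03-03"))
  expect_error(attribution_window(both[2, , drop = FALSE]),
               "contract violation")
})

lab_row <- function(loinc, analyte, value, unit, date, pid = "P1") {
  data.frame(patient_id = pid, loinc_code = loinc, analyte_name = analyte,
             value = value, unit = unit,
             datetime = as.POSIXct(paste(date, "08:00:00"), tz = "UTC"),
             stringsAsFactors = FALSE)
}

test_that("baseline-relative lab rules fire only on in-window excursions", {
  win <- list(start = as.Date("2021-02-01"), end = as.Date("2021-03-15"))
  rule <- rules$acute_renal_failure
  labs <- rbind(
    lab_row("2160-0", "creatinine", 70, "umol/L", "2021-01-20"),   # baseline
    lab_row("2160-0", "creatinine", 150, "umol/L", "2021-02-10"))  # >1.5x
  s <- eval_lab_indicator(labs, rule, win, "acute_renal_failure")
  expect_equal(nrow(s), 1)
  expect_equal(s$date, as.Date("2021-02-10"))
  expect_equal(s$channel, "lab")

  # the same excursion before the window start: no signal
  labs$datetime[2] <- as.POSIXct("2021-01-25 08:00:00", tz = "UTC")
  expect_equal(nrow(eval_lab_indicator(labs, rule, win)), 0)

  # no baseline available: rule skipped
  expect_equal(nrow(eval_lab_indicator(labs[2, ], rule, win)), 0)
})

test_that("absolute lab thresholds fire at the configured CTCAE boundary", {
  win <- list(start = as.Date("2021-02-01"), end = as.Date("2021-03-15"))
  labs <- lab_row("1975-2", "total bilirubin", 80, "umol/L", "2021-02-20")
  s <- eval_lab_indicator(labs, rules$hepatic_toxicity, win, "hepatic_toxicity")
  expect_equal(nrow(s), 1)
  labs$value <- 40  # below threshold
  expect_equal(nrow(eval_lab_indicator(labs, rules$hepatic_toxicity, win)), 0)
})

test_that("unit mismatches between rule and lab row are evaluation errors", {
  win <- list(start = as.Date("2021-02-01"), end = as.Date("2021-03-15"))
  labs <- lab_row("1975-2", "total bilirubin", 4.7, "mg/dL", "2021-02-20")
  expect_error(eval_lab_indicator(labs, rules$hepatic_toxicity, win),
               "evaluation error.*unit")
})

test_that("drug trigger sets require all members within 3 days, inside the window", {
  win <- list(start = as.Date("2021-02-01"), end = as.Date("2021-03-15"))
  two_drug_rule <- list(drugs = list(list("J01DH02", "J01XD01")))
  p <- rbind(rx("P1", "J01DH02", "meropenem", 3, "2021-02-05", "2021-02-12"),
             rx("P1", "J01XD01", "metronidazole", 1.5, "2021-02-07", "2021-02-14"))
  expect_equal(nrow(eval_drug_indicator(p, two_drug_rule, win)), 1)

  p$start_date[2] <- as.Date("2021-02-10")  # 5 days apart: incomplete set
  expect_equal(nrow(eval_drug_indicator(p, two_drug_rule, win)), 0)

  # single-member set outside the window
  p2 <- rx("P1", "J01DH02", "meropenem", 3, "2021-01-05", "2021-01-12")
  expect_equal(nrow(eval_drug_indicator(p2, rules$sepsis, win)), 0)
  expect_equal(nrow(eval_drug_indicator(p2[0, ], rules$sepsis, win)), 0)
})

report_row <- function(text, date, pid = "P1") {
  data.frame(patient_id = pid,
             datetime = as.POSIXct(paste(date, "10:00:00"), tz = "UTC"),
             modality = "CT", text = text, stringsAsFactors = FALSE)
}

test_that("keyword scanning is whole-word, case-insensitive and negation-blind", {
  win <- list(start = as.Date("2021-02-01"), end = as.Date("2021-03-15"))
  rule <- rules$invasive_aspergillosis
  expect_equal(nrow(scan_reports(report_row(
    "Nodule suspect for Aspergillosis.", "2021-02-10"), rule, win)), 1)
  # negation is deliberately ignored
  expect_equal(nrow(scan_reports(report_row(
    "No evidence of aspergillosis.", "2021-02-10"), rule, win)), 1)
  # substring inside another word is not a whole-word hit
  expect_equal(nrow(scan_reports(report_row(
    "pseudoaspergillosisoid artifact", "2021-02-10"), rule, win)), 0)
  # outside the window
  expect_equal(nrow(scan_reports(report_row(
    "aspergillosis", "2021-04-20"), rule, win)), 0)
})

adm_row <- function(admit, discharge, main, secondary = "", icu = FALSE,
                    pid = "P1") {
  data.frame(patient_id = pid, admit_date = as.Date(admit),
             discharge_date = as.Date(discharge), main_icd10 = main,
             secondary_icd10 = secondary, icu = icu, stringsAsFactors = FALSE)
}

test_that("admission diagnoses signal on main or secondary codes overlapping the window", {
  win <- list(start = as.Date("2021-02-01"), end = as.Date("2021-03-15"))
  expect_equal(nrow(map_admissions(adm_row("2021-02-10", "2021-02-17", "A41.9"),
                                   rules$sepsis, win)), 1)
  s <- map_admissions(adm_row("2021-02-10", "2021-02-17", "Z51.1",
                              secondary = "J96.0;A41.9"), rules$sepsis, win)
  expect_equal(nrow(s), 1)
  # listed code outside the window
  expect_equal(nrow(map_admissions(adm_row("2021-04-01", "2021-04-07", "A41.9"),
                                   rules$sepsis, win)), 0)
  # ICU flag fires the ICU category regardless of codes
  expect_equal(nrow(map_admissions(adm_row("2021-02-10", "2021-02-17", "Z51.1",
                                           icu = TRUE),
                                   rules$icu_admission, win)), 1)
})

test_that("combine_findings keeps first dates and channel unions, order-invariantly", {
  s <- rbind(
    data.frame(patient_id = "P1", category = "sepsis",
               date = as.Date("2021-02-10"), channel = "drug", evidence = "a"),
    data.frame(patient_id = "P1", category = "sepsis",
               date = as.Date("2021-02-05"), channel = "admission", evidence = "b"),
    data.frame(patient_id = "P1", category = "hemorrhage",
               date = as.Date("2021-02-12"), channel = "keyword", evidence = "c"))
  f <- combine_findings(s)
  expect_equal(nrow(f), 2)
  sep <- f[f$category == "sepsis", ]
  expect_equal(sep$first_date, as.Date("2021-02-05"))
  expect_equal(sep$channels, "admission;drug")
  expect_identical(combine_findings(s[c(3, 1, 2), ]), f)   # order-invariant
  expect_identical(combine_findings(rbind(s, s)), f)       # idempotent
  expect_equal(nrow(combine_findings(s[0, ])), 0)
})

test_that("every planted toxicity event is signaled and no signal leaves its window", {
  plan <- rbind(
    toxicity_plan("acute_renal_failure", 2, "lab"),
    toxicity_plan("hepatic_toxicity", 2, "lab"),
    toxicity_plan("sepsis", 2, "drug"),
    toxicity_plan("icu_admission", 2, "admission"),
    toxicity_plan("invasive_aspergillosis", 1, "keyword"),
    toxicity_plan("venous_thrombosis", 1, "drug"))
  cfg <- generator_config(
    n_patients = c(AML = 12), regimen_plan = aml_study_plan()[1:2, ],
    toxicity_plan = plan, regimen_tumor_group = "AML",
    noise = FALSE, seed = 17)
  g <- generate_cohort(cfg, catalog = aml_regimen_catalog())
  tox <- detect_toxicity(g$dataset, catalog = aml_regimen_catalog())

  truth_keys <- paste(g$truth$toxicity$patient_id, g$truth$toxicity$category)
  found_keys <- paste(tox$findings$patient_id, tox$findings$category)
  expect_true(all(truth_keys %in% found_keys))         # sensitivity 1
  expect_true(all(found_keys %in% truth_keys))         # no FP with noise off

  for (i in seq_len(nrow(tox$signals))) {
    w <- tox$windows[[tox$signals$patient_id[i]]]
    expect_true(tox$signals$date[i] >= w$start && tox$signals$date[i] <= w$end)
  }
})

test_that("events are attributed within the 30-day boundary and cut at transplantation", {
  mkds <- function(event_date, sct_date = NULL) {
    cdm_dataset(
      patients = data.frame(patient_id = "P1", birth_year = 1960L,
                            sex = "male", resident_nl = TRUE),
      prescriptions = rbind(
        rx("P1", "L04AX04", "lenalidomide", 25, "2021-01-01", "2021-02-01"),
        rx("P1", "H02AB02", "dexamethasone", 40, "2021-01-01", "2021-02-01"),
        rx("P1", "J01DH02", "meropenem", 3, event_date, event_date)),
      sct = if (is.null(sct_date)) NULL else
        data.frame(patient_id = "P1", date = as.Date(sct_date), kind = "allo"))
  }
  n_sepsis <- function(ds) {
    tox <- detect_toxicity(ds, catalog = mm_regimen_catalog())
    sum(tox$signals$category == "sepsis")
  }
  expect_equal(n_sepsis(mkds("2021-03-03")), 1)  # exactly day 30 after end
  expect_equal(n_sepsis(mkds("2021-03-04")), 0)  # day 31: outside
  expect_equal(n_sepsis(mkds("2021-02-14", sct_date = "2021-02-15")), 1)
  expect_equal(n_sepsis(mkds("2021-02-15", sct_date = "2021-02-15")), 0)
})
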