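test_that("candidates surface exactly four weeks after first contact", {
  ds <- tiny_dataset()  # first contacts 2022-03-01 and 2022-06-01
  expect_equal(nrow(detect_candidates(ds, as.Date("2022-03-28"))), 0)  # 27 days
  c28 <- detect_candidates(ds, as.Date("2022-03-29"))                  # 28 days
  expect_equal(c28$patient_id, "P1")
  both <- detect_candidates(ds, as.Date("2022-06-29"))
  expect_equal(both$patient_id, c("P1", "P2"))  # sorted by first contact
  expect_equal(nrow(detect_candidates(cdm_dataset(), Sys.Date())), 0)
})

test_that("the earliest trajectory per patient and tumor group defines first contact", {
  ds <- tiny_dataset()
  ds$trajectories <- rbind(ds$trajectories, data.frame(
    trajectory_id = "T3", patient_id = "P1", hospital_id = "H2",
    start_date = as.Date("2022-05-01"), tumor_group = "AML"))
  cands <- detect_candidates(ds, as.Date("2023-01-01"))
  expect_equal(nrow(cands[cands$patient_id == "P1", ]), 1)
  expect_equal(cands$first_contact_date[cands$patient_id == "P1"],
               as.Date("2022-03-01"))
})

test_that("exclusion reasons follow residency > relapse > preliminary precedence", {
  ds <- tiny_dataset()
  # P1: non-resident AND an old confirmed diagnosis -> residency wins
  ds$patients$resident_nl[1] <- FALSE
  ds$diagnoses <- rbind(ds$diagnoses, data.frame(
    patient_id = "P1", icd10_code = "C92.0", date = as.Date("2019-01-01"),
    status = "confirmed", tumor_group = "AML"))
  # P2: old confirmed diagnosis -> relapse trajectory
  ds$diagnoses <- rbind(ds$diagnoses, data.frame(
    patient_id = "P2", icd10_code = "C92.0", date = as.Date("2020-05-01"),
    status = "confirmed", tumor_group = "AML"))
  cands <- detect_candidates(ds, as.Date("2023-01-01"))
  dec <- classify_inclusion(cands, ds, as.Date("2023-01-01"))
  expect_equal(dec$reason[dec$patient_id == "P1"], "NON_RESIDENT")
  expect_equal(dec$reason[dec$patient_id == "P2"], "RELAPSE_TRAJECTORY")
  expect_true(all((dec$decision == "include") == (dec$reason == "NONE")))
})

test_that("preliminary-only diagnoses exclude, confirmed new diagnoses include", {
  ds <- tiny_dataset()
  ds$diagnoses$status[1] <- "preliminary"
  dec <- classify_inclusion(detect_candidates(ds, as.Date("2023-01-01")), ds,
                            as.Date("2023-01-01"))
  expect_equal(dec$reason[dec$patient_id == "P1"], "PRELIMINARY_DIAGNOSIS")
  expect_equal(dec$decision[dec$patient_id == "P2"], "include")
})

test_that("classify_inclusion recovers every planted exclusion reason", {
  cfg <- generator_config(
    n_patients = c(AML = 30, lung = 40),
    exclusion_scenarios = c(non_resident = 4, relapse_trajectory = 6,
                            preliminary_diagnosis = 5),
    noise = FALSE, seed = 13)
  g <- generate_cohort(cfg)
  as_of <- max(g$dataset$trajectories$start_date) + 28
  dec <- classify_inclusion(detect_candidates(g$dataset, as_of), g$dataset, as_of)
  truth <- g$truth$inclusion
  m <- match(dec$patient_id, truth$patient_id)
  expect_equal(dec$decision, truth$decision[m])
  expect_equal(dec$reason, truth$reason[m])
})

test_that("retrospective matching categorizes registry records and partitions them", {
  ds <- tiny_dataset()  # P1 AML 2022, P2 AML 2022
  ds$trajectories$start_date[2] <- as.Date("2019-05-01")
  registry <- data.frame(
    patient_id = c("P1", "P1", "P1", "P9"),
    tumor_group = c("AML", "AML", "lung", "AML"),
    diagnosis_year = c(2022L, 2018L, 2022L, 2020L),
    hospital_id = "H1", stringsAsFactors = FALSE)
  rep <- retrospective_match(registry, ds)
  expect_equal(rep$category,
               c("matched_same_year", "year_mismatch", "diagnosis_mismatch",
                 "absent"))
  counts <- table(rep$category)
  expect_equal(sum(counts), nrow(registry))
})

test_that("decisions are a pure function of dataset and as-of date", {
  g <- generate_cohort(generator_config(
    n_patients = c(AML = 12),
    exclusion_scenarios = c(non_resident = 2), noise = FALSE, seed = 21))
  as_of <- max(g$dataset$trajectories$start_date) + 40
  d1 <- classify_inclusion(detect_candidates(g$dataset, as_of), g$dataset, as_of)
  d2 <- classify_inclusion(detect_candidates(g$dataset, as_of), g$dataset, as_of)
  expect_identical(d1, d2)
})
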