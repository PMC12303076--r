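test_that("a config with all counts zero yields an empty dataset and truth", {
  cfg <- generator_config(n_patients = c(AML = 0, lung = 0, MM = 0, breast = 0),
                          seed = 1)
  g <- generate_cohort(cfg)
  for (nm in cdm_table_set) expect_equal(nrow(g$dataset[[nm]]), 0)
  expect_equal(nrow(g$truth$inclusion), 0)
  expect_equal(nrow(g$truth$regimens), 0)
})

test_that("the same config and seed produce byte-identical datasets", {
  cfg <- generator_config(n_patients = c(AML = 8, MM = 6),
                          regimen_plan = regimen_plan("D-Rd", 4), seed = 11)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dataset(generate_cohort(cfg)$dataset, d1)
  write_dataset(generate_cohort(cfg)$dataset, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f), encoding = "UTF-8"),
                     readLines(file.path(d2, f), encoding = "UTF-8"),
                     info = f)
  }
})

test_that("a planted D-Rd regimen is realized as its three drugs co-started within one week", {
  cfg <- generator_config(n_patients = c(MM = 1),
                          regimen_plan = regimen_plan("D-Rd", 1),
                          noise = FALSE, seed = 3)
  g <- generate_cohort(cfg)
  p <- g$dataset$prescriptions
  expect_setequal(p$drug_name, c("daratumumab", "lenalidomide", "dexamethasone"))
  expect_lt(as.integer(max(p$start_date) - min(p$start_date)), 7)
  expect_equal(g$truth$regimens$regimen, "D-Rd")
})

test_that("every ground-truth fact references rows present in the dataset", {
  g <- small_clean_cohort(seed = 9, noise = TRUE)
  ids <- g$dataset$patients$patient_id
  expect_true(all(g$truth$inclusion$patient_id %in% ids))
  expect_true(all(g$truth$regimens$patient_id %in% ids))
  # planted regimen dates are recoverable from the prescriptions/sct tables
  for (i in seq_len(nrow(g$truth$regimens))) {
    tr <- g$truth$regimens[i, ]
    if (tr$category == "HSCT") {
      expect_true(any(g$dataset$sct$patient_id == tr$patient_id &
                        g$dataset$sct$date == tr$start_date))
    } else {
      p <- g$dataset$prescriptions
      expect_true(any(p$patient_id == tr$patient_id &
                        p$start_date == tr$start_date))
    }
  }
})

test_that("distinct planted regimen episodes are separated by more than the merge gap", {
  g <- small_clean_cohort(seed = 5)
  tr <- g$truth$regimens
  for (pid in unique(tr$patient_id)) {
    p <- tr[tr$patient_id == pid, ]
    p <- p[order(p$start_date), ]
    if (nrow(p) > 1) {
      gaps <- as.integer(p$start_date[-1] - p$end_date[-nrow(p)])
      expect_true(all(gaps >= 8))
    }
  }
})

test_that("make_failure_fixture validates scenario names and handles the empty list", {
  expect_error(make_failure_fixture("no_such_mode"), "config error")
  g <- make_failure_fixture(character(0))
  expect_equal(nrow(g$dataset$patients), 0)
})

test_that("corrupt_manual_labs perturbs exactly n rows, deterministically", {
  labs <- generate_cohort(generator_config(
    n_patients = c(breast = 4), routine_labs_per_patient = 10,
    noise = FALSE, seed = 2))$dataset$labs

  same <- corrupt_manual_labs(labs, 0, seed = 1)
  expect_identical(same$manual, labs)
  expect_length(same$typo_rows, 0)

  c1 <- corrupt_manual_labs(labs, 7, seed = 4)
  c2 <- corrupt_manual_labs(labs, 7, seed = 4)
  expect_identical(c1$manual, c2$manual)
  diff_rows <- which(c1$manual$value != labs$value)
  expect_equal(diff_rows, c1$typo_rows)
  expect_length(diff_rows, 7)
  # only values change, all other fields identical
  expect_identical(c1$manual[setdiff(names(labs), "value")],
                   labs[setdiff(names(labs), "value")])

  expect_error(corrupt_manual_labs(labs, nrow(labs) + 1, seed = 1),
               "config error")
})

test_that("infeasible plans are config errors", {
  expect_error(generator_config(
    n_patients = c(MM = 2),
    toxicity_plan = toxicity_plan("sepsis", 1, "drug")),
    "no treatment")
  expect_error(generator_config(
    n_patients = c(MM = 2),
    regimen_plan = regimen_plan("D-Rd", 1, failure_mode = "bogus")),
    "unknown failure_mode")
  expect_error(generate_cohort(generator_config(
    n_patients = c(MM = 1),
    regimen_plan = regimen_plan("Not-a-regimen", 1), seed = 1)),
    "not in catalog")
})
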