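test_that("identical config and seed give byte-identical output", {
  cfg <- generator_config(n_patients = 60, seed = 99)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1, g2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_tables(g1[c("patients", "centers", "logons", "results")], d1)
  write_tables(g2[c("patients", "centers", "logons", "results")], d2)
  for (f in c("patients.csv", "centers.csv", "logons.csv", "results.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("degenerate mixtures and invalid configs behave as specified", {
  cfg <- generator_config(
    n_patients = 50, seed = 1,
    class_mixture = c(never_logged_on = 1, early_lapser = 0,
                      late_lapser = 0, persistent_user = 0))
  g <- generate_cohort(cfg)
  expect_equal(nrow(g$logons), 0L)
  expect_true(all(g$ground_truth$true_class == "never_logged_on"))

  expect_error(generator_config(
    class_mixture = c(never_logged_on = 0.5, early_lapser = 0.2,
                      late_lapser = 0.2, persistent_user = 0.2)),
    "sum to 1")
  expect_error(generator_config(study_months = 12), "late lapsers")
})

test_that("a pure-baseline persistent cohort reproduces its Poisson rate", {
  cfg <- generator_config(
    n_patients = 600, seed = 21,
    class_mixture = c(never_logged_on = 0, early_lapser = 0,
                      late_lapser = 0, persistent_user = 1),
    logon_process = list(baseline_rate = 0.066, burst_rate = 0,
                         burst_days = 0, post_rate = 0, post_window_days = 0,
                         pre_rate = 0, pre_window_days = 0, rate_sdlog = 0))
  g <- generate_cohort(cfg)
  ap <- activity_profiles(g$patients, g$logons, as.Date("2009-09-07"),
                          "registration_to_census")
  target <- 0.066 * 30.4375
  se <- stats::sd(ap$logons_per_month) / sqrt(nrow(ap))
  expect_lt(abs(mean(ap$logons_per_month) - target), 3 * se)
})

test_that("hospital-HD result schedules average the configured interval", {
  g <- generate_cohort(generator_config(n_patients = 500, seed = 31))
  hosp <- g$patients$patient_id[g$patients$treatment == "hospital_hd"]
  gaps <- g$results |>
    dplyr::filter(patient_id %in% hosp) |>
    dplyr::group_by(patient_id) |>
    dplyr::reframe(gap = diff(as.numeric(sample_date))) |>
    dplyr::pull(gap)
  se <- stats::sd(gaps) / sqrt(length(gaps))
  expect_lt(abs(mean(gaps) - 30), 3 * se)
})

test_that("the classifier recovers generated lifecycle labels", {
  g <- generate_cohort(generator_config(n_patients = 800, seed = 41))
  cl <- classify_cohort(g$patients, g$logons, g$results,
                        as.Date("2009-09-07"))
  m <- dplyr::inner_join(cl, g$ground_truth, by = "patient_id")
  expect_gte(mean(as.character(m$usage_class) == m$true_class), 0.99)
})

test_that("post-result excess concentrates logons just after results", {
  mix <- c(never_logged_on = 0, early_lapser = 0, late_lapser = 0,
           persistent_user = 1)
  base <- list(baseline_rate = 0.05, burst_rate = 0, burst_days = 0,
               post_rate = 0, post_window_days = 0, pre_rate = 0,
               pre_window_days = 0, rate_sdlog = 0.3)
  excess <- base
  excess$post_rate <- 0.4
  excess$post_window_days <- 3
  g0 <- generate_cohort(generator_config(n_patients = 400, seed = 51,
                                         class_mixture = mix,
                                         logon_process = base))
  g1 <- generate_cohort(generator_config(n_patients = 400, seed = 51,
                                         class_mixture = mix,
                                         logon_process = excess))
  f0 <- headline_fractions(pooled_intervals(g0$logons, g0$results))
  f1 <- headline_fractions(pooled_intervals(g1$logons, g1$results))
  expect_gt(f1$frac_after_0_3, f0$frac_after_0_3)
})

test_that("YAML configs mirror the generator arguments", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_patients: 25",
    "seed: 7",
    "census_date: 2009-09-07",
    "class_mixture:",
    "  never_logged_on: 0.25",
    "  early_lapser: 0.25",
    "  late_lapser: 0.25",
    "  persistent_user: 0.25",
    "lapse_hazard: 0.1"), path)
  cfg <- generator_config_from_yaml(path)
  expect_s3_class(cfg, "generator_config")
  expect_equal(cfg$n_patients, 25L)
  expect_equal(unname(cfg$class_mixture["late_lapser"]), 0.25)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))

  writeLines("nonsense_field: 3", path)
  expect_error(generator_config_from_yaml(path), "unknown config field")
})

test_that("the activity fixture satisfies its eligibility filter by design", {
  fx <- make_activity_fixture()
  per <- dplyr::count(fx$logons, patient_id)
  expect_equal(nrow(per), 5808L)
  expect_true(all(per$n >= 3))
  expect_setequal(activity_eligible(fx$logons), fx$patients$patient_id)
})
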