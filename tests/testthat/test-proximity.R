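test_that("nearest-result intervals follow the sign and tie conventions", {
  expect_equal(nearest_result_interval(as.Date("2008-05-10"),
                                       as.Date("2008-05-10")), 0L)
  expect_equal(nearest_result_interval(as.Date("2008-05-08"),
                                       as.Date("2008-05-10")), -2L)
  d0 <- as.Date("2008-01-01")
  expect_equal(nearest_result_interval(d0 + 6, d0 + c(0, 10)), -4L)
  # equidistant tie resolves to the positive (after) interval
  expect_equal(nearest_result_interval(d0 + 5, d0 + c(0, 10)), 5L)
  expect_true(is.na(nearest_result_interval(d0, as.Date(character(0)))))
})

test_that("vectorized nearest intervals agree with a linear-scan oracle", {
  set.seed(123)
  d0 <- as.Date("2007-01-01")
  for (case in 1:40) {
    n_pat <- sample(1:6, 1)
    logons <- purrr::map_dfr(seq_len(n_pat), function(i) {
      mk_logons(paste0("P", i), d0 + sample(0:900, sample(1:12, 1)))
    })
    results <- purrr::map_dfr(seq_len(n_pat), function(i) {
      k <- sample(0:8, 1)
      if (k == 0) return(no_results())
      mk_results(paste0("P", i), d0 + sample(0:900, k))
    })
    got <- pooled_intervals(logons, results)
    want <- purrr::map_int(seq_len(nrow(logons)), function(j) {
      rd <- results$sample_date[results$patient_id == logons$patient_id[j]]
      as.integer(scan_nearest(
        as.numeric(as.Date(logons$timestamp[j], tz = "UTC")),
        as.numeric(rd)))
    })
    expect_identical(got, want)
    # single-patient path agrees too
    for (i in unique(logons$patient_id)) {
      expect_identical(
        nearest_result_interval(
          logons$timestamp[logons$patient_id == i],
          results$sample_date[results$patient_id == i]),
        got[logons$patient_id == i])
    }
  }
})

test_that("proximity histograms pool, bin and normalize as documented", {
  d0 <- as.Date("2008-01-01")
  logons <- mk_logons(c("P1", "P2"), c(d0 + 11, d0 + 31))
  results <- mk_results(c("P1", "P2"), c(d0 + 10, d0 + 30))
  h <- proximity_histogram(logons, results)
  expect_equal(h$bins$proportion[h$bins$bin_start == 1], 1)
  expect_equal(sum(h$bins$count), 2L)
  expect_equal(h$n_in_window, 2L)

  far <- mk_results(c("P1", "P2"), c(d0 + 300, d0 + 300))
  h2 <- proximity_histogram(logons, far)
  expect_equal(h2$n_in_window, 0L)
  expect_equal(h2$n_logons_total, 2L)

  # logons of a patient without results stay in the total denominator
  logons3 <- dplyr::bind_rows(logons, mk_logons("P3", d0 + 11))
  h3 <- proximity_histogram(logons3, results)
  expect_equal(h3$n_logons_total, 3L)
  expect_equal(sum(h3$bins$proportion), 2 / 3)

  expect_error(proximity_histogram(logons, no_results()), "no patient")
})

test_that("headline fractions use the stated half-open bins", {
  expect_equal(headline_fractions(c(0L, 0L, 5L))$frac_after_0_1, 2 / 3)
  expect_equal(headline_fractions(c(-1L, -2L, -3L))$frac_pre_3, 1)
  expect_equal(headline_fractions(c(20L, 25L, 40L))$frac_within_14, 0)
  expect_equal(headline_fractions(c(0L, 1L, 2L, 3L))$frac_after_0_3, 3 / 4)
  expect_error(headline_fractions(NA_integer_), "no defined")
})

test_that("a result-coupled cohort puts the histogram mode just after results", {
  mix <- c(never_logged_on = 0, early_lapser = 0, late_lapser = 0,
           persistent_user = 1)
  g <- generate_cohort(generator_config(
    n_patients = 300, seed = 71, class_mixture = mix,
    logon_process = list(baseline_rate = 0.01, burst_rate = 0,
                         burst_days = 0, post_rate = 0.5,
                         post_window_days = 3, pre_rate = 0,
                         pre_window_days = 0, rate_sdlog = 0)))
  h <- proximity_histogram(g$logons, g$results)
  expect_true(h$bins$bin_start[which.max(h$bins$count)] %in% 0:2)
})

test_that("the permutation null is reproducible and coherent", {
  mix <- c(never_logged_on = 0, early_lapser = 0, late_lapser = 0,
           persistent_user = 1)
  g <- generate_cohort(generator_config(n_patients = 120, seed = 81,
                                        class_mixture = mix))
  sn <- shuffle_null(g$logons, g$results, CENSUS, n_permutations = 100,
                     seed = 3)
  sn2 <- shuffle_null(g$logons, g$results, CENSUS, n_permutations = 100,
                      seed = 3)
  expect_identical(sn$bins, sn2$bins)
  expect_true(all(sn$bins$p >= 1 / 101 & sn$bins$p <= 1))
  expect_true(all(sn$bins$null_lo <= sn$bins$null_hi))
  # every null histogram preserves the logon count
  expect_true(all(abs(rowSums(sn$null_histograms) * nrow(g$logons) -
                        round(rowSums(sn$null_histograms) *
                                nrow(g$logons))) < 1e-9))
  expect_error(shuffle_null(g$logons, g$results, CENSUS,
                            n_permutations = 10), "at least 100")

  # the strongly coupled cohort rejects the [0,3) bins
  g2 <- generate_cohort(generator_config(
    n_patients = 200, seed = 91, class_mixture = mix,
    logon_process = list(baseline_rate = 0.01, burst_rate = 0,
                         burst_days = 0, post_rate = 0.5,
                         post_window_days = 3, pre_rate = 0,
                         pre_window_days = 0, rate_sdlog = 0)))
  sn3 <- shuffle_null(g2$logons, g2$results, CENSUS, n_permutations = 199,
                      seed = 5)
  expect_true(all(sn3$bins$p[sn3$bins$bin_start %in% 0:2] <= 1 / 100))
})

test_that("shuffling result dates also detects the coupling", {
  mix <- c(never_logged_on = 0, early_lapser = 0, late_lapser = 0,
           persistent_user = 1)
  g <- generate_cohort(generator_config(
    n_patients = 150, seed = 101, class_mixture = mix,
    logon_process = list(baseline_rate = 0.01, burst_rate = 0,
                         burst_days = 0, post_rate = 0.5,
                         post_window_days = 3, pre_rate = 0,
                         pre_window_days = 0, rate_sdlog = 0)))
  sn <- shuffle_null(g$logons, g$results, CENSUS, n_permutations = 199,
                     seed = 7, mode = "shuffle_results")
  expect_true(all(sn$bins$p[sn$bins$bin_start %in% 0:2] <= 0.05))
})
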