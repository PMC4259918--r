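test_that("a saturated 2x2 logistic fit reproduces the cross-product OR", {
  # cells {{10,20},{40,30}}: OR = (10*30)/(20*40) = 0.375
  fm <- fit_factor_model(expand_2x2(10, 20, 40, 30), "x")
  expect_equal(fm$table$odds_ratio, 0.375, tolerance = 1e-6)
  set.seed(15)
  for (case in 1:50) {
    cells <- sample(1:40, 4, replace = TRUE)
    fm <- fit_factor_model(do.call(expand_2x2, as.list(cells)), "x")
    want <- (cells[1] * cells[4]) / (cells[2] * cells[3])
    expect_equal(fm$table$odds_ratio, want, tolerance = 1e-6)
  }
})

test_that("degenerate designs raise explicit errors", {
  d <- expand_2x2(10, 0, 0, 10)   # outcome == exposure: separation
  expect_error(fit_factor_model(d, "x"), "separation")
  one <- tibble::tibble(outcome = rep(1L, 10),
                        x = factor(rep(c("a", "b"), 5)))
  expect_error(fit_factor_model(one, "x"), "single class")
})

test_that("reference levels carry OR 1 implicitly and orient the table", {
  set.seed(25)
  n <- 600
  d <- tibble::tibble(
    treatment = sample(c("hospital_hd", "transplant"), n, TRUE),
    outcome = rbinom(n, 1, 0.3))
  fm <- fit_factor_model(d, "treatment")
  expect_equal(fm$table$level, "transplant")   # hospital_hd is the reference
  expect_equal(nrow(fm$table), 1L)
})

test_that("backward elimination drops noise and keeps signal", {
  set.seed(35)
  n <- 3000
  x <- sample(c("lo", "hi"), n, TRUE)
  noise <- sample(letters[1:3], n, TRUE)
  p <- stats::plogis(-1 + 1 * (x == "hi"))
  d <- tibble::tibble(outcome = rbinom(n, 1, p),
                      x = x, noise = noise)
  el <- eliminate_factors(d, c("x", "noise"))
  expect_equal(el$retained, "x")
  expect_equal(el$removed$factor, "noise")

  # all-null factors collapse to the intercept-only model
  dn <- tibble::tibble(outcome = rbinom(n, 1, 0.4), x = x, noise = noise)
  eln <- eliminate_factors(dn, c("x", "noise"))
  expect_length(eln$retained, 0)
  expect_null(eln$model)

  # threshold extremes: alpha = 1 never drops; alpha = 0 drops everything
  expect_setequal(eliminate_factors(d, c("x", "noise"),
                                    alpha = 1)$retained, c("x", "noise"))
  expect_length(eliminate_factors(d, c("x", "noise"), alpha = 0)$retained, 0)
})

test_that("elimination is deterministic and final factors are significant", {
  set.seed(45)
  n <- 1500
  d <- tibble::tibble(
    outcome = rbinom(n, 1, 0.3),
    a = sample(c("u", "v"), n, TRUE),
    b = sample(c("p", "q", "r"), n, TRUE),
    c = sample(c("y", "z"), n, TRUE))
  d$outcome <- rbinom(n, 1, stats::plogis(-1 + 0.8 * (d$a == "v")))
  e1 <- eliminate_factors(d, c("a", "b", "c"))
  e2 <- eliminate_factors(d, c("a", "b", "c"))
  expect_identical(e1$retained, e2$retained)
  if (length(e1$retained)) {
    fit <- e1$model$fit
    dr <- stats::drop1(fit, test = "LRT")
    expect_true(all(dr[["Pr(>Chi)"]][-1] <= 0.05))
  }
})

test_that("hurdle cohorts select the documented comparison groups", {
  g <- generate_cohort(generator_config(n_patients = 400, seed = 55))
  cl <- classify_cohort(g$patients, g$logons, g$results, CENSUS,
                        classification_params(
                          cohort_restriction = "first_logon_3m"))
  truth <- g$ground_truth

  h1 <- build_hurdle_cohort(cl, g$patients, g$centers, CENSUS,
                            "not_complete_first_logon")
  expect_equal(sum(h1$data$outcome),
               sum(truth$true_class == "never_logged_on"))
  expect_equal(h1$n, 400L)

  h2 <- build_hurdle_cohort(cl, g$patients, g$centers, CENSUS, "early_lapse")
  expect_equal(h2$n, sum(cl$usage_class %in%
                           c("early_lapser", "late_lapser",
                             "persistent_user")))
  h3 <- build_hurdle_cohort(cl, g$patients, g$centers, CENSUS, "late_lapse")
  expect_false(any(
    h3$data$patient_id %in%
      cl$patient_id[cl$usage_class == "early_lapser"]))

  # complete-case dropping shrinks n without touching other outcomes
  pats <- g$patients
  pats$treatment[1] <- NA
  h1b <- build_hurdle_cohort(cl, pats, g$centers, CENSUS,
                             "not_complete_first_logon")
  expect_equal(h1b$n, 399L)
  expect_equal(h1b$n_dropped, 1L)
  keep <- intersect(h1$data$patient_id, h1b$data$patient_id)
  expect_equal(h1$data$outcome[match(keep, h1$data$patient_id)],
               h1b$data$outcome[match(keep, h1b$data$patient_id)])
})

test_that("reference-population comparisons match the Pearson formula", {
  r <- compare_to_reference(c(30L, 10L), c(100L, 100L))
  expect_equal(r$chi_square, 12.5)
  expect_equal(r$proportions, c(0.3, 0.1))

  eq <- compare_to_reference(c(50L, 25L), c(200L, 100L))
  expect_lt(eq$chi_square, 1e-9)
  expect_equal(eq$p, 1, tolerance = 1e-6)

  set.seed(65)
  for (case in 1:25) {
    k <- sample(2:5, 1)
    pop <- sample(50:500, k)
    reg <- vapply(pop, function(m) sample(1:(m - 1), 1), 1L)
    r <- compare_to_reference(reg, pop)
    expect_equal(r$chi_square, pearson_chisq(cbind(reg, pop - reg)),
                 tolerance = 1e-9)
  }

  single <- compare_to_reference(10L, 50L)
  expect_equal(single$df, 0L)
  expect_true(is.na(single$chi_square))
  expect_error(compare_to_reference(60L, 50L), "exceeds")
})
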