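# Small in-code builders shared across tests.

CENSUS <- as.Date("2009-09-07")

mk_patient <- function(id = "P1", reg = CENSUS - 365, age = 50,
                       gender = "male", treatment = "transplant",
                       decile = 5L, center = "C1") {
  tibble::tibble(patient_id = id, registration_date = as.Date(reg),
                 age_years = age, gender = gender, treatment = treatment,
                 deprivation_decile = as.integer(decile), center_id = center)
}

mk_center <- function(id = "C1", start = CENSUS - 1000, assisted = FALSE,
                      rrt_pop = 100L) {
  tibble::tibble(center_id = id, rpv_start_date = as.Date(start),
                 assisted_start = assisted, rrt_population = rrt_pop)
}

mk_logons <- function(id, dates, hour = 10) {
  tibble::tibble(
    patient_id = rep(id, length.out = length(dates)),
    timestamp = as.POSIXct(as.numeric(as.Date(dates)) * 86400 + hour * 3600,
                           origin = "1970-01-01", tz = "UTC"))
}

mk_results <- function(id, dates) {
  tibble::tibble(patient_id = rep(id, length.out = length(dates)),
                 sample_date = as.Date(dates))
}

no_logons <- function() mk_logons(character(0), as.Date(character(0)))
no_results <- function() mk_results(character(0), as.Date(character(0)))

# Independent oracle: empirical survival over uncensored event times.
empirical_survival <- function(times, t) mean(times > t)

# Independent oracle: linear-scan nearest signed interval, positive ties.
scan_nearest <- function(day, result_days) {
  if (length(result_days) == 0) return(NA_integer_)
  d <- day - result_days
  best <- min(abs(d))
  cand <- d[abs(d) == best]
  if (any(cand >= 0)) best else -best
}

# Independent oracle: Pearson chi-square by the textbook formula.
pearson_chisq <- function(tab) {
  exp_ <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - exp_)^2 / exp_)
}

# Expand a 2x2 table to patient rows. Cells in reading order
# {{a, b}, {c, d}} with rows = exposure (x0, x1) and cols = outcome (0, 1),
# so the logistic coefficient for x1 vs x0 satisfies OR = (a*d)/(b*c).
expand_2x2 <- function(a, b, c, d) {
  tibble::tibble(
    outcome = c(rep(0L, a), rep(1L, b), rep(0L, c), rep(1L, d)),
    x = factor(c(rep("x0", a + b), rep("x1", c + d)), levels = c("x0", "x1")))
}
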