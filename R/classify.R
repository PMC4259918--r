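#' Classification parameters
#'
#' Bundles the tunable thresholds of the five-way lifecycle classification.
#'
#' @param min_followup_months Minimum registration-to-census follow-up
#'   (months) required for classification under the `registration_6m`
#'   restriction; shorter follow-up yields `insufficient_follow_up`.
#' @param early_window_days The "first month" window after registration
#'   (exact days, boundary inclusive): a patient whose every logon falls
#'   within this window is an early lapser.
#' @param late_gap_months Minimum gap (months) from last logon to census for
#'   the late-lapse rule; a gap of exactly this many months counts as lapsed.
#' @param late_min_results Minimum number of result uploads dated strictly
#'   after the last logon required to call the lapse informative (the patient
#'   is alive and still monitored).
#' @param cohort_restriction Which patients are classifiable at all:
#'   `"registration_6m"` (default) excludes patients enrolled within
#'   `min_followup_months` of census; `"first_logon_3m"` restricts to patients
#'   whose *first logon* predates census by more than `restriction_months`
#'   months (used for the lapse analyses; patients with no logon fail this
#'   restriction and are reported as `insufficient_follow_up`).
#' @param restriction_months Months for the `first_logon_3m` restriction.
#' @param month_days Days per month for interval arithmetic.
#' @return A list of class `classification_params`.
#' @export
classification_params <- function(min_followup_months = 6,
                                  early_window_days = 30,
                                  late_gap_months = 6,
                                  late_min_results = 2L,
                                  cohort_restriction = c("registration_6m",
                                                         "first_logon_3m"),
                                  restriction_months = 3,
                                  month_days = MONTH_DAYS) {
  cohort_restriction <- match.arg(cohort_restriction)
  stopifnot(min_followup_months > 0, early_window_days > 0,
            late_gap_months > 0, late_min_results > 0,
            restriction_months > 0, month_days > 0)
  structure(list(min_followup_months = min_followup_months,
                 early_window_days = early_window_days,
                 late_gap_months = late_gap_months,
                 late_min_results = as.integer(late_min_results),
                 cohort_restriction = cohort_restriction,
                 restriction_months = restriction_months,
                 month_days = month_days),
            class = "classification_params")
}

# Per-patient logon stream summary; safe on empty streams.
logon_stream_summary <- function(logons) {
  if (nrow(logons) == 0) {
    return(tibble::tibble(patient_id = character(0), n_logons = integer(0),
                          first_logon_date = as.Date(character(0)),
                          last_logon_date = as.Date(character(0))))
  }
  logons |>
    dplyr::mutate(date = as.Date(.data$timestamp, tz = "UTC")) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(n_logons = dplyr::n(),
                     first_logon_date = min(.data$date),
                     last_logon_date = max(.data$date), .groups = "drop")
}

#' First logon date of a patient's stream
#'
#' @param logons Tibble of one patient's logons (column `timestamp`), or a
#'   vector of timestamps.
#' @return The calendar date of the earliest logon, or `NA` for an empty
#'   stream.
#' @export
first_logon_date <- function(logons) {
  ts <- if (is.data.frame(logons)) logons$timestamp else logons
  if (length(ts) == 0) return(as.Date(NA))
  as.Date(min(ts), tz = "UTC")
}

#' Did a patient complete first logon?
#'
#' @param logons Tibble of one patient's logons, or a vector of timestamps.
#' @return `TRUE` iff the stream is non-empty.
#' @export
completed_first_logon <- function(logons) {
  ts <- if (is.data.frame(logons)) logons$timestamp else logons
  length(ts) > 0
}

#' Classify a cohort into the five lifecycle classes
#'
#' Applies the lifecycle rules to every patient, in strict priority order:
#'
#' 1. **insufficient_follow_up** -- the patient fails the cohort restriction
#'    (too little time since registration, or -- under `first_logon_3m` --
#'    no first logon more than `restriction_months` months before census);
#' 2. **never_logged_on** -- zero logons;
#' 3. **early_lapser** -- every logon within `early_window_days` exact days
#'    of registration (day 30 counts as within);
#' 4. **late_lapser** -- no logon in the `late_gap_months` before census
#'    (a gap of exactly the threshold counts as lapsed) *and* at least
#'    `late_min_results` result uploads dated strictly after the last logon
#'    (a result on the day of the last logon does not count);
#' 5. **persistent_user** -- all other patients.
#'
#' A patient satisfying both the early and the late rule is an early lapser
#' (priority order).
#'
#' @param patients Patients tibble (see [read_tables()]).
#' @param logons,results Event tibbles for the whole cohort.
#' @param census Census date (`Date` or ISO string); all analyses are frozen
#'   at this date.
#' @param params A [classification_params()] object.
#' @return Tibble with one row per patient: `patient_id`, `usage_class`
#'   (factor over the five classes), `n_logons`, `first_logon_date`,
#'   `last_logon_date`.
#' @seealso [class_counts()] for the category counts and percentages.
#' @export
classify_cohort <- function(patients, logons, results, census,
                            params = classification_params()) {
  census <- as.Date(census)
  if (any(patients$registration_date > census)) {
    stop("census date precedes registration for patient(s): ",
         paste(head(patients$patient_id[patients$registration_date > census],
                    5), collapse = ", "), call. = FALSE)
  }

  logon_summary <- logon_stream_summary(logons)

  df <- patients |>
    dplyr::select("patient_id", "registration_date") |>
    dplyr::left_join(logon_summary, by = "patient_id") |>
    dplyr::mutate(n_logons = dplyr::coalesce(.data$n_logons, 0L))

  df <- df |>
    dplyr::left_join(
      results |>
        dplyr::inner_join(dplyr::select(df, "patient_id", "last_logon_date"),
                          by = "patient_id") |>
        dplyr::filter(!is.na(.data$last_logon_date),
                      .data$sample_date > .data$last_logon_date) |>
        dplyr::count(.data$patient_id, name = "n_results_after"),
      by = "patient_id") |>
    dplyr::mutate(n_results_after = dplyr::coalesce(.data$n_results_after, 0L))

  md <- params$month_days
  insufficient <- if (params$cohort_restriction == "registration_6m") {
    as.numeric(census - df$registration_date) <
      params$min_followup_months * md
  } else {
    is.na(df$first_logon_date) |
      as.numeric(census - df$first_logon_date) <=
        params$restriction_months * md
  }
  early <- !is.na(df$last_logon_date) &
    as.numeric(df$last_logon_date - df$registration_date) <=
      params$early_window_days
  late <- !is.na(df$last_logon_date) &
    as.numeric(census - df$last_logon_date) >= params$late_gap_months * md &
    df$n_results_after >= params$late_min_results

  cls <- dplyr::case_when(
    insufficient ~ "insufficient_follow_up",
    df$n_logons == 0L ~ "never_logged_on",
    early ~ "early_lapser",
    late ~ "late_lapser",
    TRUE ~ "persistent_user"
  )
  tibble::tibble(patient_id = df$patient_id,
                 usage_class = factor(cls, levels = USAGE_CLASSES),
                 n_logons = df$n_logons,
                 first_logon_date = df$first_logon_date,
                 last_logon_date = df$last_logon_date)
}

#' Classify a single patient
#'
#' Single-patient wrapper around [classify_cohort()].
#'
#' @param patient One-row patients tibble (or list with `patient_id` and
#'   `registration_date`).
#' @param logons,results The patient's event tibbles.
#' @inheritParams classify_cohort
#' @return A single usage-class string.
#' @export
classify_user <- function(patient, logons, results, census,
                          params = classification_params()) {
  patient <- tibble::as_tibble(patient[c("patient_id", "registration_date")])
  stopifnot(nrow(patient) == 1)
  if (as.Date(census) < patient$registration_date) {
    stop("census date precedes registration", call. = FALSE)
  }
  res <- classify_cohort(patient, logons, results, census, params)
  as.character(res$usage_class)
}

#' Category counts and percentages
#'
#' Tallies a classification result. `pct` is the share of all patients;
#' `pct_classified` is the share of the classified cohort (patients passing
#' the cohort restriction, i.e. excluding `insufficient_follow_up`), the
#' denominator used for the lapse-analysis percentages.
#'
#' @param classes Output of [classify_cohort()].
#' @param digits Decimal places for percentages (default 2).
#' @return Tibble `usage_class`, `n`, `pct`, `pct_classified`.
#' @export
class_counts <- function(classes, digits = 2) {
  n_total <- nrow(classes)
  tab <- table(classes$usage_class)
  n_classified <- n_total - tab[["insufficient_follow_up"]]
  tibble::tibble(
    usage_class = factor(names(tab), levels = USAGE_CLASSES),
    n = as.integer(tab),
    pct = if (n_total > 0) round(100 * as.integer(tab) / n_total, digits)
          else rep(NA_real_, length(tab)),
    pct_classified = ifelse(
      names(tab) == "insufficient_follow_up", NA_real_,
      if (n_classified > 0)
        round(100 * as.integer(tab) / n_classified, digits)
      else NA_real_)
  )
}
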