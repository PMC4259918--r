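#' Logon-intensity profiles
#'
#' Computes logons per month for every eligible patient under one of two
#' denominators:
#'
#' * `registration_to_census` -- total logons divided by the months between
#'   registration and census (any patient with at least one logon is
#'   eligible);
#' * `first_to_last_logon` -- total logons divided by the months spanned from
#'   first to last logon, restricted to patients with at least `min_logons`
#'   logons spanning at least `min_span_months` months.
#'
#' Patients failing the eligibility rules (including a zero-length
#' denominator) are excluded, not errors; their ids are attached as the
#' `"excluded"` attribute of the result.
#'
#' @inheritParams classify_cohort
#' @param denominator Which rate denominator to use (see Details).
#' @param min_logons,min_span_months Eligibility for the span denominator.
#' @param month_days Days per month.
#' @return Tibble `patient_id`, `logons_total`, `denominator_months`,
#'   `logons_per_month`, `log_lpm` (natural log), with attribute `excluded`
#'   (character vector of excluded patient ids). The `denominator` used is
#'   attached as an attribute as well.
#' @export
activity_profiles <- function(patients, logons, census,
                              denominator = c("registration_to_census",
                                              "first_to_last_logon"),
                              min_logons = 3L, min_span_months = 3,
                              month_days = MONTH_DAYS) {
  denominator <- match.arg(denominator)
  census <- as.Date(census)
  if (nrow(logons) == 0) {
    out <- tibble::tibble(patient_id = character(0), logons_total = integer(0),
                          denominator_months = double(0),
                          logons_per_month = double(0), log_lpm = double(0))
    attr(out, "excluded") <- patients$patient_id
    attr(out, "denominator") <- denominator
    return(out)
  }
  summ <- logons |>
    dplyr::mutate(date = as.Date(.data$timestamp, tz = "UTC")) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(logons_total = dplyr::n(),
                     first = min(.data$date), last = max(.data$date),
                     .groups = "drop") |>
    dplyr::inner_join(dplyr::select(patients, "patient_id",
                                    "registration_date"),
                      by = "patient_id")

  if (denominator == "registration_to_census") {
    summ <- dplyr::mutate(
      summ,
      denominator_months =
        as.numeric(census - .data$registration_date) / month_days,
      eligible = .data$denominator_months > 0)
  } else {
    summ <- dplyr::mutate(
      summ,
      denominator_months = as.numeric(.data$last - .data$first) / month_days,
      eligible = .data$logons_total >= min_logons &
        .data$denominator_months >= min_span_months)
  }

  excluded <- c(setdiff(patients$patient_id, summ$patient_id),
                summ$patient_id[!summ$eligible])
  out <- summ |>
    dplyr::filter(.data$eligible) |>
    dplyr::transmute(
      patient_id = .data$patient_id,
      logons_total = .data$logons_total,
      denominator_months = .data$denominator_months,
      logons_per_month = .data$logons_total / .data$denominator_months,
      log_lpm = log(.data$logons_per_month))
  attr(out, "excluded") <- excluded
  attr(out, "denominator") <- denominator
  out
}

#' Patient ids meeting the activity-analysis eligibility filter
#'
#' At least `min_logons` logons spanning at least `min_span_months` months
#' between first and last logon.
#'
#' @param logons Cohort logons tibble.
#' @inheritParams activity_profiles
#' @return Character vector of eligible patient ids.
#' @export
activity_eligible <- function(logons, min_logons = 3L, min_span_months = 3,
                              month_days = MONTH_DAYS) {
  if (nrow(logons) == 0) return(character(0))
  logons |>
    dplyr::mutate(date = as.Date(.data$timestamp, tz = "UTC")) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(n = dplyr::n(),
                     span = as.numeric(max(.data$date) - min(.data$date)),
                     .groups = "drop") |>
    dplyr::filter(.data$n >= min_logons,
                  .data$span >= min_span_months * month_days) |>
    dplyr::pull("patient_id")
}

# Rank-based quartile assignment: order by value then id (stable tie-break),
# split ranks into four near-equal parts (sizes differ by at most 1).
rank_quartile <- function(x, ids) {
  n <- length(x)
  r <- integer(n)
  r[order(x, ids)] <- seq_len(n)
  ceiling(4 * r / n)
}

#' Assign activity quartiles
#'
#' Classifies patients by the quartile of their log(logons per month) within
#' the analyzed cohort (Q4 = heaviest use). Cut points are the empirical
#' 25/50/75 percentiles; a value falling exactly on a cut point goes to the
#' lower quartile, and ties are broken by stable patient-id order, so the
#' four quartiles always partition the cohort into parts whose sizes differ
#' by at most one.
#'
#' @param profiles Tibble from [activity_profiles()].
#' @return `profiles` with a `quartile` factor column (`Q1`..`Q4`).
#' @export
quartile_classify <- function(profiles) {
  if (nrow(profiles) < 4) {
    stop("quartile classification needs at least 4 patients", call. = FALSE)
  }
  q <- rank_quartile(profiles$log_lpm, profiles$patient_id)
  dplyr::mutate(profiles,
                quartile = factor(paste0("Q", q),
                                  levels = paste0("Q", 1:4)))
}

#' Flag the most active fraction of users
#'
#' Flags the `ceiling(fraction * n)` patients with the highest logons per
#' month (ties broken by patient id, so the flagged set is invariant to
#' input order).
#'
#' @param profiles Tibble from [activity_profiles()].
#' @param fraction Fraction to flag (default 0.05, the top 5%).
#' @return `profiles` with a logical `top5` column.
#' @export
top_fraction_flag <- function(profiles, fraction = 0.05) {
  n <- nrow(profiles)
  if (n < 1 / fraction) {
    stop("cohort smaller than 1/fraction; nothing to flag", call. = FALSE)
  }
  k <- ceiling(fraction * n)
  r <- integer(n)
  r[order(-profiles$logons_per_month, profiles$patient_id)] <- seq_len(n)
  dplyr::mutate(profiles, top5 = r <= k)
}

#' Weekday and hour-of-day logon histograms
#'
#' Tallies logons by day of week (Monday first) and by hour of day (0-23).
#' Both histograms conserve mass: each sums to the number of logons.
#' Date-only timestamps carry no usable time-of-day, so the hour histogram is
#' refused for them.
#'
#' @param logons Cohort logons tibble with POSIXct `timestamp`.
#' @return List with tibbles `weekday` (`weekday`, `label`, `count`) and
#'   `hour` (`hour`, `count`).
#' @export
time_histograms <- function(logons) {
  if (!inherits(logons$timestamp, "POSIXt")) {
    stop("timestamps are date-only: the hour histogram needs time-of-day",
         call. = FALSE)
  }
  wd <- lubridate::wday(logons$timestamp, week_start = 1)
  hr <- lubridate::hour(logons$timestamp)
  list(
    weekday = tibble::tibble(
      weekday = 1:7,
      label = c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"),
      count = as.integer(table(factor(wd, levels = 1:7)))),
    hour = tibble::tibble(
      hour = 0:23,
      count = as.integer(table(factor(hr, levels = 0:23))))
  )
}
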