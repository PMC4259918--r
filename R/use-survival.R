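#' Use durations with event-derived right-censoring
#'
#' A patient's portal use is taken to begin at the first logon and end at the
#' last logon. The duration is right-censored (still in use) when the last
#' logon is consistent with continuing use: either it falls within
#' `censor_gap_months` of the census date, or it is older but fewer than
#' `censor_min_results` result uploads are dated strictly after it (follow-up
#' too infrequent to infer abandonment; this branch also censors patients who
#' used the portal up to death). Patients with no logon are omitted -- use
#' duration is undefined for them.
#'
#' @inheritParams classify_cohort
#' @param censor_gap_months Recency window before census within which a last
#'   logon is treated as ongoing use (boundary inclusive).
#' @param censor_min_results Result uploads strictly after the last logon
#'   needed before a stale last logon is treated as a true stop.
#' @param month_days Days per month for duration arithmetic.
#' @return Tibble `patient_id`, `start_date`, `end_date`, `duration_months`,
#'   `censored` (TRUE = still in use at census).
#' @export
use_durations <- function(patients, logons, results, census,
                          censor_gap_months = 6, censor_min_results = 2L,
                          month_days = MONTH_DAYS) {
  census <- as.Date(census)
  if (nrow(logons) == 0) {
    stop("no logons: use duration is undefined for every patient",
         call. = FALSE)
  }
  span <- logons |>
    dplyr::mutate(date = as.Date(.data$timestamp, tz = "UTC")) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(start_date = min(.data$date),
                     end_date = max(.data$date), .groups = "drop") |>
    dplyr::semi_join(patients, by = "patient_id")

  after <- results |>
    dplyr::inner_join(dplyr::select(span, "patient_id", "end_date"),
                      by = "patient_id") |>
    dplyr::filter(.data$sample_date > .data$end_date) |>
    dplyr::count(.data$patient_id, name = "n_results_after")

  span |>
    dplyr::left_join(after, by = "patient_id") |>
    dplyr::mutate(
      n_results_after = dplyr::coalesce(.data$n_results_after, 0L),
      duration_months =
        as.numeric(.data$end_date - .data$start_date) / month_days,
      censored =
        as.numeric(census - .data$end_date) <= censor_gap_months * month_days |
        .data$n_results_after < censor_min_results) |>
    dplyr::select("patient_id", "start_date", "end_date", "duration_months",
                  "censored")
}

#' Product-limit survival of continuing portal use
#'
#' Kaplan-Meier estimate over use durations, with Greenwood-variance,
#' log-transformed 95% pointwise confidence limits (via
#' [survival::survfit()]). At tied times events precede censorings. The curve
#' starts at `S(0) = 1`; an all-censored input yields a flat curve at 1.
#'
#' @param durations Tibble from [use_durations()] (needs `duration_months`
#'   and `censored`).
#' @return Tibble `time` (months, ascending, starting at 0), `n_risk`,
#'   `survival`, `ci_low`, `ci_high`.
#' @export
km_estimate <- function(durations) {
  if (is.null(durations) || nrow(durations) == 0) {
    stop("km_estimate needs at least one duration", call. = FALSE)
  }
  fit <- survival::survfit(
    survival::Surv(durations$duration_months, !durations$censored) ~ 1,
    conf.type = "log", conf.int = 0.95)
  surv <- fit$surv
  lo <- ifelse(is.na(fit$lower), ifelse(surv == 0, 0, surv), fit$lower)
  hi <- ifelse(is.na(fit$upper), ifelse(surv == 0, 0, surv), fit$upper)
  tibble::tibble(
    time = c(0, fit$time),
    n_risk = c(nrow(durations), fit$n.risk),
    survival = c(1, surv),
    ci_low = c(1, pmin(lo, surv)),
    ci_high = c(1, pmax(hi, surv)))
}

#' Survival curves by factor level
#'
#' Splits durations by a covariate and fits one product-limit curve per
#' level (complete-case: patients missing the covariate are dropped).
#'
#' @param durations Tibble from [use_durations()].
#' @param covariates Tibble with `patient_id` and the factor column (e.g.
#'   from [patient_covariates()]).
#' @param factor_name Name of the covariate column.
#' @return Tibble of stacked curves with `level` and per-level `n` columns.
#' @export
survival_by_group <- function(durations, covariates, factor_name) {
  if (!factor_name %in% names(covariates)) {
    stop("unknown factor: ", factor_name, call. = FALSE)
  }
  df <- durations |>
    dplyr::inner_join(
      dplyr::select(covariates, "patient_id",
                    level = dplyr::all_of(factor_name)),
      by = "patient_id") |>
    dplyr::filter(!is.na(.data$level))
  if (nrow(df) == 0) stop("no complete-case durations", call. = FALSE)
  df |>
    dplyr::group_by(.data$level) |>
    dplyr::group_modify(function(d, key) {
      dplyr::mutate(km_estimate(d), n = nrow(d))
    }) |>
    dplyr::ungroup()
}

#' Annualized attrition between two points of a survival curve
#'
#' Evaluates the step function at `from_months` and `to_months` and returns
#' the drop in the probability of continuing use per year:
#' `(S(from) - S(to)) / ((to - from) / 12)`.
#'
#' The curve may come from [km_estimate()] or be assembled directly from a
#' published series of `(time, survival)` values.
#'
#' @param curve Tibble with ascending `time` (months) and `survival`.
#' @param from_months,to_months Evaluation times, `from < to`, both within
#'   the curve's support.
#' @return Attrition probability per year.
#' @examples
#' printed <- tibble::tibble(time = c(6, 12, 18, 24, 30),
#'                           survival = c(0.61, 0.58, 0.56, 0.54, 0.52))
#' attrition_rate(printed, 6, 30) # 0.045 per year
#' @export
attrition_rate <- function(curve, from_months, to_months) {
  stopifnot(is.numeric(from_months), is.numeric(to_months))
  if (from_months >= to_months) {
    stop("from_months must be smaller than to_months", call. = FALSE)
  }
  if (from_months < min(curve$time) || to_months > max(curve$time)) {
    stop("evaluation times outside the curve's support", call. = FALSE)
  }
  s_at <- function(t) {
    curve$survival[findInterval(t, curve$time)]
  }
  (s_at(from_months) - s_at(to_months)) / ((to_months - from_months) / 12)
}

#' Patient-level covariate table
#'
#' Convenience builder joining the banded patient covariates (and, when
#' `centers` is supplied, the center covariates of [center_covariates()])
#' for use in [survival_by_group()] and the factor models.
#'
#' @inheritParams classify_cohort
#' @param centers Optional centers tibble.
#' @param census Census date, required when `centers` is supplied.
#' @return Tibble keyed by `patient_id` with `age_band`, `gender`,
#'   `treatment`, `deprivation_group` and any center covariates.
#' @export
patient_covariates <- function(patients, centers = NULL, census = NULL) {
  out <- patients |>
    dplyr::transmute(
      patient_id = .data$patient_id,
      age_band = age_band(.data$age_years),
      gender = factor(.data$gender, levels = GENDERS),
      treatment = factor(.data$treatment, levels = TREATMENTS),
      deprivation_group = deprivation_group(.data$deprivation_decile),
      center_id = .data$center_id)
  if (!is.null(centers)) {
    stopifnot(!is.null(census))
    out <- dplyr::left_join(out,
                            center_covariates(patients, centers, census),
                            by = "center_id")
  }
  out
}
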