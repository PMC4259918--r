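#' Deterministic fixture realizing the published cohort flow
#'
#' Builds, without any randomness, a full registry of 11,352 patients whose
#' event streams -- when run through [classify_cohort()] -- realize the
#' published cohort flow exactly: 2,634 registrants who never logged on;
#' 469 whose first logon fell within 3 months of census (excluded from the
#' lapse analyses); and, among the remaining 8,249 first-logon completers,
#' 822 early lapsers, 1,404 late lapsers and 6,023 persistent users. Every
#' late lapser's stream carries at least 2 result uploads and more than 6
#' months of silence before census; every persistent user has a logon within
#' 6 months of census.
#'
#' Covariates are assigned cyclically (they carry no signal; the fixture
#' exists to pin the classification arithmetic, not the associations).
#'
#' @param census_date Census date (default 2009-09-07).
#' @return Named list of `patients`, `centers`, `logons`, `results` tibbles.
#' @export
make_printed_cohort_fixture <- function(census_date = as.Date("2009-09-07")) {
  census <- as.Date(census_date)
  counts <- c(never = 2634L, recent = 469L, early = 822L,
              persistent = 6023L, late = 1404L)
  n <- sum(counts)
  group <- rep(names(counts), counts)
  within <- unlist(lapply(counts, seq_len), use.names = FALSE)

  reg_offset <- c(never = 400, recent = 100, early = 500,
                  persistent = 600, late = 700)[group] +
    dplyr::case_when(group == "never" ~ within %% 200,
                     group == "recent" ~ 0L,
                     group == "early" ~ within %% 100,
                     group == "persistent" ~ within %% 300,
                     group == "late" ~ within %% 200)
  reg <- census - reg_offset

  ids <- sprintf("P%05d", seq_len(n))
  n_centers <- 10L
  center_ids <- sprintf("C%02d", seq_len(n_centers))
  patients <- tibble::tibble(
    patient_id = ids,
    registration_date = reg,
    age_years = c(10, 25, 45, 65, 80)[(seq_len(n) %% 5) + 1],
    gender = c("male", "female")[(seq_len(n) %% 2) + 1],
    treatment = TREATMENTS[(seq_len(n) %% 4) + 1],
    deprivation_decile = as.integer((seq_len(n) %% 10) + 1),
    center_id = center_ids[(seq_len(n) %% n_centers) + 1])

  at <- function(dates, idx) {   # minute-resolution working-hours stamps
    as.POSIXct(as.numeric(dates) * 86400 + (9 + idx %% 10) * 3600 +
                 (idx %% 60) * 60, origin = "1970-01-01", tz = "UTC")
  }
  logon_spec <- list(
    recent = function(r, i) census - 70 - (i %% 20),
    early = function(r, i) list(r + 2, r + 20),
    persistent = function(r, i) list(r + 5, r + 100, r + 200, census - 40),
    late = function(r, i) list(r + 5, r + 50))
  logons <- purrr::imap_dfr(logon_spec, function(fn, g) {
    sel <- group == g
    days <- fn(reg[sel], within[sel])
    if (!is.list(days)) days <- list(days)
    purrr::map_dfr(days, function(d) {
      tibble::tibble(patient_id = ids[sel],
                     timestamp = at(d, within[sel]))
    })
  })

  result_spec <- list(
    never = c(60, 150), recent = c(30, 60), early = c(60, 120),
    persistent = c(30, 90), late = c(100, 200))
  results <- purrr::imap_dfr(result_spec, function(offsets, g) {
    sel <- group == g
    purrr::map_dfr(offsets, function(o) {
      tibble::tibble(patient_id = ids[sel], sample_date = reg[sel] + o)
    })
  })

  n_rrt <- patients |>
    dplyr::filter(.data$treatment %in% RRT_TREATMENTS) |>
    dplyr::count(.data$center_id) |>
    dplyr::pull("n", name = "center_id")
  centers <- tibble::tibble(
    center_id = center_ids,
    rpv_start_date = census - 1000,
    assisted_start = center_ids == "C01",
    rrt_population = as.integer(2 * n_rrt[center_ids]))

  validate_dataset(list(patients = patients, centers = centers,
                        logons = logons, results = results))
}

#' Deterministic fixture for the activity-analysis cohort
#'
#' Builds, without randomness, the 5,808-user activity cohort: every user
#' has at least three logons spanning at least 3 months after first logon,
#' of whom 5,085 satisfy the persistent-user rules at census and 723 the
#' late-lapse rules (no logon for over 6 months before census and at least
#' 2 result uploads after the last logon).
#'
#' @param census_date Census date (default 2009-09-07).
#' @return Named list of `patients`, `logons`, `results` tibbles.
#' @export
make_activity_fixture <- function(census_date = as.Date("2009-09-07")) {
  census <- as.Date(census_date)
  counts <- c(persistent = 5085L, late = 723L)
  n <- sum(counts)
  group <- rep(names(counts), counts)
  within <- unlist(lapply(counts, seq_len), use.names = FALSE)
  ids <- sprintf("A%05d", seq_len(n))
  reg <- census - 700 - (within %% 100)

  patients <- tibble::tibble(
    patient_id = ids,
    registration_date = reg,
    age_years = c(30, 50, 70)[(seq_len(n) %% 3) + 1],
    gender = c("male", "female")[(seq_len(n) %% 2) + 1],
    treatment = TREATMENTS[(seq_len(n) %% 4) + 1],
    deprivation_decile = as.integer((seq_len(n) %% 10) + 1),
    center_id = "C01")

  at <- function(dates, idx) {
    as.POSIXct(as.numeric(dates) * 86400 + (9 + idx %% 10) * 3600 +
                 (idx %% 60) * 60, origin = "1970-01-01", tz = "UTC")
  }
  p <- group == "persistent"
  logons <- dplyr::bind_rows(
    tibble::tibble(patient_id = ids[p], timestamp = at(reg[p] + 1, within[p])),
    tibble::tibble(patient_id = ids[p],
                   timestamp = at(reg[p] + 120, within[p])),
    tibble::tibble(patient_id = ids[p],
                   timestamp = at(census - 50, within[p])),
    tibble::tibble(patient_id = ids[!p],
                   timestamp = at(reg[!p] + 1, within[!p])),
    tibble::tibble(patient_id = ids[!p],
                   timestamp = at(reg[!p] + 60, within[!p])),
    tibble::tibble(patient_id = ids[!p],
                   timestamp = at(reg[!p] + 120, within[!p])))
  results <- dplyr::bind_rows(
    tibble::tibble(patient_id = ids[p], sample_date = reg[p] + 30),
    tibble::tibble(patient_id = ids[p], sample_date = reg[p] + 90),
    tibble::tibble(patient_id = ids[!p], sample_date = reg[!p] + 200),
    tibble::tibble(patient_id = ids[!p], sample_date = reg[!p] + 300))

  list(patients = patients,
       logons = dplyr::arrange(logons, .data$patient_id, .data$timestamp),
       results = dplyr::arrange(results, .data$patient_id,
                                .data$sample_date))
}
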