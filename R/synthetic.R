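#' Configuration for the synthetic cohort generator
#'
#' Parameterizes [generate_cohort()]. Defaults emulate the structure of a
#' mature national renal-portal registry: covariate frequencies matching the
#' registered population, a lifecycle-class mixture matching the observed
#' cohort flow, treatment-dependent blood-result schedules (roughly monthly
#' for hospital haemodialysis, 3-12-monthly otherwise), and logon streams
#' built as a superposition of piecewise-constant-intensity Poisson
#' components: a per-patient baseline (log-normal rate multipliers produce
#' the heavy-tailed activity observed in practice), an early
#' post-registration burst, an excess in the days following each result
#' upload, and a small bump in the days leading up to one.
#'
#' @param n_patients Number of patients.
#' @param census_date Census (extraction) date.
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   output.
#' @param study_months Length of the enrolment window before census
#'   (registrations span up to this many months before census).
#' @param covariate_frequencies List of named probability vectors for
#'   `age_band`, `gender`, `treatment` and `deprivation_decile` (names
#'   `"1"`..`"10"`).
#' @param n_centers,assisted_fraction Number of centers and the fraction
#'   (at least one) operating an assisted first logon.
#' @param class_mixture Named probabilities over `never_logged_on`,
#'   `early_lapser`, `late_lapser`, `persistent_user`; must sum to 1.
#' @param assisted_class_weights Named multipliers applied to the mixture
#'   weights for patients at assisted-start centers (then renormalized);
#'   the default down-weights never-logging-on.
#' @param result_schedule List with elements `hospital_hd` and `other`, each
#'   `c(min, max)` days: inter-result intervals are uniform on that range.
#' @param logon_process List: `baseline_rate` (logons/day),
#'   `burst_rate`/`burst_days` (early post-registration burst),
#'   `post_rate`/`post_window_days` (excess after each result),
#'   `pre_rate`/`pre_window_days` (bump before each result),
#'   `rate_sdlog` (sd of the log-normal per-patient rate multiplier, mean 1).
#' @param lapse_hazard Per-month stopping hazard for late lapsers (their
#'   stop date is drawn exponentially from 45 days after registration,
#'   truncated to the feasible window); `NULL` draws the stop date uniformly
#'   over the feasible window instead.
#' @param tod_weights Length-24 non-negative weights for logon hour-of-day;
#'   the default concentrates logons between 08:00 and 22:00.
#' @param month_days Days per month.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(
    n_patients = 2000L,
    census_date = as.Date("2009-09-07"),
    seed = 1L,
    study_months = 42,
    covariate_frequencies = list(
      age_band = c(lt18 = 0.016, a18_34 = 0.116, a35_54 = 0.379,
                   a55_74 = 0.389, gt75 = 0.100),
      gender = c(male = 0.599, female = 0.401),
      treatment = c(hospital_hd = 0.194, home_hd_pd = 0.067,
                    transplant = 0.328, not_rrt = 0.411),
      deprivation_decile = setNames(seq(0.06, 0.14, length.out = 10) /
                                      sum(seq(0.06, 0.14, length.out = 10)),
                                    as.character(1:10))),
    n_centers = 12L,
    assisted_fraction = 0.15,
    class_mixture = c(never_logged_on = 0.232, early_lapser = 0.072,
                      late_lapser = 0.124, persistent_user = 0.572),
    assisted_class_weights = c(never_logged_on = 0.31, early_lapser = 1,
                               late_lapser = 1, persistent_user = 1),
    result_schedule = list(hospital_hd = c(21, 39), other = c(90, 365)),
    logon_process = list(baseline_rate = 0.03, burst_rate = 0.25,
                         burst_days = 14, post_rate = 0.45,
                         post_window_days = 3, pre_rate = 0.10,
                         pre_window_days = 3, rate_sdlog = 0.7),
    lapse_hazard = 0.06,
    tod_weights = c(rep(0.1, 8), rep(1, 14), rep(0.1, 2)),
    month_days = MONTH_DAYS) {
  cfg <- list(n_patients = as.integer(n_patients),
              census_date = as.Date(census_date), seed = as.integer(seed),
              study_months = study_months,
              covariate_frequencies = covariate_frequencies,
              n_centers = as.integer(n_centers),
              assisted_fraction = assisted_fraction,
              class_mixture = class_mixture,
              assisted_class_weights = assisted_class_weights,
              result_schedule = result_schedule,
              logon_process = logon_process, lapse_hazard = lapse_hazard,
              tod_weights = tod_weights, month_days = month_days)
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$n_patients < 1) stop("n_patients must be positive", call. = FALSE)
  cm <- cfg$class_mixture
  expected <- c("never_logged_on", "early_lapser", "late_lapser",
                "persistent_user")
  if (!setequal(names(cm), expected)) {
    stop("class_mixture must be named over: ",
         paste(expected, collapse = ", "), call. = FALSE)
  }
  if (any(cm < 0) || any(cm > 1) || abs(sum(cm) - 1) > 1e-8) {
    stop("class_mixture probabilities must lie in [0,1] and sum to 1",
         call. = FALSE)
  }
  lp <- cfg$logon_process
  rates <- unlist(lp)
  if (any(rates < 0)) stop("logon_process values must be >= 0", call. = FALSE)
  if (cfg$study_months <= 7) {
    stop("study_months too short: census precedes feasible registrations",
         call. = FALSE)
  }
  if (cm[["late_lapser"]] > 0 && cfg$study_months * cfg$month_days < 540) {
    stop("study window too short for late lapsers (needs ~18 months)",
         call. = FALSE)
  }
  if (length(cfg$tod_weights) != 24 || any(cfg$tod_weights < 0)) {
    stop("tod_weights must be 24 non-negative values", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a generator configuration from YAML
#'
#' The YAML schema mirrors the [generator_config()] arguments field for
#' field; absent fields keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `generator_config`.
#' @export
generator_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(generator_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (nm in c("covariate_frequencies", "class_mixture",
               "assisted_class_weights")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist_keep(raw[[nm]])
  }
  if (!is.null(raw$result_schedule)) {
    raw$result_schedule <- lapply(raw$result_schedule, unlist)
  }
  do.call(generator_config, raw)
}

unlist_keep <- function(x) {
  if (is.list(x) && all(vapply(x, is.list, TRUE))) lapply(x, unlist)
  else unlist(x)
}

# Uniform-interval result schedules for a group of patients sharing one
# (lo, hi) range: first result at registration + phase, then cumulative
# uniform intervals, truncated at census.
draw_result_days <- function(reg_day, census_day, lo, hi) {
  n <- length(reg_day)
  if (n == 0) {
    return(tibble::tibble(idx = integer(), day = numeric()))
  }
  followup <- census_day - reg_day
  nmax <- max(2L, ceiling(max(followup) / lo) + 1L)
  gaps <- matrix(runif(n * nmax, lo, hi), nrow = n)
  gaps[, 1] <- runif(n, 0, hi)   # phase of the first result
  days <- reg_day + t(apply(gaps, 1, cumsum))
  keep <- days <= census_day
  tibble::tibble(idx = rep(seq_len(n), times = nmax)[as.vector(keep)],
                 day = as.vector(days)[as.vector(keep)])
}

# Poisson counts in windows [ws, we) at per-window rates, with uniform
# positions inside each window. Returns a numeric vector of event days.
pois_window_events <- function(ws, we, rate) {
  len <- pmax(we - ws, 0)
  counts <- rpois(length(len), rate * len)
  if (sum(counts) == 0) return(list(idx = integer(), day = numeric()))
  i <- rep(seq_along(counts), counts)
  list(idx = i, day = rep(ws, counts) + runif(sum(counts)) * rep(len, counts))
}

#' Generate a synthetic registry with ground-truth lifecycle labels
#'
#' Simulates patients, centers, result schedules and logon point processes
#' under a [generator_config()], together with the true lifecycle class of
#' every patient. Classes shape the logon stream: `never_logged_on` patients
#' make no logon; `early_lapser` logons are confined to the first ~25 days
#' after registration (safely inside the 30-day early-lapse rule);
#' `late_lapser` streams stop at a true stop date drawn so that at least 2
#' results and comfortably more than 6 months separate it from census;
#' `persistent_user` streams run to census with a guaranteed recent logon.
#' Margins are deliberately generated strictly inside the classification
#' rule boundaries so the classifier can recover the labels.
#'
#' @param config A [generator_config()].
#' @return Named list: `patients`, `centers`, `logons`, `results` (the four
#'   standard tables) and `ground_truth` (`patient_id`, `true_class`,
#'   `true_stop_date`).
#' @export
generate_cohort <- function(config) {
  validate_generator_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  census_day <- as.numeric(config$census_date)
  md <- config$month_days
  study_days <- round(config$study_months * md)
  cf <- config$covariate_frequencies

  ids <- sprintf("S%06d", seq_len(n))
  band <- sample(names(cf$age_band), n, TRUE, prob = cf$age_band)
  age_lo <- c(lt18 = 2, a18_34 = 18, a35_54 = 35, a55_74 = 55, gt75 = 75.5)
  age_hi <- c(lt18 = 17.9, a18_34 = 34.9, a35_54 = 54.9, a55_74 = 74.9,
              gt75 = 92)
  age <- round(runif(n, age_lo[band], age_hi[band]), 1)
  gender <- sample(names(cf$gender), n, TRUE, prob = cf$gender)
  treatment <- sample(names(cf$treatment), n, TRUE, prob = cf$treatment)
  decile <- as.integer(sample(names(cf$deprivation_decile), n, TRUE,
                              prob = cf$deprivation_decile))

  n_assisted <- max(1L, round(config$assisted_fraction * config$n_centers))
  center_ids <- sprintf("C%02d", seq_len(config$n_centers))
  assisted <- seq_len(config$n_centers) <= n_assisted
  center <- sample(center_ids, n, TRUE)

  # Lifecycle class: mixture, re-weighted at assisted-start centers.
  w_plain <- config$class_mixture
  w_assist <- w_plain * config$assisted_class_weights[names(w_plain)]
  w_assist <- w_assist / sum(w_assist)
  is_assisted <- assisted[match(center, center_ids)]
  cls <- character(n)
  cls[!is_assisted] <- sample(names(w_plain), sum(!is_assisted), TRUE,
                              prob = w_plain)
  cls[is_assisted] <- sample(names(w_assist), sum(is_assisted), TRUE,
                             prob = w_assist)

  # Registration: boundary-safe with respect to the 6-month follow-up rule;
  # late lapsers need room for a stop >= 7.4 months before census with >= 2
  # later results.
  reg_min <- census_day - study_days
  reg_day <- numeric(n)
  late <- cls == "late_lapser"
  reg_day[!late] <- floor(runif(sum(!late), reg_min, census_day - 210))
  reg_day[late] <- floor(runif(sum(late), reg_min, census_day - 480))

  # Result schedules by treatment.
  hosp <- treatment == "hospital_hd"
  rs <- config$result_schedule
  res_h <- draw_result_days(reg_day[hosp], census_day,
                            rs$hospital_hd[1], rs$hospital_hd[2])
  res_o <- draw_result_days(reg_day[!hosp], census_day,
                            rs$other[1], rs$other[2])
  res_pid <- c(which(hosp)[res_h$idx], which(!hosp)[res_o$idx])
  res_day <- floor(c(res_h$day, res_o$day))

  # True stop dates for late lapsers: exponential stopping hazard from 45
  # days post-registration (or uniform if no hazard), truncated to keep the
  # lapse unambiguous (>= 225 days before census).
  stop_day <- rep(NA_real_, n)
  if (any(late)) {
    lo <- reg_day[late] + 45
    hi <- census_day - 225
    stop_day[late] <- if (is.null(config$lapse_hazard)) {
      floor(runif(sum(late), lo, hi))
    } else {
      floor(pmin(lo + rexp(sum(late), config$lapse_hazard) * md, hi))
    }
  }

  # Guarantee >= 2 results strictly after each late lapser's stop.
  if (any(late)) {
    li <- which(late)
    has_stop <- !is.na(stop_day[res_pid])
    n_after <- tabulate(res_pid[has_stop & res_day > stop_day[res_pid]],
                        nbins = n)
    short <- li[n_after[li] < 2]
    if (length(short)) {
      res_pid <- c(res_pid, rep(short, each = 2))
      res_day <- c(res_day,
                   as.vector(rbind(stop_day[short] + 60,
                                   stop_day[short] + 120)))
    }
  }

  # Active logon window per class.
  lp <- config$logon_process
  w_start <- reg_day + 1
  w_end <- rep(NA_real_, n)
  w_end[cls == "persistent_user"] <- census_day
  w_end[cls == "early_lapser"] <- reg_day[cls == "early_lapser"] + 25
  w_end[late] <- stop_day[late]
  active <- !is.na(w_end)

  mult <- if (lp$rate_sdlog > 0) {
    rlnorm(n, meanlog = -lp$rate_sdlog^2 / 2, sdlog = lp$rate_sdlog)
  } else rep(1, n)

  logon_pid <- integer(0)
  logon_day <- numeric(0)
  add_events <- function(ev, idx_map) {
    logon_pid <<- c(logon_pid, idx_map[ev$idx])
    logon_day <<- c(logon_day, ev$day)
  }
  ai <- which(active)
  if (length(ai)) {
    add_events(pois_window_events(w_start[ai], w_end[ai],
                                  lp$baseline_rate * mult[ai]), ai)
    if (lp$burst_rate > 0 && lp$burst_days > 0) {
      add_events(pois_window_events(
        w_start[ai], pmin(reg_day[ai] + lp$burst_days, w_end[ai]),
        lp$burst_rate * mult[ai]), ai)
    }
    keep_r <- active[res_pid]
    if (lp$post_rate > 0 && lp$post_window_days > 0 && any(keep_r)) {
      rpid <- res_pid[keep_r]
      rday <- res_day[keep_r]
      add_events(pois_window_events(
        pmax(rday, w_start[rpid]),
        pmin(rday + lp$post_window_days, w_end[rpid]),
        lp$post_rate * mult[rpid]), rpid)
    }
    if (lp$pre_rate > 0 && lp$pre_window_days > 0 && any(keep_r)) {
      rpid <- res_pid[keep_r]
      rday <- res_day[keep_r]
      add_events(pois_window_events(
        pmax(rday - lp$pre_window_days, w_start[rpid]),
        pmin(rday, w_end[rpid]),
        lp$pre_rate * mult[rpid]), rpid)
    }
  }
  logon_day <- floor(logon_day)

  # Forced logons keeping every stream strictly inside its class rules:
  # early lapsers log on at least once; late lapsers' first/last logons pin
  # the span (registration + 1 .. stop); persistent users get a recent logon
  # only if the random components left a >150-day silent tail before census.
  ei <- which(cls == "early_lapser")
  ei_none <- setdiff(ei, unique(logon_pid))
  li <- which(late)
  pi <- which(cls == "persistent_user")
  recent <- unique(logon_pid[logon_day >= census_day - 150])
  pi_force <- setdiff(pi, recent)
  logon_pid <- c(logon_pid, ei_none, li, li, pi_force)
  logon_day <- c(logon_day, reg_day[ei_none] + 2, reg_day[li] + 1,
                 stop_day[li], rep(census_day - 21, length(pi_force)))

  logon_day <- pmax(logon_day, reg_day[logon_pid] + 1)

  hour <- sample(0:23, length(logon_day), TRUE, prob = config$tod_weights)
  minute <- sample(0:59, length(logon_day), TRUE)
  timestamp <- as.POSIXct(logon_day * 86400 + hour * 3600 + minute * 60,
                          origin = "1970-01-01", tz = "UTC")

  patients <- tibble::tibble(
    patient_id = ids,
    registration_date = as.Date(reg_day, origin = "1970-01-01"),
    age_years = age, gender = gender, treatment = treatment,
    deprivation_decile = decile, center_id = center)

  n_rrt <- tabulate(match(center[treatment %in% RRT_TREATMENTS], center_ids),
                    nbins = config$n_centers)
  penetration <- runif(config$n_centers, 0.06, 0.75)
  centers <- tibble::tibble(
    center_id = center_ids,
    rpv_start_date = as.Date(
      census_day - round(runif(config$n_centers, 180, 1460)),
      origin = "1970-01-01"),
    assisted_start = assisted,
    rrt_population = pmax(as.integer(ceiling(n_rrt / penetration)),
                          n_rrt, 1L))

  logons <- tibble::tibble(patient_id = ids[logon_pid],
                           timestamp = timestamp) |>
    dplyr::arrange(.data$patient_id, .data$timestamp)
  results <- tibble::tibble(patient_id = ids[res_pid],
                            sample_date = as.Date(res_day,
                                                  origin = "1970-01-01")) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$patient_id, .data$sample_date)

  ground_truth <- tibble::tibble(
    patient_id = ids, true_class = cls,
    true_stop_date = as.Date(stop_day, origin = "1970-01-01"))

  list(patients = patients, centers = centers, logons = logons,
       results = results, ground_truth = ground_truth)
}
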