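#' Covariate codings
#'
#' `age_band()` assigns ages to the five analysis bands used throughout the
#' package; `deprivation_group()` consolidates rank-deprivation deciles
#' (1 = most deprived) into three groups focusing on the extremes.
#'
#' @details
#' Bands are `[0,18)`, `[18,35)`, `[35,55)`, `[55,75]`, `(75,Inf)`: lower
#' edges are inclusive (35.0 is `a35_54`), and because the top band is
#' labelled "over 75" it is strictly open below, so an exact 75.0 belongs to
#' `a55_74`. The bands are exhaustive and mutually exclusive on
#' non-negative ages.
#'
#' @param age_years Numeric vector of non-negative ages (years). `NA` allowed.
#' @return Factor with levels `lt18, a18_34, a35_54, a55_74, gt75`.
#' @examples
#' age_band(c(17.9, 35, 74.9, 75, 75.1))
#' deprivation_group(c(1, 5, 10))
#' @export
age_band <- function(age_years) {
  stopifnot(is.numeric(age_years))
  if (any(age_years < 0, na.rm = TRUE)) {
    stop("age_years must be non-negative", call. = FALSE)
  }
  out <- dplyr::case_when(
    is.na(age_years) ~ NA_character_,
    age_years < 18 ~ "lt18",
    age_years < 35 ~ "a18_34",
    age_years < 55 ~ "a35_54",
    age_years <= 75 ~ "a55_74",
    TRUE ~ "gt75"
  )
  factor(out, levels = AGE_BANDS)
}

#' @param decile Integer vector of deprivation deciles in 1..10
#'   (1 = most deprived). `NA` allowed.
#' @return For `deprivation_group()`, a factor with levels
#'   `high`, `middle`, `low` (deciles 1-2, 3-8, 9-10).
#' @rdname age_band
#' @export
deprivation_group <- function(decile) {
  stopifnot(is.numeric(decile))
  ok <- is.na(decile) | (decile %in% 1:10)
  if (!all(ok)) {
    stop("deprivation decile out of range 1..10: ",
         paste(unique(decile[!ok]), collapse = ", "), call. = FALSE)
  }
  out <- dplyr::case_when(
    is.na(decile) ~ NA_character_,
    decile <= 2 ~ "high",
    decile <= 8 ~ "middle",
    TRUE ~ "low"
  )
  factor(out, levels = DEPRIVATION_GROUPS)
}

patients_cols <- c("patient_id", "registration_date", "age_years", "gender",
                   "treatment", "deprivation_decile", "center_id")
centers_cols <- c("center_id", "rpv_start_date", "assisted_start",
                  "rrt_population")
logons_cols <- c("patient_id", "timestamp")
results_cols <- c("patient_id", "sample_date")

check_schema <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(what, ": missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

# Verify the header before the typed read so a missing column surfaces as a
# schema error rather than a parser warning.
check_header <- function(path, required, what) {
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                               col_types = readr::cols(.default = "c")))
  missing <- setdiff(required, hdr)
  if (length(missing)) {
    stop(what, ": missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(hdr)
}

#' Read the four registry tables
#'
#' Reads the patients, centers, logons and results CSV tables, types the
#' columns, sorts event streams per patient, and validates referential
#' integrity and event invariants (every logon timestamp must fall on or after
#' its patient's registration date).
#'
#' Expected headers: `patients.csv` has
#' `patient_id,registration_date,age_years,gender,treatment,deprivation_decile,center_id`;
#' `centers.csv` has `center_id,rpv_start_date,assisted_start,rrt_population`;
#' `logons.csv` has `patient_id,timestamp`; `results.csv` has
#' `patient_id,sample_date`. Dates are ISO-8601; logon timestamps carry
#' time-of-day; booleans are written `true`/`false`.
#'
#' @param patients_path,centers_path,logons_path,results_path File paths.
#' @return A named list of tibbles: `patients`, `centers`, `logons`, `results`.
#' @seealso [write_tables()]
#' @export
read_tables <- function(patients_path, centers_path, logons_path,
                        results_path) {
  check_header(patients_path, patients_cols, "patients")
  check_header(centers_path, centers_cols, "centers")
  check_header(logons_path, logons_cols, "logons")
  check_header(results_path, results_cols, "results")
  patients <- readr::read_csv(
    patients_path, show_col_types = FALSE,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      registration_date = readr::col_date(),
      age_years = readr::col_double(),
      gender = readr::col_character(),
      treatment = readr::col_character(),
      deprivation_decile = readr::col_integer(),
      center_id = readr::col_character()
    ))
  centers <- readr::read_csv(
    centers_path, show_col_types = FALSE,
    col_types = readr::cols(
      center_id = readr::col_character(),
      rpv_start_date = readr::col_date(),
      assisted_start = readr::col_logical(),
      rrt_population = readr::col_integer()
    ))
  logons <- readr::read_csv(
    logons_path, show_col_types = FALSE,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      timestamp = readr::col_datetime(format = "")
    ))
  results <- readr::read_csv(
    results_path, show_col_types = FALSE,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      sample_date = readr::col_date()
    ))
  check_schema(patients, patients_cols, "patients")
  check_schema(centers, centers_cols, "centers")
  check_schema(logons, logons_cols, "logons")
  check_schema(results, results_cols, "results")
  validate_dataset(list(patients = patients, centers = centers,
                        logons = logons, results = results))
}

#' Validate a registry dataset
#'
#' Checks enum codings, referential integrity (patients reference known
#' centers, events reference known patients) and the logon-after-registration
#' invariant, then returns the dataset with event streams sorted per patient.
#'
#' @param dataset Named list with `patients`, `centers`, `logons`, `results`.
#' @return The dataset, event streams sorted ascending within patient.
#' @export
validate_dataset <- function(dataset) {
  patients <- dataset$patients
  centers <- dataset$centers
  logons <- dataset$logons
  results <- dataset$results

  bad_gender <- setdiff(unique(patients$gender[!is.na(patients$gender)]),
                        GENDERS)
  if (length(bad_gender)) {
    stop("invalid gender value(s): ", paste(bad_gender, collapse = ", "),
         call. = FALSE)
  }
  bad_treat <- setdiff(unique(patients$treatment[!is.na(patients$treatment)]),
                       TREATMENTS)
  if (length(bad_treat)) {
    stop("invalid treatment value(s): ", paste(bad_treat, collapse = ", "),
         call. = FALSE)
  }
  dd <- patients$deprivation_decile
  if (any(!is.na(dd) & !(dd %in% 1:10))) {
    stop("deprivation_decile outside 1..10", call. = FALSE)
  }
  orphan_centers <- setdiff(patients$center_id, centers$center_id)
  if (length(orphan_centers)) {
    stop("patients reference unknown center(s): ",
         paste(orphan_centers, collapse = ", "), call. = FALSE)
  }
  for (ev in c("logons", "results")) {
    orphans <- setdiff(dataset[[ev]]$patient_id, patients$patient_id)
    if (length(orphans)) {
      stop(ev, " reference unknown patient(s): ",
           paste(head(orphans, 5), collapse = ", "), call. = FALSE)
    }
  }

  reg <- patients$registration_date[match(logons$patient_id,
                                          patients$patient_id)]
  early <- as.Date(logons$timestamp, tz = "UTC") < reg
  if (any(early)) {
    stop("logon timestamp predates registration for patient(s): ",
         paste(unique(logons$patient_id[early]), collapse = ", "),
         call. = FALSE)
  }

  dataset$logons <- dplyr::arrange(logons, .data$patient_id, .data$timestamp)
  dataset$results <- dplyr::arrange(results, .data$patient_id,
                                    .data$sample_date)
  dataset
}

#' Write the four registry tables
#'
#' Inverse of [read_tables()]: writes `patients.csv`, `centers.csv`,
#' `logons.csv` and `results.csv` under `dir` in the documented schemas
#' (ISO-8601 dates, `true`/`false` booleans). A read of the written files
#' reproduces the input collections exactly.
#'
#' @param dataset Named list with `patients`, `centers`, `logons`, `results`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the four file paths.
#' @export
write_tables <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("patients.csv", "centers.csv", "logons.csv",
                            "results.csv"))
  names(paths) <- c("patients", "centers", "logons", "results")
  centers <- dataset$centers
  centers$assisted_start <- ifelse(centers$assisted_start, "true", "false")
  logons <- dataset$logons
  logons$timestamp <- format(logons$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                             tz = "UTC")
  readr::write_csv(dataset$patients, paths["patients"], na = "")
  readr::write_csv(centers, paths["centers"], na = "")
  readr::write_csv(logons, paths["logons"], na = "")
  readr::write_csv(dataset$results, paths["results"], na = "")
  invisible(paths)
}
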