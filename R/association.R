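#' Center-level covariates
#'
#' Derives, for each center: whether it had been offering the portal for
#' less than `recent_years` years at census (`offering_lt2y`), its
#' registration rate (registered RRT patients / RRT population, a measure of
#' recruiting effectiveness), and the quartile of that rate across centers
#' (`rate_quartile`, Q4 = highest), alongside the `assisted_start` flag.
#'
#' @inheritParams classify_cohort
#' @param centers Centers tibble (see [read_tables()]).
#' @param recent_years Threshold in years for the recent-offering flag.
#' @return Tibble keyed by `center_id`.
#' @export
center_covariates <- function(patients, centers, census, recent_years = 2) {
  census <- as.Date(census)
  rrt_counts <- patients |>
    dplyr::filter(.data$treatment %in% RRT_TREATMENTS) |>
    dplyr::count(.data$center_id, name = "n_rrt_registered")
  df <- centers |>
    dplyr::left_join(rrt_counts, by = "center_id") |>
    dplyr::mutate(
      n_rrt_registered = dplyr::coalesce(.data$n_rrt_registered, 0L),
      offering_lt2y =
        as.numeric(census - .data$rpv_start_date) < recent_years * 365.25,
      registration_rate = .data$n_rrt_registered / .data$rrt_population)
  df$rate_quartile <- factor(
    paste0("Q", rank_quartile(df$registration_rate, df$center_id)),
    levels = paste0("Q", 1:4))
  dplyr::select(df, "center_id", "assisted_start", "offering_lt2y",
                "registration_rate", "rate_quartile")
}

#' Build the analysis cohort for one participation hurdle
#'
#' The three hurdles at which registrants stop participating:
#'
#' * `not_complete_first_logon` -- all registrants; outcome = never made a
#'   single logon;
#' * `early_lapse` -- registrants classified beyond the cohort restriction
#'   (early, late or persistent); outcome = early lapser;
#' * `late_lapse` -- late lapsers vs persistent users (early lapsers
#'   excluded); outcome = late lapser.
#'
#' Covariates (age band, gender, treatment, deprivation group, plus the
#' center covariates) are complete-case: patients missing any of them are
#' dropped and counted in `n_dropped`.
#'
#' @param classes Output of [classify_cohort()] (run with the restriction
#'   appropriate to the hurdle, typically `first_logon_3m` for the lapse
#'   hurdles).
#' @inheritParams classify_cohort
#' @param centers Centers tibble.
#' @param hurdle Which hurdle to model.
#' @return List: `data` (tibble with `patient_id`, integer `outcome` and the
#'   covariate columns), `hurdle`, `n`, `n_dropped`.
#' @export
build_hurdle_cohort <- function(classes, patients, centers, census,
                                hurdle = c("not_complete_first_logon",
                                           "early_lapse", "late_lapse")) {
  hurdle <- match.arg(hurdle)
  covs <- patient_covariates(patients, centers, census)
  df <- dplyr::inner_join(classes, covs, by = "patient_id")
  df <- switch(
    hurdle,
    not_complete_first_logon = dplyr::mutate(
      df, outcome = as.integer(.data$n_logons == 0L)),
    early_lapse = df |>
      dplyr::filter(.data$usage_class %in%
                      c("early_lapser", "late_lapser", "persistent_user")) |>
      dplyr::mutate(outcome = as.integer(.data$usage_class == "early_lapser")),
    late_lapse = df |>
      dplyr::filter(.data$usage_class %in%
                      c("late_lapser", "persistent_user")) |>
      dplyr::mutate(outcome = as.integer(.data$usage_class == "late_lapser"))
  )
  if (nrow(df) == 0) stop("empty hurdle cohort", call. = FALSE)
  covariate_cols <- c("age_band", "gender", "treatment", "deprivation_group",
                      "assisted_start", "offering_lt2y", "rate_quartile")
  out <- df |>
    dplyr::select("patient_id", "outcome",
                  dplyr::all_of(covariate_cols))
  complete <- stats::complete.cases(out)
  list(data = out[complete, ], hurdle = hurdle, n = sum(complete),
       n_dropped = sum(!complete))
}

default_references <- c(age_band = "a35_54", treatment = "hospital_hd",
                        deprivation_group = "middle")

relevel_factors <- function(data, factors, references) {
  for (f in factors) {
    if (is.logical(data[[f]])) data[[f]] <- factor(data[[f]],
                                                   levels = c(FALSE, TRUE))
    if (!is.factor(data[[f]])) data[[f]] <- factor(data[[f]])
    data[[f]] <- droplevels(data[[f]])
    if (f %in% names(references) &&
        references[[f]] %in% levels(data[[f]])) {
      data[[f]] <- stats::relevel(data[[f]], ref = references[[f]])
    }
  }
  data
}

or_table <- function(fit, factors) {
  cf <- summary(fit)$coefficients
  purrr::map_dfr(factors, function(f) {
    lv <- levels(fit$model[[f]])
    if (is.null(lv)) lv <- character(0)
    terms <- paste0(f, lv[-1])
    present <- terms %in% rownames(cf)
    est <- cf[terms[present], "Estimate"]
    se <- cf[terms[present], "Std. Error"]
    p <- cf[terms[present], "Pr(>|z|)"]
    tibble::tibble(factor = f, level = lv[-1][present],
                   odds_ratio = exp(est),
                   ci_low = exp(est - 1.96 * se),
                   ci_high = exp(est + 1.96 * se),
                   p_value = p)
  })
}

#' Fit a logistic factor-association model
#'
#' Maximum-likelihood logistic regression of a binary participation outcome
#' on categorical factors, reporting per-level odds ratios
#' `exp(coefficient)` with Wald 95% intervals `exp(coefficient +- 1.96 SE)`
#' against the stated reference levels (defaults: age 35-54, hospital HD,
#' middle deprivation; reference levels carry OR 1 implicitly and are not
#' listed). Aliased (singular) designs and apparent complete separation are
#' reported as errors naming the offending terms.
#'
#' @param data Tibble with an integer/logical `outcome` column and factor
#'   columns (e.g. `build_hurdle_cohort()$data`).
#' @param factors Character vector of covariate column names to include
#'   (default: every column except `patient_id` and `outcome`).
#' @param references Named character vector of reference levels.
#' @return List of class `factor_model`: `table` (tibble `factor`, `level`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p_value`), `fit` (the `glm`),
#'   `factors`, `n`, `deviance`, `null_deviance`.
#' @export
fit_factor_model <- function(data, factors = NULL,
                             references = default_references) {
  if (is.null(factors)) {
    factors <- setdiff(names(data), c("patient_id", "outcome"))
  }
  stopifnot(length(factors) > 0, "outcome" %in% names(data))
  d <- data[stats::complete.cases(data[c("outcome", factors)]),
            c("outcome", factors)]
  if (length(unique(d$outcome)) < 2) {
    stop("outcome has a single class; model not identifiable", call. = FALSE)
  }
  d <- relevel_factors(d, factors, references)
  fit <- stats::glm(stats::reformulate(factors, response = "outcome"),
                    family = stats::binomial(), data = d)
  cf <- stats::coef(fit)
  if (any(is.na(cf))) {
    stop("singular design; aliased term(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  if (any(abs(cf[-1]) > 10)) {
    stop("apparent complete separation in term(s): ",
         paste(names(cf)[-1][abs(cf[-1]) > 10], collapse = ", "),
         call. = FALSE)
  }
  structure(list(table = or_table(fit, factors), fit = fit,
                 factors = factors, n = nrow(d),
                 deviance = stats::deviance(fit),
                 null_deviance = fit$null.deviance),
            class = "factor_model")
}

#' Backward factor elimination by likelihood-ratio test
#'
#' Starting from the full model, repeatedly refits without each remaining
#' factor and compares nested models by the deviance difference against a
#' chi-square (likelihood-ratio test). The factor whose removal gives the
#' largest p-value is dropped -- whole, all levels at once -- while that
#' p-value exceeds `alpha`; elimination stops when every remaining factor is
#' significant at `alpha` (or no factor remains). Deterministic given the
#' data and `alpha`.
#'
#' @inheritParams fit_factor_model
#' @param alpha Retention threshold for the LRT p-value (default 0.05).
#' @return List: `model` (the final [fit_factor_model()] result, or `NULL`
#'   if every factor was removed), `retained` (character), `removed`
#'   (tibble `step`, `factor`, `p_removed` -- the removal trail).
#' @export
eliminate_factors <- function(data, factors = NULL,
                              references = default_references,
                              alpha = 0.05) {
  if (is.null(factors)) {
    factors <- setdiff(names(data), c("patient_id", "outcome"))
  }
  d <- data[stats::complete.cases(data[c("outcome", factors)]),
            c("outcome", factors)]
  d <- relevel_factors(d, factors, references)
  remaining <- factors
  trail <- tibble::tibble(step = integer(), factor = character(),
                          p_removed = double())
  step <- 0L
  repeat {
    if (length(remaining) == 0) break
    fit <- stats::glm(stats::reformulate(remaining, response = "outcome"),
                      family = stats::binomial(), data = d)
    dr <- stats::drop1(fit, test = "LRT")
    p <- dr[["Pr(>Chi)"]][-1]
    names(p) <- rownames(dr)[-1]
    worst <- names(p)[which.max(p)]
    if (max(p) <= alpha) break
    step <- step + 1L
    trail <- dplyr::bind_rows(trail,
                              tibble::tibble(step = step, factor = worst,
                                             p_removed = max(p)))
    remaining <- setdiff(remaining, worst)
  }
  model <- if (length(remaining) > 0) {
    fit_factor_model(d, remaining, references)
  } else NULL
  list(model = model, retained = remaining, removed = trail)
}

#' Compare registered proportions against a reference population
#'
#' Per-stratum registration proportions and a Pearson chi-square test of the
#' registered / not-registered by stratum contingency table. With a single
#' stratum no comparison is possible and the test is reported as not
#' applicable (`df = 0`).
#'
#' @param registered_counts Integer vector of registered patients per
#'   stratum.
#' @param population_counts Integer vector of the reference population per
#'   stratum (same order; must dominate `registered_counts`).
#' @return List: `proportions` (per stratum), `overall`, `chi_square`, `df`,
#'   `p`.
#' @export
compare_to_reference <- function(registered_counts, population_counts) {
  stopifnot(length(registered_counts) == length(population_counts))
  if (any(registered_counts > population_counts)) {
    stop("registered count exceeds population in some stratum",
         call. = FALSE)
  }
  if (any(population_counts <= 0)) {
    stop("population counts must be positive", call. = FALSE)
  }
  props <- registered_counts / population_counts
  overall <- sum(registered_counts) / sum(population_counts)
  if (length(registered_counts) < 2) {
    return(list(proportions = props, overall = overall,
                chi_square = NA_real_, df = 0L, p = NA_real_))
  }
  tab <- cbind(registered = registered_counts,
               not_registered = population_counts - registered_counts)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(proportions = props, overall = overall,
       chi_square = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}
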