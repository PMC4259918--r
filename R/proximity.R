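#' Signed interval from each logon to the nearest result
#'
#' For one patient: the whole-day difference from each logon date to the
#' closest result date by absolute distance. Positive intervals mean the
#' logon came *after* the nearest result; an equidistant tie is resolved to
#' the positive (after) interval, since post-result viewing is the object of
#' the analysis. Time-of-day is ignored -- intervals are computed on calendar
#' dates, matching date-only result events.
#'
#' @param logon_dates Dates (or date-times) of one patient's logons.
#' @param result_dates Sorted dates of the same patient's result uploads.
#' @return Integer vector of signed days, `NA` if the patient has no results.
#' @export
nearest_result_interval <- function(logon_dates, result_dates) {
  ld <- as.numeric(as.Date(logon_dates, tz = "UTC"))
  rd <- sort(as.numeric(as.Date(result_dates)))
  if (length(rd) == 0) return(rep(NA_integer_, length(ld)))
  idx <- findInterval(ld, rd)
  d_prev <- ld - rd[pmax(idx, 1L)]          # >= 0 when idx >= 1
  d_next <- ld - rd[pmin(idx + 1L, length(rd))]
  has_prev <- idx >= 1L
  has_next <- idx < length(rd)
  out <- ifelse(has_prev & has_next,
                ifelse(d_prev <= -d_next, d_prev, d_next),
                ifelse(has_prev, d_prev, d_next))
  as.integer(out)
}

# Pooled nearest intervals across patients. Maps each patient's timeline onto
# a disjoint segment of a single axis so one findInterval serves the whole
# cohort; neighbours from a different patient are masked out.
pooled_nearest <- function(logon_pid, logon_day, result_pid, result_day) {
  big <- 2^22   # > any plausible day span
  gl <- logon_day + logon_pid * big
  o <- order(result_pid, result_day)
  rp <- result_pid[o]
  gr <- result_day[o] + rp * big
  nr <- length(gr)
  if (nr == 0) return(rep(NA_integer_, length(gl)))
  idx <- findInterval(gl, gr)
  prev_ok <- idx >= 1L & rp[pmax(idx, 1L)] == logon_pid
  next_ok <- idx < nr & rp[pmin(idx + 1L, nr)] == logon_pid
  d_prev <- gl - gr[pmax(idx, 1L)]
  d_next <- gl - gr[pmin(idx + 1L, nr)]
  out <- rep(NA_real_, length(gl))
  both <- prev_ok & next_ok
  out[both] <- ifelse(d_prev[both] <= -d_next[both],
                      d_prev[both], d_next[both])
  only_p <- prev_ok & !next_ok
  out[only_p] <- d_prev[only_p]
  only_n <- !prev_ok & next_ok
  out[only_n] <- d_next[only_n]
  as.integer(out)
}

#' Pooled signed logon-to-result intervals for a cohort
#'
#' @param logons,results Cohort event tibbles.
#' @return Integer vector, one signed-day interval per logon (`NA` for
#'   logons of patients without any result).
#' @export
pooled_intervals <- function(logons, results) {
  pids <- unique(c(logons$patient_id, results$patient_id))
  pooled_nearest(match(logons$patient_id, pids),
                 as.numeric(as.Date(logons$timestamp, tz = "UTC")),
                 match(results$patient_id, pids),
                 as.numeric(results$sample_date))
}

#' Proximity histogram of logons around result dates
#'
#' One-day-bin histogram of the signed interval from every logon to its
#' nearest result, pooled over patients, over `[-window_days, +window_days)`.
#' Bin `[k, k+1)` holds logons exactly `k` whole days from the nearest result
#' (negative = logon precedes the result). Proportions are relative to *all*
#' logons: logons of patients without any result count in the denominator
#' `n_logons_total` but cannot fall in any bin, so bin proportions sum to
#' `n_in_window / n_logons_total`.
#'
#' @param logons,results Cohort event tibbles.
#' @param window_days Half-width of the histogram window (default 28).
#' @return List with `bins` (tibble `bin_start`, `count`, `proportion`),
#'   `n_logons_total`, `n_in_window`, `window_days`.
#' @export
proximity_histogram <- function(logons, results, window_days = 28) {
  if (nrow(results) == 0 ||
      !any(logons$patient_id %in% results$patient_id)) {
    stop("no patient has result events: proximity histogram undefined",
         call. = FALSE)
  }
  iv <- pooled_intervals(logons, results)
  hist_from_intervals(iv, n_total = length(iv), window_days)
}

hist_from_intervals <- function(iv, n_total, window_days) {
  w <- window_days
  iv <- iv[!is.na(iv)]
  inw <- iv[iv >= -w & iv < w]
  counts <- tabulate(inw + w + 1L, nbins = 2L * w)
  list(bins = tibble::tibble(bin_start = seq(-w, w - 1L),
                             count = counts,
                             proportion = if (n_total > 0) counts / n_total
                                          else rep(NA_real_, 2 * w)),
       n_logons_total = n_total,
       n_in_window = length(inw),
       window_days = w)
}

#' Headline proximity fractions
#'
#' Shares of logons by signed interval to the nearest result, with all
#' defined intervals as denominator: `frac_after_0_1` (same day, `[0,1)`),
#' `frac_after_0_3` (`[0,3)`), `frac_pre_3` (the 3 days before, `[-3,0)`),
#' and `frac_within_14` (`[0,14)`, within 2 weeks after).
#'
#' @param intervals Integer vector of pooled signed-day intervals
#'   (e.g. from [pooled_intervals()]); `NA`s are dropped.
#' @return Named list of four fractions in `[0, 1]`.
#' @export
headline_fractions <- function(intervals) {
  iv <- intervals[!is.na(intervals)]
  if (length(iv) == 0) {
    stop("no defined intervals: headline fractions undefined", call. = FALSE)
  }
  list(frac_after_0_1 = mean(iv >= 0 & iv < 1),
       frac_after_0_3 = mean(iv >= 0 & iv < 3),
       frac_pre_3 = mean(iv >= -3 & iv < 0),
       frac_within_14 = mean(iv >= 0 & iv < 14))
}

#' Permutation null for the proximity histogram
#'
#' Assesses whether logons cluster around result dates beyond chance by
#' comparing the observed proximity histogram with histograms recomputed
#' after shuffling event times. Per permutation, each patient's logon dates
#' (mode `shuffle_logons`) or result dates (mode `shuffle_results`) are
#' redrawn uniformly at random over whole days within that patient's
#' observation window (first logon to census), preserving per-patient event
#' counts and windows exactly. Shuffling per patient (rather than pooling
#' across patients) preserves per-patient rate heterogeneity, which global
#' shuffling would destroy and thereby inflate significance.
#'
#' Per-bin exceedance p-values use the add-one permutation estimator
#' `(1 + #\{null >= observed\}) / (1 + n_permutations)`.
#'
#' @param logons,results Cohort event tibbles.
#' @param census Census date.
#' @param n_permutations Number of permutations (at least 100).
#' @param seed Integer seed for the permutation stream.
#' @param mode `"shuffle_logons"` or `"shuffle_results"`.
#' @param window_days Histogram half-width in days.
#' @return List: `observed` histogram (as [proximity_histogram()]), tibble
#'   `bins` with per-bin `null_mean`, `null_lo`, `null_hi` (2.5/97.5
#'   percentile envelope) and `p`, the null proportion matrix
#'   `null_histograms` (permutations x bins), and the call parameters.
#' @export
shuffle_null <- function(logons, results, census, n_permutations = 999,
                         seed = 1L, mode = c("shuffle_logons",
                                             "shuffle_results"),
                         window_days = 28) {
  mode <- match.arg(mode)
  if (n_permutations < 100) {
    stop("n_permutations must be at least 100", call. = FALSE)
  }
  census_day <- as.numeric(as.Date(census))

  pids <- unique(logons$patient_id)
  lp <- match(logons$patient_id, pids)
  ld <- as.numeric(as.Date(logons$timestamp, tz = "UTC"))
  keep <- results$patient_id %in% pids
  rp <- match(results$patient_id[keep], pids)
  rd <- as.numeric(results$sample_date[keep])

  mins <- tapply(ld, lp, min)
  w0 <- unname(as.numeric(mins[as.character(seq_along(pids))]))
  if (all(w0 >= census_day)) {
    stop("all observation windows have zero length", call. = FALSE)
  }
  wlen <- census_day - w0   # whole days available: w0..census_day

  observed <- hist_from_intervals(pooled_nearest(lp, ld, rp, rd),
                                  n_total = length(ld), window_days)

  nb <- 2L * window_days
  null_mat <- matrix(NA_real_, n_permutations, nb)
  set.seed(seed)
  for (i in seq_len(n_permutations)) {
    if (mode == "shuffle_logons") {
      new_ld <- w0[lp] + floor(runif(length(ld)) * (wlen[lp] + 1))
      iv <- pooled_nearest(lp, new_ld, rp, rd)
    } else {
      new_rd <- w0[rp] + floor(runif(length(rd)) * (wlen[rp] + 1))
      iv <- pooled_nearest(lp, ld, rp, new_rd)
    }
    null_mat[i, ] <- hist_from_intervals(iv, n_total = length(ld),
                                         window_days)$bins$proportion
  }

  obs_prop <- observed$bins$proportion
  exceed <- colSums(sweep(null_mat, 2, obs_prop, `>=`))
  bins <- dplyr::mutate(
    observed$bins,
    null_mean = colMeans(null_mat),
    null_lo = apply(null_mat, 2, quantile, probs = 0.025, names = FALSE),
    null_hi = apply(null_mat, 2, quantile, probs = 0.975, names = FALSE),
    p = (1 + exceed) / (1 + n_permutations))
  list(observed = observed, bins = bins, null_histograms = null_mat,
       n_permutations = n_permutations, seed = seed, mode = mode,
       window_days = window_days)
}
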