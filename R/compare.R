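# Pairing and contrast of Fixed-Period and Moving-Window EHRM sets.

#' Remove EHRMs not available to the other method
#'
#' Fixed-Period EHRMs initiated during the establishment of the first
#' Moving-Window PreHR could not have been detected by the Moving-Window
#' method; Moving-Window EHRMs initiated in seasonal segments with fewer
#' than `min_days` days of data could not have been detected by the
#' Fixed-Period method.  Both are set aside before pairing.
#'
#' @param ehrms_fixed,ehrms_moving EHRM tables from the two detectors.
#' @param traj the `ehrm_traj` both were run on.
#' @param mw_cfg the [moving_window_config()] used.
#' @param defs season definitions used by the Fixed-Period run.
#' @param min_days seasonal eligibility threshold (default 60).
#' @return list with `fixed`, `moving` (available sets) and
#'   `excluded_fixed`, `excluded_moving`.
#' @export
availability_filter <- function(ehrms_fixed, ehrms_moving, traj,
                                mw_cfg = moving_window_config(),
                                defs = season_defs_default(),
                                min_days = 60) {
  origin_day <- as.POSIXct(format(min(traj$fixes$timestamp), "%Y-%m-%d"),
                           tz = "UTC")
  first_window <- origin_day + mw_cfg$prehr_days * 86400
  f_avail <- ehrms_fixed$initiation_time >= first_window
  seg <- assign_seasons(traj, defs, min_days = min_days)
  m_avail <- rep(TRUE, nrow(ehrms_moving))
  for (i in seq_len(nrow(seg))) {
    if (seg$eligible[i]) next
    in_seg <- ehrms_moving$initiation_time >= seg$season_start[i] &
      ehrms_moving$initiation_time < seg$season_end[i]
    m_avail[in_seg] <- FALSE
  }
  # segments with no fixes at all never appear in `seg`; EHRMs cannot be
  # initiated there either, so the loop covers every case
  list(fixed = ehrms_fixed[f_avail, , drop = FALSE],
       moving = ehrms_moving[m_avail, , drop = FALSE],
       excluded_fixed = ehrms_fixed[!f_avail, , drop = FALSE],
       excluded_moving = ehrms_moving[!m_avail, , drop = FALSE])
}

.interval_bounds <- function(e) {
  s <- e$start_time
  s[is.na(s)] <- e$initiation_time[is.na(s)]
  en <- e$end_time
  # open-ended EHRMs have no return fix; close their interval at the
  # initiation instant so overlap still matches a detection of the same
  # departure by the other method
  en[is.na(en)] <- e$initiation_time[is.na(en)]
  en <- pmax(en, s)
  data.frame(s = s, e = en)
}

#' Pair EHRMs detected by both methods
#'
#' Two EHRMs are paired when their `[start_time, end_time]` intervals
#' overlap (both methods bracket the same outside run when they both see
#' it).  Matching is greedy by earliest end time, taking the
#' earliest-ending unused partner -- the rule that attains the maximum
#' number of pairs for interval overlap.  Each EHRM joins at most one pair;
#' the remainder are unique to their method.
#'
#' @param fixed,moving availability-filtered EHRM tables for one animal.
#' @return list of class `ehrm_match`: `paired` (data.frame of index pairs
#'   `fixed_idx`, `moving_idx` plus both metric columns), `unique_fixed`,
#'   `unique_moving` (row subsets).
#' @export
match_ehrms <- function(fixed, moving) {
  fb <- .interval_bounds(fixed)
  mb <- .interval_bounds(moving)
  fo <- order(fb$e)
  used_m <- rep(FALSE, nrow(moving))
  pairs <- NULL
  for (i in fo) {
    cand <- which(!used_m & mb$s <= fb$e[i] & mb$e >= fb$s[i])
    if (!length(cand)) next
    j <- cand[order(mb$e[cand])][1]
    used_m[j] <- TRUE
    pairs <- rbind(pairs, data.frame(
      fixed_idx = i, moving_idx = j,
      fixed_distance_m = fixed$max_distance_m[i],
      moving_distance_m = moving$max_distance_m[j],
      fixed_duration_h = fixed$duration_h[i],
      moving_duration_h = moving$duration_h[j]))
  }
  paired_f <- if (is.null(pairs)) integer() else pairs$fixed_idx
  structure(list(
    paired = if (is.null(pairs)) data.frame() else pairs,
    unique_fixed = fixed[setdiff(seq_len(nrow(fixed)), paired_f), ,
                         drop = FALSE],
    unique_moving = moving[!used_m, , drop = FALSE]),
    class = "ehrm_match")
}

#' Paired comparison of maximum EHRM distances
#'
#' Paired differences are moving-window minus fixed-period; the t statistic
#' is the standard paired-sample t with `n - 1` degrees of freedom.  The
#' percent difference is the mean difference relative to the Fixed-Period
#' mean.
#'
#' @param pairs the `paired` data.frame from [match_ehrms()] (>= 2 rows).
#' @return list: `n`, `mean_difference_m`, `se_difference_m`,
#'   `mean_percent_difference`, `t_statistic`, `df`, `p_value`.
#' @export
paired_distance_summary <- function(pairs) {
  if (nrow(pairs) < 2) stop("need at least 2 pairs")
  d <- pairs$moving_distance_m - pairs$fixed_distance_m
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    warning("all paired differences identical; t undefined, reported as 0")
    t <- 0
  } else {
    t <- m / (s / sqrt(n))
  }
  list(n = n, mean_difference_m = m, se_difference_m = s / sqrt(n),
       mean_percent_difference = 100 * m / mean(pairs$fixed_distance_m),
       t_statistic = t, df = n - 1,
       p_value = if (s == 0) NA_real_ else 2 * stats::pt(-abs(t), n - 1))
}

#' Method comparison summary table
#'
#' Totals, counts detectable by both methods, unique counts with percents,
#' and a distance-band breakdown (0.5-1.0 km vs >= 1.0 km) of the unique
#' EHRMs, in the shape conventional for reporting the two methods side by
#' side.
#'
#' @param ehrms_fixed,ehrms_moving full (unfiltered) EHRM tables.
#' @param avail result of [availability_filter()].
#' @param match result of [match_ehrms()] on the available sets.
#' @return data.frame with `comparison`, `fixed_n`, `fixed_pct`,
#'   `moving_n`, `moving_pct`.
#' @export
method_comparison_table <- function(ehrms_fixed, ehrms_moving, avail, match) {
  uf <- match$unique_fixed
  um <- match$unique_moving
  band <- function(e, lo, hi) sum(e$max_distance_m >= lo &
                                    e$max_distance_m < hi)
  pct <- function(x, n) if (n > 0) round(100 * x / n, 1) else NA_real_
  nf <- nrow(avail$fixed); nm <- nrow(avail$moving)
  data.frame(
    comparison = c("Total EHRMs detected", "EHRMs detectable by both methods",
                   "Unique EHRMs", "Unique EHRMs 0.5-1.0 km",
                   "Unique EHRMs >=1.0 km"),
    fixed_n = c(nrow(ehrms_fixed), nf, nrow(uf),
                band(uf, 0, 1000), band(uf, 1000, Inf)),
    fixed_pct = c(NA, NA, pct(nrow(uf), nf),
                  pct(band(uf, 0, 1000), nrow(uf)),
                  pct(band(uf, 1000, Inf), nrow(uf))),
    moving_n = c(nrow(ehrms_moving), nm, nrow(um),
                 band(um, 0, 1000), band(um, 1000, Inf)),
    moving_pct = c(NA, NA, pct(nrow(um), nm),
                   pct(band(um, 0, 1000), nrow(um)),
                   pct(band(um, 1000, Inf), nrow(um))),
    stringsAsFactors = FALSE)
}
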