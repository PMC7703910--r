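# Iterative Moving-Window EHRM detection: each calendar day's relocations are
# screened against a home range (PreHR) built exclusively from the
# immediately preceding `prehr_days` of data, so no contour ever uses fixes
# collected after the movement it is testing.

#' Dispersal (new-range fidelity) configuration
#'
#' When an animal leaves its PreHR and never returns, the extension of the
#' detection window ends at the first indication of fidelity to a new area:
#' the earliest time from which all fixes over `fidelity_days` consecutive
#' days stay within `fidelity_radius` of their own centroid.  These
#' operational defaults stand in for the visual review used in field
#' practice and should be adjusted per species.
#'
#' @param fidelity_radius meters (default 1000).
#' @param fidelity_days consecutive days of settlement required (default 7).
#' @param post_dispersal_wait_days days of fresh data required before
#'   iteration restarts after a confirmed dispersal; defaults to the PreHR
#'   length at run time when `NULL`.
#' @return list of class `ehrm_dispersal_config`.
#' @export
dispersal_config <- function(fidelity_radius = 1000, fidelity_days = 7,
                             post_dispersal_wait_days = NULL) {
  stopifnot(fidelity_radius > 0, fidelity_days > 0)
  structure(list(fidelity_radius = fidelity_radius,
                 fidelity_days = fidelity_days,
                 post_dispersal_wait_days = post_dispersal_wait_days),
            class = "ehrm_dispersal_config")
}

#' Moving-Window configuration
#'
#' @param prehr_days length of the pre-EHRM home range period in days
#'   (default 60).
#' @param window_days length of the detection window (default 2; EHRMs are
#'   only accepted when initiated on day 1, so day 2 exists to capture
#'   movements that run past midnight).
#' @param detection a [detection_config()].
#' @param dispersal a [dispersal_config()].
#' @param cell_size UD grid cell edge in meters (default 100).
#' @param delta telemetry error SD in meters (default 15).
#' @param sigma2_m optional fixed Brownian motion variance (m^2/s);
#'   re-estimated from each PreHR's fixes when `NULL`.
#' @return list of class `ehrm_mw_config`.
#' @export
moving_window_config <- function(prehr_days = 60, window_days = 2,
                                 detection = detection_config(),
                                 dispersal = dispersal_config(),
                                 cell_size = 100, delta = 15,
                                 sigma2_m = NULL) {
  stopifnot(prehr_days >= 2, window_days >= 1)
  structure(list(prehr_days = as.integer(prehr_days),
                 window_days = as.integer(window_days),
                 detection = detection, dispersal = dispersal,
                 cell_size = cell_size, delta = delta, sigma2_m = sigma2_m),
            class = "ehrm_mw_config")
}

#' Iteration schedule of the Moving-Window algorithm
#'
#' Iteration `i` has a PreHR spanning days `[i, i + prehr_days - 1]` and a
#' detection window spanning days
#' `[i + prehr_days, i + prehr_days + window_days - 1]` (under the defaults:
#' iteration 1 uses days 1-60 with a window over days 61-62).  The schedule
#' advances one day per iteration so every day from `prehr_days + 1` to the
#' last day serves as window day 1 exactly once.
#'
#' @param n_days number of days of data.
#' @param cfg a [moving_window_config()].
#' @return data.frame with columns `i`, `prehr_from`, `prehr_to`,
#'   `window_from`, `window_to` (day indices, day 1 = first data day).
#' @export
iteration_schedule <- function(n_days, cfg = moving_window_config()) {
  p <- cfg$prehr_days
  if (n_days <= p) {
    warning("trajectory spans ", n_days, " days <= prehr_days = ", p,
            "; empty schedule")
    return(data.frame(i = integer(), prehr_from = integer(),
                      prehr_to = integer(), window_from = integer(),
                      window_to = integer()))
  }
  i <- seq_len(n_days - p)
  data.frame(i = i, prehr_from = i, prehr_to = i + p - 1,
             window_from = i + p,
             window_to = pmin(i + p + cfg$window_days - 1, n_days))
}

# Day index of a timestamp: day 1 is the calendar day (UTC midnight) of
# `origin`.
.day_index <- function(t, origin_day) {
  as.integer(floor(as.numeric(difftime(t, origin_day, units = "days")))) + 1L
}

#' First indication of fidelity to a new area
#'
#' Scans candidate anchor fixes in time order; fidelity is established at
#' the earliest fix time from which every fix in the following
#' `fidelity_days` days lies within `fidelity_radius` of the centroid of
#' those same fixes.  The window must be fully covered by data.
#'
#' @param fixes time-ordered fix data.frame (post-departure fixes).
#' @param cfg a [dispersal_config()].
#' @return the fidelity start time (POSIXct), or `NULL` if never satisfied.
#' @export
detect_dispersal_fidelity <- function(fixes, cfg = dispersal_config()) {
  n <- nrow(fixes)
  if (n == 0) return(NULL)
  tt <- as.numeric(fixes$timestamp)
  span <- cfg$fidelity_days * 86400
  for (i in seq_len(n)) {
    if (tt[n] - tt[i] < span) break       # window not fully covered by data
    j <- which(tt >= tt[i] & tt < tt[i] + span)
    cx <- mean(fixes$x[j]); cy <- mean(fixes$y[j])
    r <- sqrt((fixes$x[j] - cx)^2 + (fixes$y[j] - cy)^2)
    if (all(r <= cfg$fidelity_radius)) return(fixes$timestamp[i])
  }
  NULL
}

#' Schedule restart day after a confirmed dispersal
#'
#' Iteration is postponed until a full fresh PreHR can be built from
#' post-dispersal data: the new PreHR begins the day after the dispersal
#' concluded and the first new window day is
#' `dispersal_end_day + prehr_days + 1`.
#'
#' @param dispersal_end_day day index on which fidelity was established.
#' @param n_days total days of data.
#' @param cfg a [moving_window_config()].
#' @return the restart day index, or `NA` (with a warning) if insufficient
#'   data remain.
#' @export
resume_after_dispersal <- function(dispersal_end_day, n_days,
                                   cfg = moving_window_config()) {
  wait <- cfg$dispersal$post_dispersal_wait_days
  if (is.null(wait)) wait <- cfg$prehr_days
  d <- dispersal_end_day + wait + 1L
  if (d > n_days) {
    warning("insufficient data after dispersal (needs day ", d,
            ", data end day ", n_days, "); schedule ends")
    return(NA_integer_)
  }
  as.integer(d)
}

.prehr_contour <- function(fixes, cfg, max_gap) {
  s2 <- if (is.null(cfg$sigma2_m))
    estimate_sigma2m(fixes, delta = cfg$delta, max_gap = max_gap)
  else cfg$sigma2_m
  par <- bbmm_params(s2, delta = cfg$delta, max_gap = max_gap)
  tt <- as.numeric(fixes$timestamp)
  tmax <- max(pmin(diff(tt), max_gap), 0)
  grid <- fit_grid(fixes$x, fixes$y, cfg$cell_size, par, tmax)
  ud <- compute_ud(fixes, grid, par)
  extract_contour(ud, cfg$detection$contour_level, source = "prehr")
}

#' Run the Moving-Window EHRM detector
#'
#' For each iteration the PreHR contour is built from the preceding
#' `prehr_days` days of fixes only, and the window's fixes are scanned for a
#' departure.  An EHRM is accepted only if its first outside fix falls on
#' window day 1; departures on later window days are deferred to the next
#' iteration, where they are day 1.  When an accepted EHRM runs past the
#' window, the PreHR is frozen and the window extended day by day until the
#' animal returns inside the (frozen) contour, or until fidelity to a new
#' area marks a dispersal, in which case the EHRM is returned open-ended and
#' iteration restarts once a full fresh PreHR of post-dispersal data exists.
#'
#' @param traj projected, censored `ehrm_traj` spanning more than
#'   `prehr_days` days.
#' @param cfg a [moving_window_config()].
#' @return EHRM data.frame (`method = "moving_window"`) with `prehr_from`
#'   and `prehr_to` day columns; attribute `audit` holds one row per
#'   iteration (day spans, PreHR fix count and period, outcome) and
#'   attribute `dispersals` the confirmed dispersal events.
#' @export
run_moving_window <- function(traj, cfg = moving_window_config()) {
  stopifnot(inherits(traj, "ehrm_traj"))
  fx <- traj$fixes
  out <- .empty_ehrms()
  out$prehr_from <- integer(0); out$prehr_to <- integer(0)
  audit <- list()
  dispersals <- list()
  if (nrow(fx) < 3) {
    warning("too few fixes for moving-window detection")
    return(out)
  }
  origin_day <- as.POSIXct(format(min(fx$timestamp), "%Y-%m-%d"), tz = "UTC")
  day <- .day_index(fx$timestamp, origin_day)
  n_days <- max(day)
  p <- cfg$prehr_days
  if (n_days <= p) {
    warning("trajectory spans ", n_days, " days <= prehr_days = ", p)
    return(out)
  }
  max_gap <- if (is.finite(traj$median_interval))
    8 * traj$median_interval else Inf
  last_time <- as.POSIXct(-Inf, origin = "1970-01-01", tz = "UTC")
  d <- p + 1L
  while (d <= n_days) {
    pre_idx <- which(day >= d - p & day <= d - 1L)
    rec <- list(day = d, prehr_from = d - p, prehr_to = d - 1L,
                window_from = d,
                window_to = min(d + cfg$window_days - 1L, n_days),
                n_prehr_fixes = length(pre_idx),
                prehr_start = if (length(pre_idx)) min(fx$timestamp[pre_idx])
                  else as.POSIXct(NA, tz = "UTC"),
                prehr_end = if (length(pre_idx)) max(fx$timestamp[pre_idx])
                  else as.POSIXct(NA, tz = "UTC"),
                outcome = "none")
    if (length(pre_idx) < 3) {
      rec$outcome <- "skipped_sparse_prehr"
      audit[[length(audit) + 1]] <- rec
      d <- d + 1L
      next
    }
    ctr <- .prehr_contour(fx[pre_idx, , drop = FALSE], cfg, max_gap)
    win_idx <- which(day >= d & day <= d + cfg$window_days - 1L &
                       fx$timestamp > last_time)
    if (!length(win_idx)) {
      rec$outcome <- "no_window_fixes"
      audit[[length(audit) + 1]] <- rec
      d <- d + 1L
      next
    }
    inside_win <- point_in_contour(fx$x[win_idx], fx$y[win_idx], ctr)
    n <- nrow(fx)
    # scan day-1 departures in order: an outside fix on window day 1 whose
    # preceding fix is inside.  Sub-threshold edge flickers (a 95% contour
    # leaves ~5% of fixes just outside) must not consume the day, so
    # scanning continues past any run that fails the thresholds.
    saw_day2 <- FALSE
    resolved <- FALSE
    j <- 1
    while (j <= length(win_idx)) {
      gi <- win_idx[j]
      if (inside_win[j]) { j <- j + 1; next }
      if (day[gi] > d) { saw_day2 <- TRUE; break } # initiated day 2+: defer
      if (gi == 1 ||
          !point_in_contour(fx$x[gi - 1], fx$y[gi - 1], ctr)) {
        j <- j + 1   # no start bracket, or continuation of an earlier run
        next
      }
      dep <- gi
      # follow the run forward through the full sequence until the animal
      # returns inside the frozen contour or shows fidelity to a new area,
      # whichever comes first
      rest <- dep:n
      inside_rest <- point_in_contour(fx$x[rest], fx$y[rest], ctr)
      ret_rel <- which(inside_rest)[1]
      ft <- detect_dispersal_fidelity(fx[dep:n, , drop = FALSE],
                                      cfg$dispersal)
      if (!is.null(ft)) {
        # fidelity must be to a genuinely new area: if the settlement
        # centroid lies inside the PreHR contour the animal has simply
        # come home (return-transit fixes can otherwise anchor a spurious
        # settlement a few fixes early)
        w <- which(fx$timestamp >= ft &
                     fx$timestamp < ft + cfg$dispersal$fidelity_days * 86400)
        if (point_in_contour(mean(fx$x[w]), mean(fx$y[w]), ctr)) ft <- NULL
      }
      if (!is.na(ret_rel) && !is.null(ft) &&
          ft < fx$timestamp[rest[ret_rel]]) ret_rel <- NA
      if (!is.na(ret_rel)) {
        ret <- rest[ret_rel]                     # first fix back inside
        run <- dep:(ret - 1)
        maxd <- max(distance_to_contour(fx$x[run], fx$y[run], ctr))
        n_fixes <- length(run) + 2L
        if (n_fixes < cfg$detection$min_points ||
            maxd < cfg$detection$min_distance) {
          # sub-threshold: skip past this run, keep scanning day 1
          while (j <= length(win_idx) && win_idx[j] < ret) j <- j + 1
          next
        }
        e <- data.frame(
          animal_id = traj$animal_id, method = "moving_window",
          start_time = fx$timestamp[dep - 1], end_time = fx$timestamp[ret],
          initiation_time = fx$timestamp[dep], n_fixes = n_fixes,
          max_distance_m = maxd,
          duration_h = as.numeric(difftime(fx$timestamp[ret],
                                           fx$timestamp[dep - 1],
                                           units = "hours")),
          open_ended = FALSE, open_start = FALSE,
          start_idx = dep - 1L, end_idx = as.integer(ret),
          prehr_from = d - p, prehr_to = d - 1L,
          stringsAsFactors = FALSE)
        out <- rbind(out, e)
        last_time <- fx$timestamp[ret]
        ret_day <- day[ret]
        rec$outcome <- if (ret_day > rec$window_to) "ehrm_extended"
          else "ehrm"
        audit[[length(audit) + 1]] <- rec
        # resume at the next calendar day after the (possibly extended)
        # window; a same-day second departure is still caught because
        # last_time guards against re-reading earlier fixes
        d <- max(d + 1L, ret_day)
        resolved <- TRUE
        break
      }
      # no return (or fidelity first): dispersal candidate; member fixes
      # run to the first indication of fidelity when there is one
      run <- if (!is.null(ft)) dep:max(which(fx$timestamp <= ft)) else dep:n
      maxd <- max(distance_to_contour(fx$x[run], fx$y[run], ctr))
      if (maxd >= cfg$detection$min_distance &&
          (length(run) + 1L) >= cfg$detection$min_points - 1L) {
        e <- data.frame(
          animal_id = traj$animal_id, method = "moving_window",
          start_time = fx$timestamp[dep - 1],
          end_time = as.POSIXct(NA, tz = "UTC"),
          initiation_time = fx$timestamp[dep],
          n_fixes = length(run) + 1L, max_distance_m = maxd,
          duration_h = NA_real_, open_ended = TRUE, open_start = FALSE,
          start_idx = dep - 1L, end_idx = as.integer(max(run)),
          prehr_from = d - p, prehr_to = d - 1L,
          stringsAsFactors = FALSE)
        out <- rbind(out, e)
      }
      if (!is.null(ft)) {
        fd <- .day_index(ft, origin_day)
        dispersals[[length(dispersals) + 1]] <-
          data.frame(initiation_time = fx$timestamp[dep],
                     fidelity_time = ft, fidelity_day = fd,
                     stringsAsFactors = FALSE)
        rec$outcome <- "dispersal"
        audit[[length(audit) + 1]] <- rec
        nd <- suppressWarnings(resume_after_dispersal(fd, n_days, cfg))
        last_time <- ft
        d <- if (is.na(nd)) n_days + 1L else nd
      } else {
        rec$outcome <- "open_ended_at_data_end"
        audit[[length(audit) + 1]] <- rec
        d <- n_days + 1L
      }
      resolved <- TRUE
      break
    }
    if (!resolved) {
      rec$outcome <- if (saw_day2) "deferred_day2" else "none"
      audit[[length(audit) + 1]] <- rec
      d <- d + 1L
    }
  }
  rownames(out) <- NULL
  attr(out, "audit") <- do.call(rbind, lapply(audit, as.data.frame))
  attr(out, "dispersals") <- if (length(dispersals))
    do.call(rbind, dispersals) else NULL
  attr(out, "origin_day") <- origin_day
  out
}
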