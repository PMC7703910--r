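# The conventional Fixed-Period (seasonal) EHRM detection driver: per season,
# build a BBMM 95% contour from all of that season's fixes and scan the same
# fixes against it.

#' Default season definitions
#'
#' Three seasons anchored to month-day pairs: spring (1 Mar - 30 Jun),
#' summer (1 Jul - 31 Oct), fall/winter (1 Nov - 28/29 Feb).  Anchors are
#' calendar month-days; fall/winter spans the year boundary and absorbs
#' 29 February in leap years.
#'
#' @return data.frame with columns `name`, `start_md`, `end_md`.
#' @export
season_defs_default <- function() {
  data.frame(name = c("spring", "summer", "fall_winter"),
             start_md = c("03-01", "07-01", "11-01"),
             end_md = c("06-30", "10-31", "02-28"),
             stringsAsFactors = FALSE)
}

#' A single annual "season" covering the whole year
#'
#' Useful for Fixed-Period analyses against an annual home range.
#'
#' @param start_md month-day anchor at which the annual period begins.
#' @return one-row season definition table.
#' @export
season_defs_annual <- function(start_md = "01-01") {
  smd <- as.integer(strsplit(start_md, "-")[[1]])
  prev <- as.Date(sprintf("2001-%02d-%02d", smd[1], smd[2])) - 1
  data.frame(name = "annual", start_md = start_md,
             end_md = format(prev, "%m-%d"), stringsAsFactors = FALSE)
}

.md_num <- function(md) {
  p <- do.call(rbind, strsplit(md, "-"))
  as.integer(p[, 1]) * 100 + as.integer(p[, 2])
}

.season_instances <- function(defs, t_min, t_max) {
  years <- seq(as.integer(format(t_min, "%Y")) - 1,
               as.integer(format(t_max, "%Y")) + 1)
  inst <- do.call(rbind, lapply(seq_len(nrow(defs)), function(i) {
    smd <- defs$start_md[i]; emd <- defs$end_md[i]
    wraps <- .md_num(emd) < .md_num(smd)
    do.call(rbind, lapply(years, function(y) {
      s <- as.POSIXct(paste0(y, "-", smd, " 00:00:00"), tz = "UTC")
      ey <- if (wraps) y + 1 else y
      # day AFTER the season end (half-open interval end), leap-day safe
      e_date <- if (emd == "02-28") {
        as.Date(paste0(ey, "-03-01"))  # absorbs 29 Feb in leap years
      } else {
        as.Date(paste0(ey, "-", emd)) + 1
      }
      e <- as.POSIXct(paste0(e_date, " 00:00:00"), tz = "UTC")
      data.frame(name = defs$name[i], year = y, start = s, end = e,
                 stringsAsFactors = FALSE)
    }))
  }))
  inst <- inst[inst$end > t_min & inst$start <= t_max, , drop = FALSE]
  inst <- inst[order(inst$start), ]
  rownames(inst) <- NULL
  inst
}

#' Assign a trajectory's fixes to seasonal segments
#'
#' Every fix falls in exactly one segment (season instances are half-open
#' `[start, end)` and tile the calendar).  A segment is `complete` when its
#' data span the full season, and `eligible` when at least `min_days` days
#' of relocation data (elapsed span between first and last fix in the
#' segment) are available.
#'
#' @param traj an `ehrm_traj`.
#' @param defs season definition table (default [season_defs_default()]).
#' @param min_days eligibility threshold in days (default 60).
#' @return data.frame of segments: `name`, `year`, `season_start`,
#'   `season_end`, `first_fix`, `last_fix`, `n_fixes`, `n_days`, `complete`,
#'   `eligible`, plus a list-column `fix_idx` of fix indices.
#' @export
assign_seasons <- function(traj, defs = season_defs_default(), min_days = 60) {
  stopifnot(inherits(traj, "ehrm_traj"))
  fx <- traj$fixes
  if (nrow(fx) == 0) stop("trajectory has no fixes")
  inst <- .season_instances(defs, min(fx$timestamp), max(fx$timestamp))
  # overlap check (definitions must tile the year)
  if (nrow(inst) > 1 && any(inst$start[-1] < inst$end[-nrow(inst)]))
    stop("season definitions overlap")
  seg <- lapply(seq_len(nrow(inst)), function(i) {
    idx <- which(fx$timestamp >= inst$start[i] & fx$timestamp < inst$end[i])
    if (!length(idx)) return(NULL)
    span_days <- as.numeric(difftime(fx$timestamp[max(idx)],
                                     fx$timestamp[min(idx)], units = "days"))
    season_days <- as.numeric(difftime(inst$end[i], inst$start[i],
                                       units = "days"))
    data.frame(name = inst$name[i], year = inst$year[i],
               season_start = inst$start[i], season_end = inst$end[i],
               first_fix = fx$timestamp[min(idx)],
               last_fix = fx$timestamp[max(idx)],
               n_fixes = length(idx), n_days = span_days,
               complete = span_days >= season_days - 1,
               eligible = span_days >= min_days,
               fix_from = min(idx), fix_to = max(idx),
               stringsAsFactors = FALSE)
  })
  seg <- do.call(rbind, seg)
  if (is.null(seg)) stop("no fixes fall in any season instance")
  rownames(seg) <- NULL
  seg
}

#' Run the Fixed-Period EHRM detector
#'
#' For each eligible seasonal segment: estimate the Brownian motion variance
#' from the segment's fixes, compute the BBMM utilization distribution on a
#' 100-m grid, extract the 95% contour, and scan the same segment's fixes
#' for EHRMs.  Contour and scan both use only the segment's own data -- the
#' method's defining property (and the source of its masking problem when
#' space use changes within a season).
#'
#' @param traj projected, censored `ehrm_traj`.
#' @param cfg a [detection_config()].
#' @param defs season definition table.
#' @param delta telemetry error SD in meters.
#' @param cell_size UD grid cell edge in meters (default 100).
#' @param min_days segment eligibility threshold (default 60).
#' @param min_lead_days optionally drop EHRMs initiated within this many days
#'   of the segment's first fix (default 0: keep all, as in conventional
#'   practice).
#' @param sigma2_m optional fixed Brownian motion variance; estimated per
#'   segment when `NULL`.
#' @return EHRM data.frame (`method = "fixed_period"`) with `season` and
#'   `season_year` columns; attribute `segments` holds the segment table and
#'   attribute `contours` the per-segment `ehrm_contour`s.
#' @export
run_fixed_period <- function(traj, cfg = detection_config(),
                             defs = season_defs_default(), delta = 15,
                             cell_size = 100, min_days = 60,
                             min_lead_days = 0, sigma2_m = NULL) {
  stopifnot(inherits(traj, "ehrm_traj"))
  seg <- assign_seasons(traj, defs, min_days = min_days)
  out <- .empty_ehrms()
  out$season <- character(0); out$season_year <- integer(0)
  contours <- list()
  if (!any(seg$eligible)) {
    warning("no eligible seasonal segments (>= ", min_days, " days)")
    attr(out, "segments") <- seg
    return(out)
  }
  max_gap <- if (is.finite(traj$median_interval))
    8 * traj$median_interval else Inf
  for (i in which(seg$eligible)) {
    idx <- seg$fix_from[i]:seg$fix_to[i]
    fx <- traj$fixes[idx, , drop = FALSE]
    if (nrow(fx) < 3) next
    s2 <- if (is.null(sigma2_m))
      estimate_sigma2m(fx, delta = delta, max_gap = max_gap) else sigma2_m
    par <- bbmm_params(s2, delta = delta, max_gap = max_gap)
    tt <- as.numeric(fx$timestamp)
    tmax <- max(pmin(diff(tt), max_gap), 0)
    grid <- fit_grid(fx$x, fx$y, cell_size, par, tmax)
    ud <- compute_ud(fx, grid, par)
    ctr <- extract_contour(ud, cfg$contour_level, source = "fixed_period")
    e <- detect_ehrms(fx, ctr, cfg, animal_id = traj$animal_id,
                      method = "fixed_period")
    if (nrow(e)) {
      if (min_lead_days > 0) {
        lead_cut <- seg$first_fix[i] + min_lead_days * 86400
        e <- e[e$initiation_time >= lead_cut, , drop = FALSE]
      }
      if (nrow(e)) {
        # member indices refer to the whole trajectory
        e$start_idx <- e$start_idx + seg$fix_from[i] - 1L
        e$end_idx <- e$end_idx + seg$fix_from[i] - 1L
        e$season <- seg$name[i]
        e$season_year <- seg$year[i]
        out <- rbind(out, e)
      }
    }
    contours[[paste0(seg$name[i], "_", seg$year[i])]] <- ctr
  }
  rownames(out) <- NULL
  attr(out, "segments") <- seg
  attr(out, "contours") <- contours
  out
}
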