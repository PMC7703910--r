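# Synthetic GPS trajectories with known ground truth.  The home-ranging
# baseline is a discretized Ornstein-Uhlenbeck (mean-reverting) process
# around a home center; planted events splice sallies (out-and-back
# excursions), permanent range shifts, and dispersals on top of it.  Scales
# default to a deer-like regime: stationary SD ~400 m (home ranges 1-3 km
# across), sally and shift offsets 1-8 km, fixes every 1 h or 3.5 h,
# 15-m telemetry error.

#' Simulated event
#'
#' @param kind `"sally"` (out-and-back excursion), `"shift"` (permanent
#'   home-center move) or `"dispersal"` (a large permanent move).
#' @param start_day day on which the event begins (day 1 = first data day).
#' @param start_hour hour of day at which it begins (default 6).
#' @param target_offset numeric length-2 vector (meters) from the current
#'   home center to the event target.
#' @param out_duration_hours total time away for a sally (transit out +
#'   dwell + transit back); ignored for shifts/dispersals.
#' @return list of class `ehrm_sim_event`.
#' @export
sim_event <- function(kind = c("sally", "shift", "dispersal"), start_day,
                      target_offset, out_duration_hours = 12,
                      start_hour = 6) {
  kind <- match.arg(kind)
  stopifnot(length(target_offset) == 2, start_day >= 1)
  structure(list(kind = kind, start_day = start_day, start_hour = start_hour,
                 target_offset = as.numeric(target_offset),
                 out_duration_hours = out_duration_hours),
            class = "ehrm_sim_event")
}

#' Simulation configuration
#'
#' @param seed RNG seed; the whole trajectory is reproducible from it.
#' @param duration_days length of the record.
#' @param fix_interval_hours fix schedule (1 and 3.5 are the two field
#'   regimes emulated).
#' @param start_date first fix date (UTC midnight), default `"2015-03-01"`.
#' @param home_center length-2 numeric, meters.
#' @param ou_attraction mean-reversion rate in 1/hours (default 0.1, i.e. a
#'   ~10 h return timescale).
#' @param ou_sd stationary SD of the OU process per axis, meters (default
#'   400: a home range roughly 1.5-2.5 km across at the 95% level).
#' @param error_sd telemetry error SD per fix, meters (default 15).
#' @param travel_speed speed of event transits, m/h (default 1000).
#' @param dwell_sd positional SD while dwelling at a sally target, meters
#'   (default 100).
#' @param events list of [sim_event()]s, non-overlapping in time.
#' @return list of class `ehrm_sim_config`.
#' @export
sim_config <- function(seed = 1, duration_days = 365,
                       fix_interval_hours = 3.5,
                       start_date = "2015-03-01", home_center = c(0, 0),
                       ou_attraction = 0.1, ou_sd = 400, error_sd = 15,
                       travel_speed = 1000, dwell_sd = 100,
                       events = list()) {
  stopifnot(ou_sd > 0, fix_interval_hours > 0, ou_attraction > 0)
  structure(list(seed = seed, duration_days = duration_days,
                 fix_interval_hours = fix_interval_hours,
                 start_date = start_date, home_center = home_center,
                 ou_attraction = ou_attraction, ou_sd = ou_sd,
                 error_sd = error_sd, travel_speed = travel_speed,
                 dwell_sd = dwell_sd, events = events),
            class = "ehrm_sim_config")
}

# Exact OU transition over a time step dt (hours): new = c + (old - c) * rho
# + N(0, sd^2 (1 - rho^2)), rho = exp(-beta * dt).
.ou_step <- function(prev, center, beta, sd, dt) {
  rho <- exp(-beta * dt)
  center + (prev - center) * rho + stats::rnorm(2, 0, sd * sqrt(1 - rho^2))
}

.event_times <- function(ev, cfg) {
  t0 <- (ev$start_day - 1) * 24 + ev$start_hour      # hours since record start
  dist <- sqrt(sum(ev$target_offset^2))
  transit <- dist / cfg$travel_speed
  if (ev$kind == "sally") {
    dwell <- max(ev$out_duration_hours - 2 * transit, 0)
    c(t0 = t0, t_arrive = t0 + transit, t_leave = t0 + transit + dwell,
      t_end = t0 + 2 * transit + dwell)
  } else {
    c(t0 = t0, t_arrive = t0 + transit, t_leave = Inf, t_end = Inf)
  }
}

#' Simulate a GPS trajectory with planted movement events
#'
#' Baseline positions follow the exact discrete OU transition around the
#' (possibly shifting) home center.  During a sally the animal travels to
#' `home_center + target_offset` at `travel_speed`, dwells there with
#' positional SD `dwell_sd`, and returns; the OU state resumes where it left
#' off.  A shift or dispersal moves the home center permanently, with a
#' single transit at `travel_speed`.  Independent Gaussian telemetry error
#' of SD `error_sd` is added to every fix.
#'
#' @param cfg an [sim_config()].
#' @return list: `traj` (an `ehrm_traj`, planar CRS) and `truth`
#'   (data.frame: one row per event with realized first/last fix index of
#'   the away period).
#' @export
simulate_trajectory <- function(cfg) {
  stopifnot(inherits(cfg, "ehrm_sim_config"))
  evs <- cfg$events
  if (length(evs) > 1) {
    spans <- t(vapply(evs, function(e) {
      tm <- .event_times(e, cfg)
      if (e$kind == "sally") c(tm["t0"], tm["t_end"])
      else c(tm["t0"], tm["t_arrive"])
    }, numeric(2)))
    o <- order(spans[, 1])
    if (any(spans[o, 1][-1] < spans[o, 2][-length(evs)]))
      stop("events overlap in time")
  }
  set.seed(cfg$seed)
  dt <- cfg$fix_interval_hours
  times_h <- seq(0, cfg$duration_days * 24 - 1e-9, by = dt)
  n <- length(times_h)
  t0 <- as.POSIXct(paste(cfg$start_date, "00:00:00"), tz = "UTC")
  beta <- cfg$ou_attraction
  center <- cfg$home_center
  ou <- center + stats::rnorm(2, 0, cfg$ou_sd)    # stationary start
  xs <- ys <- numeric(n)
  away_from <- rep(NA_integer_, length(evs))
  away_to <- rep(NA_integer_, length(evs))
  etimes <- lapply(evs, .event_times, cfg = cfg)
  for (k in seq_len(n)) {
    th <- times_h[k]
    if (k > 1) ou <- .ou_step(ou, center, beta, cfg$ou_sd, dt)
    pos <- ou
    for (j in seq_along(evs)) {
      ev <- evs[[j]]; tm <- etimes[[j]]
      if (th < tm["t0"]) next
      target <- center + ev$target_offset
      if (ev$kind == "sally") {
        if (th >= tm["t_end"]) next
        # along the out-leg, dwelling, or along the back-leg
        pos <- if (th < tm["t_arrive"]) {
          frac <- (th - tm["t0"]) / (tm["t_arrive"] - tm["t0"])
          center + frac * ev$target_offset
        } else if (th < tm["t_leave"]) {
          target + stats::rnorm(2, 0, cfg$dwell_sd)
        } else {
          frac <- (th - tm["t_leave"]) / (tm["t_end"] - tm["t_leave"])
          center + (1 - frac) * ev$target_offset
        }
        if (is.na(away_from[j])) away_from[j] <- k
        away_to[j] <- k
      } else {
        # permanent shift/dispersal: transit, then re-center the OU
        if (th < tm["t_arrive"]) {
          frac <- (th - tm["t0"]) / (tm["t_arrive"] - tm["t0"])
          pos <- center + frac * ev$target_offset
          if (is.na(away_from[j])) away_from[j] <- k
          away_to[j] <- k
        } else {
          center <- center + ev$target_offset
          ou <- center + (ou - (center - ev$target_offset)) # keep deviation
          etimes[[j]]["t0"] <- Inf                          # consumed
          if (is.na(away_from[j])) away_from[j] <- k
          pos <- ou
        }
      }
    }
    xs[k] <- pos[1]; ys[k] <- pos[2]
  }
  xs <- xs + stats::rnorm(n, 0, cfg$error_sd)
  ys <- ys + stats::rnorm(n, 0, cfg$error_sd)
  fixes <- data.frame(timestamp = t0 + times_h * 3600, x = xs, y = ys)
  truth <- if (length(evs)) data.frame(
    kind = vapply(evs, `[[`, "", "kind"),
    start_day = vapply(evs, `[[`, 0, "start_day"),
    offset_x = vapply(evs, function(e) e$target_offset[1], 0),
    offset_y = vapply(evs, function(e) e$target_offset[2], 0),
    fix_from = away_from, fix_to = away_to,
    stringsAsFactors = FALSE)
  else data.frame(kind = character(), start_day = numeric(),
                  offset_x = numeric(), offset_y = numeric(),
                  fix_from = integer(), fix_to = integer())
  list(traj = trajectory(fixes, animal_id = paste0("sim", cfg$seed),
                         crs = "planar"),
       truth = truth)
}

#' Named scenario presets
#'
#' Frozen study-condition presets used throughout validation:
#' * `stationary` -- 130 days, no events.
#' * `single_sally` -- one 2.5-km out-and-back sally on day 70.
#' * `sally_then_shift` -- two paired-detectable sallies (days 62 and 66,
#'   2.5 km N and S), a sally on day 69 into the area 2.5 km E that the
#'   animal then shifts to permanently on day 74: the masking scenario in
#'   which a seasonal home range swallows the visited area, hiding the
#'   day-69 movement from Fixed-Period detection.
#' * `mid_season_shift` -- permanent 4-km shift on day 65, then sallies on
#'   days 90 and 105 from the new range back into the old one (inside the
#'   seasonal contour, so invisible to Fixed-Period detection).
#' * `dispersal` -- permanent 10-km move on day 70.
#' * `year_of_sallies` -- a full 365-day record with twelve sallies of
#'   1.5-4 km spread across the year (days 65-352), directions drawn from
#'   the seed; used for whole-year detection and criteria summaries.
#'
#' All use 3.5-h fixes starting 1 March, OU SD 400 m, 15-m error.
#'
#' @param name scenario name.
#' @param seed RNG seed.
#' @return an [sim_config()].
#' @export
scenario_config <- function(name = c("stationary", "single_sally",
                                     "sally_then_shift", "mid_season_shift",
                                     "dispersal", "year_of_sallies"),
                            seed = 1) {
  name <- match.arg(name)
  if (name == "year_of_sallies") {
    set.seed(seed + 1003L)
    evs <- lapply(round(seq(65, 352, length.out = 12)), function(d) {
      th <- stats::runif(1, 0, 2 * pi)
      sim_event("sally", start_day = d,
                target_offset = round(stats::runif(1, 1500, 4000)) *
                  c(cos(th), sin(th)),
                out_duration_hours = sample(8:24, 1))
    })
    return(sim_config(seed = seed, duration_days = 365,
                      fix_interval_hours = 3.5, events = evs))
  }
  base <- function(days, events = list())
    sim_config(seed = seed, duration_days = days, fix_interval_hours = 3.5,
               events = events)
  switch(name,
    stationary = base(130),
    single_sally = base(130, list(
      sim_event("sally", start_day = 70, target_offset = c(2500, 0),
                out_duration_hours = 14))),
    sally_then_shift = base(110, list(
      sim_event("sally", start_day = 62, target_offset = c(0, 2500),
                out_duration_hours = 12),
      sim_event("sally", start_day = 66, target_offset = c(0, -2500),
                out_duration_hours = 12),
      sim_event("sally", start_day = 69, target_offset = c(2500, 0),
                out_duration_hours = 16),
      sim_event("shift", start_day = 74, target_offset = c(2500, 0)))),
    mid_season_shift = base(130, list(
      sim_event("shift", start_day = 65, target_offset = c(4000, 0)),
      sim_event("sally", start_day = 90, target_offset = c(-3000, 0),
                out_duration_hours = 12),
      sim_event("sally", start_day = 105, target_offset = c(-3000, 0),
                out_duration_hours = 12))),
    dispersal = base(150, list(
      sim_event("dispersal", start_day = 70,
                target_offset = c(7000, 7000)))))
}

#' Write the scenario fixture suite to disk
#'
#' One relocation CSV (gps_io dialect, planar `x`/`y`) and one ground-truth
#' CSV per scenario.
#'
#' @param out_dir writable directory (created if missing).
#' @param seed RNG seed shared by all scenarios.
#' @return invisibly, the vector of files written.
#' @export
emit_fixture_suite <- function(out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  names <- c("stationary", "single_sally", "sally_then_shift",
             "mid_season_shift", "dispersal")
  files <- character()
  for (nm in names) {
    sim <- simulate_trajectory(scenario_config(nm, seed))
    f1 <- file.path(out_dir, paste0(nm, ".csv"))
    f2 <- file.path(out_dir, paste0(nm, "_truth.csv"))
    write_fixes(sim$traj, f1)
    utils::write.csv(sim$truth, f2, row.names = FALSE)
    files <- c(files, f1, f2)
  }
  invisible(files)
}
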