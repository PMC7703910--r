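# Reading, validation, censoring and projection of GPS relocation data.

#' Default CSV dialect for relocation files
#'
#' Maps the logical fields of a fix to CSV column names.  Coordinate input can
#' be geographic (`lon`/`lat`, degrees) or already projected (`x`/`y`,
#' meters); at least one pair must be present in the file.
#'
#' @param animal_id,timestamp,lon,lat,x,y,fix_dim,hdop,pdop column names.
#' @param tz timezone used to interpret timestamps (default `"UTC"`).
#' @return a named list describing the dialect.
#' @export
csv_dialect <- function(animal_id = "animal_id", timestamp = "timestamp",
                        lon = "lon", lat = "lat", x = "x", y = "y",
                        fix_dim = "fix_dim", hdop = "hdop", pdop = "pdop",
                        tz = "UTC") {
  list(animal_id = animal_id, timestamp = timestamp, lon = lon, lat = lat,
       x = x, y = y, fix_dim = fix_dim, hdop = hdop, pdop = pdop, tz = tz)
}

#' Trajectory constructor
#'
#' A trajectory is one animal's time-ordered fix sequence plus metadata.  The
#' fix table has one row per relocation with (at least) columns `timestamp`
#' (POSIXct), and `x`,`y` in meters once projected.  Duplicate timestamps are
#' dropped (first kept) and rows are sorted by time.
#'
#' @param fixes data.frame of fixes.
#' @param animal_id identifier.
#' @param capture_time optional POSIXct capture instant (needed for
#'   post-capture censoring).
#' @param crs coordinate system descriptor: `"planar"` for abstract projected
#'   meters, or a list `list(proj = "utm", zone =, hemisphere =)`.
#' @return object of class `ehrm_traj`.
#' @export
trajectory <- function(fixes, animal_id, capture_time = NULL, crs = "planar") {
  stopifnot(is.data.frame(fixes), "timestamp" %in% names(fixes))
  o <- order(fixes$timestamp)
  fixes <- fixes[o, , drop = FALSE]
  dup <- duplicated(fixes$timestamp)
  n_dropped <- sum(dup)
  fixes <- fixes[!dup, , drop = FALSE]
  rownames(fixes) <- NULL
  iv <- if (nrow(fixes) > 1) {
    stats::median(as.numeric(diff(fixes$timestamp), units = "secs"))
  } else NA_real_
  structure(
    list(animal_id = as.character(animal_id), fixes = fixes,
         capture_time = capture_time, crs = crs,
         median_interval = iv, n_duplicates_dropped = n_dropped),
    class = "ehrm_traj")
}

#' @export
print.ehrm_traj <- function(x, ...) {
  cat("<ehrm_traj> animal", x$animal_id, "-", nrow(x$fixes), "fixes")
  if (nrow(x$fixes)) {
    cat(", ", format(min(x$fixes$timestamp)), " to ",
        format(max(x$fixes$timestamp)), sep = "")
  }
  cat("\n")
  invisible(x)
}

.parse_ts <- function(x, tz) {
  out <- as.POSIXct(x, tz = tz,
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                   "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"),
                    optional = TRUE)
  out
}

#' Read relocation CSV into trajectories
#'
#' Splits the file by animal, parses timestamps, drops rows with unparseable
#' time or coordinates (counted in the attached report), deduplicates
#' timestamps within an animal (first kept) and sorts by time.
#'
#' @param path CSV file.
#' @param dialect column mapping from [csv_dialect()].
#' @return named list of [trajectory()] objects, one per animal, with a
#'   `report` attribute (rows read / dropped by reason).
#' @export
read_fixes <- function(path, dialect = csv_dialect()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("animal_id", "timestamp"))
    if (!dialect[[col]] %in% names(raw))
      stop("missing required column: ", dialect[[col]])
  has_geo <- all(c(dialect$lon, dialect$lat) %in% names(raw))
  has_xy <- all(c(dialect$x, dialect$y) %in% names(raw))
  if (!has_geo && !has_xy)
    stop("missing required coordinate columns: need ",
         dialect$lon, "/", dialect$lat, " or ", dialect$x, "/", dialect$y)
  if (nrow(raw) == 0) {
    warning("empty relocation file: ", path)
    return(structure(list(),
                     report = data.frame(rows_read = 0, rows_dropped = 0,
                                         duplicates_dropped = 0)))
  }
  ts <- .parse_ts(raw[[dialect$timestamp]], dialect$tz)
  if (has_geo) {
    cx <- suppressWarnings(as.numeric(raw[[dialect$lon]]))
    cy <- suppressWarnings(as.numeric(raw[[dialect$lat]]))
  } else {
    cx <- suppressWarnings(as.numeric(raw[[dialect$x]]))
    cy <- suppressWarnings(as.numeric(raw[[dialect$y]]))
  }
  keep <- !is.na(ts) & is.finite(cx) & is.finite(cy)
  n_bad <- sum(!keep)
  df <- data.frame(animal_id = as.character(raw[[dialect$animal_id]]),
                   timestamp = ts, stringsAsFactors = FALSE)
  if (has_geo) { df$lon <- cx; df$lat <- cy }
  if (has_xy) {
    df$x <- suppressWarnings(as.numeric(raw[[dialect$x]]))
    df$y <- suppressWarnings(as.numeric(raw[[dialect$y]]))
  } else if (!has_geo) { df$x <- cx; df$y <- cy }
  for (col in c("fix_dim", "hdop", "pdop")) {
    if (dialect[[col]] %in% names(raw)) {
      v <- raw[[dialect[[col]]]]
      df[[col]] <- if (col == "fix_dim") as.character(v)
        else suppressWarnings(as.numeric(v))
    }
  }
  df <- df[keep, , drop = FALSE]
  crs <- if (has_geo && !has_xy) "geographic" else "planar"
  out <- lapply(split(df, df$animal_id), function(d)
    trajectory(d, d$animal_id[1], crs = crs))
  n_dup <- sum(vapply(out, function(tr) tr$n_duplicates_dropped, 0L))
  attr(out, "report") <- data.frame(rows_read = nrow(raw),
                                    rows_dropped = n_bad,
                                    duplicates_dropped = n_dup)
  out
}

#' Write a fix table (or trajectory) back to CSV
#'
#' Output uses the same dialect as input plus `x`,`y`,`crs` columns when the
#' trajectory is projected.
#'
#' @param traj an `ehrm_traj` or a plain fix data.frame.
#' @param path output file.
#' @param dialect column mapping.
#' @export
write_fixes <- function(traj, path, dialect = csv_dialect()) {
  fx <- if (inherits(traj, "ehrm_traj")) traj$fixes else traj
  out <- fx
  if (inherits(traj, "ehrm_traj") && !"animal_id" %in% names(out))
    out <- cbind(animal_id = traj$animal_id, out)
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (inherits(traj, "ehrm_traj") && "x" %in% names(out))
    out$crs <- .crs_label(traj$crs)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
}

.crs_label <- function(crs) {
  if (is.character(crs)) return(crs)
  paste0(crs$proj, crs$zone, crs$hemisphere)
}

#' Censor fixes on dilution-of-precision quality
#'
#' Removes 2D fixes with HDOP > 5 and 3D fixes with PDOP > 10 or HDOP > 6.
#' Fixes whose dimension or relevant DOP value is missing are retained
#' (absence of the quality metric is not evidence of a bad fix); the number
#' retained that way is reported in the `n_missing_dop` attribute.
#'
#' @param fixes fix data.frame with `fix_dim`, `hdop`, `pdop` columns (any
#'   may be absent or NA).
#' @return the filtered data.frame (row order preserved).
#' @export
censor_dop <- function(fixes) {
  n <- nrow(fixes)
  dim3 <- if ("fix_dim" %in% names(fixes)) fixes$fix_dim else rep(NA, n)
  hdop <- if ("hdop" %in% names(fixes)) fixes$hdop else rep(NA_real_, n)
  pdop <- if ("pdop" %in% names(fixes)) fixes$pdop else rep(NA_real_, n)
  is2d <- !is.na(dim3) & dim3 %in% c("2D", "2d", "2")
  is3d <- !is.na(dim3) & dim3 %in% c("3D", "3d", "3")
  bad2 <- is2d & !is.na(hdop) & hdop > 5
  bad3 <- is3d & ((!is.na(pdop) & pdop > 10) | (!is.na(hdop) & hdop > 6))
  keep <- !(bad2 | bad3)
  miss <- sum((is2d & is.na(hdop)) | (is3d & is.na(pdop) & is.na(hdop)))
  out <- fixes[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- n - nrow(out)
  attr(out, "n_missing_dop") <- miss
  out
}

#' Censor the post-capture acclimation period
#'
#' Removes all fixes with timestamp earlier than `capture_time + days`
#' (half-open: a fix exactly at the boundary is retained).
#'
#' @param traj an `ehrm_traj` with `capture_time` set (unless `days = 0`).
#' @param days length of the censoring window, default 7.
#' @return the censored trajectory.
#' @export
censor_post_capture <- function(traj, days = 7) {
  stopifnot(inherits(traj, "ehrm_traj"))
  if (days == 0) return(traj)
  if (is.null(traj$capture_time))
    stop("capture_time is not set for animal ", traj$animal_id,
         "; set it on the trajectory or pass days = 0")
  cutoff <- traj$capture_time + days * 86400
  traj$fixes <- traj$fixes[traj$fixes$timestamp >= cutoff, , drop = FALSE]
  rownames(traj$fixes) <- NULL
  traj
}

#' Project a trajectory into planar UTM coordinates
#'
#' Geographic trajectories are projected to the UTM zone of their centroid
#' (or a given zone); already-planar trajectories are returned unchanged.
#' All downstream analysis expects meters in one planar CRS.
#'
#' @param traj an `ehrm_traj`.
#' @param zone optional UTM zone override.
#' @param hemisphere `"N"` or `"S"`; inferred from the centroid by default.
#' @return trajectory with `x`,`y` columns in meters and `crs` recorded.
#' @export
project_fixes <- function(traj, zone = NULL, hemisphere = NULL) {
  stopifnot(inherits(traj, "ehrm_traj"))
  fx <- traj$fixes
  if (!all(c("lon", "lat") %in% names(fx))) {
    if (all(c("x", "y") %in% names(fx))) return(traj)  # already planar
    stop("trajectory has neither lon/lat nor x/y coordinates")
  }
  bad <- which(abs(fx$lat) > 84 | abs(fx$lon) > 180)
  if (length(bad))
    stop("coordinates outside projection validity at rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  if (is.null(zone)) zone <- utm_zone(mean(fx$lon))
  if (is.null(hemisphere)) hemisphere <- if (mean(fx$lat) >= 0) "N" else "S"
  xy <- utm_forward(fx$lon, fx$lat, zone, hemisphere)
  traj$fixes$x <- xy$x
  traj$fixes$y <- xy$y
  traj$crs <- list(proj = "utm", zone = zone, hemisphere = hemisphere)
  traj
}
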