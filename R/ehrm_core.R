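# EHRM extraction: maximal runs of fixes outside a home-range contour,
# bracketed by the last fix inside before departure and the first fix back
# inside after return.

#' Detection configuration
#'
#' @param min_points minimum member fixes for a closed EHRM, counting the two
#'   bracketing inside fixes (default 3: inside-outside-inside).  This makes
#'   the minimum possible duration two fix intervals.
#' @param min_distance minimum distance (m) that at least one member fix must
#'   extend beyond the contour edge (default 500).
#' @param contour_level isopleth level of the home-range contour used for
#'   detection (default 0.95).
#' @return list of class `ehrm_detection_config`.
#' @export
detection_config <- function(min_points = 3, min_distance = 500,
                             contour_level = 0.95) {
  stopifnot(min_points >= 3, min_distance >= 0,
            contour_level > 0, contour_level <= 1)
  structure(list(min_points = min_points, min_distance = min_distance,
                 contour_level = contour_level),
            class = "ehrm_detection_config")
}

.empty_ehrms <- function() {
  data.frame(animal_id = character(), method = character(),
             start_time = as.POSIXct(character(), tz = "UTC"),
             end_time = as.POSIXct(character(), tz = "UTC"),
             initiation_time = as.POSIXct(character(), tz = "UTC"),
             n_fixes = integer(), max_distance_m = numeric(),
             duration_h = numeric(), open_ended = logical(),
             open_start = logical(), start_idx = integer(),
             end_idx = integer(), stringsAsFactors = FALSE)
}

#' Detect extra-home range movements against a contour
#'
#' Scans a time-ordered fix sequence for maximal runs of consecutive fixes
#' outside the contour.  Each run is bracketed by the preceding inside fix
#' (the EHRM start) and the following inside fix (the EHRM end).  A run
#' qualifies when its total member count (brackets included) is at least
#' `min_points` and at least one outside fix lies `min_distance` or more
#' beyond the contour edge.  A fix exactly on the contour boundary counts as
#' inside (the half-open cell rule).
#'
#' Runs still outside at the end of the sequence are returned with
#' `open_ended = TRUE` and no end fix (dispersal candidates); a sequence that
#' begins outside yields a leading run with `open_start = TRUE` and no start
#' fix.  Both are excluded from closed-EHRM duration statistics.
#'
#' @param fixes time-ordered fix data.frame with `x`, `y`, `timestamp`.
#' @param contour an `ehrm_contour`.
#' @param cfg a [detection_config()].
#' @param animal_id,method metadata copied onto the results.
#' @return data.frame with one row per EHRM: `animal_id`, `method`,
#'   `start_time`, `end_time`, `initiation_time` (first outside fix),
#'   `n_fixes`, `max_distance_m`, `duration_h`, `open_ended`, `open_start`,
#'   and member index range `start_idx`/`end_idx` into `fixes`.
#' @export
detect_ehrms <- function(fixes, contour, cfg = detection_config(),
                         animal_id = "animal", method = "fixed_period") {
  if (inherits(fixes, "ehrm_traj")) {
    animal_id <- fixes$animal_id
    fixes <- fixes$fixes
  }
  stopifnot(inherits(contour, "ehrm_contour"))
  if (nrow(contour$cells) == 0) stop("contour is empty")
  n <- nrow(fixes)
  if (n == 0) return(.empty_ehrms())
  inside <- point_in_contour(fixes$x, fixes$y, contour)
  if (all(inside)) return(.empty_ehrms())
  dist <- numeric(n)
  dist[!inside] <- distance_to_contour(fixes$x[!inside], fixes$y[!inside],
                                       contour)
  r <- rle(!inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- .empty_ehrms()
  for (k in which(r$values)) {
    o1 <- starts[k]; o2 <- ends[k]          # outside run
    s <- o1 - 1                             # bracketing inside fixes
    e <- o2 + 1
    open_start <- s < 1
    open_ended <- e > n
    n_fixes <- (o2 - o1 + 1) + (!open_start) + (!open_ended)
    maxd <- max(dist[o1:o2])
    closed <- !open_start && !open_ended
    min_needed <- if (closed) cfg$min_points else cfg$min_points - 1L
    if (n_fixes < min_needed || maxd < cfg$min_distance) next
    row <- data.frame(
      animal_id = animal_id, method = method,
      start_time = if (!open_start) fixes$timestamp[s] else
        as.POSIXct(NA, tz = "UTC"),
      end_time = if (!open_ended) fixes$timestamp[e] else
        as.POSIXct(NA, tz = "UTC"),
      initiation_time = fixes$timestamp[o1],
      n_fixes = as.integer(n_fixes), max_distance_m = maxd,
      duration_h = if (closed)
        as.numeric(difftime(fixes$timestamp[e], fixes$timestamp[s],
                            units = "hours")) else NA_real_,
      open_ended = open_ended, open_start = open_start,
      start_idx = as.integer(max(s, o1)), end_idx = as.integer(min(e, n)),
      stringsAsFactors = FALSE)
    out <- rbind(out, row)
  }
  rownames(out) <- NULL
  out
}

#' Maximum distance of an EHRM beyond the contour edge
#'
#' @param e one-row EHRM data.frame (or a row subset).
#' @return meters.
#' @export
ehrm_max_distance <- function(e) e$max_distance_m

#' Duration of a closed EHRM
#'
#' Elapsed time from the last fix inside the contour before departure to the
#' first fix back inside after return.
#'
#' @param e one-row EHRM data.frame.
#' @return hours.
#' @export
ehrm_duration <- function(e) {
  if (any(e$open_ended | e$open_start))
    stop("EHRM is open-ended; duration undefined (see dispersal handling)")
  e$duration_h
}

#' Write an EHRM table to CSV
#'
#' @param ehrms EHRM data.frame from a detector.
#' @param path output file.
#' @export
write_ehrms <- function(ehrms, path) {
  out <- ehrms
  for (col in c("start_time", "end_time", "initiation_time"))
    out[[col]] <- format(out[[col]], "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an EHRM table written by [write_ehrms()]
#'
#' @param path CSV file.
#' @return EHRM data.frame with POSIXct time columns.
#' @export
read_ehrms <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("start_time", "end_time", "initiation_time"))
    if (col %in% names(df))
      df[[col]] <- as.POSIXct(df[[col]], tz = "UTC",
                              format = "%Y-%m-%dT%H:%M:%S")
  df
}
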