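# Literature-derived EHRM definition criteria: distance and/or duration
# thresholds with AND/OR conjunctions, applied to a detected EHRM set to
# report how many movements each definition would have retained.

#' Construct a definition criterion
#'
#' @param name label for reports.
#' @param distance_km distance threshold in kilometers (`NULL` if unused).
#' @param distance_strict `TRUE` for a strict `>` comparison, `FALSE` for
#'   `>=`.
#' @param duration_h duration threshold in hours (`NULL` if unused).
#' @param duration_strict strictness of the duration comparison.
#' @param conjunction one of `"distance_only"`, `"duration_only"`, `"AND"`,
#'   `"OR"`.
#' @return list of class `ehrm_criteria_spec`.
#' @export
criteria_spec <- function(name, distance_km = NULL, distance_strict = FALSE,
                          duration_h = NULL, duration_strict = FALSE,
                          conjunction = c("distance_only", "duration_only",
                                          "AND", "OR")) {
  conjunction <- match.arg(conjunction)
  needs_dist <- conjunction %in% c("distance_only", "AND", "OR")
  needs_dur <- conjunction %in% c("duration_only", "AND", "OR")
  if (needs_dist && is.null(distance_km))
    stop("conjunction ", conjunction, " requires a distance threshold")
  if (needs_dur && is.null(duration_h))
    stop("conjunction ", conjunction, " requires a duration threshold")
  structure(list(name = name, distance_km = distance_km,
                 distance_strict = distance_strict, duration_h = duration_h,
                 duration_strict = duration_strict,
                 conjunction = conjunction),
            class = "ehrm_criteria_spec")
}

.spec_label <- function(s) {
  dpart <- if (!is.null(s$distance_km))
    paste0(if (s$distance_strict) ">" else ">=", s$distance_km, " km")
  tpart <- if (!is.null(s$duration_h))
    paste0(if (s$duration_strict) ">" else ">=", s$duration_h, " h")
  switch(s$conjunction,
         distance_only = dpart,
         duration_only = tpart,
         AND = paste(dpart, "AND", tpart),
         OR = paste(dpart, "OR", tpart))
}

#' Built-in registry of published white-tailed deer EHRM criteria
#'
#' The fixed distance and/or duration definitions used by earlier
#' white-tailed deer excursion studies, with strict/non-strict comparisons
#' taken literally from each study's printed symbols.  Non-standard "OR"
#' clauses (such as percent-of-daily-points rules) are omitted.
#'
#' @return named list of [criteria_spec()] objects.
#' @export
builtin_criteria <- function() {
  list(
    nelson_mech_1981 = criteria_spec("Nelson and Mech 1981",
      distance_km = 1.6, distance_strict = TRUE,
      conjunction = "distance_only"),
    kolodzinski_2010 = criteria_spec("Kolodzinski et al. 2010",
      distance_km = 0.75, distance_strict = TRUE,
      conjunction = "distance_only"),
    lutz_2016 = criteria_spec("Lutz et al. 2016",
      distance_km = 1.5, distance_strict = TRUE,
      conjunction = "distance_only"),
    sullivan_2017 = criteria_spec("Sullivan et al. 2017",
      distance_km = 0.5, distance_strict = FALSE,
      conjunction = "distance_only"),
    karns_2011 = criteria_spec("Karns et al. 2011",
      distance_km = 0.5, distance_strict = TRUE,
      duration_h = 6, duration_strict = FALSE, conjunction = "AND"),
    olson_2015 = criteria_spec("Olson et al. 2015",
      distance_km = 1.6, distance_strict = FALSE,
      duration_h = 12, duration_strict = FALSE, conjunction = "AND"),
    simoneaux_2015 = criteria_spec("Simoneaux 2015",
      distance_km = 1.6, distance_strict = FALSE,
      duration_h = 13, duration_strict = TRUE, conjunction = "AND"))
}

.criteria_mask <- function(ehrms, spec) {
  cmp <- function(v, thr, strict) if (strict) v > thr else v >= thr
  dmask <- if (!is.null(spec$distance_km)) {
    if (!"max_distance_m" %in% names(ehrms))
      stop("EHRM table lacks max_distance_m required by criterion")
    cmp(ehrms$max_distance_m / 1000, spec$distance_km, spec$distance_strict)
  }
  tmask <- if (!is.null(spec$duration_h)) {
    if (!"duration_h" %in% names(ehrms))
      stop("EHRM table lacks duration_h required by criterion")
    m <- cmp(ehrms$duration_h, spec$duration_h, spec$duration_strict)
    m & !is.na(m)  # open-ended EHRMs (NA duration) never satisfy a
                   # duration clause
  }
  switch(spec$conjunction,
         distance_only = dmask,
         duration_only = tmask,
         AND = dmask & tmask,
         OR = dmask | tmask)
}

#' Apply a definition criterion to an EHRM set
#'
#' @param ehrms EHRM data.frame with `max_distance_m` and `duration_h`.
#' @param spec a [criteria_spec()].
#' @return the subset of rows satisfying the criterion.
#' @export
apply_criteria <- function(ehrms, spec) {
  out <- ehrms[.criteria_mask(ehrms, spec), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify an EHRM into the distance/duration sectors
#'
#' Given non-strict distance and duration thresholds: sector II satisfies
#' both, I distance only, III duration only, IV neither.  The four sectors
#' partition any EHRM set, so `n(OR) = n(I) + n(II) + n(III)`,
#' `n(AND) = n(II)`, and inclusion-exclusion
#' `n(OR) = n(distance) + n(duration) - n(AND)` holds exactly.
#'
#' @param max_distance_m,duration_h EHRM metrics (vectors).
#' @param distance_thr_m distance threshold in meters.
#' @param duration_thr_h duration threshold in hours.
#' @return character vector of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @export
sector_classify <- function(max_distance_m, duration_h, distance_thr_m,
                            duration_thr_h) {
  d <- max_distance_m >= distance_thr_m
  t <- !is.na(duration_h) & duration_h >= duration_thr_h
  ifelse(d & t, "II", ifelse(d, "I", ifelse(t, "III", "IV")))
}

#' Detection-fraction report over a list of criteria
#'
#' @param ehrms nonempty EHRM data.frame.
#' @param specs list of [criteria_spec()]s (default the built-in registry).
#' @return data.frame with one row per criterion: `name`, `criteria`,
#'   `n_detected`, `percent` (of `nrow(ehrms)`).
#' @export
criteria_report <- function(ehrms, specs = builtin_criteria()) {
  if (nrow(ehrms) == 0) stop("empty EHRM set")
  rows <- lapply(specs, function(s) {
    n <- sum(.criteria_mask(ehrms, s))
    data.frame(name = s$name, criteria = .spec_label(s), n_detected = n,
               percent = 100 * n / nrow(ehrms), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
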