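#' Effort metric names
#'
#' The nine parental-effort metrics supported by the pipeline. `care` is
#' incubation during the incubation stage and brooding post-hatching;
#' `attendance` is the union of care time and time merely inside the nest box.
#' `joint_*` is the interval intersection of the two parents' sets (both
#' parents simultaneously), `total_*` the union (at least one parent).
#' `prop_male_feedings` is a count ratio, not a duration metric.
#'
#' @export
EFFORT_METRICS <- c("male_care", "female_care",
                    "male_attendance", "female_attendance",
                    "joint_care", "joint_attendance",
                    "total_care", "total_attendance",
                    "prop_male_feedings")

PARENTS <- c("male", "female")
STATES  <- c("care", "inside")
STAGES  <- c("incubation", "provisioning")

#' Seconds since midnight for an "HH:MM" string
#'
#' @param x character vector like `"07:00"`.
#' @return numeric seconds since local midnight.
#' @export
hms_seconds <- function(x) {
  p <- strsplit(x, ":", fixed = TRUE)
  vapply(p, function(q) {
    q <- as.numeric(q)
    q[1] * 3600 + q[2] * 60 + if (length(q) > 2) q[3] else 0
  }, numeric(1))
}

#' A coded nest recording
#'
#' Container for all coded behaviour of one nest on one recording day: state
#' intervals (care / inside) per parent, feeding point events, and footage
#' gaps. Times are seconds since local midnight; intervals are half-open
#' `[start, end)`. The canonical full-day recording spans 07:00-19:00
#' (25200-68400 s) and the canonical mid-stage recording 10:00-13:00.
#'
#' On construction each (parent, state) track is normalized (sorted,
#' overlapping or touching intervals merged), all invariants are checked, and
#' violations raise errors naming the offending record.
#'
#' @param nest_id nest identifier (character).
#' @param stage `"incubation"` or `"provisioning"`.
#' @param stage_day integer day within the stage (3/8/13 or 3/10/17 in the
#'   reference design; any positive integer is accepted).
#' @param record_start,record_end recording span, seconds since midnight.
#' @param intervals data frame with columns `parent` (`male`/`female`),
#'   `state` (`care`/`inside`), `start`, `end` (seconds).
#' @param feedings data frame with columns `parent`, `time`; empty for
#'   incubation-stage recordings.
#' @param gaps data frame with columns `start`, `end`: spans with no footage.
#' @return an object of class `nest_recording`.
#' @export
nest_recording <- function(nest_id, stage, stage_day,
                           record_start, record_end,
                           intervals = NULL, feedings = NULL, gaps = NULL) {
  tag <- sprintf("nest %s %s day %s", nest_id, stage, stage_day)
  stage <- match.arg(stage, STAGES)
  if (!is.numeric(record_start) || !is.numeric(record_end) ||
      record_end <= record_start)
    stop(sprintf("%s: record_end must exceed record_start", tag))
  if (is.null(intervals))
    intervals <- data.frame(parent = character(0), state = character(0),
                            start = numeric(0), end = numeric(0))
  if (is.null(feedings))
    feedings <- data.frame(parent = character(0), time = numeric(0))
  if (is.null(gaps))
    gaps <- data.frame(start = numeric(0), end = numeric(0))

  if (nrow(intervals)) {
    bad <- which(intervals$end <= intervals$start)
    if (length(bad))
      stop(sprintf("%s: interval %d has end <= start (%.1f, %.1f)",
                   tag, bad[1], intervals$start[bad[1]], intervals$end[bad[1]]))
    if (!all(intervals$parent %in% PARENTS))
      stop(sprintf("%s: unknown parent level", tag))
    if (!all(intervals$state %in% STATES))
      stop(sprintf("%s: unknown state level", tag))
    if (any(intervals$start < record_start - 1e-9) ||
        any(intervals$end > record_end + 1e-9))
      stop(sprintf("%s: interval outside the recording span", tag))
  }
  if (nrow(feedings)) {
    if (!all(feedings$parent %in% PARENTS))
      stop(sprintf("%s: unknown parent level in feedings", tag))
    if (any(feedings$time < record_start - 1e-9) ||
        any(feedings$time > record_end + 1e-9))
      stop(sprintf("%s: feeding event outside the recording span", tag))
  }

  # normalized per-(parent, state) tracks
  tracks <- list()
  for (p in PARENTS) for (s in STATES) {
    sel <- intervals$parent == p & intervals$state == s
    iv <- if (any(sel))
      iv_normalize(cbind(intervals$start[sel], intervals$end[sel]))
    else empty_intervals()
    tracks[[paste(p, s, sep = ".")]] <- iv
  }

  gap_iv <- if (nrow(gaps))
    iv_normalize(cbind(gaps$start, gaps$end)) else empty_intervals()
  if (nrow(gap_iv)) {
    if (gap_iv[1, 1] < record_start - 1e-9 ||
        gap_iv[nrow(gap_iv), 2] > record_end + 1e-9)
      stop(sprintf("%s: gap outside the recording span", tag))
  }

  structure(list(nest_id = as.character(nest_id), stage = stage,
                 stage_day = as.integer(stage_day),
                 record_start = as.numeric(record_start),
                 record_end = as.numeric(record_end),
                 tracks = tracks, feedings = feedings, gaps = gap_iv),
            class = "nest_recording")
}

#' @export
print.nest_recording <- function(x, ...) {
  cat(sprintf("<nest_recording> %s, %s day %d, %05.2f-%05.2fh\n",
              x$nest_id, x$stage, x$stage_day,
              x$record_start / 3600, x$record_end / 3600))
  for (nm in names(x$tracks))
    cat(sprintf("  %-14s %3d intervals, %6.1f min\n", nm,
                nrow(x$tracks[[nm]]), iv_total(x$tracks[[nm]]) / 60))
  cat(sprintf("  feedings: %d, gaps: %d\n", nrow(x$feedings), nrow(x$gaps)))
  invisible(x)
}

#' Interval set realizing a duration metric
#'
#' Individual metrics are the parent's normalized track (attendance = care
#' union inside); joint metrics are the intersection of the two parents'
#' sets, total metrics the union.
#'
#' @param rec a [nest_recording()].
#' @param metric one of [EFFORT_METRICS] except `prop_male_feedings`.
#' @return an interval matrix.
#' @export
metric_intervals <- function(rec, metric) {
  metric <- match.arg(metric, EFFORT_METRICS)
  if (metric == "prop_male_feedings")
    stop("prop_male_feedings is a count ratio, not a duration metric")
  parts <- strsplit(metric, "_", fixed = TRUE)[[1]]
  side <- parts[1]; kind <- parts[2]
  one <- function(parent) {
    if (kind == "care") rec$tracks[[paste(parent, "care", sep = ".")]]
    else iv_union(rec$tracks[[paste(parent, "care", sep = ".")]],
                  rec$tracks[[paste(parent, "inside", sep = ".")]])
  }
  switch(side,
         male   = one("male"),
         female = one("female"),
         joint  = iv_intersect(one("male"), one("female")),
         total  = iv_union(one("male"), one("female")))
}

metric_parents <- function(metric) {
  side <- strsplit(metric, "_", fixed = TRUE)[[1]][1]
  switch(side, male = "male", female = "female", "pair")
}

#' Occupied and observable seconds within a window
#'
#' @param iv interval matrix (e.g. from [metric_intervals()]).
#' @param window numeric length-2, half-open `[start, end)`.
#' @param gaps interval matrix of footage gaps (may be empty).
#' @return named numeric: `occupied` = duration of `iv` inside the window and
#'   outside gaps; `observable` = window duration outside gaps.
#' @export
duration_in_window <- function(iv, window, gaps = NULL) {
  w <- cbind(window[1], window[2])
  gaps <- as_intervals(gaps)
  obs_iv <- if (nrow(gaps)) iv_diff(w, gaps) else w
  occ <- iv_total(iv_intersect(iv, obs_iv))
  c(occupied = occ, observable = iv_total(obs_iv))
}

#' Proportion of feedings performed by the male
#'
#' Count ratio m / (m + f) of feeding bouts in a window; `NA` when no parent
#' fed in the window. Only meaningful for provisioning-stage recordings.
#'
#' @param rec a [nest_recording()] with `stage == "provisioning"`.
#' @param window numeric length-2 `[start, end)`; defaults to the whole span.
#' @return proportion in `[0, 1]`, or `NA` for a zero-feed window.
#' @export
proportion_male_feedings <- function(rec, window = NULL) {
  if (rec$stage != "provisioning")
    stop(sprintf("nest %s: proportion of male feedings is undefined during %s",
                 rec$nest_id, rec$stage))
  if (is.null(window)) window <- c(rec$record_start, rec$record_end)
  f <- rec$feedings
  inw <- f$time >= window[1] & f$time < window[2]
  m <- sum(inw & f$parent == "male")
  tot <- sum(inw)
  if (tot == 0) NA_real_ else m / tot
}
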