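#' Partition a recording into fixed sampling windows
#'
#' Tiles `[record_start, record_end)` with consecutive half-open windows of
#' `width_h` hours. A full-day 07:00-19:00 recording yields 12 one-hour or 4
#' three-hour windows; the mid-stage 10:00-13:00 recording yields a single
#' 3 h window.
#'
#' @param rec a [nest_recording()].
#' @param width_h window width in hours; must divide the recording span.
#' @return data frame with `index`, `start`, `end` (seconds).
#' @export
make_windows <- function(rec, width_h) {
  span <- rec$record_end - rec$record_start
  w <- width_h * 3600
  k <- span / w
  if (abs(k - round(k)) > 1e-9)
    stop(sprintf("window width %g h does not divide the %.2f h recording span",
                 width_h, span / 3600))
  k <- as.integer(round(k))
  start <- rec$record_start + (seq_len(k) - 1L) * w
  data.frame(index = seq_len(k), start = start, end = start + w)
}

#' Effort matrix: individuals x sampling windows
#'
#' Builds the per-metric matrix of effort proportions for a set of recordings
#' sharing one stage and stage day. Rows are nests (one parent per nest for
#' individual metrics, the pair for joint/total metrics and the feeding
#' ratio); columns are consecutive windows. Duration metrics are occupied /
#' observable time; windows whose observable time falls below
#' `min_observable` of the nominal width are set to `NA` (the footage-gap
#' rule). Zero-feed windows of `prop_male_feedings` are `NA`.
#'
#' @param recs list of [nest_recording()] objects, same stage/day/span.
#' @param metric one of [EFFORT_METRICS].
#' @param width_h window width in hours (1 or 3 in the reference design).
#' @param min_observable minimum observable fraction of the window width for
#'   a cell to be retained; default 0.95.
#' @return object of class `effort_matrix`: list with `metric`, `width_h`,
#'   `values` (matrix, rows named by nest), `windows`, `parent`, `stage`,
#'   `stage_day`.
#' @export
effort_matrix <- function(recs, metric, width_h, min_observable = 0.95) {
  metric <- match.arg(metric, EFFORT_METRICS)
  if (!length(recs)) stop("no recordings supplied")
  stages <- unique(vapply(recs, `[[`, "", "stage"))
  days <- unique(vapply(recs, function(r) r$stage_day, integer(1)))
  spans <- unique(t(vapply(recs, function(r)
    c(r$record_start, r$record_end), numeric(2))))
  if (length(stages) != 1L || length(days) != 1L || nrow(spans) != 1L)
    stop("all recordings must share stage, stage_day and recording span")
  win <- make_windows(recs[[1]], width_h)
  k <- nrow(win)
  vals <- matrix(NA_real_, nrow = length(recs), ncol = k,
                 dimnames = list(vapply(recs, `[[`, "", "nest_id"),
                                 sprintf("w%02d", win$index)))
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    if (metric == "prop_male_feedings") {
      for (j in seq_len(k))
        vals[i, j] <- proportion_male_feedings(rec, c(win$start[j], win$end[j]))
    } else {
      iv <- metric_intervals(rec, metric)
      for (j in seq_len(k)) {
        d <- duration_in_window(iv, c(win$start[j], win$end[j]), rec$gaps)
        vals[i, j] <- if (d["observable"] < min_observable * width_h * 3600)
          NA_real_ else d["occupied"] / d["observable"]
      }
    }
  }
  structure(list(metric = metric, width_h = width_h, values = vals,
                 windows = win, parent = metric_parents(metric),
                 stage = stages, stage_day = days),
            class = "effort_matrix")
}

#' @export
print.effort_matrix <- function(x, ...) {
  cat(sprintf("<effort_matrix> %s, %s day %d, %d nests x %d windows (%gh)\n",
              x$metric, x$stage, x$stage_day, nrow(x$values),
              ncol(x$values), x$width_h))
  invisible(x)
}

#' Daily effort of one nest
#'
#' Effort proportion over the whole observable recording: occupied /
#' observable seconds for duration metrics, the overall male share for
#' `prop_male_feedings`. With no gaps this equals the unweighted mean of the
#' nest's window values; with gaps it equals their observable-time-weighted
#' mean.
#'
#' @inheritParams metric_intervals
#' @param metric one of [EFFORT_METRICS].
#' @return a single proportion (or `NA` for a zero-feed recording).
#' @export
daily_effort <- function(rec, metric) {
  metric <- match.arg(metric, EFFORT_METRICS)
  if (metric == "prop_male_feedings")
    return(proportion_male_feedings(rec))
  iv <- metric_intervals(rec, metric)
  d <- duration_in_window(iv, c(rec$record_start, rec$record_end), rec$gaps)
  if (d["observable"] <= 0)
    stop(sprintf("nest %s: no observable footage", rec$nest_id))
  unname(d["occupied"] / d["observable"])
}

#' Long-format export of an effort matrix
#'
#' @param em an [effort_matrix()].
#' @return tidy data frame: `metric`, `nest_id`, `parent`, `window_index`,
#'   `window_start_s`, `value`.
#' @export
effort_long <- function(em) {
  stopifnot(inherits(em, "effort_matrix"))
  k <- ncol(em$values)
  data.frame(metric = em$metric,
             nest_id = rep(rownames(em$values), each = k),
             parent = em$parent,
             window_index = rep(em$windows$index, times = nrow(em$values)),
             window_start_s = rep(em$windows$start, times = nrow(em$values)),
             value = as.vector(t(em$values)))
}
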