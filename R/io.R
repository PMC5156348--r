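#' Write a corpus of nest recordings to the ethogram CSV format
#'
#' Long CSV with header `nest_id, stage, stage_day, parent, record_type,
#' state, start_s, end_s`. `record_type` is `span` (one row per recording,
#' carrying the recording span so round-trips are lossless), `state` (a care
#' or inside interval) or `feed` (a point event; `end_s` empty). Footage gaps
#' go to a sidecar CSV `nest_id, stage, stage_day, start_s, end_s`.
#'
#' @param recs list of [nest_recording()] objects.
#' @param path output CSV path.
#' @param gaps_path optional sidecar CSV path for gaps; written only if any
#'   recording has gaps (or if explicitly given).
#' @return `path`, invisibly.
#' @export
write_corpus <- function(recs, path, gaps_path = NULL) {
  rows <- list(); gap_rows <- list()
  for (rec in recs) {
    key <- data.frame(nest_id = rec$nest_id, stage = rec$stage,
                      stage_day = rec$stage_day)
    rows[[length(rows) + 1L]] <- cbind(key, parent = "", record_type = "span",
                                       state = "", start_s = rec$record_start,
                                       end_s = rec$record_end)
    for (p in PARENTS) for (s in STATES) {
      iv <- rec$tracks[[paste(p, s, sep = ".")]]
      if (nrow(iv))
        rows[[length(rows) + 1L]] <- cbind(
          key, parent = p, record_type = "state", state = s,
          start_s = iv[, 1], end_s = iv[, 2])
    }
    if (nrow(rec$feedings))
      rows[[length(rows) + 1L]] <- cbind(
        key, parent = rec$feedings$parent, record_type = "feed", state = "",
        start_s = rec$feedings$time, end_s = NA_real_)
    if (nrow(rec$gaps))
      gap_rows[[length(gap_rows) + 1L]] <- cbind(
        key, start_s = rec$gaps[, 1], end_s = rec$gaps[, 2])
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  if (!is.null(gaps_path) || length(gap_rows)) {
    if (is.null(gaps_path))
      gaps_path <- sub("\\.csv$", "_gaps.csv", path)
    gp <- if (length(gap_rows)) do.call(rbind, gap_rows) else
      data.frame(nest_id = character(0), stage = character(0),
                 stage_day = integer(0), start_s = numeric(0),
                 end_s = numeric(0))
    utils::write.csv(gp, gaps_path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a corpus of nest recordings from the ethogram CSV format
#'
#' Inverse of [write_corpus()]. Validation errors cite the offending CSV row;
#' overlapping same-(parent, state) intervals are normalized with a warning.
#' If a recording has no `span` row, its span is inferred from the extreme
#' event times with a warning.
#'
#' @param path ethogram CSV path.
#' @param gaps_path optional gap sidecar CSV path.
#' @return list of [nest_recording()] objects.
#' @export
read_corpus <- function(path, gaps_path = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(nest_id = "character"))
  need <- c("nest_id", "stage", "stage_day", "parent", "record_type",
            "state", "start_s", "end_s")
  if (!all(need %in% names(d)))
    stop("ethogram CSV must have columns: ", paste(need, collapse = ", "))
  d$.row <- seq_len(nrow(d)) + 1L   # header is line 1
  bad <- which(d$record_type == "state" &
                 (is.na(d$end_s) | d$end_s <= d$start_s))
  if (length(bad))
    stop(sprintf("%s line %d: state interval with end_s <= start_s",
                 path, d$.row[bad[1]]))
  gaps <- NULL
  if (!is.null(gaps_path)) {
    gaps <- utils::read.csv(gaps_path, stringsAsFactors = FALSE,
                            colClasses = c(nest_id = "character"))
  }
  keys <- unique(d[, c("nest_id", "stage", "stage_day")])
  recs <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- d[d$nest_id == keys$nest_id[i] & d$stage == keys$stage[i] &
               d$stage_day == keys$stage_day[i], ]
    sp <- sub[sub$record_type == "span", ]
    if (nrow(sp) >= 1L) {
      span <- c(sp$start_s[1], sp$end_s[1])
    } else {
      span <- range(c(sub$start_s, sub$end_s), na.rm = TRUE)
      warning(sprintf("nest %s %s day %s: no span row; inferred %g-%g s",
                      keys$nest_id[i], keys$stage[i], keys$stage_day[i],
                      span[1], span[2]))
    }
    st <- sub[sub$record_type == "state", ]
    # warn on overlaps within a track before the constructor merges them
    for (p in unique(st$parent)) for (s in unique(st$state[st$parent == p])) {
      tr <- st[st$parent == p & st$state == s, ]
      if (nrow(tr) > 1L) {
        o <- order(tr$start_s)
        if (any(tr$start_s[o][-1] < tr$end_s[o][-nrow(tr)]))
          warning(sprintf(
            "nest %s %s day %s: overlapping %s/%s intervals normalized",
            keys$nest_id[i], keys$stage[i], keys$stage_day[i], p, s))
      }
    }
    fd <- sub[sub$record_type == "feed", ]
    gp <- NULL
    if (!is.null(gaps)) {
      gsub <- gaps[gaps$nest_id == keys$nest_id[i] &
                     gaps$stage == keys$stage[i] &
                     gaps$stage_day == keys$stage_day[i], ]
      if (nrow(gsub)) gp <- data.frame(start = gsub$start_s, end = gsub$end_s)
    }
    recs[[i]] <- nest_recording(
      keys$nest_id[i], keys$stage[i], keys$stage_day[i], span[1], span[2],
      intervals = if (nrow(st)) data.frame(
        parent = st$parent, state = st$state,
        start = st$start_s, end = st$end_s) else NULL,
      feedings = if (nrow(fd)) data.frame(
        parent = fd$parent, time = fd$start_s) else NULL,
      gaps = gp)
  }
  recs
}

#' Import a wide per-second state table
#'
#' TSV with columns `time_s`, `male_state`, `female_state` (one row per
#' second; states `off`, `inside`, `care`), converted to half-open intervals
#' `[t, t+1)` and wrapped in a [nest_recording()].
#'
#' @param path TSV path.
#' @param nest_id,stage,stage_day recording identity.
#' @return a [nest_recording()].
#' @export
read_wide_track <- function(path, nest_id, stage, stage_day) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("time_s", "male_state", "female_state")
  if (!all(need %in% names(d)))
    stop("wide track TSV must have columns: ", paste(need, collapse = ", "))
  d <- d[order(d$time_s), ]
  rows <- list()
  for (p in PARENTS) {
    sv <- d[[paste0(p, "_state")]]
    ok <- sv %in% STATES
    if (any(ok)) {
      t <- d$time_s[ok]; s <- sv[ok]
      rows[[p]] <- data.frame(parent = p, state = s, start = t, end = t + 1)
    }
  }
  nest_recording(nest_id, stage, stage_day,
                 min(d$time_s), max(d$time_s) + 1,
                 intervals = if (length(rows)) do.call(rbind, rows) else NULL)
}

#' Write a run manifest
#'
#' One JSON manifest per CLI run: command, arguments, seed, input/output
#' files, package version and timestamp. Reruns with identical manifest
#' inputs give identical outputs for deterministic commands.
#'
#' @param path manifest path (JSON).
#' @param command CLI command name.
#' @param args character vector of raw CLI arguments.
#' @param seed integer seed used (or `NA`).
#' @param inputs,outputs character vectors of file paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, args, seed = NA,
                           inputs = character(0), outputs = character(0)) {
  input_md5 <- if (length(inputs))
    as.list(tools::md5sum(inputs[file.exists(inputs)])) else list()
  m <- list(command = command, args = as.list(args), seed = seed,
            inputs = as.list(inputs), input_md5 = input_md5,
            outputs = as.list(outputs),
            package = "nestbudget",
            version = as.character(utils::packageVersion("nestbudget")),
            timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(m, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
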