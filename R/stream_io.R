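# Stream ingestion and epoch-grid reduction. All matching happens on a
# canonical 10-second grid anchored at Unix-epoch-aligned boundaries
# (timestamp seconds == 0 mod 10); devices are assumed NTP-synchronised,
# so no lag search is performed.

EPOCH_SECONDS <- 10

#' Raw heart-rate stream for one participant, device, and phase
#'
#' @param participant_id,device_id character scalars.
#' @param phase `"lab"` or `"free"`.
#' @param time POSIXct timestamps, strictly increasing, second resolution.
#' @param hr_bpm non-negative heart-rate readings, bpm; 0 denotes a
#'   dropout/no-contact reading that downstream matching filters out.
#' @param age,resting_hr optional participant metadata carried as
#'   attributes (the simulator sets them; files round-trip without them).
#' @return an object of class `hr_stream` with a `readings` data.frame.
#' @export
hr_stream <- function(participant_id, device_id, phase, time, hr_bpm,
                      age = NULL, resting_hr = NULL) {
  phase <- match.arg(phase, c("lab", "free"))
  if (!inherits(time, "POSIXct")) stop("`time` must be POSIXct", call. = FALSE)
  if (length(time) != length(hr_bpm)) {
    stop("`time` and `hr_bpm` must have equal length", call. = FALSE)
  }
  if (anyNA(time)) stop("`time` contains unparseable timestamps", call. = FALSE)
  if (anyNA(hr_bpm) || any(hr_bpm < 0)) {
    bad <- which(is.na(hr_bpm) | hr_bpm < 0)[1]
    stop(sprintf("negative or missing hr_bpm at row %d", bad), call. = FALSE)
  }
  d <- diff(as.numeric(time))
  if (any(d == 0)) {
    stop(sprintf("duplicate timestamp at row %d", which(d == 0)[1] + 1L),
         call. = FALSE)
  }
  if (any(d < 0)) stop("timestamps must be increasing", call. = FALSE)
  structure(
    list(participant_id = as.character(participant_id),
         device_id = as.character(device_id),
         phase = phase,
         readings = data.frame(time = time, hr_bpm = as.numeric(hr_bpm))),
    age = age, resting_hr = resting_hr,
    class = "hr_stream"
  )
}

#' @export
print.hr_stream <- function(x, ...) {
  cat(sprintf("<hr_stream> %s / %s / %s: %d readings, %s .. %s\n",
              x$participant_id, x$device_id, x$phase, nrow(x$readings),
              format_timestamp(x$readings$time[1]),
              format_timestamp(x$readings$time[nrow(x$readings)])))
  invisible(x)
}

#' Write a stream to long-format CSV
#'
#' Columns: `participant_id, device_id, phase, timestamp, hr_bpm` with
#' ISO-8601 timestamps at second resolution.
#'
#' @param stream an [hr_stream()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_stream_csv <- function(stream, path) {
  df <- data.frame(participant_id = stream$participant_id,
                   device_id = stream$device_id,
                   phase = stream$phase,
                   timestamp = format_timestamp(stream$readings$time),
                   hr_bpm = stream$readings$hr_bpm)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a stream CSV
#'
#' Expects the long-format schema written by [write_stream_csv()]. The
#' file must contain a single participant, device, and phase; malformed
#' timestamps, negative readings, and duplicate timestamps are rejected
#' with the offending row named.
#'
#' @param path CSV file path.
#' @return an [hr_stream()].
#' @export
read_stream <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("participant_id", "device_id", "phase", "timestamp", "hr_bpm")
  if (!all(need %in% names(df))) {
    stop(sprintf("%s: missing columns %s", path,
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  }
  for (col in c("participant_id", "device_id", "phase")) {
    if (length(unique(df[[col]])) > 1L) {
      stop(sprintf("%s: multiple values in column %s", path, col),
           call. = FALSE)
    }
  }
  time <- parse_timestamp(df$timestamp)
  if (anyNA(time)) {
    stop(sprintf("%s: malformed timestamp at row %d", path,
                 which(is.na(time))[1]), call. = FALSE)
  }
  hr <- suppressWarnings(as.numeric(df$hr_bpm))
  if (anyNA(hr) || any(hr < 0)) {
    stop(sprintf("%s: invalid hr_bpm at row %d", path,
                 which(is.na(hr) | hr < 0)[1]), call. = FALSE)
  }
  ord <- order(time)
  if (anyDuplicated(as.numeric(time))) {
    stop(sprintf("%s: duplicate timestamp at row %d", path,
                 which(duplicated(as.numeric(time)))[1]), call. = FALSE)
  }
  hr_stream(df$participant_id[1], df$device_id[1], df$phase[1],
            time[ord], hr[ord])
}

#' Reduce a stream to the canonical 10-second epoch grid
#'
#' The default `"instantaneous"` rule takes, for each epoch, the reading
#' whose timestamp falls exactly on the epoch start (seconds == 0 mod 10);
#' this is the only rule a 0.1 Hz device can satisfy, so it is uniform
#' across devices. The `"window_mean"` alternative averages all readings
#' within \[start, start + 10). Epochs with no reading are absent, never
#' zero-filled; zero readings are retained here and filtered at matching.
#'
#' @param stream an [hr_stream()].
#' @param rule extraction rule, `"instantaneous"` (default) or
#'   `"window_mean"`.
#' @return an object of class `epoch_series` with an `epochs` data.frame
#'   (`epoch_start` POSIXct on the grid, `hr_bpm`).
#' @export
to_epochs <- function(stream, rule = c("instantaneous", "window_mean")) {
  rule <- match.arg(rule)
  if (!inherits(stream, "hr_stream")) {
    stop("`stream` must be an hr_stream", call. = FALSE)
  }
  secs <- as.numeric(stream$readings$time)
  hr <- stream$readings$hr_bpm
  if (rule == "instantaneous") {
    on_grid <- secs %% EPOCH_SECONDS == 0
    epoch_start <- stream$readings$time[on_grid]
    value <- hr[on_grid]
  } else {
    grid <- floor(secs / EPOCH_SECONDS) * EPOCH_SECONDS
    agg <- tapply(hr, grid, mean)
    epoch_start <- as.POSIXct(as.numeric(names(agg)), tz = "UTC",
                              origin = "1970-01-01")
    value <- as.numeric(agg)
  }
  structure(
    list(participant_id = stream$participant_id,
         device_id = stream$device_id,
         phase = stream$phase,
         epochs = data.frame(epoch_start = epoch_start,
                             hr_bpm = as.numeric(value))),
    class = "epoch_series"
  )
}

#' Time-match tracker epochs to the criterion
#'
#' Inner join of the two epoch series on epoch start, keeping only epochs
#' where both devices report a nonzero (physiological) value: tracker
#' zeros are dropout readings, and a zero criterion would be
#' nonphysiological and break percentage errors. Disjoint grids yield an
#' empty result, not an error.
#'
#' @param criterion,tracker [to_epochs()] output for the same participant
#'   and phase.
#' @return a `matched_pairs` data.frame with columns `participant_id`,
#'   `phase`, `tracker`, `epoch_start`, `criterion_bpm`, `tracker_bpm`,
#'   sorted by epoch.
#' @export
match_pairs <- function(criterion, tracker) {
  for (obj in list(criterion, tracker)) {
    if (!inherits(obj, "epoch_series")) {
      stop("inputs must be epoch_series objects", call. = FALSE)
    }
  }
  if (criterion$participant_id != tracker$participant_id ||
      criterion$phase != tracker$phase) {
    stop("criterion and tracker must share participant and phase",
         call. = FALSE)
  }
  m <- merge(criterion$epochs, tracker$epochs, by = "epoch_start",
             suffixes = c("_criterion", "_tracker"))
  m <- m[m$hr_bpm_criterion > 0 & m$hr_bpm_tracker > 0, , drop = FALSE]
  m <- m[order(m$epoch_start), , drop = FALSE]
  out <- data.frame(
    participant_id = rep(criterion$participant_id, nrow(m)),
    phase = rep(criterion$phase, nrow(m)),
    tracker = rep(tracker$device_id, nrow(m)),
    epoch_start = m$epoch_start,
    criterion_bpm = m$hr_bpm_criterion,
    tracker_bpm = m$hr_bpm_tracker
  )
  rownames(out) <- NULL
  class(out) <- c("matched_pairs", "data.frame")
  out
}

#' Minimum-data inclusion rule
#'
#' A participant-phase-tracker combination enters the analysis only with
#' enough time-matched data: at least 10 minutes (60 epochs) for the
#' laboratory phase and at least 180 minutes (1,080 epochs) for the
#' free-living phase, boundaries inclusive. Excluded combinations carry a
#' machine-readable reason.
#'
#' @param pairs a `matched_pairs` data.frame for one participant-phase.
#' @param phase `"lab"` or `"free"`; defaults to the phase recorded in
#'   `pairs`.
#' @param min_lab_minutes,min_free_minutes inclusion thresholds, minutes.
#' @return list with `included` (logical), `n_pairs`, and `reason`
#'   (`"ok"`, `"insufficient_lab_data"`, or `"insufficient_free_data"`).
#' @export
apply_inclusion <- function(pairs, phase = NULL, min_lab_minutes = 10,
                            min_free_minutes = 180) {
  if (is.null(phase)) {
    phase <- unique(as.character(pairs$phase))
    if (length(phase) != 1L) stop("`pairs` spans multiple phases",
                                  call. = FALSE)
  }
  phase <- match.arg(phase, c("lab", "free"))
  n <- nrow(pairs)
  min_epochs <- if (phase == "lab") min_lab_minutes * 60 / EPOCH_SECONDS
                else min_free_minutes * 60 / EPOCH_SECONDS
  included <- n >= min_epochs
  reason <- if (included) "ok"
            else sprintf("insufficient_%s_data", phase)
  list(included = included, n_pairs = n, reason = reason,
       min_epochs = min_epochs)
}

#' Wear time of an epoch series
#'
#' Epochs with a nonzero reading count as worn; wear time is their count
#' times 10 seconds, in hours.
#'
#' @param series an `epoch_series`.
#' @return wear time in hours.
#' @export
wear_time <- function(series) {
  if (!inherits(series, "epoch_series")) {
    stop("`series` must be an epoch_series", call. = FALSE)
  }
  sum(series$epochs$hr_bpm > 0) * EPOCH_SECONDS / 3600
}

#' Restrict two trackers' matched pairs to complete triplets
#'
#' Secondary-analysis mode: keep only epochs at which the criterion and
#' both trackers all reported nonzero values, i.e. the intersection of the
#' two matched sets per participant and phase.
#'
#' @param pairs_a,pairs_b `matched_pairs` data.frames for the two trackers
#'   (may pool several participants; the intersection is taken within
#'   participant and phase).
#' @return list of the two filtered `matched_pairs` data.frames.
#' @export
complete_triplets <- function(pairs_a, pairs_b) {
  key <- function(p) paste(p$participant_id, p$phase,
                           as.numeric(p$epoch_start))
  common <- intersect(key(pairs_a), key(pairs_b))
  fa <- pairs_a[key(pairs_a) %in% common, , drop = FALSE]
  fb <- pairs_b[key(pairs_b) %in% common, , drop = FALSE]
  rownames(fa) <- rownames(fb) <- NULL
  list(fa, fb)
}
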