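#' Construct a telemetry track
#'
#' @param individual_id label.
#' @param time_h fix times in hours from the window start, strictly
#'   increasing.
#' @param x_m,y_m projected coordinates in meters.
#' @param window_id analysis-window label.
#' @param segment_id per-fix segment label (independently imputed periods,
#'   e.g. around a mid-window relocation); default one segment.
#' @param start_clock clock hours in `[0, 24)` at the window start.
#' @return a `telemetry_track` data.frame.
#' @export
telemetry_track <- function(individual_id, time_h, x_m, y_m, window_id = "w1",
                            segment_id = "s1", start_clock = 0) {
  if (any(diff(time_h) <= 0)) stop_invalid("times must be strictly increasing")
  if (!all(is.finite(x_m)) || !all(is.finite(y_m)))
    stop_invalid("coordinates must be finite")
  n <- length(time_h)
  tr <- data.frame(individual_id = rep_len(individual_id, n),
                   time_h = time_h, x_m = x_m, y_m = y_m,
                   window_id = rep_len(window_id, n),
                   segment_id = rep_len(segment_id, n))
  attr(tr, "start_clock") <- clock24(start_clock)
  class(tr) <- c("telemetry_track", "data.frame")
  tr
}

## Reference epoch used to render hour offsets as ISO timestamps.
TRACK_EPOCH <- as.POSIXct("2011-04-01 00:00:00", tz = "UTC")

#' Write / read telemetry tracks as CSV
#'
#' Format: header `individual_id,timestamp_iso,x_m,y_m,window_id,segment_id`;
#' timestamps are rendered from the track's window start clock against a
#' fixed reference date, and hour offsets are recovered exactly on read.
#' Multiple individuals may share one file.
#'
#' @param track a `telemetry_track` (or row-bound collection of them).
#' @param path file path.
#' @return `path` (write); a `telemetry_track` (read).
#' @export
write_track <- function(track, path) {
  sc <- attr(track, "start_clock"); if (is.null(sc)) sc <- 0
  ts <- TRACK_EPOCH + (sc + track$time_h) * 3600
  out <- data.frame(individual_id = track$individual_id,
                    timestamp_iso = format(ts, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC"),
                    x_m = track$x_m, y_m = track$y_m,
                    window_id = track$window_id,
                    segment_id = track$segment_id)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  ts <- as.POSIXct(d$timestamp_iso, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
  hours <- as.numeric(difftime(ts, TRACK_EPOCH, units = "hours"))
  sc <- clock24(hours[1L])
  tr <- data.frame(individual_id = d$individual_id,
                   time_h = round(hours - hours[1L], 9),
                   x_m = d$x_m, y_m = d$y_m, window_id = d$window_id,
                   segment_id = if ("segment_id" %in% names(d)) d$segment_id else "s1")
  attr(tr, "start_clock") <- sc
  class(tr) <- c("telemetry_track", "data.frame")
  tr
}

#' Split a multi-individual track data.frame into one track per individual
#' @param track a `telemetry_track` possibly holding several individuals.
#' @return named list of `telemetry_track`s.
#' @export
split_track <- function(track) {
  sc <- attr(track, "start_clock"); if (is.null(sc)) sc <- 0
  lapply(split(track, track$individual_id), function(tr) {
    tr <- tr[order(tr$time_h), , drop = FALSE]
    attr(tr, "start_clock") <- sc
    class(tr) <- c("telemetry_track", "data.frame")
    tr
  })
}

#' Write / read discretized cell sequences as CSV
#'
#' Format: `individual_id,draw_index,segment_id,row,col,tau_hours,
#' entry_clock_hours` plus a `label` column marking the fit/score partition.
#'
#' @param seqs a cell-sequence data.frame (as from [discretize_path()],
#'   possibly row-bound over draws and individuals).
#' @param path file path.
#' @return `path` (write); the data.frame (read).
#' @export
write_cell_sequences <- function(seqs, path) {
  cols <- c("individual_id", "draw_index", "segment_id", "row", "col",
            "tau_hours", "entry_clock_hours")
  if ("label" %in% names(seqs)) cols <- c(cols, "label")
  write.csv(seqs[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cell_sequences
#' @export
read_cell_sequences <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
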