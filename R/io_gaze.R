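## Gaze sample streams: construction, validation, TSV read/write.

GAZE_EVENTS <- c("fixation", "saccade", "missing")

#' Construct a gaze recording
#'
#' One participant's time-stamped gaze sample stream.  Timestamps are in
#' milliseconds relative to the start of the analysis window and must be
#' strictly increasing; coordinates are 0-based screen pixels and may lie
#' off-screen (off-screen samples are valid but fall outside every ROI);
#' every sample carries an event label (`fixation`, `saccade`, `missing`).
#'
#' @param samples `data.frame` with columns `t_ms`, `x_px`, `y_px`, `event`.
#' @param sampling_rate_hz Nominal sampling rate in Hz.
#' @param eye `"left"` or `"right"`.
#' @param validation_error_deg Average calibration-validation error of the
#'   recorded eye in degrees (optional, `NA` if unknown).
#'
#' @return Object of class `gaze_recording`.
#' @export
gaze_recording <- function(samples, sampling_rate_hz = 1000,
                           eye = c("left", "right"),
                           validation_error_deg = NA_real_) {
  eye <- match.arg(eye)
  need <- c("t_ms", "x_px", "y_px", "event")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("gaze samples lack required column(s): ", paste(miss, collapse = ", "))
  bad <- which(!samples$event %in% GAZE_EVENTS)
  if (length(bad))
    stop(sprintf("unknown event label '%s' at row %d", samples$event[bad[1]], bad[1]))
  dt <- diff(samples$t_ms)
  if (length(dt) && any(dt <= 0)) {
    row <- which(dt <= 0)[1] + 1L
    stop(sprintf("timestamps must be strictly increasing; violation at row %d (t = %g)",
                 row, samples$t_ms[row]))
  }
  if (sampling_rate_hz <= 0) stop("sampling_rate_hz must be > 0")
  structure(list(samples = samples[need],
                 sampling_rate_hz = sampling_rate_hz,
                 eye = eye,
                 validation_error_deg = validation_error_deg),
            class = "gaze_recording")
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf("gaze_recording: %d samples @ %g Hz, eye %s, validation error %.3g deg\n",
              nrow(x$samples), x$sampling_rate_hz, x$eye, x$validation_error_deg))
  invisible(x)
}

#' Column and event-label dialect for gaze sample files
#'
#' Eye-tracker sample reports differ in column naming and in the strings
#' used for event classes.  A dialect maps file columns to the canonical
#' `t_ms`/`x_px`/`y_px`/`event` schema and vendor event strings to the
#' three-label vocabulary `fixation`/`saccade`/`missing`.
#'
#' @param col_time,col_x,col_y,col_event Column names in the file.
#' @param event_map Named character vector mapping file event strings to
#'   canonical labels; unmapped strings are rejected.
#' @param sep Field separator (default tab).
#' @return Object of class `gaze_dialect`.
#' @export
gaze_dialect <- function(col_time = "t_ms", col_x = "x_px", col_y = "y_px",
                         col_event = "event",
                         event_map = c(fixation = "fixation",
                                       saccade = "saccade",
                                       missing = "missing"),
                         sep = "\t") {
  if (!all(event_map %in% GAZE_EVENTS))
    stop("event_map values must be in {fixation, saccade, missing}")
  structure(list(col_time = col_time, col_x = col_x, col_y = col_y,
                 col_event = col_event, event_map = event_map, sep = sep),
            class = "gaze_dialect")
}

#' Read a gaze sample stream from a delimited text file
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect A [gaze_dialect()] describing the file's columns and
#'   event vocabulary.
#' @param sampling_rate_hz,eye,validation_error_deg Passed to
#'   [gaze_recording()].
#' @return A [gaze_recording()].
#' @export
read_gaze_samples <- function(path, dialect = gaze_dialect(),
                              sampling_rate_hz = 1000,
                              eye = c("left", "right"),
                              validation_error_deg = NA_real_) {
  if (!file.exists(path)) stop("gaze file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", "."))
  cols <- c(dialect$col_time, dialect$col_x, dialect$col_y, dialect$col_event)
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("gaze file lacks column(s): ", paste(miss, collapse = ", "))
  ev_raw <- as.character(df[[dialect$col_event]])
  unknown <- setdiff(unique(ev_raw), names(dialect$event_map))
  if (length(unknown))
    stop("unmapped event string(s): ", paste(unknown, collapse = ", "))
  samples <- data.frame(t_ms = as.numeric(df[[dialect$col_time]]),
                        x_px = as.numeric(df[[dialect$col_x]]),
                        y_px = as.numeric(df[[dialect$col_y]]),
                        event = unname(dialect$event_map[ev_raw]),
                        stringsAsFactors = FALSE)
  gaze_recording(samples, sampling_rate_hz = sampling_rate_hz,
                 eye = match.arg(eye),
                 validation_error_deg = validation_error_deg)
}

#' Write a gaze recording as tab-separated text
#'
#' Numbers are serialised at full double precision so that a write/read
#' round trip is lossless to within 1e-12 relative error.
#'
#' @param recording A [gaze_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaze_samples <- function(recording, path) {
  df <- recording$samples
  df$t_ms <- format(df$t_ms, digits = 17, trim = TRUE, scientific = FALSE)
  df$x_px <- format(df$x_px, digits = 17, trim = TRUE, scientific = FALSE)
  df$y_px <- format(df$y_px, digits = 17, trim = TRUE, scientific = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
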