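## Eye-tracking data-quality metrics: eye selection by validation error,
## RMS sample-to-sample precision, and data loss.

#' Select the eye with the lower validation error
#'
#' In binocular recordings only the eye with the lower average error during
#' eye-tracker validation is analysed.  Ties go to the configurable
#' preference (left by default); a missing value disqualifies that eye.
#'
#' @param validation_error_left,validation_error_right Average validation
#'   errors in degrees (`NA` if that eye was not validated).
#' @param tie Eye returned on exact ties.
#' @return `"left"` or `"right"`.
#' @export
select_eye <- function(validation_error_left, validation_error_right,
                       tie = c("left", "right")) {
  tie <- match.arg(tie)
  l <- validation_error_left; r <- validation_error_right
  if (is.na(l) && is.na(r)) stop("validation error missing for both eyes")
  if (!is.na(l) && l < 0 || !is.na(r) && r < 0)
    stop("validation errors must be >= 0")
  if (is.na(l)) return("right")
  if (is.na(r)) return("left")
  if (l < r) "left" else if (r < l) "right" else tie
}

#' RMS sample-to-sample precision of a gaze recording
#'
#' The root mean square of the angular displacement between consecutive
#' valid samples: displacements are converted per axis from pixels to
#' degrees of visual angle, and only pairs of directly consecutive samples
#' that are both in scope enter the mean.  By field convention the default
#' scope restricts to fixation-labelled samples, where precision reflects
#' instrument noise rather than eye movement; `"all_valid"` uses every
#' non-missing sample.
#'
#' @param recording A [gaze_recording()].
#' @param geometry A [screen_geometry()] for the pixel-to-degree factors.
#' @param scope `"fixations_only"` (default) or `"all_valid"`.
#' @return Precision in degrees (>= 0).
#' @export
precision_rms_s2s <- function(recording, geometry = screen_geometry(),
                              scope = c("fixations_only", "all_valid")) {
  scope <- match.arg(scope)
  s <- recording$samples
  ok <- is.finite(s$x_px) & is.finite(s$y_px) &
    if (scope == "fixations_only") s$event == "fixation" else s$event != "missing"
  n <- nrow(s)
  if (n < 2) stop("need at least 2 samples")
  pair <- ok[-n] & ok[-1]
  if (!any(pair)) stop("no consecutive pair of valid samples in scope")
  dx <- (s$x_px[-1] - s$x_px[-n]) * geometry$width_deg / geometry$width_px
  dy <- (s$y_px[-1] - s$y_px[-n]) * geometry$height_deg / geometry$height_px
  sqrt(mean((dx^2 + dy^2)[pair]))
}

#' Data loss of a gaze recording over a window
#'
#' Percentage of expected samples that are missing.  The expected count is
#' the nominal sampling rate times the window duration (missing samples may
#' carry no timestamp of their own in some exports); the missing count is
#' the expected count minus the number of valid (non-missing) samples
#' recorded inside the window.
#'
#' @param recording A [gaze_recording()].
#' @param window Numeric `c(start_ms, end_ms)`; samples with
#'   `start <= t < end` are in the window.
#' @return Percentage in `[0, 100]`.
#' @export
data_loss <- function(recording, window) {
  if (window[2] <= window[1]) stop("window must have positive duration")
  expected <- round((window[2] - window[1]) * recording$sampling_rate_hz / 1000)
  if (expected == 0) stop("window shorter than one sampling interval")
  s <- recording$samples
  inw <- s$t_ms >= window[1] & s$t_ms < window[2]
  n_valid <- sum(inw & s$event != "missing")
  100 * max(0, expected - n_valid) / expected
}

#' Data-quality report for one recording
#'
#' @param recording A [gaze_recording()].
#' @param window Analysis window `c(start_ms, end_ms)`.
#' @param geometry A [screen_geometry()].
#' @param scope Precision scope, see [precision_rms_s2s()].
#' @return List with `accuracy_deg` (the recording's validation error),
#'   `precision_rms_s2s_deg`, `data_loss_pct`, and `eye`.
#' @export
quality_report <- function(recording, window, geometry = screen_geometry(),
                           scope = "fixations_only") {
  list(accuracy_deg = recording$validation_error_deg,
       precision_rms_s2s_deg = precision_rms_s2s(recording, geometry, scope),
       data_loss_pct = data_loss(recording, window),
       eye = recording$eye)
}
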