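#' Screen geometry of the stimulus display
#'
#' Bundles the pixel resolution of the stimulus video, its angular extent at
#' the observer's eye, the viewing distance, and the video frame rate.  The
#' defaults describe a 1920 x 1080 video shown at 25 frames per second,
#' subtending 47.5 degrees horizontally and 27.8 degrees vertically at a
#' viewing distance of 62 cm.
#'
#' Pixel coordinates throughout the package are 0-based pixel centers with
#' the origin at the top-left corner and y increasing downward, matching the
#' convention of video frames.
#'
#' @param width_px,height_px Screen resolution in pixels.
#' @param width_deg,height_deg Angular extent of the display in degrees of
#'   visual angle.
#' @param viewing_distance_cm Eye-to-screen distance in centimetres.
#' @param frame_rate_hz Video frame rate in frames per second.
#'
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry()
#' deg_to_px(0.5, geom, "x")
#' @export
screen_geometry <- function(width_px = 1920, height_px = 1080,
                            width_deg = 47.5, height_deg = 27.8,
                            viewing_distance_cm = 62, frame_rate_hz = 25) {
  vals <- c(width_px = width_px, height_px = height_px,
            width_deg = width_deg, height_deg = height_deg,
            viewing_distance_cm = viewing_distance_cm,
            frame_rate_hz = frame_rate_hz)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all screen_geometry fields must be finite and strictly positive")
  structure(as.list(vals), class = "screen_geometry")
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("screen_geometry: %d x %d px, %.1f x %.1f deg, %g cm, %g fps\n",
              x$width_px, x$height_px, x$width_deg, x$height_deg,
              x$viewing_distance_cm, x$frame_rate_hz))
  invisible(x)
}

#' Convert degrees of visual angle to pixels
#'
#' Linear small-angle conversion using the per-axis pixels-per-degree factor
#' of the display (`width_px / width_deg` horizontally, `height_px /
#' height_deg` vertically).
#'
#' @param d Distance in degrees of visual angle (vectorised, must be >= 0).
#' @param geometry A [screen_geometry()].
#' @param axis `"x"` (horizontal) or `"y"` (vertical).
#'
#' @return Distance in pixels.
#' @export
deg_to_px <- function(d, geometry = screen_geometry(), axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (any(d < 0, na.rm = TRUE)) stop("degrees of visual angle must be >= 0")
  if (axis == "x") d * geometry$width_px / geometry$width_deg
  else d * geometry$height_px / geometry$height_deg
}

#' Convert pixels to degrees of visual angle
#'
#' Inverse of [deg_to_px()].
#'
#' @inheritParams deg_to_px
#' @param p Distance in pixels.
#' @return Distance in degrees.
#' @export
px_to_deg <- function(p, geometry = screen_geometry(), axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (axis == "x") p * geometry$width_deg / geometry$width_px
  else p * geometry$height_deg / geometry$height_px
}

# canonical ROI label vocabulary, in default priority order
roi_labels <- function() {
  c("critical_object", "perpetrator_head", "perpetrator_body",
    "victim_head", "victim_body")
}
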