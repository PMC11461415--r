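# Small geometries, masks, tracks and recordings built in code for tests.

# 200 x 100 px screen spanning 20 x 10 degrees -> 10 px per degree on both
# axes, which keeps conversions easy to reason about
tiny_geometry <- function(frame_rate_hz = 25) {
  screen_geometry(width_px = 200, height_px = 100,
                  width_deg = 20, height_deg = 10,
                  viewing_distance_cm = 62, frame_rate_hz = frame_rate_hz)
}

disk_mask <- function(cx, cy, r, nrow = 100, ncol = 200) {
  ellipse_mask(c(cx, cy), c(r, r), 0, nrow, ncol)
}

random_mask <- function(nrow = 8, ncol = 11, p = 0.4) {
  matrix(runif(nrow * ncol) < p, nrow, ncol)
}

# single-condition track: critical object disk, perpetrator body rectangle
# with head disk on top, victim likewise, optionally static
tiny_track <- function(n_frames = 5, geometry = tiny_geometry(),
                       window = c(0, n_frames * 1000 / geometry$frame_rate_hz)) {
  nr <- geometry$height_px; nc <- geometry$width_px
  frames <- lapply(seq_len(n_frames), function(f) {
    shift <- f - 1
    list(critical_object = disk_mask(120 + shift, 60, 6, nr, nc),
         perpetrator_body = rect_mask(c(130 + shift, 60), c(24, 60), nr, nc),
         perpetrator_head = disk_mask(130 + shift, 25, 8, nr, nc),
         victim_body = rect_mask(c(50, 60), c(24, 60), nr, nc),
         victim_head = disk_mask(50, 25, 8, nr, nc))
  })
  roi_track(geometry, frames, window)
}

# recording with explicit samples at the given times/positions/events
make_recording <- function(t_ms, x_px, y_px, event, rate = 1000,
                           validation_error_deg = 0.3) {
  gaze_recording(data.frame(t_ms = t_ms, x_px = x_px, y_px = y_px,
                            event = event, stringsAsFactors = FALSE),
                 sampling_rate_hz = rate,
                 validation_error_deg = validation_error_deg)
}

# assigned-stream stand-in built directly (bypasses assignment) for
# time-course tests: labels per sample at 10-ms spacing by default
make_stream <- function(labels, excluded = rep(FALSE, length(labels)),
                        dt_ms = 10, window = NULL, rate = 1000 / dt_ms) {
  n <- length(labels)
  t_ms <- (seq_len(n) - 1) * dt_ms
  if (is.null(window)) window <- c(0, n * dt_ms)
  structure(data.frame(t_ms = t_ms, label = labels, excluded = excluded,
                       stringsAsFactors = FALSE),
            class = c("assigned_stream", "data.frame"),
            window = window, sampling_rate_hz = rate,
            labels = setdiff(unique(labels),
                             c("other", "saccade", "missing")))
}
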