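## Priority-resolved per-sample ROI assignment.

#' ROI priority order
#'
#' When dilated ROIs overlap, a gaze sample is assigned to the first
#' matching label in priority order: primarily to the critical object, then
#' to the person ROIs, and within each person the head before the body.
#' Samples matching no ROI get the label `"other"`.
#'
#' @param labels Character vector of unique ROI labels, highest priority
#'   first.
#' @return Object of class `priority_order`.
#' @export
priority_order <- function(labels = roi_labels()) {
  if (anyDuplicated(labels)) stop("priority labels must be unique")
  structure(labels, class = "priority_order")
}

# Integer label field for one frame: 0 = other, i = i-th priority label.
# Masks are dilated by margin_deg; higher-priority labels overwrite lower.
frame_label_field <- function(frame, priority, margin_deg, geometry) {
  labs <- as.character(priority)
  first <- frame[[labs[[1]]]]
  field <- matrix(0L, nrow(first), ncol(first))
  for (i in rev(seq_along(labs))) {
    m <- frame[[labs[i]]]
    if (is.null(m)) stop("track lacks priority label: ", labs[i])
    if (margin_deg > 0 && any(m))
      m <- dilate_roi(m, margin_deg, geometry)
    field[m] <- i
  }
  field
}

#' Precompute priority-resolved label fields for a track
#'
#' For every frame, collapses the margin-dilated masks into a single
#' integer matrix giving the assigned label at each pixel.  Assignment of
#' many samples against the same track (e.g. a whole cohort watching one
#' video) then costs one array lookup per sample.  Memory is one integer
#' per pixel per frame, so precomputation suits down-scaled geometries or
#' short windows; [assign_samples()] otherwise builds fields frame by
#' frame on the fly.
#'
#' @param track An [roi_track()].
#' @param priority A [priority_order()].
#' @param margin_deg ROI margin in degrees of visual angle.
#' @return Object of class `label_fields`.
#' @export
build_label_fields <- function(track, priority = priority_order(),
                               margin_deg = 0.5) {
  fields <- lapply(track$frames, frame_label_field,
                   priority = priority, margin_deg = margin_deg,
                   geometry = track$geometry)
  structure(list(fields = fields, priority = priority,
                 margin_deg = margin_deg, window = track$window,
                 geometry = track$geometry),
            class = "label_fields")
}

#' Assign gaze samples to dynamic ROIs
#'
#' Each in-window sample is matched against the margin-dilated ROI masks of
#' the frame active at its timestamp (`floor(t * frame_rate / 1000)`; masks
#' are constant within a frame) and receives the first matching label in
#' priority order, or `"other"` if it falls in no ROI (including off-screen
#' coordinates).  Matching is per individual gaze sample, not per fixation
#' centroid, so slow pursuit of a moving ROI is credited to that ROI.
#' Samples labelled `saccade` or `missing` carry their event label through
#' and are flagged excluded; samples outside the track window are dropped
#' and counted.
#'
#' @param recording A [gaze_recording()].
#' @param track An [roi_track()]; ignored when `fields` is supplied.
#' @param priority A [priority_order()].
#' @param margin_deg ROI margin in degrees (default 0.5, the conventional
#'   allowance for eye-tracker inaccuracy).
#' @param fields Optional precomputed [build_label_fields()] result.
#' @return An `assigned_stream`: `data.frame` with columns `t_ms`, `label`,
#'   `excluded`, plus attributes `window`, `sampling_rate_hz` and
#'   `n_dropped`.
#' @export
assign_samples <- function(recording, track = NULL,
                           priority = priority_order(), margin_deg = 0.5,
                           fields = NULL) {
  if (is.null(fields)) {
    if (is.null(track)) stop("either track or fields must be supplied")
    window <- track$window
    geometry <- track$geometry
    n_frames <- length(track$frames)
  } else {
    priority <- fields$priority
    margin_deg <- fields$margin_deg
    window <- fields$window
    geometry <- fields$geometry
    n_frames <- length(fields$fields)
  }
  s <- recording$samples
  inw <- s$t_ms >= window[1] & s$t_ms < window[2]
  n_dropped <- sum(!inw)
  s <- s[inw, , drop = FALSE]
  labs <- as.character(priority)
  label <- s$event             # saccade / missing carried through
  excluded <- s$event != "fixation"
  fix <- which(!excluded)
  if (length(fix)) {
    fi <- floor((s$t_ms[fix] - window[1]) * geometry$frame_rate_hz / 1000)
    fi <- pmin(pmax(fi, 0L), n_frames - 1L)
    xi <- round(s$x_px[fix]); yi <- round(s$y_px[fix])
    on <- is.finite(xi) & is.finite(yi) &
      xi >= 0 & xi < geometry$width_px & yi >= 0 & yi < geometry$height_px
    code <- integer(length(fix))   # 0 = other
    for (f in unique(fi)) {
      sel <- which(fi == f & on)
      if (!length(sel)) next
      fld <- if (is.null(fields))
        frame_label_field(track$frames[[f + 1L]], priority, margin_deg, geometry)
      else fields$fields[[f + 1L]]
      code[fi == f & on] <- fld[cbind(yi[sel] + 1L, xi[sel] + 1L)]
    }
    label[fix] <- c("other", labs)[code + 1L]
  }
  out <- data.frame(t_ms = s$t_ms, label = label, excluded = excluded,
                    stringsAsFactors = FALSE)
  structure(out, class = c("assigned_stream", "data.frame"),
            window = window, sampling_rate_hz = recording$sampling_rate_hz,
            labels = labs, n_dropped = n_dropped)
}
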