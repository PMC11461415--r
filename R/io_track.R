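## ROI tracks: per-frame labelled binary masks plus screen geometry,
## serialised as a JSON header line followed by one RLE record per
## frame/label pair.

#' Construct an ROI track
#'
#' Per-frame binary masks for every ROI label over an analysis window.
#' Frame 0 covers the first `1000 / frame_rate_hz` milliseconds of the
#' window, and masks are constant within a frame.
#'
#' @param geometry A [screen_geometry()].
#' @param frames List of frames (index 0 first); each frame is a named list
#'   of logical matrices, one per label, of dimension
#'   `height_px` x `width_px`.
#' @param window Numeric `c(start_ms, end_ms)` of the analysis segment.
#' @param labels Label vocabulary; defaults to the union of labels present.
#' @return Object of class `roi_track`.
#' @export
roi_track <- function(geometry, frames, window,
                      labels = sort(unique(unlist(lapply(frames, names))))) {
  if (length(window) != 2 || window[2] <= window[1])
    stop("window must be c(start_ms, end_ms) with end > start")
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    miss <- setdiff(labels, names(fr))
    if (length(miss))
      stop(sprintf("frame %d lacks label(s): %s", i - 1, paste(miss, collapse = ", ")))
    for (lab in labels) {
      m <- fr[[lab]]
      if (!all(dim(m) == c(geometry$height_px, geometry$width_px)))
        stop(sprintf("frame %d label %s: mask dimension mismatch", i - 1, lab))
    }
  }
  structure(list(geometry = geometry, frames = frames,
                 window = as.numeric(window), labels = labels),
            class = "roi_track")
}

#' @export
print.roi_track <- function(x, ...) {
  cat(sprintf("roi_track: %d frames, window [%g, %g) ms, labels: %s\n",
              length(x$frames), x$window[1], x$window[2],
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

# frame index for a timestamp (ms relative to window start), 0-based
frame_index <- function(t_ms, track) {
  floor((t_ms - track$window[1]) * track$geometry$frame_rate_hz / 1000)
}

#' Write an ROI track to its text container
#'
#' Line 1 is a JSON header (geometry, window, labels, frame count, mask
#' dimensions); each subsequent line is `frame<TAB>label<TAB>runs`, where
#' `runs` is the comma-separated run-length code of [rle_encode_mask()]
#' (column-major over the `[y, x]` mask, starting with a zero run).
#'
#' @param track An [roi_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roi_track <- function(track, path) {
  g <- track$geometry
  header <- jsonlite::toJSON(list(
    format = "dynroi-track-v1",
    geometry = g[c("width_px", "height_px", "width_deg", "height_deg",
                   "viewing_distance_cm", "frame_rate_hz")],
    window = track$window,
    labels = track$labels,
    n_frames = length(track$frames)), auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(header), con)
  for (i in seq_along(track$frames)) {
    for (lab in track$labels) {
      runs <- rle_encode_mask(track$frames[[i]][[lab]])
      writeLines(sprintf("%d\t%s\t%s", i - 1L, lab,
                         paste(runs, collapse = ",")), con)
    }
  }
  invisible(path)
}

#' Read an ROI track from its text container
#'
#' Inverse of [write_roi_track()]; decoded masks equal the encoded masks
#' pixel for pixel.  Every frame `0 .. n_frames - 1` must be present for
#' every label; gaps raise an integrity error listing the missing frames.
#'
#' @param path Path to a track file.
#' @return An [roi_track()].
#' @export
read_roi_track <- function(path) {
  if (!file.exists(path)) stop("track file not found: ", path)
  lines <- readLines(path)
  hd <- jsonlite::fromJSON(lines[1])
  if (is.null(hd$format) || hd$format != "dynroi-track-v1")
    stop("not a dynroi ROI-track file: ", path)
  g <- do.call(screen_geometry, as.list(hd$geometry))
  nr <- g$height_px; nc <- g$width_px
  labels <- hd$labels
  n_frames <- hd$n_frames
  frames <- rep(list(stats::setNames(vector("list", length(labels)), labels)),
                n_frames)
  seen <- matrix(FALSE, n_frames, length(labels),
                 dimnames = list(NULL, labels))
  for (ln in lines[-1]) {
    if (!nzchar(ln)) next
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    fi <- as.integer(parts[1]) + 1L
    lab <- parts[2]
    runs <- as.integer(strsplit(parts[3], ",", fixed = TRUE)[[1]])
    frames[[fi]][[lab]] <- rle_decode_mask(runs, nr, nc)
    seen[fi, lab] <- TRUE
  }
  if (!all(seen)) {
    gaps <- which(rowSums(!seen) > 0) - 1L
    stop("track has missing frame(s): ", paste(gaps, collapse = ", "))
  }
  roi_track(g, frames, as.numeric(hd$window), labels = labels)
}

#' Write an analysis results table as CSV
#'
#' Plain-text CSV with a header row; numeric columns are serialised at full
#' double precision (display rounding is left to display columns), so a
#' write/read round trip preserves values to better than 1e-12 relative
#' error.
#'
#' @param records A `data.frame` (possibly with zero rows).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  if (!is.data.frame(records)) stop("records must be a data.frame")
  out <- records
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- format(out[[j]], digits = 17, trim = TRUE, scientific = TRUE)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
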