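## Total viewing times and cumulative / non-cumulative time-course
## statistics over assigned gaze streams.

stream_labels <- function(stream, labels = NULL) {
  if (is.null(labels)) labels <- attr(stream, "labels")
  if (is.null(labels))
    labels <- setdiff(unique(stream$label), c("saccade", "missing", "other"))
  c(labels, "other")
}

#' Total viewing time per ROI
#'
#' The summed duration of all retained (fixation-labelled, non-missing)
#' gaze samples in each ROI, standardised as a percentage.  With the
#' default denominator `"retained"` the base is the number of retained
#' samples, so the percentages over the full label partition (including
#' `"other"`) sum to exactly 100.  With denominator `"window"` the base is
#' the expected sample count for the window duration at the nominal
#' sampling rate, i.e. the percentage of the video segment's duration;
#' percentages then sum to less than 100 whenever saccade or missing
#' samples occur.
#'
#' @param stream An `assigned_stream` from [assign_samples()].
#' @param denominator `"retained"` (default) or `"window"`.
#' @param labels ROI label set; defaults to the stream's vocabulary.
#' @return Named numeric vector of percentages over `c(labels, "other")`.
#' @export
compute_tvt <- function(stream, denominator = c("retained", "window"),
                        labels = NULL) {
  denominator <- match.arg(denominator)
  labs <- stream_labels(stream, labels)
  kept <- stream$label[!stream$excluded]
  if (!length(kept)) stop("no retained samples in stream")
  counts <- vapply(labs, function(l) sum(kept == l), numeric(1))
  D <- if (denominator == "retained") length(kept) else {
    w <- attr(stream, "window")
    round((w[2] - w[1]) * attr(stream, "sampling_rate_hz") / 1000)
  }
  100 * counts / D
}

# bin index of each retained sample: bin k covers (0, k * bin_ms] relative
# to window start; a sample exactly at window start joins bin 1
retained_bins <- function(stream, bin_ms) {
  w <- attr(stream, "window")
  kept <- !stream$excluded
  t_rel <- stream$t_ms[kept] - w[1]
  k <- ceiling(t_rel / bin_ms)
  k[k < 1] <- 1L
  list(bin = k, label = stream$label[kept],
       n_bins = max(1, ceiling((w[2] - w[1]) / bin_ms)))
}

#' Discrete cumulative time course of an ROI
#'
#' For time bins of width `bin_ms`, the proportion of all retained gaze
#' samples up to and including bin `k` that fell within the ROI:
#' `DCTC(k) = sum(S[t, r], t <= k * bin_ms) / sum(S[t], t <= k * bin_ms)`,
#' where `S[t]` counts retained samples at time `t` and `S[t, r]` those in
#' ROI `r`.  Bins whose cumulative denominator is empty yield `NA`.
#'
#' @param stream An `assigned_stream`.
#' @param label ROI label (may be `"other"`).
#' @param bin_ms Bin width in milliseconds (default 100).
#' @return Numeric vector of proportions in `[0, 1]`, one per bin.
#' @export
compute_dctc <- function(stream, label, bin_ms = 100) {
  rb <- retained_bins(stream, bin_ms)
  tot <- tabulate(rb$bin, nbins = rb$n_bins)
  hit <- tabulate(rb$bin[rb$label == label], nbins = rb$n_bins)
  num <- cumsum(hit); den <- cumsum(tot)
  ifelse(den > 0, num / den, NA_real_)
}

#' Cumulative time course of an ROI, in percent
#'
#' `CTC(t) = 100 * DCTC(ceiling(t / bin_ms))`.  The value at the end of the
#' window equals the ROI's relative total viewing time under the
#' retained-samples denominator, and the value at time `t` equals the TVT
#' restricted to the first `t` milliseconds.
#'
#' @inheritParams compute_dctc
#' @param at Optional times (ms relative to window start) at which to
#'   evaluate the curve; by default the full per-bin curve is returned.
#' @return Numeric vector of percentages.
#' @export
compute_ctc <- function(stream, label, bin_ms = 100, at = NULL) {
  dctc <- compute_dctc(stream, label, bin_ms)
  if (is.null(at)) return(100 * dctc)
  k <- pmax(1L, pmin(length(dctc), ceiling(at / bin_ms)))
  100 * dctc[k]
}

#' Non-cumulative time course of an ROI, in percent
#'
#' Per bin, the percentage of that bin's retained samples (only) that fell
#' within the ROI; empty bins yield `NA`.  The running average of these
#' values weighted by per-bin retained-sample counts reproduces the
#' cumulative time course.
#'
#' @inheritParams compute_dctc
#' @return Numeric vector of percentages, one per bin.
#' @export
compute_noncumulative <- function(stream, label, bin_ms = 100) {
  rb <- retained_bins(stream, bin_ms)
  tot <- tabulate(rb$bin, nbins = rb$n_bins)
  hit <- tabulate(rb$bin[rb$label == label], nbins = rb$n_bins)
  ifelse(tot > 0, 100 * hit / tot, NA_real_)
}

#' Tidy time-course table over all labels
#'
#' @param stream An `assigned_stream`.
#' @param mode `"cumulative"` or `"noncumulative"`.
#' @param bin_ms Bin width in milliseconds.
#' @param labels Label set; defaults to the stream's vocabulary plus
#'   `"other"`.
#' @return `data.frame` with columns `label`, `bin`, `t_ms` (bin end) and
#'   `value` (percent).
#' @export
timecourse_table <- function(stream, mode = c("cumulative", "noncumulative"),
                             bin_ms = 100, labels = NULL) {
  mode <- match.arg(mode)
  labs <- stream_labels(stream, labels)
  f <- if (mode == "cumulative") compute_ctc else compute_noncumulative
  rows <- lapply(labs, function(l) {
    v <- f(stream, l, bin_ms)
    data.frame(label = l, bin = seq_along(v), t_ms = seq_along(v) * bin_ms,
               value = v, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
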