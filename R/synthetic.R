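## Seeded synthetic-data generation: ROI tracks with known motion, gaze
## recordings with fixation/saccade/missing structure and known dwell
## ground truth, and memory tallies.  Everything is deterministic given the
## seed, so the whole analysis pipeline can be validated in closed loop.

#' Reduced-resolution screen geometry for simulation
#'
#' The stimulus display downsampled by an integer factor while keeping its
#' angular extents and frame rate, so visual-angle computations are
#' unchanged and per-frame masks stay small.  ROI assignment operates in
#' degrees, so results are resolution-independent up to pixel quantisation
#' (about 0.2 degrees per pixel at the default factor 8).
#'
#' @param scale Integer downsampling factor of the 1920 x 1080 display.
#' @return A [screen_geometry()].
#' @export
synthetic_geometry <- function(scale = 8) {
  screen_geometry(width_px = round(1920 / scale),
                  height_px = round(1080 / scale))
}

#' Default scene motion specification
#'
#' A schematic staged-crime scene in degrees of visual angle: a static
#' victim (body rectangle with head ellipse) on the left, a perpetrator
#' entering from the right and translating slowly leftward, and a small
#' critical object carried at the perpetrator's side.  Heads overlap the
#' tops of their bodies and the object overlaps the perpetrator's body
#' edge, reproducing the ROI-overlap structure that makes priority
#' resolution necessary.
#'
#' @param object_semi_deg Semi-axes of the critical object's ellipse in
#'   degrees; vary per condition to emulate objects of different size.
#' @return Named list of per-label shape specs (fields `shape`,
#'   `size_deg`/`semi_deg`, `from_deg`, `to_deg`).
#' @export
default_motion_spec <- function(object_semi_deg = c(1.1, 1.6)) {
  list(
    perpetrator_body = list(shape = "rect", size_deg = c(5, 13),
                            from_deg = c(33, 17), to_deg = c(27, 17)),
    perpetrator_head = list(shape = "ellipse", semi_deg = c(1.3, 1.7),
                            from_deg = c(33, 12), to_deg = c(27, 12)),
    victim_body = list(shape = "rect", size_deg = c(5, 13),
                       from_deg = c(14, 17), to_deg = c(14, 17)),
    victim_head = list(shape = "ellipse", semi_deg = c(1.3, 1.7),
                       from_deg = c(14, 12), to_deg = c(14, 12)),
    critical_object = list(shape = "ellipse", semi_deg = object_semi_deg,
                           from_deg = c(29.5, 20), to_deg = c(23.5, 20)))
}

#' Generate a synthetic ROI track
#'
#' Rasterises the motion specification into per-frame binary masks:
#' positions are linearly interpolated between `from_deg` and `to_deg`
#' over the window, with a small seeded sinusoidal sway emulating natural
#' body motion.  Deterministic given the seed.
#'
#' @param seed Integer seed.
#' @param geometry A [screen_geometry()]; defaults to the reduced
#'   simulation geometry.
#' @param motion_spec See [default_motion_spec()].
#' @param window_ms Analysis window `c(start, end)` in ms.
#' @param sway_deg Amplitude of the sinusoidal positional sway in degrees.
#' @return An [roi_track()].
#' @export
generate_roi_track <- function(seed, geometry = synthetic_geometry(),
                               motion_spec = default_motion_spec(),
                               window_ms = c(0, 12000), sway_deg = 0.15) {
  set.seed(seed)
  fps <- geometry$frame_rate_hz
  n_frames <- max(1L, ceiling((window_ms[2] - window_ms[1]) * fps / 1000))
  nr <- geometry$height_px; nc <- geometry$width_px
  ppd_x <- geometry$width_px / geometry$width_deg
  ppd_y <- geometry$height_px / geometry$height_deg
  phases <- stats::runif(length(motion_spec), 0, 2 * pi)
  u <- if (n_frames == 1) 0 else (seq_len(n_frames) - 1) / (n_frames - 1)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    fr <- list()
    for (i in seq_along(motion_spec)) {
      sp <- motion_spec[[i]]
      moving <- any(sp$from_deg != sp$to_deg)
      pos <- sp$from_deg + u[f] * (sp$to_deg - sp$from_deg)
      if (moving && sway_deg > 0)
        pos <- pos + sway_deg * sin(2 * pi * u[f] + phases[i]) * c(1, 0.3)
      cen <- c(pos[1] * ppd_x, pos[2] * ppd_y)
      if (sp$shape == "rect") {
        size <- c(sp$size_deg[1] * ppd_x, sp$size_deg[2] * ppd_y)
        if (cen[1] - size[1] / 2 < 0 || cen[1] + size[1] / 2 >= nc ||
            cen[2] - size[2] / 2 < 0 || cen[2] + size[2] / 2 >= nr)
          stop("motion spec places '", names(motion_spec)[i], "' off-screen")
        m <- rect_mask(cen, size, nr, nc)
      } else {
        semi <- c(sp$semi_deg[1] * ppd_x, sp$semi_deg[2] * ppd_y)
        if (cen[1] - semi[1] < 0 || cen[1] + semi[1] >= nc ||
            cen[2] - semi[2] < 0 || cen[2] + semi[2] >= nr)
          stop("motion spec places '", names(motion_spec)[i], "' off-screen")
        m <- ellipse_mask(cen, semi, 0, nr, nc)
      }
      fr[[names(motion_spec)[i]]] <- m
    }
    frames[[f]] <- fr
  }
  tr <- roi_track(geometry, frames, window_ms, labels = names(motion_spec))
  tr$centroids <- track_centroids(tr)
  tr
}

# per-frame mask centroids for every label: list of two frame x label
# matrices (x and y, 0-based pixels); cached on generated tracks
track_centroids <- function(track) {
  labs <- track$labels
  n_frames <- length(track$frames)
  cen_x <- matrix(NA_real_, n_frames, length(labs),
                  dimnames = list(NULL, labs))
  cen_y <- cen_x
  for (f in seq_len(n_frames)) for (l in labs) {
    c0 <- mask_centroid(track$frames[[f]][[l]])
    cen_x[f, l] <- c0[["x"]]; cen_y[f, l] <- c0[["y"]]
  }
  list(x = cen_x, y = cen_y)
}

#' Session configuration for the gaze simulator
#'
#' Defaults emulate a 1000-Hz recording of a 12-s scene: lognormal fixation
#' durations (median ~245 ms), 30-ms saccades, a per-fixation positional
#' offset with SD matching a typical 0.32-degree validation error, small
#' per-sample jitter producing an RMS sample-to-sample precision near
#' 0.019 degrees, and a 1.7% missing-sample rate.
#'
#' @param seed Integer seed (mandatory).
#' @param window_ms Analysis window `c(start, end)` in ms.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param dwell Named probability vector over ROI labels plus `"other"`;
#'   each fixation targets a label drawn from it.  Ignored when `schedule`
#'   is given.
#' @param schedule Optional deterministic dwell schedule: `data.frame`
#'   with columns `start_ms`, `end_ms`, `label`; a fixation targets the
#'   label of the segment containing its onset.
#' @param fixation_meanlog,fixation_sdlog Lognormal fixation-duration
#'   parameters (ms scale).
#' @param saccade_ms Saccade duration in ms.
#' @param noise_sd_deg SD of the per-fixation positional offset (degrees).
#' @param jitter_sd_deg SD of per-sample positional jitter (degrees).
#' @param missing_rate Probability that any sample is missing.
#' @param validation_error_deg Validation error recorded in the metadata.
#' @return Object of class `session_config`.
#' @export
session_config <- function(seed, window_ms = c(0, 12000),
                           sampling_rate_hz = 1000,
                           dwell = c(perpetrator_head = 0.38,
                                     perpetrator_body = 0.11,
                                     critical_object = 0.11,
                                     victim_head = 0.08,
                                     victim_body = 0.10,
                                     other = 0.22),
                           schedule = NULL,
                           fixation_meanlog = 5.5, fixation_sdlog = 0.35,
                           saccade_ms = 30, noise_sd_deg = 0.32,
                           jitter_sd_deg = 0.0096, missing_rate = 0.017,
                           validation_error_deg = 0.32) {
  if (missing(seed)) stop("session_config requires a seed")
  if (is.null(schedule)) {
    if (abs(sum(dwell) - 1) > 1e-8) stop("dwell probabilities must sum to 1")
    if (any(dwell < 0)) stop("dwell probabilities must be >= 0")
  }
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate must be in [0, 1]")
  structure(list(seed = as.integer(seed), window_ms = window_ms,
                 sampling_rate_hz = sampling_rate_hz, dwell = dwell,
                 schedule = schedule, fixation_meanlog = fixation_meanlog,
                 fixation_sdlog = fixation_sdlog, saccade_ms = saccade_ms,
                 noise_sd_deg = noise_sd_deg, jitter_sd_deg = jitter_sd_deg,
                 missing_rate = missing_rate,
                 validation_error_deg = validation_error_deg),
            class = "session_config")
}

# anchor points (px) for "other" fixations: inset corners of the screen
other_anchors <- function(geometry) {
  ix <- deg_to_px(2, geometry, "x"); iy <- deg_to_px(2, geometry, "y")
  rbind(c(ix, iy), c(geometry$width_px - 1 - ix, iy),
        c(ix, geometry$height_px - 1 - iy),
        c(geometry$width_px - 1 - ix, geometry$height_px - 1 - iy))
}

#' Simulate one participant's gaze recording against an ROI track
#'
#' Builds an alternating fixation/saccade timeline, draws a target ROI per
#' fixation from the dwell distribution (or schedule), and places fixation
#' samples on the target's mask centroid for the frame active at each
#' sample — so gaze follows a moving ROI like smooth pursuit — plus a
#' per-fixation offset and per-sample jitter.  Saccade samples interpolate
#' between the surrounding fixation positions.  Missing samples are
#' injected independently at the configured rate.  Fixations targeting
#' `"other"` land at a screen-corner anchor away from all ROIs.
#'
#' Components draw from sub-streams seeded at fixed offsets from the
#' session seed (timeline, targets, offsets, jitter, missingness), so each
#' can be regenerated independently.
#'
#' @param config A [session_config()].
#' @param track An [roi_track()] providing geometry and ROI centroids.
#' @return List with `recording` (a [gaze_recording()]), `ground_truth`
#'   (named vector: realised proportion of retained samples targeting each
#'   label), and `targets` (per-sample intended label).
#' @export
generate_session <- function(config, track) {
  g <- track$geometry
  w <- config$window_ms
  rate <- config$sampling_rate_hz
  n <- floor((w[2] - w[1]) * rate / 1000)
  if (n < 1) stop("window shorter than one sampling interval")
  t_ms <- w[1] + (seq_len(n) - 1) * 1000 / rate

  # timeline of alternating fixation / saccade segments
  set.seed(config$seed + 1L)
  total <- w[2] - w[1]
  durs <- c(); kinds <- c()
  acc <- 0
  while (acc < total) {
    fd <- min(1500, max(50, stats::rlnorm(1, config$fixation_meanlog,
                                          config$fixation_sdlog)))
    if (fd < 1000 / rate) stop("fixation segment shorter than one sample")
    durs <- c(durs, fd, config$saccade_ms)
    kinds <- c(kinds, "fixation", "saccade")
    acc <- acc + fd + config$saccade_ms
  }
  seg_start <- w[1] + cumsum(c(0, durs[-length(durs)]))
  seg_of <- findInterval(t_ms, seg_start)
  fix_segs <- which(kinds == "fixation")

  # per-fixation targets
  set.seed(config$seed + 2L)
  labs <- track$labels
  if (is.null(config$schedule)) {
    vocab <- names(config$dwell)
    targets_fix <- sample(vocab, length(fix_segs), replace = TRUE,
                          prob = config$dwell)
  } else {
    sch <- config$schedule
    targets_fix <- vapply(seg_start[fix_segs], function(t0) {
      hit <- which(sch$start_ms <= t0 & t0 < sch$end_ms)
      if (length(hit)) sch$label[hit[1]] else "other"
    }, character(1))
  }
  anchors <- other_anchors(g)
  anchor_of <- sample(nrow(anchors), length(fix_segs), replace = TRUE)

  # per-fixation offsets, degrees -> pixels per axis
  set.seed(config$seed + 3L)
  off_x <- stats::rnorm(length(fix_segs), 0, deg_to_px(config$noise_sd_deg, g, "x"))
  off_y <- stats::rnorm(length(fix_segs), 0, deg_to_px(config$noise_sd_deg, g, "y"))

  # centroid of each label at each frame (cached on generated tracks)
  n_frames <- length(track$frames)
  cen <- if (!is.null(track$centroids)) track$centroids
         else track_centroids(track)
  cen_x <- cen$x; cen_y <- cen$y

  frame_i <- pmin(pmax(floor((t_ms - w[1]) * g$frame_rate_hz / 1000), 0L),
                  n_frames - 1L) + 1L
  x <- numeric(n); y <- numeric(n)
  event <- rep("saccade", n)
  target <- rep(NA_character_, n)
  fix_index <- match(seg_of, fix_segs)    # NA for saccade samples
  is_fix <- !is.na(fix_index)
  event[is_fix] <- "fixation"
  target[is_fix] <- targets_fix[fix_index[is_fix]]

  on_roi <- is_fix & target[] != "other"
  if (any(on_roi)) {
    ti <- match(target[on_roi], labs)
    x[on_roi] <- cen_x[cbind(frame_i[on_roi], ti)] + off_x[fix_index[on_roi]]
    y[on_roi] <- cen_y[cbind(frame_i[on_roi], ti)] + off_y[fix_index[on_roi]]
  }
  on_other <- is_fix & !on_roi
  if (any(on_other)) {
    a <- anchor_of[fix_index[on_other]]
    x[on_other] <- anchors[a, 1] + off_x[fix_index[on_other]]
    y[on_other] <- anchors[a, 2] + off_y[fix_index[on_other]]
  }

  # saccade samples: linear interpolation between neighbouring fixations
  sac <- which(!is_fix)
  if (length(sac)) {
    fx <- which(is_fix)
    prev_i <- findInterval(sac, fx)
    next_i <- pmin(prev_i + 1L, length(fx))
    prev_i <- pmax(prev_i, 1L)
    p0 <- fx[prev_i]; p1 <- fx[next_i]
    frac <- ifelse(p1 > p0, (sac - p0) / (p1 - p0), 0)
    frac <- pmin(pmax(frac, 0), 1)
    x[sac] <- x[p0] + frac * (x[p1] - x[p0])
    y[sac] <- y[p0] + frac * (y[p1] - y[p0])
  }

  # per-sample jitter
  set.seed(config$seed + 4L)
  x <- x + stats::rnorm(n, 0, deg_to_px(config$jitter_sd_deg, g, "x"))
  y <- y + stats::rnorm(n, 0, deg_to_px(config$jitter_sd_deg, g, "y"))

  # missing samples
  set.seed(config$seed + 5L)
  miss <- stats::runif(n) < config$missing_rate
  x[miss] <- NA_real_; y[miss] <- NA_real_
  event[miss] <- "missing"

  retained <- event == "fixation"
  vocab_all <- c(labs, "other")
  gt <- vapply(vocab_all, function(l) sum(retained & target == l), numeric(1))
  gt <- if (sum(gt) > 0) gt / sum(gt) else gt

  rec <- gaze_recording(
    data.frame(t_ms = t_ms, x_px = x, y_px = y, event = event,
               stringsAsFactors = FALSE),
    sampling_rate_hz = rate, eye = "left",
    validation_error_deg = config$validation_error_deg)
  list(recording = rec, ground_truth = gt, targets = target)
}

#' Cohort configuration for the gaze simulator
#'
#' Defaults reflect a three-condition between-subjects design with 54
#' participants per condition watching a 12-s scene, with subject-level
#' heterogeneity in how much gaze the critical object attracts, and
#' binomial memory tallies around 77% detail accuracy.
#'
#' `effect_d` injects a standardised difference in the focus label's dwell
#' share between the first and second condition: the second condition's
#' mean share is raised by `effect_d` times the total between-subject SD
#' of the recovered dwell share (subject heterogeneity plus within-session
#' sampling noise, computed from the session parameters).
#'
#' @param seed Integer seed (mandatory).
#' @param n_per_condition Participants per condition.
#' @param conditions Condition names.
#' @param base_dwell Baseline dwell probability vector (labels + other).
#' @param focus_label Label carrying subject heterogeneity and any
#'   injected effect.
#' @param subject_sd Between-subject SD of the focus label's dwell share.
#' @param effect_d Injected standardised effect size (0 = null).
#' @param memory_p Probability a recalled detail is correct.
#' @param n_details Details scored per participant.
#' @param window_ms,sampling_rate_hz Session window and rate.
#' @param geometry Simulation [screen_geometry()].
#' @param session_args Extra arguments passed to every [session_config()].
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(seed, n_per_condition = 54,
                          conditions = c("knife", "water_bottle", "plunger"),
                          base_dwell = c(perpetrator_head = 0.38,
                                         perpetrator_body = 0.11,
                                         critical_object = 0.11,
                                         victim_head = 0.08,
                                         victim_body = 0.10,
                                         other = 0.22),
                          focus_label = "critical_object",
                          subject_sd = 0.10, effect_d = 0,
                          memory_p = 0.77, n_details = 40,
                          window_ms = c(0, 12000), sampling_rate_hz = 1000,
                          geometry = synthetic_geometry(),
                          session_args = list()) {
  if (missing(seed)) stop("cohort_config requires a seed")
  if (n_per_condition < 2) stop("need at least 2 participants per condition")
  structure(list(seed = as.integer(seed), n_per_condition = n_per_condition,
                 conditions = conditions, base_dwell = base_dwell,
                 focus_label = focus_label, subject_sd = subject_sd,
                 effect_d = effect_d, memory_p = memory_p,
                 n_details = n_details, window_ms = window_ms,
                 sampling_rate_hz = sampling_rate_hz, geometry = geometry,
                 session_args = session_args),
            class = "cohort_config")
}

# expected SD of a participant's recovered dwell share: subject
# heterogeneity plus within-session sampling noise.  A session has about
# m = window / (mean fixation + saccade) fixations; each contributes its
# duration as weight, inflating the binomial share variance by (1 + cv^2).
dwell_share_sd <- function(cfg, session_defaults = session_config(seed = 0L)) {
  sa <- utils::modifyList(
    session_defaults[c("fixation_meanlog", "fixation_sdlog", "saccade_ms")],
    cfg$session_args[intersect(names(cfg$session_args),
                               c("fixation_meanlog", "fixation_sdlog",
                                 "saccade_ms"))])
  mean_fix <- exp(sa$fixation_meanlog + sa$fixation_sdlog^2 / 2)
  m <- (cfg$window_ms[2] - cfg$window_ms[1]) / (mean_fix + sa$saccade_ms)
  cv2 <- exp(sa$fixation_sdlog^2) - 1
  p <- cfg$base_dwell[[cfg$focus_label]]
  sqrt(cfg$subject_sd^2 + p * (1 - p) * (1 + cv2) / m)
}

# per-subject dwell vector: shift the focus label to p_subj, rescale the
# rest proportionally
subject_dwell <- function(base, focus_label, p_subj) {
  p_subj <- min(max(p_subj, 0.01), 0.95)
  out <- base
  others <- setdiff(names(base), focus_label)
  out[focus_label] <- p_subj
  out[others] <- base[others] * (1 - p_subj) / sum(base[others])
  out
}

#' Generate a synthetic cohort with known ground truth
#'
#' Generates one ROI track per condition (all conditions share the default
#' scene motion), independent gaze sessions for every participant with
#' subject-specific dwell probabilities, and binomial memory tallies.
#' Deterministic given the cohort seed; per-session seeds are derived from
#' it by fixed offsets.
#'
#' @param cfg A [cohort_config()].
#' @param tracks Optional named list of prebuilt [roi_track()]s, one per
#'   condition; the scene is fixed per condition in a typical design, so
#'   replicated cohorts can share tracks instead of regenerating them.
#' @return List with `tracks` (per condition), `participants`
#'   (`data.frame`: id, condition, subject-level focus dwell share),
#'   `recordings` (list of [gaze_recording()]), `ground_truth`
#'   (`data.frame` of realised per-label retained-sample proportions), and
#'   `tallies` (memory tally `data.frame`).
#' @export
generate_cohort <- function(cfg, tracks = NULL) {
  conds <- cfg$conditions
  delta <- if (cfg$effect_d != 0) cfg$effect_d * dwell_share_sd(cfg) else 0
  cond_p <- stats::setNames(rep(cfg$base_dwell[[cfg$focus_label]],
                                length(conds)), conds)
  if (length(conds) >= 2) cond_p[2] <- cond_p[2] + delta

  if (is.null(tracks)) {
    tracks <- stats::setNames(lapply(seq_along(conds), function(i) {
      generate_roi_track(cfg$seed + i, geometry = cfg$geometry,
                         window_ms = cfg$window_ms)
    }), conds)
  } else if (!all(conds %in% names(tracks))) {
    stop("prebuilt tracks must be named by condition")
  }

  n_total <- cfg$n_per_condition * length(conds)
  ids <- sprintf("p%03d", seq_len(n_total))
  participants <- data.frame(
    participant = ids,
    condition = rep(conds, each = cfg$n_per_condition),
    stringsAsFactors = FALSE)

  set.seed(cfg$seed + 100L)
  p_subject <- stats::rnorm(n_total,
                            cond_p[participants$condition], cfg$subject_sd)
  participants$dwell_focus <- pmin(pmax(p_subject, 0.01), 0.95)

  recordings <- vector("list", n_total)
  gt_rows <- vector("list", n_total)
  for (k in seq_len(n_total)) {
    dw <- subject_dwell(cfg$base_dwell, cfg$focus_label,
                        participants$dwell_focus[k])
    sess_seed <- (cfg$seed + 104729L * k) %% 2147483647L
    sc_args <- c(list(seed = sess_seed, window_ms = cfg$window_ms,
                      sampling_rate_hz = cfg$sampling_rate_hz, dwell = dw),
                 cfg$session_args)
    sess <- generate_session(do.call(session_config, sc_args),
                             tracks[[participants$condition[k]]])
    recordings[[k]] <- sess$recording
    gt_rows[[k]] <- data.frame(participant = ids[k],
                               t(sess$ground_truth),
                               check.names = FALSE,
                               stringsAsFactors = FALSE)
  }

  set.seed(cfg$seed + 200L)
  n_correct <- stats::rbinom(n_total, cfg$n_details, cfg$memory_p)
  tallies <- data.frame(participant = ids, rater = 1L,
                        n_correct = n_correct,
                        n_incorrect = cfg$n_details - n_correct,
                        stringsAsFactors = FALSE)

  list(tracks = tracks, participants = participants,
       recordings = recordings,
       ground_truth = do.call(rbind, gt_rows),
       tallies = tallies,
       condition_focus_mean = cond_p)
}
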