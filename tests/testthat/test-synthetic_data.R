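# Seeded synthetic generator: determinism, geometry, and the closed loop
# between generated ground truth and the analysis pipeline.

small_geom <- function() synthetic_geometry(12)

test_that("track generation is deterministic and respects the screen", {
  g <- small_geom()
  t1 <- generate_roi_track(5, g, window_ms = c(0, 2000))
  t2 <- generate_roi_track(5, g, window_ms = c(0, 2000))
  expect_identical(t1$frames, t2$frames)
  t3 <- generate_roi_track(6, g, window_ms = c(0, 2000))
  expect_false(identical(t1$frames, t3$frames))

  # static spec: identical masks every frame
  spec <- default_motion_spec()
  spec <- lapply(spec, function(s) { s$to_deg <- s$from_deg; s })
  ts <- generate_roi_track(5, g, motion_spec = spec, window_ms = c(0, 1000))
  for (f in seq_along(ts$frames))
    expect_identical(ts$frames[[f]], ts$frames[[1]])

  bad <- default_motion_spec()
  bad$perpetrator_body$to_deg <- c(60, 17)   # walks off a 47.5-deg screen
  expect_error(generate_roi_track(5, g, motion_spec = bad), "off-screen")
})

test_that("heads stay inside the dilated body region in every frame", {
  tr <- generate_roi_track(7, small_geom(), window_ms = c(0, 2000))
  g <- tr$geometry
  for (f in seq(1, length(tr$frames), by = 10)) {
    body_region <- dilate_roi(tr$frames[[f]]$perpetrator_body, 2.5, g)
    expect_true(all(body_region[tr$frames[[f]]$perpetrator_head]))
  }
})

test_that("sessions are reproducible and structurally sound", {
  tr <- generate_roi_track(8, small_geom(), window_ms = c(0, 3000))
  cfg <- session_config(seed = 123, window_ms = c(0, 3000),
                        sampling_rate_hz = 500)
  s1 <- generate_session(cfg, tr)
  s2 <- generate_session(cfg, tr)
  expect_identical(s1$recording$samples, s2$recording$samples)
  expect_identical(s1$ground_truth, s2$ground_truth)

  sam <- s1$recording$samples
  expect_equal(nrow(sam), 1500)
  expect_true(all(diff(sam$t_ms) > 0))
  expect_true(all(sam$event %in% c("fixation", "saccade", "missing")))
  expect_true(anyNA(sam$x_px[sam$event == "missing"]))
  expect_equal(sum(s1$ground_truth), 1, tolerance = 1e-12)
})

test_that("a pure-critical-object schedule with no noise recovers 100% TVT", {
  tr <- generate_roi_track(9, small_geom(), window_ms = c(0, 3000))
  cfg <- session_config(seed = 77, window_ms = c(0, 3000),
                        sampling_rate_hz = 500,
                        schedule = data.frame(start_ms = 0, end_ms = 3000,
                                              label = "critical_object"),
                        noise_sd_deg = 0, jitter_sd_deg = 0,
                        missing_rate = 0)
  ses <- generate_session(cfg, tr)
  st <- assign_samples(ses$recording, tr, margin_deg = 0.5)
  tvt <- compute_tvt(st)
  expect_equal(unname(tvt["critical_object"]), 100)
})

test_that("recovered TVT tracks the generated dwell mix within 2%", {
  tr <- generate_roi_track(10, small_geom(), window_ms = c(0, 12000))
  dw <- c(perpetrator_head = 0.6, critical_object = 0.4,
          perpetrator_body = 0, victim_head = 0, victim_body = 0, other = 0)
  cfg <- session_config(seed = 99, window_ms = c(0, 12000),
                        sampling_rate_hz = 500, dwell = dw)
  ses <- generate_session(cfg, tr)
  st <- assign_samples(ses$recording, tr, margin_deg = 0.5)
  tvt <- compute_tvt(st)
  gt <- 100 * ses$ground_truth
  expect_lt(max(abs(tvt[names(gt)] - gt)), 2)
})

test_that("the injected missing rate is recovered by the data-loss metric", {
  tr <- generate_roi_track(11, small_geom(), window_ms = c(0, 12000))
  cfg <- session_config(seed = 13, window_ms = c(0, 12000),
                        sampling_rate_hz = 1000, missing_rate = 0.017)
  ses <- generate_session(cfg, tr)
  loss <- data_loss(ses$recording, c(0, 12000))
  se <- 100 * sqrt(0.017 * 0.983 / 12000)
  expect_lt(abs(loss - 1.70), 4 * se)
})

test_that("cohorts are seed-reproducible with binomial memory tallies", {
  g <- small_geom()
  cfg <- cohort_config(seed = 3, n_per_condition = 3,
                       conditions = c("A", "B"), window_ms = c(0, 1000),
                       sampling_rate_hz = 250, geometry = g,
                       memory_p = 0.77, n_details = 40)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$recordings[[4]]$samples, c2$recordings[[4]]$samples)
  expect_identical(c1$tallies, c2$tallies)
  expect_equal(nrow(c1$participants), 6)
  expect_true(all(c1$tallies$n_correct + c1$tallies$n_incorrect == 40))
  acc <- memory_accuracy(c1$tallies$n_correct, c1$tallies$n_incorrect)
  expect_true(all(acc >= 0 & acc <= 100))
})

test_that("large generated cohorts centre memory accuracy on its p", {
  cfg <- cohort_config(seed = 17, n_per_condition = 2, conditions = "A",
                       window_ms = c(0, 400), sampling_rate_hz = 250,
                       geometry = small_geom(), memory_p = 0.77,
                       n_details = 40)
  set.seed(cfg$seed + 200L)
  n_correct <- rbinom(500, 40, 0.77)     # the generator's tally model
  acc <- memory_accuracy(n_correct, 40 - n_correct)
  expect_lt(abs(mean(acc) - 77), 3 * 100 * sqrt(0.77 * 0.23 / 40) / sqrt(500))
})
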