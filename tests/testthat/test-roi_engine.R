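# ROI construction, transformation and priority-resolved assignment.

test_that("degree-to-pixel conversion is linear in the screen extents", {
  g <- screen_geometry()
  expect_equal(deg_to_px(0, g, "x"), 0)
  expect_equal(deg_to_px(47.5, g, "x"), 1920)
  expect_equal(deg_to_px(27.8, g, "y"), 1080)
  expect_equal(deg_to_px(0.5, g, "x"), 1920 / 47.5 * 0.5)
  expect_error(deg_to_px(-1, g, "x"), ">= 0")
  expect_equal(px_to_deg(deg_to_px(3.7, g, "y"), g, "y"), 3.7)
})

test_that("margin dilation matches the discrete elliptical kernel", {
  g <- tiny_geometry()
  m <- matrix(FALSE, g$height_px, g$width_px)
  m[50, 100] <- TRUE
  d <- dilate_roi(m, 0.5, g)  # 0.5 deg -> 5 px radius on both axes
  # oracle: enumerate kernel offsets around the single pixel
  kernel_px <- sum(outer(-5:5, -5:5,
                         function(i, j) (i / 5)^2 + (j / 5)^2 <= 1))
  expect_equal(sum(d), kernel_px)
  expect_true(all(d[m]))            # superset of the input
  expect_identical(dilate_roi(m, 0, g), m)
})

test_that("dilation clips at frame bounds and grows monotonically", {
  g <- tiny_geometry()
  m <- matrix(FALSE, g$height_px, g$width_px)
  m[1, 1] <- TRUE                   # touching the top-left corner
  d <- dilate_roi(m, 1, g)
  expect_equal(dim(d), dim(m))
  expect_true(sum(d) > 1)
  d1 <- dilate_roi(disk_mask(100, 50, 8), 0.3, g)
  d2 <- dilate_roi(disk_mask(100, 50, 8), 0.9, g)
  expect_true(all(d2[d1]))          # larger margin contains smaller
  expect_warning(dilate_roi(matrix(FALSE, 4, 4), 0.5, g), "empty")
})

test_that("head-ellipse fitting recovers symmetric shapes by moments", {
  rect <- rect_mask(c(60, 40), c(30, 16), 100, 200)
  e <- fit_head_ellipse(rect, top_fraction = 1)
  expect_equal(unname(e$center), unname(mask_centroid(rect)), tolerance = 1e-9)
  expect_lt(abs(e$rotation), 1e-6)

  disk <- disk_mask(80, 30, 12)
  body <- disk | rect_mask(c(80, 70), c(20, 50), 100, 200)
  # top ~30% of the vertical extent isolates the disk
  ed <- fit_head_ellipse(body, top_fraction = 0.32)
  expect_lt(abs(ed$semi_axes[["a"]] - ed$semi_axes[["b"]]) /
              ed$semi_axes[["a"]], 0.02)
  expect_equal(unname(ed$center), c(80, 30), tolerance = 0.5)
  # area-equivalence: pi * a * b equals the region pixel count
  expect_equal(pi * prod(ed$semi_axes), sum(disk), tolerance = 1e-6)

  # two disjoint lobes give one ellipse at the joint centroid
  lobes <- disk_mask(40, 20, 6) | disk_mask(90, 20, 6)
  el <- fit_head_ellipse(lobes, top_fraction = 1)
  expect_equal(el$center[["x"]], 65, tolerance = 0.5)
  expect_error(fit_head_ellipse(matrix(FALSE, 5, 5)), "empty")
})

test_that("size equalisation matches average areas across conditions", {
  g <- tiny_geometry()
  # frames at varying subpixel positions, as in a real moving-ROI track,
  # so rasterisation steps average out over the window
  mk_track <- function(r) {
    frames <- lapply(1:8, function(f)
      list(critical_object = disk_mask(100 + f * 0.37, 50 + f * 0.21, r,
                                       g$height_px, g$width_px)))
    roi_track(g, frames, c(0, 320), labels = "critical_object")
  }
  # identical tracks: factors stay 1
  eq0 <- equalize_roi_sizes(list(a = mk_track(10), b = mk_track(10)),
                            "critical_object")
  expect_equal(unname(eq0$factors), c(1, 1), tolerance = 1e-9)

  # areas A and ~3A: both equalised averages within 1% of the grand mean
  ra <- 8; rb <- ra * sqrt(3)
  ta <- mk_track(ra); tb <- mk_track(rb)
  avg <- function(tr) mean(vapply(tr$frames,
    function(fr) sum(fr$critical_object), numeric(1)))
  target <- mean(c(avg(ta), avg(tb)))
  eq <- equalize_roi_sizes(list(a = ta, b = tb), "critical_object")
  areas <- vapply(eq$tracks, avg, numeric(1))
  expect_lt(max(abs(areas - target) / target), 0.01)

  # scaling preserves the centroid
  cen0 <- mask_centroid(mk_track(ra)$frames[[1]]$critical_object)
  cen1 <- mask_centroid(eq$tracks$a$frames[[1]]$critical_object)
  expect_lt(max(abs(cen1 - cen0)), 0.5)
})

test_that("assignment follows priority order within overlapping ROIs", {
  tr <- tiny_track(n_frames = 1)
  # (120, 60) lies in both the critical object and the perpetrator body;
  # (130, 25) in both perpetrator head and body; (10, 5) in nothing
  rec <- make_recording(t_ms = c(0, 1, 2, 3),
                        x_px = c(120, 130, 10, 121),
                        y_px = c(60, 25, 5, 60),
                        event = c("fixation", "fixation", "fixation", "saccade"))
  st <- assign_samples(rec, tr, margin_deg = 0)
  expect_equal(st$label, c("critical_object", "perpetrator_head", "other",
                           "saccade"))
  expect_equal(st$excluded, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("saccade and missing samples are carried through excluded", {
  tr <- tiny_track(n_frames = 1)
  rec <- make_recording(t_ms = 0:2, x_px = c(120, NA, 120),
                        y_px = c(60, NA, 60),
                        event = c("saccade", "missing", "fixation"))
  st <- assign_samples(rec, tr)
  expect_equal(st$label, c("saccade", "missing", "critical_object"))
  expect_equal(sum(st$excluded), 2)
})

test_that("samples outside the track window are dropped and counted", {
  tr <- tiny_track(n_frames = 2)  # window [0, 80)
  rec <- make_recording(t_ms = c(-5, 0, 79, 80, 200),
                        x_px = rep(120, 5), y_px = rep(60, 5),
                        event = rep("fixation", 5))
  st <- assign_samples(rec, tr)
  expect_equal(nrow(st), 2)
  expect_equal(attr(st, "n_dropped"), 3)
})

test_that("assignment agrees with a brute-force membership oracle and is
           permutation-consistent", {
  set.seed(21)
  tr <- tiny_track(n_frames = 4)
  g <- tr$geometry
  n <- 300
  rec <- make_recording(t_ms = sort(runif(n, 0, 159.9)),
                        x_px = runif(n, 0, g$width_px - 1),
                        y_px = runif(n, 0, g$height_px - 1),
                        event = rep("fixation", n))
  margin <- 0.4
  prios <- list(priority_order(),
                priority_order(rev(roi_labels())),
                priority_order(c("victim_head", "critical_object",
                                 "perpetrator_body", "perpetrator_head",
                                 "victim_body")))
  # oracle: full membership matrix from explicitly dilated masks
  memberships <- function(rec, tr, margin) {
    dil <- lapply(tr$frames, function(fr)
      lapply(fr, dilate_roi, margin_deg = margin, geometry = g))
    t(sapply(seq_len(nrow(rec$samples)), function(i) {
      f <- floor(rec$samples$t_ms[i] * g$frame_rate_hz / 1000) + 1
      xi <- round(rec$samples$x_px[i]) + 1; yi <- round(rec$samples$y_px[i]) + 1
      vapply(roi_labels(), function(l) dil[[f]][[l]][yi, xi], logical(1))
    }))
  }
  mem <- memberships(rec, tr, margin)
  for (pr in prios) {
    st <- assign_samples(rec, tr, priority = pr, margin_deg = margin)
    oracle <- apply(mem, 1, function(row) {
      hit <- as.character(pr)[which(row[as.character(pr)])[1]]
      if (is.na(hit)) "other" else hit
    })
    expect_identical(st$label, unname(oracle))
  }
  # permuting priority can only change labels of multiply-covered samples
  stA <- assign_samples(rec, tr, priority = prios[[1]], margin_deg = margin)
  stB <- assign_samples(rec, tr, priority = prios[[2]], margin_deg = margin)
  changed <- stA$label != stB$label
  expect_true(all(rowSums(mem)[changed] >= 2))
})

test_that("enlarging the margin never reassigns an ROI sample to other", {
  set.seed(22)
  tr <- tiny_track(n_frames = 2)
  g <- tr$geometry
  rec <- make_recording(t_ms = sort(runif(200, 0, 79.9)),
                        x_px = runif(200, 0, g$width_px - 1),
                        y_px = runif(200, 0, g$height_px - 1),
                        event = rep("fixation", 200))
  st1 <- assign_samples(rec, tr, margin_deg = 0.2)
  st2 <- assign_samples(rec, tr, margin_deg = 0.8)
  expect_false(any(st1$label != "other" & st2$label == "other"))
})

test_that("precomputed label fields reproduce on-the-fly assignment", {
  set.seed(23)
  tr <- tiny_track(n_frames = 3)
  g <- tr$geometry
  rec <- make_recording(t_ms = sort(runif(150, 0, 119.9)),
                        x_px = runif(150, -10, g$width_px + 10),
                        y_px = runif(150, -10, g$height_px + 10),
                        event = sample(c("fixation", "saccade"), 150, TRUE))
  fl <- build_label_fields(tr, margin_deg = 0.5)
  expect_identical(assign_samples(rec, tr, margin_deg = 0.5)$label,
                   assign_samples(rec, fields = fl)$label)
})
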