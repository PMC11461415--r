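## Binary mask primitives: run-length coding, rasterisation, dilation,
## moments-based ellipse fitting, and isotropic rescaling.
##
## Masks are logical matrices indexed [row = y + 1, col = x + 1] for 0-based
## pixel coordinates (x, y).

#' Run-length encode a binary mask
#'
#' Flattens the mask in column-major order (R's native layout over
#' `[y, x]` matrices) and stores the lengths of alternating runs, starting
#' with a run of zeros (possibly of length 0 when the first pixel is set).
#'
#' @param mask Logical or 0/1 matrix.
#' @return Integer vector of run lengths; `sum(lengths) == length(mask)`.
#' @seealso [rle_decode_mask()]
#' @export
rle_encode_mask <- function(mask) {
  v <- as.integer(mask)
  if (anyNA(v) || any(v < 0L | v > 1L)) stop("mask must be binary")
  r <- rle(v)
  if (length(r$values) == 0L) return(integer(0))
  lens <- r$lengths
  if (r$values[1] == 1L) lens <- c(0L, lens)
  as.integer(lens)
}

#' Decode a run-length encoded binary mask
#'
#' @param lengths Integer run lengths as produced by [rle_encode_mask()].
#' @param nrow,ncol Mask dimensions.
#' @return Logical matrix of dimension `nrow` x `ncol`.
#' @export
rle_decode_mask <- function(lengths, nrow, ncol) {
  n <- nrow * ncol
  if (sum(lengths) != n)
    stop(sprintf("run lengths sum to %d, expected %d", sum(lengths), n))
  vals <- rep_len(c(0L, 1L), length(lengths))
  matrix(as.logical(inverse.rle(list(lengths = as.integer(lengths),
                                     values = vals))), nrow, ncol)
}

mask_area <- function(mask) sum(mask)

# centroid in 0-based pixel coordinates c(x, y); NA for empty masks
mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(c(x = NA_real_, y = NA_real_))
  c(x = mean(idx[, 2] - 1), y = mean(idx[, 1] - 1))
}

#' Rasterise an ellipse into a binary mask
#'
#' @param center Numeric `c(x, y)` in 0-based pixel coordinates.
#' @param semi_axes Numeric `c(a, b)`: semi-axis lengths in pixels along the
#'   (rotated) x and y directions; must be > 0.
#' @param rotation Rotation in radians (counter-clockwise in screen
#'   coordinates).
#' @param nrow,ncol Mask dimensions (screen height and width in pixels).
#' @return Logical matrix.
#' @export
ellipse_mask <- function(center, semi_axes, rotation = 0, nrow, ncol) {
  if (any(semi_axes <= 0)) stop("semi-axes must be strictly positive")
  x <- matrix(rep(0:(ncol - 1), each = nrow), nrow, ncol) - center[1]
  y <- matrix(rep(0:(nrow - 1), times = ncol), nrow, ncol) - center[2]
  u <- cos(rotation) * x + sin(rotation) * y
  v <- -sin(rotation) * x + cos(rotation) * y
  (u / semi_axes[1])^2 + (v / semi_axes[2])^2 <= 1
}

#' Rasterise an axis-aligned rectangle into a binary mask
#'
#' @param center Numeric `c(x, y)` in 0-based pixel coordinates.
#' @param size Numeric `c(width, height)` in pixels.
#' @inheritParams ellipse_mask
#' @return Logical matrix.
#' @export
rect_mask <- function(center, size, nrow, ncol) {
  x <- 0:(ncol - 1); y <- 0:(nrow - 1)
  in_x <- abs(x - center[1]) <= size[1] / 2
  in_y <- abs(y - center[2]) <= size[2] / 2
  outer(in_y, in_x, "&")
}

# discrete elliptical structuring element with integer radii rx, ry (pixels)
elliptical_kernel <- function(rx, ry) {
  rx <- max(0L, as.integer(round(rx))); ry <- max(0L, as.integer(round(ry)))
  dy <- -ry:ry; dx <- -rx:rx
  k <- outer(dy, dx, function(i, j) {
    (i / max(ry, 0.5))^2 + (j / max(rx, 0.5))^2 <= 1
  })
  storage.mode(k) <- "integer"
  k
}

#' Dilate a binary ROI mask by a visual-angle margin
#'
#' Morphological dilation with an elliptical structuring element whose
#' per-axis pixel radii correspond to `margin_deg` degrees of visual angle
#' under `geometry` (so the margin is isotropic in degrees, anisotropic in
#' pixels).  The result always contains the input and is clipped to the
#' frame bounds.  A margin that rounds to zero pixels on both axes returns
#' the mask unchanged.
#'
#' @param mask Logical matrix.
#' @param margin_deg Margin in degrees of visual angle (>= 0); the
#'   conventional allowance for eye-tracker inaccuracy is 0.5 degrees.
#' @param geometry A [screen_geometry()] used for the degree-to-pixel
#'   conversion.
#' @return Logical matrix of the same dimension.
#' @export
dilate_roi <- function(mask, margin_deg, geometry = screen_geometry()) {
  if (margin_deg < 0) stop("margin_deg must be >= 0")
  if (!any(mask)) {
    warning("dilating an empty mask; returning it unchanged")
    return(mask)
  }
  rx <- round(deg_to_px(margin_deg, geometry, "x"))
  ry <- round(deg_to_px(margin_deg, geometry, "y"))
  if (rx < 1 && ry < 1) return(mask)
  k <- elliptical_kernel(rx, ry)
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  EBImage::dilate(m, k) > 0
}

#' Elliptical head ROI fitted to the top of a body mask
#'
#' Takes the top `top_fraction` of the mask's vertical extent and fits an
#' ellipse by image moments: the ellipse is centred on the region centroid,
#' oriented along the principal axes of the region's second central moments,
#' and scaled so that its area equals the region's pixel area.  For a region
#' that is itself elliptical this recovers the region.  Disconnected regions
#' yield a single ellipse at the joint centroid.
#'
#' @param body_mask Logical matrix covering the whole body.
#' @param top_fraction Fraction (0, 1] of the mask's vertical extent, from
#'   the top, used for the fit.  Default 0.15, roughly the head's share of a
#'   standing person's height.
#' @return An object of class `ellipse_spec`: list with `center` (x, y),
#'   `semi_axes` (a, b) and `rotation` (radians).
#' @export
fit_head_ellipse <- function(body_mask, top_fraction = 0.15) {
  if (!any(body_mask)) stop("body mask is empty")
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must be in (0, 1]")
  rows <- which(rowSums(body_mask) > 0)
  y0 <- min(rows); y1 <- max(rows)
  cut <- y0 + max(1, ceiling(top_fraction * (y1 - y0 + 1))) - 1
  region <- body_mask
  if (cut < nrow(region)) region[(cut + 1):nrow(region), ] <- FALSE
  idx <- which(region, arr.ind = TRUE)
  n <- nrow(idx)
  if (n < 5) stop("top region has fewer than 5 pixels; cannot fit ellipse")
  xs <- idx[, 2] - 1; ys <- idx[, 1] - 1
  cx <- mean(xs); cy <- mean(ys)
  # second central moments with a 1/12 term for the unit-square pixel extent
  mxx <- mean((xs - cx)^2) + 1 / 12
  myy <- mean((ys - cy)^2) + 1 / 12
  mxy <- mean((xs - cx) * (ys - cy))
  theta <- 0.5 * atan2(2 * mxy, mxx - myy)
  tr <- mxx + myy
  det_ <- mxx * myy - mxy^2
  disc <- sqrt(max(0, (tr / 2)^2 - det_))
  l1 <- tr / 2 + disc; l2 <- max(tr / 2 - disc, 1e-9)
  a <- 2 * sqrt(l1); b <- 2 * sqrt(l2)  # uniform-ellipse relation var = a^2/4
  s <- sqrt(n / (pi * a * b))           # match region area exactly
  structure(list(center = c(x = cx, y = cy),
                 semi_axes = c(a = a * s, b = b * s),
                 rotation = theta),
            class = "ellipse_spec")
}

# isotropic rescale of a mask about a fixed point by nearest-neighbour
# inverse mapping; factor 1 returns the input unchanged
scale_mask <- function(mask, factor, about = mask_centroid(mask)) {
  if (factor <= 0) stop("scale factor must be > 0")
  if (factor == 1) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  x <- rep(0:(nc - 1), each = nr); y <- rep(0:(nr - 1), times = nc)
  sx <- round(about[["x"]] + (x - about[["x"]]) / factor)
  sy <- round(about[["y"]] + (y - about[["y"]]) / factor)
  ok <- sx >= 0 & sx < nc & sy >= 0 & sy < nr
  out <- logical(nr * nc)
  out[ok] <- mask[cbind(sy[ok] + 1, sx[ok] + 1)]
  matrix(out, nr, nc)
}

#' Equalise the average size of an ROI across conditions
#'
#' Rescales the masks of one label so that every condition's time-averaged
#' mask area matches the grand mean of the conditions' time-averaged areas.
#' Each condition uses a single constant factor applied isotropically about
#' each frame's mask centroid, so mask positions are preserved.  The factor
#' is refined iteratively until the realised average area is within `tol`
#' of the target (discrete rasterisation makes the area only approximately
#' quadratic in the factor).
#'
#' @param tracks Named list of [roi_track()] objects, one per condition,
#'   each containing `label` in every frame.
#' @param label ROI label to equalise (e.g. `"critical_object"`).
#' @param tol Relative tolerance on the equalised average area (default 1%).
#'   Rasterisation makes the realised area a step function of the factor,
#'   so for very small or static masks the nearest achievable average may
#'   sit outside `tol`; a warning reports the residual in that case.
#' @return List with `tracks` (rescaled copies) and `factors` (final linear
#'   scale factor per condition).
#' @export
equalize_roi_sizes <- function(tracks, label, tol = 0.01) {
  label_masks <- function(track) lapply(track$frames, function(fr) {
    if (is.null(fr[[label]]))
      stop(sprintf("label '%s' missing in a frame", label))
    fr[[label]]
  })
  masks <- lapply(tracks, label_masks)
  areas <- vapply(masks, function(ms)
    mean(vapply(ms, mask_area, numeric(1))), numeric(1))
  if (any(areas == 0)) stop("zero average mask area for label in some condition")
  target <- mean(areas)
  scaled_avg <- function(ms, f)
    mean(vapply(ms, function(m) mask_area(scale_mask(m, f)), numeric(1)))
  factors <- numeric(length(tracks))
  out <- tracks
  for (i in seq_along(tracks)) {
    f0 <- sqrt(target / areas[i])
    # discrete rasterisation makes area(f) a monotone step function;
    # search a coarse then a fine factor grid, keeping the best
    best <- f0; best_err <- abs(scaled_avg(masks[[i]], f0) - target)
    for (span in c(0.15, 0.02)) {
      if (best_err / target <= tol / 4) break
      for (f in best * exp(seq(-span, span, length.out = 21))) {
        err <- abs(scaled_avg(masks[[i]], f) - target)
        if (err < best_err) { best <- f; best_err <- err }
      }
    }
    if (best_err / target > tol)
      warning(sprintf(
        "condition %d: nearest achievable average area misses the target by %.2f%%",
        i, 100 * best_err / target))
    factors[i] <- best
    tr <- tracks[[i]]
    tr$frames <- lapply(tr$frames, function(fr) {
      fr[[label]] <- scale_mask(fr[[label]], best)
      fr
    })
    out[[i]] <- tr
  }
  list(tracks = out, factors = factors)
}
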