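#' Magic-wand (seeded region-growing) segmentation of one frame
#'
#' Implements the classic magic-wand selection used to segment the
#' heart-chamber lumen out of an M-mode frame: a 4-connected flood fill of
#' all pixels whose intensity lies within `tolerance` of the seed pixel's
#' intensity, followed by hole filling (speckle voids inside the lumen
#' otherwise fragment the mask). The fill region is by construction the
#' connected component containing the seed. A single 3x3 median-filter pass
#' precedes the fill by default to knock down speckle extremes; tolerance is
#' an absolute window around the (filtered) seed intensity.
#'
#' A mask whose border contact exceeds `max_border_frac` of the image border
#' is rejected as a runaway fill (tolerance too high, or seed outside the
#' lumen).
#'
#' @param frame Numeric matrix (rows = depth, cols = transverse).
#' @param seed Length-2 integer vector `(row, col)`, 1-based.
#' @param tolerance Absolute intensity tolerance (>= 0). `NULL` picks a
#'   default from the frame histogram: half the distance between the mean
#'   intensities below and above the Otsu threshold.
#' @param median_filter Apply the 3x3 median pre-filter? Default `TRUE`.
#' @param max_border_frac Maximum tolerated fraction of border pixels in the
#'   mask before declaring a runaway fill (default 0.25).
#'
#' @return An object of class `chamber_mask`: list with `mask` (logical
#'   matrix), `seed`, `tolerance`, `frame_index` (`NA` here; set by
#'   [segment_series()]).
#' @export
magic_wand <- function(frame, seed, tolerance = NULL, median_filter = TRUE,
                       max_border_frac = 0.25) {
  stopifnot(is.matrix(frame), is.numeric(frame))
  seed <- as.integer(round(seed))
  if (length(seed) != 2 || any(is.na(seed)) ||
      seed[1] < 1 || seed[1] > nrow(frame) ||
      seed[2] < 1 || seed[2] > ncol(frame)) {
    stop("seed out of bounds")
  }
  if (median_filter) frame <- median3x3(frame)
  if (is.null(tolerance)) tolerance <- default_tolerance(frame)
  if (!is.numeric(tolerance) || tolerance < 0) stop("tolerance must be >= 0")

  mask <- flood_fill_cpp(frame, seed[1], seed[2], tolerance)
  mask <- EBImage::fillHull(mask * 1L) > 0

  nb <- 2 * nrow(mask) + 2 * ncol(mask) - 4
  border_hits <- sum(mask[1, ]) + sum(mask[nrow(mask), ]) +
    sum(mask[-c(1, nrow(mask)), 1]) + sum(mask[-c(1, nrow(mask)), ncol(mask)])
  if (border_hits > max_border_frac * nb) {
    stop("runaway fill: mask touches ", border_hits, " of ", nb,
         " border pixels (tolerance too high?)")
  }
  structure(list(mask = mask, seed = seed, tolerance = tolerance,
                 frame_index = NA_integer_),
            class = "chamber_mask")
}

# 3x3 median filter with edge replication (compiled)
median3x3 <- function(frame) {
  median3x3_cpp(frame)
}

# Default absolute tolerance: half the separation between the mean intensity
# below and above the Otsu threshold of the frame (i.e. ~0.5 x (wall - lumen)
# for a two-level chamber image).
default_tolerance <- function(frame) {
  thr <- EBImage::otsu(EBImage::Image(frame / 65535), range = c(0, 1)) * 65535
  lo <- mean(frame[frame <= thr])
  hi <- mean(frame[frame > thr])
  if (!is.finite(lo) || !is.finite(hi)) return(stats::sd(frame))
  (hi - lo) / 2
}

#' Automatic lumen seed for the first frame
#'
#' Finds the centroid of the darkest blob within a central search window:
#' the frame is median filtered and thresholded at a low intensity quantile
#' of the central half of the frame (the lumen is the darkest structure in
#' the cross-section), and the dark connected component with the largest
#' presence in that window supplies the seed.
#'
#' @param frame Numeric matrix.
#' @param dark_quantile Intensity quantile (within the central window)
#'   defining "dark" (default 0.15).
#' @return Integer `(row, col)` seed.
#' @export
auto_seed <- function(frame, dark_quantile = 0.15) {
  f <- median3x3(frame)
  h <- nrow(f); w <- ncol(f)
  win_r <- seq.int(floor(h / 4) + 1, ceiling(3 * h / 4))
  win_c <- seq.int(floor(w / 4) + 1, ceiling(3 * w / 4))
  thr <- stats::quantile(f[win_r, win_c], dark_quantile, names = FALSE)
  dark <- f <= thr
  lab <- EBImage::bwlabel(dark * 1L)
  cen <- lab[win_r, win_c]
  ids <- setdiff(unique(as.vector(cen)), 0)
  if (length(ids) == 0) stop("no dark blob found in the central window")
  sizes <- vapply(ids, function(i) sum(cen == i), numeric(1))
  best <- ids[which.max(sizes)]
  # centroid of the blob's in-window pixels (the lumen may extend beyond)
  idx <- which(lab == best, arr.ind = TRUE)
  in_win <- idx[, 1] %in% win_r & idx[, 2] %in% win_c
  seed <- round(colMeans(idx[in_win, , drop = FALSE]))
  # centroid of a crescent can fall outside the blob; snap to nearest member
  if (lab[seed[1], seed[2]] != best) {
    d2 <- (idx[, 1] - seed[1])^2 + (idx[, 2] - seed[2])^2
    seed <- idx[which.min(d2), ]
  }
  as.integer(seed)
}

#' Segment every frame of a recording
#'
#' Runs [magic_wand()] on each frame. Frame 1 uses `initial_seed` (or
#' [auto_seed()]); each later frame is seeded at the centroid of the previous
#' frame's mask, which tracks the moving chamber. A frame whose fill fails
#' (runaway, or empty) is retried with `initial_seed`; if that also fails the
#' frame is flagged as failed and carries no geometry -- failures are never
#' silently interpolated.
#'
#' @param rec An [ocm_recording()].
#' @param initial_seed `(row, col)` seed in the lumen of frame 1, or `NULL`
#'   for automatic seeding.
#' @param tolerance Absolute intensity tolerance; `NULL` estimates it once
#'   from frame 1 (see [magic_wand()]).
#' @param median_filter Apply the 3x3 median pre-filter per frame?
#' @param keep_masks Keep the per-frame binary masks? With `FALSE` only the
#'   geometry table is retained, which saves memory on long recordings.
#' @param max_failed_frac Maximum tolerated fraction of failed frames before
#'   the whole series errors (default 0.5).
#'
#' @return An object of class `mask_series`: list with `geometry` (data.frame
#'   with columns `frame_index`, `area_um2`, `diameter_x_um`, `diameter_z_um`,
#'   `seed_row`, `seed_col`, `failed`), `masks` (list of logical matrices, or
#'   `NULL`s when `keep_masks = FALSE`), and `metadata`.
#' @export
segment_series <- function(rec, initial_seed = NULL, tolerance = NULL,
                           median_filter = TRUE, keep_masks = TRUE,
                           max_failed_frac = 0.5) {
  stopifnot(inherits(rec, "ocm_recording"))
  nf <- n_frames(rec)
  meta <- rec$metadata
  frame1 <- rec$frames[1, , ]
  if (median_filter) frame1 <- median3x3(frame1)
  if (is.null(initial_seed)) initial_seed <- auto_seed(rec$frames[1, , ])
  if (is.null(tolerance)) tolerance <- default_tolerance(frame1)

  geometry <- data.frame(frame_index = seq_len(nf),
                         area_um2 = NA_real_,
                         diameter_x_um = NA_real_, diameter_z_um = NA_real_,
                         seed_row = NA_integer_, seed_col = NA_integer_,
                         failed = FALSE)
  masks <- if (keep_masks) vector("list", nf) else NULL
  seed <- as.integer(round(initial_seed))

  for (k in seq_len(nf)) {
    m <- tryCatch(
      magic_wand(rec$frames[k, , ], seed, tolerance,
                 median_filter = median_filter),
      error = function(e) NULL)
    if (is.null(m) && !identical(seed, as.integer(round(initial_seed)))) {
      m <- tryCatch(
        magic_wand(rec$frames[k, , ], initial_seed, tolerance,
                   median_filter = median_filter),
        error = function(e) NULL)
    }
    if (is.null(m) || sum(m$mask) == 0) {
      geometry$failed[k] <- TRUE
      seed <- as.integer(round(initial_seed))
      next
    }
    m$frame_index <- k
    g <- mask_geometry(m, meta)
    geometry$area_um2[k] <- g$area_um2
    geometry$diameter_x_um[k] <- g$diameter_x_um
    geometry$diameter_z_um[k] <- g$diameter_z_um
    geometry$seed_row[k] <- m$seed[1]
    geometry$seed_col[k] <- m$seed[2]
    if (keep_masks) masks[[k]] <- m$mask
    idx <- which(m$mask, arr.ind = TRUE)
    seed <- as.integer(round(colMeans(idx)))
    seed[1] <- min(max(seed[1], 1L), nrow(m$mask))
    seed[2] <- min(max(seed[2], 1L), ncol(m$mask))
    if (!m$mask[seed[1], seed[2]]) {
      d2 <- (idx[, 1] - seed[1])^2 + (idx[, 2] - seed[2])^2
      seed <- as.integer(idx[which.min(d2), ])
    }
  }

  if (mean(geometry$failed) > max_failed_frac) {
    stop("segmentation failed on ", sum(geometry$failed), " of ", nf,
         " frames")
  }
  structure(list(geometry = geometry, masks = masks, metadata = meta,
                 tolerance = tolerance),
            class = "mask_series")
}

#' @export
print.mask_series <- function(x, ...) {
  cat(sprintf("mask_series: %d frames, %d failed; tolerance %.1f\n",
              nrow(x$geometry), sum(x$geometry$failed), x$tolerance))
  invisible(x)
}

#' Geometric measurements of a chamber mask
#'
#' Area is pixel count times pixel area; the diameters are full axis-aligned
#' extents of the mask (`max - min + 1` pixels times pitch) along the
#' transverse (x, columns) and axial (z, rows) axes, matching the
#' horizontal / vertical diameter convention for end-diastolic and
#' end-systolic dimensions.
#'
#' @param mask A `chamber_mask` (or plain logical matrix).
#' @param meta A [recording_metadata()] supplying pixel sizes.
#' @return List with `area_um2`, `diameter_x_um`, `diameter_z_um`.
#' @export
mask_geometry <- function(mask, meta) {
  m <- if (inherits(mask, "chamber_mask")) mask$mask else mask
  stopifnot(is.matrix(m))
  if (sum(m) == 0) stop("empty mask")
  idx <- which(m, arr.ind = TRUE)
  list(
    area_um2 = sum(m) * meta$pixel_size_x_um * meta$pixel_size_z_um,
    diameter_x_um = (max(idx[, 2]) - min(idx[, 2]) + 1) * meta$pixel_size_x_um,
    diameter_z_um = (max(idx[, 1]) - min(idx[, 1]) + 1) * meta$pixel_size_z_um
  )
}
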