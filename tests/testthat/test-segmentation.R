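# Independent oracle for the magic wand: threshold the image at
# |I - I(seed)| <= tol, label 4-connected components exhaustively, and keep
# the component containing the seed (no region growing involved).
wand_oracle <- function(frame, seed, tol) {
  sel <- abs(frame - frame[seed[1], seed[2]]) <= tol
  lab <- EBImage::bwlabel(sel * 1L)
  lab == lab[seed[1], seed[2]] & lab > 0
}

test_that("magic wand equals the exhaustive connected-component oracle", {
  # two-level image: dark disc (10) on bright background (200)
  img <- matrix(200, 40, 40)
  cc <- outer((1:40 - 20)^2, (1:40 - 24)^2, "+") <= 81
  img[cc] <- 10
  m <- magic_wand(img, c(20, 24), tolerance = 50, median_filter = FALSE)
  expect_identical(m$mask, wand_oracle(img, c(20, 24), 50))
  expect_identical(m$mask, cc)

  # seeded in the background: fill selects the background component
  expect_error(magic_wand(img, c(2, 2), tolerance = 50,
                          median_filter = FALSE),
               "runaway")

  # speckled two-level image, no hole in the oracle comparison region
  withr::with_seed(99, {
    noisy <- img + matrix(rnorm(1600, 0, 5), 40, 40)
  })
  m2 <- magic_wand(noisy, c(20, 24), tolerance = 50, median_filter = FALSE)
  or2 <- wand_oracle(noisy, c(20, 24), 50)
  or2 <- EBImage::fillHull(or2 * 1L) > 0
  expect_identical(m2$mask, or2)
})

test_that("degenerate fills are rejected", {
  flat <- matrix(7, 20, 20)
  expect_error(magic_wand(flat, c(10, 10), tolerance = 0,
                          median_filter = FALSE), "runaway")
  expect_error(magic_wand(flat, c(0, 5), tolerance = 1), "out of bounds")
  expect_error(magic_wand(flat, c(25, 5), tolerance = 1), "out of bounds")
  expect_error(magic_wand(flat, c(10, 10), tolerance = -2,
                          median_filter = FALSE), "tolerance")
})

test_that("mask grows monotonically with tolerance", {
  sim <- mixed_recording()
  f <- sim$recording$frames[1, , ]
  seed <- auto_seed(f)
  prev <- NULL
  for (tol in c(4000, 8000, 12000, 16000)) {
    m <- magic_wand(f, seed, tol)$mask
    if (!is.null(prev)) expect_true(all(m[prev]))
    prev <- m
  }
})

test_that("mask geometry follows the pixel-count and extent conventions", {
  meta2 <- recording_metadata(frame_rate_hz = 10, pixel_size_x_um = 2,
                              pixel_size_z_um = 2)
  m <- matrix(FALSE, 10, 10); m[4, 7] <- TRUE
  g <- mask_geometry(m, meta2)
  expect_equal(g$area_um2, 4)
  expect_equal(g$diameter_x_um, 2)
  expect_equal(g$diameter_z_um, 2)

  meta1 <- recording_metadata(frame_rate_hz = 10, pixel_size_x_um = 1,
                              pixel_size_z_um = 1)
  rect <- matrix(FALSE, 30, 30); rect[11:20, 6:25] <- TRUE  # 10 x 20 px
  g2 <- mask_geometry(rect, meta1)
  expect_equal(g2$area_um2, 200)
  expect_equal(g2$diameter_x_um, 20)
  expect_equal(g2$diameter_z_um, 10)

  # digital ellipse, semi-axes (25, 15) px: pixel count close to pi*a*b
  ell <- outer(((1:80) - 40)^2 / 15^2, ((1:80) - 40)^2 / 25^2, "+") <= 1
  g3 <- mask_geometry(ell, meta1)
  expect_equal(g3$area_um2, pi * 25 * 15, tolerance = 0.03)
  expect_error(mask_geometry(matrix(FALSE, 5, 5), meta1), "empty")
})

test_that("segment_series tracks the noiseless phantom to within 5% per frame", {
  sim <- generate_recording(test_phantom_clean(), beat_waveform_spec(),
                            schedule_all_on(3), test_meta(), 3)
  series <- segment_series(sim$recording)
  expect_false(any(series$geometry$failed))
  rel <- series$geometry$area_um2 / sim$truth$frames$area_um2 - 1
  expect_lt(max(abs(rel)), 0.05)
  expect_gt(stats::cor(series$geometry$area_um2, sim$truth$frames$area_um2),
            0.99)
})

test_that("segmented area trace correlates with truth on noisy phantoms", {
  sim <- mixed_recording()
  series <- mixed_quantified()$series
  expect_gt(stats::cor(series$geometry$area_um2[!series$geometry$failed],
                       sim$truth$frames$area_um2[!series$geometry$failed]),
            0.99)
})

test_that("seed trajectory is continuous on synthetic data", {
  series <- mixed_quantified()$series
  g <- series$geometry[!series$geometry$failed, ]
  jumps <- sqrt(diff(g$seed_row)^2 + diff(g$seed_col)^2) * 3.5
  # per-frame centroid jump stays below one chamber diameter
  expect_lt(max(jumps), max(g$diameter_x_um))
})

test_that("an all-black recording fails as a series error", {
  frames <- array(0, dim = c(8, 24, 24))
  frames[, 1, 1] <- 1  # keep the non-negativity but essentially flat
  rec <- ocm_recording(frames, test_meta())
  expect_error(segment_series(rec, initial_seed = c(12, 12), tolerance = 10),
               "failed")
})
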