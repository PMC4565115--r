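make_events <- function(dia_t, sys_t = numeric(0), trace = NULL,
                        seg = rep(1L, length(dia_t))) {
  di <- if (is.null(trace)) integer(0) else match(dia_t, trace$time_s)
  si <- if (is.null(trace)) integer(0) else match(sys_t, trace$time_s)
  structure(list(diastole_idx = di, systole_idx = si,
                 diastole_times_s = dia_t, systole_times_s = sys_t,
                 segment_id = seg),
            class = "beat_events")
}

test_that("smoothing is identity at window 0, inert on constants, and reduces noise", {
  t <- (0:199) / 50
  withr::with_seed(1, x <- rnorm(200))
  tr <- area_trace(t, x)
  expect_equal(smooth_trace(tr, 0), tr)
  const <- area_trace(t, rep(5, 200))
  expect_equal(smooth_trace(const, 0.2)$area_um2, rep(5, 200))
  expect_lt(stats::var(smooth_trace(tr, 0.2)$area_um2), stats::var(x))
  expect_error(smooth_trace(tr, 10), "longer than trace")
})

test_that("diastoles of a pure cosine fall at multiples of the period", {
  fr <- 64
  t <- (0:(fr * 4 - 1)) / fr
  x <- 1000 + 300 * cos(2 * pi * t / 0.25)
  tr <- area_trace(t, x)
  ev <- detect_beats(tr, min_period_s = 0.1)
  # interior maxima at 0.25, 0.5, ... (the t = 0 boundary peak is not a
  # local interior maximum)
  expect_true(all(abs(ev$diastole_times_s %% 0.25) < 1 / fr + 1e-9 |
                    abs(ev$diastole_times_s %% 0.25 - 0.25) < 1 / fr + 1e-9))
  expect_gte(length(ev$diastole_idx), 14)
  # systoles interleave strictly
  all_t <- sort(c(ev$diastole_times_s, ev$systole_times_s))
  lab <- ifelse(all_t %in% ev$diastole_times_s, "d", "s")
  expect_true(all(lab[-1] != lab[-length(lab)]))
})

test_that("a constant trace yields no events", {
  tr <- area_trace((0:99) / 50, rep(1000, 100))
  ev <- detect_beats(tr, min_period_s = 0.1)
  expect_length(ev$diastole_idx, 0)
  expect_length(ev$systole_idx, 0)
})

test_that("detected diastoles match the per-cycle argmax oracle on noisy sinusoids", {
  fr <- 64; period <- 0.5
  t <- (0:(fr * 8 - 1)) / fr
  clean <- 1000 + 300 * cos(2 * pi * t / period)
  withr::with_seed(4, noisy <- clean + rnorm(length(t), 0, 30))  # SNR ~10
  tr <- area_trace(t, noisy)
  ev <- detect_beats(tr, min_period_s = 0.3)
  # oracle: brute-force argmax within each cycle window centred on k*period
  cycles <- 1:15
  oracle <- vapply(cycles, function(k) {
    win <- which(t >= (k - 0.5) * period & t < (k + 0.5) * period)
    t[win[which.max(noisy[win])]]
  }, numeric(1))
  matched <- vapply(oracle, function(ot) {
    any(abs(ev$diastole_times_s - ot) <= 1 / fr + 1e-9)
  }, logical(1))
  expect_true(all(matched))
})

test_that("heart rate pools diastole intervals and flags beatless input", {
  ev <- make_events(seq(0, 2, by = 0.25))
  hr <- heart_rate(ev)
  expect_equal(hr$hr_bpm, 240)
  expect_equal(hr$flag, "")
  none <- make_events(numeric(0), seg = integer(0))
  hr0 <- heart_rate(none)
  expect_equal(hr0$hr_bpm, 0)
  expect_equal(hr0$flag, "no-beat")
  # one diastole per segment: no usable interval
  lone <- make_events(c(1, 5), seg = c(1L, 2L))
  expect_equal(heart_rate(lone)$flag, "no-beat")
  # intervals never pool across segments: two segments with the same
  # within-segment spacing give that spacing, not the cross-gap
  two <- make_events(c(0, 0.5, 10, 10.5), seg = c(1L, 1L, 2L, 2L))
  expect_equal(heart_rate(two)$hr_bpm, 120)
})

test_that("chamber parameters average the event frames", {
  t <- (0:9) / 10
  tr <- area_trace(t, c(1000, 400, 1000, 400, 1000, 400, 1000, 400, 1000, 400),
                   diameter_x_um = rep(c(50, 30), 5),
                   diameter_z_um = rep(c(70, 40), 5))
  ev <- make_events(dia_t = c(0.0, 0.2), sys_t = 0.1, trace = tr,
                    seg = c(1L, 1L))
  cp <- chamber_params(ev, tr)
  expect_equal(cp$EDA_um2, 1000)
  expect_equal(cp$ESA_um2, 400)
  expect_equal(cp$EDD_x_um, 50)
  expect_equal(cp$ESD_z_um, 40)
  empty <- make_events(numeric(0), seg = integer(0))
  expect_true(is.nan(chamber_params(empty, tr)$EDA_um2))
})

test_that("fractional shortening follows (EDD - ESD)/EDD x 100", {
  expect_equal(fractional_shortening(100, 100), 0)
  expect_equal(fractional_shortening(100, 50), 50)
  expect_equal(fractional_shortening(80, 60), 25)
  # invariant under unit rescaling
  for (c in c(0.01, 1, 17.3)) {
    expect_equal(fractional_shortening(80 * c, 60 * c), 25)
  }
  expect_error(fractional_shortening(0, 10), "positive")
  expect_warning(fs <- fractional_shortening(50, 60), "exceeds")
  expect_equal(fs, -20)
})

test_that("recording summary is internally consistent on synthetic data", {
  q <- mixed_quantified()
  p <- q$params
  # HR unaffected by the off-period
  expect_equal(p$HR_bpm, 120, tolerance = 0.02)
  # FS-area recomputed from the reported EDA/ESA matches
  expect_equal(p$FS_area_pct, (p$EDA_um2 - p$ESA_um2) / p$EDA_um2 * 100)
  expect_lte(p$ESA_um2, p$EDA_um2)
  expect_lte(p$ESD_x_um, p$EDD_x_um)
  expect_lte(p$ESD_z_um, p$EDD_z_um)
  expect_true(p$FS_x_pct >= 0 && p$FS_x_pct <= 100)
})

test_that("a beatless recording reports frozen diastolic geometry with a flag", {
  pre <- stage_preset("PD2 32h", duration_s = 4)
  sim <- generate_recording(test_phantom(6), pre$waveform, pre$schedule,
                            test_meta(stage_label = "PD2 32h"), 4)
  q <- quantify_recording(sim$recording)
  expect_equal(q$params$HR_bpm, 0)
  expect_equal(q$params$CAP_pct, 0)
  expect_match(q$params$flags, "no-beat")
  expect_equal(q$params$EDA_um2, sim$truth$eda_um2, tolerance = 0.05)
  expect_true(is.na(q$params$ESA_um2))
  expect_true(is.na(q$params$FS_area_pct))
})
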