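test_that("schedules enforce contiguity and alternation", {
  expect_error(activity_schedule(data.frame(start_s = 1, end_s = 2,
                                            state = "on")), "start at 0")
  expect_error(activity_schedule(data.frame(start_s = c(0, 3), end_s = c(2, 4),
                                            state = c("off", "on"))),
               "contiguous")
  expect_error(activity_schedule(data.frame(start_s = c(0, 2), end_s = c(2, 4),
                                            state = c("on", "on"))),
               "alternate")
  s <- schedule_off_then_on(4.8, 7.6)
  expect_equal(s$segments$end_s, c(4.8, 12.4))
})

test_that("waveform spec rejects inverted and degenerate semi-axes", {
  expect_error(beat_waveform_spec(sys_semiaxis_x_um = 70), "<= diastolic")
  expect_error(beat_waveform_spec(systole_fraction = 1), "systole_fraction")
  expect_error(phantom_spec(lumen_mean = 5e4, wall_mean = 4e4), "lumen_mean")
})

test_that("generator is deterministic under a fixed seed", {
  a <- generate_recording(test_phantom(7), beat_waveform_spec(),
                          schedule_all_on(2), test_meta(), 2)
  b <- generate_recording(test_phantom(7), beat_waveform_spec(),
                          schedule_all_on(2), test_meta(), 2)
  expect_identical(a$recording$frames, b$recording$frames)
  c <- generate_recording(test_phantom(8), beat_waveform_spec(),
                          schedule_all_on(2), test_meta(), 2)
  expect_false(identical(a$recording$frames, c$recording$frames))
})

test_that("ground truth carries the defining identities", {
  sim <- mixed_recording()  # 4.8 s off then 7.6 s on, 0.5 s beat period
  expect_equal(sim$truth$cap_pct, 100 * 7.6 / 12.4)
  expect_equal(round(sim$truth$cap_pct), 61)
  expect_equal(sim$truth$hr_bpm, 120)
  # diastole instants: on-segment start, then every period
  expect_equal(sim$truth$beat_times_s[1:3], c(4.8, 5.3, 5.8))
  # all-on recording: HR = 60 / period, CAP = 100
  sim2 <- generate_recording(test_phantom(3),
                             beat_waveform_spec(beat_period_s = 0.25),
                             schedule_all_on(10), test_meta(), 10)
  expect_equal(sim2$truth$hr_bpm, 240)
  expect_equal(sim2$truth$cap_pct, 100)
})

test_that("noiseless phantom renders exact compartment intensities", {
  ph <- test_phantom_clean()
  sim <- generate_recording(ph, beat_waveform_spec(), schedule_all_off(0.5),
                            test_meta(), 0.5)
  f <- sim$recording$frames[1, , ]
  wf <- beat_waveform_spec()
  zc <- (seq_len(96) - ph$center_row) * 3.5
  xc <- (seq_len(64) - ph$center_col) * 3.5
  inside <- outer((zc / wf$dia_semiaxis_z_um)^2,
                  (xc / wf$dia_semiaxis_x_um)^2, "+") <= 1
  expect_true(all(f[inside] == ph$lumen_mean))
  expect_true(all(f[!inside] %in% c(ph$wall_mean, ph$tissue_mean)))
})

test_that("true area equals pixel-counted mask area within discretization", {
  ph <- test_phantom_clean()
  meta <- test_meta()
  sim <- generate_recording(ph, beat_waveform_spec(), schedule_all_off(0.5),
                            meta, 0.5)
  f <- sim$recording$frames[1, , ]
  # pixel-counting oracle: exact count of lumen-valued pixels
  n_px <- sum(f == ph$lumen_mean)
  area_px <- n_px * meta$pixel_size_x_um * meta$pixel_size_z_um
  expect_equal(area_px, sim$truth$frames$area_um2[1], tolerance = 0.03)
})

test_that("lumen is darker than wall in every generated frame", {
  ph <- test_phantom(5)
  sim <- generate_recording(ph, beat_waveform_spec(), schedule_all_on(1),
                            test_meta(), 1)
  clean <- generate_recording(test_phantom_clean(), beat_waveform_spec(),
                              schedule_all_on(1), test_meta(), 1)
  lumen <- clean$recording$frames == test_phantom_clean()$lumen_mean
  wall <- clean$recording$frames == test_phantom_clean()$wall_mean
  for (k in seq_len(dim(sim$recording$frames)[1])) {
    f <- sim$recording$frames[k, , ]
    expect_lt(mean(f[lumen[k, , ]]), mean(f[wall[k, , ]]))
  }
})

test_that("generator rejects Nyquist violations and geometry overflow", {
  expect_error(
    generate_recording(test_phantom(), beat_waveform_spec(beat_period_s = 0.02),
                       schedule_all_on(1), test_meta(), 1),
    "Nyquist")
  big <- beat_waveform_spec(dia_semiaxis_x_um = 200, dia_semiaxis_z_um = 200,
                            sys_semiaxis_x_um = 100, sys_semiaxis_z_um = 100)
  expect_error(
    generate_recording(test_phantom(), big, schedule_all_on(1),
                       test_meta(), 1),
    "fit inside")
})

test_that("stage presets reproduce the published stage means", {
  expect_equal(stage_preset("AD1")$hr_bpm, 391)
  expect_equal(stage_preset("L2")$hr_bpm, 277)
  expect_equal(stage_preset("PD1 24h")$hr_bpm, 26)
  expect_equal(stage_preset("PD2 48h")$hr_bpm, 17)
  expect_equal(stage_preset("PD2 48h")$cap_pct, 5)
  expect_equal(stage_preset("AD1")$cap_pct, 95)
  expect_error(stage_preset("embryo"), "stage_label")
  # preset waveform encodes the HR as its beat period
  expect_equal(60 / stage_preset("AD1")$waveform$beat_period_s, 391)
})

test_that("timelines are deterministic, five recordings per stage, with a silent PD2 span", {
  stages <- c("PD2 32h", "PD2 40h")
  tl1 <- generate_timeline(11, "control", stages = stages, n_recordings = 5,
                           duration_s = 0.5, phantom = test_phantom(),
                           meta_template = test_meta())
  tl2 <- generate_timeline(11, "control", stages = stages, n_recordings = 5,
                           duration_s = 0.5, phantom = test_phantom(),
                           meta_template = test_meta())
  expect_identical(tl1[[1]]$recordings[[3]]$recording$frames,
                   tl2[[1]]$recordings[[3]]$recording$frames)
  expect_length(tl1[[1]]$recordings, 5)
  # the cardiac developmental diastasis: zero on-time throughout PD2 32-40h
  for (st in tl1) {
    for (r in st$recordings) {
      expect_equal(r$truth$cap_pct, 0)
      expect_equal(r$truth$hr_bpm, 0)
    }
  }
  # dCry-RNAi resumes beating at PD2 40h (shorter diastasis), control does not
  tlr <- generate_timeline(11, "dCry-RNAi", stages = "PD2 40h",
                           n_recordings = 1, duration_s = 2,
                           phantom = test_phantom(),
                           meta_template = test_meta())
  expect_gt(tlr[[1]]$recordings[[1]]$truth$cap_pct, 0)
})
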