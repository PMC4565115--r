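seg_df <- function(starts, ends, states) {
  data.frame(start_s = starts, end_s = ends, state = states,
             stringsAsFactors = FALSE)
}

test_that("CAP is the on-fraction of total imaging time", {
  s <- seg_df(c(0, 4.8), c(4.8, 12.4), c("off", "on"))
  expect_equal(compute_cap(s), 100 * 7.6 / 12.4)
  expect_equal(round(compute_cap(s)), 61)
  expect_equal(compute_cap(seg_df(0, 10, "on")), 100)
  expect_equal(compute_cap(seg_df(0, 10, "off")), 0)
  expect_error(compute_cap(seg_df(numeric(0), numeric(0), character(0))),
               "zero total")
  # accepts schedule objects too
  expect_equal(compute_cap(schedule_off_then_on(4.8, 7.6)), 100 * 7.6 / 12.4)
})

test_that("CAP is invariant to time reversal and uniform rescaling", {
  s <- seg_df(c(0, 3, 10), c(3, 10, 12), c("on", "off", "on"))
  cap <- compute_cap(s)
  total <- max(s$end_s)
  rev <- seg_df(total - rev(s$end_s), total - rev(s$start_s),
                rev(s$state))
  expect_equal(compute_cap(rev), cap)
  for (c in c(0.1, 3, 128)) {
    expect_equal(compute_cap(seg_df(s$start_s * c, s$end_s * c, s$state)),
                 cap)
  }
})

test_that("average CAP over recordings is the arithmetic mean", {
  expect_equal(average_cap(61), 61)
  expect_equal(average_cap(c(0, 100)), 50)
  expect_error(average_cap(numeric(0)), "empty")
})

test_that("activity detection recovers flat, beating and mixed traces", {
  fr <- 64
  t <- (0:(12.4 * fr - 1)) / fr
  # flat throughout -> CAP 0
  flat <- area_trace(t, rep(1000, length(t)))
  expect_equal(detect_activity(flat)$cap_pct, 0)
  # sinusoid throughout -> CAP 100
  sine <- area_trace(t, 1000 - 300 * (1 - cos(2 * pi * t / 0.5)) / 2)
  expect_equal(detect_activity(sine)$cap_pct, 100)
  # flat 4.8 s then beating 7.6 s: one off and one on segment, boundary
  # within half a window of 4.8 s, CAP rounding to 61
  x <- rep(1000, length(t))
  on <- t >= 4.8
  x[on] <- 1000 - 300 * (1 - cos(2 * pi * (t[on] - 4.8) / 0.5)) / 2
  act <- detect_activity(area_trace(t, x), window_s = 4)
  expect_equal(act$segments$state, c("off", "on"))
  expect_lt(abs(act$segments$end_s[1] - 4.8), 2)
  expect_equal(act$cap_pct_int, 61)
  expect_lt(abs(act$cap_pct - 100 * 7.6 / 12.4), 1)
})

test_that("detected CAP tracks the schedule truth within the window bound", {
  fr <- 64
  for (cap_true in c(25, 50, 75)) {
    dur <- 16
    t <- (0:(dur * fr - 1)) / fr
    on_start <- dur * (1 - cap_true / 100)
    x <- rep(2000, length(t))
    on <- t >= on_start
    x[on] <- 2000 - 800 * (1 - cos(2 * pi * (t[on] - on_start) / 0.4)) / 2
    act <- detect_activity(area_trace(t, x), window_s = 2)
    expect_lt(abs(act$cap_pct - cap_true), (2 / dur) * 100)
  }
})

test_that("detection rejects traces shorter than the window", {
  tr <- area_trace((0:63) / 64, rnorm(64) + 100)
  expect_error(detect_activity(tr, window_s = 2), "shorter than")
  expect_error(detect_activity(tr, window_s = 0.01), "at least 2 frames")
})

test_that("CDD duration is the longest silent run times the sampling interval", {
  tl <- data.frame(hours_apf = c(24, 32, 40, 48),
                   beats_present = c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(cdd_duration(tl)$cdd_h, 16)
  expect_equal(cdd_duration(tl)$flag, "")
  all_beat <- data.frame(hours_apf = c(24, 32), beats_present = c(TRUE, TRUE))
  expect_equal(cdd_duration(all_beat)$cdd_h, 0)
  dead <- data.frame(hours_apf = c(24, 32, 40),
                     beats_present = c(FALSE, FALSE, FALSE))
  d <- cdd_duration(dead)
  expect_equal(d$cdd_h, 24)
  expect_equal(d$flag, "death-censored")
  expect_error(cdd_duration(dead[0, ]), "no pupal")
  expect_equal(cdd_duration(tl, sampling_interval_h = 4)$cdd_h, 8)
})

test_that("timeline aggregation averages recordings and scores the CDD", {
  row <- function(stage, idx, hr, cap) {
    data.frame(specimen_id = "s1", stage_label = stage,
               recording_index = idx, HR_bpm = hr, CAP_pct = cap,
               EDD_x_um = 100, EDD_z_um = 140, ESD_x_um = 60, ESD_z_um = 80,
               EDA_um2 = 11000, ESA_um2 = 3800, FS_x_pct = 40, FS_z_pct = 43,
               FS_area_pct = 65, flags = "", stringsAsFactors = FALSE)
  }
  params <- rbind(row("PD1 24h", 1, 25, 28), row("PD1 24h", 2, 27, 36),
                  row("PD2 32h", 1, 0, 0), row("PD2 40h", 1, 0, 0),
                  row("PD2 48h", 1, 17, 5))
  tl <- build_timeline(params)
  expect_equal(tl$cdd_h, 16)
  expect_equal(tl$cdd_flag, "")
  pt <- tl$points[tl$points$stage_label == "PD1 24h", ]
  expect_equal(pt$HR_bpm, 26)
  expect_equal(pt$CAP_pct, 32)
  expect_equal(pt$n_recordings, 2)
  # single non-pupal stage: CDD unavailable
  tl1 <- build_timeline(row("L2", 1, 277, 85))
  expect_equal(nrow(tl1$points), 1)
  expect_equal(tl1$cdd_flag, "unavailable")
  # duplicate (stage, recording) rows are rejected
  expect_error(build_timeline(rbind(row("L2", 1, 277, 85),
                                    row("L2", 1, 280, 90))),
               "duplicate")
  # multiple specimens are rejected
  p2 <- row("L2", 1, 277, 85); p2$specimen_id <- "s2"
  expect_error(build_timeline(rbind(row("L2", 1, 277, 85), p2)),
               "single specimen")
})

test_that("a pipeline-built control timeline shows the PD2 diastasis", {
  stages <- c("L3", "PD2 32h", "PD2 40h", "PD3 72h")
  tl <- generate_timeline(21, "control", stages = stages, n_recordings = 1,
                          duration_s = 6, phantom = test_phantom(),
                          meta_template = test_meta())
  rows <- do.call(rbind, lapply(tl, function(st) {
    quantify_recording(st$recordings[[1]]$recording)$params
  }))
  tline <- build_timeline(rows)
  expect_equal(tline$cdd_h, 16)
  expect_equal(tline$cdd_flag, "")
  expect_gt(rows$HR_bpm[rows$stage_label == "L3"], 0)
  expect_equal(rows$HR_bpm[rows$stage_label == "PD2 32h"], 0)
})
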