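#' Detect beating (on) and resting (off) periods of an area trace
#'
#' The fly heart stops beating for long stretches during metamorphosis, so a
#' recording is first partitioned into on/off periods before any rate or
#' duty-cycle statistic is computed. The detector works on the linearly
#' detrended area trace:
#'
#' 1. a centered sliding-window SD is computed over `window_s` seconds;
#' 2. the noise floor is the 5th percentile of the window SDs whenever the
#'    window-SD distribution contains a distinctly quiet subpopulation
#'    (5th percentile below half the 90th); otherwise -- a recording that
#'    beats (or rests) throughout, where all windows look alike -- the floor
#'    falls back to a third-difference noise estimate (the 0.8 quantile of
#'    `|diff(x, differences = 3)|`, scaled for half-normal data), which
#'    tracks frame-to-frame noise but suppresses smooth oscillations sampled
#'    well above their frequency, so continuous beating is not mistaken for
#'    rest;
#' 3. frames whose window SD exceeds `k_threshold` times the noise floor are
#'    "on"; runs shorter than `min_segment_s` are merged into their
#'    neighbours;
#' 4. each on/off boundary is then refined within `window_s` of its coarse
#'    position to the first/last frame whose detrended area departs from the
#'    resting baseline by more than `refine_frac` of the beating amplitude --
#'    the sliding window alone blurs every transition by up to half a window.
#'
#' The window must be long enough to contain at least one full beat of the
#' slowest rate of interest: a window much shorter than the beat period reads
#' the quiet diastolic plateau of a slow beat as rest. The default of 4 s
#' covers the slowest heart rates seen around the pupal cardiac pause
#' (~17 bpm, i.e. a ~3.5 s period).
#'
#' @param trace An `area_trace`.
#' @param window_s Sliding-window length, s (default 4.0; must not exceed
#'   the trace length).
#' @param k_threshold On/off threshold as a multiple of the noise floor
#'   (default 4).
#' @param min_segment_s Minimum segment duration, s; shorter runs are merged
#'   (default 0.5).
#' @param refine_frac Departure-from-baseline fraction used in boundary
#'   refinement (default 0.2); set `NA` to skip refinement.
#'
#' @return An object of class `activity_segments`: list with `segments`
#'   (data.frame `start_s`, `end_s`, `state`), `cap_pct` (full precision),
#'   `cap_pct_int` (reported integer percent).
#' @export
detect_activity <- function(trace, window_s = 4.0, k_threshold = 4,
                            min_segment_s = 0.5, refine_frac = 0.2) {
  stopifnot(inherits(trace, "area_trace"))
  fr <- attr(trace, "frame_rate_hz")
  if (window_s < 2 / fr) stop("window_s must span at least 2 frames")
  w <- round(window_s * fr)
  if (w %% 2 == 0) w <- w + 1
  n <- nrow(trace)
  if (n < w) stop("trace shorter than the sliding window")

  tt <- trace$time_s
  x <- stats::residuals(stats::lm(trace$area_um2 ~ tt))
  sds <- zoo::rollapply(x, w, stats::sd, partial = TRUE, align = "center")
  d3 <- abs(diff(x, differences = 3))
  hf_noise <- stats::quantile(d3, 0.8, names = FALSE) /
    (stats::qnorm(0.9) * sqrt(20))
  p5 <- stats::quantile(sds, 0.05, names = FALSE)
  q90 <- stats::quantile(sds, 0.9, names = FALSE)
  # numerically flat traces (SDs at round-off level) are entirely at rest
  eps <- 1e-9 * (abs(mean(trace$area_um2)) + 1)
  floor_sd <- if (p5 < 0.5 * q90) p5 else hf_noise
  on <- if (q90 <= eps) rep(FALSE, n) else sds > k_threshold * floor_sd

  # runs -> segments; frame k covers [t_k, t_k + 1/fr)
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  seg <- data.frame(start_s = tt[starts],
                    end_s = c(tt[utils::head(ends, -1) + 1L],
                              tt[n] + 1 / fr),
                    state = ifelse(r$values, "on", "off"),
                    stringsAsFactors = FALSE)

  seg <- merge_short_segments(seg, min_segment_s)
  if (!is.na(refine_frac) && nrow(seg) > 1) {
    seg <- refine_boundaries(seg, tt, trace$area_um2, fr, window_s,
                             refine_frac)
  }
  total <- seg$end_s[nrow(seg)] - seg$start_s[1]
  cap <- 100 * sum(seg$end_s[seg$state == "on"] -
                     seg$start_s[seg$state == "on"]) / total
  structure(list(segments = seg, cap_pct = cap, cap_pct_int = round(cap)),
            class = "activity_segments")
}

merge_short_segments <- function(seg, min_segment_s) {
  repeat {
    if (nrow(seg) <= 1) break
    dur <- seg$end_s - seg$start_s
    short <- which(dur < min_segment_s)
    if (length(short) == 0) break
    i <- short[which.min(dur[short])]
    seg$state[i] <- if (seg$state[i] == "on") "off" else "on"
    # coalesce identical neighbours (runs of consecutive same-state segments)
    keep <- c(TRUE, seg$state[-1] != seg$state[-nrow(seg)])
    first <- which(keep)
    last <- c(first[-1] - 1L, nrow(seg))
    seg <- data.frame(start_s = seg$start_s[first],
                      end_s = seg$end_s[last],
                      state = seg$state[first],
                      stringsAsFactors = FALSE)
  }
  seg
}

# Sharpen each on/off boundary on the raw (smoothed) area: during rest the
# lumen sits frozen at its diastolic area, so the resting baseline is the
# median area of the off side nearest the boundary, and the boundary moves to
# the first (off->on) or last (on->off) frame whose departure from that
# baseline exceeds refine_frac x beating amplitude, confirmed by the next
# frame.
refine_boundaries <- function(seg, tt, x, fr, window_s, refine_frac) {
  exceeds <- function(j, thr, base) abs(x[j] - base) > thr
  for (b in seq_len(nrow(seg) - 1)) {
    off_i <- if (seg$state[b] == "off") b else b + 1
    on_i <- if (seg$state[b] == "on") b else b + 1
    bt0 <- seg$end_s[b]
    off_rows <- which(tt >= max(seg$start_s[off_i],
                                min(bt0, seg$end_s[off_i]) - window_s) - 1e-9 &
                        tt < seg$end_s[off_i] - 1e-9)
    on_rows <- which(tt >= seg$start_s[on_i] - 1e-9 &
                       tt < min(seg$end_s[on_i],
                                max(bt0, seg$start_s[on_i]) + window_s) - 1e-9)
    if (length(off_rows) < 3 || length(on_rows) < 3) next
    base <- stats::median(x[off_rows])
    amp <- max(abs(x[on_rows] - base))
    thr <- refine_frac * amp
    bt <- seg$end_s[b]
    cand <- which(tt >= bt - window_s & tt <= bt + window_s)
    cand <- cand[cand < length(x)]
    if (length(cand) == 0) next
    hit <- vapply(cand, function(j) {
      exceeds(j, thr, base) && exceeds(min(j + 1, length(x)), thr, base)
    }, logical(1))
    if (!any(hit)) next
    new_bt <- if (seg$state[b] == "off") {
      tt[cand[which(hit)[1]]]                  # first beating frame
    } else {
      tt[cand[utils::tail(which(hit), 1)]] + 1 / fr  # after last beating frame
    }
    lo <- seg$start_s[b] + 1 / fr
    hi <- seg$end_s[b + 1] - 1 / fr
    new_bt <- min(max(new_bt, lo), hi)
    seg$end_s[b] <- new_bt
    seg$start_s[b + 1] <- new_bt
  }
  seg
}

#' @export
print.activity_segments <- function(x, ...) {
  on_s <- sum(x$segments$end_s[x$segments$state == "on"] -
                x$segments$start_s[x$segments$state == "on"])
  cat(sprintf("activity_segments: %d segments, %.1f s on, CAP %d%%\n",
              nrow(x$segments), on_s, x$cap_pct_int))
  invisible(x)
}

#' Cardiac activity period (CAP)
#'
#' CAP is the percentage of the total imaging time during which the heart is
#' beating: `100 * sum(on) / (sum(on) + sum(off))`. Reported values are
#' conventionally rounded to integer percent (see `cap_pct_int` on
#' [detect_activity()] results); this function returns full precision.
#'
#' @param segments An `activity_segments`, an [activity_schedule()], or a
#'   data.frame with `start_s`, `end_s`, `state` columns.
#' @return CAP in percent (full precision).
#' @export
compute_cap <- function(segments) {
  seg <- if (inherits(segments, "activity_segments") ||
               inherits(segments, "activity_schedule")) {
    segments$segments
  } else {
    segments
  }
  stopifnot(is.data.frame(seg),
            all(c("start_s", "end_s", "state") %in% names(seg)))
  dur <- seg$end_s - seg$start_s
  total <- sum(dur)
  if (total <= 0) stop("zero total duration")
  100 * sum(dur[seg$state == "on"]) / total
}

#' Average CAP over repeated recordings
#'
#' Cardiac beating during metamorphosis is intermittent and irregular, so a
#' time point's CAP is the arithmetic mean over its (typically five)
#' recording sessions.
#'
#' @param caps Numeric vector of per-recording CAP values (percent).
#' @return Mean CAP in percent.
#' @export
average_cap <- function(caps) {
  if (length(caps) == 0) stop("empty CAP list")
  mean(caps)
}

#' Cardiac developmental diastasis (CDD) duration
#'
#' During pupa day 2 the heart stops beating entirely while it remodels --
#' the cardiac developmental diastasis. Its duration is scored as the
#' longest run of consecutive pupal time points without beats, times the
#' sampling interval (8 h by design).
#'
#' @param timeline Data.frame with columns `hours_apf` (time-ordered) and
#'   `beats_present` (logical), pupal time points only.
#' @param sampling_interval_h Sampling interval, hours (default 8).
#' @return List with `cdd_h` and `flag` (`""`, or `"death-censored"` when no
#'   time point ever beats, in which case `cdd_h` covers the whole span).
#' @export
cdd_duration <- function(timeline, sampling_interval_h = 8) {
  stopifnot(is.data.frame(timeline),
            all(c("hours_apf", "beats_present") %in% names(timeline)))
  if (nrow(timeline) == 0) stop("no pupal time points")
  if (is.unsorted(timeline$hours_apf)) stop("time points must be ordered")
  r <- rle(!timeline$beats_present)
  silent <- r$lengths[r$values]
  cdd <- if (length(silent)) max(silent) * sampling_interval_h else 0
  flag <- if (all(!timeline$beats_present)) "death-censored" else ""
  list(cdd_h = cdd, flag = flag)
}

#' Build a developmental timeline from a per-recording parameter table
#'
#' Aggregates a single specimen's parameter rows into one point per stage
#' (mean over recordings; CAP via [average_cap()]), orders the points
#' developmentally, and computes the CDD duration from the pupal points'
#' beat flags (`HR_bpm > 0` in any recording at a stage counts as beating).
#'
#' @param params Data.frame in [param_table_columns()] layout, one specimen.
#' @param sampling_interval_h Pupal sampling interval, hours (default 8).
#' @return An object of class `developmental_timeline`: list with `points`
#'   (per-stage data.frame: `stage_label`, `hours_apf`, `n_recordings`,
#'   `beats_present`, recording-averaged parameter columns), `cdd_h`,
#'   `cdd_flag` (`"unavailable"` when there are no pupal points).
#' @export
build_timeline <- function(params, sampling_interval_h = 8) {
  stopifnot(is.data.frame(params))
  ids <- unique(params$specimen_id)
  if (length(ids) > 1) {
    stop("build_timeline expects a single specimen; got: ",
         paste(ids, collapse = ", "))
  }
  if (anyDuplicated(params[, c("stage_label", "recording_index")])) {
    stop("duplicate (stage_label, recording_index) rows")
  }
  info <- stage_info()
  if (!all(params$stage_label %in% info$stage_label)) {
    stop("unknown stage labels in parameter table")
  }
  num_cols <- c("HR_bpm", "CAP_pct", "EDD_x_um", "EDD_z_um", "ESD_x_um",
                "ESD_z_um", "EDA_um2", "ESA_um2", "FS_x_pct", "FS_z_pct",
                "FS_area_pct")
  stages <- info$stage_label[info$stage_label %in% params$stage_label]
  pts <- do.call(rbind, lapply(stages, function(st) {
    sub <- params[params$stage_label == st, ]
    means <- vapply(num_cols, function(cl) {
      v <- sub[[cl]]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
    cbind(data.frame(stage_label = st,
                     hours_apf = info$hours_apf[info$stage_label == st],
                     n_recordings = nrow(sub),
                     beats_present = any(sub$HR_bpm > 0, na.rm = TRUE),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(means)))
  }))
  rownames(pts) <- NULL
  pts$CAP_pct <- vapply(stages, function(st) {
    average_cap(params$CAP_pct[params$stage_label == st])
  }, numeric(1))

  pupal <- pts[pts$stage_label %in% info$stage_label[info$is_pupal], ]
  if (nrow(pupal) == 0) {
    cdd_h <- NA_real_
    cdd_flag <- "unavailable"
  } else {
    cdd <- cdd_duration(pupal[, c("hours_apf", "beats_present")],
                        sampling_interval_h)
    cdd_h <- cdd$cdd_h
    cdd_flag <- cdd$flag
  }
  structure(list(points = pts, cdd_h = cdd_h, cdd_flag = cdd_flag),
            class = "developmental_timeline")
}

#' @export
print.developmental_timeline <- function(x, ...) {
  cat(sprintf("developmental_timeline: %d stages, CDD %.0f h%s\n",
              nrow(x$points), x$cdd_h,
              if (x$cdd_flag != "") paste0(" [", x$cdd_flag, "]") else ""))
  print(x$points[, c("stage_label", "hours_apf", "n_recordings",
                     "HR_bpm", "CAP_pct")])
  invisible(x)
}
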