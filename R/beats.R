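#' Chamber-area trace
#'
#' Per-frame time series of lumen geometry extracted from a segmented
#' recording: timestamps, chamber area and the two diameters. Frames whose
#' segmentation failed are excluded; the timestamps of the remaining frames
#' are preserved (no interpolation).
#'
#' @param series A `mask_series` from [segment_series()].
#' @return An object of class `area_trace`: data.frame with columns
#'   `frame_index`, `time_s`, `area_um2`, `diameter_x_um`, `diameter_z_um`
#'   and attribute `frame_rate_hz`.
#' @export
extract_area_trace <- function(series) {
  stopifnot(inherits(series, "mask_series"))
  g <- series$geometry[!series$geometry$failed, ]
  if (nrow(g) < 2) stop("fewer than 2 successfully segmented frames")
  fr <- series$metadata$frame_rate_hz
  tr <- data.frame(frame_index = g$frame_index,
                   time_s = (g$frame_index - 1) / fr,
                   area_um2 = g$area_um2,
                   diameter_x_um = g$diameter_x_um,
                   diameter_z_um = g$diameter_z_um)
  attr(tr, "frame_rate_hz") <- fr
  class(tr) <- c("area_trace", "data.frame")
  tr
}

#' Build an area trace directly from vectors
#'
#' Mostly for testing and for working with externally computed geometry.
#'
#' @param time_s,area_um2 Equal-length numeric vectors.
#' @param diameter_x_um,diameter_z_um Optional diameter vectors (default
#'   `NA`).
#' @param frame_rate_hz Sampling rate, Hz; default inferred from the median
#'   time step.
#' @return An `area_trace`.
#' @export
area_trace <- function(time_s, area_um2, diameter_x_um = NA_real_,
                       diameter_z_um = NA_real_, frame_rate_hz = NULL) {
  stopifnot(length(time_s) == length(area_um2))
  if (is.unsorted(time_s, strictly = TRUE)) {
    stop("time_s must be strictly increasing")
  }
  if (is.null(frame_rate_hz)) {
    frame_rate_hz <- 1 / stats::median(diff(time_s))
  }
  tr <- data.frame(frame_index = seq_along(time_s), time_s = time_s,
                   area_um2 = area_um2,
                   diameter_x_um = diameter_x_um,
                   diameter_z_um = diameter_z_um)
  attr(tr, "frame_rate_hz") <- frame_rate_hz
  class(tr) <- c("area_trace", "data.frame")
  tr
}

#' Moving-average smoothing of an area trace
#'
#' Centered moving average over `round(window_s * frame_rate)` frames (forced
#' odd); shrinking windows are used at the trace edges. A window of 0 returns
#' the trace unchanged. Only `area_um2` is smoothed; the diameters keep their
#' frame-wise values.
#'
#' @param trace An `area_trace`.
#' @param window_s Window length in seconds (>= 0).
#' @return The smoothed `area_trace`.
#' @export
smooth_trace <- function(trace, window_s) {
  stopifnot(inherits(trace, "area_trace"), window_s >= 0)
  if (window_s == 0) return(trace)
  fr <- attr(trace, "frame_rate_hz")
  w <- round(window_s * fr)
  if (w %% 2 == 0) w <- w + 1
  if (w > nrow(trace)) stop("smoothing window longer than trace")
  if (w <= 1) return(trace)
  trace$area_um2 <- zoo::rollapply(trace$area_um2, w, mean,
                                   partial = TRUE, align = "center")
  trace
}

# Local maxima of x with prominence >= min_prom and index spacing >=
# min_dist. Prominence of a peak: height above the higher of the two minima
# separating it from the nearest higher point (or the series end) on each
# side. Peaks are accepted greedily from highest to lowest.
find_peaks <- function(x, min_prom, min_dist) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(cand) == 0) return(integer(0))
  prom <- vapply(cand, function(i) {
    lhs <- x[seq_len(i - 1)]
    higher_l <- which(lhs > x[i])
    base_l <- min(x[(if (length(higher_l)) max(higher_l) else 1):(i - 1)])
    rhs_idx <- seq.int(i + 1, n)
    rhs <- x[rhs_idx]
    higher_r <- which(rhs > x[i])
    base_r <- min(rhs[seq_len(if (length(higher_r)) min(higher_r) else
      length(rhs))])
    x[i] - max(base_l, base_r)
  }, numeric(1))
  keep <- cand[prom >= min_prom]
  if (length(keep) <= 1) return(keep)
  ord <- keep[order(x[keep], decreasing = TRUE)]
  taken <- integer(0)
  for (i in ord) {
    if (all(abs(i - taken) >= min_dist)) taken <- c(taken, i)
  }
  sort(taken)
}

#' Detect diastolic and systolic beat events on an area trace
#'
#' Diastoles are local maxima of the chamber-area trace with prominence at
#' least `min_prominence_frac` of the within-segment area range and spacing
#' at least `min_period_s`; each systole is the global area minimum between
#' two consecutive diastoles of the same on-segment. Detection is restricted
#' to beating (on) periods; off-periods contribute no events. Diastoles and
#' systoles strictly interleave by construction.
#'
#' @param trace An `area_trace` (typically [smooth_trace()]ed first).
#' @param on_segments An `activity_segments` object from [detect_activity()],
#'   or `NULL` to treat the whole trace as beating.
#' @param min_prominence_frac Minimum peak prominence as a fraction of the
#'   segment's area range (default 0.2).
#' @param min_period_s Minimum beat period, s (default 0.1, i.e. a 600 bpm
#'   ceiling, above any physiological fly heart rate).
#'
#' @return An object of class `beat_events`: list with `diastole_idx`,
#'   `systole_idx` (row indices into `trace`), `diastole_times_s`,
#'   `systole_times_s`, and `segment_id` (on-segment of each diastole).
#' @export
detect_beats <- function(trace, on_segments = NULL,
                         min_prominence_frac = 0.2, min_period_s = 0.1) {
  stopifnot(inherits(trace, "area_trace"))
  fr <- attr(trace, "frame_rate_hz")
  if (min_period_s <= 2 / fr) {
    stop("min_period_s must exceed two frame intervals")
  }
  segs <- if (is.null(on_segments)) {
    data.frame(start_s = min(trace$time_s),
               end_s = max(trace$time_s) + 1 / fr, state = "on")
  } else {
    on_segments$segments
  }
  dia <- integer(0); sys <- integer(0); seg_id <- integer(0)
  for (i in seq_len(nrow(segs))) {
    if (segs$state[i] != "on") next
    rows <- which(trace$time_s >= segs$start_s[i] - 1e-9 &
                    trace$time_s < segs$end_s[i] - 1e-9)
    if (length(rows) < 3) next
    x <- trace$area_um2[rows]
    rng <- max(x) - min(x)
    if (rng <= 0) next
    pk <- find_peaks(x, min_prominence_frac * rng,
                     round(min_period_s * fr))
    if (length(pk) == 0) next
    dia <- c(dia, rows[pk])
    seg_id <- c(seg_id, rep.int(i, length(pk)))
    if (length(pk) >= 2) {
      for (j in seq_len(length(pk) - 1)) {
        between <- seq.int(pk[j] + 1, pk[j + 1] - 1)
        if (length(between) == 0) next
        sys <- c(sys, rows[between[which.min(x[between])]])
      }
    }
  }
  structure(list(diastole_idx = dia, systole_idx = sys,
                 diastole_times_s = trace$time_s[dia],
                 systole_times_s = trace$time_s[sys],
                 segment_id = seg_id),
            class = "beat_events")
}

#' @export
print.beat_events <- function(x, ...) {
  cat(sprintf("beat_events: %d diastoles, %d systoles\n",
              length(x$diastole_idx), length(x$systole_idx)))
  invisible(x)
}

#' Heart rate from beat events
#'
#' HR = 60 / mean diastole-to-diastole interval, intervals pooled over
#' on-segments; an interval never spans an off-period (events are grouped by
#' the on-segment they fall in). Only beating time enters the calculation,
#' so long cardiac pauses do not dilute the rate. A recording with fewer
#' than two diastoles in every on-segment gets HR 0 and the `"no-beat"`
#' flag.
#'
#' @param events A `beat_events` object.
#' @return List with `hr_bpm`, `n_intervals`, `flag` (`""` or `"no-beat"`).
#' @export
heart_rate <- function(events) {
  stopifnot(inherits(events, "beat_events"))
  ints <- numeric(0)
  for (s in unique(events$segment_id)) {
    ts <- sort(events$diastole_times_s[events$segment_id == s])
    if (length(ts) >= 2) ints <- c(ints, diff(ts))
  }
  if (length(ints) == 0) {
    return(list(hr_bpm = 0, n_intervals = 0L, flag = "no-beat"))
  }
  list(hr_bpm = 60 / mean(ints), n_intervals = length(ints), flag = "")
}

#' End-diastolic and end-systolic dimensions and areas
#'
#' EDA / EDD are the means of chamber area / diameters over all detected
#' diastole frames; ESA / ESD the means over systole frames. Averaging over
#' every event in the recording (rather than a single beat) suppresses
#' frame-level segmentation noise.
#'
#' @param events A `beat_events` object.
#' @param trace The `area_trace` the events refer to (unsmoothed geometry is
#'   recommended here).
#' @return List with `EDA_um2`, `ESA_um2`, `EDD_x_um`, `EDD_z_um`,
#'   `ESD_x_um`, `ESD_z_um`; all `NaN` (with flag) when there are no events.
#' @export
chamber_params <- function(events, trace) {
  stopifnot(inherits(events, "beat_events"), inherits(trace, "area_trace"))
  if (length(events$diastole_idx) == 0 || length(events$systole_idx) == 0) {
    return(list(EDA_um2 = NaN, ESA_um2 = NaN,
                EDD_x_um = NaN, EDD_z_um = NaN,
                ESD_x_um = NaN, ESD_z_um = NaN, flag = "no-events"))
  }
  d <- events$diastole_idx; s <- events$systole_idx
  list(EDA_um2 = mean(trace$area_um2[d]),
       ESA_um2 = mean(trace$area_um2[s]),
       EDD_x_um = mean(trace$diameter_x_um[d]),
       EDD_z_um = mean(trace$diameter_z_um[d]),
       ESD_x_um = mean(trace$diameter_x_um[s]),
       ESD_z_um = mean(trace$diameter_z_um[s]),
       flag = "")
}

#' Fractional shortening
#'
#' FS = (EDD - ESD) / EDD x 100, for diameters along one axis or (as
#' "FS-area") for areas. Scale-invariant: multiplying both arguments by any
#' positive constant leaves FS unchanged. ESD > EDD yields a negative FS
#' with a warning -- a data-quality signal rather than an error.
#'
#' @param EDD End-diastolic diameter (um) or area (um^2); > 0.
#' @param ESD End-systolic diameter or area; >= 0.
#' @return FS in percent.
#' @export
fractional_shortening <- function(EDD, ESD) {
  if (any(!is.finite(EDD)) || any(EDD <= 0)) stop("EDD must be positive")
  if (any(is.finite(ESD) & ESD < 0)) stop("ESD must be non-negative")
  if (any(is.finite(ESD) & ESD > EDD)) {
    warning("ESD exceeds EDD; negative fractional shortening reported")
  }
  (EDD - ESD) / EDD * 100
}

#' Summarize one recording into a cardiac-parameter row
#'
#' Combines activity detection and beat events into the standard parameter
#' set: HR (beating time only), CAP, EDD/ESD along both axes, EDA/ESA, and
#' fractional shortening per axis and by area. For a beatless recording
#' (no detected events) HR and CAP are 0, the structural parameters are
#' taken from the overall mean geometry (the lumen sits frozen at diastole
#' during a cardiac pause), ESA/ESD/FS are `NA`, and the row is flagged
#' `"no-beat"`.
#'
#' @param trace The (unsmoothed) `area_trace`.
#' @param events `beat_events` from [detect_beats()].
#' @param activity `activity_segments` from [detect_activity()].
#' @param meta Optional [recording_metadata()] supplying specimen / stage
#'   labels.
#' @param recording_index 1-based index of this recording within its session.
#' @return One-row data.frame with the [param_table_columns()] columns.
#' @export
summarize_recording <- function(trace, events, activity, meta = NULL,
                                recording_index = 1L) {
  hr <- heart_rate(events)
  cp <- chamber_params(events, trace)
  flags <- character(0)
  if (hr$flag != "") flags <- c(flags, hr$flag)
  cap <- if (hr$flag == "no-beat") 0 else activity$cap_pct
  if (hr$flag == "no-beat") {
    cp$EDA_um2 <- mean(trace$area_um2)
    cp$EDD_x_um <- mean(trace$diameter_x_um)
    cp$EDD_z_um <- mean(trace$diameter_z_um)
    cp$ESA_um2 <- NA_real_
    cp$ESD_x_um <- NA_real_
    cp$ESD_z_um <- NA_real_
  }
  fs <- function(edd, esd) {
    if (!is.finite(edd) || !is.finite(esd) || edd <= 0) return(NA_real_)
    suppressWarnings(fractional_shortening(edd, esd))
  }
  data.frame(
    specimen_id = if (is.null(meta)) "" else meta$specimen_id,
    stage_label = if (is.null(meta)) "unknown" else meta$stage_label,
    recording_index = as.integer(recording_index),
    HR_bpm = hr$hr_bpm,
    CAP_pct = cap,
    EDD_x_um = cp$EDD_x_um, EDD_z_um = cp$EDD_z_um,
    ESD_x_um = cp$ESD_x_um, ESD_z_um = cp$ESD_z_um,
    EDA_um2 = cp$EDA_um2, ESA_um2 = cp$ESA_um2,
    FS_x_pct = fs(cp$EDD_x_um, cp$ESD_x_um),
    FS_z_pct = fs(cp$EDD_z_um, cp$ESD_z_um),
    FS_area_pct = fs(cp$EDA_um2, cp$ESA_um2),
    flags = paste(flags, collapse = ","),
    stringsAsFactors = FALSE
  )
}

#' Run the full quantification pipeline on one recording
#'
#' Convenience wrapper: segmentation, area-trace extraction, smoothing,
#' activity detection, beat detection, and parameter summary.
#'
#' @param rec An [ocm_recording()].
#' @param initial_seed,tolerance Passed to [segment_series()].
#' @param smooth_window_s Moving-average window for the beat-detection trace
#'   (default 5 frames' worth at the recording frame rate).
#' @param activity_window_s Sliding-window length for [detect_activity()];
#'   default is the detector's own default, capped at half the recording
#'   duration so short recordings remain analysable.
#' @param recording_index Passed through to [summarize_recording()].
#' @param ... Further arguments to [detect_activity()].
#' @return List with `params` (one-row data.frame), `trace`, `activity`,
#'   `events`, `series`.
#' @export
quantify_recording <- function(rec, initial_seed = NULL, tolerance = NULL,
                               smooth_window_s = NULL,
                               activity_window_s = NULL,
                               recording_index = 1L, ...) {
  series <- segment_series(rec, initial_seed = initial_seed,
                           tolerance = tolerance, keep_masks = FALSE)
  trace <- extract_area_trace(series)
  fr <- rec$metadata$frame_rate_hz
  if (is.null(smooth_window_s)) smooth_window_s <- 5 / fr
  if (is.null(activity_window_s)) {
    activity_window_s <- min(formals(detect_activity)$window_s,
                             duration_s(rec) / 2)
  }
  sm <- smooth_trace(trace, smooth_window_s)
  activity <- detect_activity(sm, window_s = activity_window_s, ...)
  events <- detect_beats(sm, activity)
  params <- summarize_recording(trace, events, activity,
                                meta = rec$metadata,
                                recording_index = recording_index)
  list(params = params, trace = trace, activity = activity,
       events = events, series = series)
}
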