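#' Beat waveform specification
#'
#' Describes one cardiac cycle of the synthetic heart-tube lumen: an ellipse
#' whose semi-axes pulse between diastolic and systolic values following a
#' raised-cosine modulation. `systole_fraction` warps the cycle so a fraction
#' of each period is spent contracting (diastole to systole) and the rest
#' relaxing; 0.5 gives the symmetric default.
#'
#' @param beat_period_s Seconds per beat (> 0).
#' @param dia_semiaxis_x_um,dia_semiaxis_z_um Diastolic lumen semi-axes, um
#'   (transverse x, axial z).
#' @param sys_semiaxis_x_um,sys_semiaxis_z_um Systolic semi-axes, um; each
#'   must be positive and no larger than its diastolic counterpart.
#' @param systole_fraction Fraction of the cycle spent contracting, in (0, 1).
#'
#' @return An object of class `beat_waveform_spec`.
#' @export
beat_waveform_spec <- function(beat_period_s = 0.5,
                               dia_semiaxis_x_um = 60,
                               dia_semiaxis_z_um = 80,
                               sys_semiaxis_x_um = 35,
                               sys_semiaxis_z_um = 45,
                               systole_fraction = 0.5) {
  stopifnot(is.numeric(beat_period_s), beat_period_s > 0)
  if (sys_semiaxis_x_um <= 0 || sys_semiaxis_z_um <= 0 ||
      sys_semiaxis_x_um > dia_semiaxis_x_um ||
      sys_semiaxis_z_um > dia_semiaxis_z_um) {
    stop("systolic semi-axes must be positive and <= diastolic semi-axes")
  }
  if (systole_fraction <= 0 || systole_fraction >= 1) {
    stop("systole_fraction must be in (0, 1)")
  }
  structure(list(beat_period_s = beat_period_s,
                 dia_semiaxis_x_um = dia_semiaxis_x_um,
                 dia_semiaxis_z_um = dia_semiaxis_z_um,
                 sys_semiaxis_x_um = sys_semiaxis_x_um,
                 sys_semiaxis_z_um = sys_semiaxis_z_um,
                 systole_fraction = systole_fraction),
            class = "beat_waveform_spec")
}

#' Cardiac activity schedule
#'
#' An ordered, contiguous partition of the recording time into beating
#' ("on") and resting ("off") periods. During pupal development the fly heart
#' stops beating for long stretches, so recordings routinely contain both.
#'
#' @param segments Data.frame with columns `start_s`, `end_s`, `state`
#'   (`"on"`/`"off"`), contiguous from 0 with alternating states.
#' @return An object of class `activity_schedule`.
#' @export
activity_schedule <- function(segments) {
  stopifnot(is.data.frame(segments),
            all(c("start_s", "end_s", "state") %in% names(segments)))
  if (nrow(segments) == 0) stop("schedule must contain at least one segment")
  if (!all(segments$state %in% c("on", "off"))) {
    stop("states must be 'on' or 'off'")
  }
  if (abs(segments$start_s[1]) > 1e-9) stop("schedule must start at 0")
  if (any(segments$end_s <= segments$start_s)) {
    stop("segments must have positive duration")
  }
  if (nrow(segments) > 1) {
    if (any(abs(segments$start_s[-1] -
                segments$end_s[-nrow(segments)]) > 1e-9)) {
      stop("segments must be contiguous (no gaps or overlaps)")
    }
    if (any(segments$state[-1] == segments$state[-nrow(segments)])) {
      stop("consecutive segments must alternate state")
    }
  }
  structure(list(segments = segments), class = "activity_schedule")
}

#' Convenience schedule constructors
#'
#' `schedule_all_on()` / `schedule_all_off()` build single-segment schedules;
#' `schedule_off_then_on()` builds the two-segment pattern typical of early
#' pupal recordings (a resting period followed by regular beating);
#' `schedule_from_cap()` builds an off-then-on schedule whose on-fraction
#' equals a target cardiac activity period (CAP, %).
#'
#' @param duration_s Total schedule duration, s.
#' @param off_s,on_s Durations of the off and on periods, s.
#' @param cap_pct Target CAP in percent (0-100).
#' @return An [activity_schedule()].
#' @export
schedule_all_on <- function(duration_s) {
  activity_schedule(data.frame(start_s = 0, end_s = duration_s, state = "on"))
}

#' @rdname schedule_all_on
#' @export
schedule_all_off <- function(duration_s) {
  activity_schedule(data.frame(start_s = 0, end_s = duration_s, state = "off"))
}

#' @rdname schedule_all_on
#' @export
schedule_off_then_on <- function(off_s, on_s) {
  activity_schedule(data.frame(start_s = c(0, off_s),
                               end_s = c(off_s, off_s + on_s),
                               state = c("off", "on")))
}

#' @rdname schedule_all_on
#' @export
schedule_from_cap <- function(duration_s, cap_pct) {
  stopifnot(cap_pct >= 0, cap_pct <= 100)
  if (cap_pct >= 100) return(schedule_all_on(duration_s))
  if (cap_pct <= 0) return(schedule_all_off(duration_s))
  on_s <- duration_s * cap_pct / 100
  schedule_off_then_on(duration_s - on_s, on_s)
}

#' Phantom appearance specification
#'
#' Describes the static appearance of the synthetic M-mode cross-section: a
#' dark elliptical lumen, a bright wall annulus and mid-intensity surrounding
#' tissue, all modulated by a multiplicative speckle field (unit-mean
#' exponential intensities low-pass filtered to a ~2 px correlation length, a
#' stylized stand-in for coherent-imaging speckle) plus additive Gaussian
#' read noise. Intensities are on the 16-bit scale (0-65535).
#'
#' @param frame_height_px,frame_width_px Frame dimensions (rows = depth,
#'   cols = transverse).
#' @param center_row,center_col Lumen center in pixel coordinates (defaults:
#'   frame center).
#' @param wall_thickness_um Wall annulus thickness, um.
#' @param lumen_mean,wall_mean,tissue_mean Mean intensities of the three
#'   compartments; `lumen_mean < wall_mean` required.
#' @param speckle_contrast Multiplicative speckle strength in \[0, 1\); 0
#'   disables speckle.
#' @param gaussian_noise_sd Additive Gaussian noise SD (intensity units).
#' @param rng_seed Integer seed; identical seeds give identical recordings.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(frame_height_px = 256,
                         frame_width_px = 128,
                         center_row = NULL,
                         center_col = NULL,
                         wall_thickness_um = 15,
                         lumen_mean = 8000,
                         wall_mean = 45000,
                         tissue_mean = 25000,
                         speckle_contrast = 0.3,
                         gaussian_noise_sd = 800,
                         rng_seed = 1L) {
  if (lumen_mean >= wall_mean) stop("lumen_mean must be < wall_mean")
  if (speckle_contrast < 0 || speckle_contrast >= 1) {
    stop("speckle_contrast must be in [0, 1)")
  }
  structure(list(frame_height_px = as.integer(frame_height_px),
                 frame_width_px = as.integer(frame_width_px),
                 center_row = center_row %||% (frame_height_px + 1) / 2,
                 center_col = center_col %||% (frame_width_px + 1) / 2,
                 wall_thickness_um = wall_thickness_um,
                 lumen_mean = lumen_mean,
                 wall_mean = wall_mean,
                 tissue_mean = tissue_mean,
                 speckle_contrast = speckle_contrast,
                 gaussian_noise_sd = gaussian_noise_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

# Instantaneous lumen semi-axes for a vector of times.
# Phase resets to full diastole at the start of every on-segment; during off
# segments the lumen is frozen at its diastolic size (flat M-mode bands).
semiaxes_at <- function(times, waveform, schedule) {
  seg <- schedule$segments
  ax <- rep(waveform$dia_semiaxis_x_um, length(times))
  az <- rep(waveform$dia_semiaxis_z_um, length(times))
  f <- waveform$systole_fraction
  for (i in seq_len(nrow(seg))) {
    if (seg$state[i] != "on") next
    in_seg <- times >= seg$start_s[i] - 1e-12 & times < seg$end_s[i] - 1e-12
    if (!any(in_seg)) next
    u <- ((times[in_seg] - seg$start_s[i]) / waveform$beat_period_s) %% 1
    theta <- ifelse(u < f, 0.5 * u / f, 0.5 + 0.5 * (u - f) / (1 - f))
    g <- (1 + cos(2 * pi * theta)) / 2   # 1 at diastole, 0 at systole
    ax[in_seg] <- waveform$sys_semiaxis_x_um +
      (waveform$dia_semiaxis_x_um - waveform$sys_semiaxis_x_um) * g
    az[in_seg] <- waveform$sys_semiaxis_z_um +
      (waveform$dia_semiaxis_z_um - waveform$sys_semiaxis_z_um) * g
  }
  list(ax = ax, az = az)
}

# 5x5 Gaussian kernel (sigma ~ 1 px) used to correlate the speckle field.
.speckle_kernel <- local({
  g <- stats::dnorm(-2:2, sd = 1)
  k <- outer(g, g)
  k / sum(k)
})

#' Generate a synthetic M-mode recording with known ground truth
#'
#' Renders the phantom frame by frame: during on-segments of the schedule the
#' lumen semi-axes follow the raised-cosine beat cycle (phase reset to full
#' diastole at each on-segment start); during off-segments they are frozen at
#' the diastolic values. Each frame is the three-level geometry (lumen, wall,
#' tissue) multiplied by a unit-mean correlated speckle field and with
#' additive Gaussian noise, clamped to the 16-bit range.
#'
#' @param phantom A [phantom_spec()].
#' @param waveform A [beat_waveform_spec()]; its period must exceed two frame
#'   intervals (Nyquist) of `meta`.
#' @param schedule An [activity_schedule()] covering `[0, duration_s]`.
#' @param meta A [recording_metadata()] providing frame rate and pixel sizes.
#' @param duration_s Recording duration, s (default 30, one imaging session).
#'
#' @return A list with elements `recording` (an [ocm_recording()]) and
#'   `truth` (class `synthetic_truth`): per-frame true semi-axes and lumen
#'   area (`frames` data.frame), true diastole instants `beat_times_s`,
#'   `hr_bpm` (60 / beat period; 0 if never beating), `cap_pct`
#'   (100 x on-time / duration), `eda_um2` and `esa_um2` (analytic ellipse
#'   areas pi a b at diastole and systole).
#' @export
generate_recording <- function(phantom, waveform, schedule, meta,
                               duration_s = 30) {
  stopifnot(inherits(phantom, "phantom_spec"),
            inherits(waveform, "beat_waveform_spec"),
            inherits(schedule, "activity_schedule"),
            inherits(meta, "recording_metadata"))
  fr <- meta$frame_rate_hz
  if (waveform$beat_period_s <= 2 / fr) {
    stop("beat_period_s must exceed two frame intervals (Nyquist)")
  }
  seg <- schedule$segments
  if (abs(seg$end_s[nrow(seg)] - duration_s) > 1e-9) {
    stop("schedule must cover [0, duration_s] exactly")
  }
  # geometry overflow check at diastole
  max_x_um <- (waveform$dia_semiaxis_x_um + phantom$wall_thickness_um)
  max_z_um <- (waveform$dia_semiaxis_z_um + phantom$wall_thickness_um)
  if (phantom$center_col - max_x_um / meta$pixel_size_x_um < 1 ||
      phantom$center_col + max_x_um / meta$pixel_size_x_um >
        phantom$frame_width_px ||
      phantom$center_row - max_z_um / meta$pixel_size_z_um < 1 ||
      phantom$center_row + max_z_um / meta$pixel_size_z_um >
        phantom$frame_height_px) {
    stop("diastolic lumen plus wall does not fit inside the frame")
  }

  nf <- round(duration_s * fr)
  if (nf < 2) stop("duration too short: need at least 2 frames")
  times <- (seq_len(nf) - 1) / fr
  axes <- semiaxes_at(times, waveform, schedule)

  h <- phantom$frame_height_px
  w <- phantom$frame_width_px
  zc <- (seq_len(h) - phantom$center_row) * meta$pixel_size_z_um
  xc <- (seq_len(w) - phantom$center_col) * meta$pixel_size_x_um
  wt <- phantom$wall_thickness_um

  frames <- array(0, dim = c(nf, h, w))
  withr::with_seed(phantom$rng_seed, {
    for (k in seq_len(nf)) {
      ax <- axes$ax[k]; az <- axes$az[k]
      d_lumen <- outer((zc / az)^2, (xc / ax)^2, "+")
      d_wall <- outer((zc / (az + wt))^2, (xc / (ax + wt))^2, "+")
      img <- matrix(phantom$tissue_mean, h, w)
      img[d_wall <= 1] <- phantom$wall_mean
      img[d_lumen <= 1] <- phantom$lumen_mean
      if (phantom$speckle_contrast > 0) {
        s <- matrix(stats::rexp(h * w), h, w)
        s <- EBImage::filter2(s, .speckle_kernel)
        img <- img * ((1 - phantom$speckle_contrast) +
                        phantom$speckle_contrast * s)
      }
      if (phantom$gaussian_noise_sd > 0) {
        img <- img + matrix(stats::rnorm(h * w, 0, phantom$gaussian_noise_sd),
                            h, w)
      }
      frames[k, , ] <- pmin(pmax(img, 0), 65535)
    }
  })

  beat_times <- unlist(lapply(seq_len(nrow(seg)), function(i) {
    if (seg$state[i] != "on") return(numeric(0))
    seq(seg$start_s[i], seg$end_s[i] - 1e-9, by = waveform$beat_period_s)
  }))
  on_total <- sum(seg$end_s[seg$state == "on"] - seg$start_s[seg$state == "on"])
  truth <- structure(list(
    frames = data.frame(time_s = times,
                        semiaxis_x_um = axes$ax,
                        semiaxis_z_um = axes$az,
                        area_um2 = pi * axes$ax * axes$az),
    beat_times_s = as.numeric(beat_times),
    hr_bpm = if (on_total > 0) 60 / waveform$beat_period_s else 0,
    cap_pct = 100 * on_total / duration_s,
    eda_um2 = pi * waveform$dia_semiaxis_x_um * waveform$dia_semiaxis_z_um,
    esa_um2 = pi * waveform$sys_semiaxis_x_um * waveform$sys_semiaxis_z_um
  ), class = "synthetic_truth")

  list(recording = ocm_recording(frames, meta), truth = truth)
}

# Stage-wise HR (bpm) and CAP (%) trajectory used by the presets. HR and CAP
# at L2, PD1 24h, PD2 48h and AD1 follow the reported 24B-GAL4/+ stage means;
# values at the remaining stages interpolate the described trajectory (HR
# falling through PD1, silent heart during early PD2, steady recovery through
# PD3/PD4). Chamber sizes are plausible defaults only: absolute lumen
# dimensions are not pinned by published numbers.
.stage_presets <- data.frame(
  stage_label = c("L2", "L3",
                  "PD1 16h", "PD1 24h",
                  "PD2 32h", "PD2 40h", "PD2 48h",
                  "PD3 56h", "PD3 64h", "PD3 72h",
                  "PD4 80h", "PD4 88h", "PD4 96h",
                  "AD1"),
  hr_bpm = c(277, 300, 150, 26, 0, 0, 17, 60, 120, 180, 240, 300, 340, 391),
  cap_pct = c(85, 100, 70, 30, 0, 0, 5, 20, 40, 55, 70, 80, 88, 95),
  size_class = c("larva", "larva", "pupa", "pupa", "pupa", "pupa", "pupa",
                 "pupa", "pupa", "pupa", "adult", "adult", "adult", "adult"),
  stringsAsFactors = FALSE
)

.size_presets <- data.frame(
  size_class = c("larva", "pupa", "adult"),
  dia_x = c(60, 40, 50), dia_z = c(80, 55, 70),
  sys_x = c(35, 26, 28), sys_z = c(45, 36, 38),
  stringsAsFactors = FALSE
)

#' Synthetic waveform and schedule presets per developmental stage
#'
#' Returns generator settings whose ground-truth heart rate and cardiac
#' activity period equal the reported control-group stage means where those
#' are published (L2: 277 bpm; PD1 24h: 26 bpm; PD2 48h: 17 bpm, CAP 5%;
#' AD1: 391 bpm, CAP 95%); intermediate stages interpolate the described
#' developmental trajectory, and PD2 32h/40h are fully silent (the cardiac
#' developmental diastasis). Chamber dimensions are plausible defaults, not
#' published values.
#'
#' @param stage_label A label from [stage_vocabulary()] (not `"unknown"`).
#' @param duration_s Schedule duration, s.
#' @return A list with elements `waveform` ([beat_waveform_spec()]),
#'   `schedule` ([activity_schedule()]), `hr_bpm`, `cap_pct`.
#' @export
stage_preset <- function(stage_label, duration_s = 30) {
  i <- match(stage_label, .stage_presets$stage_label)
  if (is.na(i)) stop("unknown stage_label '", stage_label,
                     "'; see stage_vocabulary()")
  p <- .stage_presets[i, ]
  s <- .size_presets[match(p$size_class, .size_presets$size_class), ]
  period <- if (p$hr_bpm > 0) 60 / p$hr_bpm else 1
  wf <- beat_waveform_spec(beat_period_s = period,
                           dia_semiaxis_x_um = s$dia_x,
                           dia_semiaxis_z_um = s$dia_z,
                           sys_semiaxis_x_um = s$sys_x,
                           sys_semiaxis_z_um = s$sys_z)
  sched <- schedule_from_cap(duration_s, if (p$hr_bpm > 0) p$cap_pct else 0)
  list(waveform = wf, schedule = sched,
       hr_bpm = p$hr_bpm, cap_pct = if (p$hr_bpm > 0) p$cap_pct else 0)
}

# Multiplicative deficits applied to the dCry-RNAi genotype. Synthetic effect
# sizes chosen to make group comparisons detectable; not published values.
.rnai_effects <- list(hr = 0.8, cap = 0.7, size = 0.85)

#' Generate a longitudinal developmental timeline of synthetic recordings
#'
#' Emulates the longitudinal imaging design: one specimen followed from L2 to
#' AD1 with pupal stages sampled every 8 h and five recordings per time
#' point. The `"dCry-RNAi"` genotype applies fixed multiplicative deficits
#' (HR x0.8, CAP x0.7, chamber semi-axes x0.85 -- synthetic effect sizes) and
#' resumes beating one 8-h time point earlier during PD2, so its cardiac
#' developmental diastasis is shorter. Between-recording variability jitters
#' HR and chamber size by ~3% (CV).
#'
#' Pupal beating is intermittent from session to session, so a stage's
#' on-time budget (`cap_pct / 100 x duration_s x n_recordings`) is
#' concentrated into as few recordings as possible (the first recording
#' beats up to 100% CAP, then the next, and so on), and any nonzero bout
#' spans at least 2.5 beat periods -- a bout is a run of beats, not a
#' fraction of one. The mean CAP across a stage's recordings therefore
#' equals the stage preset except at nearly-silent slow-beating stages,
#' where the bout floor raises it slightly; individual sessions always
#' contain either no beating or a measurable run of beats.
#'
#' @param specimen_seed Integer seed; same seed, genotype and sizes give an
#'   identical timeline.
#' @param genotype `"control"` or `"dCry-RNAi"`.
#' @param stages Stage labels to include (default: the full vocabulary in
#'   developmental order).
#' @param n_recordings Recordings per stage (default 5).
#' @param duration_s Duration of each recording, s (default 30).
#' @param phantom A [phantom_spec()] template; its `rng_seed` is re-derived
#'   per recording from `specimen_seed`.
#' @param meta_template A [recording_metadata()] providing frame rate and
#'   pixel sizes.
#'
#' @return A list with one element per stage, each a list with
#'   `stage_label`, `hours_apf`, and `recordings` -- a list of `n_recordings`
#'   `list(recording, truth)` pairs as returned by [generate_recording()].
#' @export
generate_timeline <- function(specimen_seed,
                              genotype = c("control", "dCry-RNAi"),
                              stages = stage_info()$stage_label,
                              n_recordings = 5,
                              duration_s = 30,
                              phantom = phantom_spec(),
                              meta_template = recording_metadata()) {
  genotype <- match.arg(genotype)
  info <- stage_info()
  stopifnot(all(stages %in% info$stage_label))
  out <- vector("list", length(stages))
  names(out) <- stages
  for (si in seq_along(stages)) {
    st <- stages[si]
    preset <- stage_preset(st, duration_s)
    hr <- preset$hr_bpm
    cap <- preset$cap_pct
    if (genotype == "dCry-RNAi") {
      # resumes beating one time point earlier, at the control's own
      # resumption rate and activity level
      if (st == "PD2 40h") { hr <- 17; cap <- 5 }
      hr <- hr * .rnai_effects$hr
      cap <- cap * .rnai_effects$cap
    }
    # concentrate the stage's on-time budget into the leading recordings
    caps_r <- numeric(n_recordings)
    remaining <- cap * n_recordings
    for (r in seq_len(n_recordings)) {
      caps_r[r] <- min(remaining, 100)
      remaining <- remaining - caps_r[r]
    }
    recs <- vector("list", n_recordings)
    for (r in seq_len(n_recordings)) {
      rec_seed <- (specimen_seed * 1009L + si * 101L + r * 7L +
                     (genotype == "dCry-RNAi") * 13L) %% .Machine$integer.max
      jit <- withr::with_seed(rec_seed, stats::rnorm(2, 1, 0.03))
      hr_r <- hr * jit[1]
      size_mult <- jit[2] *
        if (genotype == "dCry-RNAi") .rnai_effects$size else 1
      wf0 <- preset$waveform
      wf <- beat_waveform_spec(
        beat_period_s = if (hr_r > 0) 60 / hr_r else 1,
        dia_semiaxis_x_um = wf0$dia_semiaxis_x_um * size_mult,
        dia_semiaxis_z_um = wf0$dia_semiaxis_z_um * size_mult,
        sys_semiaxis_x_um = wf0$sys_semiaxis_x_um * size_mult,
        sys_semiaxis_z_um = wf0$sys_semiaxis_z_um * size_mult)
      cap_r <- if (hr_r > 0) caps_r[r] else 0
      if (cap_r > 0) {
        # a bout is a run of beats: at least 2.5 periods long
        on_s <- max(cap_r / 100 * duration_s, 2.5 * 60 / hr_r)
        cap_r <- 100 * min(on_s, duration_s) / duration_s
      }
      sched <- schedule_from_cap(duration_s, cap_r)
      ph <- phantom
      ph$rng_seed <- rec_seed
      meta <- recording_metadata(
        frame_rate_hz = meta_template$frame_rate_hz,
        pixel_size_x_um = meta_template$pixel_size_x_um,
        pixel_size_z_um = meta_template$pixel_size_z_um,
        stage_label = st,
        specimen_id = paste0("sim", specimen_seed),
        genotype = genotype)
      recs[[r]] <- generate_recording(ph, wf, sched, meta, duration_s)
    }
    out[[si]] <- list(stage_label = st,
                      hours_apf = info$hours_apf[info$stage_label == st],
                      recordings = recs)
  }
  out
}

#' Draw cardiac parameters from the stage presets without rendering images
#'
#' A lightweight truth-level sampler for statistical work (group comparisons,
#' power and type-I-error simulations): draws per-specimen HR, CAP, EDA and
#' ESA from the stage-preset means with log-normal between-specimen
#' variability, applying the same genotype deficits as [generate_timeline()].
#'
#' @param stage_label Stage from [stage_vocabulary()].
#' @param genotype `"control"` or `"dCry-RNAi"`.
#' @param n Number of specimens.
#' @param cv Between-specimen coefficient of variation (default 0.15).
#' @return Data.frame with columns `HR_bpm`, `CAP_pct`, `EDA_um2`, `ESA_um2`.
#' @export
simulate_stage_params <- function(stage_label,
                                  genotype = c("control", "dCry-RNAi"),
                                  n, cv = 0.15) {
  genotype <- match.arg(genotype)
  preset <- stage_preset(stage_label)
  hr <- preset$hr_bpm
  cap <- preset$cap_pct
  size <- 1
  if (genotype == "dCry-RNAi") {
    hr <- hr * .rnai_effects$hr
    cap <- cap * .rnai_effects$cap
    size <- .rnai_effects$size
  }
  wf <- preset$waveform
  eda <- pi * wf$dia_semiaxis_x_um * wf$dia_semiaxis_z_um * size^2
  esa <- pi * wf$sys_semiaxis_x_um * wf$sys_semiaxis_z_um * size^2
  sdlog <- sqrt(log(1 + cv^2))
  draw <- function(mu) {
    if (mu <= 0) rep(0, n) else stats::rlnorm(n, log(mu) - sdlog^2 / 2, sdlog)
  }
  data.frame(HR_bpm = draw(hr),
             CAP_pct = pmin(draw(cap), 100),
             EDA_um2 = draw(eda),
             ESA_um2 = draw(esa))
}
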