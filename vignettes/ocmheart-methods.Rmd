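---
title: "Quantifying Drosophila heart function from M-mode OCM: methods and design notes"
author: "ocmheart"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Drosophila heart function from M-mode OCM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

The *Drosophila* heart is a dorsal tube that remodels dramatically during
metamorphosis: the larval heart histolyses its posterior portion, builds the
adult conical chamber, and — remarkably — stops beating for a long stretch of
pupa day 2 while it does so. Optical coherence microscopy (OCM) can image a
transverse cross-section of this tube through the intact cuticle at
micron-scale resolution and hundreds of frames per second, producing M-mode
recordings: the same cross-section sampled repeatedly over a ~30 s session,
at 128 Hz in the acquisition design this package targets.

From such a recording the package derives the standard echocardiographic
parameter set, adapted to the fly:

* **HR** — heart rate in beats per minute, computed *only over time in which
  the heart is actually beating*;
* **EDD / ESD** — end-diastolic and end-systolic diameters of the chamber
  lumen, along the transverse (horizontal, x) and axial (vertical, z) axes;
* **EDA / ESA** — end-diastolic and end-systolic lumen areas;
* **FS** — fractional shortening, $\mathrm{FS} = \frac{EDD - ESD}{EDD}
  \times 100$, per axis and analogously for areas;
* **CAP** — the cardiac activity period, the percentage of the session the
  heart spends beating: $\mathrm{CAP} = 100 \times \sum t_{on} / t_{total}$.
  A session resting 4.8 s and then beating 7.6 s has
  $\mathrm{CAP} = 100 \times 7.6 / 12.4 \approx 61\%$;
* **CDD** — the cardiac developmental diastasis, the prolonged pupal cardiac
  pause, scored as the longest run of consecutive beatless 8-h time points
  times the sampling interval.

Intermittent beating is the rule during metamorphosis, so CAP is averaged
over the (typically five) sessions of a time point, and HR never counts
resting time in its denominator.

## Pipeline

### Lumen segmentation (magic wand)

Each frame shows a dark elliptical lumen inside a bright muscular wall,
embedded in speckled tissue. The lumen is segmented per frame by seeded
region growing — the classic "magic wand":

1. a single 3×3 median-filter pass knocks down speckle extremes
   (switchable);
2. a 4-connected flood fill selects every pixel within an absolute
   intensity tolerance of the (filtered) seed pixel;
3. holes are filled — speckle voids inside the lumen otherwise fragment the
   mask; the filled fill region is by construction the connected component
   containing the seed.

Design choices where the method leaves room:

* **Connectivity** is 4-connected: conservative, and it cannot leak
  diagonally through a one-pixel wall.
* **Tolerance** is an absolute window around the seed intensity, defaulting
  to half the separation between the mean intensities below and above the
  frame's Otsu threshold (≈ ½ (wall − lumen) for a two-level chamber
  image). A running-mean adaptive tolerance was deliberately avoided — it
  makes the mask depend on fill order.
* **Runaway guard**: a mask touching more than 25% of the image border is
  rejected; with tolerance set too high the fill escapes the wall and floods
  the frame.
* **Diameters** are full axis-aligned extents of the mask
  (max − min + 1 pixels × pitch), matching the horizontal/vertical naming of
  EDD and ESD, not centroid chords.

Across frames, frame *k* is seeded at the centroid of frame *k − 1*'s mask,
which tracks slow chamber drift; a failed fill retries the initial seed and
is otherwise flagged — failed frames carry no geometry and are never
interpolated. The initial seed may be supplied or found automatically as the
centroid of the darkest blob in the central half of frame 1.

### Beat detection and parameters

The per-frame lumen area (with timestamps preserved across any failed
frames) is smoothed by a centred moving average (default 5 frames, ~39 ms at
128 Hz). Diastoles are local maxima with prominence at least 0.2 of the
within-segment area range and spacing at least 0.1 s (a 600 bpm ceiling,
comfortably above any fly heart rate); each systole is the global area
minimum between consecutive diastoles of the same on-segment, so events
strictly interleave by construction.

HR is 60 over the mean diastole-to-diastole interval, intervals pooled over
on-segments and never spanning a pause. Pooling means the estimate
telescopes to (time span)/(beat count) within each segment, so single-frame
peak jitter largely cancels. EDD/ESD/EDA/ESA are means over *all* detected
event frames of a recording rather than single-beat values, suppressing
frame-level segmentation noise, and FS is computed from those means. A
recording with no detected beats reports HR 0 and CAP 0 with a `no-beat`
flag; its structural parameters come from the overall mean geometry (during
a pause the lumen sits frozen at diastole) and its systolic parameters are
`NA`.

### Activity detection (on/off periods)

Beating is detected on the linearly detrended area trace by a centred
sliding-window SD. Frames whose window SD exceeds `k = 4` times a noise
floor are "on"; runs shorter than 0.5 s merge into their neighbours.

Two details matter and are worth stating openly:

* **The noise floor.** The natural floor is the 5th percentile of the
  window SDs — the quietest windows of a recording that contains rest. A
  recording that beats (or rests) throughout has no quiet subpopulation, and
  that percentile would sit at the beating level itself; when the 5th
  percentile is not clearly below the bulk (below half the 90th percentile)
  the floor instead falls back to a third-difference noise estimate, the
  0.8 quantile of $|\Delta^3 x|$ scaled for half-normal data. Third
  differencing attenuates an oscillation of frequency $f$ by
  $(2\sin(\pi f/f_s))^3$ — negligible leakage even at 391 bpm sampled at
  128 Hz — so it tracks frame noise, not beating. Numerically flat traces
  (SDs at round-off level) are classified entirely at rest.
* **Window length and boundary refinement.** The window must contain at
  least one full beat of the slowest rate of interest, or the quiet
  diastolic plateau of a slow beat is misread as rest; the default is 4 s,
  covering the ~3.5 s period of the ~17 bpm beating seen around the pupal
  pause. A sliding window this long blurs each on/off transition by up to
  half a window, which would be fatal to CAP on a 12 s recording; each
  coarse boundary is therefore refined to the first (off→on) or last
  (on→off) frame whose raw smoothed area departs from the resting baseline
  (the median area of the off side adjacent to the boundary — during rest
  the lumen sits at its diastolic area) by more than 0.2 of the beating
  amplitude, confirmed by the following frame. On clean recordings this
  pins the boundary to within roughly a tenth of a beat period.

CAP is stored at full precision and reported rounded to integer percent;
`detect_activity()` exposes both. On a synthetic session resting 4.8 s and
beating 7.6 s the full pipeline lands within one percentage point of the
61.29% truth before rounding (this is asserted by the test suite).

### CDD and timelines

A specimen's per-recording parameter rows aggregate to one point per stage
(CAP via its arithmetic session mean); a stage counts as beating when any of
its recordings yields detected beats. The CDD is the longest run of
consecutive silent pupal points × the 8-h sampling interval — run length
rather than midpoint interpolation, the simplest convention consistent with
8-h sampling, stated openly because finer conventions are equally
defensible. A timeline whose pupal points are all silent is flagged
`death-censored`; a timeline with no pupal points reports the CDD as
unavailable.

### Statistics

Group results are mean ± s.e.m. (sample SD/√n). Genotype comparisons use
the classical pooled-variance two-tailed unpaired Student's t-test
(df = nₐ + n_b − 2), with Welch's variant behind a flag; "Student's t-test"
is taken literally, and whether the original comparisons at repeated time
points were pooled or Welch, paired or unpaired, is not stated anywhere we
could check — unpaired pooled is the documented choice. No multiple-testing
correction is applied by default, matching the stage-wise phenotyping
convention of reporting raw per-comparison p-values (* < 0.05, ** < 0.01,
*** < 0.001); Holm adjustment is available behind an option.

## The synthetic phantom

There is no public raw OCM data for this design, so validation rests on a
synthetic M-mode generator with exact ground truth.

```{r}
library(ocmheart)
meta <- recording_metadata(frame_rate_hz = 128)
sim <- generate_recording(phantom_spec(rng_seed = 1),
                          beat_waveform_spec(beat_period_s = 0.5),
                          schedule_off_then_on(4.8, 7.6),
                          meta, duration_s = 12.4)
q <- quantify_recording(sim$recording)
q$activity$cap_pct_int   # 61
sim$truth$cap_pct        # 61.29...
```

What it emulates:

* a dark elliptical lumen (default diastolic semi-axes 60 × 80 µm) inside a
  bright 15 µm wall annulus in mid-intensity tissue, on a 256 × 128 px
  frame at 2.2 µm isotropic pitch — chamber dimensions are plausible
  defaults for a larval heart tube, **not** published measurements, and are
  freely settable;
* a raised-cosine beat cycle between diastolic and systolic semi-axes with
  `systole_fraction` warping available (default 0.5, symmetric; no waveform
  shape is published, so symmetric is the default and asymmetry an option);
* phase reset to full diastole at each on-segment start, so short bouts
  contain no partial first beat, and freezing at diastole during
  off-segments (the flat bands seen in real pupal M-modes);
* multiplicative speckle — a unit-mean exponential-intensity field low-pass
  filtered to a ~2 px correlation length — plus additive Gaussian read
  noise, clamped to the 16-bit range. This is a *stylized* speckle model:
  visually OCT-like and cheap, not a coherent-imaging forward model.

Ground truth carries per-frame semi-axes and area ($\pi a b$), exact beat
times, HR = 60/period, CAP from the schedule, and analytic EDA/ESA. Under a
fixed `rng_seed` the generator is bitwise reproducible.

Stage presets encode the published control-group trajectory where numbers
exist — L2 277 bpm, PD1 24h 26 bpm, PD2 48h 17 bpm with CAP 5%, AD1 391 bpm
with CAP 95%, and full silence at PD2 32–40h — and interpolate the described
rise through PD3/PD4 elsewhere. The `dCry-RNAi` genotype applies
multiplicative deficits (HR ×0.8, CAP ×0.7, semi-axes ×0.85) and resumes
beating one 8-h point earlier during PD2; these effect sizes are synthetic
fixtures chosen to make group comparisons detectable, not published values.
Within a time point the on-time budget is concentrated into the leading
recordings of the five-session set — mirroring the session-to-session
intermittency that motivates five-session averaging in the first place —
and any nonzero bout spans at least 2.5 beat periods, because a bout is a
run of beats, not a fraction of one. The session-mean CAP therefore equals
the stage preset except at nearly-silent slow-beating stages (e.g. ~5% CAP
at ~17 bpm), where the bout floor raises it slightly; the alternative — a
1.5 s "bout" of a 3.5 s beat — is physiologically incoherent and would be
censored as beatless by any beat-interval method, including this one.

What passing tests on this phantom do **not** show: robustness to real OCM
artefacts (attenuation with depth, refraction at the cuticle, motion of the
whole animal, the pupal air bubble), to anisotropic resolution, or to
chambers that deviate from an ellipse. The segmentation and activity
detector are validated against the statistical structure the analysis
assumes, no more.

## Numerical choices and degenerate inputs

* Frame axis first, `frames[k, , ]`, 0-based time: frame *k* is stamped
  (k − 1)/rate s, at frame start. One convention, stated once.
* Files store 16-bit unsigned intensities; memory is numeric. Integer input
  round-trips exactly through the TIFF + JSON sidecar pair. A sidecar
  without `frame_rate_hz` is an error — event timing depends on it, so
  there is no silent default.
* A recording needs ≥ 2 frames; a series with > 50% failed frames is an
  error; an all-flat frame under tolerance 0 is a runaway fill, not a mask.
* `smooth_trace(width = 0)` is the identity; windows are forced odd;
  trace edges use shrinking windows rather than padding.
* Boundary frames between on and off belong to the segment whose refined
  boundary they fall inside; segment times tile `[0, n/rate]` exactly.
* Ties in peak height are resolved by taking peaks greedily from highest to
  lowest under the minimum-spacing constraint.
* `ESD > EDD` (possible under segmentation noise) reports negative FS with
  a warning — a data-quality signal, deliberately not an error.

## Problem sizes

The test suite exercises the full pipeline on reduced phantoms
(96 × 64 px at 3.5 µm, 64–128 Hz, 3–12.4 s) — spatially smaller but
temporally faithful; the package's own validation targets (HR within 2%
of truth across 17–391 bpm, areas within 5% of the analytic ellipse,
end-to-end CAP within 1 point of 61.29% before rounding) are asserted
there. The analysis scripts under `analysis/` run the default-geometry
phantom for the showcase recordings and 30 s sessions for the longitudinal
runs; these sizes are the package's choices for a desk-scale study and are
stated in each script's header.

## Known limitations

* Diameters are 2-D mask extents; whether the original MATLAB analysis
  measured on a fixed M-mode line instead is unknowable from the published
  description. Extents match the horizontal/vertical parameter naming.
* HR requires at least two diastoles within one on-segment; a session whose
  beating bout is shorter than one beat period is reported beatless rather
  than guessed at. At time points like PD2 48h (CAP ≈ 5% of a 30 s session
  at ≈ 17 bpm) this is a real censoring effect, handled by the five-session
  design rather than by extrapolation.
* No arrhythmia indices (arrhythmicity index, interval histograms), no
  circadian analysis of HR, no 3-D volumetric segmentation, and no
  physical OCM forward model — all out of scope by design.
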