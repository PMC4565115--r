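#!/usr/bin/env Rscript
# Simulate the two showcase M-mode recordings used throughout the analysis:
#  (a) an early-pupa-style session whose heart rests for 4.8 s and then
#      beats regularly for 7.6 s (the canonical CAP = 61% example), and
#  (b) a fully beating larva-style (L3) session, CAP = 100%.
# Recordings are written as multi-page TIFF + JSON sidecar plus a
# ground-truth CSV under scratch/data/ (large binary intermediates; the
# derived tables in results/ are the analysis record). Reduced phantom
# geometry (96 x 64 px at 3.5 um) keeps runtimes short; temporal structure
# is untouched.

suppressPackageStartupMessages(library(ocmheart))

out_dir <- file.path("scratch", "data")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

phantom <- phantom_spec(frame_height_px = 96, frame_width_px = 64,
                        rng_seed = 20260921L)
meta <- function(stage) recording_metadata(frame_rate_hz = 64,
                                           pixel_size_x_um = 3.5,
                                           pixel_size_z_um = 3.5,
                                           stage_label = stage,
                                           specimen_id = "showcase",
                                           genotype = "control")

message("simulating PD1-style off/on recording (4.8 s off + 7.6 s on) ...")
pd1 <- generate_recording(phantom,
                          beat_waveform_spec(beat_period_s = 0.5,
                                             dia_semiaxis_x_um = 40,
                                             dia_semiaxis_z_um = 55,
                                             sys_semiaxis_x_um = 26,
                                             sys_semiaxis_z_um = 36),
                          schedule_off_then_on(4.8, 7.6),
                          meta("PD1 24h"), duration_s = 12.4)
write_recording(pd1$recording,
                file.path(out_dir, "pd1_offon.tiff"),
                file.path(out_dir, "pd1_offon.json"), force = TRUE)

message("simulating L3-style continuously beating recording ...")
ph2 <- phantom; ph2$rng_seed <- 20260922L
l3 <- generate_recording(ph2,
                         beat_waveform_spec(beat_period_s = 0.2),
                         schedule_all_on(12),
                         meta("L3"), duration_s = 12)
write_recording(l3$recording,
                file.path(out_dir, "l3_allon.tiff"),
                file.path(out_dir, "l3_allon.json"), force = TRUE)

truth <- rbind(
  data.frame(recording = "pd1_offon", hr_bpm = pd1$truth$hr_bpm,
             cap_pct = pd1$truth$cap_pct, eda_um2 = pd1$truth$eda_um2,
             esa_um2 = pd1$truth$esa_um2),
  data.frame(recording = "l3_allon", hr_bpm = l3$truth$hr_bpm,
             cap_pct = l3$truth$cap_pct, eda_um2 = l3$truth$eda_um2,
             esa_um2 = l3$truth$esa_um2))
write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)

message("ground truth:")
print(truth, row.names = FALSE)
message("wrote ", out_dir)
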