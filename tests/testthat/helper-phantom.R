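# Shared small-phantom fixtures. Tests use a reduced geometry (96 x 64 px at
# 3.5 um pitch) and, where full temporal fidelity is not needed, a 64 Hz
# frame rate, to keep runtimes short; the spatial structure matches the
# default phantom (dark lumen, bright wall, speckled tissue).

test_meta <- function(frame_rate_hz = 64, stage_label = "unknown") {
  recording_metadata(frame_rate_hz = frame_rate_hz,
                     pixel_size_x_um = 3.5, pixel_size_z_um = 3.5,
                     stage_label = stage_label)
}

test_phantom <- function(rng_seed = 1, ...) {
  phantom_spec(frame_height_px = 96, frame_width_px = 64,
               rng_seed = rng_seed, ...)
}

# Noiseless variant: exact three-level geometry.
test_phantom_clean <- function(rng_seed = 1) {
  test_phantom(rng_seed, speckle_contrast = 0, gaussian_noise_sd = 0)
}

# One mixed off/on recording shared by several test files (cached).
.fixture_env <- new.env(parent = emptyenv())

mixed_recording <- function() {
  if (is.null(.fixture_env$mixed)) {
    .fixture_env$mixed <- generate_recording(
      test_phantom(rng_seed = 42),
      beat_waveform_spec(beat_period_s = 0.5),
      schedule_off_then_on(4.8, 7.6),
      test_meta(), duration_s = 12.4)
  }
  .fixture_env$mixed
}

mixed_quantified <- function() {
  if (is.null(.fixture_env$mixed_q)) {
    .fixture_env$mixed_q <- quantify_recording(mixed_recording()$recording)
  }
  .fixture_env$mixed_q
}
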