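# Shared fixture builders (all generated in code; nothing on disk).

fixture_regions <- function() list(
  pos = region_spec("pos", c(1.5, 2.2), 15, exposure_multiplier = 1.6,
                    usv_coupling = 0.9),
  neg = region_spec("neg", c(-0.2, 0.8), 20, exposure_multiplier = 1.0,
                    usv_coupling = -0.9),
  soc = region_spec("soc", c(-0.6, 0.2), 18, exposure_multiplier = 1.6,
                    usv_coupling = 0),
  nul = region_spec("nul", c(-1.0, 1.0), 22, exposure_multiplier = 1.0,
                    usv_coupling = 0))

fixture_truth_categories <- c(pos = "usv-positive", neg = "usv-negative",
                              soc = "social-interaction-related",
                              nul = "unrelated")

small_cohort <- function(seed, regions = fixture_regions()) {
  suppressWarnings(generate_cohort(cohort_config(unname(regions),
                                                 master_seed = seed)))
}

unit_square <- rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000))

square_landmarks <- function() striatal_landmarks(
  dorsal_edge_left = c(0, 0), dorsal_edge_right = c(1000, 0),
  ac_point = c(500, 1000), nacs_tip = c(0, 1000),
  lateral_boundary = c(1000, 0))

# A synthetic spectrogram whose call-positive frames can be dictated exactly:
# tonal frames carry a narrow 70-kHz line well above the floor, the rest are
# flat noise floor. hop = 0.5 ms.
constructed_spectrogram <- function(positive, hop_ms = 0.5) {
  n_frames <- length(positive)
  freq <- seq(0, 125000, by = 500)
  mag <- matrix(-100, nrow = length(freq), ncol = n_frames)
  k70 <- which.min(abs(freq - 70000))
  mag[k70, positive] <- -30
  structure(list(mag_db = mag, freq_hz = freq,
                 time_s = (seq_len(n_frames) - 1) * hop_ms / 1000,
                 band = freq >= 30000 & freq <= 120000,
                 hop_s = hop_ms / 1000, sample_rate_hz = 250000,
                 params = spectrogram_params()),
            class = "usv_spectrogram")
}

# Two-tone waveform with a configurable gap, for audio-level merge tests.
two_tone_audio <- function(gap_ms, tone_ms = 30, snr_db = 20) {
  calls <- data.frame(
    start_s = c(0.05, 0.05 + tone_ms / 1000 + gap_ms / 1000),
    duration_s = tone_ms / 1000, f_start_khz = 70, f_end_khz = 70,
    amplitude_db = -60 + snr_db)
  generate_usv_audio(usv_audio_spec(calls, noise_floor_db = -60))
}
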