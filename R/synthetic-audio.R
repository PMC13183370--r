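# Synthetic ultrasonic audio: linearly frequency-modulated tones in the
# 30-120 kHz band over a white-noise floor, with a ground-truth event list.

#' Audio specification for synthetic USV recordings
#'
#' @param calls data.frame with columns start_s, duration_s, f_start_khz,
#'   f_end_khz, amplitude_db (dB full scale; the noise floor sets the SNR).
#'   Calls must not overlap in time.
#' @param sample_rate_hz sampling rate (default 250 kHz, an ultrasonic rate
#'   whose Nyquist covers the 30-120 kHz analysis band).
#' @param noise_floor_db white-noise RMS level in dB full scale.
#' @param duration_s total recording length; defaults to the last call end
#'   plus 100 ms.
#' @return object of class `usv_audio_spec`.
#' @export
usv_audio_spec <- function(calls, sample_rate_hz = 250000,
                           noise_floor_db = -60, duration_s = NULL) {
  calls <- as.data.frame(calls)
  need <- c("start_s", "duration_s", "f_start_khz", "f_end_khz", "amplitude_db")
  if (nrow(calls) && !all(need %in% names(calls)))
    stop("calls needs columns: ", paste(need, collapse = ", "))
  if (nrow(calls) > 1) {
    o <- order(calls$start_s)
    calls <- calls[o, ]
    ends <- calls$start_s + calls$duration_s
    if (any(calls$start_s[-1] < ends[-nrow(calls)]))
      stop("calls must be non-overlapping in time")
  }
  if (is.null(duration_s))
    duration_s <- if (nrow(calls)) max(calls$start_s + calls$duration_s) + 0.1 else 0.5
  structure(list(calls = calls, sample_rate_hz = sample_rate_hz,
                 noise_floor_db = noise_floor_db, duration_s = duration_s),
            class = "usv_audio_spec")
}

#' Random non-overlapping call table
#'
#' Convenience builder for detector-evaluation fixtures: `n` tonal calls with
#' uniform durations and linear frequency sweeps inside the ultrasonic band,
#' separated by inter-call gaps large enough that the hold-time rule never
#' merges distinct truth events.
#'
#' @param n number of calls.
#' @param snr_db amplitude above the noise floor, dB.
#' @param noise_floor_db noise floor, dB full scale.
#' @param duration_range_s,gap_range_s call duration and inter-call gap ranges.
#' @param f_range_khz frequency range for the sweep endpoints.
#' @return data.frame suitable for [usv_audio_spec()].
#' @export
random_usv_calls <- function(n, snr_db = 20, noise_floor_db = -60,
                             duration_range_s = c(0.03, 0.08),
                             gap_range_s = c(0.06, 0.15),
                             f_range_khz = c(50, 100)) {
  start <- 0.05
  out <- vector("list", n)
  for (i in seq_len(n)) {
    dur <- stats::runif(1, duration_range_s[1], duration_range_s[2])
    f0 <- stats::runif(1, f_range_khz[1], f_range_khz[2])
    f1 <- pmin(pmax(f0 + stats::runif(1, -15, 15), f_range_khz[1]), f_range_khz[2])
    out[[i]] <- data.frame(start_s = start, duration_s = dur,
                           f_start_khz = f0, f_end_khz = f1,
                           amplitude_db = noise_floor_db + snr_db)
    start <- start + dur + stats::runif(1, gap_range_s[1], gap_range_s[2])
  }
  do.call(rbind, out)
}

#' Synthesize a USV recording
#'
#' Sums linearly frequency-modulated tones and Gaussian white noise at the
#' configured floor. Returns the waveform together with the truth event list
#' used by detector-evaluation tests.
#'
#' @param spec a [usv_audio_spec()].
#' @return list with `waveform` (numeric, full scale 1), `sample_rate_hz`,
#'   and `truth_events` (data.frame start_s, end_s, f_start_khz, f_end_khz).
#' @export
generate_usv_audio <- function(spec) {
  stopifnot(inherits(spec, "usv_audio_spec"))
  sr <- spec$sample_rate_hz
  nyq_khz <- sr / 2000
  if (nrow(spec$calls) &&
      max(spec$calls$f_start_khz, spec$calls$f_end_khz) > nyq_khz)
    stop("call frequency exceeds the Nyquist limit (", nyq_khz, " kHz): aliasing")
  n <- round(spec$duration_s * sr)
  wav <- stats::rnorm(n, 0, 10^(spec$noise_floor_db / 20))
  for (i in seq_len(nrow(spec$calls))) {
    cl <- spec$calls[i, ]
    i0 <- round(cl$start_s * sr) + 1L
    m <- round(cl$duration_s * sr)
    if (m < 1 || i0 + m - 1L > n) stop("call ", i, " extends beyond the recording")
    t <- (seq_len(m) - 1) / sr
    f0 <- cl$f_start_khz * 1000; f1 <- cl$f_end_khz * 1000
    phase <- 2 * pi * (f0 * t + (f1 - f0) * t^2 / (2 * cl$duration_s))
    amp <- 10^(cl$amplitude_db / 20)
    wav[i0:(i0 + m - 1L)] <- wav[i0:(i0 + m - 1L)] + amp * sin(phase)
  }
  truth <- if (nrow(spec$calls))
    data.frame(start_s = spec$calls$start_s,
               end_s = spec$calls$start_s + spec$calls$duration_s,
               f_start_khz = spec$calls$f_start_khz,
               f_end_khz = spec$calls$f_end_khz)
  else data.frame(start_s = numeric(0), end_s = numeric(0),
                  f_start_khz = numeric(0), f_end_khz = numeric(0))
  list(waveform = wav, sample_rate_hz = sr, truth_events = truth)
}
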