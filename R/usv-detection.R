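# USV event segmentation and per-event features.
#
# Pipeline: band-limited STFT (Hann window) -> per-frame call criterion
# (in-band energy above an adaptive floor AND a narrow 50%-energy spectral
# bandwidth, i.e. tonality) -> run merging with a 20-ms hold time (gaps no
# longer than the hold time join adjacent syllable segments into one event)
# -> a 1-ms post-filter discarding shorter events -> per-event peak frequency
# and amplitude at the start, end, and maximum-amplitude frames.

#' Spectrogram parameters
#'
#' @param window_samples STFT window length (Hann); default 512, ~2 ms at
#'   250 kHz.
#' @param overlap_fraction window overlap in [0, 1); default 0.75 (~0.5 ms
#'   hop at 250 kHz, resolving the 1-ms post-filter).
#' @param band_low_khz,band_high_khz analysis band (defaults 30-120 kHz, the
#'   ultrasonic call band; energy outside is zero-weighted).
#' @return object of class `spectrogram_params`.
#' @export
spectrogram_params <- function(window_samples = 512, overlap_fraction = 0.75,
                               band_low_khz = 30, band_high_khz = 120) {
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1)")
  if (band_low_khz >= band_high_khz) stop("band_low_khz must be < band_high_khz")
  structure(list(window_samples = as.integer(window_samples),
                 overlap_fraction = overlap_fraction,
                 band_low_khz = band_low_khz, band_high_khz = band_high_khz),
            class = "spectrogram_params")
}

#' Segmentation parameters
#'
#' @param energy_threshold_db call threshold above the recording's median
#'   in-band frame energy (default 6 dB).
#' @param bandwidth_fraction energy fraction for the spectral-bandwidth
#'   (tonality) criterion (default 0.5).
#' @param hold_time_ms maximum inter-syllable gap merged into one event
#'   (default 20 ms).
#' @param postfilter_ms minimum event duration retained (default 1 ms).
#' @param tonality_khz ceiling on the 50%-energy interval width for a frame to
#'   count as tonal (default 20 kHz).
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(energy_threshold_db = 6, bandwidth_fraction = 0.5,
                                hold_time_ms = 20, postfilter_ms = 1,
                                tonality_khz = 20) {
  if (!(hold_time_ms > postfilter_ms && postfilter_ms > 0))
    stop("need hold_time_ms > postfilter_ms > 0")
  if (bandwidth_fraction <= 0 || bandwidth_fraction >= 1)
    stop("bandwidth_fraction must be in (0, 1)")
  structure(list(energy_threshold_db = energy_threshold_db,
                 bandwidth_fraction = bandwidth_fraction,
                 hold_time_ms = hold_time_ms, postfilter_ms = postfilter_ms,
                 tonality_khz = tonality_khz),
            class = "segmentation_params")
}

#' Compute a band-annotated magnitude spectrogram
#'
#' STFT with a Hann window; magnitudes in dB relative to full scale (a
#' full-scale sinusoid peaks near 0 dB). Frame times are window centers in
#' seconds from recording start.
#'
#' @param waveform numeric samples in [-1, 1].
#' @param sample_rate_hz sampling rate.
#' @param params a [spectrogram_params()].
#' @return object of class `usv_spectrogram`: list with `mag_db`
#'   (frequency x time), `freq_hz`, `time_s`, `band` (logical over bins),
#'   `hop_s`, `sample_rate_hz`, `params`.
#' @export
compute_spectrogram <- function(waveform, sample_rate_hz,
                                params = spectrogram_params()) {
  n <- params$window_samples
  if (length(waveform) < n)
    stop("waveform shorter than one analysis window (", n, " samples)")
  hop <- max(1L, as.integer(round(n * (1 - params$overlap_fraction))))
  sg <- signal::specgram(waveform, n = n, Fs = sample_rate_hz,
                         window = signal::hanning(n), overlap = n - hop)
  # normalize so a full-scale sine reaches ~0 dBFS: |S| peaks at sum(w)/2
  ref <- sum(signal::hanning(n)) / 2
  mag_db <- 20 * log10(abs(sg$S) / ref + 1e-12)
  n_frames <- ncol(mag_db)
  time_s <- (seq_len(n_frames) - 1) * hop / sample_rate_hz + (n - 1) / (2 * sample_rate_hz)
  freq_hz <- as.numeric(sg$f)
  band <- freq_hz >= params$band_low_khz * 1000 & freq_hz <= params$band_high_khz * 1000
  if (!any(band)) stop("analysis band contains no frequency bins")
  structure(list(mag_db = mag_db, freq_hz = freq_hz, time_s = time_s,
                 band = band, hop_s = hop / sample_rate_hz,
                 sample_rate_hz = sample_rate_hz, params = params),
            class = "usv_spectrogram")
}

# In-band frame energy in dB and the 50%-energy bandwidth (Hz) per frame.
frame_band_stats <- function(spec, fraction) {
  P <- (10^(spec$mag_db[spec$band, , drop = FALSE] / 20))^2
  freq <- spec$freq_hz[spec$band]
  df <- if (length(freq) > 1) freq[2] - freq[1] else 1
  e <- colSums(P)
  bw <- vapply(seq_len(ncol(P)), function(j) {
    p <- P[, j]
    tot <- sum(p)
    if (tot <= 0) return(Inf)
    k <- which.max(p)
    lo <- k; hi <- k; acc <- p[k]
    while (acc < fraction * tot) {
      left <- if (lo > 1) p[lo - 1] else -Inf
      right <- if (hi < length(p)) p[hi + 1] else -Inf
      if (left >= right) { lo <- lo - 1; acc <- acc + left }
      else { hi <- hi + 1; acc <- acc + right }
    }
    (hi - lo + 1) * df
  }, 0)
  list(energy_db = 10 * log10(e + 1e-24), bandwidth_hz = bw)
}

#' Merge call-positive runs separated by short gaps
#'
#' Intervals (frame-index runs) whose gap to the previous run is at most the
#' hold time are merged; the operation is idempotent.
#'
#' @param runs data.frame with columns start, end (frame indices, inclusive).
#' @param hold_frames maximum gap, in frames, that still merges two runs.
#' @return merged run data.frame.
#' @export
merge_event_runs <- function(runs, hold_frames) {
  if (!nrow(runs)) return(runs)
  runs <- runs[order(runs$start), , drop = FALSE]
  out <- runs[1, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1]) {
    gap <- runs$start[i] - out$end[nrow(out)] - 1L
    if (gap <= hold_frames) out$end[nrow(out)] <- max(out$end[nrow(out)], runs$end[i])
    else out <- rbind(out, runs[i, ])
  }
  out
}

positive_frames <- function(spec, params) {
  st <- frame_band_stats(spec, params$bandwidth_fraction)
  floor_db <- stats::median(st$energy_db)
  st$energy_db >= floor_db + params$energy_threshold_db &
    st$bandwidth_hz < params$tonality_khz * 1000
}

runs_from_logical <- function(pos) {
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Segment USV events from a spectrogram
#'
#' A frame is call-positive iff its in-band energy exceeds the recording's
#' median in-band energy by `energy_threshold_db` and the minimal contiguous
#' frequency interval around the spectral peak holding `bandwidth_fraction` of
#' the frame's in-band energy is narrower than `tonality_khz`. Positive runs
#' separated by gaps of at most `hold_time_ms` are merged; merged runs shorter
#' than `postfilter_ms` are discarded.
#'
#' @param spec a [compute_spectrogram()] result.
#' @param params a [segmentation_params()].
#' @return data.frame of class `usv_events` with columns start_s, end_s,
#'   duration_ms, start_frame, end_frame (time-ordered, non-overlapping);
#'   zero rows when nothing is detected.
#' @export
segment_events <- function(spec, params = segmentation_params()) {
  stopifnot(inherits(spec, "usv_spectrogram"))
  pos <- positive_frames(spec, params)
  runs <- runs_from_logical(pos)
  hold_frames <- floor(params$hold_time_ms / 1000 / spec$hop_s + 1e-9)
  runs <- merge_event_runs(runs, hold_frames)
  if (nrow(runs)) {
    dur_s <- (runs$end - runs$start + 1L) * spec$hop_s
    keep <- dur_s >= params$postfilter_ms / 1000
    runs <- runs[keep, , drop = FALSE]
    dur_s <- dur_s[keep]
  } else dur_s <- numeric(0)
  out <- data.frame(start_s = spec$time_s[runs$start],
                    end_s = spec$time_s[runs$end],
                    duration_ms = dur_s * 1000,
                    start_frame = runs$start, end_frame = runs$end)
  rownames(out) <- NULL
  class(out) <- c("usv_events", "data.frame")
  out
}

#' Extract per-event peak frequency and amplitude features
#'
#' For each event: the start frame, end frame, and maximum-amplitude frame are
#' the three loci; per locus, peak frequency is the argmax-magnitude in-band
#' bin and peak amplitude is that magnitude in dB.
#'
#' @param events a [segment_events()] result.
#' @param spec the spectrogram the events came from.
#' @return `events` with added columns pf_start_khz, pf_end_khz, pf_max_khz,
#'   amp_start_db, amp_end_db, amp_max_db.
#' @export
extract_features <- function(events, spec) {
  stopifnot(inherits(spec, "usv_spectrogram"))
  n_frames <- ncol(spec$mag_db)
  if (nrow(events) && (min(events$start_frame) < 1 || max(events$end_frame) > n_frames))
    stop("event extends outside the spectrogram")
  M <- spec$mag_db[spec$band, , drop = FALSE]
  freq_khz <- spec$freq_hz[spec$band] / 1000
  locus <- function(frame) {
    k <- which.max(M[, frame])
    c(freq = freq_khz[k], amp = M[k, frame])
  }
  feats <- lapply(seq_len(nrow(events)), function(i) {
    fr <- events$start_frame[i]:events$end_frame[i]
    peak_amp <- vapply(fr, function(j) max(M[, j]), 0)
    f_max <- fr[which.max(peak_amp)]
    s <- locus(events$start_frame[i]); e <- locus(events$end_frame[i])
    m <- locus(f_max)
    c(pf_start_khz = unname(s["freq"]), pf_end_khz = unname(e["freq"]),
      pf_max_khz = unname(m["freq"]), amp_start_db = unname(s["amp"]),
      amp_end_db = unname(e["amp"]), amp_max_db = unname(m["amp"]))
  })
  cbind(events, as.data.frame(do.call(rbind, feats)))
}

#' Per-session event summary
#'
#' @param events a `usv_events` data.frame.
#' @return list with `n_events` and `total_vocal_time_s`.
#' @export
count_events <- function(events) {
  list(n_events = nrow(events),
       total_vocal_time_s = if (nrow(events)) sum(events$duration_ms) / 1000 else 0)
}

#' Detect USV events in a waveform
#'
#' Convenience wrapper: spectrogram, segmentation, and feature extraction.
#'
#' @param waveform,sample_rate_hz audio samples and rate.
#' @param spec_params,seg_params parameter objects.
#' @return `usv_events` data.frame with features.
#' @export
detect_usv_events <- function(waveform, sample_rate_hz,
                              spec_params = spectrogram_params(),
                              seg_params = segmentation_params()) {
  sg <- compute_spectrogram(waveform, sample_rate_hz, spec_params)
  extract_features(segment_events(sg, seg_params), sg)
}

#' @export
print.usv_events <- function(x, ...) {
  cat("USV events:", nrow(x), "\n")
  if (nrow(x)) {
    cat("  total vocal time:", round(sum(x$duration_ms) / 1000, 3), "s\n")
    print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
    if (nrow(x) > 10) cat("  ...\n")
  }
  invisible(x)
}
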