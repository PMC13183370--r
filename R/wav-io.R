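# Minimal PCM WAV reader/writer (16- or 32-bit integer, mono or first channel).
# Ultrasonic recordings are plain RIFF/WAVE PCM; only the canonical chunks are
# handled.

#' Read a PCM WAV file
#'
#' @param path file path.
#' @return list with `samples` (numeric in [-1, 1]), `sample_rate_hz`,
#'   `bits_per_sample`, `n_channels`. Multi-channel files return channel 1.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, size = 2, endian = "little"),
        n_channels   = readBin(con, "integer", 1, size = 2, endian = "little"),
        sample_rate  = readBin(con, "integer", 1, size = 4, endian = "little"),
        byte_rate    = readBin(con, "integer", 1, size = 4, endian = "little"),
        block_align  = readBin(con, "integer", 1, size = 2, endian = "little"),
        bits         = readBin(con, "integer", 1, size = 2, endian = "little"))
      if (sz > 16) invisible(readBin(con, "raw", sz - 16))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt/data chunk in ", path)
  if (fmt$audio_format != 1) stop("only PCM (format 1) WAV is supported")
  size <- fmt$bits / 8
  vals <- readBin(data_raw, "integer", n = length(data_raw) / size,
                  size = size, signed = TRUE, endian = "little")
  if (fmt$n_channels > 1) vals <- vals[seq(1, length(vals), by = fmt$n_channels)]
  list(samples = vals / (2^(fmt$bits - 1)),
       sample_rate_hz = fmt$sample_rate,
       bits_per_sample = fmt$bits,
       n_channels = fmt$n_channels)
}

#' Write a mono PCM WAV file
#'
#' @param samples numeric vector in [-1, 1]; values outside are clipped.
#' @param sample_rate_hz sampling rate in Hz.
#' @param path output path.
#' @param bits 16 or 32.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate_hz, path, bits = 16) {
  if (!bits %in% c(16, 32)) stop("bits must be 16 or 32")
  size <- bits / 8
  x <- pmin(pmax(samples, -1), 1)
  ints <- as.integer(round(x * (2^(bits - 1) - 1)))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- length(ints) * size
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(sample_rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate_hz * size), con, size = 4, endian = "little")
  writeBin(as.integer(size), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(ints, con, size = size, endian = "little")
  invisible(path)
}
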