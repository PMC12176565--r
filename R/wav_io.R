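#' Read a mono RIFF PCM WAV file
#'
#' Minimal reader for 16-bit PCM mono WAV. Amplitudes are scaled by the PCM
#' full-scale value (32768 for 16-bit), preserving relative loudness across
#' recordings, so values lie in \[-1, 1).
#'
#' @param path path to a `.wav` file
#' @return list with `samples` (numeric) and `sampling_rate` (Hz)
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", size)
      audio_format <- readBin(raw_fmt[1:2], "integer", 1, 2, endian = "little")
      n_channels <- readBin(raw_fmt[3:4], "integer", 1, 2, endian = "little")
      sample_rate <- readBin(raw_fmt[5:8], "integer", 1, 4, endian = "little")
      bits <- readBin(raw_fmt[15:16], "integer", 1, 2, endian = "little")
      if (audio_format != 1L) stop("only PCM WAV supported: ", path)
      if (n_channels != 1L) stop("stereo input rejected (mono required): ", path)
      if (bits != 16L) stop("only 16-bit PCM supported: ", path)
      fmt <- list(rate = sample_rate, bits = bits)
    } else if (identical(id, "data")) {
      n <- size %/% 2L
      ints <- readBin(con, "integer", n, 2, signed = TRUE, endian = "little")
      samples <- ints / 32768
      if (size %% 2L == 1L) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
    if (!is.null(fmt) && !is.null(samples)) break
  }
  if (is.null(fmt) || is.null(samples)) stop("malformed WAV (missing fmt/data chunk): ", path)
  list(samples = samples, sampling_rate = fmt$rate)
}

#' Write a mono 16-bit PCM WAV file
#'
#' Values outside \[-1, 1) are clamped to the 16-bit range. `read_wav()`
#' recovers the quantized samples bitwise.
#'
#' @param samples numeric vector in \[-1, 1)
#' @param sampling_rate sampling rate in Hz
#' @param path output path
#' @return `path`, invisibly
#' @export
write_wav <- function(samples, sampling_rate, path) {
  ints <- as.integer(pmax(pmin(round(samples * 32768), 32767), -32768))
  n_bytes <- length(ints) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + n_bytes, con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")                    # PCM
  writeBin(1L, con, 2, endian = "little")                    # mono
  writeBin(as.integer(sampling_rate), con, 4, endian = "little")
  writeBin(as.integer(sampling_rate) * 2L, con, 4, endian = "little")  # byte rate
  writeBin(2L, con, 2, endian = "little")                    # block align
  writeBin(16L, con, 2, endian = "little")                   # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, 4, endian = "little")
  writeBin(ints, con, 2, endian = "little")
  invisible(path)
}
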