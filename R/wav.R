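# Minimal PCM WAV reader/writer. Only uncompressed integer PCM (16/24-bit,
# plus 8-bit for completeness) is supported, which covers the clinical voice
# recordings this package targets.

read_wav_raw <- function(path) {
  if (!file.exists(path)) abort_io("cannot read WAV file '%s': no such file", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort_io("'%s' is not a RIFF/WAV file", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) abort_io("'%s' is not a WAVE file", path)

  fmt <- NULL
  data_bytes <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, size = 2, endian = "little", signed = FALSE),
        n_channels   = readBin(fmt_raw[3:4], "integer", 1, size = 2, endian = "little", signed = FALSE),
        sample_rate  = readBin(fmt_raw[5:8], "integer", 1, size = 4, endian = "little"),
        bits         = readBin(fmt_raw[15:16], "integer", 1, size = 2, endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      data_bytes <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + (size %% 2L)))
      next
    }
    if (size %% 2L == 1L) invisible(readBin(con, "raw", 1))
    if (!is.null(fmt) && !is.null(data_bytes)) break
  }
  if (is.null(fmt) || is.null(data_bytes)) {
    abort_io("corrupt WAV file '%s': missing fmt or data chunk", path)
  }
  if (fmt$audio_format != 1L) {
    abort_io("'%s': only uncompressed PCM WAV is supported (format tag %d)",
             path, fmt$audio_format)
  }

  x <- switch(as.character(fmt$bits),
    "8"  = (as.numeric(readBin(data_bytes, "integer", length(data_bytes),
                               size = 1, signed = FALSE)) - 128) / 128,
    "16" = as.numeric(readBin(data_bytes, "integer", length(data_bytes) %/% 2L,
                              size = 2, endian = "little")) / 32768,
    "24" = {
      n <- length(data_bytes) %/% 3L
      b <- matrix(as.integer(data_bytes[seq_len(3L * n)]), nrow = 3L)
      v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
      v[v >= 8388608] <- v[v >= 8388608] - 16777216
      v / 8388608
    },
    abort_io("'%s': unsupported PCM bit depth %d", path, fmt$bits)
  )
  if (length(x) == 0) abort_io("'%s': zero-length audio data", path)
  nch <- fmt$n_channels
  if (nch > 1L) x <- matrix(x, nrow = nch)  # interleaved -> channels x frames
  list(samples = x, sample_rate = fmt$sample_rate, n_channels = nch, bits = fmt$bits)
}

#' Write a waveform to a 16-bit PCM WAV file
#'
#' @param samples numeric vector (mono) or channels-by-frames matrix, in
#'   \[-1, 1\]; values outside are clipped.
#' @param sample_rate sampling rate in Hz.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  if (is.matrix(samples)) {
    nch <- nrow(samples)
    interleaved <- as.numeric(samples)
  } else {
    nch <- 1L
    interleaved <- as.numeric(samples)
  }
  assert_that(length(interleaved) > 0, "cannot write empty waveform")
  pcm <- as.integer(round(pmin(pmax(interleaved, -1), 32767 / 32768) * 32768))
  data_size <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                 # PCM
  writeBin(as.integer(nch), con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * nch * 2L), con, size = 4, endian = "little")
  writeBin(as.integer(nch * 2L), con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

# Linear-interpolation resampler; adequate for the feature pipeline at the
# default 22050 Hz target (no audio DSP package is available).
resample_linear <- function(x, from_rate, to_rate) {
  if (from_rate == to_rate) return(x)
  n_out <- max(1L, round(length(x) * to_rate / from_rate))
  t_out <- (seq_len(n_out) - 1) / to_rate
  t_in <- (seq_along(x) - 1) / from_rate
  stats::approx(t_in, x, xout = pmin(t_out, t_in[length(t_in)]), rule = 2)$y
}
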