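# Short-time spectral analysis primitives: STFT, mel filterbanks under the
# two standard mel-scale conventions, DCT-II, chroma mappings and the tonal
# centroid (tonnetz) projection. Everything is built on stats::fft; no audio
# DSP package is available in the target environment.

EPS_FLOOR <- 1e-10  # added before any logarithm / denominator

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))

# Frame a signal into columns (no padding). start step = hop.
frame_signal <- function(x, frame_length, hop) {
  n_frames <- 1L + (length(x) - frame_length) %/% hop
  idx <- outer(seq_len(frame_length), (seq_len(n_frames) - 1L) * hop, `+`)
  matrix(x[idx], nrow = frame_length)
}

# Magnitude STFT with reflect-padded centred frames, Hann window.
# Rows: n_fft/2 + 1 frequency bins; columns: frames.
stft_magnitude <- function(x, n_fft = 2048, hop = 512, center = TRUE) {
  assert_that(length(x) >= n_fft,
              "segment shorter than one analysis frame (%d samples < n_fft = %d)",
              length(x), n_fft)
  if (center) {
    pad <- n_fft %/% 2L
    x <- c(rev(x[2:(pad + 1L)]), x, rev(x[(length(x) - pad):(length(x) - 1L)]))
  }
  frames <- frame_signal(x, n_fft, hop) * hann_window(n_fft)
  spec <- stats::mvfft(frames)
  Mod(spec[seq_len(n_fft %/% 2L + 1L), , drop = FALSE])
}

fft_bin_freqs <- function(n_fft, sample_rate) {
  (0:(n_fft %/% 2L)) * sample_rate / n_fft
}

# Mel scale conversions -------------------------------------------------------

hz_to_mel <- function(f, htk = FALSE) {
  if (htk) return(2595 * log10(1 + f / 700))
  # Slaney / Auditory Toolbox: linear below 1 kHz, log above
  f_sp <- 200 / 3
  min_log_hz <- 1000
  logstep <- log(6.4) / 27
  m <- f / f_sp
  hi <- f >= min_log_hz
  m[hi] <- min_log_hz / f_sp + log(f[hi] / min_log_hz) / logstep
  m
}

mel_to_hz <- function(m, htk = FALSE) {
  if (htk) return(700 * (10^(m / 2595) - 1))
  f_sp <- 200 / 3
  min_log_hz <- 1000
  logstep <- log(6.4) / 27
  f <- m * f_sp
  min_log_mel <- min_log_hz / f_sp
  hi <- m >= min_log_mel
  f[hi] <- min_log_hz * exp(logstep * (m[hi] - min_log_mel))
  f
}

# Triangular mel filterbank (n_mels x n_bins), area-normalized.
mel_filterbank <- function(sample_rate, n_fft, n_mels = 128, fmin = 0,
                           fmax = sample_rate / 2, htk = FALSE) {
  mel_pts <- seq(hz_to_mel(fmin, htk), hz_to_mel(fmax, htk), length.out = n_mels + 2L)
  hz_pts <- mel_to_hz(mel_pts, htk)
  freqs <- fft_bin_freqs(n_fft, sample_rate)
  fb <- matrix(0, nrow = n_mels, ncol = length(freqs))
  for (m in seq_len(n_mels)) {
    lower <- hz_pts[m]; centre <- hz_pts[m + 1L]; upper <- hz_pts[m + 2L]
    up <- (freqs - lower) / max(centre - lower, EPS_FLOOR)
    down <- (upper - freqs) / max(upper - centre, EPS_FLOOR)
    fb[m, ] <- pmax(0, pmin(up, down)) * 2 / (upper - lower)  # area norm
  }
  fb
}

# Orthonormal DCT-II matrix (n_out x n_in).
dct_matrix <- function(n_out, n_in) {
  n <- seq_len(n_in) - 1
  mat <- t(sapply(seq_len(n_out) - 1, function(k) cos(pi * (n + 0.5) * k / n_in)))
  mat <- mat * sqrt(2 / n_in)
  mat[1, ] <- mat[1, ] / sqrt(2)
  mat
}

power_to_db <- function(p) 10 * log10(p + EPS_FLOOR)

# Chroma ---------------------------------------------------------------------

# Pitch-class assignment of FFT bins. soft = Gaussian weighting (sigma in
# semitones) across neighbouring classes; hard = nearest class.
chroma_map <- function(n_fft, sample_rate, soft = FALSE, sigma = 1) {
  freqs <- fft_bin_freqs(n_fft, sample_rate)
  keep <- freqs > 0
  pitch <- 69 + 12 * log2(freqs[keep] / 440)
  mapm <- matrix(0, nrow = 12, ncol = length(freqs))
  if (soft) {
    for (cls in 0:11) {
      d <- (pitch - cls) %% 12
      d <- pmin(d, 12 - d)
      mapm[cls + 1L, keep] <- exp(-0.5 * (d / sigma)^2)
    }
  } else {
    cls <- as.integer(round(pitch)) %% 12L
    for (j in seq_along(cls)) mapm[cls[j] + 1L, which(keep)[j]] <- 1
  }
  mapm
}

normalize_cols <- function(m, type = c("max", "l1", "l2")) {
  type <- match.arg(type)
  den <- switch(type,
    max = apply(abs(m), 2, max),
    l1 = colSums(abs(m)),
    l2 = sqrt(colSums(m^2)))
  sweep(m, 2, pmax(den, EPS_FLOOR), "/")
}

# Log-frequency (constant-Q-like) chroma: power folded into semitone bands
# from C1 upward, then into 12 pitch classes.
chroma_logfreq <- function(S_pow, n_fft, sample_rate) {
  freqs <- fft_bin_freqs(n_fft, sample_rate)
  f0 <- 440 * 2^((24 - 69) / 12)  # C1 ~ 32.7 Hz
  n_bins <- 12 * 7                # 7 octaves
  chroma <- matrix(0, nrow = 12, ncol = ncol(S_pow))
  pitch_bin <- round(12 * log2(pmax(freqs, EPS_FLOOR) / f0))
  for (b in seq_len(n_bins) - 1L) {
    sel <- which(pitch_bin == b & freqs > 0)
    if (length(sel)) {
      chroma[(b %% 12L) + 1L, ] <- chroma[(b %% 12L) + 1L, ] +
        colSums(S_pow[sel, , drop = FALSE])
    }
  }
  chroma
}

# CENS-style smoothing: l1-normalize, quantize, average over a time window,
# l2-normalize.
chroma_cens_from <- function(chroma, win = 9L) {
  c1 <- normalize_cols(chroma, "l1")
  q <- matrix(0, nrow = nrow(c1), ncol = ncol(c1))
  steps <- c(0.05, 0.1, 0.2, 0.4)
  for (s in steps) q <- q + (c1 > s)
  q <- q / length(steps)
  if (ncol(q) > 1) {
    k <- min(win, ncol(q))
    kernel <- rep(1 / k, k)
    q <- t(apply(q, 1, function(r) stats::filter(r, kernel, sides = 2)))
    q[is.na(q)] <- 0
  }
  normalize_cols(q, "l2")
}

# Tonal centroid (tonnetz) projection matrix: 6 x 12.
tonnetz_basis <- function() {
  j <- 0:11
  rbind(
    sin(j * 7 * pi / 6), cos(j * 7 * pi / 6),        # circle of fifths
    sin(j * 3 * pi / 2), cos(j * 3 * pi / 2),        # minor thirds
    0.5 * sin(j * 2 * pi / 3), 0.5 * cos(j * 2 * pi / 3)  # major thirds
  )
}
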