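# The 281-column acoustic feature schema and its per-segment extraction.
#
# Sixteen techniques produce per-frame matrices; each coefficient/band is
# aggregated across frames (default: mean) to a single number, giving one
# fixed-width row per voice segment.

#' Default acoustic feature schema (281 columns)
#'
#' Ordered blocks: MFCC-Slaney 40, MFCC-HTK 40, mel-spectrogram 128, four
#' chroma variants of 12 each, RMSE 1, spectral contrast 7, flatness /
#' centroid / bandwidth / roll-off 1 each, ZCR 1, and two tonnetz variants of
#' 6 each.
#'
#' @return a `feature_schema` object with `blocks` (data frame of
#'   `block`, `technique`, `width`) and `total`.
#' @export
default_feature_schema <- function() {
  blocks <- data.frame(
    block = c("mfcc_slaney", "mfcc_htk", "melspec",
              "chroma", "chroma_stft", "chroma_cqt", "chroma_cens",
              "rmse", "spec_contrast", "spec_flatness", "spec_centroid",
              "spec_bandwidth", "spec_rolloff", "zcr",
              "tonnetz_normal", "tonnetz_harmonic"),
    technique = c("mfcc-slaney", "mfcc-htk", "mel-spectrogram",
                  "chroma-only", "chroma-stft", "chroma-cqt", "chroma-cens",
                  "rmse", "spectral-contrast", "spectral-flatness",
                  "spectral-centroid", "spectral-bandwidth",
                  "spectral-rolloff", "zcr", "tonnetz-normal",
                  "tonnetz-harmonic"),
    width = c(40L, 40L, 128L, 12L, 12L, 12L, 12L, 1L, 7L, 1L, 1L, 1L, 1L, 1L,
              6L, 6L),
    stringsAsFactors = FALSE
  )
  feature_schema(blocks)
}

#' Construct a feature schema from a block table
#' @param blocks data frame with columns `block`, `technique`, `width`.
#' @export
feature_schema <- function(blocks) {
  assert_that(all(blocks$width > 0), "schema block widths must be positive")
  structure(list(blocks = blocks, total = sum(blocks$width)),
            class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  cat(sprintf("<feature_schema> %d blocks, %d columns\n", nrow(x$blocks), x$total))
  invisible(x)
}

#' Column names of a feature schema
#' @param schema a `feature_schema`.
#' @export
schema_colnames <- function(schema) {
  unlist(lapply(seq_len(nrow(schema$blocks)), function(i) {
    b <- schema$blocks[i, ]
    w <- b$width
    digits <- nchar(as.character(w - 1L))
    sprintf("%s.%0*d", b$block, digits, seq_len(w) - 1L)
  }), use.names = FALSE)
}

# Per-technique frame matrices ------------------------------------------------

frame_zcr <- function(x, frame_length, hop) {
  if (length(x) < frame_length) return(matrix(0, 1, 1))
  fr <- frame_signal(x, frame_length, hop)
  sign_change <- abs(diff(sign(fr))) > 0
  matrix(colMeans(sign_change), nrow = 1)
}

frame_rms <- function(x, frame_length, hop) {
  fr <- frame_signal(x, frame_length, hop)
  matrix(sqrt(colMeans(fr^2)), nrow = 1)
}

spectral_contrast <- function(S_mag, sample_rate, n_fft, n_bands = 6L,
                              fmin = 200, quantile_frac = 0.02) {
  freqs <- fft_bin_freqs(n_fft, sample_rate)
  edges <- c(0, fmin * 2^(0:n_bands))
  out <- matrix(0, nrow = n_bands + 1L, ncol = ncol(S_mag))
  for (b in seq_len(n_bands + 1L)) {
    sel <- which(freqs >= edges[b] & freqs < min(edges[b + 1L], sample_rate / 2 + 1))
    if (!length(sel)) next
    sub <- S_mag[sel, , drop = FALSE]^2
    k <- max(1L, round(quantile_frac * length(sel)))
    for (j in seq_len(ncol(sub))) {
      v <- sort(sub[, j])
      valley <- mean(v[seq_len(k)])
      peak <- mean(v[(length(v) - k + 1L):length(v)])
      out[b, j] <- power_to_db(peak) - power_to_db(valley)
    }
  }
  out
}

#' Extract the numeric feature vector of one segment
#'
#' @param segment an `audio_segment` (or `audio_record`).
#' @param schema a `feature_schema`; default [default_feature_schema()].
#' @param frame_length,hop STFT frame and hop sizes in samples.
#' @param aggregate frame aggregation function (default `mean`), applied per
#'   coefficient/band across frames.
#' @return named numeric vector of length `schema$total`, all finite.
#' @export
extract_numeric_features <- function(segment, schema = default_feature_schema(),
                                     frame_length = 2048, hop = 512,
                                     aggregate = mean) {
  x <- segment$samples
  sr <- segment$sample_rate
  assert_that(length(x) > 0, "empty segment")
  if (all(x == 0)) x <- x + EPS_FLOOR   # epsilon amplitude floor for silence

  S <- stft_magnitude(x, n_fft = frame_length, hop = hop)
  S_pow <- S^2
  freqs <- fft_bin_freqs(frame_length, sr)

  agg <- function(m) apply(m, 1, aggregate)

  mel_s <- mel_filterbank(sr, frame_length, n_mels = 128, htk = FALSE) %*% S_pow
  mel_h <- mel_filterbank(sr, frame_length, n_mels = 128, htk = TRUE) %*% S_pow
  dct40 <- dct_matrix(40, 128)
  mfcc_slaney <- dct40 %*% power_to_db(mel_s)
  mfcc_htk <- dct40 %*% power_to_db(mel_h)

  chroma_hard <- normalize_cols(chroma_map(frame_length, sr, soft = FALSE) %*% S_pow, "max")
  chroma_soft <- normalize_cols(chroma_map(frame_length, sr, soft = TRUE) %*% S_pow, "l2")
  chroma_cq <- chroma_logfreq(S_pow, frame_length, sr)
  chroma_cq_n <- normalize_cols(chroma_cq, "max")
  chroma_cens <- chroma_cens_from(chroma_cq)

  col_energy <- colSums(S_pow) + EPS_FLOOR
  centroid <- colSums(S_pow * freqs) / col_energy
  bandwidth <- sqrt(colSums(S_pow * (outer(freqs, centroid, `-`))^2 ) / col_energy)
  flatness <- exp(colMeans(log(S_pow + EPS_FLOOR))) / (colMeans(S_pow) + EPS_FLOOR)
  cum_energy <- apply(S_pow, 2, cumsum)
  rolloff <- freqs[apply(cum_energy >= 0.85 * rep(colSums(S_pow), each = nrow(S_pow)),
                         2, which.max)]

  ton_basis <- tonnetz_basis()
  ton_normal <- ton_basis %*% normalize_cols(chroma_cq, "l1")
  # harmonic variant: time-median smoothing of the chroma emphasises sustained
  # (harmonic) content before projection
  chroma_sm <- if (ncol(chroma_cq) >= 3) {
    t(apply(chroma_cq, 1, stats::runmed, k = min(9L, ncol(chroma_cq) - (1 - ncol(chroma_cq) %% 2))))
  } else chroma_cq
  ton_harm <- ton_basis %*% normalize_cols(chroma_sm, "l1")

  values <- c(
    agg(mfcc_slaney), agg(mfcc_htk), agg(mel_s),
    agg(chroma_hard), agg(chroma_soft), agg(chroma_cq_n), agg(chroma_cens),
    aggregate(as.numeric(frame_rms(x, frame_length, hop))),
    agg(spectral_contrast(S, sr, frame_length)),
    aggregate(flatness), aggregate(centroid), aggregate(bandwidth),
    aggregate(rolloff),
    aggregate(as.numeric(frame_zcr(x, frame_length, hop))),
    agg(ton_normal), agg(ton_harm)
  )
  values[!is.finite(values)] <- 0
  names(values) <- schema_colnames(schema)
  assert_that(length(values) == schema$total,
              "feature vector length %d != schema total %d", length(values), schema$total)
  values
}

#' Build a per-segment feature table
#'
#' One row per segment (ordered by record then index), one column per schema
#' entry, plus `record_id`, `segment_index`, `duration_s`, `label`.
#'
#' @param segments list of `audio_segment` objects sharing one sample rate.
#' @param schema a `feature_schema`.
#' @param duration_tag tag stored on the table (a duration or `"combined"`).
#' @param ... passed to [extract_numeric_features()].
#' @return a `feature_table`: data frame with attribute `schema`.
#' @export
build_feature_table <- function(segments, schema = default_feature_schema(),
                                duration_tag = NA, ...) {
  if (length(segments) == 0) {
    df <- as.data.frame(matrix(numeric(0), 0, schema$total))
    names(df) <- schema_colnames(schema)
    df <- cbind(data.frame(record_id = character(0), segment_index = integer(0),
                           duration_s = numeric(0), label = character(0)), df)
    attr(df, "schema") <- schema
    attr(df, "duration_tag") <- duration_tag
    class(df) <- c("feature_table", class(df))
    return(df)
  }
  rates <- unique(vapply(segments, `[[`, 0, "sample_rate"))
  assert_that(length(rates) == 1, "segments have mixed sample rates: %s",
              paste(rates, collapse = ", "))
  ord <- order(vapply(segments, `[[`, "", "parent_id"),
               vapply(segments, `[[`, 0L, "index"))
  segments <- segments[ord]
  mat <- t(vapply(segments, extract_numeric_features, numeric(schema$total),
                  schema = schema, ...))
  df <- data.frame(
    record_id = vapply(segments, `[[`, "", "parent_id"),
    segment_index = vapply(segments, `[[`, 0L, "index"),
    duration_s = vapply(segments, `[[`, 0, "duration_s"),
    label = vapply(segments, `[[`, "", "label"),
    stringsAsFactors = FALSE
  )
  df <- cbind(df, as.data.frame(mat))
  attr(df, "schema") <- schema
  attr(df, "duration_tag") <- duration_tag
  class(df) <- c("feature_table", class(df))
  df
}

#' Numeric feature matrix and labels of a feature table
#' @param table a `feature_table`.
#' @return list with `x` (matrix) and `y` (character labels).
#' @export
feature_matrix <- function(table) {
  meta <- c("record_id", "segment_index", "duration_s", "label")
  x <- as.matrix(table[, setdiff(names(table), meta), drop = FALSE])
  list(x = x, y = table$label)
}

#' Write a feature table as CSV
#' @param table a `feature_table`.
#' @param path output path.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table CSV written by [write_feature_table()]
#' @param path CSV path.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  class(df) <- c("feature_table", class(df))
  df
}
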