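# The 281-column feature schema, extraction and graph rendering.

tone_segment <- function(freq = 1000, duration = 2, rate = 22050) {
  rec <- make_synthetic_audio(duration, rate = rate,
                              profile = voice_profile(freqs = freq, amps = 1,
                                                      noise_sd = 0),
                              seed = 123)
  segment_record(rec, duration)[[1]]
}

test_that("default schema matches the published block layout (total 281)", {
  sch <- default_feature_schema()
  expect_equal(sch$total, 281)
  w <- setNames(sch$blocks$width, sch$blocks$block)
  expect_equal(w[["mfcc_slaney"]], 40)
  expect_equal(w[["mfcc_htk"]], 40)
  expect_equal(w[["melspec"]], 128)
  chroma_blocks <- c("chroma", "chroma_stft", "chroma_cqt", "chroma_cens")
  expect_true(all(w[chroma_blocks] == 12))
  expect_equal(sum(w[chroma_blocks]), 48)
  expect_equal(w[["spec_contrast"]], 7)
  expect_true(all(w[c("rmse", "spec_flatness", "spec_centroid",
                      "spec_bandwidth", "spec_rolloff", "zcr")] == 1))
  expect_true(all(w[c("tonnetz_normal", "tonnetz_harmonic")] == 6))
  expect_length(schema_colnames(sch), 281)
})

test_that("any valid segment yields a finite vector of schema length", {
  seg <- tone_segment(440, duration = 1, rate = 8000)
  fv <- extract_numeric_features(seg)
  expect_length(fv, 281)
  expect_true(all(is.finite(fv)))
  # deterministic for fixed input
  expect_identical(fv, extract_numeric_features(seg))
})

test_that("silence is handled by the epsilon floor and gives zero ZCR", {
  rec <- audio_record(rep(0, 8000), 8000, record_id = "silent")
  seg <- segment_record(rec, 1)[[1]]
  fv <- extract_numeric_features(seg)
  expect_true(all(is.finite(fv)))
  expect_equal(unname(fv["zcr.0"]), 0)
})

test_that("segments shorter than one analysis frame are rejected", {
  rec <- audio_record(rnorm(1000), 8000)
  seg <- segment_record(rec, 0.1)[[1]]
  expect_error(extract_numeric_features(seg), "shorter than one analysis frame")
})

test_that("spectral centroid of a 1 kHz tone is within 5% of 1 kHz", {
  seg <- tone_segment(1000, duration = 2, rate = 22050)
  fv <- extract_numeric_features(seg)
  expect_lt(abs(fv[["spec_centroid.0"]] - 1000) / 1000, 0.05)
  # independent oracle: centroid of the raw periodogram
  x <- seg$samples
  P <- Mod(fft(x))[1:(length(x) %/% 2)]^2
  f <- (seq_along(P) - 1) * seg$sample_rate / length(x)
  oracle <- sum(f * P) / sum(P)
  expect_lt(abs(fv[["spec_centroid.0"]] - oracle) / oracle, 0.05)
})

test_that("mean aggregation is invariant to duplicating the segment", {
  seg <- tone_segment(700, duration = 1, rate = 8000)
  doubled <- seg
  doubled$samples <- c(seg$samples, seg$samples)
  doubled$duration_s <- 2 * seg$duration_s
  a <- extract_numeric_features(seg)
  b <- extract_numeric_features(doubled)
  # spectral summaries agree closely; allow edge-frame effects
  keys <- c("spec_centroid.0", "spec_rolloff.0", "zcr.0", "rmse.0")
  for (k in keys) {
    expect_equal(b[[k]], a[[k]], tolerance = 0.05, label = k)
  }
})

test_that("feature tables conserve rows, order and labels", {
  cohort <- make_cohort(n_per_class = 1, duration_s = 10, rate = 4000)
  sets <- build_segment_sets(cohort, durations = c(4, 7))
  tbl <- build_feature_table(sets$combined)
  expect_s3_class(tbl, "feature_table")
  expect_equal(nrow(tbl), length(sets$combined))
  expect_equal(ncol(tbl), 281 + 4)
  expect_setequal(unique(tbl$label), c("HC", "PD"))
  # ordered by record then index
  expect_true(!is.unsorted(order(tbl$record_id, tbl$segment_index)))

  empty <- build_feature_table(list())
  expect_equal(nrow(empty), 0)
  expect_equal(ncol(empty), 281 + 4)

  mixed <- sets$combined
  mixed[[1]]$sample_rate <- 999
  expect_error(build_feature_table(mixed), "mixed sample rates")
})

test_that("feature tables round-trip through CSV", {
  seg <- tone_segment(500, 1, 8000)
  tbl <- build_feature_table(list(seg))
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tbl, f)
  back <- read_feature_table(f)
  expect_equal(nrow(back), 1)
  expect_equal(back[["spec_centroid.0"]], tbl[["spec_centroid.0"]], tolerance = 1e-8)
})

test_that("graph rendering honours the shape contract and is deterministic", {
  seg <- tone_segment(800, 1, 8000)
  for (tech in c("specgram", "mel-specgram", "stft", "mfcc-slaney", "mfcc-htk")) {
    g <- render_graph(seg, tech, out_size = c(100, 100))
    expect_equal(dim(g$pixels), c(100, 100, 3), label = tech)
    expect_true(all(g$pixels >= 0 & g$pixels <= 255), label = tech)
  }
  g1 <- render_graph(seg, "mel-specgram")
  g2 <- render_graph(seg, "mel-specgram")
  expect_identical(g1$pixels, g2$pixels)
  expect_error(render_graph(seg, "wavelet"), "valid")
})

test_that("a pure tone's brightest mel band matches the filterbank mapping", {
  seg <- tone_segment(1000, 2, 22050)
  m <- pdscreen:::graph_matrix(seg, "mel-specgram")
  observed_band <- which.max(rowMeans(m))
  # oracle: the mel filter with the largest weight at the tone's FFT bin
  fb <- pdscreen:::mel_filterbank(22050, 2048, 128)
  bin <- round(1000 / (22050 / 2048)) + 1
  expect_equal(observed_band, which.max(fb[, bin]), tolerance = 1)
})
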