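# Voice record containers and multi-duration segmentation.
#
# A record is cut into non-overlapping fixed-duration windows; the trailing
# remainder shorter than the window is discarded (never padded). Cutting the
# same cohort at several durations and pooling the pieces is the
# diversity-increasing trick the rest of the pipeline builds on.

#' Construct an audio record
#'
#' @param samples numeric amplitude vector in \[-1, 1\].
#' @param sample_rate sampling rate in Hz (> 0).
#' @param record_id opaque identifier.
#' @param label class tag (e.g. `"PD"` / `"HC"`).
#' @param source_category free-text source tag (e.g. `"ReadText"`).
#' @return an object of class `audio_record`.
#' @export
audio_record <- function(samples, sample_rate, record_id = "record",
                         label = NA_character_, source_category = NA_character_) {
  samples <- as.numeric(samples)
  assert_that(length(samples) > 0, "audio record '%s' has zero-length audio", record_id)
  assert_that(all(is.finite(samples)), "audio record '%s' contains non-finite samples", record_id)
  assert_that(is.numeric(sample_rate) && sample_rate > 0, "sample_rate must be > 0")
  structure(list(record_id = as.character(record_id), samples = samples,
                 sample_rate = as.numeric(sample_rate),
                 label = as.character(label),
                 source_category = as.character(source_category)),
            class = "audio_record")
}

#' @export
print.audio_record <- function(x, ...) {
  cat(sprintf("<audio_record '%s'> %.2f s @ %g Hz, label=%s\n",
              x$record_id, record_duration(x), x$sample_rate, x$label))
  invisible(x)
}

#' Duration of an audio record in seconds
#' @param record an `audio_record`.
#' @export
record_duration <- function(record) length(record$samples) / record$sample_rate

#' Load a PCM WAV file as an audio record
#'
#' Stereo channels are averaged to mono and the waveform is resampled to
#' `target_rate` by linear interpolation.
#'
#' @param path path to a PCM WAV file (16/24-bit, mono or stereo).
#' @param target_rate target sampling rate in Hz.
#' @param record_id identifier; defaults to the file stem.
#' @param label,source_category optional class and source tags.
#' @return an `audio_record` at `target_rate`.
#' @export
load_audio <- function(path, target_rate = 22050, record_id = NULL,
                       label = NA_character_, source_category = NA_character_) {
  raw <- read_wav_raw(path)
  x <- raw$samples
  if (is.matrix(x)) x <- colMeans(x)   # stereo -> mono by channel mean
  x <- resample_linear(x, raw$sample_rate, target_rate)
  audio_record(x, target_rate,
               record_id = record_id %||% tools::file_path_sans_ext(basename(path)),
               label = label, source_category = source_category)
}

#' Cut a record into fixed-duration, non-overlapping segments
#'
#' Returns exactly `floor(duration(record) / duration_s)` segments; the
#' trailing remainder shorter than `duration_s` is discarded. Segment length
#' is computed in whole samples (`floor(duration_s * sample_rate)`).
#'
#' @param record an `audio_record`.
#' @param duration_s segment duration in seconds (> 0).
#' @return list of `audio_segment` objects (possibly empty).
#' @export
segment_record <- function(record, duration_s) {
  assert_that(inherits(record, "audio_record"), "record must be an audio_record")
  assert_that(is.numeric(duration_s) && length(duration_s) == 1 && duration_s > 0,
              "duration_s must be a single positive number")
  seg_len <- floor(duration_s * record$sample_rate)
  assert_that(seg_len >= 1, "duration_s shorter than one sample period")
  n_seg <- length(record$samples) %/% seg_len
  if (n_seg == 0) return(list())
  lapply(seq_len(n_seg), function(i) {
    idx <- ((i - 1L) * seg_len + 1L):(i * seg_len)
    structure(list(parent_id = record$record_id, index = i - 1L,
                   duration_s = duration_s,
                   samples = record$samples[idx],
                   sample_rate = record$sample_rate,
                   label = record$label),
              class = "audio_segment")
  })
}

#' @export
print.audio_segment <- function(x, ...) {
  cat(sprintf("<audio_segment %s#%d> %g s @ %g Hz, label=%s\n",
              x$parent_id, x$index, x$duration_s, x$sample_rate, x$label))
  invisible(x)
}

#' Segment a cohort of records at several durations
#'
#' Each record is cut at every duration; the result maps each duration to its
#' pooled segment list and adds a `"combined"` entry concatenating all of
#' them (labels preserved).
#'
#' @param records list of `audio_record` objects.
#' @param durations numeric vector of segmentation durations in seconds;
#'   defaults to the four study durations `c(5, 15, 30, 60)`.
#' @return named list: one entry per duration plus `"combined"`.
#' @export
build_segment_sets <- function(records, durations = c(5, 15, 30, 60)) {
  assert_that(length(durations) > 0 && all(durations > 0),
              "durations must be non-empty and positive")
  if (length(records) == 0) warning("empty record list: returning empty segment sets")
  sets <- lapply(durations, function(d) {
    do.call(c, lapply(records, segment_record, duration_s = d))
  })
  names(sets) <- as.character(durations)
  sets$combined <- do.call(c, unname(sets))
  lapply(sets, function(s) s %||% list())
}

#' Write a segment manifest as CSV
#'
#' @param segments list of `audio_segment` objects.
#' @param path output CSV path.
#' @return the manifest data frame, invisibly.
#' @export
write_segment_manifest <- function(segments, path) {
  df <- data.frame(
    record_id = vapply(segments, `[[`, "", "parent_id"),
    index = vapply(segments, `[[`, 0L, "index"),
    duration_s = vapply(segments, `[[`, 0, "duration_s"),
    label = vapply(segments, `[[`, "", "label"),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
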