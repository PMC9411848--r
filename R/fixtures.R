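# Synthetic fixtures emulating the shape of the public datasets: voice
# records as tone+noise mixtures whose roughness tracks the class label, and
# drawn-shape rasters (spiral / meander / circle) whose tremor jitter tracks
# the class label. A zero tremor / zero roughness setting gives null data
# for chance-level tests.

#' Voice synthesis profile
#'
#' @param freqs sinusoid frequencies in Hz.
#' @param amps relative amplitudes (recycled).
#' @param noise_sd white-noise standard deviation before normalization.
#' @param am_freq,am_depth amplitude-modulation (vocal tremor) frequency in
#'   Hz and depth in \[0, 1\].
#' @export
voice_profile <- function(freqs = c(140, 280, 420), amps = c(1, 0.5, 0.25),
                          noise_sd = 0.01, am_freq = 0, am_depth = 0) {
  structure(list(freqs = freqs, amps = rep_len(amps, length(freqs)),
                 noise_sd = noise_sd, am_freq = am_freq, am_depth = am_depth),
            class = "voice_profile")
}

#' Healthy-control and patient voice profiles
#'
#' The patient profile shifts the fundamental, adds roughness (noise) and a
#' 5 Hz amplitude tremor — label-correlated structure only, not a model of
#' dysarthric acoustics.
#' @export
hc_voice_profile <- function() voice_profile()

#' @rdname hc_voice_profile
#' @export
pd_voice_profile <- function() {
  voice_profile(freqs = c(110, 220, 330), amps = c(1, 0.6, 0.3),
                noise_sd = 0.15, am_freq = 5, am_depth = 0.6)
}

#' Generate a synthetic voice record
#'
#' Sum of configured sinusoids plus white noise, optionally amplitude
#' modulated, peak-normalized to 0.9.
#'
#' @param duration_s duration in seconds (> 0).
#' @param rate sampling rate in Hz.
#' @param profile a [voice_profile()].
#' @param label,record_id,source_category record metadata.
#' @param seed optional seed; same seed gives an identical waveform.
#' @return an `audio_record`.
#' @export
make_synthetic_audio <- function(duration_s, rate = 22050,
                                 profile = hc_voice_profile(),
                                 label = "HC", record_id = "synthetic",
                                 source_category = "synthetic", seed = NULL) {
  assert_that(duration_s > 0, "duration_s must be > 0")
  with_seed_or_stream(seed, {
    n <- round(duration_s * rate)
    t <- (seq_len(n) - 1) / rate
    x <- numeric(n)
    for (i in seq_along(profile$freqs)) {
      x <- x + profile$amps[i] * sin(2 * pi * profile$freqs[i] * t)
    }
    if (profile$am_depth > 0 && profile$am_freq > 0) {
      x <- x * (1 - profile$am_depth / 2 +
                (profile$am_depth / 2) * sin(2 * pi * profile$am_freq * t))
    }
    if (profile$noise_sd > 0) x <- x + stats::rnorm(n, sd = profile$noise_sd)
    x <- 0.9 * x / max(abs(x))
    audio_record(x, rate, record_id = record_id, label = label,
                 source_category = source_category)
  })
}

DRAWING_SHAPES <- c("spiral", "meander", "circle")

#' Generate a synthetic drawn-shape image
#'
#' Parametric curve (Archimedean spiral, square-wave meander, or circle) with
#' per-point tremor jitter, rasterized dark-on-white to `size x size x 3`.
#' A zero-tremor circle is rendered analytically, so its raster is exactly
#' symmetric under 90-degree rotation.
#'
#' @param shape `"spiral"`, `"meander"` or `"circle"`.
#' @param tremor jitter amplitude in pixels (>= 0).
#' @param size raster side length (default 100).
#' @param class_label class tag.
#' @param seed optional seed.
#' @return an `image_sample` with pixels in \[0, 255\].
#' @export
make_synthetic_drawing <- function(shape, tremor = 0, size = 100,
                                   class_label = NA_character_, seed = NULL) {
  assert_that(shape %in% DRAWING_SHAPES, "unknown shape '%s'; valid: %s",
              shape, paste(DRAWING_SHAPES, collapse = ", "))
  assert_that(tremor >= 0, "tremor must be >= 0")
  with_seed_or_stream(seed, {
    canvas <- matrix(255, size, size)
    centre <- (size + 1) / 2
    if (shape == "circle" && tremor == 0) {
      r <- 0.35 * size
      d <- sqrt(outer((seq_len(size) - centre)^2, (seq_len(size) - centre)^2, `+`))
      canvas[abs(d - r) <= 1] <- 30
    } else {
      n_pts <- 4000L
      tt <- seq(0, 1, length.out = n_pts)
      if (shape == "circle") {
        r <- 0.35 * size
        px <- centre + r * cos(2 * pi * tt)
        py <- centre + r * sin(2 * pi * tt)
      } else if (shape == "spiral") {
        theta <- tt * 6 * pi
        r <- 0.42 * size * tt
        px <- centre + r * cos(theta)
        py <- centre + r * sin(theta)
      } else { # meander: square-wave zigzag sweeping down the canvas
        n_waves <- 6
        px <- 0.1 * size + 0.8 * size * tt
        phase <- (tt * n_waves) %% 1
        wave <- ifelse(phase < 0.5, 1, -1)
        py <- centre + 0.3 * size * wave
        # vertical strokes at the transitions are filled by dense sampling
        trans <- abs(phase - 0.5) < 0.02 | phase < 0.02 | phase > 0.98
        py[trans] <- centre + 0.3 * size * stats::runif(sum(trans), -1, 1)
      }
      if (tremor > 0) {
        px <- px + stats::rnorm(n_pts, sd = tremor)
        py <- py + stats::rnorm(n_pts, sd = tremor)
      }
      ix <- round(px); iy <- round(py)
      for (dd in list(c(0, 0), c(0, 1), c(1, 0))) {  # ~1.5 px stroke
        xi <- pmin(pmax(ix + dd[1], 1), size)
        yi <- pmin(pmax(iy + dd[2], 1), size)
        canvas[cbind(yi, xi)] <- 30
      }
    }
    image_sample(array(rep(canvas, 3), dim = c(size, size, 3)),
                 class_label = class_label, provenance = "original")
  })
}

#' Fixture specification
#'
#' @param audio data frame with columns `label`, `duration_s`, `count` and
#'   optionally `profile` (`"hc"`/`"pd"`).
#' @param images data frame with columns `class_name`, `count`, `shape`,
#'   `tremor`.
#' @param seed global seed; per-item seeds are derived by stable hashing so
#'   any subset regenerates identically.
#' @export
fixture_spec <- function(audio = NULL, images = NULL, seed = 1) {
  structure(list(audio = audio, images = images, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Image fixture specification mirroring the handwriting dataset layout
#'
#' Default class counts 140/140/35/31/124/124 across three healthy and three
#' patient shape classes; patient classes get tremor jitter.
#'
#' @param counts per-class image counts.
#' @param tremor_pd tremor amplitude (pixels) for the patient classes.
#' @export
newhandpd_like_spec <- function(counts = c(140, 140, 35, 31, 124, 124),
                                tremor_pd = 2.5) {
  data.frame(
    class_name = c("HealthyMeander", "HealthySpiral", "HealthyCircle",
                   "PatientCircle", "PatientMeander", "PatientSpiral"),
    count = counts,
    shape = c("meander", "spiral", "circle", "circle", "meander", "spiral"),
    tremor = c(0, 0, 0, tremor_pd, tremor_pd, tremor_pd),
    stringsAsFactors = FALSE)
}

#' Generate audio records in memory from a fixture spec
#' @param spec a [fixture_spec()] with an `audio` table.
#' @return list of `audio_record` objects.
#' @export
make_fixture_audio <- function(spec) {
  out <- list()
  i <- 0L
  for (r in seq_len(nrow(spec$audio))) {
    row <- spec$audio[r, ]
    prof <- if (identical(row$profile %||% "hc", "pd")) pd_voice_profile() else hc_voice_profile()
    for (j in seq_len(row$count)) {
      i <- i + 1L
      out[[i]] <- make_synthetic_audio(
        row$duration_s, profile = prof, label = row$label,
        record_id = sprintf("%s_%03d", row$label, j),
        seed = derive_seed(spec$seed, i))
    }
  }
  out
}

#' Generate image samples in memory from a fixture spec
#' @param spec a [fixture_spec()] with an `images` table.
#' @return list of `image_sample` objects.
#' @export
make_fixture_images <- function(spec) {
  out <- list()
  i <- 0L
  for (r in seq_len(nrow(spec$images))) {
    row <- spec$images[r, ]
    for (j in seq_len(row$count)) {
      i <- i + 1L
      out[[i]] <- make_synthetic_drawing(
        row$shape, tremor = row$tremor, class_label = row$class_name,
        seed = derive_seed(spec$seed, 100000L + i))
    }
  }
  out
}

#' Materialize a fixture dataset on disk
#'
#' Writes WAV files, class-folder PNG images and a `manifest.csv` listing
#' every item. Fully reproducible from `(spec, seed)`.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory.
#' @return the manifest data frame, invisibly.
#' @export
make_fixture_dataset <- function(spec, dir) {
  ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) abort_io("cannot create fixture directory '%s'", dir)
  manifest <- list()
  if (!is.null(spec$audio) && nrow(spec$audio)) {
    audio_dir <- file.path(dir, "audio")
    dir.create(audio_dir, showWarnings = FALSE)
    recs <- make_fixture_audio(spec)
    for (rec in recs) {
      f <- file.path(audio_dir, paste0(rec$record_id, ".wav"))
      write_wav(rec$samples, rec$sample_rate, f)
      manifest[[length(manifest) + 1L]] <- data.frame(
        kind = "audio", path = f, label = rec$label,
        detail = sprintf("%.1fs", record_duration(rec)))
    }
  }
  if (!is.null(spec$images) && nrow(spec$images)) {
    img_dir <- file.path(dir, "images")
    imgs <- make_fixture_images(spec)
    write_image_folder(imgs, img_dir)
    for (img in imgs) {
      manifest[[length(manifest) + 1L]] <- data.frame(
        kind = "image", path = file.path(img_dir, img$class_label),
        label = img$class_label, detail = "100x100")
    }
  }
  mf <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(kind = character(0), path = character(0),
               label = character(0), detail = character(0))
  utils::write.csv(mf, file.path(dir, "manifest.csv"), row.names = FALSE)
  log_stage("fixtures", "wrote %d items under %s", nrow(mf), dir)
  invisible(mf)
}
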