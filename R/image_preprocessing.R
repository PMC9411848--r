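# Image pipeline: the four scale-conversion formulas, the six augmentation
# transforms (shift, shear, zoom, flip, rotation, brightness) and class
# equalization by random augmentation up to the majority class count.

SCALER_KINDS <- c("normalize255", "minmax", "standard", "maxabs")

#' Construct an image sample
#'
#' @param pixels H x W x 3 numeric array, values in \[0, 255\] before scaling.
#' @param class_label class tag.
#' @param provenance `"original"` or `"augmented"`.
#' @return an `image_sample`.
#' @export
image_sample <- function(pixels, class_label = NA_character_,
                         provenance = c("original", "augmented")) {
  provenance <- match.arg(provenance)
  assert_that(length(dim(pixels)) == 3 && dim(pixels)[3] == 3,
              "pixels must be an H x W x 3 array")
  structure(list(pixels = pixels, class_label = as.character(class_label),
                 provenance = provenance),
            class = "image_sample")
}

#' @export
print.image_sample <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_sample> %dx%dx%d, class=%s (%s)\n", d[1], d[2], d[3],
              x$class_label, x$provenance))
  invisible(x)
}

#' Apply one of the four scale-conversion formulas to an image
#'
#' `normalize255`: in/255; `minmax`: (in - min)/(max - min); `standard`:
#' (in - mean)/sd; `maxabs`: in/max(|in|). Formulas are whole-image (scalar
#' statistics over all channels jointly). Degenerate denominators (constant
#' or all-zero images) return all-zeros with a warning instead of failing.
#'
#' @param image an `image_sample` or numeric array.
#' @param method one of `"normalize255"`, `"minmax"`, `"standard"`, `"maxabs"`.
#' @return scaled numeric array of the same shape.
#' @export
scale_image <- function(image, method = SCALER_KINDS) {
  method <- match.arg(method)
  px <- if (inherits(image, "image_sample")) image$pixels else image
  assert_that(length(px) > 0, "empty image")
  switch(method,
    normalize255 = px / 255,
    minmax = {
      rng <- range(px)
      if (diff(rng) == 0) {
        warning("constant image under minmax scaling: returning zeros")
        px * 0
      } else (px - rng[1]) / diff(rng)
    },
    standard = {
      s <- stats::sd(px)
      if (!is.finite(s) || s == 0) {
        warning("constant image under standard scaling: returning zeros")
        px * 0
      } else (px - mean(px)) / s
    },
    maxabs = {
      m <- max(abs(px))
      if (m == 0) px * 0 else px / m
    })
}

#' Augmentation configuration
#'
#' Defaults are the first-location (pre-training equalization) ranges: 15%
#' width/height shift, 15% shear, 15% zoom, both flips permitted, 25 degree
#' rotation, brightness multipliers in \[0.8, 1.2\].
#'
#' @param rotation_deg maximum absolute rotation in degrees.
#' @param width_shift,height_shift maximum shift as a fraction of size.
#' @param shear maximum shear fraction.
#' @param zoom maximum zoom fraction (scale drawn in \[1-z, 1+z\]).
#' @param horizontal_flip,vertical_flip whether flips may be applied.
#' @param brightness_range multiplier bounds `(low, high)`, low <= high.
#' @return an `augmentation_config`.
#' @export
augmentation_config <- function(rotation_deg = 25, width_shift = 0.15,
                                height_shift = 0.15, shear = 0.15, zoom = 0.15,
                                horizontal_flip = TRUE, vertical_flip = TRUE,
                                brightness_range = c(0.8, 1.2)) {
  assert_that(all(c(rotation_deg, width_shift, height_shift, shear, zoom) >= 0),
              "augmentation ranges must be >= 0")
  assert_that(brightness_range[1] <= brightness_range[2],
              "brightness_range low must be <= high")
  structure(list(rotation_deg = rotation_deg, width_shift = width_shift,
                 height_shift = height_shift, shear = shear, zoom = zoom,
                 horizontal_flip = isTRUE(horizontal_flip),
                 vertical_flip = isTRUE(vertical_flip),
                 brightness_range = brightness_range),
            class = "augmentation_config")
}

# Inverse-mapped affine warp about the image centre with nearest-edge fill.
affine_warp <- function(px, rot_rad, dx, dy, shear, scale) {
  h <- dim(px)[1]; w <- dim(px)[2]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  # forward transform: rotate, shear, zoom, then translate; sample by inverse
  A <- matrix(c(cos(rot_rad), -sin(rot_rad), sin(rot_rad), cos(rot_rad)),
              2, 2, byrow = TRUE)
  A <- A %*% matrix(c(1, shear, 0, 1), 2, 2, byrow = TRUE) * scale
  Ainv <- solve(A)
  gy <- rep(seq_len(h), times = w) - cy - dy
  gx <- rep(seq_len(w), each = h) - cx - dx
  sy <- Ainv[1, 1] * gy + Ainv[1, 2] * gx + cy
  sx <- Ainv[2, 1] * gy + Ainv[2, 2] * gx + cx
  iy <- pmin(pmax(round(sy), 1), h)   # nearest-edge fill
  ix <- pmin(pmax(round(sx), 1), w)
  out <- px
  for (ch in 1:3) out[, , ch] <- matrix(px[, , ch][cbind(iy, ix)], h, w)
  out
}

#' Randomly augment an image
#'
#' Each transform amount is drawn uniformly within its configured range:
#' rotation in \[-r, r\], shifts in \[-s, s\] of the image size, shear in
#' \[-sh, sh\], zoom scale in \[1-z, 1+z\], each flip applied with
#' probability 1/2 when permitted, brightness multiplier in the configured
#' interval (clipped to \[0, 255\]).
#'
#' @param image an `image_sample`.
#' @param config an `augmentation_config`.
#' @param seed optional integer seed for reproducibility.
#' @return an augmented `image_sample` of identical shape, provenance
#'   `"augmented"`.
#' @export
augment_image <- function(image, config = augmentation_config(), seed = NULL) {
  assert_that(inherits(image, "image_sample"), "image must be an image_sample")
  with_seed_or_stream(seed, {
    px <- image$pixels
    h <- dim(px)[1]; w <- dim(px)[2]
    rot <- stats::runif(1, -config$rotation_deg, config$rotation_deg) * pi / 180
    dx <- stats::runif(1, -config$width_shift, config$width_shift) * w
    dy <- stats::runif(1, -config$height_shift, config$height_shift) * h
    sh <- stats::runif(1, -config$shear, config$shear)
    sc <- stats::runif(1, 1 - config$zoom, 1 + config$zoom)
    flip_h <- config$horizontal_flip && stats::runif(1) < 0.5
    flip_v <- config$vertical_flip && stats::runif(1) < 0.5
    bright <- stats::runif(1, config$brightness_range[1], config$brightness_range[2])
    if (!(rot == 0 && dx == 0 && dy == 0 && sh == 0 && sc == 1)) {
      px <- affine_warp(px, rot, dx, dy, sh, sc)
    }
    if (flip_h) px <- px[, rev(seq_len(w)), , drop = FALSE]
    if (flip_v) px <- px[rev(seq_len(h)), , , drop = FALSE]
    px <- pmin(pmax(px * bright, 0), 255)
    image_sample(px, class_label = image$class_label, provenance = "augmented")
  })
}

#' Equalize class counts by random augmentation
#'
#' Finds the largest class and augments randomly chosen originals (with
#' replacement) of every other class until all classes reach that count.
#' Originals are always retained.
#'
#' @param dataset list of `image_sample` objects.
#' @param config an `augmentation_config` for the synthesized copies.
#' @param seed optional integer seed.
#' @return list of `image_sample` objects, every class at the maximum
#'   original count.
#' @export
equalize_classes <- function(dataset, config = augmentation_config(), seed = NULL) {
  assert_that(length(dataset) > 0, "empty dataset")
  labels <- vapply(dataset, `[[`, "", "class_label")
  counts <- table(labels)
  assert_that(all(counts > 0), "cannot augment a class with zero originals")
  target <- max(counts)
  with_seed_or_stream(seed, {
    extra <- list()
    for (cls in names(counts)) {
      deficit <- target - counts[[cls]]
      if (deficit == 0) next
      pool <- which(labels == cls)
      picks <- pool[sample.int(length(pool), deficit, replace = TRUE)]
      extra <- c(extra, lapply(picks, function(i) augment_image(dataset[[i]], config)))
    }
    c(dataset, extra)
  })
}

#' Load an image folder dataset (`class_name/*.png` layout)
#' @param dir root directory with one subdirectory per class.
#' @return list of `image_sample` objects.
#' @export
load_image_folder <- function(dir) {
  if (!dir.exists(dir)) abort_io("image folder '%s' does not exist", dir)
  classes <- list.dirs(dir, recursive = FALSE)
  out <- list()
  for (cls_dir in classes) {
    cls <- basename(cls_dir)
    files <- sort(list.files(cls_dir, pattern = "\\.(png|jpe?g)$", full.names = TRUE))
    out <- c(out, lapply(files, read_image, class_label = cls))
  }
  out
}

#' Write an image dataset in `class_name/*.png` layout
#'
#' Augmented samples get an `aug_` filename prefix.
#'
#' @param dataset list of `image_sample` objects.
#' @param dir output root directory.
#' @export
write_image_folder <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counters <- new.env()
  for (img in dataset) {
    cls_dir <- file.path(dir, img$class_label)
    dir.create(cls_dir, showWarnings = FALSE)
    n <- (get0(img$class_label, counters, ifnotfound = 0L)) + 1L
    assign(img$class_label, n, counters)
    prefix <- if (img$provenance == "augmented") "aug_" else ""
    write_image_png(img, file.path(cls_dir, sprintf("%s%04d.png", prefix, n)))
  }
  invisible(dir)
}
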