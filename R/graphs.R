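# Rendering of the five graphical time-frequency representations as
# axis-free colour rasters for CNN input. Rendering bypasses any plotting
# device: the matrix is colour-mapped (viridis), rasterized at dpi x dpi and
# bilinearly resized to the requested output shape, so output is
# deterministic pixel-for-pixel.

GRAPH_TECHNIQUES <- c("specgram", "mel-specgram", "stft", "mfcc-slaney", "mfcc-htk")

bilinear_resize_matrix <- function(m, out_h, out_w) {
  in_h <- nrow(m); in_w <- ncol(m)
  if (in_h == out_h && in_w == out_w) return(m)
  ry <- if (out_h == 1) rep(1, 1) else seq(1, in_h, length.out = out_h)
  rx <- if (out_w == 1) rep(1, 1) else seq(1, in_w, length.out = out_w)
  y0 <- pmin(floor(ry), in_h - 1L); y0[in_h == 1] <- 1
  x0 <- pmin(floor(rx), in_w - 1L); x0[in_w == 1] <- 1
  if (in_h == 1) { y0 <- rep(1, out_h); wy <- rep(0, out_h) } else wy <- ry - y0
  if (in_w == 1) { x0 <- rep(1, out_w); wx <- rep(0, out_w) } else wx <- rx - x0
  y1 <- pmin(y0 + 1L, in_h); x1 <- pmin(x0 + 1L, in_w)
  a <- m[y0, x0, drop = FALSE]; b <- m[y0, x1, drop = FALSE]
  c_ <- m[y1, x0, drop = FALSE]; d <- m[y1, x1, drop = FALSE]
  WY <- matrix(wy, out_h, out_w); WX <- matrix(wx, out_h, out_w, byrow = TRUE)
  a * (1 - WY) * (1 - WX) + b * (1 - WY) * WX + c_ * WY * (1 - WX) + d * WY * WX
}

graph_matrix <- function(segment, technique, frame_length = 2048, hop = 512) {
  S <- stft_magnitude(segment$samples, n_fft = frame_length, hop = hop)
  sr <- segment$sample_rate
  switch(technique,
    "specgram" = power_to_db(S^2),
    "stft" = log(S + EPS_FLOOR),
    "mel-specgram" = power_to_db(mel_filterbank(sr, frame_length, 128) %*% S^2),
    "mfcc-slaney" = dct_matrix(40, 128) %*%
      power_to_db(mel_filterbank(sr, frame_length, 128, htk = FALSE) %*% S^2),
    "mfcc-htk" = dct_matrix(40, 128) %*%
      power_to_db(mel_filterbank(sr, frame_length, 128, htk = TRUE) %*% S^2),
    abort_validation("unknown graph technique '%s'; valid: %s", technique,
                     paste(GRAPH_TECHNIQUES, collapse = ", "))
  )
}

#' Render a segment as a colour time-frequency raster
#'
#' @param segment an `audio_segment`.
#' @param technique one of `"specgram"`, `"mel-specgram"`, `"stft"`,
#'   `"mfcc-slaney"`, `"mfcc-htk"`.
#' @param dpi intermediate rasterization resolution (square, default 480).
#' @param out_size output `(height, width)`; default `c(100, 100)`.
#' @param frame_length,hop STFT parameters.
#' @return a `graph_image`: list with `pixels` (H x W x 3 integer array in
#'   \[0, 255\]), `technique`, segment reference and label.
#' @export
render_graph <- function(segment, technique = "mel-specgram", dpi = 480,
                         out_size = c(100, 100), frame_length = 2048, hop = 512) {
  assert_that(technique %in% GRAPH_TECHNIQUES,
              "unknown graph technique '%s'; valid: %s", technique,
              paste(GRAPH_TECHNIQUES, collapse = ", "))
  m <- graph_matrix(segment, technique, frame_length, hop)
  rng <- range(m)
  m01 <- if (diff(rng) < EPS_FLOOR) matrix(0, nrow(m), ncol(m)) else (m - rng[1]) / diff(rng)
  m01 <- m01[rev(seq_len(nrow(m01))), , drop = FALSE]  # low frequency at bottom
  # 480-DPI square intermediate, then the model input size
  m_hi <- bilinear_resize_matrix(m01, dpi, dpi)
  m_out <- bilinear_resize_matrix(m_hi, out_size[1], out_size[2])
  pal <- grDevices::hcl.colors(256, "viridis")
  rgb <- t(grDevices::col2rgb(pal))  # 256 x 3
  idx <- pmin(pmax(as.integer(m_out * 255) + 1L, 1L), 256L)
  pixels <- array(0L, dim = c(out_size[1], out_size[2], 3))
  for (ch in 1:3) pixels[, , ch] <- matrix(rgb[idx, ch], out_size[1], out_size[2])
  structure(list(technique = technique, pixels = pixels,
                 parent_id = segment$parent_id %||% NA_character_,
                 index = segment$index %||% NA_integer_,
                 label = segment$label %||% NA_character_),
            class = "graph_image")
}

#' Write a graph image (or any 0-255 pixel array) as PNG
#' @param image a `graph_image` or `image_sample`.
#' @param path output PNG path.
#' @export
write_image_png <- function(image, path) {
  px <- if (is.list(image)) image$pixels else image
  png::writePNG(px / 255, path)
  invisible(path)
}

#' Read a PNG/JPEG file as an `image_sample`
#' @param path image path.
#' @param class_label class tag.
#' @export
read_image <- function(path, class_label = NA_character_) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    jpg = , jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE)) {
        abort_io("reading '%s' requires the jpeg package", path)
      }
      jpeg::readJPEG(path)
    },
    abort_io("unsupported image format '%s' for '%s'", ext, path))
  if (length(dim(px)) == 2) px <- array(rep(px, 3), dim = c(dim(px), 3))
  if (dim(px)[3] > 3) px <- px[, , 1:3, drop = FALSE]
  image_sample(px * 255, class_label = class_label, provenance = "original")
}
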