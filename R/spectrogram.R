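#' Spectrogram configuration
#'
#' STFT and image-geometry settings used to turn a fixed-length segment into
#' a grayscale spectrogram image. Defaults: Hann window of 256 samples
#' (128 ms at 2 kHz), 64-sample hop, 512-point FFT — resolving the
#' 10–400 Hz band where S1/S2 and murmur energy lives while giving >150 time
#' frames per 5-s segment — and a 504 x 864 (height x width) output image.
#'
#' @param window STFT window length in samples (Hann window)
#' @param hop hop size in samples
#' @param nfft FFT length (zero-padded); must be >= `window`
#' @param eps floor added to the power spectrum before taking log10
#' @param height,width output image size in pixels (height = frequency axis)
#' @return an object of class `spectrogram_config`
#' @export
spectrogram_config <- function(window = 256L, hop = 64L, nfft = 512L,
                               eps = 1e-10, height = 504L, width = 864L) {
  stopifnot(window > 0, hop > 0, nfft >= window, eps > 0,
            height > 0, width > 0)
  structure(list(window = as.integer(window), hop = as.integer(hop),
                 nfft = as.integer(nfft), eps = eps,
                 height = as.integer(height), width = as.integer(width)),
            class = "spectrogram_config")
}

# Log-power STFT matrix: (nfft/2 + 1) frequency rows (row 1 = DC) by
# n_frames columns. Kept separate from the image geometry so shift/scale
# properties can be stated at STFT resolution.
stft_log_power <- function(samples, cfg) {
  n <- length(samples)
  if (n < cfg$window) stop("segment shorter than the STFT window")
  starts <- seq(1L, n - cfg$window + 1L, by = cfg$hop)
  win <- signal::hanning(cfg$window)
  frames <- vapply(starts, function(s) {
    samples[s:(s + cfg$window - 1L)] * win
  }, numeric(cfg$window))
  padded <- rbind(frames, matrix(0, cfg$nfft - cfg$window, ncol(frames)))
  spec <- stats::mvfft(padded)[seq_len(cfg$nfft %/% 2L + 1L), , drop = FALSE]
  log10(Mod(spec)^2 + cfg$eps)
}

new_spectrogram_image <- function(pixels, parent_id, index, label) {
  structure(list(pixels = pixels, parent_id = parent_id,
                 index = as.integer(index), label = label),
            class = "spectrogram_image")
}

#' Compute a grayscale spectrogram image from a segment
#'
#' Pipeline: Hann-windowed STFT, power, `log10(.^2 + eps)`, frequency axis
#' flipped so row 1 is the highest frequency, bilinear resize to the
#' configured height x width, then per-image min–max normalization to
#' \[0, 1\]. A constant segment (e.g. all zeros) yields a constant image of
#' zeros (the degenerate max = min case), never NaN. Deterministic: the same
#' segment and config give a bitwise-identical image.
#'
#' @param seg a `pcg_segment`
#' @param cfg a [spectrogram_config()]
#' @return a `spectrogram_image` with `pixels` of dim `c(height, width)`
#' @export
compute_spectrogram <- function(seg, cfg = spectrogram_config()) {
  stopifnot(inherits(seg, "pcg_segment"))
  lp <- stft_log_power(seg$samples, cfg)
  lp <- lp[nrow(lp):1L, , drop = FALSE]        # row 1 = highest frequency
  px <- EBImage::resize(lp, w = cfg$height, h = cfg$width)
  rng <- range(px)
  if (rng[2] > rng[1]) {
    px <- (px - rng[1]) / (rng[2] - rng[1])
  } else {
    px <- matrix(0, nrow(px), ncol(px))
  }
  new_spectrogram_image(px, seg$parent_id, seg$index, seg$label)
}

#' Write / read a spectrogram image as an 8-bit grayscale PNG
#'
#' Pixels are quantized to 8 bits with round-half-away (`round(x * 255)`),
#' so a read-back image differs from the original by at most 1/255.
#'
#' @param img a `spectrogram_image`
#' @param path output PNG path
#' @return `path` invisibly (write); a `spectrogram_image` (read)
#' @export
write_spectrogram_png <- function(img, path) {
  stopifnot(inherits(img, "spectrogram_image"))
  if (!nzchar(path)) stop("empty path")
  q <- round(img$pixels * 255) / 255
  png::writePNG(q, path)
  invisible(path)
}

#' @rdname write_spectrogram_png
#' @param parent_id,index,label metadata to attach on read
#' @export
read_spectrogram_png <- function(path, parent_id = NA_character_,
                                 index = NA_integer_, label = NA_character_) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  new_spectrogram_image(px, parent_id, index, label)
}

#' Spectrograms for a list of segments
#'
#' @param segments list of `pcg_segment`
#' @param cfg a [spectrogram_config()]
#' @return list of `spectrogram_image`
#' @export
compute_spectrograms <- function(segments, cfg = spectrogram_config()) {
  lapply(segments, compute_spectrogram, cfg = cfg)
}
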