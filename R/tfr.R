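# Analytic-wavelet time-frequency representations and spectrogram images.
#
# The transform is a continuous wavelet transform with an analytic (complex)
# Morlet mother wavelet evaluated on a log-spaced frequency grid; only
# positive frequencies carry support, so coefficients are analytic and the
# magnitude is an amplitude envelope per frequency row.

#' Analytic (Morlet) wavelet time-frequency representation
#'
#' Computes `|CWT|` of `signal` on `n_scales` log-spaced center frequencies
#' between `f_min` and `f_max` using an analytic Morlet wavelet
#' (non-dimensional center frequency `omega0`, default 6). At a pure tone
#' `f0`, the row of maximum time-averaged magnitude lies within one grid
#' step of `f0`.
#'
#' @param signal numeric vector.
#' @param sampling_rate Hz.
#' @param n_scales number of frequency rows, >= 4.
#' @param f_min,f_max frequency band in Hz, `f_min < f_max <= sampling_rate/2`.
#' @param omega0 Morlet center frequency parameter (rad), default 6.
#' @param provenance optional list (subject, trial, channel, class) carried
#'   through to images and feature keys.
#' @return object of class `spectrogram`: `magnitude` (`n_scales x n_times`,
#'   rows in increasing frequency order), `frequencies` (Hz), `times` (s),
#'   `provenance`.
#' @export
analytic_wavelet_tfr <- function(signal, sampling_rate, n_scales = 64,
                                 f_min = 1, f_max = 45, omega0 = 6,
                                 provenance = NULL) {
  if (!is_number(sampling_rate) || sampling_rate <= 0)
    stop_config("analytic_wavelet_tfr: sampling_rate must be > 0")
  if (!is_count(n_scales, min = 4)) stop_config("analytic_wavelet_tfr: n_scales must be >= 4")
  if (!is_number(f_min) || !is_number(f_max) || f_min <= 0 ||
      f_min >= f_max || f_max > sampling_rate / 2)
    stop_config("analytic_wavelet_tfr: need 0 < f_min < f_max <= sampling_rate/2")
  if (length(signal) < 4 || any(!is.finite(signal)))
    stop_data("analytic_wavelet_tfr: signal must be finite with length >= 4")
  n <- length(signal)
  freqs <- exp(seq(log(f_min), log(f_max), length.out = n_scales))
  X <- stats::fft(signal)
  k <- 0:(n - 1)
  pos <- k >= 1 & k <= floor(n / 2)          # positive-frequency bins only
  w <- 2 * pi * k / n                         # rad / sample
  mag <- matrix(0, nrow = n_scales, ncol = n)
  for (i in seq_len(n_scales)) {
    s <- omega0 / (2 * pi * freqs[i] / sampling_rate)  # scale in samples
    H <- numeric(n)
    H[pos] <- pi^(-0.25) * sqrt(2 * pi * s) * exp(-0.5 * (s * w[pos] - omega0)^2)
    mag[i, ] <- Mod(stats::fft(X * H, inverse = TRUE) / n)
  }
  structure(list(magnitude = mag, frequencies = freqs,
                 times = (k) / sampling_rate, provenance = provenance),
            class = "spectrogram")
}

# Memoized 3 x 256 RGB palette lookup.
palette_cache <- new.env(parent = emptyenv())
palette_rgb <- function(colormap) {
  p <- palette_cache[[colormap]]
  if (is.null(p)) {
    p <- grDevices::col2rgb(viridisLite::viridis(256, option = colormap))
    palette_cache[[colormap]] <- p
  }
  p
}

# Bilinear resize of a numeric matrix to out_rows x out_cols; corners map to
# corners.
bilinear_resize <- function(mat, out_rows, out_cols) {
  sr <- nrow(mat); sc <- ncol(mat)
  ri <- if (sr == 1) rep(1, out_rows) else seq(1, sr, length.out = out_rows)
  ci <- if (sc == 1) rep(1, out_cols) else seq(1, sc, length.out = out_cols)
  r0 <- pmin(floor(ri), sr); r1 <- pmin(r0 + 1, sr); fr <- ri - r0
  c0 <- pmin(floor(ci), sc); c1 <- pmin(c0 + 1, sc); fc <- ci - c0
  FR <- matrix(fr, out_rows, out_cols)
  FC <- matrix(fc, out_rows, out_cols, byrow = TRUE)
  A <- mat[r0, c0, drop = FALSE]; B <- mat[r0, c1, drop = FALSE]
  C <- mat[r1, c0, drop = FALSE]; D <- mat[r1, c1, drop = FALSE]
  (A * (1 - FC) + B * FC) * (1 - FR) + (C * (1 - FC) + D * FC) * FR
}

#' Render a spectrogram as a fixed-size RGB image
#'
#' Min-max normalizes the magnitude to `[0, 1]` (a constant magnitude maps
#' to a single color), applies a perceptually ordered colormap, and
#' bilinearly resizes each RGB plane to `size x size`. Low frequencies are
#' placed at the bottom of the image. Rendering is deterministic and
#' scale-invariant: `spec` and `2 * spec` produce identical bytes.
#'
#' @param spec a `spectrogram` from [analytic_wavelet_tfr()].
#' @param colormap a palette name understood by [viridisLite::viridis()]
#'   (`"viridis"`, `"magma"`, ...).
#' @param size output edge length in pixels (default 224).
#' @return object of class `spectro_image`: integer array
#'   `size x size x 3` with values 0-255 and the spectrogram's provenance.
#' @export
render_image <- function(spec, colormap = "viridis", size = 224) {
  if (!inherits(spec, "spectrogram")) stop_data("render_image: expected a spectrogram")
  m <- spec$magnitude
  if (length(m) == 0) stop_data("render_image: empty magnitude")
  rng <- range(m)
  v <- if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else matrix(0, nrow(m), ncol(m))
  pal <- palette_rgb(colormap)
  # v is exactly in [0, 1], and bilinear interpolation of 0..255 values
  # stays in range, so no clamping is needed anywhere downstream
  idx <- matrix(as.integer(round(v * 255)) + 1L, nrow(v), ncol(v))
  idx <- idx[rev(seq_len(nrow(idx))), , drop = FALSE]  # low frequency at bottom
  pixels <- array(0L, dim = c(size, size, 3))
  for (ch in 1:3) {
    plane <- matrix(pal[ch, idx], nrow(idx), ncol(idx))
    pixels[, , ch] <- as.integer(round(bilinear_resize(plane, size, size)))
  }
  structure(list(pixels = pixels, provenance = spec$provenance),
            class = "spectro_image")
}

#' Write a spectrogram image as PNG
#'
#' @param image a `spectro_image`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  if (!inherits(image, "spectro_image")) stop_data("write_image_png: expected a spectro_image")
  png::writePNG(image$pixels / 255, target = path)
  invisible(path)
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("spectrogram: %d scales (%.2f-%.2f Hz) x %d samples\n",
              nrow(x$magnitude), min(x$frequencies), max(x$frequencies),
              ncol(x$magnitude)))
  invisible(x)
}
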