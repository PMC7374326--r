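# Empirical mode decomposition, fast variant.
#
# Canonical sifting with two modifications: (i) only every other extremum is
# used for the envelope splines ("halved extrema", a speed device), and
# (ii) the sifting stop rule is the normalized squared-difference sum
# between successive mean envelopes, SD = sum((m_prev - m)^2 / m_prev^2),
# stopped when SD < stop_threshold.

#' Sifting configuration
#'
#' @param max_imfs maximum number of intrinsic mode functions (default 5).
#' @param stop_threshold sifting stop threshold applied to the normalized
#'   squared-difference sum between successive mean envelopes (default 0.2,
#'   the classical sifting SD criterion).
#' @param halve_extrema keep only every other extremum when fitting
#'   envelopes (default `TRUE`); applied at every sifting pass.
#' @param max_sift_iter practical cap on sifting passes per IMF (default
#'   10, the classical fixed-sift compromise); the effective cap is
#'   `min(max_sift_iter, floor(n/2))`.
#' @param interpolation envelope interpolation; only `"cubic_spline"`.
#' @return an object of class `sift_config`.
#' @export
sift_config <- function(max_imfs = 5, stop_threshold = 0.2,
                        halve_extrema = TRUE, max_sift_iter = 10,
                        interpolation = c("cubic_spline")) {
  if (!is_count(max_imfs)) stop_config("sift_config: max_imfs must be >= 1")
  if (!is_number(stop_threshold) || stop_threshold <= 0)
    stop_config("sift_config: stop_threshold must be > 0")
  if (!isTRUE(halve_extrema) && !isFALSE(halve_extrema))
    stop_config("sift_config: halve_extrema must be TRUE or FALSE")
  if (!is_count(max_sift_iter)) stop_config("sift_config: max_sift_iter must be >= 1")
  interpolation <- match.arg(interpolation)
  structure(list(max_imfs = as.integer(max_imfs),
                 stop_threshold = stop_threshold,
                 halve_extrema = halve_extrema,
                 max_sift_iter = as.integer(max_sift_iter),
                 interpolation = interpolation),
            class = "sift_config")
}

#' Strict local extrema of a signal
#'
#' Plateaus (runs of equal values) count once, at the plateau midpoint, and
#' only when the neighbouring runs are strictly lower (maxima) or strictly
#' higher (minima). End samples are never extrema, so maxima and minima
#' interleave. A monotone signal yields empty index vectors.
#'
#' @param x numeric vector, length >= 3.
#' @return list with integer vectors `maxima` and `minima` (1-based).
#' @export
find_extrema <- function(x) {
  if (length(x) < 3) stop_data("find_extrema: signal must have length >= 3")
  if (any(!is.finite(x))) stop_data("find_extrema: signal must be finite")
  r <- rle(x)
  k <- length(r$values)
  if (k < 3) return(list(maxima = integer(0), minima = integer(0)))
  starts <- cumsum(c(1, r$lengths[-k]))
  mids <- starts + (r$lengths - 1L) %/% 2L
  v <- r$values
  interior <- 2:(k - 1)
  is_max <- v[interior] > v[interior - 1] & v[interior] > v[interior + 1]
  is_min <- v[interior] < v[interior - 1] & v[interior] < v[interior + 1]
  list(maxima = as.integer(mids[interior][is_max]),
       minima = as.integer(mids[interior][is_min]))
}

#' Keep every other extremum
#'
#' Retains ordinal positions 1, 3, 5, ... of each index list (so
#' `ceiling(n/2)` survive), preserving order. Lists of length <= 1 pass
#' through unchanged.
#'
#' @param maxima,minima integer index vectors from [find_extrema()].
#' @return list with thinned `maxima` and `minima`.
#' @export
halve_extrema <- function(maxima, minima) {
  thin <- function(idx) if (length(idx) <= 1) idx else idx[seq(1, length(idx), by = 2)]
  list(maxima = thin(maxima), minima = thin(minima))
}

# Cubic-spline envelope through (idx, value) with end extrema mirrored about
# the first/last sample to curb end swings.
spline_envelope <- function(idx, val, n) {
  if (length(idx) == 0) return(NULL)
  xi <- idx
  yi <- val
  if (idx[1] > 1) { xi <- c(2 - idx[1], xi); yi <- c(val[1], yi) }
  if (idx[length(idx)] < n) { xi <- c(xi, 2 * n - idx[length(idx)]); yi <- c(yi, val[length(val)]) }
  if (length(xi) == 1) return(rep(yi, n))
  stats::spline(xi, yi, method = "fmm", xout = seq_len(n))$y
}

#' Empirical mode decomposition by sifting
#'
#' Extracts up to `max_imfs` IMFs. Each sifting pass fits upper/lower
#' cubic-spline envelopes through the (optionally halved) maxima/minima,
#' subtracts the mean envelope, and stops when the normalized
#' squared-difference sum between successive mean envelopes drops below
#' `stop_threshold`, or when fewer than 3 extrema remain, or at the
#' iteration cap. The residue is whatever remains after the last IMF.
#'
#' @param x numeric signal, length >= 8, all finite.
#' @param config a [sift_config()].
#' @return an object of class `imf_set`: list with `imfs` (list of numeric
#'   vectors), `residue`, `n_sift_iterations` (per IMF) and `source_length`.
#'   The element-wise sum of IMFs and residue reproduces `x` to within
#'   `1e-8 * max(abs(x))`.
#' @export
sift <- function(x, config = sift_config()) {
  if (!inherits(config, "sift_config")) stop_config("sift: config must be a sift_config")
  if (length(x) < 8) stop_data("sift: signal must have length >= 8")
  if (any(!is.finite(x))) stop_data("sift: signal contains non-finite samples")
  n <- length(x)
  iter_cap <- min(config$max_sift_iter, max(1L, n %/% 2L))
  r <- as.numeric(x)
  imfs <- list()
  iters <- integer(0)
  for (k in seq_len(config$max_imfs)) {
    ext <- find_extrema(r)
    if (length(ext$maxima) + length(ext$minima) < 3) break
    h <- r
    m_prev <- NULL
    it <- 0L
    repeat {
      ext <- find_extrema(h)
      if (length(ext$maxima) + length(ext$minima) < 3 ||
          length(ext$maxima) == 0 || length(ext$minima) == 0) break
      e <- if (config$halve_extrema) halve_extrema(ext$maxima, ext$minima) else ext
      upper <- spline_envelope(e$maxima, h[e$maxima], n)
      lower <- spline_envelope(e$minima, h[e$minima], n)
      m <- (upper + lower) / 2
      h <- h - m
      it <- it + 1L
      if (!is.null(m_prev)) {
        ok <- abs(m_prev) > 1e-12
        sd_crit <- if (any(ok)) sum((m_prev[ok] - m[ok])^2 / m_prev[ok]^2) else 0
        if (sd_crit < config$stop_threshold) break
      }
      if (it >= iter_cap) break
      m_prev <- m
    }
    if (it == 0L) break
    imfs[[k]] <- h
    iters[k] <- it
    r <- r - h
  }
  structure(list(source_length = n, imfs = imfs, residue = r,
                 n_sift_iterations = iters),
            class = "imf_set")
}

#' Reconstruct a signal from its IMF set
#'
#' Element-wise sum of all IMFs plus the residue.
#'
#' @param imfset an `imf_set` from [sift()].
#' @return numeric vector of length `source_length`.
#' @export
reconstruct <- function(imfset) {
  if (!inherits(imfset, "imf_set")) stop_data("reconstruct: expected an imf_set")
  Reduce(`+`, imfset$imfs, imfset$residue)
}

#' Sum of IMFs without the residue (the "denoised" signal)
#'
#' @param imfset an `imf_set` from [sift()].
#' @return numeric vector; zero vector when no IMFs were extracted.
#' @export
imf_sum <- function(imfset) {
  if (!inherits(imfset, "imf_set")) stop_data("imf_sum: expected an imf_set")
  Reduce(`+`, imfset$imfs, numeric(imfset$source_length))
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("imf_set: %d IMFs + residue over %d samples (sift iterations: %s)\n",
              length(x$imfs), x$source_length,
              paste(x$n_sift_iterations, collapse = ", ")))
  invisible(x)
}
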