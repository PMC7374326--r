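# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# Periodogram band power via stats::spec.pgram (independent of
# eegdfc::band_power's raw-fft path).
oracle_band_power <- function(x, fs, band) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0, plot = FALSE,
                          detrend = FALSE, fast = FALSE)
  sum(sp$spec[sp$freq >= band[1] & sp$freq < band[2]])
}

# Dominant periodogram frequency of a signal.
oracle_peak_freq <- function(x, fs) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  keep <- f > 0 & f <= fs / 2
  f[keep][which.max(p[keep])]
}

# Brute-force discernibility entropy from two partitions given as lists of
# vectors: direct per-element evaluation of the formula.
oracle_discernibility <- function(C, P) {
  u <- sort(unlist(C))
  total <- 0
  for (x in u) {
    szC <- lengths(C)[vapply(C, function(b) x %in% b, logical(1))]
    szP <- lengths(P)[vapply(P, function(b) x %in% b, logical(1))]
    total <- total + log2(szC / szP)
  }
  -total / length(u)
}

# Random partition of 1..n into at most k blocks.
random_partition <- function(n, k) {
  ids <- sample.int(k, n, replace = TRUE)
  unname(split(seq_len(n), ids))
}

# Coarsen a partition by merging random block pairs.
coarsen_partition <- function(P) {
  if (length(P) < 2) return(P)
  pick <- sample.int(length(P), 2)
  merged <- c(P[[pick[1]]], P[[pick[2]]])
  c(P[-pick], list(merged))
}

# Refine a partition by splitting a random block in two.
refine_partition <- function(P) {
  sizes <- lengths(P)
  splittable <- which(sizes >= 2)
  if (!length(splittable)) return(P)
  i <- if (length(splittable) == 1) splittable else sample(splittable, 1)
  b <- P[[i]]
  cut <- sample(seq_len(length(b) - 1), 1)
  b <- sample(b)
  c(P[-i], list(sort(b[seq_len(cut)]), sort(b[-seq_len(cut)])))
}

# Reference EMD: canonical sifting with a fixed number of passes (10), all
# extrema (no halving), cubic splines via splinefun with natural ends.
# Written as an independent implementation for IMF-count comparison.
oracle_emd_n_imfs <- function(x, max_imfs = 8) {
  extrema <- function(v) {
    n <- length(v)
    d <- diff(v)
    mx <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
    mn <- which(d[-length(d)] < 0 & d[-1] >= 0) + 1L
    list(mx = mx, mn = mn)
  }
  env <- function(idx, val, n) {
    xi <- c(1 - (idx[1] - 1), idx, n + (n - idx[length(idx)]))
    yi <- c(val[1], val, val[length(val)])
    stats::splinefun(xi, yi, method = "natural")(seq_len(n))
  }
  r <- x
  count <- 0
  for (k in seq_len(max_imfs)) {
    e <- extrema(r)
    if (length(e$mx) + length(e$mn) < 3) break
    h <- r
    for (it in 1:10) {
      e <- extrema(h)
      if (length(e$mx) < 1 || length(e$mn) < 1) break
      m <- (env(e$mx, h[e$mx], length(h)) + env(e$mn, h[e$mn], length(h))) / 2
      h <- h - m
    }
    count <- count + 1
    r <- r - h
  }
  count
}
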