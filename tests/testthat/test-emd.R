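test_that("find_extrema handles inspection, plateau and monotone cases", {
  e <- find_extrema(c(0, 1, 0, 1, 0))
  expect_identical(e$maxima, c(2L, 4L))
  expect_identical(e$minima, 3L)
  e <- find_extrema(seq_len(10))           # strictly increasing ramp
  expect_identical(e$maxima, integer(0))
  expect_identical(e$minima, integer(0))
  # plateau takes the midpoint and counts once
  e <- find_extrema(c(0, 2, 2, 2, 0, -1, -1, 0))
  expect_identical(e$maxima, 3L)
  expect_identical(e$minima, 6L)
  expect_error(find_extrema(c(1, 2)), class = "eegdfc_data_error")
  expect_error(find_extrema(c(1, NA, 2)), class = "eegdfc_data_error")
})

test_that("extrema of a 5 Hz tone match the derivative-sign oracle", {
  fs <- 200
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 5 * t)
  e <- find_extrema(x)
  d <- diff(x)
  n_max_oracle <- sum(d[-length(d)] > 0 & d[-1] < 0)
  expect_lte(abs(length(e$maxima) - 5), 1)
  expect_lte(abs(length(e$minima) - 5), 1)
  expect_equal(length(e$maxima), n_max_oracle)
  # maxima and minima interleave
  merged <- sort(c(e$maxima, e$minima))
  kinds <- merged %in% e$maxima
  expect_true(all(diff(kinds) != 0))
})

test_that("halve_extrema keeps every other extremum", {
  h <- halve_extrema(c(1L, 5L, 9L, 13L), c(3L, 7L, 11L))
  expect_identical(h$maxima, c(1L, 9L))
  expect_identical(h$minima, c(3L, 11L))
  expect_identical(halve_extrema(2L, integer(0))$maxima, 2L)
  # property: length ceil(n/2), subset, sorted — against brute enumeration
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(1:10, 1)
    idx <- sort(sample(1:100, n))
    out <- halve_extrema(idx, integer(0))$maxima
    expect_identical(out, idx[seq(1, n, by = 2)])
    expect_length(out, ceiling(n / 2))
    expect_true(all(out %in% idx))
    expect_true(!is.unsorted(out))
  }
})

test_that("sift handles constants and preserves the reconstruction identity", {
  const <- rep(3.5, 64)
  s <- sift(const)
  expect_length(s$imfs, 0)
  expect_equal(s$residue, const)
  expect_error(sift(c(1, NA, rep(0, 10))), class = "eegdfc_data_error")

  fs <- 200
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  signals <- list(
    tone = sin(2 * pi * 10 * t),
    twotone = sin(2 * pi * 5 * t) + 0.5 * sin(2 * pi * 40 * t),
    chirp = sin(2 * pi * (5 * t + 0.5 * 8 * t^2)),
    noise = { set.seed(1); rnorm(256) },
    trend = t^2 + sin(2 * pi * 8 * t)
  )
  for (nm in names(signals)) {
    x <- signals[[nm]]
    for (halve in c(TRUE, FALSE)) {
      s <- sift(x, sift_config(halve_extrema = halve))
      expect_lte(length(s$imfs), 5)
      err <- max(abs(reconstruct(s) - x))
      expect_lt(err, 1e-8 * max(abs(x)))
    }
  }
})

test_that("a pure tone concentrates in the first IMF", {
  fs <- 200
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10 * t)
  s <- sift(x)
  expect_gte(length(s$imfs), 1)
  expect_gte(sum(s$imfs[[1]]^2) / sum(x^2), 0.95)
})

test_that("two-tone signals split by frequency with decreasing IMF peaks", {
  fs <- 200
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 5 * t) + sin(2 * pi * 40 * t)
  s <- sift(x)
  peaks <- vapply(s$imfs, oracle_peak_freq, numeric(1), fs = fs)
  expect_equal(peaks[1], 40, tolerance = 0.1)
  expect_true(any(abs(peaks[-1] - 5) < 1))
  # non-strictly decreasing dominant frequency across IMFs
  expect_true(all(diff(peaks) <= 1e-9))
})

test_that("each IMF except possibly the last has at least 2 extrema", {
  set.seed(3)
  x <- rnorm(400)
  s <- sift(x)
  if (length(s$imfs) > 1) {
    for (k in seq_len(length(s$imfs) - 1)) {
      e <- find_extrema(s$imfs[[k]])
      expect_gte(length(e$maxima) + length(e$minima), 2)
    }
  }
})

test_that("reconstruct is the element-wise sum and handles empty IMF sets", {
  r <- runif(32)
  empty <- structure(list(source_length = 32L, imfs = list(), residue = r,
                          n_sift_iterations = integer(0)), class = "imf_set")
  expect_identical(reconstruct(empty), r)
  set.seed(9)
  x <- rnorm(256)
  s <- sift(x)
  expect_lt(max(abs(reconstruct(s) - x)), 1e-8 * max(abs(x)))
  expect_equal(reconstruct(s), imf_sum(s) + s$residue)
})

test_that("without halving the IMF count tracks a reference EMD within 1", {
  fs <- 200
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  mixtures <- list(sin(2 * pi * 5 * t) + sin(2 * pi * 40 * t),
                   sin(2 * pi * 3 * t) + 0.7 * sin(2 * pi * 15 * t) +
                     0.4 * sin(2 * pi * 45 * t))
  for (x in mixtures) {
    ours <- length(sift(x, sift_config(halve_extrema = FALSE, max_imfs = 8))$imfs)
    ref <- oracle_emd_n_imfs(x)
    expect_lte(abs(ours - ref), 1)
  }
})
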