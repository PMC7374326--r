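test_that("vocabulary size is k_per_class x n_classes", {
  cfv3 <- toy_cfv(n_per_class = 15, n_classes = 3)
  v3 <- build_vocabulary(cfv3, k_per_class = 10, seed = 1)
  expect_identical(nrow(v3$centers), 30L)
  expect_identical(table(v3$center_class), table(rep(paste0("c", 1:3), 10)))
  # determinism under a fixed seed
  v3b <- build_vocabulary(cfv3, k_per_class = 10, seed = 1)
  expect_identical(v3$centers, v3b$centers)
  # class with too few rows errors, naming the class
  small <- toy_cfv(n_per_class = 4, n_classes = 3)
  expect_error(build_vocabulary(small, k_per_class = 10), "c1",
               class = "eegdfc_data_error")
})

test_that("k = 1 centers equal the class means", {
  cfv <- toy_cfv(n_per_class = 20, n_classes = 3, sep = 50, seed = 5)
  v <- build_vocabulary(cfv, k_per_class = 1, seed = 2)
  for (ci in 1:3) {
    cl <- paste0("c", ci)
    mu <- colMeans(cfv$rows[cfv$keys$class == cl, ])
    expect_lt(max(abs(v$centers[v$center_class == cl, ] - mu)), 1e-6)
  }
})

test_that("sweep_k SSE matches the variance oracle and is monotone", {
  cfv <- toy_cfv(n_per_class = 25, n_classes = 2, sep = 0, seed = 6)
  sse <- sweep_k(cfv, k_values = 1, seed = 3)
  # k = 1: SSE = sum over classes and dims of (n_c - 1) * var
  oracle <- sum(vapply(c("c1", "c2"), function(cl) {
    m <- cfv$rows[cfv$keys$class == cl, ]
    sum(apply(m, 2, stats::var)) * (nrow(m) - 1)
  }, numeric(1)))
  expect_equal(unname(sse), oracle, tolerance = 1e-8)
  # k = n -> 0
  sse_n <- sweep_k(cfv, k_values = 25, seed = 3)
  expect_equal(unname(sse_n), 0, tolerance = 1e-8)
  # monotone non-increasing over k in {2, 4, 8}
  s <- sweep_k(cfv, k_values = c(2, 4, 8), seed = 3, nstart = 10)
  expect_true(all(diff(s) <= 1e-6 * s[1]))
})

test_that("histogram assignment matches the brute-force oracle", {
  set.seed(20)
  vocabs_dims <- 1000
  centers <- matrix(rnorm(4 * vocabs_dims), 4, vocabs_dims)
  vocab <- structure(list(k_per_class = 2L, n_classes = 2L, centers = centers,
                          center_class = c("c1", "c1", "c2", "c2"),
                          sse = 0, seed = 1L), class = "vocabulary")
  tab <- toy_feature_table(n_units = 10, channels = c("A", "B"), seed = 21)
  h <- histogram_features(vocab, tab)
  # oracle: explicit nearest-center loop
  oracle_counts <- matrix(0L, nrow(h$counts), 4)
  units <- paste(tab$keys$subject, tab$keys$trial)
  ulev <- sort(unique(units))
  for (i in seq_len(nrow(tab$rows))) {
    d <- apply(centers, 1, function(cc) sqrt(sum((tab$rows[i, ] - cc)^2)))
    j <- which.min(d)
    u <- match(units[i], ulev)
    oracle_counts[u, j] <- oracle_counts[u, j] + 1L
  }
  expect_identical(unname(h$counts), oracle_counts)
  # count conservation: each unit contributed one row per channel
  expect_true(all(rowSums(h$counts) == 2))
})

test_that("histograms are invariant to feature-row order and handle ties", {
  vocab <- structure(list(k_per_class = 1L, n_classes = 2L,
                          centers = matrix(c(rep(0, 1000), rep(0, 1000)), 2,
                                           byrow = TRUE),
                          center_class = c("c1", "c2"), sse = 0, seed = 1L),
                     class = "vocabulary")
  tab <- toy_feature_table(n_units = 6, channels = "A", seed = 22)
  h <- histogram_features(vocab, tab)
  # identical centers: ties all go to the lowest center index
  expect_true(all(h$counts[, 1] == 1 & h$counts[, 2] == 0))
  # permuted row order gives identical histograms
  perm <- sample(nrow(tab$rows))
  tabp <- feature_table(tab$rows[perm, ], tab$keys[perm, ], stage = tab$stage)
  expect_identical(histogram_features(vocab, tabp)$counts, h$counts)
})

test_that("single-center vocabularies count every row", {
  vocab <- structure(list(k_per_class = 1L, n_classes = 1L,
                          centers = matrix(0, 1, 1000),
                          center_class = "c1", sse = 0, seed = 1L),
                     class = "vocabulary")
  tab <- toy_feature_table(n_units = 5, channels = c("A", "B", "C"), seed = 23)
  h <- histogram_features(vocab, tab)
  expect_true(all(h$counts == 3))  # one row per channel per unit
  # column mismatch is a data error
  bad <- vocab
  bad$centers <- matrix(0, 1, 10)
  expect_error(histogram_features(bad, tab), class = "eegdfc_data_error")
})
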