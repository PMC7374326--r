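test_that("discernibility entropy matches hand-derived values", {
  U4 <- list(1:4)
  expect_equal(discernibility_entropy(list(1:2, 3:4), list(1:2, 3:4)), 0)
  expect_equal(discernibility_entropy(list(1:2, 3:4), U4), 1.0)
  expect_equal(discernibility_entropy(list(1, 2, 3, 4), U4), 2.0)
  # non-partition and refinement violations are data errors
  expect_error(discernibility_entropy(list(1:2, 2:4), U4), class = "eegdfc_data_error")
  expect_error(discernibility_entropy(list(1:2, 3:4), list(1:3, 4)),
               class = "eegdfc_data_error")
  expect_error(discernibility_entropy(list(1:2), list(1:3)), class = "eegdfc_data_error")
})

test_that("entropy matches the brute-force oracle on random refinements", {
  set.seed(14)
  for (rep in 1:40) {
    n <- sample(6:16, 1)
    P <- random_partition(n, sample(2:4, 1))
    C <- P
    for (s in 1:3) C <- refine_partition(C)
    expect_equal(discernibility_entropy(C, P), oracle_discernibility(C, P))
  }
})

test_that("refinement chains obey monotonicity and the equality case", {
  set.seed(15)
  for (rep in 1:40) {
    n <- sample(8:20, 1)
    P <- random_partition(n, 2)
    B <- refine_partition(refine_partition(P))
    C <- refine_partition(refine_partition(B))
    eB <- discernibility_entropy(C, B)
    eP <- discernibility_entropy(C, P)
    expect_lte(eB, eP + 1e-12)
    expect_equal(discernibility_entropy(C, C), 0)
  }
})

test_that("channel_entropy agrees with a hand-built partition oracle", {
  # 8 observations, 2 channels, 2 bins, 1 attribute: constructed so channel
  # A's median split gives blocks {1..4}, {5..8} while the full set's
  # partition is finer via channel B
  rows_a <- matrix(0, 8, 1000); rows_a[, 1] <- c(1, 1, 2, 2, 9, 9, 10, 10)
  rows_b <- matrix(0, 8, 1000); rows_b[, 1] <- c(1, 1, 9, 9, 1, 1, 9, 9)
  keys <- function(ch) data.frame(subject = 1, trial = 1:8, channel = ch,
                                  model = "m", class = "c1")
  tab <- feature_table(rbind(rows_a, rows_b), rbind(keys("A"), keys("B")))
  eA <- channel_entropy(tab, "A", n_bins = 2, attributes = 1)
  # partitions: P_A = {1:4, 5:8}; C = A x B bins = {12, 34, 56, 78}
  oracle <- oracle_discernibility(list(1:2, 3:4, 5:6, 7:8), list(1:4, 5:8))
  expect_equal(eA, oracle)
  # channel whose features induce the full partition scores 0
  eB <- channel_entropy(tab, "B", n_bins = 2, attributes = 1)
  oracleB <- oracle_discernibility(list(1:2, 3:4, 5:6, 7:8),
                                   list(c(1, 2, 5, 6), c(3, 4, 7, 8)))
  expect_equal(eB, oracleB)
  expect_error(channel_entropy(tab, "Z"), class = "eegdfc_key_error")
})

test_that("adding attributes to the subset never increases channel entropy", {
  tab <- toy_feature_table(n_units = 16, channels = c("A", "B"), seed = 4)
  e_prev <- Inf
  for (k in c(1, 2, 4, 8)) {
    e <- channel_entropy(tab, "A", n_bins = 2, attributes = seq_len(k),
                         full_attributes = 1:8)
    expect_lte(e, e_prev + 1e-12)
    e_prev <- e
  }
})

test_that("select_channels obeys threshold semantics and symmetry", {
  tab <- toy_feature_table(n_units = 12, channels = c("A", "B", "C"),
                           informative = character(0), seed = 6)
  # all-identical channels: equal entropies, all-or-none selection
  tabs <- feature_table(rbind(tab$rows[tab$keys$channel == "A", ],
                              tab$rows[tab$keys$channel == "A", ],
                              tab$rows[tab$keys$channel == "A", ]),
                        tab$keys)
  rep_eq <- select_channels(tabs, threshold = 0.5)
  expect_length(unique(rep_eq$table$entropy), 1)
  expect_true(all(rep_eq$table$selected) || !any(rep_eq$table$selected))
  # +Inf threshold -> empty selection, flagged but legal
  rep_inf <- select_channels(tab, threshold = Inf)
  expect_true(rep_inf$empty_selection)
  expect_length(rep_inf$selected_channels, 0)
  # strict >: exact threshold ties excluded
  e <- select_channels(tab)$table$entropy[1]
  rep_tie <- select_channels(tab, threshold = e)
  expect_false(rep_tie$table$selected[1])
  # selected set is exactly the strict superlevel set
  rep <- select_channels(tab, threshold = 0)
  expect_identical(rep$table$selected, rep$table$entropy > 0)
})

test_that("informative channels outrank noise channels by entropy", {
  tab <- toy_feature_table(n_units = 24, channels = LETTERS[1:6],
                           informative = c("A", "B"), seed = 8, noise = 0.3)
  rep <- select_channels(tab, mode = "rank", top_m = 2, n_bins = 2)
  expect_setequal(rep$selected_channels, c("A", "B"))
})

test_that("concat_models stacks four aligned tables and rejects others", {
  tabs <- lapply(paste0("m", 1:4), function(m)
    toy_feature_table(n_units = 6, channels = "A", model = m, seed = 2))
  cfv <- concat_models(tabs)
  expect_identical(nrow(cfv$rows), 24L)
  expect_identical(cfv$stage, "CFV")
  expect_setequal(unique(cfv$keys$model), paste0("m", 1:4))
  expect_error(concat_models(tabs[1:3]), class = "eegdfc_data_error")
  # key mismatch is reported
  bad <- tabs
  bad[[4]]$keys$trial <- bad[[4]]$keys$trial + 100
  expect_error(concat_models(bad), "mismatch", class = "eegdfc_data_error")
})

test_that("eliminate_redundant drops near-duplicates per the greedy contract", {
  set.seed(10)
  base <- matrix(rnorm(10 * 1000), 10, 1000)
  rows <- rbind(base, base[1:5, ] + 1e-9)
  keys <- data.frame(subject = 1, trial = seq_len(15), channel = "A",
                     model = "m", class = "c1")
  cfv <- feature_table(rows, keys, stage = "CFV")
  out <- eliminate_redundant(cfv, epsilon = 1e-3)
  expect_identical(nrow(out$rows), 10L)
  expect_identical(out$stage, "CFV_rfe")
  # brute-force O(n^2) oracle: greedy scan over the full distance matrix
  D <- as.matrix(stats::dist(rows))
  keep <- logical(15)
  for (i in 1:15) keep[i] <- !any(D[i, which(keep)] < 1e-3)
  expect_identical(nrow(out$rows), sum(keep))
  expect_equal(unname(out$rows), unname(rows[keep, ]))
  # idempotence and pairwise-distance guarantee
  out2 <- eliminate_redundant(out, epsilon = 1e-3)
  expect_identical(out$rows, out2$rows)
  expect_true(all(stats::dist(out$rows) >= 1e-3))
  # epsilon 0 retains everything
  expect_identical(nrow(eliminate_redundant(cfv, epsilon = 0)$rows), 15L)
  expect_error(eliminate_redundant(cfv, epsilon = -1), class = "eegdfc_config_error")
})

test_that("apply_channel_selection restricts rows and advances the stage", {
  tab <- toy_feature_table(n_units = 6, channels = c("A", "B"), seed = 3)
  sel <- apply_channel_selection(tab, "A")
  expect_identical(unique(sel$keys$channel), "A")
  expect_identical(sel$stage, "FV_selected")
  expect_error(apply_channel_selection(tab, character(0)), class = "eegdfc_data_error")
})
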