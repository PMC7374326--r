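make_gaussians <- function(n = 200, d = 10, sep = 4, n_classes = 2, seed = 1) {
  set.seed(seed)
  per <- n %/% n_classes
  x <- NULL
  y <- NULL
  for (ci in seq_len(n_classes)) {
    m <- matrix(rnorm(per * d), per, d)
    m[, ci] <- m[, ci] + sep * ci
    x <- rbind(x, m)
    y <- c(y, rep(paste0("c", ci), per))
  }
  list(x = x, y = y)
}

test_that("all three classifiers separate well-separated Gaussians", {
  g <- make_gaussians(n = 200, d = 10, sep = 4)
  for (clf in c("svm_cubic", "knn_fine", "rf")) {
    rep <- crossval_classify(g$x, clf, n_folds = 10, seed = 2, labels = g$y)
    expect_gte(rep$accuracy, 0.95)
    expect_identical(sum(rep$per_class$TP + rep$per_class$FN), 200L)
  }
})

test_that("shuffled labels give chance-level accuracy", {
  g <- make_gaussians(n = 120, d = 5, sep = 4, n_classes = 3)
  set.seed(100)
  accs <- vapply(1:10, function(s) {
    y <- sample(g$y)   # break the label-feature link
    crossval_classify(g$x, "knn_fine", n_folds = 6, seed = s,
                      labels = y)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 1 / 3), 0.12)
})

test_that("folds are stratified, disjoint and support leave-one-out", {
  y <- rep(c("a", "b"), each = 10)
  fold <- eegdfc:::stratified_folds(y, 5, seed = 3)
  expect_identical(sort(unique(fold)), 1:5)
  expect_true(all(table(fold) == 4))
  expect_true(all(table(fold, y) == 2))     # stratification
  loo <- eegdfc:::stratified_folds(y, 20, seed = 3)
  expect_true(all(table(loo) == 1))          # leave-one-out fold sizes 1
  # single-class input errors
  g <- make_gaussians(n = 20, n_classes = 2)
  expect_error(crossval_classify(g$x, "knn_fine", labels = rep("a", 20)),
               class = "eegdfc_data_error")
  # determinism
  r1 <- crossval_classify(g$x, "rf", n_folds = 4, seed = 9, labels = g$y)
  r2 <- crossval_classify(g$x, "rf", n_folds = 4, seed = 9, labels = g$y)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$fold_accuracies, r2$fold_accuracies)
})

test_that("cost entropy matches hand evaluations", {
  t1 <- matrix(1)
  expect_lt(cost_entropy(t1, matrix(1)), 1e-9)             # clipped perfect
  expect_equal(cost_entropy(t1, matrix(0.5)), log(2) + log(2) * 0,
               tolerance = 1e-12)                           # t=1, a=0.5 -> ln 2
  # uniform 1/C over C = 4 one-hot targets matches direct summation
  targets <- diag(4)
  actual <- matrix(1 / 4, 4, 4)
  direct <- -mean(rowSums(targets * log(actual) + (1 - targets) * log(1 - actual)))
  expect_equal(cost_entropy(targets, actual), direct)
  expect_error(cost_entropy(diag(3), matrix(0.5, 2, 2)), class = "eegdfc_data_error")
})

test_that("precision/sensitivity/F1 follow the macro formulas", {
  perfect <- precision_sensitivity_f1(c(5, 5), c(0, 0), c(0, 0))
  expect_equal(unname(perfect), c(1, 1, 1))
  # P = S implies f1 = P
  r <- precision_sensitivity_f1(c(3, 3), c(1, 1), c(1, 1))
  expect_equal(r[["precision"]], r[["sensitivity"]])
  expect_equal(r[["f1"]], r[["precision"]])
  # hand arithmetic: TP=(3,2), FP=(1,2), FN=(2,1)
  h <- precision_sensitivity_f1(c(3, 2), c(1, 2), c(2, 1))
  expect_equal(h[["precision"]], 0.625)
  expect_equal(h[["sensitivity"]], (3 / 5 + 2 / 3) / 2)
  P <- 0.625; S <- (3 / 5 + 2 / 3) / 2
  expect_equal(h[["f1"]], 2 * P * S / (P + S))
  # f1 <= max(P, S) on random confusions; 0/0 -> 0
  set.seed(4)
  for (i in 1:25) {
    v <- precision_sensitivity_f1(rpois(3, 4), rpois(3, 2), rpois(3, 2))
    expect_lte(v[["f1"]], max(v[["precision"]], v[["sensitivity"]]) + 1e-12)
  }
  z <- precision_sensitivity_f1(c(0, 0), c(0, 0), c(0, 0))
  expect_equal(unname(z), c(0, 0, 0))
})

test_that("mutual information is symmetric, non-negative, MI(X,X) = H(X)", {
  set.seed(6)
  x <- rnorm(4000)
  y <- rnorm(4000)
  expect_identical(mutual_information(x, y, 8), mutual_information(y, x, 8))
  expect_gte(mutual_information(x, y, 8), 0)
  expect_equal(mutual_information(x, x, 8), binned_entropy(x, 8))
  expect_warning(mi0 <- mutual_information(rep(1, 100), x[1:100]), "degenerate")
  expect_identical(mi0, 0)
  expect_error(mutual_information(1:5, 1:6), class = "eegdfc_data_error")
})

test_that("paired t-test behaves under null, power and degeneracy", {
  expect_warning(p0 <- paired_ttest(c(1, 2, 3), c(1, 2, 3) - 0.5), "zero-variance")
  expect_true(is.na(p0))
  set.seed(7)
  # power: shifted differences give tiny p
  ps <- vapply(1:100, function(i) {
    a <- rnorm(30, mean = 1)
    paired_ttest(a + rnorm(30, sd = 0.001) * 0, rnorm(30) * 0)  # a vs 0
  }, numeric(1))
  expect_lt(stats::median(ps), 0.001)
  # agreement with stats::t.test
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(paired_ttest(a, b), stats::t.test(a, b, paired = TRUE)$p.value)
})

test_that("class distance report separates point masses and Gaussians", {
  x <- rbind(matrix(0, 5, 3), matrix(1 / sqrt(3), 5, 3))
  r <- class_distance_report(x, rep(c("a", "b"), each = 5))
  expect_equal(r$mean_intra, 0)
  expect_equal(r$mean_inter, 1)
  # one class duplicated under two labels: intra = inter
  set.seed(8)
  z <- matrix(rnorm(40), 20, 2)
  x2 <- rbind(z, z)
  r2 <- class_distance_report(x2, rep(c("a", "b"), each = 20))
  expect_equal(r2$mean_intra, r2$mean_inter, tolerance = 0.25)
  # separated Gaussians: intra < inter in every seeded draw
  for (s in 1:20) {
    g <- make_gaussians(n = 30, d = 4, sep = 6, seed = s)
    rg <- class_distance_report(g$x, g$y)
    expect_lt(rg$mean_intra, rg$mean_inter)
  }
})

test_that("svm vote scores and rf probabilities are proper", {
  g <- make_gaussians(n = 60, d = 5, sep = 3, n_classes = 3, seed = 11)
  fit <- eegdfc:::fit_svm_cubic(g$x, g$y)
  sc <- eegdfc:::predict_scores(fit, g$x)
  expect_equal(unname(rowSums(sc)), rep(1, 60))
  set.seed(1)
  fit_rf <- eegdfc:::fit_rf(g$x, g$y, ntree = 25)
  sc_rf <- eegdfc:::predict_scores(fit_rf, g$x)
  expect_equal(unname(rowSums(sc_rf)), rep(1, 60), tolerance = 1e-9)
  expect_true(all(sc_rf >= 0 & sc_rf <= 1))
})
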