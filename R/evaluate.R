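# Cross-validated classification and evaluation metrics: pooled accuracy,
# macro precision/sensitivity/F1, binary cross-entropy cost, paired t-test,
# plug-in mutual information and class-distance summaries.

# Extract (x, labels, subjects) from the containers the pipeline produces.
as_dataset <- function(features, labels = NULL) {
  if (inherits(features, "histogram_features")) {
    list(x = features$counts, labels = features$units$class,
         subjects = features$units$subject)
  } else if (inherits(features, "feature_table")) {
    list(x = features$rows, labels = as.character(features$keys$class),
         subjects = features$keys$subject)
  } else if (is.matrix(features) || is.data.frame(features)) {
    if (is.null(labels)) stop_data("crossval_classify: labels are required for matrix input")
    list(x = as.matrix(features), labels = as.character(labels),
         subjects = NULL)
  } else stop_data("crossval_classify: unsupported feature container")
}

# Stratified fold assignment: shuffle within class (seeded), then deal into
# folds with a global rotating counter so fold sizes stay balanced and
# n_folds == n gives leave-one-out.
stratified_folds <- function(labels, n_folds, seed) {
  n <- length(labels)
  n_folds <- as.integer(n_folds)
  fold <- integer(n)
  ctr <- 0L
  with_seed(derive_seed(seed, 7L), {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- if (length(idx) > 1) sample(idx) else idx
      for (i in idx) {
        fold[i] <- (ctr %% n_folds) + 1L
        ctr <- ctr + 1L
      }
    }
  })
  fold
}

#' Cross-validated classification
#'
#' Stratified, non-overlapping k-fold cross-validation (default 10-fold)
#' with one of three classifiers: `"svm_cubic"` (one-vs-one SVM with a
#' degree-3 polynomial kernel, solved as a dual QP), `"knn_fine"` (1-nearest
#' neighbour, Euclidean), or `"rf"` (random forest, 100 trees). Predictions
#' are pooled over folds; the report carries pooled accuracy, per-class
#' confusion counts, macro precision/sensitivity/F1, the cross-entropy cost
#' of the pooled class scores, mutual information between predicted and true
#' labels, and per-fold accuracies. Deterministic for a fixed seed.
#'
#' @param features a [histogram_features()], a [feature_table()], or a
#'   numeric matrix (then `labels` is required).
#' @param classifier `"svm_cubic"`, `"knn_fine"` or `"rf"`.
#' @param n_folds number of folds (>= 2; `n_folds = n` is leave-one-out).
#' @param seed integer seed controlling fold assignment and classifier
#'   randomness.
#' @param labels class labels for matrix input.
#' @param group_by_subject assign whole subjects to folds (subject-independent
#'   evaluation) instead of stratified trial-level folds.
#' @param ... passed to the classifier fit (e.g. `ntree`, `cost`).
#' @return object of class `evaluation_report`.
#' @export
crossval_classify <- function(features, classifier = c("svm_cubic", "knn_fine", "rf"),
                              n_folds = 10, seed = 1, labels = NULL,
                              group_by_subject = FALSE, ...) {
  classifier <- match.arg(classifier)
  ds <- as_dataset(features, labels)
  y <- factor(ds$labels)
  if (nlevels(y) < 2) stop_data("crossval_classify: need at least 2 classes")
  n <- nrow(ds$x)
  if (!is_count(n_folds, min = 2) || n_folds > n)
    stop_config("crossval_classify: n_folds must be in 2..n_units")
  if (group_by_subject) {
    if (is.null(ds$subjects)) stop_data("crossval_classify: no subject ids available for grouping")
    subj <- unique(ds$subjects)
    sf <- with_seed(derive_seed(seed, 11L), sample(rep_len(seq_len(n_folds), length(subj))))
    fold <- sf[match(ds$subjects, subj)]
  } else {
    fold <- stratified_folds(as.character(y), n_folds, seed)
  }
  classes <- levels(y)
  pred <- character(n)
  scores <- matrix(NA_real_, n, length(classes), dimnames = list(NULL, classes))
  fold_acc <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    test <- fold == f
    if (!any(test)) { fold_acc[f] <- NA_real_; next }
    fit <- with_seed(derive_seed(seed, 100L + f),
                     fit_classifier(classifier, ds$x[!test, , drop = FALSE],
                                    y[!test], ...))
    sc <- with_seed(derive_seed(seed, 200L + f),
                    predict_scores(fit, ds$x[test, , drop = FALSE]))
    sc <- sc[, classes, drop = FALSE]
    pred[test] <- classes[max.col(sc, ties.method = "first")]
    scores[test, ] <- sc
    fold_acc[f] <- mean(pred[test] == as.character(y)[test])
  }
  truth <- as.character(y)
  confusion <- table(factor(truth, classes), factor(pred, classes))
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  psf <- precision_sensitivity_f1(tp, fp, fn)
  targets <- matrix(0, n, length(classes))
  targets[cbind(seq_len(n), as.integer(y))] <- 1
  structure(list(classifier = classifier,
                 accuracy = mean(pred == truth),
                 confusion = confusion,
                 per_class = data.frame(class = classes, TP = as.integer(tp),
                                        FP = as.integer(fp), FN = as.integer(fn)),
                 precision = psf[["precision"]],
                 sensitivity = psf[["sensitivity"]],
                 f1 = psf[["f1"]],
                 cost = cost_entropy(targets, scores),
                 mi = mutual_information(as.integer(factor(pred, classes)),
                                         as.integer(y), n_bins = length(classes)),
                 t_test_p = NA_real_,
                 fold_accuracies = fold_acc,
                 n_folds = n_folds, seed = seed),
            class = "evaluation_report")
}

#' Binary cross-entropy cost over classes
#'
#' `Cost = -(1/n) * sum_rows sum_c [t * ln(a) + (1 - t) * ln(1 - a)]`, the
#' mean (over rows, i.e. training traits) of the summed per-class binary
#' cross-entropies. Probabilities are clipped to `[1e-12, 1 - 1e-12]`.
#'
#' @param targets one-hot (or binary) numeric matrix.
#' @param actual matrix of predicted probabilities, same shape.
#' @return non-negative scalar (nats).
#' @export
cost_entropy <- function(targets, actual) {
  targets <- as.matrix(targets)
  actual <- as.matrix(actual)
  if (!all(dim(targets) == dim(actual)))
    stop_data("cost_entropy: targets and actual must have identical shape")
  a <- pmin(1 - 1e-12, pmax(1e-12, actual))
  -sum(targets * log(a) + (1 - targets) * log(1 - a)) / nrow(targets)
}

#' Macro-averaged precision, sensitivity and F1
#'
#' `P = (1/N) * sum_c TP_c / (TP_c + FP_c)`, likewise `S` with FN, and
#' `F1 = 2 * P * S / (P + S)`. Degenerate `0/0` class ratios count as 0.
#'
#' @param tp,fp,fn non-negative integer vectors, one entry per class.
#' @return named numeric vector `precision`, `sensitivity`, `f1`.
#' @export
precision_sensitivity_f1 <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop_data("precision_sensitivity_f1: counts must be >= 0")
  safe_ratio <- function(num, den) ifelse(den == 0, 0, num / den)
  P <- mean(safe_ratio(tp, tp + fp))
  S <- mean(safe_ratio(tp, tp + fn))
  f1 <- if (P + S == 0) 0 else 2 * P * S / (P + S)
  c(precision = P, sensitivity = S, f1 = f1)
}

#' Plug-in mutual information from a joint histogram
#'
#' Bins `x` and `y` into `n_bins` equal-width bins each and computes
#' `MI = sum p(x, y) * log(p(x, y) / (p(x) p(y)))` in nats (or bits).
#' Non-negative and symmetric; a constant input yields 0 with a warning.
#'
#' @param x,y numeric vectors of equal length (>= `n_bins^2` recommended).
#' @param n_bins equal-width bins per axis.
#' @param unit `"nats"` (natural log, default) or `"bits"`.
#' @return non-negative scalar.
#' @export
mutual_information <- function(x, y, n_bins = 8, unit = c("nats", "bits")) {
  unit <- match.arg(unit)
  if (length(x) != length(y)) stop_data("mutual_information: x and y must have equal length")
  bin <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) return(NULL)
    findInterval(v, seq(r[1], r[2], length.out = n_bins + 1),
                 rightmost.closed = TRUE, all.inside = TRUE)
  }
  bx <- bin(x); by <- bin(y)
  if (is.null(bx) || is.null(by)) {
    warning("mutual_information: degenerate (constant) input; returning 0")
    return(0)
  }
  joint <- table(bx, by) / length(x)
  px <- rowSums(joint); py <- colSums(joint)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
  if (unit == "bits") mi / log(2) else mi
}

#' Entropy of an equal-width binned variable
#'
#' Companion to [mutual_information()]: `MI(X, X)` equals this entropy.
#'
#' @param x numeric vector.
#' @param n_bins equal-width bins.
#' @param unit `"nats"` or `"bits"`.
#' @return non-negative scalar.
#' @export
binned_entropy <- function(x, n_bins = 8, unit = c("nats", "bits")) {
  unit <- match.arg(unit)
  r <- range(x)
  if (r[1] == r[2]) return(0)
  b <- findInterval(x, seq(r[1], r[2], length.out = n_bins + 1),
                    rightmost.closed = TRUE, all.inside = TRUE)
  p <- as.numeric(table(b)) / length(x)
  h <- -sum(p * log(p))
  if (unit == "bits") h / log(2) else h
}

#' Two-sided paired t-test p-value
#'
#' Compares paired score vectors (e.g. per-fold accuracies of two feature
#' representations). Zero-variance differences make the statistic
#' undefined; `NA` is returned with a warning.
#'
#' @param scores_a,scores_b equal-length numeric vectors (length >= 2).
#' @return p-value in `[0, 1]`, or `NA` when undefined.
#' @export
paired_ttest <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b) || length(scores_a) < 2)
    stop_data("paired_ttest: need equal-length vectors of length >= 2")
  d <- scores_a - scores_b
  if (stats::sd(d) == 0) {
    warning("paired_ttest: zero-variance differences; p-value undefined")
    return(NA_real_)
  }
  stats::t.test(scores_a, scores_b, paired = TRUE)$p.value
}

#' Intra-/inter-class distance and correlation summary
#'
#' Mean Euclidean distance over all within-class and between-class row
#' pairs, plus the mean Pearson correlation of rows within and between
#' classes. Well-separated classes have intra < inter distance.
#'
#' @param features numeric matrix (rows = observations).
#' @param labels class labels, length `nrow(features)`.
#' @return list `mean_intra`, `mean_inter`, `pearson_intra`,
#'   `pearson_inter`.
#' @export
class_distance_report <- function(features, labels) {
  x <- as.matrix(features)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop_data("class_distance_report: need >= 2 classes")
  D <- as.matrix(stats::dist(x))
  same <- outer(labels, labels, "==")
  ut <- upper.tri(D)
  res <- list(mean_intra = mean(D[ut & same]), mean_inter = mean(D[ut & !same]))
  if (ncol(x) >= 2 && all(apply(x, 1, stats::sd) > 0)) {
    R <- suppressWarnings(stats::cor(t(x)))
    res$pearson_intra <- mean(R[ut & same])
    res$pearson_inter <- mean(R[ut & !same])
  } else {
    res$pearson_intra <- NA_real_
    res$pearson_inter <- NA_real_
  }
  res
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report [%s, %d-fold]: accuracy %.3f, P %.3f, S %.3f, F1 %.3f, cost %.3f\n",
              x$classifier, x$n_folds, x$accuracy, x$precision, x$sensitivity,
              x$f1, x$cost))
  invisible(x)
}
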