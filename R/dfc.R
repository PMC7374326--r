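# Deep Feature Clustering: per-class k-means vocabularies and
# histogram-of-features.
#
# A vocabulary is the stack of k cluster centers per class (k x n_classes
# centers in total). Each deep-feature row is then matched to its nearest
# center and the per-unit (subject, trial) match counts form the reduced
# histogram representation.

#' Build a per-class k-means vocabulary
#'
#' Runs k-means (k-means++-free stats::kmeans with `nstart` restarts,
#' 300-iteration cap, seeded per class) on each class's feature rows and
#' stacks the centers class by class. The total vocabulary size is
#' `k_per_class * n_classes`.
#'
#' @param cfv a [feature_table()] whose key `class` labels the rows.
#' @param k_per_class clusters per class (default 10, the elbow of the SSE
#'   sweep in the published setting).
#' @param seed integer seed; results are deterministic for a fixed seed.
#' @param nstart random restarts per class (default 10).
#' @return object of class `vocabulary`: `centers`
#'   (`(k_per_class * n_classes) x 1000`), `center_class`, `k_per_class`,
#'   `n_classes`, total within-cluster `sse`, `seed`.
#' @export
build_vocabulary <- function(cfv, k_per_class = 10, seed = 1, nstart = 10) {
  if (!inherits(cfv, "feature_table")) stop_data("build_vocabulary: expected a feature_table")
  if (!is_count(k_per_class)) stop_config("build_vocabulary: k_per_class must be >= 1")
  cls <- as.character(cfv$keys$class)
  classes <- sort(unique(cls))
  if (length(classes) < 2) stop_data("build_vocabulary: need at least 2 classes")
  centers <- NULL
  center_class <- character(0)
  sse <- 0
  for (i in seq_along(classes)) {
    rows <- cfv$rows[cls == classes[i], , drop = FALSE]
    if (nrow(rows) < k_per_class)
      stop_data("build_vocabulary: class '", classes[i], "' has ", nrow(rows),
                " rows, fewer than k_per_class = ", k_per_class)
    if (nrow(rows) == k_per_class) {
      # one point per cluster: exact solution, SSE 0 (kmeans refuses k = n)
      km <- list(centers = rows, tot.withinss = 0)
    } else {
      km <- with_seed(derive_seed(seed, i), suppressWarnings(
        stats::kmeans(rows, centers = k_per_class, nstart = nstart,
                      iter.max = 300)))
    }
    centers <- rbind(centers, km$centers)
    center_class <- c(center_class, rep(classes[i], k_per_class))
    sse <- sse + km$tot.withinss
  }
  structure(list(k_per_class = as.integer(k_per_class),
                 n_classes = length(classes), centers = unname(centers),
                 center_class = center_class, sse = sse,
                 seed = as.integer(seed)),
            class = "vocabulary")
}

#' Sweep k and report the within-cluster SSE
#'
#' Builds a vocabulary for every `k` in `k_values` and returns the total
#' within-cluster sum of squared errors, the quantity minimized when
#' choosing `k` by elbow inspection. With enough restarts SSE is
#' non-increasing in `k` up to Monte Carlo tolerance.
#'
#' @param cfv a [feature_table()] with class labels.
#' @param k_values integer vector of candidate `k_per_class` values.
#' @param seed integer seed.
#' @param nstart restarts per k-means run.
#' @return named numeric vector: SSE per k.
#' @export
sweep_k <- function(cfv, k_values = 2:10, seed = 1, nstart = 10) {
  if (!length(k_values) || !all(vapply(k_values, is_count, logical(1))))
    stop_config("sweep_k: k_values must be positive integers")
  sse <- vapply(k_values, function(k)
    build_vocabulary(cfv, k_per_class = k, seed = seed, nstart = nstart)$sse,
    numeric(1))
  names(sse) <- k_values
  sse
}

#' Histogram-of-features against a vocabulary
#'
#' Assigns every feature row to its nearest vocabulary center (Euclidean;
#' ties go to the lowest center index) and accumulates counts per
#' observation unit (subject, trial). Row sums equal the number of feature
#' rows contributed by each unit.
#'
#' @param vocab a [build_vocabulary()] result.
#' @param features a [feature_table()] restricted to the selected channels.
#' @param normalize L1-normalize each histogram row (default `FALSE`,
#'   raw frequencies of occurrence).
#' @return object of class `histogram_features`: `counts`
#'   (`n_units x vocabulary_size`), `units` data frame (subject, trial,
#'   class), `normalized` flag.
#' @export
histogram_features <- function(vocab, features, normalize = FALSE) {
  if (!inherits(vocab, "vocabulary")) stop_data("histogram_features: expected a vocabulary")
  if (!inherits(features, "feature_table")) stop_data("histogram_features: expected a feature_table")
  if (ncol(features$rows) != ncol(vocab$centers))
    stop_data("histogram_features: feature columns (", ncol(features$rows),
              ") do not match vocabulary columns (", ncol(vocab$centers), ")")
  assign <- nearest_center(features$rows, vocab$centers)
  uf <- factor(paste(features$keys$subject, features$keys$trial, sep = "\r"))
  counts <- unclass(table(uf, factor(assign, levels = seq_len(nrow(vocab$centers)))))
  dimnames(counts) <- NULL
  counts <- matrix(as.integer(counts), nrow = nlevels(uf))
  parts <- do.call(rbind, strsplit(levels(uf), "\r", fixed = TRUE))
  cls <- tapply(as.character(features$keys$class), uf, function(v) {
    u <- unique(v)
    if (length(u) != 1) stop_data("histogram_features: conflicting class labels within a unit")
    u
  })
  units <- data.frame(subject = type.convert(parts[, 1], as.is = TRUE),
                      trial = type.convert(parts[, 2], as.is = TRUE),
                      class = as.character(cls[levels(uf)]),
                      stringsAsFactors = FALSE)
  if (normalize) {
    rs <- rowSums(counts)
    counts <- counts / pmax(1, rs)
  }
  structure(list(counts = counts, units = units, normalized = normalize),
            class = "histogram_features")
}

# Nearest-center assignment (Euclidean); ties resolved to the lowest center
# index.
nearest_center <- function(rows, centers) {
  s <- tcrossprod(rows, centers)                 # n x k inner products
  d2 <- sweep(-2 * s, 2, rowSums(centers^2), "+")  # + |c|^2 (row norms cancel in argmin)
  max.col(-d2, ties.method = "first")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("vocabulary: %d centers (%d per class x %d classes), SSE %.4g (seed %d)\n",
              nrow(x$centers), x$k_per_class, x$n_classes, x$sse, x$seed))
  invisible(x)
}

#' @export
print.histogram_features <- function(x, ...) {
  cat(sprintf("histogram_features: %d units x %d vocabulary entries%s\n",
              nrow(x$counts), ncol(x$counts),
              if (x$normalized) " (L1-normalized)" else ""))
  invisible(x)
}
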