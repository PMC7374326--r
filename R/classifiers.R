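# Internal classifiers: cubic-kernel SVM (one-vs-one dual QP), fine (k=1)
# k-NN, and a compact random forest. Each returns a fitted object with a
# common predict interface yielding hard labels and per-class scores in
# [0, 1] summing to 1.

# ---- cubic-kernel SVM ------------------------------------------------------

# Polynomial kernel (gamma * <x, y> + coef0)^degree, libsvm-style defaults.
poly_kernel <- function(A, B, gamma, coef0, degree) {
  (gamma * tcrossprod(A, B) + coef0)^degree
}

fit_svm_cubic <- function(x, y, cost = 1, degree = 3, coef0 = 1, gamma = NULL) {
  y <- factor(y)
  x <- as.matrix(x)
  gamma <- gamma %||% (1 / ncol(x))
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(x, ctr, scl)
  classes <- levels(y)
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  models <- lapply(pairs, function(pr) {
    sel <- y %in% pr
    xi <- xs[sel, , drop = FALSE]
    yy <- ifelse(y[sel] == pr[1], 1, -1)
    n <- nrow(xi)
    K <- poly_kernel(xi, xi, gamma, coef0, degree)
    Q <- (yy %o% yy) * K
    diag(Q) <- diag(Q) + 1e-8 * max(1, mean(abs(diag(Q))))
    sol <- quadprog::solve.QP(
      Dmat = Q, dvec = rep(1, n),
      Amat = cbind(yy, diag(n), -diag(n)),
      bvec = c(0, rep(0, n), rep(-cost, n)), meq = 1)
    alpha <- pmin(cost, pmax(0, sol$solution))
    sv <- alpha > 1e-8 * cost
    coefs <- (alpha * yy)[sv]
    xsv <- xi[sv, , drop = FALSE]
    on_margin <- sv & alpha < cost * (1 - 1e-6)
    ref <- if (any(on_margin)) which(on_margin) else which(sv)
    f_ref <- poly_kernel(xi[ref, , drop = FALSE], xsv, gamma, coef0, degree) %*% coefs
    b <- mean(yy[ref] - f_ref)
    list(pair = pr, coefs = coefs, sv = xsv, b = b)
  })
  structure(list(models = models, classes = classes, center = ctr, scale = scl,
                 gamma = gamma, coef0 = coef0, degree = degree),
            class = "eegdfc_svm")
}

predict_scores.eegdfc_svm <- function(fit, newx) {
  xs <- scale(as.matrix(newx), fit$center, fit$scale)
  votes <- matrix(0, nrow(xs), length(fit$classes),
                  dimnames = list(NULL, fit$classes))
  for (m in fit$models) {
    f <- poly_kernel(xs, m$sv, fit$gamma, fit$coef0, fit$degree) %*% m$coefs + m$b
    win <- ifelse(f >= 0, m$pair[1], m$pair[2])
    for (cl in m$pair) votes[, cl] <- votes[, cl] + (win == cl)
  }
  votes / length(fit$models)
}

# ---- fine k-NN (k = 1) -----------------------------------------------------

fit_knn_fine <- function(x, y, k = 1) {
  structure(list(x = as.matrix(x), y = factor(y), k = k,
                 classes = levels(factor(y))),
            class = "eegdfc_knn")
}

predict_scores.eegdfc_knn <- function(fit, newx) {
  pred <- FNN::knn(fit$x, as.matrix(newx), fit$y, k = fit$k)
  scores <- matrix(0, nrow(as.matrix(newx)), length(fit$classes),
                   dimnames = list(NULL, fit$classes))
  scores[cbind(seq_along(pred), match(as.character(pred), fit$classes))] <- 1
  scores
}

# ---- random forest ---------------------------------------------------------

# CART-style trees, gini splitting, feature subsampling (mtry), bootstrap
# bagging. Nodes are stored in a flat list; leaves carry class proportions.

grow_tree <- function(x, y_int, n_classes, mtry, min_node = 5, max_depth = 20) {
  nodes <- list()
  new_node <- function(node) { nodes[[length(nodes) + 1]] <<- node; length(nodes) }
  build <- function(idx, depth) {
    counts <- tabulate(y_int[idx], n_classes)
    if (length(idx) < min_node || depth >= max_depth || sum(counts > 0) == 1)
      return(new_node(list(leaf = TRUE, prob = counts / sum(counts))))
    feats <- sample.int(ncol(x), mtry)
    best <- NULL
    parent_gini <- 1 - sum((counts / length(idx))^2)
    for (f in feats) {
      xv <- x[idx, f]
      ord <- order(xv)
      xo <- xv[ord]
      yo <- y_int[idx][ord]
      n <- length(idx)
      onehot <- matrix(0L, n, n_classes)
      onehot[cbind(seq_len(n), yo)] <- 1L
      cs <- apply(onehot, 2, cumsum)
      if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1)
      i <- seq_len(n - 1)
      valid <- xo[i] < xo[i + 1]
      if (!any(valid)) next
      nl <- i
      nr <- n - i
      gl <- 1 - rowSums((cs[i, , drop = FALSE] / nl)^2)
      right <- sweep(-cs[i, , drop = FALSE], 2, counts, "+")
      gr <- 1 - rowSums((right / nr)^2)
      w <- (nl * gl + nr * gr) / n
      w[!valid] <- Inf
      j <- which.min(w)
      if (w[j] < (best$score %||% parent_gini) - 1e-12)
        best <- list(score = w[j], feat = f, thr = (xo[j] + xo[j + 1]) / 2)
    }
    if (is.null(best))
      return(new_node(list(leaf = TRUE, prob = counts / sum(counts))))
    go_left <- x[idx, best$feat] <= best$thr
    left_id <- build(idx[go_left], depth + 1)
    right_id <- build(idx[!go_left], depth + 1)
    new_node(list(leaf = FALSE, feat = best$feat, thr = best$thr,
                  left = left_id, right = right_id))
  }
  root <- build(seq_len(nrow(x)), 0)
  list(nodes = nodes, root = root)
}

tree_predict_prob <- function(tree, newx, n_classes) {
  out <- matrix(0, nrow(newx), n_classes)
  for (r in seq_len(nrow(newx))) {
    id <- tree$root
    repeat {
      node <- tree$nodes[[id]]
      if (node$leaf) { out[r, ] <- node$prob; break }
      id <- if (newx[r, node$feat] <= node$thr) node$left else node$right
    }
  }
  out
}

fit_rf <- function(x, y, ntree = 100, mtry = NULL, min_node = 5) {
  x <- as.matrix(x)
  y <- factor(y)
  classes <- levels(y)
  y_int <- as.integer(y)
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(x))))
  trees <- lapply(seq_len(ntree), function(t) {
    boot <- sample.int(nrow(x), nrow(x), replace = TRUE)
    grow_tree(x[boot, , drop = FALSE], y_int[boot], length(classes), mtry,
              min_node = min_node)
  })
  structure(list(trees = trees, classes = classes),
            class = "eegdfc_rf")
}

predict_scores.eegdfc_rf <- function(fit, newx) {
  newx <- as.matrix(newx)
  acc <- matrix(0, nrow(newx), length(fit$classes),
                dimnames = list(NULL, fit$classes))
  for (tr in fit$trees) acc <- acc + tree_predict_prob(tr, newx, length(fit$classes))
  acc / length(fit$trees)
}

# ---- dispatch --------------------------------------------------------------

fit_classifier <- function(classifier, x, y, ...) {
  switch(classifier,
         svm_cubic = fit_svm_cubic(x, y, ...),
         knn_fine = fit_knn_fine(x, y, ...),
         rf = fit_rf(x, y, ...),
         stop_config("unknown classifier '", classifier, "'"))
}

predict_scores <- function(fit, newx) {
  switch(class(fit),
         eegdfc_svm = predict_scores.eegdfc_svm(fit, newx),
         eegdfc_knn = predict_scores.eegdfc_knn(fit, newx),
         eegdfc_rf = predict_scores.eegdfc_rf(fit, newx))
}
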