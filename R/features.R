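# 1000-attribute deep-feature rows per spectrogram image.
#
# Pretrained CNN backbones (ResNet-50, GoogLeNet, Inception V4, VGG-16) are
# adapters tapping a 1000-way fully connected layer; they require externally
# supplied weights and are not bundled. The `lite` extractor is a
# self-contained stand-in with the same 1000-column contract: pooled image
# patch statistics passed through a fixed seeded random projection and a
# ReLU, so the whole pipeline is testable offline.

FEATURE_DIM <- 1000L

#' Rectified linear unit
#'
#' `max(0, x)`, vectorized and shape-preserving.
#'
#' @param x numeric vector, matrix or array.
#' @return numeric of the same shape.
#' @export
relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Specification of a deep-feature extractor
#'
#' @param name one of `"lite"`, `"resnet50"`, `"googlenet"`,
#'   `"inception_v4"`, `"vgg16"`. Only `"lite"` runs without external
#'   weights.
#' @param weights_source optional path/URI to pretrained weights (adapters).
#' @param seed integer seed for the lite extractor's fixed projection.
#' @param layer tapped fully connected layer name for pretrained adapters.
#' @param label model name recorded in feature-table keys; defaults to
#'   `name` (for lite, `"lite<seed>"`), letting several seeded lite
#'   extractors play the role of distinct models.
#' @return an object of class `extractor_spec`.
#' @export
extractor_spec <- function(name = c("lite", "resnet50", "googlenet",
                                    "inception_v4", "vgg16"),
                           weights_source = NULL, seed = 1, layer = NULL,
                           label = NULL) {
  name <- match.arg(name)
  if (!is_count(seed, min = 0)) stop_config("extractor_spec: seed must be a non-negative integer")
  label <- label %||% if (name == "lite") paste0("lite", seed) else name
  structure(list(name = name, weights_source = weights_source,
                 seed = as.integer(seed), layer = layer, label = label),
            class = "extractor_spec")
}

# Fixed seeded 384 x 1000 Gaussian projection for the lite extractor.
lite_projection <- function(seed) {
  with_seed(derive_seed(seed, 384L, FEATURE_DIM),
            matrix(stats::rnorm(384 * FEATURE_DIM, sd = 1 / sqrt(384)),
                   nrow = 384, ncol = FEATURE_DIM))
}

# 8x8 grid of per-cell mean and SD per RGB channel -> 384 values in [0, 1]
# scale. Cell size must divide the image edge (224 -> 28).
image_patch_stats <- function(pixels) {
  d <- dim(pixels)
  if (length(d) != 3 || d[3] != 3 || d[1] != d[2] || d[1] %% 8 != 0)
    stop_data("image_patch_stats: expected a square size x size x 3 array with size divisible by 8")
  g <- rep(seq_len(8), each = d[1] / 8)
  out <- numeric(0)
  for (ch in 1:3) {
    p <- pixels[, , ch] / 255
    s1 <- rowsum(p, g)                   # sum over row blocks
    s1 <- t(rowsum(t(s1), g))            # then column blocks -> 8 x 8 sums
    s2 <- rowsum(p^2, g)
    s2 <- t(rowsum(t(s2), g))
    ncell <- (d[1] / 8)^2
    mu <- s1 / ncell
    sdv <- sqrt(pmax(0, s2 / ncell - mu^2))
    out <- c(out, as.numeric(mu), as.numeric(sdv))
  }
  out
}

#' A table of 1000-attribute deep-feature rows
#'
#' @param rows numeric matrix with exactly 1000 columns, finite entries.
#' @param keys data frame with columns `subject`, `trial`, `channel`,
#'   `model`, `class`; rows parallel to `rows` and unique on
#'   (subject, trial, channel, model).
#' @param stage processing stage tag, one of `"FV"`, `"FV_selected"`,
#'   `"CFV"`, `"CFV_rfe"`.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(rows, keys, stage = "FV") {
  rows <- as.matrix(rows)
  if (ncol(rows) != FEATURE_DIM)
    stop_data("feature_table: rows must have exactly ", FEATURE_DIM, " columns")
  if (any(!is.finite(rows))) stop_data("feature_table: rows must be finite")
  keys <- as.data.frame(keys)
  need <- c("subject", "trial", "channel", "model", "class")
  if (!all(need %in% names(keys)))
    stop_data("feature_table: keys must have columns ", paste(need, collapse = ", "))
  if (nrow(keys) != nrow(rows)) stop_data("feature_table: keys and rows must align")
  id <- paste(keys$subject, keys$trial, keys$channel, keys$model, sep = "\r")
  if (anyDuplicated(id)) stop_data("feature_table: duplicate (subject, trial, channel, model) keys")
  stage <- match.arg(stage, c("FV", "FV_selected", "CFV", "CFV_rfe"))
  structure(list(rows = rows, keys = keys, stage = stage),
            class = "feature_table")
}

#' Extract deep features from spectrogram images
#'
#' One 1000-dimensional row per image, deterministic for a fixed extractor
#' and image. The `lite` extractor computes an 8x8 grid of per-cell
#' mean/SD per RGB channel (384 values), applies a fixed seeded
#' `384 x 1000` Gaussian projection, and rectifies. Pretrained names
#' require externally supplied weights and raise a dependency error here.
#'
#' @param images list of `spectro_image` objects (provenance must carry
#'   subject, trial, channel and class).
#' @param extractor an [extractor_spec()].
#' @return a [feature_table()] with `length(images)` rows.
#' @export
extract_features <- function(images, extractor = extractor_spec("lite")) {
  if (!inherits(extractor, "extractor_spec")) stop_config("extract_features: extractor must be an extractor_spec")
  if (extractor$name != "lite")
    stop_dependency("extract_features: pretrained extractor '", extractor$name,
                    "' requires external weights (none bundled); use the 'lite' extractor ",
                    "or supply a weights adapter")
  if (!length(images)) stop_data("extract_features: no images given")
  stats_mat <- t(vapply(images, function(im) {
    if (!inherits(im, "spectro_image")) stop_data("extract_features: images must be spectro_image objects")
    image_patch_stats(im$pixels)
  }, numeric(384)))
  rows <- lite_features_from_stats(stats_mat, extractor$seed)
  keys <- do.call(rbind, lapply(images, function(im) {
    pv <- im$provenance
    if (is.null(pv$subject) || is.null(pv$trial) || is.null(pv$channel))
      stop_data("extract_features: image provenance must carry subject, trial and channel")
    data.frame(subject = pv$subject, trial = pv$trial, channel = pv$channel,
               model = extractor$label, class = pv$class %||% NA_character_,
               stringsAsFactors = FALSE)
  }))
  feature_table(rows, keys, stage = "FV")
}

# Shared path for the lite extractor so pipelines can compute patch stats
# once and project them under several model seeds.
lite_features_from_stats <- function(stats_mat, seed) {
  relu(stats_mat %*% lite_projection(seed))
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table [%s]: %d rows x %d attributes, %d model(s), %d channel(s)\n",
              x$stage, nrow(x$rows), ncol(x$rows),
              length(unique(x$keys$model)), length(unique(x$keys$channel))))
  invisible(x)
}
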