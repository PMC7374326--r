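# Discernibility-entropy channel selection, multi-model fusion and
# redundant feature elimination.
#
# Channel quality is scored with a rough-set style discernibility entropy:
# observations are partitioned by their binned feature values, once under
# the full feature set (partition C) and once under the candidate channel's
# features alone (partition P; C refines P by construction), and
#   E(P | U + C) = -(1/|U|) * sum_x log2(|x_C| / |x_P|)
# where x_C, x_P are the partition blocks containing observation x. E is 0
# iff the channel alone discerns observations exactly as the full set does,
# and can only decrease as attributes are added to the subset.

# ---- partitions ------------------------------------------------------------

# A partition is a list of disjoint vectors covering a universe. Validate and
# return a named block-id vector over sorted universe elements.
partition_ids <- function(blocks, what) {
  if (!is.list(blocks) || !length(blocks)) stop_data(what, ": partition must be a non-empty list of blocks")
  u <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(u)) stop_data(what, ": partition blocks overlap")
  ids <- rep(seq_along(blocks), lengths(blocks))
  names(ids) <- as.character(u)
  ids
}

#' Discernibility entropy between two partitions
#'
#' For partitions C and P of the same finite universe U, with C refining P,
#' computes `E = -(1/|U|) * sum_{x in U} log2(|x_C| / |x_P|)` where `x_C`,
#' `x_P` are the blocks containing `x`. E is 0 iff the partitions coincide,
#' and for refinement chains P within B within C, `E(B) <= E(P)`.
#'
#' @param partition_C,partition_P lists of vectors forming partitions of the
#'   same universe; every C block must lie inside some P block.
#' @return non-negative scalar (bits).
#' @export
discernibility_entropy <- function(partition_C, partition_P) {
  idC <- partition_ids(partition_C, "discernibility_entropy (C)")
  idP <- partition_ids(partition_P, "discernibility_entropy (P)")
  if (length(idC) != length(idP) ||
      !setequal(names(idC), names(idP)))
    stop_data("discernibility_entropy: partitions must cover the same universe")
  idP <- idP[names(idC)]
  # refinement: every C block maps into exactly one P block
  if (any(tapply(idP, idC, function(v) length(unique(v))) != 1))
    stop_data("discernibility_entropy: partition_C does not refine partition_P")
  sizeC <- table(idC)[as.character(idC)]
  sizeP <- table(idP)[as.character(idP)]
  -mean(log2(as.numeric(sizeC) / as.numeric(sizeP)))
}

# Equal-frequency binning of a numeric vector into at most n_bins codes.
# Interpolated (type 7) quantiles place cut points between tied runs.
equal_freq_bin <- function(x, n_bins) {
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                               type = 7, names = FALSE))
  if (length(qs) < 2) return(rep(1L, length(x)))
  findInterval(x, qs, rightmost.closed = TRUE, all.inside = TRUE)
}

# Observation units of a feature table: everything in the key except the
# channel (and including the model, if several are present).
unit_ids <- function(keys) paste(keys$subject, keys$trial, keys$model, sep = "\r")

# Binned code matrix for one channel over the given attribute (column)
# indices: units x attributes integer codes.
channel_codes <- function(tab, channel, n_bins, attributes) {
  sel <- tab$keys$channel == channel
  if (!any(sel)) stop_key("channel_entropy: channel '", channel, "' not present in feature table")
  rows <- tab$rows[sel, , drop = FALSE]
  units <- unit_ids(tab$keys[sel, , drop = FALSE])
  if (anyDuplicated(units)) stop_data("channel_entropy: duplicate observation units within a channel")
  ord <- order(units)
  rows <- rows[ord, , drop = FALSE]
  codes <- apply(rows[, attributes, drop = FALSE], 2, equal_freq_bin, n_bins = n_bins)
  list(units = units[ord], codes = matrix(codes, nrow = nrow(rows)))
}

# Default per-channel attribute choice: the n highest-variance columns
# (ties broken by column index).
top_variance_attributes <- function(tab, channel, n) {
  rows <- tab$rows[tab$keys$channel == channel, , drop = FALSE]
  v <- apply(rows, 2, stats::var)
  order(-v, seq_along(v))[seq_len(min(n, ncol(rows)))]
}

codes_to_partition <- function(units, codes) {
  key <- apply(codes, 1, paste, collapse = ",")
  unname(split(units, key))
}

#' Discernibility entropy of one channel's features
#'
#' Discretizes deep-feature attributes into equal-frequency bins (default
#' `n_bins = 4`, over each channel's `n_attributes` highest-variance
#' attributes) to induce partitions of the observation units: P from the
#' candidate channel's binned attributes, C from the binned attributes of
#' all channels together (so C refines P). Returns
#' [discernibility_entropy()] of (C, P). When the table carries several
#' extractor models, the entropy is computed per model and averaged
#' (columns of different models are incommensurable). Deterministic for
#' fixed inputs.
#'
#' @param features a [feature_table()].
#' @param channel channel label present in the table.
#' @param n_bins bins per attribute (equal-frequency).
#' @param n_attributes attributes used per channel (highest variance first).
#' @param attributes optional explicit attribute (column) indices for the
#'   candidate channel's subset partition P, overriding the variance-based
#'   choice. The full-set partition C always includes these columns too, so
#'   C keeps refining P.
#' @param full_attributes optional explicit attribute indices used for
#'   every channel when building the full-set partition C (must contain
#'   `attributes`); useful for monotonicity sweeps with a fixed C.
#' @return non-negative scalar (bits).
#' @export
channel_entropy <- function(features, channel, n_bins = 4, n_attributes = 8,
                            attributes = NULL, full_attributes = NULL) {
  if (!inherits(features, "feature_table")) stop_data("channel_entropy: expected a feature_table")
  if (!is_count(n_bins, min = 2)) stop_config("channel_entropy: n_bins must be >= 2")
  models <- unique(features$keys$model)
  if (length(models) > 1) {
    # attribute columns of different extractor models are incommensurable;
    # score the channel per model and average the entropies
    if (!any(features$keys$channel == channel))
      stop_key("channel_entropy: channel '", channel, "' not present in feature table")
    return(mean(vapply(models, function(m) {
      keep <- features$keys$model == m
      channel_entropy(feature_table(features$rows[keep, , drop = FALSE],
                                    features$keys[keep, , drop = FALSE],
                                    stage = features$stage),
                      channel, n_bins = n_bins, n_attributes = n_attributes,
                      attributes = attributes, full_attributes = full_attributes)
    }, numeric(1))))
  }
  channels <- unique(features$keys$channel)
  ci <- match(channel, channels)
  if (is.na(ci)) stop_key("channel_entropy: channel '", channel, "' not present in feature table")
  p_attrs <- attributes %||% top_variance_attributes(features, channel, n_attributes)
  c_attrs <- lapply(channels, function(ch) {
    if (!is.null(full_attributes)) full_attributes
    else if (ch == channel) union(top_variance_attributes(features, ch, n_attributes), p_attrs)
    else top_variance_attributes(features, ch, n_attributes)
  })
  if (!all(p_attrs %in% c_attrs[[ci]]))
    stop_config("channel_entropy: full_attributes must contain the candidate attributes")
  per_ch <- lapply(seq_along(channels), function(i)
    channel_codes(features, channels[i], n_bins, c_attrs[[i]]))
  units <- per_ch[[1]]$units
  for (pc in per_ch) {
    if (!identical(pc$units, units))
      stop_data("channel_entropy: channels do not cover the same observation units")
  }
  codes_all <- do.call(cbind, lapply(per_ch, `[[`, "codes"))
  P <- codes_to_partition(units, channel_codes(features, channel, n_bins, p_attrs)$codes)
  C <- codes_to_partition(units, codes_all)
  discernibility_entropy(C, P)
}

#' Select channels by discernibility entropy
#'
#' Scores every channel with [channel_entropy()] and selects either the
#' strict superlevel set `E > threshold` (`mode = "threshold"`, the
#' published rule with threshold 1.145) or the `top_m` channels by entropy
#' (`mode = "rank"`, recommended for corpora whose entropy scale differs
#' from the published binning). Ties at exactly the threshold are excluded.
#'
#' @param features a [feature_table()].
#' @param threshold entropy threshold (bits), default 1.145.
#' @param n_bins,n_attributes,attributes passed to [channel_entropy()].
#' @param mode `"threshold"` or `"rank"`.
#' @param top_m number of channels kept in rank mode.
#' @return object of class `channel_report`: data frame `table` (channel,
#'   entropy, selected), `threshold`, `mode`, ordered `selected_channels`,
#'   and `empty_selection` flag.
#' @export
select_channels <- function(features, threshold = 1.145, n_bins = 4,
                            n_attributes = 8, attributes = NULL,
                            mode = c("threshold", "rank"), top_m = 2) {
  mode <- match.arg(mode)
  if (!inherits(features, "feature_table")) stop_data("select_channels: expected a feature_table")
  channels <- unique(features$keys$channel)
  if (!length(channels)) stop_data("select_channels: no channels present")
  e <- vapply(channels, function(ch)
    channel_entropy(features, ch, n_bins = n_bins, n_attributes = n_attributes,
                    attributes = attributes), numeric(1))
  selected <- if (mode == "threshold") e > threshold
              else rank(-e, ties.method = "first") <= top_m
  tab <- data.frame(channel = channels, entropy = unname(e),
                    selected = unname(selected), stringsAsFactors = FALSE)
  sel <- tab$channel[tab$selected][order(-tab$entropy[tab$selected])]
  structure(list(table = tab, threshold = threshold, mode = mode,
                 selected_channels = sel,
                 empty_selection = length(sel) == 0),
            class = "channel_report")
}

#' Restrict a feature table to selected channels
#'
#' @param features a [feature_table()] at stage `"FV"`.
#' @param channels character vector of channel labels, or a
#'   `channel_report`.
#' @return a [feature_table()] at stage `"FV_selected"`.
#' @export
apply_channel_selection <- function(features, channels) {
  if (inherits(channels, "channel_report")) channels <- channels$selected_channels
  if (!length(channels)) stop_data("apply_channel_selection: empty channel selection")
  keep <- features$keys$channel %in% channels
  if (!any(keep)) stop_data("apply_channel_selection: no rows match the selected channels")
  feature_table(features$rows[keep, , drop = FALSE],
                features$keys[keep, , drop = FALSE], stage = "FV_selected")
}

#' Concatenate four per-model feature tables into a combined feature vector
#'
#' Row-wise stacking of exactly four tables sharing the same
#' (subject, trial, channel) key set; the result has `4 x` the per-model
#' row count and keys preserving each model name.
#'
#' @param tables list of exactly 4 [feature_table()] objects.
#' @return a [feature_table()] at stage `"CFV"`.
#' @export
concat_models <- function(tables) {
  if (!is.list(tables) || length(tables) != 4)
    stop_data("concat_models: exactly 4 feature tables are required (got ",
              length(tables), ")")
  key_of <- function(t) sort(paste(t$keys$subject, t$keys$trial, t$keys$channel, sep = "\r"))
  ref <- key_of(tables[[1]])
  for (i in 2:4) {
    ki <- key_of(tables[[i]])
    if (!identical(ref, ki)) {
      missing <- c(setdiff(ref, ki), setdiff(ki, ref))
      stop_data("concat_models: (subject, trial, channel) key sets differ; mismatched keys: ",
                paste(gsub("\r", "/", utils::head(missing, 5)), collapse = ", "))
    }
  }
  sort_tab <- function(t) {
    ord <- order(t$keys$subject, t$keys$trial, t$keys$channel)
    list(rows = t$rows[ord, , drop = FALSE], keys = t$keys[ord, , drop = FALSE])
  }
  sorted <- lapply(tables, sort_tab)
  feature_table(do.call(rbind, lapply(sorted, `[[`, "rows")),
                do.call(rbind, lapply(sorted, `[[`, "keys")),
                stage = "CFV")
}

#' Eliminate redundant feature rows by Euclidean distance
#'
#' Greedy scan in row (manifest key) order: a row is dropped when its
#' Euclidean distance to any already-retained row is `< epsilon`. The
#' result is idempotent and has pairwise distances `>= epsilon`.
#'
#' @param cfv a [feature_table()] (typically stage `"CFV"`).
#' @param epsilon non-negative radius; `NULL` (default) uses
#'   `1e-6 * median(row norm)`. `epsilon = 0` retains every row.
#' @return a [feature_table()] at stage `"CFV_rfe"`.
#' @export
eliminate_redundant <- function(cfv, epsilon = NULL) {
  if (!inherits(cfv, "feature_table")) stop_data("eliminate_redundant: expected a feature_table")
  n <- nrow(cfv$rows)
  nrm2 <- rowSums(cfv$rows^2)
  if (is.null(epsilon)) epsilon <- 1e-6 * stats::median(sqrt(nrm2))
  if (!is_number(epsilon) || epsilon < 0) stop_config("eliminate_redundant: epsilon must be >= 0")
  keep <- logical(n)
  if (epsilon == 0) {
    keep[] <- TRUE
  } else {
    G <- tcrossprod(cfv$rows)
    eps2 <- epsilon^2
    for (i in seq_len(n)) {
      ks <- which(keep)
      if (!length(ks)) { keep[i] <- TRUE; next }
      d2 <- pmax(0, nrm2[i] + nrm2[ks] - 2 * G[i, ks])
      keep[i] <- all(d2 >= eps2)
    }
  }
  feature_table(cfv$rows[keep, , drop = FALSE], cfv$keys[keep, , drop = FALSE],
                stage = "CFV_rfe")
}

#' @export
print.channel_report <- function(x, ...) {
  cat(sprintf("channel_report (%s mode, threshold %.3f): %d/%d channels selected\n",
              x$mode, x$threshold, length(x$selected_channels), nrow(x$table)))
  print(x$table, row.names = FALSE)
  invisible(x)
}
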