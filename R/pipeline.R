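# End-to-end orchestration: configuration, stage caching, the one-command
# run, and the stage-dimension ledger.

#' Default pipeline configuration
#'
#' Nested list of every stage's parameters. The default run generates the
#' default synthetic corpus, decomposes each channel (5 IMFs), renders
#' analytic-wavelet spectrogram images, extracts features with four seeded
#' lite extractors playing the role of the four backbone models, selects
#' channels by entropy rank, fuses and deduplicates the combined feature
#' vector, builds a k = 10 per-class vocabulary and evaluates histogram
#' features with a cubic-kernel SVM under 10-fold cross-validation.
#'
#' @return nested named list.
#' @export
default_pipeline_config <- function() {
  list(
    corpus = list(n_subjects = 5, n_trials_per_subject = 9, n_channels = 8,
                  n_classes = 3, sampling_rate = 200, trial_duration = 4,
                  informative_channels = c(1, 2), noise_sd = 1, seed = 1),
    sift = list(max_imfs = 5, stop_threshold = 0.2, halve_extrema = TRUE,
                max_sift_iter = 10),
    tfr = list(n_scales = 64, f_min = 1, f_max = 45, omega0 = 6,
               colormap = "viridis", image_size = 224),
    extract = list(model = "lite", n_models = 4, seed = 11),
    selection = list(mode = "rank", threshold = 1.145, n_bins = 3,
                     n_attributes = 8, top_m = 2, rfe_epsilon = NULL),
    dfc = list(k_per_class = 10, seed = 23, normalize = FALSE),
    evaluate = list(classifier = "svm_cubic", n_folds = 10, seed = 31,
                    group_by_subject = FALSE),
    io = list(cache_dir = NULL)
  )
}

merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    here <- if (path == "") nm else paste0(path, ".", nm)
    if (!nm %in% names(base))
      stop_config("pipeline_config: unknown key '", here, "'")
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(user[[nm]])) stop_config("pipeline_config: '", here, "' must be a section")
      base[[nm]] <- merge_config(base[[nm]], user[[nm]], here)
    } else {
      base[nm] <- list(user[[nm]])   # [[<- would drop NULL values
    }
  }
  base
}

#' Build a pipeline configuration
#'
#' Starts from [default_pipeline_config()] and overlays the supplied
#' sections; unknown keys are rejected by name. The result round-trips
#' losslessly through [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param ... named sections (e.g. `corpus = list(seed = 7)`).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  if (length(user) == 1 && is.null(names(user)) ) user <- user[[1]]
  cfg <- merge_config(default_pipeline_config(), user)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_config("read_pipeline_config: no such file ", path)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop_data("read_pipeline_config: corrupted config file ", path))
  cfg <- merge_config(default_pipeline_config(), raw)
  structure(cfg, class = "pipeline_config")
}

#' Write a pipeline configuration as YAML
#'
#' @param config a `pipeline_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Stage-dimension ledger
#'
#' Computes the row counts of every pipeline stage from the corpus shape:
#' `FV = obs_per_channel * n_channels`, selected
#' `FV = obs_per_channel * n_selected`, `CFV = n_models * selected FV`;
#' the redundancy-elimination stage is an upper bound (`<= CFV`).
#'
#' @param obs_per_channel observations (images) per channel per model.
#' @param n_channels total channels.
#' @param n_models number of extractor models.
#' @param n_selected selected channels.
#' @return data frame with stage names and row counts.
#' @export
shape_report <- function(obs_per_channel, n_channels, n_models, n_selected) {
  for (v in c(obs_per_channel, n_channels, n_models, n_selected))
    if (!is_count(v)) stop_config("shape_report: all arguments must be positive integers")
  if (n_selected > n_channels) stop_config("shape_report: n_selected cannot exceed n_channels")
  fv <- obs_per_channel * n_channels
  fv_sel <- obs_per_channel * n_selected
  cfv <- n_models * fv_sel
  data.frame(stage = c("FV", "FV_selected", "CFV", "CFV_rfe_max"),
             rows = c(fv, fv_sel, cfv, cfv),
             stringsAsFactors = FALSE)
}

# ---- staged execution with content-hash caching ----------------------------

stage_cached <- function(cache_dir, name, key, fun, log) {
  if (is.null(cache_dir)) {
    t0 <- Sys.time()
    val <- fun()
    log(name, FALSE, as.numeric(difftime(Sys.time(), t0, units = "secs")))
    return(list(value = val, hash = digest::digest(key)))
  }
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  h <- digest::digest(key)
  fpath <- file.path(cache_dir, paste0(name, "_", h, ".rds"))
  if (file.exists(fpath)) {
    val <- tryCatch(readRDS(fpath),
                    error = function(e) stop_data("run_pipeline: corrupted cached stage file ", fpath))
    log(name, TRUE, 0)
    return(list(value = val, hash = h))
  }
  t0 <- Sys.time()
  val <- fun()
  saveRDS(val, fpath)
  log(name, FALSE, as.numeric(difftime(Sys.time(), t0, units = "secs")))
  list(value = val, hash = h)
}

# Decompose, transform and extract features for every (record, channel):
# EMD -> sum of IMFs -> analytic-wavelet spectrogram -> image -> patch
# stats, projected under each of n_models seeded lite extractors.
compute_feature_tables <- function(corpus, cfg) {
  sc <- sift_config(max_imfs = cfg$sift$max_imfs,
                    stop_threshold = cfg$sift$stop_threshold,
                    halve_extrema = cfg$sift$halve_extrema,
                    max_sift_iter = cfg$sift$max_sift_iter)
  stats_rows <- list()
  keys <- list()
  i <- 0
  for (rec in corpus) {
    for (ch in seq_len(nrow(rec$samples))) {
      imf <- sift(rec$samples[ch, ], sc)
      denoised <- imf_sum(imf)
      if (all(denoised == 0)) denoised <- rec$samples[ch, ]
      spec <- analytic_wavelet_tfr(denoised, rec$sampling_rate,
                                   n_scales = cfg$tfr$n_scales,
                                   f_min = cfg$tfr$f_min, f_max = cfg$tfr$f_max,
                                   omega0 = cfg$tfr$omega0,
                                   provenance = list(subject = rec$subject_id,
                                                     trial = rec$trial_id,
                                                     channel = rec$channel_labels[ch],
                                                     class = rec$class_label))
      img <- render_image(spec, colormap = cfg$tfr$colormap,
                          size = cfg$tfr$image_size)
      i <- i + 1
      stats_rows[[i]] <- image_patch_stats(img$pixels)
      keys[[i]] <- data.frame(subject = rec$subject_id, trial = rec$trial_id,
                              channel = rec$channel_labels[ch],
                              class = rec$class_label, stringsAsFactors = FALSE)
    }
  }
  stats_mat <- do.call(rbind, stats_rows)
  key_df <- do.call(rbind, keys)
  lapply(seq_len(cfg$extract$n_models), function(m) {
    seed <- derive_seed(cfg$extract$seed, m)
    rows <- lite_features_from_stats(stats_mat, seed)
    kd <- key_df
    kd$model <- sprintf("lite_m%d", m)
    feature_table(rows, kd[, c("subject", "trial", "channel", "model", "class")],
                  stage = "FV")
  })
}

#' Run the full pipeline
#'
#' Executes synth (or a supplied corpus) -> EMD decomposition ->
#' analytic-wavelet spectrograms -> lite feature extraction (one table per
#' model) -> entropy channel selection -> model fusion + redundant-row
#' elimination -> Deep Feature Clustering -> cross-validated evaluation.
#' With `io$cache_dir` set, each stage is cached keyed by the content hash
#' of its config subsection plus the upstream hash, so an unchanged rerun
#' skips every stage.
#'
#' @param config a [pipeline_config()] (or list coercible to one).
#' @param corpus optional pre-built `eeg_corpus`; otherwise generated from
#'   `config$corpus`.
#' @param verbose print stage progress to stderr.
#' @return object of class `pipeline_result`: `report` (the DFC
#'   [crossval_classify()] report), `cfv_report` (same classifier on the
#'   unreduced combined feature vector rows), `channel_report`, `vocab`,
#'   `histograms`, `cfv`, `shapes` (predicted vs observed row counts),
#'   `stage_log`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), corpus = NULL,
                         verbose = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  cfg <- unclass(config)
  log_rows <- list()
  log <- function(name, cached, secs) {
    log_rows[[length(log_rows) + 1]] <<- data.frame(stage = name, cached = cached,
                                                    seconds = round(secs, 3))
    if (verbose) message(sprintf("[%s] %s (%.1fs)", name,
                                 if (cached) "cached" else "computed", secs))
  }
  cache <- cfg$io$cache_dir

  st_corpus <- stage_cached(cache, "corpus", list(cfg$corpus, corpus),
                            function() corpus %||% generate_corpus(do.call(corpus_spec, cfg$corpus)),
                            log)
  corpus <- st_corpus$value

  st_feat <- stage_cached(cache, "features",
                          list(st_corpus$hash, cfg$sift, cfg$tfr, cfg$extract),
                          function() compute_feature_tables(corpus, cfg), log)
  tables <- st_feat$value

  st_sel <- stage_cached(cache, "selection",
                         list(st_feat$hash, cfg$selection),
                         function() {
                           # entropy scored on all models' tables (averaged
                           # per model inside channel_entropy)
                           stacked <- feature_table(
                             do.call(rbind, lapply(tables, `[[`, "rows")),
                             do.call(rbind, lapply(tables, `[[`, "keys")),
                             stage = "FV")
                           select_channels(stacked,
                                           threshold = cfg$selection$threshold,
                                           n_bins = cfg$selection$n_bins,
                                           n_attributes = cfg$selection$n_attributes,
                                           mode = cfg$selection$mode,
                                           top_m = cfg$selection$top_m)
                         }, log)
  chan_report <- st_sel$value
  if (chan_report$empty_selection)
    stop_data("run_pipeline: channel selection selected no channels (stage selection)")

  st_cfv <- stage_cached(cache, "cfv", list(st_sel$hash, cfg$selection$rfe_epsilon),
                         function() {
                           selected <- lapply(tables, apply_channel_selection,
                                              channels = chan_report)
                           cfv <- if (length(selected) == 4) concat_models(selected)
                                  else feature_table(do.call(rbind, lapply(selected, `[[`, "rows")),
                                                     do.call(rbind, lapply(selected, `[[`, "keys")),
                                                     stage = "CFV")
                           list(pre_rfe_rows = nrow(cfv$rows),
                                table = eliminate_redundant(cfv, epsilon = cfg$selection$rfe_epsilon))
                         }, log)
  cfv <- st_cfv$value$table

  st_dfc <- stage_cached(cache, "dfc", list(st_cfv$hash, cfg$dfc),
                         function() {
                           vocab <- build_vocabulary(cfv, k_per_class = cfg$dfc$k_per_class,
                                                     seed = cfg$dfc$seed)
                           hist <- histogram_features(vocab, cfv,
                                                      normalize = cfg$dfc$normalize)
                           list(vocab = vocab, hist = hist)
                         }, log)

  st_eval <- stage_cached(cache, "evaluate", list(st_dfc$hash, cfg$evaluate),
                          function() crossval_classify(st_dfc$value$hist,
                                                       classifier = cfg$evaluate$classifier,
                                                       n_folds = cfg$evaluate$n_folds,
                                                       seed = cfg$evaluate$seed,
                                                       group_by_subject = cfg$evaluate$group_by_subject),
                          log)

  n_obs <- length(corpus)
  predicted <- shape_report(n_obs, cfg$corpus$n_channels, cfg$extract$n_models,
                            length(chan_report$selected_channels))
  observed <- c(FV = nrow(tables[[1]]$rows),
                FV_selected = sum(tables[[1]]$keys$channel %in% chan_report$selected_channels),
                CFV = st_cfv$value$pre_rfe_rows,
                CFV_rfe_max = nrow(cfv$rows))
  predicted$observed <- as.numeric(unname(observed))

  structure(list(report = st_eval$value,
                 channel_report = chan_report,
                 vocab = st_dfc$value$vocab,
                 histograms = st_dfc$value$hist,
                 cfv = cfv,
                 shapes = predicted,
                 stage_log = do.call(rbind, log_rows),
                 config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  cat(sprintf("  selected channels: %s\n",
              paste(x$channel_report$selected_channels, collapse = ", ")))
  cat(sprintf("  vocabulary: %d centers\n", nrow(x$vocab$centers)))
  cat(sprintf("  DFC accuracy [%s]: %.3f\n", x$report$classifier, x$report$accuracy))
  invisible(x)
}
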