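# Shared fixtures built in code.

tiny_corpus <- function(seed = 7, n_subjects = 2, n_trials = 3, n_channels = 4,
                        duration = 2) {
  generate_corpus(corpus_spec(n_subjects = n_subjects,
                              n_trials_per_subject = n_trials,
                              n_channels = n_channels,
                              trial_duration = duration, seed = seed))
}

# A deterministic feature table with known per-channel structure: rows for
# `channels` x `units`, class-dependent mean shifts on informative
# channels.
toy_feature_table <- function(n_units = 12, channels = c("A", "B"),
                              informative = "A", n_classes = 2, seed = 1,
                              model = "m1", noise = 0.1) {
  set.seed(seed)
  classes <- paste0("c", ((seq_len(n_units) - 1) %% n_classes) + 1)
  rows <- NULL
  keys <- NULL
  for (ch in channels) {
    base <- matrix(rnorm(n_units * 1000, sd = noise), n_units, 1000)
    if (ch %in% informative) {
      shift <- outer(as.integer(factor(classes)), rep(1, 1000))
      base <- base + shift
    }
    rows <- rbind(rows, base)
    keys <- rbind(keys, data.frame(subject = 1, trial = seq_len(n_units),
                                   channel = ch, model = model,
                                   class = classes, stringsAsFactors = FALSE))
  }
  feature_table(rows, keys)
}

# Well-separated Gaussian clouds in 1000 dims embedded from d effective dims.
toy_cfv <- function(n_per_class = 30, n_classes = 3, sep = 10, seed = 2) {
  set.seed(seed)
  rows <- NULL
  keys <- NULL
  for (ci in seq_len(n_classes)) {
    m <- matrix(rnorm(n_per_class * 1000), n_per_class, 1000)
    m[, ci] <- m[, ci] + sep
    rows <- rbind(rows, m)
    keys <- rbind(keys, data.frame(subject = ci, trial = seq_len(n_per_class),
                                   channel = "A", model = "m1",
                                   class = paste0("c", ci),
                                   stringsAsFactors = FALSE))
  }
  feature_table(rows, keys, stage = "CFV")
}

toy_image <- function(seed = 1, size = 224) {
  set.seed(seed)
  structure(list(pixels = array(sample(0:255, size * size * 3, replace = TRUE),
                                dim = c(size, size, 3)),
                 provenance = list(subject = 1, trial = 1, channel = "Fp1",
                                   class = "positive")),
            class = "spectro_image")
}
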