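# Synthetic multichannel EEG corpora with class-dependent rhythm power.
#
# The generator emulates the shape of affective-EEG corpora (subjects x
# trials x channels, 3 or 4 emotion classes) without any physiological
# realism: each class concentrates oscillatory power in one conventional EEG
# band, informative channels carry that class signature, and the remaining
# channels carry label-independent background activity plus white noise.

#' Conventional EEG frequency bands
#'
#' Band edges in Hz: delta 1-4, theta 4-8, alpha 8-13, beta 13-30,
#' gamma 30-45. These fixed edges are used by the generator and by
#' band-power summaries.
#'
#' @return named list of length-2 numeric vectors `c(low, high)`.
#' @export
eeg_bands <- function() {
  list(
    delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
    beta = c(13, 30), gamma = c(30, 45)
  )
}

# Default class -> band-power map. Emotion discrimination is carried mostly
# by the high-frequency rhythms, so dominant bands are assigned from gamma
# downwards: gamma, beta, alpha (, theta for a 4th class). Dominant band
# variance 4, background 0.25 (per-sample signal variance units).
default_class_band_powers <- function(n_classes) {
  bands <- names(eeg_bands())
  dominant <- c("gamma", "beta", "alpha", "theta")[seq_len(n_classes)]
  m <- matrix(0.25, nrow = n_classes, ncol = length(bands),
              dimnames = list(NULL, bands))
  for (i in seq_len(n_classes)) m[i, dominant[i]] <- 4
  m
}

default_class_labels <- function(n_classes) {
  if (n_classes == 3) c("positive", "neutral", "negative")
  else if (n_classes == 4) c("HAHV", "HALV", "LAHV", "LALV")
  else paste0("class", seq_len(n_classes))
}

# A pool of 10-20 system electrode names for channel labelling.
ten_twenty_labels <- function(n) {
  pool <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T7", "C3", "Cz",
            "C4", "T8", "P7", "P3", "Pz", "P4", "P8", "O1", "Oz", "O2",
            "AF3", "AF4", "FC1", "FC2", "FC5", "FC6", "CP1", "CP2", "CP5",
            "CP6", "PO3", "PO4")
  if (n <= length(pool)) pool[seq_len(n)]
  else c(pool, paste0("EEG", seq_len(n - length(pool))))
}

#' Specification of a synthetic EEG corpus
#'
#' Describes the stated world that [generate_corpus()] realizes. Defaults
#' mirror a miniature affective-EEG study: 5 subjects x 9 trials x 8
#' channels, 3 classes, 200 Hz, 4 s trials, with channels 1-2 informative.
#'
#' @param n_subjects,n_trials_per_subject,n_channels positive integers.
#' @param n_classes number of emotion classes, 3 or 4.
#' @param sampling_rate sampling rate in Hz.
#' @param trial_duration trial length in seconds.
#' @param class_band_powers `n_classes x 5` non-negative matrix of relative
#'   band variances (columns delta/theta/alpha/beta/gamma). `NULL` for the
#'   default map (dominant band variance 4, background 0.25).
#' @param informative_channels integer indices (1-based) of channels that
#'   carry the class-dependent spectrum; the rest are label-independent.
#' @param noise_sd standard deviation of the additive white noise.
#' @param seed integer corpus seed; identical seeds give bit-identical
#'   corpora.
#' @return an object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_subjects = 5, n_trials_per_subject = 9,
                        n_channels = 8, n_classes = 3, sampling_rate = 200,
                        trial_duration = 4, class_band_powers = NULL,
                        informative_channels = c(1, 2), noise_sd = 1,
                        seed = 1) {
  if (!is_count(n_subjects)) stop_config("invalid corpus spec: n_subjects must be a positive integer")
  if (!is_count(n_trials_per_subject)) stop_config("invalid corpus spec: n_trials_per_subject must be a positive integer")
  if (!is_count(n_channels)) stop_config("invalid corpus spec: n_channels must be a positive integer")
  if (!is_count(n_classes, min = 2) || !(n_classes %in% c(3, 4)))
    stop_config("invalid corpus spec: n_classes must be 3 or 4")
  if (!is_number(sampling_rate) || sampling_rate <= 0)
    stop_config("invalid corpus spec: sampling_rate must be > 0")
  if (!is_number(trial_duration) || trial_duration <= 0)
    stop_config("invalid corpus spec: trial_duration must be > 0")
  if (is.null(class_band_powers))
    class_band_powers <- default_class_band_powers(n_classes)
  class_band_powers <- as.matrix(class_band_powers)
  if (nrow(class_band_powers) != n_classes ||
      ncol(class_band_powers) != length(eeg_bands()) ||
      any(!is.finite(class_band_powers)) || any(class_band_powers < 0))
    stop_config("invalid corpus spec: class_band_powers must be a non-negative ",
                n_classes, " x 5 matrix")
  colnames(class_band_powers) <- names(eeg_bands())
  informative_channels <- as.integer(informative_channels)
  if (length(informative_channels) &&
      (anyNA(informative_channels) || any(informative_channels < 1) ||
       any(informative_channels > n_channels) || anyDuplicated(informative_channels)))
    stop_config("invalid corpus spec: informative_channels must be distinct indices in 1..n_channels")
  if (!is_number(noise_sd) || noise_sd < 0)
    stop_config("invalid corpus spec: noise_sd must be >= 0")
  if (!is_count(seed, min = 0)) stop_config("invalid corpus spec: seed must be a non-negative integer")
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_trials_per_subject = as.integer(n_trials_per_subject),
         n_channels = as.integer(n_channels),
         n_classes = as.integer(n_classes),
         sampling_rate = sampling_rate,
         trial_duration = trial_duration,
         class_band_powers = class_band_powers,
         informative_channels = informative_channels,
         noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "corpus_spec"
  )
}

#' One EEG trial with metadata
#'
#' @param samples `n_channels x n_samples` numeric matrix (all finite).
#' @param sampling_rate sampling rate in Hz.
#' @param subject_id,trial_id integer identifiers.
#' @param class_label character or factor class label.
#' @param channel_labels character vector, one per channel.
#' @return an object of class `eeg_record`.
#' @export
eeg_record <- function(samples, sampling_rate, subject_id, trial_id,
                       class_label, channel_labels = NULL) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 1 || ncol(samples) < 2)
    stop_data("eeg_record: samples must be n_channels x n_samples with n_channels >= 1, n_samples >= 2")
  if (any(!is.finite(samples))) stop_data("eeg_record: samples must be finite")
  if (!is_number(sampling_rate) || sampling_rate <= 0)
    stop_data("eeg_record: sampling_rate must be > 0")
  channel_labels <- channel_labels %||% ten_twenty_labels(nrow(samples))
  if (length(channel_labels) != nrow(samples))
    stop_data("eeg_record: channel_labels must match the number of channels")
  rownames(samples) <- channel_labels
  structure(
    list(subject_id = as.integer(subject_id), trial_id = as.integer(trial_id),
         class_label = as.character(class_label),
         sampling_rate = sampling_rate, channel_labels = channel_labels,
         samples = samples),
    class = "eeg_record"
  )
}

# Simulate one channel: white noise + per-band sums of 3 random-phase
# sinusoids whose total variance equals the band weight.
simulate_channel <- function(tt, band_weights, noise_sd) {
  x <- if (noise_sd > 0) stats::rnorm(length(tt), sd = noise_sd) else numeric(length(tt))
  bands <- eeg_bands()
  for (b in seq_along(bands)) {
    p <- band_weights[[b]]
    if (p <= 0) next
    f <- stats::runif(3, bands[[b]][1], bands[[b]][2])
    ph <- stats::runif(3, 0, 2 * pi)
    amp <- sqrt(2 * p / 3)  # 3 sinusoids of variance amp^2/2 sum to variance p
    for (j in 1:3) x <- x + amp * sin(2 * pi * f[j] * tt + ph[j])
  }
  x
}

#' Generate a synthetic EEG corpus
#'
#' Produces exactly `n_subjects * n_trials_per_subject` records with balanced
#' class labels (counts differ by at most one). Channels listed in
#' `informative_channels` follow the class's band-power profile; all other
#' channels carry a flat, label-independent background spectrum. Each record
#' uses an RNG substream derived from `(seed, subject, trial)`, so any subset
#' of the corpus is reproducible and the full corpus is bit-identical under
#' a fixed seed.
#'
#' @param spec a [corpus_spec()].
#' @return a list of [eeg_record()] objects with class `eeg_corpus`; the
#'   generating spec is attached as attribute `spec`.
#' @export
generate_corpus <- function(spec) {
  if (!inherits(spec, "corpus_spec")) stop_config("generate_corpus: spec must be a corpus_spec")
  n <- round(spec$sampling_rate * spec$trial_duration)
  tt <- (seq_len(n) - 1) / spec$sampling_rate
  labels <- default_class_labels(spec$n_classes)
  ch_labels <- ten_twenty_labels(spec$n_channels)
  background <- rep(0.25, length(eeg_bands()))
  records <- vector("list", spec$n_subjects * spec$n_trials_per_subject)
  idx <- 0
  for (s in seq_len(spec$n_subjects)) {
    for (tr in seq_len(spec$n_trials_per_subject)) {
      idx <- idx + 1
      cls <- ((idx - 1) %% spec$n_classes) + 1
      samples <- with_seed(derive_seed(spec$seed, s, tr), {
        m <- matrix(0, nrow = spec$n_channels, ncol = n)
        for (ch in seq_len(spec$n_channels)) {
          w <- if (ch %in% spec$informative_channels)
            spec$class_band_powers[cls, ] else background
          m[ch, ] <- simulate_channel(tt, w, spec$noise_sd)
        }
        m
      })
      records[[idx]] <- eeg_record(samples, spec$sampling_rate, s, tr,
                                   labels[cls], ch_labels)
    }
  }
  structure(records, class = "eeg_corpus", spec = spec)
}

#' Band power of a signal by raw periodogram
#'
#' Sums the one-sided periodogram over `[band[1], band[2])` Hz. Used for
#' sanity checks on generated corpora and for the trivial band-power
#' baseline classifier.
#'
#' @param x numeric signal.
#' @param sampling_rate Hz.
#' @param band length-2 numeric `c(low, high)` in Hz, or a band name from
#'   [eeg_bands()].
#' @return non-negative scalar.
#' @export
band_power <- function(x, sampling_rate, band) {
  if (is.character(band)) band <- eeg_bands()[[match.arg(band, names(eeg_bands()))]]
  n <- length(x)
  sp <- Mod(stats::fft(x))^2 / n
  freqs <- (seq_len(n) - 1) * sampling_rate / n
  keep <- freqs >= band[1] & freqs < band[2] & freqs <= sampling_rate / 2
  sum(sp[keep])
}

#' @export
print.corpus_spec <- function(x, ...) {
  cat(sprintf("corpus_spec: %d subjects x %d trials, %d channels, %d classes, %g Hz, %g s (seed %d)\n",
              x$n_subjects, x$n_trials_per_subject, x$n_channels, x$n_classes,
              x$sampling_rate, x$trial_duration, x$seed))
  invisible(x)
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("eeg_record: subject %d trial %d class %s, %d ch x %d samples @ %g Hz\n",
              x$subject_id, x$trial_id, x$class_label, nrow(x$samples),
              ncol(x$samples), x$sampling_rate))
  invisible(x)
}
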