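# File interchange: minimal EDF writer/reader, corpus directory layout with
# a CSV manifest, and columnar serialization of feature tables, vocabularies
# and histograms.

pad <- function(x, width) formatC(as.character(x), width = width, flag = "-")

edf_num <- function(x, width) {
  s <- formatC(signif(x, 7), width = width, format = "g", flag = "-")
  if (nchar(s) > width) s <- substr(s, 1, width)
  s
}

#' Write one EEG record as an EDF file
#'
#' Minimal single-data-record EDF: every channel is stored as 16-bit
#' integers scaled to its physical range, with subject/trial/class metadata
#' in the recording-identification field. Round-tripping through
#' [read_edf()] is exact up to the 16-bit quantization step.
#'
#' @param record an [eeg_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(record, path) {
  if (!inherits(record, "eeg_record")) stop_data("write_edf: expected an eeg_record")
  ns <- nrow(record$samples)
  n <- ncol(record$samples)
  dur <- n / record$sampling_rate
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, width) writeChar(pad(s, width), con, nchars = width, eos = NULL)
  wr("0", 8)
  wr(sprintf("subject %d", record$subject_id), 80)
  wr(sprintf("trial %d class %s", record$trial_id, record$class_label), 80)
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(as.character(256 * (ns + 1)), 8)
  wr("", 44)
  wr("1", 8)
  wr(edf_num(dur, 8), 8)
  wr(as.character(ns), 4)
  pmin_ <- apply(record$samples, 1, min)
  pmax_ <- apply(record$samples, 1, max)
  pmax_ <- ifelse(pmax_ > pmin_, pmax_, pmin_ + 1)
  for (lab in record$channel_labels) wr(lab, 16)
  for (i in seq_len(ns)) wr("synthetic", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(edf_num(pmin_[i], 8), 8)
  for (i in seq_len(ns)) wr(edf_num(pmax_[i], 8), 8)
  for (i in seq_len(ns)) wr("-32768", 8)
  for (i in seq_len(ns)) wr("32767", 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(as.character(n), 8)
  for (i in seq_len(ns)) wr("", 32)
  for (i in seq_len(ns)) {
    dig <- round((record$samples[i, ] - pmin_[i]) / (pmax_[i] - pmin_[i]) * 65535 - 32768)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' Parses the header and rescales the 16-bit samples to physical units.
#' Metadata written by [write_edf()] (subject, trial, class) is recovered
#' from the identification fields when present.
#'
#' @param path EDF file path.
#' @return an [eeg_record()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)
  patient <- rd(80)
  recording <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  n_records <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  samples <- matrix(0, nrow = ns, ncol = spr[1] * n_records)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[i], size = 2, endian = "little")
      phys <- pmin_[i] + (dig - dmin_[i]) / (dmax_[i] - dmin_[i]) * (pmax_[i] - pmin_[i])
      samples[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <- phys
    }
  }
  subject <- as.integer(sub(".*subject (\\d+).*", "\\1", patient))
  trial <- suppressWarnings(as.integer(sub(".*trial (\\d+).*", "\\1", recording)))
  cls <- sub(".*class (\\S+).*", "\\1", recording)
  eeg_record(samples, spr[1] * n_records / (dur * n_records), subject %||% 0L,
             trial %||% 0L, cls, labels)
}

#' Write a corpus as a directory of per-record files plus a CSV manifest
#'
#' @param corpus an `eeg_corpus` (list of [eeg_record()]).
#' @param dir output directory (created if needed).
#' @param format `"bin"` (little-endian doubles, one file per record),
#'   `"csv"` (plain text matrices) or `"edf"`.
#' @return the manifest path, invisibly.
#' @export
write_corpus_dir <- function(corpus, dir, format = c("bin", "csv", "edf")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(corpus, function(rec) {
    stub <- sprintf("s%02d_t%02d", rec$subject_id, rec$trial_id)
    fname <- paste0(stub, switch(format, bin = ".bin", csv = ".csv", edf = ".edf"))
    fpath <- file.path(dir, fname)
    switch(format,
           bin = {
             con <- file(fpath, "wb")
             writeBin(as.numeric(t(rec$samples)), con, size = 8, endian = "little")
             close(con)
           },
           csv = utils::write.csv(t(rec$samples), fpath, row.names = FALSE),
           edf = write_edf(rec, fpath))
    data.frame(subject = rec$subject_id, trial = rec$trial_id,
               class = rec$class_label, file = fname,
               n_channels = nrow(rec$samples), n_samples = ncol(rec$samples),
               sampling_rate = rec$sampling_rate,
               channels = paste(rec$channel_labels, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a corpus directory written by [write_corpus_dir()]
#'
#' @param dir directory containing `manifest.csv`.
#' @return an `eeg_corpus` list of [eeg_record()].
#' @export
read_corpus_dir <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop_data("read_corpus_dir: no manifest.csv in ", dir)
  manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  records <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    fpath <- file.path(dir, m$file)
    if (!file.exists(fpath)) stop_data("read_corpus_dir: manifest names missing file ", m$file)
    chans <- strsplit(m$channels, ";")[[1]]
    if (grepl("\\.edf$", m$file)) return(read_edf(fpath))
    samples <- if (grepl("\\.bin$", m$file)) {
      con <- file(fpath, "rb")
      v <- readBin(con, numeric(), n = m$n_channels * m$n_samples, size = 8,
                   endian = "little")
      close(con)
      matrix(v, nrow = m$n_channels, byrow = TRUE)
    } else {
      t(as.matrix(utils::read.csv(fpath)))
    }
    eeg_record(samples, m$sampling_rate, m$subject, m$trial, m$class, chans)
  })
  structure(records, class = "eeg_corpus")
}

#' Write a feature table as columnar binary + CSV key manifest
#'
#' Creates `<stub>.bin` (row-major doubles), `<stub>_keys.csv` and
#' `<stub>_meta.json` (dimensions and stage).
#'
#' @param tab a [feature_table()].
#' @param stub path stub without extension.
#' @return `stub`, invisibly.
#' @export
write_feature_table <- function(tab, stub) {
  if (!inherits(tab, "feature_table")) stop_data("write_feature_table: expected a feature_table")
  con <- file(paste0(stub, ".bin"), "wb")
  writeBin(as.numeric(t(tab$rows)), con, size = 8, endian = "little")
  close(con)
  utils::write.csv(tab$keys, paste0(stub, "_keys.csv"), row.names = FALSE)
  jsonlite::write_json(list(n_rows = nrow(tab$rows), n_cols = ncol(tab$rows),
                            stage = tab$stage),
                       paste0(stub, "_meta.json"), auto_unbox = TRUE)
  invisible(stub)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param stub path stub without extension.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(stub) {
  meta_path <- paste0(stub, "_meta.json")
  if (!file.exists(meta_path)) stop_data("read_feature_table: missing manifest ", meta_path)
  meta <- tryCatch(jsonlite::read_json(meta_path),
                   error = function(e) stop_data("read_feature_table: corrupted manifest ", meta_path))
  keys <- utils::read.csv(paste0(stub, "_keys.csv"), stringsAsFactors = FALSE)
  con <- file(paste0(stub, ".bin"), "rb")
  v <- readBin(con, numeric(), n = meta$n_rows * meta$n_cols, size = 8,
               endian = "little")
  close(con)
  feature_table(matrix(v, nrow = meta$n_rows, byrow = TRUE), keys,
                stage = meta$stage)
}
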