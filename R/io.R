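#' Write a recording to disk
#'
#' Two on-disk formats are supported. `"delimited"` is the canonical,
#' loss-free interchange format: a tab-separated table (samples in rows,
#' channels in columns, full double precision) preceded by `#`-prefixed
#' metadata lines. `"edf"` writes a minimal European Data Format file
#' (16-bit, one data record per second) for interoperability; EDF is a
#' quantized integer format, so round-trips are exact only to the 16-bit
#' amplitude resolution.
#'
#' @param rec A [recording].
#' @param path Output file path.
#' @param format `"delimited"` or `"edf"`; default guessed from the file
#'   extension (`.edf` selects EDF).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = NULL) {
  validate_recording(rec)
  format <- format %||% guess_format(path)
  switch(match.arg(format, c("delimited", "edf")),
         delimited = write_recording_delim(rec, path),
         edf = write_recording_edf(rec, path))
  invisible(path)
}

#' Read a recording from disk
#'
#' @param path File path written by [write_recording()] (or any EDF/TSV file
#'   with the same layout).
#' @param format `"delimited"` or `"edf"`; default guessed from extension.
#' @return A [recording].
#' @export
read_recording <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- format %||% guess_format(path)
  switch(match.arg(format, c("delimited", "edf")),
         delimited = read_recording_delim(path),
         edf = read_recording_edf(path))
}

guess_format <- function(path) {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "delimited"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- delimited (canonical, exact) ----

write_recording_delim <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#stepconn_recording\tv1",
               sprintf("#fs\t%.17g", rec$fs),
               sprintf("#subject_id\t%s", rec$subject_id),
               sprintf("#condition\t%s", rec$condition),
               paste(rec$channel_labels, collapse = "\t")), con)
  # samples in rows; full precision so read(write(x)) is bit-identical
  txt <- apply(rec$data, 2L, function(col)
    paste(sprintf("%.17g", col), collapse = "\t"))
  writeLines(txt, con)
}

read_recording_delim <- function(path) {
  lines <- readLines(path)
  meta_idx <- grep("^#", lines)
  meta <- strsplit(sub("^#", "", lines[meta_idx]), "\t", fixed = TRUE)
  kv <- stats::setNames(vapply(meta, function(x) x[2], ""),
                        vapply(meta, function(x) x[1], ""))
  if (is.na(kv["fs"])) stop("no sampling rate in header: ", path)
  fs <- as.numeric(kv[["fs"]])
  if (!is.finite(fs) || fs <= 0) stop("non-positive sampling rate in ", path)
  body <- lines[-meta_idx]
  labels <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  ncol_ok <- vapply(rows, length, 0L) == length(labels)
  if (!all(ncol_ok)) stop("row length does not match number of labels in ", path)
  data <- t(vapply(rows, function(r) as.numeric(r), numeric(length(labels))))
  if (length(labels) == 1L) data <- matrix(unlist(rows), ncol = 1)
  recording(t(data), fs, labels,
            subject_id = kv[["subject_id"]] %||na% "unknown",
            condition = kv[["condition"]] %||na% NA_character_)
}

`%||na%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

## ---- EDF (minimal 16-bit implementation) ----

pad_ascii <- function(x, n) {
  x <- substr(as.character(x), 1L, n)
  formatC(x, width = -n, flag = " ")
}

write_recording_edf <- function(rec, path) {
  if (rec$fs != round(rec$fs)) stop("EDF writer requires an integer sampling rate")
  m <- nrow(rec$data); n <- ncol(rec$data); fs <- as.integer(rec$fs)
  n_rec <- as.integer(ceiling(n / fs))
  pmin_ <- apply(rec$data, 1, min); pmax_ <- apply(rec$data, 1, max)
  flat <- pmax_ - pmin_ < .Machine$double.eps
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_ascii("0", 8), pad_ascii(rec$subject_id, 80),
    pad_ascii(paste0("Startdate X cond=", rec$condition, " ns=", n), 80),
    pad_ascii("01.01.00", 8), pad_ascii("00.00.00", 8),
    pad_ascii(256L * (1L + m), 8), pad_ascii("", 44),
    pad_ascii(n_rec, 8), pad_ascii(1L, 8), pad_ascii(m, 4))
  sig <- paste0(
    paste(pad_ascii(rec$channel_labels, 16), collapse = ""),
    paste(rep(pad_ascii("", 80), m), collapse = ""),
    paste(rep(pad_ascii("uV", 8), m), collapse = ""),
    paste(pad_ascii(sprintf("%.8g", pmin_), 8), collapse = ""),
    paste(pad_ascii(sprintf("%.8g", pmax_), 8), collapse = ""),
    paste(rep(pad_ascii(dmin, 8), m), collapse = ""),
    paste(rep(pad_ascii(dmax, 8), m), collapse = ""),
    paste(rep(pad_ascii("", 80), m), collapse = ""),
    paste(rep(pad_ascii(fs, 8), m), collapse = ""),
    paste(rep(pad_ascii("", 32), m), collapse = ""))
  writeChar(paste0(hdr, sig), con, eos = NULL)
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    idx <- pmin(idx, n)                       # pad final record with last sample
    block <- rec$data[, idx, drop = FALSE]
    dig <- round((block - pmin_) * scale + dmin)
    writeBin(as.integer(t(dig)), con, size = 2L, endian = "little")
  }
}

read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  ver <- rd(8); subject <- trimws(rd(80)); recid <- trimws(rd(80))
  rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8))
  m <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(m), function(i) rd(16), ""))
  rd(80 * m); rd(8 * m)
  pmin_ <- as.numeric(vapply(seq_len(m), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(m), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(m), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(m), function(i) rd(8), ""))
  rd(80 * m)
  spr <- as.integer(vapply(seq_len(m), function(i) rd(8), ""))
  rd(32 * m)
  if (length(unique(spr)) != 1L) stop("EDF reader supports uniform rates only")
  fs <- spr[1] / rec_dur
  raw <- readBin(con, "integer", n = n_rec * sum(spr), size = 2L,
                 signed = TRUE, endian = "little")
  data <- matrix(0, m, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    block <- matrix(raw[((r - 1) * m * spr[1] + 1):(r * m * spr[1])],
                    nrow = spr[1], ncol = m)
    data[, ((r - 1) * spr[1] + 1):(r * spr[1])] <- t(block)
  }
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  data <- (data - dmin) * scale + pmin_
  ns <- sub(".*ns=([0-9]+).*", "\\1", recid)
  if (grepl("^[0-9]+$", ns)) data <- data[, seq_len(as.integer(ns)), drop = FALSE]
  cond <- sub(".*cond=([A-Za-z_]+).*", "\\1", recid)
  if (!cond %in% condition_labels()) cond <- NA_character_
  recording(data, fs, labels, subject_id = subject, condition = cond)
}

## ---- events (BIDS-style events.tsv) ----

#' Write an event table as events.tsv
#'
#' Columns are `onset`, `duration` and `trial_type` (the limb label),
#' tab-separated, as in BIDS events files.
#'
#' @param events An [event_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  df <- data.frame(onset = sprintf("%.17g", events$onset),
                   duration = "0",
                   trial_type = events$limb)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an events.tsv file
#'
#' @param path Tab-separated file with columns `onset`, `duration`,
#'   `trial_type`; `trial_type` must be a limb label.
#' @return An [event_table()], sorted by onset.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(df))) {
    stop("events file must have columns onset, duration, trial_type")
  }
  bad <- setdiff(unique(df$trial_type), limb_labels())
  if (length(bad)) stop("unknown trial_type: ", paste(bad, collapse = ", "))
  if (any(df$onset < 0)) stop("negative onset in events file")
  event_table(df$onset, df$trial_type)
}

## ---- generic delimited matrix helpers ----

write_matrix_tsv <- function(x, path, col_names = NULL) {
  x <- as.matrix(x)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(col_names)) writeLines(paste(col_names, collapse = "\t"), con)
  writeLines(apply(x, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t")),
             con)
}

read_matrix_tsv <- function(path, header = FALSE) {
  as.matrix(utils::read.table(path, header = header, sep = "\t"))
}
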