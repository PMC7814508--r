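# I/O for ECG records, beat annotations and prediction tables.
#
# Two on-disk dialects are supported behind one interface:
#   * csv  — the canonical plain-text dialect: record files with columns
#            (sample_index, value), annotation files with (sample_index, label).
#   * wfdb — a minimal WFDB codec (single-signal .hea/.dat in formats 16 and
#            212, MIT-format .atr beat annotations) so MIT-BIH-style records
#            can be loaded when a user supplies them. Best effort: only the
#            header fields needed to recover the signal are interpreted.

# WFDB annotation type codes for the five beat classes handled here.
.WFDB_CODE <- c(N = 1L, V = 5L, F = 6L, A = 8L, S = 9L)

#' Read an ECG record
#'
#' @param path File path. For `format = "csv"` a two-column CSV
#'   (`sample_index,value`) with a header line; for `format = "wfdb"` the
#'   `.hea` header file (or the record base name) of a single-signal record.
#' @param format `"csv"` or `"wfdb"`.
#' @param fs Sampling rate in Hz; required for CSV (the dialect carries none),
#'   ignored for WFDB (read from the header).
#' @param patient_id Patient identifier; defaults to the file base name.
#' @return An [ecg_record()].
#' @seealso [write_ecg()], [read_annotations()]
#' @export
read_ecg <- function(path, format = c("csv", "wfdb"), fs = NULL,
                     patient_id = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    if (!file.exists(path)) stop("missing file: ", path)
    if (is.null(fs)) stop("fs is required for CSV records")
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("sample_index", "value") %in% names(df)))
      stop("record CSV must have columns sample_index,value")
    if (nrow(df) == 0L) stop("empty signal")
    if (!is.numeric(df$value) || anyNA(df$value))
      stop("non-numeric signal values")
    df <- df[order(df$sample_index), , drop = FALSE]
    if (is.null(patient_id))
      patient_id <- sub("\\.[^.]*$", "", basename(path))
    ecg_record(df$value, fs = fs, patient_id = patient_id)
  } else {
    read_wfdb_record(path, patient_id = patient_id)
  }
}

#' Write an ECG record
#'
#' @param record An [ecg_record()].
#' @param path Output path. For CSV, the file to write; for WFDB, the record
#'   base name (`.hea` and `.dat` are appended).
#' @param format `"csv"` or `"wfdb"`. WFDB output uses format 16 with gain
#'   200, so amplitudes round-trip to within 1/400 of a unit.
#' @return `path`, invisibly.
#' @export
write_ecg <- function(record, path, format = c("csv", "wfdb")) {
  stopifnot(inherits(record, "ecg_record"))
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(
      data.frame(sample_index = seq_len(record$L) - 1L, value = record$signal),
      path, row.names = FALSE, quote = FALSE)
  } else {
    write_wfdb_record(record, path)
  }
  invisible(path)
}

#' Read beat annotations
#'
#' @param path Annotation file: CSV with columns `sample_index,label`, or a
#'   WFDB (MIT-format) `.atr` file.
#' @param format `"csv"` or `"wfdb"`.
#' @param L Optional owning-record length for bounds checking.
#' @return A validated data frame from [beat_annotations()], sorted by
#'   `sample_index`.
#' @export
read_annotations <- function(path, format = c("csv", "wfdb"), L = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("missing file: ", path)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c("integer", "character"))
    if (!all(c("sample_index", "label") %in% names(df)))
      stop("annotation CSV must have columns sample_index,label")
    beat_annotations(df$sample_index, df$label, L = L)
  } else {
    read_wfdb_annotations(path, L = L)
  }
}

#' Write beat annotations
#'
#' @param ann Annotation data frame (see [beat_annotations()]).
#' @param path Output path.
#' @param format `"csv"` or `"wfdb"` (MIT-format `.atr`).
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  ann <- beat_annotations(ann$sample_index, ann$label)
  if (format == "csv") {
    utils::write.csv(ann, path, row.names = FALSE, quote = FALSE)
  } else {
    write_wfdb_annotations(ann, path)
  }
  invisible(path)
}

#' Write a predictions table
#'
#' Emits the fixed-schema CSV
#' `patient_id,window_index,true_label,predicted_label,distance`, sorted by
#' patient then window index so output is deterministic regardless of input
#' order.
#'
#' @param predictions Data frame with the five schema columns;
#'   `predicted_label` must be one of N, V, ANOMALY.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  cols <- c("patient_id", "window_index", "true_label", "predicted_label",
            "distance")
  if (!all(cols %in% names(predictions)))
    stop("predictions must have columns ", paste(cols, collapse = ","))
  predictions <- predictions[, cols, drop = FALSE]
  if (anyNA(predictions$predicted_label) ||
      !all(predictions$predicted_label %in% c("N", "V", "ANOMALY")))
    stop("predicted_label must be one of N, V, ANOMALY")
  ord <- order(predictions$patient_id, predictions$window_index)
  utils::write.csv(predictions[ord, , drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- minimal WFDB codec -------------------------------------------------

wfdb_base <- function(path) sub("\\.(hea|dat|atr)$", "", path)

read_wfdb_record <- function(path, patient_id = NULL) {
  base <- wfdb_base(path)
  hea <- paste0(base, ".hea")
  if (!file.exists(hea)) stop("missing file: ", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 4L) stop("malformed WFDB header")
  nsig <- as.integer(top[2])
  fs <- as.numeric(sub("/.*$", "", top[3]))  # drop counter-frequency suffix
  nsamp <- as.integer(top[4])
  if (is.na(fs) || fs <= 0) stop("non-positive fs in WFDB header")
  if (nsig != 1L) stop("only single-signal WFDB records are supported")
  sig <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  datfile <- file.path(dirname(hea), sig[1])
  fmt <- as.integer(sub("[x:+].*$", "", sig[2]))
  gainfield <- if (length(sig) >= 3) sig[3] else "200"
  gain <- as.numeric(sub("[(/].*$", "", gainfield))
  if (is.na(gain) || gain == 0) gain <- 200
  baseline <- if (grepl("\\(", gainfield))
    as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gainfield)) else 0
  adc <- read_wfdb_dat(datfile, fmt, nsamp)
  if (is.null(patient_id)) patient_id <- basename(base)
  ecg_record((adc - baseline) / gain, fs = fs, patient_id = patient_id)
}

read_wfdb_dat <- function(datfile, fmt, nsamp) {
  if (!file.exists(datfile)) stop("missing file: ", datfile)
  raw <- readBin(datfile, "raw", file.info(datfile)$size)
  if (fmt == 16L) {
    adc <- readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
                   signed = TRUE, endian = "little")
  } else if (fmt == 212L) {
    b <- as.integer(raw)
    ntrip <- length(b) %/% 3L
    b0 <- b[seq_len(ntrip) * 3L - 2L]
    b1 <- b[seq_len(ntrip) * 3L - 1L]
    b2 <- b[seq_len(ntrip) * 3L]
    s1 <- b0 + bitwShiftL(bitwAnd(b1, 0x0FL), 8L)
    s2 <- b2 + bitwShiftL(bitwShiftR(b1, 4L), 8L)
    s1 <- ifelse(s1 >= 2048L, s1 - 4096L, s1)  # 12-bit two's complement
    s2 <- ifelse(s2 >= 2048L, s2 - 4096L, s2)
    adc <- as.vector(rbind(s1, s2))
  } else {
    stop("unsupported WFDB signal format: ", fmt)
  }
  if (!is.na(nsamp) && nsamp > 0L) adc <- adc[seq_len(min(nsamp, length(adc)))]
  adc
}

write_wfdb_record <- function(record, path, gain = 200) {
  base <- wfdb_base(path)
  adc <- as.integer(round(record$signal * gain))
  if (any(adc > 32767L | adc < -32768L))
    stop("signal amplitude out of range for 16-bit WFDB output")
  writeLines(c(
    sprintf("%s 1 %g %d", basename(base), record$fs, record$L),
    sprintf("%s.dat 16 %d(0)/mV 16 0 %d 0 0 ECG", basename(base), gain,
            if (length(adc)) adc[1] else 0L)
  ), paste0(base, ".hea"))
  writeBin(adc, paste0(base, ".dat"), size = 2L, endian = "little")
  invisible(base)
}

read_wfdb_annotations <- function(path, L = NULL) {
  raw <- as.integer(readBin(path, "raw", file.info(path)$size))
  i <- 1L; time <- 0L
  idx <- integer(0); lab <- character(0)
  while (i + 1L <= length(raw)) {
    low <- raw[i]; high <- raw[i + 1L]; i <- i + 2L
    code <- bitwShiftR(high, 2L)
    interval <- bitwOr(bitwShiftL(bitwAnd(high, 3L), 8L), low)
    if (code == 0L && interval == 0L) break                    # EOF
    if (code == 59L) {                                         # SKIP
      if (interval == 0L) {
        hi <- raw[i] + bitwShiftL(raw[i + 1L], 8L)
        lo <- raw[i + 2L] + bitwShiftL(raw[i + 3L], 8L)
        i <- i + 4L
        time <- time + bitwShiftL(hi, 16L) + lo
      }
      next
    }
    if (code %in% 60:62) next                                  # NUM/SUB/CHN
    if (code == 63L) {                                         # AUX string
      i <- i + interval + (interval %% 2L)
      next
    }
    time <- time + interval
    hit <- names(.WFDB_CODE)[match(code, .WFDB_CODE)]
    if (is.na(hit)) stop("unknown label: WFDB annotation code ", code)
    idx <- c(idx, time); lab <- c(lab, hit)
  }
  beat_annotations(idx, lab, L = L)
}

write_wfdb_annotations <- function(ann, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  prev <- 0L
  for (j in seq_len(nrow(ann))) {
    delta <- ann$sample_index[j] - prev
    prev <- ann$sample_index[j]
    if (delta > 1023L) {
      writeBin(as.raw(c(0L, bitwShiftL(59L, 2L))), con)         # SKIP word
      hi <- bitwShiftR(delta, 16L); lo <- bitwAnd(delta, 0xFFFFL)
      writeBin(as.raw(c(bitwAnd(hi, 0xFFL), bitwShiftR(hi, 8L),
                        bitwAnd(lo, 0xFFL), bitwShiftR(lo, 8L))), con)
      delta <- 0L
    }
    code <- .WFDB_CODE[[ann$label[j]]]
    word <- bitwOr(bitwShiftL(code, 10L), delta)
    writeBin(as.raw(c(bitwAnd(word, 0xFFL), bitwShiftR(word, 8L))), con)
  }
  writeBin(as.raw(c(0L, 0L)), con)                              # EOF
  invisible(path)
}
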