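#' ECG record container
#'
#' Bundles one patient's raw single-lead signal with its sampling rate.
#' Amplitude units are not interpreted; whatever units the source file
#' carries are propagated unchanged.
#'
#' @param signal Numeric vector of amplitude samples (length >= 1).
#' @param fs Sampling rate in Hz (> 0); heartbeat segmentation assumes 180.
#' @param patient_id Character scalar identifying the patient.
#' @return An object of class `ecg_record` with fields `signal`, `fs`,
#'   `patient_id` and `L` (the sample count).
#' @examples
#' rec <- ecg_record(sin(seq(0, 10, length.out = 360)), fs = 180, patient_id = "p1")
#' rec$L
#' @export
ecg_record <- function(signal, fs, patient_id = "unknown") {
  signal <- as.numeric(signal)
  if (length(signal) < 1L) stop("empty signal")
  if (anyNA(signal)) stop("signal contains non-numeric or missing values")
  if (!is.numeric(fs) || length(fs) != 1L || is.na(fs) || fs <= 0)
    stop("sampling rate fs must be a positive number")
  structure(
    list(patient_id = as.character(patient_id), fs = as.numeric(fs),
         signal = signal, L = length(signal)),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("ECG record '%s': %d samples at %g Hz (%.1f s)\n",
              x$patient_id, x$L, x$fs, x$L / x$fs))
  invisible(x)
}

.BEAT_LABELS <- c("N", "V", "A", "F", "S")

#' Beat annotation table
#'
#' Validates a set of beat annotations: 0-based fiducial sample indices with
#' one of the five beat-class symbols N, V, A, F, S. Indices must be strictly
#' increasing.
#'
#' @param sample_index Integer vector of 0-based sample positions.
#' @param label Character vector of beat labels, same length.
#' @param L Optional record length; when given, indices must lie in `[0, L)`.
#' @return A `data.frame` with columns `sample_index` and `label`.
#' @export
beat_annotations <- function(sample_index, label, L = NULL) {
  sample_index <- as.integer(sample_index)
  label <- as.character(label)
  if (length(sample_index) != length(label))
    stop("sample_index and label lengths differ")
  if (anyNA(sample_index)) stop("non-numeric sample index")
  if (length(sample_index) && any(sample_index < 0L)) stop("negative sample index")
  bad <- setdiff(unique(label), .BEAT_LABELS)
  if (length(bad)) stop("unknown label: ", paste(bad, collapse = ", "))
  if (length(sample_index) > 1L && any(diff(sample_index) <= 0L))
    stop("annotations out of order: sample_index must be strictly increasing")
  if (!is.null(L) && length(sample_index) && any(sample_index >= L))
    stop("annotation sample_index beyond end of record")
  data.frame(sample_index = sample_index, label = label,
             stringsAsFactors = FALSE)
}

#' Labeled heartbeat set
#'
#' The working container for fixed-length heartbeats (pattern units): a
#' numeric matrix with one W-sample beat per row plus per-beat provenance.
#'
#' @param X Numeric matrix, one beat per row (n x W).
#' @param patient_id Character vector (length 1 or n) of patient ids.
#' @param window_index Integer vector of 0-based window indices.
#' @param label Character vector of beat labels, or `NA` for unlabeled windows.
#' @param fs Sampling rate the beats were cut at.
#' @param start_sample Optional 0-based start sample of each window; defaults
#'   to `window_index * W`.
#' @return An object of class `beat_set`.
#' @export
beat_set <- function(X, patient_id, window_index, label = NA_character_,
                     fs = 180, start_sample = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  patient_id <- rep_len(as.character(patient_id), n)
  window_index <- rep_len(as.integer(window_index), n)
  label <- rep_len(as.character(label), n)
  if (is.null(start_sample)) start_sample <- window_index * ncol(X)
  start_sample <- rep_len(as.integer(start_sample), n)
  structure(
    list(X = X, patient_id = patient_id, window_index = window_index,
         label = label, start_sample = start_sample,
         fs = as.numeric(fs), W = ncol(X)),
    class = "beat_set"
  )
}

#' Number of beats in a beat set
#' @param beats A `beat_set`.
#' @return Integer count.
#' @export
n_beats <- function(beats) {
  stopifnot(inherits(beats, "beat_set"))
  nrow(beats$X)
}

#' @export
`[.beat_set` <- function(x, i, ...) {
  beat_set(x$X[i, , drop = FALSE], x$patient_id[i], x$window_index[i],
           x$label[i], fs = x$fs, start_sample = x$start_sample[i])
}

#' Concatenate beat sets (e.g. pooling patients for a generalized model)
#' @param ... `beat_set` objects with identical window length W.
#' @return One combined `beat_set`, rows in argument order.
#' @export
bind_beats <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !inherits(sets[[1]], "beat_set"))
    sets <- sets[[1]]
  stopifnot(length(sets) >= 1L, all(vapply(sets, inherits, TRUE, "beat_set")))
  W <- unique(vapply(sets, function(s) s$W, 0L))
  if (length(W) != 1L) stop("mixed window lengths")
  beat_set(do.call(rbind, lapply(sets, function(s) s$X)),
           unlist(lapply(sets, function(s) s$patient_id)),
           unlist(lapply(sets, function(s) s$window_index)),
           unlist(lapply(sets, function(s) s$label)),
           fs = sets[[1]]$fs,
           start_sample = unlist(lapply(sets, function(s) s$start_sample)))
}

#' @export
print.beat_set <- function(x, ...) {
  tab <- table(factor(x$label, levels = .BEAT_LABELS), useNA = "ifany")
  cat(sprintf("beat_set: %d beats x %d samples, %d patient(s)\n",
              nrow(x$X), x$W, length(unique(x$patient_id))))
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}
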