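# Training-sample sizing and fixed-grid segmentation.
#
# A recording of length L is sampled from its start: the training stretch is
# S = floor(L * t) samples for training ratio t, and a stretch of S samples
# yields M = floor(S / W) consecutive non-overlapping pattern units of W
# samples each (W defaults to 180, one beat per window at 180 Hz). Fractional
# trailing samples/windows are discarded; windows are half-open
# [start, start + W) on 0-based sample indices.

#' Training sample length
#'
#' Number of samples taken from the start of a record for training:
#' `S = floor(L * t)`.
#'
#' @param L Record length in samples (>= 1).
#' @param t Training ratio in (0, 1); `t = 1` is additionally allowed to
#'   segment a whole record.
#' @return Integer sample count `S <= L`.
#' @examples
#' training_sample_length(324000, 0.1)  # 30 min at 180 Hz -> 32400
#' @export
training_sample_length <- function(L, t) {
  if (!is.numeric(L) || length(L) != 1L || L < 1) stop("L must be >= 1")
  if (!is.numeric(t) || length(t) != 1L || t <= 0 || t > 1)
    stop("training ratio t must lie in (0, 1]")
  as.integer(floor(L * t))
}

#' Segment a record into fixed-length pattern units
#'
#' Cuts the first `S` samples of a record into `M = floor(S / W)` consecutive
#' non-overlapping windows of `W` samples starting at sample 0. The windows
#' tile `[0, M * W)` exactly; a trailing remainder shorter than `W` is
#' discarded.
#'
#' @param record An [ecg_record()].
#' @param S Number of samples to segment (defaults to the whole record).
#' @param W Window length in samples (>= 2; default 180).
#' @return An unlabeled [beat_set()] of `M` windows.
#' @export
segment_record <- function(record, S = record$L, W = 180L) {
  stopifnot(inherits(record, "ecg_record"))
  if (W < 2L) stop("window length W must be >= 2")
  if (S > record$L) stop("S exceeds record length")
  M <- S %/% W
  if (M < 1L) stop("sample too short for one pattern unit")
  X <- matrix(record$signal[seq_len(M * W)], nrow = M, ncol = W, byrow = TRUE)
  beat_set(X, patient_id = record$patient_id, window_index = seq_len(M) - 1L,
           label = NA_character_, fs = record$fs)
}

#' Label pattern units from beat annotations
#'
#' Assigns each window the label of the single annotated fiducial falling in
#' its half-open span. Windows with no fiducial, more than one fiducial, or a
#' fiducial whose label is outside `keep_labels` are dropped ("noisy" beat
#' removal) and itemized in a discard report.
#'
#' @param windows Unlabeled [beat_set()] from [segment_record()].
#' @param annotations Annotation data frame (see [beat_annotations()]).
#' @param keep_labels Labels retained; default `c("N", "V")`.
#' @return A list with `beats` (labeled [beat_set()]) and `discards`
#'   (data frame `patient_id, window_index, discard_reason` with reasons
#'   `none`, `multiple` or `excluded_label`).
#' @export
label_windows <- function(windows, annotations, keep_labels = c("N", "V")) {
  stopifnot(inherits(windows, "beat_set"))
  if (!length(keep_labels) || !all(keep_labels %in% .BEAT_LABELS))
    stop("keep_labels must be a non-empty subset of N,V,A,F,S")
  W <- windows$W
  n <- n_beats(windows)
  # map each fiducial to its window: fiducial s lies in window floor(s / W)
  win_of <- annotations$sample_index %/% W
  counts <- tabulate(win_of + 1L, nbins = n)
  lab <- rep(NA_character_, n)
  one <- which(counts == 1L)
  first_in <- match(one - 1L, win_of)
  lab[one] <- annotations$label[first_in]
  keep <- !is.na(lab) & lab %in% keep_labels
  reason <- ifelse(counts == 0L, "none",
            ifelse(counts > 1L, "multiple",
            ifelse(keep, NA_character_, "excluded_label")))
  discards <- data.frame(
    patient_id = windows$patient_id[!keep],
    window_index = windows$window_index[!keep],
    discard_reason = reason[!keep],
    stringsAsFactors = FALSE)
  beats <- windows[keep]
  beats$label <- lab[keep]
  list(beats = beats, discards = discards)
}

#' Per-class prefix train/test split (personalized sampling)
#'
#' For each retained class with `n_c` beats, the first `ceiling(t * n_c)`
#' beats in time order go to the training set; everything else is test. A
#' class absent from the record contributes nothing. Train and test partition
#' the input exactly.
#'
#' @param beats A labeled [beat_set()] from a single patient, time-ordered.
#' @param t Training ratio in (0, 1).
#' @return A list with `train` and `test` beat sets.
#' @export
stratified_prefix_split <- function(beats, t) {
  stopifnot(inherits(beats, "beat_set"))
  if (!is.numeric(t) || length(t) != 1L || t <= 0 || t >= 1)
    stop("training ratio t must lie in (0, 1)")
  if (length(unique(beats$patient_id)) > 1L)
    stop("stratified_prefix_split expects beats from a single patient")
  n <- n_beats(beats)
  take <- logical(n)
  for (cl in unique(beats$label)) {
    idx <- which(beats$label == cl)
    take[idx[seq_len(max(1L, ceiling(t * length(idx))))]] <- TRUE
  }
  list(train = beats[take], test = beats[!take])
}
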