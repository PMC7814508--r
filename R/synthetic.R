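# Seeded synthetic multi-patient ECG cohort generator.
#
# Beats are synthesized as sums of Gaussian bumps: the normal (N) template
# carries the five P-Q-R-S-T deflections of a healthy beat; the ventricular
# (V) template is a wide, inverted-polarity QRS complex without a P wave.
# Each patient draws its own bump amplitudes, timings and widths once
# (inter-patient morphology divergence); each beat then jitters the
# patient's template (intra-patient variability) and additive Gaussian
# sample noise is applied. Beats are laid on a fixed grid of one beat per
# W = fs samples with the fiducial annotation at the window center, so
# fixed-grid segmentation recovers exactly one labeled fiducial per window;
# a misalignment option shifts fiducials off-grid to exercise the
# window-labeling discard rules. Everything is deterministic given the
# cohort seed: patient p of a spec re-simulates bit-identically regardless
# of how many other patients are generated.

.N_BUMPS <- data.frame(
  wave  = c("P", "Q", "R", "S", "T"),
  amp   = c(0.12, -0.14, 1.00, -0.22, 0.30),
  mu    = c(0.30, 0.45, 0.50, 0.55, 0.72),   # fraction of window
  sigma = c(0.022, 0.010, 0.014, 0.011, 0.045))

.V_BUMPS <- data.frame(
  wave  = c("Rp", "Sp", "Tp"),
  amp   = c(-0.90, 0.65, 0.35),
  mu    = c(0.48, 0.60, 0.78),
  sigma = c(0.050, 0.055, 0.050))

#' Specification of a synthetic ECG cohort
#'
#' Defaults give the desk-scale study cohort: 8 patients, 5 minutes each at
#' 180 Hz (300 beats per patient), 10% ventricular beats, strongly divergent
#' morphologies across patients and mild within-patient variability. Set
#' `n_patients = 32, duration_min = 30` for the full-scale shape.
#'
#' @param n_patients Number of patients (>= 1).
#' @param duration_min Minutes of signal per patient.
#' @param fs Sampling rate in Hz; one beat occupies `fs` samples.
#' @param v_fraction Probability a beat is ventricular (V).
#' @param other_fraction Probability a beat carries one of the excluded
#'   labels A/F/S (emitted only to exercise noisy-beat removal).
#' @param inter_patient_sd Morphology divergence across patients: sd of the
#'   per-patient log-amplitude perturbation of each waveform deflection
#'   (timing and width perturbations scale with it).
#' @param intra_patient_sd Beat-to-beat jitter within a patient: sd of the
#'   per-beat log amplitude scale; time jitter scales with it.
#' @param noise_sd Additive Gaussian sample noise, in units of the R-wave
#'   amplitude (1.0).
#' @param hr_bpm_range Range the patient's resting heart rate is drawn from;
#'   compresses or dilates the PQRST complex within its window.
#' @param misalign_jitter Maximum fiducial shift in samples (0 keeps beats
#'   window-aligned).
#' @param seed Integer cohort seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 8L, duration_min = 5, fs = 180,
                        v_fraction = 0.1, other_fraction = 0,
                        inter_patient_sd = 0.4, intra_patient_sd = 0.02,
                        noise_sd = 0.02, hr_bpm_range = c(55, 75),
                        misalign_jitter = 0L, seed = 1L) {
  stopifnot(n_patients >= 1L, duration_min > 0, fs > 0,
            v_fraction >= 0, v_fraction < 1,
            other_fraction >= 0, v_fraction + other_fraction < 1,
            inter_patient_sd >= 0, intra_patient_sd >= 0, noise_sd >= 0,
            length(hr_bpm_range) == 2L, all(hr_bpm_range > 0))
  structure(list(n_patients = as.integer(n_patients),
                 duration_min = duration_min, fs = fs,
                 v_fraction = v_fraction, other_fraction = other_fraction,
                 inter_patient_sd = inter_patient_sd,
                 intra_patient_sd = intra_patient_sd, noise_sd = noise_sd,
                 hr_bpm_range = as.numeric(hr_bpm_range),
                 misalign_jitter = as.integer(misalign_jitter),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

patient_seed <- function(spec, patient_index) {
  with_seed(spec$seed,
            sample.int(.Machine$integer.max, patient_index)[patient_index])
}

#' Draw a patient's beat morphology
#'
#' Perturbs the base N and V bump parameters once for a patient:
#' log-amplitudes by `inter_patient_sd`, timings by `0.05 * inter_patient_sd`
#' (fraction of the window), log-widths by `0.5 * inter_patient_sd`, plus a
#' heart-rate-dependent stretch of the whole complex.
#'
#' @param spec A [cohort_spec()].
#' @param patient_index Patient number, 1-based.
#' @return A list with per-class bump tables (`N`, `V`) and the drawn
#'   heart rate `hr_bpm`; deterministic given `(spec$seed, patient_index)`.
#' @export
patient_morphology <- function(spec, patient_index) {
  with_seed(patient_seed(spec, patient_index), {
    hr <- stats::runif(1, spec$hr_bpm_range[1], spec$hr_bpm_range[2])
    stretch <- 60 / hr
    perturb <- function(bumps) {
      nb <- nrow(bumps)
      bumps$amp <- bumps$amp * exp(stats::rnorm(nb, 0, spec$inter_patient_sd))
      bumps$mu <- 0.5 + (bumps$mu - 0.5 +
                         stats::rnorm(nb, 0, 0.05 * spec$inter_patient_sd)) *
                  stretch
      bumps$sigma <- bumps$sigma *
        exp(stats::rnorm(nb, 0, 0.5 * spec$inter_patient_sd)) * stretch
      bumps
    }
    list(N = perturb(.N_BUMPS), V = perturb(.V_BUMPS), hr_bpm = hr)
  })
}

#' Render a beat template from a morphology
#'
#' @param label `"N"` or `"V"`.
#' @param morphology A patient morphology from [patient_morphology()].
#' @param W Window length in samples.
#' @return Numeric vector of `W` amplitude values.
#' @export
beat_template <- function(label, morphology, W = 180L) {
  if (!label %in% c("N", "V")) stop("label must be N or V")
  bumps <- morphology[[label]]
  x <- (seq_len(W) - 0.5) / W
  y <- numeric(W)
  for (j in seq_len(nrow(bumps)))
    y <- y + bumps$amp[j] *
      exp(-(x - bumps$mu[j])^2 / (2 * bumps$sigma[j]^2))
  y
}

# Render n jittered instances of a bump table: per-beat log-amplitude scale
# sd = intra_sd, per-beat time shift sd = intra_sd / 20 (fraction of window).
beat_instances <- function(bumps, n, W, intra_sd) {
  x <- (seq_len(W) - 0.5) / W
  amp_scale <- exp(stats::rnorm(n, 0, intra_sd))
  shift <- stats::rnorm(n, 0, intra_sd / 20)
  Y <- matrix(0, n, W)
  for (j in seq_len(nrow(bumps))) {
    mu <- bumps$mu[j] + shift                  # n centers
    Y <- Y + (amp_scale * bumps$amp[j]) *
      exp(-(outer(-mu, x, "+"))^2 / (2 * bumps$sigma[j]^2))
  }
  Y
}

#' Simulate one patient's annotated ECG record
#'
#' @param spec A [cohort_spec()].
#' @param patient_index Patient number, 1-based.
#' @return A list with `record` (an [ecg_record()]), `annotations` (see
#'   [beat_annotations()]) and `morphology`. Deterministic given
#'   `(spec$seed, patient_index)`.
#' @export
simulate_patient <- function(spec, patient_index) {
  stopifnot(inherits(spec, "cohort_spec"))
  W <- as.integer(round(spec$fs))
  n_win <- as.integer(floor(spec$duration_min * 60 * spec$fs / W))
  if (n_win < 1L) stop("duration too short for one beat window")
  morph <- patient_morphology(spec, patient_index)
  pid <- sprintf("p%02d", patient_index)
  with_seed(patient_seed(spec, patient_index) + 1L, {
    u <- stats::runif(n_win)
    lab <- ifelse(u < spec$v_fraction, "V",
           ifelse(u < spec$v_fraction + spec$other_fraction,
                  sample(c("A", "F", "S"), n_win, replace = TRUE), "N"))
    X <- matrix(0, n_win, W)
    for (cl in c("N", "V")) {
      # A/F/S fidelity is a non-goal: excluded labels reuse the N shape
      rows <- if (cl == "N") which(lab != "V") else which(lab == "V")
      if (length(rows))
        X[rows, ] <- beat_instances(morph[[cl]], length(rows), W,
                                    spec$intra_patient_sd)
    }
    signal <- as.vector(t(X)) +
      stats::rnorm(n_win * W, 0, spec$noise_sd)
    fid <- (seq_len(n_win) - 1L) * W + W %/% 2L
    if (spec$misalign_jitter > 0L) {
      fid <- pmin(pmax(fid + sample(-spec$misalign_jitter:spec$misalign_jitter,
                                    n_win, replace = TRUE), 0L),
                  n_win * W - 1L)
      # heavy jitter can reorder or collide fiducials; keep a valid,
      # strictly increasing annotation stream (collisions are dropped)
      ord <- order(fid)
      fid <- fid[ord]
      lab <- lab[ord]
      keep <- !duplicated(fid)
      fid <- fid[keep]
      lab <- lab[keep]
    }
    list(record = ecg_record(signal, fs = spec$fs, patient_id = pid),
         annotations = beat_annotations(fid, lab, L = n_win * W),
         morphology = morph)
  })
}

#' Simulate a cohort, optionally writing it to disk
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional directory; when given, each patient is written in the
#'   CSV dialect (`<id>.csv`, `<id>_ann.csv`) together with a
#'   `manifest.yaml` recording the spec and per-patient seeds.
#' @return Named list (by patient id) of `simulate_patient()` outputs, with
#'   the spec attached as attribute `spec`.
#' @export
simulate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  patients <- lapply(seq_len(spec$n_patients), simulate_patient, spec = spec)
  names(patients) <- vapply(patients, function(p) p$record$patient_id, "")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (p in patients) {
      write_ecg(p$record, file.path(dir, paste0(p$record$patient_id, ".csv")))
      write_annotations(p$annotations,
                        file.path(dir, paste0(p$record$patient_id, "_ann.csv")))
    }
    yaml::write_yaml(
      c(unclass(spec),
        list(patient_seeds = vapply(seq_len(spec$n_patients),
                                    function(i) patient_seed(spec, i), 0L))),
      file.path(dir, "manifest.yaml"))
  }
  attr(patients, "spec") <- spec
  patients
}

#' Read a cohort directory written by [simulate_cohort()]
#' @param dir Directory containing `<id>.csv`, `<id>_ann.csv` and
#'   `manifest.yaml`.
#' @return Named list of `list(record, annotations)` per patient.
#' @export
read_cohort <- function(dir) {
  mf <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  files <- sort(list.files(dir, pattern = "^p[0-9]+\\.csv$", full.names = TRUE))
  if (!length(files)) stop("no patient records found in ", dir)
  out <- lapply(files, function(f) {
    pid <- sub("\\.csv$", "", basename(f))
    rec <- read_ecg(f, fs = mf$fs, patient_id = pid)
    ann <- read_annotations(file.path(dir, paste0(pid, "_ann.csv")), L = rec$L)
    list(record = rec, annotations = ann)
  })
  names(out) <- vapply(out, function(p) p$record$patient_id, "")
  out
}

#' Segment and label one simulated/loaded patient into heartbeats
#' @param patient A `list(record, annotations)` element.
#' @param W Window length; defaults to one beat per second (`fs` samples).
#' @param keep_labels Labels retained, see [label_windows()].
#' @return A labeled [beat_set()].
#' @export
patient_beats <- function(patient, W = NULL,
                          keep_labels = c("N", "V")) {
  if (is.null(W)) W <- as.integer(round(patient$record$fs))
  win <- segment_record(patient$record, W = W)
  label_windows(win, patient$annotations, keep_labels)$beats
}

#' Segment and label a whole cohort into per-patient beat sets
#' @param cohort Output of [simulate_cohort()] or [read_cohort()].
#' @param W,keep_labels See [patient_beats()].
#' @return Named list of labeled [beat_set()]s, ready for [monitor_model()]
#'   or [run_sweep()].
#' @export
cohort_beats <- function(cohort, W = NULL, keep_labels = c("N", "V")) {
  lapply(cohort, patient_beats, W = W, keep_labels = keep_labels)
}
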