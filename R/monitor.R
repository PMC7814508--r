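#' Fit a monitoring model to a cohort under a training policy
#'
#' The top-level fitting interface. Splits the cohort according to the chosen
#' policy (see [pmm_split()], [gmm1_split()], [gmm2_split()]), then fits one
#' artificial logical network per patient (personalized policy) or one pooled
#' network (generalized policies) via [motif_network()].
#'
#' @param cohort Named list of per-patient labeled [beat_set()]s, e.g. from
#'   [cohort_beats()].
#' @param policy `"pmm"` (personalized), `"gmm1"` (pooled prefix) or
#'   `"gmm2"` (pooled class-stratified random).
#' @param r Similarity threshold / matching radius.
#' @param k Motifs per class.
#' @param t Training ratio in (0, 1).
#' @param normalize Distance mode, see [beat_distance()].
#' @param seed Seed for the `gmm2` random draw; ignored otherwise.
#' @param anomaly How `ANOMALY` predictions enter accuracy: `"error"` counts
#'   them as incorrect (default), `"exclude"` removes them from the
#'   denominator.
#' @return An object of class `monitor_model` with the split, the fitted
#'   network(s) and the call parameters. Methods: `print`, `summary`
#'   (per-patient and average accuracy), `predict` (predictions for all test
#'   beats, or for `newdata`), `plot` (per-patient accuracy bars).
#' @examples
#' cohort <- cohort_beats(simulate_cohort(cohort_spec(n_patients = 2,
#'                                                    duration_min = 2,
#'                                                    seed = 11)))
#' fit <- monitor_model(cohort, policy = "pmm", r = 1.0, k = 2, t = 0.2)
#' summary(fit)
#' @export
monitor_model <- function(cohort, policy = c("pmm", "gmm1", "gmm2"),
                          r = 1.0, k = 4L, t = 0.2,
                          normalize = c("znorm", "none"), seed = NULL,
                          anomaly = c("error", "exclude")) {
  policy <- match.arg(policy)
  normalize <- match.arg(normalize)
  anomaly <- match.arg(anomaly)
  split <- cohort_split(cohort, policy, t = t, seed = seed)
  networks <- fit_split(split, r = r, k = k, normalize = normalize)
  structure(
    list(policy = policy, r = r, k = k, t = t, normalize = normalize,
         seed = split$seed, anomaly = anomaly, split = split,
         networks = networks),
    class = "monitor_model")
}

# Fit the network(s) a cohort_split calls for; returns a named list (one
# entry per patient for pmm, a single "pooled" entry otherwise). D_cache is
# an optional environment of precomputed per-class training distance
# matrices keyed by split_cache_key().
fit_split <- function(split, r, k, normalize, D_cache = NULL) {
  getD <- function(key_pid, beats) {
    out <- list()
    for (cl in intersect(c("N", "V"), unique(beats$label))) {
      key <- split_cache_key(split, key_pid, cl)
      if (!is.null(D_cache) && !is.null(D_cache[[key]])) {
        out[[cl]] <- D_cache[[key]]
      } else {
        out[[cl]] <- pairwise_distances(beats[beats$label == cl], normalize)
        if (!is.null(D_cache)) D_cache[[key]] <- out[[cl]]
      }
    }
    out
  }
  if (split$policy == "pmm") {
    nets <- lapply(names(split$train_by_patient), function(pid) {
      b <- split$train_by_patient[[pid]]
      motif_network(b, r = r, k = k, normalize = normalize,
                    D = getD(pid, b), patient_id = pid)
    })
    names(nets) <- names(split$train_by_patient)
    nets
  } else {
    b <- split$train_pooled
    list(pooled = motif_network(b, r = r, k = k, normalize = normalize,
                                D = getD("pooled", b),
                                patient_id = "pooled"))
  }
}

split_cache_key <- function(split, pid, cl) {
  paste(split$policy, format(split$t), split$seed, pid, cl, sep = "|")
}

network_for <- function(object, pid) {
  if (object$policy == "pmm") object$networks[[pid]] else object$networks$pooled
}

#' Predict method for monitoring models
#'
#' Without `newdata`, classifies every patient's held-out test beats with the
#' network the policy assigns to that patient. With `newdata` (a named list
#' of [beat_set()]s), classifies those beats instead.
#'
#' @param object A `monitor_model`.
#' @param newdata Optional named list of beat sets, keyed by patient.
#' @param ... Unused.
#' @return A prediction data frame (see [classify_beats()]) covering all
#'   patients.
#' @export
predict.monitor_model <- function(object, newdata = NULL, ...) {
  sets <- if (is.null(newdata)) object$split$test_by_patient else newdata
  out <- lapply(names(sets), function(pid) {
    if (n_beats(sets[[pid]]) == 0L) return(NULL)
    classify_beats(network_for(object, pid), sets[[pid]])
  })
  do.call(rbind, out)
}

#' @export
print.monitor_model <- function(x, ...) {
  cat(sprintf("Monitoring model [%s]: r = %g, k = %d, t = %g, %s distance\n",
              toupper(x$policy), x$r, x$k, x$t, x$normalize))
  cat(sprintf("  %d patient(s); %s\n", length(x$split$test_by_patient),
              if (x$policy == "pmm") "one network per patient"
              else sprintf("pooled network with %d node(s)",
                           length(x$networks$pooled$nodes))))
  invisible(x)
}

#' Per-patient and average accuracy of a fitted monitoring model
#'
#' @param object A `monitor_model`.
#' @param ... Unused.
#' @return A data frame with one row per patient plus an `AVERAGE` row whose
#'   accuracy is the unweighted mean of the per-patient accuracies.
#' @export
summary.monitor_model <- function(object, ...) {
  pred <- predict(object)
  rows <- lapply(names(object$split$test_by_patient), function(pid) {
    p <- pred[pred$patient_id == pid, , drop = FALSE]
    cbind(data.frame(patient_id = pid, stringsAsFactors = FALSE),
          acc_components(p$predicted, p$true_label, object$anomaly))
  })
  tab <- do.call(rbind, rows)
  avg <- data.frame(patient_id = "AVERAGE",
                    n_test = sum(tab$n_test),
                    n_correct = sum(tab$n_correct),
                    n_anomaly = sum(tab$n_anomaly),
                    accuracy = mean(tab$accuracy[tab$n_test > 0]))
  structure(rbind(tab, avg), class = c("summary.monitor_model", "data.frame"),
            policy = object$policy)
}

#' @export
print.summary.monitor_model <- function(x, ...) {
  cat(sprintf("Accuracy by patient [%s]\n", toupper(attr(x, "policy"))))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot per-patient accuracy of a fitted monitoring model
#' @param x A `monitor_model`.
#' @param ... Passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.monitor_model <- function(x, ...) {
  s <- summary(x)
  pats <- s[s$patient_id != "AVERAGE", ]
  graphics::barplot(pats$accuracy, names.arg = pats$patient_id, las = 2,
                    ylim = c(0, 1), ylab = "accuracy",
                    main = sprintf("%s: r=%g k=%d t=%g", toupper(x$policy),
                                   x$r, x$k, x$t), ...)
  graphics::abline(h = s$accuracy[s$patient_id == "AVERAGE"], lty = 2)
  invisible(x)
}
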