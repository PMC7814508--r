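# Accuracy and the (R, K, T) parameter-sweep harness.
#
# Accuracy is the fraction of tested heartbeats whose predicted label equals
# the annotated label. The cohort AVERAGE is the unweighted mean of
# per-patient accuracies (not pooled-beat accuracy); a pooled-beat column is
# reported alongside for reference. ANOMALY predictions count as incorrect
# by default; `anomaly = "exclude"` instead drops them from the denominator.
#
# Sweeps report, per grid cell and policy, per-patient rows plus an AVERAGE
# row, together with algorithmic cost counters: the number of training
# pairwise distances (sum over discovery sets of n(n-1)/2) and of test
# distances (test beats x network nodes). Counters, not wall-clock, carry
# the efficiency contrast between personalized and pooled training; the
# personalized total grows linearly in the number of patients at fixed
# record length, the pooled total quadratically.

acc_components <- function(predicted, truth, anomaly = c("error", "exclude")) {
  anomaly <- match.arg(anomaly)
  n_anom <- sum(predicted == "ANOMALY")
  n_correct <- sum(predicted == truth)
  denom <- if (anomaly == "exclude") length(predicted) - n_anom
           else length(predicted)
  data.frame(n_test = length(predicted), n_correct = n_correct,
             n_anomaly = n_anom,
             accuracy = if (denom > 0) n_correct / denom else NA_real_)
}

#' Classification accuracy
#'
#' The number of heartbeats predicted correctly divided by the number of
#' heartbeats tested.
#'
#' @param predicted Character vector of predicted labels (may contain
#'   `"ANOMALY"`).
#' @param truth Character vector of annotated labels, same length.
#' @param anomaly `"error"` (anomalies are wrong; default) or `"exclude"`
#'   (anomalies leave the denominator).
#' @return Accuracy in `[0, 1]`; `NA` if the denominator is empty.
#' @export
beat_accuracy <- function(predicted, truth, anomaly = c("error", "exclude")) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  acc_components(predicted, truth, anomaly)$accuracy
}

#' Parameter grid for a sweep
#'
#' Defaults reproduce the study grid: similarity thresholds 0.8 to 1.6 by
#' 0.2, motif counts 2 to 10 by 2, training ratios 0.1 to 0.25 by 0.05, all
#' three policies.
#'
#' @param R_values Similarity thresholds.
#' @param K_values Motif counts per class.
#' @param T_values Training ratios.
#' @param policies Subset of `c("pmm", "gmm1", "gmm2")`.
#' @param seed Seed for the `gmm2` draws.
#' @param normalize Distance mode.
#' @param anomaly Anomaly accounting mode, see [beat_accuracy()].
#' @return A `sweep_grid` list.
#' @export
sweep_grid <- function(R_values = seq(0.8, 1.6, by = 0.2),
                       K_values = seq(2L, 10L, by = 2L),
                       T_values = seq(0.10, 0.25, by = 0.05),
                       policies = c("pmm", "gmm1", "gmm2"),
                       seed = 1L, normalize = c("znorm", "none"),
                       anomaly = c("error", "exclude")) {
  normalize <- match.arg(normalize)
  anomaly <- match.arg(anomaly)
  stopifnot(length(R_values) >= 1L, length(K_values) >= 1L,
            length(T_values) >= 1L,
            all(policies %in% c("pmm", "gmm1", "gmm2")))
  for (r in R_values) motif_params(r = r)
  for (k in K_values) motif_params(k = k)
  if (any(T_values <= 0 | T_values >= 1)) stop("T values must lie in (0, 1)")
  structure(list(R_values = as.numeric(R_values),
                 K_values = as.integer(K_values),
                 T_values = as.numeric(T_values), policies = policies,
                 seed = as.integer(seed), normalize = normalize,
                 anomaly = anomaly),
            class = "sweep_grid")
}

#' Evaluate one grid cell
#'
#' Trains the given policy at `(r, k, t)`, classifies every patient's test
#' beats and reports per-patient rows plus one AVERAGE row.
#'
#' @param cohort Named list of per-patient labeled [beat_set()]s.
#' @param policy One of `"pmm"`, `"gmm1"`, `"gmm2"`.
#' @param r,k,t Cell parameters.
#' @param seed Seed for the `gmm2` draw.
#' @param normalize Distance mode.
#' @param anomaly Anomaly accounting mode.
#' @param cache Optional environment used to reuse training distance
#'   matrices across cells that share a `(policy, t)` split.
#' @return A data frame with columns `policy, r, k, t, patient_id, n_test,
#'   n_correct, n_anomaly, accuracy, pooled_accuracy, train_dist_ops,
#'   test_dist_ops, elapsed`; `patient_id = "AVERAGE"` carries the unweighted
#'   mean of per-patient accuracies. Patients with no test beats are excluded
#'   from the average (accuracy `NA`).
#' @export
run_cell <- function(cohort, policy = c("pmm", "gmm1", "gmm2"), r, k, t,
                     seed = NULL, normalize = c("znorm", "none"),
                     anomaly = c("error", "exclude"), cache = NULL) {
  policy <- match.arg(policy)
  normalize <- match.arg(normalize)
  anomaly <- match.arg(anomaly)
  t0 <- proc.time()[["elapsed"]]
  split <- cohort_split(cohort, policy, t = t, seed = seed)
  networks <- suppressWarnings(
    fit_split(split, r = r, k = k, normalize = normalize, D_cache = cache))
  train_sets <- if (policy == "pmm") split$train_by_patient
                else list(pooled = split$train_pooled)
  train_ops <- sum(vapply(train_sets, function(b) {
    sum(vapply(intersect(c("N", "V"), unique(b$label)), function(cl) {
      n <- sum(b$label == cl); n * (n - 1) / 2
    }, 0))
  }, 0))
  rows <- lapply(names(split$test_by_patient), function(pid) {
    net <- if (policy == "pmm") networks[[pid]] else networks$pooled
    tb <- split$test_by_patient[[pid]]
    if (n_beats(tb) == 0L) {
      warning("patient ", pid, " has no test beats; excluded from average")
      comp <- data.frame(n_test = 0L, n_correct = 0L, n_anomaly = 0L,
                         accuracy = NA_real_)
      ops <- 0
    } else {
      p <- classify_beats(net, tb)
      comp <- acc_components(p$predicted, p$true_label, anomaly)
      ops <- n_beats(tb) * length(net$nodes)
    }
    cbind(data.frame(policy = policy, r = r, k = k, t = t, patient_id = pid,
                     stringsAsFactors = FALSE),
          comp, pooled_accuracy = NA_real_,
          train_dist_ops = NA_real_, test_dist_ops = ops)
  })
  tab <- do.call(rbind, rows)
  elapsed <- proc.time()[["elapsed"]] - t0
  avg <- data.frame(policy = policy, r = r, k = k, t = t,
                    patient_id = "AVERAGE",
                    n_test = sum(tab$n_test), n_correct = sum(tab$n_correct),
                    n_anomaly = sum(tab$n_anomaly),
                    accuracy = mean(tab$accuracy[tab$n_test > 0L]),
                    pooled_accuracy =
                      if (anomaly == "error")
                        sum(tab$n_correct) / sum(tab$n_test)
                      else sum(tab$n_correct) /
                        max(1L, sum(tab$n_test) - sum(tab$n_anomaly)),
                    train_dist_ops = train_ops,
                    test_dist_ops = sum(tab$test_dist_ops),
                    stringsAsFactors = FALSE)
  out <- rbind(tab, avg)
  out$elapsed <- elapsed
  out
}

#' Run a full (R, K, T) parameter sweep
#'
#' Evaluates every grid cell for every requested policy via [run_cell()],
#' reusing training distance matrices across cells that share a split so the
#' full study grid stays cheap.
#'
#' @param cohort Named list of per-patient labeled [beat_set()]s.
#' @param grid A [sweep_grid()].
#' @return A long-format data frame of class `sweep_result` (rbind of
#'   [run_cell()] outputs).
#' @export
run_sweep <- function(cohort, grid = sweep_grid()) {
  stopifnot(inherits(grid, "sweep_grid"))
  cache <- new.env(parent = emptyenv())
  out <- list()
  for (t in grid$T_values)
    for (policy in grid$policies)
      for (r in grid$R_values)
        for (k in grid$K_values)
          out[[length(out) + 1L]] <-
            run_cell(cohort, policy, r = r, k = k, t = t, seed = grid$seed,
                     normalize = grid$normalize, anomaly = grid$anomaly,
                     cache = cache)
  res <- do.call(rbind, out)
  class(res) <- c("sweep_result", "data.frame")
  res
}

#' Average-accuracy rows of a sweep result
#' @param result A `sweep_result`.
#' @return The `AVERAGE` rows only.
#' @export
sweep_averages <- function(result) {
  result[result$patient_id == "AVERAGE", , drop = FALSE]
}

#' Write a sweep result to CSV
#' @param result A `sweep_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(result, path) {
  utils::write.csv(result, path, row.names = FALSE)
  invisible(path)
}

#' Plot cohort-average accuracy against each swept parameter
#'
#' One panel per swept parameter (r, k, t): average accuracy per policy,
#' averaged over the other two parameters.
#'
#' @param result A `sweep_result`.
#' @param dir Optional directory; when given, one PNG per panel is written
#'   there instead of drawing on the current device.
#' @return Invisibly, the list of panel data frames.
#' @export
plot_sweep <- function(result, dir = NULL) {
  avg <- sweep_averages(result)
  panels <- list()
  for (par in c("r", "k", "t")) {
    agg <- stats::aggregate(list(accuracy = avg$accuracy),
                            by = list(x = avg[[par]], policy = avg$policy),
                            FUN = mean)
    names(agg)[1] <- par
    panels[[par]] <- agg
    draw <- function() {
      pols <- unique(agg$policy)
      cols <- stats::setNames(c("forestgreen", "steelblue", "darkorange")
                              [seq_along(pols)], pols)
      graphics::plot(NULL, xlim = range(agg[[par]]), ylim = c(0, 1),
                     xlab = toupper(par), ylab = "average accuracy",
                     main = sprintf("Accuracy vs %s", toupper(par)))
      for (p in pols) {
        sub <- agg[agg$policy == p, ]
        graphics::lines(sub[[par]], sub$accuracy, type = "b", col = cols[[p]])
      }
      graphics::legend("bottomright", legend = toupper(pols),
                       col = cols[pols], lty = 1, bty = "n")
    }
    if (is.null(dir)) draw()
    else {
      grDevices::png(file.path(dir, sprintf("accuracy_vs_%s.png", par)),
                     width = 700, height = 500)
      draw()
      grDevices::dev.off()
    }
  }
  invisible(panels)
}
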