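# The artificial logical network: an ordered set of class-tagged motif nodes
# plus a nearest-node decision rule with an anomaly fallback. A test beat is
# compared against every node center; if the closest node lies strictly
# within the matching radius r its class is returned, otherwise the beat is
# flagged ANOMALY (it met no node's matching criterion) for review or future
# learning. Node order is fixed (N motifs by rank, then V motifs by rank) and
# breaks exact distance ties, so classification is deterministic.

#' Fit an artificial logical network of heartbeat motifs
#'
#' The core model fit: discovers the top-`k` motif circles independently for
#' each beat class present in the training beats (see [discover_motifs()])
#' and assembles their centers into the classifying network.
#'
#' @param beats A labeled [beat_set()] of training beats (classes N and/or V).
#' @param r Similarity threshold used both for motif-circle membership and as
#'   the matching radius at prediction time.
#' @param k Motifs per class.
#' @param normalize Distance mode, see [beat_distance()].
#' @param D Optional named list of precomputed per-class pairwise distance
#'   matrices (names = class labels), forwarded to [discover_motifs()].
#' @param patient_id Identifier stored on the network (`"pooled"` for
#'   generalized models).
#' @return An object of class `motif_network` with fields `patient_id`,
#'   `nodes` (a `motif_set`, N before V, ranks ascending), `r`, `normalize`,
#'   `W`, and `train_size` (beats per class used in discovery). Supports
#'   [predict()][predict.motif_network], `print`, `summary`, `plot` and
#'   `coef` (matrix of node centers).
#' @examples
#' spec <- cohort_spec(n_patients = 1, duration_min = 2, seed = 7)
#' beats <- patient_beats(simulate_patient(spec, 1))
#' split <- stratified_prefix_split(beats, t = 0.2)
#' net <- motif_network(split$train, r = 1.0, k = 2)
#' pred <- predict(net, split$test)
#' mean(pred$predicted == split$test$label)
#' @export
motif_network <- function(beats, r, k, normalize = c("znorm", "none"),
                          D = NULL, patient_id = NULL) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(beats, "beat_set"))
  if (anyNA(beats$label)) stop("training beats must be labeled")
  if (is.null(patient_id)) {
    ids <- unique(beats$patient_id)
    patient_id <- if (length(ids) == 1L) ids else "pooled"
  }
  classes <- intersect(c("N", "V"), unique(beats$label))
  if (!length(classes)) stop("no N or V beats to train on")
  motifs <- list()
  train_size <- integer(0)
  for (cl in classes) {
    sub <- beats[beats$label == cl]
    train_size[[cl]] <- n_beats(sub)
    motifs <- c(motifs, discover_motifs(sub, r, k, normalize,
                                        D = D[[cl]]))
  }
  build_network(motifs, r = r, normalize = normalize,
                patient_id = patient_id, train_size = train_size)
}

#' Assemble a network from already-discovered motifs
#'
#' @param motifs List of `motif` objects (e.g. the concatenation of the N and
#'   V `motif_set`s, or the result of [read_motifs_json()]).
#' @param r Matching radius.
#' @param normalize Distance mode; must equal the mode used at discovery.
#' @param patient_id Identifier stored on the network.
#' @param train_size Optional named per-class training-beat counts.
#' @return A `motif_network`; see [motif_network()].
#' @export
build_network <- function(motifs, r, normalize = c("znorm", "none"),
                          patient_id = "unknown", train_size = integer(0)) {
  normalize <- match.arg(normalize)
  motifs <- unclass(motifs)
  if (!length(motifs)) stop("a network needs at least one motif node")
  motifs <- lapply(motifs, function(m) { m$rank <- as.integer(m$rank); m })
  W <- unique(vapply(motifs, function(m) length(m$center), 0L))
  if (length(W) != 1L) stop("mixed window lengths among motifs")
  if (!is.numeric(r) || r < 0) stop("r must be >= 0")
  lab <- vapply(motifs, function(m) m$label, "")
  rnk <- vapply(motifs, function(m) as.integer(m$rank), 0L)
  ord <- order(match(lab, c("N", "V")), rnk)
  structure(
    list(patient_id = patient_id,
         nodes = structure(motifs[ord], class = "motif_set", W = W),
         r = as.numeric(r), normalize = normalize, W = W,
         train_size = train_size),
    class = "motif_network")
}

#' Append a motif node to a network
#'
#' Supports the "future learning" path: a reviewed anomaly can be promoted to
#' a new node. The node is inserted after the existing nodes of its class;
#' beats previously matched by other nodes are unaffected.
#'
#' @param network A `motif_network`.
#' @param motif A `motif` object with the same window length.
#' @return The extended `motif_network`.
#' @export
add_node <- function(network, motif) {
  stopifnot(inherits(network, "motif_network"))
  if (length(motif$center) != network$W) stop("window length mismatch")
  build_network(c(unclass(network$nodes), list(motif)), r = network$r,
                normalize = network$normalize,
                patient_id = network$patient_id,
                train_size = network$train_size)
}

#' Classify heartbeats with a motif network
#'
#' Each beat is compared to every node center; the nearest node's class is
#' returned when its distance is strictly below the matching radius `r`,
#' otherwise `ANOMALY`. Exact distance ties go to the earlier node in the
#' fixed node order. A beat whose z-normalization is undefined (constant
#' vector, `normalize = "znorm"`) is flagged `ANOMALY` with reason
#' `zero_variance` rather than erroring.
#'
#' @param network A `motif_network`.
#' @param beats A [beat_set()], numeric matrix (one beat per row), or a
#'   single numeric vector of length W.
#' @return A data frame with one row per beat: `patient_id`, `window_index`,
#'   `true_label` (NA when unknown), `predicted` (N/V/ANOMALY),
#'   `best_distance` (`Inf` for zero-variance beats), `best_node_rank`,
#'   `best_node_label` and `note`.
#' @export
classify_beats <- function(network, beats) {
  stopifnot(inherits(network, "motif_network"))
  if (inherits(beats, "beat_set")) {
    X <- beats$X
    pid <- beats$patient_id
    wi <- beats$window_index
    truth <- beats$label
  } else {
    X <- if (is.matrix(beats)) beats else matrix(beats, nrow = 1L)
    pid <- rep(NA_character_, nrow(X))
    wi <- seq_len(nrow(X)) - 1L
    truth <- rep(NA_character_, nrow(X))
  }
  if (ncol(X) != network$W) stop("window length mismatch")
  n <- nrow(X)
  if (n == 0L)
    return(data.frame(patient_id = character(0), window_index = integer(0),
                      true_label = character(0), predicted = character(0),
                      best_distance = numeric(0), best_node_rank = integer(0),
                      best_node_label = character(0), note = character(0),
                      stringsAsFactors = FALSE))
  centers <- do.call(rbind, lapply(network$nodes, function(m) m$center))
  note <- rep("", n)
  ok <- rep(TRUE, n)
  if (network$normalize == "znorm") {
    s <- apply(X, 1L, stats::sd)
    ok <- s > 0
    note[!ok] <- "zero_variance"
  }
  best_d <- rep(Inf, n)
  best_j <- rep(NA_integer_, n)
  if (any(ok)) {
    Dx <- cross_distances(X[ok, , drop = FALSE], centers, network$normalize)
    best_j[ok] <- apply(Dx, 1L, which.min)   # ties -> earlier node order
    best_d[ok] <- Dx[cbind(seq_len(nrow(Dx)), best_j[ok])]
  }
  matched <- best_d < network$r
  node_lab <- vapply(network$nodes, function(m) m$label, "")
  node_rnk <- vapply(network$nodes, function(m) m$rank, 0L)
  data.frame(
    patient_id = pid, window_index = wi, true_label = truth,
    predicted = ifelse(matched, node_lab[best_j], "ANOMALY"),
    best_distance = best_d,
    best_node_rank = ifelse(matched, node_rnk[best_j], NA_integer_),
    best_node_label = ifelse(is.na(best_j), NA_character_, node_lab[best_j]),
    note = note, stringsAsFactors = FALSE)
}

#' Predict method for motif networks
#' @param object A `motif_network`.
#' @param newdata Beats to classify (see [classify_beats()]).
#' @param ... Unused.
#' @return The prediction data frame of [classify_beats()].
#' @export
predict.motif_network <- function(object, newdata, ...) {
  classify_beats(object, newdata)
}

#' @export
print.motif_network <- function(x, ...) {
  lab <- vapply(x$nodes, function(m) m$label, "")
  cat(sprintf("Artificial logical network '%s': %d node(s) (%s), r = %g (%s), W = %d\n",
              x$patient_id, length(x$nodes),
              paste(sprintf("%s=%d", names(table(lab)), table(lab)),
                    collapse = " "),
              x$r, x$normalize, x$W))
  invisible(x)
}

#' @export
summary.motif_network <- function(object, ...) {
  df <- data.frame(
    node = seq_along(object$nodes),
    label = vapply(object$nodes, function(m) m$label, ""),
    rank = vapply(object$nodes, function(m) m$rank, 0L),
    member_count = vapply(object$nodes, function(m) m$member_count, 0L))
  structure(list(patient_id = object$patient_id, r = object$r,
                 normalize = object$normalize, nodes = df,
                 train_size = object$train_size),
            class = "summary.motif_network")
}

#' @export
print.summary.motif_network <- function(x, ...) {
  cat(sprintf("Motif network '%s' (r = %g, %s)\n", x$patient_id, x$r,
              x$normalize))
  if (length(x$train_size))
    cat("  training beats:",
        paste(sprintf("%s=%d", names(x$train_size), x$train_size),
              collapse = " "), "\n")
  print(x$nodes, row.names = FALSE)
  invisible(x)
}

#' Node centers of a network
#' @param object A `motif_network`.
#' @param ... Unused.
#' @return Numeric matrix of node centers (one row per node), row names
#'   `label.rank`.
#' @export
coef.motif_network <- function(object, ...) {
  M <- do.call(rbind, lapply(object$nodes, function(m) m$center))
  rownames(M) <- vapply(object$nodes,
                        function(m) paste0(m$label, ".", m$rank), "")
  M
}

#' Plot the motif node centers of a network
#' @param x A `motif_network`.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.motif_network <- function(x, ...) {
  M <- coef(x)
  lab <- vapply(x$nodes, function(m) m$label, "")
  col <- ifelse(lab == "V", "firebrick", "steelblue")
  graphics::matplot(t(M), type = "l", lty = 1, col = col,
                    xlab = "sample within window", ylab = "amplitude",
                    main = sprintf("Motif nodes: %s", x$patient_id), ...)
  graphics::legend("topright", legend = unique(lab),
                   col = unique(col), lty = 1, bty = "n")
  invisible(x)
}

#' Serialize a network to JSON
#' @param network A `motif_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(network, path) {
  obj <- list(
    patient_id = network$patient_id, r = network$r,
    normalize = network$normalize, W = network$W,
    nodes = lapply(network$nodes, function(m)
      list(label = m$label, rank = m$rank, member_count = m$member_count,
           center = as.numeric(m$center))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a network from JSON
#' @param path File written by [write_network_json()].
#' @return A `motif_network`.
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  motifs <- lapply(obj$nodes, function(m)
    structure(list(center = as.numeric(m$center), center_index = NA_integer_,
                   label = m$label, rank = m$rank,
                   member_count = m$member_count, member_indices = NULL,
                   center_window_index = NA_integer_,
                   r = obj$r, normalize = obj$normalize),
              class = "motif"))
  build_network(motifs, r = obj$r, normalize = obj$normalize,
                patient_id = obj$patient_id)
}
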