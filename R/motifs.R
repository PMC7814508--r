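# Radius-constrained motif discovery.
#
# A motif circle is the set of training subsequences lying strictly within
# distance r of a chosen center subsequence; circles of one discovery run may
# not share subsequences, and the k retained circles' centers become the
# class prototypes ("motifs"). Circles are extracted largest-first: the
# winning circle is removed from the candidate pool and the remaining circles
# shrink accordingly, so member counts are non-increasing with rank. When
# several candidate circles tie for the largest count, a lookahead over the
# tied candidates picks the branch whose whole count sequence is
# lexicographically maximal (first among equals in time order), which keeps
# the procedure deterministic and makes the selection independent of input
# row order quirks.

#' Motif discovery parameters
#' @param r Similarity threshold (radius), `>= 0`; the study grid is
#'   0.8 to 1.6 on the z-normalized distance scale.
#' @param k Number of motifs per class, `>= 1`; study grid 2 to 10.
#' @param normalize Distance mode, see [beat_distance()].
#' @return A list of validated parameters.
#' @export
motif_params <- function(r = 1.0, k = 4L, normalize = c("znorm", "none")) {
  normalize <- match.arg(normalize)
  if (!is.numeric(r) || length(r) != 1L || r < 0) stop("r must be >= 0")
  if (!is.numeric(k) || length(k) != 1L || k < 1) stop("k must be >= 1")
  list(r = as.numeric(r), k = as.integer(k), normalize = normalize)
}

#' Discover the top-k motif circles of one beat class
#'
#' @param beats A [beat_set()] holding training beats of a single class.
#' @param r Similarity threshold; circle membership requires distance
#'   strictly less than `r`.
#' @param k Maximum number of motifs to return.
#' @param normalize Distance mode, see [beat_distance()].
#' @param D Optional precomputed pairwise distance matrix for `beats`
#'   (from [pairwise_distances()] with the same `normalize`), to avoid
#'   recomputation across parameter settings.
#' @return An object of class `motif_set`: a list of `motif` objects, each
#'   with fields `center` (the central subsequence), `center_index` (row in
#'   `beats`), `label`, `rank`, `member_count`, `member_indices` (rows in
#'   `beats`, including the center), `r` and `normalize`. Fewer than `k`
#'   motifs are returned, with a warning, when the pool is exhausted.
#' @export
discover_motifs <- function(beats, r, k, normalize = c("znorm", "none"),
                            D = NULL) {
  normalize <- match.arg(normalize)
  p <- motif_params(r, k, normalize)
  stopifnot(inherits(beats, "beat_set"))
  lab <- unique(beats$label[!is.na(beats$label)])
  if (length(lab) > 1L)
    stop("discover_motifs expects beats of a single class; got ",
         paste(lab, collapse = ","))
  if (length(lab) == 0L) lab <- NA_character_
  n <- n_beats(beats)
  if (n < 1L) stop("need at least one beat")
  if (is.null(D)) D <- pairwise_distances(beats, normalize)
  C <- D < p$r
  sel <- lex_select(C, p$k, rep(TRUE, n))
  if (length(sel$centers) < p$k)
    warning(sprintf("only %d motif circle(s) discoverable (k = %d)",
                    length(sel$centers), p$k))
  alive <- rep(TRUE, n)
  motifs <- vector("list", length(sel$centers))
  for (i in seq_along(sel$centers)) {
    ctr <- sel$centers[i]
    mem <- which(C[ctr, ] & alive)
    motifs[[i]] <- structure(
      list(center = beats$X[ctr, ], center_index = ctr, label = lab,
           rank = i, member_count = length(mem), member_indices = mem,
           center_window_index = beats$window_index[ctr],
           r = p$r, normalize = normalize),
      class = "motif")
    alive[mem] <- FALSE
  }
  structure(motifs, class = "motif_set", W = ncol(beats$X))
}

# Largest-circle-first selection with lexicographic lookahead on count ties.
# C is the boolean circle-membership matrix (C[i, j]: j within r of i);
# returns the chosen center indices and their member counts at selection
# time. Tied candidates with identical member sets are collapsed; a run of
# singleton circles (max count 1) is resolved in closed form.
lex_select <- function(C, k, alive) {
  n_alive <- sum(alive)
  if (k == 0L || n_alive == 0L)
    return(list(counts = integer(0), centers = integer(0)))
  idx <- which(alive)
  cnt <- vapply(idx, function(i) sum(C[i, alive]), 0L)
  m <- max(cnt)
  if (m == 0L) return(list(counts = integer(0), centers = integer(0)))
  if (m == 1L) {
    take <- idx[cnt == 1L][seq_len(min(k, sum(cnt == 1L)))]
    return(list(counts = rep(1L, length(take)), centers = take))
  }
  tied <- idx[cnt == m]
  mems <- lapply(tied, function(i) idx[C[i, idx]])
  keep <- !duplicated(vapply(mems, paste, "", collapse = ","))
  tied <- tied[keep]
  mems <- mems[keep]
  best <- NULL
  best_ctr <- NA_integer_
  best_rest <- NULL
  for (j in seq_along(tied)) {
    a2 <- alive
    a2[mems[[j]]] <- FALSE
    rest <- lex_select(C, k - 1L, a2)
    cand <- c(m, rest$counts)
    if (is.null(best) || lex_greater(cand, best)) {
      best <- cand; best_ctr <- tied[j]; best_rest <- rest
    }
  }
  list(counts = best, centers = c(best_ctr, best_rest$centers))
}

lex_greater <- function(a, b) {
  L <- max(length(a), length(b))
  a <- c(a, rep(-1L, L - length(a)))
  b <- c(b, rep(-1L, L - length(b)))
  i <- which(a != b)[1]
  !is.na(i) && a[i] > b[i]
}

#' @export
print.motif_set <- function(x, ...) {
  cat(sprintf("motif_set: %d motif(s), W = %d\n", length(x), attr(x, "W")))
  for (m in x)
    cat(sprintf("  rank %d [%s]: %d member(s), r = %g (%s)\n",
                m$rank, m$label, m$member_count, m$r, m$normalize))
  invisible(x)
}

#' Serialize motifs to JSON
#'
#' Writes the per-patient motif library in a stable schema loadable by
#' [read_motifs_json()] and by the network constructors.
#'
#' @param motifs A `motif_set` (or plain list of `motif` objects).
#' @param path Output file.
#' @param patient_id Patient the motifs belong to (`"pooled"` for
#'   generalized models).
#' @return `path`, invisibly.
#' @export
write_motifs_json <- function(motifs, path, patient_id = "unknown") {
  stopifnot(length(motifs) >= 1L)
  obj <- list(
    patient_id = patient_id,
    r = motifs[[1]]$r,
    k = length(motifs),
    normalize = motifs[[1]]$normalize,
    motifs = lapply(motifs, function(m)
      list(label = m$label, rank = m$rank, member_count = m$member_count,
           center = as.numeric(m$center))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read motifs from JSON
#' @param path File written by [write_motifs_json()] (or the motif block of a
#'   network file).
#' @return A list with `patient_id`, `r`, `normalize` and `motifs` (a
#'   `motif_set`).
#' @export
read_motifs_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  motifs <- lapply(obj$motifs, function(m)
    structure(list(center = as.numeric(m$center), center_index = NA_integer_,
                   label = m$label, rank = m$rank,
                   member_count = m$member_count,
                   member_indices = NULL, center_window_index = NA_integer_,
                   r = obj$r, normalize = obj$normalize),
              class = "motif"))
  W <- length(motifs[[1]]$center)
  list(patient_id = obj$patient_id, r = obj$r, normalize = obj$normalize,
       motifs = structure(motifs, class = "motif_set", W = W))
}
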