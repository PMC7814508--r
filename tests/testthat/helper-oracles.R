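# Independent oracles and small fixture builders, coded without reference to
# the package internals they check.

# Plain/z-normalized Euclidean distance by direct summation.
oracle_distance <- function(a, b, normalize = "none") {
  if (normalize == "znorm") {
    a <- (a - mean(a)) / sd(a)
    b <- (b - mean(b)) / sd(b)
  }
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  d <- sqrt(s)
  if (normalize == "znorm") d <- d / sqrt(length(a))
  d
}

# Exhaustive lexicographic-maximum motif-count oracle: enumerates center
# sequences under the disjointness rule and returns the count vector that is
# lexicographically largest.
oracle_motif_counts <- function(D, r, k, alive = rep(TRUE, nrow(D))) {
  if (k == 0 || !any(alive)) return(integer(0))
  C <- D < r
  idx <- which(alive)
  cnt <- sapply(idx, function(i) sum(C[i, alive]))
  m <- max(cnt)
  if (m < 1) return(integer(0))
  best <- NULL
  for (ctr in idx[cnt == m]) {
    a2 <- alive
    a2[which(C[ctr, ] & alive)] <- FALSE
    cand <- c(m, oracle_motif_counts(D, r, k - 1, a2))
    if (is.null(best) || oracle_lex_gt(cand, best)) best <- cand
  }
  best
}

oracle_lex_gt <- function(a, b) {
  L <- max(length(a), length(b))
  a <- c(a, rep(-1L, L - length(a)))
  b <- c(b, rep(-1L, L - length(b)))
  i <- which(a != b)[1]
  !is.na(i) && a[i] > b[i]
}

# Random one-class beat set for discovery tests.
random_beats <- function(n, W = 8, label = "N", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  beat_set(matrix(rnorm(n * W), n, W), patient_id = "px",
           window_index = seq_len(n) - 1L, label = label)
}

# Two well-separated clusters: sizes n1, n2, intra-cluster spread `eps`,
# centers 10 apart on every coordinate (raw Euclidean geometry).
cluster_beats <- function(n1, n2, W = 6, eps = 0.01, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n1 * W, 0, eps), n1, W),
             matrix(rnorm(n2 * W, 10, eps), n2, W))
  beat_set(X, "px", seq_len(n1 + n2) - 1L, "N")
}

# Small simulated cohort already segmented into labeled beats.
tiny_cohort <- function(n_patients = 2, duration_min = 2, seed = 5, ...) {
  cohort_beats(simulate_cohort(cohort_spec(n_patients = n_patients,
                                           duration_min = duration_min,
                                           seed = seed, ...)))
}
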