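# Subsequence distances.
#
# Two modes share one interface:
#   * none  — plain Euclidean distance on raw amplitudes.
#   * znorm — each subsequence is z-scored (mean 0, unit sd) before the
#     Euclidean distance, which is then divided by sqrt(W). The result is
#     invariant to amplitude offset/scale and to window length, so one
#     similarity threshold r is meaningful across records and W; unrelated
#     beats sit near sqrt(2) on this scale and identical shapes at 0.
#
# A package-level counter tallies how many pairwise subsequence distances
# have been evaluated; the evaluation module uses it to contrast the
# training cost of personalized vs pooled models without relying on
# wall-clock time.

.ops <- new.env(parent = emptyenv())
.ops$dist <- 0

#' Reset the pairwise-distance operation counter
#' @return Invisibly, the counter value before the reset.
#' @export
reset_dist_ops <- function() {
  old <- .ops$dist
  .ops$dist <- 0
  invisible(old)
}

#' Read the pairwise-distance operation counter
#'
#' Counts every subsequence-to-subsequence distance evaluated since the last
#' [reset_dist_ops()], whether during motif discovery (all training pairs) or
#' classification (test beat x network node).
#' @return Numeric count.
#' @export
dist_ops <- function() .ops$dist

.count_ops <- function(n) .ops$dist <- .ops$dist + n

znorm_rows <- function(X) {
  W <- ncol(X)
  mu <- rowMeans(X)
  X0 <- X - mu
  s <- sqrt(rowSums(X0^2) / (W - 1))
  if (any(s == 0)) stop("zero-variance subsequence")
  X0 / s
}

#' Distance between two subsequences
#'
#' @param a,b Numeric vectors of equal length W.
#' @param normalize `"znorm"` (default) or `"none"`; see the package vignette
#'   for the scale each mode puts the similarity threshold r on.
#' @return Non-negative scalar distance.
#' @examples
#' beat_distance(rep(0, 180), rep(1, 180), normalize = "none")  # sqrt(180)
#' @export
beat_distance <- function(a, b, normalize = c("znorm", "none")) {
  normalize <- match.arg(normalize)
  if (length(a) != length(b)) stop("length mismatch")
  .count_ops(1)
  if (normalize == "none") return(sqrt(sum((a - b)^2)))
  Z <- znorm_rows(rbind(a, b))
  sqrt(sum((Z[1, ] - Z[2, ])^2)) / sqrt(length(a))
}

#' All pairwise distances within a beat set
#'
#' @param beats A [beat_set()] or a numeric matrix (one subsequence per row).
#' @param normalize Distance mode, as in [beat_distance()].
#' @return A symmetric n x n matrix with zero diagonal.
#' @export
pairwise_distances <- function(beats, normalize = c("znorm", "none")) {
  normalize <- match.arg(normalize)
  X <- if (inherits(beats, "beat_set")) beats$X else as.matrix(beats)
  if (nrow(X) < 1L) stop("need at least one beat")
  .count_ops(nrow(X) * (nrow(X) - 1) / 2)
  if (normalize == "znorm") {
    D <- as.matrix(stats::dist(znorm_rows(X))) / sqrt(ncol(X))
  } else {
    D <- as.matrix(stats::dist(X))
  }
  dimnames(D) <- NULL
  D
}

# Cross distances between rows of A and rows of B (n x m), counted.
cross_distances <- function(A, B, normalize) {
  if (ncol(A) != ncol(B)) stop("length mismatch")
  .count_ops(nrow(A) * nrow(B))
  if (normalize == "znorm") {
    A <- znorm_rows(A)
    B <- znorm_rows(B)
  }
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  D <- sqrt(pmax(d2, 0))
  if (normalize == "znorm") D <- D / sqrt(ncol(A))
  D
}
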