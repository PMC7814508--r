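test_that("distances match a direct-summation oracle in both modes", {
  expect_equal(beat_distance(rep(0, 180), rep(1, 180), "none"), sqrt(180))
  set.seed(9)
  for (i in 1:10) {
    a <- rnorm(37); b <- rnorm(37)
    expect_equal(beat_distance(a, a, "none"), 0)
    expect_equal(beat_distance(a, b, "none"), oracle_distance(a, b, "none"),
                 tolerance = 1e-12)
    expect_equal(beat_distance(a, b, "znorm"), oracle_distance(a, b, "znorm"),
                 tolerance = 1e-12)
  }
  # znorm kills offset and scale
  a <- rnorm(50)
  expect_equal(beat_distance(a, 3 * a + 7, "znorm"), 0, tolerance = 1e-8)
  expect_error(beat_distance(1:5, 1:4), "length mismatch")
  expect_error(beat_distance(rep(1, 8), rnorm(8), "znorm"), "zero-variance")
})

test_that("pairwise distance matrix is symmetric and equals looped calls", {
  one <- random_beats(1, seed = 1)
  expect_equal(pairwise_distances(one, "none"), matrix(0, 1, 1))
  beats <- random_beats(10, W = 12, seed = 2)
  for (mode in c("none", "znorm")) {
    D <- pairwise_distances(beats, mode)
    expect_equal(D, t(D))
    expect_equal(diag(D), rep(0, 10))
    for (i in 1:10) for (j in 1:10)
      expect_equal(D[i, j], oracle_distance(beats$X[i, ], beats$X[j, ], mode),
                   tolerance = 1e-12)
  }
})

test_that("two separated clusters give motifs with their cluster sizes", {
  beats <- cluster_beats(4, 2)
  m <- discover_motifs(beats, r = 1, k = 2, normalize = "none")
  expect_length(m, 2)
  expect_equal(m[[1]]$member_count, 4L)
  expect_equal(m[[2]]$member_count, 2L)
  expect_setequal(m[[1]]$member_indices, 1:4)
  expect_setequal(m[[2]]$member_indices, 5:6)
  # counts agree with the exhaustive oracle
  D <- pairwise_distances(beats, "none")
  expect_identical(vapply(m, function(x) x$member_count, 0L),
                   as.integer(oracle_motif_counts(D, 1, 2)))
})

test_that("a single beat yields one singleton motif and a warning", {
  beats <- random_beats(1, seed = 3)
  expect_warning(m <- discover_motifs(beats, r = 5, k = 5, normalize = "none"),
                 "only 1 motif")
  expect_length(m, 1)
  expect_equal(m[[1]]$member_count, 1L)
  expect_equal(m[[1]]$member_indices, 1L)
})

test_that("discovery output satisfies the structural motif invariants", {
  set.seed(11)
  for (i in 1:30) {
    n <- sample(5:40, 1)
    beats <- random_beats(n, W = 6)
    D <- pairwise_distances(beats, "none")
    r <- quantile(D[upper.tri(D)], runif(1, 0.1, 0.7))
    m <- suppressWarnings(discover_motifs(beats, r, sample(1:6, 1),
                                          normalize = "none", D = D))
    counts <- vapply(m, function(x) x$member_count, 0L)
    members <- lapply(m, function(x) x$member_indices)
    # disjointness
    expect_equal(length(unlist(members)), length(unique(unlist(members))))
    # counts non-increasing with rank
    expect_true(all(diff(counts) <= 0))
    # strict radius, center among members
    for (x in m) {
      expect_true(all(D[x$center_index, x$member_indices] < x$r))
      expect_true(x$center_index %in% x$member_indices)
      expect_equal(x$member_count, length(x$member_indices))
    }
  }
})

test_that("discovery is deterministic for identical inputs", {
  beats <- random_beats(25, W = 6, seed = 21)
  m1 <- suppressWarnings(discover_motifs(beats, 2.2, 4, normalize = "none"))
  m2 <- suppressWarnings(discover_motifs(beats, 2.2, 4, normalize = "none"))
  expect_identical(m1, m2)
})

test_that("motif sets serialize to JSON and back", {
  beats <- cluster_beats(5, 3)
  m <- discover_motifs(beats, r = 1, k = 2, normalize = "none")
  f <- withr::local_tempfile(fileext = ".json")
  write_motifs_json(m, f, patient_id = "px")
  back <- read_motifs_json(f)
  expect_equal(back$patient_id, "px")
  expect_equal(back$r, 1)
  expect_equal(length(back$motifs), 2)
  expect_equal(back$motifs[[1]]$center, m[[1]]$center)
  expect_equal(back$motifs[[2]]$member_count, 3L)
})

test_that("invalid motif parameters are rejected", {
  expect_error(motif_params(r = -0.1), ">= 0")
  expect_error(motif_params(k = 0), ">= 1")
  b <- beat_set(matrix(rnorm(20), 4, 5), "p", 0:3, c("N", "N", "V", "V"))
  expect_error(discover_motifs(b, 1, 2), "single class")
})
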