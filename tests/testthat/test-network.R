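
# A hand-built network with known geometry (raw Euclidean mode): two N nodes
# at 0 and 10, two V nodes at 20 and 30 on every coordinate, W = 4.
toy_network <- function(r = 3) {
  mk <- function(v, lab, rank) structure(
    list(center = rep(v, 4), center_index = NA_integer_, label = lab,
         rank = rank, member_count = 5L - rank, member_indices = NULL,
         center_window_index = NA_integer_, r = r, normalize = "none"),
    class = "motif")
  build_network(list(mk(0, "N", 1), mk(10, "N", 2), mk(20, "V", 1),
                     mk(30, "V", 2)), r = r, normalize = "none",
                patient_id = "toy")
}

test_that("networks assemble with fixed node order and validation", {
  net <- toy_network()
  expect_length(net$nodes, 4)
  expect_equal(vapply(net$nodes, function(m) m$label, ""),
               c("N", "N", "V", "V"))
  expect_equal(vapply(net$nodes, function(m) m$rank, 0L), c(1L, 2L, 1L, 2L))
  expect_error(build_network(list(), r = 1), "at least one motif")
  # one-class network is valid (all-N patient)
  n_only <- build_network(net$nodes[1:2], r = 3, normalize = "none")
  expect_length(n_only$nodes, 2)
  expect_true(all(predict(n_only, matrix(20, 1, 4))$predicted == "ANOMALY"))
})

test_that("classification is nearest-node with the anomaly fallback", {
  net <- toy_network(r = 3)
  p <- classify_beats(net, rep(0, 4))
  expect_equal(p$predicted, "N")
  expect_equal(p$best_distance, 0)
  expect_equal(p$best_node_rank, 1L)
  # within r of the V.1 node
  p <- classify_beats(net, rep(19, 4))
  expect_equal(p$predicted, "V")
  # far from everything
  p <- classify_beats(net, rep(100, 4))
  expect_equal(p$predicted, "ANOMALY")
  expect_true(p$best_distance >= net$r)
  expect_true(is.na(p$best_node_rank))
  # exact tie between N.2 (at 10) and V.1 (at 20): earlier node order wins
  p <- classify_beats(toy_network(r = 12), rep(15, 4))
  expect_equal(p$predicted, "N")
  expect_equal(p$best_distance, 10)
  expect_error(classify_beats(net, rep(0, 5)), "length mismatch")
})

test_that("classify matches a brute-force arg-min loop on random beats", {
  net <- toy_network(r = 12)
  set.seed(7)
  X <- matrix(runif(40 * 4, -5, 40), 40, 4)
  got <- classify_beats(net, X)
  centers <- lapply(net$nodes, function(m) m$center)
  for (i in 1:40) {
    d <- vapply(centers, function(cc) oracle_distance(X[i, ], cc, "none"), 0)
    j <- which.min(d)
    expect_equal(got$best_distance[i], d[j], tolerance = 1e-12)
    want <- if (d[j] < net$r) net$nodes[[j]]$label else "ANOMALY"
    expect_equal(got$predicted[i], want)
  }
})

test_that("batch classification equals per-beat calls and keeps order", {
  net <- toy_network(r = 12)
  beats <- beat_set(matrix(runif(24, 0, 35), 6, 4), "p", c(3L, 0L, 5L, 1L, 9L, 2L),
                    c("N", "V", "N", "N", "V", "N"))
  batch <- classify_beats(net, beats)
  expect_equal(batch$window_index, beats$window_index)
  for (i in 1:6) {
    single <- classify_beats(net, beats$X[i, ])
    expect_equal(batch$predicted[i], single$predicted)
    expect_equal(batch$best_distance[i], single$best_distance)
  }
  empty <- classify_beats(net, beats[integer(0)])
  expect_equal(nrow(empty), 0L)
})

test_that("raising r only converts anomalies and never moves the arg-min", {
  net_lo <- toy_network(r = 2)
  set.seed(8)
  X <- matrix(runif(60 * 4, -5, 40), 60, 4)
  lo <- classify_beats(net_lo, X)
  for (r in c(5, 12, 40)) {
    hi <- classify_beats(build_network(net_lo$nodes, r = r,
                                       normalize = "none"), X)
    expect_equal(hi$best_distance, lo$best_distance)
    expect_equal(hi$best_node_label, lo$best_node_label)
    # labeled stays labeled with the same label
    lab <- lo$predicted != "ANOMALY"
    expect_equal(hi$predicted[lab], lo$predicted[lab])
  }
})

test_that("zero-variance test beats are flagged anomalies under znorm", {
  beats <- tiny_cohort(1)[[1]]
  sp <- stratified_prefix_split(beats, 0.2)
  net <- suppressWarnings(motif_network(sp$train, r = 1, k = 2))
  p <- classify_beats(net, rep(2.5, net$W))
  expect_equal(p$predicted, "ANOMALY")
  expect_equal(p$note, "zero_variance")
  expect_equal(p$best_distance, Inf)
})

test_that("add_node appends after its class and can adopt anomalies", {
  net <- toy_network(r = 3)
  novel <- structure(
    list(center = rep(50, 4), center_index = NA_integer_, label = "V",
         rank = 3L, member_count = 1L, member_indices = NULL,
         center_window_index = NA_integer_, r = 3, normalize = "none"),
    class = "motif")
  bigger <- add_node(net, novel)
  expect_length(bigger$nodes, 5)
  expect_equal(vapply(bigger$nodes, function(m) m$label, "")[5], "V")
  x <- rep(50, 4)
  expect_equal(classify_beats(net, x)$predicted, "ANOMALY")
  expect_equal(classify_beats(bigger, x)$predicted, "V")
  # duplicating an existing node changes no classification
  dup <- add_node(net, net$nodes[[3]])
  set.seed(10)
  X <- matrix(runif(30 * 4, -5, 40), 30, 4)
  expect_equal(classify_beats(dup, X)$predicted,
               classify_beats(net, X)$predicted)
  novel$center <- rep(50, 5)
  expect_error(add_node(net, novel), "length mismatch")
})

test_that("fitted networks expose model methods and JSON round-trip", {
  beats <- tiny_cohort(1)[[1]]
  sp <- stratified_prefix_split(beats, 0.25)
  net <- suppressWarnings(motif_network(sp$train, r = 1, k = 3))
  expect_s3_class(net, "motif_network")
  expect_output(print(net), "Artificial logical network")
  s <- summary(net)
  expect_output(print(s), "Motif network")
  cf <- coef(net)
  expect_equal(ncol(cf), net$W)
  expect_equal(nrow(cf), length(net$nodes))
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(net))
  f <- withr::local_tempfile(fileext = ".json")
  write_network_json(net, f)
  back <- read_network_json(f)
  expect_equal(length(back$nodes), length(net$nodes))
  expect_equal(predict(back, sp$test)$predicted,
               predict(net, sp$test)$predicted)
})
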