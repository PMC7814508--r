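test_that("accuracy is the exact correct/tested ratio", {
  pred <- c(rep("N", 9), "V")
  truth <- rep("N", 10)
  expect_equal(beat_accuracy(pred, truth), 0.9)
  expect_equal(beat_accuracy(truth, truth), 1.0)
  expect_error(beat_accuracy(pred, truth[1:5]), "length mismatch")
})

test_that("anomaly accounting switches between error and excluded modes", {
  pred <- c(rep("N", 8), "ANOMALY", "ANOMALY")
  truth <- rep("N", 10)
  expect_equal(beat_accuracy(pred, truth, anomaly = "error"), 0.8)
  expect_equal(beat_accuracy(pred, truth, anomaly = "exclude"), 1.0)
  expect_true(is.na(beat_accuracy(rep("ANOMALY", 3), rep("N", 3),
                                  anomaly = "exclude")))
})

test_that("a cleanly separated single-patient cell scores accuracy 1", {
  cohort <- tiny_cohort(1, duration_min = 3, seed = 4,
                        intra_patient_sd = 0, noise_sd = 0)
  cell <- suppressWarnings(run_cell(cohort, "pmm", r = 1, k = 2, t = 0.2))
  expect_equal(cell$accuracy[cell$patient_id == "AVERAGE"], 1.0)
})

test_that("run_cell is deterministic and averages the patient rows", {
  cohort <- tiny_cohort(3, seed = 6)
  a <- suppressWarnings(run_cell(cohort, "gmm2", r = 1, k = 4, t = 0.15,
                                 seed = 9))
  b <- suppressWarnings(run_cell(cohort, "gmm2", r = 1, k = 4, t = 0.15,
                                 seed = 9))
  expect_equal(a[names(a) != "elapsed"], b[names(b) != "elapsed"])
  pats <- a[a$patient_id != "AVERAGE", ]
  avg <- a[a$patient_id == "AVERAGE", ]
  expect_equal(avg$accuracy, mean(pats$accuracy))
  expect_equal(avg$n_test, sum(pats$n_test))
  expect_equal(avg$n_correct, sum(pats$n_correct))
})

test_that("the distance counter matches the closed-form operation counts", {
  cohort <- tiny_cohort(2, seed = 8)
  for (policy in c("pmm", "gmm1")) {
    reset_dist_ops()
    cell <- suppressWarnings(run_cell(cohort, policy, r = 1, k = 3, t = 0.2))
    avg <- cell[cell$patient_id == "AVERAGE", ]
    # training: sum over discovery sets of n(n-1)/2; testing: beats x nodes
    expect_equal(dist_ops(), avg$train_dist_ops + avg$test_dist_ops)
    sp <- cohort_split(cohort, policy, t = 0.2)
    sets <- if (policy == "pmm") sp$train_by_patient else list(sp$train_pooled)
    formula_ops <- sum(vapply(sets, function(b) {
      nN <- sum(b$label == "N"); nV <- sum(b$label == "V")
      nN * (nN - 1) / 2 + nV * (nV - 1) / 2
    }, 0))
    expect_equal(avg$train_dist_ops, formula_ops)
  }
})

test_that("personalized training cost scales linearly, pooled quadratically", {
  # fixed per-patient record length; growing patient count
  counts <- lapply(c(2L, 4L, 8L), function(P) {
    cohort <- tiny_cohort(P, duration_min = 2, seed = 17)
    pmm <- suppressWarnings(run_cell(cohort, "pmm", r = 1, k = 2, t = 0.2))
    gmm <- suppressWarnings(run_cell(cohort, "gmm1", r = 1, k = 2, t = 0.2))
    c(P = P,
      pmm = pmm$train_dist_ops[pmm$patient_id == "AVERAGE"],
      gmm = gmm$train_dist_ops[gmm$patient_id == "AVERAGE"])
  })
  tab <- do.call(rbind, counts)
  # doubling the cohort doubles personalized work (~2x) but quadruples pooled
  expect_equal(unname(tab[2, "pmm"] / tab[1, "pmm"]), 2, tolerance = 0.15)
  expect_equal(unname(tab[3, "pmm"] / tab[2, "pmm"]), 2, tolerance = 0.15)
  expect_equal(unname(tab[2, "gmm"] / tab[1, "gmm"]), 4, tolerance = 0.3)
  expect_equal(unname(tab[3, "gmm"] / tab[2, "gmm"]), 4, tolerance = 0.3)
})

test_that("sweeps cover the grid product and match single cells", {
  cohort <- tiny_cohort(2, seed = 12)
  grid <- sweep_grid(R_values = c(0.9, 1.2), K_values = 2L, T_values = 0.2,
                     policies = c("pmm", "gmm1"), seed = 1)
  res <- suppressWarnings(run_sweep(cohort, grid))
  avg <- sweep_averages(res)
  expect_equal(nrow(avg), 2 * 1 * 1 * 2)
  one <- suppressWarnings(run_cell(cohort, "pmm", r = 0.9, k = 2, t = 0.2,
                                   seed = 1))
  sub <- res[res$policy == "pmm" & res$r == 0.9, ]
  keep <- setdiff(names(res), "elapsed")
  expect_equal(sub[keep], one[keep], ignore_attr = TRUE)
  f <- withr::local_tempfile(fileext = ".csv")
  write_sweep_csv(res, f)
  expect_equal(nrow(utils::read.csv(f)), nrow(res))
  pdir <- withr::local_tempdir()
  plot_sweep(res, dir = pdir)
  expect_length(list.files(pdir, pattern = "accuracy_vs_.*png"), 3)
})
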