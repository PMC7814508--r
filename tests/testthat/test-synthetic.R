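test_that("a simulated patient lays one annotated beat per window", {
  spec <- cohort_spec(n_patients = 1, duration_min = 5, seed = 2)
  p <- simulate_patient(spec, 1)
  expect_equal(p$record$L, 5 * 60 * 180)
  expect_equal(nrow(p$annotations), 300)       # 300 one-second windows
  expect_true(all(p$annotations$sample_index %% 180 == 90))
  beats <- patient_beats(p)
  expect_equal(n_beats(beats), 300)
  expect_true(all(beats$label %in% c("N", "V")))
})

test_that("simulation is deterministic and patient-wise stable", {
  spec <- cohort_spec(n_patients = 3, duration_min = 1, seed = 9)
  a <- simulate_patient(spec, 2)
  b <- simulate_patient(spec, 2)
  expect_identical(a$record$signal, b$record$signal)
  expect_identical(a$annotations, b$annotations)
  # patient 2 is unchanged by simulating a bigger cohort with the same seed
  spec8 <- cohort_spec(n_patients = 8, duration_min = 1, seed = 9)
  expect_identical(simulate_patient(spec8, 2)$record$signal, a$record$signal)
})

test_that("the zero-noise limit reproduces each beat exactly", {
  spec <- cohort_spec(n_patients = 1, duration_min = 2, seed = 3,
                      intra_patient_sd = 0, noise_sd = 0)
  beats <- patient_beats(simulate_patient(spec, 1))
  XN <- beats$X[beats$label == "N", ]
  expect_true(all(abs(sweep(XN, 2, XN[1, ])) == 0))
  tmpl <- beat_template("N", patient_morphology(spec, 1))
  expect_equal(XN[1, ], tmpl)
})

test_that("class and patient morphologies are separated as designed", {
  spec <- cohort_spec(seed = 21)
  m1 <- patient_morphology(spec, 1)
  m2 <- patient_morphology(spec, 2)
  n1 <- beat_template("N", m1); v1 <- beat_template("V", m1)
  n2 <- beat_template("N", m2)
  beats <- patient_beats(simulate_patient(spec, 1))
  jitteredN <- beats$X[beats$label == "N", ][1:20, ]
  d_to_own <- apply(jitteredN, 1, beat_distance, b = n1)
  # own class template is closer than the V template of the same patient
  expect_true(beat_distance(n1, v1) > max(d_to_own))
  # ... and closer than the other patient's N template
  expect_true(beat_distance(n1, n2) > max(d_to_own))
})

test_that("the ventricular fraction matches its binomial expectation", {
  spec <- cohort_spec(n_patients = 4, duration_min = 3, seed = 31)
  beats <- cohort_beats(simulate_cohort(spec))
  labs <- unlist(lapply(beats, function(b) b$label))
  n <- length(labs)
  phat <- mean(labs == "V")
  expect_lt(abs(phat - spec$v_fraction),
            3 * sqrt(spec$v_fraction * (1 - spec$v_fraction) / n))
})

test_that("v_fraction 0 gives an all-N record", {
  spec <- cohort_spec(n_patients = 1, duration_min = 1, v_fraction = 0, seed = 4)
  expect_equal(unique(simulate_patient(spec, 1)$annotations$label), "N")
})

test_that("excluded-label beats and misaligned fiducials exercise discards", {
  spec <- cohort_spec(n_patients = 1, duration_min = 2, other_fraction = 0.2,
                      seed = 6)
  p <- simulate_patient(spec, 1)
  expect_true(any(p$annotations$label %in% c("A", "F", "S")))
  out <- label_windows(segment_record(p$record, W = 180), p$annotations)
  expect_true(any(out$discards$discard_reason == "excluded_label"))

  spec_j <- cohort_spec(n_patients = 1, duration_min = 2,
                        misalign_jitter = 120L, seed = 6)
  pj <- simulate_patient(spec_j, 1)
  outj <- label_windows(segment_record(pj$record, W = 180), pj$annotations)
  expect_true(all(c("none", "multiple") %in% outj$discards$discard_reason))
})

test_that("a cohort writes to disk and reads back identically", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(n_patients = 2, duration_min = 1, seed = 8)
  sim <- simulate_cohort(spec, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  expect_length(list.files(dir, pattern = "^p[0-9]+\\.csv$"), 2)
  back <- read_cohort(dir)
  expect_equal(names(back), names(sim))
  expect_equal(back$p01$record$signal, sim$p01$record$signal)
  expect_identical(back$p01$annotations, sim$p01$annotations)
  expect_equal(back$p02$record$fs, 180)
})

test_that("shrinking morphology divergence shrinks the personalized edge", {
  grid <- sweep_grid(R_values = 1.0, K_values = 2L, T_values = 0.2,
                     policies = c("pmm", "gmm1"), seed = 1)
  gap <- vapply(c(0.4, 0.02), function(sd_) {
    cohort <- tiny_cohort(4, duration_min = 2, seed = 19,
                          inter_patient_sd = sd_)
    avg <- sweep_averages(suppressWarnings(run_sweep(cohort, grid)))
    avg$accuracy[avg$policy == "pmm"] - avg$accuracy[avg$policy == "gmm1"]
  }, 0)
  expect_gte(gap[1], gap[2])
  expect_lt(abs(gap[2]), 0.02)  # near-identical patients: gap ~ 0
})
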