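# Training samplers for the three monitoring policies.
#
#   pmm  — personalized: per patient, the first t fraction of N beats plus
#          the first t fraction of V beats train that patient's own network.
#   gmm1 — generalized, prefix-sampled: the first t fraction of each
#          patient's beats (classes mixed) are pooled into one training set.
#   gmm2 — generalized, class-stratified random: t fractions of the cohort's
#          pooled N beats and pooled V beats are drawn without replacement
#          under a recorded seed.
#
# In every policy a patient's test set is exactly its beats not drawn into
# training, so there is no train/test leakage; gmm1 and pmm share identical
# per-patient test sets (both are prefix rules), which makes their accuracy
# difference attributable to training composition alone.

ceil_share <- function(t, n) if (n == 0L) 0L else max(1L, as.integer(ceiling(t * n)))

check_cohort <- function(cohort) {
  if (!length(cohort) || !all(vapply(cohort, inherits, TRUE, "beat_set")))
    stop("cohort must be a non-empty named list of beat_set objects")
  if (is.null(names(cohort)) || any(!nzchar(names(cohort))))
    stop("cohort list must be named by patient_id")
  invisible(cohort)
}

new_cohort_split <- function(policy, train_by_patient, train_pooled,
                             test_by_patient, t, seed = NA_integer_) {
  structure(list(policy = policy, train_by_patient = train_by_patient,
                 train_pooled = train_pooled,
                 test_by_patient = test_by_patient,
                 t = t, seed = seed),
            class = "cohort_split")
}

#' @export
print.cohort_split <- function(x, ...) {
  ntr <- if (!is.null(x$train_pooled)) n_beats(x$train_pooled) else
    sum(vapply(x$train_by_patient, n_beats, 0L))
  cat(sprintf("cohort_split [%s]: t = %g, %d training beat(s), %d patient test set(s)\n",
              x$policy, x$t, ntr, length(x$test_by_patient)))
  invisible(x)
}

#' Personalized (per-patient) train/test split
#'
#' Applies [stratified_prefix_split()] to each patient independently; one
#' model is later fitted per patient, never seeing any other patient's beats.
#'
#' @param cohort Named list of per-patient labeled [beat_set()]s.
#' @param t Training ratio in (0, 1).
#' @return A `cohort_split` with `train_by_patient` and `test_by_patient`.
#' @export
pmm_split <- function(cohort, t) {
  check_cohort(cohort)
  sp <- lapply(cohort, stratified_prefix_split, t = t)
  new_cohort_split("pmm",
                   train_by_patient = lapply(sp, `[[`, "train"),
                   train_pooled = NULL,
                   test_by_patient = lapply(sp, `[[`, "test"),
                   t = t)
}

#' Generalized prefix-pooled train/test split
#'
#' Per patient, the first `ceiling(t * n)` beats in time order (classes
#' mixed) join the pooled training set; the remainder is that patient's test
#' set.
#'
#' @inheritParams pmm_split
#' @return A `cohort_split` with `train_pooled` and `test_by_patient`.
#' @export
gmm1_split <- function(cohort, t) {
  check_cohort(cohort)
  if (t <= 0 || t >= 1) stop("training ratio t must lie in (0, 1)")
  train <- list(); test <- list()
  for (pid in names(cohort)) {
    b <- cohort[[pid]]
    ntr <- ceil_share(t, n_beats(b))
    train[[pid]] <- b[seq_len(ntr)]
    test[[pid]] <- b[setdiff(seq_len(n_beats(b)), seq_len(ntr))]
  }
  new_cohort_split("gmm1", train_by_patient = NULL,
                   train_pooled = bind_beats(train),
                   test_by_patient = test, t = t)
}

#' Generalized class-stratified random train/test split
#'
#' Pools every patient's N beats and V beats, draws `ceiling(t * n_class)` of
#' each class uniformly without replacement under `seed`, and tests each
#' patient on its beats not drawn. A class absent from the whole cohort
#' contributes nothing (with a warning).
#'
#' @inheritParams pmm_split
#' @param seed Integer seed recorded in the split (the draw is seedless in
#'   principle; fixing one makes runs reproducible).
#' @return A `cohort_split` with `train_pooled`, `test_by_patient` and `seed`.
#' @export
gmm2_split <- function(cohort, t, seed) {
  check_cohort(cohort)
  if (t <= 0 || t >= 1) stop("training ratio t must lie in (0, 1)")
  if (missing(seed) || is.null(seed)) stop("gmm2_split requires a seed")
  pooled <- bind_beats(cohort)
  pooled_pid <- rep(names(cohort), vapply(cohort, n_beats, 0L))
  take <- logical(n_beats(pooled))
  with_seed(seed, {
    for (cl in c("N", "V")) {
      idx <- which(pooled$label == cl)
      if (!length(idx)) {
        warning("class ", cl, " absent from the entire cohort")
        next
      }
      take[sample(idx, ceil_share(t, length(idx)))] <- TRUE
    }
  })
  test <- lapply(names(cohort), function(pid)
    pooled[!take & pooled_pid == pid])
  names(test) <- names(cohort)
  new_cohort_split("gmm2", train_by_patient = NULL,
                   train_pooled = pooled[take],
                   test_by_patient = test, t = t, seed = as.integer(seed))
}

#' Split a cohort under a named policy
#' @inheritParams pmm_split
#' @param policy One of `"pmm"`, `"gmm1"`, `"gmm2"`.
#' @param seed Seed for `"gmm2"` (ignored otherwise).
#' @return A `cohort_split`.
#' @export
cohort_split <- function(cohort, policy = c("pmm", "gmm1", "gmm2"), t,
                         seed = NULL) {
  policy <- match.arg(policy)
  switch(policy,
         pmm = pmm_split(cohort, t),
         gmm1 = gmm1_split(cohort, t),
         gmm2 = gmm2_split(cohort, t, seed))
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
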