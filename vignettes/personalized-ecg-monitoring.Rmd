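---
title: "Personalized ECG monitoring by motif discovery: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized ECG monitoring by motif discovery: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgmotif)
```

## The problem and the model

Single-lead ECG monitoring produces long beat streams that must be labeled
in near-real time: normal sinus beats (N), ventricular ectopic beats (V),
and everything the model cannot confidently match. Heartbeat morphology is
strongly patient-specific — one person's normal beat can resemble another
person's pathology — which is why pooled ("generalized") classifiers
trained across patients lose accuracy exactly where it matters.
`ecgmotif` implements a *personalized monitoring model* (PMM): a tiny,
transparent classifier trained on the opening stretch of each patient's own
recording.

The procedure has three stages.

**1. Sampling.** A recording of $L$ samples at $f_s = 180$ Hz is truncated
to its training prefix of $S = \lfloor L\,t \rfloor$ samples, where
$t \in (0,1)$ is the training ratio, and cut into
$M = \lfloor S / W \rfloor$ consecutive non-overlapping windows of
$W = 180$ samples (one beat per second-long window). Each window holding
exactly one annotated fiducial whose label is N or V becomes a training
heartbeat; windows with no fiducial, several fiducials, or an excluded
label (A, F, S) are treated as noisy and dropped, itemized in a discard
report.

**2. Motif discovery.** Within one class, the *motif circle* of a candidate
center $c$ under similarity threshold $r$ is
$\{x : d(x, c) < r\}$ (strict inequality). Circles are extracted
largest-first: the most populous circle becomes the rank-1 motif, its
members leave the pool, and the rule repeats until $k$ motifs exist or the
pool is exhausted, so member counts are non-increasing with rank and member
sets are pairwise disjoint. Two centers may lie closer than $2r$ provided
their member sets are disjoint. The circle *centers* — actual recorded
beats, not averages — are the class prototypes.

**3. The artificial logical network.** The $k$ N-motifs and $k$ V-motifs
become ordered evaluation nodes (N before V, ranks ascending). A test beat
is compared with every node; if the nearest node is strictly within $r$ its
class is the prediction, otherwise the beat is flagged `ANOMALY` for review
or, via `add_node()`, future learning. Exact distance ties fall to the
earlier node in the fixed order, so classification is deterministic.

Two pooled baselines reuse stages 2–3 unchanged and differ only in
training-set construction: **GMM1** pools the first $t$ fraction of every
patient's beats (classes mixed, per the prefix rule); **GMM2** pools all
beats cohort-wide and draws $t$ fractions of the N class and of the V class
uniformly without replacement under a recorded seed. The personalized
policy takes the first $t$ fraction of N beats plus the first $t$ fraction
of V beats of the one patient being modeled.

## Parameters that matter

| Parameter | Meaning | Default | Grid |
|---|---|---|---|
| `r` | similarity threshold = motif radius = matching radius (z-normalized distance units) | 1.0 | 0.8–1.6 by 0.2 |
| `k` | motifs per class | 4 | 2–10 by 2 |
| `t` | training ratio (fraction of the record/class prefix) | 0.2 | 0.10–0.25 by 0.05 |
| `W` | window length in samples | 180 (= `fs`) | fixed |
| `normalize` | `"znorm"` or `"none"` | `"znorm"` | fixed |

The single most consequential choice is the distance scale. The method's
$r$ grid (0.8–1.6) is unitless, but raw Euclidean distance between
$W$-sample windows depends on amplifier gain, offset, and $W$. The default
`"znorm"` mode therefore z-scores each window (mean 0, unit sd, sample sd
with $n-1$) and divides the Euclidean distance by $\sqrt W$. On this scale
identical shapes sit at 0, uncorrelated windows near $\sqrt 2 \approx
1.41$, and perfectly anti-correlated shapes at 2 — so the 0.8–1.6 grid
spans "clearly same shape" to "essentially unrelated" regardless of units.
`normalize = "none"` is retained for experiments in raw amplitude units;
discovery and classification must use the same mode.

## Numerical and algorithmic choices

* **Integer handling.** Fractional samples and windows are floored
  ($S = \lfloor Lt \rfloor$, $M = \lfloor S/W \rfloor$); a partial trailing
  window is discarded. Per-class training counts use
  $\lceil t\,n_c \rceil$, so any class present in a record contributes at
  least one training beat and remains representable.
* **Tie-breaking in discovery.** When several candidate circles tie for
  the largest member count, a local tie-break (e.g. earliest window) can
  pick a center whose removal strands beats that a tied alternative would
  have kept together, producing a count sequence that is not the
  lexicographic maximum the largest-first rule aims for. Discovery
  therefore looks ahead across count-tied candidates (deduplicating
  candidates with identical member sets, and resolving runs of singleton
  circles in closed form) and keeps the branch whose full count sequence
  is lexicographically largest; among equivalent branches the earliest
  window wins. The procedure is deterministic, independent of row-order
  quirks, and on small instances provably equal to exhaustive enumeration
  — the test suite checks it against an independently coded oracle on
  hundreds of random instances.
* **Strict radius.** Membership and matching both use $d < r$; with
  $r = 0$ no circle can exist and every beat is an anomaly.
* **Degenerate inputs.** A constant (zero-variance) window cannot be
  z-scored; at discovery time it is an error (such windows should have
  been discarded as noise), at classification time the beat is flagged
  `ANOMALY` with reason `zero_variance` rather than crashing a monitoring
  stream. A pool that yields fewer than `k` circles returns what exists
  with a warning. A patient with no beats of one class gets a one-class
  network whose foreign beats surface as anomalies.
* **Anomaly accounting.** Whether an `ANOMALY` on a labeled test beat
  counts as an error or leaves the denominator is a reporting decision the
  accuracy definition does not settle; the conservative `anomaly = "error"`
  is the default and `"exclude"` is available, with both interpretable
  from the reported `n_anomaly`.
* **Cohort average.** The `AVERAGE` row is the unweighted mean of
  per-patient accuracies (so every patient counts equally); pooled-beat
  accuracy is emitted alongside as `pooled_accuracy`.
* **Cost accounting.** Wall-clock time is recorded but never asserted:
  it is hardware-dependent. The package counts subsequence-distance
  evaluations instead. At fixed record length the personalized total grows
  linearly with the number of patients $P$ (sum of per-patient
  $O(M_p^2)$ terms) while pooled training grows as
  $O\left(\left(\sum_p M_p\right)^2\right)$, so the pooled/personalized
  ratio grows linearly in $P$ — the package's form of the training-cost
  contrast.

## What the synthetic cohort emulates — and what it does not

No public corpus ships with the package, so `cohort_spec()` /
`simulate_cohort()` generate a fully seeded stand-in designed to reproduce
the *statistical situation* the personalized model assumes:

* beats highly self-similar within a patient (default beat-to-beat
  log-amplitude jitter 2%, timing jitter 0.1% of the window, additive
  noise 2% of the R amplitude — within-patient same-class distances stay
  well below the smallest grid radius 0.8);
* morphologically divergent across patients (default per-patient
  log-amplitude divergence 0.4 per PQRST deflection, plus timing/width
  perturbations and a heart-rate stretch drawn from 55–75 bpm — different
  patients' normal beats are usually farther apart than the largest grid
  radius);
* V beats wide, inverted and P-wave-free, far from every N beat of the
  same patient (~1.6 on the z-normalized scale).

Beats are window-aligned by construction so fixed-grid segmentation
recovers exactly one fiducial per window; `misalign_jitter` shifts
fiducials off-grid (sorting and deduplicating collisions) purely to
exercise the discard rules, and `other_fraction` sprinkles A/F/S labels to
exercise noisy-beat removal. The default desk-scale cohort is 8 patients ×
5 minutes at 180 Hz (300 beats each); `n_patients = 32, duration_min = 30`
reproduces the full-scale shape.

What passing tests on this cohort show is that the pipeline is correct and
that the personalized-vs-pooled contrast follows from morphology
heterogeneity; what they do not show is performance on real ECG. Real
recordings have baseline wander, electrode artifacts, rhythm-driven beat
spacing (beats are *not* window-aligned), class imbalance far more extreme
than 10%, and pathologies whose morphology overlaps N. The generator's
separability is an explicit dial: as `inter_patient_sd` shrinks toward 0
the personalized advantage provably shrinks toward 0, and the test suite
checks that too.

```{r separability, eval = FALSE}
cohort <- cohort_beats(simulate_cohort(cohort_spec(seed = 1)))
res <- run_sweep(cohort, sweep_grid())
subset(sweep_averages(res), r == 1 & k == 4 & t == 0.2)
```

## Design decisions that were genuinely open

* **Fixed-grid windows, not beat-aligned windows.** Segmentation cuts
  every $W$ samples from sample 0 rather than centering on detected R
  peaks. This is the simpler contract, needs no beat detector, and the
  one-fiducial-per-window rule absorbs the alignment consequences;
  beat-aligned windowing could be added behind `segment_record()` without
  touching discovery or classification.
* **One radius for two jobs.** The matching criterion of the anomaly path
  reuses the discovery radius $r$ instead of introducing a second
  threshold: one coherent similarity scale, one fewer parameter, and the
  monotonicity guarantee that raising $r$ can only convert anomalies into
  labels, never the reverse.
* **Top-$k$ by population.** "First $k$ motif circles" is read as the $k$
  most populous circles (largest-first extraction), matching the intended
  rank semantics (rank 1 has the most members).
* **GMM1's prefix is class-mixed while the personalized prefix is
  per-class.** The asymmetry is deliberate: the pooled prefix sampler
  takes each patient's first beats wholesale, while the personalized
  sampler guarantees both classes are represented for the one patient it
  serves.
* **GMM2's test sets exclude its randomly drawn training beats**, so no
  policy ever tests on a beat it trained on; GMM2's test sets consequently
  differ from the prefix policies' and are reported separately.
* **Seeding.** Every stochastic step (the GMM2 draw, the generator) flows
  from one integer seed; per-patient generator seeds are derived so that
  patient $p$ is bit-identical whether simulated alone or within any
  larger cohort. The RNG state of the calling session is restored
  afterwards.

## Problem sizes used by the tests

The test suite and the acceptance script run entirely on generated data:
the default 8 × 5-minute cohort (2,400 beats) for the full 5 × 5 × 4-cell
grid over three policies, a zero-noise variant of the same cohort for the
exactness check, cohorts of 2–16 patients at 2 minutes for the cost-scaling
check, and instances of at most 12 subsequences for the exhaustive
discovery oracle. These sizes keep every property observable — dominance
per grid cell, exactness, linear-vs-quadratic cost growth — at desk scale.

## Known limitations

* No R-peak detection: unannotated records cannot be labeled, and records
  sampled at other rates should be resampled upstream (`W` tracks `fs`,
  but the 180-sample window constant is assumed throughout the defaults).
* Single-lead only; no multi-channel fusion.
* Detection of A, F and S pathologies is out of scope: those labels are
  recognized only to be discarded as noise, matching the two-class
  benchmark design.
* Motif discovery is exact ($O(M^2)$ distances); no approximate index
  (matrix profile, random projection) is provided, which is the right
  trade-off at personalized training sizes but not for pooled corpora.
* The anomaly path stores no history; `add_node()` is the hook for
  human-in-the-loop extension, not an online learner.
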