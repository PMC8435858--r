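---
title: "Dynamic functional-connectivity states: model, conventions and validation"
author: "dfcStates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic functional-connectivity states: model, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfcStates)
```

## The problem

Resting-state fMRI is commonly reduced by spatial ICA to a set of C
independent components (ICs), each with a time course of T samples (one per
repetition time, TR). Static functional connectivity summarizes each pair of
components by a single correlation; dynamic functional connectivity (dFC)
instead tracks how those correlations evolve, by estimating them inside a
window that slides along the time axis. Recurring connectivity patterns
("states") can then be identified by clustering the windowed correlation
vectors of all subjects, and the time each subject spends in each state
becomes a compact, interpretable feature for comparing groups — here, a
clinical group ("case") against controls ("normal").

`dfcStates` implements that pipeline end to end: sliding-window correlation,
k-means state discovery with elbow-based model selection, per-subject
state-occupancy counts, decision-tree group classification under
cross-validation, and state-, window- and connection-level group statistics
with Benjamini–Hochberg (BH) false-discovery-rate control. A
Markov-switching simulator generates cohorts with known ground truth so
every stage can be validated.

## Sliding-window correlation

Each subject's T × C time-course matrix is converted to a W × E feature
matrix: window w spans TRs [start, start + width) (0-based, half-open),
starts advance in strides of `step`, the Pearson correlation matrix of each
windowed slice is computed, and its strictly upper triangle is vectorized in
row-major order into E = C(C−1)/2 connection features
(`vectorizeUpper()` / `devectorizeUpper()` are exact inverses).

**Window-count convention.** We define W = floor((T − width)/step), with
starts 0, step, …, (W−1)·step. The fencepost-inclusive count of full windows
would be W + 1; the adopted convention drops the last start, keeps every
window full, and makes the default geometry (T = 215, width = 25 TR,
step = 2 TR) produce exactly 95 windows of 946 features for a 44-component
analysis. Windows are rectangular (untapered); the defaults sit inside the
30–60 s range generally considered a reasonable compromise between
sensitivity to state changes and correlation-estimation noise at TR = 2 s.
No Fisher z-transform is applied before clustering, and features are not
standardized: correlations are already on a common [−1, 1] scale, and
z-transforming would only stretch the tails.

## State discovery

All subjects' windows are pooled and clustered with k-means (Lloyd
iterations via `stats::kmeans`, k-means++ seeding, best of `nInit = 20`
restarts by within-cluster SSE, `maxIter = 300`, fixed seed). Euclidean
distance on the correlation vectors is used — the standard choice for dFC
state analysis. Final labels are recomputed as the argmin-distance centroid
so the model is always post-hoc consistent; all ties (seeding, assignment)
resolve to the lowest index, and an empty cluster is re-seeded at the point
farthest from its centroid.

**Elbow rule.** "Use the elbow criterion" is not by itself an algorithm, so
the package makes it explicit: fit k over a candidate range, normalize both
axes of the SSE-versus-k curve to [0, 1], and select the k whose point lies
farthest from the chord joining the endpoints (the kneedle construction).
This is deterministic, parameter-free, and coincides with the visual elbow
on convex curves. Two guards: a curve whose total SSE drop is below 1e-8
relative (a structureless point mass) falls back to the smallest candidate
k, and a non-monotone curve (possible in principle with finitely many
restarts) triggers a warning but is still scored. SSE monotonicity in k is
asserted in the test suite at 1e-8 relative tolerance.

Each subject's occupancy vector — the number of its windows assigned to
each state, summing to W — is the 1 × k feature passed to classification.

## Classification

A CART decision tree (Gini impurity, `rpart`, minimum leaf size 1, no
depth cap or pruning by default — occupancy features are low-dimensional,
and the tree stays interpretable) is evaluated under stratified fivefold
cross-validation. Stratification guarantees both classes in every fold;
folds are drawn once under the global seed. The positive class is the
*normal* group: TP is a correctly identified control. Sensitivity,
specificity, precision, accuracy and F1 follow their standard proportions
(accuracy = (TP+TN)/(TP+TN+FP+FN)); both fold-averaged and pooled-count
versions are reported, since with equal fold sizes and a deterministic tree
they agree and otherwise both are informative. ROC curves sweep a threshold
across the held-out positive-class probabilities and AUC is the trapezoidal
integral, equal to the Mann–Whitney concordance probability.

**A deliberate caveat.** In the default pipeline the states are learned on
*all* subjects' windows before cross-validation, so occupancy features are
not leakage-free — test subjects' windows shaped the centroids. This
mirrors common practice in dFC state analyses and is kept as the default;
`runPipeline(cleanCV = TRUE)` additionally runs a leakage-free variant that
re-learns states on each training fold and assigns held-out windows to the
nearest learned centroid.

## Group statistics

* **Per-state occupancy tests** — a two-sample t-test per state on subjects'
  window counts (pooled-variance by default, matching the classical
  two-sample t-test; Welch by flag). The state with the smallest p-value is
  flagged as the discriminative state.
* **Window-difference selection** — for the discriminative state, count per
  window index how many subjects of each group occupy it, take the absolute
  group difference d_w, and select windows with d_w strictly above the mean
  of d over all windows. The absolute difference is used because the
  selection is about *where* the groups diverge, not in which direction.
* **Connection tests** — each subject's connection values are averaged over
  the selected windows (keeping one observation per subject, so the t-test's
  independence assumption holds; pooling windows would pseudo-replicate),
  then each of the E connections is tested between groups and BH-adjusted
  across all E. A connection is significant when its *adjusted* p-value
  falls below the threshold (default 1e-4): applying the threshold to raw
  p-values after computing an FDR correction would make the correction
  inert, but a raw-p mode is available. Summaries count significant
  connections per network and per network pair, split by which group's mean
  connectivity is higher, and a Pajek export of the significant-connection
  graph is provided.
* **Spatial-domain tests** — per network, a two-sample t-test on a scalar
  subject-level spatial summary. Which summary the original analyses used
  is ambiguous in this literature; the adopted convention (documented, and
  replaceable by any subjects × networks matrix) is the mean map intensity
  within the network mask.

Motion QC consumes six-column realignment series (3 translations in mm, 3
rotations in degrees) and excludes a subject when any absolute translation
exceeds 2 mm or any rotation exceeds 2° — strict inequalities, so a subject
exactly at a threshold is kept.

## Network assignment

IC spatial maps are allocated to the resting-state network whose binary
template mask they correlate with most strongly. Maps are z-scored and the
correlation is computed over the union of all mask voxels: including empty
background voxels would inflate every coefficient with structural zeros.
Whole-volume support is available by flag; ties break by atlas order. Maps
are used unthresholded. The conventional atlas has 11 networks (ASN, AN,
DDMN, HVN, LN, PSN, PN, RECN, SN, VDMN, VN), but any named mask set on a
common grid is accepted; real templates are user-supplied, and the test
suite builds toy atlases with known ground truth.

## The synthetic cohort generator

The generator is the package's source of ground truth, not a model of raw
BOLD physics. Each subject's hidden state sequence follows a first-order
Markov chain over K states (initial state from the chain's stationary
distribution); given the state, the C-vector at each TR is multivariate
Gaussian with that state's covariance, plus isotropic observation noise.
State covariances are convex combinations of a shared and a state-specific
random SPD matrix, normalized to correlation form; the `separation`
parameter sets the state-specific weight, so patterns coincide as it
approaches 0 and decorrelate as it grows.

Default conditions (chosen once, a priori): 40 subjects per group, C = 44,
T = 215, K = 5, noise SD 0.2 (mild attenuation of the latent correlations),
stay probability 0.98 — a mean dwell of ~50 TR, about twice the window
width, so that windowed correlations predominantly reflect single regimes,
consistent with the slow state switching described in the resting-state dFC
literature — and a planted group difference: the case group's stay
probability in the last state is lowered to 0.90, shrinking its occupancy
of that state (stationary occupancy ≈ 0.05 versus 0.20 for controls). With
long dwells a subject's T = 215 samples contain only a handful of state
visits, so occupancy counts are highly variable between subjects; group
effects are therefore realistic rather than trivially separable.

What the generator does *not* emulate: hemodynamic autocorrelation,
convolution or scanner artifacts (both would blur state boundaries without
changing what the tests verify), ICA estimation error, and spatial maps.
Passing recovery tests therefore demonstrate the pipeline's correctness and
its behavior under known switching dynamics — not performance on real fMRI.

## Validation and problem sizes

The test suite validates every stage against independent oracles:
brute-force per-window Pearson correlation (1e-10), exhaustive-partition
k-means optima at n = 6, the closed-form pooled t statistic, a brute-force
BH step-up oracle, Mann–Whitney pair counting for AUC (cross-checked
against pROC), and direct recounts for occupancy and network tallies.
Stochastic checks run under fixed seeds: per-state type-I error over 200
simulated null cohorts (within 3 binomial SEs of 5%), label-shuffled
classification at chance over 100 replicates, dwell fractions against the
chains' stationary laws, and state recovery — on a 20-subject,
10-component, 215-TR cohort with separation 8, the elbow rule over
k ∈ [2, 9] returns k = 5 and the adjusted Rand index between window labels
and the generating state at each window's center exceeds 0.8. These sizes
keep the whole suite fast while leaving the statistical conclusions stable;
`scripts/acceptance.R` re-runs the state-recovery computation from scratch.

## Known limitations

* The window-count convention is a documented choice; other toolchains
  include the final fencepost window.
* Occupancy features ignore within-state dwell structure (number and length
  of visits), which carries additional group information.
* The default pipeline's clustering-before-CV leakage (above) means its
  cross-validated metrics are optimistic; use `cleanCV = TRUE` for honest
  generalization estimates.
* The elbow rule, like any knee heuristic, is only well defined on convex
  decreasing SSE curves; inspect `sseCurve()` when in doubt.
* Group inference assumes two groups; multi-group designs are out of scope.
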