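---
title: "Screening acute leukemia from ALOT cytometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening acute leukemia from ALOT cytometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The EuroFlow acute leukemia orientation tube (ALOT) is an eight-antibody
screening panel (CyCD3, CD45, CyMPO, CyCD79a, CD34, CD19, CD7, SmCD3) used
to triage suspected acute leukemia. A cytometer records up to 250,000
events per sample, each event a cell described by 12 channels: the eight
fluorescence intensities plus FSC-A/FSC-H/SSC-A/SSC-H scatter. Manual
gating of these files takes minutes per sample and is reader-dependent.
`everflow` implements an automated three-phase workflow:

* **Phase I** — diagnose the patient directly from the raw event cloud.
* **Phase II** — classify every single event into one of 16 cell types
  (nine physiological populations, debris, and six pathological blast or
  lymphoproliferative populations) with the EverFlow 1-D CNN.
* **Phase III** — diagnose the patient from the AI-derived cellular
  composition produced by Phase II, optionally augmented with per-class
  channel summaries.

Patients fall into five groups: Normal, AML, B-ALL, Complex (possible
myelodysplasia, to be followed up with a dedicated AML/MDS tube), and
Other (T-ALL, lymphoma, myeloma, ...).

## Models

### EverFlow (Phase II)

Each event is treated as a length-12, single-channel 1-D signal in fixed
panel order. The network is a stack of *Flow Blocks* — 1-D convolution →
batch normalization → ReLU → optional max-pooling — followed by adaptive
average pooling and a 16-way linear softmax head. The default
configuration has exactly three convolutional layers, three
batch-normalization layers and two max-pooling stages (widths 32/64/128,
kernel 3), trains with the Ranger optimizer (RAdam wrapped in Lookahead,
k = 6, alpha = 0.5) at learning rate 5e-3, and caps training at 75 epochs.
An Adam fallback at the same rate sits behind a config flag.

The signal axis is a modeling choice: a 12-sample "signal" has no physical
ordering, but convolution over the fixed panel order gives the small
parameter budget and local mixing that make this architecture resistant to
overfitting on per-event data, where patient-level networks overfit badly.
The channel order is therefore part of the model contract and is frozen in
the configuration.

Class imbalance in gated training data is extreme (neutrophils outnumber
rare CD34+ precursors by roughly 100:1), so inverse-frequency class
weights are the default. Ties at the argmax resolve to the lowest class
index. Early stopping watches a stratified 10% validation split with a
patience of 10 epochs; the weights reported are those of the best
validation epoch.

### Patient-level models (Phases I and III)

No fixed-size representation of a variable-length event cloud is given a
priori, so Phase I renders each sample into a stack of six 64x64 2-D
density histograms over the canonical ALOT gating views (CD45xSSC-A,
CD34xCD45, CD19xCyCD79a, CyCD3xSmCD3, CyMPOxSSC-A, CD7xSmCD3), computed on
fixed per-channel ranges so images are comparable across patients, then
`log1p`-scaled to unit maximum. This preserves what a human gater sees in
dot plots, is permutation-invariant, and feeds a residual CNN. The
desk-scale default is `resnet_tiny` (a ~10-layer residual network); the
`resnet50` variant builds the canonical 50-weight-layer bottleneck stack
for full-fidelity runs.

Phase III consumes the 16-vector of class fractions, optionally
concatenated with a 16x12 matrix of per-class medians of transformed
intensities (192 extra features). Medians were chosen over means for
robustness in heavy-tailed fluorescence data; classes absent from a sample
get a zero row plus an explicit presence mask rather than imputed values,
so the model can learn absence. Input is 1-D, so the residual family is
realized as a residual dense stack (two blocks in the tiny variant).
Whether raw per-event data should re-enter alongside the composition is
genuinely open; the package exposes both the summary representation and
the density-image path rather than guessing a single answer.

### Transform

Fluorescence channels are transformed `asinh(x/150)` (the standard
cofactor for conventional fluorescence cytometry); scatter channels are
scaled linearly to [0, 1] by the instrument full range (262,144 by
default). Values are read from FCS files as stored; whether source files
are compensated is an acquisition-side question the package does not
second-guess.

## The synthetic cohort simulator

Real ALOT patient files cannot ship with a package, so every downstream
stage is exercised on a simulator whose defaults define the package's
study conditions:

* Each cell type is a Gaussian cluster in transformed space, truncated at
  zero, with locations encoding canonical marker logic (T cells
  SmCD3+/CyCD3+/CD45-high; T-ALL CyCD3+/CD7+ but SmCD3-/CD45-negative;
  CD34+ precursors CD45-dim; neutrophils MPO+/SSC-high; and so on).
  Fluorescence SD is 0.35 arcsinh units, scatter SD 0.05 of full range;
  debris is a broad low-scatter cluster.
* The deliberately hard cases mirror clinical reality: BCLPD overlaps
  mature B cells, and each CD34-negative blast template equals its
  CD34-positive counterpart except on the CD34 channel, anchored near its
  physiological confounder. A single `separation` scalar moves these
  templates toward (0) or away from (1, default) their anchors.
* Each diagnosis is a Dirichlet prior over the 16-class composition:
  Normal is neutrophil-dominated with rare CD34+ precursors; AML and
  B-ALL carry ~40% blasts on average (mostly CD34-positive); Complex is
  Normal plus an abnormal CD34+ myeloid excess (the possible-MDS group has
  no published cytometric definition, only the clinical label, so an
  elevated precursor fraction is the package's modeling choice); Other
  mixes T-ALL and BCLPD burdens.
* A patient is simulated by drawing a composition, multinomial class
  counts, per-class events, and a recorded shuffle. One global seed drives
  a counter-based per-patient seed stream, so any patient is reproducible
  in isolation and cohorts are byte-identical across runs.

A quadratic-discriminant oracle fit on 1,000 events per class reaches at
least 95% held-out accuracy on the physiological classes at default
separation — the simulator is certified learnable before any network is
judged against it. What the simulator does **not** model: doublets,
acquisition-time drift, spectral spillover, inter-patient batch effects,
and within-patient relative-expression context. Passing tests therefore
demonstrate that the pipeline machinery works end to end on separable,
honestly noisy data — not that real-cohort accuracy is reproduced.

## Evaluation

Cohorts are split 80/20 into training and test sets, stratified by
diagnosis (test-set class counts in published tables are consistent with
approximate stratification); the training set is further divided into five
stratified folds for cross-validation, each sample validated exactly once.
An exact test-set size can be requested (largest-remainder apportionment
across strata) — useful because a published 241-patient cohort reports a
185/56 split, which is slightly larger than a literal 20% holdout.
Train/test overlap anywhere in evaluation is a hard error, never a
warning.

Per-class metrics are one-vs-rest: accuracy (TP+TN)/n, sensitivity
TP/(TP+FN), specificity TN/(TN+FP), F1 = 2TP/(2TP+FP+FN). Undefined
ratios are reported as not-applicable rather than NaN; all-zero counts are
an error. Display rounds percentages half-up to one decimal while raw
fractions are retained in every written report. Model selection across
folds picks the hyperparameter set with the best mean validation accuracy,
then refits on the full training set.

## Numerical choices

* The network engine computes exact analytic gradients, verified against
  central finite differences in the test suite (best-of-two-step probing,
  since ReLU and max-pool kinks bias a centered difference at large
  steps).
* He-uniform initialization; RAdam's rectification term guards the early
  steps; Lookahead interpolates slow weights every 6 steps with
  alpha = 0.5.
* Batch statistics use running estimates (momentum 0.1, eps 1e-5) at
  inference.
* Histogram binning clamps to edge bins on fixed ranges; identical events
  land in a single bin.
* All RNG flows through R's generator from explicit seeds; training is
  bit-reproducible for a given seed and configuration.

## Desk-scale problem sizes

The bundled tests and the acceptance script run the full pipeline at
sizes chosen to exercise every code path on a single CPU: Phase II trains
on 600 events per class (9,600 events) and is scored on 250 per class;
patient-level runs use a 100-patient, five-group cohort at 4,000 events
per patient; the robustness study turns the `separation` knob down
(0.1, 0.05, 0) until Phase II blast recall drops to 50% or below — near
zero the pathological templates coincide with their confounders, so the
per-event split of the shared region is training noise — and then verifies
that patient-level AML and B-ALL sensitivity survives — the package's demonstration that a
correct diagnosis needs only a subset of pathological cells to be
recognized. The `resnet50` variant and 250,000-event files are supported
but not exercised at full scale in the default test run.

## Known limitations

* Phase II ignores within-patient context: identical cell types are
  pooled across patients, losing the relative-expression information a
  human gater uses.
* The simulator's Gaussian clusters understate the skew and multimodality
  of real populations; real-world per-class recall will be lower at equal
  separation.
* Basophils are not identifiable with the ALOT panel and are not a class;
  such events fall into neighboring classes or debris.
* The `Complex` group is modeled, not derived from any cytometric
  definition of myelodysplasia.
* T-ALL-sized cohorts (a dozen patients in published work) are too small
  for a dedicated diagnosis class; T-ALL contributes to `Other`.
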