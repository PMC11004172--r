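# everflow

Deep-learning screening of acute leukemia from EuroFlow ALOT flow
cytometry, in R.

## The problem

The acute leukemia orientation tube (ALOT) is an eight-antibody EuroFlow
panel (CyCD3, CD45, CyMPO, CyCD79a, CD34, CD19, CD7, SmCD3) for triaging
suspected acute leukemia. Each sample is an FCS file with up to 250,000
events; each event is a cell with 12 channels (8 fluorescence + FSC-A,
FSC-H, SSC-A, SSC-H). Manual gating takes minutes per file and varies
between readers. `everflow` is for cytometrists and computational
hematologists who want an automated, reproducible three-phase analysis:

1. **Phase I** — patient-level diagnosis (Normal / AML / B-ALL / Complex /
   Other) directly from the event cloud, rendered as fixed-size density
   images over the canonical gating views and classified with a residual
   CNN (`resnet_tiny` desk-scale variant, or the 50-weight-layer
   `resnet50` bottleneck stack).
2. **Phase II** — per-event cell typing into 16 classes (9 physiological
   populations, debris, 6 pathological) with **EverFlow**: each event is a
   length-12 signal passed through Flow Blocks (Conv1d → BatchNorm1d →
   ReLU → MaxPool1d), adaptive average pooling, and a softmax head. The
   default network has exactly 3 convolutional, 3 batch-norm and 2
   max-pool layers and trains with the Ranger optimizer (RAdam +
   Lookahead) at learning rate 5e-3 for at most 75 epochs.
3. **Phase III** — patient-level diagnosis from the AI-derived cellular
   composition (16 class fractions, optionally + 192 per-class channel
   medians) through a residual dense stack.

Evaluation is one-vs-rest per diagnosis: accuracy (TP+TN)/n, sensitivity
TP/(TP+FN), specificity TN/(TN+FP), F1 = 2TP/(2TP+FP+FN), with stratified
80/20 splits and five-fold cross-validation.

A bundled simulator generates synthetic ALOT cohorts (per-cell-type
Gaussian clusters in arcsinh space encoding canonical marker logic,
diagnosis-dependent Dirichlet compositions, FCS + label sidecars +
manifest), so the full pipeline is testable without patient data.

## Worked example

```r
library(everflow)

# a small synthetic cohort: 5 diagnosis groups x 10 patients
manifest <- cmd_simulate("run/cohort",
                         patients = c(Normal = 10, AML = 10, "B-ALL" = 10,
                                      Complex = 10, Other = 10),
                         n_events = 3000, seed = 7)
mdf <- read_manifest(manifest)
split <- split_cohort(mdf, seed = 7)     # stratified 80/20 + 5 folds
train_ids <- names(split$assignments)

# Phase II: train the per-event classifier on pooled gated events
ck2 <- cmd_train(2, mdf, "run/p2", train_ids = train_ids, seed = 7,
                 max_events_per_class = 500)

# gate one file with the trained model
cmd_gate(ck2, mdf$fcs_path[1], "run/gated.csv")

# Phase III: diagnose from AI-derived compositions, evaluate held-out
ck3 <- cmd_train(3, mdf, "run/p3", train_ids = train_ids,
                 event_checkpoint = ck2, seed = 7, patience = 75)
report <- cmd_evaluate(ck3, mdf, "run/eval", test_ids = split$test_ids,
                       train_ids = train_ids, event_checkpoint = ck2)
print(report)
```

```
 Disease     F1       Accuracy  Sensitivity  Specificity
  Normal  50.0%   80.0% (8/10)  50.0% (1/2)  87.5% (7/8)
     AML 100.0% 100.0% (10/10) 100.0% (2/2) 100.0% (8/8)
   B-ALL 100.0% 100.0% (10/10) 100.0% (2/2) 100.0% (8/8)
 Complex  50.0%   80.0% (8/10)  50.0% (1/2)  87.5% (7/8)
   Other 100.0% 100.0% (10/10) 100.0% (2/2) 100.0% (8/8)
```

Each row is a one-vs-rest view of the 10-patient test set: `Sensitivity`
is the fraction of patients with that diagnosis the pipeline caught,
`Specificity` the fraction of other patients not mislabeled with it, and
`F1` combines precision and recall. Leukemias are recovered perfectly on
this small cohort; the one confusion is a Normal/Complex swap — Complex
differs from Normal only by a subtle CD34+ myeloid excess, and it is the
hardest group at every scale. The simulator's `separation` knob makes the
whole problem arbitrarily harder.

The same commands are available from a shell via the thin wrapper
`inst/cli/everflow` (`simulate`, `train`, `gate`, `evaluate`, `demo`).

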