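# attrunet

Fully automated binary lesion segmentation of 2-D grayscale medical images
with an **attention-gated recurrent residual U-Net**, implemented from first
principles in R (the convolution/pooling kernels are C++ via Rcpp, and the
network is trained through a small reverse-mode autodiff tape built into the
package). The target application is nasopharyngeal-carcinoma-like tumor
segmentation in T1-weighted contrast MRI slices, where lesions vary wildly in
size, shape, and laterality, neighbouring tissue has near-identical
intensity, and the intensity scale drifts between scanners.

The package is aimed at researchers who want a fully inspectable,
CPU-reproducible implementation of this architecture family and its
evaluation protocol — not a GPU training framework.

## What it implements

**Architecture.** A five-level encoder–decoder. Each block is a residual
recurrent convolution block (RRCB): a 1×1 channel-matching shortcut `s`, two
recurrent convolutional layers as the body, output
`α·s + body(s)`. A recurrent convolutional layer applies Conv+BN+ReLU `t`
times over a constant input `X`:

    I(0) = Wf·X + b,   I(τ) = Wf·X + Wr·O(τ−1) + b,   τ = 1 … t−1

with weights shared across passes. Each skip connection is gated by soft
spatial attention driven by the coarser decoder features `X_d`:

    λ = We·Xe + Wd·Xd + b_λ,   μ = Ψ·ReLU(λ) + b_μ,   α = σ(μ) ∈ (0,1)

and the gated skip `α ⊙ Xe` is concatenated with the upsampled decoder path.
A 1×1 convolution + sigmoid head emits per-pixel lesion probabilities.

**Pipeline.** Z-score intensity normalization (dataset-wide statistics from
the training split, or per-image), ROI cropping, bilinear resizing,
geometric augmentation, 80/10/10 splitting, BCE training with Adam
(β₁ = 0.9, β₂ = 0.999), plateau learning-rate decay, per-epoch validation
Dice model selection, five-metric evaluation (Dice, Jaccard, precision,
specificity, sensitivity) with pooled precision–recall curves, a
nine-variant ablation factory, a recurrence-depth (`t`) sweep, and
patient-wise k-fold cross-validation.

**Synthetic phantoms.** Because the clinical data this family of models is
evaluated on are protected, `generateCohort()` produces multi-patient
phantom cohorts with the task's statistical structure: one star-convex
lesion of log-uniform area and random laterality, similar-intensity
distractor blobs, and per-patient scanner profiles (brightness/contrast/
noise). Every module is tested end to end against these phantoms.

## Worked example

```r
library(attrunet)

# a 24-patient phantom cohort (~200 slices, 64x64), the package's
# CPU-scale reference conditions
cfg <- scaledExperiment(seed = 42, variant = "Att+Rec+Res")
res <- runExperiment(cfg)          # ~5 minutes on one CPU core
res$report
```

```
MetricsReport (per-slice mean ± sd)
  dsc          0.9384 ± 0.0514
  jaccard      0.8880 ± 0.0880
  precision    0.9050 ± 0.0978
  specificity  0.9944 ± 0.0065
  sensitivity  0.9816 ± 0.0204
  pr-auc       0.9762
```

Held-out mean Dice 0.9384 is the per-slice average of `2·TP/(2·TP+FP+FN)`;
specificity near 1 reflects the small lesion fraction, and the pooled
PR-AUC of 0.9762 summarizes ranking quality over all test pixels. The
skeleton variant (plain U-Net blocks, no gates) trained under identical
seeds and splits reaches a similar Dice on this deliberately learnable
phantom task — but it is brittle: under other root seeds it can fail to
train at all (held-out Dice < 0.1), while the full-mechanism model remains
above 0.9. At desk scale the ablation ordering is a noisy trend; the
mechanisms buy robustness of training before they buy headline Dice.

```r
runExperiment(scaledExperiment(seed = 42, variant = "Skeleton"))$report
```

Other entry points: `runAblation()` (all nine variants + Kruskal–Wallis
p-values against the full model), `runTSweep()` (t = 1…4,
parameter-matched), `runCrossval()` (patient-wise k-fold),
`writeSliceSet()`/`readSliceSet()` (PNG + manifest dataset layout),
`saveCheckpoint()`/`loadCheckpoint()` (named-tensor checkpoint with a JSON
manifest).

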