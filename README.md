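# ctaseg

Automated detection and segmentation of acute ischemic stroke lesions from
CT angiography (CTA) head volumes, for imaging scientists who want a fully
inspectable, end-to-end reference implementation of a hemisphere-symmetry-
aware 3D convolutional segmentation pipeline — with a synthetic phantom
generator so every stage can be trained and tested without clinical data.

## The method

Early ischemia lowers parenchymal attenuation by only a few HU, near the CTA
noise floor. The pipeline makes the signal detectable by pairing every voxel
with its contralateral counterpart:

1. **Preprocess** — extract the head region (skull apex down 175 mm),
   resample to 0.5 mm isotropic, map the 30–60 HU window affinely to
   [−1, 1] (no clipping), then flip the volume left–right and co-register
   the flip back onto the original (rigid stage with a mutual-information
   metric, then a free-form B-spline stage; 16 mm control grid, 32 bins,
   2048 samples, 4 levels). Original + mirrored volumes are the two network
   input channels.
2. **Segment** — a valid-padded 3D CNN: C = 40 convolutional 3×3×3 layers of
   F = 16 filters with two-layer skip concatenations (cropped by one voxel
   per side), a 1×1×1 layer of 50 filters, and a two-class softmax —
   527,768 trainable parameters (528,000 to the nearest thousand), 81-voxel
   theoretical receptive field, 107³ → 26³ patch geometry. Valid padding
   makes tiled whole-volume inference *exactly* equal to a single pass, so
   stitched probability maps are seamless by construction.
3. **Post-process** — threshold probabilities at ≥ 0.5, drop connected
   clusters smaller than 3 mL (26-connectivity), and call a case a stroke
   when the largest cluster exceeds 25 mL (the ROC operating point).
4. **Evaluate** — pooled voxel precision/sensitivity/Dice
   (Dice = 2·P·S/(P+S) on shared counts), volume-threshold ROC with
   trapezoidal AUC and top-left operating point, stratified percentile
   bootstrap CIs (strokes and nonstrokes resampled separately, 10⁵
   replicates), and through-origin volume-agreement regression
   (slope = Σ(ref·pred)/Σ(pred²)).

Training uses Adam (lr 10⁻⁴) on per-voxel cross-entropy with exactly
class-balanced minibatches (4 positive + 4 negative patches); an epoch
visits every positive patch once — 750 iterations for 3,000 positives — and
early-stops on the validation loss. The network forward/backward passes are
implemented in RcppArmadillo (the 3D convolution runs as 27 accumulating
matrix products on shifted channel-major views).

## Worked example

Train a small network on synthetic phantoms with pronounced lesions and
evaluate on a held-out cohort (a few minutes on one CPU core):

```r
library(ctaseg)

cohort <- generate_cohort(n_stroke = 25, n_control = 25,
                          volume_range_ml = c(20, 40),
                          seed = 2026, lesion_delta_hu = 30)
split_of <- function(i) if (i <= 10) "train" else if (i <= 15) "validation" else "test"
splits <- rep(vapply(1:25, split_of, ""), 2)

config <- run_config(
  working_resolution_mm = 2,                       # phantom resolution
  network = network_config(depth_C = 6, width_F = 8, input_patch = 31),
  train = train_plan(learning_rate = 1e-3, max_epochs = 8, patience = 2, seed = 1),
  bootstrap_reps = 2000, seed = 1)

report <- run_experiment(cohort, splits, config)
print(report)
```

```
eval_report
  voxel: precision 0.972 sensitivity 0.955 Dice 0.964 (CI 0.959-0.968)
  cases: accuracy 0.800 (CI 0.650-0.950), AUC 1.000 (CI 1.000-1.000)
  optimal volume threshold: 0.0 mL
agreement: r = 0.992 (0.979-0.999), slope 1.018, rel. diff +1.8% (+0.3 to +3.5)
```

Reading the output: `voxel` pools true/false positive voxel counts over the
20 test cases inside the tissue mask and reports precision, sensitivity and
Dice, with a case-level stratified bootstrap CI for Dice. `cases` classifies
each test case by its largest predicted lesion volume at the configured
25 mL decision threshold: several phantom lesions sit in the 20–25 mL range,
so the fixed clinical threshold misses them (accuracy 0.80) even though the
volumes themselves separate the classes perfectly (AUC 1.0) — the ROC
optimal threshold on these clean phantoms is far below 25 mL because
controls produce no supra-3 mL false clusters at all. The `agreement` line
regresses the phantom ground-truth volumes on the predicted volumes through
the origin: the reference volumes are about 2% larger than the predictions
on average. Single-volume prediction (`run_predict()`) writes the
probability map and lesion mask as NIfTI, axial overlay PNGs, and a JSON
report; `inst/cli/ctaseg.R` wraps simulate/preprocess/train/predict/
evaluate/experiment for shell use.

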