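---
title: "Whole-image classification of microcalcification clusters in simulated DBT: models and methods"
author: "DBTmc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DBTmc: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Digital breast tomosynthesis (DBT) reconstructs a pseudo-3D volume from
limited-angle, low-dose projections. Microcalcification clusters (MCs) --
groups of sub-millimeter calcium deposits -- are among the most important
early biomarkers of breast cancer, and they are exceptionally hard targets
for whole-image classifiers: a cluster occupies a few dozen pixels in a
multi-megapixel slice, the reconstruction is noisy, and the anatomical
background varies strongly with breast density. `DBTmc` studies the
fully automatic setting: a convolutional network receives an *entire*
reconstructed slice -- no regions of interest, no prior detection stage --
and answers "does this slice carry a calcification cluster?"

Because the full in-silico screening archive this design emulates is tens
of gigabytes and needs days of GPU time to process, the package ships its
own seeded generator of structurally similar synthetic cohorts with exact
ground truth, so every stage of the pipeline is testable on one CPU.

# The synthetic cohort generator

`generateCohort()` draws virtual patients with the population density mix
(10% fatty, 40% scattered, 40% heterogeneous, 10% dense, rounded by
largest remainder so counts always sum to the cohort size) and an
approximately balanced absent / presentMCs split. Each case is a volume of
independent slices:

* **Breast outline.** A randomized semi-elliptical compressed-breast mask
  touching the chest-wall edge, star-shaped around the chest wall so it is
  always one connected, hole-free component. Denser classes get smaller
  outlines, mirroring the per-density grid extents of the emulated archive
  (fatty volumes are the largest, dense the smallest).
* **Anatomical texture.** A power-law ("1/f^beta") random field fills the
  mask; the spectral exponent rises from 2.0 (fatty) to 3.2 (dense) and
  the glandular level and texture amplitude rise with it, so dense breasts
  are brighter and more structured -- the property that makes MC detection
  density-dependent. Intensity tapers smoothly over the outer ~5 px of the
  breast so the rim fades the way compressed tissue does.
* **Background contamination.** Pixels outside the breast carry a small
  positive signal (white noise plus a faint periodic ripple, mean about
  0.02), emulating the out-of-breast signal contamination of reconstructed
  data that background suppression must remove.
* **Clusters.** A positive case receives exactly 4 clusters of 5 additive
  antialiased bright disks each, centers recorded as (slice, row, col)
  ground truth. Default diameters are 2-3 px: at the desk grid of 128 px
  (~0.9 mm/px) real 170-200 um lesions would be sub-pixel, so lesions are
  drawn at the smallest scale that survives resampling. The cluster radius
  (`spreadPx`, default 6 px) is a free parameter of the generator; the
  emulated archive does not state an in-plane cluster extent.

Full-scale volumes have 62/57/47/38 slices for
fatty/scattered/heterogeneous/dense; `sliceScale` shrinks these depths for
desk work (default `gridSize/512`, floored at 5 slices so absent-slice
selection always works). Voxel anisotropy is represented by slice
independence only -- training and evaluation are strictly slice-by-slice,
and nothing is ever resampled along depth.

All randomness flows from the single cohort seed through per-stage derived
seeds; regenerating with the same spec is bit-identical.

**What the generator does not emulate.** There is no X-ray physics: no
projection/reconstruction chain, no detector noise model, no spiculated
masses, no 3-D cluster morphology across slices. Passing tests on this
generator show that the pipeline's machinery (masking, preprocessing,
leakage-free validation, optimization, evaluation) works and that the
networks can learn small bright lesions against density-dependent
anatomical clutter; they do not certify performance on clinical or
physics-simulated data.

# Background suppression and the six arms

`suppressBackground()` follows the four-step mask construction: Otsu
binarization, hole filling, largest connected component, then region
growing that admits neighbors above 10% of the in-mask mean intensity
until fixation. The threshold strategy, growing rule and stopping
criterion are package choices (the emulated design states only the step
names); defaults were fixed once against the generator's contamination
levels, and the growing step exists to recover the faded breast rim that
thresholding cuts off.

The seven input arms are compositions of four primitives, with background
suppression applied to the result of every arm:

| arm | composition |
|-----|-------------|
| original | identity |
| p1 | TV denoise |
| p2 | CLAHE |
| p3 | TV denoise, then CLAHE |
| p4 | CLAHE, then TV denoise |
| p5 | square normalization |
| p6 | square normalization, then TV denoise |

* **TV denoising** is the ROF model -- minimize `lambda/2 ||u - f||^2 +
  TV(u)` with isotropic total variation -- solved by Chambolle's dual
  projection (step 0.25, tolerance 1e-4, at most 200 iterations; all
  exposed). The fidelity weight defaults to `lambda = 14`, the working
  value of the emulated study. The minimizer never increases total
  variation, which the tests assert, and the solver is cross-checked
  against an independently coded primal-dual solver to 1e-3 relative.
* **CLAHE** runs through `EBImage::clahe` (Zuiderveld's tile-based
  algorithm with bilinear blending between neighboring tiles, the same
  family as MATLAB's `adapthisteq`). The normalized clip limit 0.01 is
  converted to the backend's bin-height multiple (`0.01 * 256 bins =
  2.56`); the tile grid defaults to 8 x 8 (unstated upstream). The
  distribution parameter 0.4 is stored for configuration fidelity but is
  inert under the uniform target histogram, which is the configuration
  the study used; the Rayleigh/exponential variants are deliberately not
  implemented and raise an error.
* **Square normalization** rescales to [0, 1] and squares, attenuating low
  intensities and highlighting the bright calcifications.

The breast mask is computed **once from the original slice** and reused
after the intensity transforms: CLAHE amplifies background contamination,
so a mask recomputed from a transformed slice would be corrupted. Whether
the emulated pipeline recomputed its masks per arm is not stated; reuse is
this package's choice. Preprocessing runs at the native grid and resizing
(bilinear, in-plane only) happens afterwards, preserving lesion-scale
operations before downsampling. Slices are then quantized to 8 bits and
zero-centered (per-image mean subtraction) at model-input time.

# Slice selection, folds and augmentation

Absent volumes contribute 5 proportionally spaced slices: spacing
`s = ceiling((n-1)/4)` starting at slice 1 with the last index clamped to
`n`. The two printed reference selections (62 slices: 1/17/33/49/62 and
38 slices: 1/11/21/31/38) pin this rule down; the depths without printed
selections (57, 47) follow the same inferred rule. Positive cases
contribute the slices holding cluster centers, deduplicated when two
clusters share a slice.

Cross-validation is 3-fold at the patient level: every slice of a patient
lives in exactly one fold, so no patient is ever on both sides of a split.
Folds are additionally stratified by (density, label) -- an addition to
the stated patient-level rule, needed so small desk-scale cohorts keep
both classes and all densities in each fold. Training-time augmentation is
a left-right reflection with probability 0.5 (simulating right breasts)
followed by a uniform rotation in +/-20 degrees (bilinear, zero fill;
interpolation choices unstated upstream and fixed here). Augmentation
never touches evaluation data.

# CNN-a and the reference networks

CNN-a is the AlexNet topology with two modifications: every channel-wise
local response normalization layer is replaced by batch normalization, and
one extra 3x3 max-pooling layer (stride 2, pad 0) is inserted between the
adjacent pair of grouped convolutions (conv4/conv5). Everything else
(channel widths 96/256/384/384/256, grouped convolutions with 2 groups,
4096-wide fully connected layers, dropout 0.5) is stock AlexNet, retained
wherever the derived design prints no value. Input is single-channel and
the head is two-way. Convolution paddings follow the widely used AlexNet
parameterization (conv1 11x11/4 with pad 2); under it the layer chain
requires an input of at least 128 px, which is exactly the desk grid, and
traverses cleanly at 512. Building with a too-small input fails with the
offending layer named.

AlexNet, GoogLeNet (inception v1 with batch-norm stem, no auxiliary
heads -- they are a training aid of the original recipe and play no role
here), ResNet18 and SqueezeNet (v1.1 layout) are instantiated from
scratch as layer graphs with stock channel configurations, grayscale
input and two-way output; no pretrained weights exist anywhere in the
package.

Because no deep-learning framework is available to R, the package carries
its own CPU engine: convolution and pooling are expressed as precomputed
sparse gather (im2col) matrices so each layer-batch is one BLAS GEMM, the
transposed gather performs the col2im scatter in the backward pass
(handling overlapping windows exactly), and batch norm, LRN, dropout,
concat and residual add complete the op set. Backpropagation through
every op is verified against central finite differences to 1e-4 relative
in the test suite. Weights are Glorot-initialized (fan-in/fan-out scaled
normal draws, the default of the toolbox the emulated study used); He
scaling was rejected after it produced activation magnitudes that
saturated the softmax at initialization in these deep unnormalized tails.

# Training and evaluation

The full-scale protocol is SGD with momentum 0.9, learning rate 1e-3,
batch 32, up to 200 epochs, cross-entropy plus an L2 penalty
`l2 * ||W||^2` with `l2 = 5e-3` (applied to weight matrices, not biases
or normalization parameters -- the standard reading of "L2 regularization
on the weights"). There is no early stopping; the epoch budget is fixed.
Data order reshuffles every epoch under the training seed, so a run is
deterministic end to end.

Evaluation: per-slice positive-class probabilities; ROC thresholds at
every distinct score with ties grouped; AUC as the trapezoidal area,
which equals the positive-negative concordance probability with ties
counted one half (asserted against a brute-force pairwise oracle). Fold
curves are combined by vertical averaging on a 101-point FPR grid.
Threshold metrics (sensitivity/specificity/accuracy) default to 0.5 on
the positive-class probability; the threshold is exposed because the
emulated design does not state one. Model comparison uses an unpaired
two-tailed t-test with pooled variance on per-fold AUCs (the variant is
unstated upstream; with 3 folds per group the implied degrees of freedom
match the pooled unpaired form; statistical power at n = 3 is of course
minimal, and equal-mean zero-variance groups return p = 1 by convention).
Density-stratified testing restricts the scored test set per density
class; training always mixes densities.

# Desk-scale choices

Single-CPU problem sizes used by the test suite and examples, chosen once
as the package's desk preset:

* grids of 128 px (the minimum CNN-a input) with `sliceScale = 0.25`;
* cohorts of 24-60 cases;
* epoch budgets of 1-10, mini-batch 8, learning rate 2e-2 -- with only a
  few dozen SGD updates available, the full-scale rate of 1e-3 barely
  moves the loss, so the desk preset trades batch size for update count
  and raises the rate until optimization reliably leaves its plateau;
  momentum and the L2 penalty are unchanged;
* the end-to-end checks use the high-contrast cluster preset
  (`highContrastClusterSpec()`: contrast 0.7 against the default 0.25,
  lesion diameters 5/4/4 px -- at least the stride of the first
  convolution): at the 128-px desk grid one pixel spans roughly four
  full-scale pixels, and lesions smaller than the conv1 stride can fall
  between samples and disappear into the pooling chain, which would make
  the desk-scale detection task unlearnable rather than merely hard. The
  preset is the easy, maximally conspicuous end of the task; the
  generator default (contrast 0.25, 2-3 px) remains the nontrivial
  condition;
* training-time augmentation is part of the full-scale protocol and is
  exercised by its own tests, but the scaled-down end-to-end checks train
  without it: a +/-20 degree bilinear rotation smears a 4-px lesion to
  roughly half its peak contrast, and with only a few dozen updates the
  networks cannot absorb that variability -- at desk scale augmentation
  turns a learnable task into noise;
* the end-to-end learning checks run the full cross-validated protocol on
  24-case cohorts for 10 epochs (three patient-disjoint folds, so each
  network trains on roughly 100 slices) -- the smallest scale at which
  optimization reliably converges -- and their negative control retrains
  and evaluates the whole experiment under patient-level permuted labels,
  the standard permutation null, which must and does land at chance.

`configPreset("paper")` retains the full-scale settings (512 px grids,
full depths, 200 epochs, batch 32, rate 1e-3) for completeness; running
it requires hardware this package does not assume.

# Numerical and degenerate-input conventions

* Constant slices cannot be thresholded or range-normalized: binarization
  and square normalization return all-zero outputs flagged
  `degenerate = TRUE`, and background suppression propagates the flag.
* Largest-component ties break by label scan order (first encountered).
* TV denoising clips its output to [0, 1] (clipping is a 1-Lipschitz
  projection and cannot increase total variation).
* Slice selection clamps intermediate indices to the volume depth, so
  very shallow volumes can repeat the last slice rather than fail.
* AUC is undefined (error) when a class is missing; density-stratified
  tables report NA for single-class subsets instead of failing.
* All seeds derived from a master seed stay below 2^31.

# Known limitations

* The generator's texture is stationary power-law noise; real glandular
  tissue has oriented, non-stationary structure, and real reconstruction
  noise is neither white nor Gaussian.
* Slice independence discards the 3-D coherence of real clusters.
* The engine is CPU-only and double-precision; full-scale (512 px,
  200-epoch) training is out of its practical reach.
* n = 3 folds give the t-test comparison little power; it is reported for
  protocol fidelity, not as a strong inferential tool.
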