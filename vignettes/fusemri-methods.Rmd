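---
title: "Multimodal attention-gated 3D networks for brain tumor classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal attention-gated 3D networks for brain tumor classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fusemri)
```

## The problem

Radiological triage of brain tumors into *normal*, *benign* and *malignant*
draws on complementary MRI contrasts: diffusion-weighted imaging (DWI,
acquired at several b-values) is sensitive to restricted water diffusion —
a hallmark of cellular malignant tissue, which appears hyperintense at
b = 1000 s/mm² — while T2-weighted imaging shows lesion morphology and
fluid content at higher in-plane resolution. A classifier should exploit
both, but the two sequences live on different grids (here 256×256×18 for
DWI, 512×512×18 for T2) and carry partly redundant, partly conflicting
regional evidence.

`fusemri` implements an end-to-end volumetric architecture for this task:

1. **HFIR** (high-frequency information retention): a learnable block that
   brings the T2 grid down to the DWI grid *losslessly*;
2. two independent **3D ResNet-18** branches, one per modality;
3. **ARA** (adaptive region attention): a per-region sigmoid gate that
   aligns and re-weights the two branches' features before fusion;
4. a convolutional classification head;
5. patient-level leave-one-out cross-validation (LOOCV) training,
   percentile-bootstrap statistics, and 3D Grad-CAM explanations.

Because the clinical cohort this design targets is private, the package
ships a synthetic phantom generator that reproduces its geometry, modality
contrast, and class structure, so every stage is testable end to end.

## HFIR: lossless downsampling

Halving resolution by strided convolution or pooling discards detail.
HFIR instead uses a *pixel unshuffle*: each non-overlapping `r × r`
in-plane block becomes `r²` channels, so a `(C/r², D, H, W)` tensor maps
bijectively to `(C, D, H/r, W/r)`. Two per-slice 3×3 convolutions run
first: one lifts the single T2 channel to `C` shallow feature channels,
the second compresses to `C/r²` — an information bottleneck the network
can learn to use — and the unshuffle then trades space for channels
without dropping a single value. With the defaults `C = 16, r = 2`, an
`18×512×512` T2 volume becomes a 16-channel `18×256×256` feature volume
aligned with the DWI grid.

Two numerical choices are worth noting:

* the polyphase channel order is row-major over in-block offsets
  (`out[c·r² + Δh·r + Δw] = in[h·r + Δh, w·r + Δw]`), a fixed bijection
  chosen once and frozen in the tests;
* the two convolutions are purely linear by default (no nonlinearity in
  between, `activation = "relu"` switches one on); the block stays a
  linear map followed by a permutation, which makes the losslessness of
  the downsampling step provable and testable (`pixel_shuffle()` inverts
  `pixel_unshuffle()` exactly).

## Backbone branches

Each branch is a standard 3D ResNet-18: a stem convolution, an in-plane
max-pool, and four stages of two basic residual blocks (two 3×3×3
convolutions with batch normalization, identity or projection shortcuts)
at widths 64/128/256/512. The DWI branch takes the three b-value volumes
as input channels (b0, b500, b1000); the T2 branch takes the 16-channel
HFIR output. Features are read from the final stage ("layer 4").

The published endpoint of this geometry is a `(512, 4, 8, 8)` layer-4 map
for an `(18, 256, 256)` input. The depth path 18 → 4 admits more than one
stride plan; we use the small-integer realization
stem/pool depth stride 1, stage depth strides (1, 1, 2, 2) with depth
padding 1 at stage 3 (18 → 9) and 0 at stage 4 (9 → 4), while height and
width halve at stem, pool and stages 2–4 (256 → 8). `shape_plan()`
exposes the pure `floor((n + 2p − k)/s) + 1` arithmetic so any plan can be
validated without building the network; the chosen plan is recorded in the
`backbone_plan()` object rather than hard-coded. Where a stage uses depth
padding 0, the projection shortcut uses a depth kernel of 3 (instead of 1)
so both paths agree on the output size.

Weights are Kaiming-initialized from a seed and always trained from
scratch; there is no pretrained-weight import.

## ARA: adaptive region attention

After flattening each layer-4 map into region tokens (depth participates
in the token index — the only lossless flattening of a 3D map; a config
note records the alternative slice-wise reading), the gate scores the
concatenated token matrix `f = [f_T2, f_DWI] ∈ R^{PWH×2C}`:

```
Gamma      = sigmoid( relu(f %*% Phi1 + b1) %*% Phi2 + b2 )
alpha_T2   = Gamma[, 1:C]        * f_T2  + f_T2
alpha_DWI  = Gamma[, C + (1:C)]  * f_DWI + f_DWI
```

with `Phi1 ∈ R^{2C×C/2}`, `Phi2 ∈ R^{C/2×2C}` — a 4× bottleneck. (A
textual description of the layer as "halving the feature dimension" would
give `Phi1 ∈ R^{2C×C}`; the printed weight shapes are authoritative and
the bottleneck is `C/2`.) The first `C` score columns gate the T2 tokens,
matching the concatenation order. The FC layers act identically on every
token, so the gate is permutation-equivariant over regions and adds no
cross-token mixing; the residual skip bounds the output between 1× and 2×
the input elementwise, which both stabilizes training and guarantees
`sign(alpha) = sign(f)`. All four equations are verified against a
straight-line scalar transcription in the test suite.

## Classification head

The fused `(2C, D4, H4, W4)` map passes through dropout (p = 0.5,
training only), a 1×1×1 convolution to 3 class scores, and a global
adaptive average pool. Since a 1×1×1 convolution is a per-position linear
map, convolution-then-pool equals pool-then-linear; the implementation
uses that identity (it is exact, not an approximation). No rectifier is
applied after the classifier convolution — rectified logits would forbid
negative class scores under cross-entropy; an optional
`relu_before_head` flag rectifies the fused features instead, covering
the alternative reading of the head's ReLU placement.

## Training and evaluation protocol

Training uses AdamW (learning rate 0.001, decoupled weight decay 0.01 on
weight matrices only), batch size 8 for the full geometry, cross-entropy
loss, and a cosine annealing schedule that decays to exactly zero at the
final epoch. The
epoch budget is fixed per fold (50 for the full geometry, 24 for the tiny
preset) because LOOCV leaves no validation split to stop early on.
Augmentation is limited to seeded random in-plane flips applied to both
modalities together (`augment = FALSE` disables it); intensity
augmentation is pointless after per-volume z-scoring, and elastic
deformations would break the paired-grid contract.

Cross-validation is leave-one-out at the *patient* level: all volumes of
the held-out patient are excluded from that fold's training set, which is
re-asserted before every fold. Every source of randomness — weight
initialization, batch order, flips, dropout — derives from one root seed,
so a run is reproducible end to end.

Metrics follow the three-class one-vs-rest convention: overall accuracy
plus unweighted macro-averaged sensitivity, specificity and F1 (macro,
not micro: a prevalence-weighted average could not sit far below the
accuracy, as these quantities do in practice), and Cohen's kappa
`(po − pe)/(1 − pe)`, all in percent. Uncertainty uses the percentile
bootstrap: 10,000 resamples of the patient records with replacement, CI =
(2.5th, 97.5th) percentiles, with the bootstrap mean reported as the point
estimate and the full-sample value alongside. Model comparisons resample
*paired*: one index multiset is applied to both prediction sets and the CI
of the statistic difference is checked for excluding zero. Degenerate
cases are defined, not dropped: a class absent from a resample's truth is
excluded from the macro mean (flagged), and kappa with `pe = 1` is 0.

## Grad-CAM

For a chosen class and branch (default: the DWI branch, where such
overlays are conventionally drawn), the gradient of the class logit with
respect to the layer-4 activation is averaged over positions to give one
weight per channel; the rectified weighted channel sum, normalized to
`[0, 1]`, is the CAM, and a trilinear upsample maps it onto the input
grid for overlay. The localization check used in the tests asks whether
the CAM maximum falls within 3 voxels of the lesion mask.

## The phantom generator

`generate_patient()` renders a smooth intensity ellipsoid ("brain") on
both modality grids with modality-dependent base intensities (arbitrary
units in [0, 1]: b0 0.70, b500 0.50, b1000 0.35, T2 0.55), plus additive
Gaussian noise (σ = 0.05 by default; no Rician model — the phantom is
functional, not physical). Benign and malignant patients carry one
lesion whose morphology encodes the class:

* **benign** — near-spherical (boundary irregularity ≤ 0.2), bright on
  T2 (contrast 0.25–0.35), mild b1000 contrast (0.06–0.10);
* **malignant** — boundary perturbed by low-order angular modes
  (irregularity 0.5–0.9), strongly b1000-hyperintense (0.30–0.40), the
  diffusion-restriction analogue.

Lesion radii are 0.18–0.28 of the brain half-width (≈ 23–36 voxels on
the 256 grid, a plausible 2–3.5 cm at ~1 mm in-plane), placed uniformly
where the perturbed boundary still fits inside the brain; both modality
grids are rendered from the same normalized coordinates, so the phantoms
are pre-aligned by construction (the clinical protocol's registration is
out of scope). In the noise-free limit a threshold on (lesion present,
mean b1000 lesion contrast) classifies the cohort perfectly — the
property that makes the learning checks meaningful.

What the phantoms deliberately do *not* model: skull/air artifacts, bias
fields, Rician noise, partial-volume effects, real lesion texture, or
T1/FLAIR/contrast-enhanced sequences. Passing the desk-scale tests
therefore demonstrates that the architecture, optimization and statistics
are implemented correctly and can recover a known separable signal; it
does not certify clinical performance.

## Desk-scale configuration ("tiny" preset)

Full-geometry training is not a laptop-scale exercise, so the package
defines a reduced configuration used by the test suite and the acceptance
script, and states it here as its own choice of problem size:

* grids `(8, 64, 64)` DWI / `(8, 128, 128)` T2, cohort of 12 patients
  (4 per class), noise-free;
* backbone widths scaled by 1/16 (4/8/16/32) and HFIR `C = 4` — the
  architecture, not the capacity, is what the desk-scale checks exercise;
  the default plan keeps the canonical 64/128/256/512 widths and every
  printed-shape check runs at full width;
* a gentler stride plan (in-plane halving at the stem and stages 2–3,
  depth halving at stage 4, non-strided pool) whose layer-4 grid is
  `(4, 8, 8)` — the same 256-token region grid as the full geometry — so
  the ARA token set matches the published shape and Grad-CAM retains
  usable spatial resolution on the small grid;
* 24 epochs per fold with batches of 4 — an 11-patient LOOCV training set
  then takes three optimizer steps per epoch instead of two, which
  converges more reliably at identical arithmetic cost — and batch
  normalization in batch mode (instance mode is available as a config
  switch but converges more slowly here).

## Known limitations

* Batch normalization couples samples within a batch; fold results can
  shift slightly with batch composition (seeded, hence reproducible).
* The conv engine is im2col + BLAS on one CPU in double precision;
  full-geometry LOOCV is supported but slow — the design target for full
  runs is correctness, not throughput.
* Bootstrap CIs use the percentile rule (not BCa), matching the stated
  2.5/97.5 convention.
* The LOOCV epoch budget is fixed; no early stopping or hyperparameter
  search is provided.
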