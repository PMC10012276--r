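---
title: "Distance-informed dose prediction: models, phantoms and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-informed dose prediction: models, phantoms and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Knowledge-based radiotherapy planning predicts the 3D dose distribution a
treatment planner would accept, directly from patient anatomy, so that the
prediction can seed the objectives of inverse plan optimization. For
head-and-neck (nasopharyngeal) treatments the anatomy is demanding: two
nested prescription levels (a planning target volume, PTV, at 60.06 Gy in
33 fractions and an interior boost at 69.96 Gy) surrounded by roughly
twenty-one organs at risk (OARs), several of them serial structures whose
sparing bends the dose distribution locally.

`kbdose` implements and compares two slice-wise fully-convolutional dose
predictors:

* **ANAT** — two input channels: CT and an integer-coded structure map;
* **COM** — the same two channels plus a *distance-to-PTV* (DPTV) map: for
  every normal-tissue voxel, the minimum 3D Euclidean distance in
  millimetres to the PTV.

The physical motivation is that dose outside a target falls off primarily
with distance from it; handing the network that distance explicitly spares
it from having to derive long-range geometry through a limited receptive
field.

## The DPTV map

For voxel $i$ in the body but outside the PTV,

$$\mathrm{DPTV}_i = \min_{v \in \mathrm{PTV}} \; \lVert x_i - x_v \rVert_2,$$

with voxel-center coordinates in millimetres. PTV voxels and voxels outside
the body are coded 0. This zero-coding is deliberately ambiguous (a PTV
voxel and an out-of-body voxel read the same); the structure-map channel
disambiguates, and the convention is kept because it matches how the map is
consumed as a normalized network input.

Numerical choices:

* The transform is an **exact** separable lower-envelope (parabola)
  squared-distance transform run per axis with physical spacing, not a
  chamfer or voxel-count approximation. Clinical grids are anisotropic
  (3 mm slices vs ~1 mm in-plane), so voxel-count distances would be wrong
  by up to a factor of three along the axial direction. The suite verifies
  equality with exhaustive nearest-voxel search to below $10^{-6}$ mm.
* Distance is measured voxel-center to voxel-center. This equals distance
  to the PTV *surface* up to half-voxel discretization and keeps the
  implementation exactly the minimum over PTV voxels.
* For network input the map is divided by a configurable cap
  (`dptv_cap_mm`, default 150 mm — comfortably above the largest distances
  on a head-and-neck grid) and clipped to $[0, 1]$.

## The structure map

All ROIs are painted into one integer-labeled volume. Codes: 0 outside the
body, 1 body, 2 out-of-field, OARs 3, 4, ... in list order, targets at
100, 200, .... A voxel in both an OAR and a target carries the *sum* of the
two codes; spacing target codes by hundreds makes every sum unique by
construction (validated at table construction). Painting order is body,
out-of-field, OARs, targets, so ROI codes survive and any non-overlapping
ROI is exactly recoverable from the map. Two deliberate conventions:

* PRV expansions are listed before their core organ, so the core's code
  wins where they overlap.
* The boost is painted after the PTV and overwrites it; target-target
  sums never occur.

The map is divided by the largest possible code (plain or summed) for the
network input; CT is windowed linearly from $[-1000, 1000]$ HU to
$[0, 1]$.

## The predictor

The network is a residual encoder-decoder operating on axial slices:

* stem: 7×7 convolution, 64 filters, stride 2; batch norm; ReLU; 3×3
  max-pool stride 2;
* four stages of bottleneck blocks (1×1 → 3×3 → 1×1 convolutions with an
  identity or projected skip), with default block counts (3, 4, 23, 5);
* only the second stage downsamples further (stride 2); the last two
  stages use dilation 2 and 4 at stride 1, holding the encoder output at
  **1/8** of the input resolution — the standard dense-prediction
  adaptation of a classification backbone, and the only stride layout
  consistent with both the bottleneck stage structure and a 1/8 encoder;
* decoder: three fractionally-strided (transposed) convolutions, each ×2,
  then a 1×1 projection to one channel.

Because no deep-learning framework is available to R in this toolchain,
the layers (convolution via im2col + BLAS, transposed convolution as the
exact adjoint, max-pooling, batch normalization) and their analytic
gradients are implemented in the package itself (C++ for the
convolutions); the test suite checks the gradients against finite
differences and the shape contracts at 64–512 px.

Training choices the architecture source leaves open, fixed as defaults
here: MSE loss on dose normalized by the boost prescription (69.96 Gy, so
targets stay in $[0, 1]$), Adam at learning rate $10^{-4}$, batch size 8,
100 epochs. All are configurable; the desk-scale experiments below use a
higher rate ($10^{-3}$) suited to the much smaller models. After the last
epoch the batch-norm inference statistics are recalibrated in one pass
over up to 128 training slices — with small models and few epochs the
running averages otherwise lag the trained regime noticeably (we measured
about a percentage point of body MAE).

A `width_multiplier` scales all channel counts and `stage_blocks` the
depth, so the same code runs both a full-width backbone (~45 M parameters)
and desk-scale variants (one block per stage at 1/16 width, ~70 k
parameters) that train in under a minute per fold on one CPU.
Inputs whose height or width is not divisible by 8 are zero-padded and the
output cropped back.

## The phantom cohort and dose engine

Clinical training data for this task (VMAT plans for 100 patients) are not
publicly available, so the package ships a synthetic generator whose
role is to make every downstream claim *testable*, not to be anatomically
faithful:

* geometry: an ellipsoidal body section, an ellipsoidal PTV with a
  strictly interior boost, and 21 schematic OAR primitives (spheres,
  ellipsoids, z-cylinders) at near-to-far distances from the target,
  mirroring a nasopharyngeal OAR list with PRV expansions;
* grid: 64×64×16 voxels at (4, 4, 3) mm — clinical 3 mm slices with
  coarsened in-plane sampling, keeping the anisotropic code paths
  exercised while a full two-model comparison stays in the minutes range;
* CT: schematic HU tiers (air −1000, soft tissue ≈ 40, a bone-like shell
  ≈ 700) plus seeded Gaussian texture (SD 20 HU). CT only enters as a
  normalized channel, so tiers suffice;
* in-field region: all axial slices within `field_margin_mm` (default
  6 mm) of the target extent — a simple axial stand-in for a coplanar-arc
  field; how the clinical out-of-field region was derived is not
  something the phantom tries to infer;
* dose engine: boost voxels at 69.96 Gy, remaining PTV at 60.06 Gy,
  in-field normal tissue at
  $60.06 \cdot e^{-\mathrm{DPTV}/\tau}$ Gy with $\tau = 25$ mm,
  multiplied by a per-OAR sparing factor (minimum over covering OARs;
  stronger for serial organs), capped at 2 % of prescription out of
  field, zero outside the body, plus optional additive Gaussian noise
  (default SD 0.5 Gy) clipped at zero.

The falloff scale $\tau = 25$ mm puts the 50 %-dose line about 17 mm from
the PTV — a plausible head-and-neck gradient — and was fixed once at
design time. The engine makes dose a *deterministic function of DPTV plus
the OAR layout*, which is exactly what turns the COM-vs-ANAT comparison
into a controlled experiment: the distance channel is sufficient
information by construction, and the anatomical channels alone still
determine it implicitly (the structure map fixes the geometry). What the
phantom does **not** emulate: beam/arc physics, fluence, scatter,
build-up, inter-planner variability, or realistic CT texture — so a COM
win here demonstrates that the architecture exploits the distance channel
when distance matters, not that it would win by the same margin on
clinical plans.

## Evaluation suite

* **ME / MAE** — per-case mean (signed / absolute) voxel difference over a
  region, as a percent of prescription; cohort values aggregate per-case
  means with equal weight (not pooled voxels). With two prescription
  levels the percent denominator is ambiguous; policy: each target uses
  its own prescription, body / normal tissue / OARs use the boost
  prescription (69.96 Gy). This choice rescales all percentages and is
  exposed in `metric_prescription()`.
* **Isodose DSC** — Dice overlap of the regions receiving at least each
  level, over 1–60 Gy, with the 5–55 Gy / 5-Gy-bin extraction used for
  paired statistics. The threshold is the closed bound ($\geq$ level);
  two empty isodose volumes score 1 (flagged as degenerate) rather than
  0/0.
* **DVH, D5 %, mean dose** — cumulative histograms at 0.1 Gy bins; Dx% is
  the largest dose with coverage ≥ x, linearly interpolated within a bin
  but never past the maximum received dose (so a uniform region returns
  exactly its dose).
* **Paired comparison** — two-sided paired t-tests on per-case metrics;
  zero-variance differences are flagged degenerate instead of producing a
  p-value.

## Experiment design and problem sizes

`run_experiment()` reproduces the study structure: cohort → features →
k-fold cross-validation (folds differ by at most one case; each case is
tested exactly once) → both models per fold with independent seeded
initializations → evaluation → paired comparison → report. Every stage
logs seed, config hash and wall time; metric CSVs are byte-reproducible
from the master seed.

Desk-scale defaults, chosen once and stated here as the package's own
problem sizes: 40 cases, 2 folds, one bottleneck block per stage at 1/16
width, 8–12 epochs of Adam at $10^{-3}$, batch 16. The headline check
trains both models across five master seeds (twenty trainings) and asks
for a directional result — pooled test body MAE lower for COM than ANAT in
at least four of five seeds. The clinical configuration (100 cases,
10 folds, blocks 3-4-23-5, 100 epochs) remains reachable through the same
config objects.

## Known limitations

* The phantom's dose model is the package's own construction; none of the
  clinical tables of the motivating study can be, or are, reproduced
  numerically.
* The published backbone is described as 101 layers with stage counts
  (3, 4, 23, 5); the arithmetic of those counts does not yield exactly
  101 — the printed counts are kept as defaults and the discrepancy is
  noted rather than resolved.
* Whether training should exclude empty out-of-field slices is left open
  upstream; this implementation trains on all slices.
* The decoder carries no skip connections from the encoder, so fine
  spatial detail below the 1/8 bottleneck is reconstructed, not copied —
  visible as slightly blurred target edges in desk-scale models.
* 2D slice-wise modeling ignores inter-slice context by design; a 3D
  variant is out of scope.
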