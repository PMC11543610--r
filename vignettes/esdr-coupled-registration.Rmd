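---
title: "Coupled registration and segmentation with exponential signed distance representations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled registration and segmentation with exponential signed distance representations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esdreg)
```

## The problem

Large-scale brain mapping produces 3D whole-brain volumes in many imaging
modalities (serial two-photon tomography, fMOST, VISoR light-sheet variants,
MRI). Two core analyses — deformable **registration** (aligning a moving
volume onto a fixed one) and **segmentation** (delineating anatomical
regions) — are usually treated separately, and multi-modal registration in
particular is hard because intensity similarity metrics (MSE, mutual
information, local correlation) break down when brightness and texture differ
systematically between modalities.

`esdreg` couples the two tasks through one shared, modality-independent
latent representation with an explicit physical meaning: the **exponential
signed distance representation (ESDR)**.

## The representation

For a label volume whose regions partition the grid (background counts as a
region), the signed distance representation is

$$\mathrm{SDR}(x) \;=\; \begin{cases} \inf_{y \in \tau}\; \lVert x - y
\rVert_2 & x \in \Omega_{\mathrm{ROI}} \\ 0 & x \in \tau, \end{cases}$$

the Euclidean distance from voxel $x$ to the nearest boundary voxel $\tau$ of
the region that contains $x$. The exponential transform

$$\mathrm{ESDR}(x) \;=\; \exp(-\gamma\,\mathrm{SDR}(x)), \qquad \gamma = 1$$

maps region boundaries to exactly 1 and decays into region interiors. Two
properties make it the right currency for both tasks:

* it depends only on the **geometry of the labels**, never on intensities, so
  it is modality-independent by construction;
* the exponential concentrates the representation's gradient at region
  boundaries — precisely where registration must align and segmentation must
  decide — which also speeds up optimization relative to a raw (linearly
  scaled) distance map.

Discretization choices: the continuous boundary $\tau$ is realized as the
6-connected inter-voxel interface (boundary voxels on both sides carry 0);
the image border is *not* a boundary (real brains are surrounded by
background, which is a region of its own); distances are exact Euclidean
distance transforms honouring anisotropic voxel spacing (`compute_sdr()`
uses a separable lower-envelope scan per region, verified against exhaustive
search in the tests). Despite the conventional name, the map is non-negative
everywhere: each voxel measures the distance within its own region, and the
"sign" information is carried by which region the voxel belongs to.

## The model

Three networks share the representation:

* **G** (feature extractor): a five-stage 3D U-Net (two 3×3×3 convolutions
  per stage; 16, 32, 64, 128, 256 encoder channels; group normalization +
  ReLU; max-pool down, transposed convolution up, skip connections) mapping a
  raw intensity volume to a predicted ESDR through a 1×1×1 convolution and a
  sigmoid.
* **R** (registration): a four-stage U-Net (one convolution per stage; 16,
  32, 32, 32 channels; ReLU except after the last convolution) consuming the
  concatenated fixed and moving representations and emitting a 3-channel
  displacement field $\varphi$ (offsets in voxels). Its head is
  zero-initialized so training starts at the identity transform.
* **S** (segmentation): a four-stage U-Net (two convolutions per stage, the
  second doubling the first's 8, 16, 32, 64 channels; group normalization +
  leaky ReLU) consuming one representation and emitting per-voxel class
  probabilities via a 1×1×1 head and channel softmax.

Warping follows $W(Z_m, \varphi)[p] = Z_m[p + \varphi[p]]$ with trilinear
interpolation for scalar volumes and nearest neighbour for labels
(`warp_linear()`, `warp_nearest()`). Offsets are in voxel units, sample
coordinates are clamped to the border, and nearest-neighbour ties round half
away from the grid origin so label warps are bit-reproducible.

### Losses

* Representation regression (G): per-voxel Huber loss with $\delta = 1$.
* Registration similarity: voxel-mean squared error between the fixed
  representation and the warped moving one.
* Field smoothness: mean squared forward-difference gradients of all three
  field components along all three axes.
* Auxiliary overlap: one minus the mean Dice over the K foreground
  structures between fixed labels and warped moving labels. During training
  the one-hot moving channels are warped with *trilinear* interpolation so
  the term is differentiable in $\varphi$; evaluation always uses
  nearest-neighbour warps.
* Segmentation: one minus mean soft Dice over all $K{+}1$ classes
  (background included so the softmax is well posed; the auxiliary
  registration term uses foreground structures only, matching how overlap is
  reported).
* Total registration loss: $L_R = \alpha L_{regi} + \beta L_{smooth} + \rho
  L_{aus}$ with all weights 1 by default.

All losses reduce to voxel means so they stay on compatible scales under
unit weights. Dice denominators carry an epsilon of $10^{-5}$; two empty
masks score Dice 1.

### Two-stage training

Stage one pre-trains the three networks independently, supervised by the
ground-truth ESDR derived from labels: G regresses image → ESDR (samples
from all modalities interleaved), S maps ESDR → labels, R maps concatenated
ESDR pairs → displacement fields. Stage two concatenates the pre-trained
networks and fine-tunes the G-R and G-S branches in an alternating fashion
(one optimization step each per sample by default), with both branches now
consuming the representation *predicted* by G; the shared G receives
gradients from both branches, each branch under its own Adam optimizer.
Optimization is Adam at learning rate $10^{-3}$, batch size 1; $\gamma =
\delta = 1$.

Design points the architecture description leaves open, resolved here: the
decoders mirror the encoder widths with skip concatenation; transposed
convolutions carry no normalization or activation; group normalization uses
8 groups (capped at the layer's channel count); leaky-ReLU slope 0.01; all
3×3×3 convolutions pad by 1; He-normal initialization; G is supervised only
through the branch losses during fine-tuning.

## Numerical engine

The package implements its own differentiable numerical engine, sized for
the operations this model actually needs: 3×3×3 convolutions run as im2col + BLAS
GEMM, transposed convolutions as strided channel-mixing GEMMs, and the
trilinear warp, group normalization, max-pooling and exact Euclidean
distance transform are hand-written C++ with hand-derived gradients. Every
gradient is verified against finite differences or a direct-loop double
precision oracle in the test suite. The convolution path defaults to single
precision (the standard precision regime for network training; it roughly
doubles throughput), with a double-precision path selectable via
`options(esdreg.conv_single = FALSE)` — the exact path is what the gradient
tests use. All computation is single-threaded apart from BLAS, and every
training entry point is bit-reproducible on CPU for a fixed seed.

## The phantom generator

Real multi-modal whole-brain datasets cannot ship with a package, so all
tests and experiments run on seeded synthetic phantoms
(`make_label_phantom()`, `render_modality()`, `make_pair()`) designed to
reproduce the *structure* of the real task:

* **Geometry** — a brain-like ellipsoidal foreground whose normalized radius
  is perturbed by a smooth random field, carrying a thin outer cortex-like
  shell (label K), a mid shell (label K−1), an interior bulk (label 1) and,
  for K ≥ 4, small nucleus-like blobs at consistent "anatomical" directions
  with small seeded jitter. Shell thickness is fixed in voxels (≈2), like
  cortical thickness in millimetres, so overlap sensitivity to misalignment
  does not wash out on larger grids.
* **Modalities** — one label volume is rendered into two artificial
  modalities: per-region mean intensities (non-monotonically related between
  the presets, so no global intensity mapping aligns them), a smooth
  multiplicative bias field, band-limited texture, and Gaussian noise,
  clipped to [0, 1].
* **Deformations** — ground-truth fields are Gaussian-smoothed independent
  random fields per axis, rescaled so the *maximum* offset magnitude equals
  the requested amplitude (3 voxels by default). They are folding-free by
  construction at the default smoothness. A pair consists of fixed labels,
  the moving labels warped by the truth field, and one rendering of each in
  its own modality. Under the warp convention the field that registers the
  moving image back onto the fixed one is approximately the *negated* truth
  field, which is how endpoint error is measured.

**Calibration of the deformation smoothness.** The smoothness sigma is the
one generator parameter with no physical anchor, so it is calibrated against
the published operating point of affinely pre-aligned whole-brain data:
"global only" (affine) registration on such data leaves roughly 70–82% mean
Dice. The default sigma (18 at the default 48³ grid; 13 at the 32³ grid the
tests use) places the unregistered overlap of amplitude-3 phantom pairs at
≈75%, the midpoint of that range. What the phantoms deliberately do *not*
model: acquisition point-spread and stitching artifacts, intensity
non-stationarity across brains, anatomical variability beyond smooth
deformations, or inter-subject topology changes. Passing tests therefore
demonstrate that the machinery — representation, networks, losses, training
scheme — works as specified, not that the trained weights transfer to real
microscopy.

## Scaled experiment protocol

`run_coupled_experiment()` is the single entry point the test suite and the
acceptance script share. It generates `n_pairs` multi-modal pairs, runs the
two-stage scheme (or an ablation), and reports: mean foreground Dice before
and after registration (the *unregistered* value is the affine-only
baseline), the folding fraction of the predicted fields (voxels with
non-positive Jacobian determinant of $p + \varphi$), endpoint error against
the negated truth field, hold-out segmentation Dice through the full G→S
pipeline on unseen phantoms in both modalities, and the within- vs
cross-modality registration gap.

Problem sizes are chosen for minutes-scale CPU runs: 8 training pairs of
32³ voxels with K = 4 regions, amplitude 3, reduced channel widths (G
8–128, R 8–16, S 4–32) and reduced epochs (G 20, S 60, R 100, fine-tuning
8). The ablation comparison (full vs. no exponential transform vs. no
pre-training) runs the three arms at a smaller matched budget (G 6, S 14,
R 60, fine-tuning 3; the cold-start arm fine-tunes for 9 epochs). The
"no exponential transform" arm supervises with the raw SDR (G then carries
a linear head, since distances are unbounded); the "no pre-training" arm
fine-tunes from random initialization for a compute-matched number of
epochs. Two ablation axes reported for the real data reproduce
qualitatively at this scale: pre-training on the distance representation is
worth far more than the exponential transform, which still adds a
measurable margin.

## Degenerate inputs and edge cases

* A uniform label volume has no boundary; `compute_sdr()` rejects it.
* `dice_score()` of two empty masks is 1 by convention; a structure absent
  from both volumes scores 100% in `dsc_percent()` and is flagged.
* Amplitude-0 deformations return exact zero fields; warping with a zero
  field is the identity.
* Sample coordinates outside the grid clamp to the border, and clamped
  samples carry zero field gradient.
* The Jacobian determinant map uses forward differences with the last slice
  replicated, and evaluates $\det(I + \nabla\varphi)$ — the determinant of
  the deformation map $p + \varphi(p)$, the quantity for which a
  sub-percent folding fraction is meaningful.

## Known limitations

* Batch size is fixed at 1 (as in the reference training regime); there is
  no multi-threading, GPU path, or mixed-precision control beyond the
  single/double convolution switch.
* The registration head regresses displacements directly; no diffeomorphic
  integration or field inversion is provided, so invertibility is a
  diagnostic (folding fraction), not a guarantee.
* Phantom experiments overfit deliberately small datasets; the reported
  registration Dice is a training-pair quantity, mirroring how the
  deformation-recovery property is defined, while segmentation Dice is
  held-out.
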