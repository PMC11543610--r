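# esdreg

Joint deformable **registration** and **segmentation** of multi-modal 3D
brain volumes through a shared, modality-independent latent representation.

## The problem and the approach

Whole-brain volumes acquired with different modalities (serial two-photon
tomography, fMOST, light-sheet variants, MRI) differ systematically in
brightness and texture, which defeats the intensity similarity metrics that
mono-modal registration relies on — while registration and segmentation,
usually treated as separate problems, in fact share their hardest subproblem:
locating and aligning region boundaries.

`esdreg` couples both tasks through the **exponential signed distance
representation (ESDR)**. For a labelled volume, each voxel carries the exact
Euclidean distance d(x) to the nearest boundary of its own region (background
is a region too), and

```
ESDR(x) = exp(-γ · d(x)),   γ = 1
```

so boundaries map to exactly 1 and interiors decay towards 0. The ESDR
depends only on geometry — never on intensities — making it modality
independent by construction, and the exponential concentrates gradient at
the boundaries both tasks care about.

Three networks share it: a 3D U-Net **G** regresses raw images to predicted
ESDR; a registration network **R** maps a concatenated (fixed, moving) ESDR
pair to a displacement field φ (the warped value at p samples the moving
volume at p + φ(p), trilinear for intensities, nearest-neighbour for
labels); a segmentation network **S** maps one ESDR to per-voxel class
probabilities. Training is two-stage: G, S, R are first pre-trained
separately against ground-truth ESDR (Huber regression for G; soft Dice for
S; for R a total loss `L = α·MSE(ESDR_f, W(ESDR_m, φ)) + β·‖∇φ‖² +
ρ·(1 − Dice(labels))` with α = β = ρ = 1), then the coupled G-R and G-S
branches are fine-tuned alternately on G's *predicted* ESDR. Evaluation
reports per-structure Dice (%) and the folding fraction — the percentage of
voxels with non-positive Jacobian determinant of the deformation map
p + φ(p).

The package is self-contained scientific R: the differentiable 3D
convolution / warping / normalization kernels are implemented in
RcppArmadillo with hand-derived, finite-difference-verified gradients, and
all experiments run on seeded multi-modal brain phantoms with known
ground-truth deformations (no data downloads). See the methods vignette
(`vignettes/esdr-coupled-registration.Rmd`) for the model, the phantom
design and its calibration, and every numerical choice.

## Worked example

```r
library(esdreg)

# a multi-modal phantom pair: same geometry, two "modalities",
# known smooth ground-truth deformation (max 3 voxels)
spec <- phantom_spec(shape = c(32, 32, 32), n_regions = 4,
                     deform_amplitude = 3, deform_smoothness = 13, seed = 0)
pr <- default_presets(4)
pair <- make_pair(spec, pr$A, pr$B)

# the representation both branches consume
esdr <- esdr_from_labels(pair$fixed_labels, gamma = 1)
range(esdr)
#> [1] 5.265959e-07 1.000000e+00

# how misaligned is the pair before registration?
dsc_percent(pair$moving_labels, pair$fixed_labels)$mean_dsc
#> [1] 74.76287

# the ground-truth field is folding-free
folding_fraction(pair$truth)
#> [1] 0
```

`run_coupled_experiment()` wraps the whole study: phantom generation,
two-stage training, and evaluation. At the package's scaled test conditions
(8 pairs of 32³ voxels, K = 4 regions, reduced widths and epochs; ~11 min
on one core) the full scheme lifts mean foreground registration Dice from
75.7% (unregistered baseline) to 91.8% with zero folding, and segments
held-out phantoms of both modalities at 89.4% mean Dice through the G→S
pipeline — numbers recomputed by the acceptance script below.

A thin command-line interface (`exec/esdreg`) exposes phantom generation,
ESDR computation, the training stages, registration, segmentation and
evaluation as subcommands; every run directory records its resolved
configuration and a JSONL metric log.

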