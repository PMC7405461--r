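---
title: "Single-volume super-resolution for whole-heart bSSFP MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-volume super-resolution for whole-heart bSSFP MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Whole-heart balanced steady-state free precession (WH-bSSFP) imaging trades
spatial resolution against scan time: halving the phase- and slice-encode
resolution roughly halves the acquisition, at the cost of blurred vessel
borders and partial-volume errors in diameter measurements. Super-resolution
reconstruction (SRR) recovers high-resolution structure from a single
low-resolution magnitude volume as a post-processing step, so the patient
spends less time in the scanner while the reader keeps sharp anatomy.

`cardiosr` implements the full experimental loop for this idea in R:

1. **`phantom`** — seeded synthetic 3D volumes with WH-bSSFP-like contrast
   (bright blood pool and vessels, intermediate myocardium, dark noisy lung),
   with ground-truth region masks and vessel probes;
2. **`degrade`** — the Fourier-domain low-resolution simulator that
   manufactures aligned low/high-resolution training pairs;
3. **`model`** — a 3D residual U-Net;
4. **`train`** — the L1/ADAM whole-volume training recipe;
5. **`metrics`** — SSIM, MSE, vessel edge sharpness, eSNR/eCNR, an FWHM
   vessel caliper, and Bland-Altman agreement;
6. **`harness`** — validation, the resolution-generalisability sweep, and a
   fully seeded end-to-end pipeline.

Everything runs on synthetic phantoms: no clinical data, scanner, or GPU is
required, and every stage is reproducible from one master seed.

## The degradation model

Low-resolution volumes are simulated in k-space. The high-resolution volume
is (optionally) standardised to a fixed matrix by centered crop/pad, Fourier
transformed, and the outer part of k-space along the phase-encode (y) and
slice-encode (z) axes is zeroed; the frequency-encode (x) axis is never
masked. Partial Fourier is simulated as *additional asymmetric zeroing*: of
the retained central band, the highest-positive-frequency lines are removed
so that `round(pf * f * N)` lines survive on an axis of `N` samples with
retained fraction `f` and partial-Fourier fraction `pf`. The masked k-space
is inverse transformed, the magnitude taken (zero-filled reconstruction; no
homodyne or POCS phase correction), optionally cropped in-plane, and min-max
normalized to [0, 1]. The high-resolution partner of a training pair
receives the same crop and its own independent normalization, so pairs stay
voxel-aligned.

Numerical conventions, fixed once:

* **Centering.** DC sits at 0-based index `floor(N/2)` after `fftshift`;
  "central band" is defined in that convention.
* **Even-count tie-break.** A band of `k` retained lines spans indices
  `floor(N/2) - ceiling(k/2)` … `floor(N/2) + floor(k/2) - 1`: DC is always
  kept and the extra line goes to the negative-frequency side.
* **Partial-Fourier side.** The removed lines come off the
  positive-frequency end of the *retained band* (configurable via
  `pf_side`). Reading the zeroing as relative to the band (not the full
  matrix) matches an acquisition that collects `f * N` lines at 6/8 partial
  Fourier.
* **Minimum-line rule.** A mask that would retain fewer than 4 lines on an
  axis is an error; the generalisability sweep skips such fractions with a
  warning and records them in its provenance.
* **Degenerate normalization.** A constant volume cannot be min-max scaled;
  `normalize01()` maps it to zeros with a warning rather than an error.

`upsample_to_grid()` interpolates a coarse volume onto a finer grid covering
the same field of view by zero-padding the centered spectrum (sinc
interpolation), then taking the magnitude and renormalizing. This is the
package's stated choice for feeding prospectively low-resolution volumes to
a network trained on a finer grid; scanner-side zero-filling would be
equivalent up to implementation detail.

## The network

The model is a 3D residual U-Net: an encoder/decoder with `levels`
resolution scales, `convs_per_level` 3×3×3 convolutions per scale (ReLU
nonlinearities), channel counts doubling per scale from `base_channels`,
2× max-pool downsampling, nearest-neighbour upsampling followed by a 3×3×3
convolution, and skip connections by channel concatenation. The final
convolution produces a single-channel *residual* with no nonlinearity; the
residual is added to the input and the sum projected non-negative by a
ReLU, since magnitude MR images cannot be negative. Setting
`residual = FALSE` yields the plain U-Net comparator, and `loss = "l2"` the
squared-error comparator objective.

Choices the architecture description leaves open, and what this package
does:

* **Channel counts**: default 16 → 32 → 64 over three levels, configurable.
  Desk-scale experiments use two levels at 8 base channels (21k parameters)
  to keep a full training run in minutes on one CPU.
* **Resampling operators**: max-pool down, nearest-neighbour + convolution
  up. These are conventional; strided/transposed convolutions would be
  drop-in alternatives.
* **Initialisation**: seeded He-uniform (`bound = sqrt(6 / (27 * c_in))`),
  biases zero. Identical seeds give bit-identical networks.
* **Shape handling**: inputs whose axes are not divisible by
  `2^(levels-1)` are symmetrically zero-padded and cropped back, so
  `super_resolve()` preserves shape exactly.

The convolution forward/backward passes are implemented in C++
(im2col + BLAS matrix products, cache-blocked along the slice axis) with
analytic gradients; the test suite verifies them against finite differences.

## Training

`fit()` follows the reference recipe: minimise the mean absolute voxel
difference (L1) between the network output and the ground-truth volume with
ADAM (learning rate 1e-3, moments 0.9/0.999, epsilon 1e-8), batching two
whole volumes per step — no patch extraction — with seeded per-epoch
shuffling. The reference recipe runs 200 epochs on 500 clinical volumes;
desk-scale runs use 30 epochs on 8 phantom pairs at 48³ voxels through the
same code path. Constant learning rate, no augmentation, no early stopping;
an optional validation split reports per-epoch SSIM/MSE. Two runs with the
same dataset, configurations and seeds produce bit-identical loss traces
and weights.

## The phantom generator

`generate_phantom()` emulates the *contrast structure* of WH-bSSFP data
rather than anatomy: a blood-pool ellipsoid (intensity 0.9) wrapped in a
myocardial shell (0.5), bright cylindrical/curved vessels (0.9–0.95,
diameters 6–8 mm), and a dark lung background (0.1) with additive Gaussian
noise (sd 0.02) applied before the magnitude operation and a low-order
(linear + quadratic) multiplicative bias field (5% amplitude). Structure
borders are rendered with analytic partial-volume occupancy (3× supersampling
per axis), which is what makes edge-sharpness and FWHM measurements
meaningful at 1.6 mm voxels. The rationale: a network of this size learns
generic features — contrast and vessel edges — so geometric phantoms
exercise the same mechanism as anatomy.

Defaults were chosen once to mimic published bSSFP contrast ratios
(blood ≈ 9× lung, ≈ 1.8× myocardium) and are exposed in `phantom_spec()`
rather than asserted as clinically faithful. What the phantoms do *not*
contain: anatomy-scale texture, motion or flow artefacts, Rician noise
statistics (noise is Gaussian before the magnitude, recorded as such),
coil-sensitivity modulation beyond the polynomial bias, or arrhythmia-like
inconsistency. Tests passing on phantoms therefore demonstrate the
pipeline's correctness and the mechanism of resolution recovery, not
clinical performance.

Each vessel carries a `vessel_probe` at its centreline midpoint. The probe
plane is the vessel *cross-section*: its normal is the local centreline
tangent, so the 60 radial rays sweep around the vessel border. (Stating
this precisely matters — a plane *containing* the axis would cut the vessel
lengthwise and measure nothing useful.)

## Metrics

* **MSE** — mean squared voxel difference of normalized volumes.
* **SSIM** — volumetric, with a separable 3D Gaussian window (σ = 1.5
  voxels, 11³ support), constants K1 = 0.01, K2 = 0.03, data range 1.0,
  averaged over the interior where the window fits. Parameters are
  configurable; the implementation is validated against a brute-force
  windowed reference.
* **Edge sharpness (mm⁻¹)** — per ray: trilinear profile sampling, per-ray
  min-max normalization, maximum absolute forward difference divided by the
  step. Flat rays are excluded with a warning (all flat is an error). The
  per-ray normalization makes the metric invariant to global affine
  intensity rescaling.
* **eSNR / eCNR** — mean blood / mean lung and mean blood / mean
  myocardium intensity ratios, exactly as the quantities are defined for
  mid-thoracic ROI measurements; an sd-based denominator is deliberately
  not the default.
* **FWHM caliper (mm)** — two perpendicular diameters in the probe plane;
  half-maximum thresholds referenced to the *central lumen* level (profile
  peak within half the expected radius) and the profile minimum as
  background, with linear sub-sample crossing interpolation. Referencing
  the lumen rather than the global profile maximum keeps Gibbs overshoot at
  truncation-blurred borders from inflating the threshold and biasing the
  caliper low. Stated precision is half a voxel.
* **Bland-Altman** — bias = mean paired difference, limits of agreement
  bias ± 1.96 × sd (sample sd, n − 1).

## Desk-scale experiments and what they show

The bundled experiments (test suite and `scripts/acceptance.R`) run, on one
CPU in minutes: 8 training + 4 held-out phantoms at 48³ voxels (1.6 mm
isotropic), degradation at 50% phase/slice resolution with 6/8 partial
Fourier, a two-level 8-channel residual U-Net trained 30 epochs. At these
sizes the trained network raises held-out SSIM by ≈ 0.02 and lowers MSE
against the ground truth — a scaled-down analogue of the full-size
behaviour, produced by the identical code path.

Known limitations of the desk scale:

* Thirty epochs on eight volumes leaves the network far from convergence.
  Its improvement at the training resolution is modest, so in the
  resolution-generalisability sweep the *damage* it does to
  sharper-than-training inputs (over-sharpening) may not yet outweigh the
  intrinsic advantage of those inputs; the full-size
  resolution-specificity peak emerges with longer training.
* For the same reason the desk network over-sharpens vessel borders, which
  can erode FWHM diameters below their high-resolution values instead of
  merely undoing blur-driven overestimation.
* K-space truncation is a Dirichlet (sinc-like) blur with negative side
  lobes: unlike Gaussian blur, it can *shrink* the half-max width of a
  finite bright rod by a few hundredths of a millimetre. The caliper tests
  therefore compare widths at the caliper's own half-voxel precision.

## Data formats

Volumes and label maps travel as NIfTI-1 (`RNifti`), with voxel spacing in
the header. Paired datasets are archived as a directory of NIfTI files plus
JSON sidecars (probes, seeds) and a JSON manifest carrying the complete
generating configuration — sufficient to regenerate the archive
bit-identically. The end-to-end runner writes a manifest, JSON-lines log,
CSV loss trace, RDS checkpoint, and CSV/JSON reports; `run_from_manifest()`
reproduces a run exactly.

## A worked example

```{r example}
library(cardiosr)

deg <- degradation_spec()              # 50% phase/slice, 6/8 partial Fourier
trainset <- make_dataset(phantom_spec(), n = 8, seed = 101, deg, role = "train")
testset  <- make_dataset(phantom_spec(), n = 4, seed = 202, deg, role = "test")

fit_res <- fit(trainset,
               network_config(levels = 2, base_channels = 8, seed = 11),
               train_config(epochs = 30, seed = 12))

val <- validate(fit_res$network, testset)
val                                     # cohort SSIM/MSE before and after SRR
tidy(val)                               # per-subject table

sw <- generalisability_sweep(fit_res$network, testset,
                             seq(0.3, 0.9, by = 0.2), deg)
autoplot(sw)                            # SSIM vs input resolution fraction
```
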