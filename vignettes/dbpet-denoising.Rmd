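---
title: "Denoising dedicated breast PET at reduced emission time: models, simulator and evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Denoising dedicated breast PET at reduced emission time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Ring-type dedicated breast PET (dbPET) images a single prone breast with a
small detector ring at sub-millimetre resolution. Two properties of these
scanners shape everything in this package. First, image noise falls with the
number of detected counts, so halving the emission time (3 minutes instead
of 7) visibly degrades image quality. Second, detector sensitivity drops
towards the axial ends of the field of view (FOV), so noise is worst near
the chest wall and the nipple-side edge, not uniform across the volume.

`dbpetdn` implements a supervised denoising approach for this setting: a
residual convolutional network trained on paired low-count (LC, 3 min) and
full-count (FC, 7 min) reconstructions of the same acquisitions, so that at
inference time an LC volume can be mapped towards FC image quality. Two
conventional post-filters — a Gaussian filter and a 2-d non-local means
(NLM) filter — serve as comparators, and an FC volume smoothed with the same
Gaussian kernel serves as the reference image set. The package also
implements the full quantitative evaluation protocol (ROI placement, SUV and
coefficient-of-variation statistics, Bland–Altman agreement, paired tests)
and a synthetic phantom simulator that stands in for patient data, which is
rarely shareable in this domain.

## The denoising network

The network maps a single 2-d axial slice in raw SUV units to a denoised
slice. It is a plain convolutional stack with an identity skip connection:

* `n_conv_layers` (default 5) convolutions with "same" zero padding;
* every layer except the last has `n_filters` channels, each followed by
  batch normalisation and a PReLU activation (one learnable negative slope
  per channel, initialised at 0.25);
* the final convolution projects to 1 channel with no activation, and its
  output is **added to the input**: the network learns the residual FC − LC
  rather than the FC image itself.

At full scale the architecture uses 15 × 15 kernels and 128 filters; large
kernels buy receptive field without the down/up-sampling of U-Net-style
models, which matters at dbPET's resolution where resampling blur is
unacceptable. Training minimises the mean squared error against the FC slice
with Adam (learning rate 0.001, batch size 16), reserving 10% of slices for
validation. Slices containing only air are kept in the training set; a
denoiser deployed on whole volumes will see such slices too.

Design choices the architecture description leaves open were resolved as
follows and are recorded in the model configuration rather than asserted as
the only possibility:

* **Output layer width.** Every hidden layer has `n_filters` channels, but
  the output must be a 1-channel image; the final convolution therefore has
  a single filter.
* **Identity initialisation.** The final convolution is zero-initialised
  (hidden layers use seeded He initialisation), so an untrained network is
  exactly the identity map. This gives residual learning a neutral starting
  point and a sharp, testable contract: with `epochs = 0` the whole pipeline
  must reproduce its LC inputs bit-for-bit (to single precision).
* **Intensity handling.** Slices are fed in raw SUV units with no rescaling.
  Batch normalisation after every hidden convolution makes the network
  robust to the absolute scale.
* **Inference determinism.** Batch normalisation uses running statistics
  (momentum 0.1, epsilon 1e-5) accumulated during training, so inference is
  deterministic and batch-size independent.
* **Fully convolutional.** Only kernels, BN and PReLU appear, so any slice
  size is accepted at inference; the configured `input_shape` is provenance,
  not a constraint.

The numerical engine is the package's own: im2col + single-precision BLAS
GEMM convolutions with exact analytic gradients (verified against finite
differences in the test suite), fused batch-norm/PReLU kernels, and a plain
Adam implementation. Single precision is used for the convolutions because
it doubles throughput on one CPU core and the contracts tested here (identity
at initialisation, training progress) are insensitive to it.

## The comparison filters

**Gaussian.** Separable convolution with the kernel implied by
`fwhm = 2 sqrt(2 ln 2) * sigma`; the default FWHM of 1.17 mm matches the
post-smoothing used for clinical dbPET reference images. The kernel is
truncated at 4 sigma and renormalised to unit sum, so constant images are
exact fixed points. It is applied along all three axes by default (common
PET practice; the voxels are isotropic) with an `axes = "2d"` in-plane
option, and boundaries are handled by symmetric reflection.

**Non-local means.** Slice-wise 2-d NLM with a 3 × 3 patch and 5 × 5 search
window. Each output pixel is a convex combination of its search window with
weights `exp(-D^2 / h^2)`, where `D^2` is the squared Euclidean patch
distance normalised by the number of patch pixels. The filtering strength
`h` is the noise scale; following the protocol this package reproduces, the
pipeline sets it to the pooled standard deviation of background
fibroglandular tissue measured on the LC image being filtered. Two
conventions that differ between published NLM implementations are exposed as
options rather than guessed silently: the centre pixel's weight (keep its
zero-distance weight of 1, the default, or replace it with the maximum
neighbour weight) and the patch weighting (uniform, the default, or a
Gaussian profile over the patch). Sample standard deviations (n − 1) are
used everywhere in the package, including here.

## The phantom simulator

Patient dbPET volumes are not distributable, so the package generates
synthetic paired acquisitions whose *noise behaviour* — the property the
evaluation protocol actually measures — matches the physics:

1. **Anatomy.** A half-ellipsoid breast attached to the chest-wall edge of
   the in-plane grid (row 1), mimicking prone dbPET geometry so that
   "FOV-edge" ROIs are meaningful. Inside it, a seeded smooth Gaussian
   random field is thresholded at `gland_fraction` to split the volume into
   fibroglandular tissue (SUV 1.18, a typical clinical background level) and
   fat (SUV 0.30). The texture length (`gland_texture_sigma`, voxels) sets
   the size of gland blobs; the scaled-down 64 × 64 configuration uses 6
   voxels so that 8-mm background ROIs fit inside gland regions.
2. **Lesions.** FDG-avid uptake regions inserted as uniform spheres
   ("focus" ≤ 10 mm, "mass" larger), with an optional Gaussian edge blur
   (off by default — no partial-volume model is claimed). The default
   sampler draws the uptake-type mixture and SUV levels seen in clinical
   dbPET series: about 27% focus lesions (SUV ≈ 2.84 ± 0.85) and 73% mass
   lesions (SUV ≈ 12.61 ± 8.05).
3. **Acquisition.** Per voxel, expected counts are
   `activity × duration × sensitivity(z) × counts_per_suv_min`; a Poisson
   draw is rescaled back to SUV. The simulated volume is unbiased for the
   activity and its voxel variance is `activity / (duration × sensitivity ×
   counts_per_suv_min)` — noise scales as `1/sqrt(duration)` (so the
   LC-to-FC CV ratio is `sqrt(7/3) ≈ 1.53`) and rises towards the axial FOV
   edge. The sensitivity profile is a half-sine arch from `edge_min`
   (default 0.5) at the first/last slice to 1 at the axial centre; no
   quantitative profile of any particular scanner is claimed, and both
   `edge_min` and the profile shape are free parameters.
4. **Calibration.** `counts_per_suv_min = 15` was chosen once so that a
   7-minute simulation of SUV-1.18 gland at full sensitivity has a voxel CV
   of `1/sqrt(1.18 × 7 × 15) ≈ 9%`, a realistic reference-image noise level
   for this scanner class. It is a calibration default, not a fit.

What the simulator deliberately does **not** model: list-mode acquisition
and iterative reconstruction (noise here is voxelwise independent by
default; reconstructed PET noise is spatially correlated — a Gaussian
pre-smoothing of the noise field is available as a knob,
`noise_smooth_sigma`, and is off by default), scatter and attenuation,
anatomical realism, and lesion partial-volume effects. Consequently,
passing tests show that the *method* behaves correctly under the stated
noise physics (duration scaling, edge elevation, unbiasedness); they do not
certify performance on clinical reconstructions.

## The evaluation protocol

* **Background noise.** Five circular 2-d ROIs of 8 mm diameter per breast
  on background fibroglandular tissue, on five different slices pairwise at
  least 5 slices apart. A pixel belongs to a circle when its centre lies
  within the radius. For each ROI, `SUVmean`, the sample SD, and
  `CV = SD / SUVmean × 100%`.
* **Edge noise.** Five 10 × 30-pixel rectangles whose near edge sits exactly
  5 pixels from the chest-wall border of the in-plane FOV, confined to
  tissue. Because the simulator's sensitivity loss runs along the slice
  axis, these rectangles are drawn from the first/last `edge_band` (default
  12) slices so that they actually sample the elevated-noise region.
  Placement of both ROI families is automated and seeded; the protocol being
  reproduced used manual placement, so the feasibility constraints (interior
  circles, gap rule, lesion avoidance) encode the stated geometry instead.
* **Lesions.** `SUVmax` is the maximum over a 3-d VOI (ties broken by lowest
  (slice, row, col)); `SUVpeak` is the mean of a fixed 10-mm circular 2-d
  ROI centred at the maximum pixel. A peak ROI that would leave the grid is
  an error rather than a silent clip.
* **Agreement.** For each target set (LC, LC+Gaussian, LC+NLM, LC+DL)
  against the FC+Gaussian reference, relative differences
  `d = (SUVtgt − SUVref)/SUVref × 100%` per lesion, summarised by the
  Bland–Altman bias (mean of d) and limits (1.96 × SD of d). The report
  labels the latter "limits" — it is the half-width of the limits of
  agreement around the bias, not a variance in the statistical sense.
* **Tests.** Background CV comparisons use paired t-tests, lesion SUV
  comparisons use Wilcoxon signed-rank tests, both two-sided with a
  Bonferroni correction over the 4 target-vs-reference comparisons
  (`p_adj = min(1, 4 p)`), significance at 0.05. All-zero difference
  vectors are reported as degenerate rather than tested. Because the
  open question of per-patient versus pooled aggregation has no stated
  answer, the report keeps the per-ROI table so either aggregation can be
  recomputed.
* **Display.** Craniocaudal/mediolateral maximum intensity projections with
  an inverse-grayscale SUV window of 0–4.

## The experiment pipeline and its scaled-down defaults

`run_experiment()` wires the stages together: simulate training and test
phantoms (separated at phantom level, mirroring patient-level separation),
train the network on all axial slices of the training phantoms, produce the
five image sets per test phantom, and evaluate. The FC reference uses the
same 1.17-mm Gaussian as the LC comparator. All randomness flows from four
explicit seeds (`simulate`, `split`, `train`, `rois`); reruns with the same
configuration are bit-identical because every component, including the
network training, is deterministic on a given machine.

The default configuration is an intentionally scaled-down study sized for a
single CPU: 64 × 64 slices, 40 slices per phantom, 8 training + 4 test
phantoms (320 training slice pairs), a 5-layer network with 7 × 7 kernels
and 16 filters, 15 epochs. These sizes preserve the full-scale experiment's
structure — same pipeline, same statistics, same image-set comparisons —
at roughly 1/400 of the training compute. Full-scale values remain one
`phantom_spec()`/`denoiser_config()` call away.

On the scaled-down defaults the expected qualitative outcome, asserted by
the package's tests, is the headline ordering: mean background CV of LC+DL
below LC, and the magnitude of the mean relative SUVmax difference against
the noise-free truth no worse for LC+DL than for LC.

## Numerical conventions and degenerate inputs

* Sample SD (n − 1 denominator) everywhere; CV of a zero-mean ROI is
  reported as `NA`, not an error.
* Symmetric (edge-duplicating) reflection pads both filters.
* The Gaussian kernel is truncated at `ceiling(4 sigma)` taps per side and
  renormalised; `fwhm = 0` is the exact identity.
* Poisson simulation of a zero-activity voxel is exactly 0 for any duration.
* Infeasible ROI constraints (too few eligible slices under the gap rule)
  raise errors naming the violated constraint.
* Seeds are single integers; every function that consumes randomness
  restores the caller's RNG state.

## Known limitations

* Voxelwise-independent noise is a simplification of reconstructed PET
  noise; the CV *ratios* between durations and the edge/centre contrast are
  faithful, absolute CV values depend on the `counts_per_suv_min`
  calibration.
* The network is 2-d; 2.5-d/3-d inputs, SSIM/perceptual losses, and
  dilated-convolution variants are out of scope.
* Visual scoring (four-point scales, inter-reader kappa) is not modelled —
  only the objective metrics are computed.
* The scaled-down experiment demonstrates direction of effect, not clinical
  effect sizes; its CV values are not comparable to full-scale numbers.
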