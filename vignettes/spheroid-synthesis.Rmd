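---
title: "Synthesizing and evaluating 3D cell-culture microscopy volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesizing and evaluating 3D cell-culture microscopy volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheroidsim)
```

## The problem

Confocal stacks of 3D cell cultures (spheroids, organoids) are hard to
annotate: resolution along z is several-fold coarser than in-plane, object
boundaries smear out with depth, and both brightness and sharpness decay
as the excitation and emission light traverses more occluding tissue
above the focal plane. Deep segmentation models need exactly such labeled
3D data. `spheroidsim` therefore generates image/label pairs by
simulation: the labels are exact by construction, and the image is a
model of how a confocal microscope would have recorded that scene.

This vignette describes the model, its assumptions, the tunable
parameters, the synthetic fixtures used for verification, and the
numerical choices made where the design was genuinely open.

## Pipeline

### Nucleus database

A small set of nucleus prototypes — intensity patch plus binary mask,
tight bounding box, intensity zero outside the mask — seeds the database.
Prototypes can be extracted from a labeled recording
(`extract_prototype()`) or generated as textured ellipsoids
(`make_ellipsoid_prototype()`). Offline augmentation
(`augmentation_config()`) expands each prototype into
`variants_per_prototype` variants (default 32, so ten annotated nuclei
yield a 320-entry database):

* **rotation** (default 0–360°) and **isotropic scale** (0.85–1.15), in
  the (y, x) plane only. Free 3D rotation would be unrealistic: the axial
  extent of a confocal voxel is an order of magnitude larger than the
  lateral one, so nuclei are effectively observed in a fixed axial
  orientation. Intensity is resampled bilinearly, the mask with nearest
  neighbor, and the result re-cropped tight.
* **elastic deformation**: a coarse random displacement grid (spacing
  `elastic_spacing`, default 8 px; amplitude 0–1.5 px) upsampled
  bilinearly to voxel resolution, again in-plane.
* **blur** (in-plane Gaussian, σ up to 0.8 px) and **contrast/gamma** on
  intensities normalized to [0, 1] within the prototype, which keeps both
  parameters unit-free.

At placement time only cheap *online* augmentation runs: independent
axis flips and an optional y↔x swap — exact index permutations, so
foreground voxel counts are preserved and mask and intensity transform
identically.

### Shape mask and placement

`generate_spheroid_mask()` produces the culture outline: a voxel belongs
to the mask iff its normalized radial coordinate is below
`1 + a·f`, where `f` is a smooth random field (coarse Gaussian control
grid, trilinear upsampling, unit variance) and `a` the relative
perturbation amplitude (default 0.08). Amplitude 0 gives the exact
discrete ellipsoid, independent of the seed.

`place_nuclei()` repeats: draw a prototype (online augmentation), draw a
box corner uniformly over all in-bounds positions, accept iff the
prototype mask lies inside the culture mask and touches no existing
nucleus (optionally dilated by `min_gap`, Chebyshev metric — cheap and
separable). Acceptance stamps intensity and the next instance id;
`max_consecutive_failures` rejected attempts in a row terminate the loop
(default 1000; around 50 leaves visible holes, a few thousand fills the
culture evenly). Uniform corner sampling is the simplest unbiased
scheme; positions are *not* restricted to mask voxels before the validity
test. Instance supports are pairwise disjoint by construction.

### Imaging model

Stages run in a fixed order; each has a disable flag for ablation.

1. **Brightness attenuation.** The occlusion depth `i(z,y,x)` counts
   shape-mask voxels *strictly above* a voxel in its (y, x) column
   (exclusive, so the top surface keeps `b = 1`; the mask — not the
   nucleus labels — defines the occluding material, at simulation
   resolution). Each voxel is multiplied by
   `b = clamp((i/p + 1)^-6, 0, 1)`. For `i ≥ 0`, `p > 0` the raw power
   already lies in (0, 1], so the clamps are inert safeguards; the
   exponent −6 is treated as fixed. `p` (default 150) models clearing
   quality: larger `p`, slower decay.
2. **PSF convolution.** 3D convolution with a unit-sum kernel —
   a measured PSF from TIFF or an anisotropic Gaussian
   (`psf_sigma_um`, default (1.8, 0.3, 0.3) µm, elongated along z as
   real confocal PSFs are). Borders are reflect-padded to avoid dark
   halos. `depth_varying` mode convolves with several anchored kernels
   and interpolates per slice, emulating depth-dependent blur. Kernels
   are renormalized to unit sum on load (warning above 1% deviation).
   The convolution is implemented in the correlation (filtering)
   orientation; for the symmetric kernels used as PSFs the distinction
   is immaterial. Optionally the *labels* are enlarged with the same
   kernel (`psf_enlarge_labels()`): each instance mask is convolved and
   re-thresholded at a fraction of its own peak response, contested
   voxels go to the stronger instance, original voxels are always kept —
   mimicking the apparent size increase a human annotator would trace.
   Label enlargement runs before downsampling.
3. **Downsampling.** Gaussian prefilter (σ = (ratio − 1)/2 per axis)
   plus trilinear interpolation at the coarse voxel centers; output shape
   is `floor(extent/target)`. Non-integer ratios (the default profile's
   z ratio is 5/3) are handled by interpolation rather than block
   averaging. Labels use nearest neighbor without prefilter; an instance
   smaller than an output voxel can in principle vanish there, which is
   accepted and checked only as "never more instances than before".
4. **Poisson noise,** applied after downsampling:
   `out = Poisson(gain · in)/gain`, independent per voxel. `gain` is
   photons per intensity unit; larger gain, relatively less noise.

The default profile simulates at 0.9 × 0.122 × 0.122 µm voxels and
downsamples to 1.5 × 0.489 × 0.489 µm, with `p = 150`, no nucleus
enlargement and no placement gap.

### Patch transform

Learned refinement models operate on GPU-sized patches, which loses
global context and risks visible seams. `plan_patches()` tiles the
volume with overlapping patches (stride `patch − 2·trim`) and keeps only
the trimmed interior of each transformed patch — except at volume faces,
where there is no neighbor to take over. Retained regions tile the
volume exactly once; no averaging, so the transform's noise statistics
survive reassembly. `transform_volume()` applies any patch-shaped
operator (identity by default) and is exactly lossless for the identity
— the testable core of the seam-avoidance claim. The learned model
itself is out of scope; the contract accepts any external operator.

## Quality measures

**Region-split normalized Wasserstein.** Intensity histograms are
compared per z-slice in three disjoint regions: background outside the
culture mask, background inside, and nucleus foreground (labels dilated
by `dilation_radius`, default 1, to absorb PSF-blurred borders, then
intersected with the mask). The split prevents the score from depending
on cell density. For each region/slice,
`W_norm = 1 − W(p_real, p_syn)/W(p_real, p_black)` with `p_black` a
point mass at zero; `W` is the exact empirical first-order Wasserstein
distance (area between empirical CDFs, no binning). `W_norm = 1` iff the
distributions coincide; values below 0 (synthetic farther from real than
black) are reported unclamped. Slices whose real-side region is entirely
zero are excluded and logged. For real recordings, the caller supplies
the mask/labels (e.g. from an external segmentation).

**q95 edge-quality depth profile.** Per slice: 2D Gaussian smoothing
(σ = 3 px — large enough that the edge response measures
foreground/background contrast, not noise) followed by Sobel gradient
magnitude. The plane is tiled into non-overlapping sections (default
100 × 100 px, anchored at the origin, border remainders dropped; the
anchoring convention is a free choice). Per section and slice the 95%
quantile of the edge image is taken. Because the culture is roundish,
each section's foreground starts at a different depth, so sections are
aligned at their own peak slice (`d = i − argmax`) before averaging.
Sections with peak response below `t_b` (default 1% of the largest
response a full-range step could produce, i.e. `0.04 · max(image)`) show
only background and are dropped, as are sections whose peak lies deeper
than `t_r` (default 20) slices — unreliable alignments. The profile
value at aligned depth `d` averages the retained sections that *possess*
that `d` (sections span different d-ranges after alignment; normalizing
by the total retained count instead would down-weight edge depths —
this choice keeps the profile an unbiased mean at every `d`).

**Exact paired Wilcoxon.** Zero differences are discarded before
ranking, ties receive mid-ranks, and the one-sided p-value comes from
the exact null distribution of the positive-rank sum. The distribution
is built by convolution over the (doubled, hence integer) rank values —
mathematically identical to enumerating all 2^n sign vectors (verified
against such an oracle in the tests) but usable at realistic sample
sizes (hundreds of paired slices), where naive enumeration is
impossible.

**Detection (DET/AOGM).** Ground truth is center points, not masks:
each center maps to the predicted label at its (rounded half-up) voxel.
False negatives (centers on background), required splits (extra centers
in one label) and false positives (labels without centers; false splits
are folded in here, as the measure does not separate them) combine as
`AOGM_D = 5·ns + 10·fn + 1·fp`, normalized by the build-from-scratch
cost `10 · #centers`: `det = 1 − min(AOGM_D, AOGM_D0)/AOGM_D0`.

## Synthetic fixtures, and what the tests do and do not show

All test inputs are generated in code. `make_ellipsoid_prototype()`
provides textured ellipsoid nuclei; `make_degraded_pair()` builds a
matched pair over identical labels where the "degraded" volume has extra
in-plane blur and *less* noise inside the culture — the characteristic
signature of a too-clean simulation — so the metrics must rank the pair
correctly by construction. Fixture scale is capped (≤ 64 × 256 × 256
voxels; the full-scale verification run uses exactly that, with a
320-entry database and the default placement/imaging profile) so the
suite runs on a single CPU in minutes. These fixtures reproduce the
*statistical* structure the measures respond to — depth-dependent
dimming and blur, region-localized distribution gaps — but not the
visual appearance of real DAPI-stained spheroids: textures are smooth
random fields, shapes are perturbed ellipsoids, and the PSF is Gaussian.
Passing tests therefore validate the machinery and its contracts, not
photorealism.

## Numerical choices and limitations

* Axis convention `(z, y, x)` everywhere; TIFF page order is z. File
  coordinates (center CSVs) are 0-based; R-side array indexing is
  1-based and documented per function.
* Intensities are never rescaled on load; integer TIFF encodings
  round-trip exactly, float32 via an IEEE-float writer. Writing
  fractional values to integer encodings requires an explicit rounding
  flag.
* All randomness flows from one top-level seed through named substreams
  (mask, placement, noise, …), so stages are independently reproducible;
  identical config + seed reproduce integer outputs bytewise.
* FFT-based convolution can leave tiny negative round-off values; they
  are clamped to zero.
* Known limitations: no mitotic or otherwise atypical nucleus shapes
  beyond what the database contains; no spatially varying PSF coupled to
  the brightness field; no autofluorescence or background gradients;
  structured cell arrangements (e.g. epithelial layers) cannot arise
  from uniform random placement.
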