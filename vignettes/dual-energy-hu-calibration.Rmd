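---
title: "Dual-energy CBCT HU calibration and cross-modality agreement: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-energy CBCT HU calibration and cross-modality agreement: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Background

Voxel values of dental cone-beam CT (CBCT) are notoriously inconsistent with
the Hounsfield scale: limited tube current, detector efficiency and scatter
make the reconstructed numbers device- and position-dependent, which
undermines their use for jaw bone-density assessment in implant planning.
One hardware answer is dual-energy (DE) acquisition: the same anatomy is
reconstructed twice, at a low and a high tube voltage, and the two raw value
channels are combined voxel-by-voxel into a calibrated Hounsfield-unit (HU)
volume. `decbct` implements that calibration, the machinery needed to
validate it against multidetector CT (MDCT) — rigid registration, transfer of
cylindrical regions of interest (ROIs) between image spaces, ROI statistics —
and the agreement analysis (identity-line deviation bands and Bland–Altman
limits of agreement). A synthetic phantom generator with exact ground truth
drives the test suite end to end.

## The calibration model

The unit of calibration is not the voxel but the *region mean*. A physical
calibration phantom — an acrylic base holding hydroxyapatite (HA) inserts of
known density plus an air region — is scanned at both energies, and each
region `r` contributes a point
$(\bar{x}_r^{\,low}, \bar{x}_r^{\,high})$ in the plane of (low-kVp, high-kVp)
mean values. The model has two stages:

1. **Density line.** A straight line is fitted through the region points.
   Because both coordinates are noisy measurements, the default fit is total
   least squares (orthogonal regression): the line passes through the
   centroid $p_0$ with direction $u$ equal to the first principal axis of
   the points, minimizing the orthogonal residual sum of squares. An
   ordinary regression of high on low is available
   (`fit_density_line(..., method = "ols_high_on_low")`) for comparison.
2. **HU map.** Any value pair $x = (low, high)$ is orthogonally projected
   onto the line, giving the scalar coordinate $t = u \cdot (x - p_0)$ —
   the density surrogate. An affine map $HU = a\,t + b$ is then fitted by
   ordinary least squares to the regions of known HU (air at $-1000$ and
   the HA inserts by default).

Calibration of a volume pair is then the voxel-wise composition
$HU(v) = a \, [u \cdot ((low_v, high_v) - p_0)] + b$. The two input volumes
must live on one identical grid; the implementation refuses to resample
here, because the hardware reconstructs both channels in the same
coordinate system and silent interpolation would blur the model's
assumptions.

Two modelling choices deserve a note. The projection is *orthogonal*
because it is the unique distance-minimizing choice and makes the
calibration invariant to rotations of the value plane; nothing in the
procedure depends on which channel is called "x". And the calibration is
exactly invariant under separate affine remappings of the two channels (the
line and the projected coordinates transform consistently), which the test
suite checks: recalibrating on remapped volumes reproduces identical HU.

## Rigid registration and ROI transfer

To compare against MDCT, the MDCT volume is registered rigidly (6 degrees
of freedom) into DE-CBCT space, and the *inverse* of the estimated
transform carries each cylindrical ROI from DE-CBCT world coordinates into
MDCT world coordinates, where its statistics are evaluated on the native
MDCT grid — no MDCT values are ever interpolated onto the CBCT grid.
Rigidity matters: a cylinder stays a cylinder, so ROI geometry (height,
diameter) is preserved exactly and only its pose changes.

The registration is intensity-based and deliberately deterministic:

* three-level mean-pooled pyramid (pooling factors 4, 2, 1);
* initialization by aligning the world centroids of thresholded bone
  voxels (> 300 CT number), followed by a deterministic coarse grid search
  over the three rotation angles (±10° in 2.5° steps) with multi-start
  simplex refinement from the best candidates — the similarity surface of
  piecewise-constant anatomy has nearby local minima that a single descent
  can fall into;
* mean-squared-error metric (default; a joint-histogram mutual-information
  metric is available) evaluated on a deterministic strided sample of up to
  100 000 fixed-volume voxel centers above −500 CT number. The metric
  averages only over points that land inside the moving volume: on thin
  axial stacks a constant out-of-field fill would otherwise reward
  transforms that push anatomy out of the field of view, biasing the
  optimum toward small motions. A penalty term engages only if the
  overlapping fraction collapses below 70%;
* Nelder–Mead simplex over the 6 parameters (three z·y·x Euler angles
  about the fixed bone centroid, three translations), with a restart from
  each level's optimum to guard against premature simplex collapse.

On the synthetic jaw study the estimator recovers misalignments of up to
10 mm / 10° to within 0.3 mm and 0.5° (one CBCT voxel and well below the
angular scale that would displace an ROI by its own radius), which is the
accuracy the ROI-transfer stage needs. Registration that cannot proceed —
no bone above the initialization threshold, or no overlap after centroid
alignment — raises a typed error; a study pipeline records such cases as
excluded rather than producing a silently wrong transform.

## ROIs and their statistics

An ROI is an oriented cylinder: center (mm, world), height, diameter, and
three rotation angles about the world x, y, z axes composed in z·y·x order
(the convention is documented because only "three rotation angles" is
standard usage; any fixed order works as long as it is consistent).
Default validation warns outside the clinical adjustment ranges — height
4.0–5.0 mm, diameter 1.0–1.4 mm, angles ±90° — but proceeds, since these
are adjustment ranges, not constraints of the method.

Membership is by voxel-center inclusion with no partial-volume weighting:
a voxel belongs to the ROI iff its center is within `height/2` of the
central plane along the axis and within `diameter/2` of the axis. The
representative value of an ROI is the plain mean of its member voxels;
sample SD (n−1), min and max are reported alongside. On very coarse grids
a thin cylinder can contain no voxel center at all; that raises an
explicit empty-ROI error, and the paired-means stage records the ROI as
excluded instead of dropping it silently.

## Agreement analysis

For each ROI the pair (MDCT mean, DE-CBCT mean) enters three analyses, per
group (mandible, maxilla) and combined:

* **Identity-line deviation bands.** The deviation of a pair is the
  vertical offset from the y = x line relative to the MDCT value,
  $100\,(\bar{y} - \bar{x})/\bar{x}$ percent. Counts and percentages are
  reported in the bands $|d| \le 10$, $10 < |d| \le 15$,
  $15 < |d| \le 20$, $|d| > 20$; band edges belong to the inner band
  (closed at the outer edge). A variant relative to the pair average is
  available behind `deviation_mode = "average"`.
* **Normality gate.** The Shapiro–Wilk test (via `stats::shapiro.test`,
  Royston's AS R94 approximation) is applied to each group's percent
  differences; the gate passes at p > 0.01. Groups failing the gate are
  flagged but still analysed, since the flag, not suppression, is the
  informative output.
* **Bland–Altman.** Differences are expressed as a percentage of the pair
  average, $d = 100\,(\bar{x} - \bar{y}) / \tfrac{1}{2}(\bar{x}+\bar{y})$.
  With bias $\bar{d}$ and sample SD $s$, the limits of agreement (AL) are
  $\bar{d} \mp 1.96\,s$; the bias CI half-width is
  $t_{0.975,\,n-1}\, s/\sqrt{n}$; and the CI of each agreement limit is
  reported as the full width $2 \cdot 1.96 \cdot s \sqrt{3/n}$, the
  classical large-sample form (a Student-t variant is available via
  `loa_ci = "t"`). Counts of differences outside the ALs and outside the
  ALs' outer CI edges are both always reported, because "outside the
  limits" is used with either meaning in practice.

All quantities are serialized at full precision; display rounding (one
decimal for percentages, two for Bland–Altman quantities) is applied only
in the `display` section of the JSON report and in print methods.

## The synthetic phantom generator

The generator renders analytic scenes directly in the image domain; there
is no projection, scatter or reconstruction simulation, which matches a
device whose dual-energy combination itself operates purely on
reconstructed images. Per voxel center,
$CT = 1000\,(\mu - \mu_{water})/\mu_{water}$ at the requested energy
channel, plus optional seeded Gaussian noise and an optional
radially-quadratic in-plane bias field (a cupping surrogate, off by
default — the line model cannot absorb a spatially varying bias, and the
calibration presumes cupping-corrected reconstructions).

Materials are defined by a reference HU and converted to per-channel
attenuation through a two-channel model
$raw_c = -1000 + b_c\,(HU + 1000)$, $\mu_c = \mu_{water,c}(1 + raw_c/1000)$
with bone-sensitivity slopes $b_{low} = 1.15$, $b_{high} = 0.92$ (the
low-kVp channel sees bone as relatively denser). This construction keeps
air at exactly −1000 in both channels and places all material pairs
exactly on one line in the value plane — the geometry the calibration
assumes — so the noiseless simulated study is an exact fixture: calibrated
HU must equal the configured reference HU to machine precision, and any
discrepancy is an implementation bug, not model error.

Defaults define the study conditions:

* CBCT grid 334 × 334 in-plane at 0.3 mm pitch and 0.3 mm slices; MDCT
  grid 512 × 512 at 0.332 mm and 0.75 mm slices. Slice counts (80 and 32,
  i.e. 24 mm stacks) are chosen so the scenes fit with margin.
* HA inserts of 200/400/800/1200 mg/cm³ mapped to 300/600/1200/1800 HU
  (≈1.5 HU per mg/cm³, a typical QCT-phantom scale); acrylic 120 HU,
  cortical bone 1400 HU, trabecular 300 HU, soft tissue 40 HU. These are
  generator configuration, not claims about any physical phantom.
* Channel noise: Gaussian, SD 30 CT numbers per CBCT channel and 15 for
  MDCT, keeping ROI-mean sampling error at the few-HU level for
  default-size ROIs. All noise is seeded; a fixed seed reproduces volumes
  bit-identically.
* The MDCT channel reads true HU except for a −5% multiplicative offset on
  bone-class materials (`mdct_bone_bias`), giving the agreement module a
  realistic, known inter-modality bias to recover: DE-CBCT reads higher
  than MDCT on bone, and the combined Bland–Altman bias of the simulated
  study must come back at ≈ −5%.
* The jaw scene is two horseshoe arches (cortical shell, trabecular core)
  in soft tissue with 9 mandibular and 6 maxillary anchors placed
  mid-thickness in the outer cortical shell, where the largest default ROI
  fits entirely in cortical bone.

What the generator does *not* emulate — polychromatic beam hardening,
scatter, metal artifacts, anatomical variation, partial-volume texture —
bounds what passing tests show: they validate the calibration's
mathematics, the registration/transfer geometry and the statistics layer
under the stated noise model, not robustness to CBCT artifact physics.

## Numerical and design choices

* World frame is LPS (DICOM patient coordinates); indices are 0-based;
  voxel positions refer to voxel centers. Resampling outside the source
  field of view fills with −1000 (air).
* Trilinear interpolation is exact on affine fields; the test suite uses
  that closed form, plus round-trip and analytic-volume oracles, instead
  of golden files.
* The density-line fit is checked against a 1-D minimization of the
  orthogonal SSE over the line angle, the HU map against closed-form
  normal equations, and the Shapiro–Wilk wrapper against an independent
  reference implementation (scipy's), all to tight tolerances.
* Degenerate inputs fail loudly: coincident region samples, fewer than two
  known-HU anchors, zero-variance projections, constant Shapiro–Wilk
  input, n < 3 Bland–Altman samples, empty ROIs, mixed DICOM series,
  non-uniform slice stacks.
* DICOM I/O is a minimal explicit-VR little-endian single-frame CT
  dialect written for round-tripping this package's own volumes (one file
  per slice, MONOCHROME2, signed 16-bit with rescale slope/intercept,
  slices sorted by projected position along the orientation normal — never
  by filename). It is not a general DICOM toolkit.
* The test suite runs the geometry-heavy stages on reduced grids
  (120×120×40 at 0.8/0.6 mm CBCT-like, 150×150×30 at 0.664/0.9 mm
  MDCT-like) — small enough to iterate on, fine enough that a
  default-size ROI always contains voxel centers; the reproduction script
  (`scripts/acceptance.R`) runs the end-to-end study at the full default
  geometry.

## Known limitations

* The calibration assumes the device's two channels are affine images of
  one underlying density axis; spatially varying distortions (cupping,
  scatter) are outside the model and must be corrected upstream.
* Registration is rigid only. Similarity or affine modes are deliberately
  unsupported on the ROI-transfer path: a sheared cylinder is no longer a
  cylinder.
* Membership by voxel-center inclusion makes small-ROI statistics grid
  dependent; at clinical resolutions the default ROI sizes contain
  hundreds of voxels (CBCT) and tens of voxels (MDCT), where the effect is
  at the percent level.
* The Shapiro–Wilk gate and Bland–Altman analysis inherit their usual
  sample-size caveats; with very few ROIs per group the AL confidence
  widths are wide and the normality test has little power.
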