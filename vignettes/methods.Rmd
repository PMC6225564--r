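---
title: "Feature-based CT/CBCT registration: model, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-based CT/CBCT registration: model, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The registration problem

During endovascular repair of complex aortic aneurysms, a preoperative
contrast-enhanced CT angiography (CTA) is fused with an intraoperative,
non-contrast cone-beam CT (CBCT) so that the vascular anatomy can be overlaid
on live fluoroscopy. Automatic intensity-based registration struggles here for
four reasons: the CTA field of view is roughly three times the CBCT's; the
patient's posture differs between acquisitions; the contrast-filled aorta of
the CTA has no counterpart in the CBCT; and preoperative slice thickness
varies widely (roughly 0.7-3 mm). `siftreg` implements a fully automatic
*feature-based* alternative: sparse, distinctive keypoints are detected in
both volumes, matched by descriptor similarity, filtered geometrically, and
the surviving correspondences parameterise the transform.

All transforms in the package map CBCT physical points (mm) to CT physical
points; fusion inverts the final map numerically. Working in physical
coordinates - each volume carries voxel spacing, origin, and an orthonormal
direction matrix, with the origin at the centre of voxel (0,0,0) - keeps
every algorithmic threshold meaningful in millimetres regardless of voxel
size.

## The pipeline

1. **Intensity normalization.** Each volume is clipped at its 1st/99th
   intensity percentiles and rescaled to [0,1]. This removes the arbitrary
   scale/offset between HU-like CTA values and uncalibrated CBCT values, and
   makes the detector's contrast threshold comparable across modalities.
2. **Isotropic resampling.** Both volumes are resampled to a common isotropic
   grid (default 1.5 mm) so that scale in mm is well defined on anisotropic
   CT grids. Final transforms are expressed in physical space, so evaluation
   is independent of this working resolution.
3. **3D SIFT detection.** A difference-of-Gaussians (DoG) pyramid
   (`sigma0 = 1.6` voxels, 3 levels per octave, octaves until the smallest
   axis drops below 16 voxels). Keypoints are strict extrema over the
   3x3x3x3 scale-space neighbourhood (80 neighbours), refined to sub-voxel
   position and scale by a quadratic fit, kept when the interpolated |DoG|
   response reaches 0.02 and the spatial Hessian has same-sign eigenvalues
   with anisotropy at most 10 (plate/edge rejection - intensity surfaces and
   ridges localise poorly along their flat directions).
4. **Descriptors.** Gradient histograms over 4x4x4 spatial subregions
   (subregion width 3 sigma) with 12 solid-angle orientation bins (the
   icosahedron vertex directions), trilinear sharing between subregions,
   Gaussian window weighting, 0.2 clipping, and renormalization to unit
   length - descriptor length 768. No per-keypoint orientation frame is
   assigned: both acquisitions are made supine, so pose differences are
   small rotations that the affine stage absorbs. This is a documented
   limitation - the descriptors are *rotation-robust* over a few tens of
   degrees, not rotation-invariant.
5. **Stage 1 - global matching.** Mutual nearest-neighbour matching of
   descriptors (a pair is kept only if each member is the other's closest
   descriptor), then an affine RANSAC with a deliberately high 10 mm inlier
   threshold: the true transform is not affine, and the threshold must admit
   correspondences displaced by the nonlinear deformation. Minimal samples
   are 4 correspondences; near-coplanar samples are redrawn; candidate
   models with |det| outside [0.5, 2] are rejected as anatomically
   implausible; the iteration count adapts to the observed inlier ratio at
   0.99 confidence (cap 10000); the consensus model is refit by least
   squares on its inliers.
6. **Stage 2 - local re-matching.** CT features outside the stage-1-mapped
   CBCT field of view (dilated by a 10 mm margin) are discarded; matching is
   repeated with the search restricted to a 10 mm radius around each
   feature's transformed position (in both directions), which recovers
   soft-tissue correspondences that global matching cannot distinguish among
   thousands of candidates; RANSAC runs again at a tight 5 mm threshold.
7. **Thin-plate spline.** The final map is a 3D thin-plate spline fitted on
   the stage-2 inliers (CBCT features whose support window reaches into the
   constant background outside the reconstruction cylinder are excluded
   before any matching - half-supported keypoints localise with a
   systematic inward bias that otherwise leaks a spurious scale into the
   affine estimates): `T(p) = A p + t + sum_i w_i U(||p - c_i||)` with the
   3D biharmonic kernel `U(r) = r`, side conditions `sum w = 0`,
   `sum w c^T = 0`, and `3N + 12` parameters for `N` control points (12 of
   them the global affine block).

### Why the spline is smoothed by default

The textbook TPS interpolates its correspondences exactly (`lambda = 0`),
and `fit_tps()` keeps that as its function default. The pipeline, however,
fits the spline on hundreds of automatically detected correspondences, each
localised with voxel-scale noise (roughly 0.5-1 mm at the working
resolution). An interpolating spline reproduces that noise pointwise, so its
landmark accuracy is reliably *worse* than the stage-2 affine whenever the
true deformation is locally near-affine - the regime this application lives
in ("an affine transformation plus a rather small nonlinear deformation").
The pipeline therefore defaults to `tps_regularization = 200`. Because
`U(r) = r` has units of mm, `lambda` is also in mm and acts as a stiffness
scale: with kernel entries of order the inter-point distances (tens to
hundreds of mm), values of this order suppress incoherent per-point noise
while leaving deformation trends at the anatomically plausible >= 40 mm
scales essentially untouched. Landmark accuracy on deformed phantoms is flat
across roughly lambda 100-200; the value 200 is fixed by the negative
control that a null deformation must return a null map: on an identity
phantom pair the fitted spline deviates from the identity by well under
1 mm across the whole field of view, which smaller lambda does not achieve
at the field-of-view rim where control points are sparse. The kernel `U(r) = r` is conditionally *negative*
definite, so the smoothing term enters the linear system with a negative
sign (equivalently: fit with kernel `-r` and `+lambda`); the system is
solved in centred, scale-normalised source coordinates for conditioning.

### Numerical choices

- Gaussian pyramid smoothing is separable with edge-replicate padding,
  kernel truncation at 3 sigma, and single-precision internals (the
  convolution is memory-bound; the resulting ~1e-7 error is far below the
  0.02 contrast threshold). The Gaussian semigroup property holds to ~1e-5
  RMS away from the volume boundary; near the boundary the replicate padding
  dominates.
- Nearest-neighbour search is exact blocked BLAS distance computation. At
  descriptor dimension 768 space-partitioning trees degenerate to linear
  scans, so there is no approximate path; the tests compare the blocked
  implementation against a plain per-row brute-force oracle.
- Distance ties in matching are broken by the lower index; keypoints are
  ordered by |response| with positional tie-breaks - the whole pipeline is
  deterministic given the RANSAC seed, and RANSAC saves and restores the
  caller's RNG state.
- TPS kernel distances are computed from explicit coordinate differences;
  the algebraically equivalent `|p|^2 + |c|^2 - 2 p.c` form loses ~1e-6 mm
  to cancellation exactly at the control points, where the interpolation
  contract is checked.
- Degenerate inputs fail loudly: constant volumes (normalization), volumes
  under 8 voxels per axis (pyramid), coplanar or duplicate control points
  (affine/TPS fits), fewer than 4 matches (RANSAC), label mismatches
  (evaluation). A registration failure is an explicit staged result object
  - which stage failed, with all counts - so batch evaluations can tabulate
  failure modes rather than catch exceptions.
- Fusion inverts the final map per voxel by Newton iteration with the
  stage-2 affine linear part as Jacobian (tolerance 0.05 mm, 20 iterations,
  affine-inverse initialisation); non-converged voxels fall back to the
  affine inverse and a warning is recorded when they exceed 1%.

## The synthetic phantom

No clinical images accompany the method, so the package ships a generator
whose defaults encode the study conditions the method must survive:

| knob | default | what it emulates |
|---|---|---|
| CT extent / spacing | 360 x 360 x 480 mm at 1.5 mm | abdominal CTA, ~3x the CBCT's size |
| CBCT FOV / spacing | cylinder 250 mm diameter x 190 mm height, 1.5 mm | C-arm reconstruction volume |
| pose change | rotation <= 10 deg, translation <= 30 mm, scale <= 3% | posture difference between acquisitions |
| nonlinear warp | <= 5 mm, sum of <= 5 Gaussian bumps with sigma >= 40 mm | small smooth soft-tissue deformation |
| intensity | gain 1.4, offset 0.1, noise SD 0.02 | uncalibrated CBCT values |
| aorta contrast | CT only | the CTA lumen has no CBCT counterpart |

The scene is a soft-tissue body cylinder containing a column of 13
vertebra-like structures (body, spinous and transverse processes), a
vertical aorta tube whose lumen is bright only in the CT, six small
(1.5-4 mm) high-intensity calcification spots on the tube wall visible in
both volumes, and a dense band-limited texture field (~12000 Gaussian blobs,
sigma 3-9 mm, amplitude +/-0.06-0.14). The texture density was chosen so
that detection yields feature counts of the order observed clinically
(thousands in the CT, hundreds within the much smaller CBCT FOV). An odd
vertebra count puts one vertebra at the FOV centre, so the landmark set -
the three calcifications nearest the "renal" level plus the superior apices
of the three central vertebrae, mirroring clinically used landmark choices -
stays inside the CBCT cylinder under the full translation range.

Structural components and the ground-truth map are analytic, so the CBCT is
*sampled*, not resampled: every CBCT voxel evaluates the scene at its warped
position exactly, and the true map can be queried at any point (the texture
field alone is rendered once on the CT grid and carried through the warp by
trilinear interpolation; it is band-limited well above the grid scale). The
warp's peak displacement is calibrated on a 10 mm grid over the FOV to the
requested amplitude. Landmark partners are obtained by Newton inversion of
the true map to 1e-10 mm.

What the phantom does *not* model - and hence what passing tests do not
show about clinical data: X-ray physics (scatter, beam hardening, truncation
artefacts), modality-specific texture decorrelation (the phantom's soft
tissue is the *same* analytic field seen through the warp, so soft-tissue
matching is easier than in reality), instruments and stent grafts,
large posture changes, and pathology. The phantom validates the geometry
and robustness of the pipeline under controlled, clinically motivated
magnitudes; it cannot replace clinical evaluation.

## Validation design

- Module-level properties: coordinate maps invert to 1e-9; file round-trips
  are lossless; matching equals a brute-force oracle; affine least squares
  matches the normal equations; TPS interpolates at `lambda = 0`, reproduces
  affine data with vanishing nonlinear weights, and satisfies its side
  conditions; RANSAC recovers a known affine from 60 noisy inliers among 40
  uniform outliers.
- Pipeline-level checks on phantoms: self-registration of an identity pair
  returns the identity to under 1 mm; a structureless noise CBCT fails with
  a staged failure; accuracy does not improve when noise or warp amplitude
  is increased; registration succeeds with a CT three times the CBCT extent
  per axis.
- The headline batch: ten default-spec phantom pairs (seeds 1-10) are
  registered end to end and the 3D errors at the six landmark pairs are
  pooled; the batch median and maximum are the figures
  `scripts/acceptance.R` recomputes and reports.

Problem sizes in the shipped tests are scaled to the package's continuous
testing workflow: unit tests use 16-64 voxel grids and reduced phantoms
(~270 mm CT at 2 mm voxels); the headline batch runs the full default
phantom. Clinical-resolution grids (0.5 mm CBCT voxels) are a configuration
option, not a test default.

## Known limitations

- No per-keypoint orientation assignment: large rotations (beyond a few
  tens of degrees) would degrade descriptor matching.
- DICOM series are not read; use NIfTI or MetaImage (single-file `.mha`).
- The FOV pruning default uses the CBCT bounding box (conservative); the
  inscribed cylinder is available by option.
- Mutual matching is one-to-one by construction; repetitive anatomy
  (adjacent vertebrae) is disambiguated only by the geometric stages.
- The TPS is fitted on stage-2 inliers only; correspondences the 5 mm
  RANSAC rejects contribute nothing, so accuracy far from any inlier decays
  toward the affine.
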