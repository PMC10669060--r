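---
title: "Automatic CBCT / intraoral-scan registration: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic CBCT / intraoral-scan registration: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cone-beam computed tomography (CBCT) images the full dentition — crowns,
roots, bone — as a voxel volume at roughly 0.3 mm resolution, but its
contrast and resolution are too coarse to define occlusal surfaces for
appliance manufacturing. An intraoral scan (IOS) delivers micrometre-scale
colored surface meshes of the crowns and gingiva, but nothing below the
gum line. Clinical planning wants both in one frame: the rigid transform
that carries the scan into the CBCT world. `dentreg` implements a fully
automatic pipeline for that registration, together with the validation
metrics used to judge it, and a synthetic phantom generator that provides
exact ground truth for testing.

The chain is: (1) segment teeth from the CBCT and split them into upper
and lower jaw; (2) separate tooth crowns from gingiva in the colored scan;
(3) align the scan crowns to the CBCT jaw by global RANSAC initialization
followed by point-to-plane ICP; (4) quantify the result.

## CBCT tooth segmentation and jaw separation

**Sagittal slice masks.** Segmentation runs slice by slice along the
anteroposterior (y) traversal, each slice viewed in its (x, z) plane where
a tooth shows its full crown-and-root cross-section. This traversal is the
point of the design: when the patient clenches, upper and lower teeth
touch and no axial plane separates the jaws. The slice segmenter is an
interface: the classical default thresholds at 1200 HU-like units, labels
8-connected components, and drops components under 30 voxels. A trained
instance detector can be plugged through the same interface (the phantom
ships one derived from its own labels, `truth_slice_segmenter()`, which is
what the clenched benchmark uses — thresholding cannot split touching
teeth into instances, which is precisely why instance detectors are used
on real data).

Each mask is reduced to its bounding-box center
`(x + w/2, s, z + h/2)` — the representative point that stands in for the
mask in panoramic space.

**Dental arch and panoramic view.** The arch curve is detected on the
mean intensity projection of the volume: threshold, largest 8-connected
component, per-column foreground centroids, and a weighted least-squares
quartic fit `y(x)`, resampled uniformly by arc length (C = 400 points by
default). Thresholding uses a three-class Otsu (exhaustive two-cut search
over a 256-bin histogram, keeping the top class): the projection is
trimodal — air, soft tissue and bone, teeth — and the classic two-class
split lands between air and tissue rather than isolating the teeth. Unit
normals are the +90-degree-rotated tangents, oriented toward the side with
the greater intensity fall-off (the labial side). The panoramic image
integrates intensities along each arch normal over a band of half-width
`w` (default 8 mm, configurable; the band must cover the arch's buccal
and lingual extent):
`P(c, z) = sum_t X(r_c + t n(c), z) dt`, by midpoint sampling with
trilinear interpolation. The step defaults to one eighth of the voxel
spacing: at half a voxel the quadrature error on voxel-scale texture
reaches a few percent, while at an eighth it is an order of magnitude
below the interpolation error (measured against 16x finer integration).

**Jaw split.** Panoramic instance masks (same segmenter interface,
three-class Otsu + connected components by default) are split into upper
and lower groups by an ordinary least-squares boundary line `z = a c + b`
fitted to the mask centroids; a centroid exactly on the line counts as
upper. Every slice-mask representative point is projected to panoramic
coordinates — nearest arch sample (ties toward the smaller index), with
points whose normal offset exceeds `w` dropped — and the mask joins the
group whose panoramic mask contains its pixel. Points in neither mask
fall back to the boundary-line side (ties upper; the count is reported).
Merged per-jaw clouds are built from all mask voxels in world mm.

**Subvoxel boundary refinement.** Mask voxel *centers* are a biased
surface model: the outermost center sits anywhere up to one voxel inside
the true boundary (lattice phase), which would leave a systematic
fraction-of-a-voxel offset in the fine registration. Partial-volume
intensities carry the missing information, so boundary voxels (those with
a 6-neighbour below threshold) are moved along the local intensity
gradient to the threshold iso-level, clamped to 0.6 voxel. Interior
voxels stay at their centers. This is switchable
(`cbct$subvoxel_boundary`).

## Intraoral scan segmentation

Per-vertex RGB is converted to HSV and embedded as
`(s cos h, s sin h, v)`: hue is treated circularly, and scaling by
saturation makes the hue of near-achromatic (tooth-like) colors
irrelevant, where it is numerically meaningless. Classification is
k-nearest-neighbour (k = 15) against a labeled training set within an
embedded radius (0.3). The shipped default training set is a deterministic
grid over the phantom's color model (whitish low-saturation crowns, pink
saturated gingiva); for scanner data with different color rendering a
user-supplied seed set (`read_color_training()`) should replace it. Ties
and points with no in-range training neighbour go to "gum": mislabeling a
tooth point as gum only thins the registration source, while the converse
pollutes it. The teeth subset is then cleaned spatially — Euclidean
clustering at 1 mm, clusters under 30 points dropped. Whether the paper's
neighbourhood radius lives in color space or 3D space is ambiguous; we
take it in color space, which is the reading under which KNN actually
classifies by color.

## Registration

Both clouds are voxel-down-sampled (0.5 mm default, each occupied bucket
replaced by its centroid). Normals come from the smallest eigenvector of
the 30-neighbourhood covariance. Orientation is the subtle part:

* thin surface scans use consistency propagation along a minimum spanning
  tree weighted by `1 - |n_i . n_j|`, with likely sheet-crossing edges
  (edge direction nearly parallel to the normals — e.g. between facing
  walls of adjacent crowns) cut, and each remaining component signed by a
  majority vote of outwardness from its own centroid;
* filled voxel clouds (the CBCT jaw) orient each normal away from its
  neighbourhood centroid, which the solid interior pulls inward;
* scans that already carry normals (meshes usually do, and the phantom
  exports exact analytic normals, as scanners export winding-consistent
  ones) keep them.

The covariance eigenvalues also yield the surface variation
`lambda_0 / sum(lambda)`; points above 0.15 (isotropic, interior-like)
are excluded from the descriptor stage, since the inside of a filled
voxel cloud carries no usable local surface geometry.

**Coarse stage.** 33-bin fast point feature histograms over a 2.5 mm
support are computed on the surface-like subsets of both clouds and
matched by nearest descriptor with a mutual filter. RANSAC then draws 3
mutual correspondences per iteration, prunes by pairwise edge-length
ratio (0.9), estimates the transform in closed form (SVD), and scores by
inlier fitness at twice the down-sampling voxel on a 2000-point subsample.
The standard confidence-0.999 early stop only engages after a hypothesis
clears the match-rate threshold (fitness 0.2) *and* a floor of 20000
iterations has been sampled. The floor exists because a dental arch is
nearly mirror-symmetric: a competing, half-turn-rotated pose basin often
scores almost as well, and it must actually be sampled to be ruled out.
The best hypothesis from a pose-distinct second basin (relative rotation
over 20 degrees or translation over 5 mm) is retained alongside the
global best.

**Fine stage.** Point-to-plane ICP minimizes
`sum ((T p_i - q_i) . n_i)^2` with correspondences within 1.5 mm,
re-linearized each iteration (small-angle closed form, 6x6 normal
equations with scale-adjusted Tikhonov damping); the step is halved until
the fixed-correspondence objective does not increase, so the inner solve
is monotone by construction. Convergence requires the relative change of
both fitness and inlier RMSE to fall below 1e-6; the whole ICP is then
re-run twice with the correspondence radius halved, which tightens the
final pose. The fine target is the *full-resolution* jaw cloud, not the
down-sampled one: bucket centroids of a filled cloud retreat inward from
the shell by a fraction of the bucket size, which was measured to bias
the recovered translation by about 0.24 mm before the change. Both coarse
candidates are refined and the one with the higher fitness/inlier-RMSE
ratio (the F/I score) wins.

All stochastic stages draw from R's RNG under `config$seed`; identical
seeds reproduce transforms byte for byte.

## Validation

* Nearest-neighbour distance report: per-source-point distance to the
  target, mean, and *population* standard deviation (a descriptive
  summary of the full distance set), plus fitness, inlier RMSE and their
  ratio F/I at a stated threshold (default: the ICP correspondence
  radius, which is recorded in the report).
* Chamfer (mean) and Hausdorff (max) distances, directed and symmetric.
* Coronal cross-section agreement: the aligned crown z-range is cut into
  20 equal slabs; per slab, points project to the slab mid-plane and the
  cross-section area is the area of the 2D Delaunay alpha complex
  (alpha = 1 mm) — robust to concave tooth sections where a convex hull
  overestimates. Bland-Altman on the 20 area pairs uses the *sample*
  (n-1) standard deviation, the convention of agreement analysis:
  bias +/- 1.96 SD, with inclusive limits. Because the scan contributes a
  surface shell while the CBCT contributes filled cross-sections, the
  per-slab areas differ by a stable offset that shows up as the
  Bland-Altman bias — the analysis assesses *agreement of the trend*
  (points within the limits), not equality of the areas.
* Error color map: per-point distance mapped linearly blue (0 mm) to red
  (1 mm default, clipped), exported as colored PLY, with the distance
  histogram and its mean.

## The phantom: what it emulates, and what it does not

The generator builds both modalities from one analytic scene so every
label, surface point and pose is exact:

* a parabolic arch (50 x 40 mm default) carrying 14 teeth per jaw with an
  anatomical size profile (incisors narrow, molars broad), elliptical
  cross-sections aligned to the arch tangent and a cuspal radial ripple —
  without these asymmetries a solid-of-revolution crown gives local
  descriptors nothing to latch onto, which real crowns do;
* superellipsoid crowns and conical roots; mirrored jaws with a
  configurable inter-occlusal gap (0 = clenched, the hard case);
* a volume rasterized with partial-volume blending (3x3x3 subvoxel
  occupancy), four intensity levels (teeth 2000 > bone 800 > soft 150 >
  air -1000) and additive Gaussian noise (sd 40), at 0.3 mm voxels in the
  standard preset;
* colored crown + gingival-collar surfaces with exact analytic normals
  (as scanner meshes provide) sampled at 4 points/mm^2, colored from a
  two-class HSV model that is separable by saturation;
* a seeded random rigid export pose (up to 15 degrees / 10 mm by
  default), whose inverse is the recorded ground-truth IOS-to-CBCT
  transform.

It does *not* emulate: real anatomical crown morphology (fissures,
individual cusp anatomy), enamel/dentin/pulp substructure, metal
artifacts or scanner noise physics, gingival texture, missing or
misaligned teeth, or scan coverage gaps. Passing on the phantom therefore
demonstrates the pipeline's bookkeeping and numerical behavior under
known geometry — not clinical performance on patient data, where the
instance segmenter and the color training set would both need to be
fitted to the modality.

Preset conditions: `standard` (benchmark, 14 teeth/jaw, 0.3 mm voxels,
2 mm gap), `clenched` (gap 0), `tiny` (6 teeth/jaw, 0.6 mm voxels, small
arch — used by the fast unit tests; at this resolution descriptors carry
little information, so registration tests at this scale use the standard
preset or self-alignment cases).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `cbct$threshold_hu` | 1200 | HU-like | between bone (~800) and enamel-like (~2000) levels |
| `cbct$band_halfwidth_mm` | 8 | mm | panoramic band must cover buccal-lingual tooth extent |
| `cbct$arch_points` | 400 | – | panoramic width; sub-mm arc steps on an adult arch |
| `ios$k`, `ios$max_dist` | 15, 0.3 | –, embedded | KNN votes and color-space gate |
| `register$voxel_size` | 0.5 | mm | near CBCT voxel scale; keeps clouds tractable |
| `register$fpfh_radius` | 2.5 | mm | ~5x voxel, sub-crown-scale support |
| `register$inlier_factor` | 2 | x voxel | RANSAC verification distance |
| `register$min_fitness` | 0.2 | – | required coarse match rate |
| `register$ransac_min_iter` | 20000 | – | guarantees the mirror basin is sampled |
| `register$icp_max_corr` | 1.5 | mm | fine correspondence gate; halved twice by the refinement loop |
| `validate$n_slices`, `validate$alpha` | 20, 1.0 | –, mm | coronal slabs and alpha-complex radius |

## Numerical choices and degenerate inputs

* Transforms are 4x4 homogeneous, column-vector convention
  `p' = R p + t`; `compose_transform(A, B)` applies B first. Rotation
  blocks are validated orthonormal (1e-9) and re-projected onto SO(3)
  after iterative refinement.
* Panoramic quadrature: midpoint rule, step = voxel/8, out-of-volume
  samples contribute the volume minimum; `w = 0` yields an identically
  zero image.
* Delaunay (for alpha areas): Bowyer-Watson with a deterministic
  sub-micrometre jitter to break the massive cocircularity of voxel-grid
  cross-sections; duplicate points are collapsed first. Sections with
  fewer than 3 points have area 0.
* Tie-breaks are fixed for reproducibility: boundary-line ties go upper;
  nearest-arch-sample ties go to the smaller index; KNN vote ties go to
  gum.
* Degenerate inputs error early with a message naming the problem: empty
  point sets, colorless surfaces when color is required, fewer than 2
  panoramic masks, fewer than 3 points for alignment, no correspondences
  at the ICP initialization, non-positive bounding boxes, inconsistent
  DICOM slice spacing (the offending slices are listed).

## Problem sizes

The shipped tests exercise the tiny preset (~0.4M voxels, ~4k surface
points) for unit-level checks and the standard preset (~6M voxels, ~30k
surface points, ~270k jaw voxels) for the end-to-end benchmarks: one
registered standard pair for the distance and agreement checks, five
seeds for pose-recovery stability, and gapped plus clenched phantoms for
the jaw split. A standard-phantom registration takes on the order of half
a minute on one core.

## Known limitations

* The classical threshold segmenter cannot separate touching teeth into
  instances; the clenched case therefore requires an instance-capable
  segmenter behind the slice/panoramic interfaces (on real data, a
  trained detector).
* The color KNN is only as good as its training set; scanners with
  different color pipelines need their own seed points.
* Registration assumes enough crown overlap between modalities; edentulous
  regions, large restorations or heavy metal artifacts are out of scope.
* The pipeline is rigid-only by design: it estimates pose, not
  deformation.
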