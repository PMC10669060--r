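# dentreg

Automatic rigid registration of colored intraoral scans (IOS) to dental
cone-beam CT (CBCT) volumes, for orthodontic and surgical planning
workflows that need the scanner's micrometre-scale crown surfaces placed
in the CT's anatomical frame.

The package implements the full chain:

1. **CBCT tooth segmentation** — per-slice instance masks along the
   anteroposterior traversal (each slice shows crown-and-root
   cross-sections, so the jaws stay separable even with clenched teeth),
   each mask reduced to its bounding-box center
   `(x + w/2, s, z + h/2)`;
2. **panoramic jaw split** — a quartic dental arch `y(x)` fitted on the
   axial mean-intensity projection, the panoramic image
   `P(c,z) = ∫_{-w}^{w} X(r_c + t·n(c), z) dt`, an OLS boundary line
   `z = a·c + b` through the panoramic mask centroids, and classification
   of every slice mask into upper/lower jaw via its projected
   representative point;
3. **IOS crown extraction** — per-vertex RGB → HSV, k-nearest-neighbour
   classification in the embedded color space `(s·cos h, s·sin h, v)`
   into teeth vs gingiva, plus Euclidean-cluster cleanup;
4. **registration** — voxel down-sampling, normals, 33-bin FPFH
   descriptors, mutual-filtered RANSAC (hypothesis-and-verify with
   edge-length pruning and a competing-basin safeguard for the
   near-mirror-symmetric arch), then point-to-plane ICP
   (`min Σ ((T p_i − q_i)·n_i)²`) with a halved-radius refinement loop;
5. **validation** — nearest-neighbour distance statistics, chamfer and
   Hausdorff distances, Bland–Altman agreement of 20 coronal
   cross-section areas (2D alpha-shape areas, limits at bias ± 1.96 SD),
   fitness / inlier-RMSE (F/I), and blue-to-red error color maps.

Because clinical CBCT/IOS pairs cannot be redistributed, the package
ships a synthetic dental phantom generator (`generate_phantom()`):
superellipsoid crowns with anatomical cross-sections and cusps on a
parabolic arch, conical roots, bone and soft-tissue background with
partial-volume blending and noise, colored crown + gingiva surfaces with
exact normals, and a seeded rigid export pose whose inverse is the exact
ground truth. All tests and benchmarks run against it.

## Worked example

```r
library(dentreg)

spec <- phantom_preset("standard")   # 14 teeth/jaw, 0.3 mm voxels, 2 mm gap
spec$seed <- 7
phantom <- generate_phantom(spec)

config <- pipeline_config(seed = 1)
seg    <- segment_cbct(phantom$volume, config)
seg$jaw_split
#> Jaw split: 250 upper masks (108325 voxels), 251 lower masks (109020 voxels), 122 fallback assignments

teeth <- segment_ios(phantom$upper, config)
teeth
#> Colored surface: 7258 points, RGB colors, normals, labels

reg <- register_jaw(teeth, seg$jaw_split$upper_points, config)
reg
#> Registration result (pipeline): fitness 0.9998, inlier RMSE 0.1478 mm, F/I 6.764 /mm, 12 iterations, converged

val <- validate_registration(reg, teeth, seg$jaw_split$upper_points, config)
val
#> Distances: n 7258, mean 0.1398 mm, sd 0.0498 mm, fitness 1.0000 @ 1.50 mm, inlier RMSE 0.1484 mm, F/I 6.740 /mm
#> chamfer (sym) 1.0873 mm, Hausdorff (sym) 12.7765 mm
#> Bland-Altman: n 20, bias -308.0294, limits [-479.7037, -136.3551], 95.0% within

err <- compose_transform(reg$transform, invert_transform(phantom$truth$transform))
c(rotation_angle(err), sqrt(sum(unclass(err)[1:3, 4]^2)))
#> 0.017 deg   0.0067 mm
```

Reading the numbers: after the automatic coarse + fine alignment, the
mean distance from each scanned crown point to the nearest CBCT tooth
voxel is 0.14 mm — well below the 0.3 mm voxel size — and the recovered
pose differs from the phantom's ground-truth export pose by 0.017° and
7 µm. The large symmetric Hausdorff value is expected: the CBCT cloud
contains roots the scan never sees. The Bland–Altman bias reflects the
surface-shell vs filled-section area offset between the modalities; the
agreement statement is that 19/20 slab differences lie within the limits.

A thin command-line front end mirroring the stages
(`phantom`, `segment-cbct`, `segment-ios`, `register`, `validate`, `run`)
is installed at `inst/cli/dentreg.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/dentreg.R", package="dentreg"))')" \
    run --cbct cbct.nii.gz --ios-upper upper.ply --ios-lower lower.ply \
    --seed 7 --out rundir/
```

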