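#' Crop a volume to an axis-aligned world-coordinate box
#'
#' The returned volume keeps the world position of every retained voxel:
#' its origin is advanced to the first retained voxel center.
#'
#' @param volume A [voxel_volume()].
#' @param bounds A list with `min` and `max` length-3 vectors, mm.
#' @return A cropped [voxel_volume()].
#' @export
extract_roi <- function(volume, bounds) {
  stopifnot(is.list(bounds), !is.null(bounds$min), !is.null(bounds$max))
  d <- dim(volume$intensities)
  i0 <- pmax(0, ceiling((bounds$min - volume$origin) / volume$spacing - 1e-9))
  i1 <- pmin(d - 1, floor((bounds$max - volume$origin) / volume$spacing + 1e-9))
  if (any(i1 < i0)) stop("ROI bounds do not intersect the volume")
  arr <- volume$intensities[(i0[1] + 1):(i1[1] + 1),
                            (i0[2] + 1):(i1[2] + 1),
                            (i0[3] + 1):(i1[3] + 1), drop = FALSE]
  voxel_volume(arr, volume$spacing, volume$origin + volume$spacing * i0)
}

#' Classical sagittal slice segmenter
#'
#' Returns a slice segmenter with the standard interface
#' `function(slice_matrix, slice_index0) -> list of n x 2 0-based (x, z)
#' pixel matrices`, implementing intensity thresholding, 8-connected
#' component labeling and a minimum component size. A trained instance
#' detector can be substituted through the same interface (see
#' [truth_slice_segmenter()]).
#'
#' @param threshold_hu Intensity threshold (HU-like units).
#' @param min_component_voxels Components smaller than this are dropped.
#' @return A segmenter function.
#' @export
slice_segmenter_threshold <- function(threshold_hu = 1200,
                                      min_component_voxels = 30) {
  function(slice, s) {
    bw <- slice >= threshold_hu
    if (!any(bw)) return(list())
    lab <- cpp_label_components(bw)
    tab <- tabulate(lab)
    keep <- which(tab >= min_component_voxels)
    lapply(keep, function(k) {
      px <- which(lab == k, arr.ind = TRUE) - 1L
      unname(px)
    })
  }
}

#' Segment all sagittal slices of a volume
#'
#' Sagittal slices are planes of constant y index, traversed
#' anteroposteriorly; each mask lives in that slice's (x, z) plane. One
#' `slice_mask` is produced per detected instance per slice, carrying its
#' pixel set, tight bounding box and representative point (bounding-box
#' center).
#'
#' @param volume A [voxel_volume()].
#' @param segmenter A slice segmenter (default
#'   [slice_segmenter_threshold()]).
#' @return A list of `slice_mask` objects: `s` (0-based slice index),
#'   `pixels` (n x 2, 0-based x/z), `bbox` (`c(x, z, h, w)`, voxel units)
#'   and `rep` (Eq.-style bounding-box center, voxel units).
#' @export
segment_sagittal_slices <- function(volume,
                                    segmenter = slice_segmenter_threshold()) {
  d <- dim(volume$intensities)
  out <- list()
  for (s in 0:(d[2] - 1)) {
    slice <- volume$intensities[, s + 1, ]
    masks <- segmenter(slice, s)
    for (px in masks) {
      if (nrow(px) == 0) next
      x0 <- min(px[, 1]); x1 <- max(px[, 1])
      z0 <- min(px[, 2]); z1 <- max(px[, 2])
      bbox <- c(x = x0, z = z0, h = z1 - z0 + 1, w = x1 - x0 + 1)
      out[[length(out) + 1]] <- structure(
        list(s = s, pixels = px, bbox = bbox,
             rep = representative_point(bbox, s)),
        class = "slice_mask")
    }
  }
  out
}

#' Representative point of a slice-mask bounding box
#'
#' The center of the detected bounding box `(x, z, h, w)` in slice `s`:
#' `(x + w/2, s, z + h/2)`, in voxel units.
#'
#' @param bbox Numeric `c(x, z, h, w)` (x/z corner, height in z, width in
#'   x), voxel units.
#' @param s Slice index along the sagittal traversal.
#' @return Length-3 numeric (x, y, z) in voxel units.
#' @export
representative_point <- function(bbox, s) {
  bbox <- as.numeric(bbox)
  if (length(bbox) != 4) stop("bbox must be (x, z, h, w)")
  h <- bbox[3]; w <- bbox[4]
  if (!(h > 0) || !(w > 0)) stop("bounding box height and width must be positive")
  c(bbox[1] + w / 2, s, bbox[2] + h / 2)
}

#' Mean intensity projection along z
#'
#' @param volume A [voxel_volume()].
#' @param z_range 0-based inclusive `c(lo, hi)` voxel range, or NULL for
#'   the full extent.
#' @return An x-by-y matrix of per-column mean intensities.
#' @export
mean_intensity_projection <- function(volume, z_range = NULL) {
  d <- dim(volume$intensities)
  if (is.null(z_range)) z_range <- c(0, d[3] - 1)
  z_range <- as.integer(z_range)
  if (z_range[2] < z_range[1] || z_range[1] < 0 || z_range[2] > d[3] - 1)
    stop("empty or out-of-bounds z_range")
  sub <- volume$intensities[, , (z_range[1] + 1):(z_range[2] + 1), drop = FALSE]
  rowMeans(sub, dims = 2)
}

#' Detect the dental arch curve on an axial projection
#'
#' Thresholds the projection (Otsu unless overridden), keeps the largest
#' 8-connected component, fits a weighted least-squares quartic `y(x)` to
#' the per-column foreground centroids, resamples it uniformly by arc
#' length, and orients the unit normals toward the labial (outer) side —
#' the side with the greater intensity fall-off.
#'
#' @param axial_image x-by-y matrix (e.g. [mean_intensity_projection()]).
#' @param n_points Number of arch samples C.
#' @param threshold Intensity threshold; NULL for Otsu's method.
#' @param min_foreground_fraction Error below this foreground fraction.
#' @return A `dental_arch`: `points` (C x 2, 0-based voxel coords),
#'   `normals` (C x 2 unit), `arclen` (cumulative, voxel units).
#' @export
detect_dental_arch <- function(axial_image, n_points = 400, threshold = NULL,
                               min_foreground_fraction = 1e-4) {
  rng <- range(axial_image)
  if (is.null(threshold)) {
    if (diff(rng) <= 0) stop("no arch found: constant image")
    threshold <- otsu_top_class(axial_image)
  }
  bw <- axial_image >= threshold
  if (mean(bw) < min_foreground_fraction) stop("no arch found")
  lab <- cpp_label_components(bw)
  tab <- tabulate(lab)
  comp <- lab == which.max(tab)
  # per-x-column foreground centroid in y, 0-based (comp is x-by-y)
  xs <- which(rowSums(comp) > 0)
  ys <- vapply(xs, function(i) {
    j <- which(comp[i, ])
    mean(j - 1)
  }, 0)
  wts <- rowSums(comp)[xs]
  xs0 <- xs - 1
  if (length(xs0) < 2) stop("no arch found")
  deg <- min(4, length(xs0) - 1)
  fit <- stats::lm(ys ~ stats::poly(xs0, degree = deg, raw = TRUE),
                   weights = wts)
  xf <- seq(min(xs0), max(xs0), length.out = max(4 * n_points, 800))
  yf <- stats::predict(fit, newdata = data.frame(xs0 = xf))
  seg <- sqrt(diff(xf)^2 + diff(yf)^2)
  cum <- c(0, cumsum(seg))
  s_new <- seq(0, max(cum), length.out = n_points)
  px <- stats::approx(cum, xf, xout = s_new)$y
  py <- stats::approx(cum, yf, xout = s_new)$y
  # tangents by central differences, normals by +90 deg rotation
  tx <- c(px[2] - px[1], (px[-(1:2)] - px[-c(n_points - 1, n_points)]) / 2,
          px[n_points] - px[n_points - 1])
  ty <- c(py[2] - py[1], (py[-(1:2)] - py[-c(n_points - 1, n_points)]) / 2,
          py[n_points] - py[n_points - 1])
  tl <- sqrt(tx^2 + ty^2)
  tx <- tx / tl; ty <- ty / tl
  nx <- -ty; ny <- tx
  # orient normals toward the side with greater intensity fall-off
  probe <- function(sgn) {
    acc <- 0
    for (dd in c(3, 6, 9)) {
      qx <- round(px + sgn * dd * nx) + 1
      qy <- round(py + sgn * dd * ny) + 1
      ok <- qx >= 1 & qx <= nrow(axial_image) & qy >= 1 & qy <= ncol(axial_image)
      vals <- rep(rng[1], n_points)
      vals[ok] <- axial_image[cbind(qx[ok], qy[ok])]
      acc <- acc + mean(vals)
    }
    acc
  }
  if (probe(+1) > probe(-1)) { nx <- -nx; ny <- -ny }
  arc <- c(0, cumsum(sqrt(diff(px)^2 + diff(py)^2)))
  structure(list(points = cbind(px, py), normals = cbind(nx, ny),
                 arclen = arc), class = "dental_arch")
}

# Three-class Otsu threshold: exhaustive search over two cut points of a
# 256-bin histogram maximizing the between-class variance; returns the
# upper cut (the brightest class's lower bound). CBCT-derived projections
# are typically trimodal (air | soft tissue and bone | teeth), where the
# classic two-class split lands between air and tissue; the top class of
# the three-class split isolates the teeth.
otsu_top_class <- function(img, nbins = 256) {
  rng <- range(img)
  if (diff(rng) <= 0) stop("constant image has no threshold")
  h <- tabulate(pmin(pmax(
    findInterval(img, seq(rng[1], rng[2], length.out = nbins + 1),
                 rightmost.closed = TRUE), 1L), nbins), nbins)
  p <- h / sum(h)
  centers <- rng[1] + (seq_len(nbins) - 0.5) * diff(rng) / nbins
  cw <- cumsum(p)
  cm <- cumsum(p * centers)
  mu <- cm[nbins]
  best <- -Inf; best_cut2 <- nbins - 1L
  for (cut1 in 1:(nbins - 2)) {
    w0 <- cw[cut1]
    m0 <- if (w0 > 0) cm[cut1] / w0 else 0
    for (cut2 in (cut1 + 1):(nbins - 1)) {
      w1 <- cw[cut2] - cw[cut1]
      w2 <- 1 - cw[cut2]
      m1 <- if (w1 > 0) (cm[cut2] - cm[cut1]) / w1 else 0
      m2 <- if (w2 > 0) (cm[nbins] - cm[cut2]) / w2 else 0
      v <- w0 * (m0 - mu)^2 + w1 * (m1 - mu)^2 + w2 * (m2 - mu)^2
      if (v > best) { best <- v; best_cut2 <- cut2 }
    }
  }
  rng[1] + best_cut2 * diff(rng) / nbins
}

#' Panoramic projection of a volume along the dental arch
#'
#' Integrates intensities along the arch-normal segment `[-w, w]` (mm) at
#' each arch sample and each z, by midpoint-rule sampling with trilinear
#' interpolation. Pixels are indexed `(c, z)`; values carry units of
#' intensity times mm. In-plane spacing must be isotropic.
#'
#' @param volume A [voxel_volume()].
#' @param arch A `dental_arch` from [detect_dental_arch()].
#' @param halfwidth_mm Band half-thickness w, mm.
#' @param background Contribution of out-of-volume samples (default: the
#'   volume minimum).
#' @param dt_mm Sampling step (default one eighth of the smallest voxel
#'   spacing, which keeps the midpoint-rule quadrature error below the
#'   trilinear interpolation error even on voxel-scale intensity texture).
#' @return A `panoramic_image` matrix (C x nz) with provenance attributes.
#' @export
panoramic_projection <- function(volume, arch, halfwidth_mm = 8,
                                 background = NULL, dt_mm = NULL) {
  sp <- volume$spacing
  if (abs(sp[1] - sp[2]) > 1e-9 * max(sp))
    stop("panoramic projection requires isotropic in-plane spacing")
  if (is.null(background)) background <- min(volume$intensities)
  if (is.null(dt_mm)) dt_mm <- min(sp) / 8
  img <- cpp_panoramic(as.numeric(volume$intensities),
                       dim(volume$intensities), arch$points, arch$normals,
                       halfwidth_mm, sp[1], dt_mm, background)
  structure(img, class = c("panoramic_image", "matrix"), arch = arch,
            halfwidth_mm = halfwidth_mm)
}

#' Export a panoramic image as PNG or 16-bit TIFF
#'
#' Intensities are scaled linearly to the full range; the image is written
#' with z up and the arch index along x. PNG output is 8-bit, TIFF 16-bit.
#'
#' @param pano A `panoramic_image` from [panoramic_projection()].
#' @param path Output path (`.png` or `.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_panoramic <- function(pano, path) {
  m <- unclass(pano)
  rng <- range(m)
  norm <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
  img <- t(norm)[rev(seq_len(ncol(norm))), , drop = FALSE] # z up, c along x
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(img, path)
  else if (ext %in% c("tif", "tiff"))
    tiff::writeTIFF(img, path, bits.per.sample = 16L)
  else stop("unsupported panoramic image format: ", path)
  invisible(path)
}

#' Classical panoramic instance segmenter
#'
#' Thresholds the panoramic image (Otsu unless overridden) and splits the
#' foreground into 8-connected components, dropping small ones. Interface:
#' `function(pano) -> list of n x 2 0-based (c, z) pixel matrices`.
#'
#' @param threshold NULL for Otsu.
#' @param min_pixels Minimum component size.
#' @return A segmenter function.
#' @export
pano_segmenter_threshold <- function(threshold = NULL, min_pixels = 40) {
  function(pano) {
    m <- unclass(pano)
    rng <- range(m)
    thr <- threshold
    if (is.null(thr)) {
      if (diff(rng) <= 0) return(list())
      thr <- otsu_top_class(m)
    }
    bw <- m >= thr
    if (!any(bw)) return(list())
    lab <- cpp_label_components(bw)
    tab <- tabulate(lab)
    keep <- which(tab >= min_pixels)
    lapply(keep, function(k) unname(which(lab == k, arr.ind = TRUE) - 1L))
  }
}

#' Split panoramic masks into upper and lower jaw groups
#'
#' Fits an ordinary least-squares boundary line `z = a c + b` to the mask
#' centroids; masks whose centroid lies above (or exactly on) the line are
#' upper, the rest lower.
#'
#' @param pano_masks List of n x 2 0-based (c, z) pixel matrices.
#' @param dim Panoramic image dimensions `c(C, nz)`.
#' @return A list: `upper_ids`, `lower_ids` (indices into `pano_masks`),
#'   `upper_mask`/`lower_mask` (logical C x nz), `boundary`
#'   (`c(slope, intercept)`).
#' @export
split_panoramic_upper_lower <- function(pano_masks, dim) {
  if (length(pano_masks) < 2)
    stop("need at least 2 panoramic masks to estimate the jaw boundary")
  cen <- t(vapply(pano_masks, colMeans, numeric(2)))
  fit <- stats::lsfit(cen[, 1], cen[, 2])
  b <- fit$coefficients[1]; a <- fit$coefficients[2]
  if (is.na(a)) { a <- 0 } # all centroids share one c: horizontal boundary
  up <- cen[, 2] >= a * cen[, 1] + b # ties go upper (documented)
  mk <- function(ids) {
    m <- matrix(FALSE, dim[1], dim[2])
    for (i in ids) {
      px <- pano_masks[[i]]
      inb <- px[, 1] >= 0 & px[, 1] < dim[1] & px[, 2] >= 0 & px[, 2] < dim[2]
      m[px[inb, , drop = FALSE] + 1L] <- TRUE
    }
    m
  }
  list(upper_ids = which(up), lower_ids = which(!up),
       upper_mask = mk(which(up)), lower_mask = mk(which(!up)),
       boundary = c(slope = unname(a), intercept = unname(b)))
}

#' Project slice-mask representative points into panoramic coordinates
#'
#' Each representative point's axial position is matched to its nearest
#' arch sample (ties toward the smaller index); points whose signed offset
#' along the arch normal exceeds the band half-width are dropped.
#'
#' @param masks List of `slice_mask` objects.
#' @param arch A `dental_arch`.
#' @param halfwidth_mm Band half-width w, mm.
#' @param spacing_xy In-plane voxel spacing, mm.
#' @return A data frame with columns `q` (0-based arch index), `z` (voxel
#'   units), `mask` (index into `masks`), plus attribute `n_dropped`.
#' @export
project_representative_points <- function(masks, arch, halfwidth_mm = 8,
                                          spacing_xy = 1) {
  if (length(masks) == 0)
    return(structure(data.frame(q = integer(0), z = numeric(0),
                                mask = integer(0)), n_dropped = 0L))
  reps <- t(vapply(masks, function(m) m$rep, numeric(3)))
  A <- arch$points
  qs <- integer(nrow(reps)); zs <- numeric(nrow(reps)); keep <- logical(nrow(reps))
  for (i in seq_len(nrow(reps))) {
    p <- reps[i, c(1, 2)]
    d2 <- (A[, 1] - p[1])^2 + (A[, 2] - p[2])^2
    c0 <- which.min(d2) # ties resolved toward smaller c
    off_vox <- sum((p - A[c0, ]) * arch$normals[c0, ])
    if (abs(off_vox) * spacing_xy <= halfwidth_mm) {
      qs[i] <- c0 - 1L
      zs[i] <- reps[i, 3]
      keep[i] <- TRUE
    }
  }
  structure(data.frame(q = qs[keep], z = zs[keep], mask = which(keep)),
            n_dropped = sum(!keep))
}

#' Classify slice masks into jaws via the panoramic split
#'
#' A projected representative point falling inside an upper (lower)
#' panoramic mask pixel sends its slice mask to the upper (lower) group;
#' points in neither mask fall back to the boundary-line side (ties
#' upper). Merged per-jaw point clouds are built from all foreground voxel
#' centers of the grouped masks, in world mm.
#'
#' @param projected Result of [project_representative_points()].
#' @param split Result of [split_panoramic_upper_lower()].
#' @param masks The `slice_mask` list the projections refer to.
#' @param volume The source [voxel_volume()] (for world coordinates).
#' @param subvoxel_boundary Refine boundary voxel positions to the
#'   threshold iso-level along the local intensity gradient (partial-volume
#'   intensities carry subvoxel boundary information; mask voxel centers
#'   alone are biased half a voxel inward on average). Interior voxels stay
#'   at their centers.
#' @param threshold_hu Iso-level used by the subvoxel refinement (the
#'   segmentation threshold).
#' @return A `jaw_split`: `upper_mask_ids`, `lower_mask_ids`,
#'   `upper_points`, `lower_points` (world mm), `upper_voxels`,
#'   `lower_voxels` (0-based voxel indices), `boundary`, `n_fallback`.
#' @export
classify_slice_masks <- function(projected, split, masks, volume,
                                 subvoxel_boundary = TRUE,
                                 threshold_hu = 1200) {
  dimp <- dim(split$upper_mask)
  up_ids <- integer(0); lo_ids <- integer(0); nfb <- 0L
  for (r in seq_len(nrow(projected))) {
    ci <- projected$q[r] + 1L
    zi <- round(projected$z[r]) + 1L
    mid <- projected$mask[r]
    inb <- ci >= 1 && ci <= dimp[1] && zi >= 1 && zi <= dimp[2]
    if (inb && split$upper_mask[ci, zi]) up_ids <- c(up_ids, mid)
    else if (inb && split$lower_mask[ci, zi]) lo_ids <- c(lo_ids, mid)
    else {
      nfb <- nfb + 1L
      zline <- split$boundary[1] * projected$q[r] + split$boundary[2]
      if (projected$z[r] >= zline) up_ids <- c(up_ids, mid)
      else lo_ids <- c(lo_ids, mid)
    }
  }
  vox_of <- function(ids) {
    if (length(ids) == 0) return(matrix(integer(0), 0, 3))
    do.call(rbind, lapply(ids, function(i) {
      px <- masks[[i]]$pixels
      cbind(px[, 1], masks[[i]]$s, px[, 2])
    }))
  }
  up_vox <- vox_of(up_ids); lo_vox <- vox_of(lo_ids)
  pts_of <- function(vox) {
    p <- voxel_to_world(volume, vox)
    if (subvoxel_boundary && nrow(vox) > 0)
      p <- subvoxel_refine(p, vox, volume, threshold_hu)
    p
  }
  structure(list(upper_mask_ids = up_ids, lower_mask_ids = lo_ids,
                 upper_points = pts_of(up_vox), lower_points = pts_of(lo_vox),
                 upper_voxels = up_vox, lower_voxels = lo_vox,
                 boundary = split$boundary, n_fallback = nfb),
            class = "jaw_split")
}

# move boundary voxel points to the threshold iso-level along the local
# intensity gradient (central differences), clamped to 0.6 voxel; interior
# voxels (gradient magnitude ~0 or far above threshold) are left in place
subvoxel_refine <- function(pts, vox, volume, threshold_hu) {
  arr <- volume$intensities
  d <- dim(arr)
  sp <- volume$spacing
  idx1 <- vox + 1L
  at <- function(dx, dy, dz) {
    i <- pmin(pmax(idx1[, 1] + dx, 1L), d[1])
    j <- pmin(pmax(idx1[, 2] + dy, 1L), d[2])
    k <- pmin(pmax(idx1[, 3] + dz, 1L), d[3])
    arr[cbind(i, j, k)]
  }
  I0 <- at(0L, 0L, 0L)
  xp <- at(1L, 0L, 0L); xm <- at(-1L, 0L, 0L)
  yp <- at(0L, 1L, 0L); ym <- at(0L, -1L, 0L)
  zp <- at(0L, 0L, 1L); zm <- at(0L, 0L, -1L)
  g <- cbind((xp - xm) / (2 * sp[1]), (yp - ym) / (2 * sp[2]),
             (zp - zm) / (2 * sp[3]))
  gn <- sqrt(rowSums(g^2))
  # only true boundary voxels move: at least one 6-neighbour below threshold
  boundary <- pmin(xp, xm, yp, ym, zp, zm) < threshold_hu
  move <- boundary & gn > 1e-6
  delta <- numeric(nrow(pts))
  delta[move] <- (I0[move] - threshold_hu) / gn[move]
  lim <- 0.6 * min(sp)
  delta <- pmin(pmax(delta, -lim), lim)
  pts - (delta / pmax(gn, 1e-6)) * g
}

#' @export
print.jaw_split <- function(x, ...) {
  cat(sprintf("Jaw split: %d upper masks (%d voxels), %d lower masks (%d voxels), %d fallback assignments\n",
              length(x$upper_mask_ids), nrow(x$upper_points),
              length(x$lower_mask_ids), nrow(x$lower_points), x$n_fallback))
  invisible(x)
}

#' Full CBCT teeth segmentation: slices, arch, panorama, jaw split
#'
#' Runs the complete CBCT-side extraction: optional ROI crop, sagittal
#' slice segmentation, arch detection on the mean intensity projection,
#' panoramic projection, panoramic instance segmentation, boundary
#' regression, and jaw classification of every slice mask.
#'
#' @param volume A [voxel_volume()].
#' @param config A [pipeline_config()] (its `cbct` section is used).
#' @param slice_segmenter,pano_segmenter Optional segmenter overrides
#'   (defaults: classical threshold segmenters).
#' @return A list: `jaw_split`, `arch`, `pano`, `slice_masks`,
#'   `projected`, `pano_split`.
#' @export
segment_cbct <- function(volume, config = pipeline_config(),
                         slice_segmenter = NULL, pano_segmenter = NULL) {
  cc <- config$cbct
  if (!is.null(cc$roi)) volume <- extract_roi(volume, cc$roi)
  if (is.null(slice_segmenter))
    slice_segmenter <- slice_segmenter_threshold(cc$threshold_hu,
                                                 cc$min_component_voxels)
  if (is.null(pano_segmenter))
    pano_segmenter <- pano_segmenter_threshold(min_pixels = cc$pano_min_pixels)
  masks <- segment_sagittal_slices(volume, slice_segmenter)
  mip <- mean_intensity_projection(volume, cc$mip_z_range)
  arch <- detect_dental_arch(mip, n_points = cc$arch_points,
                             threshold = cc$arch_threshold,
                             min_foreground_fraction = cc$min_foreground_fraction)
  pano <- panoramic_projection(volume, arch, cc$band_halfwidth_mm)
  pmasks <- pano_segmenter(pano)
  split <- split_panoramic_upper_lower(pmasks, dim(pano))
  projected <- project_representative_points(masks, arch,
                                             cc$band_halfwidth_mm,
                                             volume$spacing[1])
  js <- classify_slice_masks(projected, split, masks, volume,
                             subvoxel_boundary = cc$subvoxel_boundary,
                             threshold_hu = cc$threshold_hu)
  list(jaw_split = js, arch = arch, pano = pano, slice_masks = masks,
       projected = projected, pano_split = split)
}
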