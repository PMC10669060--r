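#' Synthetic dental phantom specification
#'
#' Describes a paired CBCT volume / colored intraoral-scan phantom: teeth
#' with superellipsoid crowns and tapering conical roots placed along a
#' parabolic dental arch, mirrored upper and lower jaws separated by a
#' configurable inter-occlusal gap (0 = clenched), embedded in a bone band
#' and soft-tissue background; crown surfaces plus a gingival collar are
#' sampled as colored point clouds and exported under a seeded random rigid
#' misalignment whose inverse is recorded as ground truth.
#'
#' @param arch_width Distance between the posterior arch ends, mm.
#' @param arch_depth Anterior extent of the parabolic arch, mm.
#' @param teeth_per_jaw Number of teeth in each jaw.
#' @param crown_height,root_length,crown_radius Base tooth dimensions, mm;
#'   a per-position anatomy profile (incisors smaller, molars larger) and
#'   per-tooth jitter are applied on top.
#' @param tooth_jitter Fractional uniform jitter applied per tooth to its
#'   dimensions.
#' @param occlusal_gap Vertical gap between upper and lower crowns, mm
#'   (>= 0; 0 is the clenched case).
#' @param spacing Voxel spacing, mm (length 3).
#' @param teeth_hu,bone_hu,soft_hu,air_hu Intensity levels; must be
#'   strictly decreasing in this order.
#' @param noise_sd Additive Gaussian intensity noise, HU.
#' @param teeth_hue,teeth_hue_sd,teeth_sat_max,teeth_val_min Tooth color
#'   model: hue (degrees) mean/sd, saturation cap, value floor.
#' @param gum_hue,gum_hue_sd,gum_sat,gum_val Gingiva color model: hue near
#'   red (degrees, wraps), saturation and value ranges.
#' @param surface_density Surface sampling density, points per mm^2.
#' @param pose_max_rotation,pose_max_translation Ranges of the random rigid
#'   misalignment applied to the exported IOS surfaces (deg, mm). Set both
#'   to 0 for an identity pose.
#' @param seed RNG seed used by [generate_phantom()].
#' @return A `phantom_spec` object (validated list).
#' @export
phantom_spec <- function(arch_width = 50, arch_depth = 40, teeth_per_jaw = 14,
                         crown_height = 7.5, root_length = 11,
                         crown_radius = 3.2, tooth_jitter = 0.05,
                         occlusal_gap = 2, spacing = c(0.3, 0.3, 0.3),
                         teeth_hu = 2000, bone_hu = 800, soft_hu = 150,
                         air_hu = -1000, noise_sd = 40,
                         teeth_hue = 50, teeth_hue_sd = 10,
                         teeth_sat_max = 0.15, teeth_val_min = 0.8,
                         gum_hue = 350, gum_hue_sd = 6,
                         gum_sat = c(0.4, 0.8), gum_val = c(0.4, 0.8),
                         surface_density = 4,
                         pose_max_rotation = 15, pose_max_translation = 10,
                         seed = 1) {
  spec <- as.list(environment())
  lens <- c(arch_width, arch_depth, crown_height, root_length, crown_radius,
            surface_density, spacing)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("invalid spec: lengths, densities and spacing must be positive")
  if (occlusal_gap < 0) stop("invalid spec: occlusal_gap must be >= 0")
  if (!(teeth_hu > bone_hu && bone_hu > soft_hu && soft_hu > air_hu))
    stop("invalid spec: intensities must be ordered teeth > bone > soft > air")
  if (teeth_per_jaw < 2) stop("invalid spec: need at least 2 teeth per jaw")
  structure(spec, class = "phantom_spec")
}

#' Named phantom presets
#'
#' `"standard"`: 14 teeth per jaw at 0.3 mm voxels with a 2 mm
#' inter-occlusal gap; `"clenched"`: the same with gap 0 (the hard case for
#' jaw separation); `"tiny"`: 6 teeth per jaw at 0.6 mm voxels on a smaller
#' arch, for fast tests.
#'
#' @param name Preset name.
#' @return `phantom_preset` returns one `phantom_spec`; `default_specs`
#'   returns a named list of all presets.
#' @export
phantom_preset <- function(name) {
  switch(name,
    standard = phantom_spec(),
    clenched = phantom_spec(occlusal_gap = 0),
    tiny = phantom_spec(arch_width = 34, arch_depth = 26, teeth_per_jaw = 6,
                        spacing = c(0.6, 0.6, 0.6), surface_density = 3),
    stop("unknown phantom preset: ", name))
}

#' @rdname phantom_preset
#' @export
default_specs <- function() {
  specs <- lapply(c("standard", "clenched", "tiny"), phantom_preset)
  names(specs) <- c("standard", "clenched", "tiny")
  specs
}

# parabolic arch curve y(x) = depth * (1 - (2x/width)^2), sampled finely,
# with cumulative arc length
arch_curve <- function(width, depth, n = 2001) {
  hw <- width / 2
  x <- seq(-hw, hw, length.out = n)
  y <- depth * (1 - (x / hw)^2)
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  list(x = x, y = y, arclen = c(0, cumsum(seg)))
}

# per-position anatomical profiles for k teeth per side (front to back):
# relative crown size, buccolingual ellipse factor, cuspal ripple amplitude
# and cusp count. Incisors are narrow two-lobed blades, molars broad
# multi-cusped blocks; the asymmetric cross-sections and cusps are what
# give local surface descriptors something to grab onto, as on real teeth.
tooth_size_profile <- function(per_side) {
  interp <- function(base) stats::approx(seq(0, 1, length.out = length(base)),
                                         base,
                                         xout = seq(0, 1, length.out = per_side))$y
  list(size = interp(c(0.70, 0.64, 0.76, 0.94, 1.00, 1.25, 1.19)),
       ell_b = interp(c(0.60, 0.60, 0.72, 0.85, 0.85, 0.95, 0.95)),
       cusp_amp = interp(c(0.03, 0.03, 0.05, 0.07, 0.07, 0.08, 0.08)),
       cusp_n = round(interp(c(2, 2, 3, 4, 4, 4, 4))))
}

# radial shape factor s(theta) of a crown cross-section: ellipse (minor
# factor b along the local buccolingual axis) times cuspal ripple
crown_shape_factor <- function(theta, psi, ell_b, cusp_amp, cusp_n,
                               cusp_phase) {
  th <- theta - psi
  es <- ell_b / sqrt(ell_b^2 * cos(th)^2 + sin(th)^2)
  es * (1 + cusp_amp * cos(cusp_n * th + cusp_phase))
}

#' Generate a synthetic dental phantom
#'
#' Rasterizes the phantom volume, samples the upper and lower IOS surfaces
#' (crowns colored whitish, gingival collar pink), applies a seeded random
#' rigid pose to both IOS surfaces and records its inverse as the
#' ground-truth IOS-to-CBCT transform. Deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `volume` ([voxel_volume()]), `upper` and
#'   `lower` ([colored_surface()], labels `"crown"`/`"gingiva"`), and
#'   `truth`: per-voxel tooth label array (`tooth_labels`, 0 = background),
#'   jaw of each tooth label (`jaw_of_tooth`), per-surface-point tooth id
#'   and jaw (`upper_info`, `lower_info`), the applied pose and the
#'   ground-truth `transform` mapping exported IOS coordinates into the
#'   CBCT world frame, plus the per-tooth geometry table (`teeth`).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  per_side <- spec$teeth_per_jaw / 2
  if (per_side != round(per_side))
    stop("invalid spec: teeth_per_jaw must be even")
  prof <- tooth_size_profile(per_side)
  mirror <- function(v) c(rev(v), v) # left molar .. right molar
  radii0 <- spec$crown_radius * mirror(prof$size)
  ell_b0 <- mirror(prof$ell_b)
  cusp_amp0 <- mirror(prof$cusp_amp)
  cusp_n0 <- mirror(prof$cusp_n)
  K <- spec$teeth_per_jaw
  jit <- function(n) 1 + spec$tooth_jitter * stats::runif(n, -1, 1)
  # geometry per tooth and per jaw (jaws get independent jitter)
  teeth <- list()
  curve <- arch_curve(spec$arch_width, spec$arch_depth)
  total_len <- max(curve$arclen)
  for (jaw in c("lower", "upper")) {
    radii <- radii0 * jit(K)
    ch <- spec$crown_height * jit(K)
    rl <- spec$root_length * jit(K)
    need <- sum(2 * radii) + (K - 1) * 0.12 * mean(radii) * 2
    if (need > 0.98 * total_len)
      stop("invalid spec: teeth overlap beyond tolerance (arch too short ",
           "for ", K, " teeth of this size)")
    gapw <- (0.12 * mean(radii) * 2)
    centers_s <- numeric(K)
    run <- (total_len - need) / 2
    for (i in seq_len(K)) {
      centers_s[i] <- run + radii[i]
      run <- run + 2 * radii[i] + gapw
    }
    cx <- stats::approx(curve$arclen, curve$x, xout = centers_s)$y
    cy <- stats::approx(curve$arclen, curve$y, xout = centers_s)$y
    # local arch tangent angle: crown major axis follows the arch
    eps <- total_len * 1e-4
    txv <- stats::approx(curve$arclen, curve$x, xout = centers_s + eps)$y -
      stats::approx(curve$arclen, curve$x, xout = centers_s - eps)$y
    tyv <- stats::approx(curve$arclen, curve$y, xout = centers_s + eps)$y -
      stats::approx(curve$arclen, curve$y, xout = centers_s - eps)$y
    psi <- atan2(tyv, txv)
    sgn <- if (jaw == "lower") -1 else 1
    occ <- sgn * spec$occlusal_gap / 2
    crown_zlo <- ifelse(rep(jaw == "lower", K), occ - ch, occ)
    crown_zhi <- ifelse(rep(jaw == "lower", K), occ, occ + ch)
    root_zlo <- ifelse(rep(jaw == "lower", K), crown_zlo - rl, crown_zhi)
    root_zhi <- ifelse(rep(jaw == "lower", K), crown_zlo, crown_zhi + rl)
    root_r_lo <- ifelse(rep(jaw == "lower", K), 0.15 * radii, 0.60 * radii)
    root_r_hi <- ifelse(rep(jaw == "lower", K), 0.60 * radii, 0.15 * radii)
    teeth[[jaw]] <- data.frame(
      jaw = jaw, cx = cx, cy = cy, crown_r = radii, exponent = 4,
      crown_zlo = crown_zlo, crown_zhi = crown_zhi,
      root_zlo = root_zlo, root_zhi = root_zhi,
      root_r_lo = root_r_lo, root_r_hi = root_r_hi,
      crown_h = ch, root_l = rl,
      psi = psi, ell_b = ell_b0, cusp_amp = cusp_amp0, cusp_n = cusp_n0,
      cusp_phase = stats::runif(K, 0, 2 * pi))
  }
  tt <- rbind(teeth$lower, teeth$upper)
  tt$label <- seq_len(nrow(tt))
  jaw_of_tooth <- tt$jaw

  # volume geometry
  rmax <- max(tt$crown_r)
  margin <- 5
  xlim <- c(-spec$arch_width / 2 - rmax - margin,
            spec$arch_width / 2 + rmax + margin)
  ylim <- c(-rmax - margin, spec$arch_depth + rmax + margin)
  zlim <- c(min(tt$root_zlo) - margin, max(tt$root_zhi) + margin)
  dims <- as.integer(ceiling(c(diff(xlim), diff(ylim), diff(zlim)) / spec$spacing))
  origin <- c(xlim[1], ylim[1], zlim[1])

  # bone band around the arch polyline in each root zone
  pl_idx <- round(seq(1, length(curve$x), length.out = 120))
  polyline <- cbind(curve$x[pl_idx], curve$y[pl_idx])
  bone_r <- rmax + 2.5
  bone_lo <- c(zlim[1] + 1, -spec$occlusal_gap / 2 - mean(tt$crown_h[tt$jaw == "lower"]))
  bone_hi <- c(spec$occlusal_gap / 2 + mean(tt$crown_h[tt$jaw == "upper"]), zlim[2] - 1)
  soft <- c(0, spec$arch_depth / 2,
            spec$arch_width / 2 + rmax + 3.5, spec$arch_depth / 2 + rmax + 3.5)

  ras <- cpp_rasterize_phantom(
    dims, spec$spacing, origin,
    as.matrix(tt[, c("cx", "cy", "crown_r", "exponent", "crown_zlo",
                     "crown_zhi", "root_zlo", "root_zhi", "root_r_lo",
                     "root_r_hi", "label", "psi", "ell_b", "cusp_amp",
                     "cusp_n", "cusp_phase")]),
    polyline, bone_r, bone_lo, bone_hi, soft,
    spec$teeth_hu, spec$bone_hu, spec$soft_hu, spec$air_hu)
  intens <- ras$intensities
  if (spec$noise_sd > 0)
    intens <- intens + stats::rnorm(length(intens), 0, spec$noise_sd)
  dim(intens) <- dims
  volume <- voxel_volume(intens, spec$spacing, origin)

  # IOS surfaces in the CBCT frame
  surf <- list()
  info <- list()
  for (jaw in c("lower", "upper")) {
    rows <- which(tt$jaw == jaw)
    pts <- list(); nrm <- list(); lab <- list(); ids <- list()
    for (r in rows) {
      cr <- sample_crown_surface(tt[r, ], spec$surface_density)
      co <- sample_collar_surface(tt[r, ], spec$surface_density)
      pts[[length(pts) + 1]] <- cr$points
      nrm[[length(nrm) + 1]] <- cr$normals
      lab[[length(lab) + 1]] <- rep("crown", nrow(cr$points))
      ids[[length(ids) + 1]] <- rep(tt$label[r], nrow(cr$points))
      pts[[length(pts) + 1]] <- co$points
      nrm[[length(nrm) + 1]] <- co$normals
      lab[[length(lab) + 1]] <- rep("gingiva", nrow(co$points))
      ids[[length(ids) + 1]] <- rep(tt$label[r], nrow(co$points))
    }
    p <- do.call(rbind, pts)
    l <- unlist(lab)
    colors <- phantom_colors(l, spec)
    # scanners export per-vertex normals; the phantom provides the exact
    # analytic outward normals of its surfaces
    surf[[jaw]] <- colored_surface(p, colors, normals = do.call(rbind, nrm),
                                   labels = l)
    info[[jaw]] <- data.frame(tooth = unlist(ids), type = l, jaw = jaw)
  }

  # seeded random misalignment; truth maps exported IOS coords -> CBCT world
  pose <- if (spec$pose_max_rotation > 0 || spec$pose_max_translation > 0)
    random_rigid_transform(spec$pose_max_rotation, spec$pose_max_translation)
  else rigid_transform()
  upper <- apply_transform(surf$upper, pose)
  lower <- apply_transform(surf$lower, pose)

  truth <- list(tooth_labels = ras$labels, jaw_of_tooth = jaw_of_tooth,
                applied_pose = pose, transform = invert_transform(pose),
                upper_info = info$upper, lower_info = info$lower,
                teeth = tt)
  list(volume = volume, upper = upper, lower = lower, truth = truth,
       spec = spec)
}

# area-weighted sampling of the superellipsoid-of-revolution crown surface;
# the cervical cap (hidden by gingiva/root) is excluded
sample_crown_surface <- function(tooth, density) {
  n_exp <- tooth$exponent
  r <- tooth$crown_r
  hh <- (tooth$crown_zhi - tooth$crown_zlo) / 2
  zc <- (tooth$crown_zhi + tooth$crown_zlo) / 2
  lower_jaw <- tooth$jaw == "lower"
  # profile parameterisation: phi in (0, pi), pole phi=0 at +z
  grid <- seq(1e-4, pi - 1e-4, length.out = 1024)
  e <- 2 / n_exp
  zf <- function(phi) zc + hh * sign(cos(phi)) * abs(cos(phi))^e
  rf <- function(phi) r * sin(phi)^e
  dz <- c(diff(zf(grid)), 0)
  dr <- c(diff(rf(grid)), 0)
  w <- rf(grid) * sqrt(dz^2 + dr^2)
  cdf <- cumsum(w)
  area <- 2 * pi * sum(w)
  cdf <- cdf / cdf[length(cdf)]
  n <- max(20, round(density * area))
  phi <- stats::approx(cdf, grid, xout = stats::runif(n), rule = 2,
                       ties = "ordered")$y
  theta <- stats::runif(n, 0, 2 * pi)
  z <- zf(phi)
  rho <- rf(phi) * crown_shape_factor(theta, tooth$psi, tooth$ell_b,
                                      tooth$cusp_amp, tooth$cusp_n,
                                      tooth$cusp_phase)
  keep <- if (lower_jaw) z > tooth$crown_zlo + 0.15 * 2 * hh
          else z < tooth$crown_zhi - 0.15 * 2 * hh
  pts <- cbind(tooth$cx + rho * cos(theta),
               tooth$cy + rho * sin(theta), z)[keep, , drop = FALSE]
  list(points = pts, normals = implicit_outward_normals(pts, function(p) {
    th <- atan2(p[, 2] - tooth$cy, p[, 1] - tooth$cx)
    s <- crown_shape_factor(th, tooth$psi, tooth$ell_b, tooth$cusp_amp,
                            tooth$cusp_n, tooth$cusp_phase)
    rr <- sqrt((p[, 1] - tooth$cx)^2 + (p[, 2] - tooth$cy)^2)
    (rr / (r * s))^n_exp + (abs(p[, 3] - zc) / hh)^n_exp
  }))
}

# exact outward normals of an implicit surface F = const by central
# finite differences of the (vectorised) field
implicit_outward_normals <- function(pts, F, h = 1e-5) {
  g <- matrix(0, nrow(pts), 3)
  for (a in 1:3) {
    hi <- pts; hi[, a] <- hi[, a] + h
    lo <- pts; lo[, a] <- lo[, a] - h
    g[, a] <- (F(hi) - F(lo)) / (2 * h)
  }
  g / pmax(sqrt(rowSums(g^2)), 1e-12)
}

# gingival collar: a short cylinder hugging the cervical margin plus a flat
# outward annulus (gum shoulder)
sample_collar_surface <- function(tooth, density) {
  r <- tooth$crown_r * 1.08
  lower_jaw <- tooth$jaw == "lower"
  cerv <- if (lower_jaw) tooth$crown_zlo else tooth$crown_zhi
  h <- 1.6
  zlo <- if (lower_jaw) cerv - h else cerv - 0.2
  zhi <- if (lower_jaw) cerv + 0.2 else cerv + h
  n1 <- max(10, round(density * 2 * pi * r * (zhi - zlo)))
  th1 <- stats::runif(n1, 0, 2 * pi)
  z1 <- stats::runif(n1, zlo, zhi)
  r1 <- r * crown_shape_factor(th1, tooth$psi, tooth$ell_b, tooth$cusp_amp,
                               tooth$cusp_n, tooth$cusp_phase)
  cyl <- cbind(tooth$cx + r1 * cos(th1), tooth$cy + r1 * sin(th1), z1)
  cyl_n <- implicit_outward_normals(cyl, function(p) {
    th <- atan2(p[, 2] - tooth$cy, p[, 1] - tooth$cx)
    s <- crown_shape_factor(th, tooth$psi, tooth$ell_b, tooth$cusp_amp,
                            tooth$cusp_n, tooth$cusp_phase)
    sqrt((p[, 1] - tooth$cx)^2 + (p[, 2] - tooth$cy)^2) - r * s
  })
  r2 <- tooth$crown_r * 1.6
  n2 <- max(10, round(density * pi * (r2^2 - r^2)))
  th2 <- stats::runif(n2, 0, 2 * pi)
  rr <- sqrt(stats::runif(n2, r^2, r2^2))
  zflat <- if (lower_jaw) zlo else zhi
  ann <- cbind(tooth$cx + rr * cos(th2), tooth$cy + rr * sin(th2), zflat)
  # the gum shoulder faces the occlusal opening
  ann_n <- matrix(rep(c(0, 0, if (lower_jaw) 1 else -1), each = n2), ncol = 3)
  list(points = rbind(cyl, ann), normals = rbind(cyl_n, ann_n))
}

# draw colors from the phantom color model for a crown/gingiva label vector
phantom_colors <- function(labels, spec) {
  n <- length(labels)
  h <- numeric(n); s <- numeric(n); v <- numeric(n)
  crown <- labels == "crown"
  nc <- sum(crown); ng <- n - nc
  h[crown] <- (stats::rnorm(nc, spec$teeth_hue, spec$teeth_hue_sd)) %% 360
  s[crown] <- stats::runif(nc, 0, spec$teeth_sat_max)
  v[crown] <- stats::runif(nc, spec$teeth_val_min, 1)
  h[!crown] <- (stats::rnorm(ng, spec$gum_hue, spec$gum_hue_sd)) %% 360
  s[!crown] <- stats::runif(ng, spec$gum_sat[1], spec$gum_sat[2])
  v[!crown] <- stats::runif(ng, spec$gum_val[1], spec$gum_val[2])
  t(grDevices::col2rgb(grDevices::hsv(h / 360, s, v))) / 255
}

#' Ground-truth segmenters derived from a phantom
#'
#' `truth_slice_segmenter` returns a sagittal-slice instance segmenter (the
#' same interface as [slice_segmenter_threshold()]) that reads per-tooth
#' instance masks off the phantom's voxel labels — a stand-in for the
#' trained instance detector whose output the pipeline consumes in the
#' clenched case, where intensity thresholding cannot separate touching
#' jaws. `truth_pano_segmenter` does the same in panoramic space, using the
#' arch to project the per-voxel tooth labels.
#'
#' @param phantom Result of [generate_phantom()].
#' @return A segmenter function.
#' @export
truth_slice_segmenter <- function(phantom) {
  labels <- phantom$truth$tooth_labels
  force(labels)
  function(slice, s) {
    lab <- labels[, s + 1, ]
    ids <- setdiff(unique(as.vector(lab)), 0L)
    out <- list()
    for (id in ids) {
      px <- which(lab == id, arr.ind = TRUE) - 1L # 0-based (x, z)
      out[[length(out) + 1]] <- unname(px)
    }
    out
  }
}

#' @rdname truth_slice_segmenter
#' @param band_halfwidth_mm Panoramic band half-thickness, mm (match the
#'   projection's).
#' @export
truth_pano_segmenter <- function(phantom, band_halfwidth_mm = 8) {
  labels <- phantom$truth$tooth_labels
  nlab <- nrow(phantom$truth$teeth)
  spacing <- phantom$volume$spacing
  force(labels); force(nlab); force(spacing)
  function(pano) {
    arch <- attr(pano, "arch")
    w <- attr(pano, "halfwidth_mm")
    if (is.null(arch)) stop("panoramic image lacks its arch provenance")
    masks <- cpp_pano_label_masks(labels, dim(labels), arch$points,
                                  arch$normals, w, spacing[1],
                                  min(spacing) / 2, nlab)
    out <- list()
    for (m in masks) {
      px <- which(m, arr.ind = TRUE) - 1L # 0-based (c, z)
      if (nrow(px) > 0) out[[length(out) + 1]] <- unname(px)
    }
    out
  }
}
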