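test_that("presets encode the study conditions", {
  specs <- default_specs()
  expect_equal(specs$standard$spacing, c(0.3, 0.3, 0.3))
  expect_equal(specs$standard$teeth_per_jaw, 14)
  expect_equal(specs$standard$occlusal_gap, 2)
  expect_equal(specs$clenched$occlusal_gap, 0)
  expect_equal(specs$tiny$teeth_per_jaw, 6)
  expect_equal(specs$tiny$spacing, c(0.6, 0.6, 0.6))
  expect_error(phantom_preset("molar-only"), "unknown")
})

test_that("spec validation rejects impossible phantoms", {
  expect_error(phantom_spec(occlusal_gap = -1), "gap")
  expect_error(phantom_spec(teeth_hu = 100, bone_hu = 800), "ordered")
  expect_error(phantom_spec(crown_radius = -2), "positive")
  expect_error(generate_phantom(phantom_spec(arch_width = 18, arch_depth = 10,
                                             teeth_per_jaw = 14)),
               "overlap")
})

test_that("a gapped phantom has an empty inter-occlusal slab", {
  ph <- get_phantom("tiny") # 2 mm gap
  v <- ph$volume
  d <- dim(v$intensities)
  zs <- v$origin[3] + v$spacing[3] * (0:(d[3] - 1))
  slab <- which(zs > -0.6 & zs < 0.6) # inside the 2 mm gap
  expect_gt(length(slab), 0)
  expect_equal(sum(ph$truth$tooth_labels[, , slab] > 0), 0)
  # and no teeth-level intensities there either (noise is far below)
  expect_lt(max(v$intensities[, , slab]), 1500)
})

test_that("the clenched phantom has adjacent but disjointly labeled jaws", {
  ph <- get_phantom("clenched")
  lab <- ph$truth$tooth_labels
  jaw_of <- ph$truth$jaw_of_tooth
  up <- which(array(jaw_of[ifelse(lab > 0, lab, NA)] == "upper", dim(lab)),
              arr.ind = TRUE)
  lo <- which(array(jaw_of[ifelse(lab > 0, lab, NA)] == "lower", dim(lab)),
              arr.ind = TRUE)
  expect_gt(nrow(up), 0)
  expect_gt(nrow(lo), 0)
  # disjoint by construction (one label per voxel); adjacency: some upper
  # voxel sits directly one z-step above a lower voxel at the same (x,y)
  ukey <- paste(up[, 1], up[, 2], up[, 3])
  lkey <- paste(lo[, 1], lo[, 2], lo[, 3] + 1)
  expect_gt(length(intersect(ukey, lkey)), 0)
})

test_that("the same seed reproduces the phantom bit for bit", {
  spec <- phantom_preset("tiny")
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$intensities, b$volume$intensities)
  expect_identical(a$upper$points, b$upper$points)
  expect_identical(a$upper$colors, b$upper$colors)
  expect_identical(unclass(a$truth$transform), unclass(b$truth$transform))
})

test_that("crown points lie within one voxel of a teeth-labeled voxel", {
  ph <- get_phantom("tiny")
  # undo the export pose to return to the CBCT frame
  up <- apply_transform(ph$upper, ph$truth$transform)
  crown <- up$points[ph$truth$upper_info$type == "crown", ]
  vox <- round(world_to_voxel(ph$volume, crown))
  d <- dim(ph$truth$tooth_labels)
  near_tooth <- vapply(seq_len(nrow(vox)), function(i) {
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      p <- vox[i, ] + c(dx, dy, dz)
      if (all(p >= 0) && all(p < d) &&
          ph$truth$tooth_labels[p[1] + 1, p[2] + 1, p[3] + 1] > 0)
        return(TRUE)
    }
    FALSE
  }, logical(1))
  expect_gte(mean(near_tooth), 0.999)
})

test_that("surface color classes are separable at default noise", {
  set.seed(31)
  spec <- phantom_spec()
  n <- 2000
  lab <- rep(c("crown", "gingiva"), each = n)
  hsv <- rgb_to_hsv(dentreg:::phantom_colors(lab, spec))
  # saturation alone separates the classes in this model; empirical Bayes
  # error of the best single threshold must be < 1%
  thr <- (spec$teeth_sat_max + spec$gum_sat[1]) / 2
  err <- mean(c(hsv[seq_len(n), "s"] > thr, hsv[n + seq_len(n), "s"] < thr))
  expect_lt(err, 0.01)
})

test_that("the intensity histogram shows the four material modes", {
  ph <- get_phantom("tiny")
  x <- as.numeric(ph$volume$intensities)
  spec <- ph$spec
  for (level in c(spec$air_hu, spec$soft_hu, spec$bone_hu, spec$teeth_hu)) {
    frac <- mean(abs(x - level) < 3 * spec$noise_sd)
    expect_gt(frac, 0.001) # each material occupies an appreciable mode
  }
  # and the modes are where they should be: local density near each level
  # exceeds density halfway between neighbouring levels
  dens <- stats::density(x, n = 2048)
  at <- function(v) dens$y[which.min(abs(dens$x - v))]
  expect_gt(at(spec$air_hu), at((spec$air_hu + spec$soft_hu) / 2))
  expect_gt(at(spec$teeth_hu), at((spec$bone_hu + spec$teeth_hu) / 2))
})

test_that("the recorded truth transform maps the exported scan back onto the teeth", {
  ph <- get_phantom("tiny")
  up <- apply_transform(ph$upper, ph$truth$transform)
  crown <- up$points[ph$truth$upper_info$type == "crown", ]
  # nearest teeth-voxel distance should be sub-voxel for crown points
  teeth_vox <- which(ph$truth$tooth_labels > 0, arr.ind = TRUE) - 1L
  teeth_world <- voxel_to_world(ph$volume, teeth_vox)
  nn <- dentreg:::cpp_nn(crown, teeth_world)
  expect_lt(stats::median(nn$dist), ph$volume$spacing[1])
})
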