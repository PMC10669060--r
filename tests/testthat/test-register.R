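test_that("voxel down-sampling buckets points and averages attributes", {
  # two points 0.1 mm apart in a 1 mm voxel collapse to their midpoint
  two <- matrix(c(0, 0, 0, 0.1, 0, 0), 2, 3, byrow = TRUE)
  out <- downsample_voxel(two, 1)
  expect_equal(nrow(out), 1)
  expect_equal(drop(out), c(0.05, 0, 0))
  # a voxel below the minimal pairwise gap keeps every point
  grid <- as.matrix(expand.grid(0:3, 0:3, 0:3))
  expect_equal(nrow(downsample_voxel(grid, 0.5)), 64)
  # bucket-count oracle on random points
  set.seed(41)
  pts <- matrix(runif(3e4, 0, 10), 1e4, 3)
  ds <- downsample_voxel(pts, 1)
  keys <- unique(paste(floor((pts[, 1] - min(pts[, 1])) / 1),
                       floor((pts[, 2] - min(pts[, 2])) / 1),
                       floor((pts[, 3] - min(pts[, 3])) / 1)))
  expect_equal(nrow(ds), length(keys))
  expect_lte(nrow(ds), 1000)
})

test_that("normal estimation recovers plane and sphere orientations", {
  set.seed(42)
  plane <- cbind(runif(400, -5, 5), runif(400, -5, 5), 0)
  nr <- estimate_normals(plane, 12)
  expect_lt(max(abs(abs(nr[, 3]) - 1)), 1e-6)
  # sphere sampled densely: within 2 degrees of radial after orientation
  v <- matrix(rnorm(18000), 6000, 3)
  v <- v / sqrt(rowSums(v^2))
  nr2 <- estimate_normals(v * 10, 20)
  ang <- acos(pmin(1, abs(rowSums(nr2 * v)))) * 180 / pi
  expect_lt(stats::quantile(ang, 0.99), 2)
  expect_gt(mean(rowSums(nr2 * v) > 0), 0.99) # oriented outward
  # too few points for the neighbourhood: error (covers 3 collinear points)
  line <- cbind(1:3, 0, 0)
  expect_error(estimate_normals(line, 3), "more points")
})

test_that("surface variation separates thin surfaces from filled solids", {
  set.seed(43)
  plane <- cbind(runif(500, -5, 5), runif(500, -5, 5), 0)
  sv_plane <- attr(estimate_normals(colored_surface(plane), 12),
                   "surface_variation")
  solid <- as.matrix(expand.grid(seq(0, 5, 0.5), seq(0, 5, 0.5),
                                 seq(0, 5, 0.5)))
  sv_solid <- attr(estimate_normals(colored_surface(solid), 26),
                   "surface_variation")
  expect_lt(stats::median(sv_plane), 0.02)
  interior <- rowSums(solid > 1 & solid < 4) == 3
  expect_gt(stats::median(sv_solid[interior]), 0.2)
})

test_that("registration result bookkeeping is consistent", {
  r <- registration_result(rigid_transform(), 0.8, 0.2, 12, TRUE)
  expect_equal(r$fi_ratio, 4)
  expect_error(registration_result(rigid_transform(), 1.4, 0.2, 1, TRUE))
  expect_error(registration_result(rigid_transform(), 0.5, -1, 1, TRUE))
})

test_that("RANSAC self-alignment of a seeded cloud is the identity", {
  ph <- get_phantom("tiny")
  cfg <- pipeline_config(seed = 3)
  teeth <- segment_ios(ph$upper, cfg)
  set.seed(1)
  src <- downsample_voxel(teeth, 0.5)
  res <- coarse_align_ransac(src, src, list(inlier_dist = 1))
  expect_lt(rotation_angle(res$transform), 0.01)
  expect_lt(sqrt(sum(unclass(res$transform)[1:3, 4]^2)), 1e-3)
  expect_gt(res$fitness, 0.99)
})

test_that("RANSAC recovers a known rigid transform within coarse tolerance", {
  ph <- get_phantom("tiny")
  cfg <- pipeline_config(seed = 3)
  teeth <- segment_ios(ph$upper, cfg)
  set.seed(2)
  src <- downsample_voxel(teeth, 0.5)
  G <- random_rigid_transform(30, 20)
  tgt <- apply_transform(src, G)
  res <- coarse_align_ransac(src, tgt, list(inlier_dist = 1))
  err <- compose_transform(res$transform, invert_transform(G))
  expect_lt(rotation_angle(err), 2)
  expect_lt(sqrt(sum(unclass(err)[1:3, 4]^2)), 1)
  # too few points
  tiny_cloud <- colored_surface(matrix(rnorm(6), 2, 3),
                                normals = matrix(rep(c(0, 0, 1), 2), 2, 3,
                                                 byrow = TRUE))
  expect_error(coarse_align_ransac(tiny_cloud, tiny_cloud, list()),
               "at least 3")
})

test_that("ICP at a zero-residual fixed point stays put", {
  ph <- get_phantom("tiny")
  cfg <- pipeline_config(seed = 3)
  teeth <- segment_ios(ph$upper, cfg)
  set.seed(3)
  src <- downsample_voxel(teeth, 0.5)
  res <- fine_align_icp(src, src, rigid_transform(), list(icp_refine = 0))
  expect_lt(rotation_angle(res$transform), 1e-3)
  expect_lt(res$inlier_rmse, 1e-6)
})

test_that("ICP solves a plane offset along its normal in one step", {
  set.seed(44)
  tgt_pts <- cbind(runif(3000, -10, 10), runif(3000, -10, 10), 0)
  tgt <- colored_surface(tgt_pts,
                         normals = matrix(rep(c(0, 0, 1), 3000), ncol = 3,
                                          byrow = TRUE))
  src <- tgt_pts[1:500, ]
  src[, 3] <- 0.5 # offset along the plane normal
  res <- fine_align_icp(src, tgt, rigid_transform(),
                        list(icp_max_iter = 1, icp_refine = 0,
                             icp_max_corr = 2))
  moved <- apply_transform(src, res$transform)
  expect_lt(max(abs(moved[, 3])), 1e-3)
})

test_that("ICP requires correspondences at the initial pose", {
  tgt <- colored_surface(matrix(runif(300), 100, 3),
                         normals = matrix(rep(c(0, 0, 1), 100), ncol = 3,
                                          byrow = TRUE))
  src <- matrix(runif(60), 20, 3) + 100
  expect_error(fine_align_icp(src, tgt, rigid_transform(), list()),
               "too poor")
})

test_that("the point-to-plane objective never increases within a solve", {
  ph <- get_phantom("tiny")
  seg <- get_segmented("tiny")
  cfg <- pipeline_config(seed = 3)
  teeth <- segment_ios(ph$upper, cfg)
  set.seed(5)
  src <- downsample_voxel(teeth, 0.5)
  tgt <- estimate_normals(colored_surface(seg$jaw_split$upper_points), 30,
                          orientation = "outward")
  res <- fine_align_icp(src, tgt, ph$truth$transform, list())
  tr <- attr(res, "objective_trace")
  expect_gt(length(tr$before), 0)
  expect_true(all(tr$after <= tr$before + 1e-9))
})

test_that("register_jaw is equivariant under a repose of the source", {
  ph <- get_phantom("tiny")
  seg <- get_segmented("tiny")
  cfg <- pipeline_config(seed = 7)
  teeth <- segment_ios(ph$upper, cfg)
  base <- register_jaw(teeth, seg$jaw_split$upper_points, cfg)
  G <- local({ set.seed(99); random_rigid_transform(10, 5) })
  reposed <- apply_transform(teeth, G)
  again <- register_jaw(reposed, seg$jaw_split$upper_points, cfg)
  # T2 should equal T1 o G^-1
  expected <- compose_transform(base$transform, invert_transform(G))
  err <- compose_transform(again$transform, invert_transform(expected))
  expect_lt(rotation_angle(err), 0.5)
  expect_lt(sqrt(sum(unclass(err)[1:3, 4]^2)), 0.1)
})

test_that("identical seeds give bit-identical transforms", {
  ph <- get_phantom("tiny")
  seg <- get_segmented("tiny")
  cfg <- pipeline_config(seed = 13)
  teeth <- segment_ios(ph$upper, cfg)
  a <- register_jaw(teeth, seg$jaw_split$upper_points, cfg)
  b <- register_jaw(teeth, seg$jaw_split$upper_points, cfg)
  expect_identical(unclass(a$transform), unclass(b$transform))
})
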