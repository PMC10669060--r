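test_that("representative point is the bounding-box center (x+w/2, s, z+h/2)", {
  expect_equal(representative_point(c(10, 20, 4, 6), 5), c(13, 5, 22))
  expect_equal(representative_point(c(0, 0, 2, 2), 0), c(1, 0, 1))
  # exact on an enumerated grid of boxes
  for (x in c(0, 3, 11)) for (z in c(0, 7)) for (h in 1:3) for (w in 1:3)
    expect_identical(representative_point(c(x, z, h, w), 9),
                     c(x + w / 2, 9, z + h / 2))
  expect_error(representative_point(c(1, 1, 1, 0), 2), "positive")
  expect_error(representative_point(c(1, 1, 0, 1), 2), "positive")
})

test_that("slice segmentation matches a connected-component oracle", {
  ph <- get_phantom("tiny")
  v <- ph$volume
  s <- floor(dim(v$intensities)[2] / 2) # mid-arch sagittal slice
  slice <- v$intensities[, s + 1, ]
  masks <- slice_segmenter_threshold(1200, 30)(slice, s)
  # oracle: plain-R flood fill with 8-connectivity on the same threshold
  bw <- slice >= 1200
  lab <- matrix(0L, nrow(bw), ncol(bw))
  nxt <- 0L
  for (j in seq_len(ncol(bw))) for (i in seq_len(nrow(bw))) {
    if (!bw[i, j] || lab[i, j] != 0) next
    nxt <- nxt + 1L
    stack <- list(c(i, j)); lab[i, j] <- nxt
    while (length(stack) > 0) {
      c0 <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        ni <- c0[1] + di; nj <- c0[2] + dj
        if (ni >= 1 && ni <= nrow(bw) && nj >= 1 && nj <= ncol(bw) &&
            bw[ni, nj] && lab[ni, nj] == 0) {
          lab[ni, nj] <- nxt
          stack[[length(stack) + 1]] <- c(ni, nj)
        }
      }
    }
  }
  sizes <- tabulate(lab)
  keep <- which(sizes >= 30)
  expect_equal(length(masks), length(keep))
  oracle_sets <- lapply(keep, function(k) {
    px <- which(lab == k, arr.ind = TRUE) - 1L
    paste(sort(paste(px[, 1], px[, 2])), collapse = ";")
  })
  got_sets <- lapply(masks, function(px)
    paste(sort(paste(px[, 1], px[, 2])), collapse = ";"))
  expect_setequal(unlist(got_sets), unlist(oracle_sets))
  # bounding boxes are tight
  full <- segment_sagittal_slices(v)
  m <- full[[1]]
  expect_equal(m$bbox[["x"]], min(m$pixels[, 1]))
  expect_equal(m$bbox[["w"]], diff(range(m$pixels[, 1])) + 1)
  expect_equal(m$bbox[["h"]], diff(range(m$pixels[, 2])) + 1)
})

test_that("all-air slices and sub-floor components yield no masks", {
  seg <- slice_segmenter_threshold(1200, 30)
  expect_identical(seg(matrix(-1000, 40, 40), 0), list())
  sl <- matrix(-1000, 40, 40)
  sl[10:12, 10:12] <- 2000 # 9 voxels < floor 30
  expect_identical(seg(sl, 0), list())
})

test_that("mean intensity projection averages over the requested z range", {
  arr <- array(0, c(4, 5, 6))
  v <- voxel_volume(arr + 7, c(1, 1, 1))
  expect_true(all(mean_intensity_projection(v) == 7))
  arr2 <- array(0, c(4, 4, 2)); arr2[, , 2] <- 100
  v2 <- voxel_volume(arr2, c(1, 1, 1))
  expect_true(all(mean_intensity_projection(v2, c(0, 1)) == 50))
  expect_true(all(mean_intensity_projection(v2, c(1, 1)) == 100))
  expect_error(mean_intensity_projection(v2, c(1, 0)), "z_range")
})

test_that("arch detection recovers a synthetic parabola within 0.5 px RMS", {
  nx <- 120; ny <- 90
  img <- matrix(0, nx, ny)
  a <- -0.012; cpar <- 75
  for (x0 in 5:(nx - 6)) {
    y0 <- a * (x0 - nx / 2)^2 + cpar
    for (dy in -2:2) {
      yy <- round(y0) + dy
      if (yy >= 0 && yy < ny) img[x0 + 1, yy + 1] <- 1
    }
  }
  arch <- detect_dental_arch(img, n_points = 200, threshold = 0.5)
  yfit <- arch$points[, 2]
  ytrue <- a * (arch$points[, 1] - nx / 2)^2 + cpar
  expect_lt(sqrt(mean((yfit - ytrue)^2)), 0.5)
  # normals unit and orthogonal to local tangents
  tang <- diff(arch$points)
  tang <- tang / sqrt(rowSums(tang^2))
  dots <- rowSums(tang * arch$normals[-nrow(arch$normals), ])
  expect_lt(max(abs(dots)), 0.02)
  expect_equal(rowSums(arch$normals^2), rep(1, 200), tolerance = 1e-9)
  # cumulative arc length strictly increasing
  expect_true(all(diff(arch$arclen) > 0))
})

test_that("a straight bar yields a degenerate arch with +-y normals", {
  img <- matrix(0, 80, 40)
  img[10:70, 19:21] <- 1
  arch <- detect_dental_arch(img, n_points = 50, threshold = 0.5)
  expect_lt(max(abs(arch$points[, 2] - 19)), 0.75)
  expect_lt(max(abs(arch$normals[, 1])), 1e-6)
  expect_equal(abs(arch$normals[, 2]), rep(1, 50), tolerance = 1e-9)
  expect_error(detect_dental_arch(matrix(0, 30, 30)), "threshold|no arch")
})

test_that("arch total length is invariant to the sample count C", {
  seg <- get_segmented("tiny")
  ph <- get_phantom("tiny")
  mip <- mean_intensity_projection(ph$volume)
  l1 <- max(detect_dental_arch(mip, n_points = 100)$arclen)
  l2 <- max(detect_dental_arch(mip, n_points = 800)$arclen)
  expect_lt(abs(l1 - l2) / l2, 0.001)
})

test_that("panoramic projection integrates exactly on a constant volume", {
  v <- voxel_volume(array(100, c(30, 30, 10)), c(1, 1, 1))
  arch <- structure(list(points = cbind(seq(8, 22, length.out = 15), rep(15, 15)),
                         normals = cbind(rep(0, 15), rep(1, 15)),
                         arclen = seq(0, 14)), class = "dental_arch")
  pano <- panoramic_projection(v, arch, halfwidth_mm = 3)
  expect_equal(dim(pano), c(15, 10))
  expect_equal(as.numeric(pano), rep(600, 150), tolerance = 1e-6)
  # w = 0 integrates to zero
  pano0 <- panoramic_projection(v, arch, halfwidth_mm = 0)
  expect_true(all(pano0 == 0))
})

test_that("panoramic projection matches fine-step numerical integration", {
  set.seed(8)
  v <- voxel_volume(array(runif(16^3, 0, 1000), c(16, 16, 16)), c(1, 1, 1))
  C <- 7
  arch <- structure(list(points = cbind(seq(5, 11, length.out = C),
                                        5 + 0.3 * seq_len(C)),
                         normals = matrix(rep(c(0.6, 0.8), each = C), C),
                         arclen = seq_len(C) - 1), class = "dental_arch")
  w <- 3
  pano <- panoramic_projection(v, arch, halfwidth_mm = w)
  # oracle: same integral at a 16x finer step (trilinear sampling shared
  # convention; background = volume minimum)
  fine <- dentreg:::cpp_panoramic(as.numeric(v$intensities), dim(v$intensities),
                                  arch$points, arch$normals, w, 1,
                                  (min(v$spacing) / 8) / 16,
                                  min(v$intensities))
  expect_lt(max(abs(pano - fine) / (abs(fine) + 1e-9)), 0.005)
})

test_that("panoramic projection is linear in the volume", {
  ph <- get_phantom("tiny")
  seg <- get_segmented("tiny")
  v <- ph$volume
  v2 <- v; v2$intensities <- 3 * v$intensities
  p1 <- panoramic_projection(v, seg$arch, 4, background = min(v$intensities))
  p2 <- panoramic_projection(v2, seg$arch, 4,
                             background = min(v2$intensities))
  expect_equal(as.numeric(p2), 3 * as.numeric(p1), tolerance = 1e-9)
})

test_that("panoramic images export as PNG and 16-bit TIFF", {
  seg <- get_segmented("tiny")
  fp <- withr::local_tempfile(fileext = ".png")
  ft <- withr::local_tempfile(fileext = ".tiff")
  write_panoramic(seg$pano, fp)
  write_panoramic(seg$pano, ft)
  m <- unclass(seg$pano)
  rng <- range(m)
  back <- tiff::readTIFF(ft)
  expect_equal(dim(back), rev(dim(m)))
  # 16-bit round trip recovers the normalized image to ~1/65535
  norm <- (m - rng[1]) / diff(rng)
  want <- t(norm)[rev(seq_len(ncol(norm))), , drop = FALSE]
  expect_lt(max(abs(back - want)), 1 / 65000)
})

test_that("jaw boundary regression splits masks about the fitted line", {
  mk <- function(cx, cz) {
    px <- expand.grid(cx + (-1:1), cz + (-1:1))
    as.matrix(px)
  }
  masks <- c(lapply(c(5, 15, 25, 35), mk, cz = 30),
             lapply(c(5, 15, 25, 35), mk, cz = 10))
  sp <- split_panoramic_upper_lower(masks, c(50, 45))
  expect_setequal(sp$upper_ids, 1:4)
  expect_setequal(sp$lower_ids, 5:8)
  # level rows: slope ~0, boundary midway
  expect_lt(abs(sp$boundary["slope"]), 1e-9)
  expect_equal(unname(sp$boundary["intercept"]), 20, tolerance = 1e-9)
  # analytic OLS oracle on the centroids
  cen <- t(vapply(masks, colMeans, numeric(2)))
  fit <- lm(cen[, 2] ~ cen[, 1])
  expect_equal(unname(sp$boundary["intercept"]), unname(coef(fit)[1]),
               tolerance = 1e-9)
  expect_error(split_panoramic_upper_lower(masks[1], c(50, 45)), "at least 2")
})

test_that("representative points project to their nearest arch sample", {
  set.seed(10)
  C <- 60
  arch <- structure(list(points = cbind(seq(0, 30, length.out = C),
                                        10 + 5 * sin(seq(0, pi, length.out = C))),
                         normals = NULL, arclen = NULL), class = "dental_arch")
  tang <- rbind(diff(arch$points), diff(arch$points)[C - 2, , drop = FALSE])
  tang <- tang / sqrt(rowSums(tang^2))
  arch$normals <- cbind(-tang[, 2], tang[, 1])
  arch$arclen <- c(0, cumsum(sqrt(rowSums(diff(arch$points)^2))))
  masks <- lapply(1:50, function(i) {
    p <- c(runif(1, 0, 30), runif(1, 5, 20), runif(1, 0, 40))
    structure(list(s = p[2], pixels = matrix(0, 1, 2),
                   bbox = c(x = 0, z = 0, h = 1, w = 1),
                   rep = c(p[1], p[2], p[3])), class = "slice_mask")
  })
  pr <- project_representative_points(masks, arch, halfwidth_mm = 4,
                                      spacing_xy = 1)
  # oracle: exhaustive nearest arch sample per kept point
  for (r in seq_len(nrow(pr))) {
    p <- masks[[pr$mask[r]]]$rep
    d2 <- (arch$points[, 1] - p[1])^2 + (arch$points[, 2] - p[2])^2
    expect_identical(pr$q[r], which.min(d2) - 1L)
    expect_identical(pr$z[r], p[3])
  }
  # a point exactly on the arch projects with zero offset
  on_arch <- structure(list(s = arch$points[20, 2], pixels = matrix(0, 1, 2),
                            bbox = c(0, 0, 1, 1),
                            rep = c(arch$points[20, 1], arch$points[20, 2], 7)),
                       class = "slice_mask")
  pr1 <- project_representative_points(list(on_arch), arch, 4, 1)
  expect_equal(pr1$q, 19L)
  # beyond the band: dropped
  off <- arch$points[20, ] + arch$normals[20, ] * 4.5
  far <- structure(list(s = off[2], pixels = matrix(0, 1, 2),
                        bbox = c(0, 0, 1, 1), rep = c(off[1], off[2], 7)),
                   class = "slice_mask")
  pr2 <- project_representative_points(list(far), arch, 4, 1)
  expect_equal(nrow(pr2), 0)
  expect_equal(attr(pr2, "n_dropped"), 1L)
})

test_that("mask classification honours panoramic masks and the fallback", {
  dimp <- c(20, 20)
  upper <- matrix(FALSE, 20, 20); upper[5, 16] <- TRUE # 0-based pixel (4, 15)
  lower <- matrix(FALSE, 20, 20); lower[5, 6] <- TRUE  # 0-based pixel (4, 5)
  split <- list(upper_mask = upper, lower_mask = lower,
                boundary = c(slope = 0, intercept = 10))
  vol <- voxel_volume(array(0, c(20, 20, 20)), c(1, 1, 1))
  mk <- function(rep) structure(list(s = rep[2], pixels = matrix(c(1, 2), 1),
                                     bbox = c(0, 0, 1, 1), rep = rep),
                                class = "slice_mask")
  masks <- list(mk(c(1, 1, 14.6)),  # pixel (4,15): inside upper mask
                mk(c(1, 1, 5.2)),   # pixel (4,5): inside lower mask
                mk(c(1, 1, 12)),    # neither: above boundary -> upper
                mk(c(1, 1, 3)))     # neither: below boundary -> lower
  projected <- data.frame(q = c(4L, 4L, 9L, 9L), z = c(14.6, 5.2, 12, 3),
                          mask = 1:4)
  js <- classify_slice_masks(projected, split, masks, vol,
                             subvoxel_boundary = FALSE)
  expect_setequal(js$upper_mask_ids, c(1, 3))
  expect_setequal(js$lower_mask_ids, c(2, 4))
  expect_equal(js$n_fallback, 2L)
  # merged clouds contain one world point per mask voxel
  expect_equal(nrow(js$upper_points), 2)
})

test_that("jaw assignment matches phantom ground truth on the gapped arch", {
  ph <- get_phantom("tiny")
  seg <- get_segmented("tiny")
  acc <- jaw_split_accuracy(seg$jaw_split, ph)
  expect_gt(acc, 0.95)
})
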