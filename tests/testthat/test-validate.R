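test_that("nearest-neighbour distances match the exhaustive oracle", {
  set.seed(51)
  A <- matrix(runif(300, 0, 10), 100, 3)
  B <- matrix(runif(240, 0, 10), 80, 3)
  rep <- corresponding_distances(A, B)
  oracle <- brute_nn(A, B)
  expect_equal(rep$distances, oracle$dist, tolerance = 1e-12)
  expect_equal(rep$mean, mean(oracle$dist), tolerance = 1e-12)
  # population standard deviation
  expect_equal(rep$sd, sqrt(mean((oracle$dist - mean(oracle$dist))^2)),
               tolerance = 1e-12)
  # degenerate cases
  same <- corresponding_distances(A, A)
  expect_true(all(same$distances == 0))
  one <- corresponding_distances(matrix(0, 1, 3),
                                 matrix(c(1, 0, 0, 5, 0, 0), 2, 3,
                                        byrow = TRUE))
  expect_equal(one$mean, 1)
  expect_error(corresponding_distances(matrix(numeric(0), 0, 3), B), "empty")
})

test_that("chamfer and Hausdorff distances match brute force and each other", {
  set.seed(52)
  A <- matrix(runif(150), 50, 3)
  B <- matrix(runif(150), 50, 3)
  ch <- chamfer_distance(A, B)
  hd <- hausdorff_distance(A, B)
  oAB <- brute_nn(A, B)$dist
  oBA <- brute_nn(B, A)$dist
  expect_equal(ch$ab, mean(oAB), tolerance = 1e-12)
  expect_equal(ch$ba, mean(oBA), tolerance = 1e-12)
  expect_equal(ch$symmetric, (mean(oAB) + mean(oBA)) / 2, tolerance = 1e-12)
  expect_equal(hd$ab, max(oAB), tolerance = 1e-12)
  expect_equal(hd$symmetric, max(max(oAB), max(oBA)), tolerance = 1e-12)
  # directed Hausdorff dominates directed chamfer on any input
  expect_gte(hd$ab, ch$ab)
  expect_gte(hd$ba, ch$ba)
  # identities
  expect_equal(unlist(chamfer_distance(A, A)), c(ab = 0, ba = 0, symmetric = 0))
  two <- matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(hausdorff_distance(two, two[1, , drop = FALSE])$ab, 2)
  expect_equal(hausdorff_distance(two[1, , drop = FALSE], two)$ab, 0)
})

test_that("metrics are invariant under a common rigid transform", {
  set.seed(53)
  A <- matrix(runif(300), 100, 3)
  B <- matrix(runif(300), 100, 3)
  T <- random_rigid_transform(25, 8)
  A2 <- apply_transform(A, T)
  B2 <- apply_transform(B, T)
  expect_equal(chamfer_distance(A, B)$symmetric,
               chamfer_distance(A2, B2)$symmetric, tolerance = 1e-9)
  expect_equal(hausdorff_distance(A, B)$symmetric,
               hausdorff_distance(A2, B2)$symmetric, tolerance = 1e-9)
  expect_equal(corresponding_distances(A, B)$mean,
               corresponding_distances(A2, B2)$mean, tolerance = 1e-9)
})

test_that("coronal section areas recover analytic cross-sections", {
  set.seed(54)
  # dense axis-aligned 10 mm box: every slab area ~ 100 mm^2
  n <- 40000
  box <- cbind(runif(n, 0, 10), runif(n, 0, 10), runif(n, 0, 10))
  a_box <- coronal_section_areas(box, n_slices = 5, alpha = 1.0)
  expect_true(all(abs(a_box - 100) / 100 < 0.05))
  # dense cylinder radius 4: slab areas ~ pi r^2
  r <- sqrt(runif(n, 0, 16))
  th <- runif(n, 0, 2 * pi)
  cyl <- cbind(r * cos(th), r * sin(th), runif(n, 0, 10))
  a_cyl <- coronal_section_areas(cyl, n_slices = 5, alpha = 1.0)
  expect_true(all(abs(a_cyl - pi * 16) / (pi * 16) < 0.05))
  # one slab covers the whole cloud
  expect_length(coronal_section_areas(box, n_slices = 1), 1)
  flat <- box; flat[, 3] <- 1
  expect_error(coronal_section_areas(flat, 5), "degenerate")
})

test_that("alpha-shape area agrees with an independent Delaunay implementation", {
  skip_if(Sys.which("python") == "", "no python available")
  set.seed(55)
  xy <- cbind(runif(300, 0, 10), runif(300, 0, 10))
  alpha <- 1.5
  f <- tempfile(fileext = ".csv")
  utils::write.table(xy, f, row.names = FALSE, col.names = FALSE, sep = ",")
  script <- sprintf('
import numpy as np
from scipy.spatial import Delaunay
pts = np.loadtxt("%s", delimiter=",")
tri = Delaunay(pts)
area = 0.0
for s in tri.simplices:
    a, b, c = pts[s]
    ab, ac, bc = np.linalg.norm(b-a), np.linalg.norm(c-a), np.linalg.norm(c-b)
    ar = 0.5*abs((b-a)[0]*(c-a)[1] - (b-a)[1]*(c-a)[0])
    if ar < 1e-14: continue
    circ = ab*ac*bc/(4*ar)
    if circ <= %f: area += ar
print(float(area))
', f, alpha)
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  out <- suppressWarnings(system2("python", sf, stdout = TRUE))
  skip_if(length(out) == 0, "scipy unavailable")
  oracle <- as.numeric(out[length(out)])
  got <- dentreg:::cpp_alpha_shape_area(xy, alpha)
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("bland_altman reproduces the closed-form limits", {
  # identical series: zero bias, degenerate limits, everything within
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$bias, 0)
  expect_equal(unname(ba0$limits), c(0, 0))
  expect_equal(ba0$fraction_within, 1)
  # worked example: d = (-0.5, 0.5, 0, 0.5)
  a <- c(1, 2, 3, 4)
  b <- a - c(-0.5, 0.5, 0, 0.5)
  ba <- bland_altman(a, b)
  expect_equal(ba$bias, 0.125, tolerance = 1e-12)
  expect_equal(ba$sd, sd(c(-0.5, 0.5, 0, 0.5)), tolerance = 1e-12)
  expect_equal(unname(ba$limits),
               0.125 + c(-1.96, 1.96) * sd(c(-0.5, 0.5, 0, 0.5)),
               tolerance = 1e-12)
  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("for normal differences ~95% of points fall within the limits", {
  set.seed(56)
  n <- 1e4
  a <- rnorm(n, 10, 1)
  b <- a + rnorm(n, 0.3, 0.5)
  ba <- bland_altman(a, b)
  expect_equal(ba$fraction_within, 0.95, tolerance = 0.011)
})

test_that("the error color map runs blue to red with clipping", {
  src <- matrix(c(0, 0, 0,  1, 0, 0,  3, 0, 0), 3, 3, byrow = TRUE)
  tgt <- matrix(c(0, 0, 0), 1, 3)
  em <- error_colormap(src, tgt, max_scale = 1)
  cols <- em$surface$colors
  expect_equal(unname(cols[1, ]), c(0, 0, 1))     # zero distance: blue
  expect_equal(unname(cols[2, ]), c(1, 0, 0))     # at max_scale: red
  expect_equal(unname(cols[3, ]), c(1, 0, 0))     # beyond: clipped to red
  expect_equal(em$mean, mean(c(0, 1, 3)))
  expect_equal(sum(em$histogram$counts), 3)
})
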