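as_points <- function(x) {
  if (inherits(x, "colored_surface")) x$points else as.matrix(x)
}

#' Nearest-neighbour distance report
#'
#' For every source point, the Euclidean distance to its nearest target
#' point, with summary statistics. The standard deviation uses the
#' population (n) form — a descriptive summary of the full distance
#' population. Fitness and inlier RMSE are evaluated at
#' `inlier_threshold`.
#'
#' @param source,target Point matrices or [colored_surface()]s.
#' @param inlier_threshold Inlier distance, mm, for fitness / inlier RMSE
#'   (reported alongside as `threshold`).
#' @return A `distance_report`: `distances`, `mean`, `sd` (population),
#'   `fitness`, `inlier_rmse`, `fi_ratio`, `threshold`.
#' @export
corresponding_distances <- function(source, target, inlier_threshold = 1.5) {
  s <- as_points(source); t <- as_points(target)
  if (nrow(s) == 0 || nrow(t) == 0) stop("empty point set")
  d <- cpp_nn(s, t)$dist
  inl <- d <= inlier_threshold
  structure(list(distances = d, mean = mean(d),
                 sd = sqrt(mean((d - mean(d))^2)),
                 fitness = mean(inl),
                 inlier_rmse = if (any(inl)) sqrt(mean(d[inl]^2)) else 0,
                 fi_ratio = if (any(inl) && sqrt(mean(d[inl]^2)) > 0)
                   mean(inl) / sqrt(mean(d[inl]^2)) else Inf,
                 threshold = inlier_threshold),
            class = "distance_report")
}

#' @export
print.distance_report <- function(x, ...) {
  cat(sprintf("Distances: n %d, mean %.4f mm, sd %.4f mm, fitness %.4f @ %.2f mm, inlier RMSE %.4f mm, F/I %.3f /mm\n",
              length(x$distances), x$mean, x$sd, x$fitness, x$threshold,
              x$inlier_rmse, x$fi_ratio))
  invisible(x)
}

#' Chamfer distance between point sets
#'
#' Directed value = mean nearest-neighbour distance; symmetric = mean of
#' the two directed values.
#'
#' @param A,B Point matrices or [colored_surface()]s.
#' @return List: `ab`, `ba`, `symmetric`.
#' @export
chamfer_distance <- function(A, B) {
  a <- as_points(A); b <- as_points(B)
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty point set")
  ab <- mean(cpp_nn(a, b)$dist)
  ba <- mean(cpp_nn(b, a)$dist)
  list(ab = ab, ba = ba, symmetric = (ab + ba) / 2)
}

#' Hausdorff distance between point sets
#'
#' Directed value = maximum nearest-neighbour distance; symmetric = max of
#' the two directed values.
#'
#' @inheritParams chamfer_distance
#' @return List: `ab`, `ba`, `symmetric`.
#' @export
hausdorff_distance <- function(A, B) {
  a <- as_points(A); b <- as_points(B)
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty point set")
  ab <- max(cpp_nn(a, b)$dist)
  ba <- max(cpp_nn(b, a)$dist)
  list(ab = ab, ba = ba, symmetric = max(ab, ba))
}

#' Coronal cross-section areas of a point cloud
#'
#' Splits the cloud's z range into equal slabs; in each slab the points
#' are projected to the slab mid-plane and the cross-sectional area is the
#' 2D alpha-shape area (area of the Delaunay alpha complex) — robust to
#' concave tooth sections where a convex hull would overestimate. Empty
#' slabs get area 0.
#'
#' @param cloud Point matrix or [colored_surface()].
#' @param n_slices Number of slabs (default 20).
#' @param alpha Alpha radius, mm.
#' @param z_range Optional `c(lo, hi)` world z range, mm; default the
#'   cloud's range.
#' @return Numeric vector of areas, mm^2, ordered inferior to superior.
#' @export
coronal_section_areas <- function(cloud, n_slices = 20, alpha = 1.0,
                                  z_range = NULL) {
  p <- as_points(cloud)
  if (is.null(z_range)) z_range <- range(p[, 3])
  if (diff(z_range) <= 0) stop("degenerate z extent")
  edges <- seq(z_range[1], z_range[2], length.out = n_slices + 1)
  areas <- numeric(n_slices)
  bin <- pmin(pmax(findInterval(p[, 3], edges, rightmost.closed = TRUE), 1),
              n_slices)
  inside <- p[, 3] >= z_range[1] & p[, 3] <= z_range[2]
  for (i in seq_len(n_slices)) {
    sel <- inside & bin == i
    if (sum(sel) < 3) { areas[i] <- 0; next }
    areas[i] <- cpp_alpha_shape_area(p[sel, 1:2, drop = FALSE], alpha)
  }
  areas
}

#' Bland-Altman agreement of two area series
#'
#' Differences `d_i = a_i - b_i`; bias = mean difference; limits of
#' agreement = bias +/- 1.96 * sample SD (n-1); the fraction of points
#' within the limits is inclusive.
#'
#' @param areas_A,areas_B Equal-length numeric vectors (>= 2).
#' @return A `bland_altman` list: `means`, `differences`, `bias`, `sd`,
#'   `limits` (lower, upper), `fraction_within`.
#' @export
bland_altman <- function(areas_A, areas_B) {
  if (length(areas_A) != length(areas_B))
    stop("area series must have equal length")
  if (length(areas_A) < 2) stop("need at least 2 paired areas")
  d <- areas_A - areas_B
  bias <- mean(d)
  s <- stats::sd(d) # sample, n-1
  if (!is.finite(s)) s <- 0
  limits <- c(lower = bias - 1.96 * s, upper = bias + 1.96 * s)
  structure(list(means = (areas_A + areas_B) / 2, differences = d,
                 bias = bias, sd = s, limits = limits,
                 fraction_within = mean(d >= limits[1] & d <= limits[2])),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: n %d, bias %.4f, limits [%.4f, %.4f], %.1f%% within\n",
              length(x$differences), x$bias, x$limits[1], x$limits[2],
              100 * x$fraction_within))
  invisible(x)
}

#' Bland-Altman plot
#' @param x A `bland_altman` object.
#' @param ... Passed to [plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$differences, xlab = "mean area (mm^2)",
                 ylab = "difference (mm^2)", pch = 19, ...)
  graphics::abline(h = x$bias, col = "blue")
  graphics::abline(h = x$limits, col = "red", lty = 2)
  invisible(x)
}

#' Registration error color map
#'
#' Colors each source point by its nearest-target distance, linearly from
#' blue (0 mm) to red (`max_scale` mm, clipped above), and returns the
#' histogram of distances with the mean marked.
#'
#' @param source,target Point matrices or [colored_surface()]s.
#' @param max_scale Distance mapped to pure red, mm.
#' @param bin_width Histogram bin width, mm.
#' @return A list: `surface` (colored [colored_surface()]), `histogram`
#'   (`breaks`, `counts`), `mean`.
#' @export
error_colormap <- function(source, target, max_scale = 1.0, bin_width = 0.05) {
  s <- as_points(source)
  if (nrow(s) == 0) stop("empty point set")
  d <- cpp_nn(s, as_points(target))$dist
  t01 <- pmin(d / max_scale, 1)
  cols <- cbind(t01, 0, 1 - t01)
  h <- graphics::hist(d, breaks = seq(0, max(d, bin_width) + bin_width,
                                      by = bin_width), plot = FALSE)
  list(surface = colored_surface(s, cols),
       histogram = list(breaks = h$breaks, counts = h$counts),
       mean = mean(d), distances = d)
}

#' Full validation report of a registration
#'
#' Applies the transform to the source, computes the distance report,
#' chamfer and Hausdorff distances, coronal-section Bland-Altman
#' agreement, and the error color map.
#'
#' @param result A `registration_result`.
#' @param source Source cloud (untransformed IOS teeth).
#' @param target Target cloud (CBCT jaw points).
#' @param config A [pipeline_config()] (its `validate` section).
#' @return A `validation_report` list.
#' @export
validate_registration <- function(result, source, target,
                                  config = pipeline_config()) {
  vc <- config$validate
  moved <- apply_transform(as_points(source), result$transform)
  tgt <- as_points(target)
  dr <- corresponding_distances(moved, tgt,
                                inlier_threshold = config$register$icp_max_corr)
  ch <- chamfer_distance(moved, tgt)
  hd <- hausdorff_distance(moved, tgt)
  zr <- range(moved[, 3]) # crown extent of the aligned scan
  a_src <- coronal_section_areas(moved, vc$n_slices, vc$alpha, zr)
  a_tgt <- coronal_section_areas(tgt, vc$n_slices, vc$alpha, zr)
  ba <- bland_altman(a_src, a_tgt)
  em <- error_colormap(moved, tgt, vc$error_max_scale, vc$hist_bin_width)
  structure(list(distance_report = dr, chamfer = ch, hausdorff = hd,
                 bland_altman = ba, error_map = em,
                 fitness = result$fitness, inlier_rmse = result$inlier_rmse,
                 fi_ratio = result$fi_ratio,
                 fi_threshold = config$register$icp_max_corr),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  print(x$distance_report)
  cat(sprintf("chamfer (sym) %.4f mm, Hausdorff (sym) %.4f mm\n",
              x$chamfer$symmetric, x$hausdorff$symmetric))
  print(x$bland_altman)
  invisible(x)
}
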