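#' Voxel-grid down-sampling of a point cloud
#'
#' Points are bucketed into a cubic grid; each occupied bucket yields one
#' output point, the centroid of its members. Colors and normals are
#' averaged (normals renormalized; degenerate averages are replaced by the
#' first member's normal).
#'
#' @param x A [colored_surface()] or an n x 3 matrix.
#' @param voxel_size Bucket edge length, mm (> 0).
#' @return Same kind as `x`.
#' @export
downsample_voxel <- function(x, voxel_size) {
  if (voxel_size <= 0) stop("voxel_size must be positive")
  surf <- inherits(x, "colored_surface")
  pts <- if (surf) x$points else as.matrix(x)
  cols <- if (surf && !is.null(x$colors)) x$colors else matrix(numeric(0), 0, 3)
  nrms <- if (surf && !is.null(x$normals)) x$normals else matrix(numeric(0), 0, 3)
  res <- cpp_voxel_downsample(pts, cols, nrms, voxel_size)
  if (!surf) return(res$points)
  nrm <- NULL
  if (nrow(res$normals) > 0) {
    nrm <- res$normals
    l <- sqrt(rowSums(nrm^2))
    bad <- l < 1e-9
    nrm[!bad, ] <- nrm[!bad, , drop = FALSE] / l[!bad]
    if (any(bad)) nrm[bad, ] <- matrix(rep(c(0, 0, 1), sum(bad)), ncol = 3,
                                       byrow = TRUE)
  }
  colored_surface(res$points,
                  if (nrow(res$colors) > 0) pmin(pmax(res$colors, 0), 1),
                  nrm)
}

#' Estimate point normals from local covariance
#'
#' Per-point normal = eigenvector of the k-neighbourhood covariance with
#' the smallest eigenvalue; orientations are made locally consistent by
#' propagation along the neighbourhood graph, seeded outward from the
#' point farthest from the centroid.
#'
#' @param x A [colored_surface()] or n x 3 matrix.
#' @param k_neighbors Neighbourhood size (>= 3, < number of points).
#' @param orientation `"propagate"` (consistency propagated along the
#'   neighbourhood graph; right for thin surface scans) or `"outward"`
#'   (each normal points away from its neighbourhood centroid; right for
#'   the shell of a filled voxel cloud, whose interior pulls the local
#'   centroid inward).
#' @return Same kind as `x`, with normals set (matrix input returns the
#'   normals matrix). The per-point surface variation
#'   `lambda_0 / (lambda_0 + lambda_1 + lambda_2)` — near 0 on smooth
#'   surface samples, near 1/3 deep inside an isotropically filled solid —
#'   is attached as attribute `"surface_variation"`.
#' @export
estimate_normals <- function(x, k_neighbors = 30,
                             orientation = c("propagate", "outward")) {
  orientation <- match.arg(orientation)
  pts <- if (inherits(x, "colored_surface")) x$points else as.matrix(x)
  if (k_neighbors < 3) stop("k_neighbors must be at least 3")
  if (nrow(pts) <= k_neighbors)
    stop("need more points than k_neighbors to estimate normals")
  nrm4 <- cpp_estimate_normals(pts, k_neighbors,
                               if (orientation == "outward") 1L else 0L)
  if (!inherits(x, "colored_surface")) return(nrm4[, 1:3, drop = FALSE])
  x$normals <- nrm4[, 1:3, drop = FALSE]
  attr(x, "surface_variation") <- nrm4[, 4]
  x
}

#' Registration results
#'
#' @param transform Source-to-target [rigid_transform()].
#' @param fitness Fraction of source points with a target neighbour within
#'   the inlier threshold.
#' @param inlier_rmse RMS distance of those pairs, mm.
#' @param iterations Iterations used.
#' @param converged Logical.
#' @param stage Character tag ("ransac", "icp", "pipeline").
#' @return A `registration_result` with `fi_ratio = fitness/inlier_rmse`
#'   (1/mm; Inf when the RMSE is exactly zero).
#' @export
registration_result <- function(transform, fitness, inlier_rmse, iterations,
                                converged, stage = "icp") {
  stopifnot(fitness >= 0, fitness <= 1, inlier_rmse >= 0)
  structure(list(transform = transform, fitness = fitness,
                 inlier_rmse = inlier_rmse,
                 fi_ratio = if (inlier_rmse > 0) fitness / inlier_rmse else Inf,
                 iterations = iterations, converged = converged,
                 stage = stage),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("Registration result (%s): fitness %.4f, inlier RMSE %.4f mm, F/I %.3f /mm, %d iterations%s\n",
              x$stage, x$fitness, x$inlier_rmse, x$fi_ratio, x$iterations,
              if (isTRUE(x$converged)) ", converged" else ""))
  print(x$transform)
  invisible(x)
}

#' @export
summary.registration_result <- function(object, ...) {
  c(fitness = object$fitness, inlier_rmse = object$inlier_rmse,
    fi_ratio = object$fi_ratio,
    rotation_deg = rotation_angle(object$transform),
    translation_mm = sqrt(sum(unclass(object$transform)[1:3, 4]^2)))
}

# nearest-descriptor correspondences source -> target, chunked BLAS
fpfh_correspondences <- function(fs, ft) {
  ns <- ncol(fs)
  t2 <- colSums(ft^2)
  corr <- integer(ns)
  chunk <- 1024L
  for (lo in seq(1, ns, by = chunk)) {
    hi <- min(lo + chunk - 1, ns)
    block <- fs[, lo:hi, drop = FALSE]
    D <- matrix(t2, hi - lo + 1, length(t2), byrow = TRUE) - 2 * crossprod(block, ft)
    corr[lo:hi] <- max.col(-D, ties.method = "first")
  }
  corr
}

# indices of source points whose match is mutual (source's nearest target
# maps back to that source) — the standard RANSAC mutual filter
mutual_correspondences <- function(corr_st, corr_ts) {
  which(corr_ts[corr_st] == seq_along(corr_st))
}

#' RANSAC coarse alignment over FPFH correspondences
#'
#' Computes 33-bin fast point feature histograms on both (down-sampled,
#' normal-equipped) clouds, matches each source point to its nearest
#' target descriptor, and runs hypothesis-and-verify RANSAC: 3 random
#' correspondences, pairwise edge-length-ratio pruning, closed-form SVD
#' transform estimation, inlier-count verification, early stop at the
#' confidence bound. Fails if the best hypothesis's fitness does not reach
#' `min_fitness`.
#'
#' @param source,target [colored_surface()]s with normals (from
#'   [estimate_normals()]; its surface-variation attribute, when present,
#'   restricts the descriptor stage to surface-like points — interior
#'   points of a filled voxel cloud carry no usable local geometry).
#' @param params List of parameters (see [pipeline_config()]'s `register`
#'   section): `fpfh_radius`, `ransac_max_iter`, `ransac_confidence`,
#'   `edge_similarity`, `inlier_dist`, `min_fitness`, `score_subset`,
#'   `max_surface_variation`.
#' @return A `registration_result` (stage "ransac").
#' @export
coarse_align_ransac <- function(source, target, params = list()) {
  p <- modify_defaults(list(fpfh_radius = 2.5, ransac_max_iter = 1e5,
                            ransac_min_iter = 20000,
                            ransac_confidence = 0.999, edge_similarity = 0.9,
                            inlier_dist = 1.0, min_fitness = 0.2,
                            score_subset = 2000,
                            max_surface_variation = 0.15), params)
  if (is.null(source$normals) || is.null(target$normals))
    stop("coarse alignment requires normals on both clouds")
  surf_idx <- function(cloud) {
    sv <- attr(cloud, "surface_variation")
    if (is.null(sv)) return(seq_len(n_points(cloud)))
    idx <- which(sv <= p$max_surface_variation)
    if (length(idx) < 3) seq_len(n_points(cloud)) else idx
  }
  si <- surf_idx(source); ti <- surf_idx(target)
  sp <- source$points[si, , drop = FALSE]
  tp <- target$points[ti, , drop = FALSE]
  if (nrow(source$points) < 3 || nrow(target$points) < 3)
    stop("need at least 3 points on each side for coarse alignment")
  fs <- cpp_fpfh(sp, source$normals[si, , drop = FALSE], p$fpfh_radius)
  ft <- cpp_fpfh(tp, target$normals[ti, , drop = FALSE], p$fpfh_radius)
  corr <- fpfh_correspondences(fs, ft)
  mut <- mutual_correspondences(corr, fpfh_correspondences(ft, fs))
  if (length(mut) < 10) mut <- seq_len(nrow(sp)) # degenerate: sample everywhere
  ns <- nrow(sp)
  samples <- matrix(0L, p$ransac_max_iter, 3)
  for (j in 1:3) samples[, j] <- mut[sample.int(length(mut),
                                                p$ransac_max_iter,
                                                replace = TRUE)]
  score_idx <- if (ns <= p$score_subset) seq_len(ns)
               else sort(sample.int(ns, p$score_subset))
  res <- cpp_ransac(sp, tp, corr, samples, p$edge_similarity, p$inlier_dist,
                    score_idx, p$ransac_confidence, p$min_fitness,
                    p$ransac_min_iter)
  if (!res$found || res$fitness < p$min_fitness)
    stop(sprintf("coarse alignment failed (best fitness %.3f < %.3f)",
                 if (res$found) res$fitness else 0, p$min_fitness))
  out <- registration_result(rigid_transform(project_so3(res$transform)),
                             res$fitness, res$inlier_rmse, res$iterations,
                             TRUE, stage = "ransac")
  # best hypothesis from a pose-distinct second basin, if one scored well:
  # near-symmetric anatomy (the dental arch) can sustain a competing
  # alignment that only the fine stage can tell apart
  if (isTRUE(res$has_alternative) && res$alt_fitness >= p$min_fitness)
    attr(out, "alternative") <- registration_result(
      rigid_transform(project_so3(res$alt_transform)),
      res$alt_fitness, res$alt_inlier_rmse, res$iterations, TRUE,
      stage = "ransac")
  out
}

# re-orthonormalize the rotation block against accumulated roundoff
project_so3 <- function(T) {
  R <- T[1:3, 1:3]
  s <- svd(R)
  Rn <- s$u %*% t(s$v)
  if (det(Rn) < 0) {
    u <- s$u; u[, 3] <- -u[, 3]
    Rn <- u %*% t(s$v)
  }
  T[1:3, 1:3] <- Rn
  T
}

#' Point-to-plane ICP refinement
#'
#' Iterates nearest-neighbour correspondences within `max_corr` and a
#' closed-form small-angle solve of the point-to-plane objective
#' `sum ((T p_i - q_i) . n_i)^2`; the inner step is damped so the
#' objective at fixed correspondences never increases. Convergence when
#' the relative change of both fitness and inlier RMSE drops below `tol`.
#' An optional refinement loop re-runs the ICP with `max_corr` halved.
#'
#' @param source [colored_surface()] or matrix (points to move).
#' @param target [colored_surface()] with normals.
#' @param init Initial [rigid_transform()] (typically the RANSAC result).
#' @param params List: `icp_max_corr` (mm), `icp_max_iter`, `icp_tol`,
#'   `icp_refine` (number of halved-radius re-runs).
#' @return A `registration_result` (stage "icp") with attribute
#'   `objective_trace` (per-solve before/after objective values).
#' @export
fine_align_icp <- function(source, target, init = rigid_transform(),
                           params = list()) {
  p <- modify_defaults(list(icp_max_corr = 1.5, icp_max_iter = 100,
                            icp_tol = 1e-6, icp_refine = 2), params)
  sp <- if (inherits(source, "colored_surface")) source$points else as.matrix(source)
  stopifnot(inherits(target, "colored_surface"))
  if (is.null(target$normals)) stop("point-to-plane ICP requires target normals")
  tp <- target$points
  T <- unclass(init)
  max_corr <- p$icp_max_corr
  total_iter <- 0L
  trace_before <- numeric(0); trace_after <- numeric(0)
  res <- NULL
  for (round in 0:p$icp_refine) {
    res <- cpp_icp_point_to_plane(sp, tp, target$normals, T, max_corr,
                                  p$icp_max_iter, p$icp_tol)
    if (isTRUE(res$no_correspondences)) {
      if (round == 0) stop("initial alignment too poor: no correspondences ",
                           "within ", max_corr, " mm")
      break
    }
    T <- project_so3(res$transform)
    total_iter <- total_iter + res$iterations
    trace_before <- c(trace_before, res$obj_before)
    trace_after <- c(trace_after, res$obj_after)
    max_corr <- max_corr / 2
  }
  out <- registration_result(rigid_transform(T), res$fitness, res$inlier_rmse,
                             total_iter, isTRUE(res$converged), stage = "icp")
  attr(out, "objective_trace") <- list(before = trace_before,
                                       after = trace_after)
  out
}

#' Register an IOS teeth cloud to a CBCT jaw cloud
#'
#' The full chain: voxel down-sampling of both clouds, normal estimation,
#' RANSAC coarse alignment over FPFH descriptors, then point-to-plane ICP
#' refinement (with the halved-radius refinement loop). Deterministic
#' given `config$seed`.
#'
#' @param ios_teeth [colored_surface()] (source; crowns from the scan).
#' @param cbct_jaw [colored_surface()] or n x 3 matrix (target; jaw voxel
#'   cloud).
#' @param config A [pipeline_config()] (its `register` section and `seed`).
#' @return A `registration_result` (stage "pipeline") with attribute
#'   `coarse` holding the RANSAC-stage result.
#' @export
register_jaw <- function(ios_teeth, cbct_jaw, config = pipeline_config()) {
  rc <- config$register
  set.seed(config$seed)
  if (!inherits(cbct_jaw, "colored_surface"))
    cbct_jaw <- colored_surface(as.matrix(cbct_jaw))
  if (n_points(ios_teeth) == 0 || n_points(cbct_jaw) == 0)
    stop("registration inputs must be nonempty")
  src <- downsample_voxel(ios_teeth, rc$voxel_size)
  tgt <- downsample_voxel(cbct_jaw, rc$voxel_size)
  # scan-provided normals (averaged through the down-sampling) are kept;
  # estimation is the fallback for normal-less inputs
  if (is.null(src$normals)) src <- estimate_normals(src, rc$normal_k)
  # the CBCT jaw is a filled voxel cloud: orient its shell normals outward
  tgt <- estimate_normals(tgt, rc$normal_k, orientation = "outward")
  rp <- rc
  rp$inlier_dist <- rc$inlier_factor * rc$voxel_size
  coarse <- coarse_align_ransac(src, tgt, rp)
  # refine against the full-resolution target: down-sampling a filled
  # voxel cloud pulls its shell centroids inward, which would bias the
  # fine stage by a fraction of the voxel size
  tgt_full <- estimate_normals(cbct_jaw, rc$normal_k, orientation = "outward")
  fine <- fine_align_icp(src, tgt_full, coarse$transform, rc)
  # if the coarse stage flagged a competing pose basin, refine both and
  # keep the better fine-stage fit by the fitness / inlier-RMSE ratio
  alt <- attr(coarse, "alternative")
  if (!is.null(alt)) {
    fine2 <- tryCatch(fine_align_icp(src, tgt_full, alt$transform, rc),
                      error = function(e) NULL)
    if (!is.null(fine2) && fine2$fi_ratio > fine$fi_ratio) {
      fine <- fine2
      coarse <- alt
    }
  }
  out <- registration_result(fine$transform, fine$fitness, fine$inlier_rmse,
                             fine$iterations, fine$converged,
                             stage = "pipeline")
  attr(out, "coarse") <- coarse
  attr(out, "objective_trace") <- attr(fine, "objective_trace")
  out
}

# take known keys from params over defaults; unrelated keys are ignored
# (pipeline_config owns strict key validation)
modify_defaults <- function(defaults, params) {
  for (nm in names(defaults))
    if (!is.null(params[[nm]])) defaults[[nm]] <- params[[nm]]
  defaults
}
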