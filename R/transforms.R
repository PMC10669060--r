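#' Rigid transforms
#'
#' A rigid transform is stored as a 4x4 homogeneous matrix with an
#' orthonormal rotation block (determinant +1) and a translation column in
#' millimetres. The application convention is column-vector math,
#' `p' = R p + t`; [compose_transform()] follows matrix-product order, so
#' `apply_transform(x, compose_transform(A, B))` equals applying `B` first
#' and then `A`.
#'
#' @param matrix A 4x4 homogeneous matrix, or NULL to build from
#'   `rotation`/`translation`.
#' @param rotation 3x3 rotation matrix (default identity).
#' @param translation length-3 translation vector, mm (default zero).
#' @return An object of class `rigid_transform` (a 4x4 matrix).
#' @export
rigid_transform <- function(matrix = NULL, rotation = diag(3),
                            translation = c(0, 0, 0)) {
  if (is.null(matrix)) {
    matrix <- diag(4)
    matrix[1:3, 1:3] <- rotation
    matrix[1:3, 4] <- translation
  }
  matrix <- unclass(matrix)
  if (!is.matrix(matrix) || !all(dim(matrix) == c(4, 4)))
    stop("a rigid transform must be a 4x4 matrix")
  R <- matrix[1:3, 1:3]
  if (max(abs(t(R) %*% R - diag(3))) > 1e-9)
    stop("rotation block is not orthonormal (tolerance 1e-9)")
  if (abs(det(R) - 1) > 1e-9)
    stop("rotation block must have determinant +1 (no reflections)")
  if (any(matrix[4, ] != c(0, 0, 0, 1)))
    stop("last row of a homogeneous rigid transform must be (0,0,0,1)")
  structure(matrix, class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform (4x4, mm):\n")
  print(unclass(x))
  cat(sprintf("rotation angle: %.4f deg, translation norm: %.4f mm\n",
              rotation_angle(x), sqrt(sum(unclass(x)[1:3, 4]^2))))
  invisible(x)
}

#' Compose two rigid transforms
#'
#' `compose_transform(A, B)` returns the transform that applies `B` first,
#' then `A` (matrix product `A %*% B`).
#'
#' @param A,B `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose_transform <- function(A, B) {
  rigid_transform(unclass(A) %*% unclass(B))
}

#' Invert a rigid transform
#' @param T A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(T) {
  R <- unclass(T)[1:3, 1:3]
  t <- unclass(T)[1:3, 4]
  rigid_transform(rotation = t(R), translation = -t(R) %*% t)
}

#' Apply a rigid transform to points or a colored surface
#'
#' Points are mapped `p -> R p + t`; normals (when present) are rotated
#' only; colors and labels are untouched.
#'
#' @param x An n x 3 matrix of points or a [colored_surface()].
#' @param T A `rigid_transform`.
#' @return The same kind of object as `x`.
#' @export
apply_transform <- function(x, T) {
  UseMethod("apply_transform")
}

#' @export
apply_transform.default <- function(x, T) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == 3)
  R <- unclass(T)[1:3, 1:3]
  t <- unclass(T)[1:3, 4]
  sweep(x %*% t(R), 2, -t)
}

#' @export
apply_transform.colored_surface <- function(x, T) {
  R <- unclass(T)[1:3, 1:3]
  x$points <- apply_transform.default(x$points, T)
  if (!is.null(x$normals)) x$normals <- x$normals %*% t(R)
  x
}

#' Rotation angle of a rigid transform
#'
#' Geodesic rotation angle, in degrees, of the rotation block.
#' @param T A `rigid_transform` (or plain 4x4/3x3 matrix).
#' @return Angle in degrees, in `[0, 180]`.
#' @export
rotation_angle <- function(T) {
  T <- unclass(T)
  R <- if (all(dim(T) == c(4, 4))) T[1:3, 1:3] else T
  ct <- (sum(diag(R)) - 1) / 2
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

#' Rotation about a coordinate axis
#'
#' @param axis One of "x", "y", "z", or a length-3 axis vector.
#' @param angle_deg Rotation angle, degrees (right-handed).
#' @return A 3x3 rotation matrix.
#' @export
rotation_about <- function(axis, angle_deg) {
  if (is.character(axis)) {
    axis <- switch(match.arg(axis, c("x", "y", "z")),
                   x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  }
  axis <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Draw a random rigid transform
#'
#' Uniformly random rotation axis, rotation angle uniform on
#' `[0, max_rotation_deg]`, translation uniform in the cube
#' `[-max_translation_mm, max_translation_mm]^3` rescaled so its norm is
#' uniform on `[0, max_translation_mm]`. Uses R's RNG (seed with
#' [set.seed()] for reproducibility).
#'
#' @param max_rotation_deg Maximum rotation angle, degrees.
#' @param max_translation_mm Maximum translation norm, mm.
#' @return A `rigid_transform`.
#' @export
random_rigid_transform <- function(max_rotation_deg = 15,
                                   max_translation_mm = 10) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1, 0, max_rotation_deg)
  dir <- stats::rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  t <- dir * stats::runif(1, 0, max_translation_mm)
  rigid_transform(rotation = rotation_about(ax, ang), translation = t)
}

#' Read / write a rigid transform as a plain-text 4x4 matrix
#'
#' @param path File path; four whitespace-separated numbers per line, four
#'   lines.
#' @return `read_transform` returns a `rigid_transform`; `write_transform`
#'   returns `path` invisibly.
#' @export
read_transform <- function(path) {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  rigid_transform(m)
}

#' @rdname read_transform
#' @param T A `rigid_transform` to serialize.
#' @export
write_transform <- function(T, path) {
  lines <- apply(unclass(T), 1, function(r)
    paste(sprintf("%.17g", r), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}
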