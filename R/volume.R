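#' Voxel volumes
#'
#' A `voxel_volume` holds a 3D scalar intensity grid (Hounsfield-like
#' units) with its physical geometry: per-axis voxel spacing in mm and the
#' world coordinate (mm) of the *center* of voxel (0,0,0). Voxel indices are
#' 0-based in all world-coordinate arithmetic; array access in R is 1-based
#' as usual. The axis convention is x = patient left-to-right,
#' y = posterior-to-anterior, z = inferior-to-superior.
#'
#' @param intensities 3D numeric array.
#' @param spacing Length-3 positive numeric, mm per voxel edge.
#' @param origin Length-3 numeric, world mm of the center of voxel (0,0,0).
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(intensities, spacing, origin = c(0, 0, 0)) {
  if (length(dim(intensities)) != 3)
    stop("intensities must be a 3D array")
  if (any(dim(intensities) < 2))
    stop("volume dimensions must all be at least 2")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values (mm)")
  structure(list(intensities = intensities, spacing = spacing,
                 origin = as.numeric(origin), axes = "LPS-style x:L-R y:P-A z:I-S"),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("Voxel volume %d x %d x %d, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("origin (%g, %g, %g) mm; extent %g x %g x %g mm\n",
              x$origin[1], x$origin[2], x$origin[3],
              d[1] * x$spacing[1], d[2] * x$spacing[2], d[3] * x$spacing[3]))
  invisible(x)
}

#' Map voxel indices to world coordinates (and back)
#'
#' Voxel centers map to world points: `world = origin + spacing * index`,
#' with 0-based indices. Both functions accept an n x 3 matrix or a single
#' length-3 vector.
#'
#' @param volume A [voxel_volume()].
#' @param index n x 3 matrix of (possibly fractional) 0-based voxel indices.
#' @return n x 3 matrix of world coordinates (mm), or of voxel indices.
#' @export
voxel_to_world <- function(volume, index) {
  index <- rbind_vec(index)
  sweep(sweep(index, 2, volume$spacing, "*"), 2, volume$origin, "+")
}

#' @rdname voxel_to_world
#' @param world n x 3 matrix of world coordinates, mm.
#' @export
world_to_voxel <- function(volume, world) {
  world <- rbind_vec(world)
  sweep(sweep(world, 2, volume$origin, "-"), 2, volume$spacing, "/")
}

rbind_vec <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3) else as.matrix(x)
}

#' Read a volume from NIfTI, NRRD or a DICOM series
#'
#' `format` is inferred from the path when "auto": a directory is read as a
#' DICOM series, `.nii`/`.nii.gz` as NIfTI, `.nrrd` as NRRD. Intensities
#' are passed through unmodified (DICOM rescale slope/intercept applied);
#' spacing and origin come from the file metadata. Oblique volumes (non
#' axis-aligned orientation) are rejected.
#'
#' @param path File or directory path.
#' @param format One of "auto", "nifti", "nrrd", "dicom".
#' @return A [voxel_volume()].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "nrrd", "dicom")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "dicom"
    else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
    else if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd"
    else stop("unsupported volume format for path: ", path)
  }
  if (!file.exists(path)) stop("no such file or directory: ", path)
  switch(format,
         nifti = read_volume_nifti(path),
         nrrd = read_volume_nrrd(path),
         dicom = read_dicom_series(path))
}

read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  sp <- sqrt(colSums(rot^2))
  dirs <- sweep(rot, 2, sp, "/")
  if (max(abs(abs(dirs) - diag(3))) > 1e-3)
    stop("oblique or permuted NIfTI orientation is not supported; ",
         "resample the volume to axis-aligned RAS first")
  arr <- as.array(img)
  if (length(dim(arr)) != 3) stop("expected a 3D NIfTI volume")
  origin <- xf[1:3, 4]
  # flip axes with negative direction so indices increase along +world
  for (a in 1:3) {
    if (dirs[a, a] < 0) {
      arr <- flip_axis(arr, a)
      origin[a] <- origin[a] + dirs[a, a] * sp[a] * (dim(arr)[a] - 1)
    }
  }
  voxel_volume(arr, sp, origin)
}

flip_axis <- function(arr, axis) {
  idx <- lapply(dim(arr), seq_len)
  idx[[axis]] <- rev(idx[[axis]])
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

#' Write a volume to NIfTI or NRRD
#'
#' @param volume A [voxel_volume()].
#' @param path Output path, `.nii`/`.nii.gz` or `.nrrd`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(volume$intensities)
    RNifti::pixdim(img) <- volume$spacing
    m <- diag(c(volume$spacing, 1))
    m[1:3, 4] <- volume$origin
    img <- RNifti::`qform<-`(img, structure(m, code = 2L))
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    write_volume_nrrd(volume, path)
  } else stop("unsupported output format: ", path)
  invisible(path)
}

# Minimal NRRD: 3D, raw or gzip attached data, little endian, double/float/
# short/int types.
read_volume_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD000", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || nchar(line) == 0) break
    if (grepl("^#", line)) next
    kv <- strsplit(line, ":=|: ", perl = TRUE)[[1]]
    if (length(kv) >= 2)
      fields[[tolower(trimws(kv[1]))]] <- trimws(paste(kv[-1], collapse = ":"))
  }
  dims <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (length(dims) != 3) stop("only 3D NRRD volumes are supported")
  type <- fields[["type"]]
  enc <- tolower(fields[["encoding"]])
  endian <- tolower(fields[["endian"]] %||% "little")
  if (endian != "little") stop("only little-endian NRRD is supported")
  spacing <- c(1, 1, 1)
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space directions"]])) {
    vecs <- parse_nrrd_vectors(fields[["space directions"]])
    m <- do.call(rbind, vecs)
    offd <- m - diag(diag(m))
    if (max(abs(offd)) > 1e-9)
      stop("oblique NRRD space directions are not supported")
    spacing <- diag(m)
    if (any(spacing <= 0)) stop("NRRD space directions must be positive diagonal")
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  }
  if (!is.null(fields[["space origin"]]))
    origin <- parse_nrrd_vectors(fields[["space origin"]])[[1]]
  n <- prod(dims)
  raw_rest <- readBin(con, "raw", n = file.size(path))
  if (enc %in% c("gzip", "gz")) raw_rest <- memDecompress(raw_rest, type = "gzip")
  vals <- switch(type,
    "double" = readBin(raw_rest, "double", n = n, size = 8, endian = "little"),
    "float" = readBin(raw_rest, "double", n = n, size = 4, endian = "little"),
    "short" = readBin(raw_rest, "integer", n = n, size = 2, endian = "little"),
    "int" = readBin(raw_rest, "integer", n = n, size = 4, endian = "little"),
    stop("unsupported NRRD type: ", type))
  if (length(vals) < n) stop("truncated NRRD data block")
  voxel_volume(array(as.numeric(vals[seq_len(n)]), dims), spacing, origin)
}

parse_nrrd_vectors <- function(s) {
  chunks <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
  lapply(chunks, function(ch)
    as.numeric(strsplit(gsub("[()]", "", ch), ",")[[1]]))
}

write_volume_nrrd <- function(volume, path) {
  d <- dim(volume$intensities)
  sp <- volume$spacing
  o <- volume$origin
  hdr <- c("NRRD0004",
           "# Complete NRRD file format specification at:",
           "# http://teem.sourceforge.net/nrrd/format.html",
           "type: double",
           "dimension: 3",
           "space: left-posterior-superior",
           sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
           sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
                   sp[1], sp[2], sp[3]),
           "kinds: domain domain domain",
           "endian: little",
           "encoding: raw",
           sprintf("space origin: (%.17g,%.17g,%.17g)", o[1], o[2], o[3]))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("", con)
  writeBin(as.numeric(volume$intensities), con, size = 8, endian = "little")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
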