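#' Colored surfaces (point clouds)
#'
#' A `colored_surface` is a point cloud in world millimetres with optional
#' per-point RGB colors in `[0,1]`, optional unit normals and optional
#' per-point labels. Mesh connectivity is not retained: the pipeline is
#' point-based and readers take the mesh vertices as points.
#'
#' @param points n x 3 numeric matrix, mm.
#' @param colors Optional n x 3 matrix, channels in `[0,1]`.
#' @param normals Optional n x 3 matrix of unit vectors.
#' @param labels Optional length-n vector (any atomic type).
#' @return An object of class `colored_surface`.
#' @export
colored_surface <- function(points, colors = NULL, normals = NULL,
                            labels = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 1 || ncol(points) != 3 || !all(is.finite(points)))
    stop("points must be a non-empty n x 3 finite numeric matrix")
  if (!is.null(colors)) {
    colors <- as.matrix(colors)
    if (!all(dim(colors) == dim(points)))
      stop("colors must match points in shape")
    if (any(colors < 0 | colors > 1))
      stop("color channels must lie in [0, 1]")
  }
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    if (!all(dim(normals) == dim(points)))
      stop("normals must match points in shape")
    nn <- sqrt(rowSums(normals^2))
    if (any(abs(nn - 1) > 1e-6))
      stop("normals must have unit length within 1e-6")
  }
  if (!is.null(labels) && length(labels) != nrow(points))
    stop("labels must have one entry per point")
  structure(list(points = points, colors = colors, normals = normals,
                 labels = labels), class = "colored_surface")
}

#' @export
print.colored_surface <- function(x, ...) {
  cat(sprintf("Colored surface: %d points%s%s%s\n", nrow(x$points),
              if (!is.null(x$colors)) ", RGB colors" else "",
              if (!is.null(x$normals)) ", normals" else "",
              if (!is.null(x$labels)) ", labels" else ""))
  invisible(x)
}

#' Number of points in a surface
#' @param surface A [colored_surface()].
#' @return Integer count.
#' @export
n_points <- function(surface) nrow(surface$points)

#' Read a surface mesh / point cloud
#'
#' Supports PLY (ascii and binary little endian), OBJ (`v x y z [r g b]`)
#' and STL (ascii and binary; STL carries no color). Mesh vertices become
#' points; per-vertex colors and normals are preserved when present.
#'
#' @param path File path.
#' @param format One of "auto", "ply", "obj", "stl".
#' @param require_color Error if the file carries no per-vertex color
#'   (color-based teeth/gingiva separation is then impossible).
#' @return A [colored_surface()].
#' @export
read_surface <- function(path, format = c("auto", "ply", "obj", "stl"),
                         require_color = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("ply", "obj", "stl"))
      stop("unsupported surface format: ", path)
    format <- ext
  }
  surf <- switch(format,
                 ply = read_ply(path),
                 obj = read_obj(path),
                 stl = read_stl(path))
  if (require_color && is.null(surf$colors))
    stop("surface '", path, "' has no per-vertex color; color-based ",
         "teeth/gingiva segmentation is impossible for this input")
  surf
}

#' Write a surface as PLY or OBJ
#'
#' @param surface A [colored_surface()].
#' @param path Output path (`.ply` or `.obj`).
#' @param binary Write binary little-endian PLY (ignored for OBJ).
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path, binary = FALSE) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = write_ply(surface, path, binary),
         obj = write_obj(surface, path),
         stop("unsupported output surface format: ", path))
  invisible(path)
}

# ---- PLY ----

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file: ", path)
  fmt <- NULL
  nvert <- 0
  in_vertex <- FALSE
  vprops <- list() # name, type
  elements <- list() # name -> count (in order)
  repeat {
    line <- trimws(readLines(con, n = 1))
    if (length(line) == 0) stop("unterminated PLY header")
    if (line == "end_header") break
    tok <- strsplit(line, "\\s+")[[1]]
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      elements[[tok[2]]] <- as.integer(tok[3])
      in_vertex <- tok[2] == "vertex"
      if (in_vertex) nvert <- as.integer(tok[3])
    } else if (tok[1] == "property" && in_vertex) {
      if (tok[2] == "list") stop("list properties on vertices are not supported")
      vprops[[length(vprops) + 1]] <- list(type = tok[2], name = tok[3])
    }
  }
  if (is.null(fmt) || nvert < 1) stop("malformed PLY header")
  pnames <- vapply(vprops, `[[`, "", "name")
  ptypes <- vapply(vprops, `[[`, "", "type")
  if (fmt == "ascii") {
    rows <- matrix(NA_real_, nvert, length(vprops))
    got <- 0
    while (got < nvert) {
      line <- readLines(con, n = 1)
      if (length(line) == 0) stop("truncated PLY vertex data")
      vals <- suppressWarnings(as.numeric(strsplit(trimws(line), "\\s+")[[1]]))
      if (length(vals) < length(vprops)) next
      got <- got + 1
      rows[got, ] <- vals[seq_along(vprops)]
    }
  } else if (fmt == "binary_little_endian") {
    sizes <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
               short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
               int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
               float = 4L, float32 = 4L, double = 8L, float64 = 8L)
    sz <- sizes[ptypes]
    if (any(is.na(sz))) stop("unsupported PLY property type")
    stride <- sum(sz)
    raw <- readBin(con, "raw", n = nvert * stride)
    if (length(raw) < nvert * stride) stop("truncated PLY vertex data")
    rows <- matrix(NA_real_, nvert, length(vprops))
    off <- cumsum(c(0L, sz[-length(sz)]))
    for (p in seq_along(vprops)) {
      byte_idx <- rep(off[p], each = sz[p]) + seq_len(sz[p]) +
        rep((0:(nvert - 1)) * stride, each = sz[p])
      bytes <- raw[byte_idx]
      rows[, p] <- switch(ptypes[p],
        float = , float32 = readBin(bytes, "double", nvert, size = 4, endian = "little"),
        double = , float64 = readBin(bytes, "double", nvert, size = 8, endian = "little"),
        uchar = , uint8 = as.numeric(readBin(bytes, "integer", nvert, size = 1,
                                             signed = FALSE, endian = "little")),
        char = , int8 = as.numeric(readBin(bytes, "integer", nvert, size = 1,
                                           signed = TRUE, endian = "little")),
        ushort = , uint16 = as.numeric(readBin(bytes, "integer", nvert, size = 2,
                                               signed = FALSE, endian = "little")),
        short = , int16 = as.numeric(readBin(bytes, "integer", nvert, size = 2,
                                             signed = TRUE, endian = "little")),
        as.numeric(readBin(bytes, "integer", nvert, size = 4, endian = "little")))
    }
  } else stop("unsupported PLY format: ", fmt)
  need <- c("x", "y", "z")
  if (!all(need %in% pnames)) stop("PLY vertex element lacks x/y/z")
  pts <- rows[, match(need, pnames), drop = FALSE]
  colors <- NULL
  if (all(c("red", "green", "blue") %in% pnames)) {
    colors <- rows[, match(c("red", "green", "blue"), pnames), drop = FALSE]
    ctype <- ptypes[match("red", pnames)]
    if (ctype %in% c("uchar", "uint8", "char", "int8")) colors <- colors / 255
  }
  normals <- NULL
  if (all(c("nx", "ny", "nz") %in% pnames)) {
    normals <- rows[, match(c("nx", "ny", "nz"), pnames), drop = FALSE]
    nn <- sqrt(rowSums(normals^2))
    normals <- normals / pmax(nn, 1e-12)
  }
  colored_surface(pts, colors, normals)
}

write_ply <- function(surface, path, binary = FALSE) {
  n <- n_points(surface)
  has_col <- !is.null(surface$colors)
  has_nrm <- !is.null(surface$normals)
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           sprintf("element vertex %d", n),
           "property double x", "property double y", "property double z",
           if (has_nrm) c("property double nx", "property double ny",
                          "property double nz"),
           if (has_col) c("property uchar red", "property uchar green",
                          "property uchar blue"),
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  cols255 <- if (has_col) round(surface$colors * 255) else NULL
  if (binary) {
    for (i in seq_len(n)) {
      writeBin(as.numeric(surface$points[i, ]), con, size = 8, endian = "little")
      if (has_nrm) writeBin(as.numeric(surface$normals[i, ]), con, size = 8,
                            endian = "little")
      if (has_col) writeBin(as.raw(cols255[i, ]), con)
    }
  } else {
    parts <- apply(surface$points, 1, function(r)
      paste(sprintf("%.17g", r), collapse = " "))
    if (has_nrm) parts <- paste(parts, apply(surface$normals, 1, function(r)
      paste(sprintf("%.17g", r), collapse = " ")))
    if (has_col) parts <- paste(parts, apply(cols255, 1, function(r)
      paste(as.integer(r), collapse = " ")))
    writeLines(parts, con)
  }
  invisible(path)
}

# ---- OBJ ----

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- lines[startsWith(lines, "v ")]
  if (length(vlines) == 0) stop("OBJ file has no vertices: ", path)
  toks <- strsplit(trimws(sub("^v\\s+", "", vlines)), "\\s+")
  nums <- lapply(toks, function(t) suppressWarnings(as.numeric(t)))
  len <- vapply(nums, length, 0L)
  pts <- t(vapply(nums, function(v) v[1:3], numeric(3)))
  colors <- NULL
  if (all(len >= 6)) {
    colors <- t(vapply(nums, function(v) v[4:6], numeric(3)))
    if (any(!is.finite(colors))) colors <- NULL
  }
  colored_surface(pts, colors)
}

write_obj <- function(surface, path) {
  if (is.null(surface$colors)) {
    lines <- apply(surface$points, 1, function(r)
      paste("v", paste(sprintf("%.17g", r), collapse = " ")))
  } else {
    m <- cbind(surface$points, surface$colors)
    lines <- apply(m, 1, function(r)
      paste("v", paste(sprintf("%.17g", r), collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- STL (read only; STL is colorless) ----

read_stl <- function(path) {
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  head80 <- readBin(con, "raw", n = min(80, sz))
  is_ascii <- identical(rawToChar(head80[1:5]), "solid")
  if (is_ascii) {
    ntri_guess <- if (sz >= 84) {
      con2 <- file(path, "rb")
      invisible(readBin(con2, "raw", n = 80))
      nt <- readBin(con2, "integer", 1, size = 4, endian = "little")
      close(con2)
      nt
    } else -1
    # binary files can also start with "solid"; check size consistency
    if (ntri_guess >= 0 && sz == 84 + 50 * ntri_guess) is_ascii <- FALSE
  }
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (length(vlines) == 0) stop("ASCII STL has no vertices: ", path)
    pts <- t(vapply(strsplit(trimws(sub("^\\s*vertex\\s+", "", vlines)), "\\s+"),
                    function(t) as.numeric(t[1:3]), numeric(3)))
  } else {
    close(con)
    on.exit()
    con <- file(path, "rb")
    on.exit(close(con))
    invisible(readBin(con, "raw", n = 80))
    ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
    raw <- readBin(con, "raw", n = 50 * ntri)
    if (length(raw) < 50 * ntri) stop("truncated binary STL")
    pts <- matrix(NA_real_, 3 * ntri, 3)
    for (t in seq_len(ntri)) {
      block <- raw[((t - 1) * 50 + 1):(t * 50)]
      vals <- readBin(block[1:48], "double", 12, size = 4, endian = "little")
      pts[(3 * t - 2):(3 * t), ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
    }
  }
  pts <- unique(pts)
  colored_surface(pts)
}
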