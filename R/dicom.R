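# Minimal DICOM series reader: uncompressed single-frame slices in explicit
# or implicit VR little endian (transfer syntaxes 1.2.840.10008.1.2 and
# 1.2.840.10008.1.2.1). Enough to ingest axial CBCT exports; anything
# exotic (compressed pixel data, sequences of undefined length, oblique
# orientations) is rejected with a clear error.

read_dicom_series <- function(dir_path) {
  files <- sort(list.files(dir_path, full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (length(files) < 2) stop("DICOM series needs at least two slice files in ", dir_path)
  slices <- lapply(files, read_dicom_slice)
  orient <- slices[[1]]$orient
  if (max(abs(orient - c(1, 0, 0, 0, 1, 0))) > 1e-6)
    stop("oblique DICOM orientation is not supported (ImageOrientationPatient ",
         "must be 1\\0\\0\\0\\1\\0)")
  zs <- vapply(slices, function(s) s$pos[3], 0)
  ord <- order(zs)
  slices <- slices[ord]
  files <- files[ord]
  zs <- zs[ord]
  dz <- diff(zs)
  if (any(dz <= 0)) stop("duplicate DICOM slice positions in ", dir_path)
  med <- stats::median(dz)
  bad <- which(abs(dz - med) > 1e-3 * med + 1e-6)
  if (length(bad) > 0) {
    stop("inconsistent DICOM slice spacing (expected ", signif(med, 6),
         " mm): gap(s) between ",
         paste(sprintf("'%s' and '%s' (%.4f mm)", basename(files[bad]),
                       basename(files[bad + 1]), dz[bad]), collapse = "; "))
  }
  nx <- slices[[1]]$cols
  ny <- slices[[1]]$rows
  arr <- array(NA_real_, c(nx, ny, length(slices)))
  for (k in seq_along(slices)) {
    s <- slices[[k]]
    if (s$cols != nx || s$rows != ny)
      stop("DICOM slice dimensions differ across the series")
    arr[, , k] <- matrix(s$pixels, nrow = nx)
  }
  spacing <- c(slices[[1]]$spacing_col, slices[[1]]$spacing_row, med)
  origin <- c(slices[[1]]$pos[1], slices[[1]]$pos[2], zs[1])
  voxel_volume(arr, spacing, origin)
}

read_dicom_slice <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140) stop("not a DICOM file (too short): ", path)
  if (rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file (missing DICM magic): ", path)
  u16 <- function(off) as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
  u32 <- function(off) u16(off) + 65536 * u16(off + 2)
  pos <- 132L # 0-based offset just past DICM
  explicit <- TRUE
  ts <- NULL
  fields <- list()
  want <- c("0008,0060", "0020,0032", "0020,0037", "0028,0010", "0028,0011",
            "0028,0030", "0028,0100", "0028,0103", "0028,1052", "0028,1053",
            "0002,0010", "7fe0,0010")
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  meta_explicit <- TRUE
  while (pos + 8 <= length(raw)) {
    group <- u16(pos); elem <- u16(pos + 2)
    tag <- sprintf("%04x,%04x", group, elem)
    in_meta <- group == 2L
    expl <- if (in_meta) meta_explicit else explicit
    if (expl) {
      vr <- rawToChar(raw[(pos + 5):(pos + 6)])
      if (vr %in% long_vrs) {
        len <- u32(pos + 8)
        hdr <- 12L
      } else {
        len <- u16(pos + 6)
        hdr <- 8L
      }
    } else {
      vr <- ""
      len <- u32(pos + 4)
      hdr <- 8L
    }
    if (len == 4294967295) stop("DICOM undefined-length element (", tag,
                                ") is not supported: ", path)
    val_off <- pos + hdr
    if (val_off + len > length(raw)) stop("truncated DICOM element ", tag, ": ", path)
    if (tag %in% want) {
      bytes <- raw[(val_off + 1):(val_off + len)]
      fields[[tag]] <- list(vr = vr, bytes = bytes)
    }
    if (tag == "0002,0010") {
      uid_raw <- raw[(val_off + 1):(val_off + len)]
      uid_raw <- uid_raw[uid_raw != as.raw(0)] # UIs are NUL-padded
      ts <- trimws(rawToChar(uid_raw))
      if (ts == "1.2.840.10008.1.2") explicit <- FALSE
      else if (ts == "1.2.840.10008.1.2.1") explicit <- TRUE
      else stop("unsupported DICOM transfer syntax ", ts, " in ", path,
                " (only uncompressed little endian is supported)")
    }
    if (tag == "7fe0,0010") { pos <- val_off + len; break }
    pos <- val_off + len
  }
  ds <- function(tag, default = NULL) {
    f <- fields[[tag]]
    if (is.null(f)) return(default)
    as.numeric(strsplit(trimws(rawToChar(f$bytes)), "\\\\")[[1]])
  }
  us <- function(tag, default = NULL) {
    f <- fields[[tag]]
    if (is.null(f)) return(default)
    readBin(f$bytes, "integer", 1, size = 2, signed = FALSE, endian = "little")
  }
  rows <- us("0028,0010"); cols <- us("0028,0011")
  if (is.null(rows) || is.null(cols)) stop("DICOM slice lacks Rows/Columns: ", path)
  spacing <- ds("0028,0030")
  if (is.null(spacing) || length(spacing) != 2)
    stop("DICOM slice lacks PixelSpacing: ", path)
  ipp <- ds("0020,0032")
  if (is.null(ipp) || length(ipp) != 3)
    stop("DICOM slice lacks ImagePositionPatient: ", path)
  orient <- ds("0020,0037", default = c(1, 0, 0, 0, 1, 0))
  bits <- us("0028,0100", default = 16L)
  if (bits != 16) stop("only 16-bit DICOM pixel data is supported: ", path)
  signed <- identical(us("0028,0103", default = 0L), 1L)
  slope <- ds("0028,1053", default = 1)
  intercept <- ds("0028,1052", default = 0)
  pix <- fields[["7fe0,0010"]]
  if (is.null(pix)) stop("DICOM slice lacks PixelData: ", path)
  n <- rows * cols
  vals <- readBin(pix$bytes, "integer", n, size = 2, signed = signed,
                  endian = "little")
  if (length(vals) < n) stop("truncated DICOM PixelData: ", path)
  list(rows = rows, cols = cols,
       spacing_row = spacing[1], spacing_col = spacing[2],
       pos = ipp, orient = orient,
       pixels = as.numeric(vals) * slope + intercept)
}
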