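test_that("voxel volume validates geometry and maps coordinates both ways", {
  arr <- array(rnorm(8 * 6 * 4), c(8, 6, 4))
  v <- voxel_volume(arr, c(0.3, 0.4, 0.5), origin = c(-1, 2, 3))
  expect_error(voxel_volume(arr, c(0.3, 0, 0.5)), "positive")
  expect_error(voxel_volume(array(0, c(1, 5, 5)), c(1, 1, 1)), "at least 2")
  set.seed(1)
  idx <- cbind(runif(50, 0, 7), runif(50, 0, 5), runif(50, 0, 3))
  expect_equal(world_to_voxel(v, voxel_to_world(v, idx)), idx,
               tolerance = 1e-12)
})

test_that("a 768x768x576 grid at 0.3 mm spans 230.4 x 230.4 x 172.8 mm", {
  # metadata-only volume: extent must come out of spacing * dims
  v <- voxel_volume(array(0, c(4, 4, 3)), c(0.3, 0.3, 0.3))
  expect_equal(768 * v$spacing[1], 230.4)
  expect_equal(768 * v$spacing[2], 230.4)
  expect_equal(576 * v$spacing[3], 172.8)
})

test_that("NIfTI and NRRD writers round-trip data, spacing and origin", {
  set.seed(2)
  v <- voxel_volume(array(rnorm(5 * 6 * 7), c(5, 6, 7)),
                    c(0.3, 0.3, 0.3), origin = c(1.5, -2, 0.25))
  for (ext in c(".nii.gz", ".nrrd")) {
    f <- withr::local_tempfile(fileext = ext)
    write_volume(v, f)
    b <- read_volume(f)
    expect_equal(b$spacing, v$spacing, tolerance = 1e-6)
    expect_equal(b$origin, v$origin, tolerance = 1e-6)
    expect_equal(as.numeric(b$intensities), as.numeric(v$intensities),
                 tolerance = 1e-6)
  }
})

write_dicom_series <- function(dir, nx = 8, ny = 6, nz = 5, drop_slice = NULL) {
  # independent writer: pydicom through the system python
  script <- sprintf('
import numpy as np, pydicom, os, sys
from pydicom.dataset import Dataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian, generate_uid
out = sys.argv[1]
nx, ny, nz, drop = %d, %d, %d, %s
rng = np.random.default_rng(7)
vol = rng.integers(0, 3000, size=(nz, ny, nx)).astype(np.int16)
np.save(os.path.join(out, "truth.npy"), vol)
series = generate_uid()
for k in range(nz):
    if drop is not None and k == drop: continue
    ds = Dataset()
    ds.Rows, ds.Columns = ny, nx
    ds.BitsAllocated = 16; ds.BitsStored = 16; ds.HighBit = 15
    ds.PixelRepresentation = 1
    ds.SamplesPerPixel = 1
    ds.PhotometricInterpretation = "MONOCHROME2"
    ds.PixelSpacing = ["0.4", "0.3"]
    ds.ImagePositionPatient = ["1.0", "2.0", str(5.0 + 0.5 * k)]
    ds.ImageOrientationPatient = [1,0,0,0,1,0]
    ds.RescaleSlope = "1"; ds.RescaleIntercept = "0"
    ds.SeriesInstanceUID = series
    ds.SOPClassUID = "1.2.840.10008.5.1.4.1.1.2"  # CT Image Storage
    ds.SOPInstanceUID = generate_uid()
    ds.PixelData = vol[k].tobytes()
    meta = FileMetaDataset()
    meta.TransferSyntaxUID = ExplicitVRLittleEndian
    meta.MediaStorageSOPClassUID = ds.SOPClassUID
    meta.MediaStorageSOPInstanceUID = ds.SOPInstanceUID
    ds.file_meta = meta
    ds.save_as(os.path.join(out, "slice_%%03d.dcm" %% k),
               enforce_file_format=True)
', nx, ny, nz, if (is.null(drop_slice)) "None" else drop_slice)
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", c(sf, dir), stdout = TRUE, stderr = TRUE)
  file.exists(file.path(dir, "truth.npy"))
}

test_that("DICOM series written by an independent tool are read correctly", {
  skip_if(Sys.which("python") == "", "no python available")
  dir <- withr::local_tempdir()
  ok <- write_dicom_series(dir)
  skip_if(!ok, "pydicom unavailable")
  truth_txt <- system2("python", c("-c", shQuote(sprintf(
    "import numpy; v=numpy.load('%s/truth.npy'); print('\\n'.join(str(x) for x in v.flatten()))",
    dir))), stdout = TRUE)
  truth <- as.numeric(truth_txt) # (z, y, x) C-order
  file.remove(file.path(dir, "truth.npy"))
  v <- read_volume(dir)
  expect_equal(dim(v$intensities), c(8, 6, 5))
  expect_equal(v$spacing, c(0.3, 0.4, 0.5), tolerance = 1e-9)
  expect_equal(v$origin, c(1, 2, 5), tolerance = 1e-9)
  # C-order (z,y,x) flattens x-fastest, matching R's column-major (x,y,z)
  truth_arr <- array(truth, c(8, 6, 5))
  expect_equal(as.numeric(v$intensities), as.numeric(truth_arr))
})

test_that("a DICOM series with a missing slice fails naming the gap", {
  skip_if(Sys.which("python") == "", "no python available")
  dir <- withr::local_tempdir()
  ok <- write_dicom_series(dir, drop_slice = 2)
  skip_if(!ok, "pydicom unavailable")
  file.remove(file.path(dir, "truth.npy"))
  expect_error(read_volume(dir), "slice_001.*slice_003")
})

test_that("colored surfaces validate colors and normals", {
  p <- matrix(rnorm(30), 10, 3)
  expect_error(colored_surface(p, colors = matrix(2, 10, 3)), "\\[0, 1\\]")
  expect_error(colored_surface(p, normals = matrix(1, 10, 3)), "unit length")
  expect_error(colored_surface(matrix(numeric(0), 0, 3)), "non-empty")
})

test_that("PLY round-trips points, colors and normals (ascii and binary)", {
  set.seed(4)
  n <- 25
  nrm <- matrix(rnorm(3 * n), n, 3)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  s <- colored_surface(matrix(rnorm(3 * n), n, 3),
                       colors = round(matrix(runif(3 * n), n, 3) * 255) / 255,
                       normals = nrm)
  for (binary in c(FALSE, TRUE)) {
    f <- withr::local_tempfile(fileext = ".ply")
    write_surface(s, f, binary = binary)
    b <- read_surface(f)
    expect_equal(b$points, s$points, tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(b$colors, s$colors, tolerance = 1 / 255, ignore_attr = TRUE)
    expect_equal(b$normals, s$normals, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("a colored PLY with three red vertices reads back as written", {
  f <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 3",
               "property float x", "property float y", "property float z",
               "property uchar red", "property uchar green", "property uchar blue",
               "end_header",
               "0 0 0 255 0 0", "1 0 0 255 0 0", "0 1 0 255 0 0"), f)
  s <- read_surface(f)
  expect_equal(n_points(s), 3)
  expect_equal(unname(s$colors), matrix(rep(c(1, 0, 0), each = 3), 3),
               tolerance = 1e-12)
})

test_that("OBJ round-trips coordinates within 1e-6 mm", {
  set.seed(5)
  s <- colored_surface(matrix(rnorm(30), 10, 3),
                       colors = matrix(runif(30), 10, 3))
  f <- withr::local_tempfile(fileext = ".obj")
  write_surface(s, f)
  b <- read_surface(f)
  expect_lt(max(abs(b$points - s$points)), 1e-6)
  expect_lt(max(abs(b$colors - s$colors)), 1e-6)
})

test_that("STL is colorless and require_color rejects it", {
  f <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid t",
               "facet normal 0 0 1", "outer loop",
               "vertex 0 0 0", "vertex 1 0 0", "vertex 0 1 0",
               "endloop", "endfacet", "endsolid t"), f)
  s <- read_surface(f)
  expect_equal(n_points(s), 3)
  expect_null(s$colors)
  expect_error(read_surface(f, require_color = TRUE), "impossible")
})

test_that("extract_roi keeps world positions and rejects empty boxes", {
  ph <- get_phantom("tiny")
  v <- ph$volume
  d <- dim(v$intensities)
  full <- extract_roi(v, list(min = v$origin - 1,
                              max = v$origin + v$spacing * d))
  expect_equal(dim(full$intensities), d)
  zmid <- v$origin[3] + v$spacing[3] * (d[3] / 2)
  lower <- extract_roi(v, list(min = v$origin - 1,
                               max = c(v$origin[1:2] + v$spacing[1:2] * d[1:2],
                                       zmid)))
  expect_lt(dim(lower$intensities)[3], d[3])
  # a retained voxel keeps its world position
  expect_equal(drop(voxel_to_world(lower, c(3, 4, 5))),
               drop(voxel_to_world(v, c(3, 4, 5))))
  expect_error(extract_roi(v, list(min = v$origin - 10, max = v$origin - 5)),
               "intersect")
})
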