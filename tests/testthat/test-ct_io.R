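test_that("NIfTI write/read round trip is the identity for phantoms and masks", {
  ph <- tiny_phantom(lesions = list(lesion_spec("acute", 15, "left")))
  f <- tempfile(fileext = ".nii.gz")
  write_volume_nifti(ph$volume$voxels, ph$volume, f)
  back <- load_nifti(f)
  expect_equal(back$voxels, ph$volume$voxels, tolerance = 1e-6)
  expect_equal(back$spacing, ph$volume$spacing, tolerance = 1e-6)

  fm <- tempfile(fileext = ".nii.gz")
  write_mask(ph$ground_truth, ph$volume, fm)
  mask_back <- RNifti::readNifti(fm) > 0
  expect_equal(sum(mask_back), sum(ph$ground_truth))
  expect_equal(array(mask_back, dim(ph$ground_truth)), ph$ground_truth)

  empty <- array(FALSE, dim(ph$ground_truth))
  fe <- tempfile(fileext = ".nii.gz")
  write_mask(empty, ph$volume, fe)
  expect_equal(sum(RNifti::readNifti(fe)), 0)
})

test_that("load_nifti derives spacing from the affine and rejects bad inputs", {
  arr <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, c(2, 2, 2))
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, f)
  v <- load_nifti(f)
  expect_equal(v$spacing, c(2, 2, 2), tolerance = 1e-6)

  expect_error(load_nifti(tempfile(fileext = ".nii")), "not found")

  arr4 <- array(0, c(4, 4, 4, 3))
  f4 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr4), f4)
  expect_error(load_nifti(f4), "3D")
})

test_that("write_mask rejects geometry mismatch", {
  ph <- tiny_phantom()
  bad <- array(FALSE, dim(ph$volume$voxels) + c(1, 0, 0))
  expect_error(write_mask(bad, ph$volume, tempfile(fileext = ".nii")),
               "geometry")
})

test_that("DICOM series load converts to HU, sorts slices, reads geometry", {
  raw <- lapply(1:3, function(k) matrix(1000L + k, 16, 16))
  # shuffle write order via z positions out of order
  dir <- write_dicom_series(raw, z_positions = c(10, 0, 5))
  vol <- load_dicom_series(dir)
  expect_s3_class(vol, "ct_volume")
  expect_equal(dim(vol$voxels), c(16, 16, 3))
  expect_equal(vol$spacing, c(0.4297, 0.4297, 5), tolerance = 1e-6)
  # slices sorted by axial position: z order 0,5,10 -> raw slices 2,3,1
  expect_equal(unique(as.vector(vol$voxels[, , 1])), 1002 - 1024)
  expect_equal(unique(as.vector(vol$voxels[, , 3])), 1001 - 1024)
  expect_equal(vol$patient_age, 61)
})

test_that("HU conversion is affine in the raw values", {
  raw <- list(matrix(sample.int(2000, 64) - 1000L, 8, 8))
  d1 <- write_dicom_series(raw, slope = 1, intercept = -1024,
                           z_positions = 0)
  d2 <- write_dicom_series(raw, slope = 2, intercept = 10,
                           z_positions = 0)
  v1 <- load_dicom_series(d1)
  v2 <- load_dicom_series(d2)
  r <- (v1$voxels + 1024)           # recovered raw values
  expect_equal(v2$voxels, 2 * r + 10, tolerance = 1e-9)
  # raw 1024 with slope 1 intercept -1024 -> 0 HU
  d3 <- write_dicom_series(list(matrix(1024L, 8, 8)), z_positions = 0)
  expect_true(all(load_dicom_series(d3)$voxels == 0))
})

test_that("single-slice series yields a depth-1 volume without error", {
  dir <- write_dicom_series(list(matrix(0L, 8, 8)), z_positions = 0)
  vol <- load_dicom_series(dir)
  expect_equal(dim(vol$voxels), c(8, 8, 1))
})

test_that("implicit VR little endian series are readable", {
  dir <- write_dicom_series(list(matrix(500L, 8, 8), matrix(600L, 8, 8)),
                            implicit_vr = TRUE)
  vol <- load_dicom_series(dir)
  expect_equal(unique(as.vector(vol$voxels[, , 1])), 500 - 1024)
})

test_that("DICOM error contracts: mixed series, wrong modality, bad gaps", {
  d1 <- write_dicom_series(list(matrix(0L, 8, 8)), series_uid = "1.1",
                           z_positions = 0)
  f2 <- write_dicom_series(list(matrix(0L, 8, 8)), series_uid = "2.2",
                           z_positions = 5)
  file.copy(list.files(f2, full.names = TRUE), file.path(d1, "other.dcm"))
  expect_error(load_dicom_series(d1), "mixed series")

  dmr <- write_dicom_series(list(matrix(0L, 8, 8)), modality = "MR",
                            z_positions = 0)
  expect_error(load_dicom_series(dmr), "non-CT")

  dgap <- write_dicom_series(lapply(1:3, function(k) matrix(0L, 8, 8)),
                             z_positions = c(0, 5, 18))
  expect_warning(load_dicom_series(dgap), "non-uniform")
  vol <- suppressWarnings(load_dicom_series(dgap))
  expect_equal(attr(vol, "slice_gaps"), c(5, 13))

  expect_error(load_dicom_series(tempfile("nodir")), "not found")

  dmiss <- write_dicom_series(list(matrix(0L, 8, 8)), z_positions = 0,
                              omit_spacing = TRUE)
  expect_error(load_dicom_series(dmiss), "pixel_spacing")
})

test_that("ct_volume validates its invariants", {
  expect_error(ct_volume(matrix(0, 2, 2), c(1, 1, 1)), "3D")
  expect_error(ct_volume(array(0, c(2, 2, 2)), c(1, -1, 1)), "positive")
  expect_error(ct_volume(array(NA_real_, c(2, 2, 2)), c(1, 1, 1)),
               "non-finite")
})
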