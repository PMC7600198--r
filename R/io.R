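#' Load an axial CT series from a DICOM directory
#'
#' Reads every DICOM file in `directory`, checks that they form one
#' consistent axial CT series, converts stored values to Hounsfield units
#' with the per-file rescale slope/intercept, sorts slices by axial
#' position, and assembles a [ct_volume()].
#'
#' Non-CT modalities are rejected rather than guessed, because everything
#' downstream assumes HU semantics. Mixed series (differing series UID,
#' image size, pixel spacing or orientation) are a hard error. A
#' non-uniform slice gap beyond `gap_tol` (relative) triggers a warning and
#' is recorded in the `slice_gaps` attribute.
#'
#' @param directory Path containing the `.dcm` files of one series.
#' @param gap_tol Relative tolerance on slice-gap uniformity.
#' @return A [ct_volume()] in HU with spacing `(row, column, slice)` mm.
#' @export
load_dicom_series <- function(directory, gap_tol = 0.01) {
  if (!dir.exists(directory)) {
    stop(sprintf("DICOM directory not found: %s", directory), call. = FALSE)
  }
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) {
    stop(sprintf("no files in DICOM directory %s", directory), call. = FALSE)
  }
  slices <- lapply(files, read_dicom_file)

  modality <- unique(vapply(slices, function(s) s$modality %||% "", ""))
  if (!all(modality %in% c("CT"))) {
    stop(sprintf("non-CT modality in series: %s",
                 paste(setdiff(modality, "CT"), collapse = ", ")),
         call. = FALSE)
  }
  uid <- unique(vapply(slices, function(s) s$series_uid %||% "", ""))
  if (length(uid) > 1) {
    stop("directory contains a mixed series (multiple SeriesInstanceUIDs)",
         call. = FALSE)
  }
  dims <- unique(t(vapply(slices, function(s) dim(s$image), integer(2))))
  if (nrow(dims) > 1) stop("mixed series: inconsistent image dimensions", call. = FALSE)
  sp <- unique(t(vapply(slices, function(s) s$pixel_spacing, numeric(2))))
  if (nrow(sp) > 1) stop("mixed series: inconsistent PixelSpacing", call. = FALSE)

  # axial position = projection of ImagePositionPatient on the slice normal
  ori <- slices[[1]]$orientation
  normal <- if (!is.null(ori) && length(ori) == 6) {
    r <- ori[1:3]; c <- ori[4:6]
    c(r[2] * c[3] - r[3] * c[2], r[3] * c[1] - r[1] * c[3], r[1] * c[2] - r[2] * c[1])
  } else c(0, 0, 1)
  zpos <- vapply(slices, function(s) sum(s$position * normal), numeric(1))
  ord <- order(zpos)
  slices <- slices[ord]
  zpos <- zpos[ord]

  slice_gaps <- diff(zpos)
  if (length(slice_gaps) >= 1) {
    dz <- stats::median(slice_gaps)
    if (any(abs(slice_gaps - dz) > gap_tol * dz)) {
      warning("non-uniform slice gaps in series; gaps recorded in attribute",
              call. = FALSE)
    }
  } else {
    dz <- slices[[1]]$slice_thickness
    if (is.null(dz) || !is.finite(dz)) dz <- 1
  }

  d2 <- dim(slices[[1]]$image)
  vox <- array(0, c(d2[1], d2[2], length(slices)))
  for (k in seq_along(slices)) {
    s <- slices[[k]]
    vox[, , k] <- s$rescale_slope * s$image + s$rescale_intercept
  }
  age <- slices[[1]]$patient_age
  vol <- ct_volume(
    voxels = vox,
    spacing = c(slices[[1]]$pixel_spacing, dz),
    origin = c(0, 0, 0),
    patient_age = if (is.null(age)) NA_real_ else age,
    scan_id = if (nzchar(uid)) uid else basename(directory)
  )
  attr(vol, "slice_gaps") <- slice_gaps
  vol
}

#' Load a 3D NIfTI volume
#'
#' Intensities are assumed to be in Hounsfield units already. Spacing is
#' taken from the affine; 4D inputs and non-orthogonal affines are
#' rejected.
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @param scan_id Optional identifier; defaults to the file name.
#' @return A [ct_volume()].
#' @export
load_nifti <- function(path, scan_id = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("NIfTI file not found: %s", path), call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4 && d[4] == 1) {
    img <- img[, , , 1]
    d <- dim(img)
  }
  if (length(d) != 3) {
    stop(sprintf("expected a 3D volume, got %dD: %s", length(d), path),
         call. = FALSE)
  }
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  g <- crossprod(rot)
  if (max(abs(g[upper.tri(g)])) > 1e-4 * max(diag(g))) {
    stop(sprintf("non-orthogonal affine in %s; reorient the volume first", path),
         call. = FALSE)
  }
  spacing <- sqrt(diag(g))
  vox <- array(as.numeric(img), d)
  ct_volume(
    voxels = vox,
    spacing = spacing,
    origin = xf[1:3, 4],
    scan_id = scan_id %||% sub("\\.nii(\\.gz)?$", "", basename(path))
  )
}

#' Write a binary mask as NIfTI with the source geometry
#'
#' @param mask 3D logical array, same shape as `geometry`.
#' @param geometry The [ct_volume()] the mask refers to.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_mask <- function(mask, geometry, path) {
  stopifnot_same_geometry(mask, geometry$voxels, "mask and geometry")
  write_volume_nifti(array(as.integer(mask), dim(mask)), geometry, path)
}

#' Write a ct_volume (or raw array with ct_volume geometry) as NIfTI
#' @keywords internal
write_volume_nifti <- function(arr, geometry, path) {
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, geometry$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}
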