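## 3D post-processing of the initial superpixel mask: 2D component
## filtering, morphological repair against the skull, 3D continuity
## filtering, and anisotropy-aware Gaussian smoothing.

#' Threshold the probability volume into the initial mask
#'
#' @param probability 3D numeric array in `[0, 1]`.
#' @param roi_band Logical ROI mask; the initial mask never leaves it.
#' @param tau Probability threshold in `(0, 1)`.
#' @return 3D logical initial mask.
#' @export
threshold_initial <- function(probability, roi_band, tau = 0.5) {
  stopifnot(tau > 0, tau < 1)
  stopifnot_same_geometry(probability, roi_band, "probability and ROI")
  probability >= tau & roi_band
}

#' Remove small sparse 2D components
#'
#' Per axial slice, 8-connected components with area strictly below
#' `min_area_px` are dropped (a component of exactly `min_area_px` pixels
#' is kept).
#'
#' @param mask 3D logical array.
#' @param min_area_px Minimum component area, pixels.
#' @return Filtered mask.
#' @export
clean_2d <- function(mask, min_area_px = 20) {
  d <- dim(mask)
  out <- mask
  for (k in seq_len(d[3])) {
    sl <- mask[, , k]
    if (!any(sl)) next
    cc <- EBImage::bwlabel(sl * 1)
    sizes <- tabulate(cc[cc > 0L])
    drop <- which(sizes < min_area_px)
    if (length(drop)) out[, , k][cc %in% drop] <- FALSE
  }
  out
}

#' Fill holes and close gaps between the mask and the skull
#'
#' Per slice, the union of mask and skull is morphologically closed with
#' a disc of radius `fill_radius_px`, skull pixels are removed again, and
#' interior holes of the result are filled. Gaps narrower than the
#' closing scale between a subdural collection and the inner skull
#' surface are thereby bridged while the skull itself never enters the
#' mask.
#'
#' @param mask,skull 3D logical arrays sharing geometry.
#' @param fill_radius_px Closing radius in pixels.
#' @param roi_band Optional ROI mask to clip the repaired result.
#' @return Repaired mask.
#' @export
fill_against_skull <- function(mask, skull, fill_radius_px = 3, roi_band = NULL) {
  stopifnot_same_geometry(mask, skull, "mask and skull")
  d <- dim(mask)
  brush <- EBImage::makeBrush(2 * fill_radius_px + 1, "disc")
  out <- mask
  for (k in seq_len(d[3])) {
    sl <- mask[, , k]
    if (!any(sl)) next
    closed <- closing2(sl | skull[, , k], brush)
    repaired <- closed & !skull[, , k]
    # keep only repaired pixels connected to the original mask, so closing
    # artifacts far from the detection are not introduced
    cc <- EBImage::bwlabel(repaired * 1)
    keep <- unique(cc[sl & cc > 0L])
    repaired <- repaired & array(cc %in% keep, dim(cc))
    repaired <- EBImage::fillHull(repaired * 1) > 0
    out[, , k] <- repaired
  }
  if (!is.null(roi_band)) out <- out & roi_band
  out
}

#' Drop 2D detections disconnected in the third dimension
#'
#' 26-connected 3D components spanning fewer than `min_slices` axial
#' slices are removed; genuine subdural collections extend across
#' neighboring slices even at 5 mm spacing.
#'
#' @param mask 3D logical array.
#' @param min_slices Minimum axial extent, slices (>= 2).
#' @return Filtered mask.
#' @export
enforce_3d_continuity <- function(mask, min_slices = 2) {
  stopifnot(min_slices >= 2)
  if (!any(mask)) return(mask)
  lab <- label_components_3d(mask)
  n <- max(lab)
  span <- integer(n)
  for (k in seq_len(dim(mask)[3])) {
    present <- unique(lab[, , k][lab[, , k] > 0L])
    span[present] <- span[present] + 1L
  }
  keep <- which(span >= min_slices)
  mask & array(lab %in% keep, dim(lab))
}

#' Smooth the mask with a 3D Gaussian in physical units
#'
#' The binary mask is blurred with a Gaussian whose sigma is given in mm
#' and converted per axis to voxels (so 5 mm slice spacing gets a much
#' narrower kernel than sub-millimeter in-plane spacing), then
#' re-binarized at `tau_s` and clipped to the ROI band. Jagged contours
#' are smoothed and isolated voxels vanish.
#'
#' @param mask 3D logical array.
#' @param spacing mm triple.
#' @param sigma_mm Gaussian sigma per axis, mm.
#' @param tau_s Re-binarization threshold.
#' @param roi_band Optional ROI clip.
#' @return Smoothed mask.
#' @export
smooth_3d <- function(mask, spacing, sigma_mm = c(1.5, 1.5, 1.5), tau_s = 0.5,
                      roi_band = NULL) {
  stopifnot(all(sigma_mm > 0))
  if (!any(mask)) return(mask)
  sigma_vox <- sigma_mm / spacing
  sm <- gaussian_blur_3d(mask * 1, sigma_vox)
  out <- sm >= tau_s
  if (!is.null(roi_band)) out <- out & roi_band
  out
}

#' Full post-processing chain
#'
#' 2D component filtering, morphological repair against the skull, 3D
#' continuity filtering, then 3D Gaussian smoothing, in that order.
#'
#' @param initial_mask 3D logical initial mask.
#' @param masks A `head_masks` object (skull + ROI band).
#' @param spacing mm triple.
#' @param min_area_px,fill_radius_px,min_slices,sigma_mm,tau_s Stage
#'   parameters; see the individual stage functions.
#' @return 3D logical final mask, a subset of the ROI band.
#' @export
postprocess_mask <- function(initial_mask, masks, spacing,
                             min_area_px = 20, fill_radius_px = 3,
                             min_slices = 2, sigma_mm = c(1.5, 1.5, 1.5),
                             tau_s = 0.5) {
  m <- clean_2d(initial_mask, min_area_px)
  m <- fill_against_skull(m, masks$skull, fill_radius_px, masks$roi_band)
  m <- enforce_3d_continuity(m, min_slices)
  smooth_3d(m, spacing, sigma_mm, tau_s, masks$roi_band)
}

#' Segmentation result container
#'
#' @param probability,initial_mask,final_mask Arrays sharing geometry.
#' @param provenance Named list snapshot of the parameters used.
#' @return A `segmentation_result` object.
#' @export
segmentation_result <- function(probability, initial_mask, final_mask,
                                provenance = list()) {
  stopifnot_same_geometry(probability, initial_mask, "probability and initial mask")
  stopifnot_same_geometry(initial_mask, final_mask, "initial and final mask")
  structure(list(
    probability = probability,
    initial_mask = initial_mask,
    final_mask = final_mask,
    provenance = provenance
  ), class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result>  initial %d vox, final %d vox\n",
              sum(x$initial_mask), sum(x$final_mask)))
  invisible(x)
}
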