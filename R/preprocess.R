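## Pre-processing: skull segmentation, intracranial delineation, ROI band,
## and mirror padding across the irregular inner-skull boundary.

BRUSH3 <- function() EBImage::makeBrush(3, "box")

dilate2 <- function(m) EBImage::dilate(m * 1, BRUSH3()) > 0
erode2 <- function(m) EBImage::erode(m * 1, BRUSH3()) > 0

# morphological closing on a zero-padded canvas, avoiding the border
# artifact where dilated pixels at the image edge escape the erosion
closing2 <- function(m, brush) {
  p <- (dim(brush)[1] + 1) %/% 2 + 1L
  d <- dim(m)
  canvas <- matrix(0, d[1] + 2 * p, d[2] + 2 * p)
  canvas[p + seq_len(d[1]), p + seq_len(d[2])] <- m * 1
  closed <- EBImage::closing(canvas, brush)
  closed[p + seq_len(d[1]), p + seq_len(d[2])] > 0
}

#' Segment the skull by bone thresholding
#'
#' Voxels above `bone_hu` are labelled bone and the largest 26-connected 3D
#' component is retained, which drops dense artifacts disconnected from the
#' cranium. Fracture gaps and anatomical openings carve genuine holes in
#' the resulting mask; closing them is the job of
#' [segment_intracranial()].
#'
#' @param volume A [ct_volume()] in HU.
#' @param bone_hu Bone threshold in HU (default 300).
#' @return 3D logical skull mask.
#' @export
segment_skull <- function(volume, bone_hu = 300) {
  above <- volume$voxels > bone_hu
  if (!any(above)) stop("no skull found (no voxel above bone threshold)", call. = FALSE)
  lab <- label_components_3d(above)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

#' Delineate the intracranial region enclosed by the skull
#'
#' Processed per axial slice. Where the skull ring is closed, the
#' intracranial region is simply its interior fill. Where the ring is open
#' (fractures, skull-base foramina), the interior is recovered by a
#' deterministic morphological front propagation: a seed disk at the
#' centroid of sub-bone tissue grows one dilation step per iteration,
#' restricted to tissue-intensity pixels (excluding bone and air), with a
#' majority-filter curvature regularization applied each step so the front
#' cannot squeeze through gaps narrower than its smoothing scale. If the
#' front has not converged within `max_iter` the slice falls back to
#' morphological closing of the skull followed by interior fill (logged
#' via `message()`).
#'
#' @param volume A [ct_volume()] in HU.
#' @param skull Logical skull mask from [segment_skull()].
#' @param air_hu Intensities below this are treated as air/background and
#'   never included (default -200 HU).
#' @param max_iter Iteration cap for the front propagation.
#' @param closing_radius Structuring-element radius (px) of the fallback
#'   closing.
#' @return 3D logical intracranial mask (disjoint from `skull`).
#' @export
segment_intracranial <- function(volume, skull, air_hu = -200,
                                 max_iter = 200, closing_radius = 5) {
  if (!any(skull)) stop("empty skull mask", call. = FALSE)
  stopifnot_same_geometry(skull, volume$voxels, "skull and volume")
  d <- dim(skull)
  out <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    sk <- skull[, , k]
    if (!any(sk)) next   # nothing enclosed on this slice
    hu <- volume$voxels[, , k]
    interior <- EBImage::fillHull(sk * 1) > 0 & !sk
    interior <- interior & hu > air_hu
    if (any(interior)) {
      out[, , k] <- interior
      next
    }
    # open ring: evolve a curvature-regularized front from the centroid
    tissue <- !sk & hu > air_hu
    if (!any(tissue)) next
    idx <- which(tissue, arr.ind = TRUE)
    ci <- round(mean(idx[, 1])); cj <- round(mean(idx[, 2]))
    region <- matrix(FALSE, d[1], d[2])
    rr <- pmax(1, ci - 2):pmin(d[1], ci + 2)
    cc <- pmax(1, cj - 2):pmin(d[2], cj + 2)
    region[rr, cc] <- tissue[rr, cc]
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      grown <- dilate2(region) & tissue
      # curvature regularization: 3x3 majority vote
      votes <- conv2(grown * 1, matrix(1, 3, 3))
      smoothed <- (votes >= 5) & tissue
      smoothed <- smoothed | region   # front never retreats from claimed tissue
      if (identical(smoothed, region)) { converged <- TRUE; break }
      region <- smoothed
    }
    if (!converged) {
      message(sprintf(
        "slice %d: front propagation hit iteration cap; falling back to closing + fill", k))
      closed <- closing2(sk, EBImage::makeBrush(2 * closing_radius + 1, "disc"))
      region <- EBImage::fillHull(closed * 1) > 0 & !sk & hu > air_hu
    }
    out[, , k] <- region
  }
  out & !skull
}

#' Head masks: skull, intracranial region, ROI band and depth field
#'
#' Computes the physical (anisotropy-aware) Euclidean distance of every
#' intracranial voxel to the inner skull surface and thresholds it at
#' `max_depth_mm` to obtain the ROI band where subdural blood can occur.
#' The inner surface is the set of skull voxels 26-adjacent to the
#' intracranial region. The exact 3D distance is assembled from per-slice
#' 2D distance transforms: the distance from voxel `(i,j,k)` to the
#' surface is the minimum over slices `k'` of
#' `sqrt(d2(i,j;k')^2 + (dz*(k-k'))^2)` where `d2` is the in-plane
#' distance to the surface set of slice `k'`.
#'
#' @param intracranial,skull Logical masks sharing geometry.
#' @param spacing mm triple `(row, column, slice)`. In-plane spacing must
#'   be (near-)isotropic; the in-plane mean is used.
#' @param max_depth_mm Depth bound of the ROI band (default 32 mm).
#' @return A `head_masks` object: `skull`, `intracranial`, `roi_band`
#'   (logical arrays), `inner_surface_distance` (mm, `Inf` outside the
#'   intracranial mask), `spacing`, `max_depth_mm`.
#' @export
compute_roi_band <- function(intracranial, skull, spacing, max_depth_mm = 32) {
  if (!any(intracranial)) stop("empty intracranial mask", call. = FALSE)
  stopifnot_same_geometry(intracranial, skull, "intracranial and skull")
  sp_in <- mean(spacing[1:2])
  if (abs(spacing[1] - spacing[2]) > 0.05 * sp_in) {
    warning("anisotropic in-plane spacing; using the mean for the distance transform",
            call. = FALSE)
  }
  d <- dim(skull)
  # inner surface: skull voxels touching intracranial within the 3x3x3 box
  grow <- array(FALSE, d)
  dil <- array(FALSE, d)
  for (k in seq_len(d[3])) dil[, , k] <- dilate2(intracranial[, , k])
  for (k in seq_len(d[3])) {
    lo <- max(1, k - 1); hi <- min(d[3], k + 1)
    grow[, , k] <- apply(dil[, , lo:hi, drop = FALSE], c(1, 2), any)
  }
  surface <- skull & grow
  if (!any(surface)) stop("no inner skull surface adjacent to the intracranial mask",
                          call. = FALSE)

  has_surf <- vapply(seq_len(d[3]), function(k) any(surface[, , k]), TRUE)
  d2 <- array(Inf, d)   # in-plane pixel distance to surface, per slice
  for (k in seq_len(d[3])) {
    if (has_surf[k]) d2[, , k] <- EBImage::distmap((!surface[, , k]) * 1)
  }
  dist_mm <- array(Inf, d)
  for (k in seq_len(d[3])) {
    best <- array(Inf, d[1:2])
    for (k2 in seq_len(d[3])) {
      if (!has_surf[k2]) next
      dz <- (k - k2) * spacing[3]
      cand <- sqrt((d2[, , k2] * sp_in)^2 + dz^2)
      best <- pmin(best, cand)
    }
    dist_mm[, , k] <- best
  }
  dist_mm[!intracranial] <- Inf
  structure(list(
    skull = skull,
    intracranial = intracranial,
    roi_band = intracranial & dist_mm <= max_depth_mm,
    inner_surface_distance = dist_mm,
    spacing = spacing,
    max_depth_mm = max_depth_mm
  ), class = "head_masks")
}

#' @export
print.head_masks <- function(x, ...) {
  cat(sprintf(
    "<head_masks>  skull %d vox, intracranial %d vox, ROI band (<= %g mm) %d vox\n",
    sum(x$skull), sum(x$intracranial), x$max_depth_mm, sum(x$roi_band)))
  invisible(x)
}

#' Mirror-pad a slice across the irregular intracranial boundary
#'
#' Reflects brain intensities outward across the inner skull surface so
#' that texture filters applied near the boundary never see skull or air.
#' Two masks are maintained: an outer mask that grows by one 8-connected
#' dilation per iteration and an inner mask that shrinks by one erosion
#' per iteration; each newly grown pixel receives the value of the nearest
#' pixel (Euclidean, ties broken deterministically by lowest linear index
#' in R's column-major scan order) on the current inner mask. After `pad_width` iterations this reproduces classical
#' mirror reflection across a straight boundary, and generalizes it to
#' arbitrary boundary shapes. Pixels inside the intracranial mask are
#' never altered.
#'
#' If the inner mask empties before `pad_width` iterations, remaining
#' rings are filled from the last nonempty inner mask and a warning is
#' raised.
#'
#' @param slice_image 2D numeric matrix (HU), typically with skull removed.
#' @param intracranial_slice 2D logical matrix, nonempty.
#' @param pad_width Number of padding rings (>= 1).
#' @return A list: `padded` (matrix; original values inside the mask,
#'   reflected values on the padded ring, 0 elsewhere) and `valid`
#'   (logical matrix marking original union padded support).
#' @export
mirror_pad <- function(slice_image, intracranial_slice, pad_width) {
  stopifnot(pad_width >= 1)
  if (!any(intracranial_slice)) stop("empty intracranial slice", call. = FALSE)
  stopifnot_same_geometry(slice_image, intracranial_slice, "image and mask")
  d <- dim(slice_image)
  padded <- slice_image
  padded[!intracranial_slice] <- 0
  outer <- intracranial_slice
  inner <- intracranial_slice
  warned <- FALSE

  for (k in seq_len(pad_width)) {
    new_outer <- dilate2(outer)
    ring <- new_outer & !outer
    inner_next <- erode2(inner)
    if (any(inner_next)) {
      inner <- inner_next
    } else if (!warned) {
      warning("inner mask exhausted before pad_width; reusing last nonempty inner mask",
              call. = FALSE)
      warned <- TRUE
    }
    if (any(ring)) {
      # donors: boundary of the inner mask (nearest inner pixel always lies on it)
      donors_mask <- inner & !erode2(inner)
      if (!any(donors_mask)) donors_mask <- inner
      don_idx <- which(donors_mask)
      don_i <- (don_idx - 1L) %% d[1] + 1L
      don_j <- (don_idx - 1L) %/% d[1] + 1L
      ring_idx <- which(ring)
      ri <- (ring_idx - 1L) %% d[1] + 1L
      rj <- (ring_idx - 1L) %/% d[1] + 1L
      d2 <- outer(ri, don_i, `-`)^2 + outer(rj, don_j, `-`)^2
      # nearest donor; ties resolved to the lowest linear index (scan
      # order) -- which(donors_mask) is already sorted by linear index
      nearest <- max.col(-d2, ties.method = "first")
      padded[ring_idx] <- padded[don_idx[nearest]]
    }
    outer <- new_outer
  }
  list(padded = padded, valid = outer)
}
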