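#' 3D CT volume in Hounsfield units
#'
#' Light container for an axial head CT: a 3D array of Hounsfield units (HU)
#' plus the physical geometry needed for volumetric work. Arrays are indexed
#' `(row, column, slice)`; axial slices are the last dimension and slices are
#' stored in increasing axial (z) position. Voxel indices are 0-based in all
#' physical-coordinate computations, and physical positions refer to voxel
#' centers.
#'
#' @param voxels 3D numeric array of intensities in HU.
#' @param spacing Numeric length-3, physical voxel size in mm as
#'   `(row, column, slice)`. All components must be strictly positive.
#' @param origin Numeric length-3, physical position (mm) of voxel
#'   `(0, 0, 0)`. Defaults to the zero vector.
#' @param patient_age Optional age in years (auxiliary classifier covariate).
#' @param scan_id Opaque scan identifier.
#'
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                      patient_age = NA_real_, scan_id = "scan") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("`voxels` must be a 3D array", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive values (mm)", call. = FALSE)
  }
  if (any(!is.finite(voxels))) {
    stop("`voxels` contains non-finite values after HU conversion", call. = FALSE)
  }
  structure(
    list(
      voxels = voxels,
      spacing = spacing,
      origin = as.numeric(origin),
      patient_age = as.numeric(patient_age),
      scan_id = as.character(scan_id)
    ),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<ct_volume '%s'>  %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
    x$scan_id, d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  cat(sprintf("  HU range [%.1f, %.1f]", min(x$voxels), max(x$voxels)))
  if (is.finite(x$patient_age)) cat(sprintf(", age %.0f y", x$patient_age))
  cat("\n")
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

#' Physical volume of one voxel in cubic centimeters
#' @param spacing mm triple `(row, column, slice)`.
#' @return Voxel volume in cc.
#' @keywords internal
voxel_volume_cc <- function(spacing) prod(spacing) / 1000

stopifnot_same_geometry <- function(a, b, what = "masks") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s do not share geometry: %s vs %s", what,
                 paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")), call. = FALSE)
  }
  invisible(TRUE)
}

## ---- low-level array helpers ------------------------------------------------

#' Label 3D connected components (26-connectivity)
#'
#' Slices are labelled in 2D (8-connectivity) with [EBImage::bwlabel()] and
#' labels of adjacent slices are merged by union-find whenever any voxel of
#' one region touches a voxel of the other within the 3x3 in-plane
#' neighborhood, which together realizes full 26-connectivity.
#'
#' @param mask 3D logical array.
#' @return Integer array of component labels, 0 outside the mask.
#' @keywords internal
label_components_3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  offset <- 0L
  nper <- integer(d[3])
  for (k in seq_len(d[3])) {
    sl <- EBImage::bwlabel(mask[, , k] * 1)
    n <- max(sl)
    pos <- sl > 0
    lab[, , k][pos] <- as.integer(sl[pos]) + offset
    nper[k] <- n
    offset <- offset + as.integer(n)
  }
  if (offset == 0L) return(lab)

  parent <- seq_len(offset)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }

  shift2 <- function(m, di, dj) {
    out <- matrix(0L, nrow(m), ncol(m))
    ri <- seq_len(nrow(m)); rj <- seq_len(ncol(m))
    si <- ri - di; sj <- rj - dj
    ok_i <- si >= 1 & si <= nrow(m); ok_j <- sj >= 1 & sj <= ncol(m)
    out[ri[ok_i], rj[ok_j]] <- m[si[ok_i], sj[ok_j]]
    out
  }

  for (k in seq_len(d[3] - 1L)) {
    a <- lab[, , k]; b <- lab[, , k + 1L]
    if (all(a == 0L) || all(b == 0L)) next
    for (di in -1:1) for (dj in -1:1) {
      as <- shift2(a, di, dj)
      both <- as > 0L & b > 0L
      if (any(both)) {
        pairs <- unique(cbind(as[both], b[both]))
        for (r in seq_len(nrow(pairs))) unite(pairs[r, 1], pairs[r, 2])
      }
    }
  }

  roots <- vapply(seq_len(offset), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  pos <- lab > 0L
  lab[pos] <- relab[lab[pos]]
  lab
}

#' Separable Gaussian blur of a 3D array with per-axis sigma in voxels
#'
#' Implemented as three banded matrix multiplications (one per axis) with a
#' truncated, renormalized kernel (radius `ceiling(3*sigma)`), which for mask
#' smoothing is equivalent to zero-padded convolution.
#'
#' @param arr 3D numeric array.
#' @param sigma_vox length-3 sigma per axis in voxel units; a zero component
#'   skips that axis.
#' @keywords internal
gaussian_blur_3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  band_matrix <- function(n, sigma) {
    r <- max(1L, ceiling(3 * sigma))
    x <- (-r):r
    k <- exp(-x^2 / (2 * sigma^2))
    k <- k / sum(k)
    m <- matrix(0, n, n)
    for (t in seq_along(x)) {
      idx <- seq_len(n)
      src <- idx + x[t]
      ok <- src >= 1 & src <= n
      m[cbind(idx[ok], src[ok])] <- m[cbind(idx[ok], src[ok])] + k[t]
    }
    m
  }
  blur_axis <- function(a, axis, sigma) {
    if (sigma <= 0) return(a)
    d <- dim(a)
    perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- band_matrix(dp[1], sigma)
    res <- m %*% matrix(ap, nrow = dp[1])
    res <- array(res, dp)
    aperm(res, order(perm))
  }
  out <- arr
  for (ax in 1:3) out <- blur_axis(out, ax, sigma_vox[ax])
  out
}

#' 2D convolution with replicate boundary via EBImage
#' @keywords internal
conv2 <- function(img, kernel) {
  EBImage::filter2(img, kernel, boundary = "replicate")
}
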