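## Hand-crafted superpixel features: histogram statistics over a local
## window, Gabor and Laplacian-of-Gaussian filter-bank responses, and
## spherical location features, all computed on mirror-padded slices so
## skull and air never contaminate the texture descriptors.

#' Gabor kernel: oriented sinusoidal carrier under a Gaussian envelope
#'
#' `h(x, y) = exp(-1/2 (x'^2/sigma_x^2 + y'^2/sigma_y^2)) * cos(2 pi u0 x')`
#' with `(x', y')` the rigid rotation of `(x, y)` by `orientation`. The
#' kernel value at the origin is 1 for any parameters.
#'
#' @param u0 Carrier frequency, cycles/pixel (`1/wavelength`).
#' @param sigma_x,sigma_y Gaussian envelope constants along the carrier
#'   and orthogonal axes, pixels.
#' @param orientation Carrier orientation in radians, in `[0, pi)`.
#' @param half_size Kernel half-size; defaults to `ceiling(3 * max(sigma))`.
#' @return A square numeric matrix of odd side length.
#' @export
gabor_kernel <- function(u0, sigma_x, sigma_y, orientation = 0,
                         half_size = NULL) {
  stopifnot(u0 > 0, sigma_x > 0, sigma_y > 0)
  if (is.null(half_size)) half_size <- ceiling(3 * max(sigma_x, sigma_y))
  g <- seq(-half_size, half_size)
  X <- matrix(g, length(g), length(g))
  Y <- t(X)
  xr <- X * cos(orientation) + Y * sin(orientation)
  yr <- -X * sin(orientation) + Y * cos(orientation)
  exp(-0.5 * (xr^2 / sigma_x^2 + yr^2 / sigma_y^2)) * cos(2 * pi * u0 * xr)
}

#' Parameters of the default 32-filter Gabor bank
#'
#' 8 evenly spaced orientations `{0, pi/8, ..., 7 pi/8}` at 4 carrier
#' wavelengths `{2, 4, 8, 16}` pixels/cycle. Envelope constants are tied
#' to the wavelength as `sigma = 0.56 * lambda` (about one octave
#' bandwidth), the common convention when the envelope is otherwise free.
#'
#' @param wavelengths Carrier wavelengths, px/cycle.
#' @param n_orientations Number of evenly spaced orientations in `[0, pi)`.
#' @param sigma_factor Envelope constant as a multiple of the wavelength.
#' @return Tibble with `wavelength`, `orientation`, `u0`, `sigma` and a
#'   feature `name` per filter.
#' @export
gabor_bank_params <- function(wavelengths = c(2, 4, 8, 16),
                              n_orientations = 8, sigma_factor = 0.56) {
  grid <- expand.grid(
    orientation_id = seq_len(n_orientations) - 1L,
    wavelength = wavelengths
  )
  tibble::tibble(
    wavelength = grid$wavelength,
    orientation = grid$orientation_id * pi / n_orientations,
    u0 = 1 / grid$wavelength,
    sigma = sigma_factor * grid$wavelength,
    name = sprintf("gabor_l%g_o%d", grid$wavelength, grid$orientation_id)
  )
}

laplacian_kernel <- function() {
  matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
}

gaussian_kernel_2d <- function(sigma, max_half = Inf) {
  r <- min(ceiling(3 * sigma), max_half)
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Mean Gabor-magnitude responses per superpixel (32 features)
#'
#' Convolves the mirror-padded slice with each filter of the bank and
#' pools the per-pixel response magnitude by its mean over each
#' superpixel's pixels.
#'
#' @param padded_slice Mirror-padded 2D matrix.
#' @param label_slice Integer superpixel label matrix (0 = background).
#' @param ids Superpixel ids to report, in order.
#' @param bank Output of [gabor_bank_params()].
#' @return Numeric matrix `length(ids)` x `nrow(bank)`, columns named per
#'   filter.
#' @export
gabor_features <- function(padded_slice, label_slice, ids,
                           bank = gabor_bank_params()) {
  pool_filter_bank(padded_slice, label_slice, ids, bank$name, function(f) {
    k <- gabor_kernel(bank$u0[f], bank$sigma[f], bank$sigma[f],
                      bank$orientation[f],
                      half_size = min(ceiling(3 * bank$sigma[f]),
                                      (min(dim(padded_slice)) - 1) %/% 2))
    abs(conv2(padded_slice, k))
  })
}

#' Mean Laplacian-of-Gaussian responses per superpixel (5 features)
#'
#' The slice is smoothed with Gaussian kernels at five scales and the
#' discrete Laplacian of each smoothed image is pooled (mean) per
#' superpixel. The response is zero on constant images and on linear
#' ramps away from borders.
#'
#' @param padded_slice Mirror-padded 2D matrix.
#' @param label_slice Integer superpixel label matrix.
#' @param ids Superpixel ids to report.
#' @param sigmas Gaussian scales in pixels.
#' @return Numeric matrix `length(ids)` x `length(sigmas)`.
#' @export
log_features <- function(padded_slice, label_slice, ids,
                         sigmas = c(1, 2, 4, 8, 16)) {
  nm <- sprintf("log_s%g", sigmas)
  lap <- laplacian_kernel()
  pool_filter_bank(padded_slice, label_slice, ids, nm, function(f) {
    g <- gaussian_kernel_2d(sigmas[f], max_half = (min(dim(padded_slice)) - 1) %/% 2)
    conv2(conv2(padded_slice, g), lap)
  })
}

pool_filter_bank <- function(padded_slice, label_slice, ids, names, response_fun) {
  pos <- label_slice > 0L
  fac <- factor(label_slice[pos], levels = ids)
  out <- matrix(NA_real_, length(ids), length(names),
                dimnames = list(NULL, names))
  for (f in seq_along(names)) {
    resp <- response_fun(f)
    out[, f] <- as.numeric(tapply(resp[pos], fac, mean))
  }
  out
}

#' Extract a fixed-size window around a superpixel center
#'
#' @param padded_slice Mirror-padded 2D matrix (pad width >= `(size-1)/2`).
#' @param center `(row, col)` pixel coordinates of the superpixel centroid.
#' @param size Window side in pixels (odd; default 25).
#' @param valid Optional validity mask from [mirror_pad()]; if given, a
#'   window reaching outside the padded support is an error (pad width
#'   misconfigured).
#' @return `size` x `size` numeric matrix.
#' @export
extract_window <- function(padded_slice, center, size = 25, valid = NULL) {
  stopifnot(size %% 2 == 1)
  h <- (size - 1L) / 2
  ci <- round(center[1]); cj <- round(center[2])
  r0 <- ci - h; r1 <- ci + h; c0 <- cj - h; c1 <- cj + h
  d <- dim(padded_slice)
  if (r0 < 1 || c0 < 1 || r1 > d[1] || c1 > d[2]) {
    stop(sprintf("window (%d px) around (%d, %d) exceeds the slice; pad_width misconfigured",
                 size, ci, cj), call. = FALSE)
  }
  if (!is.null(valid) && !all(valid[r0:r1, c0:c1])) {
    stop(sprintf("window around (%d, %d) leaves the padded support; pad_width misconfigured",
                 ci, cj), call. = FALSE)
  }
  padded_slice[r0:r1, c0:c1]
}

#' Histogram-based statistical features of a superpixel window
#'
#' Nine statistics: window minimum, maximum, mean and standard deviation
#' of intensity; mean intensity over the superpixel's own pixels;
#' skewness and excess kurtosis of the window intensities (defined as 0
#' for constant windows); Shannon entropy (bits) of the window histogram
#' over `n_bins` bins spanning `window_hu`; and texture smoothness
#' `R = 1 - 1/(1 + sigma^2)` where `sigma` is the standard deviation of
#' the window intensities rescaled to `[0, 1]` over `window_hu` --- 0 for
#' a constant window, approaching 1 as sigma grows.
#'
#' @param patch 2D numeric window (HU).
#' @param superpixel_values Intensities of the superpixel's own pixels.
#' @param window_hu Display window for rescaling/binning.
#' @param n_bins Histogram bins for the entropy.
#' @return Named numeric vector of 9 features.
#' @export
histogram_features <- function(patch, superpixel_values,
                               window_hu = c(0, 100), n_bins = 32) {
  v <- as.numeric(patch)
  n <- length(v)
  mu <- mean(v)
  s <- stats::sd(v)
  m2 <- mean((v - mu)^2)
  if (m2 > 0) {
    skew <- mean((v - mu)^3) / m2^1.5
    kurt <- mean((v - mu)^4) / m2^2 - 3
  } else {
    skew <- 0; kurt <- 0
  }
  scaled <- pmin(pmax((v - window_hu[1]) / diff(window_hu), 0), 1)
  p <- tabulate(pmin(floor(scaled * n_bins) + 1L, n_bins), n_bins) / n
  p <- p[p > 0]
  entropy <- -sum(p * log2(p))
  sr <- stats::sd(scaled) * sqrt((n - 1) / n)   # population sd of rescaled values
  smooth <- 1 - 1 / (1 + sr^2)
  c(
    hist_min = min(v), hist_max = max(v), hist_mean = mu,
    hist_sd = if (is.na(s)) 0 else s,
    sp_mean_hu = mean(superpixel_values),
    hist_skew = skew, hist_kurt = kurt,
    hist_entropy = entropy, hist_smooth = smooth
  )
}

#' Reference frame for location features
#'
#' The origin is the center of mass of the skull on the lowest selected
#' slice (the first axial slice whose intracranial area reaches
#' `min_area_px`); the midline direction is the in-plane principal axis
#' of the intracranial mask on that slice (data-driven, so a tilted head
#' does not bias the azimuth), with a deterministic sign convention.
#'
#' @param masks A `head_masks` object.
#' @param spacing mm triple.
#' @param min_area_px Minimum intracranial area defining "selected".
#' @return List with `origin` (mm, length 3), `midline` (unit vector,
#'   length 2, in (row, col) mm space) and `origin_slice`.
#' @export
location_reference <- function(masks, spacing, min_area_px = 100) {
  d <- dim(masks$intracranial)
  areas <- vapply(seq_len(d[3]), function(k) sum(masks$intracranial[, , k]), 0L)
  k0 <- which(areas >= min_area_px)[1]
  if (is.na(k0)) stop("no slice reaches the minimum intracranial area", call. = FALSE)
  sk <- masks$skull[, , k0]
  if (!any(sk)) sk <- masks$intracranial[, , k0]
  idx <- which(sk, arr.ind = TRUE)
  origin <- c(mean(idx[, 1]) * spacing[1], mean(idx[, 2]) * spacing[2],
              k0 * spacing[3])
  ic <- which(masks$intracranial[, , k0], arr.ind = TRUE)
  pts <- cbind(ic[, 1] * spacing[1], ic[, 2] * spacing[2])
  ev <- eigen(stats::cov(pts), symmetric = TRUE)$vectors[, 1]
  if (ev[1] < 0 || (ev[1] == 0 && ev[2] < 0)) ev <- -ev
  list(origin = origin, midline = ev, origin_slice = k0)
}

#' Spherical location features of a point in the head
#'
#' `r` is the physical distance to the origin; `phi` the elevation of the
#' point above the origin's axial plane (`[-pi/2, pi/2]`, 0 in-plane);
#' `theta` the signed azimuth of the in-plane projection measured against
#' the midline direction (`(-pi, pi]`, 0 on the midline, mirrored points
#' get opposite signs); `r_prime` the distance to the inner skull surface
#' (mm).
#'
#' @param center Voxel coordinates `(row, col, slice)`, 1-based.
#' @param masks A `head_masks` object.
#' @param spacing mm triple.
#' @param ref Output of [location_reference()].
#' @return Named numeric vector `loc_r`, `loc_theta`, `loc_phi`,
#'   `loc_rprime`.
#' @export
location_features <- function(center, masks, spacing, ref) {
  ci <- round(center[1]); cj <- round(center[2]); ck <- round(center[3])
  if (!masks$intracranial[ci, cj, ck]) {
    stop(sprintf("center (%d, %d, %d) lies outside the intracranial mask",
                 ci, cj, ck), call. = FALSE)
  }
  p <- c(center[1] * spacing[1], center[2] * spacing[2], center[3] * spacing[3])
  dvec <- p - ref$origin
  r <- sqrt(sum(dvec^2))
  phi <- if (r > 0) asin(pmin(pmax(dvec[3] / r, -1), 1)) else 0
  u <- ref$midline
  inplane <- dvec[1:2]
  theta <- if (sqrt(sum(inplane^2)) > 0) {
    atan2(u[1] * inplane[2] - u[2] * inplane[1], sum(u * inplane))
  } else 0
  c(loc_r = r, loc_theta = theta, loc_phi = phi,
    loc_rprime = masks$inner_surface_distance[ci, cj, ck])
}

FEATURE_SCHEMA_VERSION <- "sdhseg-features-1"

#' Assemble the per-superpixel feature table for one scan
#'
#' Runs the full hand-crafted feature extraction: for each axial slice
#' with ROI superpixels the skull is removed, the slice is mirror-padded
#' across the intracranial boundary, the Gabor bank and LoG responses are
#' pooled per superpixel, a 25 x 25 window around each superpixel
#' centroid provides the histogram statistics, and spherical location
#' features plus patient age complete the 51-column hand-crafted block.
#' The result is deterministic given its inputs, and any non-finite
#' feature is a hard error naming the feature and superpixel.
#'
#' @param volume A [ct_volume()].
#' @param masks A `head_masks` object for the scan.
#' @param map A `superpixel_map` over the ROI band.
#' @param labels Optional output of [label_superpixels()]; if `NULL` the
#'   table carries no `label` column.
#' @param age Patient age (years); defaults to the volume's.
#' @param pad_width Mirror-padding width in pixels (>= 12 for the default
#'   window).
#' @param window_size Histogram window side, pixels.
#' @param window_hu Display window for rescaling/binning.
#' @return A tibble, one row per superpixel: `scan_id`, `superpixel_id`,
#'   `slice`, 51 feature columns, and `label`/`gt_fraction` when labels
#'   are supplied. The feature column names are in
#'   `attr(, "feature_cols")`; the schema version in `attr(, "schema")`.
#' @export
assemble_feature_table <- function(volume, masks, map, labels = NULL,
                                   age = NULL, pad_width = 12,
                                   window_size = 25,
                                   window_hu = c(0, 100)) {
  info <- map$info
  if (nrow(info) == 0) stop("superpixel map is empty", call. = FALSE)
  age <- age %||% volume$patient_age
  if (is.null(age) || !is.finite(age)) {
    stop("patient age is required (auxiliary covariate); none on the volume",
         call. = FALSE)
  }
  ref <- location_reference(masks, volume$spacing)
  bank <- gabor_bank_params()
  lab3 <- map$label_image
  d2 <- dim(volume$voxels)[1:2]
  p <- pad_width
  embed <- function(m, fill = 0) {
    out <- matrix(fill, d2[1] + 2 * p, d2[2] + 2 * p)
    out[p + seq_len(d2[1]), p + seq_len(d2[2])] <- m
    out
  }

  rows <- vector("list", length(unique(info$slice)))
  ri <- 0L
  for (k in sort(unique(info$slice))) {
    sl_info <- info[info$slice == k, ]
    ids <- sl_info$superpixel_id
    img <- volume$voxels[, , k]
    img[masks$skull[, , k]] <- 0   # skull removed before padding
    # work on a canvas expanded by pad_width so neither the padding ring
    # nor a feature window can run off the slice
    ic <- embed(masks$intracranial[, , k] > 0) > 0
    img <- embed(img)
    mp <- mirror_pad(img, ic, pad_width)
    lab <- embed(lab3[, , k])

    gab <- gabor_features(mp$padded, lab, ids, bank)
    lg <- log_features(mp$padded, lab, ids)

    hist_mat <- matrix(NA_real_, length(ids), 9)
    loc_mat <- matrix(NA_real_, length(ids), 4)
    for (s in seq_along(ids)) {
      id <- ids[s]
      ctr <- c(sl_info$center_row[s], sl_info$center_col[s]) + p
      ctr_vox <- round(ctr)
      if (!ic[ctr_vox[1], ctr_vox[2]]) {
        # concave superpixel: snap the centroid to its nearest member pixel
        px <- which(lab == id, arr.ind = TRUE)
        j <- which.min((px[, 1] - ctr[1])^2 + (px[, 2] - ctr[2])^2)
        ctr <- px[j, ]; ctr_vox <- ctr
      }
      patch <- extract_window(mp$padded, ctr, window_size, mp$valid)
      hist_mat[s, ] <- histogram_features(patch, img[lab == id], window_hu)
      loc_mat[s, ] <- location_features(c(ctr_vox - p, k), masks,
                                        volume$spacing, ref)
    }
    colnames(hist_mat) <- names(histogram_features(matrix(0, 2, 2), 0, window_hu))
    colnames(loc_mat) <- c("loc_r", "loc_theta", "loc_phi", "loc_rprime")

    ri <- ri + 1L
    rows[[ri]] <- dplyr::bind_cols(
      tibble::tibble(scan_id = volume$scan_id,
                     superpixel_id = ids, slice = k),
      tibble::as_tibble(hist_mat),
      tibble::as_tibble(gab),
      tibble::as_tibble(lg),
      tibble::as_tibble(loc_mat),
      tibble::tibble(age = as.numeric(age))
    )
  }
  tab <- dplyr::bind_rows(rows[seq_len(ri)])
  feature_cols <- setdiff(names(tab), c("scan_id", "superpixel_id", "slice"))
  bad <- which(!is.finite(as.matrix(tab[feature_cols])), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-finite feature '%s' for superpixel %d",
                 feature_cols[bad[1, 2]], tab$superpixel_id[bad[1, 1]]),
         call. = FALSE)
  }
  if (!is.null(labels)) {
    tab <- dplyr::left_join(
      tab, labels[, c("superpixel_id", "gt_fraction", "label")],
      by = "superpixel_id")
  }
  attr(tab, "feature_cols") <- feature_cols
  attr(tab, "schema") <- FEATURE_SCHEMA_VERSION
  tab
}

#' Names of the hand-crafted feature columns
#' @param with_age Include the age column.
#' @return Character vector of 51 (or 50) column names.
#' @export
handcrafted_feature_names <- function(with_age = TRUE) {
  nm <- c(
    names(histogram_features(matrix(0, 2, 2), 0)),
    gabor_bank_params()$name,
    sprintf("log_s%g", c(1, 2, 4, 8, 16)),
    c("loc_r", "loc_theta", "loc_phi", "loc_rprime")
  )
  if (with_age) nm <- c(nm, "age")
  nm
}
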