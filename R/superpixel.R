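## SLIC superpixels restricted to the ROI band, computed per axial slice.

#' Partition the ROI band into SLIC superpixels
#'
#' Runs masked SLIC (k-means in joint intensity-position space) on each
#' axial slice independently: 5 mm slice gaps make 3D supervoxels
#' incoherent, and the downstream feature extraction is slice-based.
#' Intensities are rescaled to `[0, 1]` over `window_hu` before
#' clustering. Seeds are placed on a regular grid of step
#' `sqrt(target_size_px)` restricted to the mask; after `n_iter`
#' assignment/update rounds, connectivity is enforced: for each label
#' only the largest connected piece keeps it, and small orphaned pieces
#' are merged into their dominant neighbor. Superpixel ids are unique
#' across the volume and every ROI voxel carries exactly one id, so the
#' regions tile the ROI band. The algorithm is deterministic.
#'
#' @param volume A [ct_volume()].
#' @param roi_band 3D logical mask (from [compute_roi_band()]).
#' @param target_size_px Target superpixel area in pixels (>= 4).
#' @param compactness SLIC compactness weight on the spatial term, on the
#'   scale of the `[0, 1]` rescaled intensities.
#' @param n_iter Assignment/update iterations.
#' @param window_hu Display window used to rescale HU for clustering.
#' @return A `superpixel_map`: `label_image` (3D integer array, 0 outside
#'   the ROI) and `info`, a tibble with one row per superpixel
#'   (`superpixel_id`, `slice`, `center_row`, `center_col`, `n_px`,
#'   `mean_hu`).
#' @export
generate_superpixels <- function(volume, roi_band, target_size_px = 64,
                                 compactness = 0.1, n_iter = 10,
                                 window_hu = c(0, 100)) {
  if (target_size_px < 4) {
    stop("target_size_px < 4 would give a degenerate oversegmentation", call. = FALSE)
  }
  stopifnot_same_geometry(roi_band, volume$voxels, "roi_band and volume")
  if (!any(roi_band)) stop("roi_band is empty", call. = FALSE)
  d <- dim(roi_band)
  lab3 <- array(0L, d)
  offset <- 0L
  info <- list()
  for (k in seq_len(d[3])) {
    mask <- roi_band[, , k]
    if (!any(mask)) next
    hu <- volume$voxels[, , k]
    sl <- slic_slice(hu, mask, target_size_px, compactness, n_iter, window_hu)
    pos <- sl > 0L
    lab3[, , k][pos] <- sl[pos] + offset
    ids <- sort(unique(sl[pos]))
    rows_mat <- row(mask)[pos]; cols_mat <- col(mask)[pos]
    f <- factor(sl[pos], levels = ids)
    info[[length(info) + 1L]] <- tibble::tibble(
      superpixel_id = ids + offset,
      slice = k,
      center_row = as.numeric(tapply(rows_mat, f, mean)),
      center_col = as.numeric(tapply(cols_mat, f, mean)),
      n_px = as.integer(table(f)),
      mean_hu = as.numeric(tapply(hu[pos], f, mean))
    )
    offset <- offset + max(ids)
  }
  structure(list(
    label_image = lab3,
    info = dplyr::bind_rows(info)
  ), class = "superpixel_map")
}

#' @export
print.superpixel_map <- function(x, ...) {
  cat(sprintf("<superpixel_map>  %d superpixels on %d slices, %d voxels\n",
              nrow(x$info), length(unique(x$info$slice)),
              sum(x$label_image > 0L)))
  invisible(x)
}

slic_slice <- function(hu, mask, target_size_px, compactness, n_iter, window_hu) {
  d <- dim(mask)
  intens <- pmin(pmax((hu - window_hu[1]) / diff(window_hu), 0), 1)
  step <- max(2L, round(sqrt(target_size_px)))
  si <- seq(ceiling(step / 2), d[1], by = step)
  sj <- seq(ceiling(step / 2), d[2], by = step)
  seeds <- expand.grid(i = si, j = sj)
  seeds <- seeds[mask[cbind(seeds$i, seeds$j)], , drop = FALSE]
  if (nrow(seeds) == 0) {
    # region too small for the seed grid: fall back to connected components
    return(matrix(as.integer(EBImage::bwlabel(mask * 1)), d[1], d[2]))
  }
  ci <- as.numeric(seeds$i); cj <- as.numeric(seeds$j)
  cv <- intens[cbind(seeds$i, seeds$j)]
  nlab <- length(ci)
  m2 <- compactness^2

  lab <- matrix(0L, d[1], d[2])
  for (it in seq_len(n_iter)) {
    dist <- matrix(Inf, d[1], d[2])
    lab[] <- 0L
    for (c in seq_len(nlab)) {
      r0 <- max(1L, floor(ci[c] - step)); r1 <- min(d[1], ceiling(ci[c] + step))
      c0 <- max(1L, floor(cj[c] - step)); c1 <- min(d[2], ceiling(cj[c] + step))
      sub <- mask[r0:r1, c0:c1]
      if (!any(sub)) next
      ii <- row(sub) + r0 - 1L; jj <- col(sub) + c0 - 1L
      dc2 <- (intens[r0:r1, c0:c1] - cv[c])^2
      ds2 <- ((ii - ci[c])^2 + (jj - cj[c])^2) / step^2
      D <- dc2 + m2 * ds2
      upd <- sub & D < dist[r0:r1, c0:c1]
      if (any(upd)) {
        block_d <- dist[r0:r1, c0:c1]; block_l <- lab[r0:r1, c0:c1]
        block_d[upd] <- D[upd]; block_l[upd] <- c
        dist[r0:r1, c0:c1] <- block_d; lab[r0:r1, c0:c1] <- block_l
      }
    }
    # mop up mask pixels outside every search window (can happen for
    # ragged masks): nearest center by full spatial distance
    orphan <- mask & lab == 0L
    if (any(orphan)) {
      oi <- row(orphan)[orphan]; oj <- col(orphan)[orphan]
      d2 <- outer(oi, ci, `-`)^2 + outer(oj, cj, `-`)^2
      lab[orphan] <- max.col(-d2, ties.method = "first")
    }
    # update centers
    f <- factor(lab[mask], levels = seq_len(nlab))
    keep <- tabulate(f, nlab) > 0
    mi <- tapply(row(mask)[mask], f, mean)
    mj <- tapply(col(mask)[mask], f, mean)
    mv <- tapply(intens[mask], f, mean)
    ci[keep] <- mi[keep]; cj[keep] <- mj[keep]; cv[keep] <- mv[keep]
  }
  enforce_connectivity(lab, mask, min_size = max(1L, target_size_px %/% 4L))
}

enforce_connectivity <- function(lab, mask, min_size) {
  d <- dim(lab)
  out <- matrix(0L, d[1], d[2])
  next_id <- 0L
  pending <- list()   # orphan components to merge
  for (l in sort(unique(lab[lab > 0L]))) {
    cc <- EBImage::bwlabel((lab == l) * 1)
    ncc <- max(cc)
    if (ncc == 0) next
    sizes <- tabulate(cc[cc > 0L], ncc)
    main <- which.max(sizes)
    next_id <- next_id + 1L
    out[cc == main] <- next_id
    if (ncc > 1) {
      for (p in setdiff(seq_len(ncc), main)) {
        piece <- cc == p
        if (sizes[p] >= min_size) {
          next_id <- next_id + 1L
          out[piece] <- next_id
        } else {
          pending[[length(pending) + 1L]] <- piece
        }
      }
    }
  }
  for (piece in pending) {
    ring <- dilate2(piece) & !piece
    nb <- out[ring & mask]
    nb <- nb[nb > 0L]
    if (length(nb) > 0) {
      out[piece] <- as.integer(names(which.max(table(nb))))
    } else {
      next_id <- next_id + 1L
      out[piece] <- next_id
    }
  }
  out
}

#' Derive per-superpixel training labels from a ground-truth mask
#'
#' A superpixel is positive iff the fraction of its voxels inside the
#' ground truth is at least `positive_fraction` (majority rule by
#' default). An empty ground truth yields all-negative labels.
#'
#' @param map A `superpixel_map`.
#' @param ground_truth 3D logical array sharing geometry.
#' @param positive_fraction Fraction threshold in `(0, 1]`.
#' @return The `info` tibble of `map` with `gt_fraction` and integer
#'   `label` (1 = hematoma) columns appended.
#' @export
label_superpixels <- function(map, ground_truth, positive_fraction = 0.5) {
  stopifnot_same_geometry(map$label_image, ground_truth, "map and ground truth")
  lab <- map$label_image
  pos <- lab > 0L
  ids <- map$info$superpixel_id
  f <- factor(lab[pos], levels = ids)
  inside <- tapply(ground_truth[pos], f, sum)
  total <- tabulate(f, length(ids))
  frac <- as.numeric(inside) / total
  frac[is.na(frac)] <- 0
  dplyr::mutate(map$info,
    gt_fraction = frac,
    label = as.integer(frac >= positive_fraction)
  )
}
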