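# Small, fast fixtures shared across test files. Everything is generated
# in code at test time; nothing binary ships with the package.

# A compact head phantom for unit tests (coarser grid than the default
# cohort so per-test runtime stays low).
tiny_phantom <- function(lesions = list(), seed = 42, shape = c(64, 64, 6),
                         spacing = c(2, 2, 5), ...) {
  generate_phantom(phantom_config(shape = shape, spacing = spacing,
                                  lesions = lesions, seed = seed, ...))
}

tiny_processed <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- tiny_phantom(lesions = list(lesion_spec("acute", 20, "right")))
      sk <- segment_skull(ph$volume)
      ic <- segment_intracranial(ph$volume, sk)
      hm <- compute_roi_band(ic, sk, ph$volume$spacing)
      sp <- generate_superpixels(ph$volume, hm$roi_band)
      labs <- label_superpixels(sp, ph$ground_truth)
      cache <<- list(ph = ph, masks = hm, map = sp, labels = labs)
    }
    cache
  }
})

# A hollow 2D ring (closed or with a gap) embedded in a 3D slab, for
# intracranial-segmentation tests.
ring_volume <- function(gap_deg = NULL, n = 48, radius = 18, thickness = 3,
                        nz = 1) {
  vox <- array(-1000, c(n, n, nz))
  ctr <- (n + 1) / 2
  for (k in seq_len(nz)) {
    r <- sqrt((row(vox[, , k]) - ctr)^2 + (col(vox[, , k]) - ctr)^2)
    ring <- r >= radius - thickness & r <= radius
    if (!is.null(gap_deg)) {
      ang <- atan2(col(vox[, , k]) - ctr, row(vox[, , k]) - ctr) * 180 / pi
      ring <- ring & !(abs(ang) < gap_deg / 2)
    }
    sl <- vox[, , k]
    sl[ring] <- 1000
    sl[r < radius - thickness] <- 35
    vox[, , k] <- sl
  }
  ct_volume(vox, c(1, 1, 5), scan_id = "ring")
}

# Brute-force nearest-donor mirror padding oracle: for each padded ring at
# iteration k, the donor is the nearest pixel (ties: lowest linear index)
# of the k-times-eroded intracranial mask.
mirror_pad_oracle <- function(img, mask, pad_width) {
  d <- dim(img)
  brush <- EBImage::makeBrush(3, "box")
  padded <- img
  padded[!mask] <- 0
  outer_m <- mask
  inner_m <- mask
  for (k in seq_len(pad_width)) {
    new_outer <- EBImage::dilate(outer_m * 1, brush) > 0
    ring <- which(new_outer & !outer_m)
    inner_next <- EBImage::erode(inner_m * 1, brush) > 0
    if (any(inner_next)) inner_m <- inner_next
    donors <- which(inner_m)
    di <- (donors - 1) %% d[1] + 1; dj <- (donors - 1) %/% d[1] + 1
    for (p in ring) {
      pi <- (p - 1) %% d[1] + 1; pj <- (p - 1) %/% d[1] + 1
      dist2 <- (di - pi)^2 + (dj - pj)^2
      padded[p] <- padded[donors[which.min(dist2)]]
    }
    outer_m <- new_outer
  }
  list(padded = padded, valid = outer_m)
}

# Inner skull surface: skull voxels 26-adjacent to the intracranial mask.
inner_surface_oracle <- function(skull, ic) {
  d <- dim(skull)
  out <- array(FALSE, d)
  idx <- which(skull, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    nb <- ic[max(1, i - 1):min(d[1], i + 1),
             max(1, j - 1):min(d[2], j + 1),
             max(1, k - 1):min(d[3], k + 1)]
    out[i, j, k] <- any(nb)
  }
  out
}

# Brute-force overlap metric oracle by direct set enumeration.
overlap_oracle <- function(S, GT, U) {
  s <- which(S & U); g <- which(GT & U); u <- which(U)
  tp <- length(intersect(s, g))
  fp <- length(setdiff(s, g))
  fn <- length(setdiff(g, s))
  tn <- length(setdiff(u, union(s, g)))
  list(
    dice = if (length(s) + length(g) > 0) 2 * tp / (length(s) + length(g)) else NA_real_,
    recall = if (length(g) > 0) tp / length(g) else NA_real_,
    precision = if (length(s) > 0) tp / length(s) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
  )
}

# Write a synthetic CT DICOM series with pydicom (independent writer),
# returning the directory. `raw` is a list of integer matrices.
write_dicom_series <- function(raw, dir = tempfile("dcm"),
                               pixel_spacing = c(0.4297, 0.4297),
                               slice_thickness = 5,
                               z_positions = NULL,
                               slope = 1, intercept = -1024,
                               modality = "CT", series_uid = "1.2.3.4",
                               implicit_vr = FALSE, omit_spacing = FALSE) {
  dir.create(dir, showWarnings = FALSE)
  if (is.null(z_positions)) z_positions <- (seq_along(raw) - 1) * slice_thickness
  npz <- file.path(tempdir(), "dcm_input.csv")
  mats <- vapply(raw, function(m) paste(as.integer(t(m)), collapse = " "), "")
  writeLines(mats, npz)
  script <- sprintf('
import sys
import numpy as np
import pydicom
from pydicom.dataset import Dataset, FileDataset
from pydicom.uid import ExplicitVRLittleEndian, ImplicitVRLittleEndian, generate_uid

rows, cols = %d, %d
zs = [%s]
slope, intercept = %f, %f
implicit = %s
with open("%s") as fh:
    mats = [np.array(line.split(), dtype=np.int16).reshape(rows, cols)
            for line in fh.read().splitlines()]
for i, (m, z) in enumerate(zip(mats, zs)):
    meta = Dataset()
    meta.MediaStorageSOPClassUID = pydicom.uid.CTImageStorage
    meta.MediaStorageSOPInstanceUID = generate_uid()
    meta.TransferSyntaxUID = ImplicitVRLittleEndian if implicit else ExplicitVRLittleEndian
    ds = FileDataset(None, {}, file_meta=meta, preamble=b"\\x00" * 128)
    ds.Modality = "%s"
    ds.SeriesInstanceUID = "%s"
    ds.SOPInstanceUID = meta.MediaStorageSOPInstanceUID
    ds.InstanceNumber = i + 1
    ds.ImagePositionPatient = [0.0, 0.0, float(z)]
    ds.ImageOrientationPatient = [1, 0, 0, 0, 1, 0]
    if not %s:
        ds.PixelSpacing = [%f, %f]
    ds.SliceThickness = %f
    ds.Rows, ds.Columns = rows, cols
    ds.BitsAllocated = 16
    ds.BitsStored = 16
    ds.HighBit = 15
    ds.PixelRepresentation = 1
    ds.SamplesPerPixel = 1
    ds.PhotometricInterpretation = "MONOCHROME2"
    ds.RescaleSlope = slope
    ds.RescaleIntercept = intercept
    ds.PatientAge = "061Y"
    ds.PixelData = m.tobytes()
    ds.is_little_endian = True
    ds.is_implicit_VR = implicit
    ds.save_as("%s/slice%%03d.dcm" %% i, enforce_file_format=True)
print("OK")
',
    nrow(raw[[1]]), ncol(raw[[1]]),
    paste(z_positions, collapse = ", "), slope, intercept,
    if (implicit_vr) "True" else "False",
    npz, modality, series_uid,
    if (omit_spacing) "True" else "False",
    pixel_spacing[1], pixel_spacing[2], slice_thickness, dir)
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  out <- suppressWarnings(system2("python", sf, stdout = TRUE, stderr = TRUE))
  if (!any(grepl("^OK$", out))) {
    stop("pydicom fixture generation failed: ", paste(out, collapse = "\n"))
  }
  dir
}
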