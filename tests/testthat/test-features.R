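test_that("histogram features handle constant and two-level patches exactly", {
  const <- matrix(42, 25, 25)
  f <- histogram_features(const, 42)
  expect_equal(unname(f["hist_sd"]), 0)
  expect_equal(unname(f["hist_smooth"]), 0)   # sigma = 0 -> 1 - 1/(1+0) = 0
  expect_equal(unname(f["hist_entropy"]), 0)
  expect_equal(unname(f["hist_skew"]), 0)
  expect_equal(unname(f["hist_kurt"]), 0)
  expect_equal(unname(f["hist_min"]), 42)
  expect_equal(unname(f["hist_max"]), 42)

  # half zeros / half ones under a [0, 1] window: entropy = 1 bit,
  # mean 0.5, sample sd by the closed form
  two <- matrix(rep(c(0, 1), each = 128), 16, 16)
  f2 <- histogram_features(two, c(0, 1), window_hu = c(0, 1))
  expect_equal(unname(f2["hist_entropy"]), 1)
  expect_equal(unname(f2["hist_mean"]), 0.5)
  n <- 256
  expect_equal(unname(f2["hist_sd"]), sqrt(n / (4 * (n - 1))))
})

test_that("smoothness is zero at sigma zero, monotone, and approaches 1", {
  sm <- vapply(c(0, 5, 15, 40, 90), function(a) {
    patch <- matrix(c(50 - a / 2, 50 + a / 2), 10, 10)
    unname(histogram_features(patch, 0)["hist_smooth"])
  }, numeric(1))
  expect_equal(sm[1], 0)
  expect_true(all(diff(sm) > 0))
  # matches the closed form 1 - 1/(1 + sigma^2) on the rescaled values
  set.seed(2)
  patch <- matrix(runif(100, 0, 100), 10, 10)
  scaled <- patch / 100
  sig2 <- mean((scaled - mean(scaled))^2)
  expect_equal(unname(histogram_features(patch, 0)["hist_smooth"]),
               1 - 1 / (1 + sig2))
})

test_that("the Gabor kernel is 1 at the origin for any parameters", {
  for (p in list(c(0.5, 1, 1, 0), c(1 / 16, 9, 9, 3 * pi / 4),
                 c(0.25, 2.2, 1.1, pi / 8))) {
    k <- gabor_kernel(p[1], p[2], p[3], p[4])
    h <- (dim(k)[1] + 1) / 2
    expect_equal(k[h, h], 1)
  }
})

test_that("constant images give the kernel-sum Gabor response per filter", {
  # direct convolution oracle: the response of filter h to a constant c
  # is c * sum(h) everywhere (sums of the discretely rotated kernels
  # differ slightly between orientations; the identity holds per filter)
  img <- matrix(5, 128, 128)
  lab <- matrix(0L, 128, 128); lab[55:75, 55:75] <- 1L
  feats <- gabor_features(img, lab, 1L)
  bank <- gabor_bank_params()
  for (f in seq_len(nrow(bank))) {
    k <- gabor_kernel(bank$u0[f], bank$sigma[f], bank$sigma[f],
                      bank$orientation[f])
    expect_equal(unname(feats[1, bank$name[f]]), abs(5 * sum(k)),
                 tolerance = 1e-6)
  }
})

test_that("the Gabor bank is orientation selective on gratings", {
  n <- 64
  lab <- matrix(0L, n, n); lab[25:40, 25:40] <- 1L
  bank <- gabor_bank_params()
  lambda <- 8
  # grating varying along rows (orientation 0 carrier axis)
  g0 <- matrix(sin(2 * pi * row(matrix(0, n, n)) / lambda), n, n) * 50
  f0 <- gabor_features(g0, lab, 1L, bank)
  cols <- bank$name[bank$wavelength == lambda]
  expect_equal(which.max(f0[1, cols]), 1L, ignore_attr = TRUE)
  # grating varying along columns: strongest at the pi/2 orientation
  g90 <- matrix(sin(2 * pi * col(matrix(0, n, n)) / lambda), n, n) * 50
  f90 <- gabor_features(g90, lab, 1L, bank)
  expect_equal(which.max(f90[1, cols]), 5L, ignore_attr = TRUE)  # pi/2 = index 5
})

test_that("LoG responses vanish on constants and ramps, flip sign at edges", {
  n <- 64
  lab <- matrix(0L, n, n); lab[28:36, 28:36] <- 1L
  expect_true(all(abs(log_features(matrix(3, n, n), lab, 1L)) < 1e-9))

  ramp <- matrix(as.numeric(col(matrix(0, n, n))), n, n)
  lf <- log_features(ramp, lab, 1L, sigmas = c(1, 2, 4))
  expect_true(all(abs(lf) < 1e-6))

  # step edge: pool separately on each side of the edge
  step <- matrix(0, n, n); step[, 33:n] <- 100
  lab2 <- matrix(0L, n, n)
  lab2[20:44, 28:31] <- 1L     # dark side, adjacent to edge
  lab2[20:44, 34:37] <- 2L     # bright side
  lf2 <- log_features(step, lab2, c(1L, 2L), sigmas = c(2))
  expect_gt(lf2[1, 1] * lf2[2, 1], -Inf)
  expect_true(sign(lf2[1, 1]) != sign(lf2[2, 1]))
})

test_that("extract_window returns the exact patch and guards its support", {
  padded <- matrix(seq_len(60 * 60), 60, 60)
  w <- extract_window(padded, c(30, 30), 25)
  expect_equal(dim(w), c(25, 25))
  expect_equal(length(w), 625)
  expect_equal(w, padded[18:42, 18:42])
  expect_error(extract_window(padded, c(5, 30), 25), "pad_width")
  valid <- matrix(FALSE, 60, 60); valid[25:35, 25:35] <- TRUE
  expect_error(extract_window(padded, c(30, 30), 25, valid), "pad_width")
})

test_that("windows near the boundary of a constant disk stay constant", {
  img <- matrix(0, 60, 60)
  mask <- (row(img) - 30)^2 + (col(img) - 30)^2 <= 20^2
  img[mask] <- 55
  mp <- mirror_pad(img, mask, 12)
  # centroid 1 px inside the disk boundary
  w <- extract_window(mp$padded, c(30, 48), 25)
  expect_true(all(w == 55))
})

test_that("location features obey the spherical conventions", {
  pr <- tiny_processed()
  hm <- pr$masks
  sp <- pr$ph$volume$spacing
  ref <- location_reference(hm, sp)

  # a voxel at the origin position
  ov <- round(ref$origin / sp)
  if (hm$intracranial[ov[1], ov[2], ov[3]]) {
    f <- location_features(ov, hm, sp, ref)
    expect_lt(unname(f["loc_r"]), max(sp))
  }

  # any voxel in the origin slice has zero elevation
  k0 <- ref$origin_slice
  idx <- which(hm$intracranial[, , k0], arr.ind = TRUE)[1, ]
  f0 <- location_features(c(idx, k0), hm, sp, ref)
  expect_equal(unname(f0["loc_phi"]), 0)

  # mirrored points about the midline: equal |theta|, opposite sign
  # (phantom is left-right symmetric about the row axis)
  ctr_col <- (dim(hm$intracranial)[2] + 1) / 2
  row_probe <- round(ref$origin[1] / sp[1]) + 8
  off <- 10
  p_r <- c(row_probe, ctr_col + off, k0)
  p_l <- c(row_probe, ctr_col - off, k0)
  if (hm$intracranial[p_r[1], p_r[2], p_r[3]] &&
      hm$intracranial[p_l[1], p_l[2], p_l[3]]) {
    fr <- location_features(p_r, hm, sp, ref)
    fl <- location_features(p_l, hm, sp, ref)
    expect_equal(abs(unname(fr["loc_theta"])), abs(unname(fl["loc_theta"])),
                 tolerance = 0.05)
    expect_true(sign(fr["loc_theta"]) != sign(fl["loc_theta"]))
  }

  expect_error(location_features(c(1, 1, 1), hm, sp, ref), "outside")
  expect_equal(unname(location_features(c(idx, k0), hm, sp, ref)["loc_rprime"]),
               hm$inner_surface_distance[idx[1], idx[2], k0])
})

test_that("the assembled hand-crafted block has 51 columns, one row per superpixel", {
  pr <- tiny_processed()
  # the tiny test head exhausts the inner mask during padding (documented
  # warning); the features themselves are unaffected
  ft <- suppressWarnings(
    assemble_feature_table(pr$ph$volume, pr$masks, pr$map, pr$labels))
  expect_equal(attr(ft, "feature_cols"), handcrafted_feature_names())
  expect_equal(length(handcrafted_feature_names()), 51)  # 9 + 32 + 5 + 4 + 1
  expect_equal(nrow(ft), nrow(pr$map$info))
  expect_equal(length(unique(ft$age)), 1)
  expect_false(any(!is.finite(as.matrix(ft[attr(ft, "feature_cols")]))))
})

test_that("feature extraction is deterministic and skull-intensity invariant", {
  pr <- tiny_processed()
  ft1 <- suppressWarnings(
    assemble_feature_table(pr$ph$volume, pr$masks, pr$map, pr$labels))
  ft2 <- suppressWarnings(
    assemble_feature_table(pr$ph$volume, pr$masks, pr$map, pr$labels))
  expect_identical(ft1, ft2)

  # raising skull HU must not change any feature: the skull is removed
  # before padding, so filters never see it
  vol2 <- pr$ph$volume
  vol2$voxels[pr$masks$skull] <- 1400
  ft3 <- suppressWarnings(
    assemble_feature_table(vol2, pr$masks, pr$map, pr$labels))
  expect_equal(ft1, ft3)
})

test_that("Gabor features commute with quarter-turn image rotation", {
  pr <- tiny_processed()
  k <- pr$map$info$slice[which.max(pr$map$info$n_px)]
  img <- pr$ph$volume$voxels[, , k]
  img[pr$masks$skull[, , k]] <- 0
  ic <- pr$masks$intracranial[, , k]
  mp <- mirror_pad(img, ic, 12)
  lab <- pr$map$label_image[, , k]
  ids <- sort(unique(lab[lab > 0L]))
  f <- gabor_features(mp$padded, lab, ids)

  rot <- function(m) t(m)[ncol(m):1, ]   # 90-degree rotation
  f_rot <- gabor_features(rot(mp$padded), rot(lab), ids)
  bank <- gabor_bank_params()
  for (w in c(4, 8)) {
    a <- f[, bank$name[bank$wavelength == w]]
    b <- f_rot[, bank$name[bank$wavelength == w]]
    # orientation index shifts by 4 (pi/2) under a quarter turn
    shifted <- b[, c(5:8, 1:4)]
    expect_equal(unname(as.matrix(a)), unname(as.matrix(shifted)),
                 tolerance = 0.02)
  }
})
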