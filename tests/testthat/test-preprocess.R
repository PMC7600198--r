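test_that("skull segmentation recovers the phantom shell exactly", {
  ph <- tiny_phantom(seed = 3)
  sk <- segment_skull(ph$volume)
  expect_identical(sk, ph$skull)
})

test_that("skull segmentation preserves fracture gaps", {
  ph <- tiny_phantom(seed = 3)
  vox <- ph$volume$voxels
  gap <- ph$skull & slice.index(vox, 2) >= 32 & slice.index(vox, 2) <= 34 &
    slice.index(vox, 1) < 20
  vox[gap] <- 35                      # carve a fracture through the shell
  vol <- ct_volume(vox, ph$volume$spacing)
  sk <- segment_skull(vol)
  expect_identical(sk, ph$skull & !gap)
})

test_that("an all-air volume raises 'no skull found'", {
  vol <- ct_volume(array(-1000, c(8, 8, 2)), c(1, 1, 5))
  expect_error(segment_skull(vol), "no skull found")
})

test_that("closed skull rings are filled to their geometric interior", {
  vol <- ring_volume(nz = 2)
  sk <- segment_skull(vol)
  ic <- segment_intracranial(vol, sk)
  ctr <- (dim(vol$voxels)[1] + 1) / 2
  r <- sqrt((row(vol$voxels[, , 1]) - ctr)^2 + (col(vol$voxels[, , 1]) - ctr)^2)
  interior_truth <- r < 18 - 3 & !sk[, , 1]
  expect_gt(sum(ic[, , 1] & interior_truth) / sum(interior_truth | ic[, , 1]),
            0.97)
})

test_that("open skull rings do not leak outside the ring hull", {
  vol <- ring_volume(gap_deg = 25)
  # tissue beyond the gap would be a leak path; outside is air, and the
  # front must stay within the ring interior
  sk <- segment_skull(vol)
  ic <- segment_intracranial(vol, sk)
  ctr <- (dim(vol$voxels)[1] + 1) / 2
  r <- sqrt((row(vol$voxels[, , 1]) - ctr)^2 + (col(vol$voxels[, , 1]) - ctr)^2)
  expect_equal(sum(ic[, , 1] & r > 18), 0)       # nothing outside the ring
  expect_gt(sum(ic[, , 1] & r < 15), 0.9 * sum(r < 15))  # interior recovered
})

test_that("slices without skull yield empty intracranial masks", {
  vol <- ring_volume(nz = 3)
  vol$voxels[, , 3] <- -1000
  sk <- vol$voxels > 300
  ic <- segment_intracranial(vol, sk)
  expect_false(any(ic[, , 3]))
})

test_that("intracranial segmentation recovers >= 99% of the phantom interior", {
  ph <- tiny_phantom(lesions = list(lesion_spec("acute", 15, "left")), seed = 8)
  sk <- segment_skull(ph$volume)
  ic <- segment_intracranial(ph$volume, sk)
  dice <- 2 * sum(ic & ph$interior) / (sum(ic) + sum(ph$interior))
  expect_gte(dice, 0.99)
})

test_that("ROI band respects the physical depth bound", {
  ph <- tiny_phantom(seed = 5, shape = c(96, 96, 10))
  sk <- segment_skull(ph$volume)
  ic <- segment_intracranial(ph$volume, sk)
  hm <- compute_roi_band(ic, sk, ph$volume$spacing)

  # voxels adjacent to the inner skull are in the band
  surf_adjacent <- ic & array(FALSE, dim(ic))
  k <- 5
  ring <- EBImage::dilate(sk[, , k] * 1, EBImage::makeBrush(3, "box")) > 0 & ic[, , k]
  expect_true(all(hm$roi_band[, , k][ring]))

  # brute-force distance oracle on sampled voxels: minimum physical
  # distance over every inner-surface voxel
  sp <- ph$volume$spacing
  surf_idx <- which(inner_surface_oracle(sk, ic), arr.ind = TRUE)
  smp <- which(ic, arr.ind = TRUE)
  set.seed(1)
  smp <- smp[sample(nrow(smp), 40), , drop = FALSE]
  for (i in seq_len(nrow(smp))) {
    v <- smp[i, ]
    dd <- sqrt(((surf_idx[, 1] - v[1]) * sp[1])^2 +
               ((surf_idx[, 2] - v[2]) * sp[2])^2 +
               ((surf_idx[, 3] - v[3]) * sp[3])^2)
    expect_equal(hm$inner_surface_distance[v[1], v[2], v[3]], min(dd),
                 tolerance = 1e-8)
  }

  # band monotone in the depth threshold
  hm_small <- compute_roi_band(ic, sk, sp, max_depth_mm = 15)
  expect_true(all(hm$roi_band[hm_small$roi_band]))

  # deep voxels excluded at a tight threshold
  expect_gt(sum(hm$intracranial) - sum(hm_small$roi_band), 0)
  expect_true(all(hm$inner_surface_distance[hm_small$roi_band] <= 15))
})

test_that("a small head lies entirely within the 32 mm band", {
  ph <- tiny_phantom(seed = 7)   # inner semi-axes well under 32 mm
  sk <- segment_skull(ph$volume)
  ic <- segment_intracranial(ph$volume, sk)
  hm <- compute_roi_band(ic, sk, ph$volume$spacing)
  expect_identical(hm$roi_band, hm$intracranial)
  expect_error(compute_roi_band(array(FALSE, dim(ic)), sk, ph$volume$spacing),
               "empty intracranial")
})

test_that("mirror padding equals classical reflection across a straight boundary", {
  img <- matrix(rep(1:40, each = 40), 40, 40)    # value = column index
  mask <- col(img) <= 20
  mp <- mirror_pad(img, mask, 6)
  for (k in 1:6) {
    expect_equal(mp$padded[, 20 + k], img[, 20 - k])
  }
  expect_equal(mp$padded[, 1:20], img[, 1:20])   # interior untouched
})

test_that("mirror padding of a constant disk fills the ring with the constant", {
  img <- matrix(0, 40, 40)
  mask <- (row(img) - 20)^2 + (col(img) - 20)^2 <= 144
  img[mask] <- 7
  mp <- mirror_pad(img, mask, 5)
  expect_true(all(mp$padded[mp$valid] == 7))
  expect_true(all(mp$valid[mask]))
})

test_that("every padded pixel matches its brute-force nearest donor", {
  set.seed(21)
  for (rep in 1:4) {
    img <- matrix(rnorm(35 * 35), 35, 35)
    ctr <- 17 + runif(2, -2, 2)
    ab <- runif(2, 7, 11)
    mask <- ((row(img) - ctr[1]) / ab[1])^2 + ((col(img) - ctr[2]) / ab[2])^2 <= 1
    got <- mirror_pad(img, mask, 4)
    want <- mirror_pad_oracle(img, mask, 4)
    expect_identical(got$valid, want$valid)
    expect_equal(got$padded, want$padded)
  }
})

test_that("padded donors come from within the expected Chebyshev reach", {
  img <- matrix(seq_len(30 * 30), 30, 30)
  mask <- (row(img) - 15)^2 + (col(img) - 15)^2 <= 81
  pw <- 3
  outer_m <- mask
  inner_m <- mask
  mp <- mirror_pad(img, mask, pw)
  for (k in seq_len(pw)) {
    new_outer <- EBImage::dilate(outer_m * 1, EBImage::makeBrush(3, "box")) > 0
    ring <- which(new_outer & !outer_m)
    nxt <- EBImage::erode(inner_m * 1, EBImage::makeBrush(3, "box")) > 0
    if (any(nxt)) inner_m <- nxt
    donors <- which(inner_m)
    di <- (donors - 1) %% 30 + 1; dj <- (donors - 1) %/% 30 + 1
    for (p in ring) {
      pi <- (p - 1) %% 30 + 1; pj <- (p - 1) %/% 30 + 1
      cheb <- pmax(abs(di - pi), abs(dj - pj))
      donors_near <- donors[cheb <= 2 * k + 1]
      expect_true(mp$padded[p] %in% img[donors_near])
    }
    outer_m <- new_outer
  }
})

test_that("exhausting the inner mask warns and still fills the ring", {
  img <- matrix(1, 9, 9)
  mask <- matrix(FALSE, 9, 9); mask[4:6, 4:6] <- TRUE
  img[mask] <- 3
  expect_warning(mp <- mirror_pad(img, mask, 4), "exhausted")
  expect_true(all(mp$padded[mp$valid] == 3))
})

test_that("mirror padding validates inputs", {
  expect_error(mirror_pad(matrix(0, 4, 4), matrix(FALSE, 4, 4), 2), "empty")
})
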