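#' Lesion specification for the head phantom
#'
#' Describes one crescent-shaped subdural collection hugging the inner
#' skull. The crescent is the intersection of an ellipsoidal shell (the
#' band just inside the inner skull surface), an angular sector around a
#' lateral direction, and an axial slab; its thickness (and if necessary
#' the sector and slab extents) are solved numerically so the realized
#' voxelized volume matches `target_volume_cc`.
#'
#' @param type One of `"acute"` (hyperdense to brain), `"subacute"`
#'   (isodense), `"chronic"` (hypodense) or `"mixed"` (an acute layer
#'   against the skull over a chronic layer).
#' @param target_volume_cc Target ground-truth volume in cc.
#' @param side `"left"` or `"right"` convexity.
#' @param angular_halfwidth Initial half-width of the crescent sector,
#'   radians. Escalated automatically if the target volume does not fit.
#' @param z_center_frac,z_halfwidth_frac Axial center and half-extent of
#'   the crescent as fractions of the axial field of view.
#' @param tol Relative tolerance on the realized volume.
#' @return A `lesion_spec` list.
#' @export
lesion_spec <- function(type = c("acute", "subacute", "chronic", "mixed"),
                        target_volume_cc,
                        side = c("left", "right"),
                        angular_halfwidth = pi * 35 / 180,
                        z_center_frac = 0.5,
                        z_halfwidth_frac = 0.30,
                        tol = 0.05) {
  type <- match.arg(type)
  side <- match.arg(side)
  stopifnot(target_volume_cc >= 0)
  structure(list(
    type = type, target_volume_cc = target_volume_cc, side = side,
    angular_halfwidth = angular_halfwidth,
    z_center_frac = z_center_frac, z_halfwidth_frac = z_halfwidth_frac,
    tol = tol
  ), class = "lesion_spec")
}

#' Configuration of the synthetic head phantom
#'
#' The phantom is an ellipsoidal high-density skull shell around a
#' textured brain interior with a small central CSF space, into which
#' crescentic subdural lesions are carved adjacent to the inner skull.
#' Default intensities are typical CT values: skull 1000 HU, brain 35 HU,
#' acute blood 70 HU, subacute 35 HU (isodense), chronic 15 HU, CSF 5 HU,
#' with 4 HU additive noise; brain (but not lesion) voxels additionally
#' carry a smooth 6 HU texture field emulating gray/white heterogeneity.
#' Intensity classes are ordered by construction:
#' skull > acute > brain ≈ subacute > chronic > CSF.
#'
#' @param shape Grid dimensions `(rows, columns, slices)`.
#' @param spacing Voxel size mm `(row, column, slice)`.
#' @param skull_hu,brain_hu,csf_hu,acute_hu,subacute_hu,chronic_hu Mean
#'   intensities (HU) per tissue class.
#' @param noise_sd Additive white noise, HU.
#' @param texture_sd Amplitude (HU) of the smooth brain texture field.
#' @param sulci_depression_hu Depth (HU) of the dark sulcal CSF streaks
#'   in the peripheral brain shell; a subdural collection effaces them,
#'   which is the textural cue that makes isodense (subacute) lesions
#'   detectable.
#' @param sulci_fraction Fraction of the peripheral shell covered by
#'   sulcal streaks.
#' @param lesions List of [lesion_spec()] objects.
#' @param seed Integer seed; fully determines the phantom.
#' @param scan_id Identifier for the generated scan.
#' @param patient_age Age in years attached to the volume.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(shape = c(192, 192, 14),
                           spacing = c(1, 1, 5),
                           skull_hu = 1000, brain_hu = 35, csf_hu = 5,
                           acute_hu = 70, subacute_hu = 35, chronic_hu = 15,
                           noise_sd = 4, texture_sd = 6,
                           sulci_depression_hu = 12, sulci_fraction = 0.2,
                           lesions = list(), seed = 1L,
                           scan_id = "phantom", patient_age = 60) {
  stopifnot(skull_hu > acute_hu, acute_hu > brain_hu, brain_hu > chronic_hu)
  structure(list(
    shape = as.integer(shape), spacing = as.numeric(spacing),
    skull_hu = skull_hu, brain_hu = brain_hu, csf_hu = csf_hu,
    acute_hu = acute_hu, subacute_hu = subacute_hu, chronic_hu = chronic_hu,
    noise_sd = noise_sd, texture_sd = texture_sd,
    sulci_depression_hu = sulci_depression_hu,
    sulci_fraction = sulci_fraction,
    lesions = lesions, seed = as.integer(seed),
    scan_id = scan_id, patient_age = patient_age
  ), class = "phantom_config")
}

phantom_geometry <- function(config) {
  d <- config$shape; sp <- config$spacing
  fov <- d * sp
  # physical coordinates of voxel centers, origin at the grid center
  x <- (seq_len(d[1]) - (d[1] + 1) / 2) * sp[1]
  y <- (seq_len(d[2]) - (d[2] + 1) / 2) * sp[2]
  z <- (seq_len(d[3]) - (d[3] + 1) / 2) * sp[3]
  # skull ellipsoid semi-axes scale with the field of view; thickness 6 mm
  outer <- c(0.42 * fov[1], 0.335 * fov[2], 0.71 * fov[3])
  inner <- outer - 6
  X <- array(rep(x, times = d[2] * d[3]), d)
  Y <- array(rep(rep(y, each = d[1]), times = d[3]), d)
  Z <- array(rep(z, each = d[1] * d[2]), d)
  rho_in <- sqrt((X / inner[1])^2 + (Y / inner[2])^2 + (Z / inner[3])^2)
  rho_out <- sqrt((X / outer[1])^2 + (Y / outer[2])^2 + (Z / outer[3])^2)
  list(X = X, Y = Y, Z = Z, rho_in = rho_in, rho_out = rho_out,
       inner = inner, outer = outer, x = x, y = y, z = z)
}

solve_crescent <- function(spec, geom, config, occupied) {
  vv <- voxel_volume_cc(config$spacing)
  side_sign <- if (spec$side == "left") -1 else 1
  # angle between the in-plane direction of the voxel and the lateral axis
  psi <- abs(atan2(side_sign * geom$X, side_sign * geom$Y))
  r_abs <- sqrt(geom$X^2 + geom$Y^2 + geom$Z^2)
  ray_depth <- r_abs * (1 / pmax(geom$rho_in, 1e-9) - 1)  # mm, upper bound on depth
  zspan <- range(geom$z)
  z0 <- zspan[1] + spec$z_center_frac * diff(zspan)

  brain <- geom$rho_in < 1
  candidate_mask <- function(t, alpha, zhw) {
    brain & geom$rho_in >= (1 - t) & psi <= alpha &
      abs(geom$Z - z0) <= zhw & ray_depth <= 32 & !occupied
  }
  target <- spec$target_volume_cc
  # focal small collections: axial half-extent scales with the cube root
  # of the target volume, floored at 1.5 slice thicknesses
  zhw0 <- max(1.5 * config$spacing[3],
              spec$z_halfwidth_frac * diff(zspan) *
                min(1, (target / 150)^(1 / 3)))
  grid <- expand.grid(
    alpha = c(spec$angular_halfwidth,
              pmin(pi * c(55, 75, 95, 115) / 180, pi)),
    zhw = c(zhw0, 0.40 * diff(zspan), 0.48 * diff(zspan))
  )
  grid <- grid[order(grid$zhw, grid$alpha), ]
  t_max <- 0.85
  chosen <- NULL
  for (g in seq_len(nrow(grid))) {
    vmax <- sum(candidate_mask(t_max, grid$alpha[g], grid$zhw[g])) * vv
    if (vmax >= target) { chosen <- grid[g, ]; break }
  }
  if (is.null(chosen)) {
    stop(sprintf("infeasible lesion: target %.1f cc exceeds available crescent space",
                 target), call. = FALSE)
  }
  lo <- 0; hi <- t_max
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    v <- sum(candidate_mask(mid, chosen$alpha, chosen$zhw)) * vv
    if (abs(v - target) <= spec$tol * target) break
    if (v < target) lo <- mid else hi <- mid
  }
  mask <- candidate_mask(mid, chosen$alpha, chosen$zhw)
  realized <- sum(mask) * vv
  if (target > 0 && abs(realized - target) > 0.10 * target) {
    warning(sprintf("lesion volume %.1f cc misses target %.1f cc by > 10%%",
                    realized, target), call. = FALSE)
  }
  list(mask = mask, thickness = mid, alpha = chosen$alpha, zhw = chosen$zhw,
       realized_cc = realized)
}

#' Generate a synthetic head CT with ground-truth SDH masks
#'
#' @param config A [phantom_config()].
#' @return A list with `volume` ([ct_volume()]), `ground_truth` (logical
#'   array, union of lesion masks), `lesion_masks` (list of logical
#'   arrays), `interior` (constructed intracranial mask), `skull`
#'   (constructed skull mask), and `lesion_info` (tibble of realized
#'   lesion geometry).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  geom <- phantom_geometry(config)
  d <- config$shape
  skull <- geom$rho_out <= 1 & geom$rho_in > 1
  brain <- geom$rho_in < 1
  # small central CSF space (ventricles)
  csf <- (geom$X / 22)^2 + (geom$Y / 12)^2 + (geom$Z / 16)^2 <= 1

  vox <- array(-1000, d)
  tex <- gaussian_blur_3d(array(stats::rnorm(prod(d)), d), c(2, 2, 0.5))
  tex <- tex / stats::sd(tex) * config$texture_sd
  vox[brain] <- config$brain_hu + tex[brain]
  # peripheral sulcal CSF streaks; lesions overwrite (sulcal effacement)
  if (config$sulci_fraction > 0 && config$sulci_depression_hu != 0) {
    sulci_field <- gaussian_blur_3d(array(stats::rnorm(prod(d)), d),
                                    c(1.2, 1.2, 0.2))
    shell <- brain & geom$rho_in > 0.7 & !csf
    if (any(shell)) {
      thr <- stats::quantile(sulci_field[shell], 1 - config$sulci_fraction)
      sulci <- shell & sulci_field > thr
      vox[sulci] <- vox[sulci] - config$sulci_depression_hu
    }
  }
  vox[csf & brain] <- config$csf_hu
  vox[skull] <- config$skull_hu

  occupied <- array(FALSE, d)
  lesion_masks <- list()
  info <- list()
  for (i in seq_along(config$lesions)) {
    spec <- config$lesions[[i]]
    if (spec$target_volume_cc <= 0) next
    sol <- solve_crescent(spec, geom, config, occupied | csf)
    m <- sol$mask
    hu <- switch(spec$type,
      acute = config$acute_hu,
      subacute = config$subacute_hu,
      chronic = config$chronic_hu,
      mixed = NA_real_
    )
    if (spec$type == "mixed") {
      # acute layer against the skull over a chronic inner layer
      split_rho <- 1 - sol$thickness / 2
      vox[m & geom$rho_in >= split_rho] <- config$acute_hu
      vox[m & geom$rho_in < split_rho] <- config$chronic_hu
    } else {
      vox[m] <- hu
    }
    occupied <- occupied | m
    lesion_masks[[i]] <- m
    info[[i]] <- tibble::tibble(
      lesion = i, type = spec$type, side = spec$side,
      target_cc = spec$target_volume_cc, realized_cc = sol$realized_cc,
      thickness_frac = sol$thickness, angular_halfwidth = sol$alpha
    )
  }
  vox <- vox + stats::rnorm(prod(d), sd = config$noise_sd)

  gt <- array(FALSE, d)
  for (m in lesion_masks) if (!is.null(m)) gt <- gt | m

  list(
    volume = ct_volume(vox, config$spacing,
                       patient_age = config$patient_age,
                       scan_id = config$scan_id),
    ground_truth = gt,
    lesion_masks = lesion_masks[!vapply(lesion_masks, is.null, TRUE)],
    interior = brain,
    skull = skull,
    lesion_info = if (length(info)) dplyr::bind_rows(info) else
      tibble::tibble(lesion = integer(), type = character(),
                     side = character(), target_cc = numeric(),
                     realized_cc = numeric(), thickness_frac = numeric(),
                     angular_halfwidth = numeric())
  )
}

# Lesion-type cycle for synthetic cohorts. Mixed and acute collections
# dominate (as in convexity-SDH case mixes), chronic lesions are larger
# (elderly, atrophic brains) and subacute ones small-to-moderate; every
# type occurs at least twice per 11 lesion cases so stratified scan-level
# folds can contain each type on both sides of a 2-fold split.
COHORT_TYPE_CYCLE <- c("mixed", "acute", "chronic", "mixed", "subacute",
                       "acute", "chronic", "mixed", "acute", "mixed",
                       "subacute")

#' Default cohort volume strata (cc)
#'
#' Severity bins bounded at 25, 50, 100 and 200 cc.
#' @export
default_volume_strata <- function() {
  list(c(8, 25), c(25, 50), c(50, 100), c(100, 200), c(200, 230))
}

#' Generate a cohort of head phantoms across volume strata
#'
#' Cases are assigned to strata round-robin (case `i` goes to stratum
#' `((i - 1) mod k) + 1`); target volumes are drawn uniformly within the
#' stratum; lesion types follow a fixed prevalence cycle and sides
#' alternate. When `include_normals` is `TRUE` the first case of the
#' lowest-volume stratum is generated lesion-free (a normal head CT).
#' Ages are drawn per type: chronic/mixed collections occur in older
#' patients. The whole cohort is deterministic under `seed`.
#'
#' @param n Number of cases (>= 1).
#' @param volume_strata List of `c(lo, hi)` cc ranges.
#' @param seed Integer seed.
#' @param include_normals Replace the first lowest-stratum case with a
#'   lesion-free phantom.
#' @param shape,spacing Grid geometry passed to [phantom_config()].
#' @return A list of phantom cases (as from [generate_phantom()]), each
#'   with a `manifest` tibble row; the combined manifest is attached as
#'   attribute `"manifest"`.
#' @export
generate_cohort <- function(n, volume_strata = default_volume_strata(),
                            seed = 1L, include_normals = TRUE,
                            shape = c(192, 192, 14), spacing = c(1, 1, 5)) {
  stopifnot(n >= 1)
  if (length(volume_strata) == 0) {
    stop("empty strata list", call. = FALSE)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  k <- length(volume_strata)
  stratum_id <- ((seq_len(n) - 1L) %% k) + 1L
  lower <- vapply(volume_strata, `[`, numeric(1), 1)
  normal_case <- if (include_normals) {
    which(stratum_id == which.min(lower))[1]
  } else NA_integer_

  cases <- vector("list", n)
  manifest <- vector("list", n)
  j <- 0L
  for (i in seq_len(n)) {
    st <- volume_strata[[stratum_id[i]]]
    if (!is.na(normal_case) && i == normal_case) {
      type <- "none"; target <- 0
      age <- round(stats::runif(1, 30, 80))
      lesions <- list()
    } else {
      j <- j + 1L
      type <- COHORT_TYPE_CYCLE[((j - 1L) %% length(COHORT_TYPE_CYCLE)) + 1L]
      target <- stats::runif(1, st[1], st[2])
      age <- if (type %in% c("chronic", "mixed")) round(stats::runif(1, 65, 90))
             else round(stats::runif(1, 35, 75))
      lesions <- list(lesion_spec(
        type = type, target_volume_cc = target,
        side = if (j %% 2 == 0) "left" else "right"
      ))
    }
    cfg <- phantom_config(
      shape = shape, spacing = spacing, lesions = lesions,
      seed = seed * 1000L + i,
      scan_id = sprintf("case%02d", i), patient_age = age
    )
    cases[[i]] <- generate_phantom(cfg)
    vol_cc <- sum(cases[[i]]$ground_truth) * voxel_volume_cc(spacing)
    manifest[[i]] <- tibble::tibble(
      scan_id = sprintf("case%02d", i), type = type, stratum = stratum_id[i],
      target_cc = target, true_volume_cc = vol_cc, age = age
    )
  }
  manifest <- dplyr::bind_rows(manifest)
  attr(cases, "manifest") <- manifest
  cases
}

#' Write a phantom cohort to disk (NIfTI volumes + CSV manifest)
#'
#' @param cases Output of [generate_cohort()].
#' @param dir Output directory, created if needed.
#' @return The manifest tibble, invisibly.
#' @export
write_cohort <- function(cases, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- attr(cases, "manifest")
  for (i in seq_along(cases)) {
    case <- cases[[i]]
    id <- case$volume$scan_id
    write_volume_nifti(case$volume$voxels, case$volume,
                       file.path(dir, paste0(id, "_ct.nii.gz")))
    write_mask(case$ground_truth, case$volume,
               file.path(dir, paste0(id, "_gt.nii.gz")))
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
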