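## Volumetric severity scoring and evaluation statistics: overlap
## metrics, severity confusion statistics, volumetric agreement
## (regression + Bland-Altman) and inter-rater comparison.

#' Lesion volume of a binary mask in cc
#'
#' True-voxel count times the physical voxel volume. Linear over disjoint
#' masks.
#'
#' @param mask 3D logical array.
#' @param spacing mm triple.
#' @return Volume in cc.
#' @export
measure_volume <- function(mask, spacing) {
  stopifnot(all(spacing > 0))
  sum(mask) * voxel_volume_cc(spacing)
}

#' Dichotomous severity class from hematoma volume
#'
#' Volumes below `threshold_cc` are `"non-hematoma/mild"`; at or above
#' it, `"moderate/severe"` (25 cc default boundary).
#'
#' @param volume_cc Hematoma volume in cc (vectorized).
#' @param threshold_cc Severity boundary, cc.
#' @return Factor with levels `non-hematoma/mild`, `moderate/severe`.
#' @export
classify_severity <- function(volume_cc, threshold_cc = 25) {
  stopifnot(all(volume_cc >= 0))
  factor(ifelse(volume_cc >= threshold_cc, "moderate/severe", "non-hematoma/mild"),
         levels = c("non-hematoma/mild", "moderate/severe"))
}

#' Overlap metrics between a segmentation and ground truth
#'
#' Dice `2|S∩GT|/(|S|+|GT|)`, recall `|S∩GT|/|GT|`, precision
#' `|S∩GT|/|S|` and specificity, with the complements of the specificity
#' taken within `universe` (the ROI band: the fraction of negative ROI
#' voxels correctly left unsegmented). For an empty ground truth, Dice
#' and recall are undefined and reported as `NA` (precision likewise for
#' an empty segmentation), so lesion-free scans contribute specificity
#' only.
#'
#' @param S,GT 3D logical arrays: segmentation and ground truth.
#' @param universe 3D logical array; complements are taken within it.
#' @return A one-row tibble: `dice`, `recall`, `precision`,
#'   `specificity`, and the raw counts `tp`, `fp`, `fn`, `tn`.
#' @export
overlap_metrics <- function(S, GT, universe) {
  stopifnot_same_geometry(S, GT, "S and GT")
  stopifnot_same_geometry(S, universe, "S and universe")
  s <- S & universe
  gt <- GT & universe
  tp <- sum(s & gt)
  fp <- sum(s & !gt)
  fn <- sum(!s & gt)
  tn <- sum(universe) - tp - fp - fn
  ns <- tp + fp; ng <- tp + fn
  tibble::tibble(
    dice = if (ng > 0) 2 * tp / (ns + ng) else NA_real_,
    recall = if (ng > 0) tp / ng else NA_real_,
    precision = if (ns > 0) tp / ns else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    tp = tp, fp = fp, fn = fn, tn = tn
  )
}

#' Severity confusion statistics at a volume threshold
#'
#' Cross-tabulates reference vs computed severity (rows reference,
#' columns computed, classes `<threshold` then `>=threshold`) and reports
#' recall, specificity, precision and F1 for the moderate/severe
#' (`>= threshold_cc`) class, as percentages rounded to 2 decimals.
#' `counts` may be supplied directly instead of paired volume lists.
#'
#' @param reference_cc,computed_cc Paired volume vectors (cc).
#' @param threshold_cc Severity boundary, cc.
#' @param counts Optional 2x2 matrix of counts (rows reference, cols
#'   computed, class order `<threshold`, `>=threshold`) overriding the
#'   volume vectors.
#' @return A list: `counts` (2x2 matrix) and `stats`, a one-row tibble
#'   with `recall_pct`, `specificity_pct`, `precision_pct`, `f1_pct`.
#' @export
severity_confusion <- function(reference_cc = NULL, computed_cc = NULL,
                               threshold_cc = 25, counts = NULL) {
  if (is.null(counts)) {
    if (length(reference_cc) != length(computed_cc)) {
      stop("reference and computed volume lists differ in length", call. = FALSE)
    }
    ref <- factor(reference_cc >= threshold_cc, levels = c(FALSE, TRUE))
    com <- factor(computed_cc >= threshold_cc, levels = c(FALSE, TRUE))
    counts <- unclass(table(ref, com))
  } else {
    counts <- as.matrix(counts)
    stopifnot(all(dim(counts) == c(2, 2)))
  }
  dimnames(counts) <- list(
    reference = c("<threshold", ">=threshold"),
    computed = c("<threshold", ">=threshold")
  )
  tp <- counts[2, 2]; fn <- counts[2, 1]; fp <- counts[1, 2]; tn <- counts[1, 1]
  recall <- tp / (tp + fn)
  specificity <- tn / (tn + fp)
  precision <- tp / (tp + fp)
  f1 <- 2 * precision * recall / (precision + recall)
  list(
    counts = counts,
    stats = tibble::tibble(
      recall_pct = round(100 * recall, 2),
      specificity_pct = round(100 * specificity, 2),
      precision_pct = round(100 * precision, 2),
      f1_pct = round(100 * f1, 2)
    )
  )
}

#' Volumetric agreement: regression and Bland-Altman
#'
#' Least-squares regression of computed on reference volume (slope with
#' standard error, both with an intercept and through the origin) and
#' Bland-Altman statistics: bias `mean(computed - reference)` with 95%
#' limits of agreement `bias +/- 1.96 sd(differences)`.
#'
#' @param reference_cc,computed_cc Paired volume vectors (cc), `n >= 3`.
#' @return A `volume_agreement` object (also a one-row tibble): `slope`,
#'   `slope_se`, `intercept`, `slope_origin`, `slope_origin_se`,
#'   `bias_cc`, `loa_low_cc`, `loa_high_cc`, `n`; the paired data are in
#'   `attr(, "data")`.
#' @export
volume_agreement <- function(reference_cc, computed_cc) {
  if (length(reference_cc) != length(computed_cc)) {
    stop("reference and computed volume lists differ in length", call. = FALSE)
  }
  n <- length(reference_cc)
  if (n < 3) stop("need at least 3 paired volumes", call. = FALSE)
  if (stats::sd(reference_cc) == 0) {
    stop("zero variance in reference volumes; regression undefined", call. = FALSE)
  }
  fit <- stats::lm(computed_cc ~ reference_cc)
  co <- suppressWarnings(summary(fit)$coefficients)
  fit0 <- stats::lm(computed_cc ~ reference_cc + 0)
  co0 <- suppressWarnings(summary(fit0)$coefficients)
  diffs <- computed_cc - reference_cc
  bias <- mean(diffs)
  sd_d <- stats::sd(diffs)
  out <- tibble::tibble(
    slope = co["reference_cc", "Estimate"],
    slope_se = co["reference_cc", "Std. Error"],
    intercept = co["(Intercept)", "Estimate"],
    slope_origin = co0["reference_cc", "Estimate"],
    slope_origin_se = co0["reference_cc", "Std. Error"],
    bias_cc = bias,
    loa_low_cc = bias - 1.96 * sd_d,
    loa_high_cc = bias + 1.96 * sd_d,
    n = n
  )
  attr(out, "data") <- tibble::tibble(
    reference_cc = reference_cc, computed_cc = computed_cc
  )
  class(out) <- c("volume_agreement", class(out))
  out
}

#' Regression and Bland-Altman panels for a volume agreement result
#'
#' @param object A `volume_agreement` object.
#' @param ... Unused.
#' @return A list of two ggplot objects (`regression`, `bland_altman`)
#'   that prints as both panels.
#' @export
autoplot.volume_agreement <- function(object, ...) {
  dat <- attr(object, "data")
  dat$mean_cc <- (dat$reference_cc + dat$computed_cc) / 2
  dat$diff_cc <- dat$computed_cc - dat$reference_cc
  p1 <- ggplot2::ggplot(dat, ggplot2::aes(.data$reference_cc, .data$computed_cc)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Reference volume (cc)", y = "Computed volume (cc)",
                  title = sprintf("Slope %.2f (SE %.2f)",
                                  object$slope, object$slope_se))
  p2 <- ggplot2::ggplot(dat, ggplot2::aes(.data$mean_cc, .data$diff_cc)) +
    ggplot2::geom_hline(yintercept = c(object$bias_cc, object$loa_low_cc,
                                       object$loa_high_cc),
                        linetype = c("solid", "dashed", "dashed")) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Mean of volumes (cc)", y = "Computed - reference (cc)",
                  title = sprintf("Bias %.2f cc [%.2f, %.2f]", object$bias_cc,
                                  object$loa_low_cc, object$loa_high_cc))
  patch <- list(regression = p1, bland_altman = p2)
  class(patch) <- c("volume_agreement_plots", class(patch))
  patch
}

#' @export
print.volume_agreement_plots <- function(x, ...) {
  print(x$regression)
  print(x$bland_altman)
  invisible(x)
}

#' Inter-rater comparison of two annotation sets
#'
#' Dice per case between the two raters' masks, and mean Dice per volume
#' stratum, where the stratum of a case is keyed by its reference
#' (rater A) volume.
#'
#' @param masks_a,masks_b Named lists of 3D logical masks; names are case
#'   ids and must match.
#' @param spacing mm triple shared by the masks.
#' @param strata_cc Numeric cut points (cc) defining the volume strata
#'   (default 25).
#' @return A list: `per_case` tibble (`case`, `dice`,
#'   `reference_volume_cc`, `stratum`) and `per_stratum` tibble
#'   (`stratum`, `n`, `mean_dice`).
#' @export
interrater_compare <- function(masks_a, masks_b, spacing, strata_cc = 25) {
  if (!setequal(names(masks_a), names(masks_b)) ||
      is.null(names(masks_a)) || is.null(names(masks_b))) {
    stop("case ids of the two annotation sets do not match", call. = FALSE)
  }
  ids <- sort(names(masks_a))
  per_case <- dplyr::bind_rows(lapply(ids, function(id) {
    a <- masks_a[[id]]; b <- masks_b[[id]]
    stopifnot_same_geometry(a, b, sprintf("masks of case %s", id))
    universe <- array(TRUE, dim(a))
    m <- overlap_metrics(b, a, universe)
    tibble::tibble(
      case = id,
      dice = m$dice,
      reference_volume_cc = measure_volume(a, spacing)
    )
  }))
  breaks <- c(-Inf, strata_cc, Inf)
  lab <- c(sprintf("<%g cc", strata_cc[1]),
           if (length(strata_cc) > 1)
             sprintf("%g-%g cc", strata_cc[-length(strata_cc)], strata_cc[-1]),
           sprintf(">=%g cc", strata_cc[length(strata_cc)]))
  per_case$stratum <- cut(per_case$reference_volume_cc, breaks, labels = lab,
                          right = FALSE)
  per_stratum <- dplyr::summarise(
    dplyr::group_by(per_case, .data$stratum),
    n = dplyr::n(),
    mean_dice = mean(.data$dice, na.rm = TRUE),
    .groups = "drop"
  )
  list(per_case = per_case, per_stratum = per_stratum)
}

#' Severity report for one segmented scan
#'
#' @param mask Final segmentation mask.
#' @param spacing mm triple.
#' @param threshold_cc Severity boundary, cc.
#' @return One-row tibble: `volume_cc`, `severity`, `threshold_cc`.
#' @export
severity_report <- function(mask, spacing, threshold_cc = 25) {
  v <- measure_volume(mask, spacing)
  tibble::tibble(
    volume_cc = v,
    severity = classify_severity(v, threshold_cc),
    threshold_cc = threshold_cc
  )
}
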