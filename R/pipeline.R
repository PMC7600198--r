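## End-to-end orchestration: validated configuration, per-scan
## processing, scan-level cross-validated cohort experiments, and the
## command wrappers behind the CLI script.

PIPELINE_DEFAULTS <- list(
  bone_hu = 300, air_hu = -200, max_depth_mm = 32,
  slic_target_size = 64, slic_compactness = 0.1,
  window_hu = c(0, 100), pad_width = 12, window_size = 25,
  positive_fraction = 0.5,
  n_trees = 200, mtry = NA, prob_threshold = 0.5,
  min_area_px = 20, fill_radius_px = 3, min_slices = 2,
  sigma_mm = c(1.5, 1.5, 1.5), tau_s = 0.5,
  severity_threshold_cc = 25,
  n_folds = 10, seed = 1,
  use_deep_features = FALSE, unet_base_channels = 8,
  unet_epochs = 5, unet_lr = 1e-3, unet_max_slices_per_scan = 6
)

#' Pipeline configuration
#'
#' Every tunable of the pipeline in one validated list; unknown keys are
#' rejected. A snapshot of the configuration is embedded in every output
#' artifact for provenance.
#'
#' @param ... Named overrides of the defaults (see
#'   `sdhseg:::PIPELINE_DEFAULTS`): thresholds (`bone_hu`, `air_hu`,
#'   `prob_threshold`, `severity_threshold_cc`), ROI depth
#'   (`max_depth_mm`), SLIC parameters, feature window, forest
#'   hyperparameters, post-processing magnitudes, fold count, seed, and
#'   the deep-feature toggle.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(PIPELINE_DEFAULTS))
  if (length(unknown) > 0) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  cfg <- utils::modifyList(PIPELINE_DEFAULTS, over)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file of configuration keys.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  do.call(pipeline_config, yaml::read_yaml(path))
}

config_snapshot <- function(config) {
  unclass(config)
}

#' Run pre-processing, superpixels and hand-crafted features on one scan
#'
#' @param volume A [ct_volume()].
#' @param config A [pipeline_config()].
#' @param ground_truth Optional lesion mask; when given, superpixel
#'   labels are derived and joined to the feature table.
#' @return List: `masks` (`head_masks`), `map` (`superpixel_map`),
#'   `features` (tibble), `labels` (or `NULL`).
#' @export
process_scan <- function(volume, config = pipeline_config(),
                         ground_truth = NULL) {
  skull <- segment_skull(volume, config$bone_hu)
  intracranial <- segment_intracranial(volume, skull, air_hu = config$air_hu)
  masks <- compute_roi_band(intracranial, skull, volume$spacing,
                            config$max_depth_mm)
  map <- generate_superpixels(volume, masks$roi_band,
                              target_size_px = config$slic_target_size,
                              compactness = config$slic_compactness,
                              window_hu = config$window_hu)
  labels <- NULL
  if (!is.null(ground_truth)) {
    labels <- label_superpixels(map, ground_truth, config$positive_fraction)
  }
  features <- assemble_feature_table(
    volume, masks, map, labels,
    pad_width = config$pad_width, window_size = config$window_size,
    window_hu = config$window_hu
  )
  list(masks = masks, map = map, features = features, labels = labels)
}

#' Segment one scan with a trained forest
#'
#' @param volume A [ct_volume()].
#' @param model An `sdh_forest`.
#' @param config A [pipeline_config()].
#' @param processed Optional output of [process_scan()] for this scan
#'   (recomputed when absent).
#' @return List: `result` (a `segmentation_result`), `severity` (tibble
#'   from [severity_report()]), `processed`.
#' @export
segment_scan <- function(volume, model, config = pipeline_config(),
                         processed = NULL) {
  processed <- processed %||% process_scan(volume, config)
  pred <- predict_probability(model, processed$features, processed$map)
  initial <- threshold_initial(pred$probability, processed$masks$roi_band,
                               config$prob_threshold)
  final <- postprocess_mask(initial, processed$masks, volume$spacing,
                            min_area_px = config$min_area_px,
                            fill_radius_px = config$fill_radius_px,
                            min_slices = config$min_slices,
                            sigma_mm = config$sigma_mm,
                            tau_s = config$tau_s)
  result <- segmentation_result(pred$probability, initial, final,
                                provenance = config_snapshot(config))
  list(result = result,
       severity = severity_report(final, volume$spacing,
                                  config$severity_threshold_cc),
       processed = processed)
}

# Mann-Whitney AUC of scores for a 0/1 label vector
rank_auc <- function(scores, labels) {
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

unet_training_slices <- function(cases, scan_ids, config) {
  slices <- list(); masks <- list(); ids <- character()
  for (case in cases) {
    if (!(case$volume$scan_id %in% scan_ids)) next
    pr <- case$processed
    d <- dim(case$volume$voxels)
    crop <- c(d[1] - d[1] %% 2L, d[2] - d[2] %% 2L)
    ks <- sort(unique(pr$map$info$slice))
    lesion_k <- ks[vapply(ks, function(k) any(case$ground_truth[, , k]), TRUE)]
    other_k <- setdiff(ks, lesion_k)
    keep <- c(lesion_k, other_k)[seq_len(min(length(ks), config$unet_max_slices_per_scan))]
    for (k in keep) {
      img <- case$volume$voxels[, , k]
      img[pr$masks$skull[, , k]] <- 0
      mp <- mirror_pad(img, pr$masks$intracranial[, , k], config$pad_width)
      x <- pmin(pmax((mp$padded - config$window_hu[1]) / diff(config$window_hu), 0), 1)
      slices[[length(slices) + 1L]] <- x[seq_len(crop[1]), seq_len(crop[2])]
      masks[[length(masks) + 1L]] <-
        case$ground_truth[seq_len(crop[1]), seq_len(crop[2]), k]
      ids <- c(ids, case$volume$scan_id)
    }
  }
  list(slices = slices, masks = masks, scan_ids = ids)
}

#' Cross-validated segmentation experiment on a phantom cohort
#'
#' The full study loop: every scan is pre-processed and featurized once;
#' scans are split into stratified scan-level folds; per fold a random
#' forest is trained on the 1:1 undersampled training superpixels
#' (optionally augmented with fold-isolated deep features) and applied
#' to the held-out scans; initial masks are thresholded and
#' post-processed; per-scan overlap metrics (before and after
#' post-processing), volumes, severity classes, per-fold superpixel AUC
#' (at natural prevalence and balanced), volumetric agreement and the
#' severity confusion summary are returned.
#'
#' @param cases A cohort from [generate_cohort()] (or any list of cases
#'   with `volume` and `ground_truth` and a `manifest` attribute).
#' @param config A [pipeline_config()].
#' @param keep_masks Keep per-scan final masks in the result.
#' @return An `sdh_cv_result` list: `per_scan`, `per_fold`, `fold_plan`,
#'   `agreement`, `confusion`, `config`, and optionally `masks`.
#' @export
run_cohort_cv <- function(cases, config = pipeline_config(), keep_masks = FALSE) {
  manifest <- attr(cases, "manifest")
  if (is.null(manifest)) {
    manifest <- tibble::tibble(
      scan_id = vapply(cases, function(c) c$volume$scan_id, ""))
  }
  n_folds <- min(config$n_folds, nrow(manifest))
  fold_plan <- make_folds(manifest, n_folds, seed = config$seed)

  for (i in seq_along(cases)) {
    cases[[i]]$processed <- process_scan(cases[[i]]$volume, config,
                                         cases[[i]]$ground_truth)
  }
  all_rows <- dplyr::bind_rows(lapply(cases, function(c) c$processed$features))
  feature_cols <- handcrafted_feature_names()

  per_scan <- list(); per_fold <- list(); masks_out <- list()
  for (f in sort(unique(fold_plan$fold))) {
    train_ids <- fold_plan$scan_id[fold_plan$fold != f]
    test_ids <- fold_plan$scan_id[fold_plan$fold == f]
    train_rows <- all_rows[all_rows$scan_id %in% train_ids, ]
    test_rows <- all_rows[all_rows$scan_id %in% test_ids, ]

    fold_feature_cols <- feature_cols
    unet <- NULL
    if (isTRUE(config$use_deep_features)) {
      tr <- unet_training_slices(cases, train_ids, config)
      unet <- train_unet(tr$slices, tr$masks, tr$scan_ids, fold_plan, f,
                         spec = unet_spec(config$unet_base_channels),
                         epochs = config$unet_epochs, lr = config$unet_lr,
                         seed = config$seed + f)
      deep_tr <- list(); deep_te <- list()
      for (case in cases) {
        id <- case$volume$scan_id
        if (id %in% test_ids) {
          deep_te[[id]] <- extract_deep_features(
            unet, case$volume, case$processed$map, case$processed$masks,
            fold_plan, config$pad_width, config$window_hu)
        } else {
          # training-scan deep features from the same fold model (trained
          # without any held-out scan, so no leakage into fold f)
          tmp_plan <- fold_plan
          tmp_plan$fold[tmp_plan$scan_id == id] <- f
          deep_tr[[id]] <- extract_deep_features(
            unet, case$volume, case$processed$map, case$processed$masks,
            tmp_plan, config$pad_width, config$window_hu)
        }
      }
      train_rows <- dplyr::left_join(train_rows, dplyr::bind_rows(deep_tr),
                                     by = "superpixel_id")
      test_rows <- dplyr::left_join(test_rows, dplyr::bind_rows(deep_te),
                                    by = "superpixel_id")
      fold_feature_cols <- c(feature_cols,
                             grep("^deep_", names(train_rows), value = TRUE))
    }

    balanced <- undersample(train_rows, seed = config$seed + 100 * f)
    model <- train_forest(balanced, fold_feature_cols,
                          n_trees = config$n_trees,
                          mtry = if (is.na(config$mtry)) NULL else config$mtry,
                          seed = config$seed + 1000 * f)

    scored <- predict_forest(model, test_rows)
    auc_nat <- rank_auc(scored$probability, scored$label)
    auc_bal <- if (sum(scored$label == 1) > 0 && sum(scored$label == 0) > 0) {
      bal <- suppressWarnings(undersample(scored, seed = config$seed + 7 * f))
      rank_auc(bal$probability, bal$label)
    } else NA_real_
    per_fold[[f]] <- tibble::tibble(
      fold = f, n_train = length(train_ids), n_test = length(test_ids),
      auc_natural = auc_nat, auc_balanced = auc_bal
    )

    for (case in cases[vapply(cases, function(c) c$volume$scan_id %in% test_ids, TRUE)]) {
      id <- case$volume$scan_id
      rows <- scored[scored$scan_id == id, ]
      seg <- segment_with_rows(case, rows, config)
      sp <- case$volume$spacing
      uni <- case$processed$masks$roi_band
      m_pre <- overlap_metrics(seg$initial, case$ground_truth, uni)
      m_post <- overlap_metrics(seg$final, case$ground_truth, uni)
      per_scan[[id]] <- tibble::tibble(
        scan_id = id, fold = f,
        true_volume_cc = measure_volume(case$ground_truth, sp),
        initial_volume_cc = measure_volume(seg$initial, sp),
        computed_volume_cc = measure_volume(seg$final, sp),
        dice_pre = m_pre$dice, dice_post = m_post$dice,
        recall = m_post$recall, precision = m_post$precision,
        specificity = m_post$specificity
      )
      if (keep_masks) masks_out[[id]] <- seg$final
    }
  }

  per_scan <- dplyr::bind_rows(per_scan)
  per_scan <- dplyr::left_join(per_scan, manifest,
                               by = "scan_id", suffix = c("", ".manifest"))
  per_scan <- dplyr::arrange(per_scan, .data$scan_id)
  agreement <- volume_agreement(per_scan$true_volume_cc,
                                per_scan$computed_volume_cc)
  confusion <- severity_confusion(per_scan$true_volume_cc,
                                  per_scan$computed_volume_cc,
                                  config$severity_threshold_cc)
  out <- list(
    per_scan = per_scan,
    per_fold = dplyr::bind_rows(per_fold),
    fold_plan = fold_plan,
    agreement = agreement,
    confusion = confusion,
    config = config_snapshot(config)
  )
  if (keep_masks) out$masks <- masks_out
  structure(out, class = "sdh_cv_result")
}

segment_with_rows <- function(case, rows, config) {
  prob <- paint_probability(rows, case$processed$map)
  initial <- threshold_initial(prob, case$processed$masks$roi_band,
                               config$prob_threshold)
  final <- postprocess_mask(initial, case$processed$masks,
                            case$volume$spacing,
                            min_area_px = config$min_area_px,
                            fill_radius_px = config$fill_radius_px,
                            min_slices = config$min_slices,
                            sigma_mm = config$sigma_mm,
                            tau_s = config$tau_s)
  list(probability = prob, initial = initial, final = final)
}

#' @export
print.sdh_cv_result <- function(x, ...) {
  cat(sprintf("<sdh_cv_result>  %d scans, %d folds\n",
              nrow(x$per_scan), nrow(x$per_fold)))
  cat(sprintf("  mean Dice pre/post: %.3f / %.3f\n",
              mean(x$per_scan$dice_pre, na.rm = TRUE),
              mean(x$per_scan$dice_post, na.rm = TRUE)))
  cat(sprintf("  volume slope %.3f, bias %.2f cc\n",
              x$agreement$slope, x$agreement$bias_cc))
  invisible(x)
}
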