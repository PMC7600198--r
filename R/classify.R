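## Random-forest superpixel classification under scan-level
## cross-validation with 1:1 undersampling of the negative class.

#' Stratified scan-level fold plan
#'
#' Scans are assigned to folds whole (never split by superpixel, so no
#' scan contributes to both training and testing of a fold) and the
#' assignment is stratified by `(type, volume stratum)` so each fold sees
#' a roughly balanced distribution of SDH types and sizes: within each
#' stratum the scans are shuffled (seeded) and dealt round-robin to the
#' folds, with the starting fold rotating between strata so small strata
#' do not pile onto fold 1.
#'
#' @param manifest Tibble with at least `scan_id`; stratification uses
#'   `type` and `stratum` columns when present.
#' @param n_folds Number of folds (>= 2, <= number of scans).
#' @param seed Integer seed making the plan deterministic.
#' @return A `fold_plan` tibble: `scan_id`, `fold`.
#' @export
make_folds <- function(manifest, n_folds = 10, seed = 1L) {
  stopifnot(n_folds >= 2)
  n <- nrow(manifest)
  if (n < n_folds) {
    stop(sprintf("fewer scans (%d) than folds (%d)", n, n_folds), call. = FALSE)
  }
  if (anyDuplicated(manifest$scan_id)) {
    stop("duplicate scan_id in manifest", call. = FALSE)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  key <- if (all(c("type", "stratum") %in% names(manifest))) {
    paste(manifest$type, manifest$stratum)
  } else rep("all", n)
  fold <- integer(n)
  start <- 0L
  for (g in sort(unique(key))) {
    idx <- which(key == g)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((start + seq_along(idx) - 1L) %% n_folds) + 1L
    start <- start + length(idx)
  }
  structure(
    tibble::tibble(scan_id = manifest$scan_id, fold = fold),
    class = c("fold_plan", class(tibble::tibble()))
  )
}

#' Balance a training set by undersampling the negative class
#'
#' All positive rows are kept and an equal number of negative rows is
#' drawn without replacement (seeded). If positives already outnumber
#' negatives nothing is dropped and a warning is raised.
#'
#' @param rows Feature-table subset with a `label` column (1 = positive).
#' @param seed Integer seed.
#' @return The balanced subset (positives first), a tibble.
#' @export
undersample <- function(rows, seed = 1L) {
  pos <- which(rows$label == 1L)
  neg <- which(rows$label == 0L)
  if (length(pos) == 0) {
    stop(paste("no positive superpixels in the training subset;",
               "skip this fold or evaluate hand-crafted-only on another split"),
         call. = FALSE)
  }
  if (length(pos) >= length(neg)) {
    warning("positives >= negatives; keeping all rows", call. = FALSE)
    return(rows)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  keep_neg <- sort(sample(neg, length(pos)))
  rows[c(pos, keep_neg), ]
}

#' Train the superpixel random forest
#'
#' @param balanced Training tibble (output of [undersample()]) carrying
#'   the feature columns and `label`.
#' @param feature_cols Feature column names; defaults to the table's
#'   `feature_cols` attribute or the hand-crafted schema.
#' @param n_trees,mtry Forest hyperparameters (defaults: 200 trees,
#'   `sqrt(p)` features per split, unlimited depth).
#' @param seed Integer seed; retraining with the same seed is
#'   reproducible.
#' @return An `sdh_forest` object wrapping the fitted
#'   [randomForest::randomForest()] with its feature schema.
#' @export
train_forest <- function(balanced, feature_cols = NULL, n_trees = 200,
                         mtry = NULL, seed = 1L) {
  feature_cols <- feature_cols %||% attr(balanced, "feature_cols") %||%
    handcrafted_feature_names()
  missing_cols <- setdiff(feature_cols, names(balanced))
  if (length(missing_cols) > 0) {
    stop(sprintf("feature schema mismatch; missing columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  x <- as.matrix(balanced[, feature_cols])
  y <- factor(balanced$label, levels = c(0, 1))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  rf <- randomForest::randomForest(
    x = x, y = y, ntree = n_trees,
    mtry = mtry %||% max(1, floor(sqrt(length(feature_cols))))
  )
  structure(list(
    forest = rf,
    feature_cols = feature_cols,
    n_trees = n_trees,
    seed = seed,
    trained_scans = unique(balanced$scan_id)
  ), class = "sdh_forest")
}

#' Per-superpixel hematoma probabilities
#'
#' @param model An `sdh_forest`.
#' @param rows Feature rows for the superpixels to score.
#' @return `rows` with a `probability` column (forest vote fraction for
#'   the hematoma class).
#' @export
predict_forest <- function(model, rows) {
  missing_cols <- setdiff(model$feature_cols, names(rows))
  if (length(missing_cols) > 0) {
    stop(sprintf("feature schema mismatch; missing columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  p <- stats::predict(model$forest, as.matrix(rows[, model$feature_cols]),
                      type = "prob")[, "1"]
  dplyr::mutate(rows, probability = as.numeric(p))
}

#' Paint per-superpixel probabilities into a probability volume
#'
#' Every ROI voxel receives the forest probability of its superpixel;
#' voxels outside the ROI get 0. A superpixel of the map without a scored
#' row is a hard error.
#'
#' @param model An `sdh_forest`.
#' @param rows Feature rows covering all superpixels of the scan.
#' @param map The scan's `superpixel_map`.
#' @return List: `probability` (3D numeric array in `[0, 1]`) and
#'   `scored` (the rows with probabilities).
#' @export
predict_probability <- function(model, rows, map) {
  scored <- predict_forest(model, rows)
  list(probability = paint_probability(scored, map), scored = scored)
}

#' Paint scored superpixel rows into a probability volume
#'
#' @param scored Rows with `superpixel_id` and `probability`.
#' @param map The scan's `superpixel_map`.
#' @return 3D numeric array; 0 outside the ROI.
#' @export
paint_probability <- function(scored, map) {
  ids <- map$info$superpixel_id
  if (!all(ids %in% scored$superpixel_id)) {
    miss <- setdiff(ids, scored$superpixel_id)
    stop(sprintf("missing feature rows for %d superpixels (e.g. id %d)",
                 length(miss), miss[1]), call. = FALSE)
  }
  lut <- scored$probability[match(ids, scored$superpixel_id)]
  prob <- array(0, dim(map$label_image))
  pos <- map$label_image > 0L
  prob[pos] <- lut[match(map$label_image[pos], ids)]
  prob
}
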