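## A compact U-net (encoder-decoder with skip connection) for SDH
## segmentation, used as the data-driven deep-feature extractor: the
## activations of the second layer before the output layer (64 channels)
## are pooled per superpixel. Implemented natively (im2col convolutions
## with hand-written backpropagation and Adam), sized for CPU training on
## small slice stacks; the deep block is optional and off by default in
## the pipeline.

#' U-net architecture specification
#'
#' Two encoder levels with a skip connection and a 64-channel tap layer
#' before the 1x1 output: conv-conv (base channels) -> maxpool ->
#' conv-conv (2x base) -> nearest upsample + skip concat -> conv (base)
#' -> conv to `tap_channels` (the deep-feature tap) -> 1x1 sigmoid
#' output. Input and output spatial dimensions are equal; inputs must
#' have even side lengths.
#'
#' @param base_channels Channels of the first encoder level.
#' @param tap_channels Channels of the feature tap layer (64: the width
#'   of the deep-feature block).
#' @return A `unet_spec` list.
#' @export
unet_spec <- function(base_channels = 8, tap_channels = 64) {
  stopifnot(base_channels >= 1, tap_channels >= 1)
  structure(list(base_channels = as.integer(base_channels),
                 tap_channels = as.integer(tap_channels)),
            class = "unet_spec")
}

## ---- conv-net primitives ----------------------------------------------------

im2col3 <- function(x) {
  # x: H x W x C -> (H*W) x (9*C) patch matrix, zero padding 1
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  xp <- array(0, c(H + 2L, W + 2L, C))
  xp[2:(H + 1L), 2:(W + 1L), ] <- x
  out <- matrix(0, H * W, 9L * C)
  col <- 0L
  for (dj in 0:2) for (di in 0:2) {
    blk <- xp[(1L + di):(H + di), (1L + dj):(W + dj), , drop = FALSE]
    out[, col + seq_len(C)] <- matrix(blk, H * W, C)
    col <- col + C
  }
  out
}

col2im3 <- function(m, H, W, C) {
  # adjoint of im2col3: (H*W) x (9*C) -> H x W x C
  xp <- array(0, c(H + 2L, W + 2L, C))
  col <- 0L
  for (dj in 0:2) for (di in 0:2) {
    blk <- array(m[, col + seq_len(C)], c(H, W, C))
    xp[(1L + di):(H + di), (1L + dj):(W + dj), ] <-
      xp[(1L + di):(H + di), (1L + dj):(W + dj), , drop = FALSE] + blk
    col <- col + C
  }
  xp[2:(H + 1L), 2:(W + 1L), , drop = FALSE]
}

conv_fwd <- function(x, W, b) {
  d <- dim(x)
  m <- im2col3(x)
  y <- sweep(m %*% W, 2, b, `+`)
  list(y = array(y, c(d[1], d[2], length(b))), m = m)
}

conv_bwd <- function(dy, cache_m, W, xdim) {
  cout <- ncol(W)
  dy_m <- matrix(dy, prod(xdim[1:2]), cout)
  dW <- crossprod(cache_m, dy_m)
  db <- colSums(dy_m)
  dx <- col2im3(dy_m %*% t(W), xdim[1], xdim[2], xdim[3])
  list(dx = dx, dW = dW, db = db)
}

relu_fwd <- function(x) pmax(x, 0)
relu_bwd <- function(dy, y) dy * (y > 0)

maxpool_fwd <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  h <- H %/% 2L; w <- W %/% 2L
  x4 <- array(x, c(2L, h, 2L, w, C))
  x4 <- aperm(x4, c(1, 3, 2, 4, 5))           # 2 x 2 x h x w x C
  flat <- matrix(x4, 4L, h * w * C)
  arg <- max.col(t(flat), ties.method = "first")
  y <- array(flat[cbind(arg, seq_along(arg))], c(h, w, C))
  list(y = y, arg = arg, h = h, w = w, C = C, H = H, W = W)
}

maxpool_bwd <- function(dy, cache) {
  flat <- matrix(0, 4L, cache$h * cache$w * cache$C)
  flat[cbind(cache$arg, seq_along(cache$arg))] <- as.numeric(dy)
  x4 <- array(flat, c(2L, 2L, cache$h, cache$w, cache$C))
  x4 <- aperm(x4, c(1, 3, 2, 4, 5))
  array(x4, c(cache$H, cache$W, cache$C))
}

upsample_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , drop = FALSE]
}

upsample_bwd <- function(dy) {
  d <- dim(dy); h <- d[1] %/% 2L; w <- d[2] %/% 2L; C <- d[3]
  x4 <- array(dy, c(2L, h, 2L, w, C))
  x4 <- aperm(x4, c(1, 3, 2, 4, 5))
  array(colSums(matrix(x4, 4L, h * w * C)), c(h, w, C))
}

unet_init <- function(spec, seed = 1L) {
  b <- spec$base_channels; tp <- spec$tap_channels
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  he <- function(fan_in, nin, nout) {
    matrix(stats::rnorm(nin * nout, sd = sqrt(2 / fan_in)), nin, nout)
  }
  layers <- list(
    c1a = list(W = he(9 * 1, 9 * 1, b), b = rep(0, b)),
    c1b = list(W = he(9 * b, 9 * b, b), b = rep(0, b)),
    c2a = list(W = he(9 * b, 9 * b, 2 * b), b = rep(0, 2 * b)),
    c2b = list(W = he(9 * 2 * b, 9 * 2 * b, 2 * b), b = rep(0, 2 * b)),
    c3a = list(W = he(9 * 3 * b, 9 * 3 * b, b), b = rep(0, b)),
    tap = list(W = he(9 * b, 9 * b, tp), b = rep(0, tp)),
    out = list(W1 = matrix(stats::rnorm(tp, sd = sqrt(2 / tp)), tp, 1), b1 = 0)
  )
  layers
}

unet_forward <- function(params, x2d, spec, want_cache = FALSE) {
  d <- dim(x2d)
  if (any(d %% 2L != 0L)) stop("U-net input sides must be even", call. = FALSE)
  x <- array(x2d, c(d[1], d[2], 1L))
  f1 <- conv_fwd(x, params$c1a$W, params$c1a$b); a1 <- relu_fwd(f1$y)
  f2 <- conv_fwd(a1, params$c1b$W, params$c1b$b); a2 <- relu_fwd(f2$y)
  mp <- maxpool_fwd(a2)
  f3 <- conv_fwd(mp$y, params$c2a$W, params$c2a$b); a3 <- relu_fwd(f3$y)
  f4 <- conv_fwd(a3, params$c2b$W, params$c2b$b); a4 <- relu_fwd(f4$y)
  up <- upsample_fwd(a4)
  cat34 <- array(c(up, a2), c(d[1], d[2], dim(up)[3] + dim(a2)[3]))
  f5 <- conv_fwd(cat34, params$c3a$W, params$c3a$b); a5 <- relu_fwd(f5$y)
  ft <- conv_fwd(a5, params$tap$W, params$tap$b); atap <- relu_fwd(ft$y)
  logits <- matrix(matrix(atap, d[1] * d[2], spec$tap_channels) %*%
                     params$out$W1 + params$out$b1, d[1], d[2])
  prob <- 1 / (1 + exp(-logits))
  res <- list(prob = prob, tap = atap)
  if (want_cache) {
    res$cache <- list(x = x, f1 = f1, a1 = a1, f2 = f2, a2 = a2, mp = mp,
                      f3 = f3, a3 = a3, f4 = f4, a4 = a4, up = up,
                      cat34 = cat34, f5 = f5, a5 = a5, ft = ft, atap = atap,
                      logits = logits, d = d)
  }
  res
}

# BCE + soft-Dice loss and its gradient w.r.t. the logits
unet_loss <- function(prob, target, eps = 1) {
  n <- length(prob)
  p <- pmin(pmax(prob, 1e-7), 1 - 1e-7)
  bce <- -mean(target * log(p) + (1 - target) * log(1 - p))
  inter <- sum(prob * target)
  dice <- (2 * inter + eps) / (sum(prob) + sum(target) + eps)
  loss <- bce + (1 - dice)
  # d(bce)/d(logit) = (p - t)/n ; d(dice)/d(prob) then chain via sigmoid
  denom <- sum(prob) + sum(target) + eps
  ddice_dprob <- (2 * target * denom - (2 * inter + eps)) / denom^2
  dprob_dlogit <- prob * (1 - prob)
  dlogit <- (p - target) / n - ddice_dprob * dprob_dlogit
  list(loss = loss, bce = bce, dice = dice, dlogit = dlogit)
}

unet_backward <- function(params, cache, dlogit, spec) {
  d <- cache$d
  npix <- d[1] * d[2]
  tapmat <- matrix(cache$atap, npix, spec$tap_channels)
  dlog_v <- matrix(as.numeric(dlogit), npix, 1)
  g <- list()
  g$out <- list(W1 = crossprod(tapmat, dlog_v), b1 = sum(dlog_v))
  datap <- array(dlog_v %*% t(params$out$W1), dim(cache$atap))
  dft <- relu_bwd(datap, cache$atap)
  bt <- conv_bwd(dft, cache$ft$m, params$tap$W, dim(cache$a5))
  g$tap <- list(W = bt$dW, b = bt$db)
  da5 <- relu_bwd(bt$dx, cache$a5)
  b5 <- conv_bwd(da5, cache$f5$m, params$c3a$W, dim(cache$cat34))
  g$c3a <- list(W = b5$dW, b = b5$db)
  cup <- dim(cache$up)[3]
  dup <- b5$dx[, , seq_len(cup), drop = FALSE]
  da2_skip <- b5$dx[, , cup + seq_len(dim(cache$a2)[3]), drop = FALSE]
  da4 <- relu_bwd(upsample_bwd(dup), cache$a4)
  b4 <- conv_bwd(da4, cache$f4$m, params$c2b$W, dim(cache$a3))
  g$c2b <- list(W = b4$dW, b = b4$db)
  da3 <- relu_bwd(b4$dx, cache$a3)
  b3 <- conv_bwd(da3, cache$f3$m, params$c2a$W, dim(cache$mp$y))
  g$c2a <- list(W = b3$dW, b = b3$db)
  da2 <- maxpool_bwd(b3$dx, cache$mp) + da2_skip
  da2 <- relu_bwd(da2, cache$a2)
  b2 <- conv_bwd(da2, cache$f2$m, params$c1b$W, dim(cache$a1))
  g$c1b <- list(W = b2$dW, b = b2$db)
  da1 <- relu_bwd(b2$dx, cache$a1)
  b1 <- conv_bwd(da1, cache$f1$m, params$c1a$W, dim(cache$x))
  g$c1a <- list(W = b1$dW, b = b1$db)
  g
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (ln in names(grads)) {
    for (pn in names(grads[[ln]])) {
      gkey <- paste(ln, pn)
      gval <- grads[[ln]][[pn]]
      if (is.null(state$m[[gkey]])) {
        state$m[[gkey]] <- gval * 0
        state$v[[gkey]] <- gval * 0
      }
      state$m[[gkey]] <- beta1 * state$m[[gkey]] + (1 - beta1) * gval
      state$v[[gkey]] <- beta2 * state$v[[gkey]] + (1 - beta2) * gval^2
      mhat <- state$m[[gkey]] / (1 - beta1^t)
      vhat <- state$v[[gkey]] / (1 - beta2^t)
      params[[ln]][[pn]] <- params[[ln]][[pn]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

## ---- public API -------------------------------------------------------------

#' Train the baseline U-net on one cross-validation fold
#'
#' Trains the segmentation network on the slices of the training scans
#' with a combined binary cross-entropy + soft-Dice loss, Adam, a fixed
#' epoch budget and a fixed seed. The artifact is tagged with `fold_id`;
#' a scan belonging to the held-out fold appearing among the training
#' inputs is a hard error (leakage guard).
#'
#' @param slices List of 2D matrices, network inputs (intensities
#'   rescaled to `[0, 1]`, even side lengths, all equal size).
#' @param masks List of 2D logical matrices, per-pixel lesion targets.
#' @param scan_ids Character vector, the source scan of each slice.
#' @param fold_plan A [make_folds()] plan.
#' @param fold_id The held-out fold this model will serve.
#' @param spec A [unet_spec()].
#' @param epochs Epoch budget.
#' @param lr Adam learning rate.
#' @param seed Integer seed (initialization and slice order).
#' @return A `unet_model`: `params`, `spec`, `fold_id`, `loss_history`
#'   (mean loss per epoch).
#' @export
train_unet <- function(slices, masks, scan_ids, fold_plan, fold_id,
                       spec = unet_spec(), epochs = 5, lr = 1e-3, seed = 1L) {
  stopifnot(length(slices) == length(masks), length(slices) == length(scan_ids))
  held_out <- fold_plan$scan_id[fold_plan$fold == fold_id]
  leaked <- intersect(unique(scan_ids), held_out)
  if (length(leaked) > 0) {
    stop(sprintf("leakage: held-out scan(s) %s present in training inputs",
                 paste(leaked, collapse = ", ")), call. = FALSE)
  }
  params <- unet_init(spec, seed = seed)
  state <- list(m = list(), v = list())
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  t <- 0L
  loss_history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(slices))
    losses <- numeric(length(ord))
    for (s in seq_along(ord)) {
      i <- ord[s]
      fw <- unet_forward(params, slices[[i]], spec, want_cache = TRUE)
      ls <- unet_loss(fw$prob, masks[[i]] * 1)
      grads <- unet_backward(params, fw$cache, ls$dlogit, spec)
      t <- t + 1L
      st <- adam_step(params, grads, state, lr, t)
      params <- st$params; state <- st$state
      losses[s] <- ls$loss
    }
    loss_history[ep] <- mean(losses)
  }
  structure(list(params = params, spec = spec, fold_id = fold_id,
                 loss_history = loss_history, seed = seed),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model>  fold %s, base %d ch, tap %d ch, final loss %.4f\n",
              x$fold_id, x$spec$base_channels, x$spec$tap_channels,
              utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' Per-pixel segmentation probability of a slice
#'
#' @param model A `unet_model`.
#' @param slice 2D matrix input (rescaled intensities, even sides).
#' @return Matrix of per-pixel probabilities.
#' @export
predict_unet <- function(model, slice) {
  unet_forward(model$params, slice, model$spec)$prob
}

#' Extract 64 deep features per superpixel
#'
#' Runs the fold's network on each mirror-padded, ROI-masked slice and
#' averages the tap-layer channel activations over each superpixel's
#' pixels. Inference is deterministic; the model's fold must match the
#' scan's fold assignment (the model must never have trained on the scan
#' it describes).
#'
#' @param model A `unet_model`.
#' @param volume A [ct_volume()].
#' @param map The scan's `superpixel_map`.
#' @param masks A `head_masks` object.
#' @param fold_plan A [make_folds()] plan.
#' @param pad_width Mirror-padding width (consistent with the
#'   hand-crafted features).
#' @param window_hu HU display window for input rescaling.
#' @return Tibble: `superpixel_id` plus `deep_01` ... `deep_64`.
#' @export
extract_deep_features <- function(model, volume, map, masks, fold_plan,
                                  pad_width = 12, window_hu = c(0, 100)) {
  scan_fold <- fold_plan$fold[fold_plan$scan_id == volume$scan_id]
  if (length(scan_fold) != 1 || scan_fold != model$fold_id) {
    stop(sprintf(
      "fold mismatch: scan '%s' is assigned fold %s but model serves fold %s",
      volume$scan_id,
      if (length(scan_fold)) scan_fold else "<none>", model$fold_id),
      call. = FALSE)
  }
  tp <- model$spec$tap_channels
  info <- map$info
  out <- matrix(NA_real_, nrow(info), tp)
  d <- dim(volume$voxels)
  crop <- c(d[1] - d[1] %% 2L, d[2] - d[2] %% 2L)
  for (k in sort(unique(info$slice))) {
    ids <- info$superpixel_id[info$slice == k]
    img <- volume$voxels[, , k]
    img[masks$skull[, , k]] <- 0
    mp <- mirror_pad(img, masks$intracranial[, , k], pad_width)
    x <- pmin(pmax((mp$padded - window_hu[1]) / diff(window_hu), 0), 1)
    x <- x[seq_len(crop[1]), seq_len(crop[2])]
    fw <- unet_forward(model$params, x, model$spec)
    lab <- map$label_image[seq_len(crop[1]), seq_len(crop[2]), k]
    pos <- lab > 0L
    fac <- factor(lab[pos], levels = ids)
    tapmat <- matrix(fw$tap, prod(crop), tp)
    rows <- which(info$slice == k)
    for (ch in seq_len(tp)) {
      ch_img <- matrix(tapmat[, ch], crop[1], crop[2])
      out[rows, ch] <- as.numeric(tapply(ch_img[pos], fac, mean))
    }
  }
  colnames(out) <- sprintf("deep_%02d", seq_len(tp))
  dplyr::bind_cols(tibble::tibble(superpixel_id = info$superpixel_id),
                   tibble::as_tibble(out))
}
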