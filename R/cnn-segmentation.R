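#' U-net training configuration
#'
#' @param input_size square input size in pixels; must be a multiple of
#'   `2^depth` (default 256, the full-scale receptive field).
#' @param depth encoder/decoder depth (default 6).
#' @param base_channels channel width at the first encoder level; widths
#'   double per level (default 64; reduce for desk-scale runs).
#' @param learning_rate initial SGD learning rate (default 1e-4).
#' @param momentum SGD momentum (default 0.9).
#' @param mini_batch_size mini-batch size MBS (default 6).
#' @param max_epochs maximum epochs ME (default 800).
#' @param train_fraction fraction of pairs used for training (default 0.93).
#' @param seed RNG seed for initialization, split and shuffling.
#' @return An object of class `net_config`.
#' @export
net_config <- function(input_size = 256, depth = 6, base_channels = 64,
                       learning_rate = 1e-4, momentum = 0.9,
                       mini_batch_size = 6, max_epochs = 800,
                       train_fraction = 0.93, seed = 1) {
  if (mini_batch_size < 1 || max_epochs < 1)
    stop("mini_batch_size and max_epochs must be at least 1")
  if (input_size %% 2^depth != 0)
    stop("input_size must be divisible by 2^depth")
  structure(list(input_size = as.integer(input_size), depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 learning_rate = learning_rate, momentum = momentum,
                 mini_batch_size = as.integer(mini_batch_size),
                 max_epochs = as.integer(max_epochs),
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "net_config")
}

#' Median-intensity normalization and median-frequency class weights
#'
#' Balances foreground and background: each image is divided by the median
#' of its non-zero pixels, and per-class loss weights are set by
#' median-frequency balancing (`w_c = median class frequency / class
#' frequency` over the whole set), so the sparse ridge class is not drowned
#' out by background pixels.
#'
#' @param pairs list of pairs, each a list with `image` (matrix or
#'   `pixel_grid`) and `label` (binary matrix).
#' @return List with `pairs` (normalized) and `class_weights` (named
#'   `c(background, foreground)` weights).
#' @export
normalize_and_weight <- function(pairs) {
  out <- list()
  n_fg <- 0; n_total <- 0
  for (p in pairs) {
    img <- grid_values(p$image)
    med <- stats::median(img[img > 0])
    if (!is.finite(med) || med == 0) {
      warning("skipping image with zero median intensity")
      next
    }
    out[[length(out) + 1]] <- list(image = img / med, label = p$label)
    n_fg <- n_fg + sum(p$label != 0)
    n_total <- n_total + length(p$label)
  }
  freq <- c(background = (n_total - n_fg) / n_total,
            foreground = n_fg / n_total)
  w <- stats::median(freq) / freq
  w[!is.finite(w)] <- 0
  list(pairs = out, class_weights = w)
}

#' Geometric augmentation of image/label pairs
#'
#' Appends randomly transformed copies of each pair: reflections, right-angle
#' rotations and integer translations, with the identical transform applied
#' to image and label (nearest-neighbour, zero fill), so labels stay binary.
#'
#' @param pairs list of image/label pairs.
#' @param n_aug augmented copies per pair (default 1).
#' @param max_shift maximum translation in pixels (default 5).
#' @param seed RNG seed.
#' @return Augmented list of pairs (originals first).
#' @export
augment <- function(pairs, n_aug = 1, max_shift = 5, seed = 1) {
  shift_mat <- function(m, di, dj) {
    out <- matrix(0, nrow(m), ncol(m))
    rs <- max(1, 1 + di):min(nrow(m), nrow(m) + di)
    cs <- max(1, 1 + dj):min(ncol(m), ncol(m) + dj)
    out[rs, cs] <- m[rs - di, cs - dj]
    out
  }
  rot90k <- function(m, k) {
    k <- k %% 4
    for (i in seq_len(k)) m <- t(m[nrow(m):1, , drop = FALSE])
    m
  }
  with_seed(seed, {
    aug <- pairs
    for (p in pairs) for (a in seq_len(n_aug)) {
      fh <- stats::runif(1) < 0.5
      fv <- stats::runif(1) < 0.5
      k <- sample(0:3, 1)
      di <- sample(-max_shift:max_shift, 1)
      dj <- sample(-max_shift:max_shift, 1)
      tr <- function(m) {
        m <- grid_values(m)
        if (fh) m <- m[, ncol(m):1, drop = FALSE]
        if (fv) m <- m[nrow(m):1, , drop = FALSE]
        m <- rot90k(m, k)
        shift_mat(m, di, dj)
      }
      aug[[length(aug) + 1]] <- list(image = tr(p$image), label = tr(p$label))
    }
    aug
  })
}

# Resize a pair to the network input size (bilinear image, nearest label).
resize_pair <- function(p, size) {
  img <- grid_values(p$image)
  lab <- grid_values(p$label)
  if (!all(dim(img) == c(size, size)))
    img <- as.matrix(EBImage::resize(EBImage::Image(img), size, size))
  if (!all(dim(lab) == c(size, size)))
    lab <- as.matrix(EBImage::resize(EBImage::Image(lab), size, size,
                                     filter = "none"))
  list(image = img, label = (lab != 0) * 1)
}

#' Train a U-net ridge segmenter
#'
#' Encoder-decoder semantic segmentation: `depth` levels of 3x3
#' convolution + ReLU + 2x max-pooling, a bottleneck convolution, and a
#' mirrored decoder with nearest-neighbour 2x upsampling and skip
#' connections, closed by a 1x1 classifier. Trained with median-frequency
#' weighted pixel-wise cross-entropy by stochastic gradient descent with
#' momentum. Deterministic under a fixed `cfg$seed`.
#'
#' @param pairs list of image/label pairs (any size; resized to
#'   `cfg$input_size`).
#' @param cfg `net_config`.
#' @param verbose print per-epoch loss.
#' @return An object of class `unet_model`: `params`, `cfg`,
#'   `class_weights`, `loss_history` (mean training loss per epoch),
#'   `train_idx`, `test_idx` (indices into `pairs`).
#' @export
train_unet <- function(pairs, cfg = net_config(), verbose = FALSE) {
  size <- cfg$input_size
  pairs_rs <- lapply(pairs, resize_pair, size = size)
  n <- length(pairs_rs)
  split <- with_seed(cfg$seed, sample(n))
  n_train <- max(1L, round(cfg$train_fraction * n))
  train_idx <- sort(split[seq_len(n_train)])
  test_idx <- sort(split[-seq_len(n_train)])
  nw <- normalize_and_weight(pairs_rs[train_idx])
  train <- nw$pairs
  w <- nw$class_weights
  params <- unet_init(cfg$depth, cfg$base_channels, seed = cfg$seed)
  vel <- NULL
  losses <- numeric(cfg$max_epochs)
  order_seed <- cfg$seed + 1L
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- with_seed(order_seed + epoch, sample(length(train)))
    ep_loss <- 0
    nb <- 0
    i <- 1L
    while (i <= length(ord)) {
      batch <- ord[i:min(i + cfg$mini_batch_size - 1L, length(ord))]
      i <- i + cfg$mini_batch_size
      gacc <- NULL
      bl <- 0
      for (j in batch) {
        p <- train[[j]]
        x <- array(p$image, c(size, size, 1))
        fw <- unet_forward(params, x)
        ce <- softmax_ce(fw$logits, p$label + 1L, w)
        bl <- bl + ce$loss
        gacc <- grads_add(gacc, unet_backward(params, fw$cache, ce$dlogits))
      }
      gacc <- grads_scale(gacc, 1 / length(batch))
      upd <- sgd_update(params, gacc, vel, lr = cfg$learning_rate,
                        momentum = cfg$momentum)
      params <- upd$p; vel <- upd$v
      ep_loss <- ep_loss + bl / length(batch)
      nb <- nb + 1
    }
    losses[epoch] <- ep_loss / nb
    if (verbose) message(sprintf("epoch %d/%d loss %.4f", epoch,
                                 cfg$max_epochs, losses[epoch]))
  }
  structure(list(params = params, cfg = cfg, class_weights = w,
                 loss_history = losses, train_idx = train_idx,
                 test_idx = test_idx), class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf(
    "<unet_model> depth %d, %d px input, %d epochs, final loss %.4f\n",
    x$cfg$depth, x$cfg$input_size, x$cfg$max_epochs,
    utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' Predict a binary ridge mask
#'
#' @param model `unet_model`.
#' @param image matrix or `pixel_grid`; resized to the model input size.
#' @return Binary matrix (`input_size^2`) of predicted foreground.
#' @export
predict_unet <- function(model, image) {
  size <- model$cfg$input_size
  img <- grid_values(image)
  if (!all(dim(img) == c(size, size)))
    img <- as.matrix(EBImage::resize(EBImage::Image(img), size, size))
  med <- stats::median(img[img > 0])
  if (is.finite(med) && med > 0) img <- img / med
  fw <- unet_forward(model$params, array(img, c(size, size, 1)),
                     want_cache = FALSE)
  (fw$logits[, , 2] > fw$logits[, , 1]) * 1
}

#' Segmentation metrics: mean intersection-over-union
#'
#' Per-class IoU (`|pred & label| / |pred | label|`), averaged over the
#' classes present in prediction or label, plus pixel accuracy. With binary
#' masks the two classes are background and foreground.
#'
#' @param pred,label binary matrices of equal shape.
#' @return An object of class `seg_metrics`: `mean_iou`, `iou` (named
#'   per-class vector, `NaN` for absent classes), `pixel_accuracy`.
#' @export
mean_iou <- function(pred, label) {
  pred <- grid_values(pred) != 0
  label <- grid_values(label) != 0
  if (!all(dim(pred) == dim(label))) stop("pred and label shapes differ")
  iou_of <- function(p, l) {
    u <- sum(p | l)
    if (u == 0) return(NaN)
    sum(p & l) / u
  }
  iou <- c(background = iou_of(!pred, !label),
           foreground = iou_of(pred, label))
  structure(list(mean_iou = mean(iou[is.finite(iou)]), iou = iou,
                 pixel_accuracy = mean(pred == label)),
            class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf("<seg_metrics> mean IoU %.3f (bg %.3f, fg %.3f), accuracy %.3f\n",
              x$mean_iou, x$iou[1], x$iou[2], x$pixel_accuracy))
  invisible(x)
}

#' Evaluate a model on held-out pairs
#'
#' @param model `unet_model`.
#' @param pairs list of image/label pairs.
#' @return `seg_metrics` aggregated over all pixels of all pairs, with an
#'   extra `per_image` vector of per-image mean IoUs.
#' @export
evaluate_unet <- function(model, pairs) {
  size <- model$cfg$input_size
  inter <- c(bg = 0, fg = 0); uni <- c(bg = 0, fg = 0)
  acc_n <- 0; acc_total <- 0
  per_image <- numeric(length(pairs))
  for (k in seq_along(pairs)) {
    p <- resize_pair(pairs[[k]], size)
    pred <- predict_unet(model, p$image) != 0
    lab <- p$label != 0
    inter["bg"] <- inter["bg"] + sum(!pred & !lab)
    uni["bg"] <- uni["bg"] + sum(!pred | !lab)
    inter["fg"] <- inter["fg"] + sum(pred & lab)
    uni["fg"] <- uni["fg"] + sum(pred | lab)
    acc_n <- acc_n + sum(pred == lab); acc_total <- acc_total + length(lab)
    per_image[k] <- mean_iou(pred, lab)$mean_iou
  }
  iou <- ifelse(uni > 0, inter / uni, NaN)
  names(iou) <- c("background", "foreground")
  structure(list(mean_iou = mean(iou[is.finite(iou)]), iou = iou,
                 pixel_accuracy = acc_n / acc_total, per_image = per_image),
            class = "seg_metrics")
}

#' Predict, mask and restore physical pixel sizes
#'
#' Runs the trained network on an extracted cell image, masks the grayscale
#' input with the prediction (`NM = IM * NB`, Hadamard product) and restores
#' the physical pixel sizes of the resized grid:
#' `dx = x_o * psz / input_size`, `dy = y_o * psz / input_size`, where
#' `(x_o, y_o)` is the original extracted-cell size in pixels and `psz` the
#' acquisition pixel size.
#'
#' @param model `unet_model` (or `NULL` to use the conventional
#'   [label_cell()] labeling as the segmenter).
#' @param cell_image extracted cell (`pixel_grid` or matrix).
#' @param x_o,y_o original cell width and height in pixels (defaults: the
#'   supplied image's dimensions).
#' @param psz acquisition pixel size in micrometres (default 0.1977).
#' @return An object of class `rescaled_mask`: `NB` (binary matrix), `NM`
#'   (`pixel_grid` with the restored pixel sizes), `dx_new`, `dy_new`,
#'   `x_o`, `y_o`, `psz`.
#' @export
predict_and_rescale <- function(model, cell_image, x_o = NULL, y_o = NULL,
                                psz = 0.1977) {
  img <- grid_values(cell_image)
  if (is.null(x_o)) x_o <- ncol(img)
  if (is.null(y_o)) y_o <- nrow(img)
  size <- if (is.null(model)) 256L else model$cfg$input_size
  im <- if (all(dim(img) == c(size, size))) img else
    as.matrix(EBImage::resize(EBImage::Image(img), size, size))
  NB <- if (is.null(model)) label_cell(im)$label else predict_unet(model, im)
  dx_new <- x_o * psz / size
  dy_new <- y_o * psz / size
  structure(list(NB = NB, NM = pixel_grid(im * NB, dx_new, dy_new),
                 dx_new = dx_new, dy_new = dy_new, x_o = x_o, y_o = y_o,
                 psz = psz), class = "rescaled_mask")
}

#' Restored pixel size after network resizing
#'
#' `dx = x_o * psz / input_size`: the physical pixel edge of a cell image
#' of original width `x_o` pixels after resizing to the network input grid.
#'
#' @param x_o original extracted-cell dimension in pixels.
#' @param psz acquisition pixel size in micrometres (default 0.1977).
#' @param input_size network input size (default 256).
#' @return Pixel size in micrometres.
#' @examples
#' rescaled_pixel_size(127)  # ~0.098 um
#' @export
rescaled_pixel_size <- function(x_o, psz = 0.1977, input_size = 256) {
  x_o * psz / input_size
}
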