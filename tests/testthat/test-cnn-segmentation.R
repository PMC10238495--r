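test_that("median normalization and class weighting follow their formulas", {
  img <- matrix(c(0, 1, 1, 2), 2, 2)   # median of non-zero pixels = 1
  lab <- matrix(c(0, 1, 0, 0), 2, 2)
  nw <- normalize_and_weight(list(list(image = img, label = lab)))
  expect_equal(nw$pairs[[1]]$image, img)
  # frequencies (0.75, 0.25): weights median(freq)/freq = (2/3, 2)
  expect_equal(unname(nw$class_weights),
               c(0.5 / 0.75, 0.5 / 0.25), tolerance = 1e-12)
  # balanced classes give unit weights
  lab2 <- matrix(c(0, 0, 1, 1), 2, 2)
  nw2 <- normalize_and_weight(list(list(image = img + 1, label = lab2)))
  expect_equal(unname(nw2$class_weights), c(1, 1))
  expect_warning(normalize_and_weight(list(list(image = matrix(0, 2, 2),
                                                label = lab))), "zero median")
})

test_that("augmentation applies the same transform to image and label", {
  # when image equals label, every augmented image equals its label
  sc <- make_labyrinth(0.8, c(32, 32), 0.1, "labyrinth", seed = 3)
  pairs <- list(list(image = sc$ridge_mask, label = sc$ridge_mask))
  aug <- augment(pairs, n_aug = 6, seed = 4)
  expect_length(aug, 7)
  for (p in aug) {
    expect_identical(grid_values(p$image), grid_values(p$label))
    expect_true(all(p$label %in% c(0, 1)))   # labels stay binary
    expect_equal(dim(p$label), c(32, 32))
  }
  # deterministic under the seed
  aug2 <- augment(pairs, n_aug = 6, seed = 4)
  expect_identical(aug, aug2)
})

test_that("mean IoU matches hand-counted cases", {
  a <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(mean_iou(a, a)$mean_iou, 1)
  # the four-pixel case: fg IoU 1/2, bg IoU 2/3, mean 7/12
  label <- rbind(c(1, 1), c(0, 0))
  pred <- rbind(c(1, 0), c(0, 0))
  m <- mean_iou(pred, label)
  expect_equal(unname(m$iou["foreground"]), 1 / 2)
  expect_equal(unname(m$iou["background"]), 2 / 3)
  expect_equal(m$mean_iou, 7 / 12)
  # complement prediction: both IoUs zero
  m2 <- mean_iou(1 - label, label)
  expect_equal(m2$mean_iou, 0)
  # symmetry and joint-permutation invariance
  expect_equal(mean_iou(pred, label)$mean_iou,
               mean_iou(label, pred)$mean_iou)
  set.seed(2)
  p <- matrix(rbinom(36, 1, 0.4), 6); l <- matrix(rbinom(36, 1, 0.4), 6)
  perm <- sample(36)
  expect_equal(mean_iou(p, l)$mean_iou,
               mean_iou(matrix(p[perm], 6), matrix(l[perm], 6))$mean_iou)
  expect_error(mean_iou(matrix(0, 2, 2), matrix(0, 3, 3)), "shapes")
})

test_that("network gradients match numerical differentiation", {
  ns <- asNamespace("ridgemetrics")
  set.seed(5)
  params <- ns$unet_init(2, base_ch = 2, seed = 3)
  x <- array(rnorm(64), c(8, 8, 1))
  lab <- matrix(sample(1:2, 64, TRUE), 8)
  w <- c(0.7, 1.3)
  fw <- ns$unet_forward(params, x)
  ce <- ns$softmax_ce(fw$logits, lab, w)
  g <- ns$unet_backward(params, fw$cache, ce$dlogits)
  eps <- 1e-5
  for (spec in list(c("enc", "1"), c("bott", ""), c("dec", "2"))) {
    p2 <- params
    if (spec[2] == "") {
      idx <- 7
      p2$bott$W[idx] <- p2$bott$W[idx] + eps
      ga <- g$bott$W[idx]
    } else if (spec[1] == "enc") {
      idx <- 3
      p2$enc[[1]]$W[idx] <- p2$enc[[1]]$W[idx] + eps
      ga <- g$enc[[1]]$W[idx]
    } else {
      idx <- 11
      p2$dec[[2]]$Wmerge[idx] <- p2$dec[[2]]$Wmerge[idx] + eps
      ga <- g$dec[[2]]$Wmerge[idx]
    }
    fw2 <- ns$unet_forward(p2, x)
    num <- (ns$softmax_ce(fw2$logits, lab, w)$loss - ce$loss) / eps
    expect_equal(ga, num, tolerance = 1e-4)
  }
})

test_that("training reduces the loss on a learnable fixture", {
  pairs <- mk_seg_pairs(16, shape = c(32, 32))
  cfg <- net_config(input_size = 32, depth = 2, base_channels = 4,
                    learning_rate = 0.2, mini_batch_size = 4, max_epochs = 6,
                    train_fraction = 0.9, seed = 11)
  m <- train_unet(pairs, cfg)
  expect_lt(m$loss_history[6], m$loss_history[1])
  # degenerate all-background labels collapse to background predictions
  bg_pairs <- lapply(mk_seg_pairs(6, shape = c(32, 32)), function(p) {
    p$label <- p$label * 0
    p
  })
  mb <- train_unet(bg_pairs, net_config(input_size = 32, depth = 2,
                                        base_channels = 2,
                                        learning_rate = 0.2,
                                        mini_batch_size = 3, max_epochs = 4,
                                        train_fraction = 0.8, seed = 2))
  pred <- predict_unet(mb, bg_pairs[[1]]$image)
  ev <- mean_iou(pred, bg_pairs[[1]]$label)
  expect_equal(unname(ev$iou["background"]), 1)
  expect_true(is.nan(ev$iou["foreground"]))
  # determinism of training under a fixed seed
  cfg_d <- net_config(input_size = 32, depth = 2, base_channels = 2,
                      learning_rate = 0.2, mini_batch_size = 4,
                      max_epochs = 2, train_fraction = 0.9, seed = 7)
  m1 <- train_unet(pairs[1:8], cfg_d)
  m2 <- train_unet(pairs[1:8], cfg_d)
  expect_identical(m1$params, m2$params)
})

test_that("network configuration is validated", {
  expect_error(net_config(input_size = 100, depth = 3), "divisible")
  expect_error(net_config(mini_batch_size = 0), "at least 1")
  expect_silent(net_config(input_size = 64, depth = 2))
})

test_that("pixel sizes are restored after network resizing", {
  expect_equal(rescaled_pixel_size(256, 0.1977), 0.1977)
  expect_equal(round(rescaled_pixel_size(127, 0.1977), 3), 0.098)
  expect_equal(rescaled_pixel_size(512, 0.1977), 0.3954)
  # physical extent is preserved exactly: 256 * dx = x_o * psz
  expect_equal(256 * rescaled_pixel_size(127, 0.1977), 127 * 0.1977)
  # predict_and_rescale with the conventional labeler as segmenter
  sc <- make_labyrinth(0.8, c(64, 64), 0.1977, "stripes", seed = 2,
                       noise_sd = 0.1)
  rm <- predict_and_rescale(NULL, sc$image, x_o = 64, y_o = 64)
  expect_equal(dim(rm$NB), c(256L, 256L))
  expect_equal(rm$dx_new, 64 * 0.1977 / 256)
  # NM = IM .* NB: zero off the mask, grayscale on it
  expect_true(all(rm$NM$values[rm$NB == 0] == 0))
  expect_equal(rm$NM$dx, rm$dx_new)
})
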