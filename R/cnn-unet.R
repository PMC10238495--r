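# Internal U-net engine: plain-R convolutional layers with im2col matrix
# multiplication, used by the cnn_segmentation module. Tensors are H x W x C
# arrays; a single image is processed per forward/backward call.

# --- conv layer -------------------------------------------------------------

# im2col for a 3x3 receptive field with zero padding 1.
im2col3 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  cols <- matrix(0, H * W, 9L * C)
  k <- 0L
  for (ci in seq_len(C)) {
    p <- matrix(0, H + 2, W + 2)
    p[2:(H + 1), 2:(W + 1)] <- x[, , ci]
    for (dj in -1:1) for (di in -1:1) {
      k <- k + 1L
      cols[, k] <- as.vector(p[(2 + di):(H + 1 + di), (2 + dj):(W + 1 + dj)])
    }
  }
  cols
}

# scatter-add of column gradients back to the input tensor
col2im3 <- function(dcols, H, W, C) {
  dx <- array(0, c(H, W, C))
  k <- 0L
  for (ci in seq_len(C)) {
    dp <- matrix(0, H + 2, W + 2)
    for (dj in -1:1) for (di in -1:1) {
      k <- k + 1L
      dp[(2 + di):(H + 1 + di), (2 + dj):(W + 1 + dj)] <-
        dp[(2 + di):(H + 1 + di), (2 + dj):(W + 1 + dj)] +
        matrix(dcols[, k], H, W)
    }
    dx[, , ci] <- dp[2:(H + 1), 2:(W + 1)]
  }
  dx
}

# Wmat: (9*Cin) x Cout; returns list(out, cache)
conv3_forward <- function(x, Wmat, b) {
  H <- dim(x)[1]; W <- dim(x)[2]
  cols <- im2col3(x)
  out <- cols %*% Wmat
  out <- sweep(out, 2, b, `+`)
  list(out = array(out, c(H, W, length(b))),
       cache = list(cols = cols, dims = dim(x)))
}

conv3_backward <- function(dout, Wmat, cache) {
  H <- cache$dims[1]; W <- cache$dims[2]; C <- cache$dims[3]
  dmat <- matrix(dout, H * W, dim(dout)[3])
  dW <- crossprod(cache$cols, dmat)
  db <- colSums(dmat)
  dx <- col2im3(dmat %*% t(Wmat), H, W, C)
  list(dx = dx, dW = dW, db = db)
}

# 1x1 convolution (the classifier head)
conv1_forward <- function(x, Wmat, b) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  xm <- matrix(x, H * W, C)
  out <- sweep(xm %*% Wmat, 2, b, `+`)
  list(out = array(out, c(H, W, ncol(Wmat))), cache = list(xm = xm, dims = dim(x)))
}

conv1_backward <- function(dout, Wmat, cache) {
  H <- cache$dims[1]; W <- cache$dims[2]
  dmat <- matrix(dout, H * W, dim(dout)[3])
  list(dx = array(dmat %*% t(Wmat), cache$dims),
       dW = crossprod(cache$xm, dmat), db = colSums(dmat))
}

# --- activations and resampling --------------------------------------------

relu_forward <- function(x) list(out = pmax(x, 0), mask = x > 0)
relu_backward <- function(dout, mask) dout * mask

# 2x2 max pooling; stores which of the 4 candidates won
maxpool_forward <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  i1 <- seq(1, H, 2); i2 <- i1 + 1
  j1 <- seq(1, W, 2); j2 <- j1 + 1
  a <- x[i1, j1, , drop = FALSE]; b <- x[i2, j1, , drop = FALSE]
  c2 <- x[i1, j2, , drop = FALSE]; d <- x[i2, j2, , drop = FALSE]
  out <- pmax(a, b, c2, d)
  list(out = out,
       arg = (out == a) * 1L + (out != a & out == b) * 2L +
         (out != a & out != b & out == c2) * 3L +
         (out != a & out != b & out != c2) * 4L,
       dims = dim(x))
}

maxpool_backward <- function(dout, cache) {
  H <- cache$dims[1]; W <- cache$dims[2]; C <- cache$dims[3]
  dx <- array(0, cache$dims)
  i1 <- seq(1, H, 2); i2 <- i1 + 1
  j1 <- seq(1, W, 2); j2 <- j1 + 1
  dx[i1, j1, ] <- dout * (cache$arg == 1L)
  dx[i2, j1, ] <- dout * (cache$arg == 2L)
  dx[i1, j2, ] <- dout * (cache$arg == 3L)
  dx[i2, j2, ] <- dout * (cache$arg == 4L)
  dx
}

# nearest-neighbour 2x upsampling
upsample_forward <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]
  x[rep(seq_len(H), each = 2), rep(seq_len(W), each = 2), , drop = FALSE]
}

upsample_backward <- function(dout) {
  H2 <- dim(dout)[1]; W2 <- dim(dout)[2]
  i1 <- seq(1, H2, 2); j1 <- seq(1, W2, 2)
  dout[i1, j1, , drop = FALSE] + dout[i1 + 1, j1, , drop = FALSE] +
    dout[i1, j1 + 1, , drop = FALSE] + dout[i1 + 1, j1 + 1, , drop = FALSE]
}

# --- network ----------------------------------------------------------------

# He-initialized parameter set for a U-net of the given depth.
unet_init <- function(depth, base_ch, in_ch = 1L, n_class = 2L, seed = 1) {
  ch <- base_ch * 2^(0:depth)   # ch[i] = channels at encoder level i
  he <- function(fan_in, nout) {
    matrix(stats::rnorm(fan_in * nout, sd = sqrt(2 / fan_in)), fan_in, nout)
  }
  with_seed(seed, {
    params <- list(enc = list(), dec = list())
    cin <- in_ch
    for (i in seq_len(depth)) {
      params$enc[[i]] <- list(W = he(9 * cin, ch[i]), b = numeric(ch[i]))
      cin <- ch[i]
    }
    params$bott <- list(W = he(9 * ch[depth], ch[depth + 1]),
                        b = numeric(ch[depth + 1]))
    above <- ch[depth + 1]
    for (i in rev(seq_len(depth))) {
      params$dec[[i]] <- list(
        Wup = he(9 * above, ch[i]), bup = numeric(ch[i]),
        Wmerge = he(9 * 2 * ch[i], ch[i]), bmerge = numeric(ch[i]))
      above <- ch[i]
    }
    params$out <- list(W = he(ch[1], n_class), b = numeric(n_class))
    params
  })
}

unet_forward <- function(params, x, want_cache = TRUE) {
  depth <- length(params$enc)
  cache <- list(enc = vector("list", depth), dec = vector("list", depth))
  h <- x
  skips <- vector("list", depth)
  for (i in seq_len(depth)) {
    cf <- conv3_forward(h, params$enc[[i]]$W, params$enc[[i]]$b)
    rf <- relu_forward(cf$out)
    skips[[i]] <- rf$out
    pf <- maxpool_forward(rf$out)
    if (want_cache) cache$enc[[i]] <- list(conv = cf$cache, relu = rf$mask,
                                           pool = pf[c("arg", "dims")])
    h <- pf$out
  }
  cf <- conv3_forward(h, params$bott$W, params$bott$b)
  rf <- relu_forward(cf$out)
  if (want_cache) cache$bott <- list(conv = cf$cache, relu = rf$mask)
  h <- rf$out
  for (i in rev(seq_len(depth))) {
    up <- upsample_forward(h)
    cf1 <- conv3_forward(up, params$dec[[i]]$Wup, params$dec[[i]]$bup)
    rf1 <- relu_forward(cf1$out)
    ch_i <- dim(rf1$out)[3]
    merged <- array(c(rf1$out, skips[[i]]),
                    c(dim(rf1$out)[1], dim(rf1$out)[2], 2 * ch_i))
    cf2 <- conv3_forward(merged, params$dec[[i]]$Wmerge, params$dec[[i]]$bmerge)
    rf2 <- relu_forward(cf2$out)
    if (want_cache) cache$dec[[i]] <- list(conv1 = cf1$cache, relu1 = rf1$mask,
                                           conv2 = cf2$cache, relu2 = rf2$mask,
                                           ch = ch_i)
    h <- rf2$out
  }
  of <- conv1_forward(h, params$out$W, params$out$b)
  if (want_cache) cache$out <- of$cache
  list(logits = of$out, cache = if (want_cache) cache else NULL)
}

# Backward pass; dlogits has the logits' shape. Returns gradients with the
# same structure as params, plus skip gradients handled internally.
unet_backward <- function(params, cache, dlogits) {
  depth <- length(params$enc)
  grads <- list(enc = vector("list", depth), dec = vector("list", depth))
  ob <- conv1_backward(dlogits, params$out$W, cache$out)
  grads$out <- list(W = ob$dW, b = ob$db)
  dh <- ob$dx
  dskips <- vector("list", depth)
  for (i in seq_len(depth)) {       # decoder levels from shallow to deep
    cc <- cache$dec[[i]]
    d2 <- relu_backward(dh, cc$relu2)
    cb2 <- conv3_backward(d2, params$dec[[i]]$Wmerge, cc$conv2)
    ch_i <- cc$ch
    dmerged <- cb2$dx
    dup_branch <- dmerged[, , seq_len(ch_i), drop = FALSE]
    dskips[[i]] <- dmerged[, , ch_i + seq_len(ch_i), drop = FALSE]
    d1 <- relu_backward(dup_branch, cc$relu1)
    cb1 <- conv3_backward(d1, params$dec[[i]]$Wup, cc$conv1)
    grads$dec[[i]] <- list(Wup = cb1$dW, bup = cb1$db,
                           Wmerge = cb2$dW, bmerge = cb2$db)
    dh <- upsample_backward(cb1$dx)
  }
  db <- relu_backward(dh, cache$bott$relu)
  cbb <- conv3_backward(db, params$bott$W, cache$bott$conv)
  grads$bott <- list(W = cbb$dW, b = cbb$db)
  dh <- cbb$dx
  for (i in rev(seq_len(depth))) {  # encoder levels from deep to shallow
    cc <- cache$enc[[i]]
    dpool <- maxpool_backward(dh, cc$pool)
    dpool <- dpool + dskips[[i]]    # skip connection joins here
    de <- relu_backward(dpool, cc$relu)
    cbe <- conv3_backward(de, params$enc[[i]]$W, cc$conv)
    grads$enc[[i]] <- list(W = cbe$dW, b = cbe$db)
    dh <- cbe$dx
  }
  grads
}

# Weighted pixel-wise softmax cross-entropy. labels: H x W matrix in
# {1..n_class}; class_weights: per-class loss weights. Returns loss and the
# gradient w.r.t. logits.
softmax_ce <- function(logits, labels, class_weights) {
  H <- dim(logits)[1]; W <- dim(logits)[2]; C <- dim(logits)[3]
  lm <- matrix(logits, H * W, C)
  lm <- lm - apply(lm, 1, max)
  ex <- exp(lm)
  p <- ex / rowSums(ex)
  y <- as.integer(labels)
  wpx <- class_weights[y]
  wsum <- sum(wpx)
  idx <- cbind(seq_len(H * W), y)
  loss <- -sum(wpx * log(pmax(p[idx], 1e-12))) / wsum
  dp <- p * wpx
  dp[idx] <- dp[idx] - wpx
  list(loss = loss, dlogits = array(dp / wsum, dim(logits)), prob = p)
}

# --- SGD with momentum ------------------------------------------------------

# index nested parameter/gradient structures by name where names exist, so
# the two trees need not share element order
sub_of <- function(g, key, i) if (!is.null(key) && nzchar(key)) g[[key]] else g[[i]]

sgd_update <- function(params, grads, vel, lr, momentum = 0.9) {
  walk <- function(p, g, v) {
    if (is.list(p)) {
      out_p <- p; out_v <- if (is.null(v)) vector("list", length(p)) else v
      nm <- names(p)
      for (k in seq_along(p)) {
        r <- walk(p[[k]], sub_of(g, nm[k], k),
                  if (is.null(v)) NULL else sub_of(v, nm[k], k))
        out_p[[k]] <- r$p; out_v[[k]] <- r$v
      }
      names(out_v) <- nm
      list(p = out_p, v = out_v)
    } else {
      if (is.null(v)) v <- p * 0
      v <- momentum * v - lr * g
      list(p = p + v, v = v)
    }
  }
  walk(params, grads, vel)
}

# elementwise sum of two grad structures (name-aware)
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(a)) {
    nm <- names(a)
    for (k in seq_along(a)) a[[k]] <- grads_add(a[[k]], sub_of(b, nm[k], k))
    a
  } else a + b
}

grads_scale <- function(a, s) {
  if (is.list(a)) {
    for (k in seq_along(a)) a[[k]] <- grads_scale(a[[k]], s)
    a
  } else a * s
}
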