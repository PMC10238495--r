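# Shared fixtures and independent oracles used across test files.

# image/label pairs of striped and labyrinthine scenes for network training
mk_seg_pairs <- function(n, shape = c(64, 64), seed0 = 100, noise_sd = 0.1) {
  lapply(seq_len(n), function(i) {
    mode <- if (i %% 2 == 0) "stripes" else "labyrinth"
    period <- 0.5 + 0.4 * ((i * 7) %% 10) / 10
    sc <- make_labyrinth(period, shape = shape, pixel_size = 0.1, mode = mode,
                         seed = seed0 + i, noise_sd = noise_sd)
    img <- sc$image$values
    lab <- sc$ridge_mask
    if (i %% 3 == 0) { img <- t(img); lab <- t(lab) }
    list(image = img, label = lab)
  })
}

# brute-force minimum-cost assignment by permutation enumeration (rows of a
# square matrix; Inf-forbidden entries handled by a large finite surrogate)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) for (i in seq_len(n)) {
    q <- c(p[seq_len(i - 1L)], n, p[seq(i, length.out = n - 1L - (i - 1L))])
    out[[length(out) + 1L]] <- q
  }
  out
}

brute_lap_cost <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  n <- max(nr, nc)
  finite <- cost[is.finite(cost)]
  big <- if (length(finite)) sum(abs(finite)) + max(abs(finite), 1) + 1 else 1
  a <- matrix(big, n, n)
  a[seq_len(nr), seq_len(nc)] <- ifelse(is.finite(cost), cost, big)
  best <- Inf
  for (p in all_perms(n)) {
    s <- sum(a[cbind(seq_len(n), p)])
    if (s < best) best <- s
  }
  best
}

lap_total_cost <- function(cost, assignment) {
  nr <- nrow(cost); nc <- ncol(cost)
  n <- max(nr, nc)
  finite <- cost[is.finite(cost)]
  big <- if (length(finite)) sum(abs(finite)) + max(abs(finite), 1) + 1 else 1
  linked <- sum(!is.na(assignment))
  s <- sum(cost[cbind(which(!is.na(assignment)),
                      assignment[!is.na(assignment)])])
  s + big * (n - linked)
}

# independent literal transcription of the Fourier wavelength statistic:
# explicit complex-exponential DFT matrices, no fft()
oracle_wavelength <- function(m, ds) {
  nr <- nrow(m); nc <- ncol(m)
  kx <- 2 * pi * (seq_len(nc) - 1 - floor(nc / 2)) / (nc * ds)
  ky <- 2 * pi * (seq_len(nr) - 1 - floor(nr / 2)) / (nr * ds)
  X <- (seq_len(nc) - 1) * ds
  Y <- (seq_len(nr) - 1) * ds
  Wy <- exp(-1i * outer(ky, Y))
  Wx <- exp(-1i * outer(X, kx))
  If <- (Wy %*% m %*% Wx) * ds^2 / (2 * pi)
  amp <- Mod(If)
  amp[floor(nr / 2) + 1, floor(nc / 2) + 1] <- 0
  dk <- (2 * pi / (nc * ds)) * (2 * pi / (nr * ds))
  k2 <- outer(ky^2, kx^2, `+`)
  wn <- sqrt(sum(k2 * amp / sqrt(sum(amp) * dk)) * dk)
  2 * pi / wn
}

# analytic velocity_field constructor (µm/min on a physical grid)
analytic_field <- function(kind, c0, shape = c(32, 32), ds = 0.25) {
  nr <- shape[1]; nc <- shape[2]
  xs <- (seq_len(nc) - 1) * ds
  ys <- (seq_len(nr) - 1) * ds
  X <- matrix(rep(xs, each = nr), nr, nc)
  Y <- matrix(rep(ys, times = nc), nr, nc)
  x0 <- mean(xs); y0 <- mean(ys)
  v <- switch(kind,
    translation = list(vx = matrix(c0, nr, nc), vy = matrix(0, nr, nc)),
    source = list(vx = c0 * (X - x0), vy = c0 * (Y - y0)),
    shear = list(vx = c0 * (Y - y0), vy = matrix(0, nr, nc)),
    rotation = list(vx = c0 * (Y - y0), vy = -c0 * (X - x0)))
  structure(list(vx = v$vx, vy = v$vy, dt = 1, dx = ds, dy = ds,
                 rank_deficient = matrix(FALSE, nr, nc)),
            class = "velocity_field")
}

# radial power-spectrum peak wave number of a binary mask
radial_peak <- function(mask, ds) {
  nr <- nrow(mask); nc <- ncol(mask)
  f <- Mod(stats::fft(mask - mean(mask)))^2
  kx <- 2 * pi * c(0:(floor(nc / 2)), -(ceiling(nc / 2) - 1):-1) / (nc * ds)
  ky <- 2 * pi * c(0:(floor(nr / 2)), -(ceiling(nr / 2) - 1):-1) / (nr * ds)
  kmag <- sqrt(outer(ky^2, kx^2, `+`))
  bw <- 2 * pi / (nc * ds)
  bins <- round(kmag / bw)
  pw <- tapply(as.vector(f), as.vector(bins), sum)
  as.numeric(names(pw))[which.max(pw[-1]) + 1] * bw
}
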