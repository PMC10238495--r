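#' Synthetic worm-like chains with known persistence length
#'
#' Samples 2D discrete worm-like chains: per-step turn angles are drawn
#' i.i.d. from `Normal(0, sigma^2 = step / lp_true)`, the standard 2D
#' discretization under which the rescaled-curvature distribution has
#' variance `2 / lp_true`. These chains are the ground-truth fixture for
#' persistence-length estimation.
#'
#' @param lp_true persistence length in micrometres (> 0).
#' @param step segment length in micrometres (> 0).
#' @param n_points number of points per chain (>= 10).
#' @param n_chains number of chains.
#' @param seed integer RNG seed; identical seed and parameters reproduce the
#'   chain coordinates bit-exactly.
#' @return An object of class `wlc_set`: list with `chains` (list of n x 2
#'   coordinate matrices, micrometres), `lp_true`, `step`, `n_chains`,
#'   `n_points`, `seed`.
#' @export
make_wormlike_chains <- function(lp_true, step, n_points = 100, n_chains = 10,
                                 seed = 1) {
  if (!is.numeric(lp_true) || lp_true <= 0) stop("lp_true must be positive")
  if (!is.numeric(step) || step <= 0) stop("step must be positive")
  if (n_points < 10) stop("n_points must be at least 10")
  sigma <- sqrt(step / lp_true)
  chains <- with_seed(seed, {
    lapply(seq_len(n_chains), function(i) {
      theta0 <- stats::runif(1, -pi, pi)
      phi <- stats::rnorm(n_points - 2, mean = 0, sd = sigma)
      theta <- theta0 + cumsum(c(0, phi))       # heading of each segment
      x <- cumsum(c(0, step * cos(theta)))
      y <- cumsum(c(0, step * sin(theta)))
      cbind(x = x, y = y)
    })
  })
  structure(list(chains = chains, lp_true = lp_true, step = step,
                 n_chains = n_chains, n_points = n_points, seed = seed),
            class = "wlc_set")
}

#' Synthetic labyrinthine or striped ridge scene
#'
#' Builds a binary ridge mask of known spatial period plus a grayscale
#' rendering (mask convolved with a Gaussian ridge profile, additive
#' Gaussian noise, rescaled to \[0, 1\]). `stripes` gives exact-period
#' vertical stripes; `labyrinth` thresholds isotropic band-pass noise whose
#' radial power spectrum peaks at `2 * pi / period`, emulating the crowded
#' fingerprint-like patterns of periderm cells.
#'
#' @param period spatial period in micrometres; must exceed twice the pixel
#'   size (Nyquist).
#' @param shape image size in pixels, `c(rows, cols)`.
#' @param pixel_size pixel edge in micrometres.
#' @param mode `"stripes"` or `"labyrinth"`.
#' @param seed integer RNG seed.
#' @param noise_sd additive Gaussian noise standard deviation (image scale
#'   where the noiseless ridge rendering peaks at 1).
#' @param ridge_sigma_px Gaussian ridge profile width in pixels.
#' @return An object of class `synthetic_scene`: `image` (pixel_grid, 0-1),
#'   `ridge_mask` (binary matrix), `membrane_mask`, `cell_centroids`,
#'   `params`, `seed`.
#' @export
make_labyrinth <- function(period, shape = c(128, 128), pixel_size = 0.1977,
                           mode = c("labyrinth", "stripes"), seed = 1,
                           noise_sd = 0.05, ridge_sigma_px = 1) {
  mode <- match.arg(mode)
  if (period <= 2 * pixel_size)
    stop("period must exceed twice the pixel size (Nyquist)")
  nr <- shape[1]; nc <- shape[2]
  period_px <- period / pixel_size
  mask <- with_seed(seed, {
    if (mode == "stripes") {
      cols <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
      (sin(2 * pi * cols / period_px) > 0) * 1
    } else {
      noise <- matrix(stats::rnorm(nr * nc), nr, nc)
      f <- stats::fft(noise)
      kx <- 2 * pi * c(0:(floor(nc / 2)), -(ceiling(nc / 2) - 1):-1) /
        (nc * pixel_size)
      ky <- 2 * pi * c(0:(floor(nr / 2)), -(ceiling(nr / 2) - 1):-1) /
        (nr * pixel_size)
      kmag <- sqrt(outer(ky^2, kx^2, `+`))
      k0 <- 2 * pi / period
      band <- exp(-(kmag - k0)^2 / (2 * (k0 / 6)^2))
      field <- Re(stats::fft(f * band, inverse = TRUE)) / (nr * nc)
      (field > stats::median(field)) * 1
    }
  })
  render <- conv_sep_replicate(mask, gauss_kernel_1d(ridge_sigma_px),
                               gauss_kernel_1d(ridge_sigma_px))
  if (max(render) > 0) render <- render / max(render)
  img <- with_seed(seed + 1L, {
    out <- render
    if (noise_sd > 0)
      out <- out + matrix(stats::rnorm(nr * nc, sd = noise_sd), nr, nc)
    out
  })
  img <- img - min(img)
  if (max(img) > 0) img <- img / max(img)
  structure(list(image = pixel_grid(img, pixel_size, pixel_size),
                 ridge_mask = mask,
                 membrane_mask = matrix(0, nr, nc),
                 cell_centroids = list(),
                 params = list(period = period, mode = mode,
                               pixel_size = pixel_size, noise_sd = noise_sd,
                               ridge_sigma_px = ridge_sigma_px),
                 seed = seed),
            class = "synthetic_scene")
}

#' Synthetic multicellular scene with a membrane lattice
#'
#' Renders a rectangular lattice of bright membranes enclosing
#' `n_cells_x * n_cells_y` interior cells (plus partially visible cells
#' clipped at the image border), each filled with a striped ridge texture.
#' Ground-truth interior centroids are returned for segmentation checks.
#'
#' @param n_cells_x,n_cells_y number of fully enclosed interior cells.
#' @param cell_px interior cell size in pixels (square cells).
#' @param margin_px width of the clipped border cells in pixels.
#' @param pixel_size micrometres per pixel.
#' @param membrane_px membrane line width in pixels.
#' @param ridge_period ridge period inside cells, micrometres.
#' @param noise_sd additive noise level.
#' @param gap_px if positive, a gap of this length (pixels) is cut into one
#'   membrane line — used to test morphological gap closing.
#' @param seed RNG seed.
#' @return A `synthetic_scene`; `cell_centroids` holds the interior-cell
#'   centroids in micrometres as (x, y) pairs.
#' @export
make_cell_scene <- function(n_cells_x = 3, n_cells_y = 3, cell_px = 40,
                            margin_px = 12, pixel_size = 0.1977,
                            membrane_px = 2, ridge_period = 1.2,
                            noise_sd = 0.02, gap_px = 0, seed = 1) {
  nlx <- n_cells_x + 1L; nly <- n_cells_y + 1L
  nc <- 2 * margin_px + n_cells_x * cell_px + nlx * membrane_px
  nr <- 2 * margin_px + n_cells_y * cell_px + nly * membrane_px
  membrane <- matrix(0, nr, nc)
  xlines <- margin_px + (0:n_cells_x) * (cell_px + membrane_px) + 1
  ylines <- margin_px + (0:n_cells_y) * (cell_px + membrane_px) + 1
  for (x0 in xlines) membrane[, x0:(x0 + membrane_px - 1)] <- 1
  for (y0 in ylines) membrane[y0:(y0 + membrane_px - 1), ] <- 1
  if (gap_px > 0) {
    gy <- ylines[2]
    gx <- round(nc / 2)
    membrane[gy:(gy + membrane_px - 1), gx:(gx + gap_px - 1)] <- 0
  }
  period_px <- ridge_period / pixel_size
  cols <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
  ridges <- (sin(2 * pi * cols / period_px) > 0) * 1
  ridges[membrane == 1] <- 0
  interior <- conv2_replicate(membrane, matrix(1, 3, 3)) == 0
  ridge_mask <- ridges * interior
  # ridges rendered well below membrane brightness so global thresholding of
  # the high-passed frame isolates the membrane lattice
  render <- membrane + 0.25 * ridge_mask
  render <- conv_sep_replicate(render, gauss_kernel_1d(0.8), gauss_kernel_1d(0.8))
  img <- with_seed(seed, {
    render + matrix(stats::rnorm(nr * nc, sd = noise_sd), nr, nc)
  })
  img <- img - min(img); img <- img / max(img)
  centroids <- list()
  for (iy in seq_len(n_cells_y)) for (ix in seq_len(n_cells_x)) {
    cx <- (xlines[ix] + membrane_px - 1 + (xlines[ix + 1] - 1)) / 2 - 1
    cy <- (ylines[iy] + membrane_px - 1 + (ylines[iy + 1] - 1)) / 2 - 1
    centroids[[length(centroids) + 1]] <- c(x = cx * pixel_size,
                                            y = cy * pixel_size)
  }
  structure(list(image = pixel_grid(img, pixel_size, pixel_size),
                 ridge_mask = ridge_mask,
                 membrane_mask = membrane,
                 cell_centroids = centroids,
                 params = list(n_cells_x = n_cells_x, n_cells_y = n_cells_y,
                               cell_px = cell_px, margin_px = margin_px,
                               pixel_size = pixel_size, gap_px = gap_px),
                 seed = seed),
            class = "synthetic_scene")
}

#' Synthetic image sequence advected by an analytic velocity field
#'
#' Produces frames satisfying brightness constancy under a known velocity
#' field, the oracle for optic-flow, divergence and strain-rate estimation.
#' Frame `t + 1` is frame `t` backward-warped by `v_true * dt` with bilinear
#' interpolation.
#'
#' @param field one of `"translation"`, `"source"`, `"shear"`, `"rotation"`:
#'   `v = (c, 0)`, `v = c * (x - x0, y - y0)`, `v = (c * (y - y0), 0)`,
#'   `v = c * (y - y0, -(x - x0))` respectively, with `(x0, y0)` the image
#'   centre.
#' @param magnitude the coefficient `c` (micrometres/min for translation,
#'   1/min otherwise).
#' @param shape image size in pixels `c(rows, cols)`.
#' @param dt frame interval in minutes.
#' @param n_frames number of frames (>= 2).
#' @param pixel_size micrometres per pixel.
#' @param seed RNG seed for the base texture.
#' @return An object of class `flow_scene`: `frames` (list of pixel_grid),
#'   `vx_true`, `vy_true` (micrometres/min on the grid), `dt`, `params`.
#' @export
make_flow_scene <- function(field = c("translation", "source", "shear",
                                      "rotation"),
                            magnitude = 0.1, shape = c(64, 64), dt = 0.5,
                            n_frames = 2, pixel_size = 0.2, seed = 1) {
  field <- match.arg(field)
  nr <- shape[1]; nc <- shape[2]
  xs <- (seq_len(nc) - 1) * pixel_size
  ys <- (seq_len(nr) - 1) * pixel_size
  x0 <- mean(xs); y0 <- mean(ys)
  X <- matrix(rep(xs, each = nr), nr, nc)
  Y <- matrix(rep(ys, times = nc), nr, nc)
  vfun <- switch(field,
    translation = list(vx = matrix(magnitude, nr, nc), vy = matrix(0, nr, nc)),
    source = list(vx = magnitude * (X - x0), vy = magnitude * (Y - y0)),
    shear = list(vx = magnitude * (Y - y0), vy = matrix(0, nr, nc)),
    rotation = list(vx = magnitude * (Y - y0), vy = -magnitude * (X - x0)))
  max_disp_px <- max(sqrt(vfun$vx^2 + vfun$vy^2)) * dt / pixel_size
  if (max_disp_px >= 3) {
    warning("maximum displacement ", signif(max_disp_px, 3),
            " px exceeds the small-displacement regime; clamping magnitude")
    scale <- 2.9 / max_disp_px
    vfun$vx <- vfun$vx * scale
    vfun$vy <- vfun$vy * scale
    magnitude <- magnitude * scale
  }
  base <- with_seed(seed, matrix(stats::rnorm(nr * nc), nr, nc))
  base <- conv_sep_replicate(base, gauss_kernel_1d(2), gauss_kernel_1d(2))
  base <- (base - min(base)) / (max(base) - min(base))
  warp_back <- function(img, vx, vy) {
    # sample img at (x - vx dt, y - vy dt), bilinear, clamped to the border
    xq <- (X - vx * dt) / pixel_size + 1
    yq <- (Y - vy * dt) / pixel_size + 1
    xq <- pmin(pmax(xq, 1), nc); yq <- pmin(pmax(yq, 1), nr)
    x1 <- floor(xq); y1 <- floor(yq)
    x2 <- pmin(x1 + 1, nc); y2 <- pmin(y1 + 1, nr)
    fx <- xq - x1; fy <- yq - y1
    at <- function(r, c) img[cbind(as.vector(r), as.vector(c))]
    out <- (1 - fx) * (1 - fy) * at(y1, x1) + fx * (1 - fy) * at(y1, x2) +
      (1 - fx) * fy * at(y2, x1) + fx * fy * at(y2, x2)
    matrix(out, nr, nc)
  }
  frames <- vector("list", n_frames)
  frames[[1]] <- base
  for (t in seq_len(n_frames - 1))
    frames[[t + 1]] <- warp_back(frames[[t]], vfun$vx, vfun$vy)
  frames <- lapply(frames, pixel_grid, dx = pixel_size, dy = pixel_size)
  structure(list(frames = frames, vx_true = vfun$vx, vy_true = vfun$vy,
                 dt = dt,
                 params = list(field = field, magnitude = magnitude,
                               pixel_size = pixel_size, seed = seed)),
            class = "flow_scene")
}

#' Synthetic two-layer z-stack with entropy-separable slices
#'
#' Emulates a confocal stack through the bilayered epidermis: periderm
#' slices carry sparse, smooth ridge patterns (low Shannon entropy) while
#' basal slices carry dense speckle (high entropy). Ground-truth slice
#' labels are returned so entropy-based slice filtering can be validated.
#'
#' @param n_periderm,n_basal number of slices per layer (`n_periderm >= 1`).
#' @param n_t number of time points.
#' @param shape slice size in pixels `c(rows, cols)`.
#' @param pixel_size micrometres per pixel.
#' @param seed RNG seed.
#' @return List with `stack` (4D array `[row, col, z, t]`, values 0-1),
#'   `labels` (character vector per z: `"periderm"`/`"basal"`), `pixel_size`.
#' @export
make_zstack <- function(n_periderm = 3, n_basal = 3, n_t = 1,
                        shape = c(64, 64), pixel_size = 0.1977, seed = 1) {
  if (n_periderm < 1) stop("n_periderm must be at least 1")
  nr <- shape[1]; nc <- shape[2]
  nz <- n_periderm + n_basal
  stack <- array(0, dim = c(nr, nc, nz, n_t))
  sub <- 0L
  for (t in seq_len(n_t)) {
    for (z in seq_len(n_periderm)) {
      sub <- sub + 1L
      sc <- make_labyrinth(period = 8 * pixel_size, shape = shape,
                           pixel_size = pixel_size, mode = "labyrinth",
                           seed = seed + sub, noise_sd = 0)
      # thin the labyrinth to sparse ridge curves on a dark background so the
      # slice histogram is dominated by the zero bin (low Shannon entropy)
      img <- skeletonize(sc$ridge_mask) * 1.0
      img <- conv_sep_replicate(img, gauss_kernel_1d(0.8), gauss_kernel_1d(0.8))
      stack[, , z, t] <- img / max(img)
    }
    for (z in seq_len(n_basal)) {
      sub <- sub + 1L
      stack[, , n_periderm + z, t] <-
        with_seed(seed + 1000L + sub, matrix(stats::runif(nr * nc), nr, nc))
    }
  }
  list(stack = stack,
       labels = c(rep("periderm", n_periderm), rep("basal", n_basal)),
       pixel_size = pixel_size)
}
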