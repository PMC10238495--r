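#' Gaussian smoothing with unit DC gain
#'
#' Low-pass filtering by the normalized Gaussian kernel
#' `g(x, y; sigma) = (1 / (2 pi sigma^2)) exp(-(x^2 + y^2) / (2 sigma^2))`,
#' applied separably with replicate borders. The discrete kernel is
#' renormalized to unit sum, so a constant image passes unchanged.
#'
#' @param img `pixel_grid` or matrix.
#' @param sigma standard deviation in pixels (default 0.7, the noise scale
#'   used throughout the membrane and ridge pipelines).
#' @return Smoothed image of the same class as the input carrier
#'   (`pixel_grid` in, `pixel_grid` out).
#' @export
gaussian_smooth <- function(img, sigma = 0.7) {
  if (sigma <= 0) stop("sigma must be positive")
  k <- gauss_kernel_1d(sigma)
  out <- conv_sep_replicate(grid_values(img), k, k)
  if (inherits(img, "pixel_grid")) rewrap(out, img) else out
}

#' Butterworth high-pass frequency filter
#'
#' Multiplies the centred image spectrum by
#' `H = 1 / (1 + (D0 / D)^(2n))` with `D` the distance to the spectrum
#' centre, removing low-frequency content (cell interiors, uneven
#' illumination) so that only the fine membrane/ridge structure remains.
#' `H(D0) = 0.5`, `H -> 1` far from the centre and `H(0) = 0` (DC removed).
#'
#' @param img `pixel_grid` or matrix.
#' @param n filter order (default 1).
#' @param D0 cutoff frequency in frequency-pixels (default 3).
#' @return Filtered image (real part of the inverse transform), same carrier
#'   as the input.
#' @export
butterworth_highpass <- function(img, n = 1, D0 = 3) {
  m <- grid_values(img)
  H <- butterworth_transfer(nrow(m), ncol(m), n = n, D0 = D0)
  f <- fftshift2(stats::fft(m))
  out <- Re(stats::fft(fftshift2(f * H, inverse = TRUE), inverse = TRUE)) /
    length(m)
  if (inherits(img, "pixel_grid")) rewrap(out, img) else out
}

# High-pass transfer function on an nr x nc grid centred on the spectrum
# centre (the fftshifted DC bin).
butterworth_transfer <- function(nr, nc, n = 1, D0 = 3) {
  cy <- floor(nr / 2) + 1  # fftshifted DC position
  cx <- floor(nc / 2) + 1
  y <- seq_len(nr) - cy
  x <- seq_len(nc) - cx
  D <- sqrt(outer(y^2, x^2, `+`))
  H <- 1 / (1 + (D0 / D)^(2 * n))
  H[D == 0] <- 0
  H
}

#' Binarize and close membrane gaps
#'
#' Otsu-thresholds a high-passed frame and applies morphological closing
#' with a disk structuring element to seal small gaps in the cell membrane
#' lattice so every cell becomes an enclosed region.
#'
#' @param img_hp high-passed image (`pixel_grid` or matrix).
#' @param close_radius disk radius in pixels (default 2; 0 skips closing).
#' @return Binary membrane mask (matrix of 0/1).
#' @export
close_membranes <- function(img_hp, close_radius = 2) {
  m <- grid_values(img_hp)
  m01 <- (m - min(m)) / max(max(m) - min(m), .Machine$double.eps)
  thr <- EBImage::otsu(EBImage::Image(m01), range = c(0, 1))
  bin <- m01 > thr
  if (!any(bin)) stop("binarization produced an all-background image")
  if (close_radius > 0) {
    kern <- EBImage::makeBrush(2 * close_radius + 1, shape = "disc")
    bin <- EBImage::closing(EBImage::Image(bin * 1), kern) > 0.5
  }
  bin * 1
}

#' Extract single patterned cells from a membrane mask
#'
#' Complements the membrane mask, labels the enclosed regions, drops
#' regions that touch the image border or fail the area/solidity cutoffs,
#' and for each surviving cell computes region properties and the extracted
#' patterned image: the bounding-box crop of the grayscale frame multiplied
#' elementwise by the cell's convex mask (zero outside the cell).
#'
#' @param membrane_mask binary mask from [close_membranes()].
#' @param gray_img grayscale frame (`pixel_grid` or matrix) the cells are
#'   cut from, typically the Gaussian-smoothed projection.
#' @param min_area minimum region area in pixels^2.
#' @param min_solidity minimum solidity (region area / convex hull area).
#' @return List of `cell_region` objects with fields `area`, `solidity`,
#'   `bbox` (x, y, w, h in pixels, 0-based corner), `convex_image`,
#'   `centroid` (x, y in pixels, 0-based), `patterned_image` (`pixel_grid`).
#'   Empty list (with a warning) when no cell survives.
#' @export
extract_cells <- function(membrane_mask, gray_img, min_area = 0,
                          min_solidity = 0) {
  mm <- grid_values(membrane_mask) != 0
  gray <- grid_values(gray_img)
  stopifnot(all(dim(mm) == dim(gray)))
  interior <- !mm                      # imcomplement
  lab <- EBImage::bwlabel(EBImage::Image(interior * 1))
  lab <- matrix(as.integer(lab), nrow(mm), ncol(mm))
  nlab <- max(lab)
  nr <- nrow(mm); nc <- ncol(mm)
  border_labels <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
  out <- list()
  for (id in seq_len(nlab)) {
    if (id %in% border_labels) next
    idx <- which(lab == id)
    area <- length(idx)
    if (area < min_area) next
    rows <- ((idx - 1L) %% nr) + 1L
    cols <- ((idx - 1L) %/% nr) + 1L
    r0 <- min(rows); r1 <- max(rows); c0 <- min(cols); c1 <- max(cols)
    # convex image on the bounding box (pixel-centre point-in-hull test)
    pts <- cbind(cols, rows)
    hull <- grDevices::chull(pts)
    hx <- pts[hull, 1]; hy <- pts[hull, 2]
    bw <- c1 - c0 + 1L; bh <- r1 - r0 + 1L
    gx <- rep(c0:c1, each = bh); gy <- rep(r0:r1, times = bw)
    if (length(hull) >= 3) {
      inp <- pracma::inpolygon(gx, gy, hx, hy, boundary = TRUE)
    } else {
      inp <- rep(FALSE, length(gx))
      inp[match(idx, (gx - 1L) * nr + gy)] <- TRUE
    }
    convex <- matrix(inp * 1, bh, bw)
    # make sure every region pixel is inside its convex image
    convex[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- 1
    solidity <- area / sum(convex)
    if (solidity < min_solidity) next
    crop <- gray[r0:r1, c0:c1, drop = FALSE]
    patterned <- crop * convex
    out[[length(out) + 1]] <- structure(list(
      label = id,
      area = area,
      solidity = solidity,
      bbox = c(x = c0 - 1L, y = r0 - 1L, w = bw, h = bh),
      convex_image = convex,
      centroid = c(x = mean(cols) - 1, y = mean(rows) - 1),
      patterned_image = pixel_grid(patterned, grid_dx(gray_img),
                                   grid_dy(gray_img))
    ), class = "cell_region")
  }
  if (length(out) == 0) warning("no cell survived the area/solidity cutoffs")
  out
}

#' @export
print.cell_region <- function(x, ...) {
  cat(sprintf(
    "<cell_region> area %d px^2, solidity %.3f, centroid (%.1f, %.1f) px\n",
    x$area, x$solidity, x$centroid[1], x$centroid[2]))
  invisible(x)
}
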