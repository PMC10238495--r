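#' 2D scalar field with physical pixel sizes
#'
#' The universal image carrier of the package. Values are stored as a numeric
#' matrix with the image convention that rows run along y and columns along x;
#' the origin (0, 0) sits at the top-left pixel centre, so a pixel at row `i`,
#' column `j` has physical coordinates `x = (j - 1) * dx`, `y = (i - 1) * dy`
#' in micrometres.
#'
#' @param values numeric matrix of pixel values.
#' @param dx,dy physical pixel size in micrometres (> 0).
#' @return An object of class `pixel_grid`: a list with elements `values`,
#'   `dx`, `dy`.
#' @examples
#' g <- pixel_grid(matrix(runif(64), 8, 8), dx = 0.1977, dy = 0.1977)
#' dim(g)
#' @export
pixel_grid <- function(values, dx = 1, dy = dx) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) stop("pixel_grid values must be finite")
  if (!is.numeric(dx) || !is.numeric(dy) || dx <= 0 || dy <= 0)
    stop("pixel sizes dx, dy must be positive")
  structure(list(values = values, dx = as.numeric(dx), dy = as.numeric(dy)),
            class = "pixel_grid")
}

#' @export
dim.pixel_grid <- function(x) dim(x$values)

#' @export
print.pixel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<pixel_grid> %d x %d px, dx = %g um, dy = %g um, range [%g, %g]\n",
              d[1], d[2], x$dx, x$dy, min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.matrix.pixel_grid <- function(x, ...) x$values

# Accept either a pixel_grid or a bare matrix; return the matrix.
grid_values <- function(img) {
  if (inherits(img, "pixel_grid")) img$values else {
    m <- as.matrix(img)
    storage.mode(m) <- "double"
    m
  }
}

# Pixel sizes of an image-like object (matrix defaults to 1 um).
grid_dx <- function(img) if (inherits(img, "pixel_grid")) img$dx else 1
grid_dy <- function(img) if (inherits(img, "pixel_grid")) img$dy else 1

# Re-wrap a matrix with the pixel sizes of a template image.
rewrap <- function(values, template) {
  pixel_grid(values, dx = grid_dx(template), dy = grid_dy(template))
}

# --- small numeric helpers shared across modules ---------------------------

# Replicate-pad a matrix by `k` pixels on every side.
pad_replicate <- function(m, k) {
  if (k == 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rep(1L, k), seq_len(nr), rep(nr, k))
  ci <- c(rep(1L, k), seq_len(nc), rep(nc, k))
  m[ri, ci, drop = FALSE]
}

# 2D correlation with replicate border handling; kernel must be odd-sized.
# Implemented as a sum of shifted copies so small kernels stay cheap and the
# border rule is exact.
conv2_replicate <- function(m, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  stopifnot(kr %% 2 == 1, kc %% 2 == 1)
  hr <- (kr - 1L) %/% 2L; hc <- (kc - 1L) %/% 2L
  k <- max(hr, hc)
  p <- pad_replicate(m, k)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(kr)) {
    di <- i - 1L - hr
    for (j in seq_len(kc)) {
      w <- kernel[i, j]
      if (w == 0) next
      dj <- j - 1L - hc
      out <- out + w * p[(k + 1 + di):(k + nr + di), (k + 1 + dj):(k + nc + dj)]
    }
  }
  out
}

# Separable correlation with two 1D kernels (rows = y, cols = x).
conv_sep_replicate <- function(m, ky, kx) {
  conv2_replicate(conv2_replicate(m, matrix(ky, ncol = 1)), matrix(kx, nrow = 1))
}

# Sampled, renormalized 1D Gaussian kernel (unit sum).
gauss_kernel_1d <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Sampled derivative-of-Gaussian kernel, normalized so the response to a unit
# ramp is exactly 1 (first moment -1 under correlation).
dog_kernel_1d <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  k <- -x * g
  k / sum(-x * k) * -1
}

# fftshift for matrices: forward moves the DC bin to position
# floor(n/2) + 1 on each axis; inverse undoes it (they differ for odd sizes).
fftshift2 <- function(m, inverse = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  sr <- if (inverse) floor(nr / 2) else ceiling(nr / 2)
  sc <- if (inverse) floor(nc / 2) else ceiling(nc / 2)
  ri <- c(seq(sr + 1, nr), seq_len(sr))
  ci <- c(seq(sc + 1, nc), seq_len(sc))
  m[ri, ci, drop = FALSE]
}

# Central finite differences with physical spacing; one-sided at borders.
# Returns the derivative of `m` along columns (x) or rows (y).
finite_diff <- function(m, spacing, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (axis == "y") return(t(finite_diff(t(m), spacing, "x")))
  nc <- ncol(m)
  if (nc < 2) return(matrix(0, nrow(m), nc))
  out <- matrix(0, nrow(m), nc)
  if (nc > 2)
    out[, 2:(nc - 1)] <- (m[, 3:nc] - m[, 1:(nc - 2)]) / (2 * spacing)
  out[, 1] <- (m[, 2] - m[, 1]) / spacing
  out[, nc] <- (m[, nc] - m[, nc - 1]) / spacing
  out
}

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
# Generators use this so every fixture is reproducible and adding one
# generator call never perturbs another.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
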