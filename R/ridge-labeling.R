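#' Derivative-of-Gaussian image gradient
#'
#' Gradient of an image by correlation with the first derivative of a
#' Gaussian, applied separably (derivative kernel along the gradient axis,
#' smoothing Gaussian along the other). Kernels are normalized so a unit
#' intensity ramp yields a unit gradient.
#'
#' @param img `pixel_grid` or matrix.
#' @param sigma_g Gaussian scale in pixels (default 0.7).
#' @return List with matrices `gx` (derivative along columns/x) and `gy`
#'   (derivative along rows/y), in intensity per pixel.
#' @export
gauss_gradient <- function(img, sigma_g = 0.7) {
  if (sigma_g <= 0) stop("sigma_g must be positive")
  m <- grid_values(img)
  g <- gauss_kernel_1d(sigma_g)
  d <- dog_kernel_1d(sigma_g)
  list(gx = conv_sep_replicate(m, g, d),
       gy = conv_sep_replicate(m, d, g))
}

#' Rectified Laplacian of the Gauss-gradient image
#'
#' Second derivatives are obtained by applying the derivative-of-Gaussian
#' operator to the gradient components; their sum is the image Laplacian
#' (trace of the Hessian). Only non-positive values are retained - bright
#' ridge crests have negative Laplacian - and positive values are set to 0.
#'
#' @param gx,gy gradient components from [gauss_gradient()].
#' @param sigma_g Gaussian scale in pixels used for the second derivative
#'   (default 0.7, matching the gradient).
#' @return Matrix `L` with `L <= 0` everywhere.
#' @export
rectified_laplacian <- function(gx, gy, sigma_g = 0.7) {
  g <- gauss_kernel_1d(sigma_g)
  d <- dog_kernel_1d(sigma_g)
  lxx <- conv_sep_replicate(gx, g, d)   # d/dx of gx
  lyy <- conv_sep_replicate(gy, d, g)   # d/dy of gy
  la <- lxx + lyy
  ifelse(la <= 0, la, 0)
}

#' Logistic sigmoid mask of the rectified Laplacian
#'
#' `S = 1 / (1 + exp(-sqrt(|L|)))`, an elementwise squashing of the ridge
#' response into the range \[0.5, 1): background (L = 0) maps to 0.5 and
#' stronger crests monotonically approach 1.
#'
#' @param L rectified Laplacian from [rectified_laplacian()].
#' @return Matrix `S` in \[0.5, 1).
#' @export
sigmoid_mask <- function(L) {
  1 / (1 + exp(-sqrt(abs(L))))
}

#' Conventional microridge labeling
#'
#' The classical (non-learning) microridge segmentation used to create
#' training labels: Gaussian smoothing (sigma 0.7 px), derivative-of-Gaussian
#' gradient, rectified Laplacian, logistic sigmoid, then Otsu binarization
#' of the sigmoid response.
#'
#' @param patterned_image extracted single-cell image (`pixel_grid` or
#'   matrix).
#' @param sigma smoothing scale in pixels (default 0.7).
#' @param sigma_g gradient scale in pixels (default 0.7).
#' @return An object of class `labeled_pair`: list with `gray` (the smoothed
#'   image as `pixel_grid`) and `label` (binary matrix `B`).
#' @export
label_cell <- function(patterned_image, sigma = 0.7, sigma_g = 0.7) {
  sm <- gaussian_smooth(patterned_image, sigma = sigma)
  smv <- grid_values(sm)
  gr <- gauss_gradient(smv, sigma_g = sigma_g)
  L <- rectified_laplacian(gr$gx, gr$gy, sigma_g = sigma_g)
  S <- sigmoid_mask(L)
  if (all(L == 0)) {
    warning("no ridge response; returning an all-zero label")
    B <- matrix(0, nrow(smv), ncol(smv))
  } else {
    s01 <- (S - 0.5) / 0.5   # map [0.5, 1) onto [0, 1) for Otsu
    thr <- EBImage::otsu(EBImage::Image(s01), range = c(0, 1))
    B <- (s01 > thr) * 1
  }
  structure(list(
    gray = if (inherits(patterned_image, "pixel_grid")) rewrap(smv, patterned_image)
           else pixel_grid(smv),
    label = B), class = "labeled_pair")
}

#' @export
print.labeled_pair <- function(x, ...) {
  cat(sprintf("<labeled_pair> %d x %d px, %.1f%% foreground\n",
              nrow(x$label), ncol(x$label), 100 * mean(x$label)))
  invisible(x)
}
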