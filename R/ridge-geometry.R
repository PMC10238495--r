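#' Trace skeleton branches endpoint to endpoint
#'
#' Skeletonizes a binary ridge mask, removes branch points, and walks every
#' remaining simple branch from one endpoint to the other, returning ordered
#' physical coordinates. Branches with fewer than `min_points` pixels or
#' without exactly two endpoints (loops) are skipped; the number of skipped
#' loops is reported as an attribute.
#'
#' @param ridge_mask binary matrix or `pixel_grid`.
#' @param dx,dy pixel sizes in micrometres (taken from the `pixel_grid` when
#'   one is supplied).
#' @param min_points minimum number of skeleton points per branch
#'   (default 10; shorter contours make the curvature fit unreliable).
#' @return List of `contour_trace` objects (`coords`: n x 2 matrix of x, y
#'   in micrometres; `branch_id`), with attribute `n_loops_skipped`.
#' @export
trace_branches <- function(ridge_mask, dx = NULL, dy = NULL, min_points = 10) {
  if (is.null(dx)) dx <- grid_dx(ridge_mask)
  if (is.null(dy)) dy <- grid_dy(ridge_mask)
  skel <- skeletonize(ridge_mask)
  skel[branch_points(skel)] <- 0L
  lab <- label8(skel)
  out <- list()
  loops <- 0L
  for (id in seq_len(max(lab))) {
    comp <- (lab == id) * 1L
    if (sum(comp) < min_points) next
    eps <- endpoints_of(comp)
    if (length(eps) != 2) { if (length(eps) == 0) loops <- loops + 1L; next }
    path <- walk_path(comp, min(eps))
    coords <- cbind(x = (path[, "col"] - 1) * dx, y = (path[, "row"] - 1) * dy)
    out[[length(out) + 1]] <- structure(
      list(coords = coords, branch_id = length(out) + 1L),
      class = "contour_trace")
  }
  attr(out, "n_loops_skipped") <- loops
  out
}

#' Orientation-robust Gaussian smoothing of a skeleton trace
#'
#' Smooths the ordered trace coordinates with a Gaussian-weighted moving
#' window in each of `n_angles` rotated frames spanning \[-pi, pi\], and
#' keeps the rotation whose smoothed curve (rotated back) lies closest to
#' the raw trace in mean standardized Euclidean distance. The rotation scan
#' makes the point-wise smoothing independent of how the ridge happens to be
#' oriented in the image.
#'
#' @param coords n x 2 matrix of ordered (x, y) coordinates, or a
#'   `contour_trace`.
#' @param n_angles number of rotation angles (default 21).
#' @param window moving window length in points (odd, default 5).
#' @param sigma_pts Gaussian weight scale in points (default 1).
#' @return n x 2 matrix of smoothed coordinates in the original frame.
#' @export
orient_and_smooth <- function(coords, n_angles = 21, window = 5,
                              sigma_pts = 1) {
  if (inherits(coords, "contour_trace")) coords <- coords$coords
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < window) return(coords)
  sdx <- stats::sd(coords[, 1]); sdy <- stats::sd(coords[, 2])
  if (!is.finite(sdx) || sdx < 1e-12) sdx <- 1
  if (!is.finite(sdy) || sdy < 1e-12) sdy <- 1
  w <- gauss_kernel_1d(sigma_pts, radius = (window - 1) %/% 2)
  smooth1 <- function(v) {
    out <- as.vector(stats::filter(v, w, sides = 2))
    # renormalized truncated window at the ends
    h <- (window - 1) %/% 2
    for (i in which(is.na(out))) {
      lo <- max(1, i - h); hi <- min(n, i + h)
      ww <- w[(lo - i + h + 1):(hi - i + h + 1)]
      out[i] <- sum(v[lo:hi] * ww) / sum(ww)
    }
    out
  }
  angles <- seq(-pi, pi, length.out = n_angles)
  best <- NULL; best_d <- Inf
  for (th in angles) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    rot <- coords %*% R
    sm <- cbind(smooth1(rot[, 1]), smooth1(rot[, 2]))
    back <- sm %*% t(R)
    d <- mean(sqrt(((back[, 1] - coords[, 1]) / sdx)^2 +
                     ((back[, 2] - coords[, 2]) / sdy)^2))
    if (d < best_d - 1e-15) { best_d <- d; best <- back }
  }
  best
}

#' Parametric natural cubic spline through ordered points
#'
#' Interpolates the trace with a natural cubic spline parameterized by
#' cumulative chord length, preserving the sequence of points, and samples
#' it `factor` times more densely. All input points are interpolated
#' exactly; repeated consecutive points are deduplicated first.
#'
#' @param coords n x 2 matrix of ordered coordinates (n >= 4 after
#'   deduplication).
#' @param factor density multiplier (default 10).
#' @return Dense m x 2 coordinate matrix containing the input points.
#' @export
spline_interpolate <- function(coords, factor = 10) {
  coords <- as.matrix(coords)
  keep <- c(TRUE, rowSums(abs(diff(coords))) > 0)
  coords <- coords[keep, , drop = FALSE]
  n <- nrow(coords)
  if (n < 4) stop("need at least 4 distinct points for spline interpolation")
  tt <- c(0, cumsum(sqrt(rowSums(diff(coords)^2))))
  fx <- stats::splinefun(tt, coords[, 1], method = "natural")
  fy <- stats::splinefun(tt, coords[, 2], method = "natural")
  td <- unlist(lapply(seq_len(n - 1), function(k) {
    seq(tt[k], tt[k + 1], length.out = factor + 1)[-(factor + 1)]
  }))
  td <- c(td, tt[n])
  cbind(x = fx(td), y = fy(td))
}

#' Discrete curvature series of a contour
#'
#' From ordered (x, y) coordinates computes the per-segment spacings, the
#' four-quadrant tangent angles, the total arc length, the turn angles
#' between consecutive tangents (wrapped to (-pi, pi\]), the curvature
#' `kappa = 2 phi / (ds_prev + ds_next)` and the rescaled curvature
#' `kappa_s = 2 phi / sqrt(ds_prev + ds_next)`, whose pooled distribution
#' width yields the persistence length.
#'
#' @param coords n x 2 coordinate matrix in micrometres (n >= 3).
#' @return An object of class `curvature_series` with fields `ds`, `theta`,
#'   `L`, `phi`, `kappa`, `kappa_s`.
#' @export
curvature_series <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3) stop("need at least 3 points")
  d <- diff(coords)
  ds <- sqrt(rowSums(d^2))
  if (any(ds == 0)) stop("zero-length segment in contour")
  theta <- atan2(d[, 2], d[, 1])
  n_seg <- length(ds)
  phi <- theta[seq_len(n_seg - 1)] - theta[seq_len(n_seg - 1) + 1]
  phi <- phi - 2 * pi * ceiling((phi - pi) / (2 * pi))   # wrap to (-pi, pi]
  pair <- ds[seq_len(n_seg - 1)] + ds[seq_len(n_seg - 1) + 1]
  structure(list(ds = ds, theta = theta, L = sum(ds), phi = phi,
                 kappa = 2 * phi / pair, kappa_s = 2 * phi / sqrt(pair)),
            class = "curvature_series")
}

#' Persistence length from a pooled rescaled-curvature distribution
#'
#' The rescaled curvature of a 2D worm-like chain in equilibrium is
#' zero-mean Gaussian with density
#' `P(kappa_s) = sqrt(Lp / 4 pi) exp(-Lp kappa_s^2 / 4)`, i.e. variance
#' `2 / Lp`. Both a moment estimate (`Lp = 2 / var`) and a least-squares
#' Gaussian fit to the histogram are computed; the fit is reported as the
#' headline value with the moment estimator as fallback. Flexural rigidity
#' follows as `EI = Lp * kB * T`.
#'
#' @param kappa_s_pool numeric vector of pooled rescaled curvatures
#'   (micrometre^-1/2), typically concatenated over many branches and cells.
#' @param temperature absolute temperature in Kelvin (default 300).
#' @return An object of class `lp_estimate`: `lp` (micrometres),
#'   `lp_moment`, `lp_fit` (NA if the fit failed), `ei` (N m^2), `kB`,
#'   `temperature`, `n_segments`.
#' @export
fit_lp <- function(kappa_s_pool, temperature = 300) {
  ks <- as.numeric(kappa_s_pool)
  ks <- ks[is.finite(ks)]
  n <- length(ks)
  if (n < 100) warning("fewer than 100 curvature samples; estimate unstable")
  sigma2 <- mean(ks^2)
  lp_moment <- 2 / sigma2
  lp_fit <- NA_real_
  fit <- try({
    nb <- min(200L, max(30L, grDevices::nclass.FD(ks)))
    h <- graphics::hist(ks, breaks = nb, plot = FALSE)
    df <- data.frame(x = h$mids, y = h$density)
    m <- stats::nls(y ~ sqrt(lp / (4 * pi)) * exp(-lp * x^2 / 4), data = df,
                    start = list(lp = lp_moment),
                    control = stats::nls.control(warnOnly = TRUE))
    stats::coef(m)[["lp"]]
  }, silent = TRUE)
  if (!inherits(fit, "try-error") && is.finite(fit) && fit > 0) lp_fit <- fit
  lp <- if (is.finite(lp_fit)) lp_fit else lp_moment
  kB <- 1.380649e-23
  structure(list(lp = lp, lp_moment = lp_moment, lp_fit = lp_fit,
                 ei = lp * 1e-6 * kB * temperature, kB = kB,
                 temperature = temperature, n_segments = n),
            class = "lp_estimate")
}

#' @export
print.lp_estimate <- function(x, ...) {
  cat(sprintf(
    "<lp_estimate> Lp = %.3g um (moment %.3g, fit %s), EI = %.3g N m^2, n = %d\n",
    x$lp, x$lp_moment,
    if (is.finite(x$lp_fit)) sprintf("%.3g", x$lp_fit) else "failed",
    x$ei, x$n_segments))
  invisible(x)
}

#' Critical Euler buckling force of a ridge segment
#'
#' `f_c = pi^2 kB T Lp / L^2`: the compressive load above which a filament
#' of persistence length `Lp` and length `L` buckles.
#'
#' @param lp persistence length in micrometres.
#' @param length filament length in micrometres.
#' @param temperature absolute temperature in Kelvin (default 300).
#' @return Critical force in piconewtons.
#' @examples
#' critical_force(6.1, 1)   # ~0.25 pN
#' critical_force(17, 1)    # ~0.69 pN
#' @export
critical_force <- function(lp, length, temperature = 300) {
  if (lp <= 0 || length <= 0) stop("lp and length must be positive")
  kB <- 1.380649e-23
  fc_N <- pi^2 * kB * temperature * (lp * 1e-6) / (length * 1e-6)^2
  fc_N * 1e12
}

#' Full persistence-length pipeline on a ridge mask
#'
#' Traces skeleton branches, applies orientation-robust smoothing and
#' spline interpolation to each, pools the rescaled curvatures and fits the
#' persistence length.
#'
#' @param ridge_mask binary mask or `pixel_grid`.
#' @param dx,dy pixel sizes (micrometres).
#' @param spline_factor spline densification factor (default 10).
#' @param temperature Kelvin (default 300).
#' @param min_points minimum points per branch (default 10).
#' @return `lp_estimate` with an extra field `n_branches`.
#' @export
estimate_lp_from_mask <- function(ridge_mask, dx = NULL, dy = NULL,
                                  spline_factor = 10, temperature = 300,
                                  min_points = 10) {
  traces <- trace_branches(ridge_mask, dx = dx, dy = dy,
                           min_points = min_points)
  pool <- unlist(lapply(traces, function(tr) {
    sm <- orient_and_smooth(tr$coords)
    dense <- try(spline_interpolate(sm, factor = spline_factor), silent = TRUE)
    if (inherits(dense, "try-error")) return(numeric(0))
    curvature_series(dense)$kappa_s
  }))
  est <- fit_lp(pool, temperature = temperature)
  est$n_branches <- length(traces)
  est
}
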