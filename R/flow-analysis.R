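#' Lucas-Kanade optic flow with derivative-of-Gaussian gradients
#'
#' Estimates the per-pixel velocity between two registered frames by the
#' local least-squares solution of the brightness-constancy constraint
#' `dI/dt = -v . grad(I)` over a square window. Spatial gradients use
#' derivative-of-Gaussian kernels; pixels whose local normal system is
#' rank-deficient get zero velocity and are flagged.
#'
#' @param frame_t,frame_t1 consecutive frames (`pixel_grid` or matrix);
#'   shapes must match.
#' @param dt frame interval in minutes.
#' @param window odd window size in pixels (default 5).
#' @param sigma derivative-of-Gaussian scale in pixels (default 1.5).
#' @param det_tol relative tolerance below which the local system counts as
#'   rank-deficient.
#' @return An object of class `velocity_field`: `vx`, `vy` (matrices,
#'   micrometres/min), `dt`, `dx`, `dy`, `rank_deficient` (logical matrix).
#' @export
optic_flow <- function(frame_t, frame_t1, dt, window = 5, sigma = 1.5,
                       det_tol = 1e-9) {
  a <- grid_values(frame_t); b <- grid_values(frame_t1)
  stopifnot(all(dim(a) == dim(b)))
  dx <- grid_dx(frame_t); dy <- grid_dy(frame_t)
  g <- gauss_kernel_1d(sigma); d <- dog_kernel_1d(sigma)
  mid <- (a + b) / 2
  ix <- conv_sep_replicate(mid, g, d)    # intensity per pixel along x
  iy <- conv_sep_replicate(mid, d, g)
  # temporal derivative at the same Gaussian scale as the spatial gradients,
  # so the smoothing bias cancels in the least-squares ratio
  it <- conv_sep_replicate(b - a, g, g)  # intensity per frame
  ones <- matrix(1, window, window)
  sxx <- conv2_replicate(ix * ix, ones)
  sxy <- conv2_replicate(ix * iy, ones)
  syy <- conv2_replicate(iy * iy, ones)
  sxt <- conv2_replicate(ix * it, ones)
  syt <- conv2_replicate(iy * it, ones)
  det <- sxx * syy - sxy^2
  scale <- max(det, na.rm = TRUE)
  bad <- det <= det_tol * max(scale, .Machine$double.eps)
  det[bad] <- 1
  u <- (-syy * sxt + sxy * syt) / det    # px per frame
  v <- (sxy * sxt - sxx * syt) / det
  u[bad] <- 0; v[bad] <- 0
  structure(list(vx = u * dx / dt, vy = v * dy / dt, dt = dt,
                 dx = dx, dy = dy, rank_deficient = bad),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("<velocity_field> %d x %d px, median speed %.3g um/min\n",
              nrow(x$vx), ncol(x$vx), stats::median(sqrt(x$vx^2 + x$vy^2))))
  invisible(x)
}

#' Box-smooth a velocity field
#'
#' Convolves each velocity component with the 3 x 3 mean kernel
#' (`1/9` times the ones matrix, replicate borders) to suppress low-level
#' estimation noise before differentiation. Box averaging preserves affine
#' velocity fields exactly, so repeated passes reduce estimator noise in the
#' derivatives without biasing linear flow; pass several `passes` when the
#' divergence or strain rates are the quantity of interest.
#'
#' @param field `velocity_field`.
#' @param passes number of smoothing passes (default 1).
#' @return Smoothed `velocity_field`.
#' @export
smooth_field <- function(field, passes = 1) {
  k <- matrix(1 / 9, 3, 3)
  for (i in seq_len(passes)) {
    field$vx <- conv2_replicate(field$vx, k)
    field$vy <- conv2_replicate(field$vy, k)
  }
  field
}

#' Divergence of a velocity field
#'
#' `div = dvx/dx + dvy/dy` by central finite differences with physical
#' spacing (one-sided at the borders). Positive divergence marks local
#' outflow (ridge fragmentation/shrinkage), negative marks inflow
#' (elongation/merging).
#'
#' @param vel `velocity_field` (typically smoothed).
#' @return Matrix of divergences in 1/min.
#' @export
divergence <- function(vel) {
  finite_diff(vel$vx, vel$dx, "x") + finite_diff(vel$vy, vel$dy, "y")
}

#' Growth and shrinkage event velocities
#'
#' Pixels with `div < -threshold` are growth events (inflow: elongation or
#' merging), pixels with `div > threshold` are shrinkage events (outflow:
#' fragmentation or splitting); the mean velocity magnitude over each set
#' is reported.
#'
#' @param vel `velocity_field`.
#' @param div divergence matrix from [divergence()].
#' @param threshold divergence magnitude threshold in 1/min (default 0.12).
#' @return An object of class `flow_event_stats`: `v_growth`, `v_shrinkage`
#'   (um/min, `NA` when the set is empty), `n_growth_px`, `n_shrink_px`,
#'   `div_threshold`.
#' @export
event_velocities <- function(vel, div, threshold = 0.12) {
  speed <- sqrt(vel$vx^2 + vel$vy^2)
  growth <- div < -threshold
  shrink <- div > threshold
  structure(list(
    v_growth = if (any(growth)) mean(speed[growth]) else NA_real_,
    v_shrinkage = if (any(shrink)) mean(speed[shrink]) else NA_real_,
    n_growth_px = sum(growth), n_shrink_px = sum(shrink),
    div_threshold = threshold), class = "flow_event_stats")
}

#' Strain-rate tensor of a velocity field
#'
#' Per-pixel velocity gradient by central differences; the symmetric part
#' `S = (V + V^T) / 2` is kept (the antisymmetric, rotational part is
#' discarded). Reports the shear rate `gammaS` (the off-diagonal of `S`),
#' the ordered eigenvalues `Lam1 >= Lam2` (tensile/compressive rates), the
#' divergence (`tr S`) and the principal-strain magnitude `sqrt(2) ||S||_F`.
#'
#' @param vel `velocity_field` (typically smoothed).
#' @return An object of class `strain_field` with matrices `sxx`, `sxy`,
#'   `syy`, `gammaS`, `Lam1`, `Lam2`, `div`, `principal_mag`, plus `dx`,
#'   `dy`.
#' @export
strain_tensor <- function(vel) {
  dvx_dx <- finite_diff(vel$vx, vel$dx, "x")
  dvx_dy <- finite_diff(vel$vx, vel$dy, "y")
  dvy_dx <- finite_diff(vel$vy, vel$dx, "x")
  dvy_dy <- finite_diff(vel$vy, vel$dy, "y")
  sxy <- (dvx_dy + dvy_dx) / 2
  mean_s <- (dvx_dx + dvy_dy) / 2
  r <- sqrt(((dvx_dx - dvy_dy) / 2)^2 + sxy^2)
  structure(list(
    sxx = dvx_dx, sxy = sxy, syy = dvy_dy, gammaS = sxy,
    Lam1 = mean_s + r, Lam2 = mean_s - r,
    div = dvx_dx + dvy_dy,
    principal_mag = sqrt(2) * sqrt(dvx_dx^2 + 2 * sxy^2 + dvy_dy^2),
    dx = vel$dx, dy = vel$dy), class = "strain_field")
}

#' Area-deviatoric decomposition of the strain-rate tensor
#'
#' Splits `S` into the area-changing, shape-preserving part
#' `S_area = tr(S)/2 * I` and the traceless, shape-changing part
#' `S_dev = S - S_area`, whose eigenvalues `+/- r` are the deviatoric
#' elongation and shrinkage rates.
#'
#' @param S `strain_field` from [strain_tensor()].
#' @return The input `strain_field` augmented with `s_area` (the common
#'   diagonal of `S_area`), `sdev_xx`, `sdev_xy`, `sdev_yy`, `lam1_dev`,
#'   `lam2_dev`.
#' @export
area_deviatoric_split <- function(S) {
  half_tr <- (S$sxx + S$syy) / 2
  S$s_area <- half_tr
  S$sdev_xx <- S$sxx - half_tr
  S$sdev_yy <- S$syy - half_tr
  S$sdev_xy <- S$sxy
  r <- sqrt(S$sdev_xx^2 + S$sdev_xy^2)
  S$lam1_dev <- r
  S$lam2_dev <- -r
  S
}

#' Spatially and temporally averaged principal-strain magnitude
#'
#' For each frame, averages `sqrt(2) ||S||_F` over ridge pixels with
#' non-zero divergence, then averages over frames; the per-frame series is
#' also returned. This is the summary statistic used to compare stored
#' mechanical stresses between cell populations.
#'
#' @param strain_fields list of `strain_field`s (one per frame pair).
#' @param ridge_masks list of binary masks aligned to the frames.
#' @param div_tol divergences with magnitude at or below this count as zero.
#' @return List with `per_frame` (numeric vector, `NA` for frames with an
#'   empty mask) and `time_mean`.
#' @export
principal_strain_series <- function(strain_fields, ridge_masks,
                                    div_tol = 0) {
  per_frame <- mapply(function(S, mask) {
    m <- grid_values(mask) != 0
    sel <- m & (abs(S$div) > div_tol)
    if (!any(sel)) return(NA_real_)
    mean(S$principal_mag[sel])
  }, strain_fields, ridge_masks)
  list(per_frame = as.numeric(per_frame),
       time_mean = mean(per_frame, na.rm = TRUE))
}
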