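#' Characteristic pattern wavelength from the 2D Fourier spectrum
#'
#' Computes the characteristic wave number of a segmented (binary) ridge
#' pattern as the square root of the first moment of `|k|^2` against the
#' amplitude-normalized Fourier magnitude,
#' `wn = sqrt( sum dkx dky |k|^2 |I_f| / sqrt(sum dkx dky |I_f|) )`,
#' and the wavelength `lambda = 2 pi / wn`. The transform carries the
#' `1 / (2 pi)` prefactor and the physical measure `dx dy = ds^2`;
#' frequency axes span `[-K, K)` with `K = pi / ds`; integrals are Riemann
#' sums over the frequency grid with the DC bin excluded from both moments
#' (a constant offset carries no wavelength).
#'
#' @param binary_img binary (0/1) matrix or `pixel_grid`.
#' @param ds_edge pixel edge length in micrometres (taken from the
#'   `pixel_grid` when omitted).
#' @return An object of class `spectrum_summary`: `wn` (rad/um), `lambda`
#'   (um), `ds_edge`, `k_bound` (`pi / ds`).
#' @export
pattern_wavelength <- function(binary_img, ds_edge = NULL) {
  if (is.null(ds_edge)) ds_edge <- grid_dx(binary_img)
  m <- grid_values(binary_img)
  if (!all(m %in% c(0, 1))) stop("pattern_wavelength expects a binary image")
  if (all(m == 0)) stop("all-zero image has no pattern wavelength")
  nr <- nrow(m); nc <- ncol(m)
  If <- fftshift2(stats::fft(m)) * ds_edge^2 / (2 * pi)
  kx <- 2 * pi * (seq_len(nc) - 1 - floor(nc / 2)) / (nc * ds_edge)
  ky <- 2 * pi * (seq_len(nr) - 1 - floor(nr / 2)) / (nr * ds_edge)
  k2 <- outer(ky^2, kx^2, `+`)
  dk <- (2 * pi / (nc * ds_edge)) * (2 * pi / (nr * ds_edge))
  amp <- Mod(If)
  amp[floor(nr / 2) + 1, floor(nc / 2) + 1] <- 0   # exclude DC
  norm <- sqrt(sum(amp) * dk)
  wn <- sqrt(sum(k2 * amp / norm) * dk)
  structure(list(wn = wn, lambda = 2 * pi / wn, ds_edge = ds_edge,
                 k_bound = pi / ds_edge), class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf("<spectrum_summary> wn = %.4g rad/um, lambda = %.4g um\n",
              x$wn, x$lambda))
  invisible(x)
}

#' Skeleton branch-length statistics
#'
#' Skeletonizes a binary ridge pattern, removes branch points, and measures
#' each remaining branch as its pixel count times the pixel edge length.
#'
#' @param binary_img binary matrix or `pixel_grid`.
#' @param ds_edge pixel edge length in micrometres.
#' @param min_px branches shorter than this many pixels are dropped
#'   (default 1, i.e. keep all).
#' @return An object of class `branch_stats`: `branch_lengths` (um),
#'   `mean_branch_length` (um), `n_branches`.
#' @export
branch_stats <- function(binary_img, ds_edge = NULL, min_px = 1) {
  if (is.null(ds_edge)) ds_edge <- grid_dx(binary_img)
  skel <- skeletonize(binary_img)
  skel[branch_points(skel)] <- 0L
  lab <- label8(skel)
  if (max(lab) == 0)
    return(structure(list(branch_lengths = numeric(0),
                          mean_branch_length = NA_real_, n_branches = 0L),
                     class = "branch_stats"))
  counts <- tabulate(lab[lab > 0])
  counts <- counts[counts >= min_px]
  lens <- counts * ds_edge
  structure(list(branch_lengths = lens, mean_branch_length = mean(lens),
                 n_branches = length(lens)), class = "branch_stats")
}

#' @export
print.branch_stats <- function(x, ...) {
  cat(sprintf("<branch_stats> %d branches, mean length %.3g um\n",
              x$n_branches, x$mean_branch_length))
  invisible(x)
}
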