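#' Ridge components of a segmented frame
#'
#' Labels the 8-connected components of a binary ridge mask and collects,
#' per component, the pixel coordinates (micrometres), intensity readouts
#' and the intensity-weighted centroid — the detections consumed by ridge
#' tracking and intensity profiling.
#'
#' @param mask binary matrix or `pixel_grid` (e.g. the network-segmented
#'   `NB`).
#' @param intensity_img grayscale frame of the same shape; defaults to the
#'   mask itself (unit intensities).
#' @param dx,dy pixel sizes in micrometres.
#' @param min_px minimum component size in pixels.
#' @return List of `ridge_component` objects: `coords` (n x 2, x/y um),
#'   `intensity`, `centroid` (x, y um), `n_px`.
#' @export
ridge_components <- function(mask, intensity_img = NULL, dx = NULL, dy = NULL,
                             min_px = 2) {
  if (is.null(dx)) dx <- grid_dx(mask)
  if (is.null(dy)) dy <- grid_dy(mask)
  m <- grid_values(mask) != 0
  iv <- if (is.null(intensity_img)) m * 1 else grid_values(intensity_img)
  stopifnot(all(dim(iv) == dim(m)))
  lab <- label8(m)
  nr <- nrow(m)
  out <- list()
  for (id in seq_len(max(lab))) {
    idx <- which(lab == id)
    if (length(idx) < min_px) next
    rows <- ((idx - 1L) %% nr) + 1L
    cols <- ((idx - 1L) %/% nr) + 1L
    coords <- cbind(x = (cols - 1) * dx, y = (rows - 1) * dy)
    w <- iv[idx]
    wsum <- sum(w)
    cen <- if (wsum > 0) colSums(coords * w) / wsum else colMeans(coords)
    out[[length(out) + 1]] <- structure(
      list(coords = coords, intensity = w,
           centroid = c(x = unname(cen[1]), y = unname(cen[2])),
           n_px = length(idx), dx = dx, dy = dy),
      class = "ridge_component")
  }
  out
}

#' Track ridges across frames by linear assignment
#'
#' Frame-to-frame linkage of ridge components by minimum-total-cost
#' assignment on centroid distances, with links beyond `cutoff` forbidden
#' (track death/birth instead). The small cutoff keeps identities stable
#' through merge/split events of long ridges.
#'
#' @param per_frame_components list (per frame) of lists of
#'   `ridge_component`s from [ridge_components()].
#' @param cutoff maximum linking distance in micrometres (default 2.3).
#' @return List of `ridge_track` objects: `track_id`, `points` (data.frame
#'   `t`, `cell_id` = component index, `x_um`, `y_um`), and `components`
#'   (list of the linked `ridge_component`s in frame order).
#' @export
track_ridges <- function(per_frame_components, cutoff = 2.3) {
  centroids <- lapply(per_frame_components, function(comps) {
    if (length(comps) == 0) return(matrix(numeric(0), 0, 2))
    do.call(rbind, lapply(comps, function(cp) cp$centroid))
  })
  tracks <- track_cells(centroids, cutoff = cutoff)
  lapply(tracks, function(tr) {
    comps <- lapply(seq_len(nrow(tr$points)), function(k)
      per_frame_components[[tr$points$t[k]]][[tr$points$cell_id[k]]])
    structure(list(track_id = tr$track_id, points = tr$points,
                   components = comps), class = "ridge_track")
  })
}

#' Dominant axis of a ridge component
#'
#' Unit eigenvector, with the larger eigenvalue, of the intensity-weighted
#' covariance of the component's pixel coordinates: the direction along the
#' ridge length. The sign is fixed so `e1 >= 0` (and `e2 > 0` when
#' `e1 = 0`); a component with (near-)equal eigenvalues is flagged
#' isotropic and still returns a deterministic axis.
#'
#' @param component `ridge_component` (>= 2 pixels).
#' @return Numeric `c(e1, e2)` with unit norm and attribute `isotropic`.
#' @export
ridge_axis <- function(component) {
  coords <- component$coords
  if (nrow(coords) < 2) stop("component must have at least 2 pixels")
  w <- component$intensity
  if (sum(w) <= 0) w <- rep(1, nrow(coords))
  mu <- colSums(coords * w) / sum(w)
  cc <- sweep(coords, 2, mu)
  C <- crossprod(cc * sqrt(w / sum(w)))
  eg <- eigen(C, symmetric = TRUE)
  e <- eg$vectors[, 1]
  iso <- (eg$values[1] - eg$values[2]) <= 1e-12 * max(eg$values[1], 1e-300)
  if (e[1] < 0 || (e[1] == 0 && e[2] < 0)) e <- -e
  structure(c(e1 = e[1], e2 = e[2]), isotropic = iso)
}

#' 1D intensity profile along a ridge axis
#'
#' Projects every component pixel onto the dominant ridge axis
#' (`delta_l = (x_p, y_p) . (e1, e2)`), bins the projected coordinate at the
#' source pixel pitch and sums the intensity readouts per bin. Binning
#' conserves total intensity.
#'
#' @param component `ridge_component`.
#' @param bin bin width in micrometres (default: the component's pixel
#'   pitch `dx`).
#' @return An object of class `intensity_profile`: `delta_l` (bin centres,
#'   um), `I_p` (summed intensity per bin), `e1`, `e2`.
#' @export
intensity_profile <- function(component, bin = NULL) {
  if (is.null(bin)) bin <- component$dx
  e <- ridge_axis(component)
  delta <- as.numeric(component$coords %*% c(e[1], e[2]))
  idx <- round(delta / bin)
  agg <- tapply(component$intensity, idx, sum)
  structure(list(delta_l = as.numeric(names(agg)) * bin,
                 I_p = as.numeric(agg),
                 e1 = unname(e[1]), e2 = unname(e[2])),
            class = "intensity_profile")
}

#' Gaussian curvature of the intensity-as-height surface
#'
#' Treats the fluorescence intensity as a height `z(x, y)` over the
#' physical grid (Monge patch) and evaluates the Gaussian curvature
#' `K = (L N - M^2) / (E G - F^2)` from the first (`E = 1 + zx^2`,
#' `F = zx zy`, `G = 1 + zy^2`) and second
#' (`L = zxx / q`, `M = zxy / q`, `N = zyy / q`, `q = sqrt(1 + zx^2 + zy^2)`)
#' fundamental forms. Derivatives are derivative-of-Gaussian estimates at a
#' physical scale `sigma` (micrometres).
#'
#' @param intensity_img grayscale frame (`pixel_grid` or matrix).
#' @param dx,dy pixel sizes in micrometres.
#' @param sigma derivative scale in micrometres (default 1.2).
#' @param normalize rescale the image to \[0, 1\] before differentiating
#'   (default TRUE, the convention for fluorescence frames; set FALSE for
#'   calibrated height surfaces).
#' @return An object of class `curvature_map`: `K`, `E`, `F`, `G`, `Lf`,
#'   `Mf`, `Nf` matrices plus `sigma`.
#' @export
gaussian_curvature <- function(intensity_img, dx = NULL, dy = NULL,
                               sigma = 1.2, normalize = TRUE) {
  if (is.null(dx)) dx <- grid_dx(intensity_img)
  if (is.null(dy)) dy <- grid_dy(intensity_img)
  z <- grid_values(intensity_img)
  if (normalize) {
    rng <- range(z)
    if (rng[2] > rng[1]) z <- (z - rng[1]) / (rng[2] - rng[1])
  }
  gx <- gauss_kernel_1d(sigma / dx); dxk <- dog_kernel_1d(sigma / dx)
  gy <- gauss_kernel_1d(sigma / dy); dyk <- dog_kernel_1d(sigma / dy)
  zx <- conv_sep_replicate(z, gy, dxk) / dx
  zy <- conv_sep_replicate(z, dyk, gx) / dy
  zxx <- conv_sep_replicate(zx, gy, dxk) / dx
  zyy <- conv_sep_replicate(zy, dyk, gx) / dy
  zxy <- conv_sep_replicate(zx, dyk, gx) / dy
  E <- 1 + zx^2; Fm <- zx * zy; G <- 1 + zy^2
  q <- sqrt(1 + zx^2 + zy^2)
  Lf <- zxx / q; Mf <- zxy / q; Nf <- zyy / q
  structure(list(K = (Lf * Nf - Mf^2) / (E * G - Fm^2),
                 E = E, F = Fm, G = G, Lf = Lf, Mf = Mf, Nf = Nf,
                 sigma = sigma), class = "curvature_map")
}

#' Coincidence of curvature and divergence hot spots
#'
#' Compares the pixel sets of high positive / low negative Gaussian
#' curvature at frame `t` (`|K| > k_threshold`) with the sets of positive /
#' negative divergence for `t -> t + 1` (`|div| > div_threshold`), counting
#' the four pairwise overlaps per frame, plus the fraction of
#' above-threshold curvature pixels that are positive.
#'
#' @param K_maps list of curvature matrices (or `curvature_map`s), frame t.
#' @param div_maps list of divergence matrices, frame pair t -> t + 1;
#'   must align with `K_maps` in length and shape.
#' @param k_threshold curvature magnitude threshold (default 5).
#' @param div_threshold divergence magnitude threshold in 1/min
#'   (default 0.12).
#' @return data.frame with one row per frame: `frame`, `n_pos_k`,
#'   `n_neg_k`, `n_pos_d`, `n_neg_d`, overlap counts `pk_pd`, `pk_nd`,
#'   `nk_pd`, `nk_nd`, and `pos_k_fraction`.
#' @export
coincidence_analysis <- function(K_maps, div_maps, k_threshold = 5,
                                 div_threshold = 0.12) {
  stopifnot(length(K_maps) == length(div_maps))
  rows <- lapply(seq_along(K_maps), function(i) {
    K <- K_maps[[i]]
    if (inherits(K, "curvature_map")) K <- K$K
    D <- div_maps[[i]]
    if (!all(dim(K) == dim(D))) stop("K and divergence maps misaligned")
    pk <- K > k_threshold; nk <- K < -k_threshold
    pd <- D > div_threshold; nd <- D < -div_threshold
    data.frame(frame = i,
               n_pos_k = sum(pk), n_neg_k = sum(nk),
               n_pos_d = sum(pd), n_neg_d = sum(nd),
               pk_pd = sum(pk & pd), pk_nd = sum(pk & nd),
               nk_pd = sum(nk & pd), nk_nd = sum(nk & nd),
               pos_k_fraction = if (sum(pk) + sum(nk) > 0)
                 sum(pk) / (sum(pk) + sum(nk)) else NA_real_)
  })
  do.call(rbind, rows)
}
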