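mk_comp <- function(x, y, intensity = NULL, dx = 1) {
  coords <- cbind(x = x, y = y)
  if (is.null(intensity)) intensity <- rep(1, nrow(coords))
  cen <- colSums(coords * intensity) / sum(intensity)
  structure(list(coords = coords, intensity = intensity,
                 centroid = c(x = unname(cen[1]), y = unname(cen[2])),
                 n_px = nrow(coords), dx = dx, dy = dx),
            class = "ridge_component")
}

test_that("ridge tracking keeps identities at minimal total cost", {
  f1 <- list(mk_comp(0, 0), mk_comp(5, 0))
  # stationary ridges: identity assignment
  tr <- track_ridges(list(f1, f1), cutoff = 2.3)
  expect_length(tr, 2)
  expect_true(all(vapply(tr, function(t) nrow(t$points), numeric(1)) == 2))
  # a ridge displaced 3 um dies; a new track is born
  f2 <- list(mk_comp(3, 0))
  tr2 <- track_ridges(list(list(mk_comp(0, 0)), f2), cutoff = 2.3)
  expect_length(tr2, 2)
  # cost matrix [[1, 4], [4, 1]]: LAP keeps the diagonal
  g1 <- list(mk_comp(0, 0), mk_comp(0, 4))   # wait below for clarity
  g2 <- list(mk_comp(1, 0), mk_comp(0, 5))
  # distances: d(1,1)=1, d(1,2)=5.0..., d(2,1)=4.1.., d(2,2)=1
  tr3 <- track_ridges(list(g1, g2), cutoff = 2.3)
  linked <- Filter(function(t) nrow(t$points) == 2, tr3)
  expect_length(linked, 2)
  for (t in linked)
    expect_equal(t$points$cell_id[1], t$points$cell_id[2])
})

test_that("ridge components collect pixels, intensities and centroids", {
  m <- matrix(0, 12, 12)
  m[4, 3:8] <- 1          # one horizontal ridge
  m[9:10, 10] <- 1        # one small blob
  iv <- matrix(1, 12, 12); iv[4, 5] <- 3
  comps <- ridge_components(m, iv, dx = 0.5, dy = 0.5)
  expect_length(comps, 2)
  expect_equal(sum(comps[[1]]$intensity), 8)   # 6 px, one worth 3
  expect_equal(unname(comps[[1]]$centroid["y"]), 3 * 0.5)
})

test_that("the dominant ridge axis follows the component orientation", {
  hor <- mk_comp(0:10, rep(0, 11))
  expect_equal(as.numeric(ridge_axis(hor)), c(1, 0), tolerance = 1e-12)
  diag45 <- mk_comp(0:10, 0:10)
  expect_equal(as.numeric(ridge_axis(diag45)), c(sqrt(2) / 2, sqrt(2) / 2),
               tolerance = 1e-12)
  # rotation equivariance (mod sign)
  set.seed(7)
  x <- cumsum(runif(20)); y <- 0.2 * x + rnorm(20, sd = 0.05)
  c1 <- mk_comp(x, y)
  th <- 0.6
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rc <- c1$coords %*% R
  c2 <- mk_comp(rc[, 1], rc[, 2])
  e1 <- unname(ridge_axis(c1)); e2 <- unname(ridge_axis(c2))
  e1r <- as.numeric(e1 %*% R)
  expect_lt(min(sqrt(sum((e2 - e1r)^2)), sqrt(sum((e2 + e1r)^2))), 1e-9)
  expect_error(ridge_axis(mk_comp(1, 1)), "at least 2")
})

test_that("intensity profiles conserve mass and locate bright pixels", {
  iv <- c(rep(1, 7), 9, rep(1, 3))
  comp <- mk_comp(seq(0, 10) * 0.5, rep(0, 11), intensity = iv, dx = 0.5)
  pr <- intensity_profile(comp)
  expect_equal(sum(pr$I_p), sum(iv))                 # mass conservation
  expect_equal(pr$delta_l[which.max(pr$I_p)], 7 * 0.5)
  expect_equal(pr$e1^2 + pr$e2^2, 1, tolerance = 1e-12)
  # profile of a rotated copy (axis re-estimated) matches after alignment
  th <- pi / 6
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rc <- comp$coords %*% R
  comp_r <- mk_comp(rc[, 1], rc[, 2], intensity = iv, dx = 0.5)
  pr_r <- intensity_profile(comp_r)
  expect_equal(sum(pr_r$I_p), sum(iv))
  shift_bins <- which.max(pr_r$I_p) - which.max(pr$I_p)
  expect_lte(abs((pr_r$delta_l[which.max(pr_r$I_p)] - min(pr_r$delta_l)) -
                   (pr$delta_l[which.max(pr$I_p)] - min(pr$delta_l))), 0.5)
})

test_that("Gaussian curvature matches analytic Monge surfaces", {
  nx <- 81
  xs <- (seq_len(nx) - 41) * 0.25
  X <- matrix(rep(xs, each = nx), nx)
  Y <- matrix(rep(xs, times = nx), nx)
  # plane: K = 0
  Kp <- gaussian_curvature(2 + 3 * X, 0.25, 0.25, sigma = 1.2,
                           normalize = FALSE)$K
  expect_lt(max(abs(Kp[30:52, 30:52])), 1e-12)
  # hemisphere patch, R = 10 um: K = 1/R^2 near the centre
  R <- 10
  hemi <- sqrt(pmax(R^2 - X^2 - Y^2, 0))
  Kh <- gaussian_curvature(hemi, 0.25, 0.25, sigma = 1.2,
                           normalize = FALSE)$K
  expect_equal(Kh[41, 41], 0.01, tolerance = 0.15)
  Kh2 <- gaussian_curvature(hemi, 0.25, 0.25, sigma = 0.5,
                            normalize = FALSE)$K
  expect_equal(Kh2[41, 41], 0.01, tolerance = 0.03)
  # saddle z = xy: K = -1 at the origin
  Ks <- gaussian_curvature(X * Y, 0.25, 0.25, sigma = 1.2,
                           normalize = FALSE)$K
  expect_equal(Ks[41, 41], -1, tolerance = 1e-6)
  # constant image: K identically 0; translation leaves K unchanged
  expect_lt(max(abs(gaussian_curvature(matrix(1, 32, 32), 0.25, 0.25)$K)),
            1e-12)
  Ka <- gaussian_curvature(X * Y, 0.25, 0.25, normalize = FALSE)$K
  Kb <- gaussian_curvature(X * Y + 100, 0.25, 0.25, normalize = FALSE)$K
  expect_equal(Ka, Kb, tolerance = 1e-9)
  # fundamental-form identity: denominators EG - F^2 >= 1
  cm <- gaussian_curvature(hemi, 0.25, 0.25, normalize = FALSE)
  expect_true(all(cm$E * cm$G - cm$F^2 >= 1 - 1e-12))
})

test_that("coincidence counts overlap of curvature and divergence sets", {
  K <- matrix(0, 10, 10); K[2:4, 2:4] <- 10; K[7:9, 7:9] <- -10
  D_same <- matrix(0, 10, 10); D_same[2:4, 2:4] <- 1; D_same[7:9, 7:9] <- -1
  co <- coincidence_analysis(list(K), list(D_same), k_threshold = 5,
                             div_threshold = 0.12)
  expect_equal(co$pk_pd, 9)
  expect_equal(co$nk_nd, 9)
  expect_equal(co$pk_nd, 0)
  expect_equal(co$pos_k_fraction, 0.5)
  # disjoint sets count zero
  D_off <- matrix(0, 10, 10); D_off[5:6, 5:6] <- 1
  co2 <- coincidence_analysis(list(K), list(D_off))
  expect_equal(co2$pk_pd + co2$nk_pd, 0)
  expect_error(coincidence_analysis(list(K), list(matrix(0, 4, 4))),
               "misaligned")
})

test_that("bright clusters at flow sources coincide with positive divergence", {
  # constructed movie: a bright Gaussian cluster sits at the centre of a
  # source field, so high +K pixels (intensity peak) overlap +div pixels
  nr <- 48
  xs <- (seq_len(nr) - 24.5) * 0.2
  X <- matrix(rep(xs, each = nr), nr)
  Y <- matrix(rep(xs, times = nr), nr)
  img <- exp(-(X^2 + Y^2) / (2 * 0.3^2))
  K <- gaussian_curvature(img, 0.2, 0.2, sigma = 0.15)$K
  src <- analytic_field("source", 0.1, shape = c(nr, nr), ds = 0.2)
  dv <- divergence(src)   # +0.2 everywhere
  co <- coincidence_analysis(list(K), list(dv), k_threshold = 5,
                             div_threshold = 0.12)
  expect_gt(co$pk_pd, co$pk_nd)
  expect_gt(co$n_pos_k, 0)
})
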