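test_that("worm-like chains follow the stated turn-angle law", {
  # zero-variance limit: an effectively infinite persistence length gives a
  # straight chain with zero curvature downstream
  w <- make_wormlike_chains(1e12, step = 0.1, n_points = 50, n_chains = 1,
                            seed = 3)
  cs <- curvature_series(w$chains[[1]])
  expect_lt(max(abs(cs$kappa)), 1e-4)
  expect_equal(cs$L, 0.1 * 49, tolerance = 1e-9)

  # Monte-Carlo check of the sampling law: var(phi) = step / lp
  w2 <- make_wormlike_chains(1, step = 0.1, n_points = 100002, n_chains = 1,
                             seed = 11)
  d <- diff(w2$chains[[1]])
  phi <- diff(atan2(d[, 2], d[, 1]))
  phi <- phi - 2 * pi * round(phi / (2 * pi))
  se <- 0.1 * sqrt(2 / length(phi))
  expect_lt(abs(stats::var(phi) - 0.1), 3 * se)

  # consecutive spacing equals the step
  expect_equal(max(abs(sqrt(rowSums(d^2)) - 0.1)), 0, tolerance = 1e-9)
})

test_that("worm-like chain generation is deterministic and validated", {
  a <- make_wormlike_chains(6, 0.1, n_points = 50, n_chains = 3, seed = 9)
  b <- make_wormlike_chains(6, 0.1, n_points = 50, n_chains = 3, seed = 9)
  expect_identical(a$chains, b$chains)
  expect_error(make_wormlike_chains(-1, 0.1), "positive")
  expect_error(make_wormlike_chains(1, 0), "positive")
  expect_error(make_wormlike_chains(1, 0.1, n_points = 5), "at least 10")
})

test_that("stripe masks have the exact requested period", {
  sc <- make_labyrinth(1.0, shape = c(32, 64), pixel_size = 0.1,
                       mode = "stripes", seed = 1)
  row <- sc$ridge_mask[1, ]
  ac <- vapply(0:20, function(l) {
    n <- length(row) - l
    mean(row[seq_len(n)] * row[seq_len(n) + l])
  }, numeric(1))
  # first off-origin maximum of the autocorrelation at lag = 10 px
  expect_equal(which.max(ac[-1]), 10)
  expect_true(all(sc$ridge_mask %in% c(0, 1)))
  expect_equal(dim(sc$image$values), dim(sc$ridge_mask))
})

test_that("labyrinth masks peak at the requested wave number", {
  ds <- 0.1
  p1 <- radial_peak(make_labyrinth(0.8, c(128, 128), ds, "labyrinth",
                                   seed = 1)$ridge_mask, ds)
  p2 <- radial_peak(make_labyrinth(0.8, c(128, 128), ds, "labyrinth",
                                   seed = 2)$ridge_mask, ds)
  k0 <- 2 * pi / 0.8
  bin <- 2 * pi / (128 * ds)
  expect_lt(abs(p1 - k0), 1.5 * bin)
  expect_lt(abs(p1 - p2), 1.5 * bin)
  m1 <- make_labyrinth(0.8, c(128, 128), ds, "labyrinth", seed = 1)$ridge_mask
  m2 <- make_labyrinth(0.8, c(128, 128), ds, "labyrinth", seed = 2)$ridge_mask
  expect_false(identical(m1, m2))
})

test_that("labyrinth generator validates Nyquist and noise settings", {
  expect_error(make_labyrinth(0.15, pixel_size = 0.1), "Nyquist")
  sc <- make_labyrinth(1.0, shape = c(32, 32), pixel_size = 0.1,
                       mode = "stripes", seed = 1, noise_sd = 0)
  # noiseless image is the pure ridge rendering rescaled to [0, 1]
  expect_equal(min(sc$image$values), 0)
  expect_equal(max(sc$image$values), 1)
  rend <- sc$image$values
  sc2 <- make_labyrinth(1.0, shape = c(32, 32), pixel_size = 0.1,
                        mode = "stripes", seed = 99, noise_sd = 0)
  expect_identical(rend, sc2$image$values)  # mask is seed-free in stripes mode
})

test_that("flow scenes carry the named analytic fields", {
  fs <- make_flow_scene("translation", 0.2, c(32, 32), dt = 0.5,
                        pixel_size = 0.2, seed = 1)
  dv <- divergence(structure(list(vx = fs$vx_true, vy = fs$vy_true,
                                  dx = 0.2, dy = 0.2, dt = 0.5),
                             class = "velocity_field"))
  expect_equal(max(abs(dv)), 0)

  fs2 <- make_flow_scene("source", 0.05, c(32, 32), dt = 0.5,
                         pixel_size = 0.2, seed = 1)
  dv2 <- divergence(structure(list(vx = fs2$vx_true, vy = fs2$vy_true,
                                   dx = 0.2, dy = 0.2, dt = 0.5),
                              class = "velocity_field"))
  expect_equal(max(abs(dv2 - 0.1)), 0, tolerance = 1e-12)

  fs3 <- make_flow_scene("rotation", 0.05, c(32, 32), dt = 0.5,
                         pixel_size = 0.2, seed = 1)
  S <- strain_tensor(structure(list(vx = fs3$vx_true, vy = fs3$vy_true,
                                    dx = 0.2, dy = 0.2, dt = 0.5),
                               class = "velocity_field"))
  expect_lt(max(abs(S$sxx), abs(S$sxy), abs(S$syy)), 1e-12)
})

test_that("flow scenes warn and clamp over-large displacements", {
  expect_warning(make_flow_scene("translation", 10, c(16, 16), dt = 1,
                                 pixel_size = 0.2, seed = 1),
                 "clamping")
})

test_that("flow scene warps satisfy brightness constancy", {
  fs <- make_flow_scene("translation", 0.2, c(64, 64), dt = 0.5,
                        pixel_size = 0.2, seed = 3, n_frames = 3)
  # shifting frame 2 back by the known displacement recovers frame 1 up to
  # interpolation error (< 2% RMS of the dynamic range, interior pixels)
  a <- fs$frames[[1]]$values
  b <- fs$frames[[2]]$values
  shift_px <- 0.2 * 0.5 / 0.2   # = 0.5 px along x
  nc <- ncol(b)
  approx_back <- b[, 2:nc] * shift_px + b[, 1:(nc - 1)] * (1 - shift_px)
  resid <- (approx_back - a[, 1:(nc - 1)])[5:60, 5:58]
  expect_lt(sqrt(mean(resid^2)) / diff(range(a)), 0.02)
  expect_length(fs$frames, 3)
})

test_that("z-stacks separate periderm from basal slices by entropy", {
  zs <- make_zstack(3, 3, shape = c(64, 64), seed = 1)
  ent <- apply(zs$stack[, , , 1], 3, shannon_entropy)
  expect_true(max(ent[zs$labels == "periderm"]) <
                min(ent[zs$labels == "basal"]))
  # determinism
  zs2 <- make_zstack(3, 3, shape = c(64, 64), seed = 1)
  expect_identical(zs$stack, zs2$stack)
  # no basal layer: any threshold above periderm entropy keeps everything
  zs0 <- make_zstack(2, 0, shape = c(32, 32), seed = 2)
  ent0 <- apply(zs0$stack[, , , 1], 3, shannon_entropy)
  sel <- select_and_project(zs0$stack, global_threshold = max(ent0) + 1)
  expect_equal(sel$kept_indices[[1]], 1:2)
  expect_error(make_zstack(0, 3), "n_periderm")
})
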