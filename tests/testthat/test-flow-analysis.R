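test_that("optic flow recovers known translations", {
  fs <- make_flow_scene("translation", 0.2, c(64, 64), dt = 0.5,
                        pixel_size = 0.2, seed = 3)
  # identical frames give a zero field
  v0 <- optic_flow(fs$frames[[1]], fs$frames[[1]], dt = 0.5)
  expect_equal(max(abs(v0$vx)), 0)
  expect_equal(max(abs(v0$vy)), 0)
  vel <- smooth_field(optic_flow(fs$frames[[1]], fs$frames[[2]], dt = fs$dt))
  sp <- sqrt(vel$vx^2 + vel$vy^2)[12:53, 12:53]
  expect_lt(abs(median(sp) - 0.2) / 0.2, 0.2)
  # negating dt negates the field
  vp <- optic_flow(fs$frames[[1]], fs$frames[[2]], dt = 0.5)
  vn <- optic_flow(fs$frames[[1]], fs$frames[[2]], dt = -0.5)
  expect_equal(vn$vx, -vp$vx)
  expect_equal(vn$vy, -vp$vy)
})

test_that("estimated divergence matches analytic flow scenes", {
  fs <- make_flow_scene("source", 0.05, c(64, 64), dt = 0.5,
                        pixel_size = 0.2, seed = 3)
  vel <- smooth_field(optic_flow(fs$frames[[1]], fs$frames[[2]], dt = fs$dt),
                      passes = 8)
  dv <- divergence(vel)[12:53, 12:53]
  # 2c = 0.1 per min everywhere; 20% RMS over interior textured pixels
  expect_lt(sqrt(mean((dv - 0.1)^2)) / 0.1, 0.2)
})

test_that("field smoothing is the 3x3 box mean", {
  cst <- structure(list(vx = matrix(2, 9, 9), vy = matrix(-1, 9, 9),
                        dx = 1, dy = 1, dt = 1), class = "velocity_field")
  sm <- smooth_field(cst)
  expect_equal(sm$vx, matrix(2, 9, 9))
  expect_equal(sm$vy, matrix(-1, 9, 9))
  # single spike spreads to 9 pixels of v/9
  spk <- cst; spk$vx <- matrix(0, 9, 9); spk$vx[5, 5] <- 9
  sms <- smooth_field(spk)
  expect_equal(sms$vx[4:6, 4:6], matrix(1, 3, 3))
  expect_equal(sum(sms$vx), 9)
  # box mean preserves affine fields in the interior
  aff <- analytic_field("shear", 0.3)
  sma <- smooth_field(aff)
  expect_equal(sma$vx[2:31, 2:31], aff$vx[2:31, 2:31], tolerance = 1e-12)
})

test_that("divergence and strain tensors match affine closed forms", {
  src <- analytic_field("source", 0.05)
  expect_lt(max(abs(divergence(src) - 0.1)), 1e-9)
  rot <- analytic_field("rotation", 0.07)
  expect_lt(max(abs(divergence(rot))), 1e-9)
  tra <- analytic_field("translation", 0.4)
  expect_lt(max(abs(divergence(tra))), 1e-9)

  Ssh <- strain_tensor(analytic_field("shear", 0.3))
  expect_lt(max(abs(Ssh$gammaS - 0.15)), 1e-9)
  expect_lt(max(abs(Ssh$sxx)), 1e-9)
  expect_lt(max(abs(Ssh$Lam1 - 0.15)), 1e-9)
  expect_lt(max(abs(Ssh$Lam2 + 0.15)), 1e-9)

  Ssrc <- strain_tensor(src)
  expect_lt(max(abs(Ssrc$sxx - 0.05)), 1e-9)
  expect_lt(max(abs(Ssrc$syy - 0.05)), 1e-9)
  expect_lt(max(abs(Ssrc$Lam1 - 0.05)), 1e-9)

  Srot <- strain_tensor(rot)
  expect_lt(max(abs(Srot$sxx), abs(Srot$sxy), abs(Srot$syy)), 1e-9)
})

test_that("area-deviatoric split satisfies its exact identities", {
  fs <- make_flow_scene("shear", 0.1, c(48, 48), dt = 0.5, pixel_size = 0.2,
                        seed = 5)
  vel <- smooth_field(optic_flow(fs$frames[[1]], fs$frames[[2]], dt = fs$dt))
  S <- area_deviatoric_split(strain_tensor(vel))
  # S = S_area + S_dev elementwise
  expect_lt(max(abs(S$s_area + S$sdev_xx - S$sxx)), 1e-9)
  expect_lt(max(abs(S$s_area + S$sdev_yy - S$syy)), 1e-9)
  # tr(S_dev) = 0 and tr(S) = div
  expect_lt(max(abs(S$sdev_xx + S$sdev_yy)), 1e-12)
  expect_lt(max(abs(S$sxx + S$syy - S$div)), 1e-12)
  expect_lt(max(abs(S$Lam1 + S$Lam2 - S$div)), 1e-9)
  expect_true(all(S$Lam1 >= S$Lam2))
  expect_lt(max(abs(S$lam1_dev + S$lam2_dev)), 1e-12)
  # degenerate cases
  iso <- area_deviatoric_split(strain_tensor(analytic_field("source", 0.05)))
  expect_lt(max(abs(iso$lam1_dev)), 1e-9)
  dev <- area_deviatoric_split(strain_tensor(analytic_field("shear", 0.3)))
  expect_lt(max(abs(dev$s_area)), 1e-9)
})

test_that("event velocities split by divergence sign", {
  fs <- make_flow_scene("source", 0.08, c(64, 64), dt = 0.5, pixel_size = 0.2,
                        seed = 4)
  vel <- smooth_field(optic_flow(fs$frames[[1]], fs$frames[[2]], dt = fs$dt))
  dv <- divergence(vel)
  ev <- event_velocities(vel, dv, threshold = 0.12)
  # a pure source (2c = 0.16 > 0.12) yields shrinkage pixels only
  expect_gt(ev$n_shrink_px, 0)
  # mean speed at shrinkage pixels within 20% of the analytic mean there
  sel <- dv > 0.12
  truth <- mean(sqrt(fs$vx_true^2 + fs$vy_true^2)[sel])
  expect_lt(abs(ev$v_shrinkage - truth) / truth, 0.2)
  # infinite threshold empties both sets
  ev_inf <- event_velocities(vel, dv, threshold = Inf)
  expect_equal(ev_inf$n_growth_px + ev_inf$n_shrink_px, 0)
  expect_true(is.na(ev_inf$v_growth))
  # sign-flipping the field swaps the growth and shrinkage sets
  ev_neg <- event_velocities(vel, -dv, threshold = 0.12)
  expect_equal(ev_neg$n_growth_px, ev$n_shrink_px)
  expect_equal(ev_neg$n_shrink_px, ev$n_growth_px)
})

test_that("principal strain magnitude and time series behave linearly", {
  # S = [[0, 1/2], [1/2, 0]] at one pixel: sqrt(2)||S|| = 1
  S1 <- list(sxx = matrix(0, 1, 1), sxy = matrix(0.5, 1, 1),
             syy = matrix(0, 1, 1))
  pm <- sqrt(2) * sqrt(S1$sxx^2 + 2 * S1$sxy^2 + S1$syy^2)
  expect_equal(pm[1, 1], 1)
  # zero field gives an all-zero series
  z <- analytic_field("translation", 0)
  Sz <- strain_tensor(z)
  ser <- principal_strain_series(list(Sz), list(matrix(1, 32, 32)))
  expect_true(is.na(ser$per_frame[1]) || ser$per_frame[1] == 0)
  # two shear movies with magnitudes in ratio 1.14 give series in that ratio
  Sa <- strain_tensor(analytic_field("shear", 0.10))
  Sb <- strain_tensor(analytic_field("shear", 0.114))
  mask <- matrix(1, 32, 32)
  ra <- principal_strain_series(list(Sa), list(mask), div_tol = -1)$time_mean
  rb <- principal_strain_series(list(Sb), list(mask), div_tol = -1)$time_mean
  expect_equal(rb / ra, 1.14, tolerance = 1e-9)
})
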