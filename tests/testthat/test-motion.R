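# Sub-pixel region tracking and principal-axis reduction.

test_that("a static scene tracks to zero displacement", {
  fr <- array(10, c(40, 40, 20)); fr[15:20, 15:20, ] <- 100
  d <- track_region(cine_sequence(fr, 30), cbind(x = c(8, 32, 32, 8), y = c(8, 8, 32, 32)))
  expect_lt(max(abs(c(d$dx, d$dy))), 0.01)
})

test_that("sub-pixel sinusoidal motion is recovered within 0.05 px", {
  g <- generate_cine(dim = c(64, 64), fs = 30, duration = 12, noise_sd = 0, seed = 1)
  d <- track_region(g$cine, g$blob_roi)
  expect_lt(abs((max(d$dx) - min(d$dx)) / 2 - 0.4), 0.05)
  expect_lt((max(d$dy) - min(d$dy)) / 2, 0.05)
})

test_that("tracking rejects bad regions and divergent scenes", {
  fr <- array(10, c(40, 40, 5)); fr[15:20, 15:20, ] <- 100
  cn <- cine_sequence(fr, 30)
  expect_error(track_region(cn, cbind(x = c(14, 17, 17, 14), y = c(14, 14, 17, 17))),
               "pixels")
  expect_error(track_region(cn, cbind(x = c(1, 39, 39, 1), y = c(1, 1, 39, 39))),
               "margin")
  set.seed(1)
  noise <- cine_sequence(array(abs(rnorm(40 * 40 * 5, 50, 20)), c(40, 40, 5)), 30)
  expect_error(track_region(noise, cbind(x = c(8, 32, 32, 8), y = c(8, 8, 32, 32))),
               "frame")
})

test_that("principal-axis projection matches a brute-force eigen search", {
  # motion purely along x: projection is exactly dx
  d <- structure(list(dx = sin(1:100 / 5), dy = rep(0, 100),
                      ddx = diff(sin(1:100 / 5)), ddy = rep(0, 99),
                      roi = cbind(0:1, 0:1), fs = 30, n_pixels = 200),
                 class = "displacement_series")
  pm <- project_principal(d)
  expect_equal(pm$axis, c(1, 0))
  expect_equal(pm$explained_variance_fraction, 1)
  expect_equal(pm$values, d$dx - mean(d$dx))

  # diagonal motion with small orthogonal noise: axis within 2 degrees of
  # the diagonal, agreeing with a grid search over projection variance
  set.seed(2)
  a <- sin(1:200 / 7)
  d2 <- d
  d2$dx <- a / sqrt(2) + rnorm(200, 0, 0.02)
  d2$dy <- a / sqrt(2) + rnorm(200, 0, 0.02)
  pm2 <- project_principal(d2)
  ang_grid <- seq(0, pi, length.out = 3601)
  vgrid <- vapply(ang_grid, function(th) {
    stats::var(cbind(d2$dx - mean(d2$dx), d2$dy - mean(d2$dy)) %*% c(cos(th), sin(th)))
  }, numeric(1))
  best <- ang_grid[which.max(vgrid)]
  expect_lt(abs(atan2(pm2$axis[2], pm2$axis[1]) - best) %% pi, 2 * pi / 180)
  expect_lt(abs(atan2(pm2$axis[2], pm2$axis[1]) - pi / 4), 2 * pi / 180)
})

test_that("circular motion has no principal axis", {
  th <- seq(0, 6 * pi, length.out = 200)
  d <- structure(list(dx = cos(th), dy = sin(th), ddx = diff(cos(th)),
                      ddy = diff(sin(th)), roi = cbind(0:1, 0:1), fs = 30,
                      n_pixels = 200),
                 class = "displacement_series")
  expect_error(project_principal(d), "isotropic")
})

test_that("axis sign is canonical so the projected signal is deterministic", {
  set.seed(3)
  a <- sin(1:150 / 6)
  d <- structure(list(dx = -a + rnorm(150, 0, 0.01), dy = 0.2 * a,
                      ddx = diff(-a), ddy = diff(0.2 * a),
                      roi = cbind(0:1, 0:1), fs = 30, n_pixels = 200),
                 class = "displacement_series")
  pm <- project_principal(d)
  expect_gt(pm$axis[which(abs(pm$axis) > 1e-12)[1]], 0)
})

test_that("tracked pulse motion matches the generator waveform in the CF band", {
  g <- generate_cine(dim = c(64, 64), fs = 30, duration = 12, noise_sd = 0, seed = 2)
  pm <- project_principal(track_region(g$cine, g$blob_roi))
  zr <- cf_filter(g$truth$motion_reference$values, 30, cf_band(2.5))
  zt <- cf_filter(pm$values, 30, cf_band(2.5))
  v <- coi_valid(length(pm$values), 30, cf_band(2.5))
  expect_gt(abs(stats::cor(Re(zt)[v], Re(zr)[v])), 0.95)
})

test_that("scattergram magnifies excursions and draws the principal axis", {
  a <- 0.2 * sin(1:100 / 5)
  d <- structure(list(dx = a, dy = 0.02 * a, ddx = diff(a), ddy = diff(0.02 * a),
                      roi = cbind(x = c(20, 40, 40, 20), y = c(20, 20, 40, 40)),
                      fs = 30, n_pixels = 400),
                 class = "displacement_series")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  sg <- render_scattergram(d, magnification = 500)
  # 0.2 px excursion -> 100 px plotted, centred on the roi centroid
  expect_equal(max(sg$points[, "x"]) - mean(sg$points[, "x"]),
               500 * (max(a) - mean(a)), tolerance = 1e-6)
  # axis arrow parallels project_principal
  pm <- project_principal(d)
  arrow_dir <- sg$arrow[2, ] - sg$arrow[1, ]
  arrow_dir <- arrow_dir / sqrt(sum(arrow_dir^2))
  expect_lt(abs(abs(sum(arrow_dir * pm$axis)) - 1), 1e-9)

  # zero displacements: all points at the roi centroid
  dz <- d; dz$dx <- rep(0, 100); dz$dy <- rep(0, 100)
  sz <- render_scattergram(dz)
  expect_equal(unname(apply(sz$points, 2, stats::sd)), c(0, 0))
})
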