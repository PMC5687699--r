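# Contour segmentation, polygon band construction, band series
# extraction, TIC, interval selection, and the phase analyses.

test_that("a straight contour yields 30 axis-aligned square polygons", {
  sc <- segment_contour(straight_contour(300))
  expect_identical(sc$n_segments, 30L)
  expect_equal(sc$seg_length, 10)
  pb <- build_band(sc, thickness = 10)
  expect_length(pb$polygons, 30L)
  q1 <- pb$polygons[[1]]
  expect_equal(q1[, 1], c(10, 20, 20, 10))
  expect_equal(q1[, 2], c(50, 50, 40, 40))
  areas <- vapply(pb$polygons, function(q) abs(sum(q[, 1] * c(q[-1, 2], q[1, 2]) -
                                                    c(q[-1, 1], q[1, 1]) * q[, 2]) / 2),
                  numeric(1))
  expect_equal(areas, rep(100, 30))
  expect_identical(pb$zones[c(1, 10, 11, 20, 21, 30)],
                   c("ventral", "ventral", "dorsal", "dorsal", "ventral", "ventral"))
})

test_that("semicircular contours give equal inner edges but unequal areas", {
  th <- seq(pi, 0, length.out = 121)
  arc <- cbind(x = 60 + 40 * cos(th), y = 70 - 40 * sin(th))
  sc <- segment_contour(arc)
  inner_len <- sqrt(rowSums((sc$endpoints[-1, ] - sc$endpoints[-31, ])^2))
  expect_lt(diff(range(inner_len)) / mean(inner_len), 0.005)
  pb <- build_band(sc, thickness = 12)
  areas <- vapply(pb$polygons, function(q) abs(sum(q[, 1] * c(q[-1, 2], q[1, 2]) -
                                                    c(q[-1, 1], q[1, 1]) * q[, 2]) / 2),
                  numeric(1))
  expect_true(all(areas > 0))
  expect_gt(diff(range(areas)) / mean(areas), 0.01)  # genuinely unequal
})

test_that("degenerate contours and offsets are rejected", {
  closed <- rbind(straight_contour(100), straight_contour(100)[1, ])
  expect_error(segment_contour(closed), "open")
  eight <- cbind(x = c(0, 10, 0, 10), y = c(0, 10, 10, 0))
  expect_error(segment_contour(eight), "simple")
  th <- seq(pi, 0, length.out = 121)
  arc <- cbind(x = 60 + 20 * cos(th), y = 70 - 20 * sin(th))
  # offsetting towards the curvature centre by more than the radius folds
  # the outer polyline through itself
  expect_error(build_band(segment_contour(arc), thickness = 30, side = -1),
               "intersect|degenerate")
})

test_that("band series equals a brute-force per-pixel point-in-polygon mean", {
  set.seed(4)
  h <- 20; w <- 40; nt <- 6
  vals <- matrix(complex(real = rnorm(h * w * nt), imaginary = rnorm(h * w * nt)),
                 h * w, nt)
  field <- structure(list(values = vals,
                          pixels = cbind(row = rep(1:h, times = w),
                                         col = rep(1:w, each = h)),
                          dim = c(h, w), fs = 10, band = cf_band(2),
                          reference = "global"),
                     class = "cf_field")
  sc <- segment_contour(cbind(x = seq(2.3, 37.7, length.out = 13),
                              y = rep(12.4, 13)), n_segments = 6L)
  pb <- build_band(sc, thickness = 7.8)
  bs <- band_signal(field, pb)

  # independent membership test for convex quadrilaterals via half-planes
  inside_quad <- function(px, py, q) {
    s <- sign(sum(q[, 1] * c(q[-1, 2], q[1, 2]) - c(q[-1, 1], q[1, 1]) * q[, 2]))
    for (k in 1:4) {
      a <- q[k, ]; b <- q[if (k == 4) 1 else k + 1, ]
      if (s * ((b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])) < 0)
        return(FALSE)
    }
    TRUE
  }
  taken <- matrix(FALSE, h, w)
  for (i in seq_along(pb$polygons)) {
    members <- matrix(FALSE, h, w)
    for (r in 1:h) for (cc in 1:w) {
      if (!taken[r, cc] && inside_quad(cc - 1, r - 1, pb$polygons[[i]])) {
        members[r, cc] <- TRUE; taken[r, cc] <- TRUE
      }
    }
    idx <- which(as.vector(members))
    expect_equal(bs$values[i, ], colMeans(vals[idx, , drop = FALSE]))
  }
})

test_that("band series reports a constant field and a monotone phase gradient", {
  h <- 30; w <- 60; nt <- 4
  z0 <- complex(real = 1.3, imaginary = -0.4)
  mkfield <- function(vals) structure(
    list(values = vals, pixels = cbind(row = rep(1:h, times = w), col = rep(1:w, each = h)),
         dim = c(h, w), fs = 10, band = cf_band(2), reference = "motion"),
    class = "cf_field")
  sc <- segment_contour(cbind(x = seq(3, 57, length.out = 31), y = rep(18, 31)))
  pb <- build_band(sc, thickness = 9)

  bs0 <- band_signal(mkfield(matrix(z0, h * w, nt)), pb)
  expect_true(all(bs0$values == z0))
  expect_identical(dim(bs0$values), c(30L, 4L))

  # phase increasing linearly with x -> per-polygon phase monotone 1..30
  xs <- rep(0:(w - 1), each = h)
  valsg <- matrix(exp(1i * 0.03 * xs), h * w, nt)
  bsg <- band_signal(mkfield(valsg), pb)
  expect_true(all(diff(Arg(bsg$values[, 1])) > 0))
})

test_that("polygons without pixel centers raise an error", {
  field <- structure(list(values = matrix(1 + 0i, 25, 2),
                          pixels = cbind(row = rep(1:5, 5), col = rep(1:5, each = 5)),
                          dim = c(5, 5), fs = 10, band = cf_band(2),
                          reference = "global"),
                     class = "cf_field")
  sc <- segment_contour(cbind(x = seq(0.2, 2.2, length.out = 7), y = rep(1.5, 7)),
                        n_segments = 3L)
  pb <- build_band(sc, thickness = 0.2)
  expect_error(band_signal(field, pb), "no pixel centers")
})

test_that("a p3-like acquisition yields a 30 x 140 band series", {
  g <- generate_cine(dim = c(64, 64), fs = 10, duration = 14, cardiac_freq = 2.5,
                     seed = 1)
  sc <- segment_contour(g$truth$contour)
  pb <- build_band(sc, thickness = g$truth$band_width)
  fld <- cf_angiogram(g$cine, cf_band(2.5), mask = band_mask(pb, c(64, 64)))
  bs <- band_signal(fld, pb)
  expect_identical(dim(bs$values), c(30L, 140L))
})

test_that("the TIC finds the bolus peak; flat and ramp inputs behave", {
  g <- generate_cine(dim = c(64, 64), fs = 30, duration = 16, seed = 2)
  sc <- segment_contour(g$truth$contour)
  pb <- build_band(sc, thickness = g$truth$band_width)
  tic <- time_intensity_curve(g$cine, pb, cardiac_freq = 2.5)
  expect_lt(abs(tic$time[which.max(tic$smooth)] - g$truth$bolus_peak_time),
            0.5 / 2.5)

  flat <- cine_sequence(array(7, c(64, 64, 20)), 30)
  tf <- time_intensity_curve(flat, pb)
  expect_equal(diff(range(tf$intensity)), 0)

  ramp <- cine_sequence(array(rep(1:20, each = 64 * 64), c(64, 64, 20)), 30)
  tr <- time_intensity_curve(ramp, pb, cardiac_freq = 10)
  expect_gte(which.max(tr$smooth), 19L)
})

test_that("arterial and venous intervals bracket the TIC peak with guard gaps", {
  tic <- structure(list(time = seq(0, 20, by = 1 / 30),
                        intensity = exp(-((seq(0, 20, by = 1 / 30) - 10) / 3)^2),
                        smooth = exp(-((seq(0, 20, by = 1 / 30) - 10) / 3)^2),
                        fs = 30),
                   class = "tic")
  iv <- select_av_intervals(tic, 2.5, n_beats = 5, gap_beats = c(0, 6))
  expect_equal(iv$peak_time, 10)
  expect_equal(iv$arterial, c(8, 10))
  expect_equal(iv$venous, c(12.4, 14.4))

  # peak at the first frame leaves no room for the arterial interval
  early <- tic
  early$smooth <- rev(sort(early$smooth))
  expect_error(select_av_intervals(early, 2.5), "too short")
})

test_that("each interval samples its own compartment's envelope", {
  g <- generate_cine(dim = c(64, 64), fs = 30, duration = 16, noise_sd = 0, seed = 1)
  sc <- segment_contour(g$truth$contour)
  pb <- build_band(sc, thickness = g$truth$band_width)
  tic <- time_intensity_curve(g$cine, pb, cardiac_freq = 2.5)
  iv <- select_av_intervals(tic, 2.5)
  X <- matrix(g$cine$frames, 64 * 64, dim(g$cine$frames)[3])
  env_a <- colMeans(X[as.vector(g$truth$compartment_masks == "arterial"), ]) - 10
  env_v <- colMeans(X[as.vector(g$truth$compartment_masks == "venous"), ]) - 10
  tt <- (seq_along(env_a) - 1) / 30
  in_a <- tt >= iv$arterial[1] & tt <= iv$arterial[2]
  in_v <- tt >= iv$venous[1] & tt <= iv$venous[2]
  expect_gte(mean(env_a[in_a] >= env_v[in_a]), 0.8)
  expect_gte(mean(env_v[in_v] >= env_a[in_v]), 0.8)
})

test_that("swapping zone labels negates the dorsoventral series exactly", {
  out <- run_small_pipeline(grad = 0.7, seed = 1)
  bs <- out$pa$band_series
  dv <- dorsoventral_phase(bs)
  bs2 <- bs
  bs2$zones <- ifelse(bs$zones == "dorsal", "ventral", "dorsal")
  dv2 <- dorsoventral_phase(bs2)
  expect_equal(dv2$phase, -dv$phase)
  expect_equal(dv2$summary$mean, -dv$summary$mean)
})

test_that("a null gradient gives a null dorsoventral phase", {
  out <- run_small_pipeline(grad = 0, seed = 3)
  expect_lt(abs(out$pa$dorsoventral$summary$mean), 0.1)
})

test_that("band series is invariant under joint 90-degree rotation", {
  g <- generate_cine(dim = c(64, 64), fs = 30, duration = 12, noise_sd = 0, seed = 5)
  rot_xy <- function(xy, w) cbind(x = xy[, 2], y = w - 1 - xy[, 1])
  fr <- g$cine$frames
  fr_rot <- array(0, c(64, 64, dim(fr)[3]))
  for (k in seq_len(dim(fr)[3])) fr_rot[, , k] <- t(fr[, , k])[64:1, ]
  run <- function(frames, contour) {
    sc <- segment_contour(contour)
    pb <- build_band(sc, thickness = g$truth$band_width)
    fld <- cf_angiogram(cine_sequence(frames, 30), cf_band(2.5),
                        motion = g$truth$motion_reference,
                        mask = band_mask(pb, c(64, 64)))
    band_signal(fld, pb)
  }
  bs1 <- run(fr, g$truth$contour)
  bs2 <- run(fr_rot, rot_xy(g$truth$contour, 64))
  v <- coi_valid(ncol(bs1$values), 30, bs1$cf_band)
  strong <- Mod(bs1$values[, v]) > 0.5 * stats::quantile(Mod(bs1$values[, v]), 0.9)
  dphi <- abs(wrap_angle(Arg(bs1$values[, v]) - Arg(bs2$values[, v])))
  expect_lt(max(dphi[strong]), 0.05)
  rel_mag <- abs(Mod(bs1$values[, v]) - Mod(bs2$values[, v])) /
    stats::quantile(Mod(bs1$values[, v]), 0.9)
  expect_lt(max(rel_mag[strong]), 0.02)
})

test_that("the unfolded profile has one row per segment and constant hue for constant phase", {
  out <- run_small_pipeline(grad = 0.7, seed = 1)
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  colors <- plot(out$pa$band_series)
  expect_identical(nrow(colors), 30L)

  const <- out$pa$band_series
  const$values <- matrix(complex(modulus = 1, argument = 1.1), 30, 40)
  cols2 <- plot(const)
  hues <- grDevices::rgb2hsv(grDevices::col2rgb(as.vector(cols2)))["h", ]
  expect_lt(diff(range(hues)), 0.01)
})
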