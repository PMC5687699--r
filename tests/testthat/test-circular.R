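# Circular statistics: summaries, Watson tests, histograms, angular Q-Q.

test_that("circular summary handles concentration, wrap-around and degeneracy", {
  s <- circ_summary(c(0.1, 0.1, 0.1))
  expect_equal(s$mean, 0.1)
  expect_equal(s$sd, 0)
  expect_equal(s$rbar, 1)

  sw <- circ_summary(c(pi - 0.1, -pi + 0.1))
  expect_equal(abs(sw$mean), pi)
  expect_error(circ_summary(c(0, pi)), "undefined")
})

test_that("summary is rotation-equivariant and matches brute force to 1e-12", {
  set.seed(11)
  for (i in 1:8) {
    th <- stats::runif(sample(3:12, 1), -pi, pi)
    s <- circ_summary(th)
    b <- brute_circ(th)
    expect_equal(s$mean, wrap_angle(b$mean), tolerance = 1e-12)
    expect_equal(s$sd, b$sd, tolerance = 1e-12)
    rot <- circ_summary(th + 0.9)
    expect_equal(rot$mean, wrap_angle(s$mean + 0.9), tolerance = 1e-12)
    expect_equal(rot$sd, s$sd, tolerance = 1e-12)
  }
})

test_that("one-sample Watson test accepts near-null samples and rejects shifts", {
  set.seed(12)
  keep <- replicate(60, watson_one_sample(rvonmises(60, 0.4, 3), 0.4)$p_value > 0.05)
  expect_gte(mean(keep), 0.9)
  expect_lte(watson_one_sample(rvonmises(300, 0.8, 6), 0)$p_value, 1e-5)
  expect_error(watson_one_sample(stats::runif(10, -1, 1), 0), "25")
})

test_that("one-sample p agrees with a bootstrap-of-mean oracle within 3x", {
  set.seed(13)
  for (case in 1:20) {
    n <- sample(40:80, 1)
    kappa <- stats::runif(1, 1, 3)
    mu0 <- stats::runif(1, -pi, pi)
    th <- rvonmises(n, mu0, kappa)
    p_w <- watson_one_sample(th, mu0)$p_value
    obs <- abs(wrap_angle(circ_summary(th)$mean - mu0))
    centred <- wrap_angle(th - circ_summary(th)$mean + mu0)
    boot <- replicate(1500, {
      abs(wrap_angle(circ_summary(sample(centred, n, replace = TRUE))$mean - mu0))
    })
    p_b <- (sum(boot >= obs) + 1) / 1501
    expect_true(p_w / p_b < 3 && p_b / p_w < 3 || (p_w < 0.02 && p_b < 0.02),
                info = sprintf("case %d: p_w=%.4g p_b=%.4g", case, p_w, p_b))
  }
})

test_that("two-sample Watson U2 is zero for identical samples and detects shifts", {
  set.seed(14)
  a <- rvonmises(20, 0.3, 4)
  w <- watson_two_sample(a, a, n_permutations = 200)
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 1)
  expect_true(w$tie_warning)

  # strong mean separation: decisive p in nearly all seeds, with the
  # permutation p resolving well below 0.01
  pv <- replicate(40, watson_two_sample(rvonmises(30, 0, 4), rvonmises(30, 1, 4),
                                        n_permutations = 2000,
                                        seed = sample.int(1e6, 1))$p_value)
  expect_lte(stats::median(pv), 1e-3)
  expect_gte(mean(pv <= 0.01), 0.95)
  expect_error(watson_two_sample(a[1:5], a), "at least 8")
})

test_that("two-sample U2 statistic matches its rank-sum definition on small cases", {
  set.seed(15)
  for (i in 1:6) {
    a <- stats::runif(sample(8:12, 1), -pi, pi)
    b <- stats::runif(sample(8:12, 1), -pi, pi)
    w <- watson_two_sample(a, b, n_permutations = 50)
    nn <- length(a) + length(b)
    pooled <- c(a, b)
    ord <- order(pooled)
    grp <- c(rep(1, length(a)), rep(0, length(b)))[ord]
    d <- cumsum(grp) / length(a) - cumsum(1 - grp) / length(b)
    u2 <- (length(a) * length(b) / nn^2) * sum((d - mean(d))^2)
    expect_equal(w$statistic, u2, tolerance = 1e-12)
  }
})

test_that("circular histogram conserves counts and locates the mode", {
  h <- circ_hist(wrap_angle(seq(-pi + 0.01, pi - 0.01, length.out = 36)), 36)
  expect_true(all(h$counts == 1))
  set.seed(16)
  th <- stats::runif(137, -pi, pi)
  expect_equal(sum(circ_hist(th)$counts), 137L)
  vm <- rvonmises(500, 1.0, 4)
  hv <- circ_hist(vm, 36)
  expect_lt(abs(hv$mids[which.max(hv$counts)] - 1.0), 2 * 2 * pi / 36)
})

test_that("angular Q-Q matching is exact for equal samples and rotation-invariant", {
  set.seed(17)
  a <- rvonmises(60, 0.5, 2)
  q <- angular_qq(a, a)
  expect_equal(q$quantiles[, 1], q$quantiles[, 2])
  expect_equal(q$max_abs_deviation, 0)

  qr <- angular_qq(a, wrap_angle(a + 1.3))
  expect_lt(qr$max_abs_deviation, 1e-9)

  # equal-shape samples agree in the bulk; the extreme quantiles of a
  # concentrated circular sample are order-statistic noise, so the mean
  # absolute deviation is the stable summary
  devs <- replicate(10, angular_qq(rvonmises(200, 0, 3),
                                   rvonmises(200, 1.1, 3))$mean_abs_deviation)
  expect_gte(mean(devs < 0.15), 0.9)
  expect_error(angular_qq(a[1:3], a), "at least 5")
})

test_that("rose and Q-Q plots draw without error", {
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  set.seed(18)
  expect_no_error(plot(circ_hist(rvonmises(100, 0.5, 2))))
  expect_no_error(plot(angular_qq(rvonmises(50, 0, 2), rvonmises(50, 0.3, 2))))
})
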