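# Physiology loading, clock alignment, cardiac referencing, and the
# dorsal-minus-ventral CSF pressure phase pipeline.

test_that("physiology CSV round-trips through write and load", {
  p <- generate_physio(seed = 1)
  path <- tempfile(fileext = ".csv")
  write_physio(p$ventral, path)
  rec <- load_physio(path, site = "third_ventricle")
  expect_equal(rec$csf_mmHg, p$ventral$csf_mmHg, tolerance = 1e-9)
  expect_equal(attr(rec, "fs"), attr(p$ventral, "fs"), tolerance = 1e-6)
  expect_identical(attr(rec, "site"), "third_ventricle")
  expect_false(any(attr(rec, "interpolated")))
})

test_that("the loader rejects shuffled time and missing columns, flags gaps", {
  p <- generate_physio(seed = 2)
  df <- as.data.frame(p$ventral)
  path <- tempfile(fileext = ".csv")

  shuffled <- df[sample(nrow(df)), ]
  utils::write.csv(shuffled, path, row.names = FALSE)
  expect_error(load_physio(path), "increasing")

  utils::write.csv(df[, -2], path, row.names = FALSE)
  expect_error(load_physio(path), "missing column")

  # drop 1% of rows: loaded with interpolation flags exactly there
  drop <- as.integer(seq(100, nrow(df), by = 120))
  utils::write.csv(df[-drop, ], path, row.names = FALSE)
  rec <- load_physio(path)
  expect_identical(nrow(rec), nrow(df))
  expect_identical(which(attr(rec, "interpolated")), drop)
  expect_lt(max(abs(rec$csf_mmHg[-drop] - df$csf_mmHg[-drop])), 1e-9)
})

test_that("clock alignment recovers offsets to within one video frame", {
  fp <- generate_flick_pair(clock_offset = 2.40, seed = 1)
  al <- align_clocks(fp$motion, fp$pressure)
  expect_lte(abs(al$offset_s - 2.40), 1 / 30)
  expect_equal(al$uncertainty_s, 1 / 30)

  fp0 <- generate_flick_pair(clock_offset = 0, seed = 2)
  expect_lte(abs(align_clocks(fp0$motion, fp0$pressure)$offset_s), 1 / 30)
})

test_that("alignment refuses traces with zero or multiple transients", {
  fp <- generate_flick_pair(flick_amp = 0, seed = 3)
  expect_error(align_clocks(fp$motion, fp$pressure), "no transient")

  fp2 <- generate_flick_pair(seed = 4)
  double <- fp2$motion
  spike_at <- round(5 * double$fs)
  double$values[spike_at:(spike_at + 10)] <-
    double$values[spike_at:(spike_at + 10)] + 15
  expect_error(align_clocks(double, fp2$pressure), "multiple")
})

test_that("cardiac reference phase tracks the ECG fundamental", {
  p <- generate_physio(seed = 3)
  z <- cardiac_reference_phase(p$ventral, "ecg")
  fsr <- attr(p$ventral, "fs")
  dphi <- wrap_angle(diff(Arg(z)))
  v <- coi_valid(nrow(p$ventral), fsr, attr(z, "band"))[-1]
  inst_freq <- mean(dphi[v]) * fsr / (2 * pi)
  expect_lt(abs(inst_freq - 1.2), 0.05)

  flat <- p$ventral
  flat$ecg_au <- rep(1, nrow(flat))
  expect_error(cardiac_reference_phase(flat, "ecg"), "flat")
})

test_that("ABP and ECG referencing give the same inter-site phase", {
  p <- generate_physio(seed = 3)
  de <- dorsoventral_csf_phase(p$dorsal, p$ventral, channel = "ecg")
  da <- dorsoventral_csf_phase(p$dorsal, p$ventral, channel = "abp")
  expect_lt(abs(wrap_angle(de$summary$mean - da$summary$mean)), 0.05)
})

test_that("the configured inter-site lag is recovered", {
  p <- generate_physio(site_phase_lag = 0.8, seed = 1)
  d <- dorsoventral_csf_phase(p$dorsal, p$ventral)
  expect_lt(abs(d$summary$mean - 0.8), 0.1)
  expect_lte(d$watson$p_value, 1e-5)
})

test_that("whole-period epoch shifts leave the pooled mean unchanged", {
  p1 <- generate_physio(site_phase_lag = 0.8, seed = 1)
  p2 <- generate_physio(site_phase_lag = 0.8,
                        epoch_starts = c(0, 153.2 + 7 / 1.2), seed = 1)
  d1 <- dorsoventral_csf_phase(p1$dorsal, p1$ventral)
  d2 <- dorsoventral_csf_phase(p2$dorsal, p2$ventral)
  expect_lt(abs(wrap_angle(d1$summary$mean - d2$summary$mean)), 0.05)
})

test_that("swapping site records negates the pooled mean exactly", {
  p <- generate_physio(site_phase_lag = 0.8, seed = 6)
  d <- dorsoventral_csf_phase(p$dorsal, p$ventral)
  ds <- dorsoventral_csf_phase(p$ventral, p$dorsal)
  expect_equal(ds$summary$mean, -d$summary$mean, tolerance = 1e-12)
})

test_that("identical noise-free records give all-zero phase differences", {
  p <- generate_physio(site_phase_lag = 0, noise_sd = 0,
                       amplitudes = list(csf_resp = 0), seed = 1)
  d <- dorsoventral_csf_phase(p$ventral, p$ventral)
  # beat-level estimates carry a small edge wobble shared by both record
  # copies; cross-beat differences stay well below it and the pooled
  # mean vanishes
  expect_lt(max(abs(d$samples)), 0.02)
  expect_lt(abs(d$summary$mean), 1e-3)
})

test_that("the null-lag test keeps its nominal size", {
  rej <- sapply(1:20, function(s) {
    p <- generate_physio(site_phase_lag = 0, seed = s + 300)
    dorsoventral_csf_phase(p$dorsal, p$ventral)$watson$p_value < 0.05
  })
  expect_lte(sum(rej), 2L)
})
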