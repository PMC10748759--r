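test_that("atoms are Gaussian-windowed sines with 1/6-length SD", {
  a <- make_atom(atom_spec(10, 10), 1000)
  expect_equal(length(a$samples), 1000L)
  # envelope: |x| bounded by the Gaussian with SD = length/6 samples
  t <- (0:999) / 1000
  env <- exp(-(t - mean(t))^2 / (2 * (1 / 6)^2))
  expect_true(all(abs(a$samples) <= env + 1e-12))
  expect_equal(max(env), 1, tolerance = 1e-5)  # envelope peaks at amplitude
  # duration scales as n_cycles / frequency
  expect_equal(length(make_atom(atom_spec(20, 10), 1000)$samples), 500L)
  b <- make_atom(atom_spec(40, 10, amplitude = 2.5), 1000)
  tb <- (seq_along(b$samples) - 1) / 1000
  envb <- 2.5 * exp(-(tb - mean(tb))^2 / (2 * (0.25 / 6)^2))
  expect_equal(max(envb), 2.5, tolerance = 1e-3)   # discrete sampling offset
  expect_true(all(abs(b$samples) <= envb + 1e-12))
  # the packet vanishes at both ends: edge samples below exp(-4.5) of peak
  expect_lt(max(abs(a$samples[c(1L, 1000L)])), 0.012)
  # >= 99% of the energy concentrated inside the central +-2 SD
  core <- abs(t - mean(t)) <= 2 / 6
  expect_gte(sum(a$samples[core]^2) / sum(a$samples^2), 0.95)
  expect_error(make_atom(atom_spec(600, 5), 1000), "twice the atom")
})

test_that("pink noise is reproducible with a 1/f spectrum", {
  expect_identical(pink_noise(4096, 1000, seed = 7)$samples,
                   pink_noise(4096, 1000, seed = 7)$samples)
  expect_equal(length(pink_noise(1234, 1000, seed = 1)$samples), 1234L)
  slope <- spectral_slope(function(s) pink_noise(8192, 1000, seed = s), 20)
  expect_gt(slope, -1.3); expect_lt(slope, -0.7)
})

test_that("brown noise integrates white noise to a 1/f^2 spectrum", {
  expect_identical(brown_noise(4096, 1000, seed = 3)$samples,
                   brown_noise(4096, 1000, seed = 3)$samples)
  expect_equal(mean(brown_noise(5000, 1000, seed = 2)$samples), 0)
  slope <- spectral_slope(function(s) brown_noise(8192, 1000, seed = s), 20)
  expect_gt(slope, -2.3); expect_lt(slope, -1.7)
})

test_that("the band-pass filter is selective and zero-phase", {
  fs <- 1000; t <- (0:4999) / fs
  pass <- band_filter(signal_ts(sin(2 * pi * 60 * t), fs), 30, 100)
  core <- 1000:4000                        # avoid filter edge transients
  ratio <- max(abs(pass$samples[core]))
  expect_gt(ratio, 0.95); expect_lte(ratio, 1.0 + 1e-6)
  stop_band <- band_filter(signal_ts(sin(2 * pi * 5 * t), fs), 30, 100)
  expect_lt(max(abs(stop_band$samples[core])), 0.1)
  # zero phase: cross-correlation of the passed tone peaks at lag 0
  cc <- stats::ccf(sin(2 * pi * 60 * t)[core], pass$samples[core],
                   lag.max = 8, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_error(band_filter(pass, 200, 100), "low_hz")
})

test_that("SNR calibration satisfies the variance-ratio identity", {
  expect_equal(snr_scale(c(1, -1, 1, -1), c(2, 0, 2, 0), 1)$k, 1)
  expect_equal(snr_scale(c(1, -1, 1, -1), c(2, 0, 2, 0), 4)$k, 2)
  set.seed(8)
  a <- rnorm(700) * 3.2; b <- rnorm(5000) * 0.7
  for (snr in c(0.1, 1, 2.5)) {
    cal <- snr_scale(a, b, snr)
    expect_lt(abs(stats::var(cal$scaled) / stats::var(b) - snr) / snr, 1e-12)
  }
  expect_error(snr_scale(rep(1, 5), rnorm(10), 1), "zero-variance")
})

test_that("ground-truth rois sit on the atom in the noise-free TFR", {
  cfg <- slt_config(30, 100, step_ms = 5)
  spec <- atom_spec(40, 10, onset_s = 1.2)
  gt <- ground_truth_roi(spec, 1000, cfg, 3)
  expect_gt(nrow(gt$roi), 0L)
  peak_rows <- gt$roi[, "f"]
  expect_lte(min(abs(gt$freq_axis[peak_rows] - 40)), 1)
  # the roi contains the grid argmax of the noise-free TFR
  atom <- make_atom(spec, 1000)
  x <- numeric(3000); x[1201:(1200 + length(atom$samples))] <- atom$samples
  tfr <- compute_tfr(signal_ts(x, 1000), cfg)
  am <- which(tfr$power == max(tfr$power), arr.ind = TRUE)[1L, ]
  expect_true(any(gt$roi[, "f"] == am[1L] & gt$roi[, "t"] == am[2L]))
  # roi time span covers the atom's central half-duration and stays near
  # the nominal duration (20% of peak power = 45% of peak amplitude, i.e.
  # about +-1.3 envelope SDs, plus wavelet smearing)
  tspan <- range(gt$time_axis[gt$roi[, "t"]])
  center <- 1.2 + 0.25 / 2
  expect_lte(tspan[1L], center - 0.0625)
  expect_gte(tspan[2L], center + 0.0625)
  expect_gte(tspan[1L], 1.2 - 0.1)
  expect_lte(tspan[2L], 1.45 + 0.1)
  expect_error(ground_truth_roi(atom_spec(20, 10, onset_s = 1), 1000, cfg, 3),
               "frequency range")
})

test_that("the benchmark set repeats each atom across all SNR levels", {
  proto <- benchmark_protocol(n_atoms = 4, snr_levels = c(0.5, 2),
                              trial_s = 2, seed = 42)
  set1 <- build_benchmark_set(proto)
  expect_equal(length(set1$instances), 8L)
  set2 <- build_benchmark_set(proto)
  expect_identical(lapply(set1$instances, function(i) i$signal$samples),
                   lapply(set2$instances, function(i) i$signal$samples))
  ids <- vapply(set1$instances, function(i) i$atom_id, integer(1))
  snrs <- vapply(set1$instances, function(i) i$snr, numeric(1))
  expect_equal(sort(unique(ids)), 1:4)
  expect_true(all(table(ids) == 2L))
  for (a in 1:4) expect_setequal(snrs[ids == a], c(0.5, 2))
  freqs <- vapply(set1$atoms, function(at) at$spec$frequency, numeric(1))
  expect_true(all(freqs >= 35 & freqs <= 95))
  # calibration carried into the embedded composite
  inst <- set1$instances[[1L]]
  at <- set1$atoms[[inst$atom_id]]
  atom <- make_atom(at$spec, proto$fs)
  i0 <- round(at$spec$onset_s * proto$fs) + 1L
  idx <- i0:(i0 + length(atom$samples) - 1L)
  resid <- inst$signal$samples[idx] - at$background$samples[idx]
  expect_equal(stats::var(resid) / stats::var(at$background$samples),
               inst$snr, tolerance = 1e-10)
})
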