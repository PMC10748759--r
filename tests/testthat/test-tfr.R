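tone <- function(f0, dur = 2, fs = 1000, amp = 1)
  signal_ts(amp * sin(2 * pi * f0 * (0:(dur * fs - 1)) / fs), fs)

atom_in_trial <- function(f0, n_cycles, fs, trial_s, onset_s) {
  a <- make_atom(atom_spec(f0, n_cycles, onset_s = onset_s), fs)
  x <- numeric(trial_s * fs)
  i0 <- round(onset_s * fs) + 1L
  x[i0:(i0 + length(a$samples) - 1L)] <- a$samples
  signal_ts(x, fs)
}

test_that("STFT localizes tones and handles degenerate inputs", {
  s <- tone(40)
  g <- compute_stft(s, stft_config(1, 100, bins_per_hz = 4))
  expect_equal(g$freq_axis[which.max(rowMeans(g$power))], 40,
               tolerance = 1 / 4 + 1e-9)
  expect_equal(diff(g$time_axis[1:2]), 1e-3)
  z <- signal_ts(numeric(500), 1000)
  gz <- compute_stft(z, stft_config(1, 100, window_ms = 100))
  expect_true(all(gz$power == 0))
  expect_error(compute_stft(signal_ts(rnorm(100), 1000),
                            stft_config(1, 100)), "longer")
  expect_error(compute_stft(s, stft_config(1, 600)), "Nyquist")
})

test_that("STFT peaks at the atom center, matching a direct DFT oracle", {
  fs <- 1000
  x <- atom_in_trial(50, 10, fs, 2, 0.9)       # center at 1.0 s
  g <- compute_stft(x, stft_config(30, 80, step_ms = 5))
  pk <- which(g$power == max(g$power), arr.ind = TRUE)[1L, ]
  expect_lt(abs(g$time_axis[pk[2L]] - 1.0), 0.025)
  # oracle: windowed DFT coefficient at 50 Hz for coarse window centers
  wl <- 251L
  w <- signal::blackman(wl)
  centers <- seq(300L, 1700L, by = 5L)
  resp <- vapply(centers, function(c0) {
    seg <- x$samples[(c0 - 125L):(c0 + 125L)] * w
    Mod(sum(seg * exp(-2i * pi * 50 * (0:250) / fs)))^2
  }, numeric(1))
  expect_lt(abs(centers[which.max(resp)] / fs - 1.0), 0.025)
})

test_that("amplitude-normalized CWT gives frequency-independent peak power", {
  peaks <- vapply(c(20, 40, 60, 90), function(f0) {
    g <- compute_cwt(tone(f0), cwt_config(10, 95, cycles = 7))
    max(g$power)
  }, numeric(1))
  expect_true(max(peaks) / min(peaks) < 1.1)
  z <- compute_cwt(signal_ts(numeric(1000), 1000), cwt_config(20, 80))
  expect_true(all(z$power == 0))
  expect_error(compute_cwt(signal_ts(c(1, NaN, 1), 1000),
                           cwt_config(20, 80)), "finite")
})

test_that("CWT atom ridge power matches a direct time-domain convolution", {
  fs <- 1000
  direct_peak <- function(f0) {
    x <- atom_in_trial(f0, 20, fs, 3, 1.2)
    sigma <- 7 / (6 * f0)
    hl <- ceiling(3 * sigma * fs)
    tt <- (-hl:hl) / fs
    env <- exp(-tt^2 / (2 * sigma^2))
    kern <- env * exp(2i * pi * f0 * tt) / sum(env)
    resp <- vapply(seq(1 + hl, length(x$samples) - hl, by = 10L),
                   function(i) Mod(sum(x$samples[(i - hl):(i + hl)] *
                                       rev(kern)))^2, numeric(1))
    max(resp)
  }
  p40o <- direct_peak(40); p80o <- direct_peak(80)
  grid_peak <- function(f0) {
    x <- atom_in_trial(f0, 20, fs, 3, 1.2)
    max(compute_cwt(x, cwt_config(f0 - 10, f0 + 10, cycles = 7))$power)
  }
  p40 <- grid_peak(40); p80 <- grid_peak(80)
  expect_gt(p40 / p80, 0.9); expect_lt(p40 / p80, 1.1)
  expect_equal(p40, p40o, tolerance = 0.05)
  expect_equal(p80, p80o, tolerance = 0.05)
})

test_that("superlet reduces to CWT at order 1 and sharpens with order", {
  s <- tone(55)
  g1 <- compute_slt(s, slt_config(30, 80, c1 = 3, order_min = 1,
                                  order_max = 1))
  g2 <- compute_cwt(s, cwt_config(30, 80, cycles = 3))
  expect_lt(max(abs(g1$power - g2$power)) / max(g2$power), 1e-9)

  half_width <- function(g) {
    prof <- rowMeans(g$power)
    sum(prof >= max(prof) / 2)
  }
  widths <- vapply(c(1, 2, 4, 8), function(o) {
    half_width(compute_slt(s, slt_config(30, 80, c1 = 3, order_min = o,
                                         order_max = o)))
  }, numeric(1))
  expect_true(all(diff(widths) <= 0))
  expect_lt(widths[4L], half_width(g2))
})

test_that("superlets separate atoms close in frequency where the CWT fuses them", {
  # two concurrent 20-cycle atoms 6 Hz apart: inside the 7-cycle Morlet's
  # blur but resolvable by the order-10 superlet
  fs <- 1000
  x <- atom_in_trial(40, 20, fs, 2, 0.75)$samples +
       atom_in_trial(46, 20, fs, 2, 0.75)$samples
  x <- signal_ts(x, fs)
  core_profile <- function(g) {
    rowMeans(g$power[, g$time_axis >= 0.8 & g$time_axis <= 1.2])
  }
  n_peaks <- function(prof) {
    up <- diff(prof) > 0
    sum(head(up, -1) & !tail(up, -1))
  }
  slt_prof <- core_profile(compute_slt(x, slt_config(28, 66, c1 = 3,
                                                     order_min = 10,
                                                     order_max = 10,
                                                     bins_per_hz = 2)))
  cwt_prof <- core_profile(compute_cwt(x, cwt_config(28, 66, cycles = 7,
                                                     bins_per_hz = 2)))
  expect_gte(n_peaks(slt_prof), 2)
  expect_lte(n_peaks(cwt_prof), 1)
})

test_that("all front ends keep grids finite, nonnegative and tone-aligned", {
  s <- tone(60, dur = 1)
  cfgs <- list(stft_config(30, 90, bins_per_hz = 1),
               cwt_config(30, 90), slt_config(30, 90, order_min = 5))
  for (cfg in cfgs) {
    g <- compute_tfr(s, cfg)
    expect_true(all(is.finite(g$power)) && all(g$power >= 0))
    expect_equal(g$freq_axis[which.max(rowMeans(g$power))], 60,
                 tolerance = 1 + 1e-9)
  }
})
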