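# run `expr` with a locally seeded RNG, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic oscillation atom specification
#'
#' An atom is a sine wave of `n_cycles` cycles at `frequency`, multiplied
#' by a Gaussian window whose standard deviation is 1/6 of the packet
#' length, so it vanishes at both ends like realistic oscillation bursts.
#' For a fixed cycle count the duration is frequency dependent
#' (`n_cycles / frequency` seconds), as neural bursts are shorter at higher
#' frequencies.
#'
#' @param frequency Carrier frequency in Hz.
#' @param n_cycles Integer number of cycles (`>= 1`).
#' @param amplitude Pre-scaling amplitude of the envelope peak (default 1).
#' @param onset_s Start time of the atom within its trial, in seconds.
#' @param scale_k SNR calibration factor (filled by [snr_scale()]).
#' @return A list of class `atom_spec`.
#' @export
atom_spec <- function(frequency, n_cycles, amplitude = 1, onset_s = 0,
                      scale_k = NA_real_) {
  stopifnot(frequency > 0, n_cycles >= 1)
  structure(list(frequency = frequency, n_cycles = as.integer(n_cycles),
                 amplitude = amplitude, onset_s = onset_s,
                 scale_k = scale_k),
            class = "atom_spec")
}

#' Generate the waveform of a Gaussian atom
#'
#' @param spec An [atom_spec()].
#' @param fs Sampling rate in Hz; must exceed twice the atom frequency.
#' @return An [signal_ts()] of `round(n_cycles / frequency * fs)` samples.
#' @export
make_atom <- function(spec, fs) {
  stopifnot(inherits(spec, "atom_spec"))
  if (fs <= 2 * spec$frequency)
    stop("sampling rate must exceed twice the atom frequency")
  dur <- spec$n_cycles / spec$frequency
  n <- round(dur * fs)
  t <- (seq_len(n) - 1L) / fs
  center <- (n - 1L) / (2 * fs)
  sigma <- dur / 6
  env <- spec$amplitude * exp(-(t - center)^2 / (2 * sigma^2))
  signal_ts(env * sin(2 * pi * spec$frequency * (t - center)), fs)
}

#' Pink (1/f) noise via the Voss-McCartney algorithm
#'
#' Sums `n_rows` random-hold generators whose values are redrawn every
#' `2^k` samples (`k = 0 .. n_rows - 1`), giving an approximately 1/f
#' power spectrum over the band the generators cover. The mean is removed.
#'
#' @param n Number of samples (`>= 2`).
#' @param fs Sampling rate in Hz.
#' @param n_rows Number of coefficient generator rows (default 30).
#' @param seed Optional integer for reproducible output (local RNG scope).
#' @return An [signal_ts()].
#' @export
pink_noise <- function(n, fs, n_rows = 30L, seed = NULL) {
  stopifnot(n >= 2, n_rows >= 1)
  .with_seed(seed, {
    x <- numeric(n)
    for (k in seq_len(n_rows) - 1L) {
      period <- 2^k
      nvals <- ceiling(n / period)
      x <- x + rep(stats::rnorm(nvals), each = period, length.out = n)
    }
    signal_ts(x - mean(x), fs)
  })
}

#' Brown (1/f^2) noise by integrating white noise
#'
#' @inheritParams pink_noise
#' @return An [signal_ts()] with zero mean.
#' @export
brown_noise <- function(n, fs, seed = NULL) {
  stopifnot(n >= 2)
  .with_seed(seed, {
    x <- cumsum(stats::rnorm(n))
    signal_ts(x - mean(x), fs)
  })
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (bidirectional) 3rd-order Butterworth band-pass, so the
#' output has no phase distortion.
#'
#' @param x An [signal_ts()] object.
#' @param low_hz,high_hz Band edges in Hz; `0 < low < high < fs/2`.
#' @param order Butterworth order (default 3).
#' @return The filtered [signal_ts()].
#' @export
band_filter <- function(x, low_hz, high_hz, order = 3L) {
  x <- as_signal(x)
  if (!(low_hz > 0 && high_hz > low_hz && high_hz < x$fs / 2))
    stop("need 0 < low_hz < high_hz < fs/2")
  bf <- signal::butter(order, c(low_hz, high_hz) / (x$fs / 2), type = "pass")
  signal_ts(signal::filtfilt(bf, x$samples), x$fs)
}

#' Scale an atom to a target signal-to-noise ratio
#'
#' SNR is defined as the ratio of signal variance to background variance
#' (linear in power for zero-mean signals). The scale factor is
#' `k = sqrt(snr) * sd(background) / sd(atom)`, with the atom's variance
#' taken over its own sample window and the background's over the whole
#' trial, so that `Var(k * atom) / Var(background) == snr` exactly.
#'
#' @param atom Atom waveform ([signal_ts()] or numeric).
#' @param background Background trial ([signal_ts()] or numeric).
#' @param snr Target variance ratio (`> 0`).
#' @return List with `k` (the scale factor) and `scaled` (the scaled atom
#'   samples).
#' @export
snr_scale <- function(atom, background, snr) {
  a <- if (inherits(atom, "osc_signal")) atom$samples else as.numeric(atom)
  b <- if (inherits(background, "osc_signal")) background$samples
       else as.numeric(background)
  stopifnot(snr > 0)
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) stop("zero-variance input")
  k <- sqrt(snr) * sb / sa
  list(k = k, scaled = k * a)
}

#' Ground-truth region of interest of an atom
#'
#' Computes the TFR of the atom alone (embedded at its onset in an
#' otherwise silent trial, so grid coordinates line up with the composite
#' trial's TFR) and takes all cells with power at or above 20% of the peak
#' as the reference roi; the bounding box is the roi's tight cover.
#'
#' @param spec An [atom_spec()] with its `onset_s` set.
#' @param fs Sampling rate in Hz.
#' @param tfr_cfg TFR configuration used for detection (the roi is defined
#'   on the noise-free TFR under the same front-end).
#' @param trial_s Trial length in seconds.
#' @return A list of class `ground_truth_packet` with `roi`, `bbox`,
#'   `atom_time_s` (envelope center), `atom_freq_hz`, and the grid axes.
#' @export
ground_truth_roi <- function(spec, fs, tfr_cfg, trial_s) {
  stopifnot(inherits(spec, "atom_spec"))
  if (spec$frequency < tfr_cfg$freq_min || spec$frequency > tfr_cfg$freq_max)
    stop("atom frequency outside the TFR frequency range")
  n <- round(trial_s * fs)
  atom <- make_atom(spec, fs)
  i0 <- round(spec$onset_s * fs) + 1L
  if (i0 + length(atom$samples) - 1L > n)
    stop("atom does not fit in the trial")
  x <- numeric(n)
  x[i0:(i0 + length(atom$samples) - 1L)] <- atom$samples
  tfr <- compute_tfr(signal_ts(x, fs), tfr_cfg)
  .gt_from_tfr(tfr, spec)
}

.gt_from_tfr <- function(tfr, spec) {
  g <- tfr$power
  nf <- nrow(g)
  cells <- which(g >= 0.2 * max(g))
  tf <- .cells_to_tf(cells, nf)
  dur <- spec$n_cycles / spec$frequency
  structure(list(
    roi = tf[order(cells), , drop = FALSE],
    bbox = c(t0 = min(tf[, "t"]), t1 = max(tf[, "t"]),
             f0 = min(tf[, "f"]), f1 = max(tf[, "f"])),
    atom_time_s = spec$onset_s + dur / 2,
    atom_freq_hz = spec$frequency,
    freq_axis = tfr$freq_axis, time_axis = tfr$time_axis,
    dims = dim(g)
  ), class = "ground_truth_packet")
}

#' Benchmark protocol
#'
#' Study conditions for the synthetic detection benchmark: `n_atoms`
#' ten-cycle atoms with uniformly random frequencies, each embedded in its
#' own band-limited noise trial and calibrated to every SNR level (the
#' same atom configuration is repeated across levels).
#'
#' @param n_atoms Number of distinct atom configurations (default 200).
#' @param n_cycles Cycles per atom (default 10).
#' @param freq_range Atom frequency range in Hz (default 35-95).
#' @param snr_levels SNR levels (default 0.1, 0.25, 0.5, 1, 2).
#' @param band Background band-pass range in Hz (default 30-100).
#' @param background `"pink"` or `"brown"` noise backgrounds.
#' @param trial_s Trial length in seconds (default 5).
#' @param fs Sampling rate in Hz (default 1000).
#' @param edge_margin_s Minimum distance of the whole atom from the trial
#'   edges (default 0.25 s, avoiding TFR edge effects).
#' @param n_rows Voss-McCartney rows for pink backgrounds (default 30).
#' @param seed Master seed fixing the whole benchmark set.
#' @return A list of class `benchmark_protocol`.
#' @export
benchmark_protocol <- function(n_atoms = 200L, n_cycles = 10L,
                               freq_range = c(35, 95),
                               snr_levels = c(0.1, 0.25, 0.5, 1, 2),
                               band = c(30, 100), background = c("pink", "brown"),
                               trial_s = 5, fs = 1000, edge_margin_s = 0.25,
                               n_rows = 30L, seed = 1L) {
  stopifnot(n_atoms >= 1, n_cycles >= 1, all(snr_levels > 0),
            freq_range[1L] >= band[1L], freq_range[2L] <= band[2L])
  structure(list(n_atoms = as.integer(n_atoms),
                 n_cycles = as.integer(n_cycles), freq_range = freq_range,
                 snr_levels = snr_levels, band = band,
                 background = match.arg(background), trial_s = trial_s,
                 fs = fs, edge_margin_s = edge_margin_s,
                 n_rows = as.integer(n_rows), seed = as.integer(seed)),
            class = "benchmark_protocol")
}

#' Build the synthetic benchmark set
#'
#' Draws `n_atoms` atom configurations (uniform frequency in range, random
#' onset keeping the atom away from the trial edges), generates one fresh
#' band-filtered noise trial per atom, calibrates the atom to every SNR
#' level against its own trial via [snr_scale()], and embeds it by
#' addition. The instance list (`n_atoms * length(snr_levels)` composite
#' trials) is fully determined by the protocol's master seed.
#'
#' @param protocol A [benchmark_protocol()].
#' @param backgrounds Optional list of user-supplied background trials
#'   ([signal_ts()] objects of the protocol's trial length), recycled over
#'   atoms; they are band-filtered like the generated noise.
#' @return A list of class `benchmark_set` with `atoms` (specs and shared
#'   per-atom data) and `instances` (one entry per atom x SNR:
#'   `atom_id`, `snr`, `k` and the composite [signal_ts()]).
#' @export
build_benchmark_set <- function(protocol, backgrounds = NULL) {
  stopifnot(inherits(protocol, "benchmark_protocol"))
  p <- protocol
  n <- round(p$trial_s * p$fs)
  .with_seed(p$seed, {
    atoms <- vector("list", p$n_atoms)
    instances <- vector("list", p$n_atoms * length(p$snr_levels))
    ii <- 0L
    for (a in seq_len(p$n_atoms)) {
      freq <- stats::runif(1L, p$freq_range[1L], p$freq_range[2L])
      dur <- p$n_cycles / freq
      if (p$trial_s - dur - 2 * p$edge_margin_s <= 0)
        stop("atom longer than the trial minus its edge margins")
      onset <- stats::runif(1L, p$edge_margin_s,
                            p$trial_s - p$edge_margin_s - dur)
      bg_raw <- if (!is.null(backgrounds)) {
        bg <- backgrounds[[(a - 1L) %% length(backgrounds) + 1L]]
        if (length(bg$samples) != n)
          stop("user-supplied background trial has the wrong length")
        bg
      } else if (p$background == "pink") {
        pink_noise(n, p$fs, n_rows = p$n_rows)
      } else {
        brown_noise(n, p$fs)
      }
      bg <- band_filter(bg_raw, p$band[1L], p$band[2L])
      spec <- atom_spec(freq, p$n_cycles, onset_s = onset)
      atom <- make_atom(spec, p$fs)
      i0 <- round(onset * p$fs) + 1L
      idx <- i0:(i0 + length(atom$samples) - 1L)
      atoms[[a]] <- list(spec = spec, background = bg)
      for (s in p$snr_levels) {
        cal <- snr_scale(atom, bg, s)
        comp <- bg$samples
        comp[idx] <- comp[idx] + cal$scaled
        ii <- ii + 1L
        instances[[ii]] <- list(atom_id = a, snr = s, k = cal$k,
                                signal = signal_ts(comp, p$fs))
      }
    }
    structure(list(protocol = p, atoms = atoms, instances = instances),
              class = "benchmark_set")
  })
}

#' @export
print.benchmark_set <- function(x, ...) {
  cat(sprintf("<benchmark_set> %d atoms x %d SNR levels = %d instances (%s noise, %g s @ %g Hz)\n",
              x$protocol$n_atoms, length(x$protocol$snr_levels),
              length(x$instances), x$protocol$background,
              x$protocol$trial_s, x$protocol$fs))
  invisible(x)
}
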