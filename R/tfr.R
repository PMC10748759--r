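#' Construct a time-frequency power grid
#'
#' The common substrate all detectors operate on: a matrix of nonnegative
#' power values indexed `[frequency, time]` with explicit axes.
#'
#' @param power Numeric matrix, rows = frequencies, columns = time points;
#'   all entries finite and `>= 0`.
#' @param freq_axis Strictly increasing, linearly spaced frequency axis (Hz),
#'   one entry per row.
#' @param time_axis Strictly increasing, uniformly stepped time axis (s),
#'   one entry per column.
#' @return An object of class `tfr_grid`.
#' @export
tfr_grid <- function(power, freq_axis, time_axis) {
  power <- as.matrix(power)
  if (!is.numeric(power) || !all(is.finite(power)))
    stop("`power` must be a finite numeric matrix")
  if (any(power < 0)) stop("`power` must be nonnegative")
  freq_axis <- as.numeric(freq_axis)
  time_axis <- as.numeric(time_axis)
  if (nrow(power) != length(freq_axis))
    stop("nrow(power) must equal length(freq_axis)")
  if (ncol(power) != length(time_axis))
    stop("ncol(power) must equal length(time_axis)")
  .check_axis(freq_axis, "freq_axis")
  .check_axis(time_axis, "time_axis")
  structure(list(power = power, freq_axis = freq_axis,
                 time_axis = time_axis),
            class = "tfr_grid")
}

.check_axis <- function(ax, what) {
  if (length(ax) > 1L) {
    d <- diff(ax)
    if (any(d <= 0)) stop("`", what, "` must be strictly increasing")
    if (length(d) > 1L && max(abs(d - d[1L])) > 1e-6 * abs(d[1L]))
      stop("`", what, "` must be uniformly spaced")
  }
  invisible(ax)
}

#' @export
print.tfr_grid <- function(x, ...) {
  cat(sprintf(paste0("<tfr_grid> %d freqs x %d times | %g-%g Hz | ",
                     "%.3f-%.3f s | max power %.4g\n"),
              nrow(x$power), ncol(x$power),
              min(x$freq_axis), max(x$freq_axis),
              min(x$time_axis), max(x$time_axis), max(x$power)))
  invisible(x)
}

#' @export
#' @importFrom graphics image
plot.tfr_grid <- function(x, main = "TFR power", ...) {
  image(x$time_axis, x$freq_axis, t(x$power), xlab = "Time (s)",
        ylab = "Frequency (Hz)", main = main,
        col = grDevices::hcl.colors(64, "Inferno"), ...)
  invisible(x)
}

## ------------------------------------------------------------------ configs

#' TFR configurations
#'
#' `slt_config()` parameterizes the superlet transform: at each frequency the
#' response is the geometric mean of `o(f)` amplitude-normalized Morlet
#' responses with `i * c1` cycles (`i = 1..o(f)`); the order `o(f)` is
#' interpolated linearly from `order_min` at `freq_min` to `order_max` at
#' `freq_max` and rounded to the nearest integer (ties up).
#' `cwt_config()` parameterizes a single Morlet scalogram, and
#' `stft_config()` a sliding-window spectrogram with zero-padding to a fixed
#' frequency bin density.
#'
#' @param c1 Base cycle count of the superlet set (integer `>= 1`).
#' @param order_min,order_max Superlet order range (integers `>= 1`; equal
#'   values give a fixed order).
#' @param freq_min,freq_max Frequency range of the output axis (Hz).
#' @param bins_per_hz Frequency bins per Hz on the output axis.
#' @param cycles Morlet cycle count for the scalogram.
#' @param window_ms STFT window length in milliseconds.
#' @param step_ms Hop between output time points in milliseconds (for the
#'   wavelet transforms this only decimates the output columns; the
#'   convolution is always computed at the full sampling rate).
#' @param window_kind Taper: `"blackman"`, `"hanning"` or `"hamming"`.
#' @return A config list of class `slt_config`, `cwt_config` or
#'   `stft_config`.
#' @name tfr_config
NULL

#' @rdname tfr_config
#' @export
slt_config <- function(freq_min, freq_max, c1 = 3L, order_min = 10L,
                       order_max = 10L, bins_per_hz = 1, step_ms = 1) {
  stopifnot(c1 >= 1, order_min >= 1, order_max >= 1,
            order_min <= order_max, freq_min > 0, freq_max > freq_min,
            bins_per_hz >= 1, step_ms > 0)
  structure(list(c1 = as.integer(c1), order_min = as.integer(order_min),
                 order_max = as.integer(order_max), freq_min = freq_min,
                 freq_max = freq_max, bins_per_hz = bins_per_hz,
                 step_ms = step_ms),
            class = "slt_config")
}

#' @rdname tfr_config
#' @export
cwt_config <- function(freq_min, freq_max, cycles = 7L, bins_per_hz = 1,
                       step_ms = 1) {
  stopifnot(cycles >= 1, freq_min > 0, freq_max > freq_min, bins_per_hz >= 1,
            step_ms > 0)
  structure(list(cycles = as.integer(cycles), freq_min = freq_min,
                 freq_max = freq_max, bins_per_hz = bins_per_hz,
                 step_ms = step_ms),
            class = "cwt_config")
}

#' @rdname tfr_config
#' @export
stft_config <- function(freq_min, freq_max, window_ms = 250, step_ms = 1,
                        bins_per_hz = 4,
                        window_kind = c("blackman", "hanning", "hamming")) {
  stopifnot(window_ms > 0, step_ms > 0, bins_per_hz >= 1, freq_min >= 0,
            freq_max > freq_min)
  structure(list(window_ms = window_ms, step_ms = step_ms,
                 bins_per_hz = bins_per_hz,
                 window_kind = match.arg(window_kind), freq_min = freq_min,
                 freq_max = freq_max),
            class = "stft_config")
}

## --------------------------------------------------------- wavelet machinery

.freq_axis_of <- function(cfg) {
  seq(cfg$freq_min, cfg$freq_max, by = 1 / cfg$bins_per_hz)
}

# nearest integer, ties rounded up
.round_half_up <- function(x) floor(x + 0.5)

.slt_orders <- function(cfg, freqs) {
  if (cfg$order_min == cfg$order_max || length(freqs) == 1L)
    return(rep(cfg$order_min, length(freqs)))
  span <- max(freqs) - min(freqs)
  o <- cfg$order_min + (cfg$order_max - cfg$order_min) *
    (freqs - min(freqs)) / span
  pmax(1L, as.integer(.round_half_up(o)))
}

# Complex Morlet kernel: unit-amplitude carrier under a Gaussian envelope
# whose +-3 SD support spans `cycles` periods of `f0`; amplitude-normalized
# by the discrete modulus integral of the envelope so that a sustained unit
# sine yields a response magnitude of 1/2 at any frequency.
.morlet_kernel <- function(f0, cycles, fs) {
  sigma <- cycles / (6 * f0)                  # seconds
  hl <- as.integer(max(1, ceiling(3 * sigma * fs)))
  t <- (-hl:hl) / fs
  env <- exp(-t^2 / (2 * sigma^2))
  kern <- env * exp(2i * pi * f0 * t) / sum(env)
  list(kern = kern, hl = hl)
}

# Precompute FFT'd kernels for a signal length `n` so many equal-length
# signals can share one engine (used by the benchmark harness). `step`
# decimates the output time axis (samples per output column).
.wavelet_engine <- function(freqs, cycles_list, fs, n, step = 1L) {
  kerns <- vector("list", length(freqs))
  hlmax <- 0L
  for (i in seq_along(freqs)) {
    kerns[[i]] <- lapply(cycles_list[[i]],
                         function(cy) .morlet_kernel(freqs[i], cy, fs))
    hlmax <- max(hlmax, vapply(kerns[[i]], function(k) k$hl, integer(1)))
  }
  if (hlmax >= n)
    stop("signal too short for the lowest-frequency wavelet kernel (",
         "needs > ", hlmax, " samples, got ", n, ")")
  npad <- n + 2L * hlmax
  N2 <- stats::nextn(npad + 2L * hlmax + 1L, 2)
  kfft <- lapply(kerns, function(kl) {
    lapply(kl, function(k) {
      list(fft = stats::fft(c(k$kern, rep(0, N2 - length(k$kern)))),
           hl = k$hl)
    })
  })
  sel <- seq(1L, n, by = as.integer(step))
  list(freqs = freqs, fs = fs, n = n, hlmax = hlmax, N2 = N2, kfft = kfft,
       sel = sel, time_axis = (sel - 1L) / fs)
}

.wavelet_apply <- function(engine, x) {
  n <- engine$n
  if (length(x) != n) stop("engine was built for length ", n, " signals")
  hlmax <- engine$hlmax
  xp <- c(x[(hlmax + 1L):2L], x, x[(n - 1L):(n - hlmax)])
  X <- stats::fft(c(xp, rep(0, engine$N2 - length(xp))))
  nf <- length(engine$freqs)
  sel <- engine$sel
  nt <- length(sel)
  power <- matrix(0, nrow = nf, ncol = nt)
  for (i in seq_len(nf)) {
    members <- engine$kfft[[i]]
    o <- length(members)
    logsum <- numeric(nt)
    zero_hit <- rep(FALSE, nt)
    for (m in members) {
      y <- stats::fft(X * m$fft, inverse = TRUE) / engine$N2
      seg <- y[hlmax + m$hl + sel]
      mag <- Mod(seg)
      zero_hit <- zero_hit | mag == 0
      logsum <- logsum + log(pmax(mag, .Machine$double.xmin))
    }
    gm <- exp(logsum / o)
    gm[zero_hit] <- 0
    power[i, ] <- gm^2
  }
  power
}

## -------------------------------------------------------------- transforms

#' Morlet continuous wavelet transform (scalogram)
#'
#' Convolves the signal with complex Morlet wavelets whose Gaussian envelope
#' spans the requested number of cycles within +-3 SD. Kernels are
#' amplitude-normalized (divided by the modulus integral of the envelope) so
#' that the peak power of an N-cycle burst is the same at any frequency;
#' power is the squared magnitude of the complex response. The signal is
#' reflect-padded by one maximal kernel half-length.
#'
#' @param x An [signal_ts()] object.
#' @param cfg A [cwt_config()].
#' @return A [tfr_grid()] with one column per input sample.
#' @export
compute_cwt <- function(x, cfg) {
  x <- as_signal(x)
  stopifnot(inherits(cfg, "cwt_config"))
  if (cfg$freq_max >= x$fs / 2)
    stop("frequency range must lie below the Nyquist frequency")
  freqs <- .freq_axis_of(cfg)
  eng <- .wavelet_engine(freqs, rep(list(cfg$cycles), length(freqs)),
                         x$fs, length(x$samples),
                         step = max(1, round(cfg$step_ms * x$fs / 1000)))
  tfr_grid(.wavelet_apply(eng, x$samples), freqs, eng$time_axis)
}

#' Superlet transform
#'
#' At each frequency the response is the geometric mean of the magnitudes of
#' `o(f)` amplitude-normalized Morlet responses with cycle counts
#' `c1, 2*c1, ..., o(f)*c1` (multiplicative superlet); power is the squared
#' geometric-mean magnitude. With `order_min = order_max = 1` this reduces
#' exactly to [compute_cwt()] with `cycles = c1`.
#'
#' @param x An [signal_ts()] object.
#' @param cfg An [slt_config()].
#' @return A [tfr_grid()] with one column per input sample.
#' @export
compute_slt <- function(x, cfg) {
  x <- as_signal(x)
  stopifnot(inherits(cfg, "slt_config"))
  if (cfg$freq_max >= x$fs / 2)
    stop("frequency range must lie below the Nyquist frequency")
  freqs <- .freq_axis_of(cfg)
  orders <- .slt_orders(cfg, freqs)
  cycles_list <- lapply(orders, function(o) seq_len(o) * cfg$c1)
  eng <- .wavelet_engine(freqs, cycles_list, x$fs, length(x$samples),
                         step = max(1, round(cfg$step_ms * x$fs / 1000)))
  tfr_grid(.wavelet_apply(eng, x$samples), freqs, eng$time_axis)
}

#' Short-time Fourier transform spectrogram
#'
#' Tapered windows (Blackman by default) are centered on each output time
#' point and the transform is zero-padded so the frequency spacing is
#' `1 / bins_per_hz` Hz. The signal is reflect-padded by one half-window so
#' the time axis covers the whole signal; the window length is rounded to an
#' odd sample count so windows are symmetric about their center. Power is
#' the squared magnitude of the (window-mass-normalized) transform.
#'
#' @param x An [signal_ts()] object.
#' @param cfg An [stft_config()].
#' @return A [tfr_grid()] with time step `step_ms`.
#' @export
compute_stft <- function(x, cfg) {
  x <- as_signal(x)
  stopifnot(inherits(cfg, "stft_config"))
  fs <- x$fs
  n <- length(x$samples)
  if (cfg$freq_max > fs / 2)
    stop("frequency range must lie at or below the Nyquist frequency")
  wl <- 2L * max(1L, floor(cfg$window_ms * fs / 2000)) + 1L
  if (wl > n) stop("STFT window (", wl, " samples) longer than the signal")
  nfft <- as.integer(round(fs * cfg$bins_per_hz))
  if (abs(nfft - fs * cfg$bins_per_hz) > 1e-8)
    stop("fs * bins_per_hz must be an integer FFT length")
  if (nfft < wl)
    stop("bins_per_hz too small: FFT length ", nfft,
         " is shorter than the window (", wl, " samples)")
  step <- max(1L, as.integer(round(cfg$step_ms * fs / 1000)))
  w <- switch(cfg$window_kind,
              blackman = signal::blackman(wl),
              hanning = signal::hanning(wl),
              hamming = signal::hamming(wl))
  hw <- (wl - 1L) %/% 2L
  xp <- c(x$samples[(hw + 1L):2L], x$samples, x$samples[(n - 1L):(n - hw)])
  starts <- seq(1L, n, by = step)            # window center = original index
  freqs_all <- (seq_len(nfft) - 1L) * fs / nfft
  sel <- which(freqs_all >= cfg$freq_min - 1e-9 &
               freqs_all <= cfg$freq_max + 1e-9 & freqs_all <= fs / 2)
  power <- matrix(0, nrow = length(sel), ncol = length(starts))
  wsum <- sum(w)
  block <- 512L
  for (b0 in seq(1L, length(starts), by = block)) {
    idx <- b0:min(b0 + block - 1L, length(starts))
    frames <- vapply(starts[idx],
                     function(s) xp[s:(s + wl - 1L)] * w,
                     numeric(wl))
    frames <- rbind(frames, matrix(0, nrow = nfft - wl, ncol = length(idx)))
    spec <- stats::mvfft(frames)
    power[, idx] <- Mod(spec[sel, , drop = FALSE] / wsum)^2
  }
  tfr_grid(power, freqs_all[sel], (starts - 1L) / fs)
}

#' Compute a TFR from a signal given any front-end configuration
#'
#' Dispatches on the configuration class ([slt_config()], [cwt_config()] or
#' [stft_config()]).
#'
#' @param x An [signal_ts()] object.
#' @param cfg A TFR configuration.
#' @return A [tfr_grid()].
#' @export
compute_tfr <- function(x, cfg) {
  if (inherits(cfg, "slt_config")) return(compute_slt(x, cfg))
  if (inherits(cfg, "cwt_config")) return(compute_cwt(x, cfg))
  if (inherits(cfg, "stft_config")) return(compute_stft(x, cfg))
  stop("unknown TFR configuration of class ", paste(class(cfg), collapse = "/"))
}

## ----------------------------------------------------------------- disk I/O

#' Read/write a TFR grid as delimited text
#'
#' The format is a tab-separated matrix: the first line holds
#' `freq_hz\\time_s` followed by the time axis; each further line holds a
#' frequency value followed by that row of the power matrix. Full double
#' precision is written so grids round-trip exactly.
#'
#' @param grid A [tfr_grid()].
#' @param path File path.
#' @return `write_tfr()` returns `path` invisibly; `read_tfr()` returns a
#'   [tfr_grid()].
#' @export
write_tfr <- function(grid, path) {
  stopifnot(inherits(grid, "tfr_grid"))
  fmt <- function(v) format(v, digits = 17, trim = TRUE)
  lines <- c(paste(c("freq_hz\\time_s", fmt(grid$time_axis)),
                   collapse = "\t"),
             vapply(seq_along(grid$freq_axis), function(i) {
               paste(c(fmt(grid$freq_axis[i]), fmt(grid$power[i, ])),
                     collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_tfr
#' @export
read_tfr <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("not a TFR grid file: ", path)
  head <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  time_axis <- as.numeric(head[-1L])
  rows <- lapply(lines[-1L], function(l)
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1L]]))
  freq_axis <- vapply(rows, `[`, numeric(1), 1L)
  power <- do.call(rbind, lapply(rows, `[`, -1L))
  tfr_grid(power, freq_axis, time_axis)
}
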