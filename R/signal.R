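#' Construct a sampled signal
#'
#' A signal is a finite real-valued sample vector together with its sampling
#' rate. All analysis functions in the package take signals in this form.
#'
#' @param samples Numeric vector of at least two finite samples (arbitrary
#'   amplitude units).
#' @param fs Sampling rate in Hz (positive scalar).
#' @return An object of class `osc_signal`: a list with elements `samples`
#'   and `fs`.
#' @examples
#' s <- signal_ts(sin(2 * pi * 10 * seq(0, 1, by = 1e-3)), fs = 1000)
#' s
#' @export
signal_ts <- function(samples, fs) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("a signal needs at least 2 samples")
  if (!all(is.finite(samples))) stop("signal samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive finite scalar (Hz)")
  structure(list(samples = samples, fs = as.numeric(fs)),
            class = "osc_signal")
}

as_signal <- function(x, fs = NULL) {
  if (inherits(x, "osc_signal")) return(x)
  if (is.null(fs)) stop("`fs` is required when `x` is a plain numeric vector")
  signal_ts(x, fs)
}

#' @export
print.osc_signal <- function(x, ...) {
  cat(sprintf("<osc_signal> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.osc_signal <- function(x) length(x$samples)

#' Read a signal from disk
#'
#' Supports single- or multi-column delimited text (one sample per row; one
#' column per channel) and headerless little-endian IEEE float binary.
#'
#' @param path File to read.
#' @param fs Sampling rate in Hz of the stored data.
#' @param format One of `"text"` (delimited), `"float32"` or `"float64"`
#'   (raw little-endian binary).
#' @return A single [signal_ts()] for one channel, or a named list of
#'   signals for multi-channel text files.
#' @export
read_signal <- function(path, fs, format = c("text", "float32", "float64")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "text") {
    dat <- tryCatch(utils::read.table(path, header = FALSE),
                    error = function(e) stop("malformed signal file '", path,
                                             "': ", conditionMessage(e)))
    if (nrow(dat) == 0L) stop("empty signal file: ", path)
    for (j in seq_len(ncol(dat))) {
      if (!is.numeric(dat[[j]]))
        stop("malformed signal file '", path, "': column ", j,
             " is not numeric")
    }
    if (ncol(dat) == 1L) return(signal_ts(dat[[1L]], fs))
    chans <- lapply(seq_len(ncol(dat)), function(j) signal_ts(dat[[j]], fs))
    names(chans) <- paste0("ch", seq_along(chans))
    return(chans)
  }
  size <- if (format == "float32") 4L else 8L
  n <- file.size(path) %/% size
  if (n < 2L) stop("binary signal file too short: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = n, size = size, endian = "little")
  signal_ts(x, fs)
}

#' Write a signal to disk
#'
#' @param x An [signal_ts()] object or numeric vector.
#' @param path Output file.
#' @param format `"text"` (one sample per line), `"float32"` or `"float64"`.
#' @return `path`, invisibly.
#' @export
write_signal <- function(x, path, format = c("text", "float32", "float64")) {
  format <- match.arg(format)
  samples <- if (inherits(x, "osc_signal")) x$samples else as.numeric(x)
  if (format == "text") {
    writeLines(format(samples, digits = 17, trim = TRUE, scientific = FALSE),
               path)
  } else {
    size <- if (format == "float32") 4L else 8L
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(samples, con, size = size, endian = "little")
  }
  invisible(path)
}
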