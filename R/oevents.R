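#' OEvents-style baseline detector configuration
#'
#' Bounding-box event detection by median thresholding: local maxima
#' exceeding `threshold_multiplier` times the median power (of their
#' frequency row, or of the whole TFR) seed boxes that grow while the
#' advancing edge keeps power above
#' `min(expansion_fraction * peak, threshold_multiplier * median)`;
#' heavily overlapping boxes are merged.
#'
#' @param threshold_multiplier Peak detection bound as a multiple of the
#'   median (default 4).
#' @param expansion_fraction Fraction of the peak power bounding the box
#'   expansion (default 0.5).
#' @param overlap_merge_fraction Two events are merged when their box
#'   overlap exceeds this fraction of the smaller box (default 0.5).
#' @param median_scope `"per-frequency"` (each row's own median) or
#'   `"whole-tfr"` (one global median).
#' @return A list of class `oevents_config`.
#' @export
oevents_config <- function(threshold_multiplier = 4,
                           expansion_fraction = 0.5,
                           overlap_merge_fraction = 0.5,
                           median_scope = c("per-frequency", "whole-tfr")) {
  stopifnot(threshold_multiplier > 0, expansion_fraction > 0,
            expansion_fraction <= 1, overlap_merge_fraction > 0,
            overlap_merge_fraction <= 1)
  structure(list(threshold_multiplier = threshold_multiplier,
                 expansion_fraction = expansion_fraction,
                 overlap_merge_fraction = overlap_merge_fraction,
                 median_scope = match.arg(median_scope)),
            class = "oevents_config")
}

#' Median power per frequency row (or of the whole grid)
#'
#' @param x A [tfr_grid()] or numeric matrix.
#' @param scope `"per-frequency"` for one median per row, `"whole-tfr"`
#'   for a single scalar.
#' @return Numeric vector of row medians, or a scalar.
#' @export
frequency_medians <- function(x, scope = c("per-frequency", "whole-tfr")) {
  scope <- match.arg(scope)
  g <- .grid_of(x)
  if (length(g) == 0L) stop("empty grid")
  if (scope == "whole-tfr") stats::median(as.vector(g))
  else apply(g, 1L, stats::median)
}

# Expand time bounds along the peak's frequency row and frequency bounds
# along the peak's time column, while the power stays at or above `bound`.
.grow_bbox <- function(g, f0, t0, bound) {
  nf <- nrow(g); nt <- ncol(g)
  ta <- t0; while (ta > 1L && g[f0, ta - 1L] >= bound) ta <- ta - 1L
  tb <- t0; while (tb < nt && g[f0, tb + 1L] >= bound) tb <- tb + 1L
  fa <- f0; while (fa > 1L && g[fa - 1L, t0] >= bound) fa <- fa - 1L
  fb <- f0; while (fb < nf && g[fb + 1L, t0] >= bound) fb <- fb + 1L
  c(t0 = ta, t1 = tb, f0 = fa, f1 = fb)
}

#' Detect oscillation events with the OEvents baseline
#'
#' Finds 3x3 local power maxima exceeding `threshold_multiplier` times the
#' reference median (the peak's frequency row, or the whole TFR), then seeks
#' each peak's time bounds along its frequency row and its frequency bounds
#' along its time column, expanding while the power stays at or above
#' `min(expansion_fraction * peak_power, threshold_multiplier * median)`,
#' then iteratively merges event pairs whose box overlap exceeds
#' `overlap_merge_fraction` of the smaller box area (the stronger peak is
#' retained, the union box kept) until stable.
#'
#' @param tfr A [tfr_grid()].
#' @param cfg An [oevents_config()].
#' @return An object of class `oevent_set` with one row per event in its
#'   `events` data.frame: peak indices/location, peak power, box index
#'   ranges, frequency span (Hz), time span (s) and peak frequency (Hz).
#' @export
oevents_detect <- function(tfr, cfg = oevents_config()) {
  stopifnot(inherits(tfr, "tfr_grid"), inherits(cfg, "oevents_config"))
  g <- tfr$power
  nf <- nrow(g); nt <- ncol(g)
  med <- frequency_medians(g, cfg$median_scope)
  med_of <- function(f) if (length(med) == 1L) med else med[f]
  maxima <- find_local_maxima(g, -Inf)
  keep <- g[cbind(maxima$f, maxima$t)] >
    cfg$threshold_multiplier * vapply(maxima$f, med_of, numeric(1))
  maxima <- maxima[keep, , drop = FALSE]
  events <- lapply(seq_len(nrow(maxima)), function(i) {
    f0 <- maxima$f[i]; t0 <- maxima$t[i]
    pk <- g[f0, t0]
    bound <- min(cfg$expansion_fraction * pk,
                 cfg$threshold_multiplier * med_of(f0))
    bb <- .grow_bbox(g, f0, t0, bound)
    list(peak_t = t0, peak_f = f0, peak_power = pk, bbox = bb)
  })
  n <- length(events)
  pt <- vapply(events, function(e) e$peak_t, integer(1))
  pf <- vapply(events, function(e) e$peak_f, integer(1))
  pw <- vapply(events, function(e) e$peak_power, numeric(1))
  t0v <- vapply(events, function(e) unname(e$bbox["t0"]), integer(1))
  t1v <- vapply(events, function(e) unname(e$bbox["t1"]), integer(1))
  f0v <- vapply(events, function(e) unname(e$bbox["f0"]), integer(1))
  f1v <- vapply(events, function(e) unname(e$bbox["f1"]), integer(1))
  # merge the first (lowest-index) qualifying pair, repeat until stable
  while (length(pw) > 1L) {
    ot <- outer(t1v, t1v, pmin) - outer(t0v, t0v, pmax) + 1
    of <- outer(f1v, f1v, pmin) - outer(f0v, f0v, pmax) + 1
    inter <- pmax(ot, 0) * pmax(of, 0)
    area <- as.numeric(t1v - t0v + 1) * (f1v - f0v + 1)
    qual <- inter > cfg$overlap_merge_fraction * outer(area, area, pmin)
    qual[!upper.tri(qual)] <- FALSE
    hit <- which(qual, arr.ind = TRUE)
    if (nrow(hit) == 0L) break
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    i <- hit[1L, 1L]; j <- hit[1L, 2L]
    strong <- if (pw[i] >= pw[j]) i else j
    weak <- if (strong == i) j else i
    t0v[strong] <- min(t0v[i], t0v[j]); t1v[strong] <- max(t1v[i], t1v[j])
    f0v[strong] <- min(f0v[i], f0v[j]); f1v[strong] <- max(f1v[i], f1v[j])
    keep <- -weak
    pt <- pt[keep]; pf <- pf[keep]; pw <- pw[keep]
    t0v <- t0v[keep]; t1v <- t1v[keep]
    f0v <- f0v[keep]; f1v <- f1v[keep]
  }
  df <- data.frame(peak_t = pt, peak_f = pf, peak_power = pw,
                   t0 = t0v, t1 = t1v, f0 = f0v, f1 = f1v)
  if (nrow(df)) {
    df$time_s <- tfr$time_axis[df$peak_t]
    df$freq_hz <- tfr$freq_axis[df$peak_f]
    df$time_span_s <- tfr$time_axis[df$t1] - tfr$time_axis[df$t0]
    df$freq_span_hz <- tfr$freq_axis[df$f1] - tfr$freq_axis[df$f0]
  } else {
    df$time_s <- df$freq_hz <- df$time_span_s <- df$freq_span_hz <- numeric(0)
  }
  structure(list(events = df, config = cfg, dims = c(nf, nt),
                 freq_axis = tfr$freq_axis, time_axis = tfr$time_axis),
            class = "oevent_set")
}

#' @export
print.oevent_set <- function(x, ...) {
  cat(sprintf("<oevent_set> %d event(s) | grid %d x %d\n",
              nrow(x$events), x$dims[1L], x$dims[2L]))
  invisible(x)
}

#' @export
as.data.frame.oevent_set <- function(x, ...) x$events
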