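#' Intersection-over-union match between two regions
#'
#' `m = |A intersect B| / |A union B|` over grid cell sets: 1 for identical
#' regions, 0 for disjoint ones; symmetric.
#'
#' @param a,b 2-column `(t, f)` index matrices (or vectors of linear cell
#'   ids on a common grid).
#' @return Match value in `[0, 1]`.
#' @export
match_measure <- function(a, b) {
  key <- function(x) {
    if (is.matrix(x)) paste(x[, 1L], x[, 2L]) else as.character(x)
  }
  ka <- unique(key(a)); kb <- unique(key(b))
  if (length(ka) == 0L && length(kb) == 0L) stop("both regions are empty")
  ni <- sum(ka %in% kb)
  ni / (length(ka) + length(kb) - ni)
}

.bbox_iou <- function(a, b) {
  ot <- min(a["t1"], b["t1"]) - max(a["t0"], b["t0"]) + 1
  of <- min(a["f1"], b["f1"]) - max(a["f0"], b["f0"]) + 1
  if (ot <= 0 || of <= 0) return(0)
  inter <- as.numeric(ot) * of
  aa <- as.numeric(a["t1"] - a["t0"] + 1) * (a["f1"] - a["f0"] + 1)
  ab <- as.numeric(b["t1"] - b["t0"] + 1) * (b["f1"] - b["f0"] + 1)
  inter / (aa + ab - inter)
}

.detection_candidates <- function(detections) {
  if (inherits(detections, "packet_set")) {
    lapply(.top_level(detections), function(p)
      list(bbox = p$bbox, roi = p$roi, peak_time_s = p$peak_time_s,
           peak_freq_hz = p$peak_freq_hz, id = p$id))
  } else if (inherits(detections, "oevent_set")) {
    ev <- detections$events
    lapply(seq_len(nrow(ev)), function(i)
      list(bbox = c(t0 = ev$t0[i], t1 = ev$t1[i], f0 = ev$f0[i],
                    f1 = ev$f1[i]),
           roi = NULL, peak_time_s = ev$time_s[i],
           peak_freq_hz = ev$freq_hz[i], id = i))
  } else stop("unsupported detection object")
}

#' Score one detection set against a ground-truth atom
#'
#' The best match is the detected packet maximizing the match measure `m`
#' against the ground truth (rectangular bounding boxes in `"bbox"` mode,
#' exact roi point sets in `"roi"` mode). The atom is missed iff no
#' detection has any overlap. Time and frequency errors are the absolute
#' differences between the best match's peak and the atom's envelope
#' center / nominal frequency; missed atoms carry no time, frequency or
#' box errors.
#'
#' @param gt A [ground_truth_roi()] result.
#' @param detections A `packet_set` or `oevent_set` from one detector run
#'   on the corresponding composite trial.
#' @param mode `"bbox"` or `"roi"` (roi mode requires contour-level
#'   detections, i.e. not an `oevent_set`).
#' @return A list of class `match_result` with `m`, `e = 1 - m`,
#'   `box_error`, `time_error_s`, `freq_error_hz`, `missed`, `best_id`.
#' @export
evaluate_detection <- function(gt, detections, mode = c("bbox", "roi")) {
  mode <- match.arg(mode)
  stopifnot(inherits(gt, "ground_truth_packet"))
  cands <- .detection_candidates(detections)
  if (mode == "roi" && length(cands) && is.null(cands[[1L]]$roi))
    stop("roi-mode evaluation needs contour-level detections")
  miss <- function() structure(list(m = 0, e = 1, box_error = NA_real_,
                                    time_error_s = NA_real_,
                                    freq_error_hz = NA_real_, missed = TRUE,
                                    best_id = NA_integer_),
                               class = "match_result")
  if (length(cands) == 0L) return(miss())
  ms <- vapply(cands, function(cd) {
    if (.bbox_iou(gt$bbox, cd$bbox) == 0) return(0)
    if (mode == "bbox") .bbox_iou(gt$bbox, cd$bbox)
    else match_measure(gt$roi, cd$roi)
  }, numeric(1))
  if (max(ms) == 0) return(miss())
  best <- which.max(ms)
  cd <- cands[[best]]
  structure(list(
    m = ms[best], e = 1 - ms[best],
    box_error = 1 - .bbox_iou(gt$bbox, cd$bbox),
    time_error_s = abs(cd$peak_time_s - gt$atom_time_s),
    freq_error_hz = abs(cd$peak_freq_hz - gt$atom_freq_hz),
    missed = FALSE, best_id = cd$id
  ), class = "match_result")
}

#' Run detectors over a synthetic benchmark set
#'
#' For every instance (atom x SNR) the composite trial's TFR is computed
#' with the given front-end, each requested detector is run on it, and the
#' detections are scored against the atom's noise-free ground-truth roi
#' (computed once per atom). Wavelet kernels are shared across the
#' equal-length trials.
#'
#' @param bench A [build_benchmark_set()] result.
#' @param tfr_cfg TFR configuration ([slt_config()], [cwt_config()] or
#'   [stft_config()]).
#' @param tfbm,tfpf,oevents Detector configurations.
#' @param algorithms Which detectors to run.
#' @param mode Evaluation mode passed to [evaluate_detection()] (OEvents
#'   is always scored on bounding boxes).
#' @param verbose Print progress.
#' @return A long-format data.frame: one row per instance x algorithm with
#'   columns `atom_id`, `snr`, `algorithm`, `m`, `e`, `box_error`,
#'   `time_error_s`, `freq_error_hz`, `missed`.
#' @export
run_benchmark <- function(bench, tfr_cfg,
                          tfbm = tfbm_config(90, 15, 1),
                          tfpf = tfpf_config(90, 30L),
                          oevents = oevents_config(),
                          algorithms = c("tfbm", "tfpf", "oevents"),
                          mode = c("bbox", "roi"), verbose = FALSE) {
  stopifnot(inherits(bench, "benchmark_set"))
  mode <- match.arg(mode)
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  p <- bench$protocol
  n <- round(p$trial_s * p$fs)
  wavelet <- inherits(tfr_cfg, "slt_config") || inherits(tfr_cfg, "cwt_config")
  eng <- NULL
  if (wavelet) {
    freqs <- .freq_axis_of(tfr_cfg)
    cycles_list <- if (inherits(tfr_cfg, "slt_config"))
      lapply(.slt_orders(tfr_cfg, freqs), function(o) seq_len(o) * tfr_cfg$c1)
    else rep(list(tfr_cfg$cycles), length(freqs))
    eng <- .wavelet_engine(freqs, cycles_list, p$fs, n,
                           step = max(1, round(tfr_cfg$step_ms * p$fs / 1000)))
  }
  as_tfr <- function(x) {
    if (wavelet)
      tfr_grid(.wavelet_apply(eng, x), eng$freqs, eng$time_axis)
    else compute_stft(signal_ts(x, p$fs), tfr_cfg)
  }
  gts <- lapply(bench$atoms, function(at) {
    spec <- at$spec
    atom <- make_atom(spec, p$fs)
    i0 <- round(spec$onset_s * p$fs) + 1L
    x <- numeric(n)
    x[i0:(i0 + length(atom$samples) - 1L)] <- atom$samples
    .gt_from_tfr(as_tfr(x), spec)
  })
  rows <- vector("list", length(bench$instances) * length(algorithms))
  ri <- 0L
  for (inst in bench$instances) {
    tfr <- as_tfr(inst$signal$samples)
    gt <- gts[[inst$atom_id]]
    for (alg in algorithms) {
      det <- switch(alg,
                    tfbm = tfbm_detect(tfr, tfbm),
                    tfpf = tfpf_detect(tfr, tfpf),
                    oevents = oevents_detect(tfr, oevents))
      mr <- evaluate_detection(gt, det,
                               mode = if (alg == "oevents") "bbox" else mode)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(atom_id = inst$atom_id, snr = inst$snr,
                               algorithm = alg, m = mr$m, e = mr$e,
                               box_error = mr$box_error,
                               time_error_s = mr$time_error_s,
                               freq_error_hz = mr$freq_error_hz,
                               missed = mr$missed)
    }
    if (verbose && inst$atom_id %% 10L == 0L)
      message("atom ", inst$atom_id, " snr ", inst$snr, " done")
  }
  do.call(rbind, rows)
}

#' Aggregate benchmark results
#'
#' Groups the long-format results and reports, per group, the mean and SD
#' of the error metrics over detected atoms, plus the percentage missed.
#'
#' @param results A [run_benchmark()] data.frame.
#' @param grouping Character vector of grouping columns (default
#'   `c("algorithm", "snr")`).
#' @return A data.frame of class `benchmark_summary`, one row per group.
#' @export
summarize_benchmark <- function(results, grouping = c("algorithm", "snr")) {
  if (nrow(results) == 0L) stop("empty results")
  keys <- interaction(results[grouping], drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(split(results, keys), function(d) {
    det <- d[!d$missed, , drop = FALSE]
    s <- d[1L, grouping, drop = FALSE]
    s$n <- nrow(d)
    s$percent_missed <- 100 * mean(d$missed)
    for (mt in c("e", "box_error", "time_error_s", "freq_error_hz")) {
      s[[paste0("mean_", mt)]] <- if (nrow(det)) mean(det[[mt]]) else NA_real_
      s[[paste0("sd_", mt)]] <- if (nrow(det) > 1L) stats::sd(det[[mt]])
                                else NA_real_
    }
    s
  }))
  rownames(out) <- NULL
  class(out) <- c("benchmark_summary", "data.frame")
  out
}

#' Paired comparison of two algorithms
#'
#' Paired t-tests of each error metric on jointly detected instances, with
#' Bonferroni correction over `n_comparisons` tests (adjusted p capped at
#' 1). Instances must be aligned (same atom x SNR order).
#'
#' @param results_a,results_b [run_benchmark()] rows for one algorithm
#'   each, in identical instance order.
#' @param n_comparisons Bonferroni factor (default: number of metrics).
#' @param metrics Metric columns to test.
#' @return A data.frame with `metric`, `t`, `df`, `p_raw`, `p_adj`, `n`.
#' @export
compare_algorithms <- function(results_a, results_b, n_comparisons = NULL,
                               metrics = c("box_error", "time_error_s",
                                           "freq_error_hz")) {
  if (nrow(results_a) != nrow(results_b))
    stop("paired result lists must have equal length")
  if (nrow(results_a) < 2L) stop("need at least 2 paired instances")
  if (is.null(n_comparisons)) n_comparisons <- length(metrics)
  joint <- !results_a$missed & !results_b$missed
  out <- lapply(metrics, function(mt) {
    x <- results_a[[mt]][joint]
    y <- results_b[[mt]][joint]
    d <- x - y
    if (length(d) < 2L || stats::sd(d) == 0) {
      return(data.frame(metric = mt, t = NA_real_,
                        df = length(d) - 1, p_raw = 1, p_adj = 1,
                        n = length(d)))
    }
    tt <- stats::t.test(x, y, paired = TRUE)
    data.frame(metric = mt, t = unname(tt$statistic),
               df = unname(tt$parameter), p_raw = tt$p.value,
               p_adj = min(1, tt$p.value * n_comparisons), n = length(d))
  })
  do.call(rbind, out)
}

#' Fraction of low-power TFR bins
#'
#' Percentage of grid bins whose power lies below `fraction` of the grid
#' maximum -- the power-distribution property motivating the automatic
#' percentile threshold (most of a TFR's dynamic range is covered by a
#' small fraction of bins when clear packets dominate).
#'
#' @param tfr A [tfr_grid()] or numeric matrix.
#' @param fraction Fraction of the dominant peak power (default 0.05).
#' @return Percentage in `[0, 100]`.
#' @export
power_concentration <- function(tfr, fraction = 0.05) {
  g <- .grid_of(tfr)
  100 * mean(g < fraction * max(g))
}
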