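# The desk-scale detection benchmark shared by the zero-miss and trend
# tests: 50 ten-cycle atoms (35-95 Hz) in band-limited pink noise, five SNR
# levels, SLT front-end with Fig-3-style detector parameters. Computed once
# per test run and cached.
benchmark_results <- local({
  cache <- new.env()
  function() {
    if (is.null(cache$res)) {
      proto <- benchmark_protocol(n_atoms = 50, seed = 1)
      bench <- build_benchmark_set(proto)
      cache$res <- run_benchmark(
        bench, slt_config(30, 100, c1 = 3, order_min = 10, order_max = 10,
                          bins_per_hz = 1, step_ms = 5),
        tfbm = tfbm_config(90, 15, 1), tfpf = tfpf_config(90, 30L),
        oevents = oevents_config())
    }
    cache$res
  }
})

# bootstrap SD of the difference in means of two independent samples
boot_sd_diff <- function(x, y, B = 1000L) {
  stats::sd(replicate(B, mean(sample(y, replace = TRUE)) -
                         mean(sample(x, replace = TRUE))))
}

# minimal hand-built detection containers for metric tests
fake_packet_set <- function(packets, dims, freq_axis, time_axis) {
  structure(list(packets = packets, algorithm = "manual", config = NULL,
                 dims = dims, freq_axis = freq_axis, time_axis = time_axis,
                 threshold = 0),
            class = "packet_set")
}

fake_packet <- function(id, roi, peak_tf, freq_axis, time_axis,
                        parent = NA_integer_) {
  colnames(roi) <- c("t", "f")
  structure(list(
    id = id, peak = c(t = peak_tf[1L], f = peak_tf[2L]),
    peak_time_s = time_axis[peak_tf[1L]],
    peak_freq_hz = freq_axis[peak_tf[2L]],
    peak_power = 100, prominence = 100, roi = roi, contour = roi,
    conflict_points = matrix(integer(0), 0, 2,
                             dimnames = list(NULL, c("t", "f"))),
    bbox = c(t0 = min(roi[, "t"]), t1 = max(roi[, "t"]),
             f0 = min(roi[, "f"]), f1 = max(roi[, "f"])),
    parent = parent, children = integer(0)
  ), class = "osc_packet")
}

fake_gt <- function(roi, time_s, freq_hz, dims, freq_axis, time_axis) {
  colnames(roi) <- c("t", "f")
  structure(list(
    roi = roi,
    bbox = c(t0 = min(roi[, "t"]), t1 = max(roi[, "t"]),
             f0 = min(roi[, "f"]), f1 = max(roi[, "f"])),
    atom_time_s = time_s, atom_freq_hz = freq_hz,
    freq_axis = freq_axis, time_axis = time_axis, dims = dims
  ), class = "ground_truth_packet")
}
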