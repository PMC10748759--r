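# oscpacket

Detection and delineation of oscillation packets in time-frequency
representations (TFRs) of neural signals.

Brain oscillations mostly occur as *packets* — transient bursts with a
finite extent in time and frequency that appear as localized power blobs in
a spectrogram, scalogram or superlet TFR. Standard burst detectors reduce
each event to a rectangular bounding box; `oscpacket` is for
electrophysiologists who want the exact contour, sub-peak structure and
hierarchy of each event instead. It provides:

- **TFR front-ends** — Blackman-window STFT spectrogram, amplitude-
  normalized Morlet scalogram, and the superlet transform (SLT): at each
  frequency `f` the SLT is the geometric mean of `o` Morlet responses with
  `c1, 2c1, ..., o·c1` cycles, giving sharper joint time-frequency
  localization than any single wavelet. The modulus-integral (amplitude)
  normalization makes an N-cycle burst's peak power frequency-independent,
  avoiding 1/f power dilution.
- **TFBM** (time-frequency breakdown method) — seeded region growing: local
  maxima above a percentile threshold are expanded strongest-first by a
  breadth-first search that admits a neighbor `n` of point `p` only if
  `power(n) < power(p)` and `dropoff(p) · D(p, PC) < power(n)`, where
  `dropoff(p)` is the drop to `p`'s weakest 8-neighbor and `D` a
  resolution-scaled distance to the packet center `PC`. Conflicting cells
  are disambiguated by peak-power/distance, and weakly separated packets
  merge into a hierarchy that keeps every sub-packet's ROI.
- **TFPF** (time-frequency peak finder) — descending level-set slicing with
  connected-component tracking: when ROIs merge, the largest peak takes
  ownership and the smaller ones are registered as sub-peaks with their
  pre-merge ROIs.
- **An OEvents-style baseline** — bounding boxes around 3×3 local maxima
  exceeding 4× the (per-frequency or whole-TFR) median power.
- **Synthetic ground truth and benchmarking** — Gaussian-windowed sine
  atoms (SD = length/6) embedded at exact variance-ratio SNR
  (`k = √SNR · sd(b)/sd(a)`) in band-limited Voss–McCartney pink noise or
  integrated-white brown noise; scoring by the intersection-over-union
  match `m = |A∩B| / |A∪B|` (error `e = 1 − m`) with a zero-overlap miss
  rule.

See `vignettes/oscillation-packet-detection.Rmd` for the full model
description, parameter meanings and design decisions.

## Worked example

Embed a 10-cycle 60 Hz atom at SNR 2 in band-limited pink noise, compute
the superlet TFR and delineate packets with TFBM:

```r
library(oscpacket)
fs <- 1000
bg <- band_filter(pink_noise(5 * fs, fs, seed = 42), 30, 100)
spec <- atom_spec(60, 10, onset_s = 2.0)           # 60 Hz, 10 cycles
cal <- snr_scale(make_atom(spec, fs), bg, 2)       # calibrate to SNR 2
x <- bg$samples
idx <- 2001:(2000 + length(cal$scaled))
x[idx] <- x[idx] + cal$scaled

tfr <- compute_slt(signal_ts(x, fs), slt_config(30, 100, step_ms = 5))
det <- tfbm_detect(tfr, tfbm_config(90, 15, 1))
det
#> <packet_set> tfbm: 43 top-level packet(s), 158 total | grid 71 x 1000 | threshold 8.88

df <- as.data.frame(det)
top <- df[is.na(df$parent), ]
head(top[order(-top$peak_power),
         c("id", "time_s", "freq_hz", "peak_power", "prominence", "roi_size")], 3)
#>  id time_s freq_hz peak_power prominence roi_size
#>   1  2.085      60  100.00000  100.00000      365
#>   2  1.920      60   33.02406   20.64667      176
#>   3  1.075      85   23.88567   20.74338      323

gt <- ground_truth_roi(spec, fs, slt_config(30, 100, step_ms = 5), 5)
mr <- evaluate_detection(gt, det, mode = "roi")
sprintf("best match m = %.2f, time error = %.0f ms, freq error = %.1f Hz",
        mr$m, 1000 * mr$time_error_s, mr$freq_error_hz)
#> "best match m = 0.46, time error = 2 ms, freq error = 0.0 Hz"
```

The strongest packet sits at 2.085 s / 60 Hz — the embedded atom's envelope
center (onset 2.0 s + half of its 167 ms duration) — with the grid's
maximal normalized power (100) and full prominence; the remaining packets
are noise structure far below it. The ground-truth comparison shows the
detected contour overlapping the atom's noise-free reference ROI with
m = 0.46 while the peak is located to within 2 ms and 0 Hz.

Detections serialize to JSON (`write_packets()`/`read_packets()`), grids to
delimited text (`write_tfr()`/`read_tfr()`), and a thin command-line
wrapper covers the pipeline end to end:

```sh
Rscript inst/cli/oscpacket.R tfr --input sig.txt --fs 1000 --tfr slt \
    --freq-min 30 --freq-max 100 --out grid.tsv
Rscript inst/cli/oscpacket.R detect tfbm --input grid.tsv --input-kind tfr \
    --threshold-percentile 90 --out packets.json
```

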