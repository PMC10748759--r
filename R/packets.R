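# Internal cell addressing: grids are [frequency, time] matrices; a cell is
# either a 1-based column-major linear index or a 2-column integer matrix
# with columns (t, f), 1-based. JSON output uses 0-based indices.

.cells_to_tf <- function(cells, nf) {
  cbind(t = ((cells - 1L) %/% nf) + 1L, f = ((cells - 1L) %% nf) + 1L)
}

.tf_to_cells <- function(tf, nf) {
  (tf[, 1L, drop = TRUE] - 1L) * nf + tf[, 2L, drop = TRUE]
}

.new_packet <- function(id, peak_cell, cells, nf, norm, freq_axis, time_axis,
                        prominence = NA_real_, conflicts = NULL) {
  tf <- .cells_to_tf(cells, nf)
  pk <- .cells_to_tf(peak_cell, nf)
  structure(list(
    id = id,
    peak = c(t = unname(pk[1L, "t"]), f = unname(pk[1L, "f"])),
    peak_time_s = time_axis[pk[1L, "t"]],
    peak_freq_hz = freq_axis[pk[1L, "f"]],
    peak_power = norm[peak_cell],
    prominence = prominence,
    roi = tf[order(cells), , drop = FALSE],
    contour = NULL,
    conflict_points = if (is.null(conflicts))
      matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("t", "f")))
    else conflicts,
    bbox = c(t0 = min(tf[, "t"]), t1 = max(tf[, "t"]),
             f0 = min(tf[, "f"]), f1 = max(tf[, "f"])),
    parent = NA_integer_,
    children = integer(0)
  ), class = "osc_packet")
}

.packet_set <- function(packets, algorithm, config, dims, freq_axis,
                        time_axis, threshold) {
  structure(list(packets = packets, algorithm = algorithm, config = config,
                 dims = dims, freq_axis = freq_axis, time_axis = time_axis,
                 threshold = threshold),
            class = "packet_set")
}

.top_level <- function(ps) Filter(function(p) is.na(p$parent), ps$packets)

#' @export
print.packet_set <- function(x, ...) {
  top <- .top_level(x)
  cat(sprintf("<packet_set> %s: %d top-level packet(s), %d total | grid %d x %d | threshold %.3g\n",
              x$algorithm, length(top), length(x$packets), x$dims[1L],
              x$dims[2L], x$threshold))
  invisible(x)
}

#' @export
summary.packet_set <- function(object, ...) {
  df <- as.data.frame(object)
  top <- df[is.na(df$parent), , drop = FALSE]
  cat(sprintf("%s detection: %d top-level packet(s) (%d with sub-peaks)\n",
              object$algorithm, nrow(top), sum(top$n_children > 0)))
  if (nrow(top)) {
    ord <- order(-top$peak_power)
    print(top[ord, c("id", "time_s", "freq_hz", "peak_power", "prominence",
                     "roi_size", "n_children")],
          row.names = FALSE, digits = 4)
  }
  invisible(df)
}

#' @export
as.data.frame.packet_set <- function(x, ...) {
  ps <- x$packets
  data.frame(
    id = vapply(ps, function(p) p$id, integer(1)),
    parent = vapply(ps, function(p) p$parent, integer(1)),
    n_children = vapply(ps, function(p) length(p$children), integer(1)),
    peak_t_idx = vapply(ps, function(p) unname(p$peak["t"]), integer(1)),
    peak_f_idx = vapply(ps, function(p) unname(p$peak["f"]), integer(1)),
    time_s = vapply(ps, function(p) p$peak_time_s, numeric(1)),
    freq_hz = vapply(ps, function(p) p$peak_freq_hz, numeric(1)),
    peak_power = vapply(ps, function(p) p$peak_power, numeric(1)),
    prominence = vapply(ps, function(p) p$prominence, numeric(1)),
    roi_size = vapply(ps, function(p) nrow(p$roi), integer(1)),
    t0 = vapply(ps, function(p) unname(p$bbox["t0"]), integer(1)),
    t1 = vapply(ps, function(p) unname(p$bbox["t1"]), integer(1)),
    f0 = vapply(ps, function(p) unname(p$bbox["f0"]), integer(1)),
    f1 = vapply(ps, function(p) unname(p$bbox["f1"]), integer(1))
  )
}

#' @export
#' @importFrom graphics points rect
plot.packet_set <- function(x, grid = NULL, show_bbox = TRUE, ...) {
  if (!is.null(grid)) plot(grid, ...)
  else {
    plot(NA, xlim = range(x$time_axis), ylim = range(x$freq_axis),
         xlab = "Time (s)", ylab = "Frequency (Hz)",
         main = paste(x$algorithm, "packets"))
  }
  for (p in .top_level(x)) {
    if (!is.null(p$contour) && nrow(p$contour))
      points(x$time_axis[p$contour[, "t"]], x$freq_axis[p$contour[, "f"]],
             pch = ".", cex = 1.5, col = "black")
    points(p$peak_time_s, p$peak_freq_hz, pch = 21, bg = "white")
    if (show_bbox)
      rect(x$time_axis[p$bbox["t0"]], x$freq_axis[p$bbox["f0"]],
           x$time_axis[p$bbox["t1"]], x$freq_axis[p$bbox["f1"]],
           border = "red", lty = 2)
  }
  invisible(x)
}

## ---------------------------------------------------------------- JSON I/O

.pt_out <- function(m) {
  if (is.null(m) || nrow(m) == 0L) return(list())
  unname(lapply(seq_len(nrow(m)), function(i)
    c(m[i, "t"] - 1L, m[i, "f"] - 1L)))
}

.pt_in <- function(lst) {
  if (length(lst) == 0L)
    return(matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("t", "f"))))
  m <- do.call(rbind, lapply(lst, function(v) as.integer(v) + 1L))
  colnames(m) <- c("t", "f")
  m
}

#' Write detected packets to JSON
#'
#' Serializes a full detection result. Point coordinates are written as
#' `[t_idx, f_idx]` pairs with 0-based indices; bounding boxes are closed
#' index ranges. Reading the file back reproduces every field exactly.
#'
#' @param x A `packet_set` (from [tfbm_detect()] or [tfpf_detect()]).
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_packets <- function(x, path) {
  stopifnot(inherits(x, "packet_set"))
  pk_json <- lapply(x$packets, function(p) {
    list(
      id = p$id,
      peak = list(t_idx = unname(p$peak["t"]) - 1L,
                  f_idx = unname(p$peak["f"]) - 1L,
                  time_s = p$peak_time_s, freq_hz = p$peak_freq_hz),
      peak_power = p$peak_power,
      prominence = p$prominence,
      bbox = list(t0 = unname(p$bbox["t0"]) - 1L,
                  t1 = unname(p$bbox["t1"]) - 1L,
                  f0 = unname(p$bbox["f0"]) - 1L,
                  f1 = unname(p$bbox["f1"]) - 1L),
      roi = .pt_out(p$roi),
      contour = .pt_out(p$contour),
      conflict_points = .pt_out(p$conflict_points),
      parent = if (is.na(p$parent)) NULL else p$parent,
      children = as.list(p$children)
    )
  })
  obj <- list(algorithm = x$algorithm, threshold = x$threshold,
              dims = as.list(x$dims), freq_axis = x$freq_axis,
              time_axis = x$time_axis, packets = pk_json)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_packets
#' @export
read_packets <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  dims <- as.integer(unlist(obj$dims))
  freq_axis <- as.numeric(unlist(obj$freq_axis))
  time_axis <- as.numeric(unlist(obj$time_axis))
  packets <- lapply(obj$packets, function(p) {
    structure(list(
      id = as.integer(p$id),
      peak = c(t = as.integer(p$peak$t_idx) + 1L,
               f = as.integer(p$peak$f_idx) + 1L),
      peak_time_s = as.numeric(p$peak$time_s),
      peak_freq_hz = as.numeric(p$peak$freq_hz),
      peak_power = as.numeric(p$peak_power),
      prominence = as.numeric(p$prominence),
      roi = .pt_in(p$roi),
      contour = .pt_in(p$contour),
      conflict_points = .pt_in(p$conflict_points),
      bbox = c(t0 = as.integer(p$bbox$t0) + 1L,
               t1 = as.integer(p$bbox$t1) + 1L,
               f0 = as.integer(p$bbox$f0) + 1L,
               f1 = as.integer(p$bbox$f1) + 1L),
      parent = if (is.null(p$parent)) NA_integer_ else as.integer(p$parent),
      children = as.integer(unlist(p$children))
    ), class = "osc_packet")
  })
  .packet_set(packets, obj$algorithm, NULL, dims, freq_axis, time_axis,
              as.numeric(obj$threshold))
}
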