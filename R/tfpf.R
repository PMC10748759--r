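#' TFPF configuration
#'
#' The time-frequency peak finder slices the normalized TFR with equally
#' spaced descending cutoff levels, from the grid maximum down to the
#' percentile threshold, tracking the connected components above each
#' level.
#'
#' @param threshold_percentile Percentile in `[0, 100]` fixing the lowest
#'   cutoff level (same nearest-rank rule as [tfbm_config()]; default 80).
#' @param n_cutoff_levels Number of cutoff levels (integer `>= 2`,
#'   default 30).
#' @return A list of class `tfpf_config`.
#' @export
tfpf_config <- function(threshold_percentile = 80, n_cutoff_levels = 30L) {
  stopifnot(threshold_percentile >= 0, threshold_percentile <= 100,
            n_cutoff_levels >= 2)
  structure(list(threshold_percentile = threshold_percentile,
                 n_cutoff_levels = as.integer(n_cutoff_levels)),
            class = "tfpf_config")
}

#' Equally spaced descending cutoff levels
#'
#' @param max_power Highest level (the grid maximum).
#' @param threshold Lowest level; must be strictly below `max_power`.
#' @param n_levels Number of levels (`>= 2`).
#' @return Strictly decreasing numeric vector of length `n_levels`, first
#'   element `max_power`, last element `threshold`.
#' @export
cutoff_levels <- function(max_power, threshold, n_levels) {
  if (!(threshold < max_power))
    stop("threshold must be strictly below max_power")
  if (n_levels < 2) stop("need at least 2 cutoff levels")
  seq(max_power, threshold, length.out = n_levels)
}

#' Detect oscillation packets with the time-frequency peak finder
#'
#' The normalized TFR is sliced from its maximum down to the percentile
#' threshold with equally spaced cutoff levels. At each level the mask of
#' cells with power at or above the level is decomposed into 8-connected
#' components: a component containing one tracked peak extends that peak's
#' roi; a component joining several tracked peaks is owned by the
#' highest-power peak while the others are registered as its sub-peaks,
#' keeping their rois from the previous level; components containing no
#' tracked peak spawn new peaks at their maximum cell. The components at
#' the final level (the threshold) define the top-level packets.
#'
#' @param tfr A [tfr_grid()].
#' @param cfg A [tfpf_config()].
#' @return A `packet_set`; sub-peaks link to their owner via
#'   `parent`/`children` and every roi cell's power is at or above the
#'   threshold.
#' @export
tfpf_detect <- function(tfr, cfg = tfpf_config()) {
  stopifnot(inherits(tfr, "tfr_grid"), inherits(cfg, "tfpf_config"))
  norm <- normalize_power(tfr$power)
  nf <- nrow(norm); nt <- ncol(norm)
  thr <- auto_threshold(norm, cfg$threshold_percentile)
  maxp <- max(norm)
  if (!(thr < maxp))                    # constant grid: nothing stands out
    return(.packet_set(list(), "tfpf", cfg, c(nf, nt), tfr$freq_axis,
                       tfr$time_axis, thr))
  levels <- cutoff_levels(maxp, thr, cfg$n_cutoff_levels)

  peak_cell <- integer(0)      # tracked peak cells (1-based linear)
  active <- logical(0)
  parent <- integer(0)
  children <- list()
  sub_roi <- list()            # frozen roi for absorbed sub-peaks
  prev_lab <- NULL
  lab_of_peak <- integer(0)

  argmax_cell <- function(cells) {
    v <- norm[cells]
    tied <- cells[v == max(v)]
    if (length(tied) == 1L) return(tied)
    tf <- .cells_to_tf(tied, nf)
    tied[order(tf[, "f"], tf[, "t"])][1L]
  }

  for (lv in levels) {
    lab <- cpp_label_components(norm, lv)
    cells_by_lab <- split(which(lab > 0L), lab[lab > 0L])
    peak_lab <- integer(length(peak_cell))
    if (length(peak_cell)) peak_lab[active] <- lab[peak_cell[active]]
    act_idx <- which(active)
    if (length(act_idx)) {
      by_comp <- split(act_idx, peak_lab[act_idx])
      for (grp in by_comp) {
        if (length(grp) < 2L) next
        pw <- norm[peak_cell[grp]]
        tfg <- .cells_to_tf(peak_cell[grp], nf)
        ord <- order(-pw, tfg[, "f"], tfg[, "t"])
        owner <- grp[ord[1L]]
        losers <- grp[ord[-1L]]
        for (ls in losers) {
          active[ls] <- FALSE
          parent[ls] <- owner
          children[[owner]] <- c(children[[owner]], ls)
          sub_roi[[ls]] <-
            if (!is.null(prev_lab) && prev_lab[peak_cell[ls]] > 0L)
              which(prev_lab == prev_lab[peak_cell[ls]])
            else peak_cell[ls]
        }
      }
    }
    tracked_labs <- unique(lab[peak_cell[active]])
    for (lb in setdiff(as.integer(names(cells_by_lab)), tracked_labs)) {
      cells <- cells_by_lab[[as.character(lb)]]
      peak_cell <- c(peak_cell, argmax_cell(cells))
      active <- c(active, TRUE)
      parent <- c(parent, NA_integer_)
      children <- c(children, list(integer(0)))
      sub_roi <- c(sub_roi, list(NULL))
    }
    prev_lab <- lab
  }

  final_lab <- prev_lab
  cells_by_lab <- split(which(final_lab > 0L), final_lab[final_lab > 0L])
  packets <- vector("list", length(peak_cell))
  prom <- cpp_prominence(norm, {
    tf <- .cells_to_tf(peak_cell, nf)
    cbind(tf[, "f"] - 1L, tf[, "t"] - 1L)
  })
  for (i in seq_along(peak_cell)) {
    cells <- if (active[i])
      cells_by_lab[[as.character(final_lab[peak_cell[i]])]]
    else sub_roi[[i]]
    p <- .new_packet(i, peak_cell[i], cells, nf, norm, tfr$freq_axis,
                     tfr$time_axis, prominence = prom[i])
    p$contour <- extract_contour(p$roi)
    p$parent <- if (is.na(parent[i])) NA_integer_ else parent[i]
    p$children <- children[[i]]
    packets[[i]] <- p
  }
  .packet_set(packets, "tfpf", cfg, c(nf, nt), tfr$freq_axis, tfr$time_axis,
              thr)
}
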