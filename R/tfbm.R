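#' TFBM configuration
#'
#' The time-frequency breakdown method is controlled by three parameters:
#' the percentile threshold that discards spurious low-power local maxima,
#' the merge threshold (maximum allowed drop, on the normalized 0-100 power
#' scale, between two conflicting peaks and their shared saddle for the
#' pair to be merged), and the aspect ratio weighting the time axis in the
#' scaled grid distance.
#'
#' @param threshold_percentile Percentile in `[0, 100]` of grid power below
#'   which local maxima are discarded (default 80).
#' @param merge_threshold Merge threshold in normalized power units
#'   `[0, 100]` (default 15; 0 disables merging).
#' @param aspect_ratio Positive time-axis scale factor `k_t` (with
#'   `k_f = 1`).
#' @return A list of class `tfbm_config`.
#' @export
tfbm_config <- function(threshold_percentile = 80, merge_threshold = 15,
                        aspect_ratio = 1) {
  stopifnot(threshold_percentile >= 0, threshold_percentile <= 100,
            merge_threshold >= 0, merge_threshold <= 100, aspect_ratio > 0)
  structure(list(threshold_percentile = threshold_percentile,
                 merge_threshold = merge_threshold,
                 aspect_ratio = aspect_ratio),
            class = "tfbm_config")
}

.grid_of <- function(x) {
  if (inherits(x, "tfr_grid")) x$power else as.matrix(x)
}

#' Normalize grid power to the 0-100 range
#'
#' Affine rescaling: the grid minimum maps to 0 and the maximum to 100. A
#' constant grid maps to all zeros.
#'
#' @param x A [tfr_grid()] or numeric matrix.
#' @return Same type as the input, with power in `[0, 100]`.
#' @export
normalize_power <- function(x) {
  g <- .grid_of(x)
  if (!all(is.finite(g))) stop("grid must be finite")
  rng <- range(g)
  norm <- if (rng[2L] > rng[1L]) (g - rng[1L]) / (rng[2L] - rng[1L]) * 100
          else array(0, dim(g))
  if (inherits(x, "tfr_grid")) tfr_grid(norm, x$freq_axis, x$time_axis)
  else norm
}

#' Distance scale factors from the grid resolution
#'
#' `scale_x = (min_points / points_x) * k_x` with `k_f = 1` and
#' `k_t = aspect_ratio`, compensating for the typically large difference
#' between the number of time and frequency samples of a TFR.
#'
#' @param points_t,points_f Number of grid steps along time and frequency.
#' @param aspect_ratio Positive time-axis weight.
#' @return A list of class `scale_factors` with `scale_t`, `scale_f`,
#'   `k_t`, `k_f`, `points_t`, `points_f`, `min_points`.
#' @export
compute_scales <- function(points_t, points_f, aspect_ratio = 1) {
  if (points_t < 1 || points_f < 1) stop("grid sizes must be positive")
  if (aspect_ratio <= 0) stop("aspect_ratio must be positive")
  mp <- min(points_t, points_f)
  structure(list(scale_t = mp / points_t * aspect_ratio,
                 scale_f = mp / points_f * 1,
                 k_t = aspect_ratio, k_f = 1,
                 points_t = as.integer(points_t),
                 points_f = as.integer(points_f),
                 min_points = as.integer(mp)),
            class = "scale_factors")
}

#' Scaled grid distance
#'
#' Modified Euclidean distance between two grid points, with each index
#' difference weighted by its axis scale:
#' `sqrt((scale_t * dt)^2 + (scale_f * df)^2)`.
#'
#' @param p,q Grid points as numeric `c(t_idx, f_idx)` (any common base).
#' @param scales A [compute_scales()] result.
#' @return Nonnegative scalar; zero iff `p == q`.
#' @export
scaled_distance <- function(p, q, scales) {
  sqrt((scales$scale_t * (p[[1L]] - q[[1L]]))^2 +
       (scales$scale_f * (p[[2L]] - q[[2L]]))^2)
}

#' Automatic power threshold (nearest-rank percentile)
#'
#' Returns the value below or at which `percentile` percent of the grid's
#' power values fall, using the nearest-rank definition
#' (`sorted[ceiling(percentile/100 * n)]`, with percentile 0 giving the
#' minimum).
#'
#' @param x A [tfr_grid()] or numeric matrix.
#' @param percentile Percent in `[0, 100]`.
#' @return The threshold power value.
#' @export
auto_threshold <- function(x, percentile = 80) {
  g <- .grid_of(x)
  if (length(g) == 0L) stop("empty grid")
  stopifnot(percentile >= 0, percentile <= 100)
  v <- sort(as.vector(g))
  v[max(1L, ceiling(percentile / 100 * length(v)))]
}

.shift_mat <- function(g, df, dt, fill) {
  nf <- nrow(g); nt <- ncol(g)
  out <- matrix(fill, nf, nt)
  fs <- max(1L, 1L + df):min(nf, nf + df)
  ts <- max(1L, 1L + dt):min(nt, nt + dt)
  if (length(fs) && length(ts))
    out[fs, ts] <- g[fs - df, ts - dt, drop = FALSE]
  out
}

.NBR <- cbind(df = rep(-1:1, 3L), dt = rep(-1:1, each = 3L))[-5L, ]

#' Validated local maxima of a power grid
#'
#' A cell is a candidate peak if no 8-neighbor exceeds it, it has at least
#' one strictly lower neighbor (flat plateaus in constant regions are not
#' peaks), and its power is at or above `threshold`. Among equal-valued
#' neighboring candidates (an elevated plateau) only the lexicographically
#' smallest by `(f_idx, t_idx)` is kept, so no retained maximum has another
#' retained maximum in its neighborhood. Results are ordered by descending
#' power (ties lexicographic) so the strongest peaks are expanded first.
#'
#' @param x A [tfr_grid()] or numeric matrix.
#' @param threshold Minimum power for a valid maximum.
#' @return A data.frame with columns `t`, `f` (1-based indices) and
#'   `power`, ordered by descending power.
#' @export
find_local_maxima <- function(x, threshold) {
  g <- .grid_of(x)
  nf <- nrow(g); nt <- ncol(g)
  nbr_max <- matrix(-Inf, nf, nt)
  nbr_min <- matrix(Inf, nf, nt)
  for (i in seq_len(nrow(.NBR))) {
    s <- .shift_mat(g, .NBR[i, "df"], .NBR[i, "dt"], NA)
    nbr_max <- pmax(nbr_max, s, na.rm = TRUE)
    nbr_min <- pmin(nbr_min, s, na.rm = TRUE)
  }
  cand <- which(g >= nbr_max & g > nbr_min & g >= threshold)
  if (length(cand) == 0L)
    return(data.frame(t = integer(0), f = integer(0), power = numeric(0)))
  # plateau dedup: sweep candidates with an equal-valued neighbor in
  # (f, t) lexicographic order, dropping those next to an already-kept one
  has_eq <- g[cand] == nbr_max[cand]
  if (any(has_eq)) {
    kept <- matrix(FALSE, nf, nt)
    plain <- cand[!has_eq]
    kept[plain] <- TRUE
    tf <- .cells_to_tf(cand[has_eq], nf)
    ord <- order(tf[, "f"], tf[, "t"])
    keep_eq <- logical(sum(has_eq))
    for (k in ord) {
      tt <- tf[k, "t"]; ff <- tf[k, "f"]
      nbf <- pmax(1L, ff - 1L):pmin(nf, ff + 1L)
      nbt <- pmax(1L, tt - 1L):pmin(nt, tt + 1L)
      sub <- kept[nbf, nbt, drop = FALSE]
      eqnb <- g[nbf, nbt, drop = FALSE] == g[ff, tt] & sub
      eqnb[match(ff, nbf), match(tt, nbt)] <- FALSE
      if (!any(eqnb)) {
        keep_eq[k] <- TRUE
        kept[ff, tt] <- TRUE
      }
    }
    cand <- c(plain, cand[has_eq][keep_eq])
  }
  tf <- .cells_to_tf(cand, nf)
  pw <- g[cand]
  ord <- order(-pw, tf[, "f"], tf[, "t"])
  data.frame(t = tf[ord, "t"], f = tf[ord, "f"], power = pw[ord])
}

#' Local power dropoff at a grid point
#'
#' Absolute difference between the power at `p` and the minimum power over
#' its 8-neighborhood (truncated to existing cells at grid borders).
#'
#' @param x A [tfr_grid()] or numeric matrix.
#' @param p Grid point `c(t_idx, f_idx)`, 1-based.
#' @return Nonnegative scalar.
#' @export
dropoff <- function(x, p) {
  g <- .grid_of(x)
  t_idx <- as.integer(p[[1L]]); f_idx <- as.integer(p[[2L]])
  if (t_idx < 1L || t_idx > ncol(g) || f_idx < 1L || f_idx > nrow(g))
    stop("point out of grid bounds")
  cpp_dropoff(g, f_idx - 1L, t_idx - 1L)
}

#' Expand one packet center into a region of interest
#'
#' Breadth-first expansion from a validated local maximum. A neighbor `n`
#' of the current point `p` is admitted iff it has not been visited by this
#' packet, its power is strictly below that of `p`, and
#' `dropoff(p) * D(p, PC) < power(n)` where `PC` is the packet center and
#' `D` the [scaled_distance()]; the dropoff is recomputed at every
#' expansion point. Admissible cells already owned by another packet are
#' recorded as conflict points and not absorbed.
#'
#' @param x A [tfr_grid()] or numeric matrix (normally normalized 0-100).
#' @param peak Packet center `c(t_idx, f_idx)`, 1-based.
#' @param scales A [compute_scales()] result.
#' @param owner Optional integer matrix of prior cell ownership (0 =
#'   unowned), as produced by previous expansions.
#' @param id Integer id to assign to this packet (default: one more than
#'   the largest id in `owner`).
#' @return A list with `roi` and `conflict_points` (2-column `(t, f)`
#'   matrices) and the updated `owner` matrix.
#' @export
expand_peak <- function(x, peak, scales, owner = NULL, id = NULL) {
  g <- .grid_of(x)
  nf <- nrow(g); nt <- ncol(g)
  t_idx <- as.integer(peak[[1L]]); f_idx <- as.integer(peak[[2L]])
  if (t_idx < 1L || t_idx > nt || f_idx < 1L || f_idx > nf)
    stop("peak out of grid bounds")
  if (is.null(owner)) owner <- matrix(0L, nf, nt)
  if (is.null(id)) id <- max(owner) + 1L
  res <- cpp_expand_peak(g, f_idx - 1L, t_idx - 1L, scales$scale_t,
                         scales$scale_f, as.integer(owner), as.integer(id))
  own <- matrix(res$owner, nf, nt)
  list(roi = .cells_to_tf(res$roi + 1L, nf),
       conflict_points = .cells_to_tf(res$conflict_cell + 1L, nf),
       owner = own)
}

#' Resolve conflict points between competing packets
#'
#' Each conflict point is assigned to the candidate packet maximizing
#' `peak_power / D(peak, point)` (ties broken toward the higher peak
#' power, then the lower packet id).
#'
#' @param packets List of packets; each needs `id`, `peak` (`c(t, f)`) and
#'   `peak_power`.
#' @param conflict_points A data.frame with columns `t`, `f` and a list
#'   column `candidates` of packet-id vectors able to reach each point.
#' @param scales A [compute_scales()] result.
#' @return The input data.frame with an added integer column `assigned`.
#' @export
disambiguate_conflicts <- function(packets, conflict_points, scales) {
  ids <- vapply(packets, function(p) p$id, integer(1))
  assigned <- integer(nrow(conflict_points))
  for (i in seq_len(nrow(conflict_points))) {
    cand <- conflict_points$candidates[[i]]
    pt <- c(conflict_points$t[i], conflict_points$f[i])
    best <- NA_integer_; best_ratio <- -Inf; best_power <- -Inf
    for (cid in cand) {
      p <- packets[[match(cid, ids)]]
      d <- scaled_distance(c(p$peak[["t"]], p$peak[["f"]]), pt, scales)
      ratio <- if (d > 0) p$peak_power / d else Inf
      better <- ratio > best_ratio ||
        (ratio == best_ratio && (p$peak_power > best_power ||
          (p$peak_power == best_power && cid < best)))
      if (better) {
        best <- cid; best_ratio <- ratio; best_power <- p$peak_power
      }
    }
    assigned[i] <- best
  }
  conflict_points$assigned <- assigned
  conflict_points
}

#' Inner boundary of a region of interest
#'
#' The contour is the set of roi points having at least one 8-neighbor
#' position outside the roi (positions beyond the grid edge count as
#' outside, so cells on the grid border are contour cells).
#'
#' @param roi 2-column `(t, f)` matrix of roi cells.
#' @return The subset of `roi` rows forming the contour.
#' @export
extract_contour <- function(roi) {
  if (is.null(roi) || nrow(roi) == 0L) stop("empty roi")
  t0 <- min(roi[, 1L]); f0 <- min(roi[, 2L])
  nt <- max(roi[, 1L]) - t0 + 3L
  nf <- max(roi[, 2L]) - f0 + 3L
  mem <- matrix(FALSE, nf, nt)
  mem[cbind(roi[, 2L] - f0 + 2L, roi[, 1L] - t0 + 2L)] <- TRUE
  ncount <- matrix(0L, nf, nt)
  for (i in seq_len(nrow(.NBR)))
    ncount <- ncount + .shift_mat(mem, .NBR[i, "df"], .NBR[i, "dt"], FALSE)
  on_edge <- ncount[cbind(roi[, 2L] - f0 + 2L, roi[, 1L] - t0 + 2L)] < 8L
  roi[on_edge, , drop = FALSE]
}

#' Merge connected packets into a hierarchy
#'
#' Packets are visited in increasing order of peak power. A pair sharing
#' conflict points is merged iff both peaks' drops to the shared saddle --
#' `max(peak_a, peak_b)` minus the maximum normalized power over the
#' pair's conflict points -- are strictly below `merge_threshold`, i.e.
#' the two peaks are separated from their common highest conflict point by
#' less than the threshold. The
#' stronger packet assimilates the weaker one's roi; the weaker packet is
#' retained as a child with its original roi. Passes repeat until no pair
#' qualifies, so the result is a forest of packets.
#'
#' @param packets Flat list of packets, each with `id`, `peak_power`,
#'   `roi` and a `conflicts` data.frame (`t`, `f`, `other`, `power`) of
#'   recorded conflict points with partner ids.
#' @param merge_threshold Normalized power difference below which a pair is
#'   merged (0 means never).
#' @return The packet list with `parent`/`children` links set and merged
#'   rois expanded; merged packets' `bbox` and `contour` are refreshed.
#' @export
merge_packets <- function(packets, merge_threshold) {
  ids <- vapply(packets, function(p) p$id, integer(1))
  power <- vapply(packets, function(p) p$peak_power, numeric(1))
  conf <- do.call(rbind, lapply(packets, function(p) {
    if (is.null(p$conflicts) || nrow(p$conflicts) == 0L) return(NULL)
    data.frame(a = p$id, b = p$conflicts$other, power = p$conflicts$power)
  }))
  parent <- rep(NA_integer_, length(packets))
  if (!is.null(conf) && merge_threshold > 0) {
    ai <- match(conf$a, ids)
    bi <- match(conf$b, ids)
    topmap <- seq_along(packets)      # packet index -> top-level ancestor
    repeat {
      merged_any <- FALSE
      for (w in order(power, ids)) {
        if (topmap[w] != w) next      # absorbed already
        ta <- topmap[ai]; tb <- topmap[bi]
        mine <- (ta == w | tb == w) & ta != tb
        if (!any(mine)) next
        partner <- ifelse(ta[mine] == w, tb[mine], ta[mine])
        pu <- unique(partner)
        for (s in pu[order(-power[pu], ids[pu])]) {
          saddle <- max(conf$power[mine][partner == s])
          if (max(power[w], power[s]) - saddle < merge_threshold) {
            strong <- if (power[s] > power[w] ||
                          (power[s] == power[w] && ids[s] < ids[w])) s else w
            weak <- if (strong == s) w else s
            parent[weak] <- ids[strong]
            topmap[topmap == weak] <- strong
            packets[[strong]]$children <-
              c(packets[[strong]]$children, ids[weak])
            packets[[strong]]$roi <- unique(rbind(packets[[strong]]$roi,
                                                  packets[[weak]]$roi))
            merged_any <- TRUE
            break
          }
        }
      }
      if (!merged_any) break
    }
  }
  for (i in seq_along(packets)) {
    packets[[i]]$parent <- parent[i]
    if (is.na(parent[i]) && length(packets[[i]]$children)) {
      roi <- packets[[i]]$roi
      packets[[i]]$bbox <- c(t0 = min(roi[, 1L]), t1 = max(roi[, 1L]),
                             f0 = min(roi[, 2L]), f1 = max(roi[, 2L]))
      packets[[i]]$contour <- extract_contour(roi)
    }
  }
  packets
}

#' Detect oscillation packets with the time-frequency breakdown method
#'
#' Runs the full TFBM pipeline on a TFR: normalize power to 0-100,
#' compute the percentile threshold, find validated local maxima, expand
#' each (strongest first) by dropoff-bounded breadth-first growth,
#' disambiguate conflict points, extract contours, and merge weakly
#' separated packets into a hierarchy.
#'
#' @param tfr A [tfr_grid()].
#' @param cfg A [tfbm_config()].
#' @return A `packet_set` whose `packets` list holds every packet (merged
#'   children keep their original roi and link to their parent).
#' @export
tfbm_detect <- function(tfr, cfg = tfbm_config()) {
  stopifnot(inherits(tfr, "tfr_grid"), inherits(cfg, "tfbm_config"))
  norm <- normalize_power(tfr$power)
  nf <- nrow(norm); nt <- ncol(norm)
  thr <- auto_threshold(norm, cfg$threshold_percentile)
  maxima <- find_local_maxima(norm, thr)
  scales <- compute_scales(nt, nf, cfg$aspect_ratio)
  if (nrow(maxima) == 0L)
    return(.packet_set(list(), "tfbm", cfg, c(nf, nt), tfr$freq_axis,
                       tfr$time_axis, thr))
  peaks0 <- cbind(maxima$f - 1L, maxima$t - 1L)
  res <- cpp_expand_all(norm, peaks0, scales$scale_t, scales$scale_f)
  rois <- lapply(res$rois, function(r) r + 1L)           # linear, 1-based
  peak_cells <- (maxima$t - 1L) * nf + maxima$f
  k <- nrow(maxima)

  # disambiguation: candidates at each conflict cell are its owner plus
  # every packet that flagged it
  conf_cell <- res$conflict_cell + 1L
  conf_flagger <- res$conflict_id
  conf_owner <- res$conflict_owner
  pair_records <- NULL
  if (length(conf_cell)) {
    packs_min <- lapply(seq_len(k), function(i)
      list(id = i, peak = c(t = maxima$t[i], f = maxima$f[i]),
           peak_power = maxima$power[i]))
    grp <- split(seq_along(conf_cell), conf_cell)
    ucell <- as.integer(names(grp))
    tfu <- .cells_to_tf(ucell, nf)
    cands <- lapply(grp, function(ix)
      sort(unique(c(conf_owner[ix], conf_flagger[ix]))))
    cp <- data.frame(t = tfu[, "t"], f = tfu[, "f"])
    cp$candidates <- unname(cands)
    cp <- disambiguate_conflicts(packs_min, cp, scales)
    owner_of <- vapply(grp, function(ix) conf_owner[ix][1L], integer(1))
    own_mat <- matrix(res$owner, nf, nt)
    losers <- integer(0)
    for (j in seq_along(ucell)) {
      win <- cp$assigned[j]
      if (win != owner_of[j]) {
        rois[[owner_of[j]]] <- setdiff(rois[[owner_of[j]]], ucell[j])
        rois[[win]] <- c(rois[[win]], ucell[j])
        own_mat[ucell[j]] <- win
        losers <- c(losers, owner_of[j])
      }
    }
    # Reassigning a conflict cell can strand roi cells that were only
    # reachable through it; each stranded fragment follows the adjacent
    # cell's new owner so every roi stays 8-connected to its peak.
    for (pid in unique(losers)) {
      repeat {
        cells <- rois[[pid]]
        member <- matrix(0, nf, nt)
        member[cells] <- 1
        lab <- cpp_label_components(member, 0.5)
        peak_lab <- lab[peak_cells[pid]]
        frag <- cells[lab[cells] != peak_lab]
        if (length(frag) == 0L) break
        fl <- lab[frag][1L]
        fcells <- cells[lab[cells] == fl]
        tf <- .cells_to_tf(fcells, nf)
        cand_owner <- 0L; cand_pow <- -Inf
        for (i in seq_along(fcells)) {
          for (df in -1:1) for (dt in -1:1) {
            ff <- tf[i, "f"] + df; tt <- tf[i, "t"] + dt
            if (ff < 1L || ff > nf || tt < 1L || tt > nt) next
            lin <- (tt - 1L) * nf + ff
            ow <- own_mat[lin]
            if (ow != 0L && ow != pid && norm[lin] > cand_pow) {
              cand_owner <- ow; cand_pow <- norm[lin]
            }
          }
        }
        rois[[pid]] <- setdiff(rois[[pid]], fcells)
        if (cand_owner != 0L) {
          rois[[cand_owner]] <- c(rois[[cand_owner]], fcells)
          own_mat[fcells] <- cand_owner
        } else own_mat[fcells] <- 0L
      }
    }
    pair_records <- data.frame(id = conf_flagger, other = conf_owner,
                               cell = conf_cell, power = norm[conf_cell])
  }

  prom <- cpp_prominence(norm, cbind(maxima$f - 1L, maxima$t - 1L))
  packets <- vector("list", k)
  for (i in seq_len(k)) {
    confl <- if (!is.null(pair_records)) {
      rows <- pair_records$id == i
      tfc <- .cells_to_tf(pair_records$cell[rows], nf)
      matrix(as.integer(tfc), ncol = 2L, dimnames = list(NULL, c("t", "f")))
    } else NULL
    p <- .new_packet(i, peak_cells[i], rois[[i]], nf, norm, tfr$freq_axis,
                     tfr$time_axis, prominence = prom[i], conflicts = confl)
    p$contour <- extract_contour(p$roi)
    # conflict records of this packet with partner ids, for merging
    if (!is.null(pair_records)) {
      rows <- pair_records$id == i | pair_records$other == i
      if (any(rows)) {
        tfc <- .cells_to_tf(pair_records$cell[rows], nf)
        p$conflicts <- data.frame(
          t = tfc[, "t"], f = tfc[, "f"],
          other = ifelse(pair_records$id[rows] == i,
                         pair_records$other[rows], pair_records$id[rows]),
          power = pair_records$power[rows])
      }
    }
    packets[[i]] <- p
  }
  packets <- merge_packets(packets, cfg$merge_threshold)
  packets <- lapply(packets, function(p) { p$conflicts <- NULL; p })
  .packet_set(packets, "tfbm", cfg, c(nf, nt), tfr$freq_axis, tfr$time_axis,
              thr)
}
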