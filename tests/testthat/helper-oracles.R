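# Independent reference implementations and fixture builders used by the
# tests. These deliberately avoid the package's compiled code paths.

# Gaussian bump on an (nf x nt) grid
bump_grid <- function(nf, nt, f0, t0, height, sf, st) {
  fm <- matrix(rep(seq_len(nf), nt), nf)
  tm <- matrix(rep(seq_len(nt), each = nf), nf)
  height * exp(-((fm - f0)^2 / (2 * sf^2) + (tm - t0)^2 / (2 * st^2)))
}

# smooth random grid: white noise blurred with a separable moving average
smooth_random_grid <- function(nf, nt, blur = 2L) {
  g <- matrix(stats::rnorm(nf * nt), nf, nt)
  k <- rep(1, 2L * blur + 1L)
  g <- t(apply(g, 1L, function(r) stats::filter(c(rep(r[1], blur), r,
                                                  rep(r[length(r)], blur)),
                                                k / sum(k))[(blur + 1L):(blur + nt)]))
  g <- apply(g, 2L, function(cl) stats::filter(c(rep(cl[1], blur), cl,
                                                 rep(cl[length(cl)], blur)),
                                               k / sum(k))[(blur + 1L):(blur + nf)])
  g <- matrix(as.numeric(g), nf, nt)
  g - min(g)
}

neighbors8 <- function(f, t, nf, nt) {
  out <- NULL
  for (df in -1:1) for (dt in -1:1) {
    if (df == 0 && dt == 0) next
    ff <- f + df; tt <- t + dt
    if (ff >= 1 && ff <= nf && tt >= 1 && tt <= nt)
      out <- rbind(out, c(ff, tt))
  }
  out
}

# straightforward dropoff: |g(p) - min over existing 8-neighbors|
oracle_dropoff <- function(g, f, t) {
  nb <- neighbors8(f, t, nrow(g), ncol(g))
  if (is.null(nb)) return(0)
  abs(g[f, t] - min(g[nb]))
}

# Literal breadth-first expansion of one peak under the admission rule:
# unvisited by this packet, power(n) < power(p), and
# dropoff(p) * D(p, PC) < power(n). `owner` marks cells held by other
# packets (conflicts). Returns 1-based linear cells.
oracle_expand <- function(g, peak_f, peak_t, scale_t, scale_f,
                          owner = NULL, id = 1L) {
  nf <- nrow(g); nt <- ncol(g)
  if (is.null(owner)) owner <- matrix(0L, nf, nt)
  visited <- matrix(FALSE, nf, nt)
  roi <- integer(0); conflicts <- integer(0)
  queue <- list(c(peak_f, peak_t))
  visited[peak_f, peak_t] <- TRUE
  owner[peak_f, peak_t] <- id
  roi <- (peak_t - 1L) * nf + peak_f
  while (length(queue)) {
    p <- queue[[1L]]; queue <- queue[-1L]
    bound <- oracle_dropoff(g, p[1L], p[2L]) *
      sqrt((scale_t * (p[2L] - peak_t))^2 + (scale_f * (p[1L] - peak_f))^2)
    nb <- neighbors8(p[1L], p[2L], nf, nt)
    for (i in seq_len(nrow(nb))) {
      ff <- nb[i, 1L]; tt <- nb[i, 2L]
      if (visited[ff, tt]) next
      gn <- g[ff, tt]
      if (!(gn < g[p[1L], p[2L]])) next
      if (!(bound < gn)) next
      visited[ff, tt] <- TRUE
      lin <- (tt - 1L) * nf + ff
      if (owner[ff, tt] != 0L && owner[ff, tt] != id) {
        conflicts <- c(conflicts, lin)
      } else {
        owner[ff, tt] <- id
        roi <- c(roi, lin)
        queue <- c(queue, list(c(ff, tt)))
      }
    }
  }
  list(roi = sort(roi), conflicts = sort(conflicts), owner = owner)
}

# Literal per-level flood-fill reference for the time-frequency peak
# finder, using igraph for the connected components.
oracle_tfpf <- function(g, threshold_percentile = 80, n_levels = 30L) {
  nf <- nrow(g); nt <- ncol(g)
  rng <- range(g)
  norm <- if (rng[2] > rng[1]) (g - rng[1]) / (rng[2] - rng[1]) * 100
          else matrix(0, nf, nt)
  v <- sort(as.vector(norm))
  thr <- v[max(1L, ceiling(threshold_percentile / 100 * length(v)))]
  if (!(thr < max(norm))) return(list())
  levels <- seq(max(norm), thr, length.out = n_levels)
  comps_at <- function(level) {
    cells <- which(norm >= level)
    if (!length(cells)) return(list())
    f <- (cells - 1L) %% nf + 1L; t <- (cells - 1L) %/% nf + 1L
    idx <- seq_along(cells)
    pos <- matrix(NA_integer_, nf, nt); pos[cells] <- idx
    edges <- NULL
    for (df in -1:1) for (dt in -1:1) {
      if (df == 0 && dt == 0) next
      ff <- f + df; tt <- t + dt
      ok <- ff >= 1 & ff <= nf & tt >= 1 & tt <= nt
      nb <- rep(NA_integer_, length(cells))
      nb[ok] <- pos[cbind(ff[ok], tt[ok])]
      sel <- !is.na(nb) & nb > idx
      if (any(sel)) edges <- rbind(edges, cbind(idx[sel], nb[sel]))
    }
    gr <- if (is.null(edges))
      igraph::make_empty_graph(n = length(cells), directed = FALSE)
    else igraph::graph_from_edgelist(matrix(edges, ncol = 2),
                                     directed = FALSE)
    gr <- igraph::add_vertices(gr, max(0L, length(cells) -
                                       igraph::vcount(gr)))
    mem <- igraph::components(gr)$membership
    split(cells, mem)
  }
  peaks <- list()   # each: cell, active, children(indices), sub_roi
  prev_comps <- NULL
  cell_comp_of <- function(comps, cell) {
    for (i in seq_along(comps)) if (cell %in% comps[[i]]) return(i)
    NA_integer_
  }
  argmax_cell <- function(cells) {
    v <- norm[cells]
    tied <- cells[v == max(v)]
    if (length(tied) > 1L) {
      f <- (tied - 1L) %% nf + 1L; t <- (tied - 1L) %/% nf + 1L
      tied <- tied[order(f, t)]
    }
    tied[1L]
  }
  for (lv in levels) {
    comps <- comps_at(lv)
    act <- which(vapply(peaks, function(p) p$active, logical(1)))
    comp_of <- vapply(act, function(i)
      cell_comp_of(comps, peaks[[i]]$cell), integer(1))
    for (cid in unique(comp_of)) {
      grp <- act[comp_of == cid]
      if (length(grp) < 2L) next
      pw <- vapply(grp, function(i) norm[peaks[[i]]$cell], numeric(1))
      f <- vapply(grp, function(i) (peaks[[i]]$cell - 1L) %% nf + 1L, integer(1))
      t <- vapply(grp, function(i) (peaks[[i]]$cell - 1L) %/% nf + 1L, integer(1))
      ord <- order(-pw, f, t)
      owner <- grp[ord[1L]]
      for (ls in grp[ord[-1L]]) {
        peaks[[ls]]$active <- FALSE
        peaks[[ls]]$parent <- owner
        peaks[[owner]]$children <- c(peaks[[owner]]$children, ls)
        peaks[[ls]]$sub_roi <- if (!is.null(prev_comps)) {
          pc <- cell_comp_of(prev_comps, peaks[[ls]]$cell)
          if (is.na(pc)) peaks[[ls]]$cell else sort(prev_comps[[pc]])
        } else peaks[[ls]]$cell
      }
    }
    taken <- vapply(which(vapply(peaks, function(p) p$active, logical(1))),
                    function(i) cell_comp_of(comps, peaks[[i]]$cell),
                    integer(1))
    for (cid in setdiff(seq_along(comps), taken)) {
      peaks[[length(peaks) + 1L]] <- list(cell = argmax_cell(comps[[cid]]),
                                          active = TRUE, parent = NA_integer_,
                                          children = integer(0), sub_roi = NULL)
    }
    prev_comps <- comps
  }
  for (i in seq_along(peaks)) {
    if (peaks[[i]]$active) {
      cid <- cell_comp_of(prev_comps, peaks[[i]]$cell)
      peaks[[i]]$roi <- sort(prev_comps[[cid]])
    } else peaks[[i]]$roi <- peaks[[i]]$sub_roi
  }
  peaks
}

# sorted, unnamed 1-based linear cell ids of a (t, f) index matrix
lin_cells <- function(m, nf) {
  unname(sort(as.numeric((m[, "t"] - 1) * nf + m[, "f"])))
}

# log-log slope of the seed-averaged periodogram over a band
spectral_slope <- function(gen, n_seeds, n = 8192, fs = 1000,
                           band = c(1, 100)) {
  ps <- 0
  for (s in seq_len(n_seeds)) ps <- ps + Mod(stats::fft(gen(s)$samples))^2
  f <- (seq_len(n) - 1) * fs / n
  sel <- f >= band[1] & f <= band[2]
  unname(stats::coef(stats::lm(log10(ps[sel]) ~ log10(f[sel])))[2L])
}
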