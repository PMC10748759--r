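test_that("power normalization maps grids onto the 0-100 scale affinely", {
  expect_equal(normalize_power(matrix(c(1, 3, 2, 5), 2)),
               matrix(c(0, 50, 25, 100), 2))
  expect_equal(normalize_power(matrix(7, 3, 3)), matrix(0, 3, 3))
  g <- matrix(c(0, 40, 100, 60), 2)
  expect_equal(normalize_power(g), g)
})

test_that("distance scales follow the grid resolution", {
  s <- compute_scales(1000, 100, 1)
  expect_equal(s$scale_t, 0.1); expect_equal(s$scale_f, 1)
  s <- compute_scales(100, 100, 1)
  expect_equal(s$scale_t, 1); expect_equal(s$scale_f, 1)
  s <- compute_scales(1000, 100, 2)
  expect_equal(s$scale_t, 0.2); expect_equal(s$scale_f, 1)
  expect_equal(s$k_t / s$k_f, 2)
  expect_error(compute_scales(0, 10), "positive")
})

test_that("scaled distance is a weighted Euclidean metric on indices", {
  u <- list(scale_t = 1, scale_f = 1)
  expect_equal(scaled_distance(c(3, 4), c(0, 0), u), 5)
  expect_equal(scaled_distance(c(7, 2), c(7, 2), u), 0)
  h <- list(scale_t = 0.5, scale_f = 1)
  expect_equal(scaled_distance(c(3, 4), c(0, 0), h), sqrt(2.25 + 16))
  expect_equal(scaled_distance(c(1, 5), c(4, 1), u),
               scaled_distance(c(4, 1), c(1, 5), u))
})

test_that("automatic threshold uses the nearest-rank percentile", {
  g <- matrix(1:10, 2)
  expect_equal(auto_threshold(g, 80), 8)
  expect_equal(auto_threshold(g, 0), 1)
  expect_equal(auto_threshold(g, 100), 10)
  expect_error(auto_threshold(matrix(numeric(0), 0, 0), 50), "empty")
})

test_that("local maxima are validated, deduplicated and power-ordered", {
  g <- matrix(0, 5, 5); g[3, 3] <- 10; g[2:4, 2:4] <- g[2:4, 2:4] + 1
  m <- find_local_maxima(g, 2)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$t, m$f), c(3, 3))
  expect_equal(nrow(find_local_maxima(g, 50)), 0L)
  # two equal adjacent maxima: keep exactly one, the (f, t)-smallest
  g2 <- matrix(c(0, 0, 0, 5, 5, 0, 0, 0, 0), 3)
  m2 <- find_local_maxima(g2, 0)
  expect_equal(nrow(m2), 1L)
  expect_equal(c(m2$f, m2$t), c(1, 2))
  # constant grid has no elevation, hence no maxima
  expect_equal(nrow(find_local_maxima(matrix(4, 4, 4), 0)), 0L)
  # ordering: strongest first
  g3 <- matrix(0, 5, 9); g3[2, 2] <- 3; g3[4, 5] <- 9; g3[2, 8] <- 6
  m3 <- find_local_maxima(g3, 1)
  expect_equal(m3$power, c(9, 6, 3))
})

test_that("dropoff is the descent to the weakest neighbor, truncated at borders", {
  expect_equal(dropoff(matrix(5, 3, 3), c(2, 2)), 0)
  g <- matrix(4, 3, 3); g[2, 2] <- 10; g[1, 1] <- 7
  expect_equal(dropoff(g, c(2, 2)), 6)
  gc <- matrix(c(9, 5, 7, 9), 2, 2)   # corner value 9, neighbors {5,7,9}
  expect_equal(dropoff(gc, c(1, 1)), 4)
})

test_that("peak expansion follows the dropoff-bounded admission rule", {
  unit <- list(scale_t = 1, scale_f = 1)
  row <- matrix(c(20, 40, 100, 60, 20), nrow = 1)
  ex <- expand_peak(row, c(3, 1), unit)
  expect_setequal(ex$roi[, "t"], c(2, 3, 4))
  expect_equal(nrow(ex$conflict_points), 0L)
  # single-cell grid
  ex1 <- expand_peak(matrix(5), c(1, 1), unit)
  expect_equal(unname(ex1$roi), matrix(c(1L, 1L), 1))
  # conflicts recorded by the later packet only
  g <- matrix(c(10, 60, 100, 70, 60, 55, 60, 90, 60, 25), nrow = 1)
  e1 <- expand_peak(g, c(3, 1), unit, id = 1L)
  e2 <- expand_peak(g, c(8, 1), unit, owner = e1$owner, id = 2L)
  expect_equal(nrow(e1$conflict_points), 0L)
  expect_gt(nrow(e2$conflict_points), 0L)
  expect_true(all(e2$conflict_points[, "t"] %in% e1$roi[, "t"]))
  expect_error(expand_peak(row, c(9, 1), unit), "bounds")
})

test_that("expansion equals a literal breadth-first reference on random grids", {
  set.seed(421)
  for (rep in 1:25) {
    nf <- sample(3:14, 1); nt <- sample(3:14, 1)
    g <- smooth_random_grid(nf, nt)
    mx <- find_local_maxima(g, -Inf)
    if (nrow(mx) == 0L) next
    sc <- compute_scales(nt, nf, 1)
    own <- NULL; own_o <- matrix(0L, nf, nt)
    for (i in seq_len(nrow(mx))) {
      r1 <- expand_peak(g, c(mx$t[i], mx$f[i]), sc, owner = own, id = i)
      r2 <- oracle_expand(g, mx$f[i], mx$t[i], sc$scale_t, sc$scale_f,
                          own_o, i)
      expect_equal(lin_cells(r1$roi, nf), as.numeric(r2$roi))
      expect_equal(lin_cells(r1$conflict_points, nf),
                   as.numeric(r2$conflicts))
      own <- r1$owner; own_o <- r2$owner
    }
  }
})

test_that("conflict points go to the packet with the best power/distance ratio", {
  packs <- list(list(id = 1L, peak = c(t = 1, f = 1), peak_power = 100),
                list(id = 2L, peak = c(t = 5, f = 1), peak_power = 60))
  sc <- list(scale_t = 1, scale_f = 1)
  cp <- data.frame(t = 3, f = 1)           # equidistant, D = 2
  cp$candidates <- list(c(1L, 2L))
  expect_equal(disambiguate_conflicts(packs, cp, sc)$assigned, 1L)
  cp$candidates <- list(2L)                # single candidate
  expect_equal(disambiguate_conflicts(packs, cp, sc)$assigned, 2L)
  # power 100 at D=4 vs 60 at D=2: 25 < 30, weaker-but-closer peak wins
  packs2 <- list(list(id = 1L, peak = c(t = 1, f = 1), peak_power = 100),
                 list(id = 2L, peak = c(t = 7, f = 1), peak_power = 60))
  cp2 <- data.frame(t = 5, f = 1)
  cp2$candidates <- list(c(1L, 2L))
  expect_equal(disambiguate_conflicts(packs2, cp2, sc)$assigned, 2L)
})

test_that("contours are the roi cells touching the outside", {
  block <- as.matrix(expand.grid(t = 2:4, f = 2:4))
  ct <- extract_contour(block)
  expect_equal(nrow(ct), 8L)
  expect_false(any(ct[, "t"] == 3 & ct[, "f"] == 3))
  single <- matrix(c(5L, 5L), 1, dimnames = list(NULL, c("t", "f")))
  expect_equal(extract_contour(single), single)
  run <- cbind(t = 1:5, f = rep(2L, 5))
  expect_equal(nrow(extract_contour(run)), 5L)
  expect_error(extract_contour(run[0, , drop = FALSE]), "empty")
})

test_that("packets merge when both peaks sit close to their shared saddle", {
  mk <- function(id, power, roi_t, conf = NULL) {
    p <- fake_packet(id, cbind(roi_t, 1L), c(roi_t[1L], 1L), 1:3, (1:20) / 10)
    p$peak_power <- power
    p$conflicts <- conf
    p
  }
  conf_ab <- data.frame(t = 5L, f = 1L, other = 2L, power = 90)
  a <- mk(1L, 100, 1:5, conf_ab)
  b <- mk(2L, 95, 6:9, data.frame(t = 5L, f = 1L, other = 1L, power = 90))
  merged <- merge_packets(list(a, b), 15)
  expect_equal(merged[[2L]]$parent, 1L)
  expect_equal(merged[[1L]]$children, 2L)
  expect_true(all(6:9 %in% merged[[1L]]$roi[, "t"]))   # roi absorbed
  expect_true(all(6:9 %in% merged[[2L]]$roi[, "t"]))   # child roi retained
  not_merged <- merge_packets(list(a, b), 3)
  expect_true(is.na(not_merged[[2L]]$parent))
  # without shared conflict points nothing merges
  a2 <- mk(1L, 100, 1:5); b2 <- mk(2L, 95, 6:9)
  free <- merge_packets(list(a2, b2), 50)
  expect_true(all(vapply(free, function(p) is.na(p$parent), logical(1))))
})

test_that("full TFBM detection delineates synthetic bumps", {
  g <- bump_grid(40, 60, 12, 20, 100, 3, 5) +
       bump_grid(40, 60, 28, 45, 70, 3, 5)
  d <- tfbm_detect(tfr_grid(g, 1:40, (1:60) / 100), tfbm_config(80, 15, 1))
  tops <- Filter(function(p) is.na(p$parent), d$packets)
  expect_equal(length(tops), 2L)
  apexes <- lapply(tops, function(p) p$peak)
  expect_true(any(vapply(tops, function(p)
    any(p$roi[, "t"] == 20 & p$roi[, "f"] == 12), logical(1))))
  expect_true(any(vapply(tops, function(p)
    any(p$roi[, "t"] == 45 & p$roi[, "f"] == 28), logical(1))))
  # constant grid: nothing stands out
  dc <- tfbm_detect(tfr_grid(matrix(3, 10, 10), 1:10, (1:10) / 10),
                    tfbm_config())
  expect_equal(length(dc$packets), 0L)
  # one bump: bounding box covers at least the half-height footprint
  g1 <- bump_grid(40, 60, 20, 30, 100, 3, 5)
  d1 <- tfbm_detect(tfr_grid(g1, 1:40, (1:60) / 100), tfbm_config(80, 15, 1))
  top <- Filter(function(p) is.na(p$parent), d1$packets)[[1L]]
  half_t <- 5 * sqrt(2 * log(2)); half_f <- 3 * sqrt(2 * log(2))
  expect_lte(top$bbox[["t0"]], ceiling(30 - half_t))
  expect_gte(top$bbox[["t1"]], floor(30 + half_t))
  expect_lte(top$bbox[["f0"]], ceiling(20 - half_f))
  expect_gte(top$bbox[["f1"]], floor(20 + half_f))
})

test_that("TFBM structural invariants hold on randomized grids", {
  set.seed(99)
  for (rep in 1:12) {
    nf <- sample(10:25, 1); nt <- sample(10:30, 1)
    g <- smooth_random_grid(nf, nt)
    tfr <- tfr_grid(g, 1:nf, (1:nt) / 100)
    d <- tfbm_detect(tfr, tfbm_config(60, 10, 1))
    tops <- Filter(function(p) is.na(p$parent), d$packets)
    # disjoint top-level rois
    cells <- unlist(lapply(tops, function(p)
      (p$roi[, "t"] - 1) * nf + p$roi[, "f"]))
    expect_false(any(duplicated(cells)))
    ids <- vapply(d$packets, function(p) p$id, integer(1))
    for (p in d$packets) {
      # peak inside roi, contour inside roi, peak above threshold
      expect_true(any(p$roi[, "t"] == p$peak[["t"]] &
                      p$roi[, "f"] == p$peak[["f"]]))
      expect_true(all(paste(p$contour[, 1], p$contour[, 2]) %in%
                      paste(p$roi[, 1], p$roi[, 2])))
      expect_gte(p$peak_power, d$threshold)
      # roi 8-connected to the peak
      lin <- (p$roi[, "t"] - 1) * nf + p$roi[, "f"]
      member <- matrix(0, nf, nt); member[lin] <- 1
      lab <- oscpacket:::cpp_label_components(member, 0.5)
      expect_true(all(lab[lin] == lab[(p$peak[["t"]] - 1) * nf +
                                      p$peak[["f"]]]))
      # forest: walking up parents terminates without revisiting
      seen <- integer(0); cur <- p$id
      while (!is.na(d$packets[[match(cur, ids)]]$parent)) {
        expect_false(cur %in% seen)
        seen <- c(seen, cur)
        cur <- d$packets[[match(cur, ids)]]$parent
      }
    }
    # merge threshold zero: no hierarchy at all
    d0 <- tfbm_detect(tfr, tfbm_config(60, 0, 1))
    expect_true(all(vapply(d0$packets, function(p) is.na(p$parent),
                           logical(1))))
    # determinism
    d2 <- tfbm_detect(tfr, tfbm_config(60, 10, 1))
    expect_identical(d$packets, d2$packets)
  }
})
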