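#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Grid cells are addressed by 0-based (f, t) index pairs or by the 0-based
// column-major linear index lin = f + nf * t (rows = frequency, cols = time).

static inline double scaled_dist(int f1, int t1, int f2, int t2,
                                 double scale_t, double scale_f) {
  double dt = scale_t * (double)(t1 - t2);
  double df = scale_f * (double)(f1 - f2);
  return std::sqrt(dt * dt + df * df);
}

// |g(p) - min over the (border-truncated) 8-neighborhood of p|
static double dropoff_at(const NumericMatrix& g, int f, int t) {
  int nf = g.nrow(), nt = g.ncol();
  double mn = R_PosInf;
  for (int df = -1; df <= 1; ++df) {
    for (int dt = -1; dt <= 1; ++dt) {
      if (df == 0 && dt == 0) continue;
      int ff = f + df, tt = t + dt;
      if (ff < 0 || ff >= nf || tt < 0 || tt >= nt) continue;
      double v = g(ff, tt);
      if (v < mn) mn = v;
    }
  }
  if (!R_finite(mn)) return 0.0;  // 1x1 grid: empty neighborhood
  return std::fabs(g(f, t) - mn);
}

// [[Rcpp::export]]
double cpp_dropoff(NumericMatrix g, int f0, int t0) {
  return dropoff_at(g, f0, t0);
}

// Breadth-first expansion of one packet center. `owner` holds the packet id
// owning each cell (0 = unowned) and is updated in place; `visited` holds,
// per cell, the id of the last packet whose expansion touched it (so each
// packet examines a cell at most once). A neighbor n of the current point p
// is admitted iff g(n) < g(p) and dropoff(p) * D(p, PC) < g(n); admissible
// cells already owned by another packet are recorded as conflict points and
// are not expanded through.
static void expand_one(const NumericMatrix& g, IntegerVector& owner,
                       std::vector<int>& visited, int id,
                       int f0, int t0, double scale_t, double scale_f,
                       std::vector<int>& roi,
                       std::vector<int>& conf_cell,
                       std::vector<int>& conf_owner) {
  int nf = g.nrow(), nt = g.ncol();
  int lin0 = f0 + nf * t0;
  owner[lin0] = id;
  visited[lin0] = id;
  roi.push_back(lin0);
  std::vector<int> queue;
  queue.push_back(lin0);
  size_t head = 0;
  while (head < queue.size()) {
    int cur = queue[head++];
    int cf = cur % nf, ct = cur / nf;
    double gp = g[cur];
    double bound = dropoff_at(g, cf, ct) * scaled_dist(cf, ct, f0, t0, scale_t, scale_f);
    for (int df = -1; df <= 1; ++df) {
      for (int dt = -1; dt <= 1; ++dt) {
        if (df == 0 && dt == 0) continue;
        int ff = cf + df, tt = ct + dt;
        if (ff < 0 || ff >= nf || tt < 0 || tt >= nt) continue;
        int lin = ff + nf * tt;
        if (visited[lin] == id) continue;
        double gn = g[lin];
        if (!(gn < gp)) continue;
        if (!(bound < gn)) continue;
        visited[lin] = id;
        int ow = owner[lin];
        if (ow != 0 && ow != id) {
          conf_cell.push_back(lin);
          conf_owner.push_back(ow);
        } else {
          owner[lin] = id;
          roi.push_back(lin);
          queue.push_back(lin);
        }
      }
    }
  }
}

// Expand a single peak against an existing ownership map (for unit-level use).
// Returns 0-based linear roi / conflict cells and the updated owner map.
// [[Rcpp::export]]
List cpp_expand_peak(NumericMatrix g, int f0, int t0, double scale_t,
                     double scale_f, IntegerVector owner, int id) {
  IntegerVector own = clone(owner);
  std::vector<int> visited((size_t)g.nrow() * g.ncol(), 0);
  // mark cells of other packets as "their own visit" is unnecessary: visited
  // tracks only the current packet id.
  std::vector<int> roi, cc, co;
  expand_one(g, own, visited, id, f0, t0, scale_t, scale_f, roi, cc, co);
  return List::create(_["roi"] = wrap(roi), _["conflict_cell"] = wrap(cc),
                      _["conflict_owner"] = wrap(co), _["owner"] = own);
}

// Sequential expansion of all validated peaks, strongest first (`peaks` must
// already be ordered; k x 2 matrix of 0-based (f, t)). Packet ids are 1..k.
// [[Rcpp::export]]
List cpp_expand_all(NumericMatrix g, IntegerMatrix peaks, double scale_t,
                    double scale_f) {
  int nf = g.nrow(), nt = g.ncol(), k = peaks.nrow();
  IntegerVector owner((R_xlen_t)nf * nt);
  std::vector<int> visited((size_t)nf * nt, 0);
  List rois(k);
  std::vector<int> all_id, all_cell, all_owner;
  for (int i = 0; i < k; ++i) {
    std::vector<int> roi, cc, co;
    expand_one(g, owner, visited, i + 1, peaks(i, 0), peaks(i, 1), scale_t,
               scale_f, roi, cc, co);
    rois[i] = wrap(roi);
    for (size_t j = 0; j < cc.size(); ++j) {
      all_id.push_back(i + 1);
      all_cell.push_back(cc[j]);
      all_owner.push_back(co[j]);
    }
  }
  owner.attr("dim") = Dimension(nf, nt);
  return List::create(_["owner"] = owner, _["rois"] = rois,
                      _["conflict_id"] = wrap(all_id),
                      _["conflict_cell"] = wrap(all_cell),
                      _["conflict_owner"] = wrap(all_owner));
}

// 8-connected component labeling of {cells with g >= level}; labels are
// assigned in ascending linear-index scan order (deterministic), 0 = below.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(NumericMatrix g, double level) {
  int nf = g.nrow(), nt = g.ncol();
  R_xlen_t n = (R_xlen_t)nf * nt;
  IntegerMatrix lab(nf, nt);
  std::vector<int> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (g[i] < level || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back((int)i);
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int cf = cur % nf, ct = cur / nf;
      for (int df = -1; df <= 1; ++df) {
        for (int dt = -1; dt <= 1; ++dt) {
          if (df == 0 && dt == 0) continue;
          int ff = cf + df, tt = ct + dt;
          if (ff < 0 || ff >= nf || tt < 0 || tt >= nt) continue;
          int lin = ff + nf * tt;
          if (g[lin] >= level && lab[lin] == 0) {
            lab[lin] = next;
            stack.push_back(lin);
          }
        }
      }
    }
  }
  return lab;
}

static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// Exact topographic prominence for the queried peak cells (k x 2, 0-based
// (f, t)): cells are inserted in descending value order (ties broken by
// ascending linear index); when two components meet, the one whose peak is
// lower dies with prominence = its peak value minus the value of the joining
// cell (the saddle). Surviving components get peak value minus grid minimum.
// [[Rcpp::export]]
NumericVector cpp_prominence(NumericMatrix g_, IntegerMatrix peaks) {
  int nf = g_.nrow(), nt = g_.ncol();
  int n = nf * nt;
  std::vector<double> g(g_.begin(), g_.end());
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (g[a] != g[b]) return g[a] > g[b];
    return a < b;
  });
  double gmin = g[0];
  for (int i = 1; i < n; ++i)
    if (g[i] < gmin) gmin = g[i];
  std::vector<int> parent(n, -1), comp_peak(n, -1);
  std::vector<double> prom(n, NA_REAL);
  for (int idx = 0; idx < n; ++idx) {
    int c = ord[idx];
    parent[c] = c;
    comp_peak[c] = c;
    int cf = c % nf, ct = c / nf;
    for (int df = -1; df <= 1; ++df) {
      for (int dt = -1; dt <= 1; ++dt) {
        if (df == 0 && dt == 0) continue;
        int ff = cf + df, tt = ct + dt;
        if (ff < 0 || ff >= nf || tt < 0 || tt >= nt) continue;
        int nb = ff + nf * tt;
        if (parent[nb] == -1) continue;
        int r1 = uf_find(parent, c), r2 = uf_find(parent, nb);
        if (r1 == r2) continue;
        int p1 = comp_peak[r1], p2 = comp_peak[r2];
        bool first_wins = (g[p1] > g[p2]) || (g[p1] == g[p2] && p1 < p2);
        int win = first_wins ? r1 : r2;
        int lose = first_wins ? r2 : r1;
        prom[comp_peak[lose]] = g[comp_peak[lose]] - g[c];
        parent[lose] = win;
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    if (parent[i] == i) prom[comp_peak[i]] = g[comp_peak[i]] - gmin;
  }
  int k = peaks.nrow();
  NumericVector out(k);
  for (int i = 0; i < k; ++i) {
    int lin = peaks(i, 0) + nf * peaks(i, 1);
    out[i] = prom[lin];
  }
  return out;
}
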