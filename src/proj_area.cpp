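#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Area of the union of triangles projected onto the xy-plane, overlaps
// counted once. Scanline with exact interval union in x: the y-axis is cut
// into slabs at every projected vertex y; within a slab each triangle's
// section is an interval whose endpoints are linear in y, and the union
// length is integrated with 2-point Gauss-Legendre. Exact whenever interval
// endpoints do not cross inside a slab (always true for non-overlapping
// height-field projections and for rectilinear unions); otherwise the error
// is second order in the slab height.

struct Tri2 {
  double x[3], y[3];
  double ymin, ymax;
};

static inline double union_length_at(double y, const std::vector<int>& active,
                                     const std::vector<Tri2>& tris,
                                     std::vector<std::pair<double, double>>& ivals) {
  ivals.clear();
  for (int id : active) {
    const Tri2& t = tris[id];
    if (y < t.ymin || y > t.ymax) continue;
    double lo = 0, hi = 0;
    int ncross = 0;
    for (int e = 0; e < 3; ++e) {
      int a = e, b = (e + 1) % 3;
      bool sa = t.y[a] <= y, sb = t.y[b] <= y;
      if (sa == sb) continue;
      double dy = t.y[b] - t.y[a];
      double x = t.x[a] + (y - t.y[a]) / dy * (t.x[b] - t.x[a]);
      if (ncross == 0) { lo = hi = x; }
      else { if (x < lo) lo = x; if (x > hi) hi = x; }
      ++ncross;
    }
    if (ncross >= 2 && hi > lo) ivals.push_back({lo, hi});
  }
  if (ivals.empty()) return 0.0;
  std::sort(ivals.begin(), ivals.end());
  double total = 0, cur_lo = ivals[0].first, cur_hi = ivals[0].second;
  for (size_t i = 1; i < ivals.size(); ++i) {
    if (ivals[i].first > cur_hi) {
      total += cur_hi - cur_lo;
      cur_lo = ivals[i].first;
      cur_hi = ivals[i].second;
    } else if (ivals[i].second > cur_hi) {
      cur_hi = ivals[i].second;
    }
  }
  total += cur_hi - cur_lo;
  return total;
}

// [[Rcpp::export(name = ".cpp_proj_union_area")]]
double cpp_proj_union_area(NumericMatrix V, IntegerMatrix F) {
  const int nf = F.nrow();
  if (nf == 0) return 0.0;
  std::vector<Tri2> tris;
  tris.reserve(nf);
  std::vector<double> ys;
  ys.reserve(2 * nf);
  for (int i = 0; i < nf; ++i) {
    Tri2 t;
    for (int k = 0; k < 3; ++k) {
      int vi = F(i, k) - 1;
      t.x[k] = V(vi, 0);
      t.y[k] = V(vi, 1);
    }
    t.ymin = std::min({t.y[0], t.y[1], t.y[2]});
    t.ymax = std::max({t.y[0], t.y[1], t.y[2]});
    if (t.ymax > t.ymin) {  // zero-height projections contribute nothing
      tris.push_back(t);
      ys.push_back(t.ymin);
      ys.push_back(t.ymax);
    }
    for (int k = 0; k < 3; ++k) ys.push_back(t.y[k]);
  }
  if (tris.empty()) return 0.0;
  std::sort(ys.begin(), ys.end());
  ys.erase(std::unique(ys.begin(), ys.end()), ys.end());

  // Sweep: triangles sorted by ymin; active list pruned lazily.
  std::vector<int> order(tris.size());
  for (size_t i = 0; i < order.size(); ++i) order[i] = (int)i;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return tris[a].ymin < tris[b].ymin; });

  const double g = 0.5773502691896257;  // 1/sqrt(3)
  std::vector<int> active;
  std::vector<std::pair<double, double>> scratch;
  size_t next = 0;
  double area = 0.0;
  for (size_t s = 0; s + 1 < ys.size(); ++s) {
    double y0 = ys[s], y1 = ys[s + 1];
    while (next < order.size() && tris[order[next]].ymin <= y0 + 1e-300) {
      active.push_back(order[next]);
      ++next;
    }
    // also admit triangles starting inside numerically identical slabs
    while (next < order.size() && tris[order[next]].ymin < y1) {
      active.push_back(order[next]);
      ++next;
    }
    active.erase(std::remove_if(active.begin(), active.end(),
                                [&](int id) { return tris[id].ymax <= y0; }),
                 active.end());
    if (active.empty()) continue;
    double h = y1 - y0, mid = 0.5 * (y0 + y1);
    double ya = mid - 0.5 * h * g, yb = mid + 0.5 * h * g;
    double la = union_length_at(ya, active, tris, scratch);
    double lb = union_length_at(yb, active, tris, scratch);
    area += 0.5 * h * (la + lb);
  }
  return area;
}
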