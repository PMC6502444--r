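#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Any-hit ray casting against a triangle soup through a median-split BVH.
// Used for ambient occlusion (PCV): each query asks whether a ray from an
// offset vertex position escapes the mesh in a given sky direction.

namespace {

struct BBox {
  double lo[3], hi[3];
  BBox() {
    for (int k = 0; k < 3; ++k) { lo[k] = 1e300; hi[k] = -1e300; }
  }
  void grow(const double* p) {
    for (int k = 0; k < 3; ++k) {
      if (p[k] < lo[k]) lo[k] = p[k];
      if (p[k] > hi[k]) hi[k] = p[k];
    }
  }
  void grow(const BBox& b) {
    for (int k = 0; k < 3; ++k) {
      if (b.lo[k] < lo[k]) lo[k] = b.lo[k];
      if (b.hi[k] > hi[k]) hi[k] = b.hi[k];
    }
  }
};

struct Node {
  BBox box;
  int left = -1, right = -1;  // children, or -1 for leaf
  int start = 0, count = 0;   // triangle range for leaves
};

struct BVH {
  std::vector<double> vx, vy, vz;          // triangle vertices, 9 per tri
  std::vector<BBox> tbox;
  std::vector<double> cx, cy, cz;          // centroids
  std::vector<int> idx;
  std::vector<Node> nodes;

  int build(int start, int count) {
    Node node;
    for (int i = start; i < start + count; ++i) node.box.grow(tbox[idx[i]]);
    int self = (int)nodes.size();
    nodes.push_back(node);
    if (count <= 4) {
      nodes[self].start = start;
      nodes[self].count = count;
      return self;
    }
    BBox cb;
    for (int i = start; i < start + count; ++i) {
      double c[3] = {cx[idx[i]], cy[idx[i]], cz[idx[i]]};
      cb.grow(c);
    }
    int axis = 0;
    double ext = cb.hi[0] - cb.lo[0];
    for (int k = 1; k < 3; ++k)
      if (cb.hi[k] - cb.lo[k] > ext) { ext = cb.hi[k] - cb.lo[k]; axis = k; }
    if (ext <= 0) {
      nodes[self].start = start;
      nodes[self].count = count;
      return self;
    }
    int mid = start + count / 2;
    const std::vector<double>& cc = (axis == 0 ? cx : (axis == 1 ? cy : cz));
    std::nth_element(idx.begin() + start, idx.begin() + mid,
                     idx.begin() + start + count,
                     [&](int a, int b) { return cc[a] < cc[b] || (cc[a] == cc[b] && a < b); });
    int l = build(start, mid - start);
    int r = build(mid, start + count - mid);
    nodes[self].left = l;
    nodes[self].right = r;
    return self;
  }

  bool hit_box(const Node& n, const double* o, const double* inv) const {
    double t0 = 0.0, t1 = 1e300;
    for (int k = 0; k < 3; ++k) {
      double ta = (n.box.lo[k] - o[k]) * inv[k];
      double tb = (n.box.hi[k] - o[k]) * inv[k];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
      if (t0 > t1) return false;
    }
    return true;
  }

  bool hit_tri(int t, const double* o, const double* d) const {
    const double* a = &vx[9 * t];
    double e1[3], e2[3];
    for (int k = 0; k < 3; ++k) {
      e1[k] = a[3 + k] - a[k];
      e2[k] = a[6 + k] - a[k];
    }
    double p[3] = {d[1] * e2[2] - d[2] * e2[1],
                   d[2] * e2[0] - d[0] * e2[2],
                   d[0] * e2[1] - d[1] * e2[0]};
    double det = e1[0] * p[0] + e1[1] * p[1] + e1[2] * p[2];
    if (std::fabs(det) < 1e-14) return false;
    double inv = 1.0 / det;
    double s[3] = {o[0] - a[0], o[1] - a[1], o[2] - a[2]};
    double u = (s[0] * p[0] + s[1] * p[1] + s[2] * p[2]) * inv;
    if (u < 0.0 || u > 1.0) return false;
    double q[3] = {s[1] * e1[2] - s[2] * e1[1],
                   s[2] * e1[0] - s[0] * e1[2],
                   s[0] * e1[1] - s[1] * e1[0]};
    double v = (d[0] * q[0] + d[1] * q[1] + d[2] * q[2]) * inv;
    if (v < 0.0 || u + v > 1.0) return false;
    double t_hit = (e2[0] * q[0] + e2[1] * q[1] + e2[2] * q[2]) * inv;
    return t_hit > 1e-9;
  }

  bool any_hit(const double* o, const double* d) const {
    double inv[3];
    for (int k = 0; k < 3; ++k)
      inv[k] = (d[k] != 0.0) ? 1.0 / d[k] : 1e300;
    std::vector<int> stack;
    stack.reserve(64);
    stack.push_back(0);
    while (!stack.empty()) {
      int ni = stack.back();
      stack.pop_back();
      const Node& n = nodes[ni];
      if (!hit_box(n, o, inv)) continue;
      if (n.left < 0) {
        for (int i = n.start; i < n.start + n.count; ++i)
          if (hit_tri(idx[i], o, d)) return true;
      } else {
        stack.push_back(n.left);
        stack.push_back(n.right);
      }
    }
    return false;
  }
};

}  // namespace

// Count, for each origin, how many of the given directions escape the mesh.
// [[Rcpp::export(name = ".cpp_visibility_counts")]]
IntegerVector cpp_visibility_counts(NumericMatrix V, IntegerMatrix F,
                                    NumericMatrix origins, NumericMatrix dirs) {
  const int nf = F.nrow(), no = origins.nrow(), nd = dirs.nrow();
  BVH bvh;
  bvh.vx.resize(9 * nf);
  bvh.tbox.resize(nf);
  bvh.cx.resize(nf);
  bvh.cy.resize(nf);
  bvh.cz.resize(nf);
  bvh.idx.resize(nf);
  for (int i = 0; i < nf; ++i) {
    double c[3] = {0, 0, 0};
    for (int k = 0; k < 3; ++k) {
      int vi = F(i, k) - 1;
      double p[3] = {V(vi, 0), V(vi, 1), V(vi, 2)};
      for (int a = 0; a < 3; ++a) bvh.vx[9 * i + 3 * k + a] = p[a];
      bvh.tbox[i].grow(p);
      for (int a = 0; a < 3; ++a) c[a] += p[a] / 3.0;
    }
    bvh.cx[i] = c[0];
    bvh.cy[i] = c[1];
    bvh.cz[i] = c[2];
    bvh.idx[i] = i;
  }
  bvh.build(0, nf);

  IntegerVector out(no);
  for (int i = 0; i < no; ++i) {
    double o[3] = {origins(i, 0), origins(i, 1), origins(i, 2)};
    int visible = 0;
    for (int j = 0; j < nd; ++j) {
      double d[3] = {dirs(j, 0), dirs(j, 1), dirs(j, 2)};
      if (!bvh.any_hit(o, d)) ++visible;
    }
    out[i] = visible;
  }
  return out;
}
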