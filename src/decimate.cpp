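#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <map>
#include <queue>
#include <vector>
using namespace Rcpp;

// Quadric edge-collapse decimation (Garland-Heckbert) with boundary
// preservation. Deterministic: the collapse queue is ordered by
// (cost, min vertex index, max vertex index) and nothing is randomized.

namespace {

struct Quadric {
  // symmetric 4x4: indices a00 a01 a02 a03 a11 a12 a13 a22 a23 a33
  double q[10] = {0, 0, 0, 0, 0, 0, 0, 0, 0, 0};
  void add_plane(double nx, double ny, double nz, double d, double w) {
    q[0] += w * nx * nx; q[1] += w * nx * ny; q[2] += w * nx * nz; q[3] += w * nx * d;
    q[4] += w * ny * ny; q[5] += w * ny * nz; q[6] += w * ny * d;
    q[7] += w * nz * nz; q[8] += w * nz * d;
    q[9] += w * d * d;
  }
  void add(const Quadric& o) { for (int i = 0; i < 10; ++i) q[i] += o.q[i]; }
  double eval(const double* v) const {
    double x = v[0], y = v[1], z = v[2];
    return q[0]*x*x + 2*q[1]*x*y + 2*q[2]*x*z + 2*q[3]*x
         + q[4]*y*y + 2*q[5]*y*z + 2*q[6]*y
         + q[7]*z*z + 2*q[8]*z + q[9];
  }
  // Solve A v = -b for the minimizer; false if near-singular.
  bool minimizer(double* out) const {
    double a = q[0], b = q[1], c = q[2], d = q[4], e = q[5], f = q[7];
    double det = a * (d * f - e * e) - b * (b * f - c * e) + c * (b * e - c * d);
    double scale = std::fabs(a) + std::fabs(d) + std::fabs(f) + 1e-300;
    if (std::fabs(det) < 1e-10 * scale * scale * scale) return false;
    double rx = -q[3], ry = -q[6], rz = -q[8];
    out[0] = (rx * (d * f - e * e) - b * (ry * f - rz * e) + c * (ry * e - rz * d)) / det;
    out[1] = (a * (ry * f - rz * e) - rx * (b * f - c * e) + c * (b * rz - c * ry)) / det;
    out[2] = (a * (d * rz - e * ry) - b * (b * rz - c * ry) + rx * (b * e - c * d)) / det;
    return std::isfinite(out[0]) && std::isfinite(out[1]) && std::isfinite(out[2]);
  }
};

struct HeapItem {
  double cost;
  int u, v;          // u < v
  int su, sv;        // vertex stamps at push time
};
struct HeapCmp {
  bool operator()(const HeapItem& a, const HeapItem& b) const {
    if (a.cost != b.cost) return a.cost > b.cost;
    if (a.u != b.u) return a.u > b.u;
    return a.v > b.v;
  }
};

struct Mesh {
  std::vector<double> pos;            // 3 per vertex
  std::vector<int> f;                 // 3 per face
  std::vector<char> face_alive, vert_alive, vert_boundary;
  std::vector<std::vector<int>> inc;  // vertex -> alive incident faces
  std::vector<Quadric> Q;
  std::vector<int> stamp;
  int alive_faces = 0;

  double* P(int v) { return &pos[3 * v]; }
  const double* P(int v) const { return &pos[3 * v]; }

  int shared_count(int a, int b) const {
    int c = 0;
    for (int fi : inc[a]) {
      const int* fv = &f[3 * fi];
      if (fv[0] == b || fv[1] == b || fv[2] == b) ++c;
    }
    return c;
  }

  // Boundary status from *current* connectivity: any incident edge with a
  // single incident face. (A sticky flag would spread through collapses.)
  bool is_boundary(int v) const {
    for (int fi : inc[v])
      for (int k = 0; k < 3; ++k) {
        int a = f[3 * fi + k], b = f[3 * fi + (k + 1) % 3];
        if (a != v && b != v) continue;
        int w = (a == v) ? b : a;
        if (shared_count(v, w) == 1) return true;
      }
    return false;
  }

  void face_cross(int fi, double* n) const {
    const double *a = P(f[3*fi]), *b = P(f[3*fi+1]), *c = P(f[3*fi+2]);
    double u1[3], u2[3];
    for (int k = 0; k < 3; ++k) { u1[k] = b[k] - a[k]; u2[k] = c[k] - a[k]; }
    n[0] = u1[1]*u2[2] - u1[2]*u2[1];
    n[1] = u1[2]*u2[0] - u1[0]*u2[2];
    n[2] = u1[0]*u2[1] - u1[1]*u2[0];
  }
};

static void neighbors_of(const Mesh& m, int v, std::vector<int>& out) {
  out.clear();
  for (int fi : m.inc[v])
    for (int k = 0; k < 3; ++k) {
      int w = m.f[3 * fi + k];
      if (w != v) out.push_back(w);
    }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
}

static double edge_cost(const Mesh& m, int u, int v, double* out_pos) {
  Quadric Quv = m.Q[u];
  Quv.add(m.Q[v]);
  bool bu = m.is_boundary(u), bv = m.is_boundary(v);
  double cand[4][3];
  int nc = 0;
  auto push_cand = [&](const double* p) {
    for (int k = 0; k < 3; ++k) cand[nc][k] = p[k];
    ++nc;
  };
  if (bu && !bv) {
    push_cand(m.P(u));
  } else if (bv && !bu) {
    push_cand(m.P(v));
  } else {
    double opt[3];
    if (!bu && !bv && Quv.minimizer(opt)) push_cand(opt);
    double mid[3] = {0.5 * (m.P(u)[0] + m.P(v)[0]),
                     0.5 * (m.P(u)[1] + m.P(v)[1]),
                     0.5 * (m.P(u)[2] + m.P(v)[2])};
    push_cand(mid);
    push_cand(m.P(u));
    push_cand(m.P(v));
  }
  int best = 0;
  double best_c = Quv.eval(cand[0]);
  for (int i = 1; i < nc; ++i) {
    double c = Quv.eval(cand[i]);
    if (c < best_c) { best_c = c; best = i; }
  }
  for (int k = 0; k < 3; ++k) out_pos[k] = cand[best][k];
  return best_c;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_quadric_decimate")]]
List cpp_quadric_decimate(NumericMatrix V, IntegerMatrix F, int target) {
  const int nv = V.nrow(), nf = F.nrow();
  Mesh m;
  m.pos.resize(3 * nv);
  for (int i = 0; i < nv; ++i)
    for (int k = 0; k < 3; ++k) m.pos[3 * i + k] = V(i, k);
  m.f.resize(3 * nf);
  for (int i = 0; i < nf; ++i)
    for (int k = 0; k < 3; ++k) m.f[3 * i + k] = F(i, k) - 1;
  m.face_alive.assign(nf, 1);
  m.vert_alive.assign(nv, 1);
  m.vert_boundary.assign(nv, 0);
  m.inc.assign(nv, {});
  m.Q.assign(nv, Quadric());
  m.stamp.assign(nv, 0);
  m.alive_faces = nf;
  for (int i = 0; i < nf; ++i)
    for (int k = 0; k < 3; ++k) m.inc[m.f[3 * i + k]].push_back(i);

  // Face quadrics, area-weighted.
  std::vector<double> fnormal(3 * nf);
  for (int i = 0; i < nf; ++i) {
    double n[3];
    m.face_cross(i, n);
    double len = std::sqrt(n[0]*n[0] + n[1]*n[1] + n[2]*n[2]);
    double area = 0.5 * len;
    if (len < 1e-300) { fnormal[3*i] = fnormal[3*i+1] = fnormal[3*i+2] = 0; continue; }
    for (int k = 0; k < 3; ++k) { n[k] /= len; fnormal[3 * i + k] = n[k]; }
    const double* a = m.P(m.f[3 * i]);
    double d = -(n[0]*a[0] + n[1]*a[1] + n[2]*a[2]);
    Quadric K;
    K.add_plane(n[0], n[1], n[2], d, area);
    for (int k = 0; k < 3; ++k) m.Q[m.f[3 * i + k]].add(K);
  }

  // Boundary edges: add a strong perpendicular-plane constraint quadric.
  std::map<std::pair<int, int>, std::vector<int>> edge_faces;
  for (int i = 0; i < nf; ++i)
    for (int k = 0; k < 3; ++k) {
      int a = m.f[3 * i + k], b = m.f[3 * i + (k + 1) % 3];
      edge_faces[{std::min(a, b), std::max(a, b)}].push_back(i);
    }
  for (const auto& ef : edge_faces) {
    if (ef.second.size() != 1) continue;
    int a = ef.first.first, b = ef.first.second, fi = ef.second[0];
    m.vert_boundary[a] = m.vert_boundary[b] = 1;
    double e[3], n[3];
    for (int k = 0; k < 3; ++k) e[k] = m.P(b)[k] - m.P(a)[k];
    const double* fn = &fnormal[3 * fi];
    n[0] = e[1]*fn[2] - e[2]*fn[1];
    n[1] = e[2]*fn[0] - e[0]*fn[2];
    n[2] = e[0]*fn[1] - e[1]*fn[0];
    double len = std::sqrt(n[0]*n[0] + n[1]*n[1] + n[2]*n[2]);
    double len2 = e[0]*e[0] + e[1]*e[1] + e[2]*e[2];
    if (len < 1e-300) continue;
    for (int k = 0; k < 3; ++k) n[k] /= len;
    double d = -(n[0]*m.P(a)[0] + n[1]*m.P(a)[1] + n[2]*m.P(a)[2]);
    Quadric K;
    K.add_plane(n[0], n[1], n[2], d, 1000.0 * len2);
    m.Q[a].add(K);
    m.Q[b].add(K);
  }

  std::priority_queue<HeapItem, std::vector<HeapItem>, HeapCmp> heap;
  auto push_edge = [&](int u, int v) {
    if (u > v) std::swap(u, v);
    double p[3];
    double c = edge_cost(m, u, v, p);
    heap.push({c, u, v, m.stamp[u], m.stamp[v]});
  };
  for (const auto& ef : edge_faces) push_edge(ef.first.first, ef.first.second);

  std::vector<int> nu, nvv, common, shared;
  int faces_at_last_rebuild = -1;
  while (m.alive_faces > target) {
    if (heap.empty()) {
      // Rejected edges (link/flip tests) are not re-pushed; rebuild the
      // queue and retry as long as the previous rebuild made progress.
      if (m.alive_faces == faces_at_last_rebuild) break;
      faces_at_last_rebuild = m.alive_faces;
      std::map<std::pair<int, int>, char> seen;
      for (int i = 0; i < nf; ++i) {
        if (!m.face_alive[i]) continue;
        for (int k = 0; k < 3; ++k) {
          int a = m.f[3 * i + k], b = m.f[3 * i + (k + 1) % 3];
          auto key = std::make_pair(std::min(a, b), std::max(a, b));
          if (!seen.count(key)) { seen[key] = 1; push_edge(key.first, key.second); }
        }
      }
      if (heap.empty()) break;
      continue;
    }
    HeapItem it = heap.top();
    heap.pop();
    int u = it.u, v = it.v;
    if (!m.vert_alive[u] || !m.vert_alive[v]) continue;
    if (it.su != m.stamp[u] || it.sv != m.stamp[v]) continue;

    shared.clear();
    for (int fi : m.inc[u]) {
      const int* fv = &m.f[3 * fi];
      if (fv[0] == v || fv[1] == v || fv[2] == v) shared.push_back(fi);
    }
    if (shared.empty()) continue;  // no longer an edge
    bool bu = m.is_boundary(u), bv = m.is_boundary(v);
    if (bu && bv && shared.size() != 1) continue;  // interior chord between boundary verts

    // Link condition: common neighbours must be exactly the shared faces' apices.
    neighbors_of(m, u, nu);
    neighbors_of(m, v, nvv);
    common.clear();
    std::set_intersection(nu.begin(), nu.end(), nvv.begin(), nvv.end(),
                          std::back_inserter(common));
    common.erase(std::remove(common.begin(), common.end(), u), common.end());
    common.erase(std::remove(common.begin(), common.end(), v), common.end());
    if (common.size() != shared.size()) continue;

    double p[3];
    edge_cost(m, u, v, p);

    // Normal-flip / degeneracy test on every surviving incident face.
    bool ok = true;
    for (int pass = 0; pass < 2 && ok; ++pass) {
      int w = pass == 0 ? u : v;
      for (int fi : m.inc[w]) {
        const int* fv = &m.f[3 * fi];
        bool has_u = fv[0] == u || fv[1] == u || fv[2] == u;
        bool has_v = fv[0] == v || fv[1] == v || fv[2] == v;
        if (has_u && has_v) continue;  // face dies
        double before[3];
        m.face_cross(fi, before);
        double a[3][3];
        for (int k = 0; k < 3; ++k) {
          const double* src = (fv[k] == w) ? p : m.P(fv[k]);
          for (int c = 0; c < 3; ++c) a[k][c] = src[c];
        }
        double e1[3], e2[3], after[3];
        for (int c = 0; c < 3; ++c) { e1[c] = a[1][c] - a[0][c]; e2[c] = a[2][c] - a[0][c]; }
        after[0] = e1[1]*e2[2] - e1[2]*e2[1];
        after[1] = e1[2]*e2[0] - e1[0]*e2[2];
        after[2] = e1[0]*e2[1] - e1[1]*e2[0];
        double dot = before[0]*after[0] + before[1]*after[1] + before[2]*after[2];
        double mag2 = after[0]*after[0] + after[1]*after[1] + after[2]*after[2];
        double bmag2 = before[0]*before[0] + before[1]*before[1] + before[2]*before[2];
        if (dot <= 0 || mag2 < 1e-12 * bmag2) { ok = false; break; }
      }
    }
    if (!ok) continue;

    // Collapse v into u at position p.
    for (int k = 0; k < 3; ++k) m.P(u)[k] = p[k];
    m.Q[u].add(m.Q[v]);
    std::vector<int> vfaces = m.inc[v];
    for (int fi : vfaces) {
      int* fv = &m.f[3 * fi];
      bool has_u = fv[0] == u || fv[1] == u || fv[2] == u;
      if (has_u) {
        m.face_alive[fi] = 0;
        --m.alive_faces;
        for (int k = 0; k < 3; ++k) {
          auto& lst = m.inc[fv[k]];
          lst.erase(std::remove(lst.begin(), lst.end(), fi), lst.end());
        }
      } else {
        for (int k = 0; k < 3; ++k)
          if (fv[k] == v) fv[k] = u;
        m.inc[u].push_back(fi);
      }
    }
    m.vert_alive[v] = 0;
    ++m.stamp[u];
    ++m.stamp[v];
    // Only edges incident to u changed (Q[u], position, boundary flag).
    neighbors_of(m, u, nu);
    for (int w : nu) push_edge(u, w);
  }

  // Compact output.
  std::vector<int> vmap(nv, -1);
  int nvo = 0;
  for (int i = 0; i < nf; ++i)
    if (m.face_alive[i])
      for (int k = 0; k < 3; ++k) {
        int vi = m.f[3 * i + k];
        if (vmap[vi] < 0) vmap[vi] = nvo++;
      }
  NumericMatrix Vo(nvo, 3);
  for (int i = 0; i < nv; ++i)
    if (vmap[i] >= 0)
      for (int k = 0; k < 3; ++k) Vo(vmap[i], k) = m.pos[3 * i + k];
  IntegerMatrix Fo(m.alive_faces, 3);
  int r = 0;
  for (int i = 0; i < nf; ++i)
    if (m.face_alive[i]) {
      for (int k = 0; k < 3; ++k) Fo(r, k) = vmap[m.f[3 * i + k]] + 1;
      ++r;
    }
  return List::create(_["vertices"] = Vo, _["faces"] = Fo);
}
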