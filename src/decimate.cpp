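// Quadric edge-collapse decimation (Garland-Heckbert) for closed 2-manifold
// triangle meshes, with optional per-vertex cost weights used to keep labeled
// regions (e.g. the carved ear) at higher resolution.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <array>
#include <set>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Quadric {
  // symmetric 4x4 stored as upper triangle
  double q[10] = {0, 0, 0, 0, 0, 0, 0, 0, 0, 0};
  void add_plane(double a, double b, double c, double d, double w) {
    double v[4] = {a, b, c, d};
    int m = 0;
    for (int i = 0; i < 4; ++i)
      for (int j = i; j < 4; ++j) q[m++] += w * v[i] * v[j];
  }
  void add(const Quadric& o) {
    for (int i = 0; i < 10; ++i) q[i] += o.q[i];
  }
  double eval(const double* p) const {
    double v[4] = {p[0], p[1], p[2], 1.0};
    double s = 0;
    int m = 0;
    for (int i = 0; i < 4; ++i)
      for (int j = i; j < 4; ++j) {
        double t = q[m++] * v[i] * v[j];
        s += (i == j) ? t : 2 * t;
      }
    return s;
  }
  // minimize over position; false if singular
  bool optimum(double* p) const {
    double A[3][3] = {{q[0], q[1], q[2]}, {q[1], q[4], q[5]}, {q[2], q[5], q[7]}};
    double b[3] = {-q[3], -q[6], -q[8]};
    // Gaussian elimination with partial pivoting
    int piv[3] = {0, 1, 2};
    double M[3][4];
    for (int i = 0; i < 3; ++i) {
      for (int j = 0; j < 3; ++j) M[i][j] = A[i][j];
      M[i][3] = b[i];
    }
    (void)piv;
    for (int c = 0; c < 3; ++c) {
      int best = c;
      for (int r = c + 1; r < 3; ++r)
        if (std::fabs(M[r][c]) > std::fabs(M[best][c])) best = r;
      if (std::fabs(M[best][c]) < 1e-10) return false;
      if (best != c)
        for (int j = 0; j < 4; ++j) std::swap(M[c][j], M[best][j]);
      for (int r = 0; r < 3; ++r) {
        if (r == c) continue;
        double f = M[r][c] / M[c][c];
        for (int j = c; j < 4; ++j) M[r][j] -= f * M[c][j];
      }
    }
    for (int i = 0; i < 3; ++i) p[i] = M[i][3] / M[i][i];
    return true;
  }
};

struct HeapItem {
  double cost;
  int v1, v2;
  long stamp;
  int tries = 0;
  bool operator<(const HeapItem& o) const { return cost > o.cost; } // min-heap
};

} // namespace

// cap_dense / cap_sparse (< 0 disables): maximum triangle area allowed to be
// created by a collapse, for faces touching weighted (dense-region) vertices
// and for the rest; drives uniform sizing and the dense-region area contrast.
// [[Rcpp::export]]
List cpp_decimate(NumericMatrix Vin, IntegerMatrix Fin, int target_faces,
                  NumericVector vertex_weight, double cap_dense = -1,
                  double cap_sparse = -1) {
  int nv = Vin.nrow(), nf = Fin.nrow();
  std::vector<std::array<double, 3>> V(nv);
  std::vector<std::array<int, 3>> F(nf);
  for (int i = 0; i < nv; ++i) V[i] = {Vin(i, 0), Vin(i, 1), Vin(i, 2)};
  for (int f = 0; f < nf; ++f) F[f] = {Fin(f, 0), Fin(f, 1), Fin(f, 2)};
  std::vector<double> wgt(nv, 1.0);
  if (vertex_weight.size() == nv)
    for (int i = 0; i < nv; ++i) wgt[i] = vertex_weight[i];

  std::vector<char> face_alive(nf, 1), vert_alive(nv, 1);
  std::vector<std::vector<int>> vfaces(nv);
  for (int f = 0; f < nf; ++f)
    for (int k = 0; k < 3; ++k) vfaces[F[f][k]].push_back(f);

  auto face_normal_area = [&](int f, double* n) {
    const auto& a = V[F[f][0]];
    const auto& b = V[F[f][1]];
    const auto& c = V[F[f][2]];
    double e1[3], e2[3];
    for (int k = 0; k < 3; ++k) { e1[k] = b[k] - a[k]; e2[k] = c[k] - a[k]; }
    n[0] = e1[1] * e2[2] - e1[2] * e2[1];
    n[1] = e1[2] * e2[0] - e1[0] * e2[2];
    n[2] = e1[0] * e2[1] - e1[1] * e2[0];
    double area2 = std::sqrt(n[0] * n[0] + n[1] * n[1] + n[2] * n[2]);
    return 0.5 * area2;
  };

  std::vector<Quadric> Q(nv);
  for (int f = 0; f < nf; ++f) {
    double n[3];
    double area = face_normal_area(f, n);
    if (area < 1e-18) continue;
    double nn = 2 * area;
    double a = n[0] / nn, b = n[1] / nn, c = n[2] / nn;
    const auto& p0 = V[F[f][0]];
    double d = -(a * p0[0] + b * p0[1] + c * p0[2]);
    for (int k = 0; k < 3; ++k) {
      Quadric qf;
      qf.add_plane(a, b, c, d, area / 3.0);
      Q[F[f][k]].add(qf);
    }
  }

  std::vector<long> stamp(nv, 0);
  std::priority_queue<HeapItem> heap;

  auto edge_cost = [&](int v1, int v2, double* pos) {
    Quadric qq = Q[v1];
    qq.add(Q[v2]);
    double p[3];
    if (!qq.optimum(p)) {
      // fall back to the better endpoint or midpoint
      double cands[3][3] = {{V[v1][0], V[v1][1], V[v1][2]},
                            {V[v2][0], V[v2][1], V[v2][2]},
                            {(V[v1][0] + V[v2][0]) / 2, (V[v1][1] + V[v2][1]) / 2,
                             (V[v1][2] + V[v2][2]) / 2}};
      double best = R_PosInf;
      for (int i = 0; i < 3; ++i) {
        double cst = qq.eval(cands[i]);
        if (cst < best) {
          best = cst;
          for (int k = 0; k < 3; ++k) p[k] = cands[i][k];
        }
      }
    }
    for (int k = 0; k < 3; ++k) pos[k] = p[k];
    double c = qq.eval(p);
    // small edge-length^4 term (same units as the quadric): orders collapses
    // by size even on flat patches where the quadric cost vanishes
    double l2 = 0;
    for (int m = 0; m < 3; ++m) l2 += (V[v1][m] - V[v2][m]) * (V[v1][m] - V[v2][m]);
    return (std::max(c, 0.0) + 1e-3 * l2 * l2) * std::max(wgt[v1], wgt[v2]);
  };

  auto push_edges_of = [&](int v) {
    std::set<int> nb;
    for (int f : vfaces[v])
      if (face_alive[f])
        for (int k = 0; k < 3; ++k)
          if (F[f][k] != v) nb.insert(F[f][k]);
    for (int u : nb) {
      double pos[3];
      double c = edge_cost(v, u, pos);
      heap.push({c, v, u, stamp[v] + stamp[u]});
    }
  };
  auto push_all = [&]() {
    heap = std::priority_queue<HeapItem>();
    for (int v = 0; v < nv; ++v)
      if (vert_alive[v]) {
        std::set<int> nb;
        for (int f : vfaces[v])
          if (face_alive[f])
            for (int k = 0; k < 3; ++k)
              if (F[f][k] > v) nb.insert(F[f][k]);
        for (int u : nb) {
          double pos[3];
          double c = edge_cost(v, u, pos);
          heap.push({c, v, u, stamp[v] + stamp[u]});
        }
      }
  };
  push_all();

  int alive_faces = nf;
  auto compact_vfaces = [&](int v) {
    if (vfaces[v].size() > 24) {
      auto& fv = vfaces[v];
      fv.erase(std::remove_if(fv.begin(), fv.end(),
                              [&](int f) { return !face_alive[f]; }),
               fv.end());
      std::sort(fv.begin(), fv.end());
      fv.erase(std::unique(fv.begin(), fv.end()), fv.end());
    }
  };
  auto neighbors = [&](int v) {
    std::set<int> nb;
    for (int f : vfaces[v])
      if (face_alive[f])
        for (int k = 0; k < 3; ++k)
          if (F[f][k] != v) nb.insert(F[f][k]);
    return nb;
  };

  // rejected pops are not re-queued, so the heap can drain before the target
  // is met; rebuild it a few times as long as progress is being made
  for (int round = 0; round < 8 && alive_faces > target_faces; ++round) {
    if (round > 0) {
      int before = alive_faces;
      push_all();
      (void)before;
    }
    int faces_at_round_start = alive_faces;
  while (alive_faces > target_faces && !heap.empty()) {
    HeapItem it = heap.top();
    heap.pop();
    int v1 = it.v1, v2 = it.v2;
    if (!vert_alive[v1] || !vert_alive[v2]) continue;
    if (it.stamp != stamp[v1] + stamp[v2]) continue; // stale
    compact_vfaces(v1);
    compact_vfaces(v2);
    // a rejected collapse may become valid later; requeue with escalating
    // cost so cheap-but-blocked regions cannot silently starve the ordering
    auto requeue = [&]() {
      if (it.tries < 20)
        heap.push({std::max(it.cost, 1e-300) * 2, v1, v2,
                   stamp[v1] + stamp[v2], it.tries + 1});
    };
    // shared faces must be exactly two (closed manifold edge)
    std::vector<int> shared;
    for (int f : vfaces[v1])
      if (face_alive[f])
        for (int k = 0; k < 3; ++k)
          if (F[f][k] == v2) shared.push_back(f);
    if (shared.size() != 2) { requeue(); continue; }
    // link condition: common neighbor vertices must be exactly the two opposite ones
    std::set<int> n1 = neighbors(v1), n2 = neighbors(v2), common;
    std::set_intersection(n1.begin(), n1.end(), n2.begin(), n2.end(),
                          std::inserter(common, common.begin()));
    if (common.size() != 2) { requeue(); continue; }
    double pos[3];
    edge_cost(v1, v2, pos);
    // geometric validity: no normal flips, no degenerate faces after collapse
    bool ok = true;
    for (int pass = 0; pass < 2 && ok; ++pass) {
      int v = pass == 0 ? v1 : v2;
      for (int f : vfaces[v]) {
        if (!face_alive[f]) continue;
        if (f == shared[0] || f == shared[1]) continue;
        double n_old[3];
        double area_old = face_normal_area(f, n_old);
        std::array<double, 3> saved1 = V[v1], saved2 = V[v2];
        V[v1] = {pos[0], pos[1], pos[2]};
        V[v2] = {pos[0], pos[1], pos[2]};
        double n_new[3];
        double area_new = face_normal_area(f, n_new);
        V[v1] = saved1;
        V[v2] = saved2;
        double dp = n_old[0] * n_new[0] + n_old[1] * n_new[1] + n_old[2] * n_new[2];
        // reject flips and slivers (radius-ratio quality ~ area / sum sq edges)
        int a0 = F[f][0] == v1 || F[f][0] == v2 ? -1 : F[f][0];
        (void)a0;
        double l2 = 0;
        for (int k = 0; k < 3; ++k) {
          int u = F[f][k], w = F[f][(k + 1) % 3];
          const double* pu = (u == v1 || u == v2) ? pos : V[u].data();
          const double* pw = (w == v1 || w == v2) ? pos : V[w].data();
          for (int m2 = 0; m2 < 3; ++m2)
            l2 += (pu[m2] - pw[m2]) * (pu[m2] - pw[m2]);
        }
        double qual = l2 > 0 ? 4.0 * std::sqrt(3.0) * area_new / l2 : 0.0;
        double l2_old = 0;
        for (int k = 0; k < 3; ++k) {
          int u = F[f][k], w = F[f][(k + 1) % 3];
          for (int m2 = 0; m2 < 3; ++m2)
            l2_old += (V[u][m2] - V[w][m2]) * (V[u][m2] - V[w][m2]);
        }
        double qual_old = l2_old > 0 ? 4.0 * std::sqrt(3.0) * area_old / l2_old : 0.0;
        bool degenerate_before = area_old < 1e-12 || qual_old < 0.02;
        // degenerate faces may move freely (any change improves them);
        // healthy faces must not flip or become slivers
        if (area_new < 1e-14 ||
            (!degenerate_before && (dp <= 0 || (qual < 0.02 && qual < qual_old)))) {
          ok = false;
          break;
        }
        // region-dependent area caps (only reject growth beyond the cap)
        bool dense = wgt[F[f][0]] > 1 || wgt[F[f][1]] > 1 || wgt[F[f][2]] > 1;
        double cap = dense ? cap_dense : cap_sparse;
        if (cap > 0 && area_new > cap && area_new > area_old) {
          ok = false;
          break;
        }
      }
    }
    if (!ok) { requeue(); continue; }
    // apply collapse v2 -> v1 at pos
    V[v1] = {pos[0], pos[1], pos[2]};
    Q[v1].add(Q[v2]);
    wgt[v1] = std::max(wgt[v1], wgt[v2]);
    face_alive[shared[0]] = 0;
    face_alive[shared[1]] = 0;
    alive_faces -= 2;
    for (int f : vfaces[v2]) {
      if (!face_alive[f]) continue;
      for (int k = 0; k < 3; ++k)
        if (F[f][k] == v2) F[f][k] = v1;
      vfaces[v1].push_back(f);
    }
    vert_alive[v2] = 0;
    stamp[v1]++;
    stamp[v2]++;
    push_edges_of(v1);
  }
    if (alive_faces == faces_at_round_start && round > 0) break; // stuck
  }

  // cleanup: collapse any remaining degenerate faces (they would not survive
  // the downstream merge/area tolerances and would open the surface)
  for (int cl = 0; cl < 50; ++cl) {
    std::vector<int> degen;
    for (int f = 0; f < nf; ++f) {
      if (!face_alive[f]) continue;
      double n[3];
      double area = face_normal_area(f, n);
      double emin = R_PosInf;
      for (int k = 0; k < 3; ++k) {
        double e2 = 0;
        for (int m = 0; m < 3; ++m) {
          double d = V[F[f][k]][m] - V[F[f][(k + 1) % 3]][m];
          e2 += d * d;
        }
        emin = std::min(emin, e2);
      }
      if (area < 4e-6 || emin < 1.6e-7) degen.push_back(f);
    }
    if (degen.empty()) break;
    heap = std::priority_queue<HeapItem>();
    for (int f : degen)
      for (int k = 0; k < 3; ++k) {
        int v1 = F[f][k], v2 = F[f][(k + 1) % 3];
        double pos[3];
        heap.push({edge_cost(v1, v2, pos), v1, v2, stamp[v1] + stamp[v2]});
      }
    int before = alive_faces;
    int fas = alive_faces;
    (void)fas;
    // re-run the collapse loop without the face-count target
    while (!heap.empty() && alive_faces > 4) {
      HeapItem it = heap.top();
      heap.pop();
      int v1 = it.v1, v2 = it.v2;
      if (!vert_alive[v1] || !vert_alive[v2]) continue;
      if (it.stamp != stamp[v1] + stamp[v2]) continue;
      compact_vfaces(v1);
      compact_vfaces(v2);
      std::vector<int> shared;
      for (int f : vfaces[v1])
        if (face_alive[f])
          for (int k = 0; k < 3; ++k)
            if (F[f][k] == v2) shared.push_back(f);
      if (shared.size() != 2) continue;
      std::set<int> n1 = neighbors(v1), n2 = neighbors(v2), common;
      std::set_intersection(n1.begin(), n1.end(), n2.begin(), n2.end(),
                            std::inserter(common, common.begin()));
      if (common.size() != 2) continue;
      double pos[3];
      edge_cost(v1, v2, pos);
      V[v1] = {pos[0], pos[1], pos[2]};
      Q[v1].add(Q[v2]);
      face_alive[shared[0]] = 0;
      face_alive[shared[1]] = 0;
      alive_faces -= 2;
      for (int f : vfaces[v2]) {
        if (!face_alive[f]) continue;
        for (int k = 0; k < 3; ++k)
          if (F[f][k] == v2) F[f][k] = v1;
        vfaces[v1].push_back(f);
      }
      vert_alive[v2] = 0;
      stamp[v1]++;
      stamp[v2]++;
    }
    if (alive_faces == before) break;
  }

  // compact
  std::vector<int> vmap(nv, -1);
  int nvo = 0;
  for (int v = 0; v < nv; ++v)
    if (vert_alive[v]) vmap[v] = nvo++;
  int nfo = 0;
  for (int f = 0; f < nf; ++f)
    if (face_alive[f]) nfo++;
  NumericMatrix Vout(nvo, 3);
  IntegerMatrix Fout(nfo, 3);
  for (int v = 0; v < nv; ++v)
    if (vmap[v] >= 0)
      for (int k = 0; k < 3; ++k) Vout(vmap[v], k) = V[v][k];
  int m = 0;
  for (int f = 0; f < nf; ++f)
    if (face_alive[f]) {
      for (int k = 0; k < 3; ++k) Fout(m, k) = vmap[F[f][k]];
      ++m;
    }
  return List::create(_["vertices"] = Vout, _["faces"] = Fout);
}
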