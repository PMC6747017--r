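// Geometric primitives on triangulated surfaces: signed solid angles,
// point-in-mesh tests, closest-point queries and mesh-mesh distance.
// All meshes are (V: n x 3 double, F: m x 3 0-based int) with outward CCW faces.
#include <RcppArmadillo.h>
#include <vector>
#include <algorithm>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }

// Signed solid angle of triangle (y1,y2,y3) seen from the origin
// (van Oosterom & Strackee arctangent formula). Positive when the triangle
// winds counter-clockwise as seen from the point side the normal points away from.
static double tri_solid_angle(const double* y1, const double* y2, const double* y3) {
  double n1 = norm3(y1), n2 = norm3(y2), n3 = norm3(y3);
  double cr[3];
  cross3(y2, y3, cr);
  double num = dot3(y1, cr);
  double den = n1 * n2 * n3 + dot3(y1, y2) * n3 + dot3(y1, y3) * n2 + dot3(y2, y3) * n1;
  return 2.0 * std::atan2(num, den);
}

// [[Rcpp::export]]
NumericVector cpp_solid_angle(NumericMatrix pts, NumericMatrix V, IntegerMatrix F) {
  int np = pts.nrow(), nf = F.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double x[3] = {pts(p, 0), pts(p, 1), pts(p, 2)};
    double acc = 0.0;
    for (int f = 0; f < nf; ++f) {
      double y1[3], y2[3], y3[3];
      for (int k = 0; k < 3; ++k) {
        y1[k] = V(F(f, 0), k) - x[k];
        y2[k] = V(F(f, 1), k) - x[k];
        y3[k] = V(F(f, 2), k) - x[k];
      }
      acc += tri_solid_angle(y1, y2, y3);
    }
    out[p] = acc;
  }
  return out;
}

// Per-triangle solid angles from a single point (diagnostics / near-singular report).
// [[Rcpp::export]]
NumericVector cpp_solid_angle_per_face(NumericVector pt, NumericMatrix V, IntegerMatrix F) {
  int nf = F.nrow();
  NumericVector out(nf);
  double x[3] = {pt[0], pt[1], pt[2]};
  for (int f = 0; f < nf; ++f) {
    double y1[3], y2[3], y3[3];
    for (int k = 0; k < 3; ++k) {
      y1[k] = V(F(f, 0), k) - x[k];
      y2[k] = V(F(f, 1), k) - x[k];
      y3[k] = V(F(f, 2), k) - x[k];
    }
    out[f] = tri_solid_angle(y1, y2, y3);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Uniform 3D grid over triangles for segment / proximity queries.
struct TriGrid {
  double lo[3], cell;
  int n[3];
  std::vector<std::vector<int>> bins;
  const NumericMatrix* V;
  const IntegerMatrix* F;

  int idx(int i, int j, int k) const { return (k * n[1] + j) * n[0] + i; }

  void build(const NumericMatrix& Vm, const IntegerMatrix& Fm, double cell_hint) {
    V = &Vm;
    F = &Fm;
    double hi[3];
    for (int k = 0; k < 3; ++k) { lo[k] = R_PosInf; hi[k] = R_NegInf; }
    for (int i = 0; i < Vm.nrow(); ++i)
      for (int k = 0; k < 3; ++k) {
        lo[k] = std::min(lo[k], Vm(i, k));
        hi[k] = std::max(hi[k], Vm(i, k));
      }
    double ext = 0.0;
    for (int k = 0; k < 3; ++k) ext = std::max(ext, hi[k] - lo[k]);
    cell = cell_hint > 0 ? cell_hint : std::max(ext / 64.0, 1e-6);
    for (int k = 0; k < 3; ++k) {
      lo[k] -= 0.5 * cell;
      n[k] = std::max(1, (int)std::ceil((hi[k] - lo[k]) / cell) + 1);
    }
    // cap grid size
    while ((double)n[0] * n[1] * n[2] > 2.2e7) {
      cell *= 1.5;
      for (int k = 0; k < 3; ++k) n[k] = std::max(1, (int)std::ceil((n[k] * 2) / 3.0));
    }
    bins.assign((size_t)n[0] * n[1] * n[2], {});
    for (int f = 0; f < Fm.nrow(); ++f) {
      double tlo[3] = {R_PosInf, R_PosInf, R_PosInf}, thi[3] = {R_NegInf, R_NegInf, R_NegInf};
      for (int v = 0; v < 3; ++v)
        for (int k = 0; k < 3; ++k) {
          double c = Vm(Fm(f, v), k);
          tlo[k] = std::min(tlo[k], c);
          thi[k] = std::max(thi[k], c);
        }
      int i0[3], i1[3];
      for (int k = 0; k < 3; ++k) {
        i0[k] = std::max(0, (int)std::floor((tlo[k] - lo[k]) / cell));
        i1[k] = std::min(n[k] - 1, (int)std::floor((thi[k] - lo[k]) / cell));
      }
      for (int kk = i0[2]; kk <= i1[2]; ++kk)
        for (int jj = i0[1]; jj <= i1[1]; ++jj)
          for (int ii = i0[0]; ii <= i1[0]; ++ii) bins[idx(ii, jj, kk)].push_back(f);
    }
  }
};

// Moeller-Trumbore segment/ray vs triangle. Returns t (param along dir) or NA.
static bool ray_tri(const double* orig, const double* dir,
                    const double* a, const double* b, const double* c, double& t) {
  double e1[3], e2[3], pv[3], tv[3], qv[3];
  for (int k = 0; k < 3; ++k) { e1[k] = b[k] - a[k]; e2[k] = c[k] - a[k]; }
  cross3(dir, e2, pv);
  double det = dot3(e1, pv);
  if (std::fabs(det) < 1e-14) return false;
  double inv = 1.0 / det;
  for (int k = 0; k < 3; ++k) tv[k] = orig[k] - a[k];
  double u = dot3(tv, pv) * inv;
  if (u < -1e-12 || u > 1 + 1e-12) return false;
  cross3(tv, e1, qv);
  double v = dot3(dir, qv) * inv;
  if (v < -1e-12 || u + v > 1 + 1e-12) return false;
  t = dot3(e2, qv) * inv;
  return true;
}

// Inside test by ray-casting parity with a slightly irrational direction.
// [[Rcpp::export]]
LogicalVector cpp_inside_mesh(NumericMatrix pts, NumericMatrix V, IntegerMatrix F) {
  int np = pts.nrow(), nf = F.nrow();
  LogicalVector out(np);
  // direction fixed, irrational-ish to dodge edge/vertex hits
  double dir[3] = {1.0, 1.3e-4, 0.7e-4};
  double dn = norm3(dir);
  for (int k = 0; k < 3; ++k) dir[k] /= dn;
  // bin triangles by (y,z) bbox for the near-x ray
  double loy = R_PosInf, hiy = R_NegInf, loz = R_PosInf, hiz = R_NegInf;
  for (int i = 0; i < V.nrow(); ++i) {
    loy = std::min(loy, V(i, 1)); hiy = std::max(hiy, V(i, 1));
    loz = std::min(loz, V(i, 2)); hiz = std::max(hiz, V(i, 2));
  }
  int nb = 64;
  double cy = std::max((hiy - loy) / nb, 1e-9), cz = std::max((hiz - loz) / nb, 1e-9);
  std::vector<std::vector<int>> bins((size_t)nb * nb);
  double pad = std::max(cy, cz); // generous slack for the tiny ray skew
  for (int f = 0; f < nf; ++f) {
    double ty0 = R_PosInf, ty1 = R_NegInf, tz0 = R_PosInf, tz1 = R_NegInf;
    for (int v = 0; v < 3; ++v) {
      ty0 = std::min(ty0, V(F(f, v), 1)); ty1 = std::max(ty1, V(F(f, v), 1));
      tz0 = std::min(tz0, V(F(f, v), 2)); tz1 = std::max(tz1, V(F(f, v), 2));
    }
    int j0 = std::max(0, (int)((ty0 - pad - loy) / cy)), j1 = std::min(nb - 1, (int)((ty1 + pad - loy) / cy));
    int k0 = std::max(0, (int)((tz0 - pad - loz) / cz)), k1 = std::min(nb - 1, (int)((tz1 + pad - loz) / cz));
    for (int j = j0; j <= j1; ++j)
      for (int k = k0; k <= k1; ++k) bins[(size_t)k * nb + j].push_back(f);
  }
  for (int p = 0; p < np; ++p) {
    double o[3] = {pts(p, 0), pts(p, 1), pts(p, 2)};
    int j = (int)((o[1] - loy) / cy), k = (int)((o[2] - loz) / cz);
    if (j < 0 || j >= nb || k < 0 || k >= nb) { out[p] = false; continue; }
    double t;
    std::vector<double> hits;
    for (int f : bins[(size_t)k * nb + j]) {
      double a[3], b[3], c[3];
      for (int m = 0; m < 3; ++m) {
        a[m] = V(F(f, 0), m); b[m] = V(F(f, 1), m); c[m] = V(F(f, 2), m);
      }
      if (ray_tri(o, dir, a, b, c, t) && t > 0) hits.push_back(t);
    }
    std::sort(hits.begin(), hits.end());
    // rays through shared edges are reported by both triangles: count once
    hits.erase(std::unique(hits.begin(), hits.end(),
                           [](double a, double b) { return b - a < 1e-9; }),
               hits.end());
    out[p] = (hits.size() % 2) == 1;
  }
  return out;
}

// Closest point on triangle abc to p (Ericson, Real-Time Collision Detection).
static void closest_on_tri(const double* p, const double* a, const double* b,
                           const double* c, double* out) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) { ab[k] = b[k] - a[k]; ac[k] = c[k] - a[k]; ap[k] = p[k] - a[k]; }
  double d1 = dot3(ab, ap), d2 = dot3(ac, ap);
  if (d1 <= 0 && d2 <= 0) { for (int k = 0; k < 3; ++k) out[k] = a[k]; return; }
  double bp[3];
  for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
  double d3 = dot3(ab, bp), d4 = dot3(ac, bp);
  if (d3 >= 0 && d4 <= d3) { for (int k = 0; k < 3; ++k) out[k] = b[k]; return; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + v * ab[k];
    return;
  }
  double cp[3];
  for (int k = 0; k < 3; ++k) cp[k] = p[k] - c[k];
  double d5 = dot3(ab, cp), d6 = dot3(ac, cp);
  if (d6 >= 0 && d5 <= d6) { for (int k = 0; k < 3; ++k) out[k] = c[k]; return; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + w * ac[k];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k = 0; k < 3; ++k) out[k] = b[k] + w * (c[k] - b[k]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int k = 0; k < 3; ++k) out[k] = a[k] + ab[k] * v + ac[k] * w;
}

// Closest surface point for each query point. Returns distance, point, face.
// Queries farther than max_dist return Inf / face 0 (capped ring search).
// [[Rcpp::export]]
List cpp_closest_point(NumericMatrix pts, NumericMatrix V, IntegerMatrix F,
                       double cell = -1, double max_dist = -1) {
  TriGrid g;
  g.build(V, F, cell);
  int np = pts.nrow();
  NumericVector dist(np);
  NumericMatrix cp(np, 3);
  IntegerVector face(np);
  std::vector<int> stamp(F.nrow(), -1);
  for (int p = 0; p < np; ++p) {
    double q[3] = {pts(p, 0), pts(p, 1), pts(p, 2)};
    int ci[3];
    for (int k = 0; k < 3; ++k) {
      ci[k] = (int)std::floor((q[k] - g.lo[k]) / g.cell);
      ci[k] = std::min(std::max(ci[k], 0), g.n[k] - 1);
    }
    double best = R_PosInf, bestpt[3] = {0, 0, 0};
    int bestf = -1;
    int maxr = std::max(std::max(g.n[0], g.n[1]), g.n[2]);
    if (max_dist > 0) {
      // skip rings that cannot contain the surface: start near the bbox and
      // never search beyond the cap
      double dbox = 0;
      for (int k = 0; k < 3; ++k) {
        double lo = g.lo[k], hi = g.lo[k] + g.n[k] * g.cell;
        if (q[k] < lo) dbox += (lo - q[k]) * (lo - q[k]);
        if (q[k] > hi) dbox += (q[k] - hi) * (q[k] - hi);
      }
      if (std::sqrt(dbox) > max_dist) {
        dist[p] = R_PosInf;
        face[p] = -1;
        continue;
      }
      maxr = std::min(maxr, (int)std::ceil(max_dist / g.cell) + 1);
    }
    for (int r = 0; r <= maxr; ++r) {
      // lower bound on distance achievable in ring r
      if (r > 0) {
        double lb = (r - 1) * g.cell;
        if (lb > best) break;
      }
      for (int kk = std::max(0, ci[2] - r); kk <= std::min(g.n[2] - 1, ci[2] + r); ++kk)
        for (int jj = std::max(0, ci[1] - r); jj <= std::min(g.n[1] - 1, ci[1] + r); ++jj)
          for (int ii = std::max(0, ci[0] - r); ii <= std::min(g.n[0] - 1, ci[0] + r); ++ii) {
            if (r > 0 && std::abs(ii - ci[0]) != r && std::abs(jj - ci[1]) != r &&
                std::abs(kk - ci[2]) != r)
              continue; // only the shell
            for (int f : g.bins[g.idx(ii, jj, kk)]) {
              if (stamp[f] == p) continue;
              stamp[f] = p;
              double a[3], b[3], c[3], o[3];
              for (int m = 0; m < 3; ++m) {
                a[m] = V(F(f, 0), m); b[m] = V(F(f, 1), m); c[m] = V(F(f, 2), m);
              }
              closest_on_tri(q, a, b, c, o);
              double d2 = 0;
              for (int m = 0; m < 3; ++m) d2 += (o[m] - q[m]) * (o[m] - q[m]);
              double d = std::sqrt(d2);
              if (d < best) {
                best = d;
                bestf = f;
                for (int m = 0; m < 3; ++m) bestpt[m] = o[m];
              }
            }
          }
      if (best <= (double)r * g.cell) break; // nothing closer can exist outside
    }
    dist[p] = best;
    face[p] = bestf;
    for (int m = 0; m < 3; ++m) cp(p, m) = bestpt[m];
  }
  return List::create(_["distance"] = dist, _["point"] = cp, _["face"] = face);
}

// Segment-segment closest distance squared.
static double seg_seg_d2(const double* p1, const double* q1, const double* p2, const double* q2) {
  double d1[3], d2v[3], r[3];
  for (int k = 0; k < 3; ++k) { d1[k] = q1[k] - p1[k]; d2v[k] = q2[k] - p2[k]; r[k] = p1[k] - p2[k]; }
  double a = dot3(d1, d1), e = dot3(d2v, d2v), f = dot3(d2v, r);
  double s, t;
  if (a <= 1e-18 && e <= 1e-18) { s = t = 0; }
  else if (a <= 1e-18) { s = 0; t = std::min(1.0, std::max(0.0, f / e)); }
  else {
    double c = dot3(d1, r);
    if (e <= 1e-18) { t = 0; s = std::min(1.0, std::max(0.0, -c / a)); }
    else {
      double b = dot3(d1, d2v), den = a * e - b * b;
      s = den > 1e-18 ? std::min(1.0, std::max(0.0, (b * f - c * e) / den)) : 0.0;
      t = (b * s + f) / e;
      if (t < 0) { t = 0; s = std::min(1.0, std::max(0.0, -c / a)); }
      else if (t > 1) { t = 1; s = std::min(1.0, std::max(0.0, (b - c) / a)); }
    }
  }
  double d2s = 0;
  for (int k = 0; k < 3; ++k) {
    double diff = (p1[k] + s * d1[k]) - (p2[k] + t * d2v[k]);
    d2s += diff * diff;
  }
  return d2s;
}

// Exact triangle-triangle distance: min over 9 edge pairs and 6 vertex-face cases.
static double tri_tri_dist(const double* A0, const double* A1, const double* A2,
                           const double* B0, const double* B1, const double* B2) {
  const double* TA[3] = {A0, A1, A2};
  const double* TB[3] = {B0, B1, B2};
  double best = R_PosInf;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      best = std::min(best, seg_seg_d2(TA[i], TA[(i + 1) % 3], TB[j], TB[(j + 1) % 3]));
  double o[3];
  for (int i = 0; i < 3; ++i) {
    closest_on_tri(TA[i], B0, B1, B2, o);
    double d2 = 0;
    for (int k = 0; k < 3; ++k) d2 += (TA[i][k] - o[k]) * (TA[i][k] - o[k]);
    best = std::min(best, d2);
    closest_on_tri(TB[i], A0, A1, A2, o);
    d2 = 0;
    for (int k = 0; k < 3; ++k) d2 += (TB[i][k] - o[k]) * (TB[i][k] - o[k]);
    best = std::min(best, d2);
  }
  return std::sqrt(best);
}

// Exact minimum distance between two triangulated surfaces plus the closest pair.
// Vertex queries give an upper bound; candidate face pairs within that bound are
// then resolved exactly (covers edge-edge minima between faces).
// [[Rcpp::export]]
List cpp_mesh_distance(NumericMatrix VA, IntegerMatrix FA, NumericMatrix VB, IntegerMatrix FB) {
  // upper bound via vertex-to-mesh queries both ways
  List ra = cpp_closest_point(VA, VB, FB);
  List rb = cpp_closest_point(VB, VA, FA);
  NumericVector da = ra["distance"], db = rb["distance"];
  double best = R_PosInf;
  double pA[3] = {0, 0, 0}, pB[3] = {0, 0, 0};
  NumericMatrix cpa = ra["point"], cpb = rb["point"];
  for (int i = 0; i < da.size(); ++i)
    if (da[i] < best) {
      best = da[i];
      for (int k = 0; k < 3; ++k) { pA[k] = VA(i, k); pB[k] = cpa(i, k); }
    }
  for (int i = 0; i < db.size(); ++i)
    if (db[i] < best) {
      best = db[i];
      for (int k = 0; k < 3; ++k) { pB[k] = VB(i, k); pA[k] = cpb(i, k); }
    }
  // refine with exact face-face distance for nearby pairs
  TriGrid g;
  g.build(VB, FB, -1);
  double margin = best + 1e-9;
  std::vector<int> stamp(FB.nrow(), -1);
  for (int fa = 0; fa < FA.nrow(); ++fa) {
    double tlo[3] = {R_PosInf, R_PosInf, R_PosInf}, thi[3] = {R_NegInf, R_NegInf, R_NegInf};
    double A0[3], A1[3], A2[3];
    for (int k = 0; k < 3; ++k) {
      A0[k] = VA(FA(fa, 0), k); A1[k] = VA(FA(fa, 1), k); A2[k] = VA(FA(fa, 2), k);
      tlo[k] = std::min(A0[k], std::min(A1[k], A2[k])) - margin;
      thi[k] = std::max(A0[k], std::max(A1[k], A2[k])) + margin;
    }
    int i0[3], i1[3];
    bool out = false;
    for (int k = 0; k < 3; ++k) {
      i0[k] = (int)std::floor((tlo[k] - g.lo[k]) / g.cell);
      i1[k] = (int)std::floor((thi[k] - g.lo[k]) / g.cell);
      if (i1[k] < 0 || i0[k] > g.n[k] - 1) out = true;
      i0[k] = std::max(i0[k], 0);
      i1[k] = std::min(i1[k], g.n[k] - 1);
    }
    if (out) continue;
    for (int kk = i0[2]; kk <= i1[2]; ++kk)
      for (int jj = i0[1]; jj <= i1[1]; ++jj)
        for (int ii = i0[0]; ii <= i1[0]; ++ii)
          for (int fb : g.bins[g.idx(ii, jj, kk)]) {
            if (stamp[fb] == fa) continue;
            stamp[fb] = fa;
            double B0[3], B1[3], B2[3];
            for (int k = 0; k < 3; ++k) {
              B0[k] = VB(FB(fb, 0), k); B1[k] = VB(FB(fb, 1), k); B2[k] = VB(FB(fb, 2), k);
            }
            double d = tri_tri_dist(A0, A1, A2, B0, B1, B2);
            if (d < best) best = d;
          }
  }
  return List::create(_["distance"] = best,
                      _["point_a"] = NumericVector::create(pA[0], pA[1], pA[2]),
                      _["point_b"] = NumericVector::create(pB[0], pB[1], pB[2]));
}

// Area-weighted outward vertex normals.
// [[Rcpp::export]]
NumericMatrix cpp_vertex_normals(NumericMatrix V, IntegerMatrix F) {
  NumericMatrix N(V.nrow(), 3);
  for (int f = 0; f < F.nrow(); ++f) {
    double a[3], b[3], c[3], e1[3], e2[3], n[3];
    for (int k = 0; k < 3; ++k) {
      a[k] = V(F(f, 0), k); b[k] = V(F(f, 1), k); c[k] = V(F(f, 2), k);
      e1[k] = b[k] - a[k]; e2[k] = c[k] - a[k];
    }
    cross3(e1, e2, n); // |n| = 2 * area, so summation is area weighted
    for (int v = 0; v < 3; ++v)
      for (int k = 0; k < 3; ++k) N(F(f, v), k) += n[k];
  }
  for (int i = 0; i < N.nrow(); ++i) {
    double nn = std::sqrt(N(i, 0) * N(i, 0) + N(i, 1) * N(i, 1) + N(i, 2) * N(i, 2));
    if (nn > 0)
      for (int k = 0; k < 3; ++k) N(i, k) /= nn;
  }
  return N;
}

// Signed enclosed volume (divergence theorem); positive for outward orientation.
// [[Rcpp::export]]
double cpp_mesh_volume(NumericMatrix V, IntegerMatrix F) {
  double vol = 0;
  for (int f = 0; f < F.nrow(); ++f) {
    double a[3], b[3], c[3], cr[3];
    for (int k = 0; k < 3; ++k) {
      a[k] = V(F(f, 0), k); b[k] = V(F(f, 1), k); c[k] = V(F(f, 2), k);
    }
    cross3(b, c, cr);
    vol += dot3(a, cr);
  }
  return vol / 6.0;
}
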