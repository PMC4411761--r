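// Regular (weighted Delaunay) triangulation by incremental conflict-region
// insertion on the lifted points (x, y, z, |x|^2 - w).  A symbolic vertex at
// infinity (index -1) closes the triangulation into a manifold so that hull
// facets need no special casing during cavity carving.  Degeneracies are
// expected to be resolved by a deterministic joggle applied by the caller;
// any exact tie encountered here aborts with status "precision" so the
// caller can re-joggle with a different seed.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <cstdint>
using namespace Rcpp;

static inline double det3v(const double *a, const double *b, const double *c) {
  return a[0] * (b[1] * c[2] - b[2] * c[1])
       - a[1] * (b[0] * c[2] - b[2] * c[0])
       + a[2] * (b[0] * c[1] - b[1] * c[0]);
}

struct Builder {
  int n;
  std::vector<double> X, Y, Z, L;   // joggled coordinates and lifted value
  struct Tet {
    int v[4];    // vertex indices, -1 = infinity (always at slot 3)
    int nb[4];   // nb[i] is the tet across the facet opposite v[i]
    bool alive;
  };
  std::vector<Tet> tets;
  bool failed;
  std::string why;

  double orient(int a, int b, int c, int d) const {
    double u[3] = { X[b] - X[a], Y[b] - Y[a], Z[b] - Z[a] };
    double v[3] = { X[c] - X[a], Y[c] - Y[a], Z[c] - Z[a] };
    double w[3] = { X[d] - X[a], Y[d] - Y[a], Z[d] - Z[a] };
    return det3v(u, v, w);
  }

  // Signed test of the lifted point e against the hyperplane through the
  // lifted a,b,c,d.  For a positively oriented tet the value is negative
  // exactly when e has negative power to the tet's orthosphere.
  double power4(int a, int b, int c, int d, int e) const {
    double m[4][4];
    int idx[4] = { b, c, d, e };
    for (int i = 0; i < 4; i++) {
      int p = idx[i];
      m[i][0] = X[p] - X[a];
      m[i][1] = Y[p] - Y[a];
      m[i][2] = Z[p] - Z[a];
      m[i][3] = L[p] - L[a];
    }
    double d0 = det3v(m[1], m[2], m[3]);
    double d1 = det3v(m[0], m[2], m[3]);
    double d2 = det3v(m[0], m[1], m[3]);
    double d3 = det3v(m[0], m[1], m[2]);
    return -m[0][3] * d0 + m[1][3] * d1 - m[2][3] * d2 + m[3][3] * d3;
  }

  bool conflicts(int t, int p) const {
    const Tet &T = tets[t];
    if (T.v[3] == -1)  // infinite tet: facet (v0,v1,v2) is oriented outward
      return orient(T.v[0], T.v[1], T.v[2], p) > 0;
    return power4(T.v[0], T.v[1], T.v[2], T.v[3], p) < 0;
  }

  static int64_t facetKey(int a, int b, int c, int n) {
    // sorted triple, infinity (-1) mapped to 0
    int x = a + 1, y = b + 1, z = c + 1, t;
    if (x > y) { t = x; x = y; y = t; }
    if (y > z) { t = y; y = z; z = t; }
    if (x > y) { t = x; x = y; y = t; }
    int64_t K = n + 2;
    return (static_cast<int64_t>(x) * K + y) * K + z;
  }

  // wire all unset (-9) neighbour slots among the given tets by facet matching
  bool wireByFacet(const std::vector<int> &ids) {
    std::map<int64_t, std::pair<int, int> > seen;
    for (size_t s = 0; s < ids.size(); s++) {
      int id = ids[s];
      Tet &t = tets[id];
      for (int i = 0; i < 4; i++) {
        if (t.nb[i] != -9) continue;
        int f[3]; int k = 0;
        for (int j = 0; j < 4; j++) if (j != i) f[k++] = t.v[j];
        int64_t key = facetKey(f[0], f[1], f[2], n);
        std::map<int64_t, std::pair<int, int> >::iterator it = seen.find(key);
        if (it == seen.end()) {
          seen[key] = std::make_pair(id, i);
        } else {
          int oid = it->second.first, oslot = it->second.second;
          if (tets[oid].nb[oslot] != -9) { why = "facet seen three times"; return false; }
          t.nb[i] = oid;
          tets[oid].nb[oslot] = id;
          seen.erase(it);
        }
      }
    }
    if (!seen.empty()) { why = "unmatched facet"; return false; }
    return true;
  }

  bool init(int a, int b, int c, int d) {
    if (orient(a, b, c, d) < 0) std::swap(a, b);
    if (orient(a, b, c, d) <= 0) { why = "degenerate initial tet"; return false; }
    Tet t0; t0.alive = true;
    t0.v[0] = a; t0.v[1] = b; t0.v[2] = c; t0.v[3] = d;
    for (int i = 0; i < 4; i++) t0.nb[i] = -9;
    tets.push_back(t0);
    std::vector<int> ids; ids.push_back(0);
    // one infinite tet per facet, finite facet stored outward-oriented
    for (int i = 0; i < 4; i++) {
      int f[3]; int k = 0;
      for (int j = 0; j < 4; j++) if (j != i) f[k++] = t0.v[j];
      int inner = t0.v[i];
      Tet ti; ti.alive = true;
      ti.v[0] = f[0]; ti.v[1] = f[1]; ti.v[2] = f[2]; ti.v[3] = -1;
      if (orient(ti.v[0], ti.v[1], ti.v[2], inner) > 0) std::swap(ti.v[0], ti.v[1]);
      for (int j = 0; j < 4; j++) ti.nb[j] = -9;
      ids.push_back(static_cast<int>(tets.size()));
      tets.push_back(ti);
    }
    return wireByFacet(ids);
  }

  // returns true if point was inserted, false if hidden; sets failed on error
  bool insert(int p) {
    int T = static_cast<int>(tets.size());
    std::vector<int> confl;
    std::vector<char> inconf(T, 0);
    for (int t = 0; t < T; t++) {
      if (tets[t].alive && conflicts(t, p)) { confl.push_back(t); inconf[t] = 1; }
    }
    if (confl.empty()) return false;  // redundant (hidden) point

    struct BF { int f[3]; int inside; int outside; };
    std::vector<BF> bfs;
    for (size_t s = 0; s < confl.size(); s++) {
      int t = confl[s];
      for (int i = 0; i < 4; i++) {
        int nb = tets[t].nb[i];
        if (!inconf[nb]) {
          BF b; int k = 0;
          for (int j = 0; j < 4; j++) if (j != i) b.f[k++] = tets[t].v[j];
          b.inside = t; b.outside = nb;
          bfs.push_back(b);
        }
      }
    }
    if (bfs.empty()) { failed = true; why = "empty cavity boundary"; return true; }
    for (size_t s = 0; s < confl.size(); s++) tets[confl[s]].alive = false;

    std::vector<int> newids;
    for (size_t s = 0; s < bfs.size(); s++) {
      const BF &b = bfs[s];
      Tet nt; nt.alive = true;
      for (int j = 0; j < 4; j++) nt.nb[j] = -9;
      bool hasInf = (b.f[0] == -1 || b.f[1] == -1 || b.f[2] == -1);
      int xslot;
      if (hasInf) {
        int fin[2]; int k = 0;
        for (int j = 0; j < 3; j++) if (b.f[j] != -1) fin[k++] = b.f[j];
        nt.v[0] = fin[0]; nt.v[1] = fin[1]; nt.v[2] = p; nt.v[3] = -1;
        xslot = 2;
      } else {
        nt.v[0] = b.f[0]; nt.v[1] = b.f[1]; nt.v[2] = b.f[2]; nt.v[3] = p;
        xslot = 3;
      }
      nt.nb[xslot] = b.outside;
      int id = static_cast<int>(tets.size());
      tets.push_back(nt);
      newids.push_back(id);
      // repair the surviving neighbour's back pointer
      bool fixed = false;
      for (int j = 0; j < 4; j++) {
        if (tets[b.outside].nb[j] == b.inside) { tets[b.outside].nb[j] = id; fixed = true; break; }
      }
      if (!fixed) { failed = true; why = "lost neighbour back pointer"; return true; }
    }
    if (!wireByFacet(newids)) { failed = true; return true; }

    // orientation normalisation: finite tets positively oriented first
    for (size_t s = 0; s < newids.size(); s++) {
      Tet &t = tets[newids[s]];
      if (t.v[3] == -1) continue;
      double o = orient(t.v[0], t.v[1], t.v[2], t.v[3]);
      if (o == 0) { failed = true; why = "flat new tet"; return true; }
      if (o < 0) { std::swap(t.v[0], t.v[1]); std::swap(t.nb[0], t.nb[1]); }
    }
    // then infinite tets: finite facet oriented outward, judged by the apex
    // of the finite neighbour across that facet
    for (size_t s = 0; s < newids.size(); s++) {
      Tet &t = tets[newids[s]];
      if (t.v[3] != -1) continue;
      int fin = t.nb[3];
      int z = -2;
      for (int j = 0; j < 4; j++) {
        int vv = tets[fin].v[j];
        if (vv != t.v[0] && vv != t.v[1] && vv != t.v[2]) z = vv;
      }
      if (z < 0) { failed = true; why = "infinite tet lacks finite witness"; return true; }
      double o = orient(t.v[0], t.v[1], t.v[2], z);
      if (o == 0) { failed = true; why = "flat hull facet"; return true; }
      if (o > 0) { std::swap(t.v[0], t.v[1]); std::swap(t.nb[0], t.nb[1]); }
    }
    return true;
  }
};

// [[Rcpp::export]]
List rt_build_cpp(NumericMatrix coords, NumericVector weights) {
  int n = coords.nrow();
  Builder B;
  B.n = n;
  B.failed = false;
  B.X.resize(n); B.Y.resize(n); B.Z.resize(n); B.L.resize(n);
  double ext = 0.0;
  for (int i = 0; i < n; i++) {
    B.X[i] = coords(i, 0); B.Y[i] = coords(i, 1); B.Z[i] = coords(i, 2);
    B.L[i] = B.X[i] * B.X[i] + B.Y[i] * B.Y[i] + B.Z[i] * B.Z[i] - weights[i];
    for (int k = 0; k < 3; k++) ext = std::max(ext, std::fabs(coords(i, k)));
  }
  double eps = std::max(ext, 1.0) * 1e-10;

  // greedy affinely independent seed
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  for (int j = 1; j < n && i1 < 0; j++) {
    double dx = B.X[j] - B.X[i0], dy = B.Y[j] - B.Y[i0], dz = B.Z[j] - B.Z[i0];
    if (dx * dx + dy * dy + dz * dz > eps * eps) i1 = j;
  }
  if (i1 >= 0) {
    for (int j = 1; j < n && i2 < 0; j++) {
      if (j == i1) continue;
      double a[3] = { B.X[i1] - B.X[i0], B.Y[i1] - B.Y[i0], B.Z[i1] - B.Z[i0] };
      double b[3] = { B.X[j] - B.X[i0], B.Y[j] - B.Y[i0], B.Z[j] - B.Z[i0] };
      double cx = a[1] * b[2] - a[2] * b[1];
      double cy = a[2] * b[0] - a[0] * b[2];
      double cz = a[0] * b[1] - a[1] * b[0];
      if (cx * cx + cy * cy + cz * cz > eps * eps * eps * eps) i2 = j;
    }
  }
  if (i2 >= 0) {
    for (int j = 1; j < n && i3 < 0; j++) {
      if (j == i1 || j == i2) continue;
      if (std::fabs(B.orient(i0, i1, i2, j)) > eps * eps * eps) i3 = j;
    }
  }
  if (i3 < 0)
    return List::create(_["status"] = "degenerate",
                        _["why"] = "no four affinely independent centers");
  if (!B.init(i0, i1, i2, i3))
    return List::create(_["status"] = "precision", _["why"] = B.why);

  std::vector<int> hidden;
  for (int p = 0; p < n; p++) {
    if (p == i0 || p == i1 || p == i2 || p == i3) continue;
    bool ins = B.insert(p);
    if (B.failed)
      return List::create(_["status"] = "precision", _["why"] = B.why);
    if (!ins) hidden.push_back(p);
  }

  // collect finite tets and hull facets
  std::vector<int> finiteIdx(B.tets.size(), -1);
  std::vector<int> finiteList;
  for (size_t t = 0; t < B.tets.size(); t++) {
    if (B.tets[t].alive && B.tets[t].v[3] != -1) {
      finiteIdx[t] = static_cast<int>(finiteList.size());
      finiteList.push_back(static_cast<int>(t));
    }
  }
  int m = static_cast<int>(finiteList.size());
  IntegerMatrix tetm(m, 4);
  for (int i = 0; i < m; i++) {
    const Builder::Tet &t = B.tets[finiteList[i]];
    for (int j = 0; j < 4; j++) tetm(i, j) = t.v[j] + 1;  // 1-based
  }
  std::vector<int> hv0, hv1, hv2, htet;
  for (size_t t = 0; t < B.tets.size(); t++) {
    const Builder::Tet &T = B.tets[t];
    if (!T.alive || T.v[3] != -1) continue;
    int fin = T.nb[3];
    if (fin < 0 || finiteIdx[fin] < 0)
      return List::create(_["status"] = "precision",
                          _["why"] = "hull facet without finite tet");
    hv0.push_back(T.v[0] + 1);
    hv1.push_back(T.v[1] + 1);
    hv2.push_back(T.v[2] + 1);
    htet.push_back(finiteIdx[fin] + 1);
  }
  int h = static_cast<int>(hv0.size());
  IntegerMatrix hullm(h, 4);
  for (int i = 0; i < h; i++) {
    hullm(i, 0) = hv0[i]; hullm(i, 1) = hv1[i]; hullm(i, 2) = hv2[i];
    hullm(i, 3) = htet[i];
  }
  IntegerVector hid(hidden.size());
  for (size_t i = 0; i < hidden.size(); i++) hid[i] = hidden[i] + 1;
  return List::create(_["status"] = "ok", _["tets"] = tetm,
                      _["hull"] = hullm, _["hidden"] = hid);
}

// Orthocenter and squared orthoradius ("size") of k-simplices, k = 2..4.
// For k < 4 the center is constrained to the affine hull of the vertices.
// [[Rcpp::export]]
List orthospheres_cpp(NumericMatrix coords, NumericVector weights,
                      IntegerMatrix simp) {
  int m = simp.nrow(), k = simp.ncol();
  NumericMatrix centers(m, 3);
  NumericVector sizes(m);
  LogicalVector ok(m);
  for (int r = 0; r < m; r++) {
    int v[4];
    double p[4][3], l[4];
    for (int j = 0; j < k; j++) {
      v[j] = simp(r, j) - 1;
      p[j][0] = coords(v[j], 0); p[j][1] = coords(v[j], 1); p[j][2] = coords(v[j], 2);
      l[j] = p[j][0] * p[j][0] + p[j][1] * p[j][1] + p[j][2] * p[j][2] - weights[v[j]];
    }
    double c[3] = { p[0][0], p[0][1], p[0][2] };
    bool good = true;
    if (k == 4) {
      double A[3][3], b[3];
      for (int i = 0; i < 3; i++) {
        for (int j = 0; j < 3; j++) A[i][j] = 2.0 * (p[i + 1][j] - p[0][j]);
        b[i] = l[i + 1] - l[0];
      }
      double det = A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1])
                 - A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0])
                 + A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
      if (det == 0 || !R_finite(det)) good = false;
      else {
        c[0] = (b[0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1])
              - A[0][1] * (b[1] * A[2][2] - A[1][2] * b[2])
              + A[0][2] * (b[1] * A[2][1] - A[1][1] * b[2])) / det;
        c[1] = (A[0][0] * (b[1] * A[2][2] - A[1][2] * b[2])
              - b[0] * (A[1][0] * A[2][2] - A[1][2] * A[2][0])
              + A[0][2] * (A[1][0] * b[2] - b[1] * A[2][0])) / det;
        c[2] = (A[0][0] * (A[1][1] * b[2] - b[1] * A[2][1])
              - A[0][1] * (A[1][0] * b[2] - b[1] * A[2][0])
              + b[0] * (A[1][0] * A[2][1] - A[1][1] * A[2][0])) / det;
      }
    } else if (k == 3) {
      double e1[3], e2[3];
      for (int j = 0; j < 3; j++) { e1[j] = p[1][j] - p[0][j]; e2[j] = p[2][j] - p[0][j]; }
      double g11 = 0, g12 = 0, g22 = 0, b1 = 0, b2 = 0;
      for (int j = 0; j < 3; j++) {
        g11 += e1[j] * e1[j]; g12 += e1[j] * e2[j]; g22 += e2[j] * e2[j];
      }
      // equations 2 (p_i - p_0) . c = l_i - l_0 with c = p0 + a e1 + b e2
      for (int j = 0; j < 3; j++) { b1 += e1[j] * p[0][j]; b2 += e2[j] * p[0][j]; }
      double r1 = 0.5 * (l[1] - l[0]) - b1;
      double r2 = 0.5 * (l[2] - l[0]) - b2;
      double det = g11 * g22 - g12 * g12;
      if (det == 0 || !R_finite(det)) good = false;
      else {
        double a = (r1 * g22 - g12 * r2) / det;
        double b = (g11 * r2 - r1 * g12) / det;
        for (int j = 0; j < 3; j++) c[j] = p[0][j] + a * e1[j] + b * e2[j];
      }
    } else if (k == 2) {
      double e1[3], g11 = 0, b1 = 0;
      for (int j = 0; j < 3; j++) { e1[j] = p[1][j] - p[0][j]; g11 += e1[j] * e1[j]; }
      for (int j = 0; j < 3; j++) b1 += e1[j] * p[0][j];
      if (g11 == 0) good = false;
      else {
        double a = (0.5 * (l[1] - l[0]) - b1) / g11;
        for (int j = 0; j < 3; j++) c[j] = p[0][j] + a * e1[j];
      }
    } else good = false;
    if (good) {
      double d2 = 0;
      for (int j = 0; j < 3; j++) {
        centers(r, j) = c[j];
        double dd = c[j] - p[0][j];
        d2 += dd * dd;
      }
      sizes[r] = d2 - weights[v[0]];
      ok[r] = true;
    } else {
      centers(r, 0) = NA_REAL; centers(r, 1) = NA_REAL; centers(r, 2) = NA_REAL;
      sizes[r] = NA_REAL; ok[r] = false;
    }
  }
  return List::create(_["center"] = centers, _["size"] = sizes, _["ok"] = ok);
}

// Minimum power distance over all weighted atoms at each query point.
// [[Rcpp::export]]
NumericVector min_power_cpp(NumericMatrix coords, NumericVector weights,
                            NumericMatrix pts) {
  int n = coords.nrow(), m = pts.nrow();
  NumericVector out(m);
  for (int i = 0; i < m; i++) {
    double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < n; j++) {
      double dx = coords(j, 0) - px;
      double dy = coords(j, 1) - py;
      double dz = coords(j, 2) - pz;
      double v = dx * dx + dy * dy + dz * dz - weights[j];
      if (v < best) best = v;
    }
    out[i] = best;
  }
  return out;
}
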