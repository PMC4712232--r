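#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Small fixed-size vector helpers (kept free of Rcpp sugar for speed).
static inline void vsub(const double* a, const double* b, double* out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}
static inline void vcross(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double vdot(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double vnorm(const double* a) { return std::sqrt(vdot(a, a)); }

// Moller-Trumbore ray/triangle intersection. Returns true on hit with
// t > tmin, 0 <= u, 0 <= v, u + v <= 1. det threshold guards parallel rays.
static inline bool mt_kernel(const double* o, const double* d,
                             const double* a, const double* b, const double* c,
                             double tmin, double det_eps,
                             double& t, double& u, double& v) {
  double e1[3], e2[3], pv[3], tv[3], qv[3];
  vsub(b, a, e1); vsub(c, a, e2);
  vcross(d, e2, pv);
  double det = vdot(e1, pv);
  if (std::fabs(det) < det_eps) return false;
  double inv = 1.0 / det;
  vsub(o, a, tv);
  u = vdot(tv, pv) * inv;
  if (u < 0.0 || u > 1.0) return false;
  vcross(tv, e1, qv);
  v = vdot(d, qv) * inv;
  if (v < 0.0 || u + v > 1.0) return false;
  t = vdot(e2, qv) * inv;
  return t > tmin;
}

// [[Rcpp::export]]
List mt_batch_cpp(NumericMatrix orig, NumericMatrix dir,
                  NumericMatrix a, NumericMatrix b, NumericMatrix c,
                  double tmin, double det_eps) {
  int n = orig.nrow();
  LogicalVector hit(n);
  NumericVector t(n, NA_REAL), u(n, NA_REAL), v(n, NA_REAL);
  double o_[3], d_[3], a_[3], b_[3], c_[3];
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 3; ++k) {
      o_[k] = orig(i, k); d_[k] = dir(i, k);
      a_[k] = a(i, k); b_[k] = b(i, k); c_[k] = c(i, k);
    }
    double ti, ui, vi;
    bool h = mt_kernel(o_, d_, a_, b_, c_, tmin, det_eps, ti, ui, vi);
    hit[i] = h;
    if (h) { t[i] = ti; u[i] = ui; v[i] = vi; }
  }
  return List::create(_["hit"] = hit, _["t"] = t, _["u"] = u, _["v"] = v);
}

// Does segment p->q (shrunk by delta at both ends) intersect any triangle?
static inline bool seg_blocked(const double* p, const double* q,
                               const NumericMatrix& V, const IntegerMatrix& F,
                               double delta, double det_eps) {
  double d[3], o[3];
  vsub(q, p, d);
  o[0] = p[0] + delta * d[0]; o[1] = p[1] + delta * d[1]; o[2] = p[2] + delta * d[2];
  double span = 1.0 - 2.0 * delta;
  int nf = F.nrow();
  double a_[3], b_[3], c_[3];
  for (int f = 0; f < nf; ++f) {
    int ia = F(f, 0), ib = F(f, 1), ic = F(f, 2);
    for (int k = 0; k < 3; ++k) {
      a_[k] = V(ia, k); b_[k] = V(ib, k); c_[k] = V(ic, k);
    }
    double t, u, v;
    if (mt_kernel(o, d, a_, b_, c_, 0.0, det_eps, t, u, v) && t < span) return true;
  }
  return false;
}

// [[Rcpp::export]]
LogicalVector seg_blocked_cpp(NumericMatrix P, NumericMatrix Q,
                              NumericMatrix V, IntegerMatrix F,
                              double delta, double det_eps) {
  int n = P.nrow();
  LogicalVector out(n);
  double p[3], q[3];
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 3; ++k) { p[k] = P(i, k); q[k] = Q(i, k); }
    out[i] = seg_blocked(p, q, V, F, delta, det_eps);
  }
  return out;
}

// Ray parity for point-in-surface. Returns (crossing count, clean flag);
// clean = 0 when a hit lands near a triangle edge or the determinant is
// marginal, in which case the caller retries with another direction.
// [[Rcpp::export]]
IntegerVector ray_parity_cpp(NumericVector p, NumericVector d,
                             NumericMatrix V, IntegerMatrix F,
                             double det_eps, double edge_eps) {
  int nf = F.nrow();
  int count = 0, clean = 1;
  double o[3] = { p[0], p[1], p[2] };
  double dir[3] = { d[0], d[1], d[2] };
  double a_[3], b_[3], c_[3];
  for (int f = 0; f < nf; ++f) {
    int ia = F(f, 0), ib = F(f, 1), ic = F(f, 2);
    for (int k = 0; k < 3; ++k) {
      a_[k] = V(ia, k); b_[k] = V(ib, k); c_[k] = V(ic, k);
    }
    double t, u, v;
    if (mt_kernel(o, dir, a_, b_, c_, 0.0, det_eps, t, u, v)) {
      ++count;
      if (u < edge_eps || v < edge_eps || u + v > 1.0 - edge_eps) clean = 0;
    }
  }
  return IntegerVector::create(count, clean);
}

// Candidate conduction edges: vertex pairs within radius whose connecting
// segment does not cross the blocking surface (line-of-sight rule).
// Returns a 3-column matrix (i, j, dist) with 1-based indices, i < j.
// [[Rcpp::export]]
NumericMatrix graph_edges_cpp(NumericMatrix V, NumericMatrix BV, IntegerMatrix BF,
                              double radius, double delta, double det_eps) {
  int n = V.nrow();
  double r2 = radius * radius;
  std::vector<double> out;
  double p[3], q[3];
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = V(i, 0) - V(j, 0), dy = V(i, 1) - V(j, 1), dz = V(i, 2) - V(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > r2) continue;
      for (int k = 0; k < 3; ++k) { p[k] = V(i, k); q[k] = V(j, k); }
      // canonical (lexicographic) orientation so the visibility verdict is
      // independent of vertex numbering
      bool swap = (q[0] < p[0]) || (q[0] == p[0] && q[1] < p[1]) ||
                  (q[0] == p[0] && q[1] == p[1] && q[2] < p[2]);
      if (swap) {
        for (int k = 0; k < 3; ++k) { double tmp = p[k]; p[k] = q[k]; q[k] = tmp; }
      }
      if (seg_blocked(p, q, BV, BF, delta, det_eps)) continue;
      out.push_back(i + 1.0); out.push_back(j + 1.0); out.push_back(std::sqrt(d2));
    }
  }
  int m = out.size() / 3;
  NumericMatrix res(m, 3);
  for (int e = 0; e < m; ++e) {
    res(e, 0) = out[3 * e]; res(e, 1) = out[3 * e + 1]; res(e, 2) = out[3 * e + 2];
  }
  return res;
}

// Floyd-Warshall all-pairs shortest paths, in place on a dense delay matrix.
// Loop order (k, j, i) keeps the inner loop contiguous in column-major order.
// [[Rcpp::export]]
NumericMatrix floyd_warshall_cpp(NumericMatrix D0) {
  NumericMatrix D = clone(D0);
  int n = D.nrow();
  double* d = REAL(D);
  for (int k = 0; k < n; ++k) {
    const double* dk_col = d + (size_t)k * n;   // D[., k]
    for (int j = 0; j < n; ++j) {
      double dkj = d[k + (size_t)j * n];
      if (!R_FINITE(dkj)) continue;
      double* dj_col = d + (size_t)j * n;
      for (int i = 0; i < n; ++i) {
        double via = dk_col[i] + dkj;
        if (via < dj_col[i]) dj_col[i] = via;
      }
    }
  }
  return D;
}

// van Oosterom-Strackee signed solid angle of triangle (a,b,c) seen from x.
// Positive when the right-handed normal of (a,b,c) points away from x, so a
// closed outward-oriented surface sums to +4*pi from inside.
static inline double solid_angle(const double* x, const double* a,
                                 const double* b, const double* c) {
  double r1[3], r2[3], r3[3], cr[3];
  vsub(a, x, r1); vsub(b, x, r2); vsub(c, x, r3);
  double l1 = vnorm(r1), l2 = vnorm(r2), l3 = vnorm(r3);
  vcross(r2, r3, cr);
  double num = vdot(r1, cr);
  double den = l1 * l2 * l3 + vdot(r1, r2) * l3 + vdot(r1, r3) * l2 + vdot(r2, r3) * l1;
  if (num == 0.0 && den == 0.0) return 0.0;
  return 2.0 * std::atan2(num, den);
}

// [[Rcpp::export]]
NumericVector solid_angle_cpp(NumericMatrix X, NumericVector a,
                              NumericVector b, NumericVector c) {
  int n = X.nrow();
  NumericVector out(n);
  double x[3], a_[3] = { a[0], a[1], a[2] }, b_[3] = { b[0], b[1], b[2] },
         c_[3] = { c[0], c[1], c[2] };
  for (int i = 0; i < n; ++i) {
    x[0] = X(i, 0); x[1] = X(i, 1); x[2] = X(i, 2);
    out[i] = solid_angle(x, a_, b_, c_);
  }
  return out;
}

// Analytic integral of 1/|x - y| over a flat triangle (uniform density),
// by edge decomposition (Wilton et al. style) plus the solid-angle term.
static inline double tri_single_layer(const double* x, const double* a,
                                      const double* b, const double* c) {
  double e1[3], e2[3], n[3];
  vsub(b, a, e1); vsub(c, a, e2);
  vcross(e1, e2, n);
  double nn = vnorm(n);
  if (nn <= 0.0) return 0.0;
  n[0] /= nn; n[1] /= nn; n[2] /= nn;
  double xa[3]; vsub(x, a, xa);
  double d = vdot(xa, n);
  double rho[3] = { x[0] - d * n[0], x[1] - d * n[1], x[2] - d * n[2] };
  const double* P[4] = { a, b, c, a };
  double I = 0.0;
  double diam = std::max(vnorm(e1), vnorm(e2));
  double eps = 1e-12 * (diam + std::fabs(d));
  for (int e = 0; e < 3; ++e) {
    const double* p = P[e];
    const double* q = P[e + 1];
    double s[3]; vsub(q, p, s);
    double L = vnorm(s);
    if (L <= 0.0) continue;
    double sh[3] = { s[0] / L, s[1] / L, s[2] / L };
    double mh[3]; vcross(sh, n, mh);
    double pr[3]; vsub(p, rho, pr);
    double qr[3]; vsub(q, rho, qr);
    double t0 = vdot(pr, mh);
    if (std::fabs(t0) < eps) continue;          // contribution -> 0 as t0 -> 0
    double sm = vdot(pr, sh), sp = vdot(qr, sh);
    double px[3]; vsub(p, x, px);
    double qx[3]; vsub(q, x, qx);
    double Rm = vnorm(px), Rp = vnorm(qx);
    double den = Rm + sm;
    double num = Rp + sp;
    if (den <= eps || num <= eps) {
      // swap to the numerically stable branch: (R - s) form
      den = Rp - sp; num = Rm - sm;
      if (den <= eps || num <= eps) continue;
      I += t0 * std::log(num / den);
    } else {
      I += t0 * std::log(num / den);
    }
  }
  double om = solid_angle(x, a, b, c);
  I -= std::fabs(d) * std::fabs(om);
  return I;
}

// [[Rcpp::export]]
NumericVector tri_single_layer_cpp(NumericMatrix X, NumericVector a,
                                   NumericVector b, NumericVector c) {
  int n = X.nrow();
  NumericVector out(n);
  double x[3], a_[3] = { a[0], a[1], a[2] }, b_[3] = { b[0], b[1], b[2] },
         c_[3] = { c[0], c[1], c[2] };
  for (int i = 0; i < n; ++i) {
    x[0] = X(i, 0); x[1] = X(i, 1); x[2] = X(i, 2);
    out[i] = tri_single_layer(x, a_, b_, c_);
  }
  return out;
}

// Double-layer (D) and single-layer (S) collocation blocks of one surface,
// evaluated at arbitrary collocation points. Per-triangle kernels are
// distributed equally to the triangle's three vertices (lumped linear basis):
//   D[i, v] = -sum_t Omega_t(x_i) / (4 pi * 3),
//   S[i, v] = +sum_t I_t(x_i)     / (4 pi * 3),  v in t.
// so that D * 1 = -1 for points inside the closed surface.
// [[Rcpp::export]]
List bem_blocks_cpp(NumericMatrix X, NumericMatrix V, IntegerMatrix F) {
  int m = X.nrow(), nv = V.nrow(), nf = F.nrow();
  NumericMatrix D(m, nv), S(m, nv);
  const double fourpi = 4.0 * M_PI;
  double x[3], a_[3], b_[3], c_[3];
  for (int i = 0; i < m; ++i) {
    x[0] = X(i, 0); x[1] = X(i, 1); x[2] = X(i, 2);
    double* drow = &D(i, 0);   // note: column-major, index by (i, col) below
    (void)drow;
    for (int f = 0; f < nf; ++f) {
      int ia = F(f, 0), ib = F(f, 1), ic = F(f, 2);
      for (int k = 0; k < 3; ++k) {
        a_[k] = V(ia, k); b_[k] = V(ib, k); c_[k] = V(ic, k);
      }
      double om = solid_angle(x, a_, b_, c_);
      double dv = -om / (fourpi * 3.0);
      D(i, ia) += dv; D(i, ib) += dv; D(i, ic) += dv;
      // single layer with a linear (hat) density: midpoint subdivision into
      // four sub-triangles, each with the analytic uniform integral times the
      // barycentric weights of its centroid. Keeps constants exact while
      // resolving oscillating vertex densities (no discrete null space).
      double mab[3], mbc[3], mca[3];
      for (int k = 0; k < 3; ++k) {
        mab[k] = 0.5 * (a_[k] + b_[k]);
        mbc[k] = 0.5 * (b_[k] + c_[k]);
        mca[k] = 0.5 * (c_[k] + a_[k]);
      }
      const double w23 = 2.0 / 3.0, w16 = 1.0 / 6.0, w13 = 1.0 / 3.0;
      double s1 = tri_single_layer(x, a_, mab, mca) / fourpi;
      double s2 = tri_single_layer(x, mab, b_, mbc) / fourpi;
      double s3 = tri_single_layer(x, mca, mbc, c_) / fourpi;
      double s4 = tri_single_layer(x, mab, mbc, mca) / fourpi;
      S(i, ia) += s1 * w23 + s2 * w16 + s3 * w16 + s4 * w13;
      S(i, ib) += s1 * w16 + s2 * w23 + s3 * w16 + s4 * w13;
      S(i, ic) += s1 * w16 + s2 * w16 + s3 * w23 + s4 * w13;
    }
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["D"] = D, _["S"] = S);
}

// Closest point on a triangle to point p (Ericson, Real-Time Collision
// Detection), returning the point and barycentric coordinates (w_a, w_b, w_c).
static inline double closest_on_tri(const double* p, const double* a,
                                    const double* b, const double* c,
                                    double* out, double* w) {
  double ab[3], ac[3], ap[3];
  vsub(b, a, ab); vsub(c, a, ac); vsub(p, a, ap);
  double d1 = vdot(ab, ap), d2 = vdot(ac, ap);
  double u, v;
  if (d1 <= 0.0 && d2 <= 0.0) { u = 0.0; v = 0.0; }
  else {
    double bp[3]; vsub(p, b, bp);
    double d3 = vdot(ab, bp), d4 = vdot(ac, bp);
    if (d3 >= 0.0 && d4 <= d3) { u = 1.0; v = 0.0; }
    else {
      double vc = d1 * d4 - d3 * d2;
      if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) { u = d1 / (d1 - d3); v = 0.0; }
      else {
        double cp[3]; vsub(p, c, cp);
        double d5 = vdot(ab, cp), d6 = vdot(ac, cp);
        if (d6 >= 0.0 && d5 <= d6) { u = 0.0; v = 1.0; }
        else {
          double vb = d5 * d2 - d1 * d6;
          if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) { u = 0.0; v = d2 / (d2 - d6); }
          else {
            double va = d3 * d6 - d5 * d4;
            if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
              double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              u = 1.0 - t; v = t;
            } else {
              double denom = 1.0 / (va + vb + vc);
              u = vb * denom; v = vc * denom;
            }
          }
        }
      }
    }
  }
  for (int k = 0; k < 3; ++k) out[k] = a[k] + u * ab[k] + v * ac[k];
  w[0] = 1.0 - u - v; w[1] = u; w[2] = v;
  double dp[3]; vsub(p, out, dp);
  return vnorm(dp);
}

// [[Rcpp::export]]
List closest_point_cpp(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  int n = P.nrow(), nf = F.nrow();
  NumericMatrix pts(n, 3), bary(n, 3);
  IntegerVector tri(n);
  NumericVector dist(n);
  double p[3], a_[3], b_[3], c_[3], best[3], bw[3], cand[3], w[3];
  for (int i = 0; i < n; ++i) {
    p[0] = P(i, 0); p[1] = P(i, 1); p[2] = P(i, 2);
    double bd = R_PosInf; int bt = -1;
    for (int f = 0; f < nf; ++f) {
      int ia = F(f, 0), ib = F(f, 1), ic = F(f, 2);
      for (int k = 0; k < 3; ++k) {
        a_[k] = V(ia, k); b_[k] = V(ib, k); c_[k] = V(ic, k);
      }
      double d = closest_on_tri(p, a_, b_, c_, cand, w);
      if (d < bd) {
        bd = d; bt = f;
        for (int k = 0; k < 3; ++k) { best[k] = cand[k]; bw[k] = w[k]; }
      }
    }
    for (int k = 0; k < 3; ++k) { pts(i, k) = best[k]; bary(i, k) = bw[k]; }
    tri[i] = bt + 1;
    dist[i] = bd;
  }
  return List::create(_["point"] = pts, _["triangle"] = tri,
                      _["bary"] = bary, _["dist"] = dist);
}
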