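// Exported contact / fiber force kernels.  These are the same routines the
// time-stepping engine uses; the R wrappers add argument validation.

#include "dem_common.h"
using namespace Rcpp;
using namespace bw;

// [[Rcpp::export]]
double hm_normal_cpp(double Estar, double Rstar, double mstar, double beta,
                     double dn, double vn) {
  return hm_normal(Estar, Rstar, mstar, beta, dn, vn);
}

// [[Rcpp::export]]
List hm_tangential_cpp(double Gstar, double Rstar, double mstar, double beta,
                       double mu, double dn, NumericVector delta_t,
                       NumericVector vt, double fn) {
  V3 dt(delta_t[0], delta_t[1], delta_t[2]);
  V3 v(vt[0], vt[1], vt[2]);
  V3 f = hm_tangential(Gstar, Rstar, mstar, beta, mu, dn, dt, v, fn);
  return List::create(_["force"] = NumericVector::create(f.x, f.y, f.z),
                      _["delta_t"] = NumericVector::create(dt.x, dt.y, dt.z));
}

// [[Rcpp::export]]
List sphere_facet_cpp(NumericVector center, double radius, NumericVector origin,
                      NumericVector u, NumericVector v) {
  V3 uu(u[0], u[1], u[2]), vv(v[0], v[1], v[2]);
  Facet fc;
  fc.o = V3(origin[0], origin[1], origin[2]);
  fc.ul = norm(uu);
  fc.vl = norm(vv);
  fc.uh = (1.0 / fc.ul) * uu;
  fc.vh = (1.0 / fc.vl) * vv;
  fc.nh = cross(fc.uh, fc.vh);
  FacetContact c = sphere_facet(V3(center[0], center[1], center[2]), radius, fc);
  if (!c.active) return List::create(_["active"] = false);
  return List::create(
      _["active"] = true, _["interior"] = c.interior,
      _["point"] = NumericVector::create(c.point.x, c.point.y, c.point.z),
      _["normal"] = NumericVector::create(c.nhat.x, c.nhat.y, c.nhat.z),
      _["delta_n"] = c.dn, _["coords"] = NumericVector::create(c.a, c.b));
}

// [[Rcpp::export]]
List sphere_sphere_cpp(NumericVector ca, double ra, NumericVector cb, double rb) {
  V3 a(ca[0], ca[1], ca[2]), b(cb[0], cb[1], cb[2]);
  V3 d = a - b;
  double dist = norm(d);
  if (dist < 1e-14) stop("coincident sphere centres: contact normal undefined");
  if (dist > ra + rb) return List::create(_["active"] = false);
  V3 nh = (1.0 / dist) * d;  // points from b toward a
  V3 pt = b + (rb + 0.5 * (dist - rb - ra) + 0.5 * (ra + rb - dist) * 0.0) * nh;
  // contact point: midpoint of the overlap segment
  pt = a - (ra - 0.5 * (ra + rb - dist)) * nh;
  return List::create(
      _["active"] = true,
      _["point"] = NumericVector::create(pt.x, pt.y, pt.z),
      _["normal"] = NumericVector::create(nh.x, nh.y, nh.z),
      _["delta_n"] = ra + rb - dist);
}

// [[Rcpp::export]]
List wlc_energy_cpp(NumericMatrix P, double ks, double kb, double l0,
                    int root_joint = -1) {
  const int n = P.nrow();
  double hs = 0.0, hb = 0.0;
  for (int i = 1; i < n; ++i) {
    V3 d(P(i, 0) - P(i - 1, 0), P(i, 1) - P(i - 1, 1), P(i, 2) - P(i - 1, 2));
    double l = norm(d);
    if (l < 1e-12) stop("coincident adjacent particles in chain");
    hs += 0.5 * ks * (l - l0) * (l - l0);
  }
  for (int j = 1; j + 1 < n; ++j) {
    V3 a(P(j, 0) - P(j - 1, 0), P(j, 1) - P(j - 1, 1), P(j, 2) - P(j - 1, 2));
    V3 b(P(j + 1, 0) - P(j, 0), P(j + 1, 1) - P(j, 1), P(j + 1, 2) - P(j, 2));
    double la = norm(a), lb = norm(b);
    if (la < 1e-12 || lb < 1e-12) stop("coincident adjacent particles in chain");
    const double kbw = (j == root_joint) ? 2.0 * kb : kb;
    hb += kbw * (1.0 - dot(a, b) / (la * lb));
  }
  return List::create(_["stretch"] = hs, _["bend"] = hb, _["total"] = hs + hb);
}

// [[Rcpp::export]]
NumericMatrix wlc_forces_cpp(NumericMatrix P, double ks, double kb, double l0,
                             int root_joint = -1) {
  const int n = P.nrow();
  std::vector<double> pos(3 * n), frc(3 * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) pos[3 * i + k] = P(i, k);
  int bad = -1;
  if (!wlc_accumulate(pos.data(), n, ks, kb, l0, root_joint, frc.data(), &bad))
    stop("degenerate (zero-length) bond at particle %d", bad + 1);
  NumericMatrix F(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) F(i, k) = frc[3 * i + k];
  return F;
}
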