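#ifndef BRUSHWEAR_DEM_COMMON_H
#define BRUSHWEAR_DEM_COMMON_H

#include <Rcpp.h>
#include <cmath>
#include <vector>

namespace bw {

struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
};

inline V3 operator+(const V3& a, const V3& b) { return V3(a.x + b.x, a.y + b.y, a.z + b.z); }
inline V3 operator-(const V3& a, const V3& b) { return V3(a.x - b.x, a.y - b.y, a.z - b.z); }
inline V3 operator*(double s, const V3& a) { return V3(s * a.x, s * a.y, s * a.z); }
inline V3& operator+=(V3& a, const V3& b) { a.x += b.x; a.y += b.y; a.z += b.z; return a; }
inline V3& operator-=(V3& a, const V3& b) { a.x -= b.x; a.y -= b.y; a.z -= b.z; return a; }
inline double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline V3 cross(const V3& a, const V3& b) {
  return V3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
inline double norm(const V3& a) { return std::sqrt(dot(a, a)); }

// Hertz-Mindlin normal force magnitude along the contact normal (repulsion
// positive).  vn is the normal component of the relative velocity of the
// particle w.r.t. its partner, positive when separating.  beta is stored
// signed (<= 0 for e < 1); its magnitude is applied so damping always opposes
// relative normal motion.  Total force is clamped at zero: no tensile
// (cohesive) contact.
inline double hm_normal(double Estar, double Rstar, double mstar, double beta,
                        double dn, double vn) {
  if (dn <= 0.0) return 0.0;
  const double sq = std::sqrt(Rstar * dn);
  const double fel = (4.0 / 3.0) * Estar * sq * dn;
  const double Sn = 2.0 * Estar * sq;
  const double fd = -2.0 * std::sqrt(5.0 / 6.0) * std::fabs(beta) * std::sqrt(Sn * mstar) * vn;
  double f = fel + fd;
  return f > 0.0 ? f : 0.0;
}

// Tangential spring-dashpot force with Coulomb cap.  delta_t is the
// accumulated tangential slip (already projected into the current tangent
// plane and incremented by vt*dt); on capping it is rescaled so the spring
// alone carries the Coulomb limit (standard tangential-spring truncation).
// Returns the force; delta_t is modified in place.
inline V3 hm_tangential(double Gstar, double Rstar, double mstar, double beta,
                        double mu, double dn, V3& delta_t, const V3& vt,
                        double fn) {
  if (dn <= 0.0 || fn <= 0.0) {
    delta_t = V3();
    return V3();
  }
  const double St = 8.0 * Gstar * std::sqrt(Rstar * dn);
  const double ct = 2.0 * std::sqrt(5.0 / 6.0) * std::fabs(beta) * std::sqrt(St * mstar);
  V3 f = (-St) * delta_t - ct * vt;
  const double fmag = norm(f);
  const double fcap = mu * fn;
  if (fmag > fcap) {
    const double s = fcap / fmag;
    f = s * f;
    // slip: spring stores exactly the capped force
    delta_t = (-1.0 / St) * f;
  }
  return f;
}

// One-sided rectangular facet: origin o, in-plane unit axes uh, vh with
// extents ul, vl, outward unit normal nh = uh x vh.
struct Facet {
  V3 o, uh, vh, nh;
  double ul, vl;
  bool wear, groove;
  int grid_id;  // index into wear grids, -1 if none
  int nu, nv;
};

struct FacetContact {
  bool active;
  bool interior;   // projection inside the rectangle (face contact)
  V3 point;        // closest point / contact point on facet
  V3 nhat;         // contact normal (pointing toward sphere centre)
  double dn;       // overlap
  double a, b;     // in-plane coordinates of the contact point
};

// Sphere vs bounded facet.  Interior projections use the signed distance to
// the facet plane (so a centre that crossed the plane is still pushed back
// out the front face); edge/corner closest points use the unsigned distance
// with the normal along centre - closest point.
inline FacetContact sphere_facet(const V3& c, double r, const Facet& fc) {
  FacetContact out;
  out.active = false;
  const V3 d = c - fc.o;
  const double a = dot(d, fc.uh);
  const double b = dot(d, fc.vh);
  if (a >= 0.0 && a <= fc.ul && b >= 0.0 && b <= fc.vl) {
    const double sdist = dot(d, fc.nh);
    if (sdist <= r) {
      out.active = true;
      out.interior = true;
      out.point = fc.o + a * fc.uh + b * fc.vh;
      out.nhat = fc.nh;
      out.dn = r - sdist;
      out.a = a;
      out.b = b;
    }
    return out;
  }
  const double ac = a < 0.0 ? 0.0 : (a > fc.ul ? fc.ul : a);
  const double bc = b < 0.0 ? 0.0 : (b > fc.vl ? fc.vl : b);
  const V3 q = fc.o + ac * fc.uh + bc * fc.vh;
  const V3 dv = c - q;
  const double dist = norm(dv);
  if (dist <= r && dist > 1e-14) {
    out.active = true;
    out.interior = false;
    out.point = q;
    out.nhat = (1.0 / dist) * dv;
    out.dn = r - dist;
    out.a = ac;
    out.b = bc;
  }
  return out;
}

// Worm-like-chain stretching + bending forces for one chain of n particles
// (positions P, row-major n x 3 accessed through a stride-3 array).  Forces
// are accumulated into F (same layout).  root_joint is the middle-node index
// of the joint at a built-in (clamped) end, whose bending stiffness is
// doubled: the clamp fixes the tangent, so the curvature there is carried by
// half a segment length (-1 for a free chain).  Returns false if a bond has
// (near-)zero length, in which case *bad is set to the offending bond index.
inline bool wlc_accumulate(const double* P, int n, double ks, double kb,
                           double l0, int root_joint, double* F, int* bad) {
  // stretching: H_S = 1/2 ks sum (l_i - l0)^2
  for (int i = 1; i < n; ++i) {
    const V3 p0(P[3 * (i - 1)], P[3 * (i - 1) + 1], P[3 * (i - 1) + 2]);
    const V3 p1(P[3 * i], P[3 * i + 1], P[3 * i + 2]);
    const V3 dvec = p1 - p0;
    const double l = norm(dvec);
    if (l < 1e-12) { if (bad) *bad = i; return false; }
    const double f = ks * (l - l0);
    const V3 dir = (1.0 / l) * dvec;
    F[3 * (i - 1)] += f * dir.x;  F[3 * (i - 1) + 1] += f * dir.y;  F[3 * (i - 1) + 2] += f * dir.z;
    F[3 * i]       -= f * dir.x;  F[3 * i + 1]       -= f * dir.y;  F[3 * i + 2]       -= f * dir.z;
  }
  // bending: H_B = kb sum_joints (1 - t_i . t_{i+1}),  F = -dH/dx = kb dc/dx
  for (int j = 1; j + 1 < n; ++j) {
    const V3 pm(P[3 * (j - 1)], P[3 * (j - 1) + 1], P[3 * (j - 1) + 2]);
    const V3 pj(P[3 * j], P[3 * j + 1], P[3 * j + 2]);
    const V3 pp(P[3 * (j + 1)], P[3 * (j + 1) + 1], P[3 * (j + 1) + 2]);
    const V3 a = pj - pm, b = pp - pj;
    const double la = norm(a), lb = norm(b);
    if (la < 1e-12 || lb < 1e-12) { if (bad) *bad = j; return false; }
    const double kbw = (j == root_joint) ? 2.0 * kb : kb;
    const V3 ta = (1.0 / la) * a, tb = (1.0 / lb) * b;
    const double c = dot(ta, tb);
    const V3 ga = (1.0 / la) * (tb - c * ta);  // dc/da
    const V3 gb = (1.0 / lb) * (ta - c * tb);  // dc/db
    // dc/dx_{j-1} = -ga ; dc/dx_j = ga - gb ; dc/dx_{j+1} = gb
    F[3 * (j - 1)] -= kbw * ga.x;  F[3 * (j - 1) + 1] -= kbw * ga.y;  F[3 * (j - 1) + 2] -= kbw * ga.z;
    F[3 * j]       += kbw * (ga.x - gb.x);
    F[3 * j + 1]   += kbw * (ga.y - gb.y);
    F[3 * j + 2]   += kbw * (ga.z - gb.z);
    F[3 * (j + 1)] += kbw * gb.x;  F[3 * (j + 1) + 1] += kbw * gb.y;  F[3 * (j + 1) + 2] += kbw * gb.z;
  }
  return true;
}

}  // namespace bw

#endif
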