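// Explicit DEM engine: worm-like-chain tuft forces, Hertz-Mindlin contacts
// (particle-facet and particle-particle), prescribed scrub-stroke head
// kinematics, Archard wear accumulation, and quasi-static relaxation.
//
// Semi-implicit (symplectic) Euler integration; clamped particles are moved
// kinematically with the head frame and never integrated.  The engine is
// fully deterministic: no randomness, fixed iteration order everywhere.

#include "dem_common.h"
#include <unordered_map>
#include <array>

using namespace Rcpp;
using namespace bw;

namespace {

struct TangState {
  double x, y, z;
  long long stamp;  // step index when last active
};

struct MotionOut {
  double xoff, zoff, vx, vz;
  bool in_stroke;
};

// Head offsets relative to the initial (tip-grazing) configuration.
// Phase 1: press-in at v_press down to depth dz; phase 2: hold; phase 3:
// constant-speed forward stroke L/2, instantaneous reversal, backward L/2.
inline MotionOut scrub_motion(double t, double V, double L, double dz,
                              double t_down, double t_hold) {
  MotionOut m;
  const double t0 = t_down + t_hold;
  const double T = L / V;
  if (t < t_down) {
    double vp = t_down > 0 ? dz / t_down : 0.0;
    m.xoff = 0.0; m.zoff = -vp * t; m.vx = 0.0; m.vz = -vp; m.in_stroke = false;
  } else if (t < t0) {
    m.xoff = 0.0; m.zoff = -dz; m.vx = 0.0; m.vz = 0.0; m.in_stroke = false;
  } else {
    const double ts = t - t0;
    m.zoff = -dz; m.vz = 0.0; m.in_stroke = true;
    if (ts <= 0.5 * T) { m.xoff = V * ts; m.vx = V; }
    else if (ts <= T)  { m.xoff = L - V * ts; m.vx = -V; }
    else               { m.xoff = 0.0; m.vx = 0.0; m.in_stroke = false; }
  }
  return m;
}

}  // namespace

// [[Rcpp::export]]
List dem_run_cpp(List sys, List ctrl) {
  // ---- unpack system ----
  NumericMatrix pos0m = sys["pos"], vel0m = sys["vel"];
  NumericVector radius = sys["radius"], mass = sys["mass"];
  IntegerVector clamped = sys["clamped"];
  IntegerVector chain_start = sys["chain_start"], chain_len = sys["chain_len"];
  NumericVector ksv = sys["ks"], kbv = sys["kb"], ktv = sys["kt"], l0v = sys["l0"];
  IntegerVector broot = sys["bend_root"];
  const bool torsion = as<bool>(sys["torsion"]);
  NumericMatrix facm = sys["facets"];
  IntegerVector fwear = sys["facet_wear"], fgroove = sys["facet_groove"];
  NumericVector pf = sys["pf"], pp = sys["pp"];
  const bool pp_on = as<bool>(sys["pp_on"]);
  NumericVector groove_x = sys["groove_x"];
  const double wK = as<double>(sys["wear_K"]);
  const double wH = as<double>(sys["wear_H"]);
  const double wcell = as<double>(sys["wear_cell"]);
  NumericVector grav = sys["gravity"];
  const double gamma = as<double>(sys["gamma"]);
  Nullable<NumericMatrix> fext_n(sys["fext"]);
  IntegerVector tip_idx = sys["tip_idx"];
  IntegerVector chain_of = sys["chain_of"];  // -1 if not in a chain

  const int n = pos0m.nrow();
  const int nC = chain_start.size();
  const int nF = facm.nrow();

  // ---- unpack controls ----
  const double dt = as<double>(ctrl["dt"]);
  const long long n_steps = (long long)as<double>(ctrl["n_steps"]);
  const int stride = as<int>(ctrl["stride"]);
  NumericVector snap_times = ctrl["snap_times"];
  List motion = ctrl["motion"];
  const int mtype = as<int>(motion["type"]);
  double mV = 0, mL = 0, mdz = 0, m_tdown = 0, m_thold = 0;
  if (mtype == 1) {
    mV = as<double>(motion["V"]); mL = as<double>(motion["L"]);
    mdz = as<double>(motion["d_z"]);
    m_tdown = as<double>(motion["t_down"]); m_thold = as<double>(motion["t_hold"]);
  }
  const bool relax = as<bool>(ctrl["relax"]);
  const double tol_v = as<double>(ctrl["tol_v"]);
  const double tol_f = as<double>(ctrl["tol_f"]);
  const int check_every = as<int>(ctrl["check_every"]);
  const bool record = as<bool>(ctrl["record"]);
  const double ke_abort = as<double>(ctrl["ke_abort"]);

  // ---- local state ----
  std::vector<V3> X(n), Vv(n), F(n), X0(n);
  std::vector<double> invm(n);
  for (int i = 0; i < n; ++i) {
    X[i] = V3(pos0m(i, 0), pos0m(i, 1), pos0m(i, 2));
    Vv[i] = V3(vel0m(i, 0), vel0m(i, 1), vel0m(i, 2));
    X0[i] = X[i];
    invm[i] = clamped[i] ? 0.0 : 1.0 / mass[i];
  }
  const V3 g(grav[0], grav[1], grav[2]);
  std::vector<V3> fext(n);
  if (fext_n.isNotNull()) {
    NumericMatrix fe(fext_n);
    for (int i = 0; i < n; ++i) fext[i] = V3(fe(i, 0), fe(i, 1), fe(i, 2));
  }

  // facets
  std::vector<Facet> facets(nF);
  int ngrid = 0;
  for (int f = 0; f < nF; ++f) {
    V3 o(facm(f, 0), facm(f, 1), facm(f, 2));
    V3 u(facm(f, 3), facm(f, 4), facm(f, 5));
    V3 v(facm(f, 6), facm(f, 7), facm(f, 8));
    Facet& fc = facets[f];
    fc.o = o; fc.ul = norm(u); fc.vl = norm(v);
    fc.uh = (1.0 / fc.ul) * u; fc.vh = (1.0 / fc.vl) * v;
    fc.nh = cross(fc.uh, fc.vh);
    fc.wear = fwear[f] != 0;
    fc.groove = fgroove[f] != 0;
    fc.grid_id = -1;
    if (fc.wear) {
      fc.grid_id = ngrid++;
      fc.nu = std::max(1, (int)std::ceil(fc.ul / wcell - 1e-9));
      fc.nv = std::max(1, (int)std::ceil(fc.vl / wcell - 1e-9));
    } else { fc.nu = fc.nv = 0; }
  }
  double facet_zmax = -1e300;
  for (int f = 0; f < nF; ++f) {
    for (int iu = 0; iu < 2; ++iu)
      for (int iv = 0; iv < 2; ++iv) {
        V3 cpt = facets[f].o + (iu * facets[f].ul) * facets[f].uh +
                 (iv * facets[f].vl) * facets[f].vh;
        facet_zmax = std::max(facet_zmax, cpt.z);
      }
  }
  std::vector<NumericMatrix> grids;
  for (int f = 0; f < nF; ++f)
    if (facets[f].grid_id >= 0) grids.push_back(NumericMatrix(facets[f].nu, facets[f].nv));

  const double pfE = pf[0], pfG = pf[1], pfB = pf[2], pfMu = pf[3];
  const double ppE = pp[0], ppG = pp[1], ppB = pp[2], ppMu = pp[3];
  const double gx0 = groove_x[0], gx1 = groove_x[1];

  // tangential histories
  std::unordered_map<long long, TangState> hist;
  hist.reserve(4096);
  const long long FKEY = (long long)1 << 40;

  // Verlet pair list (particle-particle)
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, radius[i]);
  const double skin = 0.6 * rmax;
  const double cutoff = 2.0 * rmax + skin;
  std::vector<std::pair<int, int> > pairs;
  std::vector<V3> Xbuild(n);
  auto adjacent_bonded = [&](int i, int j) {
    return chain_of[i] >= 0 && chain_of[i] == chain_of[j] && std::abs(i - j) == 1;
  };
  auto rebuild_pairs = [&]() {
    pairs.clear();
    const double c2 = cutoff * cutoff;
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        if (clamped[i] && clamped[j]) continue;
        if (adjacent_bonded(i, j)) continue;
        V3 d = X[i] - X[j];
        if (dot(d, d) < c2) pairs.push_back(std::make_pair(i, j));
      }
      Xbuild[i] = X[i];
    }
  };
  if (pp_on && n > 1) rebuild_pairs();

  // torsion state
  std::vector<V3> omega(n);
  std::vector<double> twist;  // per chain bond, flattened
  std::vector<int> twist_off(nC + 1, 0);
  if (torsion) {
    for (int c = 0; c < nC; ++c) twist_off[c + 1] = twist_off[c] + chain_len[c] - 1;
    twist.assign(twist_off[nC], 0.0);
  }

  // per-chain per-step accumulators
  std::vector<V3> cF(nC), cFn(nC), cFt(nC);
  std::vector<int> cGroove(nC), cCount(nC);

  // recording buffers
  const long long n_rec_max = record ? (n_steps - 1) / stride + 2 : 0;
  std::vector<double> rec_t, rec_ke;
  NumericMatrix rec_F, rec_Fn, rec_Ft, rec_tipx, rec_tipy;
  IntegerMatrix rec_groove, rec_ncont;
  if (record) {
    rec_t.reserve(n_rec_max); rec_ke.reserve(n_rec_max);
    rec_F = NumericMatrix(n_rec_max, nC); rec_Fn = NumericMatrix(n_rec_max, nC);
    rec_Ft = NumericMatrix(n_rec_max, nC); rec_tipx = NumericMatrix(n_rec_max, nC);
    rec_tipy = NumericMatrix(n_rec_max, nC);
    rec_groove = IntegerMatrix(n_rec_max, nC); rec_ncont = IntegerMatrix(n_rec_max, nC);
  }
  long long n_rec = 0;

  // snapshots
  const int nS = snap_times.size();
  int snap_ptr = 0;
  NumericMatrix snapF(std::max(nS, 1), std::max(nC, 1));
  NumericMatrix snapFn(std::max(nS, 1), std::max(nC, 1));
  NumericMatrix snapFt(std::max(nS, 1), std::max(nC, 1));
  IntegerMatrix snapC(std::max(nS, 1), std::max(nC, 1));
  NumericVector snap_actual(std::max(nS, 1));

  double wear_raw = 0.0, wear_dropped = 0.0;
  long long n_dropped = 0;
  double groove_max = 0.0, groove_max_t = NA_REAL, all_max = 0.0;

  bool converged = false, aborted = false;
  double resid_v = NA_REAL, resid_f = NA_REAL;
  int bad_particle = -1;
  long long step = 0;
  std::string abort_msg;

  std::vector<FacetContact> cand(nF);
  std::vector<int> cand_id(nF);

  for (step = 0; step < n_steps; ++step) {
    const double t = step * dt;

    // clamped kinematics
    MotionOut mo; mo.xoff = 0; mo.zoff = 0; mo.vx = 0; mo.vz = 0; mo.in_stroke = false;
    if (mtype == 1) {
      mo = scrub_motion(t, mV, mL, mdz, m_tdown, m_thold);
      for (int i = 0; i < n; ++i) {
        if (clamped[i]) {
          X[i] = V3(X0[i].x + mo.xoff, X0[i].y, X0[i].z + mo.zoff);
          Vv[i] = V3(mo.vx, 0.0, mo.vz);
        }
      }
    }
    const bool measuring = (mtype != 1) || mo.in_stroke;

    // ---- forces ----
    for (int i = 0; i < n; ++i) {
      F[i] = V3(mass[i] * g.x, mass[i] * g.y, mass[i] * g.z);
      F[i] += fext[i];
      F[i] -= (gamma * mass[i]) * Vv[i];
    }

    // WLC chain forces
    for (int c = 0; c < nC; ++c) {
      const int s0 = chain_start[c], len = chain_len[c];
      // contiguous storage guaranteed by the R assembler
      static thread_local std::vector<double> Pbuf, Fbuf;
      Pbuf.resize(3 * len); Fbuf.assign(3 * len, 0.0);
      for (int k = 0; k < len; ++k) {
        Pbuf[3 * k] = X[s0 + k].x; Pbuf[3 * k + 1] = X[s0 + k].y; Pbuf[3 * k + 2] = X[s0 + k].z;
      }
      int bad = -1;
      if (!wlc_accumulate(Pbuf.data(), len, ksv[c], kbv[c], l0v[c], broot[c], Fbuf.data(), &bad)) {
        aborted = true; bad_particle = s0 + bad;
        abort_msg = "degenerate zero-length bond";
        break;
      }
      for (int k = 0; k < len; ++k)
        F[s0 + k] += V3(Fbuf[3 * k], Fbuf[3 * k + 1], Fbuf[3 * k + 2]);
    }
    if (aborted) break;

    // torsion (optional): scalar twist per bond, restoring torque about the
    // bond axis; affects spin only (no translational coupling).
    if (torsion) {
      for (int c = 0; c < nC; ++c) {
        const int s0 = chain_start[c], len = chain_len[c];
        for (int b = 1; b < len; ++b) {
          V3 d = X[s0 + b] - X[s0 + b - 1];
          double l = norm(d);
          if (l < 1e-12) continue;
          V3 th = (1.0 / l) * d;
          double gdot = dot(omega[s0 + b] - omega[s0 + b - 1], th);
          double& gam = twist[twist_off[c] + b - 1];
          gam += gdot * dt;
          const double tq = -ktv[c] * gam;
          const double Ipa = 0.4 * mass[s0 + b - 1] * radius[s0 + b - 1] * radius[s0 + b - 1];
          const double Ipb = 0.4 * mass[s0 + b] * radius[s0 + b] * radius[s0 + b];
          if (!clamped[s0 + b]) omega[s0 + b] += (dt * tq / Ipb) * th;
          if (!clamped[s0 + b - 1]) omega[s0 + b - 1] -= (dt * tq / Ipa) * th;
        }
      }
      for (int i = 0; i < n; ++i) omega[i] -= (gamma * dt) * omega[i];
    }

    // particle-facet contacts
    for (int c = 0; c < nC; ++c) {
      cF[c] = V3(); cFn[c] = V3(); cFt[c] = V3(); cGroove[c] = 0; cCount[c] = 0;
    }
    for (int i = 0; i < n; ++i) {
      if (nF == 0) break;
      if (X[i].z - radius[i] > facet_zmax) continue;  // broad phase
      int ncand = 0;
      bool any_interior = false;
      for (int f = 0; f < nF; ++f) {
        FacetContact fc = sphere_facet(X[i], radius[i], facets[f]);
        if (fc.active) {
          cand[ncand] = fc; cand_id[ncand] = f; ++ncand;
          if (fc.interior) any_interior = true;
        }
      }
      for (int k = 0; k < ncand; ++k) {
        const FacetContact& fc = cand[k];
        const int f = cand_id[k];
        // attribution: face contacts win; edge/corner contacts count only if
        // the particle touches no face at all; coincident points deduped
        if (!fc.interior && any_interior) continue;
        bool dup = false;
        for (int k2 = 0; k2 < k; ++k2) {
          if (!cand[k2].interior && any_interior) continue;
          V3 dd = fc.point - cand[k2].point;
          if (dot(dd, dd) < 1e-20) { dup = true; break; }
        }
        if (dup) continue;

        const double vn = dot(Vv[i], fc.nhat);
        const V3 vt = Vv[i] - vn * fc.nhat;
        const double fn = hm_normal(pfE, radius[i], mass[i], pfB, fc.dn, vn);
        const long long key = FKEY + (long long)i * nF + f;
        TangState& tsd = hist[key];
        V3 dtv = (tsd.stamp == step - 1 && step > 0) ? V3(tsd.x, tsd.y, tsd.z) : V3();
        // keep slip history in the current tangent plane, then accumulate
        dtv -= dot(dtv, fc.nhat) * fc.nhat;
        dtv += dt * vt;
        V3 ft = hm_tangential(pfG, radius[i], mass[i], pfB, pfMu, fc.dn, dtv, vt, fn);
        tsd.x = dtv.x; tsd.y = dtv.y; tsd.z = dtv.z; tsd.stamp = step;

        F[i] += fn * fc.nhat + ft;

        // wear (tooth side only; Archard per increment)
        if (measuring && fn > 0.0) {
          const double slip = norm(vt) * dt;
          if (facets[f].wear) {
            const Facet& ff = facets[f];
            int iu = (int)(fc.a / wcell); if (iu >= ff.nu) iu = ff.nu - 1; if (iu < 0) iu = 0;
            int iv = (int)(fc.b / wcell); if (iv >= ff.nv) iv = ff.nv - 1; if (iv < 0) iv = 0;
            grids[ff.grid_id](iu, iv) += (wK / wH) * fn * slip;
            wear_raw += fn * slip;
          } else {
            wear_dropped += fn * slip;
            ++n_dropped;
          }
        }

        const int c = chain_of[i];
        if (c >= 0) {
          V3 tot = fn * fc.nhat + ft;
          cF[c] += tot; cFn[c] += fn * fc.nhat; cFt[c] += ft;
          cCount[c] += 1;
          if (facets[f].groove || (fc.point.x >= gx0 && fc.point.x <= gx1)) cGroove[c] = 1;
        }
      }
    }

    // particle-particle contacts
    if (pp_on && n > 1) {
      double maxdisp2 = 0.0;
      for (int i = 0; i < n; ++i) {
        V3 d = X[i] - Xbuild[i];
        maxdisp2 = std::max(maxdisp2, dot(d, d));
      }
      if (maxdisp2 > 0.25 * skin * skin) rebuild_pairs();
      for (size_t q = 0; q < pairs.size(); ++q) {
        const int i = pairs[q].first, j = pairs[q].second;
        V3 d = X[i] - X[j];
        const double dist2 = dot(d, d);
        const double rsum = radius[i] + radius[j];
        if (dist2 >= rsum * rsum) continue;
        const double dist = std::sqrt(dist2);
        if (dist < 1e-14) {
          aborted = true; bad_particle = i;
          abort_msg = "coincident particle centres in contact";
          break;
        }
        const V3 nh = (1.0 / dist) * d;  // from j toward i
        const double dn = rsum - dist;
        const double Rstar = radius[i] * radius[j] / rsum;
        const double im = invm[i] + invm[j];
        const double mstar = im > 0 ? 1.0 / im : mass[i];
        const V3 vrel = Vv[i] - Vv[j];
        const double vn = dot(vrel, nh);
        const V3 vt = vrel - vn * nh;
        const double fn = hm_normal(ppE, Rstar, mstar, ppB, dn, vn);
        const long long key = (long long)i * n + j;
        TangState& tsd = hist[key];
        V3 dtv = (tsd.stamp == step - 1 && step > 0) ? V3(tsd.x, tsd.y, tsd.z) : V3();
        dtv -= dot(dtv, nh) * nh;
        dtv += dt * vt;
        V3 ft = hm_tangential(ppG, Rstar, mstar, ppB, ppMu, dn, dtv, vt, fn);
        tsd.x = dtv.x; tsd.y = dtv.y; tsd.z = dtv.z; tsd.stamp = step;
        const V3 ftot = fn * nh + ft;
        F[i] += ftot;
        F[j] -= ftot;
      }
      if (aborted) break;
    }

    // ---- record (state + forces at time t) ----
    if (record && step % stride == 0) {
      double ke = 0.0;
      for (int i = 0; i < n; ++i)
        if (!clamped[i]) ke += 0.5 * mass[i] * dot(Vv[i], Vv[i]);
      rec_t.push_back(t); rec_ke.push_back(ke);
      for (int c = 0; c < nC; ++c) {
        rec_F(n_rec, c) = norm(cF[c]); rec_Fn(n_rec, c) = norm(cFn[c]);
        rec_Ft(n_rec, c) = norm(cFt[c]);
        rec_tipx(n_rec, c) = X[chain_start[c] + tip_idx[c]].x;
        rec_tipy(n_rec, c) = X[chain_start[c] + tip_idx[c]].y;
        rec_groove(n_rec, c) = cGroove[c]; rec_ncont(n_rec, c) = cCount[c];
      }
      ++n_rec;
    }
    if (measuring) {
      for (int c = 0; c < nC; ++c) {
        const double m = norm(cF[c]);
        if (m > all_max) all_max = m;
        if (cGroove[c] && m > groove_max) { groove_max = m; groove_max_t = t; }
      }
    }
    while (snap_ptr < nS && t >= snap_times[snap_ptr]) {
      for (int c = 0; c < nC; ++c) {
        snapF(snap_ptr, c) = norm(cF[c]); snapFn(snap_ptr, c) = norm(cFn[c]);
        snapFt(snap_ptr, c) = norm(cFt[c]); snapC(snap_ptr, c) = cCount[c] > 0 ? 1 : 0;
      }
      snap_actual[snap_ptr] = t;
      ++snap_ptr;
    }

    // ---- integrate ----
    double maxv2 = 0.0, maxf2 = 0.0;
    for (int i = 0; i < n; ++i) {
      if (invm[i] == 0.0) continue;
      Vv[i] += (dt * invm[i]) * F[i];
      X[i] += dt * Vv[i];
      if (relax) {
        maxv2 = std::max(maxv2, dot(Vv[i], Vv[i]));
        maxf2 = std::max(maxf2, dot(F[i], F[i]));
      }
    }

    if (relax && (step + 1) % check_every == 0) {
      resid_v = std::sqrt(maxv2); resid_f = std::sqrt(maxf2);
      if (resid_v < tol_v && resid_f < tol_f) { converged = true; ++step; break; }
    }

    if ((step & 255) == 0 || step == n_steps - 1) {
      double ke = 0.0;
      bool bad = false;
      for (int i = 0; i < n; ++i) {
        if (clamped[i]) continue;
        const double k2 = dot(Vv[i], Vv[i]);
        if (!std::isfinite(k2) || !std::isfinite(X[i].x + X[i].y + X[i].z)) {
          bad = true; bad_particle = i; break;
        }
        ke += 0.5 * mass[i] * k2;
      }
      if (bad || ke > ke_abort) {
        aborted = true;
        if (abort_msg.empty())
          abort_msg = bad ? "non-finite state (blow-up)" : "kinetic energy exceeded abort threshold";
        break;
      }
    }
  }

  // ---- pack outputs ----
  NumericMatrix posN(n, 3), velN(n, 3);
  for (int i = 0; i < n; ++i) {
    posN(i, 0) = X[i].x; posN(i, 1) = X[i].y; posN(i, 2) = X[i].z;
    velN(i, 0) = Vv[i].x; velN(i, 1) = Vv[i].y; velN(i, 2) = Vv[i].z;
  }
  List wear_out(nF);
  for (int f = 0; f < nF; ++f)
    wear_out[f] = facets[f].grid_id >= 0 ? (SEXP)grids[facets[f].grid_id] : R_NilValue;

  List rec_out = R_NilValue;
  if (record) {
    rec_out = List::create(
        _["time"] = NumericVector(rec_t.begin(), rec_t.end()),
        _["ke"] = NumericVector(rec_ke.begin(), rec_ke.end()),
        _["force"] = rec_F, _["fnorm"] = rec_Fn, _["ftan"] = rec_Ft,
        _["tipx"] = rec_tipx, _["tipy"] = rec_tipy,
        _["groove"] = rec_groove, _["ncontact"] = rec_ncont,
        _["n"] = (double)n_rec);
  }
  List snaps = List::create(
      _["time"] = snap_actual, _["force"] = snapF, _["fnorm"] = snapFn,
      _["ftan"] = snapFt, _["contact"] = snapC, _["n"] = snap_ptr);

  List tw = R_NilValue;
  if (torsion) tw = NumericVector(twist.begin(), twist.end());

  return List::create(
      _["pos"] = posN, _["vel"] = velN, _["steps"] = (double)step,
      _["t_end"] = (double)step * dt,
      _["converged"] = converged, _["resid_v"] = resid_v, _["resid_f"] = resid_f,
      _["wear"] = wear_out, _["wear_raw"] = wear_raw,
      _["wear_dropped"] = wear_dropped, _["n_dropped"] = (double)n_dropped,
      _["rec"] = rec_out, _["snaps"] = snaps,
      _["groove_max"] = groove_max, _["groove_max_t"] = groove_max_t,
      _["all_max"] = all_max,
      _["twist"] = tw,
      _["aborted"] = aborted, _["abort_msg"] = abort_msg,
      _["bad_particle"] = bad_particle + 1);
}
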