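// Core energy/force kernel for the subcellular element model.
//
// Evaluates, in one pass over flat arrays: linear springs, bending
// springs (quadratic and cosine forms), truncated-shifted Morse pairs,
// and per-cell area (2D volume) constraints.  Forces are the analytic
// negative gradients of the same energy expression, so force-energy
// consistency can be checked by finite differences from R.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double wrap_pi(double x) {
  // wrap to (-pi, pi]
  return std::atan2(std::sin(x), std::cos(x));
}

// [[Rcpp::export]]
List engine_eval(const NumericMatrix& pos,
                 const IntegerVector& si, const IntegerVector& sj,
                 const NumericVector& sk, const NumericVector& sL0,
                 const LogicalVector& sact,
                 const IntegerVector& ba, const IntegerVector& bb,
                 const IntegerVector& bc, const IntegerVector& bform,
                 const NumericVector& bk, const NumericVector& bth0,
                 const IntegerVector& mi, const IntegerVector& mj,
                 const NumericVector& mU, const NumericVector& mW,
                 const NumericVector& mxi, const NumericVector& mga,
                 const NumericVector& mcut, const NumericVector& mshift,
                 const IntegerVector& poly, const IntegerVector& polyoff,
                 const NumericVector& kvol, const NumericVector& omega0,
                 bool want_forces) {
  const int n = pos.nrow();
  double E = 0.0;
  NumericMatrix F(n, 2);

  // --- linear springs ----------------------------------------------------
  const int ns = si.size();
  for (int s = 0; s < ns; ++s) {
    if (!sact[s]) continue;
    const int i = si[s] - 1, j = sj[s] - 1;
    const double dx = pos(j, 0) - pos(i, 0);
    const double dy = pos(j, 1) - pos(i, 1);
    const double L = std::sqrt(dx * dx + dy * dy);
    const double st = L - sL0[s];
    E += 0.5 * sk[s] * st * st;
    if (want_forces && L > 1e-12) {
      const double f = sk[s] * st / L;  // pull toward partner when stretched
      F(i, 0) += f * dx; F(i, 1) += f * dy;
      F(j, 0) -= f * dx; F(j, 1) -= f * dy;
    }
  }

  // --- bending springs ---------------------------------------------------
  const int nb = ba.size();
  for (int s = 0; s < nb; ++s) {
    const int a = ba[s] - 1, b = bb[s] - 1, c = bc[s] - 1;
    const double ux = pos(a, 0) - pos(b, 0), uy = pos(a, 1) - pos(b, 1);
    const double vx = pos(c, 0) - pos(b, 0), vy = pos(c, 1) - pos(b, 1);
    const double u2 = ux * ux + uy * uy, v2 = vx * vx + vy * vy;
    if (u2 < 1e-24 || v2 < 1e-24) continue;
    double th = std::atan2(uy, ux) - std::atan2(vy, vx);
    // interior angle in [0, 2*pi)
    if (th < 0) th += 2.0 * M_PI;
    const double d = wrap_pi(th - bth0[s]);
    double dEdth;
    if (bform[s] == 1) {           // quadratic
      E += 0.5 * bk[s] * d * d;
      dEdth = bk[s] * d;
    } else {                       // cosine
      E += bk[s] * (1.0 - std::cos(d));
      dEdth = bk[s] * std::sin(d);
    }
    if (want_forces) {
      // dth/da = (-uy, ux)/|u|^2 ; dth/dc = (vy, -vx)/|v|^2
      const double gax = -uy / u2, gay = ux / u2;
      const double gcx = vy / v2, gcy = -vx / v2;
      F(a, 0) -= dEdth * gax; F(a, 1) -= dEdth * gay;
      F(c, 0) -= dEdth * gcx; F(c, 1) -= dEdth * gcy;
      F(b, 0) += dEdth * (gax + gcx); F(b, 1) += dEdth * (gay + gcy);
    }
  }

  // --- Morse pairs ---------------------------------------------------------
  const int nm = mi.size();
  for (int s = 0; s < nm; ++s) {
    const int i = mi[s] - 1, j = mj[s] - 1;
    const double dx = pos(i, 0) - pos(j, 0);
    const double dy = pos(i, 1) - pos(j, 1);
    const double d = std::sqrt(dx * dx + dy * dy);
    if (d >= mcut[s]) continue;
    const double er = mU[s] * std::exp(-d / mxi[s]);
    const double ea = mW[s] * std::exp(-d / mga[s]);
    E += er - ea - mshift[s];
    if (want_forces && d > 1e-12) {
      const double dEdd = -er / mxi[s] + ea / mga[s];
      const double f = -dEdd / d;
      F(i, 0) += f * dx; F(i, 1) += f * dy;
      F(j, 0) -= f * dx; F(j, 1) -= f * dy;
    }
  }

  // --- per-cell area constraints -------------------------------------------
  const int nc = kvol.size();
  NumericVector areas(nc);
  for (int c0 = 0; c0 < nc; ++c0) {
    const int lo = polyoff[c0], hi = polyoff[c0 + 1];  // [lo, hi)
    const int nv = hi - lo;
    double A = 0.0;
    for (int t = 0; t < nv; ++t) {
      const int p = poly[lo + t] - 1;
      const int q = poly[lo + (t + 1) % nv] - 1;
      A += pos(p, 0) * pos(q, 1) - pos(q, 0) * pos(p, 1);
    }
    A *= 0.5;
    areas[c0] = A;
    const double dA = A - omega0[c0];
    E += kvol[c0] * dA * dA;           // no 1/2 prefactor
    if (want_forces) {
      const double coef = 2.0 * kvol[c0] * dA;
      for (int t = 0; t < nv; ++t) {
        const int p = poly[lo + t] - 1;
        const int nxt = poly[lo + (t + 1) % nv] - 1;
        const int prv = poly[lo + (t - 1 + nv) % nv] - 1;
        F(p, 0) -= coef * 0.5 * (pos(nxt, 1) - pos(prv, 1));
        F(p, 1) -= coef * 0.5 * (pos(prv, 0) - pos(nxt, 0));
      }
    }
  }

  return List::create(_["energy"] = E, _["forces"] = F, _["areas"] = areas);
}
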