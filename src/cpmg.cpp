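// Numerical propagation of two-site chemical exchange through an ideal
// even-pulse CPMG train.  Transverse magnetization of the two exchanging
// sites is a complex 2-vector evolving under
//
//   L(off) = [ -k1        k-1          ]
//            [  k1       -k-1 + i*off  ]
//
// in the rotating frame of the ground state A (off = precession offset of
// the excited state B, rad/s).  Site-independent relaxation commutes with
// L, so the exchange-free rate R2,0 is added outside; this file returns
// only the exchange contribution.
//
// For an even number n of refocusing pulses in t_relax, the delay pattern
// is d-180-2d-180-...-180-d with d = t_relax/(2n), and the offset seen by
// site B alternates between off_p and off_m from one inter-pulse segment
// to the next (for a single-quantum coherence off_m = -off_p, the effect
// of pulse conjugation; for multiple-quantum coherences the two offsets
// carry the proton term of constant sign).  The full train propagator is
//
//   P = E_d(off_p) . [E_2d(off_m) E_2d(off_p)]^((n-2)/2) . E_2d(off_m) . E_d(off_p)
//
// evaluated with closed-form 2x2 matrix exponentials and matrix powers by
// repeated squaring, applied to M0 = (1-p_b, p_b).

#include <Rcpp.h>
#include <complex>
using namespace Rcpp;

typedef std::complex<double> cd;

struct M2 {
  cd a, b, c, d;  // [[a, b], [c, d]]
};

static inline M2 mul(const M2 &x, const M2 &y) {
  M2 r;
  r.a = x.a * y.a + x.b * y.c;
  r.b = x.a * y.b + x.b * y.d;
  r.c = x.c * y.a + x.d * y.c;
  r.d = x.c * y.b + x.d * y.d;
  return r;
}

// exp(t * [[-k1, km1], [k1, -km1 + i*off]]) via eigenvalues of the 2x2
static M2 expm2(double k1, double km1, double off, double t) {
  const cd a(-k1, 0.0), b(km1, 0.0), c(k1, 0.0), d(-km1, off);
  const cd tr = a + d;
  const cd det = a * d - b * c;
  const cd disc = std::sqrt(tr * tr - 4.0 * det);
  const cd l1 = 0.5 * (tr + disc), l2 = 0.5 * (tr - disc);
  const cd dl = l1 - l2;
  M2 r;
  if (std::abs(dl) < 1e-13 * (std::abs(l1) + std::abs(l2) + 1e-300)) {
    // degenerate eigenvalues: exp = e^(l1 t) (I + t (M - l1 I))
    const cd e = std::exp(l1 * t);
    r.a = e * (1.0 + t * (a - l1));
    r.b = e * (t * b);
    r.c = e * (t * c);
    r.d = e * (1.0 + t * (d - l1));
    return r;
  }
  const cd e1 = std::exp(l1 * t), e2 = std::exp(l2 * t);
  r.a = (e1 * (a - l2) - e2 * (a - l1)) / dl;
  r.b = (e1 - e2) * b / dl;
  r.c = (e1 - e2) * c / dl;
  r.d = (e1 * (d - l2) - e2 * (d - l1)) / dl;
  return r;
}

static M2 mpow(M2 g, long long k) {
  M2 acc;
  acc.a = 1.0; acc.b = 0.0; acc.c = 0.0; acc.d = 1.0;
  while (k > 0) {
    if (k & 1LL) acc = mul(acc, g);
    g = mul(g, g);
    k >>= 1;
  }
  return acc;
}

static double rex_one(double p_b, double k_ex, double off_p, double off_m,
                      int n, double t_relax) {
  const double p_a = 1.0 - p_b;
  const double k1 = k_ex * p_b;
  const double km1 = k_ex * p_a;
  const double dseg = t_relax / (2.0 * n);
  const M2 Ed = expm2(k1, km1, off_p, dseg);
  const M2 A = expm2(k1, km1, off_p, 2.0 * dseg);
  const M2 B = expm2(k1, km1, off_m, 2.0 * dseg);
  const M2 G = mul(B, A);
  M2 P = mul(Ed, mul(mpow(G, (n - 2) / 2), mul(B, Ed)));
  const cd ma = P.a * p_a + P.b * p_b;
  return -std::log(std::abs(ma) / p_a) / t_relax;
}

//' @noRd
// [[Rcpp::export(name = ".cpmg_rex_core")]]
NumericVector cpmg_rex_core(double p_b, double k_ex, double off_p, double off_m,
                            IntegerVector n_pulses, double t_relax) {
  const double p_a = 1.0 - p_b;
  const double k1 = k_ex * p_b;     // A -> B
  const double km1 = k_ex * p_a;    // B -> A
  const int m = n_pulses.size();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    const int n = n_pulses[i];
    if (n < 2 || (n % 2) != 0)
      stop("number of refocusing pulses must be even and >= 2 (got %d)", n);
    const double dseg = t_relax / (2.0 * n);
    const M2 Ed = expm2(k1, km1, off_p, dseg);
    const M2 A = expm2(k1, km1, off_p, 2.0 * dseg);
    const M2 B = expm2(k1, km1, off_m, 2.0 * dseg);
    const M2 G = mul(B, A);
    M2 P = mul(Ed, mul(mpow(G, (n - 2) / 2), mul(B, Ed)));
    const cd ma = P.a * p_a + P.b * p_b;  // A component of P . (p_a, p_b)
    const double mag = std::abs(ma) / p_a;
    out[i] = -std::log(mag) / t_relax;
  }
  return out;
}

// Weighted chi-square of one probe at fixed globals and shift
// differences, with the closed-form weighted least-squares baseline per
// field (non-negativity clamped).  Points must be grouped so that
// field_idx is 0-based and contiguous per field; fac_x/fac_h convert
// ppm to rad/s at each field.
//' @noRd
// [[Rcpp::export(name = ".probe_chi2_core")]]
double probe_chi2_core(bool mq, double p_b, double k_ex,
                       double dwx_ppm, double dwh_ppm, double rel_sign,
                       NumericVector fac_x, NumericVector fac_h,
                       IntegerVector field_idx, IntegerVector n_pulses,
                       NumericVector y, NumericVector w, double t_relax) {
  const int npt = y.size();
  const int nf = fac_x.size();
  std::vector<double> sw(nf, 0.0), swr(nf, 0.0);
  std::vector<double> rex(npt);
  const bool flat = (p_b <= 0.0) || (dwx_ppm == 0.0 && dwh_ppm == 0.0);
  for (int i = 0; i < npt; ++i) {
    const int f = field_idx[i];
    double r;
    if (flat) {
      r = 0.0;
    } else {
      const double ox = dwx_ppm * fac_x[f];
      if (mq) {
        const double oh = rel_sign * dwh_ppm * fac_h[f];
        const double dq = rex_one(p_b, k_ex, oh + ox, oh - ox, n_pulses[i], t_relax);
        const double zq = rex_one(p_b, k_ex, oh - ox, oh + ox, n_pulses[i], t_relax);
        r = 0.5 * (dq + zq);
      } else {
        r = rex_one(p_b, k_ex, ox, -ox, n_pulses[i], t_relax);
      }
    }
    rex[i] = r;
    sw[f] += w[i];
    swr[f] += w[i] * (y[i] - r);
  }
  std::vector<double> base(nf);
  for (int f = 0; f < nf; ++f) {
    base[f] = swr[f] / sw[f];
    if (base[f] < 0.0) base[f] = 0.0;
  }
  double chi2 = 0.0;
  for (int i = 0; i < npt; ++i) {
    const double resid = y[i] - rex[i] - base[field_idx[i]];
    chi2 += w[i] * resid * resid;
  }
  return chi2;
}

// ---- grid-node sweep -------------------------------------------------
// For the exchange-parameter grid search the per-probe shift
// differences are re-optimized at every (k_ex, p) node.  Doing the node
// loop here (simple bounded Nelder-Mead over 1 or 2 shift parameters,
// warm-started in snake order) keeps the whole sweep in compiled code.

struct ProbeObj {
  bool mq;
  double rel_sign, t_relax;
  const NumericVector &fac_x, &fac_h, &y, &w;
  const IntegerVector &fidx, &n;
  double pb, kex;
  double operator()(double dwx, double dwh) const {
    return probe_chi2_core(mq, pb, kex, dwx, dwh, rel_sign, fac_x, fac_h,
                           fidx, n, y, w, t_relax);
  }
};

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// bounded Nelder-Mead in dim 1 or 2 (dim 1: dwh held at 0)
static void nm_opt(const ProbeObj &f, int dim, double *dwx, double *dwh,
                   double ux, double uh, int maxit, double *fbest) {
  const int np = dim + 1;
  double X[3][2], F[3];
  X[0][0] = clampd(*dwx, 0.0, ux);
  X[0][1] = dim == 2 ? clampd(*dwh, 0.0, uh) : 0.0;
  for (int k = 1; k < np; ++k) {
    X[k][0] = X[0][0]; X[k][1] = X[0][1];
    const double step = (k == 1) ? std::max(0.15, 0.25 * X[0][0])
                                 : std::max(0.03, 0.25 * X[0][1]);
    X[k][k - 1] = clampd(X[k][k - 1] + step, 0.0, k == 1 ? ux : uh);
    if (X[k][k - 1] == X[0][k - 1])  // hit the bound: step inward
      X[k][k - 1] = clampd(X[0][k - 1] - step, 0.0, k == 1 ? ux : uh);
  }
  for (int k = 0; k < np; ++k) F[k] = f(X[k][0], X[k][1]);
  for (int it = 0; it < maxit; ++it) {
    // order
    for (int a = 0; a < np; ++a)
      for (int b = a + 1; b < np; ++b)
        if (F[b] < F[a]) {
          std::swap(F[a], F[b]);
          std::swap(X[a][0], X[b][0]); std::swap(X[a][1], X[b][1]);
        }
    if (F[np - 1] - F[0] <= 1e-8 * (std::fabs(F[0]) + 1e-12)) break;
    double cen[2] = {0, 0};
    for (int k = 0; k < np - 1; ++k) { cen[0] += X[k][0]; cen[1] += X[k][1]; }
    cen[0] /= (np - 1); cen[1] /= (np - 1);
    const int wI = np - 1;
    double xr0 = clampd(cen[0] + (cen[0] - X[wI][0]), 0.0, ux);
    double xr1 = dim == 2 ? clampd(cen[1] + (cen[1] - X[wI][1]), 0.0, uh) : 0.0;
    double fr = f(xr0, xr1);
    if (fr < F[0]) {  // try expansion
      double xe0 = clampd(cen[0] + 2.0 * (cen[0] - X[wI][0]), 0.0, ux);
      double xe1 = dim == 2 ? clampd(cen[1] + 2.0 * (cen[1] - X[wI][1]), 0.0, uh) : 0.0;
      double fe = f(xe0, xe1);
      if (fe < fr) { X[wI][0] = xe0; X[wI][1] = xe1; F[wI] = fe; }
      else { X[wI][0] = xr0; X[wI][1] = xr1; F[wI] = fr; }
    } else if (fr < F[wI - 1]) {
      X[wI][0] = xr0; X[wI][1] = xr1; F[wI] = fr;
    } else {  // contraction
      double xc0 = cen[0] + 0.5 * (X[wI][0] - cen[0]);
      double xc1 = dim == 2 ? cen[1] + 0.5 * (X[wI][1] - cen[1]) : 0.0;
      double fc = f(xc0, xc1);
      if (fc < F[wI]) { X[wI][0] = xc0; X[wI][1] = xc1; F[wI] = fc; }
      else {  // shrink toward best
        for (int k = 1; k < np; ++k) {
          X[k][0] = X[0][0] + 0.5 * (X[k][0] - X[0][0]);
          X[k][1] = X[0][1] + 0.5 * (X[k][1] - X[0][1]);
          F[k] = f(X[k][0], X[k][1]);
        }
      }
    }
  }
  int bi = 0;
  for (int k = 1; k < np; ++k) if (F[k] < F[bi]) bi = k;
  *dwx = X[bi][0]; *dwh = X[bi][1]; *fbest = F[bi];
}

//' @noRd
// [[Rcpp::export(name = ".grid_probe_core")]]
List grid_probe_core(bool mq, double rel_sign,
                     NumericVector fac_x, NumericVector fac_h,
                     IntegerVector field_idx, IntegerVector n_pulses,
                     NumericVector y, NumericVector w, double t_relax,
                     NumericVector kex_axis, NumericVector p_axis,
                     double dwx0, double dwh0, double upper_x,
                     double upper_h, int maxit) {
  const int nk = kex_axis.size(), np = p_axis.size();
  NumericMatrix chi2(nk, np), dwx_m(nk, np), dwh_m(nk, np);
  ProbeObj f{mq, rel_sign, t_relax, fac_x, fac_h, y, w, field_idx, n_pulses,
             0.0, 0.0};
  const int dim = mq ? 2 : 1;
  double dwx = dwx0, dwh = mq ? dwh0 : 0.0, fb;
  for (int i = 0; i < nk; ++i) {
    const bool fwd = (i % 2 == 0);
    for (int jj = 0; jj < np; ++jj) {
      const int j = fwd ? jj : (np - 1 - jj);
      f.kex = kex_axis[i];
      f.pb = p_axis[j];
      nm_opt(f, dim, &dwx, &dwh, upper_x, upper_h, maxit, &fb);
      // guard against stranding on the large-shift saturation plateau:
      // zero shift must never beat the returned optimum
      const double f0 = f(0.0, 0.0);
      if (f0 < fb) {
        double zx = 0.0, zh = 0.0, fz;
        nm_opt(f, dim, &zx, &zh, upper_x, upper_h, maxit, &fz);
        if (f0 < fz) { zx = 0.0; zh = 0.0; fz = f0; }
        if (fz < fb) { dwx = zx; dwh = zh; fb = fz; }
      }
      chi2(i, j) = fb; dwx_m(i, j) = dwx; dwh_m(i, j) = dwh;
    }
  }
  return List::create(_["chi2"] = chi2, _["dwx"] = dwx_m, _["dwh"] = dwh_m);
}
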