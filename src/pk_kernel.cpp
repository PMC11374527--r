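// Compiled kernels for the two-compartment infusion model and the FOCE-I
// inner problem. Units: time in days, amounts in mg, volumes in L, so
// concentration = amount/volume is mg/L = ug/mL (1 mg per L equals 1 ug per mL).
#define ARMA_WARN_LEVEL 1
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Closed-form propagation of the linear two-compartment system over an
// interval of length tau with constant parameters and constant zero-order
// input rate into the central compartment.
//
// Amount-space system A' = M A + (rate, 0)' with
//   M = [ -(k10+k12)  k21 ]
//       [   k12      -k21 ]
// Putzer's form: exp(M tau) = alpha*I + beta*M, and the convolution integral
// J = int_0^tau exp(M s) ds = aI*I + bI*M, valid also when M is singular
// (q = 0) or when the eigenvalues coalesce (handled by a limit branch).
// ---------------------------------------------------------------------------
struct PhiJ {
  double p11, p12, p21, p22;  // exp(M tau)
  double j11, j12, j21, j22;  // int_0^tau exp(M s) ds
};

static inline double e_lam(double lam, double tau) {
  // (exp(lam*tau) - 1)/lam with the lam -> 0 limit
  if (std::fabs(lam * tau) < 1e-12) return tau * (1.0 + 0.5 * lam * tau);
  return std::expm1(lam * tau) / lam;
}

static inline PhiJ phi_j(double cl, double vc, double q, double vp, double tau) {
  const double k10 = cl / vc, k12 = q / vc, k21 = q / vp;
  const double tr = -(k10 + k12 + k21);
  const double det = k10 * k21;
  double disc = tr * tr - 4.0 * det;
  if (disc < 0.0) disc = 0.0;  // guards rounding; analytically >= 0
  disc = std::sqrt(disc);
  const double l1 = 0.5 * (tr + disc), l2 = 0.5 * (tr - disc);

  const double e1 = std::exp(l1 * tau), e2 = std::exp(l2 * tau);
  const double E1 = e_lam(l1, tau), E2 = e_lam(l2, tau);

  double beta, bI;
  if (std::fabs(l1 - l2) > 1e-10 * std::max(std::fabs(l1), 1e-30)) {
    beta = (e1 - e2) / (l1 - l2);
    bI   = (E1 - E2) / (l1 - l2);
  } else {  // coalescent eigenvalues: L'Hopital limits
    beta = tau * e1;
    bI = (std::fabs(l1) < 1e-12) ? 0.5 * tau * tau
                                 : (tau * e1 * l1 - e1 + 1.0) / (l1 * l1);
  }
  const double alpha = e1 - beta * l1;
  const double aI    = E1 - bI * l1;

  const double m11 = -(k10 + k12), m12 = k21, m21 = k12, m22 = -k21;
  PhiJ r;
  r.p11 = alpha + beta * m11; r.p12 = beta * m12;
  r.p21 = beta * m21;         r.p22 = alpha + beta * m22;
  r.j11 = aI + bI * m11;      r.j12 = bI * m12;
  r.j21 = bI * m21;           r.j22 = aI + bI * m22;
  return r;
}

static inline void advance(double cl, double vc, double q, double vp,
                           double rate, double tau, double& a1, double& a2) {
  if (tau <= 0.0) return;
  PhiJ s = phi_j(cl, vc, q, vp, tau);
  const double n1 = s.p11 * a1 + s.p12 * a2 + s.j11 * rate;
  const double n2 = s.p21 * a1 + s.p22 * a2 + s.j21 * rate;
  a1 = n1; a2 = n2;
}

// ---------------------------------------------------------------------------
// Concentration profile for one subject with piecewise-constant parameters.
// Segments are contiguous half-open intervals [t0[k], t0[k+1]) covering all
// observation times; compartment amounts are carried as state across segment
// boundaries so the profile is continuous when parameters change.
// obs_seg is the 0-based segment index of each observation; obs at the left
// boundary of a segment returns the state at that boundary (pre-dose value).
// ---------------------------------------------------------------------------
static void profile_subject(const double* t0, const double* rate,
                            const double* cl, const double* vc,
                            const double* q, const double* vp, int nseg,
                            const double* obs_t, const int* obs_seg, int nobs,
                            double* out) {
  std::vector<double> s1(nseg), s2(nseg);  // state at each segment start
  double a1 = 0.0, a2 = 0.0;
  for (int k = 0; k < nseg; ++k) {
    s1[k] = a1; s2[k] = a2;
    if (k + 1 < nseg)
      advance(cl[k], vc[k], q[k], vp[k], rate[k], t0[k + 1] - t0[k], a1, a2);
  }
  for (int j = 0; j < nobs; ++j) {
    int k = obs_seg[j];
    double b1 = s1[k], b2 = s2[k];
    advance(cl[k], vc[k], q[k], vp[k], rate[k], obs_t[j] - t0[k], b1, b2);
    out[j] = b1 / vc[k];
  }
}

// [[Rcpp::export(name = ".profile_piecewise_cpp")]]
NumericVector profile_piecewise_cpp(NumericVector seg_t0, NumericVector seg_rate,
                                    NumericVector seg_cl, NumericVector seg_vc,
                                    NumericVector seg_q, NumericVector seg_vp,
                                    NumericVector obs_t, IntegerVector obs_seg) {
  const int nseg = seg_t0.size(), nobs = obs_t.size();
  NumericVector out(nobs);
  if (nobs == 0) return out;
  profile_subject(seg_t0.begin(), seg_rate.begin(), seg_cl.begin(),
                  seg_vc.begin(), seg_q.begin(), seg_vp.begin(), nseg,
                  obs_t.begin(), obs_seg.begin(), nobs, out.begin());
  return out;
}

// ---------------------------------------------------------------------------
// FOCE-I machinery. Random-effect vector per subject: b = (eta_CL, eta_Vc,
// eta_Vp, kappa_1..kappa_nocc). Covariate-adjusted typical values (cl0 etc.)
// are precomputed per segment in R; b scales them as
//   CL = cl0 * exp(eta_CL + kappa[occ]),  Vc = vc0 * exp(eta_Vc),
//   Vp = vp0 * exp(eta_Vp),               Q  = q0.
// seg_occ holds the 0-based kappa index of a segment, or -1.
// ---------------------------------------------------------------------------
struct SubjData {
  const double *t0, *rate, *cl0, *vc0, *q0, *vp0;
  const int* occ;
  int nseg;
  const double *obs_t, *y;
  const int* obs_seg;
  int nobs;
  int nocc;
};

static void subj_pred(const SubjData& d, const arma::vec& b, double* f,
                      std::vector<double>& cl, std::vector<double>& vc,
                      std::vector<double>& vp) {
  for (int k = 0; k < d.nseg; ++k) {
    double kap = (d.occ[k] >= 0) ? b[3 + d.occ[k]] : 0.0;
    cl[k] = d.cl0[k] * std::exp(b[0] + kap);
    vc[k] = d.vc0[k] * std::exp(b[1]);
    vp[k] = d.vp0[k] * std::exp(b[2]);
  }
  profile_subject(d.t0, d.rate, cl.data(), vc.data(), d.q0, vp.data(), d.nseg,
                  d.obs_t, d.obs_seg, d.nobs, f);
}

// prediction + Jacobian wrt active dims (central differences)
static void pred_jac(const SubjData& d, const arma::vec& b,
                     const arma::uvec& act, arma::vec& f, arma::mat& G,
                     std::vector<double>& cl, std::vector<double>& vc,
                     std::vector<double>& vp) {
  subj_pred(d, b, f.memptr(), cl, vc, vp);
  const double h = 1e-4;
  arma::vec fp(d.nobs), fm(d.nobs);
  for (arma::uword a = 0; a < act.n_elem; ++a) {
    arma::vec bp = b, bm = b;
    bp[act[a]] += h; bm[act[a]] -= h;
    subj_pred(d, bp, fp.memptr(), cl, vc, vp);
    subj_pred(d, bm, fm.memptr(), cl, vc, vp);
    G.col(a) = (fp - fm) / (2.0 * h);
  }
}

static inline double inner_g(const SubjData& d, const arma::vec& f,
                             const arma::vec& b_act, const arma::mat& Dinv,
                             double s2p, double s2a) {
  double g = arma::as_scalar(b_act.t() * Dinv * b_act);
  for (int j = 0; j < d.nobs; ++j) {
    double v = s2p * f[j] * f[j] + s2a;
    if (v < 1e-12) v = 1e-12;
    double r = d.y[j] - f[j];
    g += r * r / v + std::log(v);
  }
  return g;
}

// Inner penalized extended-least-squares problem; damped Gauss-Newton.
// Returns mode (in b, full dim), f, G, v at the mode. act = active dims.
static bool inner_mode(const SubjData& d, const arma::mat& Dinv,
                       const arma::uvec& act, double s2p, double s2a,
                       arma::vec& b, arma::vec& f, arma::mat& G,
                       arma::vec& v) {
  const int na = act.n_elem;
  std::vector<double> cl(d.nseg), vc(d.nseg), vp(d.nseg);
  f.set_size(d.nobs);
  G.set_size(d.nobs, na);
  v.set_size(d.nobs);
  if (na == 0) {
    subj_pred(d, b, f.memptr(), cl, vc, vp);
    for (int j = 0; j < d.nobs; ++j)
      v[j] = std::max(s2p * f[j] * f[j] + s2a, 1e-12);
    return true;
  }
  arma::vec ba = b.elem(act);
  pred_jac(d, b, act, f, G, cl, vc, vp);
  double g = inner_g(d, f, ba, Dinv, s2p, s2a);
  bool ok = false;
  for (int it = 0; it < 60; ++it) {
    // gradient of the full objective (residual variance depends on f)
    arma::vec dgdf(d.nobs);
    for (int j = 0; j < d.nobs; ++j) {
      double vv = std::max(s2p * f[j] * f[j] + s2a, 1e-12);
      double r = d.y[j] - f[j];
      double dv = 2.0 * s2p * f[j];
      dgdf[j] = -2.0 * r / vv + dv * (1.0 / vv - r * r / (vv * vv));
      v[j] = vv;
    }
    arma::vec grad = G.t() * dgdf + 2.0 * Dinv * ba;
    if (arma::norm(grad, "inf") < 1e-8 * (1.0 + std::fabs(g))) { ok = true; break; }
    arma::mat W = G.each_col() % (1.0 / v);
    arma::mat H = 2.0 * (G.t() * W + Dinv);
    arma::vec step;
    if (!arma::solve(step, H, -grad, arma::solve_opts::likely_sympd))
      step = -grad / (arma::norm(grad) + 1e-12);
    double t = 1.0;
    arma::vec ba_new, f_new(d.nobs), b_full = b;
    double g_new = g;
    bool improved = false;
    for (int ls = 0; ls < 25; ++ls) {
      ba_new = ba + t * step;
      b_full.zeros(); b_full.elem(act) = ba_new;
      subj_pred(d, b_full, f_new.memptr(), cl, vc, vp);
      g_new = inner_g(d, f_new, ba_new, Dinv, s2p, s2a);
      if (std::isfinite(g_new) && g_new < g) { improved = true; break; }
      t *= 0.5;
    }
    if (!improved) { ok = true; break; }  // at a (numerical) minimum
    ba = ba_new; b = b_full;
    pred_jac(d, b, act, f, G, cl, vc, vp);
    double g_old = g; g = g_new;
    if (g_old - g < 1e-10 * (1.0 + std::fabs(g))) { ok = true; break; }
  }
  for (int j = 0; j < d.nobs; ++j)
    v[j] = std::max(s2p * f[j] * f[j] + s2a, 1e-12);
  return ok;
}

// [[Rcpp::export(name = ".foce_all_cpp")]]
List foce_all_cpp(IntegerVector sub_seg_off, NumericVector seg_t0,
                  NumericVector seg_rate, NumericVector seg_cl0,
                  NumericVector seg_vc0, NumericVector seg_q0,
                  NumericVector seg_vp0, IntegerVector seg_occ,
                  IntegerVector sub_obs_off, NumericVector obs_t,
                  IntegerVector obs_seg, NumericVector y,
                  IntegerVector sub_nocc, arma::mat omega, double w2iov,
                  double s2p, double s2a, List b_init) {
  const int nsub = sub_nocc.size();
  NumericVector ofv_i(nsub);
  List b_out(nsub), ipred_out(nsub);
  LogicalVector conv(nsub);
  double total = 0.0;
  bool all_ok = true;

  for (int i = 0; i < nsub; ++i) {
    SubjData d;
    const int s0 = sub_seg_off[i], s1 = sub_seg_off[i + 1];
    const int o0 = sub_obs_off[i], o1 = sub_obs_off[i + 1];
    d.t0 = &seg_t0[s0]; d.rate = &seg_rate[s0];
    d.cl0 = &seg_cl0[s0]; d.vc0 = &seg_vc0[s0];
    d.q0 = &seg_q0[s0]; d.vp0 = &seg_vp0[s0];
    d.occ = &seg_occ[s0]; d.nseg = s1 - s0;
    d.nobs = o1 - o0; d.nocc = sub_nocc[i];
    // o0 may equal the vector length for a trailing subject with no
    // observations; never form an end-of-vector reference
    d.obs_t = d.nobs ? &obs_t[o0] : nullptr;
    d.y = d.nobs ? &y[o0] : nullptr;
    d.obs_seg = d.nobs ? &obs_seg[o0] : nullptr;

    const int dim = 3 + d.nocc;
    if (d.nobs == 0) {  // no data: prior mode, zero contribution
      conv[i] = true;
      ofv_i[i] = 0.0;
      b_out[i] = NumericVector(dim);
      ipred_out[i] = NumericVector(0);
      continue;
    }
    arma::mat D(dim, dim, arma::fill::zeros);
    D.submat(0, 0, 2, 2) = omega;
    for (int k = 0; k < d.nocc; ++k) D(3 + k, 3 + k) = w2iov;
    arma::uvec act = arma::find(D.diag() > 1e-12);
    arma::mat Dact = D.submat(act, act);
    arma::mat Dinv;
    if (act.n_elem > 0 && !arma::inv_sympd(Dinv, Dact)) {
      all_ok = false; conv[i] = false;
      ofv_i[i] = NA_REAL;
      continue;
    }

    arma::vec b(dim, arma::fill::zeros);
    if (b_init.size() == nsub && !Rf_isNull(b_init[i])) {
      NumericVector bi = b_init[i];
      if ((int)bi.size() == dim) b = arma::vec(bi.begin(), dim);
    }
    if (act.n_elem == 0) b.zeros();

    arma::vec f, v;
    arma::mat G;
    bool ok = inner_mode(d, Dinv, act, s2p, s2a, b, f, G, v);
    conv[i] = ok;
    if (!ok) all_ok = false;

    arma::vec yv(const_cast<double*>(d.y), d.nobs, false);
    double li;
    if (act.n_elem == 0) {
      arma::vec r = yv - f;
      li = arma::accu(arma::log(v) + r % r / v);
    } else {
      arma::mat C = G * Dact * G.t();
      C.diag() += v;
      arma::vec mu = f - G * b.elem(act);
      arma::mat L;
      if (!arma::chol(L, C, "lower")) {
        C.diag() += 1e-8 * arma::mean(C.diag());
        if (!arma::chol(L, C, "lower")) { conv[i] = false; all_ok = false;
          ofv_i[i] = NA_REAL; continue; }
      }
      arma::vec z = arma::solve(arma::trimatl(L), yv - mu);
      li = 2.0 * arma::accu(arma::log(L.diag())) + arma::dot(z, z);
    }
    ofv_i[i] = li;
    total += li;
    b_out[i] = NumericVector(b.begin(), b.end());
    ipred_out[i] = NumericVector(f.begin(), f.end());
  }
  return List::create(_["ofv"] = total, _["ofv_i"] = ofv_i, _["b"] = b_out,
                      _["ipred"] = ipred_out, _["converged"] = conv,
                      _["ok"] = all_ok);
}

// ---------------------------------------------------------------------------
// Adaptive RK45 (Cash-Karp) integrator for the two-compartment model with
// parallel linear + Michaelis-Menten elimination:
//   A1' = -(CL/Vc) A1 - k12 A1 + k21 A2 - Vmax * C/(Km + C) + rate,  C = A1/Vc
//   A2' =  k12 A1 - k21 A2
// Integrates across the same piecewise segments as the linear solver.
// vmax in mg/day, km in ug/mL.
// ---------------------------------------------------------------------------
struct MMPar { double cl, vc, q, vp, vmax, km, rate; };

static inline void mm_rhs(const MMPar& p, const double a[2], double da[2]) {
  const double c = a[0] / p.vc;
  const double elim = p.cl * c + (p.km > 0.0 ? p.vmax * c / (p.km + c) : 0.0);
  da[0] = -elim - (p.q / p.vc) * a[0] + (p.q / p.vp) * a[1] + p.rate;
  da[1] = (p.q / p.vc) * a[0] - (p.q / p.vp) * a[1];
}

static bool rk45_advance(const MMPar& p, double tau, double a[2],
                         double rtol, double atol) {
  static const double c2 = 0.2, c3 = 0.3, c4 = 0.6, c5 = 1.0, c6 = 0.875;
  static const double b21 = 0.2;
  static const double b31 = 3.0 / 40, b32 = 9.0 / 40;
  static const double b41 = 0.3, b42 = -0.9, b43 = 1.2;
  static const double b51 = -11.0 / 54, b52 = 2.5, b53 = -70.0 / 27, b54 = 35.0 / 27;
  static const double b61 = 1631.0 / 55296, b62 = 175.0 / 512, b63 = 575.0 / 13824,
                      b64 = 44275.0 / 110592, b65 = 253.0 / 4096;
  static const double w1 = 37.0 / 378, w3 = 250.0 / 621, w4 = 125.0 / 594,
                      w6 = 512.0 / 1771;
  static const double e1 = w1 - 2825.0 / 27648, e3 = w3 - 18575.0 / 48384,
                      e4 = w4 - 13525.0 / 55296, e5 = -277.0 / 14336,
                      e6 = w6 - 0.25;
  (void)c2; (void)c3; (void)c4; (void)c5; (void)c6;
  double t = 0.0, h = std::min(tau, 0.05);
  int nstep = 0;
  while (t < tau) {
    if (++nstep > 200000) return false;
    if (t + h > tau) h = tau - t;
    double k1[2], k2[2], k3[2], k4[2], k5[2], k6[2], tmp[2], a5[2], err[2];
    mm_rhs(p, a, k1);
    for (int i = 0; i < 2; ++i) tmp[i] = a[i] + h * b21 * k1[i];
    mm_rhs(p, tmp, k2);
    for (int i = 0; i < 2; ++i) tmp[i] = a[i] + h * (b31 * k1[i] + b32 * k2[i]);
    mm_rhs(p, tmp, k3);
    for (int i = 0; i < 2; ++i)
      tmp[i] = a[i] + h * (b41 * k1[i] + b42 * k2[i] + b43 * k3[i]);
    mm_rhs(p, tmp, k4);
    for (int i = 0; i < 2; ++i)
      tmp[i] = a[i] + h * (b51 * k1[i] + b52 * k2[i] + b53 * k3[i] + b54 * k4[i]);
    mm_rhs(p, tmp, k5);
    for (int i = 0; i < 2; ++i)
      tmp[i] = a[i] + h * (b61 * k1[i] + b62 * k2[i] + b63 * k3[i] +
                           b64 * k4[i] + b65 * k5[i]);
    mm_rhs(p, tmp, k6);
    double maxerr = 0.0;
    for (int i = 0; i < 2; ++i) {
      a5[i] = a[i] + h * (w1 * k1[i] + w3 * k3[i] + w4 * k4[i] + w6 * k6[i]);
      err[i] = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] + e6 * k6[i]);
      double sc = atol + rtol * std::max(std::fabs(a[i]), std::fabs(a5[i]));
      maxerr = std::max(maxerr, std::fabs(err[i]) / sc);
    }
    if (maxerr <= 1.0) {
      t += h;
      a[0] = a5[0]; a[1] = a5[1];
    }
    double fac = 0.9 * std::pow(std::max(maxerr, 1e-10), -0.2);
    h *= std::min(5.0, std::max(0.2, fac));
    if (h < 1e-14) return false;
  }
  return true;
}

// [[Rcpp::export(name = ".profile_mm_cpp")]]
NumericVector profile_mm_cpp(NumericVector seg_t0, NumericVector seg_rate,
                             NumericVector seg_cl, NumericVector seg_vc,
                             NumericVector seg_q, NumericVector seg_vp,
                             double vmax, double km, NumericVector obs_t,
                             IntegerVector obs_seg, double rtol, double atol) {
  const int nseg = seg_t0.size(), nobs = obs_t.size();
  NumericVector out(nobs);
  std::vector<double> s1(nseg), s2(nseg);
  double a[2] = {0.0, 0.0};
  for (int k = 0; k < nseg; ++k) {
    s1[k] = a[0]; s2[k] = a[1];
    if (k + 1 < nseg) {
      MMPar p = {seg_cl[k], seg_vc[k], seg_q[k], seg_vp[k], vmax, km, seg_rate[k]};
      if (!rk45_advance(p, seg_t0[k + 1] - seg_t0[k], a, rtol, atol))
        stop("MM ODE solver failed to converge in segment %d", k + 1);
    }
  }
  for (int j = 0; j < nobs; ++j) {
    int k = obs_seg[j];
    double b[2] = {s1[k], s2[k]};
    MMPar p = {seg_cl[k], seg_vc[k], seg_q[k], seg_vp[k], vmax, km, seg_rate[k]};
    if (!rk45_advance(p, obs_t[j] - seg_t0[k], b, rtol, atol))
      stop("MM ODE solver failed to converge at observation %d", j + 1);
    out[j] = b[0] / seg_vc[k];
  }
  return out;
}
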