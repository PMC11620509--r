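// Closed-form piecewise solver for the two-compartment disposition model with
// zero-order (infusion) input, partitioned elimination ledgers, and the
// per-patient Laplace (-2 log-likelihood) objective used by the mixed-effects
// estimator.  States: A1 central (plasma + prefilter line), A2 peripheral,
// plus cumulative urine / extracorporeal / metabolic eliminated amounts and
// cumulative infused dose.  Units package-wide: mg, L, h.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// phi1(z) = (e^z - 1)/z, phi2(z) = (e^z - 1 - z)/z^2, numerically stable
static inline double phi1(double z) {
  if (std::fabs(z) < 1e-5) return 1.0 + z / 2.0 + z * z / 6.0;
  return std::expm1(z) / z;
}
static inline double phi2(double z) {
  if (std::fabs(z) < 1e-4) return 0.5 + z / 6.0 + z * z / 24.0;
  return (std::expm1(z) - z) / (z * z);
}

struct PkPar {
  double clr, clm, clckrt, v1, v2, cld;
  double k10, k12, k21;
  bool two_cpt;
};

static PkPar make_par(const double* p) {
  PkPar q;
  q.clr = p[0]; q.clm = p[1]; q.clckrt = p[2];
  q.v1 = p[3]; q.v2 = p[4]; q.cld = p[5];
  q.k10 = (q.clr + q.clm + q.clckrt) / q.v1;
  q.two_cpt = (q.cld > 0.0 && q.v2 > 0.0);
  q.k12 = q.two_cpt ? q.cld / q.v1 : 0.0;
  q.k21 = q.two_cpt ? q.cld / q.v2 : 0.0;
  return q;
}

// Advance the full state over one constant-rate segment of length tau,
// starting from state s (A1, A2, Aur, Ackrt, Amet, Ainf); also usable to
// evaluate at interior offsets.  Analytic solution via the eigen
// decomposition of the 2x2 rate matrix; input handled with phi-functions so
// zero eigenvalues (no net elimination) stay finite.
static void advance(const PkPar& q, const double* s, double tau, double rate,
                    double* out) {
  double A1, A2, I1; // new A1, new A2, integral of A1 over the step
  if (!q.two_cpt) {
    double z = -q.k10 * tau;
    double e = std::exp(z);
    A1 = s[0] * e + rate * tau * phi1(z);
    I1 = s[0] * tau * phi1(z) + rate * tau * tau * phi2(z);
    A2 = s[1];
  } else {
    double tr = -(q.k10 + q.k12 + q.k21);
    double det = q.k10 * q.k21;
    double disc = tr * tr - 4.0 * det;
    if (disc < 0) disc = 0;
    double rt = std::sqrt(disc);
    double l1 = (tr - rt) / 2.0, l2 = (tr + rt) / 2.0;
    if (std::fabs(l1 - l2) < 1e-12 * (1.0 + std::fabs(l1))) l2 += 1e-9 + 1e-9 * std::fabs(l1);
    // eigenvectors v_i = (k21, l_i + k10 + k12): first row of (M - l I) v = 0
    double a1 = q.k21, b1 = l1 + q.k10 + q.k12;
    double a2 = q.k21, b2 = l2 + q.k10 + q.k12;
    double dV = a1 * b2 - a2 * b1; // det of V = [[a1,a2],[b1,b2]]
    // c = V^-1 * A0 ; w = V^-1 * b, b = (rate, 0)
    double c1 = (b2 * s[0] - a2 * s[1]) / dV;
    double c2 = (-b1 * s[0] + a1 * s[1]) / dV;
    double w1 = b2 * rate / dV;
    double w2 = -b1 * rate / dV;
    double e1 = std::exp(l1 * tau), e2 = std::exp(l2 * tau);
    double f1 = tau * phi1(l1 * tau), f2 = tau * phi1(l2 * tau);
    double g1 = tau * tau * phi2(l1 * tau), g2 = tau * tau * phi2(l2 * tau);
    A1 = a1 * (c1 * e1 + w1 * f1) + a2 * (c2 * e2 + w2 * f2);
    A2 = b1 * (c1 * e1 + w1 * f1) + b2 * (c2 * e2 + w2 * f2);
    I1 = a1 * (c1 * f1 + w1 * g1) + a2 * (c2 * f2 + w2 * g2);
  }
  out[0] = A1 < 0 ? 0.0 : A1;
  out[1] = A2 < 0 ? 0.0 : A2;
  out[2] = s[2] + q.clr / q.v1 * I1;
  out[3] = s[3] + q.clckrt / q.v1 * I1;
  out[4] = s[4] + q.clm / q.v1 * I1;
  out[5] = s[5] + rate * tau;
}

// params: clr, clm, clckrt, v1, v2, cld
// segments: matrix (n_seg x 3) columns t_start, t_end, rate; contiguous,
//   starting at the earliest requested time or before.
// times: nondecreasing evaluation times; a time equal to a segment boundary
//   belongs to the *earlier* segment (pre-dose convention).
// [[Rcpp::export]]
NumericMatrix cpp_profile(NumericVector params, NumericMatrix segments,
                          NumericVector times) {
  PkPar q = make_par(params.begin());
  int nt = times.size(), ns = segments.nrow();
  NumericMatrix out(nt, 6);
  double state[6] = {0, 0, 0, 0, 0, 0};
  double tmp[6];
  int j = 0;
  // times at or before the first segment start: all-zero state
  while (j < nt && times[j] <= segments(0, 0)) { j++; }
  for (int i = 0; i < ns && j < nt; ++i) {
    double t0 = segments(i, 0), t1 = segments(i, 1), rate = segments(i, 2);
    while (j < nt && times[j] <= t1 + 1e-12) {
      double tau = times[j] - t0;
      if (tau < 0) tau = 0;
      advance(q, state, tau, rate, tmp);
      for (int k = 0; k < 6; ++k) out(j, k) = tmp[k];
      j++;
    }
    advance(q, state, t1 - t0, rate, tmp);
    for (int k = 0; k < 6; ++k) state[k] = tmp[k];
  }
  // times past the final segment: decay with zero input from final state
  double tend = segments(ns - 1, 1);
  while (j < nt) {
    advance(q, state, times[j] - tend, 0.0, tmp);
    for (int k = 0; k < 6; ++k) out(j, k) = tmp[k];
    j++;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Laplace -2LL for one patient.
//
// Observation types: 0 plasma/prefilter, 1 postfilter, 2 effluent, 3 urine.
// For urine records, prediction = (Aur(t) - Aur(tstart)) / (uvol/1000) mg/L.
// eta multiplies individual parameters: eta_map entries index into
// (0 clr, 1 clm, 2 clckrt, 3 v1).
// ---------------------------------------------------------------------------

struct ObsSpec {
  arma::vec times;    // unique evaluation times (sorted)
  arma::ivec idx;     // per-obs index into times for the record's TIME
  arma::ivec idx0;    // per-obs index for urine interval start (-1 otherwise)
  arma::ivec type;
  arma::vec y;        // log observed
  arma::vec sig2;     // residual variance per obs
  arma::vec uvol;     // L
  double phi_pl, phi_eff;
};

// log-scale predictions for all observations given individual parameters
static bool pred_log(const PkPar& q, const NumericMatrix& segments,
                     const ObsSpec& ob, arma::vec& out) {
  int nt = ob.times.n_elem;
  NumericVector tv(ob.times.begin(), ob.times.end());
  NumericVector pv = NumericVector::create(q.clr, q.clm, q.clckrt, q.v1, q.v2, q.cld);
  NumericMatrix st = cpp_profile(pv, const_cast<NumericMatrix&>(segments), tv);
  (void)nt;
  int n = ob.y.n_elem;
  for (int i = 0; i < n; ++i) {
    double c;
    double a1 = st(ob.idx[i], 0);
    switch (ob.type[i]) {
    case 0: c = a1 / q.v1; break;
    case 1: {
      // infeasible clckrt >= phi_pl is clamped, not errored: the huge
      // residual steers the optimizer back into the feasible region
      double frac = 1.0 - q.clckrt / ob.phi_pl;
      if (frac < 1e-6) frac = 1e-6;
      c = a1 / q.v1 * frac; break;
    }
    case 2: c = q.clckrt * (a1 / q.v1) / ob.phi_eff; break;
    default: {
      double da = st(ob.idx[i], 2) - (ob.idx0[i] >= 0 ? st(ob.idx0[i], 2) : 0.0);
      c = da / ob.uvol[i];
    }
    }
    if (!std::isfinite(c)) return false;
    if (c < 1e-12) c = 1e-12;
    out[i] = std::log(c);
  }
  return true;
}

static const double BIG = 1e10;

// joint -2 log density up to the Laplace correction
static double qfun(const arma::vec& eta, const arma::vec& typ,
                   const arma::ivec& eta_map, const arma::mat& omega_inv,
                   double log_det_omega, const NumericMatrix& segments,
                   const ObsSpec& ob, arma::vec& resid_out) {
  double p[6] = {typ[0], typ[1], typ[2], typ[3], typ[4], typ[5]};
  for (arma::uword k = 0; k < eta_map.n_elem; ++k)
    p[eta_map[k]] *= std::exp(eta[k]);
  PkPar q = make_par(p);
  arma::vec f(ob.y.n_elem);
  if (!pred_log(q, segments, ob, f)) return BIG;
  resid_out = ob.y - f;
  double val = 0.0;
  for (arma::uword i = 0; i < ob.y.n_elem; ++i)
    val += std::log(2.0 * M_PI * ob.sig2[i]) + resid_out[i] * resid_out[i] / ob.sig2[i];
  int k = eta.n_elem;
  if (k > 0)
    val += k * std::log(2.0 * M_PI) + log_det_omega +
      arma::as_scalar(eta.t() * omega_inv * eta);
  return val;
}

// forward-difference Jacobian of log-predictions w.r.t. eta, reusing the
// predictions already computed at the expansion point
static bool jac_eta(const arma::vec& eta, const arma::vec& typ,
                    const arma::ivec& eta_map, const NumericMatrix& segments,
                    const ObsSpec& ob, arma::mat& J) {
  int k = eta.n_elem, n = ob.y.n_elem;
  const double h = 1e-5;
  arma::vec f0(n), f1(n);
  double p[6];
  for (int j = 0; j < 6; ++j) p[j] = typ[j];
  for (int j = 0; j < k; ++j) p[eta_map[j]] *= std::exp(eta[j]);
  {
    PkPar q = make_par(p);
    if (!pred_log(q, segments, ob, f0)) return false;
  }
  for (int c = 0; c < k; ++c) {
    arma::vec e = eta;
    e[c] += h;
    for (int j = 0; j < 6; ++j) p[j] = typ[j];
    for (int j = 0; j < k; ++j) p[eta_map[j]] *= std::exp(e[j]);
    PkPar q = make_par(p);
    if (!pred_log(q, segments, ob, f1)) return false;
    J.col(c) = (f1 - f0) / h;
  }
  return true;
}

// [[Rcpp::export]]
List cpp_laplace_patient(NumericVector typ, IntegerVector eta_map,
                         arma::mat omega_inv, double log_det_omega,
                         NumericMatrix segments, NumericVector ev_times,
                         IntegerVector obs_idx, IntegerVector obs_idx0,
                         IntegerVector obs_type, NumericVector obs_y,
                         NumericVector obs_sig2, NumericVector obs_uvol,
                         double phi_pl, double phi_eff,
                         NumericVector eta_start) {
  ObsSpec ob;
  ob.times = arma::vec(ev_times.begin(), ev_times.size());
  ob.idx = arma::ivec(obs_idx.size());
  ob.idx0 = arma::ivec(obs_idx0.size());
  ob.type = arma::ivec(obs_type.size());
  for (int i = 0; i < obs_idx.size(); ++i) {
    ob.idx[i] = obs_idx[i]; ob.idx0[i] = obs_idx0[i]; ob.type[i] = obs_type[i];
  }
  ob.y = arma::vec(obs_y.begin(), obs_y.size());
  ob.sig2 = arma::vec(obs_sig2.begin(), obs_sig2.size());
  ob.uvol = arma::vec(obs_uvol.begin(), obs_uvol.size());
  ob.phi_pl = phi_pl; ob.phi_eff = phi_eff;

  arma::vec typv(typ.begin(), typ.size());
  int k = eta_map.size();
  arma::ivec emap(k);
  for (int i = 0; i < k; ++i) emap[i] = eta_map[i];

  arma::vec resid(ob.y.n_elem);

  if (k == 0) { // no random effects: plain residual likelihood
    double val = qfun(arma::vec(), typv, emap, omega_inv, log_det_omega,
                      segments, ob, resid);
    return List::create(_["n2ll"] = val, _["eta"] = NumericVector(0),
                        _["converged"] = true);
  }

  arma::vec eta(eta_start.begin(), eta_start.size());
  double qcur = qfun(eta, typv, emap, omega_inv, log_det_omega, segments, ob, resid);
  if (qcur >= BIG) { eta.zeros(); qcur = qfun(eta, typv, emap, omega_inv,
      log_det_omega, segments, ob, resid); }
  if (qcur >= BIG)
    return List::create(_["n2ll"] = BIG, _["eta"] = wrap(eta), _["converged"] = false);

  arma::mat J(ob.y.n_elem, k);
  arma::mat H(k, k);
  bool ok = true;
  for (int it = 0; it < 60; ++it) {
    if (!jac_eta(eta, typv, emap, segments, ob, J)) { ok = false; break; }
    arma::mat JS = J.each_col() / ob.sig2; // Sigma^-1 J
    H = J.t() * JS + omega_inv;
    arma::vec g = J.t() * (resid / ob.sig2) - omega_inv * eta; // -(grad q)/2
    arma::vec step;
    if (!arma::solve(step, H, g)) { ok = false; break; }
    double lam = 1.0;
    arma::vec rtry(ob.y.n_elem);
    double qtry = BIG;
    for (int ls = 0; ls < 12; ++ls) {
      arma::vec etry = eta + lam * step;
      qtry = qfun(etry, typv, emap, omega_inv, log_det_omega, segments, ob, rtry);
      if (qtry < qcur + 1e-14) { eta = etry; resid = rtry; break; }
      lam /= 2.0;
    }
    double dq = qcur - qtry;
    if (qtry < qcur) qcur = qtry;
    if (arma::norm(lam * step, 2) < 1e-8 || (dq >= 0 && dq < 1e-11)) break;
  }
  // Laplace correction with the Gauss-Newton Hessian at the mode
  if (ok && jac_eta(eta, typv, emap, segments, ob, J)) {
    arma::mat JS = J.each_col() / ob.sig2;
    H = J.t() * JS + omega_inv;
  } else {
    H = omega_inv;
    ok = false;
  }
  double ldH, sgn;
  arma::log_det(ldH, sgn, H);
  double n2ll = (sgn > 0 && std::isfinite(ldH))
    ? qcur - k * std::log(2.0 * M_PI) + ldH : BIG;
  return List::create(_["n2ll"] = n2ll, _["eta"] = wrap(eta),
                      _["converged"] = ok);
}
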