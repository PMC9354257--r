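// One-compartment oral PK kernel and Laplace-with-interaction marginal
// likelihood. All amounts mg, volumes L, times h; concentrations returned
// as ng/ml (mg/L * 1000).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Superposition of first-order absorption/elimination terms.
// Near ka ~ ke the bracketed difference cancels catastrophically; switch to
// the analytic ka->ke limit D*ka*tau/V * exp(-ka*tau) when |ka-ke|*tau is
// below tolerance.
static double conc_at(double t, const double* dt, const double* da, int nd,
                      double cl, double v, double ka) {
  const double ke = cl / v;
  const double diff = ka - ke;
  double c = 0.0;
  for (int i = 0; i < nd; ++i) {
    double tau = t - dt[i];
    if (tau < 0.0) continue;
    if (std::fabs(diff) * tau < 1e-9 || std::fabs(diff) < 1e-12 * ka) {
      c += da[i] * ka * tau / v * std::exp(-ka * tau);
    } else {
      c += da[i] * ka / (v * diff) * (std::exp(-ke * tau) - std::exp(-ka * tau));
    }
  }
  return c * 1000.0;  // mg/L -> ng/ml
}

// [[Rcpp::export]]
NumericVector conc_profile_cpp(NumericVector times, NumericVector dose_time,
                               NumericVector dose_amt, double cl, double v,
                               double ka) {
  const int n = times.size(), nd = dose_time.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = conc_at(times[i], dose_time.begin(), dose_amt.begin(), nd, cl, v, ka);
  return out;
}

// Trough matrix for a population of individuals sharing one regimen:
// rows = individuals (cl[i], v[i]), cols = eval_times.
// [[Rcpp::export]]
NumericMatrix sim_troughs_cpp(NumericVector eval_times, NumericVector dose_time,
                              NumericVector dose_amt, NumericVector cl,
                              NumericVector v, double ka) {
  const int n = cl.size(), m = eval_times.size(), nd = dose_time.size();
  NumericMatrix out(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      out(i, j) = conc_at(eval_times[j], dose_time.begin(), dose_amt.begin(),
                          nd, cl[i], v[i], ka);
  return out;
}

struct SubjView {
  const double* yt; const double* y; int ny;
  const double* dt; const double* da; int nd;
  double tvcl, tvv, ka, sp, sa;
  double om1, om2;
  bool a1, a2;  // omega > 0 => eta dimension active
};

// -2 log joint density (2*pi constants dropped, log det(Omega) excluded):
// sum_j [(y-f)^2/g + log g] + eta' diag(1/om^2) eta, with g evaluated at the
// individual prediction (the "interaction").
static double h_of(const SubjView& s, double e1, double e2) {
  const double cl = s.tvcl * std::exp(e1), v = s.tvv * std::exp(e2);
  double h = 0.0;
  for (int j = 0; j < s.ny; ++j) {
    double f = conc_at(s.yt[j], s.dt, s.da, s.nd, cl, v, s.ka);
    double g = f * f * s.sp * s.sp + s.sa * s.sa;
    if (g < 1e-12) g = 1e-12;
    const double r = s.y[j] - f;
    h += r * r / g + std::log(g);
  }
  if (s.a1) h += e1 * e1 / (s.om1 * s.om1);
  if (s.a2) h += e2 * e2 / (s.om2 * s.om2);
  return h;
}

static const double FD_STEP = 1e-4;

// Central-difference gradient and Hessian of h over the active dimensions.
static void fd_derivs(const SubjView& s, const double eta[2], const int* dims,
                      int nact, double h0, double g[2], double H[2][2]) {
  for (int a = 0; a < nact; ++a) {
    double ep[2] = {eta[0], eta[1]}, em[2] = {eta[0], eta[1]};
    ep[dims[a]] += FD_STEP; em[dims[a]] -= FD_STEP;
    const double hp = h_of(s, ep[0], ep[1]), hm = h_of(s, em[0], em[1]);
    g[a] = (hp - hm) / (2.0 * FD_STEP);
    H[a][a] = (hp - 2.0 * h0 + hm) / (FD_STEP * FD_STEP);
  }
  if (nact == 2) {
    const double hpp = h_of(s, eta[0] + FD_STEP, eta[1] + FD_STEP);
    const double hpm = h_of(s, eta[0] + FD_STEP, eta[1] - FD_STEP);
    const double hmp = h_of(s, eta[0] - FD_STEP, eta[1] + FD_STEP);
    const double hmm = h_of(s, eta[0] - FD_STEP, eta[1] - FD_STEP);
    H[0][1] = H[1][0] = (hpp - hpm - hmp + hmm) / (4.0 * FD_STEP * FD_STEP);
  }
}

// Damped Newton search for the conditional mode, cold-started at eta = 0.
static bool find_mode(const SubjView& s, double eta[2], double& hval) {
  int dims[2], nact = 0;
  if (s.a1) dims[nact++] = 0;
  if (s.a2) dims[nact++] = 1;
  eta[0] = eta[1] = 0.0;
  hval = h_of(s, 0.0, 0.0);
  if (nact == 0) return true;

  for (int iter = 0; iter < 200; ++iter) {
    double g[2] = {0, 0}, H[2][2] = {{0, 0}, {0, 0}};
    fd_derivs(s, eta, dims, nact, hval, g, H);
    const double gn = std::sqrt(g[0] * g[0] + g[1] * g[1]);
    if (gn < 1e-8 * (1.0 + std::fabs(hval))) return true;

    double d[2] = {0, 0};
    double lambda = 0.0;
    bool have_dir = false;
    for (int tries = 0; tries < 15 && !have_dir; ++tries) {
      if (nact == 1) {
        const double a11 = H[0][0] + lambda;
        if (a11 > 1e-10) { d[0] = -g[0] / a11; have_dir = true; }
      } else {
        const double a = H[0][0] + lambda, b = H[0][1], c = H[1][1] + lambda;
        const double det = a * c - b * b;
        if (a > 1e-10 && det > 1e-10) {
          d[0] = (-g[0] * c + g[1] * b) / det;
          d[1] = (-g[1] * a + g[0] * b) / det;
          have_dir = true;
        }
      }
      if (!have_dir) lambda = (lambda == 0.0) ? 1.0 : lambda * 10.0;
    }
    if (!have_dir) { d[0] = -g[0] / (1.0 + gn); d[1] = -g[1] / (1.0 + gn); }

    double t = 1.0;
    bool moved = false;
    for (int ls = 0; ls < 40; ++ls) {
      double cand[2] = {eta[0], eta[1]};
      for (int a = 0; a < nact; ++a) cand[dims[a]] += t * d[a];
      const double hc = h_of(s, cand[0], cand[1]);
      if (hc < hval - 1e-13) {
        eta[0] = cand[0]; eta[1] = cand[1]; hval = hc; moved = true; break;
      }
      t *= 0.5;
    }
    if (!moved) {
      // Newton direction failed: one steepest-descent rescue pass.
      t = 1.0 / (1.0 + gn);
      for (int ls = 0; ls < 40; ++ls) {
        double cand[2] = {eta[0], eta[1]};
        for (int a = 0; a < nact; ++a) cand[dims[a]] -= t * g[a];
        const double hc = h_of(s, cand[0], cand[1]);
        if (hc < hval - 1e-13) {
          eta[0] = cand[0]; eta[1] = cand[1]; hval = hc; moved = true; break;
        }
        t *= 0.5;
      }
      if (!moved) return true;  // numerically stationary
    }
  }
  return true;
}

// Gauss-Newton fallback for a non-PD mode Hessian: H/2 ~ G'R^-1 G + Omega^-1
// built from finite-difference sensitivities of f.
static void gn_hess(const SubjView& s, const double eta[2], const int* dims,
                    int nact, double Hh[2][2]) {
  std::vector<double> f0(s.ny), Gc(2 * s.ny, 0.0);
  {
    const double cl = s.tvcl * std::exp(eta[0]), v = s.tvv * std::exp(eta[1]);
    for (int j = 0; j < s.ny; ++j)
      f0[j] = conc_at(s.yt[j], s.dt, s.da, s.nd, cl, v, s.ka);
  }
  for (int a = 0; a < nact; ++a) {
    double ep[2] = {eta[0], eta[1]}, em[2] = {eta[0], eta[1]};
    ep[dims[a]] += FD_STEP; em[dims[a]] -= FD_STEP;
    const double clp = s.tvcl * std::exp(ep[0]), vp = s.tvv * std::exp(ep[1]);
    const double clm = s.tvcl * std::exp(em[0]), vm = s.tvv * std::exp(em[1]);
    for (int j = 0; j < s.ny; ++j) {
      const double fp = conc_at(s.yt[j], s.dt, s.da, s.nd, clp, vp, s.ka);
      const double fm = conc_at(s.yt[j], s.dt, s.da, s.nd, clm, vm, s.ka);
      Gc[a * s.ny + j] = (fp - fm) / (2.0 * FD_STEP);
    }
  }
  for (int a = 0; a < nact; ++a)
    for (int b = 0; b < nact; ++b) {
      double acc = 0.0;
      for (int j = 0; j < s.ny; ++j) {
        double g = f0[j] * f0[j] * s.sp * s.sp + s.sa * s.sa;
        if (g < 1e-12) g = 1e-12;
        acc += Gc[a * s.ny + j] * Gc[b * s.ny + j] / g;
      }
      Hh[a][b] = acc;
    }
  const double om[2] = {s.om1, s.om2};
  for (int a = 0; a < nact; ++a)
    Hh[a][a] += 1.0 / (om[dims[a]] * om[dims[a]]);
}

// Per-subject -2 log marginal likelihood, Laplace approximation at the
// conditional mode (NONMEM-style: all 2*pi constants dropped).
static double subject_ofv(const SubjView& s, double eta[2]) {
  int dims[2], nact = 0;
  if (s.a1) dims[nact++] = 0;
  if (s.a2) dims[nact++] = 1;

  double hval;
  find_mode(s, eta, hval);
  double ofv = hval;
  if (s.a1) ofv += std::log(s.om1 * s.om1);
  if (s.a2) ofv += std::log(s.om2 * s.om2);
  if (nact == 0) return ofv;

  double g[2] = {0, 0}, H[2][2] = {{0, 0}, {0, 0}};
  fd_derivs(s, eta, dims, nact, hval, g, H);
  double ld;  // log det(H/2) over active dims
  if (nact == 1) {
    double q = H[0][0] / 2.0;
    if (q <= 1e-12) {
      double Hh[2][2]; gn_hess(s, eta, dims, nact, Hh);
      q = Hh[0][0];
      if (q <= 1e-12) q = 1e-12;
    }
    ld = std::log(q);
  } else {
    double det = (H[0][0] / 2.0) * (H[1][1] / 2.0) -
                 (H[0][1] / 2.0) * (H[0][1] / 2.0);
    if (det <= 1e-12 || H[0][0] <= 0.0) {
      double Hh[2][2]; gn_hess(s, eta, dims, nact, Hh);
      det = Hh[0][0] * Hh[1][1] - Hh[0][1] * Hh[1][0];
      if (det <= 1e-12) det = 1e-12;
    }
    ld = std::log(det);
  }
  return ofv + ld;
}

// obs_ptr / dose_ptr: 0-based offsets of length n_subjects + 1.
// tvcl, tvv: per-subject typical values (allometry + covariates applied in R).
// [[Rcpp::export]]
List foce_cpp(NumericVector obs_time, NumericVector obs_dv, IntegerVector obs_ptr,
              NumericVector dose_time, NumericVector dose_amt, IntegerVector dose_ptr,
              NumericVector tvcl, NumericVector tvv, double ka,
              double om_cl, double om_v, double sg_prop, double sg_add) {
  const int n = tvcl.size();
  if (obs_ptr.size() != n + 1 || dose_ptr.size() != n + 1)
    stop("subject pointer arrays inconsistent with typical-value vectors");
  NumericVector ofv_i(n), eta_cl(n), eta_v(n);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    SubjView s;
    s.yt = obs_time.begin() + obs_ptr[i];
    s.y = obs_dv.begin() + obs_ptr[i];
    s.ny = obs_ptr[i + 1] - obs_ptr[i];
    s.dt = dose_time.begin() + dose_ptr[i];
    s.da = dose_amt.begin() + dose_ptr[i];
    s.nd = dose_ptr[i + 1] - dose_ptr[i];
    s.tvcl = tvcl[i]; s.tvv = tvv[i]; s.ka = ka;
    s.sp = sg_prop; s.sa = sg_add;
    s.om1 = om_cl; s.om2 = om_v;
    s.a1 = om_cl > 1e-8; s.a2 = om_v > 1e-8;
    if (s.ny < 1) stop("subject %d has no observations", i + 1);
    if (!(s.tvcl > 0.0) || !(s.tvv > 0.0) || !R_finite(s.tvcl) || !R_finite(s.tvv))
      stop("non-finite or non-positive typical values for subject %d", i + 1);
    double eta[2];
    const double o = subject_ofv(s, eta);
    if (!R_finite(o)) stop("non-finite objective contribution for subject %d", i + 1);
    ofv_i[i] = o; eta_cl[i] = eta[0]; eta_v[i] = eta[1];
    total += o;
  }
  return List::create(_["ofv"] = total, _["ofv_by_subject"] = ofv_i,
                      _["eta_cl"] = eta_cl, _["eta_v"] = eta_v);
}
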