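// Closed-form two-compartment kinetics for zero-order IV infusions and the
// FOCE-I marginal likelihood. The analytic solution (not ODE integration) is
// the production path throughout; speed matters because the estimation and
// Monte Carlo layers evaluate these kernels millions of times.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct Macro {
  double alpha, beta, A1, A2, Vc;
};

// Hybrid rate constants and partition coefficients from (CL, Vc, Vp, Q).
// alpha*beta = k10*k21, alpha+beta = k10+k12+k21, A1+A2 = 1.
static inline Macro macro_constants(double CL, double Vc, double Vp, double Q) {
  const double k10 = CL / Vc, k12 = Q / Vc, k21 = Q / Vp;
  const double s = k10 + k12 + k21;
  const double disc = std::sqrt(std::max(s * s - 4.0 * k10 * k21, 0.0));
  Macro m;
  m.alpha = 0.5 * (s + disc);
  m.beta  = 0.5 * (s - disc);
  m.A1 = (m.alpha - k21) / (m.alpha - m.beta);
  m.A2 = (k21 - m.beta) / (m.alpha - m.beta);
  m.Vc = Vc;
  return m;
}

// Central concentration at time t (>= 0) after the start of one zero-order
// infusion of `amt` over `dur` hours.
static inline double conc_one(const Macro &m, double amt, double dur, double t) {
  if (t <= 0.0 || amt <= 0.0) return 0.0;
  const double R0 = amt / dur;
  const double lam[2] = {m.alpha, m.beta};
  const double A[2] = {m.A1, m.A2};
  double c = 0.0;
  for (int k = 0; k < 2; ++k) {
    const double l = lam[k];
    if (t <= dur)
      c += A[k] * (1.0 - std::exp(-l * t)) / l;
    else
      c += A[k] * (1.0 - std::exp(-l * dur)) * std::exp(-l * (t - dur)) / l;
  }
  return R0 * c / m.Vc;
}

// [[Rcpp::export(name = ".cpp_conc")]]
arma::vec cpp_conc(double CL, double Vc, double Vp, double Q,
                   const arma::vec &dose_time, const arma::vec &dose_amt,
                   const arma::vec &dose_dur, const arma::vec &times) {
  const Macro m = macro_constants(CL, Vc, Vp, Q);
  vec out(times.n_elem, fill::zeros);
  for (uword i = 0; i < times.n_elem; ++i) {
    double c = 0.0;
    for (uword d = 0; d < dose_time.n_elem; ++d)
      c += conc_one(m, dose_amt(d), dose_dur(d), times(i) - dose_time(d));
    out(i) = c;
  }
  return out;
}

// Steady-state profile over one dosing interval [0, tau): the single-dose
// profile plus the geometric accumulation of both exponential terms,
// factor exp(-l*tau) / (1 - exp(-l*tau)) per eigenvalue.
// [[Rcpp::export(name = ".cpp_ss_conc")]]
arma::vec cpp_ss_conc(double CL, double Vc, double Vp, double Q,
                      double amt, double dur, double tau,
                      const arma::vec &times) {
  const Macro m = macro_constants(CL, Vc, Vp, Q);
  const double R0 = amt / dur;
  const double lam[2] = {m.alpha, m.beta};
  const double A[2] = {m.A1, m.A2};
  vec out(times.n_elem);
  for (uword i = 0; i < times.n_elem; ++i) {
    const double t = times(i);
    double c = conc_one(m, amt, dur, t);
    for (int k = 0; k < 2; ++k) {
      const double l = lam[k];
      const double acc = std::exp(-l * tau) / (1.0 - std::exp(-l * tau));
      c += (R0 / m.Vc) * A[k] * (1.0 - std::exp(-l * dur)) / l *
           std::exp(-l * (t - dur)) * acc;
    }
    out(i) = c;
  }
  return out;
}

// ---------------------------------------------------------------------------
// FOCE-I machinery
//
// Parameter model: p_k,i = theta_k * (1 + sum slope_j * (x_ij - ref_j)) *
// exp(eta_k,i) for k in {CL, Vc, Vp}; Q carries no random effect. Residual
// model: y = f * (1 + eps_prop) + eps_add (the "interaction": the residual
// variance is evaluated at the individual prediction).
// ---------------------------------------------------------------------------

struct SubjData {
  vec t, y;            // observations
  vec dt, da, dd;      // dose events: time, amount, duration
};

struct ModelSpec {
  vec theta;           // base CL, Vc, Vp, Q then covariate slopes
  ivec term_par;       // per slope: 0 CL, 1 Vc, 2 Vp, 3 Q
  ivec term_cov;       // per slope: covariate column in X
  vec term_ref;        // per slope: centering constant
  vec omega;           // SDs of eta on CL, Vc, Vp (>= 0)
  double sad, sprop;   // residual SDs
};

// Typical disposition parameters for subject row x; returns false if the
// linear covariate model leaves the admissible region.
static inline bool typical_pars(const ModelSpec &ms, const rowvec &x,
                                double out[4]) {
  double mult[4] = {1.0, 1.0, 1.0, 1.0};
  for (uword j = 0; j < ms.term_par.n_elem; ++j)
    mult[ms.term_par(j)] += ms.theta(4 + j) * (x(ms.term_cov(j)) - ms.term_ref(j));
  for (int k = 0; k < 4; ++k) {
    out[k] = ms.theta(k) * mult[k];
    if (!(out[k] > 0.0) || !std::isfinite(out[k])) return false;
  }
  return true;
}

static inline vec subj_conc(const SubjData &sd, const double tp[4],
                            const vec &eta3) {
  const double CL = tp[0] * std::exp(eta3(0));
  const double Vc = tp[1] * std::exp(eta3(1));
  const double Vp = tp[2] * std::exp(eta3(2));
  const Macro m = macro_constants(CL, Vc, Vp, tp[3]);
  vec f(sd.t.n_elem, fill::zeros);
  for (uword i = 0; i < sd.t.n_elem; ++i)
    for (uword d = 0; d < sd.dt.n_elem; ++d)
      f(i) += conc_one(m, sd.da(d), sd.dd(d), sd.t(i) - sd.dt(d));
  return f;
}

static inline vec res_var(const ModelSpec &ms, const vec &f) {
  vec g = square(ms.sprop * f) + ms.sad * ms.sad;
  g.transform([](double v) { return std::max(v, 1e-12); });
  return g;
}

// Penalized conditional objective h(eta) = sum[(y-f)^2/g + log g] + eta'inv(O)eta
static double inner_obj(const ModelSpec &ms, const SubjData &sd,
                        const double tp[4], const uvec &act, const vec &eta_act) {
  vec eta3(3, fill::zeros);
  eta3.elem(act) = eta_act;
  const vec f = subj_conc(sd, tp, eta3);
  const vec g = res_var(ms, f);
  double h = accu(square(sd.y - f) / g + log(g));
  for (uword k = 0; k < act.n_elem; ++k) {
    const double w = ms.omega(act(k));
    h += eta_act(k) * eta_act(k) / (w * w);
  }
  return h;
}

// Central finite-difference sensitivities of f with respect to active etas.
static mat eta_jacobian(const ModelSpec &ms, const SubjData &sd,
                        const double tp[4], const uvec &act, const vec &eta_act,
                        vec &f0) {
  const double h = 1e-4;
  vec eta3(3, fill::zeros);
  eta3.elem(act) = eta_act;
  f0 = subj_conc(sd, tp, eta3);
  mat F(sd.t.n_elem, act.n_elem);
  for (uword k = 0; k < act.n_elem; ++k) {
    vec ep = eta3, em = eta3;
    ep(act(k)) += h;
    em(act(k)) -= h;
    F.col(k) = (subj_conc(sd, tp, ep) - subj_conc(sd, tp, em)) / (2.0 * h);
  }
  return F;
}

// Damped Gauss-Newton search for the posterior mode of eta; returns
// convergence flag, mode in eta_act.
static bool inner_newton(const ModelSpec &ms, const SubjData &sd,
                         const double tp[4], const uvec &act, vec &eta_act,
                         const vec &eta_start) {
  const uword q = act.n_elem;
  eta_act = eta_start;
  double hval = inner_obj(ms, sd, tp, act, eta_act);
  if (!std::isfinite(hval)) {
    eta_act.zeros(q);
    hval = inner_obj(ms, sd, tp, act, eta_act);
    if (!std::isfinite(hval)) return false;
  }
  for (int iter = 0; iter < 100; ++iter) {
    vec f0;
    mat F = eta_jacobian(ms, sd, tp, act, eta_act, f0);
    const vec g = res_var(ms, f0);
    const vec r = sd.y - f0;
    // gradient of h; g depends on f through the proportional term
    vec grad(q, fill::zeros);
    for (uword k = 0; k < q; ++k) {
      const vec dg = 2.0 * ms.sprop * ms.sprop * (f0 % F.col(k));
      grad(k) = accu(-2.0 * r % F.col(k) / g - square(r) % dg / square(g) + dg / g);
      const double w = ms.omega(act(k));
      grad(k) += 2.0 * eta_act(k) / (w * w);
    }
    if (norm(grad, "inf") < 1e-6) return true;
    mat H = 2.0 * F.t() * diagmat(1.0 / g) * F;
    for (uword k = 0; k < q; ++k) {
      const double w = ms.omega(act(k));
      H(k, k) += 2.0 / (w * w);
    }
    vec step;
    if (!solve(step, H, -grad, solve_opts::likely_sympd + solve_opts::no_approx))
      step = -grad / (norm(H, "inf") + 1.0);
    // backtracking line search
    double sc = 1.0;
    bool moved = false;
    for (int ls = 0; ls < 12; ++ls) {
      vec trial = eta_act + sc * step;
      double ht = inner_obj(ms, sd, tp, act, trial);
      if (std::isfinite(ht) && ht < hval) {
        eta_act = trial;
        hval = ht;
        moved = true;
        break;
      }
      sc *= 0.5;
    }
    if (!moved) return norm(grad, "inf") < 1e-2;
  }
  return false;
}

// FOCE-I objective for one cohort. Returns -2 log (approximate) marginal
// likelihood including the 2*pi constants, plus empirical Bayes estimates.
// [[Rcpp::export(name = ".cpp_foce")]]
Rcpp::List cpp_foce(const arma::vec &theta, const arma::ivec &term_par,
                    const arma::ivec &term_cov, const arma::vec &term_ref,
                    const arma::vec &omega, double sad, double sprop,
                    const arma::ivec &obs_subj, const arma::vec &obs_t,
                    const arma::vec &obs_y, const arma::ivec &dose_subj,
                    const arma::vec &dose_t, const arma::vec &dose_amt,
                    const arma::vec &dose_dur, const arma::mat &X,
                    bool details, const arma::mat &eta_start) {
  const uword n = X.n_rows;
  ModelSpec ms{theta, term_par, term_cov, term_ref, omega, sad, sprop};
  const uvec act = find(omega > 0.0);
  const uword q = act.n_elem;

  // bucket observations / doses by subject
  std::vector<SubjData> sub(n);
  {
    std::vector<std::vector<uword>> oi(n), di(n);
    for (uword i = 0; i < obs_subj.n_elem; ++i) oi[obs_subj(i)].push_back(i);
    for (uword i = 0; i < dose_subj.n_elem; ++i) di[dose_subj(i)].push_back(i);
    for (uword s = 0; s < n; ++s) {
      sub[s].t.set_size(oi[s].size());
      sub[s].y.set_size(oi[s].size());
      for (size_t k = 0; k < oi[s].size(); ++k) {
        sub[s].t(k) = obs_t(oi[s][k]);
        sub[s].y(k) = obs_y(oi[s][k]);
      }
      sub[s].dt.set_size(di[s].size());
      sub[s].da.set_size(di[s].size());
      sub[s].dd.set_size(di[s].size());
      for (size_t k = 0; k < di[s].size(); ++k) {
        sub[s].dt(k) = dose_t(di[s][k]);
        sub[s].da(k) = dose_amt(di[s][k]);
        sub[s].dd(k) = dose_dur(di[s][k]);
      }
    }
  }

  double ofv = 0.0;
  mat etas(n, 3, fill::zeros);
  mat ebe_details;
  std::vector<vec> ipred_store(details ? n : 0), cw_store(details ? n : 0);
  Rcpp::LogicalVector conv(n);
  bool ok = true;
  const double LOG2PI = std::log(2.0 * M_PI);

  for (uword s = 0; s < n; ++s) {
    double tp[4];
    if (!typical_pars(ms, X.row(s), tp)) { ok = false; break; }
    const uword ni = sub[s].t.n_elem;
    if (ni == 0) { conv(s) = true; continue; }

    if (q == 0) {
      const vec f = subj_conc(sub[s], tp, vec(3, fill::zeros));
      const vec g = res_var(ms, f);
      ofv += accu(square(sub[s].y - f) / g + log(g)) + ni * LOG2PI;
      conv(s) = true;
      if (details) {
        ipred_store[s] = f;
        cw_store[s] = (sub[s].y - f) / sqrt(g);
      }
      continue;
    }

    vec eta_act;
    vec e0(q, fill::zeros);
    if (eta_start.n_rows == n && eta_start.n_cols == 3) {
      for (uword k = 0; k < q; ++k) e0(k) = eta_start(s, act(k));
    }
    conv(s) = inner_newton(ms, sub[s], tp, act, eta_act, e0);
    vec f0;
    mat F = eta_jacobian(ms, sub[s], tp, act, eta_act, f0);
    if (!f0.is_finite() || !F.is_finite()) { ok = false; break; }
    const vec g = res_var(ms, f0);
    vec om2(q);
    for (uword k = 0; k < q; ++k) om2(k) = ms.omega(act(k)) * ms.omega(act(k));
    mat V = F * diagmat(om2) * F.t() + diagmat(g);
    V = 0.5 * (V + V.t());
    const vec r = sub[s].y - f0 + F * eta_act;
    mat L;
    if (!chol(L, V, "lower")) { ok = false; break; }
    vec z;
    if (!solve(z, trimatl(L), r, solve_opts::no_approx)) { ok = false; break; }
    ofv += 2.0 * accu(log(L.diag())) + dot(z, z) + ni * LOG2PI;
    vec eta3(3, fill::zeros);
    eta3.elem(act) = eta_act;
    etas.row(s) = eta3.t();
    if (details) {
      ipred_store[s] = f0;
      cw_store[s] = z;  // decorrelated FOCE residuals (CWRES)
    }
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("ofv") = ok ? ofv : R_PosInf,
      Rcpp::Named("ok") = ok,
      Rcpp::Named("eta") = etas,
      Rcpp::Named("conv") = conv);
  if (details && ok) {
    vec ipred(obs_subj.n_elem), cwres(obs_subj.n_elem);
    std::vector<uword> pos(n, 0);
    std::vector<std::vector<uword>> oi(n);
    for (uword i = 0; i < obs_subj.n_elem; ++i) {
      const uword s = obs_subj(i);
      ipred(i) = ipred_store[s](pos[s]);
      cwres(i) = cw_store[s](pos[s]);
      ++pos[s];
    }
    out["ipred"] = ipred;
    out["cwres"] = cwres;
  }
  return out;
}
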