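// Method-of-steps integrator for delay differential equations.
//
// Fixed-step classical RK4; delayed state lookups go through cubic Hermite
// interpolation of the stored solution (value + derivative at every accepted
// grid point), and through the history function for t <= t0.  The step size
// must not exceed the smallest delay, so every lookup lands in the already
// stored part of the solution (method of steps).
//
// Two models are compiled in for speed (the conceptual two-loop oscillator
// and the comprehensive six-gene oscillator); arbitrary R-level right-hand
// sides are supported through a callback path used for small test problems.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Hill repression: fraction of maximal activity remaining at repressor x.
static inline double hill_rep(double x, double K, double h) {
  if (x <= 0.0) return 1.0;
  double r = std::pow(x / K, h);
  return 1.0 / (1.0 + r);
}

// Hill activation by activator x.
static inline double hill_act(double x, double K, double h) {
  if (x <= 0.0) return 0.0;
  double r = std::pow(x / K, h);
  return r / (1.0 + r);
}

// ---------------------------------------------------------------------------
// Dense solution store with cubic Hermite evaluation.

struct DenseStore {
  double t0, dt;
  int nvar;
  std::vector<double> Y;  // (nstored) x nvar, row-major
  std::vector<double> F;  // derivatives at the same knots
  const double* hist;     // constant history vector (nvar)

  int nstored() const { return (int)(Y.size() / nvar); }

  // y(t) for t <= current front; history for t <= t0.
  void eval(double t, double* out) const {
    if (t <= t0) {
      for (int j = 0; j < nvar; ++j) out[j] = hist[j];
      return;
    }
    double s = (t - t0) / dt;
    int k = (int)std::floor(s);
    int last = nstored() - 1;
    if (k >= last) {  // at (or numerically past) the stored front
      for (int j = 0; j < nvar; ++j) out[j] = Y[(size_t)last * nvar + j];
      return;
    }
    double u = s - k;  // in [0,1)
    if (u < 1e-12) {
      for (int j = 0; j < nvar; ++j) out[j] = Y[(size_t)k * nvar + j];
      return;
    }
    double u2 = u * u, u3 = u2 * u;
    double h00 = 2 * u3 - 3 * u2 + 1;
    double h10 = u3 - 2 * u2 + u;
    double h01 = -2 * u3 + 3 * u2;
    double h11 = u3 - u2;
    const double* y0 = &Y[(size_t)k * nvar];
    const double* y1 = &Y[(size_t)(k + 1) * nvar];
    const double* f0 = &F[(size_t)k * nvar];
    const double* f1 = &F[(size_t)(k + 1) * nvar];
    for (int j = 0; j < nvar; ++j)
      out[j] = h00 * y0[j] + h10 * dt * f0[j] + h01 * y1[j] + h11 * dt * f1[j];
  }
};

// ---------------------------------------------------------------------------
// Compiled right-hand sides.
//
// Conceptual parameter order (see conceptual_params() on the R side):
//   0 v_P, 1 v_A, 2 K1, 3 K2, 4 h, 5 c, 6 d1, 7 d2, 8 tau_P, 9 tau_A,
//   10 al_enabled, 11 amp_scale_P, 12 amp_scale_A
// States: 0 R1, 1 R2.  R1 protein acts with delay tau_P; R2 protein acts on
// the ALBS with delay tau_A (the RORE phase runs later than the E-box).
//
// The normalized element activities (occupancy-style, in [0, 1]) are the
// Hill factors, optionally re-scaled about the half-activity midpoint by
// amp_scale_P / amp_scale_A.  At scale 1 (the default) the activities are
// exactly the Hill factors; the scales implement the in-silico amplitude
// manipulation of the binding-element activities.
static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}
static inline double plbs_eff(const double* ylagP, const double* p) {
  return clamp01(0.5 + p[11] * (hill_rep(ylagP[0], p[2], p[4]) - 0.5));
}
static inline double albs_eff(const double* ylagA, const double* p) {
  if (p[10] <= 0.5) return 0.0;
  return clamp01(0.5 + p[12] * (hill_rep(ylagA[1], p[3], p[4]) - 0.5));
}

static void conceptual_rhs_c(const double* y, const double* ylagP,
                             const double* ylagA, const double* p,
                             double* dy) {
  double plbs = plbs_eff(ylagP, p);
  double albs = albs_eff(ylagA, p);
  dy[0] = p[0] * plbs + p[1] * albs - p[6] * y[0];
  dy[1] = p[5] * p[0] * plbs - p[7] * y[1];
}

static void conceptual_signals(const double* ylagP, const double* ylagA,
                               const double* p, double* sig) {
  sig[0] = plbs_eff(ylagP, p);  // PLBS activity
  sig[1] = albs_eff(ylagA, p);  // ALBS activity
}

// Comprehensive parameter order (see comprehensive_params() on the R side):
//   0 v_B, 1 v_P1, 2 v_P2, 3 v_C1, 4 v_C1r, 5 v_C2, 6 v_R,
//   7 K_B, 8 h_B, 9 K_E, 10 w_P1, 11 w_P2, 12 w_C1, 13 w_C2, 14 h_E,
//   15 K_R, 16 h_R, 17 a_E, 18 a_R,
//   19 d_B, 20 d_P1, 21 d_P2, 22 d_C1, 23 d_C2, 24 d_R,
//   25 tau_P, 26 tau_B, 27 tau_R, 28 tau_RC,
//   29..34 b_B, b_P1, b_P2, b_C1, b_C2, b_R (constitutive production),
//   35 amp_scale_P, 36 amp_scale_A (element-activity modulation scaling,
//      as in the conceptual model; clamped to [0, 1])
//
// tau_R is the fast REV-ERBa action at the Bmal1 promoter RORE; tau_RC is
// the slow corepressor-complex action at the Cry1 intronic RORE, whose
// repressor-binding peak runs late.
// States: 0 Bmal1, 1 Per1, 2 Per2, 3 Cry1, 4 Cry2, 5 Rev.
// PER/CRY repressors act with the long post-transcriptional delay tau_P;
// BMAL1 (activator) and REV-ERBa (RORE repressor) act fast (tau_B, tau_R),
// which places RORE activity in antiphase to the E-box and gives Cry1 its
// late phase.
static inline void comp_elements(const double* ylagP, const double* ylagB,
                                 const double* ylagR, const double* ylagRC,
                                 const double* p, double* plbs, double* rore,
                                 double* roreC) {
  double act = hill_act(ylagB[0], p[7], p[8]);
  double pool = p[10] * ylagP[1] + p[11] * ylagP[2] + p[12] * ylagP[3] +
                p[13] * ylagP[4];
  double rep = hill_rep(pool, p[9], p[14]);
  // element activities, re-scaled about the half-activity midpoint by the
  // in-silico amplitude manipulation
  *plbs = clamp01(0.5 + p[35] * (act * rep - 0.5));
  *rore = clamp01(0.5 + p[36] * (hill_rep(ylagR[5], p[15], p[16]) - 0.5));
  *roreC = clamp01(0.5 + p[36] * (hill_rep(ylagRC[5], p[15], p[16]) - 0.5));
}

static void comprehensive_rhs_c(const double* y, const double* ylagP,
                                const double* ylagB, const double* ylagR,
                                const double* ylagRC, const double* p,
                                double* dy) {
  double plbs, rore, roreC;
  comp_elements(ylagP, ylagB, ylagR, ylagRC, p, &plbs, &rore, &roreC);
  dy[0] = p[0] * rore + p[29] - p[19] * y[0];                       // Bmal1
  dy[1] = p[1] * plbs + p[30] - p[20] * y[1];                       // Per1
  dy[2] = p[2] * plbs + p[31] - p[21] * y[2];                       // Per2
  dy[3] = p[17] * p[3] * plbs + p[18] * p[4] * roreC + p[32] -
          p[22] * y[3];                                             // Cry1
  dy[4] = p[5] * plbs + p[33] - p[23] * y[4];                       // Cry2
  dy[5] = p[6] * plbs + p[34] - p[24] * y[5];                       // Rev
}

// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List dde_integrate_compiled(int model, NumericVector params,
                            NumericVector history, double t0, double t1,
                            double dt) {
  int nvar = (model == 1) ? 2 : 6;
  if (history.size() != nvar) stop("history length does not match model");
  const double* p = params.begin();
  double tauP = (model == 1) ? p[8] : p[25];
  double tauB = (model == 1) ? p[9] : p[26];  // tau_A / tau_B second delay
  double tauR = (model == 1) ? tauP : p[27];
  double tauRC = (model == 1) ? tauP : p[28];

  int nstep = (int)std::llround((t1 - t0) / dt);
  DenseStore store;
  store.t0 = t0;
  store.dt = dt;
  store.nvar = nvar;
  store.hist = history.begin();
  store.Y.reserve((size_t)(nstep + 1) * nvar);
  store.F.reserve((size_t)(nstep + 1) * nvar);

  std::vector<double> y(history.begin(), history.end());
  std::vector<double> lagP(nvar), lagB(nvar), lagR(nvar), lagRC(nvar),
      dy(nvar), k1(nvar), k2(nvar), k3(nvar), k4(nvar), ytmp(nvar);

  // derivative at (t, ystate) using the store (and history) for lags
  auto deriv = [&](double t, const double* ystate, double* out) {
    store.eval(t - tauP, lagP.data());
    store.eval(t - tauB, lagB.data());
    if (model == 1) {
      conceptual_rhs_c(ystate, lagP.data(), lagB.data(), p, out);
    } else {
      store.eval(t - tauR, lagR.data());
      store.eval(t - tauRC, lagRC.data());
      comprehensive_rhs_c(ystate, lagP.data(), lagB.data(), lagR.data(),
                          lagRC.data(), p, out);
    }
  };

  // knot 0
  deriv(t0, y.data(), k1.data());
  for (int j = 0; j < nvar; ++j) {
    store.Y.push_back(y[j]);
    store.F.push_back(k1[j]);
  }

  for (int i = 0; i < nstep; ++i) {
    double t = t0 + i * dt;
    const double* f0 = &store.F[(size_t)i * nvar];  // already computed
    for (int j = 0; j < nvar; ++j) ytmp[j] = y[j] + 0.5 * dt * f0[j];
    deriv(t + 0.5 * dt, ytmp.data(), k2.data());
    for (int j = 0; j < nvar; ++j) ytmp[j] = y[j] + 0.5 * dt * k2[j];
    deriv(t + 0.5 * dt, ytmp.data(), k3.data());
    for (int j = 0; j < nvar; ++j) ytmp[j] = y[j] + dt * k3[j];
    deriv(t + dt, ytmp.data(), k4.data());
    for (int j = 0; j < nvar; ++j)
      y[j] += dt / 6.0 * (f0[j] + 2 * k2[j] + 2 * k3[j] + k4[j]);
    for (int j = 0; j < nvar; ++j)
      if (!std::isfinite(y[j]))
        stop("integration failure (non-finite state) at t = %g", t + dt);
    // provisional derivative at the new knot so in-step lookups can use it;
    // it is exact because it depends only on earlier solution values
    for (int j = 0; j < nvar; ++j) store.Y.push_back(y[j]);
    deriv(t + dt, y.data(), dy.data());
    for (int j = 0; j < nvar; ++j) store.F.push_back(dy[j]);
  }

  // time grid + derived cis-element activity signals from the same store
  NumericVector time(nstep + 1);
  NumericMatrix Y(nstep + 1, nvar), S(nstep + 1, 2), Fm(nstep + 1, nvar);
  for (int i = 0; i <= nstep; ++i) {
    double t = t0 + i * dt;
    time[i] = t;
    for (int j = 0; j < nvar; ++j) {
      Y(i, j) = store.Y[(size_t)i * nvar + j];
      Fm(i, j) = store.F[(size_t)i * nvar + j];
    }
    store.eval(t - tauP, lagP.data());
    store.eval(t - tauB, lagB.data());
    if (model == 1) {
      double sig[2];
      conceptual_signals(lagP.data(), lagB.data(), p, sig);
      S(i, 0) = sig[0];
      S(i, 1) = sig[1];
    } else {
      store.eval(t - tauR, lagR.data());
      store.eval(t - tauRC, lagRC.data());
      double plbs, rore, roreC;
      comp_elements(lagP.data(), lagB.data(), lagR.data(), lagRC.data(), p,
                    &plbs, &rore, &roreC);
      S(i, 0) = plbs;
      S(i, 1) = rore;
    }
  }
  return List::create(_["time"] = time, _["states"] = Y, _["derivs"] = Fm,
                      _["signals"] = S);
}

// Generic path: rhs is an R function f(t, y, ylag) where ylag is an
// nvar x ndelay matrix of delayed states (zero columns when no delays).
// [[Rcpp::export]]
List dde_integrate_callback(Function rhs, NumericVector delays,
                            NumericVector history, double t0, double t1,
                            double dt) {
  int nvar = history.size();
  int ndel = delays.size();
  int nstep = (int)std::llround((t1 - t0) / dt);

  DenseStore store;
  store.t0 = t0;
  store.dt = dt;
  store.nvar = nvar;
  store.hist = history.begin();
  store.Y.reserve((size_t)(nstep + 1) * nvar);
  store.F.reserve((size_t)(nstep + 1) * nvar);

  std::vector<double> y(history.begin(), history.end());
  std::vector<double> lag(nvar);

  auto deriv = [&](double t, NumericVector ystate) -> NumericVector {
    NumericMatrix ylag(nvar, ndel);
    for (int d = 0; d < ndel; ++d) {
      store.eval(t - delays[d], lag.data());
      for (int j = 0; j < nvar; ++j) ylag(j, d) = lag[j];
    }
    NumericVector out = rhs(t, ystate, ylag);
    if (out.size() != nvar) stop("rhs returned wrong length");
    return out;
  };

  NumericVector ycur(y.begin(), y.end());
  NumericVector f0 = deriv(t0, ycur);
  for (int j = 0; j < nvar; ++j) {
    store.Y.push_back(ycur[j]);
    store.F.push_back(f0[j]);
  }

  for (int i = 0; i < nstep; ++i) {
    double t = t0 + i * dt;
    NumericVector k1(nvar);
    for (int j = 0; j < nvar; ++j) k1[j] = store.F[(size_t)i * nvar + j];
    NumericVector ytmp(nvar);
    for (int j = 0; j < nvar; ++j) ytmp[j] = ycur[j] + 0.5 * dt * k1[j];
    NumericVector k2 = deriv(t + 0.5 * dt, ytmp);
    for (int j = 0; j < nvar; ++j) ytmp[j] = ycur[j] + 0.5 * dt * k2[j];
    NumericVector k3 = deriv(t + 0.5 * dt, ytmp);
    for (int j = 0; j < nvar; ++j) ytmp[j] = ycur[j] + dt * k3[j];
    NumericVector k4 = deriv(t + dt, ytmp);
    for (int j = 0; j < nvar; ++j) {
      ycur[j] += dt / 6.0 * (k1[j] + 2 * k2[j] + 2 * k3[j] + k4[j]);
      if (!std::isfinite(ycur[j]))
        stop("integration failure (non-finite state) at t = %g", t + dt);
      store.Y.push_back(ycur[j]);
    }
    NumericVector fn = deriv(t + dt, ycur);
    for (int j = 0; j < nvar; ++j) store.F.push_back(fn[j]);
  }

  NumericVector time(nstep + 1);
  NumericMatrix Y(nstep + 1, nvar), Fm(nstep + 1, nvar);
  for (int i = 0; i <= nstep; ++i) {
    time[i] = t0 + i * dt;
    for (int j = 0; j < nvar; ++j) {
      Y(i, j) = store.Y[(size_t)i * nvar + j];
      Fm(i, j) = store.F[(size_t)i * nvar + j];
    }
  }
  return List::create(_["time"] = time, _["states"] = Y, _["derivs"] = Fm);
}

// Cubic Hermite evaluation of a stored trajectory at arbitrary times
// (history value before t0).  Used for delayed-lookup consistency checks
// and post-hoc dense evaluation.
// [[Rcpp::export]]
NumericMatrix dense_eval(NumericVector time, NumericMatrix Y, NumericMatrix F,
                         NumericVector history, NumericVector at) {
  int nvar = Y.ncol();
  int n = time.size();
  double t0 = time[0];
  double dt = time[1] - time[0];
  DenseStore store;
  store.t0 = t0;
  store.dt = dt;
  store.nvar = nvar;
  store.hist = history.begin();
  store.Y.assign((size_t)n * nvar, 0.0);
  store.F.assign((size_t)n * nvar, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < nvar; ++j) {
      store.Y[(size_t)i * nvar + j] = Y(i, j);
      store.F[(size_t)i * nvar + j] = F(i, j);
    }
  NumericMatrix out(at.size(), nvar);
  std::vector<double> buf(nvar);
  for (int i = 0; i < at.size(); ++i) {
    store.eval(at[i], buf.data());
    for (int j = 0; j < nvar; ++j) out(i, j) = buf[j];
  }
  return out;
}
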