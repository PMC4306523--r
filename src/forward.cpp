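#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bilinear neural dynamics integrated with classical RK4.
//   dx/dt = (A + sum_j u_j(t) B_j) x + C u(t)
// Inputs are treated as piecewise constant on each integration step
// [ (k-1)dt, k dt ): within a step the system is linear time-invariant and
// RK4 approximates its exponential propagator to 4th order.
//
// A: n x n, B: n x n x m (flattened, column-major), C: n x m,
// U: T x m (row k = inputs on step k), x0: n.
// Returns X: (T+1) x n, row 1 = x0 (state at t = 0), row k+1 = state at k*dt.

static inline void neural_deriv(int n, int m,
                                const double* A, const double* B,
                                const double* C, const double* u,
                                const double* x, double* dx) {
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int j = 0; j < n; ++j) {
      double a = A[i + n * j];
      for (int l = 0; l < m; ++l) {
        double b = B[i + n * j + n * n * l];
        if (b != 0.0) a += u[l] * b;
      }
      acc += a * x[j];
    }
    for (int l = 0; l < m; ++l) acc += C[i + n * l] * u[l];
    dx[i] = acc;
  }
}

// [[Rcpp::export(name = ".neural_rk4_cpp")]]
List neural_rk4_cpp(NumericMatrix A, NumericVector B, NumericMatrix C,
                    NumericMatrix U, NumericVector x0, double dt) {
  const int n = A.nrow(), m = U.ncol(), T = U.nrow();
  NumericMatrix X(T + 1, n);
  std::vector<double> x(n), k1(n), k2(n), k3(n), k4(n), xt(n), u(m);
  for (int i = 0; i < n; ++i) { x[i] = x0[i]; X(0, i) = x0[i]; }
  const double* Ap = REAL(A); const double* Bp = REAL(B);
  const double* Cp = REAL(C);
  bool ok = true; double bad_time = NA_REAL;
  for (int k = 0; k < T; ++k) {
    for (int l = 0; l < m; ++l) u[l] = U(k, l);
    neural_deriv(n, m, Ap, Bp, Cp, u.data(), x.data(), k1.data());
    for (int i = 0; i < n; ++i) xt[i] = x[i] + 0.5 * dt * k1[i];
    neural_deriv(n, m, Ap, Bp, Cp, u.data(), xt.data(), k2.data());
    for (int i = 0; i < n; ++i) xt[i] = x[i] + 0.5 * dt * k2[i];
    neural_deriv(n, m, Ap, Bp, Cp, u.data(), xt.data(), k3.data());
    for (int i = 0; i < n; ++i) xt[i] = x[i] + dt * k3[i];
    neural_deriv(n, m, Ap, Bp, Cp, u.data(), xt.data(), k4.data());
    for (int i = 0; i < n; ++i) {
      x[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      X(k + 1, i) = x[i];
    }
    if (ok) {
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(x[i]) || std::fabs(x[i]) > 1e6) {
          ok = false; bad_time = (k + 1) * dt; break;
        }
    }
  }
  return List::create(_["x"] = X, _["ok"] = ok, _["bad_time"] = bad_time);
}

// Balloon-Windkessel hemodynamics per region, driven by neural activity x(t):
//   s' = epsilon x - kappa s - gamma (f - 1)
//   f' = s
//   tau v' = f - v^(1/alpha)
//   tau q' = f (1 - (1-E0)^(1/f)) / E0 - v^(1/alpha) q / v
//   y = V0 (k1 (1 - q) + k2 (1 - q/v) + k3 (1 - v))
// x supplied on the same grid as the integration (rows = t = 0, dt, ...);
// RK4 midpoints use linear interpolation of x.

struct HemoPar {
  double epsilon, kappa, gamma, tau, alpha, E0, V0, k1, k2, k3;
  double inv_alpha, inv_tau, inv_E0, log1mE0; // derived, set once
  void derive() {
    inv_alpha = 1.0 / alpha; inv_tau = 1.0 / tau; inv_E0 = 1.0 / E0;
    log1mE0 = std::log(1.0 - E0);
  }
};

static inline void hemo_deriv(const HemoPar& h, double x, const double* st,
                              double* d) {
  double s = st[0], f = st[1], v = st[2], q = st[3];
  if (f < 1e-6) f = 1e-6;
  if (v < 1e-6) v = 1e-6;
  // v^(1/alpha) and (1-E0)^(1/f) via exp/log with precomputed constants
  double fv = std::exp(h.inv_alpha * std::log(v));   // outflow
  double ef = 1.0 - std::exp(h.log1mE0 / f);         // O2 extraction
  d[0] = h.epsilon * x - h.kappa * s - h.gamma * (f - 1.0);
  d[1] = s;
  d[2] = (f - fv) * h.inv_tau;
  d[3] = (f * ef * h.inv_E0 - fv * q / v) * h.inv_tau;
}

// [[Rcpp::export(name = ".balloon_rk4_cpp")]]
List balloon_rk4_cpp(NumericMatrix Xn, double dt,
                     double epsilon, double kappa, double gamma_, double tau,
                     double alpha, double E0, double V0, double k1c,
                     double k2c, double k3c, bool keep_states) {
  const int T = Xn.nrow() - 1, n = Xn.ncol();
  HemoPar h{epsilon, kappa, gamma_, tau, alpha, E0, V0, k1c, k2c, k3c};
  h.derive();
  NumericMatrix Y(T + 1, n);
  NumericMatrix S(keep_states ? T + 1 : 1, keep_states ? 4 * n : 1);
  std::vector<double> st(4), k1(4), k2(4), k3(4), k4(4), stt(4);
  bool ok = true; double bad_time = NA_REAL;
  for (int r = 0; r < n; ++r) {
    st[0] = 0.0; st[1] = 1.0; st[2] = 1.0; st[3] = 1.0; // rest
    Y(0, r) = 0.0;
    if (keep_states) for (int a = 0; a < 4; ++a) S(0, 4 * r + a) = st[a];
    for (int k = 0; k < T; ++k) {
      double x0 = Xn(k, r), x1 = Xn(k + 1, r), xm = 0.5 * (x0 + x1);
      hemo_deriv(h, x0, st.data(), k1.data());
      for (int a = 0; a < 4; ++a) stt[a] = st[a] + 0.5 * dt * k1[a];
      hemo_deriv(h, xm, stt.data(), k2.data());
      for (int a = 0; a < 4; ++a) stt[a] = st[a] + 0.5 * dt * k2[a];
      hemo_deriv(h, xm, stt.data(), k3.data());
      for (int a = 0; a < 4; ++a) stt[a] = st[a] + dt * k3[a];
      hemo_deriv(h, x1, stt.data(), k4.data());
      for (int a = 0; a < 4; ++a)
        st[a] += dt / 6.0 * (k1[a] + 2.0 * k2[a] + 2.0 * k3[a] + k4[a]);
      double v = st[2] < 1e-6 ? 1e-6 : st[2], q = st[3];
      Y(k + 1, r) = 100.0 * h.V0 *
        (h.k1 * (1.0 - q) + h.k2 * (1.0 - q / v) + h.k3 * (1.0 - v));
      if (keep_states) for (int a = 0; a < 4; ++a) S(k + 1, 4 * r + a) = st[a];
      if (ok && (!std::isfinite(Y(k + 1, r)) || std::fabs(st[2]) > 1e6)) {
        ok = false; bad_time = (k + 1) * dt;
      }
    }
  }
  return List::create(_["y"] = Y, _["states"] = S, _["ok"] = ok,
                      _["bad_time"] = bad_time);
}

// Fused forward model used by the inversion hot loop: neural RK4 and balloon
// RK4 in one pass, returning BOLD (percent signal change) only at the
// requested grid rows (1-based indices into the t = 0, dt, 2dt, ... grid).

// [[Rcpp::export(name = ".dcm_forward_cpp")]]
List dcm_forward_cpp(NumericMatrix A, NumericVector B, NumericMatrix C,
                     NumericMatrix U, double dt,
                     NumericVector hemo, IntegerVector vol_idx) {
  const int n = A.nrow(), m = U.ncol(), T = U.nrow(), nv = vol_idx.size();
  HemoPar h{hemo[0], hemo[1], hemo[2], hemo[3], hemo[4], hemo[5],
            hemo[6], hemo[7], hemo[8], hemo[9]};
  h.derive();
  const double* Ap = REAL(A); const double* Bp = REAL(B);
  const double* Cp = REAL(C);
  std::vector<double> x(n, 0.0), k1(n), k2(n), k3(n), k4(n), xt(n), u(m);
  std::vector<double> hs(4 * n), h1(4), h2(4), h3(4), h4(4), ht(4);
  for (int r = 0; r < n; ++r) {
    hs[4 * r] = 0.0; hs[4 * r + 1] = 1.0; hs[4 * r + 2] = 1.0; hs[4 * r + 3] = 1.0;
  }
  NumericMatrix Y(nv, n);
  std::vector<int> want(T + 1, -1);
  for (int i = 0; i < nv; ++i) {
    int g = vol_idx[i] - 1;
    if (g < 0 || g > T) stop("volume index outside integration grid");
    want[g] = i;
  }
  bool ok = true; double bad_time = NA_REAL;
  if (want[0] >= 0) for (int r = 0; r < n; ++r) Y(want[0], r) = 0.0;
  for (int k = 0; k < T; ++k) {
    for (int l = 0; l < m; ++l) u[l] = U(k, l);
    // neural step
    neural_deriv(n, m, Ap, Bp, Cp, u.data(), x.data(), k1.data());
    for (int i = 0; i < n; ++i) xt[i] = x[i] + 0.5 * dt * k1[i];
    neural_deriv(n, m, Ap, Bp, Cp, u.data(), xt.data(), k2.data());
    for (int i = 0; i < n; ++i) xt[i] = x[i] + 0.5 * dt * k2[i];
    neural_deriv(n, m, Ap, Bp, Cp, u.data(), xt.data(), k3.data());
    for (int i = 0; i < n; ++i) xt[i] = x[i] + dt * k3[i];
    neural_deriv(n, m, Ap, Bp, Cp, u.data(), xt.data(), k4.data());
    for (int r = 0; r < n; ++r) {
      double x_old = x[r];
      double x_new = x_old + dt / 6.0 *
        (k1[r] + 2.0 * k2[r] + 2.0 * k3[r] + k4[r]);
      double xm = 0.5 * (x_old + x_new);
      // hemodynamic step for this region
      double* st = &hs[4 * r];
      hemo_deriv(h, x_old, st, h1.data());
      for (int a = 0; a < 4; ++a) ht[a] = st[a] + 0.5 * dt * h1[a];
      hemo_deriv(h, xm, ht.data(), h2.data());
      for (int a = 0; a < 4; ++a) ht[a] = st[a] + 0.5 * dt * h2[a];
      hemo_deriv(h, xm, ht.data(), h3.data());
      for (int a = 0; a < 4; ++a) ht[a] = st[a] + dt * h3[a];
      hemo_deriv(h, x_new, ht.data(), h4.data());
      for (int a = 0; a < 4; ++a)
        st[a] += dt / 6.0 * (h1[a] + 2.0 * h2[a] + 2.0 * h3[a] + h4[a]);
      x[r] = x_new;
      if (want[k + 1] >= 0) {
        double v = st[2] < 1e-6 ? 1e-6 : st[2], q = st[3];
        Y(want[k + 1], r) = 100.0 * h.V0 *
          (h.k1 * (1.0 - q) + h.k2 * (1.0 - q / v) + h.k3 * (1.0 - v));
      }
      if (ok && (!std::isfinite(x[r]) || std::fabs(x[r]) > 1e6)) {
        ok = false; bad_time = (k + 1) * dt;
      }
    }
  }
  return List::create(_["y"] = Y, _["ok"] = ok, _["bad_time"] = bad_time);
}

// One Levenberg-Marquardt iteration's worth of forward passes: the base
// prediction plus one forward-difference column per free parameter, over all
// runs, in a single call. kind: 0 = entry of A, 1 = entry of B (flattened
// n x n x m), 2 = entry of C; pos: 0-based flat index into that matrix.

// [[Rcpp::export(name = ".dcm_jac_cpp")]]
List dcm_jac_cpp(NumericMatrix A, NumericVector B, NumericMatrix C,
                 List runsU, List runsIdx, double dt, NumericVector hemo,
                 IntegerVector kind, IntegerVector pos, NumericVector step) {
  const int nruns = runsU.size(), p = kind.size(), n = A.nrow();
  // total observation count
  int N = 0;
  for (int r = 0; r < nruns; ++r)
    N += as<IntegerVector>(runsIdx[r]).size() * n;
  NumericVector g0(N);
  NumericMatrix J(N, p);
  bool ok_all = true; double bad = NA_REAL;

  // base pass
  {
    int off = 0;
    for (int r = 0; r < nruns; ++r) {
      NumericMatrix U = runsU[r];
      IntegerVector idx = runsIdx[r];
      List res = dcm_forward_cpp(A, B, C, U, dt, hemo, idx);
      if (!as<bool>(res["ok"])) { ok_all = false; bad = as<double>(res["bad_time"]); }
      NumericMatrix y = res["y"];
      for (int i = 0; i < y.nrow() * y.ncol(); ++i) g0[off + i] = y[i];
      off += y.nrow() * y.ncol();
    }
  }
  if (ok_all) {
    NumericMatrix A2(clone(A)); NumericVector B2(clone(B));
    NumericMatrix C2(clone(C));
    for (int j = 0; j < p; ++j) {
      double* slot =
        kind[j] == 0 ? &A2[pos[j]] : (kind[j] == 1 ? &B2[pos[j]] : &C2[pos[j]]);
      double keep = *slot;
      *slot = keep + step[j];
      bool ok_j = true;
      int off = 0;
      for (int r = 0; r < nruns; ++r) {
        NumericMatrix U = runsU[r];
        IntegerVector idx = runsIdx[r];
        List res = dcm_forward_cpp(A2, B2, C2, U, dt, hemo, idx);
        if (!as<bool>(res["ok"])) { ok_j = false; break; }
        NumericMatrix y = res["y"];
        const double inv_h = 1.0 / step[j];
        for (int i = 0; i < y.nrow() * y.ncol(); ++i)
          J(off + i, j) = (y[i] - g0[off + i]) * inv_h;
        off += y.nrow() * y.ncol();
      }
      if (!ok_j) for (int i = 0; i < N; ++i) J(i, j) = 0.0; // divergent: flat
      *slot = keep;
    }
  }
  return List::create(_["g"] = g0, _["J"] = J, _["ok"] = ok_all,
                      _["bad_time"] = bad);
}
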