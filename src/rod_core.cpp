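// Compiled core for the morphoelastic rod model: frame reconstruction on the
// rotation group, quasi-static Kirchhoff equilibrium under distributed gravity,
// and the delay-feedback time stepper shared by the reduced and full models.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

inline void crossv(const double* a, const double* b, double* o) {
  o[0] = a[1] * b[2] - a[2] * b[1];
  o[1] = a[2] * b[0] - a[0] * b[2];
  o[2] = a[0] * b[1] - a[1] * b[0];
}
inline double dotv(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
inline double norm3(const double* a) { return std::sqrt(dotv(a, a)); }

// column-major 3x3: C = A * B
inline void matmul3(const double* A, const double* B, double* C) {
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < 3; ++i)
      C[3 * j + i] = A[i] * B[3 * j] + A[3 + i] * B[3 * j + 1] + A[6 + i] * B[3 * j + 2];
}
inline void matvec3(const double* A, const double* x, double* y) {
  for (int i = 0; i < 3; ++i)
    y[i] = A[i] * x[0] + A[3 + i] * x[1] + A[6 + i] * x[2];
}

// A = exp(h*skew(k)); v = (int_0^h exp(sigma*skew(k)) dsigma) e3.
// k holds the body components of the strain vector, assumed constant over the
// interval, so the update is exact (rotation-group preserving by construction).
void rot_disp(const double* k, double h, double* A, double* v) {
  double K[9] = {0.0, k[2], -k[1], -k[2], 0.0, k[0], k[1], -k[0], 0.0};
  double K2[9];
  matmul3(K, K, K2);
  const double w2 = dotv(k, k);
  const double w = std::sqrt(w2);
  const double th = w * h;
  double cA1, cA2, cV1, cV2;
  if (th < 1e-6) {  // series limits, |u| h -> 0
    cA1 = h;
    cA2 = 0.5 * h * h;
    cV1 = 0.5 * h * h;
    cV2 = h * h * h / 6.0;
  } else {
    cA1 = std::sin(th) / w;
    cA2 = (1.0 - std::cos(th)) / w2;
    cV1 = cA2;
    cV2 = (h - std::sin(th) / w) / w2;
  }
  for (int m = 0; m < 9; ++m) A[m] = cA1 * K[m] + cA2 * K2[m];
  A[0] += 1.0; A[4] += 1.0; A[8] += 1.0;
  v[0] = cV1 * K[6] + cV2 * K2[6];
  v[1] = cV1 * K[7] + cV2 * K2[7];
  v[2] = h + cV1 * K[8] + cV2 * K2[8];
}

struct RodArrays {
  std::vector<double> P, D1, D2, D3;  // node-major [3*i + c]
  explicit RodArrays(int n) : P(3 * n), D1(3 * n), D2(3 * n), D3(3 * n) {}
};

// Reconstruct centerline + directors from body strain components u (n x 3,
// node-major) on grid s, starting from frame R0 (columns d1,d2,d3) and p0.
void frame_chain(int n, const double* u, const double* s,
                 const double* R0, const double* p0, RodArrays& o) {
  double R[9], p[3], A[9], v[3], Rn[9], w[3], k[3];
  std::copy(R0, R0 + 9, R);
  std::copy(p0, p0 + 3, p);
  for (int c = 0; c < 3; ++c) {
    o.P[c] = p[c]; o.D1[c] = R[c]; o.D2[c] = R[3 + c]; o.D3[c] = R[6 + c];
  }
  for (int i = 0; i < n - 1; ++i) {
    const double h = s[i + 1] - s[i];
    for (int c = 0; c < 3; ++c) k[c] = 0.5 * (u[3 * i + c] + u[3 * (i + 1) + c]);
    rot_disp(k, h, A, v);
    matvec3(R, v, w);
    for (int c = 0; c < 3; ++c) p[c] += w[c];
    matmul3(R, A, Rn);
    // modified Gram-Schmidt: keep the frame orthonormal to machine precision
    double n1 = std::sqrt(Rn[0] * Rn[0] + Rn[1] * Rn[1] + Rn[2] * Rn[2]);
    for (int c = 0; c < 3; ++c) Rn[c] /= n1;
    double pr = Rn[0] * Rn[3] + Rn[1] * Rn[4] + Rn[2] * Rn[5];
    for (int c = 0; c < 3; ++c) Rn[3 + c] -= pr * Rn[c];
    double n2 = std::sqrt(Rn[3] * Rn[3] + Rn[4] * Rn[4] + Rn[5] * Rn[5]);
    for (int c = 0; c < 3; ++c) Rn[3 + c] /= n2;
    crossv(Rn, Rn + 3, Rn + 6);
    std::copy(Rn, Rn + 9, R);
    const int j = 3 * (i + 1);
    for (int c = 0; c < 3; ++c) {
      o.P[j + c] = p[c]; o.D1[j + c] = R[c]; o.D2[j + c] = R[3 + c]; o.D3[j + c] = R[6 + c];
    }
  }
}

// Moment field m(s) = -int_s^l q (l - sigma) g x d3(sigma) dsigma (trapezoid
// from the free tip, so m(l) = 0 holds exactly).
void moment_field(int n, const double* s, double q, const double* g,
                  const RodArrays& rod, double* m) {
  const double l = s[n - 1];
  std::vector<double> w(3 * n);
  for (int i = 0; i < n; ++i) {
    double gx[3];
    crossv(g, &rod.D3[3 * i], gx);
    const double f = q * (l - s[i]);
    for (int c = 0; c < 3; ++c) w[3 * i + c] = f * gx[c];
  }
  for (int c = 0; c < 3; ++c) m[3 * (n - 1) + c] = 0.0;
  for (int i = n - 2; i >= 0; --i) {
    const double hh = 0.5 * (s[i + 1] - s[i]);
    for (int c = 0; c < 3; ++c)
      m[3 * i + c] = m[3 * (i + 1) + c] - hh * (w[3 * i + c] + w[3 * (i + 1) + c]);
  }
}

// Under-relaxed fixed point for the coupled system u = u* + m(u)/K.
// Returns iterations used, or -1 on failure. rod/m are outputs.
int equilibrium_core(int n, const double* s, const double* us,
                     const double* K1, const double* K3,
                     double q, const double* g, const double* R0, const double* p0,
                     double* u, double relax, double tol_tip, int max_iter,
                     RodArrays& rod, double* m) {
  double tip_prev[3] = {1e300, 1e300, 1e300};
  const double rel = (q == 0.0) ? 1.0 : relax;
  int it;
  bool ok = false;
  for (it = 0; it < max_iter; ++it) {
    frame_chain(n, u, s, R0, p0, rod);
    const double* tip = &rod.P[3 * (n - 1)];
    double d[3] = {tip[0] - tip_prev[0], tip[1] - tip_prev[1], tip[2] - tip_prev[2]};
    std::copy(tip, tip + 3, tip_prev);
    if (it > 0 && norm3(d) < tol_tip) { ok = true; break; }
    moment_field(n, s, q, g, rod, m);
    for (int i = 0; i < n; ++i) {
      const double m1 = dotv(&m[3 * i], &rod.D1[3 * i]);
      const double m2 = dotv(&m[3 * i], &rod.D2[3 * i]);
      const double m3 = dotv(&m[3 * i], &rod.D3[3 * i]);
      u[3 * i]     += rel * (us[3 * i]     + m1 / K1[i] - u[3 * i]);
      u[3 * i + 1] += rel * (us[3 * i + 1] + m2 / K1[i] - u[3 * i + 1]);
      u[3 * i + 2] += rel * (us[3 * i + 2] + m3 / K3[i] - u[3 * i + 2]);
    }
  }
  // final consistent moment field for the converged configuration
  moment_field(n, s, q, g, rod, m);
  return ok ? it : -1;
}

NumericMatrix to_mat(const std::vector<double>& a, int n) {
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) out(i, c) = a[3 * i + c];
  return out;
}

}  // namespace

// [[Rcpp::export]]
List cpp_integrate_frame(NumericMatrix u, NumericVector s,
                         NumericMatrix R0, NumericVector p0) {
  const int n = s.size();
  std::vector<double> ub(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) ub[3 * i + c] = u(i, c);
  RodArrays rod(n);
  frame_chain(n, ub.data(), REAL(s), REAL(R0), REAL(p0), rod);
  return List::create(_["p"] = to_mat(rod.P, n), _["d1"] = to_mat(rod.D1, n),
                      _["d2"] = to_mat(rod.D2, n), _["d3"] = to_mat(rod.D3, n));
}

// [[Rcpp::export]]
List cpp_solve_equilibrium(NumericMatrix u_star, NumericVector s,
                           NumericVector K1, NumericVector K3, double q,
                           NumericVector g_dir, NumericMatrix R0, NumericVector p0,
                           NumericMatrix u_init, double relax, double tol_tip,
                           int max_iter) {
  const int n = s.size();
  std::vector<double> us(3 * n), u(3 * n), m(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) {
      us[3 * i + c] = u_star(i, c);
      u[3 * i + c] = u_init(i, c);
    }
  RodArrays rod(n);
  int it = equilibrium_core(n, REAL(s), us.data(), REAL(K1), REAL(K3), q,
                            REAL(g_dir), REAL(R0), REAL(p0), u.data(), relax,
                            tol_tip, max_iter, rod, m.data());
  return List::create(
      _["p"] = to_mat(rod.P, n), _["d1"] = to_mat(rod.D1, n),
      _["d2"] = to_mat(rod.D2, n), _["d3"] = to_mat(rod.D3, n),
      _["u"] = to_mat(u, n), _["m"] = to_mat(m, n),
      _["converged"] = (it >= 0), _["iterations"] = (it >= 0 ? it : max_iter));
}

// Time stepper for the coupled delay-feedback rod. Grids/fields may be
// time-dependent: matrices s_t, eps_t, K1_t, K3_t have either 1 row (constant)
// or n_steps+1 rows (row k = value at local step k). Ring buffers store the
// per-node signals (h1, h2, u1, u2) at absolute step index m with slot
// m mod nrow(buffer); the distributed-delay integrals are advanced by the
// exactly-integrated exponential-kernel recurrence.
// [[Rcpp::export]]
List cpp_simulate(NumericMatrix s_t, NumericMatrix eps_t,
                  NumericMatrix K1_t, NumericMatrix K3_t,
                  double q, NumericVector g_dir, NumericMatrix R0, NumericVector p0,
                  NumericMatrix ustar0, NumericMatrix u0, NumericMatrix hb0,
                  NumericMatrix bufH1, NumericMatrix bufH2,
                  NumericMatrix bufU1, NumericMatrix bufU2,
                  NumericVector Ig1_0, NumericVector Ig2_0,
                  NumericVector Ip1_0, NumericVector Ip2_0,
                  double dt, int n_steps, double t0, double k0,
                  List pars, List kick, bool fast_stat, List eq_ctrl,
                  int out_every) {
  const int n = s_t.ncol();
  const bool s_var = s_t.nrow() > 1;
  const bool e_var = eps_t.nrow() > 1;
  const bool k_var = K1_t.nrow() > 1;

  const double alpha = pars["alpha"], beta = pars["beta"], eta = pars["eta"];
  const double r_org = pars["r"], tau_e = pars["tau_e"];
  const double tau_m = pars["tau_m"], tau_r = pars["tau_r"];
  const double tau_bm = pars["tau_bm"], tau_br = pars["tau_br"];
  const double tau_a = pars["tau_a"];
  const double endo_sign = pars["endo_sign"], endo_phase = pars["endo_phase"];

  const double kick_amp = kick["amp"], kick_omega = kick["omega"];
  const double kick_spin = kick["spin"], kick_tend = kick["t_end"];

  const double relax = eq_ctrl["relax"], tol_tip = eq_ctrl["tol_tip"];
  const int max_iter = eq_ctrl["max_iter"];

  const int Lg = (int)std::lround(tau_r / dt);
  const int Lp = (int)std::lround(tau_br / dt);
  const int Mg = bufH1.nrow(), Mp = bufU1.nrow();
  if (Mg != Lg + 1 || Mp != Lp + 1)
    stop("delay buffer size inconsistent with tau_r/dt");
  if (std::abs(Lg * dt - tau_r) > 1e-6 * dt || std::abs(Lp * dt - tau_br) > 1e-6 * dt)
    stop("dt must divide the reaction delays");

  // exponential-kernel recurrence coefficients (exact for piecewise-linear f)
  auto coefs = [&](double tau, double* mu, double* c0, double* c1) {
    const double a = dt / tau;
    *mu = std::exp(-a);
    *c1 = (a - 1.0 + *mu) / a;
    *c0 = (1.0 - *mu * (1.0 + a)) / a;
  };
  double mug, c0g, c1g, mup, c0p, c1p;
  coefs(tau_m, &mug, &c0g, &c1g);
  coefs(tau_bm, &mup, &c0p, &c1p);

  std::vector<double> us(3 * n, 0.0), u(3 * n), hb(3 * n), m(3 * n);
  std::vector<double> Ig1(n), Ig2(n), Ip1(n), Ip2(n), s_now(n);
  std::vector<double> K1(n), K3(n);
  NumericMatrix H1 = clone(bufH1), H2 = clone(bufH2);
  NumericMatrix U1 = clone(bufU1), U2 = clone(bufU2);
  for (int i = 0; i < n; ++i) {
    us[3 * i] = ustar0(i, 0); us[3 * i + 1] = ustar0(i, 1);
    for (int c = 0; c < 3; ++c) {
      u[3 * i + c] = u0(i, c);
      hb[3 * i + c] = hb0(i, c);
    }
    Ig1[i] = Ig1_0[i]; Ig2[i] = Ig2_0[i]; Ip1[i] = Ip1_0[i]; Ip2[i] = Ip2_0[i];
  }

  RodArrays rod(n);
  {  // frames consistent with the initial visible strains
    for (int i = 0; i < n; ++i) s_now[i] = s_t(0, i);
    frame_chain(n, u.data(), s_now.data(), REAL(R0), REAL(p0), rod);
  }

  const int n_out = n_steps / out_every + 2;
  NumericVector out_t(n_out), out_l(n_out);
  NumericMatrix out_tip(n_out, 3);
  IntegerVector out_step(n_out);
  int j_out = 0;
  auto record = [&](int k_local) {
    out_t[j_out] = t0 + k_local * dt;
    out_l[j_out] = s_var ? s_t(k_local, n - 1) : s_t(0, n - 1);
    for (int c = 0; c < 3; ++c) out_tip(j_out, c) = rod.P[3 * (n - 1) + c];
    out_step[j_out] = k_local;
    ++j_out;
  };
  record(0);

  auto slot = [](double m_abs, int M) {
    long long mm = (long long)std::llround(m_abs);
    long long s = mm % M;
    return (int)(s < 0 ? s + M : s);
  };

  int fail_step = -1, max_it_used = 0;
  const double tpi = 2.0 * M_PI;

  for (int k = 0; k < n_steps; ++k) {
    const double t = t0 + k * dt;
    const double m_abs = k0 + k;
    const int re = e_var ? k : 0;

    // statolith avalanche dynamics (RK4 on the body components, frames of
    // the current configuration held fixed over the step), then renormalize
    if (!fast_stat) {
      for (int i = 0; i < n; ++i) {
        double gb[3] = {dotv(REAL(g_dir), &rod.D1[3 * i]),
                        dotv(REAL(g_dir), &rod.D2[3 * i]),
                        dotv(REAL(g_dir), &rod.D3[3 * i])};
        double* h = &hb[3 * i];
        auto f = [&](const double* hh, double* out) {
          double t1[3], t2[3];
          crossv(hh, gb, t1);
          crossv(hh, t1, t2);
          for (int c = 0; c < 3; ++c) out[c] = t2[c] / tau_a;
        };
        double k1[3], k2[3], k3[3], k4[3], tmp[3];
        f(h, k1);
        for (int c = 0; c < 3; ++c) tmp[c] = h[c] + 0.5 * dt * k1[c];
        f(tmp, k2);
        for (int c = 0; c < 3; ++c) tmp[c] = h[c] + 0.5 * dt * k2[c];
        f(tmp, k3);
        for (int c = 0; c < 3; ++c) tmp[c] = h[c] + dt * k3[c];
        f(tmp, k4);
        for (int c = 0; c < 3; ++c)
          h[c] += dt * (k1[c] + 2 * k2[c] + 2 * k3[c] + k4[c]) / 6.0;
        const double nm = norm3(h);
        for (int c = 0; c < 3; ++c) h[c] /= nm;
      }
    }

    // spontaneous strain rates (endogenous + gravitropic + proprioceptive),
    // forward step of u*
    const double ph = tpi * t / tau_e + endo_phase;
    const double ce = std::cos(ph), se = std::sin(ph);
    for (int i = 0; i < n; ++i) {
      const double ed = eps_t(re, i);
      double du1 = alpha * ed / r_org * ce - (beta * ed / r_org) * Ig1[i] - eta * ed * Ip1[i];
      double du2 = endo_sign * alpha * ed / r_org * se + (beta * ed / r_org) * Ig2[i] - eta * ed * Ip2[i];
      if (t < kick_tend) {
        du1 += kick_amp * std::cos(kick_omega * t);
        du2 += kick_spin * kick_amp * std::sin(kick_omega * t);
      }
      us[3 * i] += dt * du1;
      us[3 * i + 1] += dt * du2;
    }

    // elastic equilibrium on the (possibly grown) grid at t_{k+1}
    const int rs = s_var ? k + 1 : 0;
    const int rk = k_var ? k + 1 : 0;
    for (int i = 0; i < n; ++i) {
      s_now[i] = s_t(rs, i);
      K1[i] = K1_t(rk, i);
      K3[i] = K3_t(rk, i);
    }
    int it = equilibrium_core(n, s_now.data(), us.data(), K1.data(), K3.data(), q,
                              REAL(g_dir), REAL(R0), REAL(p0), u.data(), relax,
                              tol_tip, max_iter, rod, m.data());
    if (it < 0) { fail_step = k; break; }
    if (it > max_it_used) max_it_used = it;

    // perceived-gravity components for the buffers
    if (fast_stat) {
      for (int i = 0; i < n; ++i) {
        hb[3 * i]     = -dotv(REAL(g_dir), &rod.D1[3 * i]);
        hb[3 * i + 1] = -dotv(REAL(g_dir), &rod.D2[3 * i]);
        hb[3 * i + 2] = -dotv(REAL(g_dir), &rod.D3[3 * i]);
      }
    }

    // delayed signals: read f(t_k - tau_r), push f(t_{k+1}), read f(t_{k+1} - tau_r)
    const int sg_old = slot(m_abs - Lg, Mg), sp_old = slot(m_abs - Lp, Mp);
    std::vector<double> h2_old(n), h1_old(n), u1_old(n), u2_old(n);
    for (int i = 0; i < n; ++i) {
      h1_old[i] = H1(sg_old, i); h2_old[i] = H2(sg_old, i);
      u1_old[i] = U1(sp_old, i); u2_old[i] = U2(sp_old, i);
    }
    const int sg_new_w = slot(m_abs + 1, Mg), sp_new_w = slot(m_abs + 1, Mp);
    for (int i = 0; i < n; ++i) {
      H1(sg_new_w, i) = hb[3 * i];
      H2(sg_new_w, i) = hb[3 * i + 1];
      U1(sp_new_w, i) = u[3 * i];
      U2(sp_new_w, i) = u[3 * i + 1];
    }
    const int sg_new = slot(m_abs + 1 - Lg, Mg), sp_new = slot(m_abs + 1 - Lp, Mp);
    for (int i = 0; i < n; ++i) {
      Ig1[i] = mug * Ig1[i] + c0g * h2_old[i] + c1g * H2(sg_new, i);
      Ig2[i] = mug * Ig2[i] + c0g * h1_old[i] + c1g * H1(sg_new, i);
      Ip1[i] = mup * Ip1[i] + c0p * u1_old[i] + c1p * U1(sp_new, i);
      Ip2[i] = mup * Ip2[i] + c0p * u2_old[i] + c1p * U2(sp_new, i);
    }

    if ((k + 1) % out_every == 0 || k == n_steps - 1) record(k + 1);
  }

  NumericMatrix ustar_out(n, 2);
  for (int i = 0; i < n; ++i) {
    ustar_out(i, 0) = us[3 * i];
    ustar_out(i, 1) = us[3 * i + 1];
  }
  return List::create(
      _["times"] = out_t[Range(0, j_out - 1)],
      _["tip"] = out_tip(Range(0, j_out - 1), _),
      _["length"] = out_l[Range(0, j_out - 1)],
      _["steps"] = out_step[Range(0, j_out - 1)],
      _["state"] = List::create(
          _["p"] = to_mat(rod.P, n), _["d1"] = to_mat(rod.D1, n),
          _["d2"] = to_mat(rod.D2, n), _["d3"] = to_mat(rod.D3, n),
          _["u"] = to_mat(u, n), _["u_star"] = ustar_out,
          _["h_body"] = to_mat(hb, n), _["m"] = to_mat(m, n),
          _["Ig1"] = NumericVector(Ig1.begin(), Ig1.end()),
          _["Ig2"] = NumericVector(Ig2.begin(), Ig2.end()),
          _["Ip1"] = NumericVector(Ip1.begin(), Ip1.end()),
          _["Ip2"] = NumericVector(Ip2.begin(), Ip2.end()),
          _["bufH1"] = H1, _["bufH2"] = H2, _["bufU1"] = U1, _["bufU2"] = U2,
          _["k_abs"] = k0 + (fail_step < 0 ? n_steps : fail_step)),
      _["fail_step"] = fail_step,
      _["max_eq_iterations"] = max_it_used);
}
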