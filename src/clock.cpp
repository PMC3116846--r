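// Core numerics for the three-variable clock model under piecewise-linear
// light forcing: fixed-step RK4 integration segmented at forcing breakpoints,
// variational (monodromy) integration, stroboscopic-map iteration, and a
// tangent-vector map Lyapunov exponent.
//
// Forcing discontinuities occur at state-independent times, so steps are
// split at every breakpoint and no RK4 stage straddles a discontinuity;
// stage evaluations at a segment's right endpoint use the left limit of X(t).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

struct Params {
  double n, KI, vs, vm, KM, ks, vd, Kd, k1, k2;
};

// mode: 0 = no forcing (DD), 1 = periodic LD, 2 = single pulse
// kind: 0 = none, 1 = adaptation (plateau Ts then linear decay Td),
//       2 = slow response (linear rise Tr then plateau Ts)
struct Profile {
  int kind, mode;
  double Xmax, Ts, Td, Tr, T, photo, pulse_start, pulse_dur;
};

static Params as_params(const NumericVector& p) {
  Params q;
  q.n = p["n"];   q.KI = p["K_I"]; q.vs = p["v_s"]; q.vm = p["v_m"];
  q.KM = p["K_M"]; q.ks = p["k_s"]; q.vd = p["v_d"]; q.Kd = p["K_d"];
  q.k1 = p["k_1"]; q.k2 = p["k_2"];
  return q;
}

static Profile as_profile(const NumericVector& v) {
  Profile pr;
  pr.kind = (int) v["kind"];
  pr.mode = (int) v["mode"];
  pr.Xmax = v["X_max"]; pr.Ts = v["T_s"]; pr.Td = v["T_d"]; pr.Tr = v["T_r"];
  pr.T = v["T"]; pr.photo = v["photoperiod"];
  pr.pulse_start = v["pulse_start"]; pr.pulse_dur = v["pulse_dur"];
  return pr;
}

static inline double mod_pos(double t, double T) {
  double u = t - T * std::floor(t / T);
  if (u >= T) u -= T;   // guard against rounding at exact multiples
  if (u < 0) u += T;
  return u;
}

// waveform value u hours after lights-on (half-open segments, right-continuous)
static inline double waveform_u(const Profile& pr, double u) {
  if (pr.kind == 1) {
    if (u < pr.Ts) return pr.Xmax;
    if (pr.Td > 0.0 && u < pr.Ts + pr.Td)
      return pr.Xmax * (1.0 - (u - pr.Ts) / pr.Td);
    return 0.0;
  } else if (pr.kind == 2) {
    if (pr.Tr > 0.0 && u < pr.Tr) return pr.Xmax * u / pr.Tr;
    if (u < pr.Tr + pr.Ts) return pr.Xmax;
    return 0.0;
  }
  return 0.0;
}

static inline double light_at(const Profile& pr, double t) {
  if (pr.mode == 0 || pr.kind == 0 || pr.Xmax == 0.0) return 0.0;
  if (pr.mode == 1) {
    double u = mod_pos(t, pr.T);
    if (u >= pr.photo) return 0.0;
    return waveform_u(pr, u);
  }
  double s = t - pr.pulse_start;
  if (s < 0.0 || s >= pr.pulse_dur) return 0.0;
  return waveform_u(pr, s);
}

// all forcing breakpoints strictly inside (t0, t1)
static std::vector<double> breakpoints(const Profile& pr, double t0, double t1) {
  std::vector<double> b;
  if (pr.mode == 0 || pr.kind == 0) return b;
  std::vector<double> offs;
  offs.push_back(0.0);
  if (pr.kind == 1) {
    offs.push_back(pr.Ts);
    if (pr.Td > 0.0) offs.push_back(pr.Ts + pr.Td);
  } else {
    if (pr.Tr > 0.0) offs.push_back(pr.Tr);
    offs.push_back(pr.Tr + pr.Ts);
  }
  const double eps = 1e-12;
  if (pr.mode == 1) {
    offs.push_back(pr.photo);
    long k0 = (long) std::floor(t0 / pr.T) - 1;
    long k1 = (long) std::ceil(t1 / pr.T) + 1;
    for (long k = k0; k <= k1; ++k) {
      double base = k * pr.T;
      for (size_t i = 0; i < offs.size(); ++i) {
        double tb = base + offs[i];
        if (tb > t0 + eps && tb < t1 - eps) b.push_back(tb);
      }
    }
  } else {
    offs.push_back(pr.pulse_dur);
    for (size_t i = 0; i < offs.size(); ++i) {
      double tb = pr.pulse_start + offs[i];
      if (tb > t0 + eps && tb < t1 - eps) b.push_back(tb);
    }
  }
  std::sort(b.begin(), b.end());
  b.erase(std::unique(b.begin(), b.end()), b.end());
  return b;
}

static inline void rhs(const Params& p, const double* y, double x, double* dy) {
  double KIn = std::pow(p.KI, p.n);
  double hill = KIn / (KIn + std::pow(y[2], p.n));
  dy[0] = p.vs * (1.0 + x) * hill - p.vm * y[0] / (p.KM + y[0]);
  dy[1] = p.ks * y[0] - p.vd * y[1] / (p.Kd + y[1]) - p.k1 * y[1] + p.k2 * y[2];
  dy[2] = p.k1 * y[1] - p.k2 * y[2];
}

static inline void jac(const Params& p, const double* y, double x, double J[3][3]) {
  double KIn = std::pow(p.KI, p.n);
  double Pn = y[2];
  double denom = KIn + std::pow(Pn, p.n);
  J[0][0] = -p.vm * p.KM / ((p.KM + y[0]) * (p.KM + y[0]));
  J[0][1] = 0.0;
  J[0][2] = -p.vs * (1.0 + x) * KIn * p.n * std::pow(Pn, p.n - 1.0) / (denom * denom);
  J[1][0] = p.ks;
  J[1][1] = -p.vd * p.Kd / ((p.Kd + y[1]) * (p.Kd + y[1])) - p.k1;
  J[1][2] = p.k2;
  J[2][0] = 0.0;
  J[2][1] = p.k1;
  J[2][2] = -p.k2;
}

// light evaluation clipped to a segment's interior so the k4 stage at a
// breakpoint uses the left limit
static inline double light_seg(const Profile& pr, double t, double t_hi) {
  double te = t;
  if (te >= t_hi) te = t_hi - 1e-9;
  return light_at(pr, te);
}

static inline void rk4_step(const Params& p, const Profile& pr, double* y,
                            double t, double h, double t_hi) {
  double k1[3], k2[3], k3[3], k4[3], yt[3];
  double x0 = light_seg(pr, t, t_hi);
  double xm = light_seg(pr, t + 0.5 * h, t_hi);
  double x1 = light_seg(pr, t + h, t_hi);
  rhs(p, y, x0, k1);
  for (int i = 0; i < 3; ++i) yt[i] = y[i] + 0.5 * h * k1[i];
  rhs(p, yt, xm, k2);
  for (int i = 0; i < 3; ++i) yt[i] = y[i] + 0.5 * h * k2[i];
  rhs(p, yt, xm, k3);
  for (int i = 0; i < 3; ++i) yt[i] = y[i] + h * k3[i];
  rhs(p, yt, x1, k4);
  for (int i = 0; i < 3; ++i)
    y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// RK4 over a breakpoint-free segment using steps of size <= dt
static void integrate_segment(const Params& p, const Profile& pr, double* y,
                              double t0, double t1, double dt) {
  double len = t1 - t0;
  if (len <= 0.0) return;
  long nst = (long) std::ceil(len / dt - 1e-9);
  if (nst < 1) nst = 1;
  double h = len / nst;
  for (long i = 0; i < nst; ++i)
    rk4_step(p, pr, y, t0 + i * h, h, t1);
}

// advance y from t0 to t1, splitting at forcing breakpoints
static void advance(const Params& p, const Profile& pr, double* y,
                    double t0, double t1, double dt) {
  std::vector<double> bp = breakpoints(pr, t0, t1);
  double tc = t0;
  for (size_t i = 0; i < bp.size(); ++i) {
    integrate_segment(p, pr, y, tc, bp[i], dt);
    tc = bp[i];
  }
  integrate_segment(p, pr, y, tc, t1, dt);
}

static inline bool finite3(const double* y) {
  return R_finite(y[0]) && R_finite(y[1]) && R_finite(y[2]);
}

// [[Rcpp::export]]
NumericVector cpp_rhs(NumericVector state, NumericVector par, double x_light) {
  Params p = as_params(par);
  double y[3] = { state[0], state[1], state[2] }, dy[3];
  rhs(p, y, x_light, dy);
  return NumericVector::create(dy[0], dy[1], dy[2]);
}

// [[Rcpp::export]]
double cpp_light_value(NumericVector prof, double t) {
  Profile pr = as_profile(prof);
  return light_at(pr, t);
}

// trajectory saved every save_dt from t0 to t1 inclusive (save_dt a multiple
// of the intended output spacing; internal steps never exceed dt)
// [[Rcpp::export]]
NumericMatrix cpp_integrate(NumericVector state, NumericVector par,
                            NumericVector prof, double t0, double t1,
                            double dt, double save_dt) {
  Params p = as_params(par);
  Profile pr = as_profile(prof);
  double y[3] = { state[0], state[1], state[2] };
  long nsave = (long) std::floor((t1 - t0) / save_dt + 1e-9);
  NumericMatrix out(nsave + 1, 5);
  out(0, 0) = t0; out(0, 1) = y[0]; out(0, 2) = y[1]; out(0, 3) = y[2];
  out(0, 4) = light_at(pr, t0);
  for (long j = 1; j <= nsave; ++j) {
    double ta = t0 + (j - 1) * save_dt;
    double tb = t0 + j * save_dt;
    advance(p, pr, y, ta, tb, dt);
    if (!finite3(y))
      stop("non-finite state encountered at t = %f during integration", tb);
    out(j, 0) = tb; out(j, 1) = y[0]; out(j, 2) = y[1]; out(j, 3) = y[2];
    out(j, 4) = light_at(pr, tb);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_final_state(NumericVector state, NumericVector par,
                              NumericVector prof, double t0, double t1,
                              double dt) {
  Params p = as_params(par);
  Profile pr = as_profile(prof);
  double y[3] = { state[0], state[1], state[2] };
  // chunked so breakpoint lists stay small for very long spans
  double tc = t0;
  double chunk = (pr.mode == 1) ? 100.0 * pr.T : (t1 - t0);
  if (chunk <= 0.0) chunk = t1 - t0;
  while (tc < t1 - 1e-12) {
    double tn = std::min(tc + chunk, t1);
    advance(p, pr, y, tc, tn, dt);
    if (!finite3(y))
      stop("non-finite state encountered at t = %f during integration", tn);
    tc = tn;
  }
  return NumericVector::create(y[0], y[1], y[2]);
}

// combined state + variational RK4 step (Phi' = J(y,x) Phi)
static inline void rk4_step_var(const Params& p, const Profile& pr, double* y,
                                double Phi[3][3], double t, double h, double t_hi) {
  double ky[4][3], kP[4][3][3];
  double yt[3], Pt[3][3], J[3][3];
  double xs[3] = { light_seg(pr, t, t_hi), light_seg(pr, t + 0.5 * h, t_hi),
                   light_seg(pr, t + h, t_hi) };
  const double cc[4] = { 0.0, 0.5, 0.5, 1.0 };
  const int xi[4] = { 0, 1, 1, 2 };
  for (int s = 0; s < 4; ++s) {
    if (s == 0) {
      for (int i = 0; i < 3; ++i) { yt[i] = y[i]; }
      for (int i = 0; i < 3; ++i) for (int j = 0; j < 3; ++j) Pt[i][j] = Phi[i][j];
    } else {
      for (int i = 0; i < 3; ++i) yt[i] = y[i] + cc[s] * h * ky[s - 1][i];
      for (int i = 0; i < 3; ++i) for (int j = 0; j < 3; ++j)
        Pt[i][j] = Phi[i][j] + cc[s] * h * kP[s - 1][i][j];
    }
    double x = xs[xi[s]];
    rhs(p, yt, x, ky[s]);
    jac(p, yt, x, J);
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        kP[s][i][j] = J[i][0] * Pt[0][j] + J[i][1] * Pt[1][j] + J[i][2] * Pt[2][j];
  }
  for (int i = 0; i < 3; ++i) {
    y[i] += h / 6.0 * (ky[0][i] + 2.0 * ky[1][i] + 2.0 * ky[2][i] + ky[3][i]);
    for (int j = 0; j < 3; ++j)
      Phi[i][j] += h / 6.0 * (kP[0][i][j] + 2.0 * kP[1][i][j] + 2.0 * kP[2][i][j] + kP[3][i][j]);
  }
}

static void advance_var(const Params& p, const Profile& pr, double* y,
                        double Phi[3][3], double t0, double t1, double dt) {
  std::vector<double> bp = breakpoints(pr, t0, t1);
  bp.push_back(t1);
  double tc = t0;
  for (size_t k = 0; k < bp.size(); ++k) {
    double tb = bp[k];
    double len = tb - tc;
    if (len <= 0.0) continue;
    long nst = (long) std::ceil(len / dt - 1e-9);
    if (nst < 1) nst = 1;
    double h = len / nst;
    for (long i = 0; i < nst; ++i)
      rk4_step_var(p, pr, y, Phi, tc + i * h, h, tb);
    tc = tb;
  }
}

// final state and monodromy matrix of the flow over [t0, t0 + t_len]
// [[Rcpp::export]]
List cpp_monodromy(NumericVector state, NumericVector par, NumericVector prof,
                   double t0, double t_len, double dt) {
  Params p = as_params(par);
  Profile pr = as_profile(prof);
  double y[3] = { state[0], state[1], state[2] };
  double Phi[3][3] = { {1, 0, 0}, {0, 1, 0}, {0, 0, 1} };
  advance_var(p, pr, y, Phi, t0, t0 + t_len, dt);
  if (!finite3(y) || !R_finite(Phi[0][0]))
    stop("non-finite sensitivity during variational integration");
  NumericMatrix M(3, 3);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) M(i, j) = Phi[i][j];
  return List::create(_["state"] = NumericVector::create(y[0], y[1], y[2]),
                      _["monodromy"] = M);
}

// iterate the stroboscopic map n times; rows are states at t = T, 2T, ..., nT
// [[Rcpp::export]]
NumericMatrix cpp_map_iterate(NumericVector state, NumericVector par,
                              NumericVector prof, int n, double dt) {
  Params p = as_params(par);
  Profile pr = as_profile(prof);
  double y[3] = { state[0], state[1], state[2] };
  NumericMatrix out(n, 3);
  for (int k = 0; k < n; ++k) {
    advance(p, pr, y, 0.0, pr.T, dt);  // forcing is T-periodic
    if (!finite3(y))
      stop("non-finite state during map iteration %d", k + 1);
    out(k, 0) = y[0]; out(k, 1) = y[1]; out(k, 2) = y[2];
  }
  return out;
}

// integrate under a custom T-periodic forcing given as a piecewise-linear
// table of (time-in-cycle, X) knots (X = 0 after the last knot, i.e. dark);
// warm-up cycles are discarded, then one cycle is recorded every save_dt;
// also reports the final cycle-to-cycle change (0 when on a fixed point)
// [[Rcpp::export]]
List cpp_integrate_knots(NumericVector state, NumericVector par,
                                  NumericVector knot_t, NumericVector knot_x,
                                  double T, int warm_cycles, double dt,
                                  double save_dt) {
  Params p = as_params(par);
  int nk = knot_t.size();
  double y[3] = { state[0], state[1], state[2] };
  // segment boundaries within one cycle
  std::vector<double> seg;
  for (int i = 0; i < nk; ++i)
    if (knot_t[i] > 1e-12 && knot_t[i] < T - 1e-12) seg.push_back(knot_t[i]);
  seg.push_back(T);
  std::sort(seg.begin(), seg.end());
  seg.erase(std::unique(seg.begin(), seg.end()), seg.end());
  // linear interpolation of the knot table, 0 beyond the last knot
  double t_last = knot_t[nk - 1];
  // cached per stage via lambda-like helper
  struct XK {
    const double* kt; const double* kx; int nk; double t_last;
    double operator()(double u) const {
      if (u >= t_last) return 0.0;
      if (u <= kt[0]) return kx[0];
      int lo = 0, hi = nk - 1;
      while (hi - lo > 1) { int mid = (lo + hi) / 2;
        if (kt[mid] <= u) lo = mid; else hi = mid; }
      double w = (u - kt[lo]) / (kt[hi] - kt[lo]);
      return kx[lo] + w * (kx[hi] - kx[lo]);
    }
  } xk = { knot_t.begin(), knot_x.begin(), nk, t_last };
  // one RK4 step with explicitly supplied stage forcings
  struct Step {
    static void go(const Params& p, double* y, double h,
                   double x0, double xm, double x1) {
      double k1[3], k2[3], k3[3], k4[3], yt[3];
      rhs(p, y, x0, k1);
      for (int i = 0; i < 3; ++i) yt[i] = y[i] + 0.5 * h * k1[i];
      rhs(p, yt, xm, k2);
      for (int i = 0; i < 3; ++i) yt[i] = y[i] + 0.5 * h * k2[i];
      rhs(p, yt, xm, k3);
      for (int i = 0; i < 3; ++i) yt[i] = y[i] + h * k3[i];
      rhs(p, yt, x1, k4);
      for (int i = 0; i < 3; ++i)
        y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    }
  };
  // warm up at least warm_cycles, then continue until the stroboscopic state
  // converges (so the recorded cycle sits on the attractor to ~1e-10)
  int max_warm = warm_cycles > 400 ? warm_cycles : 400;
  double resid = 0.0;
  for (int c = 0; c < max_warm; ++c) {
    double y_prev[3] = { y[0], y[1], y[2] };
    double tc = 0.0;
    for (size_t s = 0; s < seg.size(); ++s) {
      double tb = seg[s];
      long nst = (long) std::ceil((tb - tc) / dt - 1e-9);
      if (nst < 1) nst = 1;
      double h = (tb - tc) / nst;
      for (long i = 0; i < nst; ++i) {
        double t = tc + i * h;
        Step::go(p, y, h, xk(t), xk(t + 0.5 * h), xk(std::min(t + h, tb - 1e-9)));
      }
      tc = tb;
    }
    if (!finite3(y)) stop("non-finite state during warm-up cycle %d", c + 1);
    resid = std::max(std::fabs(y[0] - y_prev[0]),
            std::max(std::fabs(y[1] - y_prev[1]),
                     std::fabs(y[2] - y_prev[2])));
    if (c >= warm_cycles - 1 && resid < 1e-10) break;
  }
  long nsave = (long) std::floor(T / save_dt + 1e-9);
  NumericMatrix out(nsave + 1, 4);
  out(0, 0) = 0.0; out(0, 1) = y[0]; out(0, 2) = y[1]; out(0, 3) = y[2];
  size_t si = 0;
  double tc = 0.0;
  for (long j = 1; j <= nsave; ++j) {
    double tb = j * save_dt;
    while (tc < tb - 1e-12) {
      double tn = tb;
      while (si < seg.size() && seg[si] <= tc + 1e-12) ++si;
      if (si < seg.size() && seg[si] < tb - 1e-12) tn = seg[si];
      long nst = (long) std::ceil((tn - tc) / dt - 1e-9);
      if (nst < 1) nst = 1;
      double h = (tn - tc) / nst;
      for (long i = 0; i < nst; ++i) {
        double t = tc + i * h;
        Step::go(p, y, h, xk(t), xk(t + 0.5 * h), xk(std::min(t + h, tn - 1e-9)));
      }
      tc = tn;
    }
    if (!finite3(y)) stop("non-finite state at t = %f", tb);
    out(j, 0) = tb; out(j, 1) = y[0]; out(j, 2) = y[1]; out(j, 3) = y[2];
  }
  return List::create(_["cycle"] = out, _["resid"] = resid);
}

// post-transient section points plus the tangent-map Lyapunov exponent
// (per map iterate, natural log)
// [[Rcpp::export]]
List cpp_map_lyapunov(NumericVector state, NumericVector par, NumericVector prof,
                      int n_transient, int n_sample, double dt) {
  Params p = as_params(par);
  Profile pr = as_profile(prof);
  double y[3] = { state[0], state[1], state[2] };
  for (int k = 0; k < n_transient; ++k) {
    advance(p, pr, y, 0.0, pr.T, dt);
    if (!finite3(y)) stop("non-finite state during transient iteration");
  }
  double v[3] = { 1.0 / std::sqrt(3.0), 1.0 / std::sqrt(3.0), 1.0 / std::sqrt(3.0) };
  double logsum = 0.0;
  NumericMatrix pts(n_sample, 3);
  for (int k = 0; k < n_sample; ++k) {
    double Phi[3][3] = { {1, 0, 0}, {0, 1, 0}, {0, 0, 1} };
    advance_var(p, pr, y, Phi, 0.0, pr.T, dt);
    if (!finite3(y)) stop("non-finite state during sampled iteration");
    double w[3];
    for (int i = 0; i < 3; ++i)
      w[i] = Phi[i][0] * v[0] + Phi[i][1] * v[1] + Phi[i][2] * v[2];
    double nw = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
    logsum += std::log(nw);
    for (int i = 0; i < 3; ++i) v[i] = w[i] / nw;
    pts(k, 0) = y[0]; pts(k, 1) = y[1]; pts(k, 2) = y[2];
  }
  return List::create(_["points"] = pts,
                      _["lyapunov"] = logsum / n_sample);
}
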