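#include <Rcpp.h>
using namespace Rcpp;

// Integrators for linear mass-flow networks with an additive forcing term
//   dx/dt = A x + a * h(t),
// h given as a piecewise-linear time course on its own grid. Nonlinear
// models go through deSolve; this compiled path exists because the
// maximum-likelihood loop re-solves the linear systems thousands of times.

static inline double interp_lin(double t, const NumericVector& ht,
                                const NumericVector& hv) {
  int m = ht.size();
  if (m == 0) return 0.0;
  if (t <= ht[0]) return hv[0];
  if (t >= ht[m - 1]) return hv[m - 1];
  // binary search for the interval containing t
  int lo = 0, hi = m - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (ht[mid] <= t) lo = mid; else hi = mid;
  }
  double w = (t - ht[lo]) / (ht[hi] - ht[lo]);
  return hv[lo] + w * (hv[hi] - hv[lo]);
}

static inline void rhs_lin(int N, const double* A, const double* avec,
                           double h, const double* x, double* dx) {
  for (int i = 0; i < N; ++i) {
    double s = avec[i] * h;
    for (int u = 0; u < N; ++u) s += A[i + N * u] * x[u];
    dx[i] = s;
  }
}

// Dormand-Prince 5(4) coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 35.0 / 384 - 5179.0 / 57600,
                    e3 = 500.0 / 1113 - 7571.0 / 16695,
                    e4 = 125.0 / 192 - 393.0 / 640,
                    e5 = -2187.0 / 6784 + 92097.0 / 339200,
                    e6 = 11.0 / 84 - 187.0 / 2100, e7 = -1.0 / 40;

// [[Rcpp::export(name = ".dp45_linear")]]
NumericMatrix dp45_linear(NumericMatrix A, NumericVector avec,
                          NumericVector ht, NumericVector hv,
                          NumericVector x0, NumericVector times,
                          double rtol, double atol) {
  int N = x0.size();
  int nt = times.size();
  NumericMatrix out(nt, N);
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> k1(N), k2(N), k3(N), k4v(N), k5(N), k6(N), k7(N),
      xt(N), xn(N);
  const double* Ap = A.begin();
  const double* ap = avec.begin();

  for (int i = 0; i < N; ++i) out(0, i) = x[i];
  double t = times[0];
  double hstep = 0.0;
  bool have_k1 = false;

  for (int seg = 1; seg < nt; ++seg) {
    double tend = times[seg];
    if (hstep <= 0.0) hstep = (tend - t) / 10.0;
    while (t < tend) {
      double dt = hstep;
      if (t + dt > tend) dt = tend - t;
      if (!have_k1) {
        rhs_lin(N, Ap, ap, interp_lin(t, ht, hv), x.data(), k1.data());
      }
      // stages
      for (int i = 0; i < N; ++i) xt[i] = x[i] + dt * a21 * k1[i];
      rhs_lin(N, Ap, ap, interp_lin(t + c2 * dt, ht, hv), xt.data(), k2.data());
      for (int i = 0; i < N; ++i)
        xt[i] = x[i] + dt * (a31 * k1[i] + a32 * k2[i]);
      rhs_lin(N, Ap, ap, interp_lin(t + c3 * dt, ht, hv), xt.data(), k3.data());
      for (int i = 0; i < N; ++i)
        xt[i] = x[i] + dt * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
      rhs_lin(N, Ap, ap, interp_lin(t + c4 * dt, ht, hv), xt.data(), k4v.data());
      for (int i = 0; i < N; ++i)
        xt[i] = x[i] + dt * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                             a54 * k4v[i]);
      rhs_lin(N, Ap, ap, interp_lin(t + c5 * dt, ht, hv), xt.data(), k5.data());
      for (int i = 0; i < N; ++i)
        xt[i] = x[i] + dt * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                             a64 * k4v[i] + a65 * k5[i]);
      rhs_lin(N, Ap, ap, interp_lin(t + dt, ht, hv), xt.data(), k6.data());
      for (int i = 0; i < N; ++i)
        xn[i] = x[i] + dt * (b1 * k1[i] + b3 * k3[i] + b4 * k4v[i] +
                             b5 * k5[i] + b6 * k6[i]);
      rhs_lin(N, Ap, ap, interp_lin(t + dt, ht, hv), xn.data(), k7.data());
      // error estimate
      double errnorm = 0.0;
      for (int i = 0; i < N; ++i) {
        double err = dt * (e1 * k1[i] + e3 * k3[i] + e4 * k4v[i] +
                           e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
        double sc = atol + rtol * std::max(std::fabs(x[i]), std::fabs(xn[i]));
        double r = err / sc;
        errnorm += r * r;
      }
      errnorm = std::sqrt(errnorm / N);
      if (!std::isfinite(errnorm)) stop("integration diverged at t = %f", t);
      if (errnorm <= 1.0) {
        t += dt;
        x = xn;
        k1 = k7;  // FSAL
        have_k1 = true;
        double fac = 0.9 * std::pow(std::max(errnorm, 1e-10), -0.2);
        hstep = dt * std::min(5.0, std::max(0.2, fac));
      } else {
        double fac = 0.9 * std::pow(errnorm, -0.2);
        hstep = dt * std::max(0.2, fac);
        have_k1 = true;  // k1 still valid at unchanged (t, x)
      }
      if (hstep < 1e-14 * std::fabs(tend))
        stop("step size underflow at t = %f", t);
    }
    for (int i = 0; i < N; ++i) out(seg, i) = x[i];
    have_k1 = false;  // h may have a kink exactly at an output point
  }
  return out;
}

// classical fixed-step RK4, n_sub sub-steps per output interval
// [[Rcpp::export(name = ".rk4_linear")]]
NumericMatrix rk4_linear(NumericMatrix A, NumericVector avec,
                         NumericVector ht, NumericVector hv,
                         NumericVector x0, NumericVector times, int n_sub) {
  int N = x0.size();
  int nt = times.size();
  NumericMatrix out(nt, N);
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> k1(N), k2(N), k3(N), k4v(N), xt(N);
  const double* Ap = A.begin();
  const double* ap = avec.begin();
  for (int i = 0; i < N; ++i) out(0, i) = x[i];
  for (int seg = 1; seg < nt; ++seg) {
    double t = times[seg - 1];
    double dt = (times[seg] - times[seg - 1]) / n_sub;
    for (int s = 0; s < n_sub; ++s) {
      rhs_lin(N, Ap, ap, interp_lin(t, ht, hv), x.data(), k1.data());
      for (int i = 0; i < N; ++i) xt[i] = x[i] + 0.5 * dt * k1[i];
      rhs_lin(N, Ap, ap, interp_lin(t + 0.5 * dt, ht, hv), xt.data(),
              k2.data());
      for (int i = 0; i < N; ++i) xt[i] = x[i] + 0.5 * dt * k2[i];
      rhs_lin(N, Ap, ap, interp_lin(t + 0.5 * dt, ht, hv), xt.data(),
              k3.data());
      for (int i = 0; i < N; ++i) xt[i] = x[i] + dt * k3[i];
      rhs_lin(N, Ap, ap, interp_lin(t + dt, ht, hv), xt.data(), k4v.data());
      for (int i = 0; i < N; ++i)
        x[i] += dt / 6.0 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4v[i]);
      t += dt;
    }
    for (int i = 0; i < N; ++i) out(seg, i) = x[i];
  }
  return out;
}
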