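#include <Rcpp.h>
#include <cmath>
#include <vector>

// Fixed-step classical RK4 for the coupled-pendulum chain.
// State layout: phi1[0..n), phi2[0..n), v1[0..n), v2[0..n).
// forcing mode: 0 = zero, 1 = constant, 2 = cosine.

namespace {

struct Chain {
  int n;
  const double *I1, *I2, *K1, *K2, *R1, *R2, *b1, *b2, *k12, *m1, *m2;
  double lambda, s2, M0, omega;
  int mode;

  double torque(double t) const {
    switch (mode) {
      case 1: return M0;
      case 2: return M0 * std::cos(omega * t);
      default: return 0.0;
    }
  }

  // acc/vel derivative of the full state
  void deriv(double t, const std::vector<double>& y,
             std::vector<double>& dy) const {
    const double *p1 = y.data(), *p2 = y.data() + n;
    const double *v1 = y.data() + 2 * n, *v2 = y.data() + 3 * n;
    double *dp1 = dy.data(), *dp2 = dy.data() + n;
    double *a1 = dy.data() + 2 * n, *a2 = dy.data() + 3 * n;
    const double M = torque(t);
    for (int i = 0; i < n; ++i) {
      dp1[i] = v1[i];
      dp2[i] = v2[i];
      double lap1, lap2;  // backbone torque, single neighbour at the ends
      if (i == 0) {
        lap1 = K1[0] * (p1[1] - p1[0]);
        lap2 = K2[0] * (p2[1] - p2[0]);
      } else if (i == n - 1) {
        lap1 = K1[i] * (p1[i - 1] - p1[i]);
        lap2 = K2[i] * (p2[i - 1] - p2[i]);
      } else {
        lap1 = K1[i] * (p1[i - 1] - 2.0 * p1[i] + p1[i + 1]);
        lap2 = K2[i] * (p2[i - 1] - 2.0 * p2[i] + p2[i + 1]);
      }
      const double Rsum = R1[i] + R2[i];
      const double cross = k12[i] * R1[i] * R2[i];
      const double F1 = -lambda * b1[i] * v1[i] + m1[i] * M;
      const double F2 = -lambda * b2[i] * v2[i] + m2[i] * M;
      a1[i] = (lap1 - k12[i] * R1[i] * Rsum * std::sin(p1[i])
                    - cross * std::sin(p1[i] - p2[i]) + F1) / I1[i];
      a2[i] = (lap2 + s2 * k12[i] * R2[i] * Rsum * std::sin(p2[i])
                    - cross * std::sin(p2[i] - p1[i]) + F2) / I2[i];
    }
  }
};

}  // namespace

// [[Rcpp::export]]
Rcpp::List rk4_chain_cpp(Rcpp::NumericVector phi1_0, Rcpp::NumericVector phi2_0,
                         Rcpp::NumericVector v1_0, Rcpp::NumericVector v2_0,
                         Rcpp::NumericVector I1, Rcpp::NumericVector I2,
                         Rcpp::NumericVector K1, Rcpp::NumericVector K2,
                         Rcpp::NumericVector R1, Rcpp::NumericVector R2,
                         Rcpp::NumericVector beta1, Rcpp::NumericVector beta2,
                         Rcpp::NumericVector k12, double lambda, double s2,
                         int mode, double M0, double omega,
                         Rcpp::NumericVector mask1, Rcpp::NumericVector mask2,
                         double dt, int n_steps, Rcpp::IntegerVector store) {
  const int n = phi1_0.size();
  Chain ch{n, I1.begin(), I2.begin(), K1.begin(), K2.begin(), R1.begin(),
           R2.begin(), beta1.begin(), beta2.begin(), k12.begin(),
           mask1.begin(), mask2.begin(), lambda, s2, M0, omega, mode};

  const int n_store = store.size();
  Rcpp::NumericVector times(n_store);
  Rcpp::NumericMatrix P1(n_store, n), P2(n_store, n), V1(n_store, n),
      V2(n_store, n);

  std::vector<double> y(4 * n), k1(4 * n), k2(4 * n), k3(4 * n), k4(4 * n),
      tmp(4 * n);
  for (int i = 0; i < n; ++i) {
    y[i] = phi1_0[i];
    y[n + i] = phi2_0[i];
    y[2 * n + i] = v1_0[i];
    y[3 * n + i] = v2_0[i];
  }

  int next = 0;
  auto snapshot = [&](int step) {
    times[next] = step * dt;
    for (int i = 0; i < n; ++i) {
      P1(next, i) = y[i];
      P2(next, i) = y[n + i];
      V1(next, i) = y[2 * n + i];
      V2(next, i) = y[3 * n + i];
      if (!std::isfinite(y[i]) || !std::isfinite(y[n + i]) ||
          !std::isfinite(y[2 * n + i]) || !std::isfinite(y[3 * n + i]))
        Rcpp::stop("non-finite state at t = %g s (step %d)",
                   step * dt, step);
    }
    ++next;
  };
  if (next < n_store && store[next] == 0) snapshot(0);

  for (int step = 0; step < n_steps; ++step) {
    const double t = step * dt;
    ch.deriv(t, y, k1);
    for (int i = 0; i < 4 * n; ++i) tmp[i] = y[i] + 0.5 * dt * k1[i];
    ch.deriv(t + 0.5 * dt, tmp, k2);
    for (int i = 0; i < 4 * n; ++i) tmp[i] = y[i] + 0.5 * dt * k2[i];
    ch.deriv(t + 0.5 * dt, tmp, k3);
    for (int i = 0; i < 4 * n; ++i) tmp[i] = y[i] + dt * k3[i];
    ch.deriv(t + dt, tmp, k4);
    for (int i = 0; i < 4 * n; ++i)
      y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    if (next < n_store && store[next] == step + 1) snapshot(step + 1);
    if ((step & 0xFFF) == 0) Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(Rcpp::Named("times") = times,
                            Rcpp::Named("phi1") = P1,
                            Rcpp::Named("phi2") = P2,
                            Rcpp::Named("dphi1") = V1,
                            Rcpp::Named("dphi2") = V2);
}
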