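# Independent pure-R reference integrator, written term by term from the
# Newton equations of the coupled-pendulum duplex (symmetric restoring
# convention, constant torque M0 on all pendulums). It never calls the
# package's RHS or integrator and exists only to cross-check them.

oracle_rhs <- function(t, y, p) {
  n <- p$n
  p1 <- y[1:n]; p2 <- y[n + 1:n]
  v1 <- y[2 * n + 1:n]; v2 <- y[3 * n + 1:n]
  lap1 <- c(p$K1[1] * (p1[2] - p1[1]),
            if (n > 2) p$K1[2:(n - 1)] *
              (p1[1:(n - 2)] - 2 * p1[2:(n - 1)] + p1[3:n]),
            p$K1[n] * (p1[n - 1] - p1[n]))
  lap2 <- c(p$K2[1] * (p2[2] - p2[1]),
            if (n > 2) p$K2[2:(n - 1)] *
              (p2[1:(n - 2)] - 2 * p2[2:(n - 1)] + p2[3:n]),
            p$K2[n] * (p2[n - 1] - p2[n]))
  a1 <- (lap1 - p$k12 * p$R1 * (p$R1 + p$R2) * sin(p1) -
           p$k12 * p$R1 * p$R2 * sin(p1 - p2) -
           p$lambda * p$beta1 * v1 + p$M0) / p$I1
  a2 <- (lap2 - p$k12 * p$R2 * (p$R1 + p$R2) * sin(p2) -
           p$k12 * p$R1 * p$R2 * sin(p2 - p1) -
           p$lambda * p$beta2 * v2 + p$M0) / p$I2
  c(v1, v2, a1, a2)
}

oracle_rk4 <- function(p, t_end, dt, y0 = NULL) {
  y <- if (is.null(y0)) numeric(4 * p$n) else y0
  steps <- round(t_end / dt)
  t <- 0
  for (s in seq_len(steps)) {
    k1 <- oracle_rhs(t, y, p)
    k2 <- oracle_rhs(t + dt / 2, y + dt / 2 * k1, p)
    k3 <- oracle_rhs(t + dt / 2, y + dt / 2 * k2, p)
    k4 <- oracle_rhs(t + dt, y + dt * k3, p)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- s * dt
  }
  y
}

oracle_params <- function(sys, M0 = 0) {
  c(sys[c("n", "I1", "I2", "K1", "K2", "R1", "R2",
          "beta1", "beta2", "k12", "lambda")], list(M0 = M0))
}

# Frozen per-base constants (SI), hand-entered independently of the package
# table: I (kg m^2), R (m), K (J), k12 (N/m), beta (J s).
reference_constants <- list(
  A = c(I = 7.61e-44, R = 5.80e-10, K = 2.35e-18, k12 = 6.20e-2, beta = 4.25e-34),
  T = c(I = 4.86e-44, R = 4.80e-10, K = 1.61e-18, k12 = 6.20e-2, beta = 2.91e-34),
  G = c(I = 8.22e-44, R = 5.70e-10, K = 2.27e-18, k12 = 9.60e-2, beta = 4.10e-34),
  C = c(I = 4.11e-44, R = 4.70e-10, K = 1.54e-18, k12 = 9.60e-2, beta = 2.79e-34)
)

# Closed-form linearized single-pair system for an A.T pair: small-angle
# stiffness over inertia, eigen-decomposition gives the two normal-mode
# angular frequencies and mode shapes.
pair_linearization <- function() {
  a <- reference_constants$A; t <- reference_constants$T
  k12 <- a[["k12"]]; Rsum <- a[["R"]] + t[["R"]]
  d <- k12 * a[["R"]] * t[["R"]]
  B <- matrix(c(-(k12 * a[["R"]] * Rsum + d) / a[["I"]], d / a[["I"]],
                d / t[["I"]], -(k12 * t[["R"]] * Rsum + d) / t[["I"]]),
              2, 2, byrow = TRUE)
  ev <- eigen(B)
  list(omega = sqrt(-ev$values), vectors = ev$vectors)
}

# Angular frequency of a sampled single-mode oscillation from interpolated
# zero-crossing times: consecutive crossings are half a period apart.
zero_crossing_frequency <- function(times, values) {
  s <- sign(values)
  idx <- which(s[-1] * s[-length(s)] < 0)
  stopifnot(length(idx) >= 3)
  tc <- times[idx] - values[idx] * (times[idx + 1] - times[idx]) /
    (values[idx + 1] - values[idx])
  pi * (length(tc) - 1) / (tc[length(tc)] - tc[1])
}

# Minimal trajectory object for observable tests that need exact angles.
fake_trajectory <- function(times, phi1, phi2 = phi1 * 0) {
  structure(list(times = times, phi1 = phi1, phi2 = phi2,
                 dphi1 = phi1 * 0, dphi2 = phi2 * 0,
                 config = list(n = ncol(phi1), t_end = max(times))),
            class = "trajectory")
}
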