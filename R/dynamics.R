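#' External torque specification
#'
#' The external influence on pendulum (j, i) is
#' `F_ji(t) = -lambda * beta_ji * dphi_ji/dt + M(t)`: a velocity-proportional
#' dissipation term modelling the surrounding liquid, plus a driving torque
#' `M(t)`. Three driving modes are supported: a constant torque
#' `M(t) = M0`, a periodic torque `M(t) = M0 * cos(omega * t)`, and no
#' driving. By default `M(t)` acts on every pendulum of both strands; the
#' target set is configurable.
#'
#' @param mode One of `"constant"`, `"cosine"`, `"zero"`.
#' @param M0 Torque amplitude in N m (default `1e-22`, the magnitude for
#'   which a constant drive is practically indistinguishable from a cosine
#'   drive at angular frequencies up to 1e9 s^-1).
#' @param omega Angular frequency in s^-1, cosine mode only (must be >= 0).
#' @param strands Integer subset of `c(1, 2)`: which strands receive `M(t)`.
#' @param sites Optional integer vector of site indices receiving `M(t)`;
#'   `NULL` means all sites.
#' @return An object of class `forcing_spec`.
#' @export
#' @examples
#' forcing_spec("constant", M0 = 1e-22)
#' forcing_spec("cosine", M0 = 1e-22, omega = 1e9)
forcing_spec <- function(mode = c("constant", "cosine", "zero"),
                         M0 = 1e-22, omega = 0,
                         strands = c(1L, 2L), sites = NULL) {
  mode <- match.arg(mode)
  if (!is.finite(M0)) stop("'M0' must be finite", call. = FALSE)
  if (!is.finite(omega) || omega < 0)
    stop("'omega' must be a finite non-negative frequency", call. = FALSE)
  strands <- sort(unique(as.integer(strands)))
  if (length(strands) < 1L || !all(strands %in% c(1L, 2L)))
    stop("'strands' must be a non-empty subset of c(1, 2)", call. = FALSE)
  if (!is.null(sites)) {
    sites <- sort(unique(as.integer(sites)))
    if (any(sites < 1L)) stop("'sites' must be positive indices", call. = FALSE)
  }
  structure(list(mode = mode, M0 = M0, omega = omega,
                 strands = strands, sites = sites),
            class = "forcing_spec")
}

#' @export
print.forcing_spec <- function(x, ...) {
  desc <- switch(x$mode,
    zero     = "M(t) = 0",
    constant = sprintf("M(t) = %g N m", x$M0),
    cosine   = sprintf("M(t) = %g cos(%g t) N m", x$M0, x$omega))
  tgt <- if (is.null(x$sites)) "all sites" else
    sprintf("%d site(s)", length(x$sites))
  cat(sprintf("<forcing_spec> %s on strand(s) %s, %s\n", desc,
              paste(x$strands, collapse = ","), tgt))
  invisible(x)
}

#' Evaluate the driving torque M(t)
#'
#' @param t Time(s) in seconds, each >= 0.
#' @param forcing A [forcing_spec()].
#' @return Torque in N m, same length as `t`.
#' @export
external_torque <- function(t, forcing) {
  stopifnot(inherits(forcing, "forcing_spec"))
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  switch(forcing$mode,
         zero     = rep(0, length(t)),
         constant = rep(forcing$M0, length(t)),
         cosine   = forcing$M0 * cos(forcing$omega * t))
}

target_mask <- function(forcing, n) {
  mask <- matrix(0, 2, n)
  sites <- if (is.null(forcing$sites)) seq_len(n) else forcing$sites
  if (any(sites > n))
    stop("forcing targets sites beyond the chain length", call. = FALSE)
  mask[forcing$strands, sites] <- 1
  mask
}

sign_factor <- function(strand2_sign = c("symmetric", "as_printed")) {
  switch(match.arg(strand2_sign), symmetric = -1, as_printed = +1)
}

#' Initial state of the pendulum system
#'
#' The default initial condition is mechanical equilibrium: every angle and
#' angular velocity zero at t = 0. Arbitrary initial angle and velocity
#' profiles may be supplied instead.
#'
#' @param system A [build_system()] result.
#' @param phi Optional 2 x n matrix of initial angles (rad); row j = strand j.
#' @param dphi Optional 2 x n matrix of initial angular velocities (rad/s).
#' @return An object of class `chain_state` with fields `t`, `phi`, `dphi`.
#' @export
initial_state <- function(system, phi = NULL, dphi = NULL) {
  stopifnot(inherits(system, "chain_system"))
  n <- system$n
  shape <- function(m, what) {
    if (is.null(m)) return(matrix(0, 2, n))
    m <- as.matrix(m)
    if (!identical(dim(m), c(2L, n)))
      stop(sprintf("'%s' must be a 2 x %d matrix", what, n), call. = FALSE)
    if (any(!is.finite(m)))
      stop(sprintf("'%s' must be finite", what), call. = FALSE)
    unname(m)
  }
  structure(list(t = 0, phi = shape(phi, "phi"), dphi = shape(dphi, "dphi")),
            class = "chain_state")
}

#' Right-hand side of the equations of motion
#'
#' Evaluates the time derivative of a state under the Newton equations of
#' the coupled-pendulum chain. For an interior site i of strand 1,
#' \deqn{I_{1i} \ddot\varphi_{1i} = K_{1i}(\varphi_{1,i-1} - 2\varphi_{1i}
#'   + \varphi_{1,i+1}) - k_{12,i} R_{1i}(R_{1i}+R_{2i}) \sin\varphi_{1i}
#'   - k_{12,i} R_{1i} R_{2i} \sin(\varphi_{1i}-\varphi_{2i}) + F_{1i}(t),}
#' with single-neighbour backbone coupling at the two chain ends and the
#' mirrored equation on strand 2. `F_ji(t) = -lambda beta_ji dphi_ji/dt +
#' M(t)` on targeted pendulums. Under the default `"symmetric"` convention
#' the strand-2 single-base hydrogen-bond term is restoring
#' (`- k12 R2 (R1+R2) sin(phi2)`), mirroring strand 1; `"as_printed"`
#' flips that term's sign and is provided as a diagnostic only — it makes
#' the equilibrium a saddle point and solutions grow without bound.
#'
#' @param state A [initial_state()]-style `chain_state` (uses `t`, `phi`,
#'   `dphi`).
#' @param system A `chain_system`.
#' @param forcing A [forcing_spec()].
#' @param strand2_sign `"symmetric"` (default) or `"as_printed"`.
#' @return List with `dphi` (the angular velocities) and `ddphi` (angular
#'   accelerations), both 2 x n.
#' @export
chain_rhs <- function(state, system, forcing = forcing_spec("zero"),
                      strand2_sign = c("symmetric", "as_printed")) {
  stopifnot(inherits(system, "chain_system"))
  s2 <- sign_factor(strand2_sign)
  phi <- state$phi; dphi <- state$dphi
  if (any(!is.finite(phi)) || any(!is.finite(dphi)))
    stop("non-finite state", call. = FALSE)
  n <- system$n
  stopifnot(identical(dim(phi), c(2L, n)))
  mask <- target_mask(forcing, n)
  M <- external_torque(max(state$t, 0), forcing)
  lap <- function(x, K) {
    c(K[1] * (x[2] - x[1]),
      if (n > 2) K[2:(n - 1)] * (x[1:(n - 2)] - 2 * x[2:(n - 1)] + x[3:n]),
      K[n] * (x[n - 1] - x[n]))
  }
  p1 <- phi[1, ]; p2 <- phi[2, ]
  F1 <- -system$lambda * system$beta1 * dphi[1, ] + mask[1, ] * M
  F2 <- -system$lambda * system$beta2 * dphi[2, ] + mask[2, ] * M
  dd1 <- (lap(p1, system$K1) -
            system$k12 * system$R1 * (system$R1 + system$R2) * sin(p1) -
            system$k12 * system$R1 * system$R2 * sin(p1 - p2) + F1) / system$I1
  dd2 <- (lap(p2, system$K2) +
            s2 * system$k12 * system$R2 * (system$R1 + system$R2) * sin(p2) -
            system$k12 * system$R1 * system$R2 * sin(p2 - p1) + F2) / system$I2
  list(dphi = dphi, ddphi = rbind(dd1, dd2, deparse.level = 0))
}

#' Integrate the chain dynamics
#'
#' Solves the initial-value problem for the 2n Newton equations with a
#' fixed-step classical fourth-order Runge-Kutta scheme. The default step
#' `dt = 1e-14` s resolves the fastest linearized backbone mode (period
#' about 5e-13 s for the tabulated constants) roughly fifty-fold. The
#' integration is fully deterministic: identical inputs give bit-identical
#' trajectories.
#'
#' @param system A [build_system()] result.
#' @param forcing A [forcing_spec()]; default is the constant 1e-22 N m
#'   torque on all pendulums.
#' @param t_end End of the integration window (s), > 0. The realized span is
#'   `round(t_end / dt) * dt`.
#' @param dt Time step (s), default `1e-14`.
#' @param n_out Approximate number of stored snapshots (default 1000); the
#'   initial and final states are always stored. Use `Inf` to keep every
#'   step.
#' @param initial Optional [initial_state()]; default equilibrium.
#' @param strand2_sign Sign convention for the strand-2 hydrogen-bond term;
#'   see [chain_rhs()].
#' @param max_step_ratio Reject steps that under-resolve the fastest
#'   linearized mode: an error is thrown if `dt` exceeds `max_step_ratio`
#'   times the shortest backbone period `2*pi/sqrt(4*K/I)`.
#' @return An object of class `trajectory`: list with `times` (length T,
#'   starting at 0, strictly increasing), matrices `phi1`, `phi2`, `dphi1`,
#'   `dphi2` (T x n), and a `config` fingerprint (sequence, lambda, forcing,
#'   solver settings).
#' @export
#' @examples
#' sys <- build_system("ATGCAT")
#' tr <- integrate_chain(sys, t_end = 1e-12, n_out = 50)
#' tr$times[1:3]
integrate_chain <- function(system,
                            forcing = forcing_spec("constant", M0 = 1e-22),
                            t_end, dt = 1e-14, n_out = 1000,
                            initial = NULL,
                            strand2_sign = c("symmetric", "as_printed"),
                            max_step_ratio = 0.5) {
  stopifnot(inherits(system, "chain_system"), inherits(forcing, "forcing_spec"))
  strand2_sign <- match.arg(strand2_sign)
  if (!is.finite(t_end) || t_end <= 0) stop("'t_end' must be > 0", call. = FALSE)
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be > 0", call. = FALSE)
  fastest_period <- 2 * pi / sqrt(max(4 * c(system$K1 / system$I1,
                                            system$K2 / system$I2)))
  if (dt > max_step_ratio * fastest_period)
    stop(sprintf(paste0("dt = %g s is too large for stability: the fastest ",
                        "backbone mode has period %.3g s"),
                 dt, fastest_period), call. = FALSE)
  if (is.null(initial)) initial <- initial_state(system)
  stopifnot(inherits(initial, "chain_state"))
  n <- system$n
  stopifnot(identical(dim(initial$phi), c(2L, n)))
  n_steps <- max(1L, as.integer(round(t_end / dt)))
  if (is.infinite(n_out)) {
    store <- 0:n_steps
  } else {
    stride <- max(1L, n_steps %/% as.integer(n_out))
    store <- unique(c(seq.int(0L, n_steps, by = stride), n_steps))
  }
  mask <- target_mask(forcing, n)
  mode_code <- match(forcing$mode, c("zero", "constant", "cosine")) - 1L
  res <- rk4_chain_cpp(
    initial$phi[1, ], initial$phi[2, ], initial$dphi[1, ], initial$dphi[2, ],
    system$I1, system$I2, system$K1, system$K2, system$R1, system$R2,
    system$beta1, system$beta2, system$k12, system$lambda,
    sign_factor(strand2_sign), mode_code, forcing$M0, forcing$omega,
    mask[1, ], mask[2, ], dt, n_steps, as.integer(store))
  structure(list(
    times = res$times, phi1 = res$phi1, phi2 = res$phi2,
    dphi1 = res$dphi1, dphi2 = res$dphi2,
    config = list(n = n, strand1 = system$strand1, lambda = system$lambda,
                  forcing = unclass(forcing), dt = dt, t_end = n_steps * dt,
                  n_steps = n_steps, strand2_sign = strand2_sign,
                  integrator = "rk4-fixed",
                  package_version = as.character(utils::packageVersion("dnatorsion")))),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> n = %d pairs, %d snapshots over [0, %.3g s], lambda = %g\n",
    x$config$n, length(x$times), x$config$t_end, x$config$lambda))
  cat(sprintf(" integrator %s, dt = %g s, strand-2 sign: %s\n",
              x$config$integrator, x$config$dt, x$config$strand2_sign))
  invisible(x)
}

#' Final state of a trajectory
#'
#' @param traj A [integrate_chain()] result.
#' @return A `chain_state` at the last stored time.
#' @export
final_state <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  T <- length(traj$times)
  structure(list(t = traj$times[T],
                 phi = rbind(traj$phi1[T, ], traj$phi2[T, ]),
                 dphi = rbind(traj$dphi1[T, ], traj$dphi2[T, ])),
            class = "chain_state")
}

#' Total kinetic energy along a trajectory
#'
#' `sum_ji I_ji (dphi_ji/dt)^2 / 2` at every stored time; with no driving
#' torque and positive damping this decays over long windows.
#'
#' @param traj A [integrate_chain()] result.
#' @param system The `chain_system` the trajectory was computed from.
#' @return Numeric vector of energies (J), one per stored time.
#' @export
kinetic_energy <- function(traj, system) {
  stopifnot(inherits(traj, "trajectory"), inherits(system, "chain_system"))
  0.5 * (traj$dphi1^2 %*% system$I1 + traj$dphi2^2 %*% system$I2)[, 1]
}
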