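test_that("the external torque follows its mode", {
  expect_identical(external_torque(c(0, 1e-9, 5),
                                   forcing_spec("constant", M0 = 1e-22)),
                   rep(1e-22, 3))
  cosf <- forcing_spec("cosine", M0 = 1e-22, omega = 1e9)
  expect_identical(external_torque(0, cosf), 1e-22)
  expect_equal(external_torque(2e-9, cosf), 1e-22 * cos(2), tolerance = 1e-15)
  expect_identical(external_torque(c(0, 1), forcing_spec("zero")), c(0, 0))
  expect_error(external_torque(-1, cosf), "non-negative")
  expect_error(forcing_spec("cosine", omega = -1), "omega")
})

test_that("equilibrium with no driving is an exact fixed point of the RHS", {
  sys <- build_system(random_sequence(15, seed = 2), lambda = 1.3)
  st <- initial_state(sys)
  d <- chain_rhs(st, sys, forcing_spec("zero"))
  expect_identical(d$dphi, matrix(0, 2, 15))
  expect_identical(d$ddphi, matrix(0, 2, 15))
})

test_that("RHS matches a term-by-term hand evaluation on poly(A).poly(T)", {
  a <- reference_constants$A; t <- reference_constants$T
  eps <- 1e-6
  sys <- build_system("AAA")
  k12 <- a[["k12"]]; Ra <- a[["R"]]; Rt <- t[["R"]]

  # interior site displaced: backbone K_A(0 - 2e + 0), single-base and
  # pair hydrogen-bond torques, divided by I_A
  phi <- matrix(0, 2, 3); phi[1, 2] <- eps
  d <- chain_rhs(initial_state(sys, phi = phi), sys, forcing_spec("zero"))
  expected_mid <- (a[["K"]] * (-2 * eps) -
                     k12 * Ra * (Ra + Rt) * sin(eps) -
                     k12 * Ra * Rt * sin(eps)) / a[["I"]]
  expect_equal(d$ddphi[1, 2], expected_mid, tolerance = 1e-14)

  # boundary site: single-neighbour coupling K_A(phi_12 - phi_11)
  phi <- matrix(0, 2, 3); phi[1, 1] <- eps
  d <- chain_rhs(initial_state(sys, phi = phi), sys, forcing_spec("zero"))
  expected_b <- (a[["K"]] * (0 - eps) -
                   k12 * Ra * (Ra + Rt) * sin(eps) -
                   k12 * Ra * Rt * sin(eps)) / a[["I"]]
  expect_equal(d$ddphi[1, 1], expected_b, tolerance = 1e-14)
  # its neighbour only feels the backbone
  expect_equal(d$ddphi[1, 2], a[["K"]] * eps / a[["I"]], tolerance = 1e-14)

  # strand 2: restoring sign by default, printed sign under the diagnostic
  phi <- matrix(0, 2, 3); phi[2, 2] <- eps
  bb <- t[["K"]] * (-2 * eps)            # strand-2 backbone, interior site
  hb <- k12 * Rt * (Ra + Rt) * sin(eps)  # strand-2 base is T at an A site
  cross <- k12 * Ra * Rt * sin(eps)
  d_sym <- chain_rhs(initial_state(sys, phi = phi), sys, forcing_spec("zero"))
  expect_equal(d_sym$ddphi[2, 2], (bb - hb - cross) / t[["I"]],
               tolerance = 1e-14)
  d_pr <- chain_rhs(initial_state(sys, phi = phi), sys, forcing_spec("zero"),
                    strand2_sign = "as_printed")
  expect_equal(d_pr$ddphi[2, 2], (bb + hb - cross) / t[["I"]],
               tolerance = 1e-14)
})

test_that("dissipation and driving enter the RHS as F = -lambda beta v + M", {
  sys <- build_system("GCGC", lambda = 2)
  v <- matrix(rnorm(8, sd = 1e3), 2, 4)
  st <- initial_state(sys, dphi = v)
  d0 <- chain_rhs(st, sys, forcing_spec("zero"))
  dM <- chain_rhs(st, sys, forcing_spec("constant", M0 = 1e-22))
  expect_equal(dM$ddphi[1, ] - d0$ddphi[1, ], 1e-22 / sys$I1, tolerance = 1e-12)
  # damping contribution is -lambda*beta*v/I
  expect_equal(d0$ddphi[1, ], -2 * sys$beta1 * v[1, ] / sys$I1,
               tolerance = 1e-10)
  # driving can be restricted to a strand / site subset
  d1 <- chain_rhs(initial_state(sys), sys,
                  forcing_spec("constant", M0 = 1e-22, strands = 1,
                               sites = 2))
  expect_identical(d1$ddphi[2, ], rep(0, 4))
  expect_identical(d1$ddphi[1, c(1, 3, 4)], rep(0, 3))
  expect_gt(d1$ddphi[1, 2], 0)
})

test_that("initial states validate shape and keep overrides verbatim", {
  sys <- build_system("ATGC")
  st <- initial_state(sys)
  expect_identical(st$phi, matrix(0, 2, 4))
  expect_identical(st$dphi, matrix(0, 2, 4))
  phi <- matrix(runif(8), 2, 4)
  expect_identical(initial_state(sys, phi = phi)$phi, unname(phi))
  expect_error(initial_state(sys, phi = matrix(0, 2, 3)), "2 x 4")
  expect_error(initial_state(sys, phi = matrix(NaN, 2, 4)), "finite")
  expect_error(chain_rhs(structure(list(t = 0, phi = matrix(Inf, 2, 4),
                                        dphi = matrix(0, 2, 4)),
                                   class = "chain_state"),
                         sys), "non-finite")
})

test_that("integration preserves the equilibrium fixed point exactly", {
  sys <- build_system(random_sequence(12, seed = 5))
  tr <- integrate_chain(sys, forcing_spec("zero"), t_end = 5e-13, n_out = 10)
  expect_identical(max(abs(tr$phi1)), 0)
  expect_identical(max(abs(tr$phi2)), 0)
  expect_identical(max(abs(tr$dphi1)), 0)
})

test_that("trajectories are deterministic and well-formed", {
  sys <- build_system(random_sequence(8, seed = 9), lambda = 0.7)
  f <- forcing_spec("constant", M0 = 1e-22)
  tr1 <- integrate_chain(sys, f, t_end = 2e-12, n_out = 37)
  tr2 <- integrate_chain(sys, f, t_end = 2e-12, n_out = 37)
  expect_identical(tr1$phi1, tr2$phi1)
  expect_identical(tr1$dphi2, tr2$dphi2)
  expect_identical(tr1$times[1], 0)
  expect_true(all(diff(tr1$times) > 0))
  expect_identical(nrow(tr1$phi1), length(tr1$times))
  # full-resolution storage keeps every step
  trf <- integrate_chain(sys, f, t_end = 1e-13, n_out = Inf)
  expect_identical(length(trf$times), 11L)
})

test_that("invalid solver settings are rejected", {
  sys <- build_system("ATAT")
  expect_error(integrate_chain(sys, t_end = 0), "t_end")
  expect_error(integrate_chain(sys, t_end = 1e-12, dt = -1), "dt")
  expect_error(integrate_chain(sys, t_end = 1e-11, dt = 1e-12),
               "too large for stability")
})

test_that("production integrator agrees with the independent RK4 oracle", {
  sys <- build_system(random_sequence(6, seed = 21), lambda = 1)
  tr <- integrate_chain(sys, forcing_spec("constant", M0 = 1e-22),
                        t_end = 2e-12, dt = 1e-14)
  y <- oracle_rk4(oracle_params(sys, M0 = 1e-22), 2e-12, 1e-15)
  fs <- final_state(tr)
  expect_lt(max(abs(fs$phi[1, ] - y[1:6]), abs(fs$phi[2, ] - y[7:12])), 1e-9)
})

test_that("with no driving, damping makes the kinetic energy decay and
           larger viscosity damps faster", {
  s <- random_sequence(20, seed = 13)
  phi0 <- matrix(0, 2, 20); phi0[1, ] <- 1e-3
  energy_end <- sapply(c(0.5, 1, 2, 4), function(lam) {
    sys <- build_system(s, lambda = lam)
    tr <- integrate_chain(sys, forcing_spec("zero"), t_end = 4e-10,
                          n_out = 100, initial = initial_state(sys, phi = phi0))
    ke <- kinetic_energy(tr, sys)
    expect_lt(mean(tail(ke, 25)), mean(ke[2:26]))  # long-window decay
    mean(tail(ke, 25))
  })
  expect_true(all(diff(energy_end) < 0))
})

test_that("the printed strand-2 sign makes equilibrium unstable while the
           symmetric convention keeps deflections bounded", {
  sys <- build_system("ATAT")
  f <- forcing_spec("constant", M0 = 1e-22)
  sym <- integrate_chain(sys, f, t_end = 3e-11, n_out = 50)
  prn <- integrate_chain(sys, f, t_end = 3e-11, n_out = 50,
                         strand2_sign = "as_printed")
  expect_lt(max(abs(sym$phi2)), 0.05)
  expect_gt(max(abs(prn$phi2)) / max(abs(sym$phi2)), 1e2)
})

test_that("the static small-angle solve is linear in the drive and matches
           forced relaxation", {
  sys <- build_system(random_sequence(10, seed = 4), lambda = 1)
  z <- linearized_steady_state(sys, forcing_spec("zero"))
  expect_identical(max(abs(z)), 0)
  s1 <- linearized_steady_state(sys, forcing_spec("constant", M0 = 1e-22))
  s2 <- linearized_steady_state(sys, forcing_spec("constant", M0 = 2e-22))
  expect_equal(s2, 2 * s1, tolerance = 1e-12)
  expect_error(linearized_steady_state(sys, forcing_spec("cosine",
                                                         omega = 1e9)),
               "constant")
  # relaxed dynamics land on the static profile
  tr <- integrate_chain(sys, forcing_spec("constant", M0 = 1e-22),
                        t_end = 4e-9, n_out = 50)
  fs <- final_state(tr)
  expect_equal(fs$phi[1, ], unname(s1["strand1", ]),
               tolerance = 1e-3)
})
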