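test_that("rhs matches hand-derived values in the decoupled zero state", {
  p <- mf_params(tau = 10, drive = drive_params(Ibar_e = 0, Delta_e = 0))
  x <- mean_field_state(r_e = 0, u_e = 0, s_e = 0, r_i = 0, u_i = 0,
                        s_i = 0, s_n = 0)
  d <- mean_field_rhs(x, p)
  # with all couplings, widths and drives zero: dr/dt = 0, du/dt = -1/(2 tau)
  expect_equal(unname(d[c("r_e", "r_i")]), c(0, 0))
  expect_equal(unname(d[c("u_e", "u_i")]), rep(-1 / (2 * 10), 2))
  expect_equal(unname(d[c("s_e", "s_i")]), c(0, 0))
  # NMDA gate decays alone when s_e = 0
  x2 <- mean_field_state(s_n = 0.4)
  d2 <- mean_field_rhs(x2, p)
  expect_equal(unname(d2["s_n"]), -0.4 / p$kinetics$tau_n)
})

test_that("analytic Jacobian agrees with central finite differences", {
  set.seed(3)
  p <- reference_config()
  q <- pingmf:::.flat_params(p)
  h <- 1e-6
  for (k in 1:50) {
    x <- c(runif(1, 0, 0.1), runif(1, -1.5, 1.5), runif(1, 0, 0.3),
           runif(1, 0, 0.1), runif(1, -1.5, 1.5), runif(1, 0, 0.6),
           runif(1, 0, 1))
    J <- mf_jacobian(p, x)
    Jfd <- matrix(0, 7, 7)
    for (j in 1:7) {
      e <- rep(0, 7); e[j] <- h
      Jfd[, j] <- (pingmf:::.mf_rhs_core(x + e, q) -
                     pingmf:::.mf_rhs_core(x - e, q)) / (2 * h)
    }
    expect_lt(max(abs(unclass(J) - Jfd)), 1e-5)
  }
  # gating row is exactly linear
  expect_equal(mf_jacobian(p, rep(0.1, 7))["s_e", "s_e"],
               -1 / p$kinetics$tau_e)
})

test_that("homogeneous uncoupled equilibrium rate equals the closed-form QIF rate", {
  for (Ihat in c(0.6, 1, 2, 5)) {
    p <- uncoupled_params(Ihat = Ihat, tau = 10)
    eq <- find_equilibrium(p)
    expect_false(is.null(eq))
    expect_equal(unname(eq["r_e"]), qif_rate_closed_form(Ihat, 10),
                 tolerance = 1e-8)
    # closed form itself cross-checked against the quadrature oracle
    expect_equal(qif_rate_closed_form(Ihat, 10),
                 qif_rate_quadrature(Ihat, 10), tolerance = 1e-8)
  }
  # below threshold the excitatory population is silent
  p0 <- uncoupled_params(Ihat = 0.3)
  eq0 <- find_equilibrium(p0)
  expect_lt(abs(unname(eq0["r_e"])), 1e-10)
})

test_that("a stable equilibrium initial condition yields a constant trajectory", {
  p <- uncoupled_params(Ihat = 2)
  eq <- find_equilibrium(p)
  traj <- integrate_mean_field(p, x0 = eq, duration = 500)
  expect_lt(max(abs(traj$r_e - eq[["r_e"]])), 1e-6)
  expect_lt(max(abs(traj$u_e - eq[["u_e"]])), 1e-6)
})

test_that("integration converges under tolerance refinement", {
  p <- reference_config()
  t1 <- integrate_mean_field(p, duration = 800, rtol = 1e-8, atol = 1e-10)
  t2 <- integrate_mean_field(p, duration = 800, rtol = 5e-9, atol = 5e-11)
  end1 <- unlist(t1[nrow(t1), -1]); end2 <- unlist(t2[nrow(t2), -1])
  expect_lt(max(abs(end1 - end2)), 1e-5)
})

test_that("rates stay nonnegative and gates bounded along reference trajectories", {
  p <- reference_config()
  traj <- integrate_mean_field(p, duration = 2000)
  expect_gt(min(traj$r_e), -1e-9)
  expect_gt(min(traj$r_i), -1e-9)
  expect_true(all(traj$s_n >= 0 & traj$s_n <= 1))
  expect_true(all(is.finite(as.matrix(traj))))
})
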