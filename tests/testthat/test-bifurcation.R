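test_that("equilibria satisfy the residual postcondition and numerical stability", {
  p <- reference_config()
  eq <- find_equilibrium(p)
  expect_false(is.null(eq))
  expect_lt(attr(eq, "rhs_norm"), 1e-10)

  # a genuinely stable equilibrium: uncoupled population with drive
  # heterogeneity (Delta > 0 damps the rate-potential pair; at Delta = 0
  # the uncoupled reduction is a neutral center)
  p0 <- mf_params(tau = 10, drive = drive_params(Ibar_e = 2, Delta_e = 0.1))
  eq0 <- find_equilibrium(p0)
  ev <- eigen(mf_jacobian(p0, eq0), only.values = TRUE)$values
  expect_true(all(Re(ev) < 0))
  # forward integration from a small perturbation returns to it
  x1 <- as.numeric(eq0) + 1e-4
  traj <- integrate_mean_field(p0, x0 = do.call(mean_field_state,
                                                as.list(x1)),
                               duration = 2000)
  expect_lt(max(abs(unlist(traj[nrow(traj), -1]) - as.numeric(eq0))), 1e-6)
})

test_that("jacobian warns near switching manifolds", {
  p <- reference_config()
  x <- mean_field_state(u_e = p$Vhat_ex)   # exactly on the manifold
  expect_warning(mf_jacobian(p, x), "switching manifold")
})

test_that("1D Hopf scan certifies every reported point and labels directions", {
  p <- reference_config()
  pts <- hopf_scan_1d(p, "gbar_i_ampa", 0.02, 6, n_grid = 150)
  expect_gt(length(pts), 0)
  for (h in pts) {
    expect_lt(abs(Re(h$eigenvalue)), 1e-6)
    expect_gt(Im(h$eigenvalue), 0)
    expect_true(h$direction %in% c("onset", "offset"))
    # independent re-verification: fresh equilibrium + eigen-solve at the point
    ph <- set_param(p, "gbar_i_ampa", h$value)
    eqh <- find_equilibrium(ph, guess = h$state)
    ev <- eigen(mf_jacobian(ph, eqh), only.values = TRUE)$values
    cp <- ev[abs(Im(ev)) > 1e-8]
    expect_lt(abs(max(Re(cp))), 1e-6)
  }
  # crossings alternate: an onset is followed by an offset and vice versa
  if (length(pts) >= 2) {
    dirs <- vapply(pts, `[[`, "", "direction")
    expect_equal(dirs[1], "onset")
    expect_true(all(dirs[-1] != dirs[-length(dirs)]))
  }
})

test_that("a sweep without eigenvalue sign change returns an empty list", {
  p0 <- uncoupled_params(Ihat = 2)
  pts <- hopf_scan_1d(p0, "gbar_i_ampa", 0.01, 0.2, n_grid = 30)
  expect_length(pts, 0)
})

test_that("single-point 2D curve reduces to the 1D scan", {
  p <- reference_config()
  pts1 <- hopf_scan_1d(p, "gamma_i_ampa", 0.005, 3, n_grid = 100)
  cv <- hopf_curve_2d(p, "gbar_e_gaba", get_param(p, "gbar_e_gaba"),
                      "gamma_i_ampa", 0.005, 3, n_grid = 100, tol = 1e-5)
  expect_equal(nrow(cv), length(pts1))
  if (nrow(cv))
    expect_equal(sort(cv$y), sort(vapply(pts1, `[[`, 0, "value")),
                 tolerance = 1e-4)
  expect_true(all(abs(cv$re_lambda) < 1e-6))
})

test_that("amplitude metric separates the oscillatory and equilibrium sides", {
  p <- reference_config()
  amp_h <- oscillation_amplitude(p, duration = 2000, window = 800)
  expect_true(amp_h$oscillating)
  expect_gt(amp_h$amplitude, 0)
  # just past the NMDA offset: gamma oscillation dead (equilibrium side;
  # the equilibrium there is weakly damped, so integrate past the ringing)
  p_dead <- set_param(p, "gbar_i_nmda", 0.2)
  amp_d <- oscillation_amplitude(p_dead, duration = 4000, window = 800)
  expect_false(amp_d$oscillating)
})
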