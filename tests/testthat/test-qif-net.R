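test_that("network construction is deterministic and degenerate widths give identical neurons", {
  p <- reference_config()
  n1 <- build_network(p, N_e = 50, N_i = 20, seed = 99)
  n2 <- build_network(p, N_e = 50, N_i = 20, seed = 99)
  expect_identical(n1$ge, n2$ge)
  expect_identical(n1$Ihat, n2$Ihat)
  n3 <- build_network(p, N_e = 50, N_i = 20, seed = 100)
  expect_false(identical(n1$ge, n3$ge))

  p0 <- uncoupled_params(Ihat = 1)   # all half-widths zero
  n0 <- build_network(p0, N_e = 30, N_i = 10, seed = 1)
  expect_equal(length(unique(n0$Ihat[1:30])), 1)
  expect_equal(length(unique(n0$ge)), 1)
})

test_that("subthreshold quiescent network fires no spikes", {
  p <- mf_params(tau = 10, drive = drive_params(Ibar_e = 0, Delta_e = 0))
  net <- build_network(p, N_e = 20, N_i = 10, seed = 1)
  # start everyone at rest (theta = -pi/2 corresponds to u = -1)
  net$theta0 <- rep(2 * atan(-1), 30)
  rec <- simulate_network(net, duration = 200, dt = 0.02)
  expect_equal(nrow(rec$spikes), 0)
})

test_that("single uncoupled neuron reproduces the closed-form QIF frequency within 2%", {
  for (Ihat in c(0.6, 1, 2, 5)) {
    p <- uncoupled_params(Ihat = Ihat, tau = 10)
    net <- build_network(p, N_e = 1, N_i = 1, seed = 1)
    net$Ihat[2] <- 0                      # silence the lone FSI
    rec <- simulate_network(net, duration = 3000, dt = 0.01)
    st <- rec$spikes$time[rec$spikes$neuron == 1]
    expect_gt(length(st), 3)
    rate_sim <- 1 / mean(diff(st))        # 1/ms from inter-spike intervals
    rate_th <- qif_rate_closed_form(Ihat, 10)
    expect_lt(abs(rate_sim - rate_th) / rate_th, 0.02)
  }
})

test_that("population rate conserves spike counts exactly and handles empty records", {
  p <- reference_config()
  net <- build_network(p, N_e = 80, N_i = 20, seed = 3)
  rec <- simulate_network(net, duration = 400)
  for (pop in c("e", "i")) {
    n_pop <- if (pop == "e") 80 else 20
    tr <- population_rate(rec, pop, bin = 1, smooth_width = 0)
    expect_equal(sum(tr$rate) * n_pop * 1,
                 sum(rec$spikes$population == pop))
  }
  # empty record: all-zero trace
  p0 <- mf_params(tau = 10, drive = drive_params(Ibar_e = 0, Delta_e = 0))
  net0 <- build_network(p0, N_e = 10, N_i = 5, seed = 1)
  net0$theta0 <- rep(2 * atan(-1), 15)
  rec0 <- simulate_network(net0, duration = 100, dt = 0.02)
  tr0 <- population_rate(rec0, "e", bin = 1)
  expect_true(all(tr0$rate == 0))
})

test_that("a Poisson-like asynchronous population reports its mean rate correctly", {
  # quenched-heterogeneous uncoupled population firing asynchronously:
  # wide Lorentzian drive, no synapses; compare binned rate to the mean of
  # the per-neuron closed-form rates (the analytic expectation)
  p <- mf_params(tau = 10,
                 drive = drive_params(Ibar_e = 3, Delta_e = 0.5))
  net <- build_network(p, N_e = 200, N_i = 1, seed = 8)
  net$Ihat[201] <- 0
  rec <- simulate_network(net, duration = 2000, dt = 0.02)
  tr <- population_rate(rec, "e", bin = 1)
  expected <- mean(qif_rate_closed_form(net$Ihat[1:200], 10))
  observed <- mean(tr$rate[tr$t > 200])
  n_spk <- sum(rec$spikes$time > 200 & rec$spikes$population == "e")
  se <- sqrt(n_spk) / (200 * 1800 / 1000) / 1000   # Poisson SE in 1/ms
  expect_lt(abs(observed - expected), 3 * se + 0.02 * expected)
})

test_that("simulation is deterministic under a fixed seed and dt", {
  p <- reference_config()
  net <- build_network(p, N_e = 40, N_i = 10, seed = 5)
  r1 <- simulate_network(net, duration = 300)
  r2 <- simulate_network(net, duration = 300)
  expect_identical(r1$spikes, r2$spikes)
  expect_identical(r1$gates, r2$gates)
})

test_that("spike records round-trip to plain-text outputs", {
  p <- reference_config()
  net <- build_network(p, N_e = 30, N_i = 10, seed = 2)
  rec <- simulate_network(net, duration = 200)
  d <- tempfile()
  write_spike_record(rec, d)
  sp <- read.csv(file.path(d, "spikes.csv"))
  expect_equal(nrow(sp), nrow(rec$spikes))
  meta <- jsonlite::read_json(file.path(d, "spikes.json"))
  expect_equal(meta$N_e, 30)
  expect_true(file.exists(file.path(d, "rates.csv")))
})
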