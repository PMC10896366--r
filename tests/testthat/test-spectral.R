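test_that("constant traces carry no power and tones are located exactly", {
  fs <- 1000
  t <- seq(0, 5, by = 1 / fs)
  spec0 <- power_spectrum(rep(2, length(t)), fs = fs, transient_discard = 0)
  expect_lt(max(spec0$power[spec0$frequencies > 0]), 1e-20)
  gm0 <- gamma_metrics(spec0)
  expect_equal(gm0$gamma_power, 0)
  expect_true(is.na(gm0$peak_frequency))

  tone <- sin(2 * pi * 40 * t)
  spec <- power_spectrum(tone, fs = fs, transient_discard = 0)
  gm <- gamma_metrics(spec)
  df <- diff(spec$frequencies[1:2])
  expect_lt(abs(gm$peak_frequency - 40), df / 2 + 1e-9)
})

test_that("two-tone spectra pick the stronger component, matching a direct periodogram", {
  fs <- 1000
  t <- seq(0, 6, by = 1 / fs)
  x <- sin(2 * pi * 40 * t) + 2 * sin(2 * pi * 60 * t)
  spec <- power_spectrum(x, fs = fs, transient_discard = 0)
  gm <- gamma_metrics(spec)
  df <- diff(spec$frequencies[1:2])
  expect_lt(abs(gm$peak_frequency - 60), df / 2 + 1e-9)
  # independent oracle: raw periodogram via spec.pgram
  pg <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0,
                          detrend = TRUE, plot = FALSE)
  f_or <- pg$freq[which.max(pg$spec)]
  expect_lt(abs(f_or - gm$peak_frequency), 1)
})

test_that("gamma power is scale-equivariant (c^2) with unchanged peak frequency", {
  fs <- 1000
  t <- seq(0, 4, by = 1 / fs)
  x <- sin(2 * pi * 47 * t) + 0.3 * sin(2 * pi * 33 * t)
  g1 <- gamma_metrics(power_spectrum(x, fs, 0))
  g3 <- gamma_metrics(power_spectrum(3 * x, fs, 0))
  expect_equal(g3$gamma_power / g1$gamma_power, 9, tolerance = 1e-9)
  expect_equal(g3$peak_frequency, g1$peak_frequency)
})

test_that("estimator guards: short traces and bad bands are rejected", {
  expect_error(power_spectrum(rnorm(600), fs = 1000, transient_discard = 100),
               "too short")
  sp <- power_spectrum(rnorm(4000), fs = 1000, transient_discard = 0)
  expect_error(gamma_metrics(sp, band = c(400, 600)), "Nyquist")
  expect_error(gamma_metrics(sp, band = c(30, 30)), "band")
})

test_that("band-integral metric is available as an alternative", {
  fs <- 1000
  t <- seq(0, 4, by = 1 / fs)
  x <- sin(2 * pi * 50 * t)
  sp <- power_spectrum(x, fs, 0)
  gp_peak <- gamma_metrics(sp, metric = "peak")$gamma_power
  gp_int <- gamma_metrics(sp, metric = "integral")$gamma_power
  expect_gt(gp_int, 0)
  expect_false(isTRUE(all.equal(gp_peak, gp_int)))
})
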