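test_that("lambda scaling endpoints and midpoint are exact", {
  expect_equal(lambda_scale(1.3, 1.04, 0), 1.3)
  expect_equal(lambda_scale(1.3, 1.04, 1), 1.04)
  expect_equal(lambda_scale(1.3, 1.04, 0.5), 1.17)
})

test_that("percent difference lowers strengths and raises variabilities", {
  h <- healthy_state()
  sz <- apply_percent_difference(h, 20)
  expect_equal(sz[["gbar_i_ampa"]], 1.04)
  expect_equal(sz[["gbar_i_nmda"]], 0.104)
  expect_equal(sz[["gbar_e_gaba"]], 0.48)
  expect_equal(sz[["gamma_i_ampa"]], 0.012)
  expect_equal(sz[["gamma_i_nmda"]], 0.012)
  expect_identical(apply_percent_difference(h, 0), h)
  expect_error(apply_percent_difference(h, -5))
})

test_that("conditions move exactly their own parameters", {
  p <- reference_config()
  p_ei <- apply_condition(p, "ei_strength", pct = 20)
  expect_equal(get_param(p_ei, "gbar_i_ampa"), 1.04)
  expect_equal(get_param(p_ei, "gbar_i_nmda"), 0.104)
  expect_equal(get_param(p_ei, "gbar_e_gaba"),
               get_param(p, "gbar_e_gaba"))
  p_var <- apply_condition(p, "ei_variability", pct = 20)
  expect_equal(get_param(p_var, "gamma_i_ampa"), 0.012)
  expect_equal(get_param(p_var, "gbar_i_ampa"),
               get_param(p, "gbar_i_ampa"))
  # gamma_e_gaba untouched in every condition
  for (cond in c("ei_strength", "ei_variability", "ie_strength", "combined"))
    expect_equal(get_param(apply_condition(p, cond, 20), "gamma_e_gaba"),
                 get_param(p, "gamma_e_gaba"))
})

test_that("healthy-state search returns the grid argmax (single point and neighbors)", {
  p <- reference_config()
  # single-point grid reduces to that point
  res1 <- healthy_state_search(p, gie_grid = 1.3, gei_grid = 0.6,
                               duration = 2500)
  expect_equal(unname(res1$optimum["gbar_i_ampa"]), 1.3)
  expect_equal(unname(res1$optimum["gbar_e_gaba"]), 0.6)
  # small neighborhood: the returned optimum dominates all scanned points
  res <- healthy_state_search(p, gie_grid = c(1.0, 1.3, 1.6),
                              gei_grid = c(0.45, 0.6, 0.75),
                              duration = 2500)
  expect_true(all(res$optimum["power"] >= res$surface))
})

test_that("zero percent difference gives zero deficits and undefined fold ratio", {
  p <- reference_config()
  sy <- synergy_analysis(p, pct_grid = 0, duration = 2500)
  expect_equal(sy$deficit_ei, 0, tolerance = 1e-8)
  expect_equal(sy$deficit_var, 0, tolerance = 1e-8)
  expect_equal(sy$deficit_ie, 0, tolerance = 1e-8)
  expect_equal(sy$combined, 0, tolerance = 1e-8)
  expect_true(is.na(sy$fold_ratio))
})

test_that("the combined condition equals an independent all-at-once run bitwise", {
  p <- reference_config()
  pct <- 20
  combined_pipeline <- apply_condition(p, "combined", pct = pct)
  # independent single-shot construction of the same disease state
  sz <- apply_percent_difference(healthy_state(), pct)
  p_direct <- p
  for (f in names(sz)) p_direct <- set_param(p_direct, f, sz[[f]])
  expect_identical(pingmf:::.flat_params(combined_pipeline),
                   pingmf:::.flat_params(p_direct))
  g1 <- mf_gamma_power(combined_pipeline, duration = 2500)$gamma_power
  g2 <- mf_gamma_power(p_direct, duration = 2500)$gamma_power
  expect_identical(g1, g2)
})

test_that("calibration with an empty free set reports residuals unchanged", {
  p <- reference_config()
  targets <- list(list(param = "gbar_i_nmda", from = 0.13, to = 0.6,
                       type = "hopf", value = 0.15))
  res <- calibrate_reference(p, targets, free = character(), n_grid = 60)
  expect_identical(res$params, p)
  expect_equal(nrow(res$residuals), 1)
  expect_true(is.finite(res$residuals$fitted))
})

test_that("calibration recovers a perturbed drive constant from synthetic landmarks", {
  p_true <- reference_config()
  # synthetic targets generated from the known configuration
  t1 <- compute_landmark(p_true, "gbar_i_nmda", 0.13, 0.6, type = "hopf",
                         n_grid = 60)
  t2 <- compute_landmark(p_true, "gbar_e_gaba", 0.6, 4, type = "hopf",
                         n_grid = 60)
  targets <- list(
    list(param = "gbar_i_nmda", from = 0.13, to = 0.6, type = "hopf",
         value = t1),
    list(param = "gbar_e_gaba", from = 0.6, to = 4, type = "hopf",
         value = t2))
  p0 <- set_param(p_true, "Ibar_e", get_param(p_true, "Ibar_e") * 1.15)
  res <- calibrate_reference(p0, targets, free = "Ibar_e", n_grid = 60,
                             maxit = 120)
  expect_lt(abs(get_param(res$params, "Ibar_e") -
                  get_param(p_true, "Ibar_e")) /
              get_param(p_true, "Ibar_e"), 0.01)
  expect_true(all(abs(res$residuals$rel_error) < 0.02))
})
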