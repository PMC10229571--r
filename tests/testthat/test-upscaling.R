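test_that("zero-variance strata collapse to the closed form", {
  s1 <- data.frame(grassland_type = "AM", area_km2 = 2800,
                   flux_mean = 13.4, flux_sd = 0)
  est <- upscale(s1, "CH4", n_iterations = 50, seed = 1)
  closed <- 13.4 * 2800 * 200 * 16.04 * 1e-6  # 120.36416 Gg
  expect_equal(unique(est$totals), closed, tolerance = 1e-12)
  expect_equal(est$mean, closed, tolerance = 1e-12)
  expect_equal(est$q05, est$q95)

  # additivity of two deterministic strata
  s2 <- rbind(s1, data.frame(grassland_type = "AS", area_km2 = 500,
                             flux_mean = 8.7, flux_sd = 0))
  est2 <- upscale(s2, "CH4", n_iterations = 10, seed = 1)
  expect_equal(est2$mean, closed + 8.7 * 500 * 200 * 16.04 * 1e-6,
               tolerance = 1e-12)
})

test_that("Monte Carlo mean matches the truncated-normal closed form", {
  s <- data.frame(grassland_type = "AM", area_km2 = 2800,
                  flux_mean = 13.4, flux_sd = 8)
  est <- upscale(s, "CH4", n_iterations = 1e4, seed = 2)
  # E[max-0-truncated N(13.4, 8)] = mu + sd * phi(mu/sd) / Phi(mu/sd)
  mu_trunc <- 13.4 + 8 * dnorm(13.4 / 8) / pnorm(13.4 / 8)
  closed <- mu_trunc * 2800 * 200 * 16.04 * 1e-6
  expect_lt(abs(est$mean - closed) / closed, 0.01)
  expect_true(est$q05 <= est$mean && est$mean <= est$q95)
  expect_true(all(est$totals >= 0))
})

test_that("upscaling is seed-deterministic and area-linear", {
  s <- example_strata()
  a <- upscale(s, "CH4", seed = 99)
  b <- upscale(s, "CH4", seed = 99)
  expect_identical(a$totals, b$totals)
  s2 <- s; s2$area_km2 <- 2 * s2$area_km2
  d <- upscale(s2, "CH4", seed = 99)
  expect_equal(d$totals, 2 * a$totals, tolerance = 1e-12)
})

test_that("gas / carbon / CO2-equivalent conversions are exact mass ratios", {
  expect_equal(gas_to_carbon(76.6, "CH4"), 57.3544887781, tolerance = 1e-9)
  expect_equal(gas_to_carbon(0, "CH4"), 0)
  expect_equal(gas_to_carbon(2084.7, "CO2"), 2084.7 * 12.01 / 44.01,
               tolerance = 1e-12)
  expect_equal(carbon_to_gas(568.6, "CO2"), 2083.6041632, tolerance = 1e-9)
  expect_equal(carbon_to_gas(gas_to_carbon(5, "CH4"), "CH4"), 5)
  expect_equal(gas_to_co2e(76.6, "CH4"), 2144.8)
  expect_equal(gas_to_co2e(1, "CH4"), 28)
  expect_equal(gas_to_co2e(2084.7, "CO2"), 2084.7)
  expect_error(gas_to_carbon(-1, "CH4"), ">= 0")
})

test_that("ice-cover correction applies the p/(1-p) rule", {
  expect_equal(ice_cover_correction(76.6, 0.27), 28.3315068493,
               tolerance = 1e-9)
  expect_equal(ice_cover_correction(2084.7, 0.17), 426.986746988,
               tolerance = 1e-9)
  expect_equal(ice_cover_correction(100, 0), 0)
  expect_error(ice_cover_correction(100, 1), "p_ice")
  # the stated fraction holds for the implied annual total
  e <- 76.6; ic <- ice_cover_correction(e, 0.27)
  expect_equal(ic / (e + ic), 0.27, tolerance = 1e-12)
})

test_that("strata built from an analysed survey feed the upscaler", {
  sv <- generate_survey(survey_config(n_clusters = 6, campaigns = 1,
                                      seed = 17))
  an <- analyze_survey(sv)
  areas <- c(AS = 466.7, AM = 1213.3, SM = 1120)
  strata <- strata_from_analysis(an, areas, "CH4")
  expect_true(all(strata$flux_mean > 0))
  est <- upscale(strata, "CH4", n_iterations = 500, seed = 3)
  expect_gt(est$mean, 0)
  expect_equal(est$co2e[["mean"]], 28 * est$mean, tolerance = 1e-12)
  expect_equal(est$carbon[["mean"]], est$mean * 12.01 / 16.04,
               tolerance = 1e-12)
})
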