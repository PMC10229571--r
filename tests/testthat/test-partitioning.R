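test_that("Schmidt numbers evaluate the freshwater polynomial", {
  expect_equal(schmidt_number("CO2", 20), 600.3264, tolerance = 1e-6)
  expect_equal(schmidt_number("CH4", 20), 616.6192, tolerance = 1e-6)
  # gases are similar: within 10% of each other
  expect_lt(abs(schmidt_number("CH4", 20) / schmidt_number("CO2", 20) - 1),
            0.1)
  expect_gt(schmidt_number("CH4", 0), schmidt_number("CH4", 30))
  expect_gt(schmidt_number("CO2", 0), schmidt_number("CO2", 30))
  expect_warning(schmidt_number("CH4", 35), "clamping")
})

test_that("CO2 anchor velocity is flux over gradient, guarded", {
  expect_equal(k_co2_from_co2_flux(170.4, 97.2, 12.0), 2.0)
  expect_true(is.na(k_co2_from_co2_flux(170.4, 12.5, 12.0)))  # |grad| < 1
  expect_true(is.na(k_co2_from_co2_flux(-50, 97.2, 12.0)))    # sign mismatch
  # forward-simulation oracle: encode a known k and recover it
  k_true <- 2.5; c_w <- 52; c_eq <- 12
  f <- k_true * (c_w - c_eq)
  expect_lt(abs(k_co2_from_co2_flux(f, c_w, c_eq) - k_true) / k_true, 1e-12)
})

test_that("transfer velocity recovered through the pipeline matches truth", {
  sv <- generate_survey(noiseless(seed = 9))
  an <- analyze_survey(sv)
  key <- paste(an$partitioned$cluster_id, an$partitioned$lake_id,
               an$partitioned$campaign)
  tkey <- paste(sv$truth$cluster_id, sv$truth$lake_id, sv$truth$campaign)
  i <- match(key, tkey)
  expect_lt(max(abs(an$partitioned$k_co2 - sv$truth$k_co2[i]) /
                  sv$truth$k_co2[i]), 1e-6)
  expect_lt(max(abs(an$partitioned$k_ch4 - sv$truth$k_ch4[i]) /
                  sv$truth$k_ch4[i]), 1e-6)
})

test_that("Schmidt scaling of k follows the wind-regime exponent", {
  expect_equal(k_ch4(2, 600, 600, wind_speed = 1), 2)
  expect_equal(k_ch4(2, 600, 600, wind_speed = 5), 2)
  expect_equal(k_ch4(2, 660, 600, wind_speed = 5), 1.90692517849,
               tolerance = 1e-9)
  k_low <- k_ch4(2, 660, 600, wind_speed = 3.5)   # n = 2/3
  k_high <- k_ch4(2, 660, 600, wind_speed = 3.7)  # n = 1/2
  expect_equal(k_low, 2 * (660 / 600)^(-2 / 3))
  expect_equal(k_high, 2 * (660 / 600)^(-1 / 2))
  expect_gt(k_high, k_low)
  # boundary: exactly 3.6 uses n = 1/2
  expect_equal(k_ch4(2, 660, 600, wind_speed = 3.6), k_high)
  # monotonicity in k_co2 and in the Schmidt ratio
  expect_gt(k_ch4(3, 660, 600, 2), k_ch4(2, 660, 600, 2))
  expect_gt(k_ch4(2, 620, 600, 2), k_ch4(2, 700, 600, 2))
})

test_that("partitioning matches the survey means and clamps correctly", {
  p <- partition_flux(13.3, k = 2, c_w = 1.052, c_eq = 0.002)
  expect_equal(p$f_d, 2.1)
  expect_equal(p$f_e, 11.2)
  expect_equal(p$ebullition_share, 11.2 / 13.3, tolerance = 1e-12)
  expect_false(p$clamped)

  p0 <- partition_flux(5, k = 2, c_w = 2.502, c_eq = 0.002)  # F_d = F_total
  expect_equal(p0$f_e, 0)
  expect_equal(p0$ebullition_share, 0)

  pc <- partition_flux(4, k = 2, c_w = 2.502, c_eq = 0.002)  # F_d = 5 > F
  expect_true(pc$clamped)
  expect_equal(pc$f_e, 0)
  expect_equal(pc$f_e_raw, -1)
  pn <- partition_flux(4, k = 2, c_w = 2.502, c_eq = 0.002, clamp = FALSE)
  expect_equal(pn$f_e, -1)
})

test_that("unclamped partitions conserve the total flux", {
  set.seed(21)
  f_tot <- runif(200, 0.5, 30)
  k <- runif(200, 0.5, 5)
  c_w <- runif(200, 0.01, 2)
  p <- partition_flux(f_tot, k, c_w, c_eq = 0.002)
  unclamped <- !p$clamped
  expect_true(any(unclamped))
  expect_equal(p$f_d[unclamped] + p$f_e[unclamped], f_tot[unclamped],
               tolerance = 1e-12)
  # raw values always conserve
  expect_equal(p$f_d + p$f_e_raw, f_tot, tolerance = 1e-12)
})

test_that("degenerate CO2 anchors fall back to the cluster median", {
  sv <- generate_survey(noiseless(seed = 12))
  # kill the CO2 gradient of one lake-campaign: C_w == C_eq
  ws <- sv$water_samples
  kill <- which(ws$gas == "CO2" & ws$cluster_id == 1 & ws$lake_id == 1)[1]
  eq_ppm <- dissolved_to_headspace(
    equilibrium_concentration("CO2", ws$atm_ppm[kill],
                              ws$water_temperature[kill],
                              ws$air_pressure[kill]),
    "CO2", ws$water_temperature[kill], ws$air_pressure[kill])
  ws$headspace_ppm[kill] <- eq_ppm
  sv$water_samples <- ws
  an <- analyze_survey(sv)
  p <- an$partitioned
  hit <- p$cluster_id == 1 & p$lake_id == 1
  expect_true(all(p$k_provenance[hit] == "fallback_median"))
  others <- p$k_co2[p$cluster_id == 1 & !hit]
  expect_equal(p$k_co2[hit], median(others))
})

test_that("share-pressure regression behaves on collinear, null and real signals", {
  # perfectly collinear
  x <- seq(50, 70, length.out = 10)
  fit <- suppressWarnings(  # lm warns on an exactly perfect fit
    ebullition_pressure_regression(0.9 - 0.01 * x, x,
                                   screen_outliers = FALSE))
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, -0.01, tolerance = 1e-12)

  # permutation null: p roughly uniform, R^2 near zero
  set.seed(31)
  share <- runif(30, 0.6, 0.95)
  pressure <- runif(30, 55, 68)
  stats <- t(replicate(200, {
    f <- ebullition_pressure_regression(share, sample(pressure),
                                        screen_outliers = FALSE)
    c(f$p_value, f$r_squared)
  }))
  expect_lt(abs(mean(stats[, 1]) - 0.5), 0.15)
  expect_lt(mean(stats[, 1] < 0.05), 0.12)
  expect_lt(mean(stats[, 2]), 0.15)

  # configured negative dependence on pressure is recovered at n = 30
  set.seed(32)
  z <- runif(30, 3279, 5014)
  press <- pressure_from_elevation(z)
  share2 <- 0.84 + 0.06 * (z - 4146.5) / 1000 + rnorm(30, 0, 0.03)
  f2 <- ebullition_pressure_regression(share2, press)
  expect_lt(f2$slope, 0)
  expect_lt(f2$p_value, 0.05)

  expect_error(ebullition_pressure_regression(c(0.1, 0.2), c(1, 2)),
               "fewer than 3")
})
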