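test_that("barometric pressure model matches its closed form", {
  expect_equal(pressure_from_elevation(0), 101.325)
  expect_equal(pressure_from_elevation(4300), 60.7294291832, tolerance = 1e-9)
  # plausibility anchor: near the observed high-plateau mean of ~60.9 kPa
  expect_lt(abs(pressure_from_elevation(4300) - 60.9), 0.5)
  expect_equal(pressure_from_elevation(8400), 101.325 / exp(1))
  expect_error(pressure_from_elevation(-1), "elevation")
})

test_that("noise-free diffusive chamber series is an exact linear ramp", {
  s <- generate_chamber_series(13.4, share = 0, pressure_kpa = 61,
                               temperature_k = 283, noise_sd_ppm = 0)
  expect_equal(nrow(s), 171)
  # strictly linear: second differences vanish
  expect_lt(max(abs(diff(diff(s$ppm)))), 1e-12)
  rec <- compute_total_flux(s$t_s, s$ppm, 61, 283)
  expect_lt(abs(rec$flux - 13.4) / 13.4, 1e-3)
})

test_that("zero flux gives a flat series at ambient concentration", {
  s <- generate_chamber_series(0, 0, 61, 283, noise_sd_ppm = 0,
                               ambient_ppm = 1.9)
  expect_equal(s$ppm, rep(1.9, 171))
})

test_that("bubble-step series still carries the configured total flux", {
  fluxes <- vapply(1:200, function(seed) {
    s <- generate_chamber_series(13.4, 0.84, 61, 283, seed = seed)
    compute_total_flux(s$t_s, s$ppm, 61, 283)$flux
  }, numeric(1))
  se <- sd(fluxes) / sqrt(length(fluxes))
  expect_lt(abs(mean(fluxes) - 13.4), 2 * se + 1e-9)
})

test_that("surveys are deterministic for a fixed seed", {
  a <- generate_survey(tiny_config(seed = 7))
  b <- generate_survey(tiny_config(seed = 7))
  expect_identical(a$sites, b$sites)
  expect_identical(a$chamber_series, b$chamber_series)
  expect_identical(a$water_samples, b$water_samples)
  expect_identical(a$isotopes, b$isotopes)
  expect_identical(a$truth, b$truth)
  c <- generate_survey(tiny_config(seed = 8))
  expect_false(identical(a$truth, c$truth))
})

test_that("true fluxes are never negative and respect sd = 0", {
  sv <- generate_survey(survey_config(
    n_clusters = 40, lakes_per_cluster = 4, campaigns = 1,
    flux_means = c(AS = 1, AM = 1, SM = 1),
    flux_sds = c(AS = 3, AM = 3, SM = 3), seed = 3))
  expect_true(all(sv$truth$lake_flux >= 0))

  sv0 <- generate_survey(tiny_config(
    flux_sds = c(AS = 0, AM = 0, SM = 0), seed = 4))
  per_type <- tapply(sv0$truth$lake_flux, sv0$truth$grassland_type,
                     function(x) length(unique(x)))
  expect_true(all(per_type == 1))
})

test_that("per-type flux draws match configured means (law of large numbers)", {
  set.seed(42)
  cfg <- survey_config()
  for (tp in c("AS", "AM", "SM")) {
    x <- rtnorm0(1e4, cfg$flux_means[[tp]], cfg$flux_sds[[tp]])
    se <- sd(x) / sqrt(length(x))
    # truncation at zero is a negligible (< 0.02) upward shift here
    expect_lt(abs(mean(x) - cfg$flux_means[[tp]]), 2 * se + 0.02)
  }
  expect_error(rtnorm0(5, 1, -1), "sd")
  expect_identical(rtnorm0(3, 2.5, 0), rep(2.5, 3))
})

test_that("invalid configurations are rejected", {
  expect_error(survey_config(n_clusters = 0), "must be >= 1")
  expect_error(survey_config(grassland_mix = c(AS = 1, AM = 1, SM = 1)),
               "sum to 1")
  expect_error(survey_config(ebullition_fraction = 1), "ebullition")
  expect_error(survey_config(flux_sds = c(AS = -1, AM = 1, SM = 1)),
               "sds")
})

test_that("a survey round-trips through disk byte-identically", {
  sv <- generate_survey(tiny_config(seed = 11))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_survey(sv, d1)
  write_survey(generate_survey(tiny_config(seed = 11)), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  back <- read_survey(d1)
  expect_equal(back$truth$f_total, sv$truth$f_total, tolerance = 1e-12)
  expect_s3_class(back$config, "survey_config")
  expect_equal(back$config$seed, 11L)
})
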