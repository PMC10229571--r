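#' Synthesise one chamber concentration time series
#'
#' Builds a 171-sample (1 Hz, 0-170 s) chamber record whose analysis
#' window carries a known flux: a linear diffusive ramp whose implied
#' endpoint flux equals `(1 - share) * flux`, plus 1-5 instantaneous
#' concentration steps (log-normally sized bubble events, placed inside
#' the window) whose summed jumps imply `share * flux`, plus Gaussian
#' instrument noise. The ground truth is stored in the `"truth"`
#' attribute, so [compute_total_flux()] has an exact recovery target.
#'
#' @param flux True total flux, mmol m-2 d-1, >= 0.
#' @param share True ebullitive share of the flux, in `[0, 1)`.
#' @param pressure_kpa Site air pressure, kPa.
#' @param temperature_k Chamber air temperature, K.
#' @param geometry A [chamber_geometry()].
#' @param ambient_ppm Ambient mixing ratio at deployment, ppm.
#' @param noise_sd_ppm Instrument noise sigma per sample, ppm (default
#'   0.002 ppm = 2 ppb).
#' @param times Sampling times, s (default `0:170`).
#' @param window Analysis window the flux is encoded over, s.
#' @param seed Optional integer seed.
#' @return A data frame with `t_s` and `ppm`, carrying a `"truth"`
#'   attribute (list with `flux`, `share`, `slope_ppm_s`, `step_ppm`).
#' @examples
#' s <- generate_chamber_series(13.4, 0.84, 61, 283, seed = 1)
#' compute_total_flux(s$t_s, s$ppm, 61, 283)
#' @export
generate_chamber_series <- function(flux, share, pressure_kpa,
                                    temperature_k,
                                    geometry = chamber_geometry(),
                                    ambient_ppm = 1.9,
                                    noise_sd_ppm = 0.002,
                                    times = 0:170, window = c(20, 170),
                                    seed = NULL) {
  if (flux < 0) stop("flux must be >= 0")
  if (share < 0 || share >= 1) stop("share must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  span <- window[2] - window[1]
  mmol_per_ppm <- mixing_ratio_to_moles(1, geometry, pressure_kpa,
                                        temperature_k)
  # flux implied by a 1-ppm rise across the window
  flux_per_ppm <- mmol_per_ppm / (geometry$area * span) * .SEC_PER_DAY
  slope <- (1 - share) * flux / (flux_per_ppm * span)  # ppm per s
  ppm <- ambient_ppm + slope * times

  step_total <- share * flux / flux_per_ppm
  if (step_total > 0) {
    n_events <- sample(1:5, 1)
    at <- stats::runif(n_events, window[1] + 5, window[2] - 5)
    sizes <- stats::rlnorm(n_events, 0, 0.8)
    sizes <- sizes / sum(sizes) * step_total
    for (i in seq_len(n_events)) ppm <- ppm + sizes[i] * (times >= at[i])
  } else {
    n_events <- 0L
    at <- sizes <- numeric(0)
  }
  if (noise_sd_ppm > 0)
    ppm <- ppm + stats::rnorm(length(times), 0, noise_sd_ppm)

  structure(
    data.frame(t_s = times, ppm = ppm),
    truth = list(flux = flux, share = share, slope_ppm_s = slope,
                 step_ppm = sum(sizes), event_times = at)
  )
}

#' Generate a full synthetic thermokarst-lake survey
#'
#' Draws a complete field survey with known ground truth, so that every
#' downstream stage has a recovery test: lake clusters with
#' elevation-dependent air pressure, per-type zero-truncated-normal true
#' CH4 fluxes, elevation-dependent ebullition shares, chamber
#' concentration series encoding the true fluxes (CH4 with bubble steps,
#' CO2 purely diffusive), headspace water samples consistent with the
#' two-layer diffusion model at a known per-lake transfer velocity, and
#' per-cluster isotope records centred near field-observed means
#' (delta13C-CH4 -72.5 permil, delta13C-CO2 -13.4 permil; radiocarbon
#' ages right-skewed around ~320 yrs BP).
#'
#' The output is deterministic for a fixed `config$seed`.
#'
#' @param config A [survey_config()].
#' @param geometry A [chamber_geometry()].
#' @return A list of class `lake_survey` with data frames `sites` (one
#'   row per lake-campaign), `chamber_series`, `water_samples`,
#'   `isotopes`, `truth`, and the `config`.
#' @examples
#' sv <- generate_survey(survey_config(n_clusters = 2, campaigns = 1))
#' names(sv)
#' @export
generate_survey <- function(config = survey_config(),
                            geometry = chamber_geometry()) {
  stopifnot(inherits(config, "survey_config"))
  set.seed(config$seed)
  nc <- config$n_clusters
  nl <- config$lakes_per_cluster
  np <- config$campaigns

  # cluster-level: grassland type by largest-remainder apportionment
  target <- config$grassland_mix * nc
  n_type <- floor(target)
  rem <- nc - sum(n_type)
  if (rem > 0) {
    extra <- order(target - n_type, decreasing = TRUE)[seq_len(rem)]
    n_type[extra] <- n_type[extra] + 1
  }
  cluster_type <- sample(rep(names(n_type), n_type))
  elevation <- stats::runif(nc, config$elevation_range[1],
                            config$elevation_range[2])
  pressure <- pressure_from_elevation(elevation)
  z_mid <- mean(config$elevation_range)

  # lake-level truth
  lakes <- expand.grid(lake_id = seq_len(nl), cluster_id = seq_len(nc))
  lakes <- lakes[c("cluster_id", "lake_id")]
  lakes$grassland_type <- cluster_type[lakes$cluster_id]
  lakes$elevation <- elevation[lakes$cluster_id]
  lakes$air_pressure <- pressure[lakes$cluster_id]
  lakes$lake_flux <- vapply(lakes$grassland_type, function(tp) {
    rtnorm0(1, config$flux_means[[tp]], config$flux_sds[[tp]])
  }, numeric(1))
  share_raw <- config$ebullition_fraction +
    config$ebullition_elevation_slope *
      (lakes$elevation - z_mid) / 1000 +
    stats::rnorm(nrow(lakes), 0, 0.03)
  lakes$share <- pmin(pmax(share_raw, 0.02), 0.98)
  if (config$ebullition_fraction == 0 &&
      config$ebullition_elevation_slope == 0)
    lakes$share <- 0
  lakes$depth <- stats::runif(nrow(lakes), 0.3, 3.5)
  lakes$pH <- stats::rnorm(nrow(lakes), 8.5, 0.4)
  lakes$dissolved_oxygen <- pmin(pmax(
    stats::rnorm(nrow(lakes), 4.3, 1.0), 0.5), 14.5)
  lakes$salinity <- stats::runif(nrow(lakes), 0, 2.6)

  campaign_factor <- stats::rlnorm(np, -0.25^2 / 2, 0.25)

  # lake-campaign level
  lc <- lakes[rep(seq_len(nrow(lakes)), each = np), ]
  lc$campaign <- rep(seq_len(np), nrow(lakes))
  rownames(lc) <- NULL
  n_lc <- nrow(lc)
  lc$water_temperature <- pmin(pmax(stats::rnorm(n_lc, 10, 3), 1), 20)
  lc$air_temperature <- lc$water_temperature + stats::rnorm(n_lc, 0, 2)
  lc$wind_speed <- stats::rgamma(n_lc, shape = 4, scale = 0.8)
  lc$k_co2 <- stats::rlnorm(n_lc, log(3), 0.3)
  lc$f_co2 <- rtnorm0(n_lc, config$co2_flux_mean, config$co2_flux_sd)
  lc$f_total <- lc$lake_flux * campaign_factor[lc$campaign]

  sc_ch4 <- schmidt_number("CH4", lc$water_temperature)
  sc_co2 <- schmidt_number("CO2", lc$water_temperature)
  lc$k_ch4 <- k_ch4(lc$k_co2, sc_ch4, sc_co2, lc$wind_speed)
  lc$f_d <- (1 - lc$share) * lc$f_total
  lc$f_e <- lc$share * lc$f_total

  c_eq_ch4 <- equilibrium_concentration("CH4", config$atm_ch4_ppm,
                                        lc$water_temperature,
                                        lc$air_pressure)
  c_eq_co2 <- equilibrium_concentration("CO2", config$atm_co2_ppm,
                                        lc$water_temperature,
                                        lc$air_pressure)
  lc$c_w_ch4 <- c_eq_ch4 + lc$f_d / lc$k_ch4
  lc$c_w_co2 <- c_eq_co2 + lc$f_co2 / lc$k_co2

  hs_ch4 <- dissolved_to_headspace(lc$c_w_ch4, "CH4",
                                   lc$water_temperature, lc$air_pressure)
  hs_co2 <- dissolved_to_headspace(lc$c_w_co2, "CO2",
                                   lc$water_temperature, lc$air_pressure)

  # chamber series (CH4 with bubble steps, CO2 purely diffusive)
  times <- 0:170
  series <- lapply(seq_len(n_lc), function(i) {
    tk <- lc$air_temperature[i] + .KELVIN0
    s4 <- generate_chamber_series(lc$f_total[i], lc$share[i],
                                  lc$air_pressure[i], tk, geometry,
                                  config$atm_ch4_ppm,
                                  config$noise_ch4_ppm, times)
    s2 <- generate_chamber_series(lc$f_co2[i], 0, lc$air_pressure[i], tk,
                                  geometry, config$atm_co2_ppm,
                                  config$noise_co2_ppm, times)
    list(ch4 = s4$ppm, co2 = s2$ppm)
  })
  nt <- length(times)
  chamber_series <- data.frame(
    cluster_id = rep(lc$cluster_id, each = nt),
    lake_id = rep(lc$lake_id, each = nt),
    campaign = rep(lc$campaign, each = nt),
    location = 1L,
    t_s = rep(times, n_lc),
    ch4_ppm = unlist(lapply(series, `[[`, "ch4"), use.names = FALSE),
    co2_ppm = unlist(lapply(series, `[[`, "co2"), use.names = FALSE)
  )

  sites <- lc[c("cluster_id", "lake_id", "campaign", "grassland_type",
                "elevation", "air_pressure", "water_temperature",
                "air_temperature", "wind_speed", "pH",
                "dissolved_oxygen", "salinity", "depth")]

  water_samples <- rbind(
    data.frame(cluster_id = lc$cluster_id, lake_id = lc$lake_id,
               campaign = lc$campaign, gas = "CH4",
               headspace_ppm = hs_ch4,
               water_temperature = lc$water_temperature,
               air_pressure = lc$air_pressure,
               atm_ppm = config$atm_ch4_ppm,
               water_volume_ml = 50, headspace_volume_ml = 50),
    data.frame(cluster_id = lc$cluster_id, lake_id = lc$lake_id,
               campaign = lc$campaign, gas = "CO2",
               headspace_ppm = hs_co2,
               water_temperature = lc$water_temperature,
               air_pressure = lc$air_pressure,
               atm_ppm = config$atm_co2_ppm,
               water_volume_ml = 50, headspace_volume_ml = 50)
  )

  # isotope records: one lake per cluster, right-skewed radiocarbon ages
  age <- -400 + stats::rgamma(nc, shape = 1.2, scale = 600)
  isotopes <- data.frame(
    cluster_id = seq_len(nc), lake_id = 1L,
    d13c_ch4 = stats::rnorm(nc, -72.5, 4),
    d13c_co2 = stats::rnorm(nc, -13.4, 3),
    c14_fraction_modern = exp(-age / 8033)
  )

  truth <- lc[c("cluster_id", "lake_id", "campaign", "grassland_type",
                "lake_flux", "f_total", "share", "f_d", "f_e", "f_co2",
                "k_co2", "k_ch4", "c_w_ch4", "c_w_co2")]
  names(truth)[names(truth) == "share"] <- "true_ebullition_share"

  structure(
    list(sites = sites, chamber_series = chamber_series,
         water_samples = water_samples, isotopes = isotopes,
         truth = truth, config = config),
    class = "lake_survey"
  )
}

#' @export
print.lake_survey <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Synthetic lake survey: %d clusters x %d lakes x %d campaigns (seed %d)\n",
    cfg$n_clusters, cfg$lakes_per_cluster, cfg$campaigns, cfg$seed))
  cat(sprintf("  %d chamber deployments (%d samples), %d water samples, %d isotope records\n",
              nrow(x$truth), nrow(x$chamber_series),
              nrow(x$water_samples), nrow(x$isotopes)))
  cat(sprintf("  true CH4 flux: mean %.1f mmol m-2 d-1; true ebullition share: mean %.2f\n",
              mean(x$truth$f_total),
              mean(x$truth$true_ebullition_share)))
  invisible(x)
}
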