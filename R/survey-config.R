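#' Air pressure from elevation
#'
#' Isothermal barometric model `P = P0 * exp(-z / H)` with sea-level
#' pressure `P0 = 101.325 kPa` and scale height `H = 8400 m`, used to
#' synthesise plausible site pressures. At ~4300 m it gives ~60.7 kPa,
#' consistent with the ~60.9 kPa mean observed across high-plateau lake
#' sites.
#'
#' @param elevation Elevation in m above sea level, >= 0 (vectorised).
#' @return Air pressure in kPa.
#' @examples
#' pressure_from_elevation(c(0, 4300, 8400))
#' @export
pressure_from_elevation <- function(elevation) {
  if (any(elevation < 0)) stop("elevation must be >= 0")
  101.325 * exp(-elevation / 8400)
}

#' Configuration of a synthetic thermokarst-lake survey
#'
#' Collects every tunable of the synthetic-survey generator with validated
#' defaults emulating a plateau-wide field campaign: 30 lake clusters of 4
#' lakes each, sampled over 5 monthly campaigns, distributed over three
#' alpine grassland types (alpine steppe `AS`, alpine meadow `AM`, swamp
#' meadow `SM`) with per-type total-CH4-flux means of 8.7 / 16.1 / 12.5
#' mmol m-2 d-1 (the `SM` mean is a synthetic-only calibration) and an
#' overall ebullition share of 0.84 that increases with elevation.
#'
#' @param n_clusters Number of lake clusters.
#' @param lakes_per_cluster Lakes sampled in each cluster.
#' @param campaigns Monthly sampling campaigns per lake.
#' @param grassland_mix Named proportions over `AS`, `AM`, `SM`; must sum
#'   to 1.
#' @param flux_means,flux_sds Named per-type mean/sd of true total CH4
#'   flux, mmol m-2 d-1 (sds >= 0; lake draws are truncated at zero).
#' @param ebullition_fraction Mean ebullitive share of the total CH4 flux,
#'   in `[0, 1)`.
#' @param ebullition_elevation_slope Change of ebullition share per km of
#'   elevation (captures the low-pressure enhancement of bubbling).
#' @param elevation_range Two-element range of cluster elevations, m.
#' @param co2_flux_mean,co2_flux_sd Mean/sd of the (purely diffusive) CO2
#'   flux, mmol m-2 d-1.
#' @param noise_ch4_ppm,noise_co2_ppm Gaussian instrument noise of the
#'   chamber analyser, ppm (1-sigma per 1 s sample).
#' @param atm_ch4_ppm,atm_co2_ppm Ambient mixing ratios, ppm.
#' @param seed Integer RNG seed; the whole survey is deterministic given
#'   the seed.
#' @return A validated list of class `survey_config`.
#' @examples
#' survey_config(n_clusters = 4, campaigns = 1)
#' @export
survey_config <- function(n_clusters = 30,
                          lakes_per_cluster = 4,
                          campaigns = 5,
                          grassland_mix = c(AS = 5, AM = 13, SM = 12) / 30,
                          flux_means = c(AS = 8.7, AM = 16.1, SM = 12.5),
                          flux_sds = c(AS = 3.0, AM = 1.7, SM = 2.0),
                          ebullition_fraction = 0.84,
                          ebullition_elevation_slope = 0.06,
                          elevation_range = c(3279, 5014),
                          co2_flux_mean = 170.4,
                          co2_flux_sd = 50,
                          noise_ch4_ppm = 0.002,
                          noise_co2_ppm = 0.35,
                          atm_ch4_ppm = 1.9,
                          atm_co2_ppm = 415,
                          seed = 1L) {
  types <- c("AS", "AM", "SM")
  if (n_clusters < 1 || lakes_per_cluster < 1 || campaigns < 1)
    stop("n_clusters, lakes_per_cluster and campaigns must be >= 1")
  if (!setequal(names(grassland_mix), types))
    stop("grassland_mix must be named over AS, AM, SM")
  if (abs(sum(grassland_mix) - 1) > 1e-8)
    stop("grassland_mix proportions must sum to 1")
  if (!all(types %in% names(flux_means)) ||
      !all(types %in% names(flux_sds)))
    stop("flux_means and flux_sds must be named over AS, AM, SM")
  if (any(flux_sds < 0) || co2_flux_sd < 0) stop("flux sds must be >= 0")
  if (ebullition_fraction < 0 || ebullition_fraction >= 1)
    stop("ebullition_fraction must be in [0, 1)")
  if (length(elevation_range) != 2 || diff(elevation_range) < 0 ||
      any(elevation_range < 0))
    stop("elevation_range must be an increasing non-negative pair")
  structure(
    list(n_clusters = as.integer(n_clusters),
         lakes_per_cluster = as.integer(lakes_per_cluster),
         campaigns = as.integer(campaigns),
         grassland_mix = grassland_mix[types],
         flux_means = flux_means[types], flux_sds = flux_sds[types],
         ebullition_fraction = ebullition_fraction,
         ebullition_elevation_slope = ebullition_elevation_slope,
         elevation_range = elevation_range,
         co2_flux_mean = co2_flux_mean, co2_flux_sd = co2_flux_sd,
         noise_ch4_ppm = noise_ch4_ppm, noise_co2_ppm = noise_co2_ppm,
         atm_ch4_ppm = atm_ch4_ppm, atm_co2_ppm = atm_co2_ppm,
         seed = as.integer(seed)),
    class = "survey_config"
  )
}

#' @export
print.survey_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic survey config: %d clusters x %d lakes x %d campaigns (seed %d)\n",
    x$n_clusters, x$lakes_per_cluster, x$campaigns, x$seed))
  cat(sprintf("  grassland mix: %s\n",
              paste(names(x$grassland_mix),
                    sprintf("%.2f", x$grassland_mix),
                    sep = " = ", collapse = ", ")))
  cat(sprintf("  CH4 flux by type (mmol m-2 d-1): %s\n",
              paste(names(x$flux_means),
                    sprintf("%.1f +/- %.1f", x$flux_means, x$flux_sds),
                    sep = " = ", collapse = ", ")))
  cat(sprintf("  ebullition share: %.2f; elevation %g-%g m\n",
              x$ebullition_fraction, x$elevation_range[1],
              x$elevation_range[2]))
  invisible(x)
}

#' Read / write a survey configuration as YAML
#'
#' @param config A [survey_config()].
#' @param path File path of the YAML configuration.
#' @return `read_survey_config()` returns a `survey_config`;
#'   `write_survey_config()` returns `path` invisibly.
#' @export
write_survey_config <- function(config, path) {
  stopifnot(inherits(config, "survey_config"))
  yaml::write_yaml(lapply(unclass(config), function(x) {
    if (!is.null(names(x))) as.list(x) else x
  }), path)
  invisible(path)
}

#' @rdname write_survey_config
#' @export
read_survey_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (f in c("grassland_mix", "flux_means", "flux_sds"))
    raw[[f]] <- unlist(raw[[f]])
  raw$elevation_range <- unlist(raw$elevation_range)
  do.call(survey_config, raw)
}
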