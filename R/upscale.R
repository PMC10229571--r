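#' Zero-truncated normal draws by rejection
#'
#' Samples from a normal distribution conditioned on being non-negative,
#' by exact rejection. Used wherever a flux (which cannot be negative for
#' these emitting lakes) is drawn from a mean/sd summary. With `sd = 0`
#' the mean is returned deterministically.
#'
#' @param n Number of draws.
#' @param mean,sd Parameters of the untruncated normal; `sd >= 0`.
#' @return Numeric vector of `n` non-negative draws.
#' @export
rtnorm0 <- function(n, mean, sd) {
  if (sd < 0) stop("sd must be >= 0")
  if (sd == 0) {
    if (mean < 0) stop("mean < 0 with sd = 0: no non-negative mass")
    return(rep(mean, n))
  }
  if (stats::pnorm(0, mean, sd, lower.tail = FALSE) < 1e-6)
    stop("acceptance probability too low: mean far below zero")
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(n, mean, sd)
    out <- c(out, draw[draw >= 0])
  }
  out[seq_len(n)]
}

#' Monte Carlo stratified upscaling of lake fluxes to regional emissions
#'
#' Propagates per-stratum flux uncertainty to a regional annual emission
#' estimate. Each iteration draws one areal flux per stratum from a normal
#' distribution (truncated at zero) described by the stratum mean and
#' standard deviation, multiplies it by the stratum's thermokarst-lake
#' area and the ice-free season length, converts to gas mass, and sums
#' over strata. The distribution of iteration totals yields the mean and
#' the 5th/95th percentile bounds (linear-interpolation quantiles).
#'
#' @param strata Data frame with columns `grassland_type`, `area_km2`,
#'   `flux_mean` and `flux_sd` (mmol m-2 d-1).
#' @param gas `"CH4"` or `"CO2"`.
#' @param n_iterations Monte Carlo iterations (default 1000).
#' @param season_days Ice-free season length in days (default 200).
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `regional_estimate`: list with the vector of
#'   iteration `totals` (Gg gas yr-1), `mean`, `q05`, `q95`, the same three
#'   summaries as carbon mass (`carbon`, via [gas_to_carbon()]) and
#'   CO2-equivalents (`co2e`, via [gas_to_co2e()]), and the call settings.
#' @examples
#' strata <- example_strata()
#' upscale(strata, "CH4", seed = 1)
#' @export
upscale <- function(strata, gas = c("CH4", "CO2"), n_iterations = 1000,
                    season_days = 200, seed = NULL) {
  gas <- match.arg(gas)
  req <- c("grassland_type", "area_km2", "flux_mean", "flux_sd")
  if (!all(req %in% names(strata)))
    stop("strata must have columns ", paste(req, collapse = ", "))
  if (nrow(strata) == 0) stop("no strata supplied")
  if (any(strata$area_km2 < 0) || any(strata$flux_sd < 0))
    stop("areas and flux sds must be >= 0")
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  # mmol m-2 d-1 * m^2 * d * g mol-1 -> Gg:  area_km2 * 1e6 * 1e-3 / 1e9
  mass_factor <- strata$area_km2 * 1e6 * season_days *
    .MOLAR_MASS[[gas]] * 1e-3 / 1e9
  draws <- vapply(seq_len(nrow(strata)), function(i) {
    rtnorm0(n_iterations, strata$flux_mean[i], strata$flux_sd[i]) *
      mass_factor[i]
  }, numeric(n_iterations))
  totals <- if (n_iterations == 1) sum(draws) else rowSums(draws)

  summ <- function(x) c(mean = mean(x),
                        q05 = unname(stats::quantile(x, 0.05, type = 7)),
                        q95 = unname(stats::quantile(x, 0.95, type = 7)))
  s <- summ(totals)
  structure(
    list(gas = gas, totals = totals,
         mean = s[["mean"]], q05 = s[["q05"]], q95 = s[["q95"]],
         carbon = summ(gas_to_carbon(totals, gas)),
         co2e = summ(gas_to_co2e(totals, gas)),
         season_days = season_days, n_iterations = n_iterations,
         seed = seed, strata = strata),
    class = "regional_estimate"
  )
}

#' @export
print.regional_estimate <- function(x, ...) {
  cat(sprintf("Regional %s emission estimate (%d Monte Carlo iterations, %g-day season)\n",
              x$gas, x$n_iterations, x$season_days))
  cat(sprintf("  gas mass: %.1f (%.1f-%.1f) Gg %s yr-1\n",
              x$mean, x$q05, x$q95, x$gas))
  cat(sprintf("  carbon:   %.1f (%.1f-%.1f) Gg C yr-1\n",
              x$carbon[["mean"]], x$carbon[["q05"]], x$carbon[["q95"]]))
  cat(sprintf("  CO2-e:    %.1f (%.1f-%.1f) Gg CO2-e yr-1\n",
              x$co2e[["mean"]], x$co2e[["q05"]], x$co2e[["q95"]]))
  invisible(x)
}

#' @export
summary.regional_estimate <- function(object, ...) {
  data.frame(
    quantity = c("gas", "carbon", "co2e"),
    unit = c(paste0("Gg ", object$gas, " yr-1"), "Gg C yr-1",
             "Gg CO2-e yr-1"),
    mean = c(object$mean, object$carbon[["mean"]], object$co2e[["mean"]]),
    q05 = c(object$q05, object$carbon[["q05"]], object$co2e[["q05"]]),
    q95 = c(object$q95, object$carbon[["q95"]], object$co2e[["q95"]])
  )
}

#' @export
plot.regional_estimate <- function(x, ...) {
  graphics::hist(x$totals, breaks = 30,
                 main = sprintf("Regional %s emissions", x$gas),
                 xlab = sprintf("Gg %s yr-1", x$gas), ...)
  graphics::abline(v = c(x$q05, x$mean, x$q95), lty = c(2, 1, 2))
  invisible(x)
}

#' Convert a gas mass to carbon mass
#'
#' Multiplies by the carbon mass fraction of the molecule: 12.01/16.04 for
#' CH4 and 12.01/44.01 for CO2.
#'
#' @param mass Gas mass (any mass unit; vectorised), >= 0.
#' @param gas `"CH4"` or `"CO2"`.
#' @return Carbon mass in the same unit.
#' @examples
#' gas_to_carbon(76.6, "CH4")  # ~57.4
#' @export
gas_to_carbon <- function(mass, gas) {
  gas <- match_gas(gas)
  if (any(mass < 0)) stop("mass must be >= 0")
  mass * .MOLAR_MASS_C / .MOLAR_MASS[[gas]]
}

#' Convert a carbon mass back to gas mass
#'
#' Inverse of [gas_to_carbon()].
#'
#' @inheritParams gas_to_carbon
#' @param mass Carbon mass, >= 0.
#' @return Gas mass in the same unit.
#' @examples
#' carbon_to_gas(568.6, "CO2")  # ~2084
#' @export
carbon_to_gas <- function(mass, gas) {
  gas <- match_gas(gas)
  if (any(mass < 0)) stop("mass must be >= 0")
  mass * .MOLAR_MASS[[gas]] / .MOLAR_MASS_C
}

#' Convert a gas mass to CO2 equivalents
#'
#' CH4 mass is multiplied by its 100-yr global warming potential (28 on a
#' mass basis); CO2 passes through unchanged.
#'
#' @inheritParams gas_to_carbon
#' @param gwp Mass-basis GWP100 for CH4.
#' @return CO2-equivalent mass in the same unit.
#' @examples
#' gas_to_co2e(76.6, "CH4")  # ~2144.8
#' @export
gas_to_co2e <- function(mass, gas, gwp = .GWP100_CH4) {
  gas <- match_gas(gas)
  if (any(mass < 0)) stop("mass must be >= 0")
  if (gas == "CH4") mass * gwp else mass
}

#' Ice-cover-period emission from the ice-free total
#'
#' Chamber surveys cover only the ice-free season. If ice-cover-period
#' emissions are known (from comparable lake systems) to contribute a
#' fraction `p_ice` of the *annual* total, the ice-cover amount implied by
#' an ice-free total `E` is `E * p_ice / (1 - p_ice)`, so that the annual
#' total `E + E*p/(1-p)` has the stated ice-cover share.
#'
#' @param ice_free_emission Ice-free-season emission (any unit), >= 0.
#' @param p_ice Ice-cover fraction of the annual total, in `[0, 1)`.
#' @return Ice-cover-period emission in the same unit.
#' @examples
#' ice_cover_correction(76.6, 0.27)    # ~28.3
#' ice_cover_correction(2084.7, 0.17)  # ~427
#' @export
ice_cover_correction <- function(ice_free_emission, p_ice) {
  if (any(p_ice < 0 | p_ice >= 1)) stop("p_ice must be in [0, 1)")
  if (any(ice_free_emission < 0)) stop("emission must be >= 0")
  ice_free_emission * p_ice / (1 - p_ice)
}

#' Example regional strata table
#'
#' A bundled illustration of the strata input for [upscale()]: the three
#' alpine grassland types splitting a 2800 km2 total thermokarst-lake area
#' in proportion to how often each type hosts surveyed lake clusters, with
#' per-type flux means and standard deviations matching the synthetic
#' survey defaults. The areas are illustrative, not a mapped product.
#'
#' @param total_area_km2 Total lake area to split (default 2800 km2).
#' @param mix Named proportions over `AS`, `AM`, `SM` (summing to 1).
#' @param flux_mean,flux_sd Named per-type flux summaries, mmol m-2 d-1.
#' @return A strata data frame accepted by [upscale()].
#' @export
example_strata <- function(total_area_km2 = 2800,
                           mix = c(AS = 5, AM = 13, SM = 12) / 30,
                           flux_mean = c(AS = 8.7, AM = 16.1, SM = 12.5),
                           flux_sd = c(AS = 3.0, AM = 1.7, SM = 2.0)) {
  types <- names(mix)
  data.frame(grassland_type = types,
             area_km2 = unname(total_area_km2 * mix / sum(mix)),
             flux_mean = unname(flux_mean[types]),
             flux_sd = unname(flux_sd[types]))
}
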