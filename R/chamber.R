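#' Floating-chamber geometry
#'
#' Describes the cylindrical floating chamber used for flux measurements.
#' The base area intercepts the gas flux and the headspace volume converts
#' mixing ratios to molar amounts. The default dimensions (26 cm diameter,
#' 25 cm height) match a lightweight opaque chamber commonly deployed on
#' shallow lakes. The full cylinder is treated as headspace; if the chamber
#' rides with a draft, pass the effective `height`.
#'
#' @param diameter Chamber diameter in m.
#' @param height Effective headspace height in m.
#' @return An object of class `chamber_geometry` with elements `diameter`,
#'   `height`, `area` (m^2) and `volume` (m^3).
#' @examples
#' chamber_geometry()
#' @export
chamber_geometry <- function(diameter = 0.26, height = 0.25) {
  if (diameter <= 0 || height <= 0) stop("chamber dimensions must be positive")
  area <- pi * (diameter / 2)^2
  structure(
    list(diameter = diameter, height = height, area = area,
         volume = area * height),
    class = "chamber_geometry"
  )
}

#' @export
print.chamber_geometry <- function(x, ...) {
  cat(sprintf(
    "Floating chamber: d = %.3g m, h = %.3g m, A = %.5g m^2, V = %.5g m^3\n",
    x$diameter, x$height, x$area, x$volume))
  invisible(x)
}

#' Convert a mixing ratio to a molar amount in the chamber headspace
#'
#' Applies the ideal gas law to the chamber headspace: a mixing ratio of
#' `x` ppm at pressure `P` corresponds to `n = x * 1e-6 * P * V / (R * T)`
#' moles of the gas. Site pressure matters: at 4300 m elevation the same
#' ppm reading holds ~40% fewer moles than at sea level.
#'
#' @param x_ppm Mixing ratio in ppm (umol/mol). May be a vector.
#' @param geometry A [chamber_geometry()].
#' @param pressure_kpa Air pressure inside the chamber, kPa.
#' @param temperature_k Chamber air temperature, K.
#' @return Amount of gas in mmol (same length as `x_ppm`).
#' @examples
#' mixing_ratio_to_moles(1.9, chamber_geometry(), 61, 283)
#' @export
mixing_ratio_to_moles <- function(x_ppm, geometry = chamber_geometry(),
                                  pressure_kpa, temperature_k) {
  if (any(x_ppm < 0)) stop("mixing ratio must be non-negative")
  if (any(pressure_kpa <= 0)) stop("pressure must be positive")
  if (any(temperature_k <= 0)) stop("temperature must be positive (K)")
  n_mol <- x_ppm * 1e-6 * (pressure_kpa * 1000) * geometry$volume /
    (.R_GAS * temperature_k)
  n_mol * 1000  # mmol
}

#' Total gas flux from a chamber concentration time series
#'
#' Computes the total flux of CH4 or CO2 across the water surface from the
#' accumulation of gas in a closed floating chamber,
#' `F_total = (n_t - n_0) / (A * t)`, where `n_0` and `n_t` are the molar
#' amounts of gas in the chamber at the start and end of the recording
#' window and `A` is the chamber base area. The default window discards the
#' first 20 s (boundary-layer disturbance from chamber deployment) and ends
#' at 170 s, i.e. a 150 s recording span.
#'
#' Two estimators are available: `"endpoint"` uses only the two window
#' endpoints (the definition above); `"regression"` fits an ordinary
#' least-squares line to the molar amount over the whole window and uses its
#' slope, which is more robust to instrument noise. On a noise-free linear
#' series the two agree exactly. Negative fluxes (uptake) are permitted.
#'
#' @param time_s Sampling times in seconds since deployment; strictly
#'   increasing.
#' @param conc_ppm Gas mixing ratio at each time, ppm.
#' @param pressure_kpa Site air pressure, kPa.
#' @param temperature_k Chamber air temperature, K.
#' @param geometry A [chamber_geometry()].
#' @param method `"endpoint"` (default) or `"regression"`.
#' @param window Two-element numeric, start and end of the analysis window
#'   in seconds (default `c(20, 170)`).
#' @param gas Label recorded in the result (`"CH4"` or `"CO2"`).
#' @return An object of class `flux_record`: a list with `flux`
#'   (mmol m-2 d-1), `gas`, `method`, `r_squared` (regression only),
#'   `n0`/`nt` (mmol), and `window`.
#' @examples
#' t <- 0:170
#' ppm <- 1.9 + 0.004 * t
#' compute_total_flux(t, ppm, pressure_kpa = 61, temperature_k = 283)
#' @export
compute_total_flux <- function(time_s, conc_ppm, pressure_kpa, temperature_k,
                               geometry = chamber_geometry(),
                               method = c("endpoint", "regression"),
                               window = c(20, 170), gas = "CH4") {
  method <- match.arg(method)
  gas <- match_gas(gas)
  if (length(time_s) != length(conc_ppm))
    stop("time and concentration vectors must have equal length")
  if (any(diff(time_s) <= 0)) stop("timestamps must be strictly increasing")
  if (min(time_s) > window[1] || max(time_s) < window[2])
    stop(sprintf("series does not span the analysis window [%g, %g] s",
                 window[1], window[2]))

  n_mmol <- mixing_ratio_to_moles(conc_ppm, geometry, pressure_kpa,
                                  temperature_k)
  span <- window[2] - window[1]
  in_win <- time_s >= window[1] & time_s <= window[2]

  if (method == "endpoint") {
    ends <- stats::approx(time_s, n_mmol, xout = window)$y
    flux <- (ends[2] - ends[1]) / (geometry$area * span) * .SEC_PER_DAY
    r2 <- NA_real_
    n0 <- ends[1]; nt <- ends[2]
  } else {
    tw <- time_s[in_win]; nw <- n_mmol[in_win]
    fit <- stats::lm.fit(cbind(1, tw), nw)
    slope <- fit$coefficients[2]
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((nw - mean(nw))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
    if (is.finite(r2) && r2 < 0.9)
      warning(sprintf("regression fit is poor (R^2 = %.2f)", r2))
    flux <- slope / geometry$area * .SEC_PER_DAY
    n0 <- nw[1]; nt <- nw[length(nw)]
  }

  structure(
    list(gas = gas, flux = unname(flux), method = method,
         r_squared = unname(r2), n0 = unname(n0), nt = unname(nt),
         window = window),
    class = "flux_record"
  )
}

#' @export
print.flux_record <- function(x, ...) {
  cat(sprintf("%s flux: %.4g mmol m-2 d-1 (%s method", x$gas, x$flux,
              x$method))
  if (!is.na(x$r_squared)) cat(sprintf(", R^2 = %.3f", x$r_squared))
  cat(")\n")
  invisible(x)
}

#' CO2-equivalent CH4 flux
#'
#' Converts a molar CH4 flux to a CO2-equivalent molar flux using the
#' 100-year global warming potential of CH4 (28, on a gas-mass basis) and
#' the CH4:CO2 molar-mass ratio, i.e. `f * 28 * 16.04 / 44.01`. A mean
#' ice-free flux of 13.4 mmol CH4 m-2 d-1 converts to ~136.8 CO2-e
#' mmol m-2 d-1.
#'
#' @param f_ch4 CH4 flux, mmol m-2 d-1 (vectorised).
#' @param gwp 100-yr global warming potential, mass basis. Default 28.
#' @return CO2-equivalent flux, mmol CO2-e m-2 d-1.
#' @examples
#' co2_equivalent_flux(13.4)
#' @export
co2_equivalent_flux <- function(f_ch4, gwp = .GWP100_CH4) {
  stopifnot_finite(f_ch4, "f_ch4")
  f_ch4 * gwp * .MOLAR_MASS[["CH4"]] / .MOLAR_MASS[["CO2"]]
}

#' Total fluxes for every chamber deployment in a survey
#'
#' Applies [compute_total_flux()] to both gases of every deployment in a
#' long-format chamber table (columns `cluster_id`, `lake_id`, `campaign`,
#' `location`, `t_s`, `ch4_ppm`, `co2_ppm`), looking up site pressure and
#' air temperature from the site table.
#'
#' @param chamber_series Long chamber table as written by [write_survey()].
#' @param sites Site table with one row per lake-campaign, columns
#'   `cluster_id`, `lake_id`, `campaign`, `air_pressure` (kPa),
#'   `air_temperature` (deg C).
#' @param geometry A [chamber_geometry()].
#' @param method Passed to [compute_total_flux()].
#' @return A data frame with one row per deployment: keys, `f_ch4`, `f_co2`
#'   (mmol m-2 d-1), fit `r2_ch4`/`r2_co2` (regression only) and `method`.
#' @export
compute_fluxes <- function(chamber_series, sites,
                           geometry = chamber_geometry(),
                           method = c("endpoint", "regression")) {
  method <- match.arg(method)
  key <- interaction(chamber_series$cluster_id, chamber_series$lake_id,
                     chamber_series$campaign, chamber_series$location,
                     drop = TRUE)
  site_key <- paste(sites$cluster_id, sites$lake_id, sites$campaign)
  pieces <- lapply(split(chamber_series, key), function(d) {
    i <- match(paste(d$cluster_id[1], d$lake_id[1], d$campaign[1]), site_key)
    if (is.na(i)) stop("no site record for deployment ",
                       paste(d$cluster_id[1], d$lake_id[1], d$campaign[1]))
    p <- sites$air_pressure[i]
    tk <- sites$air_temperature[i] + .KELVIN0
    f4 <- compute_total_flux(d$t_s, d$ch4_ppm, p, tk, geometry, method,
                             gas = "CH4")
    f2 <- compute_total_flux(d$t_s, d$co2_ppm, p, tk, geometry, method,
                             gas = "CO2")
    data.frame(cluster_id = d$cluster_id[1], lake_id = d$lake_id[1],
               campaign = d$campaign[1], location = d$location[1],
               f_ch4 = f4$flux, f_co2 = f2$flux,
               r2_ch4 = f4$r_squared, r2_co2 = f2$r_squared,
               method = method)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$cluster_id, out$lake_id, out$campaign, out$location), ,
      drop = FALSE]
}
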