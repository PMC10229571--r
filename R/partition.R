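#' Schmidt-number polynomial coefficients
#'
#' Fourth-order freshwater polynomials `Sc(T) = a0 + a1*T + a2*T^2 +
#' a3*T^3 + a4*T^4` (T in deg C) from the standard gas-exchange
#' compilation. Both gases give Sc near 600 at 20 deg C. Override the
#' matrix to use a different parameterisation.
#'
#' @return A numeric matrix with rows `CH4`, `CO2` and columns `a0`..`a4`.
#' @export
schmidt_coefficients <- function() {
  m <- rbind(
    CH4 = c(1909.4, -120.78, 4.1555, -0.080578, 0.00065777),
    CO2 = c(1923.6, -125.06, 4.3773, -0.085681, 0.00070284)
  )
  colnames(m) <- paste0("a", 0:4)
  m
}

#' Schmidt number of CH4 or CO2 in fresh water
#'
#' Evaluates the freshwater Schmidt-number polynomial at the water
#' temperature. Schmidt numbers decrease steeply with temperature;
#' temperatures outside the 0-30 deg C calibration range are clamped with
#' a warning.
#'
#' @param gas `"CH4"` or `"CO2"`.
#' @param temperature_c Water temperature, deg C (vectorised).
#' @param coefficients Coefficient matrix, see [schmidt_coefficients()].
#' @return Dimensionless Schmidt number.
#' @examples
#' schmidt_number("CO2", 20)  # ~600
#' @export
schmidt_number <- function(gas, temperature_c,
                           coefficients = schmidt_coefficients()) {
  gas <- match_gas(gas)
  if (!gas %in% rownames(coefficients)) stop("no coefficients for gas ", gas)
  if (any(temperature_c < 0 | temperature_c > 30)) {
    warning("temperature outside 0..30 C; clamping")
    temperature_c <- pmin(pmax(temperature_c, 0), 30)
  }
  a <- unname(coefficients[gas, ])
  a[1] + a[2] * temperature_c + a[3] * temperature_c^2 +
    a[4] * temperature_c^3 + a[5] * temperature_c^4
}

#' CO2 transfer velocity from the measured CO2 flux
#'
#' Because CO2 is highly soluble its ebullitive transport is negligible and
#' the chamber CO2 flux is purely diffusive; the two-layer model
#' `F = k * (C_w - C_eq)` can then be inverted for the transfer velocity:
#' `k_CO2 = F_CO2 / (C_w - C_eq)`. A near-zero dissolved-gas gradient
#' (|C_w - C_eq| below `epsilon`) makes the division degenerate, and a
#' negative quotient (flux against the gradient) is physically invalid;
#' both cases return `NA` rather than an error so that table-level code can
#' fall back to neighbouring lakes.
#'
#' @param f_co2 Total (= diffusive) CO2 flux, mmol m-2 d-1.
#' @param c_w,c_eq Dissolved and equilibrium CO2 concentrations, mmol m-3.
#' @param epsilon Minimum usable |C_w - C_eq| gradient, mmol m-3.
#' @return Transfer velocity in m d-1, `NA` where degenerate or invalid
#'   (vectorised).
#' @examples
#' k_co2_from_co2_flux(170.4, 97.2, 12.0)  # 2.0 m d-1
#' @export
k_co2_from_co2_flux <- function(f_co2, c_w, c_eq, epsilon = 1) {
  gradient <- c_w - c_eq
  k <- ifelse(abs(gradient) > epsilon, f_co2 / gradient, NA_real_)
  ifelse(!is.na(k) & k < 0, NA_real_, k)
}

#' CH4 transfer velocity by Schmidt-number scaling
#'
#' Transfers the CO2-anchored velocity to CH4:
#' `k_CH4 = k_CO2 * (Sc_CH4 / Sc_CO2)^(-n)`, with the exponent set by the
#' wind regime: `n = 1/2` for wind speeds at or above 3.6 m s-1 (wavy,
#' turbulent surface) and `n = 2/3` below (smooth surface).
#'
#' @param k_co2 CO2 transfer velocity, m d-1.
#' @param sc_ch4,sc_co2 Schmidt numbers of CH4 and CO2 (see
#'   [schmidt_number()]).
#' @param wind_speed Wind speed at the site, m s-1.
#' @return CH4 transfer velocity, m d-1 (vectorised; `NA` propagates from
#'   `k_co2`).
#' @examples
#' k_ch4(2, sc_ch4 = 660, sc_co2 = 600, wind_speed = 2)
#' @export
k_ch4 <- function(k_co2, sc_ch4, sc_co2, wind_speed) {
  if (any(sc_ch4 <= 0) || any(sc_co2 <= 0))
    stop("Schmidt numbers must be positive")
  n <- ifelse(wind_speed >= 3.6, 1 / 2, 2 / 3)
  k_co2 * (sc_ch4 / sc_co2)^(-n)
}

#' Partition a total CH4 flux into diffusion and ebullition
#'
#' The diffusive component follows the two-layer model
#' `F_d = k_CH4 * (C_w - C_eq)`; the ebullitive component is the remainder
#' `F_e = F_total - F_d`. Measurement noise can push the remainder slightly
#' negative; since ebullition cannot be negative, such values are clamped
#' to zero (flagged, with the raw value retained). The ebullition share is
#' computed after clamping.
#'
#' @param f_total Total CH4 flux, mmol m-2 d-1.
#' @param k CH4 transfer velocity, m d-1.
#' @param c_w,c_eq Dissolved and equilibrium CH4 concentrations, mmol m-3.
#' @param clamp If `FALSE`, keep negative ebullition values.
#' @return A data frame with `f_total`, `f_d`, `f_e`, `f_e_raw`,
#'   `ebullition_share` and `clamped` (all vectorised).
#' @examples
#' partition_flux(13.3, k = 2, c_w = 1.052, c_eq = 0.002)
#' @export
partition_flux <- function(f_total, k, c_w, c_eq, clamp = TRUE) {
  f_d <- k * (c_w - c_eq)
  f_e_raw <- f_total - f_d
  clamped <- !is.na(f_e_raw) & f_e_raw < 0 & clamp
  f_e <- ifelse(clamped, 0, f_e_raw)
  share <- ifelse(!is.na(f_total) & f_total > 0, f_e / f_total, NA_real_)
  data.frame(f_total = f_total, f_d = f_d, f_e = f_e, f_e_raw = f_e_raw,
             ebullition_share = share, clamped = clamped)
}

#' Partition every lake-campaign of a survey
#'
#' Table-level driver: averages deployment fluxes over sampling locations,
#' anchors the transfer velocity on the CO2 flux and dissolved-CO2 gradient
#' of each lake-campaign, scales it to CH4 with the wind-regime Schmidt
#' exponent, and partitions the total CH4 flux. Where the CO2 anchor is
#' degenerate (near-zero gradient or sign mismatch) the cluster median of
#' the valid velocities is substituted and the provenance recorded as
#' `"fallback_median"` so no lake is discarded.
#'
#' @param fluxes Output of [compute_fluxes()].
#' @param dissolved Output of [dissolved_concentrations()].
#' @param sites Site table (per lake-campaign) with `water_temperature`
#'   (deg C) and `wind_speed` (m s-1).
#' @param epsilon Degeneracy threshold for the CO2 gradient, mmol m-3.
#' @param clamp Clamp negative ebullition to zero (default `TRUE`).
#' @param coefficients Schmidt coefficients, see [schmidt_coefficients()].
#' @return One row per lake-campaign: keys, `f_total`, `f_d`, `f_e`,
#'   `f_e_raw`, `ebullition_share`, `clamped`, `k_co2`, `k_ch4` and
#'   `k_provenance`.
#' @export
partition_fluxes <- function(fluxes, dissolved, sites, epsilon = 1,
                             clamp = TRUE,
                             coefficients = schmidt_coefficients()) {
  # mean flux per lake-campaign across sampling locations
  agg <- stats::aggregate(cbind(f_ch4, f_co2) ~ cluster_id + lake_id +
                            campaign, data = fluxes, FUN = mean)
  key <- function(d) paste(d$cluster_id, d$lake_id, d$campaign)
  dis_ch4 <- dissolved[dissolved$gas == "CH4", ]
  dis_co2 <- dissolved[dissolved$gas == "CO2", ]
  i4 <- match(key(agg), key(dis_ch4))
  i2 <- match(key(agg), key(dis_co2))
  is <- match(key(agg), key(sites))
  if (anyNA(i4) || anyNA(i2) || anyNA(is))
    stop("fluxes, dissolved and sites tables do not align on lake-campaigns")

  wt <- sites$water_temperature[is]
  k_co2 <- k_co2_from_co2_flux(agg$f_co2, dis_co2$c_w[i2], dis_co2$c_eq[i2],
                               epsilon)
  provenance <- ifelse(is.na(k_co2), "fallback_median", "direct")
  if (anyNA(k_co2)) {
    med <- tapply(k_co2, agg$cluster_id, stats::median, na.rm = TRUE)
    fallback <- med[as.character(agg$cluster_id)]
    # cluster with no valid anchor at all: survey-wide median
    fallback[is.na(fallback)] <- stats::median(k_co2, na.rm = TRUE)
    k_co2[is.na(k_co2)] <- fallback[is.na(k_co2)]
  }
  kc <- k_ch4(k_co2, schmidt_number("CH4", wt, coefficients),
              schmidt_number("CO2", wt, coefficients),
              sites$wind_speed[is])
  part <- partition_flux(agg$f_ch4, kc, dis_ch4$c_w[i4], dis_ch4$c_eq[i4],
                         clamp = clamp)
  cbind(agg[c("cluster_id", "lake_id", "campaign")], part,
        data.frame(k_co2 = unname(k_co2), k_ch4 = unname(kc),
                   k_provenance = unname(provenance)))
}

#' Regression of ebullition share on air pressure or elevation
#'
#' Ordinary least-squares regression of the per-cluster ebullition share on
#' a site predictor (air pressure or elevation), after boxplot outlier
#' screening of the shares. Lower air pressure both reduces CH4 solubility
#' and eases bubble growth in sediments, so a negative pressure slope (and
#' the mirror-image positive elevation slope) is the expected signal.
#'
#' @param share Ebullition share per cluster (fraction).
#' @param predictor Cluster-level predictor (kPa or m).
#' @param log_share Regress `log10(share)` instead of `share`.
#' @param screen_outliers Drop boxplot outliers of `share` first
#'   (see [boxplot_outliers()]).
#' @return An object of class `ebullition_regression`: list with `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n` and `n_removed`.
#' @export
ebullition_pressure_regression <- function(share, predictor,
                                           log_share = FALSE,
                                           screen_outliers = TRUE) {
  if (length(share) != length(predictor))
    stop("share and predictor must have equal length")
  ok <- is.finite(share) & is.finite(predictor)
  share <- share[ok]; predictor <- predictor[ok]
  n_removed <- 0L
  if (screen_outliers && length(share) >= 4) {
    flagged <- boxplot_outliers(share)
    n_removed <- sum(flagged)
    share <- share[!flagged]; predictor <- predictor[!flagged]
  }
  if (length(share) < 3)
    stop("fewer than 3 clusters after screening; cannot fit regression")
  y <- if (log_share) log10(share) else share
  fit <- stats::lm(y ~ predictor)
  sm <- summary(fit)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = sm$r.squared,
         p_value = unname(sm$coefficients[2, 4]),
         n = length(y), n_removed = n_removed, log_share = log_share),
    class = "ebullition_regression"
  )
}

#' @export
print.ebullition_regression <- function(x, ...) {
  cat(sprintf(
    "Ebullition-share regression (%s): slope = %.4g, R^2 = %.2f, p = %.3g (n = %d%s)\n",
    if (x$log_share) "log10 share" else "share",
    x$slope, x$r_squared, x$p_value, x$n,
    if (x$n_removed > 0) sprintf(", %d outliers removed", x$n_removed) else ""))
  invisible(x)
}
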