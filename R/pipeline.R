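#' Run the full analysis pipeline on a survey
#'
#' Chains the analysis stages on a survey (in memory or on disk): total
#' fluxes from every chamber deployment, dissolved concentrations and
#' saturation from the water samples, diffusion/ebullition partitioning
#' with the CO2-anchored transfer velocity, and the per-lake isotope
#' summary (when isotope records are present).
#'
#' @param survey A `lake_survey` (see [generate_survey()]) or a directory
#'   path accepted by [read_survey()].
#' @param geometry A [chamber_geometry()].
#' @param method Flux estimator, `"endpoint"` or `"regression"`.
#' @return An object of class `lake_analysis`: list with `fluxes`,
#'   `dissolved`, `partitioned`, `isotopes` (an `isotope_summary` or
#'   `NULL`), `clusters` (per-cluster means of flux, ebullition share,
#'   pressure and elevation) and the input `survey`.
#' @examples
#' sv <- generate_survey(survey_config(n_clusters = 2, campaigns = 1))
#' an <- analyze_survey(sv)
#' head(an$partitioned)
#' @export
analyze_survey <- function(survey, geometry = chamber_geometry(),
                           method = c("endpoint", "regression")) {
  method <- match.arg(method)
  if (is.character(survey)) survey <- read_survey(survey)
  stopifnot(inherits(survey, "lake_survey"))
  fluxes <- compute_fluxes(survey$chamber_series, survey$sites, geometry,
                           method)
  dissolved <- dissolved_concentrations(survey$water_samples)
  partitioned <- partition_fluxes(fluxes, dissolved, survey$sites)
  isot <- if (!is.null(survey$isotopes) && nrow(survey$isotopes) > 0)
    isotope_summary(survey$isotopes)

  site_cl <- stats::aggregate(
    cbind(air_pressure, elevation) ~ cluster_id, data = survey$sites,
    FUN = mean)
  part_cl <- stats::aggregate(
    cbind(f_total, f_d, f_e, ebullition_share) ~ cluster_id,
    data = partitioned, FUN = mean)
  clusters <- merge(part_cl, site_cl, by = "cluster_id")

  structure(
    list(fluxes = fluxes, dissolved = dissolved,
         partitioned = partitioned, isotopes = isot,
         clusters = clusters, survey = survey),
    class = "lake_analysis"
  )
}

#' @export
print.lake_analysis <- function(x, ...) {
  p <- x$partitioned
  cat(sprintf("Lake survey analysis: %d lake-campaigns in %d clusters\n",
              nrow(p), length(unique(p$cluster_id))))
  cat(sprintf("  total CH4 flux: %.2f mmol m-2 d-1 (mean)\n",
              mean(p$f_total)))
  cat(sprintf("  diffusion %.2f + ebullition %.2f; ebullition share of summed flux: %.1f%%\n",
              mean(p$f_d), mean(p$f_e),
              100 * sum(p$f_e) / sum(p$f_total)))
  cat(sprintf("  mean of per-lake shares: %.1f%%; clamped records: %d\n",
              100 * mean(p$ebullition_share, na.rm = TRUE),
              sum(p$clamped)))
  if (!is.null(x$isotopes)) print(x$isotopes)
  invisible(x)
}

#' Per-stratum flux summaries from an analysed survey
#'
#' Aggregates an analysis to the strata table [upscale()] expects: lakes
#' are first averaged over campaigns, then each grassland type
#' contributes its across-lake mean and standard deviation of the chosen
#' flux, joined to the supplied per-type lake areas.
#'
#' @param analysis A `lake_analysis` (see [analyze_survey()]).
#' @param areas_km2 Named per-type thermokarst-lake areas, km2.
#' @param gas `"CH4"` (total CH4 flux) or `"CO2"`.
#' @return A strata data frame for [upscale()].
#' @export
strata_from_analysis <- function(analysis, areas_km2, gas = c("CH4", "CO2")) {
  gas <- match.arg(gas)
  stopifnot(inherits(analysis, "lake_analysis"))
  p <- analysis$partitioned
  p$flux <- if (gas == "CH4") p$f_total else NULL
  if (gas == "CO2") {
    f <- stats::aggregate(f_co2 ~ cluster_id + lake_id,
                          data = analysis$fluxes, FUN = mean)
    names(f)[3] <- "flux"
  } else {
    f <- stats::aggregate(flux ~ cluster_id + lake_id, data = p,
                          FUN = mean)
  }
  key <- paste(f$cluster_id, f$lake_id)
  skey <- paste(analysis$survey$sites$cluster_id,
                analysis$survey$sites$lake_id)
  f$grassland_type <- analysis$survey$sites$grassland_type[match(key, skey)]
  agg <- stats::aggregate(flux ~ grassland_type, data = f,
                          FUN = function(x) c(mean(x), stats::sd(x)))
  out <- data.frame(grassland_type = agg$grassland_type,
                    area_km2 = unname(areas_km2[agg$grassland_type]),
                    flux_mean = agg$flux[, 1],
                    flux_sd = ifelse(is.na(agg$flux[, 2]), 0,
                                     agg$flux[, 2]))
  if (anyNA(out$area_km2))
    stop("areas_km2 must be named for every grassland type present")
  out
}
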