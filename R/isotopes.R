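#' Apparent carbon isotope fractionation factor
#'
#' `alpha_C = (d13C-CO2 + 1000) / (d13C-CH4 + 1000)`, with both delta
#' values in permil vs VPDB. Methanogenesis discriminates strongly against
#' 13C, and the CO2-reduction (hydrogenotrophic) pathway discriminates more
#' than acetate fermentation, so larger alpha_C points to hydrogenotrophic
#' CH4 production.
#'
#' @param d13c_co2,d13c_ch4 Delta 13C of co-emitted CO2 and CH4, permil.
#' @return Dimensionless fractionation factor (vectorised).
#' @examples
#' alpha_c(-13.4, -72.5)  # ~1.064
#' @export
alpha_c <- function(d13c_co2, d13c_ch4) {
  denom <- d13c_ch4 + 1000
  if (any(denom <= 0))
    stop("d13C-CH4 at or below -1000 permil: fractionation factor singular")
  (d13c_co2 + 1000) / denom
}

#' Classify the methanogenic pathway from alpha_C
#'
#' Thresholds: `alpha_C > 1.055` indicates CO2 reduction (hydrogenotrophic
#' methanogenesis), `alpha_C < 1.04` acetate fermentation (acetoclastic),
#' and the band between them a mixed signal. The published thresholds are
#' strict inequalities, so values exactly on a boundary fall in the mixed
#' class. The three classes partition the whole positive axis.
#'
#' @param alpha Apparent fractionation factor(s), > 0.
#' @return A factor with levels `acetoclastic`, `mixed`,
#'   `hydrogenotrophic`.
#' @examples
#' classify_pathway(c(1.039, 1.052, 1.064))
#' @export
classify_pathway <- function(alpha) {
  if (any(alpha <= 0)) stop("alpha must be positive")
  out <- ifelse(alpha > 1.055, "hydrogenotrophic",
                ifelse(alpha < 1.04, "acetoclastic", "mixed"))
  factor(out, levels = c("acetoclastic", "mixed", "hydrogenotrophic"))
}

#' Conventional radiocarbon age from fraction modern
#'
#' `age = -8033 * ln(F)` years before present (0 BP = AD 1950), using the
#' Libby mean life of 8033 yr, rounded to the nearest year. Samples with
#' `F > 1` carry bomb-spike carbon fixed after 1950 and get negative ages.
#'
#' @param fraction_modern Normalised 14C fraction modern, > 0 (the
#'   delta-13C fractionation correction is assumed already applied).
#' @return Conventional age in yrs BP (integer-valued, vectorised).
#' @examples
#' radiocarbon_age(c(1, exp(-1), 1.0458))
#' @export
radiocarbon_age <- function(fraction_modern) {
  if (any(fraction_modern <= 0))
    stop("fraction modern must be positive")
  round(-8033 * log(fraction_modern))
}

#' Summarise a set of radiocarbon ages
#'
#' Reports the arithmetic mean age (negative ages included), the fraction
#' of samples with modern carbon (age <= 0, i.e. fixed after AD 1950), and
#' the count of samples older than a threshold (default 1000 yrs BP, the
#' conventional marker for a substantial old-carbon contribution).
#'
#' @param ages Conventional ages, yrs BP.
#' @param old_threshold Age above which a sample counts as old, yrs BP.
#' @return A list with `n`, `mean_age`, `modern_fraction` (0-1) and
#'   `n_old`.
#' @examples
#' summarize_ages(c(-360, 3810))
#' @export
summarize_ages <- function(ages, old_threshold = 1000) {
  if (length(ages) == 0) stop("no ages supplied")
  stopifnot_finite(ages, "ages")
  list(n = length(ages),
       mean_age = mean(ages),
       modern_fraction = mean(ages <= 0),
       n_old = sum(ages > old_threshold))
}

#' Per-lake isotope summary for a survey
#'
#' Computes alpha_C, the pathway class and the conventional radiocarbon
#' age for every record of a survey isotope table, plus survey-level
#' aggregates.
#'
#' @param isotopes Data frame with columns `cluster_id`, `lake_id`,
#'   `d13c_ch4`, `d13c_co2`, `c14_fraction_modern`.
#' @return A list of class `isotope_summary` with `records` (the input
#'   plus `alpha_c`, `pathway`, `age_bp`, `is_modern`) and `summary`
#'   (mean alpha, pathway counts, age summary per [summarize_ages()]).
#' @export
isotope_summary <- function(isotopes) {
  rec <- isotopes
  rec$alpha_c <- alpha_c(rec$d13c_co2, rec$d13c_ch4)
  rec$pathway <- classify_pathway(rec$alpha_c)
  rec$age_bp <- radiocarbon_age(rec$c14_fraction_modern)
  rec$is_modern <- rec$age_bp <= 0
  structure(
    list(records = rec,
         summary = c(list(mean_alpha = mean(rec$alpha_c),
                          pathway_counts = table(rec$pathway)),
                     summarize_ages(rec$age_bp))),
    class = "isotope_summary"
  )
}

#' @export
print.isotope_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Isotope summary for %d lakes\n", s$n))
  cat(sprintf("  mean alpha_C: %.4f\n", s$mean_alpha))
  cat("  pathways:",
      paste(names(s$pathway_counts), as.integer(s$pathway_counts),
            sep = " = ", collapse = ", "), "\n")
  cat(sprintf("  mean 14C age: %.1f yrs BP; modern: %.0f%%; > 1000 BP: %d\n",
              s$mean_age, 100 * s$modern_fraction, s$n_old))
  invisible(x)
}
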