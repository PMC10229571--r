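# lakeghg

Chamber-based greenhouse-gas flux analysis for thermokarst lakes.

Thermokarst lakes — water bodies formed where thawing ice-rich permafrost
subsides — are hot spots of methane release, and quantifying their emissions
requires a chain of calculations that field studies usually re-implement ad
hoc: chamber time series to total fluxes, headspace samples to dissolved
concentrations, a two-layer model to split diffusion from bubbling, isotopes
to identify the CH₄ source, and Monte Carlo upscaling to a regional budget.
`lakeghg` packages that chain as tested, composable R functions, together
with a synthetic-survey generator with known ground truth so every stage has
a recovery test.

## The calculations

**Total flux** from a closed floating chamber (base area *A*) whose
headspace concentration is recorded at 1 Hz:

    F_total = (n_t − n_0) / (A · t)

with *n* the molar amount of CH₄ or CO₂ in the chamber (ideal gas at site
pressure) and the analysis window discarding the first 20 s of the record.
An endpoint estimator (the definition above) and a regression estimator
(OLS slope with an R² quality check) are provided.

**Dissolved gas** from headspace equilibration of a 50 mL water sample
against 50 mL of N₂, by the closed-syringe mass balance under Henry's law
(van 't Hoff temperature dependence), and saturation *S* = 100 ·
*C*<sub>w</sub> / *C*<sub>eq</sub> relative to the local atmosphere at site
pressure.

**Diffusion/ebullition partitioning** with the two-layer model
*F*<sub>d</sub> = *k* (*C*<sub>w</sub> − *C*<sub>eq</sub>). Because CO₂ is
too soluble to bubble, the CO₂ budget anchors the transfer velocity, which
is scaled to CH₄ through Schmidt numbers, *k*<sub>CH₄</sub> =
*k*<sub>CO₂</sub> (*Sc*<sub>CH₄</sub>/*Sc*<sub>CO₂</sub>)<sup>−n</sup>,
with *n* = 1/2 above 3.6 m s⁻¹ wind and 2/3 below. Ebullition is the
remainder *F*<sub>e</sub> = *F*<sub>total</sub> − *F*<sub>d</sub>, clamped
at zero.

**Isotopes**: the apparent fractionation factor α<sub>C</sub> =
(δ¹³C–CO₂ + 1000)/(δ¹³C–CH₄ + 1000) classifies the methanogenic pathway
(α<sub>C</sub> > 1.055 hydrogenotrophic, < 1.04 acetoclastic, mixed
between); radiocarbon fraction modern converts to conventional age
−8033 · ln *F* yrs BP, with age ≤ 0 marking post-1950 ("modern") carbon.

**Regional upscaling**: per grassland-type stratum, fluxes are drawn from a
zero-truncated normal, multiplied by lake area and a 200-day ice-free
season, summed over strata, and summarised by the Monte Carlo mean and
5th–95th percentiles — in Gg gas, Gg C (×12.01/*M*) and Gg CO₂-e (CH₄ ×28,
its 100-yr mass-basis GWP). An ice-cover correction *E* · *p*/(1 − *p*)
extrapolates beyond the ice-free season.

**Group statistics**: one-way ANOVA with Tukey HSD, Benjamini–Hochberg
adjustment, compact-letter displays, and Tukey-hinge boxplot outlier
screening.

## Worked example

```r
library(lakeghg)

sv <- generate_survey(survey_config(seed = 2024))  # 30 clusters x 4 lakes x 5 campaigns
an <- analyze_survey(sv)
an
#> Lake survey analysis: 600 lake-campaigns in 30 clusters
#>   total CH4 flux: 13.98 mmol m-2 d-1 (mean)
#>   diffusion 2.21 + ebullition 11.77; ebullition share of summed flux: 84.2%
#>   mean of per-lake shares: 84.0%; clamped records: 0
#> Isotope summary for 30 lakes
#>   mean alpha_C: 1.0645
#>   pathways: acetoclastic = 0, mixed = 0, hydrogenotrophic = 30
#>   mean 14C age: 396.2 yrs BP; modern: 43%; > 1000 BP: 5
```

The synthetic survey was configured with a true mean ebullition share of
0.84; the pipeline recovers 84.0% from the chamber records and water
samples alone. Low-pressure (high-elevation) clusters bubble more, and the
regression recovers the built-in dependence:

```r
cl <- an$clusters
ebullition_pressure_regression(cl$ebullition_share, cl$air_pressure)
#> Ebullition-share regression (share): slope = -0.007918, R^2 = 0.79, p = 5.94e-11 (n = 30)
```

Upscaling the per-type flux summaries over illustrative per-type lake areas
(2800 km² total):

```r
strata <- strata_from_analysis(an, c(AS = 466.7, AM = 1213.3, SM = 1120), "CH4")
est <- upscale(strata, "CH4", n_iterations = 1000, seed = 2024)
est
#> Regional CH4 emission estimate (1000 Monte Carlo iterations, 200-day season)
#>   gas mass: 125.8 (106.7-144.4) Gg CH4 yr-1
#>   carbon:   94.2 (79.9-108.1) Gg C yr-1
#>   CO2-e:    3522.9 (2988.9-4041.9) Gg CO2-e yr-1
ice_cover_correction(est$mean, 0.27)   # implied ice-cover-period emission, Gg
#> [1] 46.53475
```

The interval reflects only the configured per-type flux spread; with real
per-lake areas and flux statistics the same call produces a field regional
budget.

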