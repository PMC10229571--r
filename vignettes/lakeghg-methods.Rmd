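---
title: "Methods: from chamber records to a regional methane budget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from chamber records to a regional methane budget}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lakeghg)
```

`lakeghg` implements the analysis chain of a floating-chamber greenhouse-gas
survey of thermokarst lakes. This vignette explains each model, its
assumptions, the tunable parameters, the synthetic-data generator used for
validation, and the numerical choices made where the design was open.

## Total flux from a chamber record

A closed opaque chamber (default 26 cm diameter, 25 cm height) floats on
the lake while an analyser records headspace CH₄ and CO₂ at 1 Hz for
170 s. The total flux is the accumulation rate of gas over the chamber base
area:

$$F_\mathrm{total} = \frac{n_t - n_0}{A\,t},$$

where amounts $n$ come from the ideal gas law at *site* pressure and
chamber air temperature — essential at high elevation, where ~60 kPa air
holds 40% fewer moles per ppm than sea-level air. The first 20 s are
discarded: deploying the chamber disturbs the surface boundary layer, and
the record only becomes interpretable once accumulation is established.

Two estimators are offered. The *endpoint* estimator is the definition
above and is the default. The *regression* estimator fits an OLS line to
$n(t)$ over the window; it is preferable for noisy analysers and reports an
$R^2$ diagnostic (a warning is raised below 0.9). On a noise-free linear
series the two agree exactly, which the test suite asserts. The headspace
is treated as the full cylinder: no draft-depth correction is applied
(none is generally reported for lightweight chambers), but the effective
height is a `chamber_geometry()` argument.

Whether the analyser reports dry or wet mixing ratios is
instrument-specific; no water-vapour dilution correction is applied.

## Dissolved gas and saturation

Surface water is equilibrated in a closed syringe against an equal volume
of N₂ (defaults 50 mL / 50 mL), and the analyte is measured in the
headspace afterwards. The dissolved concentration follows from a mass
balance: everything initially dissolved is split between the headspace
(ideal gas) and the water (Henry's law at the headspace partial pressure).
Henry constants use the two-parameter van 't Hoff form
$H(T) = H^\circ \exp\!\big(B(1/T - 1/298.15)\big)$ with compilation
defaults $H^\circ_{\mathrm{CH}_4} = 1.4\times10^{-5}$,
$H^\circ_{\mathrm{CO}_2} = 3.3\times10^{-4}$ mol m⁻³ Pa⁻¹ and
$B_{\mathrm{CH}_4} = 1900$ K, $B_{\mathrm{CO}_2} = 2400$ K, all
overridable through `henry_constants()`.

Assumptions: equilibration is complete after shaking (no kinetic
correction); the syringe is at field water temperature (the equilibration
temperature is not usually logged separately); salinity effects on
solubility are ignored (≤ 2.6 ppt in these lakes, < 2% effect); CO₂ is
treated as a dissolved gas without carbonate-system speciation, which is
adequate for a transfer-velocity anchor but not for a carbonate budget.
Both the equilibrium concentration and the syringe balance use the
partial-pressure basis $x \cdot P$, so altitude is handled consistently:
`saturation()` compares against equilibrium with the *local* thin
atmosphere.

## Partitioning diffusion from ebullition

The two-layer model gives the diffusive flux
$F_d = k\,(C_w - C_\mathrm{eq})$. The transfer velocity is anchored on
CO₂ — whose high solubility makes bubble transport negligible, so its
chamber flux is entirely diffusive — and transferred to CH₄ by Schmidt
scaling:

$$k_{\mathrm{CH}_4} = k_{\mathrm{CO}_2}
  \left(\frac{Sc_{\mathrm{CH}_4}}{Sc_{\mathrm{CO}_2}}\right)^{-n},$$

with $n = 1/2$ for wind ≥ 3.6 m s⁻¹ and $2/3$ below. The published rule
leaves wind exactly 3.6 m s⁻¹ unassigned; the package assigns it the wavy
regime ($n = 1/2$), a choice that matters little since the Schmidt ratio
is near 1. Schmidt numbers are 4th-order freshwater polynomials in
temperature (standard parameterisation values, ~600 for CO₂ at 20 °C),
kept in an overridable coefficient matrix because different compilations
differ at the percent level.

Numerical guards: a CO₂ gradient below `epsilon` (default 1 mmol m⁻³)
makes the anchor division degenerate and a negative quotient is
unphysical; both yield `NA`, and `partition_fluxes()` substitutes the
cluster median of valid velocities (survey median if the whole cluster is
degenerate), recording `k_provenance = "fallback_median"` so no lake is
silently discarded. Ebullition $F_e = F_\mathrm{total} - F_d$ can come out
slightly negative under noise; it is clamped to zero with a flag and the
raw value retained (the unclamped identity $F_d + F_e = F_\mathrm{total}$
is a tested invariant). The ebullition share is reported both as the mean
of per-lake shares and as the ratio of summed fluxes (`analyze_survey()`
prints both): the two answer different questions and can differ by a few
points.

## Isotopic pathway and radiocarbon age

The apparent carbon fractionation factor
$\alpha_C = (\delta^{13}\mathrm{C{-}CO_2} + 1000) /
(\delta^{13}\mathrm{C{-}CH_4} + 1000)$ classifies the dominant
methanogenic pathway: > 1.055 CO₂ reduction (hydrogenotrophic), < 1.04
acetate fermentation (acetoclastic), mixed between. The published
thresholds are strict inequalities, so boundary values fall in the mixed
class; the three classes partition the positive axis with no gaps, which
is property-tested.

Radiocarbon ages use the conventional Libby form
$\mathrm{age} = -8033 \ln F$ yrs BP (0 BP = AD 1950), rounded to the
year; $F > 1$ (bomb carbon) gives negative ages. "Modern" is implemented
as age ≤ 0 — equivalently $F \ge 1$ — since AMS laboratory "Modern" flags
are not portable. The δ¹³C mass-fractionation normalisation of measured
¹⁴C is assumed already applied by the laboratory; the package starts from
fraction modern.

## Regional upscaling

`upscale()` propagates per-stratum (grassland-type) flux uncertainty with
a Monte Carlo of `n_iterations` (default 1000) draws: per iteration, one
flux per stratum from a normal truncated at zero (negative regional fluxes
being unphysical for these emitting lakes; truncation is by exact
rejection sampling in `rtnorm0()`), times stratum lake area, times the
ice-free season (default 200 days, the regional mean ice-free duration),
times molar mass. One draw per *type* per iteration — not per lake — is
used, treating the stratum mean as the uncertain quantity; per-lake
resampling would shrink the interval by the within-type lake count.
Percentile bounds are 5th/95th by linear-interpolation quantiles
(`stats::quantile`, type 7), standard and stable at 1000 iterations.

Whether a field study's per-type spread is an SD or an SE, per-lake or
per-cluster, varies; the strata table takes whatever spread the user deems
appropriate, and `strata_from_analysis()` uses the across-lake SD of
campaign-averaged fluxes. Strata areas are inputs: mapping lake area per
grassland type is remote-sensing work outside this package, and
`example_strata()` merely splits a 2800 km² total for illustration —
regional totals computed from it are therefore illustrative, not field
estimates.

Unit conversions are exact mass ratios: Gg gas → Gg C via $12.01/M$;
CO₂-equivalents via the 100-yr mass-basis GWP of 28 for CH₄ (identity for
CO₂); the molar-flux conversion `co2_equivalent_flux()` is
$f \cdot 28 \cdot 16.04/44.01$. The ice-cover correction answers "what
ice-cover-period emission makes the stated fraction $p$ of the annual
total?": $E_\mathrm{ice} = E_\mathrm{free}\, p/(1-p)$.

## Group statistics

`anova_tukey()` is one-way ANOVA with Tukey HSD pairwise comparisons,
BH adjustment applied across the pairwise family (both raw and adjusted
p-values are reported — combining Tukey with BH is redundant but
conventional in this literature, and the raw values let the user pick),
and a compact-letter display built by the insert-absorb algorithm at
α = 0.05. When Shapiro–Wilk rejects residual normality at 0.05 and the
response is positive, the response is log₁₀-transformed
(`log_transform = "auto"`). An all-identical degenerate response takes an
explicit p = 1 path rather than trusting a 0/0 F ratio. Boxplot outlier
screening uses Tukey hinges (`fivenum`) with 1.5·IQR fences — quartile
conventions differ across software, and the hinge rule is the one the
classical boxplot procedure defines.

## The synthetic-survey generator

`generate_survey()` emulates a plateau-scale campaign: 30 clusters × 4
lakes × 5 monthly campaigns by default, clusters spread over 3279–5014 m
elevation with barometric pressure $101.325\,e^{-z/8400}$ kPa (a
plausibility model, not a weather model; it reproduces the ~60.9 kPa
study-area mean at ~4300 m). Per-type true fluxes are zero-truncated
normals with defaults AS 8.7 ± 3.0, AM 16.1 ± 1.7, SM 12.5 ± 2.0
mmol m⁻² d⁻¹ — the AS/AM values are published survey calibration
constants; no SM mean is published, so 12.5 is an explicitly synthetic
choice between them. The mean ebullition share defaults to 0.84 and rises
with elevation (0.06 km⁻¹), mimicking the observed low-pressure
enhancement of bubbling.

Chamber records are built so the downstream estimators have exact targets:
a linear ramp encoding $(1-s)F$, plus 1–5 instantaneous log-normally
sized concentration steps (how bubbles entering the chamber actually
register) summing to $sF$, plus Gaussian analyser noise (defaults 2 ppb
CH₄, 0.35 ppm CO₂, typical 1-s precisions for near-infrared laser
analysers). Water samples are generated by the *forward* syringe balance
from dissolved concentrations that satisfy the two-layer model at a known
per-lake $k_{\mathrm{CO}_2}$ (log-normal around 3 m d⁻¹), so the whole
partitioning chain is consistent by construction and recovery is a
genuine end-to-end test. Isotope records centre on δ¹³C–CH₄ = −72.5‰ (sd
4) and δ¹³C–CO₂ = −13.4‰ (sd 3); radiocarbon ages are right-skewed,
−400 + Gamma(1.2, 600) yr (mean ≈ 320 yr BP, ~45% modern, ~13% older
than 1000 yr BP), because no symmetric fraction-modern distribution can
give a young mean together with a heavy old tail.

What the generator does **not** emulate — and hence what passing recovery
tests do not establish about real data: spatial structure within lakes and
GIS realism; seasonal dynamics beyond a shared per-campaign multiplier;
bathymetry and hydrostatic effects on bubbling; chamber artefacts
(pressure perturbation, headspace saturation feedback on the gradient);
non-Gaussian analyser drift; and any inconsistency between the two-layer
model and reality — the generator *assumes* the model the pipeline
inverts, so recovery validates the implementation, not the physics.

## Problem sizes and determinism

Every stochastic test fixes a seed, and a fixed seed reproduces a survey
bit-for-bit (tested through byte-identical CSV round trips). The validation
suite uses surveys of 6–600 deployments for unit checks, a 500-lake
single-campaign survey for ebullition-share recovery (±5 percentage
points), 10⁴ draws for law-of-large-numbers checks, 10⁴ Monte Carlo
iterations against the truncated-normal closed form (1%), and a
2000-replicate null for the ANOVA type-I rate (0.05 ± 0.02) — sizes chosen
so each check's sampling error is well inside the tolerance it asserts.

## Known limitations

The package analyses chamber surveys; it does not quantify ebullition
independently (bubble traps), model $k$ from wind speed (the CO₂ anchor is
deliberate — it is measured at the same moment and place as the CH₄ flux),
calibrate radiocarbon ages to calendar years, or partition CH₄ sources by
Keeling plots. Regional estimates are only as good as the strata table:
areas, spreads and the season length dominate the result, and the
ice-cover correction imports a fraction observed in other lake systems
rather than measuring one.
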