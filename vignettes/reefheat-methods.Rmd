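---
title: "Reef-flat heat budgets and bleaching archives: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reef-flat heat budgets and bleaching archives: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefheat)
```

# The heat budget of a shallow reef flat

A reef flat a metre or two deep behaves like a thin, well-mixed slab of
seawater. Its temperature evolves under two influences: heat exchanged with
the atmosphere across the surface, and heat carried on and off the flat by
currents exchanging reef water with the adjacent ocean. Per unit area,

$$\frac{dT}{dt} = \frac{Q_\mathrm{airsea}}{\rho\, c_p\, h} + \text{advection},$$

where $Q_\mathrm{airsea}$ (W m$^{-2}$, positive into the water) is the sum of
shortwave, longwave, latent and sensible fluxes, $\rho$ is seawater density
(default 1023 kg m$^{-3}$), $c_p$ its heat capacity (default
4000 W s kg$^{-1}$ °C$^{-1}$), and $h$ the water depth (default 2 m, the
reef-flat logger depth). The advective term cannot be measured directly from
a single logger; the analysis therefore differentiates the observed
temperature to get the *total* heating rate and attributes the residual

$$\text{rate}_\mathrm{adv} = \text{rate}_\mathrm{total} - \text{rate}_\mathrm{airsea}$$

to advection, with benthic conduction and diffusion assumed negligible. The
decomposition closes exactly by construction, and `heat_budget()` stores all
three rates per timestep.

## Bulk flux formulas

All fluxes are signed positive into the water.

* **Shortwave**: $Q_{sw} = (1-\alpha) I$ with measured insolation $I$ and
  ocean albedo $\alpha = 0.06$.
* **Longwave** (Berliand-type bulk form):
  $$Q_{lw} = -\Big[\varepsilon\sigma T_{sK}^4\,(0.39 - 0.05\sqrt{e_a})\,(1-\lambda C^2) + 4\varepsilon\sigma T_{sK}^3 (T_s - T_a)\Big]$$
  with emissivity $\varepsilon = 0.97$, cloud coefficient $\lambda = 0.7$,
  cloud fraction $C$, and air vapor pressure $e_a$ (hPa) from relative
  humidity and the Magnus form
  $e_s = 6.112\exp\{17.67\,T/(T+243.5)\}$.
* **Latent and sensible** (gradient bulk formulas):
  $$Q_{lat} = -\rho_a L_v C_E U (q_s - q_a), \qquad
    Q_{sen} = -\rho_a c_{pa} C_H U (T_s - T_a),$$
  with neutral transfer coefficients $C_E = C_H = 1.2\times10^{-3}$,
  $q_s = 0.98\, q_\mathrm{sat}(T_s, P)$ (the 0.98 reflecting salinity) and
  $q_a = (\mathrm{RH}/100)\, q_\mathrm{sat}(T_a, P)$. Pressure defaults to
  1010 hPa when not measured.

Every coefficient is exposed in `bulk_coefficients()`, so the
parameterization is transparent and adjustable rather than buried in a black
box. This is a deliberately compact bulk scheme: full surface-layer
algorithms with skin corrections, gustiness and rain fluxes are out of scope,
and a complete Monin–Obukhov iteration is out of proportion to the data such
an analysis uses.

### Stability adjustment

An optional stability correction multiplies the neutral transfer coefficients
by $(1 - 10\,\mathrm{Ri}_b)^{-1}$ clamped to $[0.25, 4]$, where

$$\mathrm{Ri}_b = \frac{g\, z\, (T_s - T_a)}{\bar T_K\, U^2}$$

is a bulk Richardson number built from the water–air temperature difference,
the sensor height $z$ (default 10 m, configurable — instrument heights are
rarely reported) and wind speed $U$. The sign convention makes
$\mathrm{Ri}_b$ *positive when the surface layer is unstable* (water warmer
than air), so the multiplier is monotone increasing in instability: unstable
conditions enhance transfer, stable conditions suppress it, as physical
reasoning requires. The factor is closed-form, so no iteration is needed.

Two caveats follow from the clamping and are worth knowing. First, at low
wind $\mathrm{Ri}_b \propto U^{-2}$ drives the factor to its upper clamp, so
the *transfer velocity* $C\,f(U)\,U$ loses much of its wind dependence below
a few m s$^{-1}$. For this reason the forward simulator (below) defaults to
neutral coefficients: its purpose is to express the wind dependence of
evaporative cooling during a calm event, which the saturated clamp would
mask. The analysis path keeps the correction on by default. Second, the
scheme is a monotone single-step adjustment, not a surface-layer similarity
solution; it should be read as "more/less transfer when unstable/stable",
not as a calibrated flux algorithm.

### Cloud fraction

When cloud fraction is not recorded, it is inferred per calendar day as
$C = \mathrm{clamp}(1 - \bar I_\mathrm{meas}/\bar I_\mathrm{clear},\, 0,\, 1)$
over daylight samples, using the package's clear-sky model; night samples
inherit the daylight estimate. Note this infers *effective* attenuation: with
insolation generated as $I_\mathrm{clear}(1 - 0.7C)$, the inferred value is
$0.7C$, which is what the longwave formula's cloud factor sees consistently.

## Differentiating the observed temperature

`observed_heating_rate()` optionally smooths the record with a centered
moving average (default 1 h — a 15-min logger's noise would otherwise
dominate the derivative) and then applies a centered or forward finite
difference, with one-sided differences at the endpoints. Sampling gaps wider
than 4× the median interval yield missing rates rather than spurious spikes.
When smoothing is enabled, `heat_budget()` applies the *same* moving average
to the air–sea rate before taking the residual, so every budget term is
filtered identically — mixing a smoothed derivative with an unsmoothed flux
term would dump all the high-frequency flux noise into the advective
residual.

Scheme choice matters when validating against the forward simulator: the
simulator integrates with explicit Euler, for which the forward difference is
the exactly consistent estimator (recovery at machine precision). The
centered difference carries a half-step error driven by sub-step stochastic
forcing variability; it converges on the truth as the step shrinks
(about 11% → 6% → 2% RMS of the RMS advective rate at 15, 5 and 1-min
steps under the default scenario noise), and the tests assert exactly that
convergence. With 15-min sampling and the default 1-h smoothing the full
decomposition recovers the simulated advective rate to better than 10% RMS.

# The synthetic scenario

`scenario_config()` encodes a three-week early-summer scenario on a 2-m reef
flat at 20.7° N: diurnal clear-sky insolation (top-of-atmosphere irradiance
× fixed transmittance 0.75 — a documented simplification; timestamps are
treated as local solar time) modulated by AR(1) cloud cover; trade winds of
8 m s$^{-1}$ with AR(1) variability; a mixed semidiurnal/diurnal tide
(M2, S2, K1, O1 at 0.5, 0.2, 0.3, 0.25 m) whose fortnightly neap falls
mid-month; and an offshore SST of 29.6 °C with a +2 °C anomaly ramping up
over the first ten days.

The *event* is a calm, warm, humid air mass sitting over the reef for about
a week (days 8–16), coinciding with the neap: wind drops to a mean of
2 m s$^{-1}$, air temperature rises 2 °C, and mean humidity rises to 88%.
All three belong to the same high-pressure forcing; removing the event
removes all three.

Reef temperature is integrated by explicit Euler (default 1-min steps;
steps producing more than 1 °C of change raise an error advising a smaller
step):

$$\frac{dT}{dt} = \frac{Q_\mathrm{airsea}(T)}{\rho c_p h} +
  \frac{c_e\, u(t)}{L}\,\big(T_\mathrm{offshore} - T\big),$$

where the advective exchange is parameterized as a flushing rate with
exchange efficiency $c_e$ (default 0.3), flushing length $L$ (default
2000 m), and current speed
$u = c_\mathrm{tide}\,|d\eta/dt| + c_\mathrm{wind}\, U$ (defaults 0.05 m s
per m hr of tidal elevation change, and 2.4% of wind speed). Explicit Euler
was chosen because it makes the closure bookkeeping exact: the stored
air–sea and advective rates reproduce each temperature step identically,
which is what gives the residual-recovery tests their ground truth. These
exchange parameters are scenario choices that set flushing timescales of a
few hours in normal conditions and roughly a day during the event — they are
not measurements of any particular reef. Under the defaults the event run
peaks about 3.2 °C above offshore while the ablated (no-event) run stays
within about 1 °C, and weakening the wind collapse weakly lowers the peak —
the mechanism, not the printed peak temperature, is the test surface.

What the generator does *not* emulate is worth stating: no waves or wave
setup, no spatially resolved circulation, no skin-layer effects, no realistic
cloud climatology, and the advective exchange is a one-parameter relaxation
rather than a flow field. Passing recovery tests on this generator shows the
estimator chain is correct and internally consistent; it does not validate
the bulk formulas against ocean observations.

# Tides and current calibration

`synthesize_tide()` is harmonic synthesis only,
$\eta(t) = \sum_i A_i \cos(\omega_i t - \varphi_i)$; fitting constituents
from data (harmonic analysis, nodal corrections) is out of scope. Numeric
times are absolute hours so phases mean what they say; POSIXct inputs are
referenced to the first timestamp. The M2+S2 pair beats at
$1/(1/12 - 1/12.4206) \approx 354.4$ h $\approx 14.77$ d — the spring–neap
cycle the scenario leans on.

Instrument cross-calibration uses **major-axis regression** (the first
principal axis of the centered scatter) rather than ordinary least squares,
because both the proxy and the reference instrument carry error; the slope
is taken from the leading eigenvector of the sample covariance, with the
sign matched to the covariance. Calibrated speeds are clamped at zero, with
a message reporting how many samples were affected.

# SST climatology and trend

Monthly climatologies are per-month means over an inclusive reference
window; anomalies subtract the month's climatology, so in-window anomalies
average to zero per month by construction. The decadal trend is ordinary
least squares of *annual means* on year (×10 per decade), with a 95%
confidence halfwidth $t_{0.975,\,n-2}\,\mathrm{SE}\times 10$. Monthly or
finer input is aggregated to annual means first, and a year enters only if
all 12 months are present (dropped years are messaged). Two documented
limitations: no autocorrelation correction is applied to the CI, and the
annual-vs-monthly regression resolution is a choice — annual means were
chosen so the CI is not artificially narrowed by within-year correlation.

# Benthic point counts

Survey arithmetic follows the photo-transect design (transects × length /
photo interval × points per photo). Cover is the fraction of points per
category; live-coral cover is the fraction of *all* points whose status is
`pigmented`. Per-genus status fractions (pigmented / bleached /
recently dead) are computed over the coral points of that genus, so
"mortality" is a fraction of all coral points of the genus, consistent with
a three-way split. Dead corals still identifiable to genus are recorded as
genus + `recently_dead`; substrate categories carry `not_coral`. Per-station
values and the point-weighted pooled value are both available — the package
reports per-station numbers rather than ranges. `compare_surveys()` flags a
category as halved when its post fraction is at most half its pre fraction.

# Coral cores: bands, stress bands, growth

The package operates on 1-D density-vs-depth profiles (e.g. axis extracts
from CT scans); 3-D image processing and density calibration are out of
scope. Annual band boundaries are successive local minima of the profile
after Gaussian smoothing with $\sigma = 0.2\times$ the expected band width
(default guess 1.5 cm, a typical massive-*Porites* extension rate), with
minima closer than half a band width pruned to the deeper one. Years are
assigned backward from the collection year; the partial bands above the
first and below the last minimum are excluded from metrics. Annual
calcification is extension × mean band density (g cm$^{-2}$ yr$^{-1}$), and
colony age is height / mean extension rounded to the nearest year.

Stress bands — thin, anomalously dense layers laid down during bleaching —
are flagged by a reproducible rule standing in for the traditional visual
call: a year is flagged when its maximum density exceeds the median plus
$k$ MADs (default $k = 3$, MAD with the usual 1.4826 consistency constant)
of the per-year maxima of that core, *and* the contiguous excursion above
that threshold is thin — between 0.1 cm (so a single noisy sample cannot
flag a year) and 0.3× that year's band width (so a generally dense year does
not). Raising $k$ never adds flags. Prevalence for a year is the number of
flagged cores over the number of cores whose record spans that year.
Against the generator's truth table (rectangular spikes of +0.5 g cm$^{-3}$,
0.25 cm wide, injected at the high-density phase of chosen years), detection
at the defaults recovers the injected set exactly when spikes are at least
5 MADs above the yearly-maximum spread.

# Numerical and degenerate-input choices

* Closure identities (`q_airsea` component sum; total = air–sea +
  advective) hold exactly as stored, not approximately.
* Zero wind gives exactly zero latent and sensible flux; an empty
  constituent table synthesizes a zero tide; zero flagged cores is a valid
  prevalence result.
* Duplicate timestamps are errors everywhere; gaps > 4× the native spacing
  become missing values rather than being bridged.
* Degenerate regression input (zero variance) and climatologies missing a
  month fail loudly with the offending items named.
* Random generation always flows from an explicit integer seed; identical
  seeds give bit-identical outputs.

# Problem sizes used in the tests

The bundled tests run the simulator at 15-min steps over the 19-day scenario
for mechanism checks, at 1-min steps over 2–3 days for recovery checks, use
22 cores × 80 years for growth-rate recovery, 20 cores × 25 years for
stress-band recovery, and 1000 Monte-Carlo replicates of a 116-year monthly
series for trend coverage. These sizes were chosen so each property is
measured with comfortable statistical margin while the suite stays quick to
run.
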