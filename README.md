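# reefheat

Heat-budget diagnostics for shallow coral reef flats, and the supporting
analyses used to connect a local heating event to coral bleaching: bulk
air–sea flux estimation, tidal synthesis and current-meter calibration, SST
climatology and trend analysis, benthic point-count statistics, and skeletal
density-band analysis of coral cores. A synthetic-data module generates
physically structured forcing and a forward-simulated reef temperature with a
known flux decomposition, so the whole pipeline is testable end to end
without any external data.

## The problem

Water on a reef flat 1–3 m deep heats strongly under the midday sun but is
normally cooled by tidal and wind-driven exchange with offshore water, so its
daily mean temperature tracks the open ocean. When the flushing currents
weaken — a calm spell coinciding with neap tide — solar heating is retained
and the reef flat can run several degrees hotter than the ocean around it,
enough to bleach and kill corals even when the open-ocean anomaly is modest.
Diagnosing such an event requires splitting the observed heating into its
air–sea and advective parts.

## The model

Per unit area of a well-mixed column of depth `h`, each air–sea heat flux
`Q` (W m⁻²) changes temperature at

    dT/dt = Q / (ρ c_p h)

with seawater density `ρ` and heat capacity `c_p`. The air–sea flux is the
component sum (all terms positive into the water)

    Q_airsea = Q_sw + Q_lw + Q_lat + Q_sen

with net shortwave `(1 − α) I`, a Berliand-type bulk net longwave, and
gradient bulk formulas for latent and sensible heat,

    Q_lat = −ρ_a L_v C_E U (q_s − q_a),   Q_sen = −ρ_a c_pa C_H U (T_s − T_a),

optionally stability-adjusted through a clamped bulk-Richardson multiplier.
The total heating rate is the time-derivative of the measured water
temperature, and the advective component is estimated as the residual

    rate_advective = rate_total − rate_airsea

(benthic and diffusive fluxes assumed negligible), so the decomposition
closes exactly by construction.

Around that core sit the supporting analyses: harmonic tide synthesis
`η(t) = Σ A_i cos(ω_i t − φ_i)`; major-axis (principal-axis) regression for
cross-calibrating a tilt current meter against an ADCP; monthly SST
climatologies, anomalies and an OLS decadal trend with 95% CI; point-count
cover and per-genus bleaching-status fractions; and annual band, stress-band,
extension and calcification analysis of 1-D skeletal density profiles.

## Worked example

Simulate the bundled calm-event scenario (wind collapsing from 8 to
2 m s⁻¹ over a neap tide, offshore anomaly ramping to +2 °C) and decompose
the resulting temperature record:

```r
library(reefheat)

cfg <- scenario_config(timestep_min = 15)
run <- simulate_reef_temperature(cfg)
run
#> Simulated reef-flat run: 1825 steps of 15 min
#>   reef temperature 29.10-34.76 degC; peak reef-offshore excess +3.16 degC

bud <- heat_budget(run$forcing, run$temp,
                   budget_params(depth = 2, smoothing_hours = 1),
                   coeffs = run$coeffs)
bud
#> Reef-flat heat budget: 1825 timesteps, depth 2 m
#>   observed rate:  mean +0.0039, range [-0.445, +0.330] degC/hr
#>   air-sea rate:   mean +0.0266 degC/hr
#>   advective rate: mean -0.0227 degC/hr
```

The air–sea term heats the flat on average while advection cools it; during
the wind collapse the advective cooling nearly vanishes and the reef runs hot
for days:

```r
anomaly_exceedance(run$temp$time, run$temp$temp_c, reference = 29.6, threshold = 2)
#>                 start                 end duration_hr max_exceedance_c
#> 1 2015-06-08 11:15:00 2015-06-16 07:30:00       188.5         5.159734
```

i.e. one contiguous event lasting ~8 days peaking 5.2 °C above the reference.
Cross-calibrating a current-speed proxy works the same way as any other
bivariate calibration:

```r
tcm  <- c(0.12, 0.30, 0.45, 0.22, 0.50, 0.08, 0.33, 0.41)  # proxy, m/s
adcp <- c(0.10, 0.20, 0.28, 0.15, 0.31, 0.06, 0.21, 0.26)  # reference, m/s
major_axis_regression(tcm, adcp)
#> Major-axis fit (n = 8): slope 0.5767, intercept 0.0225, r = 0.998
```

A command-line wrapper over the same functions is installed at
`exec/reefheat` inside the package (subcommands `simulate`, `fluxes`,
`budget`, `tide`, `calibrate`, `climatology`, `ecology`, `cores`), e.g.

```sh
Rscript inst/exec/reefheat simulate \
  --scenario inst/extdata/dongsha2015.yaml --out simdir/
```

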