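# windloft

Can a virus-sized particle ride thermospheric updrafts to 120 km?

`windloft` is a one-dimensional transport model for "biologically sized"
disc particles — nanometre dust grains, virions, bacterial organelle
fragments — driven by the extreme vertical winds (tens of m s⁻¹,
sustained for minutes to an hour) observed in the upper mesosphere and
lower thermosphere, especially along auroral arcs. It is aimed at
aerobiologists, astrobiologists and upper-atmosphere dynamicists who want
quick, reproducible order-of-magnitude answers to "which winds can loft
which particles, how fast, and how high?"

## Model

A disc of radius *r*, thickness *h* and bulk density
ρ<sub>p</sub> = m/(π r² h) sits broadside to a vertical wind *w* with drag
coefficient 1. With up positive and λ = ρ/(ρ<sub>p</sub> h):

    dv/dt = -g + H(w − v) · λ · (w − v)²

where H(·) = ±1 keeps the stagnation-pressure force pointing with the
relative wind. The model's closed-form consequences, all exported:

| quantity | formula | function |
|---|---|---|
| threshold velocity | w_T = √(g ρ_p h / ρ) | `threshold_velocity()` |
| steady-state ascent | v∞ = w − w_T | `steady_state_velocity()` |
| relaxation time | τ = 1/√(λ g) | `relaxation_time()` |
| transient from rest | tanh-like approach to v∞ | `transient_velocity()` |

Around that core: an embedded US Standard Atmosphere 1976 profile
(0–200 km, density/temperature/mean free path, `standard_atmosphere()`,
pluggable via `atmosphere_from_file()`), Knudsen-number diagnostics,
trajectory integration through the density column in quasi-steady or
full-ODE mode (`integrate_trajectory()`), ceiling-altitude solving
(`ceiling_altitude()`), a seeded oscillatory-wind generator
(`synthesize_wind()`), and a scenario runner (`run_scenario()`) with a
CLI wrapper at `system.file("cli", "windloft", package = "windloft")`.

## Worked example

A small bacterial-organelle-sized disc (ρ_p = 2000 kg m⁻³, r = 2 µm,
h = 40 nm) released at 100 km into a 50 m s⁻¹ updraft, and an H1N1-sized
disc riding a 50 m s⁻¹ updraft along an auroral arc for an hour with the
air density pinned at 9×10⁻⁸ kg m⁻³:

```r
library(windloft)
run_scenario(builtin_scenario("organelle_greenland"))
#> <scenario> organelle_greenland (bacterial_organelle, quasi_steady)
#>   threshold at z0: 36.838 m s-1; steady state: 13.162 m s-1
#>   climb: 3458.0 m in 1200 s (stop: forcing_exhausted)
#>   ceiling: 103479 m (threshold_match)

run_scenario(builtin_scenario("virus_arc"))
#> <scenario> virus_arc (h1n1_virus, full_ode)
#>   threshold at z0: 47.506 m s-1; steady state: 2.494 m s-1
#>   climb: 9091.4 m in 3600 s (stop: forcing_exhausted)
#>   ceiling: 111092 m (threshold_match)
```

Reading the first: at 100 km a 36.8 m s⁻¹ updraft just balances the
organelle's weight, so a 50 m s⁻¹ wind carries it up at
50 − 36.8 ≈ 13 m s⁻¹; the climb is less than 13 m s⁻¹ × 1200 s because
the air thins as it rises and the ascent rate decays toward the ceiling
near 103.5 km. The virion, far lighter per unit area, still ascends at
~2.5 m s⁻¹ at 110–120 km densities and gains ~9.1 km in the hour.

Threshold-velocity curves across altitude for the three built-in
archetypes (`particle_preset()`):

```r
report_thresholds(z_from = 90e3, z_to = 120e3, step = 10e3)
#>      z_m standard_dust h1n1_virus bacterial_organelle
#> 1  90000      1.670742   7.734867            14.94357
#> 2 100000      4.118580  19.067381            36.83770
#> 3 110000      9.880093  45.740889            88.37024
#> 4 120000     20.619793  95.461415           184.42904
```

Each column rises with altitude as density falls: the altitude where a
particle's threshold reaches the available wind is its ceiling.

The same things from a shell:

```sh
windloft=$(Rscript -e 'cat(system.file("cli","windloft",package="windloft"))')
Rscript "$windloft" run --scenario virus_arc --out out/
Rscript "$windloft" thresholds --from 90000 --to 120000 --step 10000
Rscript "$windloft" ceiling --particle preset:h1n1_virus --wind 50
Rscript "$windloft" synth-wind --noise-sd 5 --seed 7 --out wind.csv
```

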