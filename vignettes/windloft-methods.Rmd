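---
title: "Modelling vertical-wind lofting of biologically sized particles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling vertical-wind lofting of biologically sized particles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(windloft)
```

## The physical picture

Vertical winds of tens of metres per second, sustained for minutes to an
hour, have been observed for decades in the upper mesosphere and lower
thermosphere, particularly in the auroral zone. At 90--120 km the air is
five or more orders of magnitude thinner than at the surface, so a
nanometre- to micrometre-sized particle is far heavier than the
surrounding gas — yet the momentum flux of a strong enough updraft can
still exceed its weight. windloft quantifies that balance with a
deliberately minimal one-dimensional model and asks two questions: how
fast does a given particle ride a given updraft, and how high can it get
before the thinning air can no longer hold it up?

## Model

The test particle is a disc of radius $r$, thickness $h$ and bulk density
$\rho_p = m / (\pi r^2 h)$, always broadside to the flow, with drag
coefficient fixed at unity: the wind is treated as a directed stream that
comes to rest on the disc face, delivering the stagnation pressure
$\rho (w - v)^2$ over the area $\pi r^2$. With up positive, the signed
equation of motion is

$$\frac{dv}{dt} = -g + H(w - v)\,\frac{\rho(z)}{\rho_p h}\,(w - v)^2 ,$$

where $w$ is the vertical wind, $v$ the particle velocity, $\rho(z)$ the
local air density and $H(\cdot)$ a sign factor ($\pm 1$) that keeps the
quadratic force pointing with the relative wind. Writing
$\lambda = \rho / (\rho_p h)$ (units m$^{-1}$), the model's derived
quantities are:

* **threshold velocity** $w_T = \sqrt{g/\lambda} = \sqrt{g \rho_p h / \rho}$
  — the minimum updraft that balances the weight, identically the
  particle's terminal fall speed relative to the air
  (`threshold_velocity()`);
* **steady-state velocity** $v_\infty = w - w_T$ — the ascent (or, if
  negative, quasi-steady descent) rate once drag and weight balance
  (`steady_state_velocity()`);
* **relaxation time** $\tau = 1/\sqrt{\lambda g}$ — the e-folding
  timescale of the approach to the steady state (`relaxation_time()`);
* the **closed-form transient** from rest (`transient_velocity()`),

$$v(t) = w - \sqrt{\tfrac{g}{\lambda}}\;
  \frac{1 + A e^{-2t\sqrt{\lambda g}}}{1 - A e^{-2t\sqrt{\lambda g}}},
  \qquad
  A = \frac{\sqrt{\lambda/g}\,w - 1}{\sqrt{\lambda/g}\,w + 1}.$$

It satisfies $v(0) = 0$ and rises monotonically toward $v_\infty$,
approaching but never reaching the wind speed. The test suite checks this
closed form against an independent fourth-order Runge--Kutta integration
of the differential equation on a hundred randomized particle/air/wind
combinations at $t \in \{0.1, 1, 10\}\tau$, at a relative tolerance of
$10^{-6}$.

Only the relative-wind drag and the weight act: air resistance against
the particle's own motion beyond the relative-wind term, Brownian
kinetic fluctuations, particle charging, hygroscopic growth and all
horizontal dynamics are outside the model. The disc never tumbles; with
$C_d = 1$ fixed, shape enters only through the column density
$\rho_p h$, and the optimum shape is the thinnest pancake.

A remark on regime: at 90 km the air's mean free path (~0.024 m) is vastly
larger than the particles considered (Knudsen number ~2.4×10⁴ for a 1 µm
disc), formally the free-molecular regime. The model applies the
continuum stagnation-pressure force anyway, as the zeroth-order
description of a strong *directed* stream, neglecting the kinetic
fluctuations that dominate an otherwise quiescent rarefied gas.
`knudsen_number()` is provided so users can see how far outside the
continuum they are.

## Atmosphere and gravity

The embedded profile is the US Standard Atmosphere 1976 on a grid of 59
nodes from 0 to 200 km (2 km spacing below 86 km, the standard's
published levels above), with 90 and 100 km as exact nodes so the two
anchor values used by the worked estimates — density 5.604×10⁻⁷ kg m⁻³
at 100 km, mean free path 0.0237 m at 90 km — are reproduced exactly.
Below 86 km the table is computed from the standard's piecewise-linear
geopotential temperature layers and the hydrostatic relation; above,
the standard's tabulated temperature, density and mean molecular weight
are embedded and the mean free path follows from number density with
the standard's 3.65×10⁻¹⁰ m collision diameter (the generation script
ships in `tools/make_atmosphere_table.R`).

Density and mean free path are interpolated log-linearly (both are close
to exponential in altitude and span many decades, and log-linear
interpolation preserves positivity and is exact at nodes); temperature
linearly. Any profile in the same CSV dialect can be swapped in via
`atmosphere_from_file()` — e.g. one exported from an empirical model such
as NRLMSISE-00 — but the packaged table is what the tests pin down.

Gravity defaults to inverse-square, $g(z) = g_0 (R/(R+z))^2$ with
$g_0 = 9.80665$ m s⁻² and $R = 6371$ km. The model's source material
never states its gravity convention; inverse-square is adopted because it
reproduces both printed steady-state estimates (13 m s⁻¹ at 100 km and
~2.5 m s⁻¹ in the 110--120 km band) simultaneously, which constant
$g_0$ does only to within ±1 m s⁻¹. `gravity_model("constant")` gives
the flat-$g$ alternative.

## Trajectories and the ceiling

`integrate_trajectory()` advances altitude with coefficients frozen per
step (default `dt` = 1 s) and re-read from the profile between steps, so
multi-kilometre climbs feel the density gradient. Two modes:

* **quasi-steady** assumes the particle is always relaxed to its local
  steady state. This is the appropriate default because $\tau$ is a few
  seconds at most for the built-in presets at these densities —
  far shorter than the tens of minutes over which the observed winds
  vary. Sub-threshold wind yields descent at the terminal rate.
* **full-ODE** integrates the signed acceleration equation from rest
  with `deSolve::lsoda` (relative tolerance 10⁻¹⁰), capturing the
  transient spin-up. The suite requires the two modes to agree on final
  altitude to 1% whenever the episode lasts ≫100 relaxation times.

Forcing is piecewise: constant `wind_episode`s, a sampled `wind_series`,
or episodes segmented out of a series by `episodes_from_series()` (run
means, not maxima — conservative, matching the use of an *average*
ascent speed in climb estimates). An episode can pin the air density
(`rho_override`) to reproduce constant-density updraft estimates along an
auroral arc. Trajectories that reach the table edge truncate with a
recorded stop reason rather than extrapolating beyond the data.

`ceiling_altitude()` exploits the monotone rise of the threshold velocity
with altitude above 70 km (density falls much faster than $g$): the
ceiling is the root of $w_T(z) = w$, bracketed on 70 km--table top and
solved to 1 m with Brent's method. If $w$ is below threshold across the
whole segment an explicit no-ceiling result is returned; if above it
everywhere, the table top with reason `"table_ceiling"`. On the embedded
table a 109 nm virion-like disc in a 50 m s⁻¹ updraft stalls near 111 km;
profiles with a warmer, denser lower thermosphere push this toward
120 km, which is why ceiling claims should always be read against the
profile used.

## The synthetic wind generator

Observed high-latitude vertical winds oscillate between upward and
downward phases with magnitudes of roughly 10--50 m s⁻¹, growing to a
maximum over ~20--30 min, with long coherent upward stretches during
storms. The published records are plots, not tables, so windloft emulates
their qualitative structure rather than any numeric series:

$$w(t) = \text{mean\_offset} + A \sin(2\pi t / \text{period})
        + \mathcal N(0, \sigma^2),$$

with defaults $A = 30$ m s⁻¹, mean offset 10 m s⁻¹, period 1800 s
(mid-range of the observed growth timescale), `dt` = 10 s — numbers
chosen once to sit inside the observed ranges. Optional extra harmonics
give richer spectra. A fixed integer seed makes the series bit-for-bit
reproducible, and generation leaves the caller's RNG stream untouched.
What passing tests show is therefore that the *machinery* — segmentation,
integration, reproducibility — behaves correctly on series with the
observed amplitude and period structure; they cannot validate the model
against the actual measured winds, whose spectra, intermittency and
vertical shear the single-sinusoid generator does not attempt to emulate.

## Numerical and design choices

* **Radical restoration.** The published rendering of the transient
  solution, the steady state and the "$1/\lambda g$" timescale drop
  radical signs and are dimensionally inconsistent as printed
  ($\lambda$ has units m⁻¹). The implementation uses $\sqrt{g/\lambda}$,
  $e^{-2t\sqrt{\lambda g}}$ and $1/\sqrt{\lambda g}$ — the unique
  dimensionally consistent reading — verified against the ODE oracle and
  the stated $t = 0$ / $t \to \infty$ limits.
* **The virion preset's geometry quirk.** The H1N1 archetype is specified
  by mass 0.8 fg and *diameter* 109 nm, with quoted density ~196 kg m⁻³.
  That density only follows from the disc formula if both radius and
  thickness are set to 109 nm, so the preset does exactly that and the
  quirk is documented in `?particle_preset`. The "standard dust"
  archetype likewise uses radius (not diameter) of 1 nm, the reading
  that yields its quoted ~3×10⁻²⁴ kg mass.
* **$H(0)$** is set to +1; immaterial, since the force factor
  $(w-v)^2$ vanishes there, but it keeps the function total.
* **Sub-threshold winds.** The steady-state formula is reported signed —
  a negative value is the quasi-steady descent rate — while the
  closed-form transient, whose derivation assumes ascent from rest,
  errors outside its domain instead of extrapolating.
* **Step size.** `dt` = 1 s default; halving it moves the worked
  scenarios' final altitudes by well under 0.1% (tested). The full-ODE
  mode's stiff-capable integrator handles the sub-second relaxation
  within each step.
* **Problem sizes.** The property suites run 100 randomized
  transient-vs-RK4 cases and multi-hour trajectories at 1 s steps; the
  whole suite completes in well under a minute on one CPU.

## Limitations

One dimension only: no horizontal advection (beyond the bookkeeping
`horizontal_excursion()` check against the ~300 km correlation length of
arc-aligned winds), no stochastic up/down switching — the observed
oscillation is represented by forcing, not by a random-walk model of the
particle — no mesopause turbulence buffering, no charging or
photophoretic forces, and no cloud microphysics. Estimates should be read
as order-of-magnitude: their purpose is to show which particle/wind
combinations are dynamically capable of climbing, not to forecast any
particular event.

## A worked run

```{r}
res <- run_scenario(builtin_scenario("organelle_greenland"))
res

res2 <- run_scenario(builtin_scenario("virus_arc"))
res2$summary$steady_state_v_m_s
res2$summary$climb_m
```
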