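---
title: "whalenav: model, assumptions and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{whalenav: model, assumptions and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whalenav)
```

## The model

`whalenav` simulates a population of migrating baleen whales as a
velocity-jump random walk in a gridded ocean. Each agent carries a
position and an active heading; between reorientation events it swims at
a constant speed `s` while being advected by the local current, so the
realized motion is `dx/dt = v_active + v_passive`. Reorientation events
arrive as a Poisson process with rate `lambda`; at each event the agent
rebuilds its heading from inherent information (a von Mises draw centred
on the bearing to the target), collective information (the headings of
conspecifics whose calls it can detect), and two avoidance responses
(negative phonotaxis away from noise, bathotaxis toward deep water).

Key simplifications, all deliberate: constant swimming speed (no noise-
modulated escape speed, no energetics), no resting or feeding pauses, no
rheotaxis, a single broadband noise value per location (no frequency
dependence, no audiogram), error-free observation of neighbour headings,
and a one-coefficient spreading law instead of a propagation solver.

## Acoustics

A call of source level `SL` (dB re 1 µPa at 1 m) is received at range
`r` metres at `RL = SL − γ log10(r)`. The spreading coefficient `γ` lies
between 10 (cylindrical, shallow water) and 20 (spherical); the default
is 17.8. Ranges below the 1 m reference distance clamp to 1 m, where
`RL = SL` exactly — the loss term diverges as `r → 0` and the source
level is only defined at the reference distance.

Detection requires both `RL − N ≥ snr_min` (default −5 dB; negative
SNR detection is realistic for structured calls) and `RL ≥ rl_min`
(default 88 dB), with `N` evaluated **at the receiver**. Both
inequalities are inclusive, which makes the quiet-water communication
range exact at the boundary: `10^((178 − 88)/17.8)` m = 113.81 km. Below
`N = rl_min − snr_min = 93` dB the received-level floor binds and the
range is independent of noise (the "pristine plateau"); above it,
masking shrinks the range by one decade per `γ` dB of noise.

Synthetic noise maps power-sum (`10 log10 Σ 10^(L/10)`) a wind floor
with every active source. Mobile sources move piecewise-linearly between
time-stamped waypoints; fixed sources follow a daily active-hours
schedule evaluated on the rendering time grid (hourly by default, so a
schedule with whole-hour boundaries is represented exactly). A slowdown
zone subtracts a configurable 10 dB from mobile sources while they are
inside it — the simplest reading of speed-reduction mitigation, which
lowers the source level rather than the transit time.

## Heading fusion and the many-wrongs benefit

The fusion step is the one place where the design was genuinely open,
and the choice matters enough to document the reasoning.

Write `u(θ)` for the unit vector of a heading. At a reorientation the
agent holds an inherent sample `own ~ VM(target bearing, κ)` and the set
`θ_1..θ_n` of detected neighbour headings. We form the weighted
resultants

    R_loc  = α u(own) + (1 − α) Σ_j u(θ_j)
    R_conc = β u(own) + (1 − β) Σ_j u(θ_j)

take `μ̂ = arg(R_loc)`, `κ̂ = A⁻¹(min(|R_conc|, 1))` where
`A(κ) = I₁(κ)/I₀(κ)`, and draw the navigation heading from
`VM(μ̂, κ̂)`. With no neighbours the agent keeps its own sample exactly
(`κ̂` capped), the solitary limit.

The tempting alternative normalizes the neighbour term to its mean,
`(1/n) Σ u(θ_j)`. That version is provably *neutral*: because a
`VM(arg R, A⁻¹(|R|))` draw has expected unit vector exactly `R`, the
expected heading vector after a reorientation is *linear* in the inputs,
and the population mean heading vector contracts to the solitary value
`A(κ) u(target)` for **any** group size — communication would change
nothing, which contradicts both the many-wrongs literature and the
behaviour this model exists to study (masking slowing migration). The
unnormalized sum breaks the linearity through the `min(·, 1)` saturation:
a large well-aligned observed set pins the redrawn heading to the group
consensus, while the α-weighted own term steers the consensus toward the
target. In simulation this yields mean group alignments near 0.99 at ten
agents versus `A(1) = 0.446` alone, and roughly halves mean arrival
times in quiet water — a strong but finite benefit, consistent with
near-straight pristine trajectories. Both constructions agree on every
small-n edge case (all headings equal; an opposed pair; a symmetric
± π/2 pair), so the choice is invisible to the static contracts and only
the population dynamics distinguish them.

Ties: a zero location resultant has no argument, so `μ̂` is drawn
uniformly; `A⁻¹` is inverted by bracketed root-finding on [0, 500] with
`κ̂` capped at 500 (A saturates; the cap keeps the sampler stable) and a
small-argument expansion `A⁻¹(R̄) ≈ 2R̄` below 10⁻⁸.

## Behavioural weighting

Noise avoidance `w_na(N) = 0.5 + 0.5 tanh((N − N_threshold)/N_s)` and
land avoidance `w_la(d) = 0.5 − 0.5 tanh(0.5 (d − 30 m))` are balanced
against navigation: if `w_na + w_la > 1` both are rescaled
proportionally to sum to one, navigation receives the remainder, and the
final heading is the argument of the weighted sum of the three unit
vectors. The avoidance *directions* come from central finite differences
of the interpolated fields at ±1 native grid cell (heading of steepest
noise decrease, steepest depth increase); a gradient magnitude below
10⁻⁹ field-units per km counts as flat, in which case that response
surrenders its weight to navigation. Treating "negative phonotaxis" as
noise-gradient descent (rather than nearest-source bearing) is our
reading; it needs no source bookkeeping and coincides with the
source-bearing rule for a single dominant source.

`N_s` is not fixed by the source material; the default 5 dB concentrates
the transition over roughly ±10 dB around the threshold, which preserves
the threshold-like framing of the avoidance scenarios while keeping the
response smooth. `N_threshold` is scenario-dependent (120 dB in the
baseline scenarios, 105–115 dB in the avoidance sweep).

Noise-dependent information loss uses
`κ(N) = κ_min + (κ − κ_min)(0.5 − 0.5 tanh(0.1 (N − N_IL)))`, *decreasing*
in noise. The printed form of this expression in the source material has
the opposite tanh sign, which would make inherent information grow with
noise; every verbal description of the mechanism requires loss, so the
decreasing form is implemented. Its slope (0.1/dB) is deliberately
gentler than the avoidance sigmoids, spreading partial information loss
across a wide band of noise levels.

## Integration and numerical choices

* Fixed-step explicit Euler with `dt = 0.1 h` at reference scale
  (0.25 h in reduced presets): the active step `s·dt ≤ 0.6 km` is far
  below the grid scale, so integration error is dominated by behavioural
  stochasticity.
* Reorientation clocks are exponential; an event is processed at the
  first step boundary after it fires, and all observations within a step
  use the step-start snapshot of headings (simultaneity).
* Geometry is local-planar: displacement and gradients use an
  equirectangular tangent plane with cos(latitude) longitude scaling;
  distances and bearings are great-circle (haversine / forward azimuth).
  At step lengths ≤ 20 km the planar error is below 0.1%. Headings are
  radians counter-clockwise from local east everywhere.
* Fields interpolate bilinearly in space and linearly in time; queries
  outside the time range clamp to the nearest slice (with a warning in
  user-facing calls), matching the daily cadence of real current
  products against hourly simulation time.
* Land is the set of grid cells with depth ≤ 0 m, looked up at the
  nearest cell so the coastline is crisp; a move whose destination cell
  is land (or outside the grid) is aborted and the agent reorients
  immediately — waiting for the clock would freeze it against the shore.
  The domain edge therefore behaves like a coast; an agent *already*
  outside the grid is an inconsistent state and raises an error naming
  the agent and time.
* Arrived agents (within 50 km of the target) stop moving and leave the
  detection pool immediately.
* One RNG stream per realisation, seeded per repeat
  (`base_seed + k − 1`), with agents processed in id order: runs are
  bit-reproducible.

## The synthetic environment

`make_synthetic_sea()` generates the idealized worlds the scenarios run
in: uniformly deep open water, a conical island, an east–west land wall
pierced by a single channel (deepest on its centreline), and a radial
basin, each with a constant wind noise floor (60 dB — quiet enough that
the received-level floor, not masking, limits communication) and
optional uniform currents. Scenario presets add a small vessel fleet on
straight lanes (scaled ×1.5 for the traffic-increase scenario), a
slowdown zone, or a duty-cycled construction source. The construction
source uses an effective level of 200 dB rather than a nominal
pile-driving level: under the single-coefficient spreading law a 220 dB
source would exceed avoidance thresholds basin-wide, whereas 200 dB
gives an avoidance footprint of order 60 km — the qualitative situation
(a loud obstacle parked on the corridor) rather than a literal physical
level.

What the generator does *not* emulate: real bathymetric texture,
shelf-edge propagation effects, correlated wind fields, realistic
shipping densities, tides. A green ensemble test therefore establishes
that the *mechanisms* behave as specified (communication accelerates
migration; loud straits block it; duty cycles imprint a 24 h rhythm on
progress) — not that any real-world migration is reproduced
quantitatively. The reference-scale numbers (100 whales, 744 h, 10
repeats, start box 53.5–54.5° N × 4.5–5.5° E, target 5° W 61° N) are
carried by the `scale = "paper"` presets but are exercised at reduced
scale in the test suite.

## Metrics

The median trajectory is the intersection-switching construction: follow
one track until it crosses another, then follow that one. Determinism
requires three choices the construction itself leaves open: the walk
starts on the track whose start point is nearest the centroid of start
points; at each step the switch happens at the first intersection in
arc-length order along the current track; ties go to the lowest track
index. Intersections are computed exactly in a local planar frame, so
every output vertex lies on an input track and the result is bounded by
the outermost tracks. The spread region bins all recorded positions
(0.25° bins by default) and keeps bins whose per-bin relative frequency
reaches 0.05 — the per-bin reading of the threshold, since a cumulative
criterion would depend on bin ordering.

Arrivals are reported as initial count minus mean remaining; the
distance metric is the great-circle distance from the live-population
centroid to the target ("Euclidean" at these scales differs by < 0.5%),
carried forward once everyone has arrived; detected-conspecific counts
are averaged over live agents and steps within each simulation day, then
across repeats. With a single repeat the across-repeat standard
deviation is reported as zero.

## Limitations

Beyond the stated non-goals: the vessel fleet is an honest placeholder
(routes, counts and source levels are configuration, not calibration);
the blocked-strait and construction scenarios are qualitative
demonstrations; and the heading-fusion weighting, while chosen on
principled grounds (see above), is one member of a family the underlying
behavioural literature does not pin down. None of the quantitative
claims in this vignette go beyond what the package's test suite and
acceptance script themselves compute.
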