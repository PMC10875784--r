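# whalenav

An agent-based simulator of baleen-whale migration under ocean noise
pollution, for movement ecologists and bioacousticians who want to ask
*what-if* questions about soundscapes: What does a 50% increase in
shipping traffic do to a migration corridor? Can a loud strait trap a
population behind a wall of noise? Does a pile-driving duty cycle leave a
daily fingerprint on progress toward the migration target?

Migrating baleen whales are modelled as agents that combine three sources
of directional information every time they reorient:

* **inherent knowledge** of the target direction, held with limited
  certainty;
* **collective information** — the headings of conspecifics whose calls
  they can still hear through the ambient noise;
* **local avoidance cues** — negative phonotaxis away from loud noise and
  bathotaxis toward deeper water.

Because ambient noise masks calls, noise pollution degrades the
collective channel (the *many wrongs* benefit of group navigation), and
loud sources additionally repel or misdirect individuals. All
environmental layers are synthetic and generated in code: no data
download is needed to run any scenario.

## Model

Each whale is tracked by position **x** and heading θ and moves by

    dx/dt = v_active + v_passive

where `v_passive` is passive advection by the ocean current and
`v_active` is a velocity-jump random walk: swim at constant speed *s*
(6 km/h) with fixed heading for an Exp(λ)-distributed time (λ = 1/h),
then reorient. At a reorientation the whale:

1. samples an inherent heading from a von Mises distribution centred on
   the target bearing with concentration κ(**x**,t);
2. observes the headings of every conspecific whose call is detectable;
3. fuses own and observed headings through a weighted resultant vector
   (weights α = β = 0.5) into estimates (μ̂, κ̂);
4. draws its navigation heading from VM(μ̂, κ̂), then blends it with the
   noise-avoidance and land-avoidance directions using the behavioural
   weights below.

**Acoustics.** A call at source level SL = 178 dB re 1 µPa at 1 m decays
with range r (m) as `RL = SL − γ log₁₀ r` (γ = 17.8). It is detected iff
`RL − N(x,t) ≥ −5 dB` **and** `RL ≥ 88 dB`, where N is the ambient noise
at the receiver; in quiet water this gives a communication range of
~114 km. Synthetic noise maps power-sum a wind floor with fixed
(construction, duty-cycled by hour of day) and mobile (vessel lanes)
sources.

**Behavioural weights.**

    w_na(N) = 0.5 + 0.5 tanh((N − N_threshold) / N_s)        noise avoidance
    w_la(d) = 0.5 − 0.5 tanh(0.5 (d − 30 m))                 land avoidance
    κ(N)    = κ_min + (κ − κ_min)(0.5 − 0.5 tanh(0.1 (N − N_IL)))

Weights are balanced so they never exceed one in total; any motion that
would cross onto land is aborted (failsafe). Whales arrive when within
50 km of the target; reference runs use 100 whales, 744 h and 10
repeats, with reduced desk-scale presets (10 whales, 72 h) as the
default.

**Metrics.** Ensembles are summarized by the Buchin intersection-switching
median trajectory with a binned spread region, arrivals over time, mean
distance from the population centroid to the target, and the daily mean
number of detected conspecifics.

## Worked example

```r
library(whalenav)

sc  <- build_scenario("pristine", list(n_repeats = 2, base_seed = 7))
ens <- run_ensemble(sc$config, sc$env)

arr  <- arrivals_over_time(ens)
dist <- mean_distance_to_target(ens)
det  <- mean_detected_whales(ens)

detection_range(60)        # 113.81 km in quiet (60 dB) water
arr$mean[nrow(arr)]        # 4.5  whales arrived (of 10, 72 h) +/- 0.71
dist$mean[c(1, nrow(dist))]# 469.4 km at start -> 67.4 km at end
det$mean[1]                # 8.9 conspecifics heard per whale on day 1
```

In the quiet "pristine" preset the 10-whale group stays within
communication range (8.9 of 9 possible partners heard), so headings pool
and the population closes 400 km on the target in 72 h, with the first
arrivals inside the 50-km radius. Rerunning with
`acoustic_params(enabled = FALSE)` (no communication) roughly doubles
mean arrival times — the many-wrongs benefit the masking scenarios
erode.

Presets: `pristine`, `current_synthetic`, `avoidance_sweep` (thresholds
105/110/115 dB), `info_loss`, `traffic_increase`, `slowdown`,
`construction`. See `?build_scenario`.

## Command line

```sh
Rscript -e 'quit(status = whalenav::whalenav_cli())' \
    run --preset pristine --repeats 2 --seed 7 --out out/
Rscript -e 'quit(status = whalenav::whalenav_cli())' \
    metrics --in out/ --out out/metrics.json
```

`run` writes per-repeat trajectory CSVs
(`repeat_seed,id,t_hours,lon,lat,heading_rad,n_detected,arrived`), a
`metrics.json`, the resolved `config.json` and a `run_log.json` with
seeds and the config hash. Gridded layers import/export as long-form CSV
(`t_hours,lat,lon,value` or `...,u_east,v_north`) via
`read_grid_csv()` / `write_grid_csv()`.

## Scope

No PDE-based sound propagation, frequency-dependent audiograms, Lombard
compensation, call-timing models, energetics, pod structure or real
HYCOM/EMODnet/soundmap ingestion (generic CSV grid readers are provided;
fetching real layers is the user's concern). See the methods vignette
(`vignettes/whalenav-methods.Rmd`) for assumptions and design decisions.
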