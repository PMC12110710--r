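# disksearch

Stochastic simulation and theory for a minimal model of sperm search:
constant-speed active particles with angular diffusion exploring a disk
whose rim absorbs them, including two-state protocols in which the
persistence length drops irreversibly mid-search — the physicist's cartoon
of hyperactivation.

## The problem and who this is for

After insemination, sperm must locate an egg inside a bounded, convoluted
domain.  Rather than a race, this is a collective random search, and its
efficiency depends on the *shape* of individual trajectories: nearly
straight paths disperse quickly but oversample the region they cross,
tightly turning paths search locally but travel slowly.  `disksearch` is
for quantitative biologists and biophysicists who want to simulate and
analyse this trade-off with a minimal, fully reproducible model.

The searcher obeys the active-particle equations

    u' = v0 (cos θ, sin θ),     θ' = sqrt(2 Dθ) ξ(t)

with unit white noise ξ: constant speed `v0`, heading diffusion `Dθ`,
persistence length `ℓp = v0/Dθ`, and coarse-grained diffusion coefficient
`D = v0²/(2 Dθ)`.  Searchers start at the center of a disk of radius `R`
(absorbing rim) and may switch irreversibly from a low-`Dθ` to a
high-`Dθ` state, either at an exponential waiting time (rate `k`) or when
a trigger radius is first crossed.  Coverage is scored on 20 radial
regions by the dwell-time density `ΔT/ΔA` and its relative standard
deviation across regions — the uniformity of the search.

## Worked example

```r
library(disksearch)

baseline <- switch_policy("constant", motility_params(v0 = 1, d_theta = 2.0))
hyper <- switch_policy("positional",
                       state1 = motility_params(1, 0.67),
                       state2 = motility_params(1, 6.0),
                       r_switch = 0.5)

cfg <- sim_config(dt = 1e-3, n_trajectories = 5000, seed = 1)
summary(simulate_ensemble(cfg, baseline))
#> Search summary ( 5000 trajectories, 5000 absorbed, 0 censored )
#>   mean escape time   : 1.823
#>   density mean / std : 1.128 / 1.466
#>   relative std       : 1.301
summary(simulate_ensemble(cfg, hyper))
#> Search summary ( 5000 trajectories, 5000 absorbed, 0 censored )
#>   mean escape time   : 3.162
#>   density mean / std : 1.649 / 1.566
#>   relative std       : 0.9495
```

The position-triggered switch keeps the searcher in the disk about 70%
longer (escape time 1.82 → 3.16) and covers it markedly more evenly
(relative std of the 20 region densities 1.30 → 0.95): the tight
second state oversamples the large outer area instead of rushing through
it.

In the small-persistence-length limit the dwell density near the rim
falls off linearly, with theoretical slope magnitude `1/(2πDR)`:

```r
p <- motility_params(1, 200)                 # ℓp = 0.005, D = 2.5e-3
ens <- simulate_ensemble(sim_config(n_trajectories = 1000, seed = 1),
                         switch_policy("constant", p))
slope <- fit_outer_slope(bin_occupancy(ens))
rim_slope(diffusion_model(effective_diffusion(p), 1))
#> fitted slope: 68.2   theory: 63.7
```

The few-percent excess of the fitted slope over the zero-`ℓp` theory is
the finite-persistence-length boundary layer at the absorbing rim (see the
methods vignette, `vignettes/two-state-disk-search.Rmd`).

A command-line interface covers the same ground
(`exec/disksearch simulate|occupancy|theory|estimate-lp|reproduce`);
`reproduce fig3a|fig3b|fig3c|fig5` reruns the reference
parameterisations end to end, writing occupancy tables, summary JSON and
a run manifest.

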