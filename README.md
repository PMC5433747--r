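# metashift

Trait-based metacommunity simulation of annual plants along a warming
temperature gradient.

## The problem

How much biodiversity a region loses under climate change depends not only
on how fast niches move, but on how species' dispersal abilities interact
with competition. Adding *random* variation in dispersal capacity to a
competition model is known to inflate predicted extinction risk
dramatically — but in real plants dispersal is not free: it is tied to seed
mass, and seed mass trades off against seed number, germination success and
seedling size. `metashift` is a simulator for exploring exactly this
question: it grows a metacommunity of 200 annual plant species on a
6 °C / 50 km temperature gradient to equilibrium, warms the whole gradient
sigmoidally by 3 °C over 150 years, and compares predicted extinctions and
diversity loss under three assumptions about dispersal:

* **uniform** — all species disperse identically;
* **variable** — dispersal distance varies with seed mass but nothing else
  does (dispersal as a neutral trait);
* **tradeoff** — seed mass buys establishment (germination, seedling size,
  local seed retention) at the cost of seed numbers.

It is aimed at theoretical community ecologists and modellers studying
range shifts, coexistence mechanisms and extinction debt.

## The model in brief

Within a 120-day growing season, biomass follows discrete-time
Lotka–Volterra competition with a Gaussian thermal response,

    B[i,t+1] = B[i,t] + r_i (1 − B_i/K_i − Σ_{j≠i} α B_j/K_j) B[i,t] − m B[i,t],
    r_i(T)   = r_max exp(−(T − T_opt,i)² / 2σ²),   K_i ∝ r_i,

with α_ii = 1 and a single interspecific α < 1. Between seasons, seeds
(`fecundity · biomass`) disperse deterministically through a 2-D
exponential-power kernel

    P(d, β) = c / (2π β² Γ(2/c)) · exp(−(d/β)^c),   c = 0.5 (leptokurtic),

whose mean distance scales with seed mass as δ = 600 · SM^(−0.13) m.
Seeds germinate, become seedlings, and all adults die. Boundaries are
open; a dynamically extrapolated downslope species pool supplies
warmer-adapted immigrants at the warm edge. All response variables
(richness, inverse-Simpson α/β/γ with β = γ/α, Jaccard dissimilarity,
colonisation/exclusion events, abundance-weighted geometric mean seed
mass, climate-tracking lags) are computed over *native* species — those
regionally established at equilibrium.

See the methods vignette (`vignettes/metashift-methods.Rmd`) for the full
model description, parameter table and calibration notes.

## A worked example

```r
library(metashift)

cfg <- ms_config(scenario = "variable", n_replicates = 3, base_seed = 42)
ens <- run_replicates(cfg)
ens
#> metashift ensemble: 3 replicates, variable scenario, alpha = 0.5
#>   stable gamma richness 59.3, gamma diversity 36.9
#>   after warming: -38.7% richness, -28.3% gamma diversity
#>   events per patch: 0.00 colonisations, 12.90 exclusions
```

Under variable (neutral) dispersal differences, the kernel effect — heavy
seeds deposit most of their seeds at home, pre-empting their patches —
lets large-seeded species competitively exclude small-seeded ones: of the
200-species pool only ~59 establish regionally at equilibrium, and warming
then removes a further ~39% of those natives. Running the same
configuration with `scenario = "tradeoff"` restores most of the
coexistence (over 100 natives) and roughly halves the relative species
loss; `scenario = "uniform"` loses least. Single runs
(`metacommunity_sim()`) have `print()`, `summary()` and `plot()` methods;
`run_preset("table1_baseline", ...)` and `run_preset("fig2_sm_factorial",
...)` execute the full competition-gradient and seed-mass factorial
designs, and `inst/cli/metashift` wraps both for shell use.

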