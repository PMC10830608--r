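# matewave

Two-sex, individual-based metapopulation simulation of range expansion
through fragmented corridor landscapes — for spatial population
ecologists studying how mating systems and settlement behaviour create
lags between where a species *could* live and where it actually is.

Species tracking environmental change must colonise habitat as it
becomes available. When breeding requires finding a mate, growth at the
sparsely populated range edge is depressed (a mate-finding Allee
effect), and the expansion wave is pushed from behind rather than pulled
from the front. `matewave` simulates this directly: a stage-structured
population of individuals living in one-cell habitat patches scattered
(7% of cells) through a 20 x 1000 corridor of unsuitable matrix, with

- **mating** by the harmonic-mean mating function
  *c* = min(1, 2*hm*/(*f* + *hm*)) *f*, where *h* is the harem size
  (*h* = 1 obligate monogamy, *h* = 100 polygyny); each of *f* females
  reproduces with probability *Pr* = *c*/*f* and throws a Poisson
  litter;
- **survival** declining with local female density,
  σ = σ₀ e^(−*b·N_f*), with habitat quality 1/*b* in females/patch;
- **dispersal** of juveniles by a stochastic stepwise movement model
  (perceptual range 5 cells, directional persistence 3, per-step
  mortality 0.005, movement costs 1:10 habitat:matrix, no step limit),
  so dispersal distances are emergent;
- **settlement** by pluggable rules: first suitable patch, mate-search
  (opposite-sex conspecific required; empty patches founded only by
  simultaneous pair arrival), negative density-dependent settlement
  *P_s* = 1/(1 + e^(−(*bN* − β_s)α_s)), or mate-search plus density
  dependence.

Factorial experiment drivers, range metrics (edge, spread rate in
rows/generation, quasi-equilibrium occupancy, neighbourhood
mating-failure profiles, dispersal kernels) and the statistical layer
(LMG relative-importance variance decomposition; binomial GLM of female
mating failure) are included. The step loop is C++ (Rcpp); a full
315-run factorial takes about a minute.

## A worked example

```r
library(matewave)

cfg <- sim_config(habitat_quality = 10, fecundity = 3,
                  mating = "two_sex", harem = 100)
cfg
#> <sim_config> two_sex (h = 100), 1/b = 10 females/patch, phi = 3, settlement = habitat_only
#>   landscape 20 x 1000 (7% habitat), core 500 rows, 50 years

res <- run_simulation(cfg, seed = 42)
res
#> <sim_result> 50 years simulated; metapopulation persisted
#>   final: 4931 individuals, 780 breeding patches, edge row 626, core occupancy 0.900

spread_rate(res$yearly$edge_row)
#> [1] 2.62
```

The polygynous two-sex metapopulation persists at high core occupancy
but its front advances only 2.62 rows per generation; the matched
female-only model (no mate limitation, same seed) spreads at 6.62 —
mate finding costs more than half the spread rate. Single runs are
deterministic given `(config, seed)`. Factorial experiments:

```r
tab <- run_experiment(experiment_design("exp1"), replicates = 5,
                      years = 50, master_seed = 1)
summarize_experiment1(tab)   # spread ratios, lags, extinctions, LMG tables
```

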