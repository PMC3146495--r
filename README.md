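# volecycles

Spatially explicit, individual-based simulation of field-vole
(*Microtus agrestis*) population dynamics under specialist and
generalist predation in fragmented landscapes — together with the
time-series toolkit used to characterise the resulting dynamics and a
factorial experiment driver with ANOVA variance decomposition.

## The problem

Fennoscandian vole populations shift from regular 3–5-year cycles in
the north to stable dynamics in the south. The usual suspects — the
predator community, landscape fragmentation, and breeding-season length
— covary along the gradient, so field data cannot separate them. This
package separates them by simulation: a daily-tick agent-based model of
territorial voles and their predators is run over a full 3 × 4 × 3
factorial design (predator assembly × fragmentation × breeding season,
36 scenarios), and the simulated annual density series are analysed the
way field series are:

* **amplitude** — max/min population size;
* **cycle length** — the lag of the second positive significant
  autocorrelation maximum (counting lag 0), requiring a harmonic near
  twice that lag; the white-noise confidence band is
  `z_(1-alpha/2) / sqrt(N)`;
* **direct and delayed density dependence** — the AR1 and AR2 slopes of
  the second-order autoregressive fit
  `x_t = a0 + AR1 * x_(t-1) + AR2 * x_(t-2) + e_t` of the log series.
  Strongly negative AR2 is the signature of delayed feedback
  (specialist predation); cycles of period ~4 years have AR1 near zero.

The predator types differ in six parameters (territory, kill
efficiency, kill thresholds for survival and reproduction, failure
tolerance, dispersal range) that encode a mustelid-like specialist with
a delayed numerical response and a fox-like generalist with a weak one.

## A worked example

```r
library(volecycles)

# specialist predators, homogeneous landscape, default desk-scale
# conditions (2450 m / 10 m cells / 1.5% habitat, 50 + 50 years)
cfg <- scenario_config("specialist", n_patches = 1,
                       breeding_season = "intermediate",
                       replicates = 2, master_seed = 1)
sim <- run_scenario(cfg)
vole_endpoints(as_tibble(sim), density_optimal_ha, replicate)
#> # A tibble: 2 x 8
#>   replicate mean_n log_mean_n amplitude cycle_length     ar1    ar2 flagged
#>       <int>  <dbl>      <dbl>     <dbl>        <int>   <dbl>  <dbl> <lgl>
#> 1         1   62.7       4.14      100.            4 0.144   -0.753 FALSE
#> 2         2   85.9       4.45      198.            4 0.00442 -0.800 FALSE
```

The mean density is in voles per hectare of optimal habitat. Both
replicates show 4-year cycles (`cycle_length`), two-orders-of-magnitude
peak-to-trough amplitude, direct density dependence near zero
and strongly negative delayed density dependence (`ar2` ≈ −0.8) — the
classic signature of specialist-driven vole cycles. Replacing the
assembly with `"generalist"` yields non-cyclic series
(`cycle_length = 0`, amplitude ~2); fragmenting the habitat into 100
patches suppresses cycling for every assembly.

The full experiment and its variance decomposition:

```r
ep  <- run_grid()                      # 36 scenarios x 5 replicates
dec <- anova_decompose(ep, ar2)        # Table-style ANOVA for AR2
autoplot(dec)
```

Synthetic generators (`gen_ar2()`, `gen_periodic()`, `gen_white()`,
`gen_grid_fixture()`) provide ground-truth inputs for validating the
analysis stack without the simulator.

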