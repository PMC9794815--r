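# rgbgame

Stochastic simulation and scaling analysis of extinction in the
rock-paper-scissors (cyclic competition) ecosystem on finite,
structured populations.

Deterministic replicator theory says a three-species cyclic game with
payoff matrix

```
        A    B    C
A       0   -1    g
B       g    0   -1
C      -1    g    0
```

is stable around the coexistence point (1/3, 1/3, 1/3) for gain
`g > 1`, unstable for `g < 1`, and neutral at the critical gain
`g_c = 1`.  In a *finite* population extinction always happens
eventually; what distinguishes the regimes is the *trend* of the mean
extinction time `T_ex(N, g)`: exponential growth
`T_ex ~ N exp(N/N+)` on the stable side, logarithmic `T_ex ~ ln N` on
the unstable side, and power law `T_ex ~ N` at criticality, with all
data collapsing onto two universal branches
`T_ex = N^alpha F±(N^beta |g - g_c|)`, `alpha = beta = 1`.

The package is for researchers in evolutionary dynamics / statistical
physics who want to reproduce and extend that analysis:

* **Engine** — the local three-party Reference–Gamble–Birth (RGB)
  update (compiled inner loop): a random Gamble, a random neighbouring
  Reference that sets its death probability via the death matrix
  `D = -(P + shift)/s`, and a random neighbouring Birth that refills
  the vacancy.  Works on fully-connected networks and 2D periodic
  grids; reproduces the replicator flow (slowed by `s`) in the
  well-mixed infinite-N limit, which is tested against an exact
  one-step enumeration oracle.
* **Replicator module** — the ODE limit, linear stability at the
  interior fixed point, the biodiversity indicator `chi = abc`, and
  the intrinsic frequency `omega_0 = (g+1)/(2 sqrt(3))`.
* **Scaling analysis** — ensemble extinction tables, the exponent
  fits, the two-branch data collapse, and a critical-gain bracket from
  exponential-vs-logarithmic model comparison.
* **Global gain** — maps a local gain on a structured network to the
  equivalent fully-connected gain `G` by matching the exponential
  characteristic constant `N+`; on the 2D grid `G > 1` even at
  `g = 0` (grid-enhanced biodiversity).
* **Correlations** — steady-state spatial/temporal indicator
  correlations on the grid, with `A_s exp(-r/xi)` and
  `A_t cos(wt + phi) exp(-t/tau)` fits.

All simulated times are reported in rescaled units
`t = updates/(N*s)` (replicator-equation time); every output records
`s`, the gauge shift and the seed.

## Worked example

```r
library(rgbgame)

dm <- death_matrix(rps_payoff(1))
dm
#> death matrix (shift = -1, s = 2)
#>     A   B   C
#> A 0.5 1.0 0.0
#> B 0.0 0.5 1.0
#> C 1.0 0.0 0.5

stability(1)$class                      # "neutral"  (g_c = 1)
intrinsic_frequency(1)                  # 0.5773503 = 1/sqrt(3)

# mean extinction time at criticality, well-mixed population
ens <- run_ensemble(fully_connected(120), dm, reps = 500, seed = 1)
mean(ens$t_ex)                          # 33.75  (rescaled units, se 0.87)

# critical exponent alpha from T_ex ~ N^alpha at g = 1
tb <- measure_table(sweep_cells("fc", c(30, 60, 120, 240), 1),
                    reps = 500, seed = 101)
fit_alpha(tb)                           # 1.037

# stable-branch characteristic constant at g = 1.3
cc <- characteristic_constant("fc", 1.3, c(60, 120, 240),
                              reps = 300, seed = 12)
cc$N_plus                               # 144.7  (bootstrap se 7.7)
```

The mean extinction time grows linearly in `N` at the critical gain
(`alpha` close to 1), and on the stable side the exponential rate
constant `N+` is finite — `T_ex ~ N exp(N/145)` at `g = 1.3`.

A command-line front end with the same functionality lives in
`inst/cli/rgb`:

```sh
Rscript inst/cli/rgb simulate --network fc --N 60 --g 1 --reps 100 --seed 7 --out runs.csv
Rscript inst/cli/rgb sweep --network fc --sizes 60,120,240 --gains 0.9,1,1.1 --reps 300 --seed 1 --out sweep.csv
Rscript inst/cli/rgb collapse --table sweep.csv --out fit.json
Rscript inst/cli/rgb correlate --L 100 --g 1 --seed 1 --out corr
```

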