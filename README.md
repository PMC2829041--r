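# adhesim

Stochastic and deterministic models of the coupling between
integrin-mediated adhesion and membrane protrusion at the leading edge of a
migrating cell.

Nascent adhesions at the very edge feed a paxillin/Rac/PAK positive-feedback
circuit that drives protrusion, and protrusion in turn promotes
nascent-adhesion formation at a rate set by the extracellular-matrix (ECM)
ligand density. The same nascent pool also matures — in a myosin-reinforced
way — into stable focal adhesions that mechanically inhibit protrusion. The
competition between these loops makes the leading edge an excitable/bistable
system: depending on ECM density and on the two feedback gains, the model
edge is quiescent, fires transient protrusions, protrudes persistently, or
protrudes with pauses.

The model tracks six dimensionless densities — nascent adhesions `n`, stable
adhesions `s`, myosin `m`, phospho-paxillin adhesions `x`, active Rac `r`,
PAK-active adhesions `p` — with protrusion velocity a derived quantity:

```
v     = (v0 + r) / (v0 + r + K_v) / (1 + I_n s)
dn/dt = k_ecm v - lambda n                      lambda = k_d_n v + k_a_s f(m)
ds/dt = k_a_s f(m) n - k_d_s (1 + C_s v) s      f(m) = 1 + E_s m
dm/dt = k_d_m (s - m)
dx/dt = k_a_x (p0 + p)(n - x) - (k_d_x + lambda) x
dr/dt = k_d_r (x - r)
dp/dt = k_a_p r (x - p) - (k_d_p + k_d_x + lambda) p
```

`p <= x <= n` is an exact invariant of both the ODEs and the discrete
stochastic model. See the `methods` vignette (`vignettes/methods.Rmd`) for
derivation, parameter rationale and numerical notes.

## What's inside

* **Deterministic core** — `model_rhs()`, `integrate_ode()` (stiff lsoda),
  `signaling_quasi_steady()`.
* **Phase-plane analysis** — `compute_nullcline()`, `find_fixed_points()`
  (stability from the full 6x6 Jacobian), `bifurcation_scan()` over
  `(k_ecm, E_s)`.
* **Exact SSA** — `compile_reactions()` (18 channels whose summed drift is
  exactly the scaled ODE right-hand side), `simulate_frm()` (First Reaction
  Method), `simulate_nrm()` (Gibson–Bruck Next Reaction Method),
  `run_phenotype_matrix()`.
* **Spatial SSA** — `build_lattice()` (1-D periodic, node spacing = Rac
  length constant `sqrt(D_r/k_d_r)` = 1.94 um), `simulate_nsm()` (Next
  Subvolume Method; only Rac diffuses), kymograph rendering.
* **Trace/map analysis** — `classify_trace()` (four-way phenotype),
  `segment_protrusion_events()` (two-threshold connected-component
  segmentation), `total_protrusive_activity()`,
  `make_synthetic_velocity_map()` (seeded fixtures with ground truth).
* **I/O + CLI** — YAML/JSON config, CSV/JSON/PNG writers, and
  `inst/cli/adhesim.R` with subcommands
  `phase | scan | ssa | nsm | classify | segment | fixture`.

## Worked example

Bistability at intermediate ECM density:

```r
library(adhesim)
find_fixed_points(base_case_params(k_ecm = 0.1))[, c("v", "n", "s", "r", "stability")]
#>       v    n      s      r stability
#> 1 0.125 1.11 0.2470 0.0185    stable
#> 2 0.380 1.58 0.1650 0.1125    saddle
#> 3 0.870 1.79 0.0924 1.3328    stable
```

A stochastic trajectory at high ECM density, classified:

```r
rx <- compile_reactions(base_case_params(k_ecm = 0.3), scaling_spec(N_star = 3))
tr <- simulate_frm(rx, t_end = 300, seed = 1)
classify_trace(tr$v, tr$t)
#> [1] "protrusion_with_pauses"
```

Segmentation of a synthetic kymograph with known ground truth:

```r
vm <- make_synthetic_velocity_map(30, 60, n_events = 5, seed = 2, n_masked = 10)
segment_protrusion_events(vm)
#> protrusion events: 5 event(s) (low = 1, high = 5 nm/s)
#>   id n_cells    max_v t_start t_end activity
#> 1  1      12 6.384106       2     5 24.98255
#> 2  2      30 8.028254       5    10 67.92953
#> 3  3       6 8.873354      24    26 18.09898
#> 4  4       6 8.480615      36    37 15.20663
#> 5  5       8 9.340686      44    45 17.51991
```

Command line:

```sh
Rscript inst/cli/adhesim.R phase --out-dir out/            # nullclines + fixed points
Rscript inst/cli/adhesim.R ssa --method nrm --seed 7 --out-dir out/
Rscript inst/cli/adhesim.R nsm --out-dir out/              # kymograph PNG + CSV
```

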