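---
title: "Methods: adhesion-protrusion dynamics at the leading edge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adhesion-protrusion dynamics at the leading edge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(adhesim)
```

## Scope

`adhesim` models the coupling between integrin-mediated adhesion and membrane
protrusion at the leading edge of a migrating cell. Two antagonistic feedback
loops act on a common pool of nascent adhesions:

* a **positive** loop — nascent adhesions recruit and activate a
  paxillin/Rac/PAK signaling circuit whose output (active Rac) drives
  protrusion, and protrusion in turn promotes nascent-adhesion formation at
  a rate set by the ECM ligand density;
* a **negative** loop — nascent adhesions mature into stable focal
  adhesions, maturation recruits myosin, myosin accelerates further
  maturation (gain `E_s`), and stable adhesions mechanically inhibit
  protrusion (gain `I_n`).

The balance of the two loops, tuned by the ECM coupling `k_ecm` and the
gains, produces the experimentally observed spectrum of leading-edge
behaviors: quiescence, transient protrusions, persistent protrusion, and
protrusion interrupted by pauses.

## Model

The state is six dimensionless densities: nascent adhesions `n`, stable
adhesions `s`, recruited myosin `m`, phospho-paxillin-bearing nascent
adhesions `x`, active Rac `r`, and the PAK-active subset `p`. With
`f(m) = 1 + E_s m`, `g(s) = 1 + I_n s` and the per-capita nascent loss
`lambda = k_d_n v + k_a_s f(m)`:

```
v     = (v0 + r) / (v0 + r + K_v) / g(s)            protrusion velocity, 0..1
dn/dt = k_ecm v           - lambda n                 formation vs turnover+maturation
ds/dt = k_a_s f(m) n      - k_d_s (1 + C_s v) s      maturation vs disassembly+convection
dm/dt = k_d_m (s - m)                                myosin tracks stable adhesions
dx/dt = k_a_x (p0 + p)(n - x) - (k_d_x + lambda) x   paxillin phosphorylation
dr/dt = k_d_r (x - r)                                Rac tracks phospho-paxillin
dp/dt = k_a_p r (x - p) - (k_d_p + k_d_x + lambda) p PAK activation
```

Design choices worth calling out:

* **Subset structure.** `x` and `p` are subsets of the nascent pool
  (`p <= x <= n`); they inherit the per-capita nascent loss `lambda`, which
  makes the ordering an exact invariant of both the ODEs and the discrete
  stochastic model (no clamping anywhere).
* **Positive feedback** closes through `p`: PAK output adds to the basal
  phosphorylation drive `p0`, so Rac activity promotes its own upstream
  input. `p0 > 0` (together with `v > 0` at zero Rac, via `v0`) lets the
  system ignite from an all-zero state.
* **Velocity is a derived quantity**, a saturating function of `r`
  divisively inhibited by `s`; it is deterministic given the state in both
  the ODE and the stochastic models.

## Parameters

The packaged base case (`inst/extdata/base_case.yaml`, returned by
`base_case_params()`) was calibrated so that, with `E_s = I_n = 0`, the
deterministic model is monostable-quiescent at `k_ecm = 0.03`, bistable at
`k_ecm = 0.1`, and monostable-protrusive at `k_ecm = 0.3`.

| parameter | value | rationale |
|---|---|---|
| `k_ecm` | 0.03 / 0.1 / 0.3 | low / intermediate / high ECM ligand density |
| `k_d_r` | 4.0 /min | Rac deactivation; sets the Rac length constant |
| `D_r` | 15 um^2/min | lateral Rac diffusion (0.25 um^2/s) |
| `C_s` | 10 | convective removal of stable adhesions by protrusion |
| `K_m`, `K_r` | 10 | myosin / Rac molecule-count amplification per adhesion |
| `k_d_m` = 2, `k_d_s` = 0.01, `k_d_x` = 5, `k_d_p` = 4 /min | relaxation rates ordering fast signaling vs slow adhesion turnover |
| `k_a_s` = 0.005, `k_a_x` = 15, `k_a_p` = 18 /min | maturation slow; signaling fast |
| `p0` = 5e-3, `v0` = 1e-2, `K_v` = 0.2 | small basal drives; half-saturation of the velocity law |

A deliberate calibration choice: the model has an exact symmetry under
rescaling `(k_d_n, k_a_s, k_a_x, k_a_p) -> /c` and `(p0, v0, K_v) -> *c`,
which leaves `v(t)`, `s`, `m` and the entire bifurcation structure unchanged
while multiplying the molecule counts of `n, x, r, p` at a given `N_star` by
`c`. The base case uses this freedom (at fixed anchors above) to put enough
molecules in the signaling loop that the protrusive state is metastable on
multi-hour timescales at the reference scale `N_star = 3`; without it the
discrete positive-feedback loop (`p <= x`, so `x = p = 0` is absorbing for
the feedback) goes extinct in minutes.

## Deterministic analysis

Fixed points are found on the quasi-steady manifold of the fast signaling
subsystem (`m = s`, `x = r`, `p` and `n` closed-form in `r`), then polished
and classified by the eigenvalues of the full 6x6 Jacobian — the reduced
slow Jacobian is blind to fast-subsystem instability and would mislabel the
middle (saddle) point.

```{r phase}
fp <- find_fixed_points(base_case_params(k_ecm = 0.1))
fp[, c("v", "s", "r", "stability")]
```

`bifurcation_scan()` maps fixed-point multiplicity over `(k_ecm, E_s)`:
the bistable tongue occupies an intermediate band of `k_ecm` at `E_s = 0`,
widens with moderate stabilizing feedback, and collapses to
monostable-quiescent at large `E_s`.

## Stochastic simulation

`compile_reactions()` maps the ODEs onto 18 irreversible channels over
integer counts `(N, S, M, X, R, P)` with `N_star` molecules per unit of
dimensionless density (`M` and `R` further amplified by `K_m`, `K_r`). The
summed channel drift equals the `N_star`-scaled ODE right-hand side exactly,
so the ODE model is the mean-field limit by construction:

```{r meanfield, eval = FALSE}
rx <- compile_reactions(base_case_params(k_ecm = 0.3), scaling_spec(300))
mean(simulate_frm(rx, t_end = 300, seed = 1)$v[-(1:200)]) # ~ deterministic v
```

Two exact SSA engines are provided — the First Reaction Method
(`simulate_frm()`) and the Gibson–Bruck Next Reaction Method
(`simulate_nrm()`, indexed priority queue with firing-time rescaling). They
are distributionally equivalent; the test suite checks this both on the
production network and on an embedded birth–death toy with an analytic
Poisson stationary law.

The spatial model (`simulate_nsm()`, Next Subvolume Method) places
independent copies of the reaction network on a 1-D periodic lattice in
which **only active Rac diffuses**. The node spacing is tied to the Rac
length constant `sqrt(D_r / k_d_r)` (1.94 um), which makes the per-direction
hop frequency `D_r / h^2 = k_d_r` = 4.0 /min. A one-subvolume lattice
reduces to the compartment model; `D_r = 0` (with explicit spacing)
decouples the subvolumes.

## Trace and map analysis

`classify_trace()` applies a fixed four-way rule to the post-burn-in
(100 min), moving-average-smoothed velocity trace: the median against the
0.5 threshold separates protrusion-dominant from suppressed traces, then
pauses (>= 2 min below threshold) or excursions (above threshold) split
each side. `segment_protrusion_events()` segments kymographs by a
two-threshold rule: 4-connected components above the low threshold
(1 nm/s; masked cells break connectivity) are accepted as events only if
they reach the high threshold (5 nm/s) somewhere; summed `v - low` over
event cells is the total protrusive activity.

`make_synthetic_velocity_map()` emulates measured edge-velocity kymographs
for testing that machinery only: quiet background below the low threshold,
rectangular events (intermediate rim, supra-threshold core) placed with
one cell of clearance, optional masked cells away from events, and an exact
ground-truth labeling attached. It makes no attempt to emulate the physics
— event shapes, amplitudes and placement are uniform-random.

## Numerical notes, problem sizes, limitations

* ODE integration: `lsoda`, rtol 1e-8 / atol 1e-10; the system is stiff
  (signaling rates ~20/min vs adhesion turnover ~0.01/min).
* Root finding: bracketing + `uniroot` + bisection polish; residuals are
  re-evaluated through the full right-hand side and reported.
* Typical costs (single core): a 1000-min SSA run at `N_star = 3` is
  ~1 s; the 3x3 phenotype matrix with 5 replicates ~1 min; a 19x7
  bifurcation scan ~1 min; `N_star = 300` mean-field runs ~20 s per
  300 min.
* Limitations: the lattice is 1-D and periodic; only Rac diffuses; the
  velocity law is memoryless (no membrane tension state); phenotype labels
  from finite windows are stochastic near regime boundaries (replicates
  may fail to ignite within the window); parameters are dimensionless and
  calibrated to qualitative regime structure, not to a specific cell type.
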