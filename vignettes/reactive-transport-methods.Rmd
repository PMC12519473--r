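---
title: "Methods: PCB reactive transport in bioaugmented sediment microcosms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PCB reactive transport in bioaugmented sediment microcosms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The system being modelled

A sealed 250 mL flask holds 10 g of PCB-contaminated sediment under 100 mL
of mineral medium, with roughly 150 mL of headspace. A PUF cylinder in the
flask neck accumulates gas-phase PCBs; ~30 cm of PDMS-coated SPME fiber in
the liquid tracks the freely dissolved phase. Treatments receive a dose of
an aerobic PCB-degrading culture in the liquid; controls do not. Flasks are
either shaken (sediment suspended, well mixed) or left quiescent with a
settled bed, and are sampled sacrificially in triplicate — at days 3, 11,
16 and 35 (shaken) or 16, 35 and 75 (nonshaken).

`pcbrtm` represents one congener in one flask as a compartmental ODE
system. Congeners never interact, so a multi-congener experiment is a loop.

## Model structure and assumptions

**Aqueous bookkeeping.** The state variable `c_w` is the *total* aqueous
concentration, dissolved plus cell-sorbed. With suspended degrader biomass
`x_cells` (g/L) and a linear cell–water isotherm `k_cell` (L/g), the freely
dissolved fraction is the bioavailability factor

> B = 1 / (1 + k_cell · x_cells).

Every process that physically requires dissolved substrate — air–water
exchange, sediment exchange, SPME uptake, and biodegradation — sees
`B * c_w`. An alternative reading would let degradation also consume the
cell-sorbed pool; we chose the single consistent convention that `B`
applies uniformly, because it keeps one definition of bioavailability
across all five couplings and reduces to the control exactly when
`k_cell = 0`.

**Degradation placement.** Biodegradation is first order in the freely
dissolved overlying-water pool only: `k_bio * B * c_w * v_w` (ng/d). It
does not act in porewater or on sorbed phases — aerobic biphenyl-pathway
oxidation needs both dissolved substrate and oxygen, and oxygen is depleted
in the bed. The cumulative sink is tracked in `m_degraded` so total mass
(including what was destroyed) is a conserved audit quantity.

**Shaken sediment.** Two-site fast/slow exchange with a linear driving
force toward `f_site * f_avail * K_d * B * c_w`, where `f_avail` caps the
fraction of the sediment inventory that exchanges at all and `f_fast`
splits the available capacity. When `k_fast = k_slow` the split is
provably irrelevant (a property test pins this).

**Nonshaken sediment.** A single representative sorbing sphere, discretised
into finite volumes, with local sorption lumped into one retardation factor
(`1 + rho * K_d * (1 - eps)/eps` for a linear local-equilibrium isotherm —
supplied as a single number because any linear variant collapses to it).
The particle surface is held at the porewater concentration (Dirichlet);
porewater exchanges with overlying water through a boundary-layer film
`k_bl * a_int * (c_pw - B * c_w)`. Cells were added to the liquid phase, so
porewater carries no cell sorption (B_pw = 1).

**Porewater volume.** The bed needs a porewater volume that the flask
geometry does not state directly. The default `v_pw = 0.004` L comes from
10 g of sediment at particle density 2.5 g/cm³ (4 cm³ of solids) and a bed
porosity of 0.5, giving 4 cm³ of pore space. It is an ordinary config field
for sediments that differ.

**Samplers.** PUF: air-side film-limited uptake over the exposed face
toward a linear PUF–air equilibrium. SPME: first-order relaxation of the
coating load (per cm) toward `k_fw * v_coat * B * c_w`. Both samplers
withdraw real mass from their source compartments, so they participate in
the conservation audit. The *apparent* SPME mass adds
`alpha_fiber * (1 - B) * c_w * v_w / L`: a fraction of the cell-sorbed
aqueous pool attributed to cells fouling the fiber. This term lives in the
observation model only — it changes what the fiber *reports*, not the
dynamics — because it was introduced to reconcile measurements with the
model, not as a transport process. It is what lets a treatment show *more*
apparent aqueous PCBs while airborne PCBs drop.

## Parameters that matter

| parameter | units | default | notes |
|---|---|---|---|
| `k_bio` | 1/d | 0 | 17 (shaken) / 0.4–0.6 (nonshaken) are the reference fixed rates for a dichlorobiphenyl; controls carry native activity of order 0.1–1 |
| `k_cell` | L/g | 0 | with `x_cells = 0.5` g/L, `k_cell = 8` gives B = 0.2 |
| `f_avail`, `f_fast` | – | 1, 0.5 | availability cap and fast-site share |
| `k_fast`, `k_slow` | 1/d | 1, 0.01 | two-site desorption rates |
| `v_aw`, `a_aw` | cm/d, cm² | 50, 38 | two-film air–water exchange; 38 cm² is the flask cross-section |
| `k_bl`, `a_int` | cm/d, cm² | 2, 38 | bed boundary-layer film (nonshaken) |
| `alpha_fiber` | – | 0 | fouling attribution; 0.25 in the nonshaken treatment preset |
| particle: `radius`, `d_eff`, `retardation`, `porosity` | cm, cm²/d, –, – | 5e-3, 1e-6, 100, 0.4 | silt-sized particle; `n_particles_equiv` scales one particle to the 10 g inventory |
| PUF `k_puf`, `k_puf_a` | cm/d, – | 500, 5000 | uptake velocity and partition capacity |
| SPME `k_fw`, `k_sp`, `v_coat_per_cm` | –, 1/d, L/cm | 3e4, 2, 3.8e-9 | PDMS partitioning and kinetics |

The congener table shipped as `default_congeners()` (a dichloro-, a
trichloro- and a pentachlorobiphenyl) uses illustrative round values of
realistic magnitude — partition constants are config, not code, and real
studies should load their own compilation.

## Numerical choices

* **Integrator.** `deSolve::lsoda` (stiff-capable; the shaken system with
  `k_fast = 10³`/d and `k_bio = 17`/d is genuinely stiff and is checked
  against a fixed-step RK4 oracle at dt = 10⁻⁵ d). Default relative
  tolerance 1e-8; the synthetic-data and calibration paths use 1e-6, which
  changes sampler masses by far less than replicate noise.
* **Negative states.** Values more negative than `-10 * tol * scale` abort
  with the failure time; smaller undershoots are clipped to zero.
* **Particle mesh.** Finite volumes (not differences) make shell-mass
  change equal the surface flux exactly, so conservation audits telescope.
  Edges follow `R * (1 - (1 - u)^2)`, clustering shells at the surface:
  with 50 shells a uniform mesh misses the analytic series by 2.4% at
  `tau = 0.001` while the graded mesh stays within 0.27% across
  `tau` in [0.001, 1]. The grading exponent is a grid parameter.
* **Series oracle.** The classical sphere-uptake series is truncated at
  `n_terms`; plain truncation leaves an O(1/N) bias at `tau = 0`, so the
  value is additionally capped by the exact short-time bound
  `6 * sqrt(tau/pi)`, which is tight in that limit.
* **Censoring epsilons.** log10 transforms add half the smallest positive
  value in the relevant set (per sampler series in the objective; per
  comparison set in the t-tests), mirroring the censor-to-zero rule and
  keeping censored groups finite. Both are overridable.
* **Optimisation.** Bounded multi-start: 8 Latin-hypercube starts (seeded),
  single-evaluation screening, then `optim(method = "L-BFGS-B")` from the
  best half with the finite-difference step scaled to 1e-4 of each
  parameter's range — adaptive-integrator noise in the objective otherwise
  corrupts numerical gradients and stalls line searches. Estimates at a
  bound are flagged rather than hidden.

## Interpreting the stated method faithfully

Three points in the source method descriptions are ambiguous; the package
fixes one reading and keeps the alternative behind a switch:

* **LOQ formula.** The printed blank formula ends with a dangling "n". The
  default is `mean + 1.96 * SD` — a per-sample reporting limit — with the
  `sqrt(n)` (standard-error) variant available via `se_of_mean = TRUE`.
* **"Paired" t-tests on sacrificial triplicates** have no natural pairing;
  the default pairs by replicate index, and `pairing = "welch"` gives the
  two-sample alternative.
* **Pipeline order.** Censor below LOQ, then surrogate-correct, then
  aggregate. Correcting first would push masses past their LOQs; a
  regression test pins the canonical order's output on a fixture.

No multiple-testing correction is applied by default (per-time-point tests
at alpha = 0.05), matching the reference analysis.

## What the synthetic generator does and does not emulate

`generate_experiment()` simulates the model truth per group, reads the PUF
mass and apparent SPME mass at the sacrificial sampling days, and draws
triplicates with mean-preserving multiplicative lognormal noise (default CV
0.25 for PUF, 0.35 for SPME — read qualitatively from the spread of
reported sampler SDs; they are calibration knobs, not literature
constants). Lognormal noise is the generative assumption consistent with
log10-transforming concentrations before testing. Blanks and surrogate
recoveries are generated the same way (truncated-normal recoveries on
(0, 1.5]).

What this does **not** emulate: real congener profiles of commercial
Aroclor mixtures (only a configurable LC fraction over a small congener
list), time-varying degrader activity (activity loss is represented by
refitting `k_bio` over time windows, not by growth/decay kinetics),
instrument-side effects, or correlated replicate errors. Passing tests
therefore show the *pipeline* is correct under its own statistical
assumptions — they do not validate the model against field sediment.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script studies run single-congener designs:
12 particle shells for nonshaken calibration work (50 shells for the
solver-accuracy audit), 20 noisy seeds for the recovery study in the test
suite (10 in the acceptance script), and 20–50 seeds for the end-to-end
signature rates. These sizes give stable pass/fail behaviour at desk-scale
runtimes; nothing in the method depends on them.

## Known limitations

* Single representative particle radius; no size distribution, no
  nonlinear isotherms.
* No oxygen dynamics or microbial growth; `k_bio` is piecewise-constant at
  best.
* Each congener is independent — no dechlorination chains linking
  congeners.
* The fouling term is the simplest linear attribution consistent with the
  described refinement; its true functional form is unknown.
* Identifiability of `k_bio` is regime-dependent: in a shaken flask with a
  large fast-desorbing inventory, the sediment buffers the water column
  and small rates are nearly unobservable (bounds-hit flags and per-series
  R² are the diagnostics to watch).
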