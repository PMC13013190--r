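---
title: "Model and methods: hybrid simulation of tumour-immune dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: hybrid simulation of tumour-immune dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmesim)
```

## The model

`tmesim` simulates a tumour microenvironment (TME) as a multiscale hybrid
system with three coupled layers.

**Agents on a lattice.** Cancer cells, immune effector cells and immune
suppressor cells occupy sites of a 3D grid (at most one agent per site;
0-based coordinates, clipped non-periodic boundaries, 26-site Moore
neighbourhoods). One agent stands for $10^6$ biological cells at a density of
$10^9$ cells/cm$^3$, so 100 agents represent a 0.1 cm$^3$ tumour, 1000 agents
1 cm$^3$, and $10^6$ agents the lethal burden of 1000 cm$^3$. Immune cells
are seeded at a 1:100 immune:cancer ratio.

Cancer cells traverse an explicit cell cycle — G1 for 11 h, S for 8 h, G2 for
4 h, M for 1 h — on deterministic clocks. A cell that completes M is flagged
*division-ready* and waits until a stochastic division event selects it; both
cells then restart in G1. Under hypoxia or crowding (no free neighbour) a
cell enters reversible quiescence (G0), storing its exact cycle position and
restoring it bit-exactly on reactivation. Cancer cells can become PDL1
positive; daughters inherit the mother's PDL1 status, the spatial surrogate
of interferon-driven adaptive resistance at T-cell-rich margins. Effectors
kill adjacent cancer cells and are exhausted by contact with PDL1$^+$ cells
or suppressors; exhausted effectors neither move, kill nor divide, but keep
their site until their lifespan ends.

**Stochastic events.** Cell actions are drawn by an exact Gillespie
algorithm. Every propensity is linear in the stated counts or counters:
division and natural death in the cancer count; PDL1 expression in the
PDL1$^-$ count plus the cumulative kills by effectors, chemotherapy,
radiotherapy and the DDR inhibitor; effector kill in the active-effector
count; effector infiltration in the cancer count, the active-effector count
and cumulative effector kills (plus the post-radiation boost); suppressor
infiltration in cumulative effector kills; immune division and movement in
the respective immune counts; exhaustion in the suppressor and PDL1$^+$
counts, damped by $(1 - \text{receptor occupancy})$. Events with spatial
preconditions (kill, exhaustion, division placement) act on a uniformly
random eligible agent or pair and are logged no-ops when none exists — population-level rate semantics and
per-contact semantics are reconciled by letting the population-level
propensity fire and the adjacency guard decide.

**Deterministic layers.** Oxygen obeys a reaction–diffusion equation
$\partial_t c = D \nabla^2 c - k_o \chi_{\text{cycling}} - q_c k_o
\chi_{\text{quiescent}}$ with the periphery held at the reference value 1
(concentrations are relative), discretised with a 7-point Laplacian and
explicit Euler steps bounded by $\Delta t \le 1/(6D)$. Oxygen thresholds are
strict-lower half-open: below the necrosis threshold a cell dies, below the
quiescence threshold it rests. Vessel sites can replace the peripheral
source. Pharmacology is ODE-based: a linear six-compartment model with a
saturable PD1-binding term yields the antibody's receptor occupancy;
docetaxel follows a K/PD law $K(t) = \varepsilon A(t) e^{-\lambda t}$ whose
resistance parameter $\lambda$ erodes the kill rate; the DDR inhibitor acts
through an Emax law $E = E_{\max} C/(EC_{50} + C)$ on S-phase cells only;
chemotherapy kills G2/M cells and immune cells. Radiation applies a modified
linear-quadratic survival $S = \exp(-s_{\text{phase}}(\alpha d_{\text{eff}} +
\beta d_{\text{eff}}^2))$ per fraction with $d_{\text{eff}} =
\mathrm{OMF}(o) \cdot d$; survivors in G1 or G2 draw a cycle delay uniform on
1–9 h, consumed before the remaining phase time. Local drug exposure is the
systemic level scaled by local relative oxygen, giving the core less drug
than the edge.

## Hybrid coupling

Deterministic layers advance on a fixed macro-step (default
$\Delta t = 0.5$ h): due doses are applied, PK trajectories (precomputed on
the macro grid, since they do not depend on the agent state) are read, the
oxygen field is sub-stepped within its stability bound, clocks advance,
oxygen thresholds are evaluated, and the per-step drug death draws are made.
Within each macro-step the Gillespie layer runs as an *exact* SSA:
propensities are recomputed after every executed event. We deliberately do
not freeze propensities at the step start — freezing introduces an
$O(b\,\Delta t)$ downward bias in pure birth dynamics that would fail the
Yule-mean validation below, and recomputation is cheap because propensities
depend only on scalar counts and counters. Waiting times are re-drawn at
step boundaries, which is exact by memorylessness of the exponential.

Per-step drug death draws convert the dimensionless kill quantities into
per-step probabilities as hazards, $p = 1 - e^{-h\,\Delta t}$ with
$h = K/K_{\max}$ (chemotherapy) or $h = E$ (DDR inhibition), so halving
$\Delta t$ halves the per-step probability and results converge in
$\Delta t$. The probability drawn *per application* remains $K/K_{\max}$ as
the source model states; the hazard form is the $\Delta t$-consistent
implementation of "per application step".

## Parameters and defaults

All rate constants are explicit config entries (`tme_config()`); hours are
the base time unit everywhere. The biological source states most rules
without printing constants (they live in unavailable supplementary tables),
so the shipped defaults are documented placeholders chosen once, at
physiologically plausible magnitudes, such that the untreated baseline shows
the canonical trajectory (slow growth, accumulating PDL1 and exhaustion):

* `division` 3e-3 /h per cancer cell (population doubling ~10 days; the
  cycle is fast relative to this, so division-ready cells queue in M — the
  census consequence of coupling a 24 h cycle to slow net growth),
  `death` 1e-4 /h.
* immune rates: kill 0.02 /h per active effector; movement 0.2 /h with
  exponential-distance chemotaxis weight $e^{-\beta d}$, $\beta = 1$
  (effectors seek cancer cells, suppressors seek effectors); division
  0.02 /h with a 24 h refractory time and at most 4 divisions; lifespans
  2000 h.
* PDL1: constitutive 1e-5 /h per PDL1$^-$ cell, plus 2e-3 /h per cumulative
  eliminated cell; exhaustion 2e-3 /h per adjacent suppressor or PDL1$^+$
  contact class.
* oxygen: $D = 0.5$ lattice$^2$/h, $k_o = 0.01$ /h, $q_c = 0.5$, quiescence
  threshold 0.3, necrosis threshold 0.1 — assumed values, as the source
  itself marks them.
* PD1 antibody: placeholder six-compartment IgG-like model (central,
  peripheral, tumour vasculature, endosomal, intestinal, drug–PD1 complex)
  with fast, high-affinity binding so that 2 mg/kg Q3W yields a > 95%
  occupancy plateau; substitute published constants via `pd1$model`.
* docetaxel: $\varepsilon$ = 4e-4 /h/mg, $\lambda$ = 5e-4 /h (kill-rate
  half-life ~58 days), $K_{\max} = 1$ /h, elimination 0.063 /h. The 0.132 g
  Q3W fixture dose follows the printed value; note 1.75 m$^2 \times$
  75 mg/m$^2$ is 131.25 mg — we keep the printed 0.132 g.
* DDR inhibitor: $E_{\max}$ = 0.3 /h, $EC_{50}$ = 50 mg, elimination
  0.06 /h, BSA 1.75 m$^2$ for mg/m$^2$ dosing.
* radiotherapy: $\alpha$ = 0.3 /Gy, $\beta$ = 0.03 /Gy$^2$; phase
  sensitivities $s_{G1} = s_{G0} = 0.5 < s_S = s_{G2} = s_M = 1$; OMF
  $f(o)/f(1)$ with $f(o) = (\mathrm{OER}\,o + k_m)/(o + k_m)$, OER 3,
  $k_m = 0.5$ (normalised to 1 when oxic, floored near 1/OER when anoxic);
  immune cells use the S/G2/M sensitivity class; the delayed infiltration
  boost is amplitude $\times$ cumulative kills $\times$ a lagged
  double-exponential kernel (lag 48 h, rise 24 h, decay 240 h) — both the
  OMF and the kernel are named pluggable stand-ins for the published forms.

## Fixtures and what the tests show

`inst/extdata/configs/` ships one configuration per treatment scenario
(untreated; PD1 antibody 2 mg/kg Q3W; radiotherapy 2.5 Gy 5 d/wk;
docetaxel 0.132 g Q3W; DDRi 210 mg/m$^2$ weekly; three combinations), at
reduced scale so the whole suite runs on a desk machine: 20$^3$ lattices,
80–400 initial agents and 3–5 week horizons instead of hundreds of days.
They reproduce the *regimen structure* and the qualitative dynamics — a
growing, progressively immunosuppressive untreated TME; occupancy-mediated
exhaustion blockade; fractionation-driven G0 emptying and a census shift
towards G2 over S measured 6 h after each fraction (immediately after a
fraction the delayed G1/G2 cohorts hold while S empties; averaged over whole
days the effect washes out); weekly S-phase oscillation under DDR
inhibition. They do not reproduce the source's absolute cell counts or event
days, which depend on unavailable supplementary parameter tables; numeric
end-points of the fixtures are therefore properties of *this* package's
defaults.

The synthetic scenarios emulate idealised study conditions: a single
compact nodule, homogeneous cell behaviour, immune entry anywhere on the
grid, no vasculature, fibroblasts or cytokine fields. Passing tests
demonstrate internal correctness (process laws, conservation,
reproducibility) and qualitative fidelity, not calibration to any measured
tumour.

## Numerical choices and degenerate inputs

* Neighbour ordering is lexicographic in the offset, and every sampling site
  draws from one seeded RNG in a documented order, so a fixed seed
  reproduces the event log byte-for-byte.
* The oxygen stepper refuses explicit steps beyond $1/(6D)$; the loop
  sub-steps at 90% of the bound. Field values are clipped at 0; the discrete
  maximum principle keeps them at or below the boundary value.
* Threshold comparisons are strict-lower half-open (a level exactly at the
  quiescence threshold is proliferative); ties in the initial sphere packing
  break by site index.
* Division with no free neighbour, kill with no adjacent pair, movement of a
  boxed-in cell: all valid no-ops, logged as vacuous events.
* Extinction is absorbing; runs stop at the horizon, at extinction, or at
  the $10^6$-agent lethal ceiling, whichever comes first.
* Validation modes: `cycle$gating = FALSE` turns division into a pure
  rate-driven birth process (used for the Yule and birth–death oracles,
  which need the engine to *be* the configured process), and
  `cycle$enabled = FALSE` freezes clocks (used for the frozen-system test).
  Oracle runs seed cells scattered on a large lattice so spatial blocking is
  negligible.

## Known limitations

Lattice constraints (uniform cell size, 26-neighbour interactions), two
immune phenotypes only, no T-cell priming or trafficking, no vasculature
(a vessel-site hook exists for the oxygen source), agent-level granularity
of $10^6$ cells, and placeholder pharmacology constants. The K/PD, Emax, OMF
and infiltration-kernel forms are the package's own minimal readings of the
cited model families; each is a named function of config constants precisely
so published values can be substituted without code changes.
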