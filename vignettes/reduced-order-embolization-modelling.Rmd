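---
title: "Reduced-order modelling of embolization efficiency in arterial trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-order modelling of embolization efficiency in arterial trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emboflow)
```

## Why a 0D network model

Transcatheter arterial embolization outcomes hinge on how blood flow — and
with it, embolic material — partitions at successive bifurcations between a
catheter tip and a designated target vessel. Full three-dimensional CFD on
patient-specific geometry resolves velocity fields, but every quantity the
embolization question actually uses is a *flow split*: how much of the flow
passing an injection site ends up in the target outlets, how that split
responds to downstream pressure, and when the target branch stops carrying
forward flow. In the laminar regime that characterises hepatic arterial flow
(the packaged baseline peaks at Re ≈ 417, far below the 2300 transition),
these splits are governed by the linear resistance structure of the tree.
`emboflow` therefore solves the *equivalent laminar network problem*:

* each cylindrical segment carries the Poiseuille resistance
  $R = 8\mu L/(\pi r^4)$;
* junction pressures are continuous with zero junction loss (minor losses
  are second-order at these Reynolds numbers);
* the inlet imposes a volumetric flow, outlets impose pressures, and
  Kirchhoff's current law closes a sparse symmetric positive-definite
  system solved by Cholesky factorisation — exactly, not iteratively.

What is deliberately *not* modelled: 3D velocity fields and wall shear,
recirculation eddies, vessel compliance and fluid–structure interaction,
non-Newtonian rheology, Womersley (inertial) effects in pulsatile flow, and
particle-level transport of embolic agents. Flows are advective splits under
perfect mixing at bifurcations. These are the standard 0D idealisations;
they preserve flow partition, junction pressure, Reynolds number and every
EEI-type ratio, which is the scope of the package.

## The embolization efficiency index

For an injection site $s$ carrying flow $Q(s)$,

$$\mathrm{EEI}(s) = 100\% \times
  \frac{\sum_{o \in \mathrm{targets}(s)} \max(Q_o, 0)}{Q(s)},$$

the percentage of the carrier flow at $s$ that reaches target outlets
downstream of $s$. Two conventions matter:

* **Clamping.** A retrograde target outlet cannot receive embolic material,
  so negative outlet flows contribute zero to the numerator. Raw signed
  flows remain available in every `flow_solution`.
* **Undefined vs zero.** A site whose own flow is below tolerance
  (default $10^{-12}$ m³/s) has no carrier stream to inject into; its EEI is
  reported as `NA` with `defined = FALSE`, distinct from a genuine 0%. This
  keeps maps interpretable near flow cessation.

Three structural results follow from network linearity and are enforced as
tested invariants:

1. **Inflow invariance.** With uniform outlet pressures the pressure field
   is affine in $Q_{in}$, so every flow ratio — hence the whole EEI map — is
   independent of the inlet flow. The package's inflow sweep verifies this
   to below $10^{-6}$ percentage points.
2. **Pressure linearity.** Every segment flow is affine in the target total
   pressure (superposition), so target-branch and cross-section flows fall
   on exact straight lines below cessation. The EEI itself is a *ratio*; at
   the inlet site its denominator is the fixed $Q_{in}$, so inlet-site EEI
   is exactly affine on the pressure range where no individual target
   outlet has reversed (the clamp makes it piecewise affine beyond that
   point; the first reversal pressure follows in closed form from two
   solves).
3. **Proximity gradient.** Moving the site toward the target can only shed
   non-target side flow from the denominator, so EEI is non-decreasing along
   the inlet-to-target path — the quantitative argument for superselective
   catheter placement.

## Boundary conditions and the pressure lever

The baseline condition is a steady inlet flow of 5 cm³/s with all outlets at
300 Pa. The experimental lever is a *target total pressure* $P_T$
distributed over the target outlets in direct proportion to their
cross-sectional areas, $P_i = P_T A_i / \sum_j A_j$, while non-target
outlets stay at 300 Pa. "Distributed" is read as a partition — the shares
sum to $P_T$ exactly — since that is what distributing a total means; an
explicit per-outlet pressure map is available for any other convention.

One consequence of the partition is worth spelling out because it sets the
reachable parameter range: with $n$ target outlets of comparable area, each
outlet sees only $\sim P_T/n$, so the total pressure needed to stall the
branch scales like $n$ times the junction-pressure scale. The packaged tree
(10 target outlets, non-target pressure 300 Pa) stalls at $P_T = 5000$ Pa
even though no single outlet ever holds more than a few hundred pascals;
and a calibration request of 1000 Pa is only feasible on trees with few
target outlets. The test battery for stall-recovery therefore uses trees
with 2 target outlets.

### Stall pressure: bisection and closed form

`find_stall_pressure()` defines flow cessation operationally, as the paper's
"approaches 0" does: the target total pressure at which the target-branch
flow falls to a fraction (default 1%) of its 0 Pa baseline. Bisection
brackets from 0 by doubling and narrows to 1 Pa. Because the flow is affine
in $P_T$, the same quantity has a closed form from two exact solves,
$P^\ast_{thr} = (1-thr)\,Q_0/c$ with slope $c$; `analytic_stall_pressure()`
computes it and every bisection result is cross-checked against it (warning
beyond 2 Pa). At `rel_threshold = 0` this is the true zero-flow stall, which
for a two-outlet network reduces to the textbook
$P^\ast = P_{nt} + Q_{in} R_{nt}$.

### Calibration

`calibrate_stall_pressure()` makes a synthetic tree honour a requested stall
pressure by applying one global multiplicative scale to the *non-target
terminal* radii only. Shrinking peripheral outlets raises the junction
pressure the target pressure must overcome, monotonically, so a 1D root
find on the closed-form stall (over log-scale, `uniroot` to ~1e-12)
suffices; the result is verified with the bisection finder. Restricting the
scale to non-target terminals keeps the target subtree, the path geometry
and hence the EEI structure untouched. The trade-off is explicit: the
calibrated tree no longer satisfies Murray's law at the parents of rescaled
outlets (`murray_closure()` reports this), which is accepted as the price of
matching the macroscopic stall behaviour.

## The synthetic tree generator

No patient geometry is distributed, so `generate_tree()` builds seeded
stochastic stand-ins that reproduce the *hierarchy statistics* the analysis
depends on:

* a binary tree with a designated inlet-to-target path; the target branch
  sits at a configurable depth (inlet = level 1, incrementing at each
  bifurcation) and subtends a configured number of outlets;
* one side branch leaves the path at each bifurcation and receives a random
  share of the remaining outlets;
* radii obey Murray's law $r_p^k = \sum r_c^k$ (default $k = 3$) with each
  child's share proportional to its outlet count times a log-uniform jitter
  $\exp(U(-a, a))$, $a$ = `branching_asymmetry` (default 0.3) — count-
  proportional splits are the deterministic physiological baseline, and the
  jitter supplies realistic asymmetry without destroying the hierarchy;
* segment length is a fixed multiple of radius (default 20, a standard
  arterial length-to-radius scale), since no length data exist to fit.

The packaged reference tree uses 43 outlets, 10 of them under a target
branch at depth 5, and an inlet radius of 2.31 mm — the diameter back-solved
from $Re = 4\rho Q/(\pi \mu D)$ so that the 5 cm³/s baseline gives the
study's inlet Reynolds number of 417. Its peripheral radii are calibrated to
a 5000 Pa stall and the JSON file is byte-stable (numbers serialised with 17
significant digits, so write–read is the identity on doubles).

What the generator does **not** emulate: real trees are not strictly binary,
have length and tortuosity variation, imaging-derived surface irregularity,
and inter-patient topology differences. Tests passing on generated trees
demonstrate correctness of the *mechanics* (conservation, linearity,
monotonicity, calibration) — not anatomical fidelity of any particular
patient.

## Pulsatile flow and backflow

The inlet waveform is a strictly positive two-harmonic Fourier series with
period 0.8 s and pulsatility index $(Q_{max}-Q_{min})/\bar{Q} = 1$ by
default — representative arterial values, exposed in
`pulsatile_waveform()`. The zero-mean harmonic construction makes the time
average equal the nominal mean exactly. Solves are quasi-steady (one steady
solve per sample, 64 left-endpoint samples per period by default), which is
exact for flow-ratio quantities in the absence of inertance and compliance.

Backflow is the model's surrogate for reflux-mediated non-target
embolization: a segment flowing toward the inlet (below $-10^{-12}$ m³/s).
Linearity gives a sharp criterion, verified in the tests: the target branch
experiences retrograde episodes within the cycle exactly when the target
pressure exceeds the instantaneous zero-flow stall pressure evaluated at
the waveform minimum; above the stall at the waveform maximum it is
retrograde for the entire cycle. `run_backflow_study()` reports per-segment
retrograde fractions together with this diastolic–systolic stall window.

## Numerical choices

* Linear solves: sparse Cholesky (`Matrix`); junction mass residuals are
  checked below $10^{-10}$ relative on every solve, and the solver is
  validated against an independently assembled dense reference on small
  trees to $10^{-9}$ relative.
* Degenerate inputs: non-positive radii/lengths, cycles, multiple roots and
  missing outlet pressures are rejected with named validation errors;
  a singular system aborts with a solver error identifying the condition.
* Re > 2300 anywhere triggers a laminar-validity warning rather than an
  error: the solve is still exact for the linear model, but the model is
  outside its regime.
* Tolerances: flow thresholds (stall definition, backflow, EEI
  definedness) default to $10^{-12}$ m³/s absolute and 1% relative for the
  stall definition; bisection to 1 Pa; all exposed as arguments.
* Determinism: tree generation is seeded (and restores the caller's RNG
  state); sweep pipelines and `report()` regenerate byte-identical JSON
  summaries for identical inputs.

## Problem sizes

The packaged analyses run on the 85-segment reference tree (43 outlets) in
well under a second per solve; the test batteries use 20 seeded trees for
the stall cross-check and 10 for calibration recovery, with 12–20 outlets —
sizes chosen to exercise every structural property (asymmetry, depth,
multi-outlet targets) while keeping the whole suite interactive.

## Limitations

Everything the 0D reduction discards (3D fields, compliance, non-Newtonian
effects, particle inertia and size selectivity at bifurcations) is absent
by design; conclusions about *spatial* flow structure or device-level
embolic behaviour require 3D CFD or in-vitro work. The EEI here is a
perfect-mixing flow-split proxy; real microsphere distribution deviates
where particle Stokes numbers are non-negligible. Calibration compensates
peripheral resistance only through terminal radii; it reproduces a stall
pressure, not a measured impedance spectrum.
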