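# emboflow

Reduced-order hemodynamic modelling of transcatheter arterial embolization
(TAE) efficiency.

During TAE, an interventional radiologist injects embolic material into a
hepatic artery branch to starve a tumour of blood. How much of that material
reaches the intended (*target*) vessels depends on where in the arterial tree
the catheter sits and on the pressures downstream — not only on how hard the
blood is flowing. `emboflow` is for researchers studying these questions
computationally: it models the arterial tree as a zero-dimensional (0D)
Poiseuille resistance network and quantifies delivery with the
**embolization efficiency index (EEI)** at every candidate injection site.

## The model

A vascular tree is a rooted network of cylindrical segments. Each segment has
the laminar Poiseuille resistance

    R = 8 mu L / (pi r^4)

with blood treated as Newtonian and incompressible (rho = 1060 kg/m^3,
mu = 0.0035 Pa.s). A prescribed volumetric flow Q_in enters at the inlet;
every outlet holds a Dirichlet pressure; Kirchhoff's current law at each
junction closes the sparse symmetric linear system, which is solved exactly.
Per-segment Reynolds numbers, Re = 4 rho |Q| / (pi mu D), verify the laminar
regime (Re <= 2300 everywhere; ~417 at the inlet under baseline conditions).
Pulsatile inflow is treated quasi-steadily: one steady solve per time sample
of a strictly positive harmonic waveform.

The embolization efficiency index of an injection site s is the flow-split
statistic

    EEI(s) = 100% * sum(Q_target downstream of s) / Q(s)

i.e. the percentage of the flow passing s that reaches the target outlets
(retrograde outlet flows are clamped out of the numerator). A *target total
pressure* — the experimental lever for downstream occlusion — is distributed
over the target outlets in direct proportion to their cross-sectional areas.
The package finds the **flow-cessation (stall) pressure** at which the
target branch stops carrying forward flow, by bisection with an exact
closed-form cross-check, and can calibrate a synthetic tree's peripheral
radii so its stall pressure matches a requested value.

Because no patient geometry is distributed, the package ships a seeded
Murray's-law tree generator and a packaged, pre-calibrated synthetic
reference tree: one inlet (4.62 mm diameter), 43 outlets, a target branch at
depth level 5 with 10 target outlets, stall pressure 5000 Pa.

## Worked example

```r
library(emboflow)

tree <- reference_fixture()
tree
#> <vascular_tree> 85 segments, 43 outlets (max depth 11)
#>   inlet: s001 (radius 2.31 mm)
#>   target branch: s067 (depth 5, 10 target outlets)
#>   fluid: rho = 1060 kg/m^3, mu = 0.0035 Pa.s

sol <- solve_steady(tree, boundary_conditions(5e-6))  # 5 cm^3/s, 300 Pa outlets
glance(sol)
#> # A tibble: 1 x 6
#>    time inlet_flow n_segments max_reynolds max_mass_residual n_retrograde
#>   <dbl>      <dbl>      <int>        <dbl>             <dbl>        <int>
#> 1     0   0.000005         85         417.          1.52e-15            0

sweep <- run_pressure_sweep(tree)   # 0, 1000, ..., 5000 Pa target pressure
eei_path <- subset(tidy(sweep, "eei"),
                   segment_id %in% path_to_target(tree) & defined)
tidyr::pivot_wider(eei_path[c("target_pressure", "segment_id", "eei")],
                   names_from = segment_id, values_from = eei)
#> # A tibble: 6 x 6
#>   target_pressure  s001  s003  s011  s035  s067
#>             <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1               0 30.0  39.8  48.4  60.0    100
#> 2            1000 24.0  32.4  40.0  51.1    100
#> 3            2000 18.1  24.7  31.1  40.9    100
#> 4            3000 12.2  16.9  21.6  29.4    100
#> 5            4000  6.59  9.28 12.1  17.1    100
#> 6            5000  2.75  3.93  5.22  7.73   100

find_stall_pressure(tree, boundary_conditions(5e-6))
#> [1] 4999.512

run_inflow_sweep(tree, inlet_scales = c(0.5, 1, 2))$invariance
#> $max_delta_eei
#> [1] 8.526513e-13
#> $pass
#> [1] TRUE
```

Reading the table: each column is an injection site along the inlet-to-target
path (s001 is the inlet, s067 the target branch). EEI rises toward the target
at every pressure — superselective catheter placement pays off — and falls
as the target outlet pressure rises, down to flow cessation near 5000 Pa.
The inflow sweep shows the counterpart null result: with uniform outlet
pressures, scaling the inlet flow changes the EEI map by ~1e-13 percentage
points, i.e. not at all.

`run_backflow_study()` adds the pulsatile picture: when the target pressure
exceeds the instantaneous stall pressure at the diastolic waveform minimum,
the target branch spends part of each cardiac cycle in retrograde flow — the
network surrogate for embolic reflux risk. `report()` writes the CSV tables,
a JSON summary and the standard figures for a run.

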