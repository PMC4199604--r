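# shmoolysis

Steady-state diffusion of cell-wall-remodeling enzymes in mating yeast,
and a synthetic population simulator for pheromone-induced osmotic lysis.

## The problem

During mating, a pheromone-stimulated yeast cell grows a shmoo and secretes
wall-degrading enzymes (glucanases) at its tip so that two partners can
dissolve the wall between them and fuse. The same enzymes are dangerous: a
cell that degrades its own wall without a partner's wall behind it lyses
under turgor pressure. Why does wall dissolution happen only at a contact
site?

The model this package implements answers with geometry alone. Enzymes in
the wall of a **free** cell escape straight through the wall thickness
(taken as the length unit, h = 0.1 µm) into the surrounding medium — an
infinite sink — giving a linear concentration profile with surface value
*J/D* and depth mean *J/2D* (*J* the secretion flux density, *D* the
in-wall diffusion coefficient; all concentrations are reported in *J/D*
units). Enzymes under an **apposed** contact patch (radius r_max = 10 wall
thicknesses ≈ 1 µm) must diffuse radially to the rim of the patch. With a
uniform source disc of radius r_s = 2.5, flux balance through each circle
gives the piecewise steady profile with drops

    C_s = J r_s² / (4D)              (across the secretion disc)
    C_d = J r_s² / (2D) · ln(r_max/r_s)   (across the annulus)

so the contact-center concentration is C_tot = C_s + C_d = 5.89 J/D —
about 11.8× the free-cell wall mean. Apposition alone concentrates
wall-degrading activity more than tenfold, enough to flip a safe cell into
a self-lysing one.

The package provides:

* the closed forms (`apposed_drops()`, `enhancement_ratio()`,
  `profile_table()`, ...);
* two independent oracles — cell-centered finite-volume solvers (1-D slab,
  axisymmetric radial, depth-resolved r–z, and a transient) and a Brownian
  random-walk occupancy/first-passage estimator — that validate the closed
  forms without sharing any machinery with them;
* a synthetic lysis-population simulator (`simulate_population()`) in which
  each cell's contact geometry sets its local enzyme concentration and a
  threshold breach-plus-osmotic-lysis rule (a documented model extension)
  emulates the confinement, pheromone-dose, sorbitol and deletion-mutant
  experiments qualitatively.

## Worked example

```r
library(shmoolysis)

apposed_drops()
#> apposed_solution: C_s = 1.5625, C_d = 4.3322, C_tot = 5.8947 (J/D units)
enhancement_ratio()
#> [1] 11.78934

# independent finite-volume check, 1024 cells
fd <- solve_steady_radial(wall_geometry(), radial_grid(1024, 10))
fd$profile$concentration[1]
#> [1] 5.894674

# synthetic cohorts: flow-chamber confinement vs bulk culture
flow <- simulate_population(1000, make_condition("flow"), seed = 1)
bulk <- simulate_population(1000, make_condition("bulk"), seed = 1)
fraction_dead(flow, 300); fraction_dead(bulk, 300)
#> [1] 0.934
#> [1] 0.014
```

The first three numbers are the model's headline result: the concentration
drop across the secretion disc (1.56 J/D), across the annulus (4.33 J/D),
and their total (5.89 J/D), reproduced by the solver to 5 significant
figures. The cohort fractions illustrate the qualitative prediction the
population simulator is calibrated to: enforced contact with two surfaces
kills most arrested cells within five hours, while free cells mostly
survive.

The numbered scripts under `analysis/` run the full study: closed-form
profiles (`01`), solver validation and mesh convergence (`02`), the
particle-oracle cross-check (`03`), and the synthetic population
experiments (`04`). Each writes its tables under `results/`.

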