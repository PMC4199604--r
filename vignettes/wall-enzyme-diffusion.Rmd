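---
title: "Enzyme diffusion in the apposed cell wall: model, oracles, and the synthetic lysis population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enzyme diffusion in the apposed cell wall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shmoolysis)
```

## The physical picture

A pheromone-stimulated haploid yeast cell polarizes its secretory machinery
toward the shmoo tip, where vesicles deliver cell-wall-remodeling enzymes
(glucanases such as Scw4 and Scw11) into the wall. What happens to those
enzymes next depends entirely on what the tip touches.

* **Free cell.** The wall (thickness $h \approx 0.1\,\mu m$) faces aqueous
  medium, which is effectively an infinite sink. Enzymes escape by diffusing
  straight through the wall thickness.
* **Apposed cell.** When the tip is pressed against an impermeable surface —
  a mating partner's wall held by agglutinins, a ConA-coated coverslip, a
  flow-chamber ceiling — enzymes secreted under the contact patch can leave
  only by diffusing *radially*, in the plane of the wall, out to the rim of
  the patch. The longer escape path concentrates them.

All lengths are nondimensionalized by the wall thickness $h$ and all
concentrations are reported as multiples of $J/D$, where $J$ is the
secretion flux density (enzymes per membrane area per time) and $D$ the
diffusion coefficient inside the wall. Neither $J$ nor $D$ is known
separately for the yeast wall, but every model output is a pure multiple of
$J/D$ (and is tested to be invariant under $(J, D) \to (kJ, kD)$), so no
absolute calibration is needed. Times, where they appear, are in units of
$h^2/D$.

## Closed forms

**Unapposed.** At steady state the flux through every depth is $J$, so the
profile is linear: $C(x) = (J/D)(1-x)$ with $C(0) = J/D$ at the membrane
and $C(1) = 0$ at the sink. The depth-mean concentration is $J/2D$.

**Apposed.** The wall sheet under the contact patch has both faces
reflecting (membrane below, impermeable surface above), so the
concentration is uniform across the depth and the problem is
two-dimensional and axisymmetric. Secretion is a uniform areal flux $J$
over the disc $r \le r_s$ (default $r_s = 2.5$, i.e. $0.25\,\mu m$); the
rim of the apposed patch at $r_{max}$ (default $10$, i.e. $1\,\mu m$) is
absorbing. Flux balance through the circle of radius $r$ —
$-D\,C'(r)\,2\pi r = \pi \min(r, r_s)^2 J$ — integrates to

$$
C_s = \frac{J r_s^2}{4D}, \qquad
C_d = \frac{J r_s^2}{2D}\,\ln\frac{r_{max}}{r_s},
$$

the drops across the secretion disc and across the source-free annulus.
With the default geometry:

```{r}
apposed_drops()
enhancement_ratio()
```

$C_{tot} = C_s + C_d = 5.89\,J/D$ is the concentration at the contact
center, about $11.8\times$ the depth-mean of the free-cell wall. The
piecewise profile is continuous and differentiable at $r_s$ (both one-sided
derivatives equal $-J r_s/2D$) and strictly decreasing.

## Why two independent oracles

The closed forms were reconstructed from the flux-balance argument, so the
package validates them twice, by methods that share nothing with each other
or with the algebra:

1. **Finite volumes** (`solve_steady_slab()`, `solve_steady_radial()`,
   `solve_steady_rz()`, `solve_transient_radial()`). Cell-centered in $r$
   with face fluxes, which keeps the $r = 0$ singularity off the grid and
   makes conservation exact discretely; the cell cut by $r_s$ receives the
   source weighted by its covered area fraction, which preserves
   second-order convergence across the source discontinuity. Steady
   problems use a direct banded solve (residual $\le 10^{-10}$); the
   acceptance tolerance against the closed form is 0.5% at 1024 cells,
   comfortably above the $\sim 10^{-5}$ discretization error and far below
   any plausible implementation bug. The $(r,z)$ solver checks the
   depth-averaging assumption itself: with a reflecting contact face the
   depth variation at the center is under 8% at the default aspect ratio,
   and the depth average reproduces the 2-D radial solution (exactly so in
   the continuum limit, because integrating over depth removes the axial
   fluxes).
2. **Brownian walkers** (`simulate_residence()`, `occupancy_profile()`).
   Isotropic Gaussian steps of per-axis sd $\sqrt{2\,dt}$, uniform
   injection over the source disc, absorption at the rim. The stationary
   occupancy per annular bin, normalized by bin area and injection rate,
   estimates $C$ in $J/D$ units; the mean first-passage time must equal
   $\int C\,dA / (\pi r_s^2 J)$ by Little's law (about $24.2\,h^2/D$ at
   defaults).

Numerical choices for the walk that matter:

* Absorption is only checked at step ends, which is known to push the
  effective absorbing boundary outward by $0.5826\,\sigma$ per step sd
  $\sigma$ (the Broadie–Glasserman–Gobet continuity correction). We apply
  the correction by absorbing at $r_{max} - 0.5826\sqrt{2\,dt}$; without it
  the $O(\sqrt{dt})$ bias is visible in both the residence time and the
  outer occupancy bins at any practical $dt$. Bin averages are taken over
  the corrected support so the estimator and its analytic reference
  describe the same region. The default $dt = 0.02$ keeps the residual
  $O(dt)$ bias below the Monte-Carlo noise at $10^4$ particles.
* The occupancy estimator realizes the stationary state directly:
  continuous Poisson injection at the physical rate $\pi r_s^2 J$, a
  burn-in of five mean residence times, then time-averaged bin counts over
  a window of at least twelve residence times. Standard errors come from
  batch means (16 batches) inflated by the pooled lag-1 autocorrelation
  factor $\sqrt{(1+\rho)/(1-\rho)}$ — successive batches remain correlated
  through the slowly fluctuating total particle count, and ignoring that
  understates the error roughly twofold.
* One root seed drives the single serial RNG stream, so identical
  configurations give bit-identical output; the package does not
  parallelize the walk.

## The synthetic lysis population

The wet-lab observable is cell death. The diffusion model supplies only a
local steady enzyme concentration; everything that turns concentration into
death is a **model extension, not derived content**, and is labelled so in
the function documentation. The rule (`simulate_population()`):

* **Local concentration.** Per cell, the condition's contact geometry picks
  the formula: bulk culture — unapposed, $C = J_{\mathrm{eff}}/D$; ConA
  coverslip — one attached surface, apposed disc with half the flow-chamber
  contact radius ($r_{max} = 5$); flow chamber — confinement, full contact
  ($r_{max} = 10$). Whether ConA attachment truly creates a diffusion
  barrier is not established; treating it as an intermediate contact radius
  is a modeling choice, flagged here.
* **Dose map.** Higher pheromone dose gives tighter polarization (smaller
  effective source disc, from 4.0 wall thicknesses at 5 nM to 2.5 at 50 nM)
  and more secretion (saturating from 0 at 0 nM to 1 at 50 nM). Total
  secretion is conserved when the disc shrinks, so the areal flux scales as
  $(2.5/r_s^{\mathrm{eff}})^2$ — tighter polarization concentrates the same
  enzyme output. Both maps are invented monotone parameterizations.
* **Heterogeneity.** Lognormal per-cell secretion multiplier (geometric SD
  1.3) and lognormal per-cell breach threshold (median 1.7 $J/D$, geometric
  SD 1.8, representing wall-strength variation). The threshold median sits
  above the free-cell surface concentration ($1\,J/D$), so a baseline
  unattached shmoo does not self-lyse; the spread produces graded rather
  than all-or-none death fractions. Shmoo onset is gamma-distributed
  (shape 8, mean 60 min).
* **Breach.** After onset, damage accumulates at rate
  $\max(0, C - \theta)$; the wall is breached when the accumulated excess
  exceeds the integrity capacity (200 $J/D\cdot$min).
* **Lysis.** At each 10-minute imaging frame a breached, living cell lyses
  with probability $1/(1 + e^{-k(\Delta\Pi - \Pi_0)})$ ($k = 10$,
  $\Pi_0 = 0.6$); the osmotic differential $\Delta\Pi$ is 1 in plain medium
  and 0.1 in 1 M sorbitol. Sorbitol therefore suppresses lysis without
  touching breach, which is what makes the wash-out protocol produce a
  burst: breached-but-supported cells accumulate for five hours and fail in
  the first frame after the osmoticum is removed.
* **Genotypes.** fus1&Delta;/fus2&Delta; disperse the secretion focus
  (effective disc radius divided by 0.5/0.6/0.35 for the single and double
  deletions); scw4&Delta;/scw11&Delta; scale enzyme activity (0.6 each,
  0.36 combined). The individual multipliers are free parameters — the
  relative contributions of the two glucanases are unknown.

The extension's defaults were calibrated **only** against the qualitative
orderings the emulated experiments establish — flow > ConA > bulk >
benomyl ≈ 0 across confinement regimes, monotone dose response, wash-in
lowering the 80→140-min fold change, a wash-out death burst, and every
deletion preset lowering death relative to wild type — never against
measured percentages, which reflect biology (wall synthesis, repair,
signaling feedback) the model does not contain. Passing these tests shows
the mechanism is qualitatively sufficient, not that the simulator is
quantitatively predictive.

```{r}
cond <- make_condition("flow")
rec <- simulate_population(500, cond, seed = 1)
fraction_dead(rec, 300)
head(population_summary(rec, 300))
```

What the generator deliberately does not emulate: cell–cell variation in
contact geometry within a condition, wall repair and the hyperosmotic
response, two-cell prezygote fusion, spatial pheromone gradients, and any
imaging noise. Death between frames is reported at the next frame,
mirroring the 10-minute imaging cadence.

## Degenerate inputs and tie-breaks

* $r_s = r_{max}$: the annulus vanishes, $C_d = 0$, and the radial solver
  reduces to the parabolic full-disc solution $(J/4D)(r_{max}^2 - r^2)$.
* $J = 0$: all profiles identically zero; the enhancement ratio is an
  error (undefined), not `NaN`.
* $\theta = \infty$: no cell ever breaches, in any condition.
* Zero injected particles: zero occupancy with infinite standard errors,
  and z-scores defined as 0 rather than `NaN`.
* `fold_change()` with no deaths in the reference window reports `NA` with
  a warning — an undefined ratio, never infinity.
* The between-condition test is Welch's unequal-variance two-sample
  t-test, two-sided, on replicate-level death fractions; plain Student
  pooling is deliberately not used because replicate variances differ
  strongly between near-floor and mid-range conditions.

## Problem sizes

The shipped analyses use 1024 radial cells for solver validation, $10^4$
walkers ($dt = 0.02$) for the stochastic cross-check, and cohorts of 1000
cells over 5 seeds per condition for the population runs; those sizes put
discretization error around $10^{-5}$ relative, Monte-Carlo bin errors
around 2–4%, and between-seed SDs of death fractions under one percentage
point, while keeping any single script or the full test suite in the
seconds-to-minutes range on one CPU.
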