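Package: shmoolysis
Title: Steady-State Diffusion of Cell-Wall-Remodeling Enzymes in Mating Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Closed-form steady-state concentration profiles for cell-wall
    remodeling enzymes secreted by pheromone-stimulated yeast, for cells
    free in solution and cells apposed to an impermeable surface.  Includes
    independent finite-volume and Brownian random-walk oracles for the
    closed forms, and a population-level osmotic-lysis simulator that
    generates synthetic cohorts of arrested cells under confinement,
    pheromone-dose, osmolarity and deletion-mutant regimes.  All
    concentrations are reported in multiples of the secretion flux over the
    wall diffusion coefficient (J/D); all lengths in wall-thickness units.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
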