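Package: cgdelta
Title: Coarse-Graining Water Molecules into One-Site Solvent Particles on
    Quadratic Potential-Energy Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reduces a protein-water second-order potential-energy surface by
    eliminating the relative displacements of water hydrogens from their water
    centers through a mass-weighted stationarity condition (a Schur-complement
    reduction that remains valid away from energy minima).  Extracts effective
    pairwise forces and spring constants between atoms and one-site solvent
    particles, decomposes them into direct (atom-oxygen, atom-hydrogen,
    electrostatic and van der Waals) and indirect (collective hydrogen
    dynamics) components, computes distance-binned trimmed interaction
    profiles, a per-atom hydrophilic degree (separation energy), and
    eigenmode-based motion correlations with exponential decay-ratio fits.
    Includes a minimal molecular-mechanics engine (Coulomb, 12-6
    Lennard-Jones, harmonic bonds and angles, analytic forces and Hessians),
    Tinker-style XYZ and minimal PDB readers, and seeded generators for rigid
    TIP3P water droplets sampled by Metropolis Monte Carlo at 298 K.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
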