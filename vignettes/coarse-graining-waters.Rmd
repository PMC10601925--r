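---
title: "Coarse-graining waters on quadratic energy surfaces: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-graining waters on quadratic energy surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cgdelta)
```

## The model

A solute/water system at a fixed conformation has a potential energy surface
that `cgdelta` approximates to second order in the atomic displacements
$\delta$:

$$V(\delta) = V_0 - \mathbf{f}^\top \delta + \tfrac12\,\delta^\top \mathbf{H}\,\delta,$$

where $\mathbf{f}$ is the force vector (the negative gradient — the
conformation need *not* be a minimum) and $\mathbf{H}$ the Hessian of a
standard molecular-mechanics force field (Coulomb, 12-6 Lennard-Jones with
Lorentz–Berthelot combination on $(r_{min}/2, \varepsilon)$, harmonic bonds
and angles; 1-2 and 1-3 nonbonded exclusions; no dihedrals).

The displacements are then re-expressed per water as the displacement of the
*water center* — fixed to the oxygen site, so the relative oxygen
displacement vanishes identically and is dropped — plus the relative
displacements $\Delta_1, \Delta_2$ of the two hydrogens from that center.
Solvent rows of the transformed force vector are sums of the member-site
forces, and solvent Hessian blocks are sums over the member-site blocks; the
transformation is linear and exact (`aggregate_blocks()` reproduces the
original surface to machine precision, which the tests assert on random
quadratic systems).

The reduction eliminates $\Delta_{12} = (\Delta_1, \Delta_2)$ by requiring
the gradient of $V$ with respect to the mass-weighted hydrogen coordinates
to vanish — the hydrogens instantaneously relax so that no energy is
exchanged with the eliminated coordinates.  Substituting the stationary
response

$$\Delta_{12}^\ast = \mathbf{H}_{12,12}^{-1}\left(\mathbf{f}_{12} - \mathbf{H}_{12,ps}\,\delta_{ps}\right)$$

back into the quadratic form gives an effective surface over solute atoms
and one-site solvent particles with

$$\mathbf{H}' = \mathbf{H}_{ps,ps} - \mathbf{H}_{ps,12}\mathbf{H}_{12,12}^{-1}\mathbf{H}_{12,ps},
\qquad
\mathbf{f}' = \mathbf{f}_{ps} - \mathbf{H}_{ps,12}\mathbf{H}_{12,12}^{-1}\mathbf{f}_{12},
\qquad
V_0' = V_0 - \tfrac12\,\mathbf{f}_{12}^\top\mathbf{H}_{12,12}^{-1}\mathbf{f}_{12}.$$

$\mathbf{H}'$ is the Schur complement familiar from normal-mode model
reduction; with $\mathbf{f} = 0$ the reduction *is* that classical
reduction, which the tests verify against an independently written textbook
formula.  The closed forms above were derived by completing the square and
are pinned uniquely by a surface-equality oracle: for any $\delta_{ps}$,
evaluating the coarse surface must equal evaluating the full reduced-variable
surface at $(\delta_{ps}, \Delta_{12}^\ast)$.  The $V_0'$ correction never
affects forces or spring constants and is reported as a diagnostic only.

## Pairwise forces and the five components

The coarse force $\mathbf{f}'$ decomposes into a pairwise force matrix with
a *direct* part — the summed all-atom pair forces between two units, which
is exactly antisymmetric — and an *indirect* part
$-\mathbf{H}_{ps,12}\mathbf{H}_{12,12}^{-1}\mathbf{F}_{12\leftarrow ps}$
mediated by the collective hydrogen dynamics, which is **not** antisymmetric:
coarse-graining breaks the antisymmetry of nonbonded pair forces.  The
package asserts both facts exactly and restores antisymmetry by averaging,

$$[\mathbf{F}'']_{i,j} = [\mathbf{F}_{direct}]_{i,j} + \tfrac12\left([\Delta\mathbf{F}']_{i,j} - [\Delta\mathbf{F}']_{j,i}\right),$$

Each atom–solvent entry (force and 3×3 spring block alike) splits into five
components: `o_elec`, `o_vdw` (atom–oxygen electrostatic / van der Waals),
`h_elec`, `h_vdw` (atom–both-hydrogens), and `s_indir` (the
collective-hydrogen term).  The five parts sum to the full entry to 1e-9,
enforced entrywise in the tests.

Effective scalars project onto the inter-unit direction
$\hat r = (x_i - x_j)/r$, so a positive effective force is repulsive.  The
effective spring constant is the projected off-diagonal Hessian block,
$k_{ij} = \hat r^\top [\mathbf{H}']_{i,j}\,\hat r$; for an isolated pair
potential this makes $k_{ij} = \mathrm{d}f_{ij}/\mathrm{d}r$, so the
spring-integrated approximated force uses a $+1$ sign,
$\hat f(x) = \int_{x_{min}}^{x} k + g$.  The Coulomb-pair oracle in the test
suite fixes this sign convention numerically.

## Angle-term pair attribution

A harmonic angle is a three-body term.  Its end-atom forces are attributed
to the (end, vertex) pairs and zero force to the (end, end) pair, which
keeps per-term antisymmetry and reassembles the total force exactly; the
(end, end) Hessian coupling block is kept as a genuine pair block.  Only
intra-water pairs are affected, and those never enter profiled records.

## Profiles, the hydrophilic degree, and correlations

Records are kept for atom–solvent and solvent–solvent pairs within 12 Å
(center-to-center).  Profiles bin by distance in 0.1 Å half-open bins
centered on the grid; per-bin means and standard deviations use only values
between the 5th and 95th percentiles (outlier trimming), while the reported
10/25/75/90 percentiles are computed untrimmed — the most literal reading of
the procedure, noted here because trimming-before-percentiles is the other
defensible order.  Bins with fewer than 25 records are masked, and the
profile grid starts at the first unmasked bin.

The hydrophilic degree of an atom type is the separation energy: the
averaged area of the negative regions of the mean effective force curve and
of its spring-integrated approximation, up to 12 Å.  The offset $g$ of the
approximated force makes its average vanish over 8–12 Å (where the true
interaction has decayed); the classification threshold defaults to
0.1 kcal/mol, with 3.0 marking the strongly hydrophilic atoms.

Motion correlations come from the mass-weighted eigenmodes of
$\mathbf{H}'$ (solvent-particle mass = full water mass).  The six
smallest-magnitude modes (rigid body) are excluded; remaining modes are
weighted by $1/|\lambda|$.  Unstable (negative-$\lambda$) modes thus
contribute through their magnitude — the unique weighting that keeps the
self-covariance positive so the normalization is well defined; a
`zero_count` argument and the weighting are the configurable knobs.  The
decay ratio fits $\ln(y - b)$ against distance over 5–10 Å and reports
`exp(slope)`; the baseline $b$ defaults to zero and can be supplied for
systems whose correlation plateaus away from zero (see below).

## The synthetic ensembles

The generator builds droplets of rigid ideal-geometry TIP3P waters
(O–H 0.9572 Å, H–O–H 104.52°, charges −0.834/+0.417 e) at the liquid number
density 0.0334 Å⁻³, with optional fixed probe particles at the center, and
samples them by Metropolis Monte Carlo at 298 K with rigid-body water moves
(0.2 Å translations, 0.35 rad rotations; acceptance ≈ 0.4).  A flat-bottom
spherical restraint on the oxygens prevents evaporation during sampling and
is deliberately excluded from the analysis-stage Hessian.  Monte Carlo
replaces a molecular-dynamics stage because the analysis needs only
Boltzmann-weighted conformations, not dynamics.  Waters are rigid while
sampling; the analysis-stage expansion adds flexible CHARMM-style internal
terms (bond 450 kcal/mol/Å², angle 55 kcal/mol/rad²) so that the hydrogen
block of the Hessian is invertible — at the rigid ideal geometry the
internal terms contribute stiffness but no force.  Truncation also differs
by stage: sampling uses a C² quintic switch from 7.8 Å to zero at 12 Å (a
smoothstep rather than the classic switching polynomial, so that analytic
Hessians match finite differences even inside the switching region), while
analysis evaluates interactions untruncated to avoid cutoff artifacts.

Reference study conditions, chosen once: the solvent-structure experiment
uses 100 waters, 300 burn-in sweeps, 200 frames every 5 sweeps; the probe
experiments use 80 waters and 300 frames around a methine-carbon-like probe
(ε = 0.02 kcal/mol, r_min/2 = 2.275 Å) that is either neutral or carries
+0.5 e.  These sizes keep a full run in minutes on one core while giving
roughly 10³ records per 0.1 Å bin in the first shell.

```{r, eval = FALSE}
water <- solvent_structure_experiment(seed = 1)
water$r_min          # first-shell minimum of the effective pair potential
neutral <- probe_hydrophilicity_experiment(seed = 2, charge = 0)
charged <- probe_hydrophilicity_experiment(seed = 3, charge = 0.5)
c(neutral$result$degree, charged$result$degree)
```

## What the droplet does and does not emulate

The droplets reproduce liquid-like local structure: the O–O first peak falls
in 2.6–2.9 Å and the integrated solvent–solvent effective pair potential has
its first-shell minimum at 2.7–2.8 Å, matching the radial-distribution
signature of the three-site water model.  A charged probe develops a deep
negative well in its mean effective force (hydrophilic, separation energy
≈ 1–2 kcal/mol under the reference conditions) while the neutral probe stays
below 0.1 kcal/mol; `h_elec` vanishes identically for an uncharged probe, so
the hydrogen-pose physics is exercised only by charged solutes.

They do **not** emulate bulk-scale collective motion.  A free droplet's
mode-weighted displacement covariances must nearly balance across the
system, so the solvent–solvent motion-correlation curve crosses zero around
6–7 Å and plateaus slightly negative — whereas a protein-plus-solvent-layer
system tens of Å across shows a gentle exponential decay (ratio ≈ 0.86/Å)
throughout 5–10 Å.  The decay-ratio experiment therefore subtracts a
baseline estimated from the outermost 1 Å of bins (the paper-model
$y = a\,r^x + b$ with $b$ estimated rather than zero) and still lands near
0.6 per Å at 100 waters, rising with droplet size: a finite-size effect, not
a pipeline defect — the pipeline recovers a planted exponential ratio to
±0.01 in the unit tests.  Results on these droplets transfer to
protein-scale systems only for local (first/second shell) quantities.

Statistical noise is dominated by the indirect component, whose per-record
deviations exceed its mean by orders of magnitude; with ~10³ records per bin
the spring-integrated force estimate of the separation energy carries an
absolute uncertainty of a few tenths of kcal/mol, so classifications near
the 0.1 kcal/mol threshold need larger ensembles.

## Numerical choices

* Hydrogen-block solves use a dense LU factorization; if the reciprocal
  condition estimate drops below 1e-10, an eigendecomposition pseudo-inverse
  in mass-weighted coordinates is used instead, dropping
  $|\lambda| < 10^{-8}\max|\lambda|$ — the mass weighting of the
  stationarity condition is the canonical metric for truncating degenerate
  directions.  The fallback and dropped count are reported per solve.
* An isolated water's hydrogen block is singular (free molecular rotation);
  in droplets, intermolecular electrostatics provides librational stiffness,
  so the plain solve path is the norm.
* Profile bins use `floor(x / w + 0.5 + 1e-9)`: the epsilon keeps exactly
  representable boundary values (3.05 with 0.1 Å bins) in the upper bin, as
  the half-open convention requires.
* Ties in the potential-minimum search (`which.min` on a 0.1 Å grid) resolve
  to the smaller distance; the reported minimum is grid-quantized.

## Limitations

Desk scale targets systems up to a few thousand atoms with dense linear
algebra; there are no periodic boundaries, no Ewald summation, no dihedral
or Urey–Bradley terms, and probes are fixed rather than sampled.  The
hydrophilic degrees of real protein atom types require a solvated-protein
ensemble as input; this package supplies the machinery and validates it on
droplet probes.
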