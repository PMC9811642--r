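---
title: "Methods: calcium-carboxylate association and ACC cluster analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calcium-carboxylate association and ACC cluster analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calcarb)
```

`calcarb` packages the computational layer around metadynamics studies of
Ca²⁺ binding to the carboxylate groups of aspartate/glutamate and of
amorphous calcium carbonate (ACC) cluster formation: Lennard-Jones
parameter refinement, conversion of free-energy profiles into association
constants, and structural trajectory analyses. This vignette records the
models, the tunable parameters, and the design decisions taken where the
underlying procedures left genuine freedom.

## Force-field arithmetic

Homoatomic 12-6 Lennard-Jones parameters are stored in eV and Ångström
(the units of the published calcium parameter tables); constructors accept
kcal/mol because AMBER distributes well depths in those units
(1 kcal/mol = 0.0433641 eV). Heteroatomic pairs follow the
Lorentz–Berthelot rules: arithmetic mean for σ, geometric mean for ε. The
A/B representation is

$$U(r) = \frac{A}{r^{12}} - \frac{B}{r^6}, \qquad A = 4\varepsilon\sigma^{12},
\quad B = 4\varepsilon\sigma^{6}, \quad A/B = \sigma^6 .$$

Two interpretation choices were required:

* **A/B without π.** The comparison table of published calcium
  descriptions is sometimes quoted with a factor 4π in the A and B
  definitions, but the tabulated integers are only reproduced by
  $A = 4\varepsilon\sigma^{12}$ (all twelve rows match exactly after
  rounding). The package therefore computes A and B without π; the
  π-variant is regarded as a typographical slip and is not implemented.
* **"Average" in the Set_3 construction.** The refined calcium
  description (Set_3) is built by averaging the CaCO₃-derived Set_2
  calcium with the AMBER carboxylate oxygen. Interpreting "average" as
  arithmetic for σ and geometric for ε — i.e. the Lorentz–Berthelot
  combination itself — is the only reading that reproduces the published
  Set_3 row (σ = 3.247210 Å, ε = 0.001104240 eV), so `build_set3()`
  implements exactly that.

The AMBER carboxylate-oxygen homoatomic parameters are not part of the
published tables; they are shipped as a documented constant
(`amber_carboxylate_oxygen()`: σ = 2.95992190164468 Å, ε = 0.2100
kcal/mol) recovered by inverting the published mixed values. Because the
published Set_3 row is itself rounded to six decimals, reconstructing it
from these constants agrees to ≈2 × 10⁻⁶ relative rather than exactly;
the 14-decimal heteroatomic σ values, by contrast, are reproduced
bit-for-bit by `scale_sigma()` from the unmodified mixed value
(+0.5 % → 3.11908378057645 Å, +2.0 % → 3.16563726983879 Å).

## From free-energy profile to association constant

A profile $E(r)$ (kJ/mol, distance in nm) along the Ca–carboxylate-carbon
distance is processed as:

1. **Plateau normalization.** The mean of $E$ over 1.0–1.4 nm — where the
   ion pair is fully dissolved — is subtracted, so the dissociated
   plateau averages zero. The operation is idempotent and required before
   any Boltzmann inversion.
2. **Ideal-dilution g(r).** $g(r) = \exp(-E(r)/RT)$ with $R$ the molar
   gas constant (8.314462 J mol⁻¹ K⁻¹). The profile's energies are molar,
   so the molar gas constant is the dimensionally consistent form of the
   Boltzmann factor.
3. **Dissociation boundary.** $R_U$ is the first strict local minimum of
   $g(r)$ beyond the solvent-shared-pair maximum (the last local maximum
   at or below the 0.8 nm hint). Profiles whose tail decays monotonically
   to the plateau have no such minimum; the configured fallback
   (default 1.0 nm, roughly where the ions count as dissolved) is then
   used and flagged in the result.
4. **Radial integration.**
   $K_a = \int_0^{R_U} 4\pi r^2 g(r)\,dr$ by composite trapezoid on the
   native grid, with $g = 0$ below the first grid point (hard-core
   region) and a partial trapezoid when $R_U$ falls between grid points.
   Accuracy is controlled by grid-refinement stability rather than a
   particular quadrature rule: halving the grid of a sharp
   (−20 kJ/mol, width 0.02 nm) well moves ΔG by well under 5 %.
5. **Standard state.** $K_a$ in nm³ is converted to the dimensionless
   1 M standard-state form via $N_A/10^{24}$; this is the quantity
   compared with experimental stability constants, and
   $\Delta G = -RT\ln K_a$ uses it. The conversion convention is the
   standard one; the original comparison to experiment does not state
   its bridge, so this is a documented assumption.

Local minima are reported when they are strict three-point minima at
least 0.5 kJ/mol below the normalized baseline (a prominence floor that
suppresses sampling noise; ties resolve toward smaller r), and are
labelled by distance windows — biCIP < 0.31 nm, monoCIP 0.31–0.40 nm,
SIP 0.40–0.65 nm, SSIP 0.65–0.85 nm, read off the reported minima
positions (0.290, 0.346, 0.513, 0.677 nm) and fully user-overridable.

## Trajectory observables

All analyses use the minimum-image convention in orthorhombic boxes;
positions are in nm throughout, including the extended-XYZ and LAMMPS
dump readers.

* **RDF.** Standard shell-histogram estimator (default bin 0.002 nm)
  with ideal-gas normalization at the partner density; the running
  coordination integral $N(r)$ accumulates the raw histogram. Published
  figures of this kind are B-spline smoothed for display with unstated
  parameters; here smoothing (`smooth_rdf()`) is presentation-only and
  never feeds quantitative use.
* **ADF.** Angle histogram at a vertex species for triplets within two
  cutoffs, normalized to unit area. The hydrogen-bond criterion is not
  fixed by the source procedure; defaults are 0.35 nm (donor–acceptor)
  and 0.12 nm (covalent O–H), both configurable.
* **Local density.** Mean over Ca centers and frames of the whole-ion
  mass within 0.9 nm (center included) divided by the sphere volume, in
  g/cm³, with unit masses Ca 40.078 and CO₃ 60.009 g/mol. Ions are
  counted as units located at Ca or at the carbonate carbon, which makes
  planted-cluster values exactly hand-computable.
* **SASA.** Shrake–Rupley with a deterministic Fibonacci point set
  (default 960 points) on each probe-expanded sphere; a point is exposed
  when outside every other expanded sphere. Neighbors are taken at their
  minimum image, so a finite cluster in a periodic box is treated as the
  compact object with no self-image occlusion. The van der Waals radii
  behind the original SASA numbers are not recoverable; the package
  ships a Bondi-style default table (Ca 0.231, O 0.152, C 0.170,
  N 0.155, H 0.120 nm) and expects an explicit table for
  publication-grade numbers.

## Cluster detection

Ions belong to the same cluster when any two of their atoms lie within
the first-coordination-shell distance of the two species; clusters are
connected components of that contact graph (via `igraph`), labelled
deterministically by the smallest member index. A carbonate contributes
exactly one ion to a cluster size regardless of how many of its atoms
make contact. Only the Ca–O_c cutoff (0.34 nm, the first minimum of the
Ca–O_c RDF) is fixed by the method description; other pair cutoffs
default to "absent = never bonded" and should be supplied from the first
RDF minimum of the pair at hand. Size distributions are ion-weighted by
default (probability that an ion sits in a cluster of size s); the
cluster-count weighting is also available and the two interconvert
exactly through a factor of s.

## Configuration similarity

Starting configurations are flattened to order-invariant vectors by a
greedy chain: anchor at the ion atom nearest the biomolecule's center of
mass, append its minimum-image distances to all unvisited atoms in
ascending order, move to the nearest unvisited atom, repeat. "Distances
to the other atoms" is read as distances to the not-yet-anchored atoms,
sorted — the only reading that makes vectors of equal length comparable
across configurations; the anchor trace is returned for audit. Equal
length is enforced by construction (same ion counts), never by padding.
Vectors are compared with the continuous Tanimoto distance
$d = 1 - a\!\cdot\!b/(|a|^2+|b|^2-a\!\cdot\!b)$.

The acceptance rule for replicate starting configurations is stated in
two contradictory forms in the source material (Tanimoto *distance*
< 0.7 versus *similarity* < 70 %). `accept_pairwise()` implements both
modes and defaults to `similarity_below` — requiring low similarity is
the reading under which the threshold actually guarantees that
configurations differ — while recording the applied mode in its report.

## The metadynamics surrogate

Production free-energy profiles come from full molecular dynamics; the
package's validator is a one-dimensional overdamped Langevin walker on an
analytic Gaussian-well potential, biased with the well-tempered protocol
(hill height 1.0 kJ/mol, width 0.02 nm, deposition every 10 ps, bias
factor γ = 10, upper wall at 1.6 nm, 300 K). This surrogate exercises
every downstream formula — hill bookkeeping, the
$F(s) = -\frac{\gamma}{\gamma-1}V_\mathrm{bias}(s)$ sum-of-hills
estimator, normalization, and the K_a integration — with exactly known
ground truth.

Numerical choices:

* The wall is $\kappa(s-s_\mathrm{wall})^2$ with κ in kJ mol⁻¹ nm⁻²
  (the bare "2000" of the protocol read in PLUMED's default quadratic
  form and unit offset).
* The Euler–Maruyama step must resolve the wall stiffness:
  stability requires $2\kappa D\,\Delta t/RT < 1$, giving
  Δt ≤ 0.006 ps at the default diffusion coefficient D = 0.1 nm²/ps;
  the default is Δt = 0.005 ps. D itself is a free parameter of the
  surrogate and the recovered thermodynamics are insensitive to it.
* A reflecting boundary at 0.05 nm keeps the radial coordinate positive;
  an optional $-2RT\ln s$ Jacobian term lets the model potential stand
  for a 3D pair potential instead of the free energy along s.
* The free-energy estimate uses the sum-of-hills form, time-averaged
  over the second half of the deposition history: the instantaneous
  estimate oscillates around the converged profile by roughly a thermal
  energy, and averaging the running estimate damps that oscillation.
* Because K_a depends exponentially on well depths, single walkers
  recover it only to ≈25 %; the package's validation (and acceptance
  script) averages the profiles of four independent walkers — mirroring
  how replicate production simulations are averaged — which brings the
  recovery comfortably inside that band.

One property of the protocol is worth stating plainly: at convergence
the well-tempered bias flattens every feature it can reach by the factor
γ, including the wall. With κ = 2000 and γ = 10 the region just beyond
the wall (1.6–1.8 nm) therefore retains of order 1 % occupancy — a thin
boundary layer — while the far side stays empty (occupancy beyond
1.85 nm below 10⁻³). Tests assert the bound at the location where it
physically holds.

## Synthetic data: what it does and does not emulate

* **Ion solutions.** 255 Ca²⁺ and 255 rigid planar carbonates
  (D₃ₕ, C–O 0.129 nm — only connectivity and mass matter downstream)
  placed by rejection sampling with a 0.45 nm minimum center separation.
  The production box size is not printed anywhere; the default edge
  (≈7.79 nm) is derived from 15831 water molecules at 1 g/cm³ and gives
  the quoted 0.89 M calcium concentration. Explicit water is *not*
  generated: it served the MD engine, which is out of scope here; water
  enters only through the SASA probe radius and the volume bookkeeping.
* **Planted clusters.** Grown by random sequential attachment at 0.9 ×
  the contact distance inside a compact ball, with groups spaced so the
  contact graph provably equals the planted partition — the ground truth
  used to test the cluster scanner.
* **Profiles.** Sums of Gaussian wells at the canonical ion-pair
  positions, optionally with noise. Real profiles additionally carry
  inter-well barriers and sampling artefacts; synthetic ones return
  exactly to baseline, which is why the dissociation-boundary fallback
  exists.

Passing tests on these generators therefore demonstrates the correctness
of the estimators and bookkeeping, not the physics of real ACC
trajectories: cluster-size magnitudes (hundreds of ions), SASA decay
percentages and absolute densities of production simulations require the
full MD and are only checked for qualitative ordering on planted-growth
fixtures (earlier aggregation but smaller final clusters, and weaker
SASA decay, in biomolecule-doped systems).

## Problem sizes

The test suite runs ideal-gas RDF checks at 400–500 particles over
30–50 frames, cluster-oracle sweeps over 100 random frames of up to 200
ions, and metadynamics validations of 10⁶–1.6 × 10⁷ Langevin steps
(seconds to about a minute each); the acceptance script's four-walker
recovery uses 4 × 4 × 10⁶ steps. These sizes were chosen so every check
carries statistical weight while the whole suite stays interactive.

## Known limitations

* Orthorhombic boxes only; no triclinic cells, no velocity-dependent
  observables.
* The association pipeline assumes infinite dilution of the ion pair
  (no activity corrections) and a one-dimensional collective variable;
  two-variable landscapes are out of scope.
* The metadynamics surrogate is not an MD engine: it validates the
  estimator chain, not force-field dynamics, water structure or
  multi-dimensional association mechanisms.
* Binary trajectory formats are not read; convert to extended XYZ or a
  text LAMMPS dump first.
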