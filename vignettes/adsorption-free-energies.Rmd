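---
title: "Estimating adsorption free energies at nanosurfaces with nanosorb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating adsorption free energies at nanosurfaces with nanosorb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanosorb)
```

## The problem

How strongly does a small biomolecule stick to an inorganic nanosurface?
The standard computational answer is the adsorption free energy
$\Delta G_\mathrm{ads}$, the free-energy difference between the molecule
bound in a thin layer at the surface and the molecule free in bulk
solution.  It is obtained from the potential of mean force (PMF)
$W(s)$ along a surface separation coordinate $s$:

$$ W(s) = -k_B T \,\ln\frac{\rho(s)}{\rho(s\to\infty)}, \qquad
   \Delta G_\mathrm{ads}
   = -k_B T \,\ln\!\Big(\frac{1}{\delta}
     \int_{r_c}^{r_c+\delta} e^{-W(s)/k_BT}\, ds\Big), $$

where $r_c$ is the closest approach and $\delta$ the thickness of the
adsorption layer, delimited by where $W(s)$ returns to zero.  Because
bound states can be separated from the bulk by barriers much larger than
$k_BT$, plain equilibrium sampling does not converge; the package
therefore implements metadynamics along the surface separation distance
(SSD) — the minimum distance between the sorbate's centre of mass and
the nearest surface atom — and recovers $W(s)$ by integrating the binned
average of the *bias-excluded* force along the coordinate,

$$ W(s) = \int_{s_n}^{s} \langle F(s')\rangle \, ds' + C, \qquad
   F = \frac{\nabla s \cdot \mathbf{F}_\mathrm{sys}}{|\nabla s|^2}, $$

which converges faster and more stably than reconstructing $W$ from the
accumulated bias itself.

The package covers the full desk-scale workflow around this estimator
for zinc-blende ZnS nanomaterials: structure construction, a bonded
force field, molecular dynamics with metadynamics, free-energy
post-processing and interfacial-structure analysis — with synthetic
systems whose exact answers are known, so that every stage is testable.

## Structures

Zinc-blende ZnS is built by replicating the conventional cubic cell
(4 Zn + 4 S).  The (110) cleavage — the stable, non-polar surface — is
generated as a slab periodic in $x$ and $y$ and open in $z$, with
$n_x$ repeats of length $a$ along the $[001]$-type axis, $n_y$ repeats
of $a\sqrt2$ along $[\bar110]$, and $n_\mathrm{layers}$ atomic layers of
spacing $a/(2\sqrt2)$, each holding 2 Zn + 2 S per surface cell:

```{r slab}
slab <- build_slab_110(lattice_spec(5.41), 8, 6, 14)
slab
```

The lattice constant is not part of the shipped parameter table; the
default $a = 5.41\ \mathring{A}$ is the standard room-temperature value
for zinc-blende ZnS and is configurable everywhere.

Spherical nanoparticles are carved from the replicated lattice and
single-coordinated atoms are removed in one pass (`iterate = TRUE`
prunes to a fixpoint instead).  Carved spheres are only stoichiometric
and charge-neutral for symmetric cut centres;
`nanoparticle_center_scan()` searches the high-symmetry candidates
(atom sites, bond midpoint, tetrahedral hole) and reports counts and net
charge, which is how the shipped 2-nm fixture (bond-midpoint centre,
196 atoms, neutral) was selected.  Bonded topology is derived
geometrically: all unlike-species pairs within a cutoff of 2.9 A —
between the first (2.34 A) and second (3.83 A) neighbour shells — are
bonds, all bonded triples around an apex are angles, and atoms with
fewer than 4 unlike neighbours are flagged as surface atoms.

## The bonded force field

The reference interaction model for ZnS treats Zn–S as non-bonded
(Buckingham + Coulomb with formal charges $\pm 2e$).  For stable
desk-scale dynamics the package follows the bonded reformulation: the
total Zn–S pair potential is refitted by a harmonic bond over the window
of physical bond lengths (2.0–2.5 A), and the three-body term by a
harmonic angle at the crystal S–S distance (3.4 A).
`fit_harmonic_bond()` and `fit_harmonic_angle()` implement the
least-squares fits on a dense uniform grid (512 points, constant offset
fitted and discarded) and accept any tabulated curve, since the
reference model's own parameters are inputs, not package constants.

The shipped parameter set (`default_zns_forcefield()`) carries the
published constants: Zn–S bond (92,000, $r_0 = 1.6$ A), S–Zn–S and
Zn–S–Zn angles (274.022 kJ/mol/rad², 109.47°), per-species LJ
parameters, and special surface-Zn/OC and surface-S/OC Lennard-Jones
pairs for carbonyl oxygens of a PMMA coating.  Two numerical points
deserve emphasis:

* **Bond-constant units.**  The published table prints the bond constant
  as "92,000 kJ/mol" with no length unit.  Read per nm² (the native unit
  of the MD engine the model was built for), the bond tension of the
  resulting stretched-spring network ($r_0 = 1.6$ A is well below the
  crystal bond length of 2.34 A) is of the same order as the non-bonded
  like-charge repulsion it balances, and the crystal is mechanically
  stable — the package verifies that a reduced (110) slab holds
  heavy-atom RMSD ≤ 0.4 A over 20 ps at 300 K.  Read per A², the
  network collapses.  The per-nm² reading is therefore the default,
  with `kb_units = "kJ/mol/A2"` available for the literal reading.
* **Surface atoms** for the special LJ pairs are defined as atoms of
  coordination < 4, since the published footnote does not define
  "surface".

Unlike-pair LJ parameters follow Lorentz–Berthelot mixing
($\sigma_{ij}$ arithmetic, $\epsilon_{ij}$ geometric), with special
pairs taking precedence.  Electrostatic and LJ interactions are excluded
between bonded atoms (1–3 exclusion across angles is available behind a
flag).  Desk-scale electrostatics uses a shifted-force Coulomb sum at a
1.4-nm cutoff rather than a mesh Ewald method — a documented deviation
appropriate for the package's system sizes; a bare truncated sum
(`coulomb = "plain"`) serves as a direct all-pairs sum for non-periodic
toys.

```{r lb}
zn <- list(species = "Zn", sigma = 3.816, epsilon = 0.022)
s  <- list(species = "S",  sigma = 4.27,  epsilon = 1.087)
unlist(lorentz_berthelot(zn, s))
```

## Dynamics

The engine (compiled, velocity-Verlet) supports energy minimisation by
adaptive-step steepest descent, NVE, velocity-rescale NVT (coupling time
1 ps by default, matching the reference protocol) and Langevin (BAOAB)
dynamics, frozen-atom and per-axis mobility masks, and a neighbour list
rebuilt every 10 steps with a 2-A skin.  The default timestep is 1 fs.
There is deliberately no barostat, no constraint algorithm and no mesh
electrostatics: the engine exists to exercise the estimators on reduced
systems, not to replicate microsecond solvated production runs.  Given
identical seed and configuration, trajectories are bit-identical.

Model validation mirrors the published stability check at reduced size:
a 4×3-cell, 8-layer slab (384 atoms) is minimised and run for 20 ps at
300 K, and the RMSD from the ideal crystal (translation removed; optimal
rigid superposition available via Kabsch) stays below 0.4 A — in
practice around 0.17 A, dominated by surface relaxation.

## Metadynamics and the mean-force PMF

The SSD collective variable is implemented as a soft minimum
$s = -\beta^{-1}\ln\sum_i e^{-\beta d_i}$ over the sorbate-COM-to-
surface-atom distances so its gradient is continuous; $\beta$ defaults
to 200 nm⁻¹ for dynamics (the soft minimum is within $10^{-3}$ nm of the
hard minimum on well-separated configurations and is always a lower
bound), with the hard minimum available for post-hoc analysis.

Gaussian bias is deposited along $s$ with the published protocol
defaults: height $\omega = 0.01$ kJ/mol every $\tau = 1$ ps.  The two
printed width values disagree between sections (0.05 A vs 0.05 nm);
0.05 nm is the physically sensible CV-scale value and is the default.
A one-sided quartic wall $\kappa (s-a)^4$ with $a = 1.5$ nm and
$\kappa = 40$ kJ mol⁻¹ A⁻⁴ confines the sorbate near the surface (the
printed functional form is two-sided; the accompanying text calls it an
upper wall, so one-sided is the default with `two_sided_wall`
available).

At every step the instantaneous *unbiased* generalised force
$(\nabla s \cdot \mathbf F_\mathrm{sys})/|\nabla s|^2$ (bias and wall
excluded) is accumulated into bins of width $\sigma_G/2$; the PMF is the
inward trapezoidal integral of the binned means.  Numerical choices:

* the first 1/6 of the run is excluded from force averaging (mirroring
  the 50-of-300-ns burn-in of the reference protocol), and the remainder
  is split into blocks (5 by default) for block-error estimates;
* interior gaps of at most 2 empty bins are bridged by linear
  interpolation of the mean force and flagged; larger gaps raise an
  "unconverged sampling" error rather than silently interpolating;
* the PMF zero is the mean over the outer quarter of the occupied range
  (excluding the two outermost bins): referencing to a single edge bin
  would inherit both its statistical noise and any perturbation from the
  wall-turnaround region, which is visibly non-equilibrium for flexible
  sorbates;
* the binning resolution and the instantaneous-force estimator are not
  specified in the reference protocol; both choices above are the
  package's own.

## Free-energy post-processing

`find_binding_region()` locates $r_c$ (smallest $s$ with defined $W$),
the PMF minima (plateau-aware, so square-well test fixtures behave), and
the layer edge $r_c+\delta$ — the first point at or beyond the last
bound minimum where $|W|$ is within `zero_tol` (default 0.1 kJ/mol; no
tolerance is stated in the reference) and stays there toward the bulk,
allowing up to 5% noisy excursions.  Where a PMF oscillates around zero
the choice of crossing is genuinely ambiguous; the "last minimum, then
first sustained crossing" rule is the package's own and is configurable
through `zero_tol`.  Binding modes follow the published classification:
a global minimum below 0.4 nm is direct surface binding; one at
0.4–0.7 nm is water-mediated (binding through the hydration shell).

`adsorption_free_energy()` evaluates the layer average by the trapezoid
rule on the stored grid, `standard_state_shift()` applies the
$k_BT\ln(c/c_\mathrm{st})$ re-referencing between the excess and a
standard-state convention, and `block_error()` implements block
averaging with the trailing partial block discarded.

```{r closed-form}
s <- seq(0.3, 1.2, 0.005)
pmf <- pmf_curve(s, ifelse(s <= 0.6, -5, 0))
adsorption_free_energy(pmf)
```

## Synthetic systems: what passing tests show

Because the study deposits no data accession, every input is generated
in code with known answers:

* `make_toy_surface_system()` builds a single sorbate (or rigid two-site
  dimer) over a frozen surface atom, moving on the $z$ axis in a
  prescribed potential along $s$ — smoothed square well (with a steep
  quadratic contact core, so the layer has a genuine closest approach),
  harmonic, quartic double well, or 9–3 wall.  The exact PMF equals the
  constructed potential, making the system an end-to-end oracle: the
  square-well demo must recover $\Delta G \approx -5$ kJ/mol, the double
  well must be reconstructed within 0.5 $k_BT$, and COM- vs site-based
  CV definitions must give the same $\Delta G$ within combined block
  errors (the reference-independence property of the layer average).
  For the dimer study the site masses (18 g/mol) and Langevin friction
  (0.5 ps⁻¹) are chosen to keep the conditional bond-force noise — whose
  variance scales with $k_B T m \gamma$ — small against the mean force.
* `sample_orientations()` provides isotropic and axially biased unit
  vectors for the orientation analysis; `layered_fluid_trajectory()`
  places particles by inverse-transform sampling of a target $\rho(z)$.
* One user seed fans out to independent per-generator streams
  (`seed * 48271 + generator-id mod 2³¹−1`), so adding a generator never
  perturbs existing fixtures.

These toys exercise the estimators, not the chemistry: they contain no
explicit water, no competing hydration layer, no rough binding-site
landscape.  Passing tests therefore demonstrate that the machinery is
correct at desk scale, not that microsecond solvated results (e.g. the
strong anionic-sorbate binding at nanoparticle edges reported for the
real systems) are reproduced.

Problem sizes used by the shipped checks — a 384-atom slab for 20 ps,
4–24-ns toy metadynamics runs — were chosen as the smallest systems on
which the statistical targets (0.5 $k_BT$, block-error agreement) are
comfortably met.

## Interfacial structure

The hydration module reproduces the reference study's descriptive
analyses on any trajectory: density profiles along $z$ (per slab
cross-section), radially from a particle centre (per shell volume), or
against the distance to the nearest surface atom (per Monte-Carlo
estimated accessible volume, so profiles always integrate back to the
particle count); water dipole and OH-bond orientation angles relative to
the surface normal or radial direction, restricted to a shell (default:
up to the first minimum of the relevant density profile, i.e. the first
solvation shell); and pairwise RDFs with ideal-gas normalisation,
including sorbent-COM-to-group RDFs.  Orientation histograms are
reported raw by default (an isotropic ensemble then shows the
$\sin\theta$ solid-angle shape, maximal at 90°); a sin-corrected mode
divides by $\sin\theta$ so the isotropic baseline is flat — the
reference figures do not state which convention they use, so both are
provided and the peak angles are not treated as quantitative targets.

## Limitations

The engine is a teaching-scale NVT/NVE code: no PME, no barostat, no
constraints, no polarizable (core–shell) sulfur model, and the
Buckingham form itself is never simulated — only its harmonic refit.
PMMA coating construction and GAFF/AM1-BCC parameter generation are out
of scope; coating parameters enter only as the special LJ pairs.  The
published per-molecule adsorption free energies for the 29 biomolecular
fragments require microsecond solvated simulations and are documentation
here, not validation targets.
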