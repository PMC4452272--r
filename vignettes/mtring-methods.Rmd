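---
title: "Ring energetics of microtubule lattices: models, conventions and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ring energetics of microtubule lattices: models, conventions and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtring)
```

## The problem

Microtubules are hollow cylinders of alpha/beta-tubulin heterodimers: 13
protofilaments packed side by side as a 3-start helix with one B-lattice
seam. Their stability is set by two families of protein-protein
interfaces - lateral contacts between neighboring protofilaments and
longitudinal contacts between consecutive dimers along a protofilament -
and the balance between them changes with the nucleotide in the
exchangeable site of beta-tubulin (GTP versus GDP). A per-residue energy
balance over one complete ring of 13 dimers makes that balance
quantitative: it identifies which residues, secondary-structure domains
and subunits hold the ring together, how the longitudinal interaction
energy is distributed radially (the lever arm of the outward-curling
torque that drives disassembly), and why the seam is the weakest point of
the lattice.

`mtring` implements that analysis as a reusable pipeline: an idealized
ring builder, a per-residue MM/GBSA-style interaction-energy engine, the
ring-level aggregation algebra, spatial energy profiles, trajectory
geometry observables, and seeded synthetic-data generators so every stage
can be exercised without any external structure, force-field file or
trajectory.

## The lattice model

A `lattice_spec()` captures the idealized 13_3 B-lattice:

* `n_pf = 13` protofilaments, `helix_start = 3` monomers of rise per turn;
* an axial dimer repeat `c` of 81.20 Å in the GDP state or 83.38 Å in
  the GTP state, with the monomer rise `h = c/2`;
* a ring radius (axis to dimer center of mass) of 105 Å by default, a
  realistic value for a 13-protofilament cylinder;
* a periodic cell of 293.85 × 293.85 × `c` ų, so the +z image of the
  ring continues each protofilament.

The lateral neighbor transform is a rotation by `2*pi/13` plus a rise of
`3h/13` (≈ 9.37 Å); thirteen lateral steps therefore close into a pure
translation of exactly three monomer rises, which is the helix-closure
identity that defines the 13_3 lattice. Because three monomer rises are
one and a half dimer repeats, the returning contact cannot be in dimer
register: the seam neighbor of dimer 13 is a longitudinal periodic image
of dimer 1 displaced one monomer from the helical continuation, so an
alpha subunit meets a beta subunit there. `make_subsystem()` uses the
image displaced by `3h + h = 2c`, which puts the ligand's alpha against
the receptor's beta; the complementary monomer contact (receptor alpha
against ligand beta) belongs to the `+c` image, and a finite two-dimer
subsystem can only contain one of the two. Subsystems follow the
receptor/ligand convention used throughout: in lateral pairs the dimer
whose M-loop faces the interface is the receptor (dimer `k`, ligand
`k+1`); in longitudinal pairs the receptor is the dimer whose
alpha-tubulin faces the interface and the ligand is its `+z` periodic
image. Residues are renumbered continuously over receptor-alpha,
receptor-beta, ligand-alpha, ligand-beta.

The ideal ring deliberately has exact helical symmetry. Rings extracted
from real trajectories (or hybrid cryo-EM models) carry small per-dimer
deviations; all downstream operations accept such frames unchanged, and
the per-frame axis refit (below) exists precisely because trajectory
rings ovalize.

## The energy model

Each subsystem is scored with a single-trajectory MM/GBSA-style
interaction energy: every component is `E(complex) - E(receptor) -
E(ligand)` evaluated on identical coordinates, so all intramolecular
terms cancel and only interface effects remain. The components, all in
kcal/mol:

* **van der Waals**: 12-6 Lennard-Jones,
  `eps_ij * ((r_min,ij/r)^12 - 2 (r_min,ij/r)^6)` with
  `r_min,ij = r_min,i/2 + r_min,j/2` summed and `eps_ij` geometric-mean
  combined. For the interaction energy this reduces to the cross-molecular
  pair sum, half-assigned to each partner atom.
* **Electrostatics**: Coulomb, `k_e q_i q_j / (eps_in r)` with
  `k_e = 332.0636` kcal Å mol⁻¹ e⁻² and solute dielectric
  `eps_in = 1`; cross-molecular pair sum, half to each partner.
* **Polar solvation**: generalized Born with the Still pairwise function
  `f_GB = sqrt(r² + R_i R_j exp(-r²/(4 R_i R_j)))` and effective radii
  from the OBC-II recipe (pairwise HCT descreening, tanh rescaling with
  alpha = 1.0, beta = 0.8, gamma = 4.85, intrinsic-radius offset 0.09 Å),
  at `eps_in = 1`, `eps_out = 80`. The GB interaction term is a per-atom
  difference (complex minus isolated molecule), because burial changes the
  effective radii.
* **Non-polar solvation**: `gamma * SASA + beta` with Shrake-Rupley
  areas (default 960 deterministic golden-spiral points per atom, probe
  1.4 Å), `gamma = 0.0072` kcal mol⁻¹ Å⁻², `beta = 0`. The interaction
  term is `gamma` times the buried area.

Because the MM terms are split half/half, receptor and ligand totals can
differ only through the solvation terms - which is exactly the mechanism
by which the two molecules of an interface contribute unequally despite
identical direct interactions.

Design choices worth stating explicitly:

* **GB flavor**: OBC-II was chosen because it is the de facto standard
  behind common MM/GBSA rescoring implementations and is fully specified
  in the open literature; the surface-tension constant is likewise a
  declared default, not a measured fact. Both are configurable.
* **No cutoffs**: subsystems are small after dimer extraction, so all
  pairwise sums are evaluated in full; this removes a tolerance knob.
* **No entropy term**: the pipeline reports interaction energies only.
* **Cofactors are first-class residues**: the nucleotide (GTP/GDP) and
  the magnesium ion are represented as named residues assigned to their
  host subunit, so they appear as rows of the per-residue tables and as
  entries of the domain map (`cofactor`, `Mg2+`) rather than vanishing
  into a subunit total. Bulk solvent and ions are assumed stripped before
  scoring.
* **Spread convention**: ensemble spreads are population standard
  deviations over frames, and the SD of a total is computed from the
  per-frame totals, never by summing per-residue SDs. Ring-level SDs are
  also available as quadrature propagation of per-subsystem SDs; the two
  conventions are reported side by side because published "±" values do
  not always say which one they are.

## Aggregation to the ring

Per-ring contributions follow the interface sums

```
E_x(lateral)      = eps_x(R13 L'1) + sum_{k=1..12} eps_x(Rk Lk+1)
E_x(longitudinal) = sum_{k=1..13}  eps_x(Rk L'k)
```

where `x` is any entity - a residue, a domain, a subunit in a role, or
the whole interface - and the seam term is the 13th element of the
lateral sum. Entities are keyed on (role, subunit, residue number), not
on the continuous index, so templates whose models differ by a few
residues still join correctly; the continuous index is derivable.
`subunit_matrix()` produces the 2×2 ligand/receptor-by-subunit table with
margins; `model_difference()` takes entity-wise `A - B` (GTP minus GDP by
convention) with an outer join and zero fill, flagged per entity;
`ring_diagram()` orders the 13 interface energies and reports the
weakest interface as the argmin of |E|, with ties reported as a set. The
domain map is data, not code: a YAML file of residue ranges per subunit
following the standard tubulin nomenclature, shipped as an editable
default because published domain figures rarely print their exact
ranges. Unmapped residues aggregate under `unassigned` so conservation
remains checkable.

## Spatial profiles

The radial coordinate of a residue is the distance of its mass-weighted
center from the microtubule lumen: (distance from the axis) minus a
lumen reference radius. Two conventions needed to be fixed because they
are not standard anywhere:

* **Axis refit**: direction fixed to z, center refit per frame as the
  mean x/y of the dimer centers of mass. Trajectory rings ovalize, so a
  fixed axis would bias radii.
* **Lumen reference**: the 1st percentile of atomic axis distances over
  the whole ring - a robust inner-surface estimate that puts the tubulin
  center of mass near x ≈ 30 Å on realistic wall geometry. It is
  configurable (including a fixed value) and is recorded alongside any
  profile.

The tangential coordinate is the signed distance along the local
tangential unit vector (perpendicular to axis and radial direction at
the protofilament's azimuth), measured from the plane through the
closest-contact midpoint with a designated laterally adjacent dimer. The
sign is chosen so the subsystem's own residues are positive - i.e. the
coordinate is the distance *from* the adjacent dimer, with the center of
mass again near +30 Å, the intermediate domain below it and the
nucleotide-binding domain above it. This is a declared convention; any
profile should be read together with it.

Energies are summed over half-open bins `[x, x+3)` anchored at 0 (the
lower edge is inclusive, so a residue at exactly 3.000 Å falls in the
second bin). Binning is purely a partition: the bin sums of every
component reproduce the ring totals exactly, and halving the width and
re-merging adjacent bins reproduces the coarse profile bit for bit.
`inner_outer_split()` cuts a profile at a threshold (default the
center-of-mass mark, 30 Å) and reports the inner sum, outer sum and
outer fraction - the quantity that measures how much of the longitudinal
attraction acts outward of the center of mass and hence feeds the
outward-curling torque.

## Geometry observables

`diameters()` implements the two near-perpendicular cylinder diameters
used to monitor ovalization: Dx from the center of mass of dimer 4 to
the joint center of mass of dimers 10 and 11, Dy from dimer 1 to dimers
7 and 8, both projected on the x-y plane. `backbone_rmsd()` superposes
by default (Kabsch) and also offers the unfitted variant, since
published RMSD traces do not always state whether fitting was applied;
"backbone" means atoms named N, CA, C, O of protein residues, with
cofactors excluded (bead models without those names fall back to all
atoms).

## What the synthetic data emulate - and what they do not

`make_toy_dimer()` builds a coarse-grained bead dimer: two labeled
subunits of bead-residues on a compact scaffold ~80 Å tall and ~45 Å
wide, seeded partial charges adjusted exactly to a tubulin-like net
negative charge, a bespoke nonbonded preset (bead r_min/2 of 8-9 Å, GB
radii to match), and optional cofactor residues (N-site GTP + Mg; E-site
GDP, or GTP + Mg). The beads are coarse so that neighbors at the real
lattice spacings make genuine vdW and SASA contact; the terminal residue
of each monomer sits on the dimer axis to act as the longitudinal
contact surface. The toy exercises every term of the energy engine with
realistic geometry, but its energetics are not tubulin's: magnitudes are
order-of-magnitude at best and the net interface sign can differ (the
bead monopoles dominate). Conclusions about real microtubules should
never be drawn from toy magnitudes - that is what the planted mock
tables are for.

`make_ring_trajectory()` emulates the circular-to-oval breathing seen in
simulated rings: frame `t` maps the dimer-COM radius to `R ± e_t` along
x/y with `e_t = delta * sin(2*pi*t/n_frames)`, plus isotropic Gaussian
jitter. Because the map is linear, the distorted dimer centers of mass
are known in closed form, which is what the diameter-recovery tests
compare against.

`make_mock_tables()` generates 13 per-subsystem residue tables with
planted ground truth: exact ligand/receptor-by-subunit cells (via
per-group rescaling), an exact outer fraction at the 30 Å mark (via an
energy-conserving transfer inside each role/subunit group, so planted
cells are preserved), and/or planted per-subsystem totals (e.g. a weak
seam). Planted coordinates avoid the 27-30 Å band so no residue
straddles the threshold bin. These tables stand in for per-residue
supplementary datasets and give the aggregation and profiling machinery
known answers that are recovered exactly in the noiseless case.

Passing tests on these generators therefore demonstrate that the
*machinery* is correct - lattice geometry, energy decomposition,
aggregation algebra, binning, recovery - not that any particular real
microtubule number is reproduced. The headline per-ring energies of real
systems come from long explicit-solvent trajectories of ~720,000-atom
models, which are far outside desk scale; the package's worked examples
instead feed the published summary tables through the same aggregation
code paths.

## Numerical choices and degenerate inputs

* Component additivity (`E_total = E_vdW + E_ele + E_GB + E_SA`) holds to
  1e-9 relative by construction and per-residue sums reproduce subsystem
  totals to better than 1e-6 relative.
* Coincident atoms raise explicit singularity/overlap errors in the
  Coulomb, LJ and Born-radius routines rather than returning infinities.
* The SASA point grid is a fixed global golden-spiral set, so areas are
  deterministic and translation-invariant; under rigid *rotation* they
  are reproducible only to sampling accuracy (tested at 2% with 240-960
  points), while the MM and GB terms are rotation-invariant to 1e-6.
* Ties in `ring_diagram()` are resolved by reporting the whole tie set
  (tolerance 1e-9 kcal/mol), never by picking an arbitrary winner.
* Residues inside the lumen reference clamp to x = 0 and are flagged;
  empty interior bins are reported as explicit zeros.
* All generators are pure functions of (spec, seed): the RNG state is
  saved and restored around every draw, and text writers emit full
  double precision (`%.17g`), so reruns are byte-identical.

## Problem sizes

The shipped tests and the acceptance script run entirely at desk scale,
chosen so the whole suite completes in seconds: toy dimers of 3-5
residues × 2-3 beads per subunit (22-50 atoms per subsystem), all 26
subsystems of both nucleotide states for additivity checks, 13-subsystem
mock tables of 20-28 residues for aggregation and profile recovery, and
12-16-frame synthetic trajectories for the geometry observables. The
brute-force oracles (scalar pair loops, scalar OBC radii, a numerical
descreening integral, the analytic two-sphere SASA lens) are evaluated
on systems of at most 50 atoms, where they are exact or near-exact
references.

## Known limitations

* The energy engine is a rescoring engine: no minimization, dynamics,
  explicit solvent, PME, entropy terms or protonation-state prediction.
  Protonation differences between models are input properties of the
  template.
* The ideal ring has perfect helical symmetry; heterogeneous lattices
  (11-16 protofilaments beyond simple parameterization, mixed states
  within a ring) are out of scope.
* The lumen reference and tangential origin are declared conventions;
  alternative choices shift profiles by a constant offset and must be
  reported with any comparison.
* Toy-dimer energetics are qualitative. The package makes no attempt to
  reproduce real tubulin interface magnitudes from first principles at
  desk scale.
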