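---
title: "Analysing cargo permeation through oligomeric membrane pores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing cargo permeation through oligomeric membrane pores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

porescape is a trajectory-analysis toolkit for a specific class of
simulation: a protein cargo (cytochrome c is the motivating case)
permeating an oligomeric protein pore (a ring of Bax-type BH3-in-groove
dimers) embedded in a lipid bilayer, sampled by coarse-grained
replica-exchange simulation. The package does not run molecular dynamics;
it takes trajectories (or generates statistically controlled synthetic
ones) and computes the quantities such a study reports: free-energy
landscapes, stage-wise potentials of mean force, contact statistics,
membrane profiles, pore-shape and surface-polarity metrics, and
coarse-grained-to-all-atom back-mapping.

This vignette records the models and conventions behind each stage, the
parameters that matter, and the design decisions taken where more than
one defensible choice existed.

## Coordinate framing

All reaction coordinates are defined in a pore-centred frame:
`recenter()` translates every frame so the pore's xy centre of mass sits
on the z axis and z = 0 lies midway between the mean z of the two
leaflet headgroup planes. The pore centre of mass is computed under the
minimum-image convention (each bead is mapped to its image nearest a
reference bead before averaging), so a pore split across the periodic
boundary behaves like its unwrapped copy. This requires the pore to fit
inside half the box — the usual situation — and only orthorhombic boxes
are supported; triclinic boxes are rejected with an explicit error. The
centre of mass and the radius of gyration are mass-unweighted
throughout: coarse-grained beads have near-uniform masses, and the
choice avoids importing force-field mass tables for a sub-percent
effect.

Two positional coordinates describe the cargo: `xy`, the planar radial
distance of the cargo centre of mass from the pore axis, and `z`, its
axial position. A third, `shape`, is a property of the pore itself (see
below). The cargo is summarised by its centre of mass rather than by its
closest bead; the centre of mass is what a rigid-body permeation
coordinate should track, and it is insensitive to surface-bead
fluctuations.

## Free-energy landscapes and PMFs

Landscapes are built by Boltzmann inversion of a positional histogram:
`F(c1, c2) = -RT ln P(c1, c2)`, with R = 1.987e-3 kcal/(mol K) and T the
trajectory temperature (default 310 K, the bottom of the replica
ladder). Default bin widths are 2 Å for the positional coordinates and
1 Å for the shape coordinate — fine enough to resolve 10–15 Å wide
basin regions with at least five bins, coarse enough that well-sampled
trajectories put hundreds of counts in each occupied bin.

The zero of free energy follows a *plateau* convention: bins that are
never sampled (the far-field plateau where the cargo simply does not go)
define F = 0, and the occupied bins are shifted so the least-sampled
occupied bin touches that reference. Occupied bins therefore have F ≤ 0,
and basin depths read directly as binding free energies relative to the
unsampled far field. Two alternative conventions (`max_F`, `global_min`)
are provided; free-energy *differences* between occupied bins are
invariant to the choice, which a test asserts.

One-dimensional PMFs are obtained per stage region by restricting the
2D histogram to a rectangular window, marginalising over the other
coordinate, and inverting the marginal. The three shipped stage regions
are the release stages of the motivating system: stage 1 at the wide
(entry) mouth (25 < xy < 40 Å, 15 < z < 30 Å), stage 2 in the inner
cavity (xy < 10 Å, |z| < 5 Å), stage 3 at the narrow (exit) mouth
(10 < xy < 25 Å, −30 < z < −20 Å). Basins are local minima of the
profile below the reference; the barrier from basin A to basin B is the
maximum profile value between them minus F(A), reported for both
directions. Barrier search is deliberately limited to 1D profiles; a 2D
minimum-energy-path search is out of scope, as is any multi-temperature
reweighting (WHAM/MBAR) — analyses run on the single bottom-of-ladder
trajectory.

Binning biases barrier estimates low by roughly `w^2 U''/24` for bin
width `w`; at the default 2 Å this is ~0.1 kcal/mol for the synthetic
double-well used in validation, and the recovery tests therefore bin at
1 Å.

## Synthetic data: what it emulates and what it does not

Every analysis stage is validated against generators with known ground
truth, because the original microsecond-scale simulations cannot be
regenerated at desk scale:

* `sample_boltzmann_mc()` — a single-particle Metropolis random walk
  targeting exp(−U/RT) for harmonic, double-well or tabulated
  potentials. Metropolis MC was chosen over Langevin/Brownian dynamics
  deliberately: the analyses need correct *stationary distributions*,
  not kinetics, and MC is the simplest sampler that is exact in that
  sense. Chains are seeded and bit-reproducible; a 10% burn-in is
  discarded by default.
* `run_replica_exchange()` — parallel chains on an ascending temperature
  ladder (default 309–380 K, the range of the emulated setup) with
  neighbour configuration swaps attempted every `swap_interval` steps
  (default 1000) under the criterion min(1, exp[(βi − βj)(Ui − Uj)]),
  alternating even/odd pairs. The lowest-temperature trajectory is
  tagged as the analysis trajectory.
* `make_bilayer()` — one PO4 headgroup bead per lipid near its leaflet
  plane (±24 Å by default, matching the ~48 Å peak-to-peak thickness of
  the emulated membrane) plus a chain of beads along a direction drawn
  from a von Mises–Fisher distribution about the normal. The vMF
  concentration κ is the tilt dial: `kappa_for_order()` inverts the
  closed form ⟨P2⟩(κ) = 1 − 3L(κ)/κ (L the Langevin function) so a
  target mean order parameter — 0.60 is the value the emulated membrane
  fluctuates around — can be hit exactly in expectation.
* `make_pore_assembly()` — dimer centres of mass on a regular n-gon
  (n = 6 default, 8 for the larger pore; n must be even so opposite
  vertices pair up), optionally stretched along x so the ring becomes an
  ellipse. Beads are placed symmetrically about each vertex, so dimer
  COMs sit exactly on the vertices and the shape metrics have closed
  forms to test against.
* `place_cargo_replicas()` — the replica seeding scheme: 6 axial
  positions at 13 Å spacing × 8 uniformly random orientations
  (Shoemake quaternion sampling) = 48 initial frames, with a clash
  check against the pore at the two mouth positions.
* `add_ions()` — counts from round(c·N_A·V) at 0.035 M NaCl and CaCl2
  defaults, chloride added to keep the added ions neutral, and a
  two-slab acceptance bias placing Ca²⁺ preferentially near the leaflet
  planes. The calcium surface layer of the emulated system is thereby
  reproduced *statistically*, not mechanistically — there is no
  electrostatics in the generator.

What the generators do **not** emulate: real lipid force fields, water,
protein internal flexibility, kinetics (MC "time" is not physical time),
and any correlation structure beyond what the samplers produce. Passing
the parameter-recovery tests therefore shows the *analysis* code is
correct and well-calibrated; it does not validate force-field-level
claims about real membranes.

## Contacts and interface diagnostics

Two residues are in contact when their minimum bead–bead distance is
below 6.5 Å (minimum image), the cutoff appropriate at coarse-grained
(Martini) resolution; contact aggregation over frames is reported as the
frame fraction, and the production distance path is verified *exactly*
against a naive O(N²) double loop in the tests. Bead–bead minimum
distance (not residue-centre distance) is the deliberate reading of the
cutoff. Polarity-classified contact fractions partition contacting pairs
into hydrophilic–hydrophilic, hydrophobic–hydrophobic and mixed, summing
to 100%.

All-atom interface counts use standard-literature geometric criteria,
all configurable: H-bond donor–acceptor < 3.5 Å with donor–H⋯acceptor
angle > 120° (distance-only < 3.0 Å fallback, with a warning, when the
structure has no hydrogens); salt bridge = basic side-chain N to acidic
side-chain O < 4.0 Å per residue pair; hydrophobic contact = side-chain
carbon pair of hydrophobic residues < 5.0 Å per residue pair. The
electrostatic/van der Waals split is a fixed-charge Coulomb (εr = 1,
332.06 kcal mol⁻¹ Å e⁻²) plus 12-6 Lennard-Jones sum over cross-group
pairs within 12 Å, with user-supplied parameters — a diagnostic of which
force dominates an interface, not a force-field reimplementation (no
PME/reaction field, no polarisability).

## Membrane profiles and order parameter

Axial densities are normalised z histograms per species. Peak detection
applies a 3-bin moving average before locating local maxima; the implied
bilayer thickness is the separation of the two dominant peaks. The chain
order parameter is P2 = 0.5(3cos²τ − 1) of the angle between each
lipid's chain vector and the membrane normal, averaged over lipids and
then frames; the chain vector runs from the first to the last chain bead
of the lipid, the simplest reading of a "chain vector" at CG resolution.
P2 is 1 for perfect alignment, 0 for an isotropic melt, −0.5 for chains
lying in the plane — limits the tests pin exactly.

## Pore shape and surfaces

The shape coordinate Δd is the difference between the longest and
shortest opposite-dimer COM distances; opposite means index offset n/2
around the ring, the only pairing consistent with a convex ring. Δd is
invariant under rigid motion and scales linearly with uniform scaling
(both tested). The cavity diameter is measured on a radius grid
(default step 0.5 Å) as twice the largest axis-centred cylinder radius
free of pore-bead centres, evaluated in a slab around z = 0; the full
radius-versus-z profile is out of scope.

SASA uses Shrake–Rupley point counting on a deterministic golden-spiral
point set (default 960 points per atom; the isolated-sphere error at
that density is well under 2%, and doubling the point count moves totals
by < 1% on all fixtures). Radii: a Bondi-type heavy-atom element table
with a 1.4 Å probe for all-atom structures; a uniform 2.3 Å bead radius
and 2.6 Å probe (half a CG water bead) at coarse-grained resolution.
Surface decomposition sums per-residue areas into the four polarity
classes; the shipped residue classification is: positive {ARG, LYS,
HIS}, negative {ASP, GLU}, polar uncharged {SER, THR, ASN, GLN, TYR,
CYS, TRP, GLY}, hydrophobic {ALA, VAL, LEU, ILE, PRO, PHE, MET}, heme
hydrophobic at residue level. Published surface percentages of this kind
rarely state their classification table, so comparisons against reported
values are approximate by construction; the table is an explicit,
overridable default rather than a hidden constant, and fractions always
sum to exactly 1. The buried fraction of a component is
(SASA_isolated − SASA_in_complex)/SASA_isolated.

## Back-mapping

Coarse-grained helices are reconstructed by rigid superposition of
all-atom reference fragments: each segment's position is its backbone
bead centroid, its orientation the dominant principal component of the
backbone beads with the sign fixed N→C, and the fragment is placed by
the Kabsch least-squares fit (proper rotations only — the determinant
correction excludes reflections, so chirality cannot invert) with one
anchor per residue (Cα, or the backbone-atom mean when no Cα exists).
Residues between consecutive segments are emitted as straight-line Cα
placeholders flagged `placeholder = TRUE`: loop relaxation (constrained
minimisation plus short MD in the emulated workflow) is explicitly out
of scope, so the placeholders are honest markers of unrefined geometry
and are excluded from the steric clash report. Segments are whatever the
caller lists — omitting a domain (as the emulated workflow omits the
α6–α8 region) is expressed simply by omitting its segments.

## Numerical and degenerate-input choices

* Gas constant 1.987e-3 kcal/(mol K); lengths in Å, energies kcal/mol,
  temperatures K, 1-based residue numbers in all I/O.
* Unknown residue names classify as hydrophobic with a logged warning,
  so lipid/ion systems flow through protein-oriented analyses.
* Empty selections, single-temperature ladders, odd dimer counts,
  non-finite sampler starts, truncated trajectory files, and regions
  outside the grid all raise typed errors (or warnings with empty
  results where the contract says so) rather than silently degrading.
* Coincident atoms in the SASA kernel occlude each other fully (a small
  tolerance on the occlusion test), so pathological overlap fixtures
  behave as full burial.
* The PDB writer truncates residue names to the 3-character field; GRO
  carries 4-character CG residue names.

## Problem sizes used in the shipped checks

The bundled demo (`generate_demo()` + `run_pipeline()`) runs 120 frames
of a ~900-particle system and completes in a few seconds; the
statistical recovery checks use 10⁵–10⁶ Metropolis steps and 10³–10⁵
synthetic lipids. These sizes were chosen so every distributional
assertion sits many standard errors away from its pass boundary while
the whole suite runs in minutes on one CPU.

## Known limitations

Kinetics and rates are out of scope everywhere (no committor analysis,
no diffusion estimates). No WHAM/MBAR. Triclinic boxes unsupported.
Loops are placeholders, side chains are not rebuilt, and no energy
minimisation is performed after back-mapping. The surface-percentage
benchmark against a real cytochrome c crystal structure requires that
structure to be supplied externally (it is not redistributed with the
package).
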