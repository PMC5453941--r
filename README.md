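# porescape

Trajectory analysis of protein cargo permeation through oligomeric
membrane pores.

## The problem

When a pro-apoptotic Bax-type oligomer forms a pore in the mitochondrial
outer membrane, cytochrome c escapes through it. Simulation studies of
this process — a coarse-grained cargo/pore/bilayer system sampled by
replica-exchange — all need the same analysis layer: turn positional
sampling into free-energy landscapes, localize the release stages,
identify the residues that hold each intermediate, quantify how the
membrane and the pore deform, and rebuild all-atom coordinates from the
coarse-grained end state. porescape implements that layer as a tested R
package for anyone analysing (or prototyping analyses of) pore-permeation
trajectories, with seeded synthetic generators so every stage can be
validated against known ground truth without microsecond simulations.

## What it computes

* **Free-energy landscapes** by Boltzmann inversion of positional
  histograms, `F(xy, z) = −RT ln P(xy, z)`, over the cargo's planar
  radial distance `xy` and axial position `z` (or the pore-shape
  coordinate), with a plateau zero-reference: never-sampled far-field
  bins define `F = 0`.
* **Stage-wise 1D PMFs** `F(z) = −RT ln P(z)` restricted to release-stage
  windows, plus basin locations and inter-basin barrier heights
  (`barrier(A→B) = max F on the path − F(A)`).
* **Residue–residue contact maps** at a 6.5 Å minimum bead–bead distance
  cutoff, per-residue contact numbers, and polarity-classified contact
  fractions; all-atom H-bond / salt-bridge / hydrophobic counts with a
  Coulomb + Lennard-Jones energy split.
* **Membrane profiles**: axial densities (PO4 headgroups, ions), peak
  detection and implied thickness, and the second-rank chain order
  parameter `P2 = 0.5(3 cos²τ − 1)`.
* **Pore shape and surfaces**: ellipticity Δd (spread of opposite-dimer
  COM distances), central cavity diameter, Shrake–Rupley SASA, four-class
  surface decomposition (positive / negative / polar-uncharged /
  hydrophobic), and buried-surface fractions.
* **CG→AA back-mapping**: helix position/orientation extraction, Kabsch
  rigid fits of all-atom reference fragments (proper rotations only),
  straight-line loop placeholders, clash reports.
* **Synthetic generators** with known ground truth: Metropolis MC and
  replica exchange on analytic potentials, bilayers with tunable chain
  tilt, dimer-ring pores with controllable ellipticity, cargo replica
  placement (6 axial positions × 8 orientations), counter-ion placement
  with surface enrichment.

Structures read/write PDB (via bio3d) and GRO; trajectories use a
plain-text multi-frame format plus a DCD adapter. Analysis results are
tibbles (or carry `tidy()`/`glance()` methods) and have `autoplot()`
methods.

## Worked example

The bundled demo builds a six-dimer pore ring, a bilayer with headgroup
planes at ±24 Å and chain tilt targeting ⟨P2⟩ = 0.60, a cargo whose
centre of mass samples a double-well axial potential with a 3 kcal/mol
barrier, and counter ions:

```r
library(porescape)

demo <- generate_demo(seed = 1, n_frames = 120)
traj <- recenter(demo$trajectory, pore_sel = "pore",
                 leaflet_sel = function(p) p$group == "lipid" & p$name == "PO4")

profile_peaks(axial_density(traj, function(p) p$name == "PO4", 1))[c("thickness")]
#> $thickness
#> [1] 47

chain_order_parameter(traj)$mean
#> [1] 0.5989

fel <- free_energy(bin_probability(traj, "cargo", c("xy", "z"), c(2, 2)))
basin_barriers(pmf_1d(fel, "z"))$barriers
#> # A tibble: 2 × 3
#>    from    to barrier
#>   <dbl> <dbl>   <dbl>
#> 1   -13    13    1.85
#> 2    13   -13    2.01

contact_matrix(traj, "pore", "cargo")
#> <contact_matrix> 72 x 8 residues, cutoff 6.5 A over 120 frame(s); 32 pairs ever in contact
```

The PO4 peaks land at ±23.5 Å (47 Å apparent thickness for 24 Å leaflet
planes at 1 Å binning), the order parameter recovers the 0.60 target,
and the two PMF basins sit at z = ±13 Å — the wells of the generating
potential — with barriers below the 3 kcal/mol input, as expected for a
120-frame sample. `autoplot(fel)` draws the landscape;
`run_pipeline(outdir = "out", seed = 1)` writes every stage's CSV/JSON
tables with provenance metadata, byte-reproducibly for a fixed seed.

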