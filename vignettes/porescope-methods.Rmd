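---
title: "porescope: models, conventions and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{porescope: models, conventions and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

porescope computes permeation statistics for wide membrane channels from
MD trajectories. This vignette documents the underlying models and every
convention the numerical results depend on: the reaction coordinate, the
contact criteria and their boundary semantics, the profile estimators,
the event definition, the synthetic Brownian-dynamics generator, and the
limits of what a green test suite does and does not establish.

## The pore frame

All profiles and events are expressed in a signed axial coordinate z.
The origin is the geometric (unweighted) center of a user-designated
atom selection; for mouse VDAC1 this is the backbone carbons of seven
residues distributed around the barrel midplane (R15, V17, L58, F99,
A141, S193, L259), which pins z = 0 to the protein rather than the
laboratory frame. "Backbone carbons" is read literally as both CA and C
per residue (`backbone_atoms = c("CA","C")`); a CA-only option exists
because the literature is ambiguous here, and the difference displaces
the origin by fractions of an Angstrom. The axis defaults to the
laboratory +z (membrane normal of a standard bilayer build), positive
toward the cytosolic side; synthetic or tilted systems can supply any
axis. z of a tracked particle is the dot product of (particle − center)
with the unit axis. This makes z translation-invariant and invariant
under co-rotation of system and axis, which the property tests verify.

Slabs are half-open intervals [lo, hi) on z; a value exactly on an
interior edge belongs to the upper bin. The default grid spans −22 to
+22 Å, the reaction-coordinate range across the full pore.

## Contact criteria and boundary semantics

Six geometric criteria are implemented (distances in Å, angles in
degrees): electrostatic phosphate–Lys/Arg (min O–N distance ≤ 4.0,
*inclusive*), phosphate–cation pairing (< 4.0, strict), π–π
(ring-center distance < 6 and inter-plane angle < 30), cation–π
(N-to-ring-center < 6 and N–H vector at > 60 to the ring plane),
guanidinium stacking (< 6 and inter-plane angle < 30), and hydrogen
bonds (heavy-atom distance < 3.5 and D–H–A angle > 120). Boundary
inclusivity mirrors the wording of each rule: only the electrostatic
cutoff is inclusive. These events have zero measure in real data, but a
deterministic test suite needs a fixed convention, and the fixtures
exercise each boundary exactly.

Angle conventions: the angle between two planes is the angle between
their normals folded into [0, 90]; the angle between a vector and a
plane is 90 minus the folded vector–normal angle, also in [0, 90]. Ring
planes are defined by three non-collinear atoms (for adenine the default
triplet spans the six-membered ring; any non-collinear purine triplet
gives a near-identical plane, and the triplet is user-configurable
precisely because the canonical choice is not standardised). Hydrogens
must be explicit in the input; donors are validated (|D–H| ≤ 1.2 Å) and
no hydrogen construction is attempted, matching how MD systems with
explicit-hydrogen force fields are analysed.

When a frame carries an orthorhombic box, all pair distances use the
minimum-image convention; otherwise plain Euclidean.

Contacts are aggregated one record per (ligand group, residue) with the
minimal distance — the residue, not each nitrogen, is the interaction
unit. Contact lifetimes: a run of k consecutive frames counts k·dt ns
(each snapshot stands for one sampling interval), and a pair is
long-lived when its maximal run strictly exceeds 5 ns.

## Profile estimators

* **Occupancy histogram**: fraction of snapshots with the tracked atom's
  z in each slab; sums to 1 when the atom never leaves the grid.
* **Interaction profile (N_int)**: per slab, snapshots with the contact
  formed over snapshots with the tracked group in the slab. Slab width
  defaults to 1 Å for H-bond/electrostatic and 2 Å for π-type contacts.
  Unvisited slabs report NA with zero samples rather than 0 — absence of
  evidence is not evidence of absence.
* **Pairing profile**: mean number of distinct simultaneously paired
  cations over the in-slab snapshots.
* **Concentration profile**: time-averaged species count in a sampling
  cylinder (default radius 12 Å) per slab, divided by the slab cylinder
  volume. The cylinder is an explicit stand-in for the channel's
  accessible cross-section; results should be quoted with the cutoff
  that produced them.
* **Free energy**: ΔG(z) = −RT ln(C(z)/C_bulk), R = 0.0019872041
  kcal/mol/K. Temperature defaults to 300 K (RT = 0.5962 kcal/mol) and is
  configurable; it is a parameter of the analysis, not something the
  trajectory determines. Zero-concentration bins give NA (an unresolved,
  effectively infinite barrier) instead of a clipped large number —
  clipping would fabricate barrier heights. C_bulk comes either from a
  user-designated bulk z-range (outside the pore slab plus a margin) or,
  for synthetic data, from the generator's ground truth.
* **Block standard error**: the series is cut into n contiguous
  near-equal blocks; the SE is the sd of block means over sqrt(n). This
  is the standard windowed error estimate for time-correlated series;
  with too few blocks it inherits the small-sample bias of the sd
  (E[s] = c4·σ), which the tests account for explicitly.
* **Selectivity ratio**: time-averaged simultaneous counts of anions and
  cations in the cylinder |z| ≤ 15 Å, r < 12 Å. The axial bound matches
  the translocation slab; the radial cutoff is configurable because the
  "visiting the pore" region is a modelling choice, not a measurement.

## Translocation events

The event definition is a full passage between the boundary regions
z > +15 Å and z < −15 Å. The literal inequality pair "from z<15 to
z>-15" describes overlapping regions and is vacuous as printed; the only
reading that defines a countable crossing of a ±15 Å slab is hysteresis:
an event is recorded when a particle whose last boundary visit was one
region reaches the other, with the entry frame being the last frame in
the departure region. Jitter around a single boundary can never count,
partial entries are not events, and a particle starting inside the slab
counts only after it first reaches a boundary region. Mirror symmetry
(negating z swaps the direction counts exactly) and equivalence with an
independent two-state replay oracle are tested properties.

## Conservation statistics

Per reference-sequence position, the column is located by counting
non-gap reference characters; over the other sequences with a non-gap
character there, the percentage identical to the reference and the
percentages substituted to K or R are reported to one decimal. Two
conventions are unspecified in the source material and fixed here:
gaps are excluded from the denominator (reported via
`n_sequences_counted`), and the reference sequence is excluded
(conservation *across* the other species; configurable via
`include_reference`). Notably, the 139-sequence acceptance fixture
(129 K / 9 R / 1 other at a reference-K column) rounds to 92.8 % / 6.5 %
under both reference conventions, so it validates the arithmetic without
discriminating the convention.

## Conductance

The I/V slope over points within ±20 mV, by ordinary least squares with
a free intercept: bilayer recordings can carry offset currents, which
must load the intercept and never the slope (a tested invariant).
pA/mV is numerically nS. Normalized conductance is a plain ratio;
0.90 means a 10 % decrease upon metabolite addition.

## The synthetic generator: what it emulates, what it does not

`simulate_bd` integrates overdamped Langevin (Euler–Maruyama) dynamics,
dr = −(D/RT)∇U dt + sqrt(2D dt) η, in a reflecting cylinder, with a
Gaussian-sum axial potential U(z) acting on selected species. This is
the simplest dynamics whose stationary law is the Boltzmann distribution
exp(−U/RT) — exactly the assumption Boltzmann inversion rests on — so
parameter recovery is a genuine closed loop: the generator's ground
truth (potential, bulk densities, expected occupancy ratio) is computed
analytically (1D quadrature of the Boltzmann factor), never from the
trajectory.

Defaults state the emulated world once: a pore of radius 12 Å and
half-length 15 Å in a 90 Å box; an ATP-like double well with depths 2.0
and 1.0 kcal/mol at z = −5 and +7 Å (the scaled-down analogue of the
deep central and shallow cytosolic wells of the real system — desk-scale
sampling cannot converge 5 kcal/mol wells, and the recovery property is
depth-independent); diffusion 200 Å²/ns, about the bulk value for small
ions in water; a 0.002 ns time step, keeping D·dt two orders of
magnitude below the squared width of the narrowest potential feature
(warned about otherwise, and divergent steps abort). Anions feel the
potential; cations see a flat landscape, mirroring the observation that
the channel's landscape is sculpted for anions. One master seed drives
the whole generation; identical spec + seed is bit-identical.

What the generator does **not** emulate: explicit solvent, inter-particle
electrostatics, applied fields, Mg²⁺ chelation, protein flexibility, or
the 3D geometry of a real barrel. A green recovery test therefore
establishes that the *analysis operators* are correct on data satisfying
their assumptions — it says nothing about force fields or sampling of
the real system. The toy pore's decorated sites (a central three-site
basic cluster within |z| < 5 Å plus one cytosolic and one
intermembrane-side site) reproduce the *topology* of the charged-brush
arrangement for contact-detection tests, not its energetics.

## Numerical choices and degenerate inputs

Half-open bins with ties upward; folded angles in [0, 90]; collinear
ring triplets are an error (no plane); empty selections are errors, not
empty results, because they almost always indicate a broken tagging rule;
an all-gap alignment column yields NA with a zero count; a zero
time-averaged cation occupancy makes the selectivity ratio an error
(undefined), not Inf. Exact-threshold geometries are deterministic in
the package's own frame but are excluded from rotation-invariance
properties: a rigid rotation perturbs distances at the 1e-15 level,
which legitimately flips a comparison exactly on a boundary.

The CLI stores configuration as JSON (flags > config file > defaults)
and writes the effective configuration next to every output; the
`report` bundle is TSV-only, with plotting left to downstream tools.

## Known limitations

Straight pore axis only (no curved/instantaneous axes, no radius
profiling); no PBC unwrapping of molecules split across boundaries; DCD
support targets the CHARMM/NAMD flavour (validated against an
independent reader during development); conservation takes the alignment
as given (no alignment construction or phylogenetic weighting); the
Brownian generator is not a substitute for MD where solvent structure,
ion–ion correlation or field-driven transport matter.
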