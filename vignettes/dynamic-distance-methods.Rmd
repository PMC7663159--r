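---
title: "Constrained dynamics and free energies of a dinuclear Hg(II)-mediated base pair"
author: "dyndist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained dynamics and free energies of a dinuclear Hg(II)-mediated base pair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyndist)
```

## The problem

Metal-mediated base pairs replace the hydrogen bonds of a canonical DNA
base pair by coordinate bonds to one or more metal ions.  The pair
studied here is the first dinuclear example with mercury: a thymine,
deprotonated at N3, facing the artificial nucleobase
1,N^6^-ethenoadenine (eA), whose two nitrogen donors (N6 and N7) have
near-parallel lone pairs and can therefore chelate two Hg(II) ions at
close distance.  Embedded in a parallel-stranded duplex (isoguanine:
cytosine pairs make parallel pairing possible), the T–Hg(II)~2~–eA pair
has two competing coordination isomers: the **NO** pattern (Hg1 between
eA-N7 and T-O4, Hg2 between eA-N6 and T-O2) and the **NN** pattern (Hg1
between eA-N7 and T-N3).  Questions of interest are how stable the
mercurated pair is relative to its Hg-free analogue, which coordination
pattern dominates, and along which path an Hg(II) ion enters or leaves
the duplex.

`dyndist` implements the simulation *methodology* used to answer such
questions — a collective-variable constraint, a constrained MD engine,
blue-moon thermodynamic integration, a coarse duplex builder, and the
trajectory observables — on top of a synthetic classical energy model.
The package makes no claim to reproduce quantum-chemical energetics;
what it reproduces, and what its tests check, are the *method
properties*: exact constraint satisfaction, thermodynamic consistency
against closed-form references, correct neutralization arithmetic,
protocol endpoints, and the qualitative mechanical structure (bistable
Hg coordination, the modified pair as the duplex's weak spot).

## The dynamic-distance collective variable

The central object is a single scalar coordinate defined over a set of
non-overlapping atom pairs (NOP):

$$D \;=\; \left(\sum_{(i,j)\in\mathrm{NOP}}
  \frac{\mu_{ij}}{\mu^*}\, (\mathbf r_i-\mathbf r_j)^2\right)^{1/2},
\qquad
\mu_{ij}=\frac{m_i m_j}{m_i+m_j},\quad \mu^*=\sum \mu_{ij},$$

a reduced-mass-weighted root-mean-square over pair distances.  The
square of the pair vector is read as its squared Euclidean norm — the
only reading that yields a scalar with units of length.  Because only
the *collective* value is constrained, individual pairs trade distance
freely: a duplex can be "zipped up" (all hydrogen bonds driven to a
common tight value) or dissociated without prescribing which pair opens
first.  The mass weighting has a useful consequence: heavy-atom pairs
(N···O, $\mu\approx7.5$ amu) carry roughly eight times the weight of
N···H pairs ($\mu\approx0.94$ amu), so the Hg-bridged distances of the
modified pair dominate the dissociation coordinate.

Three pair-set variants are built by `select_constraint_pairs()`:
**EQUI** (every inter-base hydrogen bond of the regular pairs; 30 pairs
for the default duplex), **DNA** (one N···H bond per regular pair plus
the two Hg-bridged N···O distances; 14 pairs), and **ISO** (the two
N···O distances only).  Atom masses are standard atomic weights; no
isotope convention is applied.

## Constrained dynamics and the mean constraint force

The engine is velocity Verlet with the constraint $D=\xi$ enforced by a
Lagrange multiplier.  Because the constraint is a single scalar, the
SHAKE system is $1\times1$ and is solved by damped Newton iteration on
$g(\lambda)=D\!\left(q' + \tfrac{\Delta t^2}{2m}\lambda\,\nabla
D(q)\right)-\xi$ to $|g|\le$ `tol` (default $10^{-8}$ Å, maximum 50
iterations, with one final polish iteration that typically leaves a
residual near machine precision).  A RATTLE projection removes the
velocity component along $\nabla D$ after the second half-kick, so
$\dot D = 0$ to $10^{-10}$ Å/fs.  The multiplier is reported in
kJ/mol/Å with the standard Lagrangian sign convention (constraint force
$+\lambda\nabla D$): on a harmonic dimer held beyond its rest length
the multiplier is positive, and integrating it over increasing $D$
gives a positive free energy of stretching.

The free-energy profile follows the blue-moon relation

$$\Delta A \;=\; \int_{D_\mathrm{min}}^{D_\mathrm{max}}
 \langle F(D)\rangle\, \mathrm d D,$$

with $\langle F(D)\rangle$ the time-averaged multiplier at each
constraint value.  Windows are visited sequentially (the target jumps
to the next value and the system re-equilibrates; the first 20% of each
window's trace is discarded by default), means are block-averaged
(5 blocks) for error bars, and the integral is a cumulative trapezoid —
exact for linear mean-force profiles and robust for the mixed 0.1/0.2/
0.5 Å step schedules the protocols use.  The raw multiplier average is
integrated without a mass-metric (Fixman) correction; for a
two-particle distance constraint the metric is constant, so the
correction vanishes identically there, and the dimer oracle (below)
quantifies the convention.

**The dimer oracle.**  For two particles bound by
$U(r)=\tfrac12 k (r-r_0)^2$ with the distance rigidly constrained, the
configurational density is $\propto r^2 e^{-U/k_BT}$, hence

$$A(r) = U(r) - 2k_BT\ln r + C, \qquad
\frac{\mathrm dA}{\mathrm dr} = k(r-r_0) - \frac{2k_BT}{r},$$

the second term being the centrifugal contribution of the two
rotational degrees of freedom.  This closed form is the independent
reference for the whole TI machinery: the package's test suite runs TI
over a 1 Å range at 300 K and requires agreement within 2%, plus
forward/reverse consistency within combined errors.  In practice the
agreement is a few tenths of a percent.

**Thermostats.**  A Nosé–Hoover chain (length 3, time constant 1 ps —
the settings used for all NVT stages) provides deterministic canonical
sampling with a tracked conserved quantity; a Langevin thermostat
(OBABO splitting) is available where stochastic sampling of a small
system is preferable, e.g. the dimer TI and the bistable-well
occupancy runs.  Uniform NHC velocity scaling preserves the RATTLE
velocity condition; after a Langevin noise kick the projection is
re-applied.  Pressure coupling is not implemented: the original
protocol's NPT stages concern explicit water, which the toy model
replaces; all runs here are NVT on pre-sized non-periodic systems.
Velocities are initialized from the Maxwell–Boltzmann distribution at
the target temperature with the centre-of-mass motion removed (when no
atom is held fixed).

**Units.** Å, fs, amu, kJ/mol, K throughout;
$k_B = 0.0083144621$ kJ/mol/K.  With these units
1 amu Å²/fs² = 10^4^ kJ/mol exactly.

## Building the duplex models

The builder works at the resolution the analyses need: each base is a
rigid planar template of its named donor/acceptor sites (N1, N3, N6,
N7, O2, O4, amino/imino hydrogens), the glycosidic C1', and one
backbone phosphate bead, placed on an ideal fiber helix (rise 3.38 Å,
twist 36°, C1'–C1' span 10.4 Å — B-DNA fiber values, since the original
work delegates this step to a helix generator without printing values).
Template distances are tuned so that paired donor-H···acceptor
separations come out near 1.9 Å.  Full-atom sugars and sequence-
dependent helix parameters are out of scope: every observable the
package computes is a function of the named sites.

The construction route for the experimental parallel duplex is:

1. `build_antiparallel_duplex("GAGGGATAGAAAG")` — the 13-mer with its
   Watson–Crick complementary second strand (5'-d(CTCCCTATCTTTC)-3').
2. `parallelize()` — the strand flip.  A literal end-over-end rigid
   rotation of strand 2 would re-pair base $i$ with base $n{+}1{-}i$
   and, for this non-palindromic sequence, break complementarity.  The
   flip is therefore implemented base-wise: each strand-2 nucleotide
   rotates in place about the local pair axis, presenting its reversed
   Watson–Crick edge, and the strand's 5'→3' numbering is re-indexed
   from the new 5' end.  Pairing partners are preserved, both strands
   then run 5'→3' in the same direction, and the second strand reads
   5'-d(CTCCCTATCTTTC)-3' along the helix axis.
3. `guanine_to_isoguanine()` — swaps the exocyclic O6 and N2H~2~
   coordinates of every guanine (an involution).  With the templates
   used here this exactly restores the three G:C hydrogen bonds in the
   reversed-WC parallel geometry — which is the structural reason
   isoguanine enables parallel-stranded pairing.
4. `insert_modified_pair(position = 7)` — replaces the central A:T pair
   by the T:eA pair with two Hg(II) ions in the NO pattern, each
   coordinate bond at 2.15 Å (the median coordinate-bond distance of
   the mercurated pair; configurable, since the optimized internal
   geometry is not tabulated numerically anywhere).  The pair moiety
   carries +3 (two Hg^2+^, one deprotonation).  Residues are numbered
   1–13 (strand 1) and 14–26 (strand 2), so the modified pair is
   T7:eA20.
5. `neutralize()` — 26 phosphate charges and the +3 pair leave −23, so
   23 Na^+^ are placed uniformly at random (seeded) outside a 3 Å
   exclusion shell.  Counter-ion placement is not modelled beyond
   that.  The Hg-free analogue (`remove_hg()`: delete both ions,
   re-protonate T7-N3) shifts the net charge by −3; a second
   neutralization pass adds exactly three more cations, reproducing the
   published ion arithmetic for that system.

## The synthetic energy model

`duplex_topology()` equips a duplex model with a classical energy
surface whose *structure* matches what the analysis assumes, with
deliberately simple ingredients:

* intra-unit all-pair harmonic springs (800 kJ/mol/Å², 300 for X–H
  pairs) keep each base template near-rigid;
* consecutive C1' and P beads along each strand are joined by 100
  kJ/mol/Å² springs (the backbone);
* every regular-pair hydrogen bond is a Morse well (depth 20 kJ/mol,
  width 2 Å⁻¹, r₀ 1.9 Å) — Morse rather than harmonic so dissociation
  is representable;
* Hg coordinate bonds are Morse wells (depth 25 kJ/mol, width 2 Å⁻¹,
  r₀ 2.15 Å), and Hg1 additionally sees a weaker well (12 kJ/mol) at
  T-N3, which creates the NO/NN bistability inside the duplex;
* weak "stacking-proxy" springs (30 kJ/mol/Å²) tether the Watson–Crick
  edge site of each base to that of its strand neighbour.  Without
  them, a base anchored only at its C1' can flip outward and carry its
  constrained pair distance to >10 Å at zero energy cost — a spurious
  dissociation channel that real stacking forbids;
* WCA (purely repulsive Lennard-Jones) cores prevent pair collapse,
  keep counter ions off the charged sites, and act between the
  Hg-bridged N/O heavy atoms so that compressing the collective
  coordinate cannot overlap them; counter ions are weakly restrained
  to their placement sites, standing in for the solvent cage;
* point charges (P −1, Na^+^ +1, Hg +2, deprotonated N3 −1) interact
  by a Coulomb term switched smoothly to zero between 6 and 8 Å and
  screened by a uniform dielectric of 78.5 (implicit water).  The
  screening is essential, not cosmetic: with bare charges the 26
  phosphates put the duplex under a net tension of order 10³ kJ/mol
  and strand separation becomes downhill, which no hydrogen-bond well
  survives.  The systems are small and non-periodic, so no Ewald
  summation.  Within the mercurated-pair core the Coulomb term is
  excluded: its interactions are represented by the explicit Morse
  terms, exactly as a force field absorbs bonded electrostatics into
  bonded parameters.

An optional coarse solvent (`add_solvent()`) adds neutral
Lennard-Jones spheres — dipole-free collision partners, not a
dielectric medium (screening is handled by the uniform permittivity).
Topologies serialize to a versioned YAML schema
(`write_topology()` / `read_topology()`).

No parameter of this model is fitted to quantum-chemical data; Hg–N/O
classical parameters do not exist in the source material, and the toy
values are stated as synthetic and tunable.  Consequently the
free-energy *numbers* the package produces for the duplex are
illustrative; only their qualitative structure (which pair opens first,
bistable oscillation) is asserted, and the published QM/MM dissociation
energies (100–200 kJ/mol) are deliberately not targets.

**The bistable fixture.**  `make_bistable_hg_pair()` isolates the
NO/NN competition in its minimal form: a mobile Hg between two
competing Morse acceptors (T-O4 at +2.9 Å, T-N3 at −2.9 Å on the y
axis, width 3 Å⁻¹, r₀ 2.15 Å), a weak isotropic restraint (5
kJ/mol/Å²) standing in for the pocket, the eA-N7 site beside the
pocket, and the second (fixed) Hg with its own bridge so pattern
classification sees a complete pair.  The geometry was chosen once so
that (a) the minimum-energy difference equals `depth_NO − depth_NN`
within 0.5 kJ/mol (the far-acceptor residual is ≤0.3 kJ/mol), and (b)
the inter-well barrier is a few $k_BT$ at 300 K, so both basins are
visited on desk-scale Langevin runs.  The canonical reference for
occupancy tests is computed by direct Boltzmann quadrature of the
mobile-ion density on a 3-D grid, with every grid point labelled by the
*same* geometric classification rule used on trajectories.  A bare
two-state $e^{-\Delta E/k_BT}$ estimate is *not* used as the reference:
when the two depths differ, the well curvatures differ
($k = 2D_ea^2$), and the curvature prefactor shifts the true canonical
ratio by a factor ~2 — a real physical effect the quadrature captures.

## Protocols

**Zip-up.**  The freshly built duplex has all hydrogen bonds near 1.9 Å
(D~EQUI~ ≈ 1.90 Å).  `zip_up()` constrains the EQUI pair set and ramps
the target linearly from 1.88 Å to 1.56 Å over 10,000 steps of 0.5 fs
at 300 K, imposing the predefined hydrogen-bond pattern while letting
individual bonds redistribute.  During this stage the modified pair's
atoms are held fixed (there is no reliable classical parametrization of
its coordination), mirroring the original equilibration.  The endpoint
is exact to the solver tolerance for any seed — this is the package's
one deterministic protocol-endpoint check.

**Simulated annealing.**  `anneal()` multiplies the thermostat target
by 0.99 every 100 steps (30,000 steps by default), relaxing the
backbone.  The rescale interval is a package choice; only the factor is
prescribed by the protocol.

**Dissociation TI.**  `run_ti()` replays the window schedules: fifteen
0.2 Å windows for the full-duplex coordinate, piecewise schedules like
`"2.5:3.5:0.1,3.5:8.5:0.5"` for the Hg-free system, and 0.2 Å steps
for the isolated pair.  Each point runs at least a fixed number of
steps (1 ps at the default time step) with an optional 500 fs
pre-equilibration at the first point.  One deliberate adaptation: a
dissociation schedule starts at the *system's own* equilibrium dynamic
distance.  The published full-duplex schedule starts at 3.0 Å because
that is (near) the QM/MM system's free-energy minimum; the coarse toy
duplex, whose Hg coordinate bonds sit at 2.15 Å and whose N···O spans
are 4.3 Å, has its minimum near D = 3.4 Å.  Forcing the toy down to
3.0 Å first *compresses* the heavy Hg-bridged pairs (they carry ~8×
the weight of the N···H pairs) and tears regular pairs during the
squeeze — an artifact of transplanting a system-specific number onto a
different equilibrium geometry.  The default toy schedule is therefore
3.4 → 6.2 Å in 0.2 Å steps, preserving the protocol's structure.
Window sizes in the test suite are scaled to desk hardware (0.5–10 ps
per window depending on the check), stated here as the package's
choices.

## What the generator does and does not emulate

The synthetic systems reproduce: the pairing topology, charges, and
numbering of the experimental duplex; hydrogen-bond and coordinate-bond
geometry at the named-site level; the bistable Hg coordination; the
mass-weighting structure of the collective variable; and the protocol
schedules.  They do not emulate: explicit or implicit water (dielectric
screening is absent; the Coulomb switch is a crude stand-in),
electronic polarization and charge transfer at Hg (hence no
proton-transfer chemistry — the N3···H/N3···Hg monitor only *observes*
distances), sugar puckers and backbone torsions, or sequence-dependent
stacking.  Passing tests therefore demonstrate the correctness of the
machinery and the qualitative mechanics of the toy model, not the
energetics of real mercurated DNA.

## Numerical choices and degenerate inputs

* Constraint solver: tol 10⁻⁸ Å, max 50 damped-Newton iterations, one
  polish iteration; non-convergence aborts the step with diagnostics.
* The constraint entry precondition for single-step use is strict;
  `project_to_constraint()` places a configuration exactly on the
  constraint surface first.
* Degenerate CV inputs are rejected: empty pair lists, overlapping
  pairs (an atom in two pairs), and gradients at $D=0$.
* Coordination classification uses a 2.6 Å cutoff by default — between
  the 2.12–2.20 Å coordinate-bond medians and the 2.8 Å distance
  explicitly described as a broken bond.  The bistable-fixture analyses
  use 3.0 Å because that toy's pocket is wider; the cutoff is an
  argument everywhere.  Ties between patterns go to the smaller summed
  coordinate-bond distance.
* Oscillation counting applies a 3-frame majority filter (the source
  material reports oscillation qualitatively, with no counting rule);
  occupancy estimates use the raw labels.
* Median distances are reported both over the full trace and over the
  trailing half, since the averaging window of the published medians is
  unstated.
* Dihedral series are unwrapped across the ±180° branch cut; degenerate
  (collinear) frames are masked as NA.
* Free-energy profiles are reported relative to each run's first
  window, as no absolute reference is defined.

## Known limitations

Beyond the generator limitations above: the NHC integrator uses a
single Trotter cycle per half-step (adequate at 0.5–4 fs with a 1 ps
chain time constant); block-average errors assume windows long enough
for ≥5 roughly independent blocks; ion placement is rejection sampling,
not electrostatics-aware; and the weak-spot test is a property of the
mass-weighted coordinate plus the toy sterics, expected to be robust
but not a statement about force-field accuracy.  The engine is pure,
vectorized R — comfortable for a few hundred atoms and a few hundred
thousand steps, not for solvated all-atom systems.
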