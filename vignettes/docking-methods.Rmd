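---
title: "Contact-driven coarse-grained peptide docking: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact-driven coarse-grained peptide docking: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgdock)
```

## The problem

Protein-peptide docking asks for the bound pose of a short, flexible
peptide on a receptor protein.  Exhaustive all-atom sampling is
impractical, so cgdock works at a coarse-grained resolution in the style of
the CABS model family: each residue is reduced to its Calpha (restricted to
a cubic lattice), a Cbeta, a single side-chain interaction center (SC), and
a virtual peptide-bond center at each Calpha-Calpha midpoint.  Sampling is
replica-exchange Metropolis Monte Carlo with a fully flexible peptide and a
receptor that is flexible but held near its input conformation.

Often a little is known about the interface - one side-chain contact from
mutagenesis, cross-linking or NMR is common.  cgdock turns each such
contact $(i_\text{rec}, j_\text{pep})$ into a soft one-sided restraint on
the distance $D$ between the two SC pseudoatoms:

$$E(D) = \begin{cases} 0 & D \le D_0 \\ s\,(D - D_0) & D > D_0 \end{cases}$$

with defaults $D_0 = 5.0$ Å and $s = 1.0$.  Two properties matter.  The
potential is flat below $D_0$, so it never rewards squeezing the contact
tighter than a typical side-chain contact distance; and it is only added to
the *sampling* energy that drives Monte Carlo acceptance, never to the
*scoring* energy used to rank models.  The restraint steers the search
toward the binding site; the final ranking remains a pure force-field
judgement.

## The surrogate force field

The statistical potentials of the original CABS force field are not
reproduced here; cgdock ships pluggable surrogate terms with the same
structure:

* **Excluded volume** - a fixed penalty (`ev_penalty`, default 5) per
  pseudoatom pair closer than `hard_radius` (default 3.0 Å), counting
  cross-chain pairs and same-chain pairs at sequence separation of at
  least 2.
* **Pairwise SC-SC contacts** - for every SC pair within `r_on` (default
  6.0 Å), an energy read from a symmetric 20 x 20 residue-type matrix.
  The packaged default is a hydropathy-product matrix,
  $e_{ij} = -0.15\,h_i h_j$ on the Kyte-Doolittle scale, so
  hydrophobic-hydrophobic contacts are favourable and hydrophobic-polar
  contacts are penalised.  Any statistical contact matrix can be swapped in
  as a whitespace table via `dock_params()`.
* **Secondary-structure bias** - the peptide's preference string (H/E/C)
  is scored against the local Calpha geometry: a helix residue should have
  a Calpha pseudo-angle in [80°, 105°], an extended residue in (105°,
  145°], coil always matches; each mismatch costs `ss_weight` (default 1).
  The pseudo-angle windows alone separate helical from extended Calpha
  traces, so no pseudo-dihedral term is used.
* **Receptor near-native restraints** - all native Calpha pairs with
  sequence separation >= 3 and distance <= 8 Å are recorded once from the
  input receptor and held by flat-bottom penalties
  `rr_weight * max(0, |d - d_native| - rr_tolerance)` (tolerance 1.0 Å).
  The receptor moves, but not far.

All energies are in reduced units with $k_B \equiv 1$; temperatures are on
the same scale.  Every term depends only on internal distances and angles,
so the model is exactly invariant under rigid motion (property-tested).

## Sampling

Ten replicas run on a geometric temperature ladder from `t_min = 1.0` to
`t_max = 2.0`.  One cycle attempts one move per mobile residue; moves are
drawn from peptide rigid translations and rotations, single-residue kinks,
two-residue crankshafts, chain-end flips, and single-residue receptor
perturbations, with configurable weights.  On-lattice proposals draw from
the set of integer lattice vectors whose length falls in the physical
Calpha-Calpha window of 3.3-4.3 Å (lattice spacing 0.61 Å, the CABS-family
convention; the lattice can be disabled).  Proposals that would break that
bond window, or carry the peptide centroid beyond a bounding sphere
(receptor extent + scatter distance + 5 Å - a finite simulation volume),
are null moves.  Acceptance is Metropolis on the sampling energy; adjacent
ladder pairs attempt exchanges every 50 cycles with alternating parity,
swapping temperatures while replica identities stay with their
configurations.

Initial poses are self-avoiding random walks scattered around the receptor
at up to 20 Å from its surface (pseudoatom proxy), clash-free by
construction.  The default run length of 2000 cycles was chosen so that a
toy system equilibrates (the cold replica's restrained-distance trace
flattens in the first half) while a complete run remains interactive; it is
config-exposed like every other protocol parameter.

The production inner loop is compiled (Rcpp/RcppArmadillo).  Each replica
owns a splitmix64 stream seeded from the master seed, and exchanges use a
separate stream, so runs are bit-reproducible from `seed` and unaffected by
R's global RNG state; a test asserts that the kernel's per-snapshot energy
breakdown equals the R energy model's to floating-point accuracy.

## Model selection

A run emits 10 replicas x 1000 snapshots = 10,000 models.  Selection is a
three-stage funnel:

1. **Energy filter** - the 1000 models with the lowest scoring energy
   (ties broken by cycle, then replica).
2. **k-medoid clustering** (k = 10) on pairwise ligand RMSD - the peptide
   Calpha RMSD after Kabsch superposition of the receptors.  The clustering
   is PAM: alternation from k-medoids++-style seeded starts (5 restarts,
   best cost) followed by greedy swap refinement, because alternation alone
   stalls in local optima on a noticeable fraction of instances; instances
   small enough to enumerate are solved exactly.  It matches exhaustive
   search on all small random instances in the tests.
3. **Density ranking** - each cluster's density is its size divided by the
   mean pairwise ligand RMSD among its members ("average difference" read
   literally as the mean over unordered pairs; a mean-distance-to-medoid
   variant is available via `cluster_models(density = "medoid")`).
   Medoids are returned in density order; ties fall back to cluster size,
   then medoid energy.  Singleton or zero-spread clusters are given
   size/10^-3 and flagged, so degenerate densities are visible rather than
   infinite.

With a known reference pose the accuracy report gives the lowest ligand
RMSD within the pool, the filtered set, the top 100 by energy, and the
final 10 - nested sets, hence monotone minima.

## Synthetic systems

`make_toy_complex()` builds the test world: a compact self-avoiding
lattice globule with a concave binding pocket (a spherical cavity of radius
5 Å carved `pocket_depth` into the surface), a hydrophobic peptide laid
through the pocket mouth in a known native pose with alternating side
chains pointing into the cavity, a hydrophobic pocket lining with polar
remaining surface, and - deliberately - a second, unoccupied hydrophobic
concavity on the opposite face.  That decoy site makes the docking
landscape ambiguous the way real receptor surfaces are: without it,
default-mode docking nearly always finds the single funnel and contact
information has nothing to add, which would make the method's central claim
untestable.  Construction retries until the native pose is clash-free, has
at least one SC-SC receptor contact within 5 Å, and scores a lower
pair-contact energy than at least 95 of 100 random scattered placements
(the funnel guarantee, checked across a seed battery in the tests).

What the toys do *not* emulate: real side-chain rotamers (SC centers sit on
deterministic outward bisectors), realistic secondary structure, sequence
patterns beyond a hydrophobic/polar split, or the true CABS statistical
energetics.  Passing tests on toys therefore demonstrates that the
*machinery* - representation, sampling, restraints, selection - behaves as
specified, not that the surrogate force field would rank real complexes as
the original statistical potentials do.

## Numerical choices and degenerate inputs

* Lattice snapping rounds per axis; a repair pass moves offending residues
  to nearby lattice points if rounding pushes a bond outside 3.3-4.3 Å.
  Cbeta/SC ride along with their Calpha's snap displacement, preserving
  intra-residue geometry.
* Glycine has no side chain: its Cbeta and SC collapse to a point 1 Å
  along the outward bisector (at the termini, onto Calpha itself).
  Alanine's SC is its Cbeta.  Unknown residue types are scored with the
  contact-matrix column means and reported.
* Kabsch superposition uses the SVD with the determinant correction, so
  reflections are never returned; ligand RMSD is symmetric to 10^-6 and a
  pseudometric on models sharing a receptor.
* k-medoid ties (equal-cost medoids, equidistant points) break
  deterministically toward the lowest index; clustering restarts consume
  R's RNG, and `cg_dock()` seeds that stream from the master seed.
* Chain breaks (Calpha gap > 4.5 Å) warn and keep the chain: docking needs
  the receptor roughly intact, not covalently continuous.

## Problem sizes used in the checks

The packaged validation runs on toy complexes of 40 receptor residues and
6-residue peptides: full funnels (10 x 1000 snapshots, filter to 1000,
k = 10) for the cardinality and efficacy checks, with eight paired seeds
for the default-vs-contact comparison; smaller trajectories (10 x 100) back
the unit tests.  These sizes keep the complete suite in the minutes range
on one core while exercising every stage at full funnel cardinality.

## Known limitations

* The surrogate force field is structural, not statistical: absolute
  energies and energy gaps have no physical calibration.
* Whether the original protocol applies the contact restraint per replica
  temperature is not documented; cgdock applies it uniformly across the
  ladder, and sums multiple simultaneous contacts.
* The all-atom refinement stage of the published pipeline is out of scope;
  the coarse-grained top-10 models are exported (multi-MODEL PDB) as the
  hook point for external refinement tools.
* On-lattice rigid rotations are snapped and bond-checked, which rejects a
  fraction of large rotations; rotational mixing at low temperature relies
  correspondingly more on replica exchange.
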