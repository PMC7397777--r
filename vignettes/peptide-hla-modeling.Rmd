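---
title: "Modeling peptide-HLA binding modes with pHLAdock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling peptide-HLA binding modes with pHLAdock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pHLAdock)
```

## The modeling problem

Class I HLA receptors present short peptides (8-11 residues) in a binding
groove whose conserved A and F pockets anchor the peptide termini.
Predicting the bound geometry of a given peptide, estimating its binding
energy, and ranking large candidate libraries are the three tasks this
package addresses.  Two complementary sampling strategies are provided:

* **Incremental meta-docking** (`incrementalDock`): a small N-terminal
  fragment with at most *k* rotatable bonds is docked from many starts;
  the *n* best modes are grown by one residue per round, newly added bonds
  become flexible and the oldest flexible bonds are frozen at their
  optimized values, until the whole peptide is reconstructed in the site.
* **Anchored ensemble generation** (`generateEnsemble`): the peptide
  termini are placed on template anchor coordinates, the backbone in
  between is closed many times by randomized coordinate descent, side
  chains are rebuilt from a discrete rotamer set, and each mode is locally
  optimized; optionally the best mode's termini seed the next round.

Both produce `Ensemble` objects of `BindingMode`s that are scored and
re-ranked by three empirical pairwise scoring functions and consumed by
three workflows: geometry prediction, ensemble binding-energy prediction,
and two-stage virtual screening.

## The molecular data model

A `PeptideConformation` stores heavy atoms only.  Cartesian coordinates
are the ground truth; a named torsion tree (phi/psi per residue, side
chain chi angles, and the terminal carboxylate rotation) is edited with
`setDihedral`, implemented as a rigid rotation of the atoms distal to the
bond axis.  Because each edit is an exact rigid rotation, bond lengths and
angles are preserved to machine precision no matter how many edits are
applied -- the property that makes torsion-space search sound.  Ideal
geometry comes from internal-coordinate (NeRF) construction in
`buildExtendedPeptide`; conformations read from PDB keep their as-read
geometry.

Two special cases are worth knowing about.  Proline's ring chi angles are
fixed and the ring-closure bond is not part of the kinematic tree, so
proline's phi remains formally rotatable without an explicit ring
constraint -- a simplification that slightly misrepresents proline
backbone preferences.  Aromatic rings are built planar and move as rigid
units on their chi axes.

```{r}
pep <- buildExtendedPeptide("QFKDNVILL")
pep
head(listDihedrals(pep))
checkGeometry(pep)$max_bond_dev
```

## Scoring functions

Three scoring variants share one pairwise machinery operating on surface
distance (interatomic distance minus the two van der Waals radii), summed
over all receptor-peptide heavy-atom pairs within 8 Angstrom, plus a
torsional penalty proportional to the number of active rotatable bonds:

* `vina_class`: two Gaussian attraction terms, quadratic repulsion at
  negative surface distance, linear hydrophobic ramp (0.5-1.5 A) between
  hydrophobic carbons, and a linear hydrogen-bond ramp (-0.7-0 A) between
  donor and acceptor heteroatoms, with the published weights.
* `vinardo_class`: one Gaussian, shifted radii, and its published weights.
* `ad4_class`: a grid-free direct sum of 12-6 van der Waals wells with a
  12-10 hydrogen-bond well and the force-field scaling coefficients; no
  partial charges or desolvation are modeled, so electrostatics are
  absent by design.

The torsional penalty is additive (weight times rotatable-bond count)
rather than the divisive form some docking engines use, so that a score
breakdown's total is exactly the sum of its terms.  Energies are in
kcal/mol and lower is always better.  Atom classes (hydrophobic carbon,
polar carbon, donor, acceptor, donor-acceptor, other) are looked up from
per-residue topology tables; a carbon is hydrophobic exactly when it has
no N/O/S neighbour in the bond graph.

During optimization the docking objective adds an intra-peptide clash
penalty: quadratic repulsion between atom pairs more than five bonds
apart, with a 0.5 A buffer so that the near-contacts of legitimate
compact backbones are not punished.  Reported scores from `scoreMode`
remain pure receptor-peptide terms.

## The incremental docking engine

The per-run optimizer is an annealed Metropolis search: a soft phase with
repulsion scaled to 25% lets clashed starts relax across barriers, a
full-energy phase at low temperature localizes, and a deterministic
line-search polish (per-dihedral sweeps over coarse-to-fine angle steps,
plus gradient line searches over the rigid-body coordinates) finishes.
A run never returns a pose worse than its input.

Round bookkeeping follows the fragment-growth contract: the flexible set
is always the newest at most *k* bonds; frozen values live in the
coordinates and are carried over exactly.  Three engine choices go beyond
the minimal scheme and are the package's own design: round-1 starts
include poses seeded on the receptor's A-pocket anchor coordinates (the
`Receptor` class records them for exactly this purpose) alongside
random-box samples; expansion restarts initialize new backbone bonds from
the beta basin, where bound class I peptides overwhelmingly sit; and
after each round a sliding *k*-window refinement relaxes previously
frozen bonds -- never more than *k* simultaneously -- so early rounds'
small errors do not accumulate unchecked.  Selection between rounds is
energy-sorted with an RMSD diversity gate (2 A on active atoms) so
distinct binding registers survive pruning.

Defaults: `k = 6`, `n = 10`, 50 Monte-Carlo steps per run, one residue
per expansion round, `vina_class` as the round objective.  Parallel
workers only partition runs; each run seeds its own generator
(base seed + run index), so results are bit-identical for any thread
count.

## Anchored ensemble generation

`placeAnchors` superposes the first residue's backbone on the template's
N-terminal anchor and registers the C-terminal anchor as the closure
target; feasibility requires the anchor span to be within the chain's
maximum reach (3.8 A per residue step).  `closeLoops` runs randomized
coordinate descent on the interior phi/psi: each step sets one dihedral
to the closed-form angle minimizing the distance of the last residue's
N/CA/C to the target, with an escape perturbation after 15 stalled
iterations and up to 3 fresh initializations per sample; samples that
fail to reach the 0.3 A default tolerance within 1000 iterations are
dropped with a message.  The first sample starts from the canonical beta
backbone (phi -80, psi 90), which is deterministic and comparable across
peptides; later samples draw mostly from the beta basin with a
uniform-random minority for breadth.

Side chains are rebuilt greedily N-to-C from a discrete rotamer set
(chi1/chi2 in {-60, 60, 180}, at most 9 combinations per residue; later
chis start anti), scored against the docking objective, then refined by
an anchor-bounded Monte-Carlo pass and bounded line searches over
backbone and chi angles that reject any move taking the anchors outside
the template tolerance.  Iterative rounds carry the best mode forward, so
the per-round best energy is non-increasing by construction.

## Workflows

* `geometryPrediction`: incremental docking, removal of
  reverse-orientation modes (first-to-last CA vector against the groove
  axis), rescoring with all three functions, top-5 reporting per
  function, and -- when a reference pose is given -- all-heavy-atom RMSDs
  in the receptor frame with a near-native flag at the 2.5 A threshold.
  No peptide-level superposition is applied; for cross-receptor
  comparisons superpose receptors first (`superposeReceptors`).  No
  symmetry correction is applied for chemically equivalent atoms
  (terminal carboxylate oxygens, ring flips); atoms are matched by name.
* `bindingPrediction`: one anchored ensemble per peptide, the median
  ensemble energy per scoring function (even counts average the central
  pair), and Pearson R against log10(affinity nM) when at least three
  experimental affinities are supplied.  The log10 transform is the field
  convention for affinity data spanning orders of magnitude.
* `virtualScreen`: stage 1 keeps peptide-allele pairs at or below the
  affinity threshold (500 nM default; infinity disables the filter),
  stage 2 models survivors with a single ensemble round and records the
  top-scored mode's energy, stage 3 ranks per allele by ascending energy.
  The prefilter interface is pluggable; the built-in baseline is a
  position-weight-matrix model with additive pseudocount 1 over a uniform
  background, mapped to a pseudo-nM scale by nM = 50000^(1 - s) with s
  the min-max-normalized log-odds score.

The internal minimizer behind the pluggable minimization interface is a
bounded greedy line-search descent over peptide dihedrals; an external
molecular-mechanics minimizer can be supplied as a plain function and is
never required.

## The synthetic fixture generator

`makeToyPocket` builds a rigid pseudo-atom groove around a planted
peptide conformation: the backbone is set to the beta region (phi -80,
psi 90; about 2.9 A of anchor span per residue, as in real grooves), and
for every peptide heavy atom complementary contact atoms are placed on
the walls-and-floor side (hydrogen-bond partners slightly inside the
contact surface, where the scoring functions' H-bond wells live).  Four
structural elements make the pocket behave like a solid receptor rather
than a thin shell: a backing atom directly behind every contact, a
neutral lid on the opposite side at a larger offset (force balance
without rewards, and a deliberate top-bottom asymmetry so mirrored
backbones lose), end-cap walls beyond both termini, and a thin
void-filling crust of neutral atoms on a 1.8 A grid wherever the shells
leave room.  The emitted ground-truth mode is the pocket's own energy
minimum: the construction pose relaxed by the deterministic polish, so
that an ideal search should return exactly it.  At construction the
planted pose is verified to beat at least a thousand random probe poses;
otherwise the pocket regenerates with a derived seed (at most 5
attempts).

What these pockets emulate: a sequence-specific, sterically closed groove
with known global minimum, anchors, axis and box, enough to exercise
every sampling and scoring path.  What they do not emulate: real HLA
geometry, electrostatics, solvation, receptor flexibility, or the
statistics of real immunopeptidomes.  A green test on these fixtures
shows algorithmic correctness, not predictive accuracy on real
structures.

`makeScreeningSet` draws motif-matched binders (each position from the
preferred residues with probability 0.9) and uniform decoys, disjoint by
construction, at the 500/1000 per-allele composition or any scale of it.
The six-allele synthetic panel (`makeAllelePanel`) uses medium-sized
planted residues throughout, so that screening discrimination has both
channels available: larger decoy side chains clash with the solid
groove, smaller ones forfeit contacts.

## Numerical choices

* Cutoff 8 A on interatomic distance; direct summation, no grids.
* Closure tolerance 0.3 A (RMSD over the last residue's N/CA/C).
* Dihedral edits are exact rotations; geometry checks assert 1e-9.
* Ties in ranking break by (round, replicate, seed) provenance.
* All child seeds derive from one base seed by a stable integer hash, so
  every stage is reproducible in isolation and results are independent
  of scheduling; seeds stay below 2^31.
* Problem sizes in the shipped tests are desk-scale by choice: toy
  pockets of 150-300 pseudo-atoms, ensembles of 4-10 backbones for
  screening, 10 binders + 20 decoys per allele (a 2% scale model of the
  500/1000 design), and five-pocket recovery batches.

## Known limitations

* Blind planted-pose recovery by the incremental engine at default
  effort is unreliable on these fixtures: the engine's best mode
  typically lands 3-7 A from the planted pose, in register-correct but
  conformationally distinct local minima 0.5-1.5 kcal/mol above the
  planted one.  Local recovery works (starts within ~2.5 A converge
  about half the time), and the anchored ensemble generator reaches the
  planted basin far more cheaply; combining the two (ensemble-seeded
  refinement) is the practical route to near-native geometry here.
* Screening enrichment rests on steric fit plus matched hydrogen-bond
  wells; the functional forms contain no electrostatic mismatch penalty,
  so size-matched decoys occasionally out-rank mutated binders.
* The scoring implementations follow the published functional forms but
  are not calibrated against any external docking binary's numeric
  output, and the ad4-class variant omits charges and desolvation.
* No receptor flexibility, no hydrogens, no protonation states, no
  symmetry-corrected RMSD.

## A short session

```{r, eval = FALSE}
fx <- makeToyPocket(seed = 1)
ens <- incrementalDock(peptideSequence(fx$truth), fx$receptor,
                       DockingConfig(seed = 1))
rep <- geometryPrediction(peptideSequence(fx$truth), fx$receptor,
                          reference = fx$truth,
                          dock_config = DockingConfig(seed = 1))
rep$min_rmsd
rep$near_native
```
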