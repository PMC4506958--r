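---
title: "Characterising protein–ligand binding modes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterising protein–ligand binding modes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindmode)
```

## The problem

A small-molecule ligand bound in a crystal is not necessarily bound the way
it is in solution. When the ligand itself mediates crystal packing — making
contacts to a symmetry-related copy of the protein as well as to the
asymmetric unit — the observed pose can be selected by the lattice rather
than by the protein. Deciding whether that has happened takes three kinds of
evidence, and this package computes all three:

1. **What the crystal says.** Classify every protein–ligand contact in the
   deposited structure (hydrogen bond, water-mediated hydrogen bond,
   nonpolar, electrostatic), list the recognising residues, and count how
   many ligand contacts go to the asymmetric protein chain versus its
   symmetry mates.
2. **What simulation says.** From an MD trajectory of the complex, count
   protein–ligand contacts per frame, take an equilibrated analysis window,
   and cluster the frames into binding modes by all-pair fitted RMSD.
3. **How the two relate.** Superpose MD cluster centres and other reference
   complexes onto the crystal structure and measure positional mimicry of
   key groups (e.g. a carboxylate standing in for a substrate glutamate).

The motivating system is the Kelch domain of human Keap1 — the β-propeller
that binds the ETGE and DLG motifs of Nrf2 — in complex with a carboxylate-
bearing ligand, and the package's defaults (atom names such as OAA/OAB/OAC,
3.4 Å contact cutoff, 500-frame windows at 20 ps stride) follow that analysis
setting. Everything is configurable, and nothing is specific to that
protein.

## Contact classification

The classifier works on heavy atoms only; crystal structures at typical
resolution carry no hydrogens, and published contact tables are heavy-atom
rows. Each protein-atom/ligand-atom pair within the electrostatic range is
assigned exactly one type, with precedence **HB > NP > ES**:

* **HB** — distance ≤ `hb_max` (default 3.4 Å), both atoms N or O, the pair
  donor/acceptor-complementary, and the donor-angle criterion satisfied.
* **NP** — any other pair with distance ≤ `contact_max` (default 3.4 Å).
* **ES** — a formally charged positive/negative pair with distance in
  `(hb_max, es_max]` (default 4.0 Å).

Reserving ES for the shell beyond `hb_max` is deliberate: published
classifications of this kind label charged pairs *inside* hydrogen-bond
range as hydrogen bonds (e.g. an arginine Nε to carboxylate-O at 2.88 Å)
and use ES only for the longer charged contacts (3.44–3.51 Å). This
precedence reproduces such tables without contradiction.

**The angle criterion.** With no hydrogens, donor geometry is checked on
heavy atoms: the angle *antecedent–donor–acceptor* must be at least
`hb_angle_min` (default 90°), where the antecedent is the donor's nearest
covalently bonded heavy atom (≤ 2.0 Å within the same residue). A donor
whose bonded neighbour lies between it and the acceptor cannot point a
hydrogen at the acceptor; such pairs are demoted to NP. The 90° default is
a permissive, conventional choice — the criterion used in the original
analyses of such tables is rarely stated — and it is exposed in
`interaction_rules()` precisely because it is a judgement call.

**Donor/acceptor typing.** A built-in table covers the 20 amino acids
(backbone N donor, backbone O acceptor, the usual side-chain assignments;
hydroxyls are both). Ligand atoms are typed by a per-ligand block, because
no general chemistry perception is attempted: the default block types the
carboxylate oxygens (OAA/OAC) as acceptors and formally negative, the
ureido oxygen (OAB) and an oxadiazole ring nitrogen (NAO) as acceptors, and
three nitrogens (NAM/NAN/NAP) as donors. Ether and ring oxygens (OAQ, OAR,
OAO) are deliberately *not* acceptors: aryl/alkyl ether oxygens are poor
acceptors, and typing them as acceptors would turn several published
nonpolar rows into spurious hydrogen bonds. The whole block can be replaced
from YAML (`read_interaction_rules()`).

**Water bridges.** A water that makes one hydrogen-bond leg to the protein
and one to the ligand (each leg ≤ `hb_max`, donor/acceptor-complementary;
water counts as both) is one water-mediated hydrogen bond — one interaction
per (protein atom, water, ligand atom) triple, not two, matching how such
bridges are counted in published summaries even though they print as two
table rows.

## Crystal-packing audit

`count_packing_contacts()` counts ligand–protein pairs at ≤ 3.4 Å twice
over: against the deposited chain (`n_asu_contacts`) and against every
symmetry image of it (`n_sym_contacts`, with a per-mate breakdown).
Operators for P1, P2₁2₁2₁ and P6₅22 — the groups the packing analyses here
need — are tabulated in-package from International Tables generators; the
operator list is validated by closure/determinant property tests.

Conventions, each exposed as an argument:

* Both counts use **protein atoms only**; crystallographic waters are
  excluded (`include_waters` flips this for the symmetry images). The
  published counts this module mirrors describe contacts "to the
  asymmetric and the symmetry-related molecules" of the protein, which
  reads as protein atoms; with no deposited coordinates bundled here the
  convention could not be re-validated against the published 20/5 and 16/7
  counts, so it is documented rather than asserted.
* The lattice-shift search range is derived per axis from the fractional
  extents of ligand and image plus a radius-dependent margin and one full
  cell of padding — never hard-coded — and the result is cross-checked in
  tests against exhaustive ±2-cell enumeration.
* The identity image with zero shift (the molecule itself) is never a mate.

A useful invariant holds by construction and is property-tested: applying
any space-group operator to the *entire* model (choosing a different copy
as the asymmetric unit) leaves both counts unchanged.

## Trajectory analysis

Multi-model PDB files are read as trajectories (`read_multimodel_pdb()`),
with frame times `start + (i-1)·stride` (defaults 20 ps / 20 ps). All
models must share one atom roster; the first mismatching model is named in
the error. The analysis window — e.g. frames 501–1000 of a 1000-frame,
20 ns production run — is taken with `window()`, which preserves times and
original frame numbers (1-based, so "frame 892" means the same thing in a
report as in the source trajectory).

**Superposition-atom selection** (`derive_superposition_atoms()`): a
protein–ligand atom pair qualifies if its *minimum* distance over the
window is ≤ 3.4 Å; the superposition set is the union of atoms in
qualifying pairs minus flip-ambiguous atoms — tyrosine/phenylalanine
CD1/CD2/CE1/CE2 and the ligand carboxylate oxygens OAA/OAC, whose names can
swap under ring flips or carboxylate rotation during MD. Arginine NH1/NH2
are *not* excluded by default, matching the published selection rule this
implements. The exclusion set is configuration, not code.

**Per-pair statistics** (`pair_stats()`): occurrence count, mean distance
over occurring frames, and frequency as % of the window; sorted by count
descending with deterministic tie-breaks (mean distance ascending, then
protein atom index) and filtered at a 20% frequency threshold by default.
Values are kept at full precision internally; `format_pair_stats()` rounds
to the report precision (2 decimals / 1 decimal) only at output. A
conservation law ties the two views together and is tested: the unfiltered
occurrence counts sum to the per-frame contact counts summed over frames.

## RMSD clustering

`pairwise_rmsd()` builds the all-pair matrix of fitted RMSDs over the
selected atoms using the Kabsch algorithm (SVD form, reflection branch
corrected so the rotation is always proper). The implementation is verified
against an independent quaternion characteristic-polynomial oracle and
against bio3d's fitting routine in the test suite. Collinear point sets are
rejected (the rotation about the line is undetermined); the zero-RMSD
tolerance used in assertions is 10⁻⁶ Å.

`daura_cluster()` implements the greedy neighbour-count algorithm: among
unassigned frames, each frame's neighbours are the other unassigned frames
with RMSD **strictly less than** the cutoff; the frame with the most
neighbours becomes a centre, it and its neighbours form a cluster and are
removed; repeat. Ties in the neighbour count go to the lowest frame index
(the algorithm's source description is silent; determinism is required),
and a centre's cluster includes itself but its neighbour count does not.
Cluster sizes are non-increasing in extraction order, the result is always
a partition, and the implementation is tested against an exhaustive
re-derivation for all small frame sets.

**Cutoff heuristic.** `cutoff_from_mean()` returns the stated fraction
(default 0.70) of the mean off-diagonal RMSD, snapped to the nearest 0.1 Å.
For a window with mean intratrajectory RMSD 1.232 Å this gives
0.70 × 1.232 = 0.8624 → **0.9 Å**. The heuristic is a default, not a claim:
analyses of this kind describe *searching around* 70% of the mean, and at
least one published choice (2.8 Å where 0.70 × 4.179 snaps to 2.9 Å) shows
a search rather than a rounding. The exact unsnapped value is returned for
diagnostics and an explicit cutoff can always be passed instead.

`cluster_report()` reports, for each cluster holding ≥ 10% of the window:
size, centre frame and time, mean intracluster RMSD, per-cluster contact
statistics, and — given a crystal reference sharing the roster — the mean
member RMSD to the crystal, the crystal-to-centre RMSD, and whether the
crystal would join the cluster (centre RMSD strictly below the cutoff),
which is how "the crystal structure does not belong to any cluster" is made
operational.

## Pose-mimicry metric

Published comparisons of a ligand group against a substrate side chain are
usually qualitative ("the carboxylate overlaps the first glutamate").
`mimicry_overlap()` quantifies this as the centroid–centroid distance
between small probe atom groups after a Cα-anchored superposition of the
query complex onto the reference. Centroid distance was chosen over
per-atom RMSD because the compared groups (a carboxylate vs a glutamate
carboxylate) need not have a canonical atom correspondence — the two
oxygens are chemically equivalent. Anchors correspond by order; when
comparing different crystal forms, atoms are paired by residue number and
atom name with missing counterparts dropped, and an explicit residue
exclusion list handles terminal residues modelled differently between
forms (auto-detection is deliberately avoided).

## The synthetic-data generator

`simulate_trajectory()` provides the ground truth the pipeline tests need
without any external data. It emulates exactly the statistical structure
the clustering analysis assumes:

* a rigid receptor (a deterministic helix-like pseudo-protein whose residue
  cycle includes Tyr/Phe ring carbons, Arg guanidinium nitrogens and
  Ser/Asn polar atoms, so selection and flip-exclusion logic is exercised);
* a 39-atom ligand template (26 named heavy atoms echoing the
  oxyacetic-acid/ureido/oxadiazole naming, 13 hydrogens) parked against the
  receptor surface at a distance chosen to give a realistic ~10–15
  contacts per engaged frame without steric clash;
* per frame, a pose drawn from *k* planted modes — rigid transform of the
  template plus isotropic Gaussian noise (default σ 0.18 Å) — with stated
  occupancies (defaults 0.60/0.25/0.15 over 500 frames at 20 ps stride);
* optional dissociation frames (the weight left over from the modes), with
  the ligand displaced ≥ 20 Å beyond any contact range, so zero-contact
  frames appear at a stated rate.

Mode counts are realised by largest-remainder apportionment of the stated
occupancies and a seeded permutation of frame order, rather than i.i.d.
draws: realised occupancies then match the stated occupancies exactly, which is
what a generator used as ground truth for cluster-size recovery should do.
Draws are i.i.d. in order — there is no Markov kinetics, no solvent, no
internal ligand flexibility, and no force field. Passing the recovery tests
therefore shows that the clustering machinery identifies well-separated
rigid poses at stated occupancies; it says nothing about conformational
exchange, partial occupancy along a pathway, or force-field quality in real
trajectories. Each simulation uses one explicit seed and restores the
caller's RNG state.

`make_crystal_fixture()` places a sparse pseudo-protein and ligand in a
chosen cell/space group so that the packing audit finds exactly a requested
number of asymmetric-unit and symmetry-mate contacts (the construction is
verified geometrically and fails loudly if the cell is too small).
`make_interaction_fixture()` builds isolated interaction units (serine HB,
alanine NP, arginine ES, serine–water–ligand bridge, 50 Å apart) realising
an exact classification profile.

## Numerical and scale choices

* Superposition: unweighted (no weighting scheme is published for the
  comparisons this mirrors); reflection-corrected; degenerate inputs error.
* Coordinates are stored in Å in the orthogonal frame; fractionalisation
  happens only inside the packing module.
* Altloc policy on reading: keep blank or "A", drop others (configurable);
  residue numbering is taken verbatim from the file.
* Where a modelled range is ambiguous (a construct boundary residue absent
  from the file), selections use what the file contains; nothing is
  guessed or renumbered.
* Report rounding happens only at format time; all statistics are computed
  at full precision.
* The test suite runs its trajectory problems at 40–200 frames and its
  property sweeps at 10–200 random instances; these sizes give the
  clustering and superposition checks full coverage of the algorithms'
  decision points while keeping the suite quick, and every size-dependent
  assertion (occupancy recovery, purity) is formulated to hold at any
  window length.

## Known limitations

* No π-stacking, cation-π or halogen-bond classes; no protonation-state
  prediction; histidine charge is off by default (configurable).
* Ligand chemistry is typed by configuration, not perceived from the
  molecular graph.
* Trajectory input is multi-model PDB only; binary MD formats are out of
  scope.
* Space-group support covers the tabulated groups; other symbols error
  with the supported list rather than guessing.
* The mimicry metric assumes the anchor superposition is meaningful, i.e.
  the protein scaffolds are essentially rigid between the compared
  complexes.
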