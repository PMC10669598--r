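---
title: "Semi-rigid docking of sulfated glycosaminoglycans: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-rigid docking of sulfated glycosaminoglycans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycodock)
```

## The problem

Heparin/heparan sulfate (Hp/HS) oligosaccharides are linear, highly
anionic chains of alternating glucosamine (GlcN) and uronic acid
(GlcA/IdoA) residues, variably N- and O-sulfated. Their conformation is
dominated by the glycosidic torsions Phi and Psi about each inter-residue
linkage, and their binding sites on proteins are shallow, cationic and
solvent-exposed. Pose prediction for such ligands sits between two bad
extremes: holding every glycosidic torsion at its reference value (rigid
docking) forfeits the small adjustments an optimal fit needs, while
letting all of them rotate freely (flexible docking) turns a di- to
decasaccharide into a 12-60-rotatable-bond search problem that a
stochastic search cannot cover.

The middle course implemented here is *semi-rigid* docking: each
glycosidic torsion is sampled from a bounded, bell-shaped probability
histogram of half-width 30 degrees centered on a reference value, while
substituent torsions (sulfates, carboxylates, N-acetyl groups) rotate
freely and ring puckers never move. The 30-degree window reflects how
tightly curated crystallographic Phi/Psi observations cluster around
their class minima: UA->GlcN linkages populate two minima, near
(-80, -100) and (-80, 65) degrees, GlcN->UA linkages one, near
(80, -145); `default_torsion_centers()` records these.

## The search

Poses are chromosomes: three translation genes bounded by the binding
site box (all residues within 6 A of the reference pose, plus a 2 A
margin), a unit quaternion for orientation, and one gene per rotatable
bond tagged `fixed`, `bounded` (histogram resample) or `free` (uniform
on the circle) according to the regime. Decoding applies torsions along
a spanning tree rooted at the reducing end (so a torsion change moves
only atoms distal to its bond), then the rigid-body placement.

The genetic algorithm is steady-state: tournament selection (size 2),
one-point crossover over the flattened gene vector (probability 0.9),
per-gene mutation (probability 0.1; at least one gene is always mutated,
since an unmutated clone is a wasted evaluation), and crowding
replacement - a child competes with the most similar member of a random
subset - so distinct binding modes survive side by side instead of the
population collapsing into the first good basin. Mutation mixes local
moves (translation sd 1 A, rotations of sd 15 or 4 degrees) with
occasional global jumps (uniform translation or orientation), and
rotations may pivot about a randomly chosen ligand atom rather than the
centroid: a pose held by contacts at one end is refined by rotations
about that end, a move that centroid rotations plus independent
translations essentially never produce. Because elongated
polysaccharides bind grooves with their long axis along the site, half
of each initial population is seeded axis-aligned (either direction,
random roll and slide); the other half is fully random. A run performs
exactly `n_operations` offspring evaluations and returns its all-time
best poses, deduplicated at 0.25 A RMSD.

Replicate orchestration mirrors the triplicate convention: replicate r
uses seed `base + r - 1`; each run contributes its top two distinct
poses to the replicate pool, of which the two highest-scoring distinct
poses are kept, giving 3 x 2 = 6 analysis poses. Ties are broken by
(replicate, run, pose index), deterministically.

## The score

The score is a documented surrogate for a commercial docking score,
additive over four terms, higher is better:

* **H-bonds**: receptor donors (charged N) vs ligand acceptor oxygens;
  full weight at <= 3.0 A, linear taper to zero at 3.5 A. Each donor
  saturates at three H-bond equivalents (an ammonium carries three
  hydrogens), so crowding acceptors around one donor is not rewarded.
  Heavy-atom geometry only: the package deliberately works without
  hydrogens, so the well is distance-based with no angle term.
* **Electrostatics**: 332 q_i q_j / (4 r^2), a distance-dependent
  dielectric eps = 4r on a kcal/mol-like scale, with r clamped at the
  2.8 A contact distance so that burying charges into each other is
  never better than a formed salt bridge. Attractive and repulsive
  parts enter the total separately (repulsion is always a penalty).
* **van der Waals**: 6-12 Lennard-Jones on summed per-element radii,
  well depth 0.2, with the repulsive branch capped at 10 per pair (a
  soft clash wall keeps the landscape searchable).
* **Internal strain**: a quadratic penalty when ligand atom pairs more
  than four bonds apart fall below 80% of their summed vdW radii - and
  never below their distance in the reference conformation, which is
  strain-free by definition (idealized sugar geometry legitimately
  holds some through-space pairs close).

Formal charges are a group model: each sulfate -1 split over its
terminal oxygens, each carboxylate -1 over its two oxygens, free amines
+1; sulfate terminal oxygens carry the carboxylate-oxygen (`O.co2`)
surrogate atom type. The default term weights put most of the pose
discrimination on the H-bond term (weight 9 per H-bond equivalent): a
formed bidentate salt bridge is worth roughly 25-30 points, register-
shifted or flipped poses satisfy clearly fewer of them, and typical
native scores of tight synthetic complexes run 120 (disaccharide) to
600 (decasaccharide) - a scale on which the default selectivity
threshold (ratio 50, below) is meaningful.

A pose whose centroid leaves the site box by more than twice the margin
scores -Inf and can never be retained.

## The metrics

All RMSDs are in-place over heavy atoms in canonical atom order - the
docked and native poses share the receptor frame, and superposition
would erase exactly the translational error being measured. For a
six-pose analysis set against a native pose:

* `RMSD_AVERAGE`: mean of the six native-vs-pose RMSDs (interpreting
  "the average of the poses" as the average of the RMSDs; an
  `rmsd-to-centroid` mode - RMSD to the coordinate-averaged phantom
  structure - is available for sensitivity analysis but unphysical as a
  default).
* `RMSD_LOWEST`: the single best match.
* `RMSD_INTRAPOSE`: mean over all 15 unordered pose pairs; a
  single-pose set reports NA, not 0.

A system *recapitulates* when `RMSD_AVERAGE` is at or below the
geometric-equivalence threshold (2.5 A) and is *consistent* when
`RMSD_INTRAPOSE` is; both thresholds are configuration, surfaced in
every report. An optional per-chain-length scaling hook exists but is
off by default. Sulfate and carboxylate terminal oxygens are
exchange-equivalent; `symmetry_handling` permutes them within groups
(independent per group, which is globally optimal for disjoint groups)
before the RMSD - off by default, since the canonical-order metric is
what the pose files preserve.

Torsional deviations are computed per linkage as the magnitude of the
circular difference between the circular mean of the docked Phi (or
Psi) values and the native value, in [0, 180] degrees; linkage "2->1"
joins the reducing-end residue 1 to residue 2. The selectivity ratio is
mean score / RMSD_AVERAGE, with a +Inf sentinel at zero RMSD and a
configurable cut (default 50) above which a system is flagged
selective; the threshold is on this package's score scale and must be
recalibrated for any other scoring function.

## The synthetic fixtures

Everything the tests and the benchmark need is generated in code.
Chains are idealized: regular-hexagon pyranose footprints with
Cremer-Pople out-of-plane displacements (Q = 0.57 A chairs, 0.62 A for
the 2SO skew-boat; canonical azimuth 270 degrees under the C1-first
ring indexing), C-C 1.52 A / C-O 1.43 A bonds, tetrahedral exocyclic
directions, and glycosidic torsions set exactly to a per-linkage plan
(re-measured agreement is better than 0.01 degree). Pucker
classification uses theta <= 45 (4C1), theta >= 135 (1C4), and a +/-30
degree azimuth window in the equatorial band (2SO); the windows are
configurable constants, since only the conformer names, not the cuts,
are fixed by convention.

Receptors are toy grooves, not proteins: one cationic pseudo-residue
per anionic anchor in bidentate salt-bridge geometry (straddling two
terminal oxygens of the group), plus neutral carbon walls forming a
U-channel around the chain. `tightness` scales the fraction of anchors
and walls kept: 1 is the tight benchmark pocket, 0.35 a loose pocket
with a flat, inconsistent landscape, and 0 leaves nothing within 6 A
(the empty-site error path).

Two fixture design points deserve emphasis. First, redocking fixtures
use a *heterogeneous* sulfation pattern (N-sulfated and N-acetylated
glucosamines, one rare 3-O-sulfate, variably 2-O-sulfated uronic
acids): a uniformly sulfated chain in a self-complementary groove is
register-shift degenerate - every disaccharide step looks alike - and
"the" native pose of such a system is ill-posed for any docking
program. The *minimal* pattern (GlcN: NS + 6S; UA: carboxylate + 2S) is
retained as the default spec because it realizes the minimal per-residue
rotatable-bond complements (5 per uronic acid, 7 per glucosamine,
counting each residue's share of the glycosidic bonds and the terminal
O1/O4 cap bonds), which is what makes the 12/36/60 di-/hexa-/deca-
rotatable-bond tallies exact. Whether those per-residue minima include
the glycosidic bonds is not fixed by convention; this decomposition is
documented, not asserted as the only bookkeeping. Second, what passing
the synthetic benchmark shows is algorithmic: the search, the metrics
and the regime logic behave as designed on well-posed pockets. It does
not show that real protein sites are recovered - real sites have
protein flexibility, waters, and crystallographic context that the toy
grooves deliberately omit.

## Problem sizes and defaults

Full-scale searches (100 runs x 10,000 operations, in triplicate) are
one flag away, but the package's own benchmark preset runs 3 runs x
2,000 operations with population 60 (mutation probability 0.2,
tournament size 3) per replicate across six fixtures
(di- to decasaccharide tight grooves plus a loose hexasaccharide) and
all three regimes - sizes chosen so the full benchmark completes on one
CPU in minutes while leaving the qualitative contrasts (rigid and
semi-rigid recapitulate at least as often as flexible; flexible Psi
deviations are far larger; tight pockets sit above the selectivity
threshold, loose below) clearly resolved. The number of genetic
operations per run is configurable; 10,000 is the default, and a
methods-text vs figure-caption discrepancy in its source (10,000 vs
100,000) is resolved in favor of the smaller documented value.

## Numerical conventions

Angles live in the half-open interval (-180, 180] and all angle
arithmetic is circular; angle means are circular means. Dihedrals use
the atan2 formulation with Phi = O5-C1-Ox-Cx and Psi = C1-Ox-Cx-C(x-1)
(heavy-atom crystallographic convention; the tag is recorded in every
chain so users of other conventions can convert). Histograms default to
1-degree bins with a raised-cosine bell, cos^2(pi d / (2 h)), exactly
zero outside the window - the hard reading of a +/-30 degree range; a
truncated Gaussian (sd = halfwidth/2) and a flat shape are options.
Sampling is inverse-CDF over bins with in-bin jitter, clamped to the
support, so the +/-30 bound is an invariant of the sampler, not a
statistical tendency. Ring puckers are held invariant throughout every
search. Score ties in pose retention break by (replicate, run, pose)
order; near-identical poses are deduplicated at 0.25 A. All randomness
flows from user-supplied integer seeds; a rerun with the same manifest
inputs reproduces every deterministic output.

## Known limitations

The receptor is rigid and pseudo-atomic; protonation states, explicit
waters and protein flexibility are out of scope. The score surrogate is
not calibrated to any experimental affinity scale - only ratios and
orderings on its own scale are meaningful. Flexible-regime searches at
benchmark sizes are undersampled by design; that undersampling is the
phenomenon the regime comparison measures, not an artifact to be tuned
away. Disaccharides bind tight grooves with near-degenerate geometry
even here, and their recapitulation is correspondingly poor - which
mirrors how short sulfated glycans behave in practice.
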