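---
title: "Generating chemical intermediates for free-energy perturbation networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating chemical intermediates for free-energy perturbation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intergen)
```

## The problem

Relative free-energy perturbation (FEP) computes the difference in binding
or hydration free energy between two ligands by alchemically transforming
one into the other. The transformation converges well only when the two
end states overlap in phase space, which in practice means the two ligands
must be structurally similar. Perturbation networks over a congeneric
series therefore try to avoid "long" edges — pairs that differ at several
substituent positions at once.

`intergen` breaks such an edge up: given two parent ligands it enumerates
*chemical intermediates* — real molecules, not alchemical lambda states —
that combine substituents from both parents on their shared scaffold. A
transformation A &rarr; B can then be split into A &rarr; I &rarr; B, two
smaller perturbations with better phase-space overlap. The package also
ranks the candidates by similarity to both parents, and ships the small
arithmetic used to analyse such split paths (uncertainty propagation,
cycle closure, a convergence-time criterion).

## The enumeration procedure

For a parent pair (A, B) the workflow is:

1. **Core identification.** The maximum common substructure (MCS) of A and
   B becomes the shared core. The search is a partition-based
   branch-and-bound over atom mappings (label classes with a
   sum-of-minima bound, connected variant), matching atoms by element and
   bonds by kekulized order, with aromatic bonds collapsed into one class
   so that differently kekulized rings still match. Two ring rules are on
   by default: ring bonds only match ring bonds, and any matched ring atom
   must belong to a completely matched ring. Together they guarantee the
   core never ends half-way through a ring, so enumeration can never be
   forced to break one.
2. **Attachment sites.** Core atoms with a non-core neighbour in either
   parent are the attachment sites; each records the bonds crossing from
   core to substituent.
3. **Fused-site grouping.** If a substituent ring is fused to the core it
   touches the core at two (or more) sites. Those sites are frozen into
   one *site group* — the ring travels as a single substituent and is
   never opened. Grouping is computed per parent (sites whose crossing
   bonds lead into the same connected non-core component are grouped) and
   the two partitions are merged, so a group frozen in either parent is
   frozen overall.
4. **R-group table.** For every site group, each parent's substituent is
   excised by cutting the single bonds that cross from core to non-core.
   A site where one parent carries only hydrogen contributes an explicit
   zero-atom "H" group, so hydrogen can be placed against the other
   parent's substituent. Crossing bonds of order above one are not cut
   (cutting a double bond leaves ambiguous valence and geometry); such a
   group is frozen, and if the two parents' fragments there differ the
   pair is rejected with an `unsupported_bond` error.
5. **Enumeration and assembly.** With k site groups whose substituents
   differ, all 2^k − 2 cross-parent combinations (excluding the two
   parents themselves) are assembled: fragments are bonded back to the
   core, implicit hydrogens adjust, and each product is valence-checked.
   Products are deduplicated by isomeric canonical SMILES and anything
   identical to a parent is dropped.
6. **Self-check.** The all-A and all-B assignments are also assembled and
   must reproduce the inputs by canonical form. If they do not, the pair
   is flagged (`parents_reconstructed = FALSE`) rather than silently
   trusted — the standard failure mode being stereochemistry the
   bookkeeping could not carry, e.g. parents that disagree about a
   stereocentre inside the shared core.

## How stereochemistry is preserved

Stereoisomerism changes simulation outcomes, so intermediates must
inherit each stereocentre exactly as it was in the parent that
contributed it. The package never re-derives stereo from geometry during
assembly. Every molecule carries tetrahedral parities in the MDL
convention (reference order: bonded neighbours by ascending atom index,
implicit hydrogen last). All graph surgery — excising a fragment,
renumbering, re-attaching — only *permutes* that reference list, and an
odd permutation flips the parity. When a substituent is swapped, the
incoming neighbour takes the exact position of the outgoing one in the
reference list; hydrogen-for-substituent swaps move through the
implicit-hydrogen slot. After assembly, parities on atoms that are no
longer stereocentres (two branches became identical) are cleared.

Perception at the package boundary is delegated to OpenBabel: input SDF
(3D coordinates, 2D wedges, or a parity column) and isomeric SMILES are
normalized to hydrogen-suppressed graphs with parity columns, and
canonical forms are produced by writing a 0D V2000 record whose parity
column carries the stereo. An independent check is available in-package:
`cip_descriptors()` assigns R/S labels by the atomic-number CIP hierarchy
over the hierarchical digraph (duplicate atoms for multiple bonds and
ring closures), and the test suite verifies both against reference
compounds and, through candidates assembled by the generator, against a
second implementation.

Limitations: cis/trans double-bond stereo is carried only when
coordinates accompany the molecule through I/O — the 0D canonical form
tracks tetrahedral centres only. Crossing bonds are single by
construction, so no E/Z information is ever adjacent to a cut. The CIP
implementation applies the atomic-number hierarchy without the
stereo-dependent or isotope rules; for drug-like stereocentres this is
decisive.

## Scoring and pruning

Enumerating k differing groups yields 2^k − 2 candidates, more than one
usually wants to simulate, so candidates are ranked by similarity to
*both* parents:

- **Tanimoto** over circular environments: each atom contributes a
  canonical identifier for its neighbourhood at radius 0, 1 and 2 (an
  ECFP-style environment, kept as an explicit set rather than folded
  bits, so the identifiers can be enumerated by hand); the score is the
  Tanimoto coefficient of the two sets.
- **LOMAP-style score** `exp(-beta * (N_a + N_b - 2 N_mcs))` with heavy
  atom counts and the heavy-atom size of the pair's MCS; `beta = 0.1` is
  the conventional decay. The full LOMAP rule set (ring-size and
  net-charge penalty multipliers) is deliberately not reimplemented; the
  score here is the MCS-exponential distance only.
- **3D shape** through a plugin protocol: any function mapping two
  molecules with coordinates to [0, 1] can be registered
  (`register_shape_backend()`), accommodating proprietary shape/colour
  overlays. A naive voxel-overlap backend (`"grid_overlap"`, 0.5 Å grid,
  van der Waals radii, Tanimoto of occupied voxels, no alignment) ships
  for testing; it is a synthetic stand-in, not a reimplementation of any
  commercial score.

The two per-parent scores are combined by sum, weighted sum, or (the
default) the harmonic mean `2ab/(a+b)`, which punishes imbalance — a
candidate identical to A and unlike B scores poorly. Columns can be
min–max normalized over the candidate pool first; a constant column maps
to zero, since it carries no ranking information. A heavy-atom filter
can drop candidates whose enumerated R-groups fall outside a size window.
When several metrics are requested, ordering follows the first listed
metric's combined score (ties broken by canonical form); the rest are
reported alongside, because no cross-metric aggregate is defined.

Per-pair summaries (`summarize_pair()`) report the parent–parent
similarity as the baseline an intermediate should beat, plus the mean and
maximum harmonic-mean score over the candidates; `summarize_series()`
averages these over a series.

## Path analysis

For a split edge A &rarr; I &rarr; B, `path_estimate()` adds the two leg
free energies and propagates the uncertainty as the root of the summed
squared standard deviations. `cycle_closure()` reports the discrepancy
between the direct and the split path with its propagated uncertainty —
free energies are path functions, so the two should agree within noise.
`convergence_time()` finds the earliest time after which a dG time
series stays converged: every full window of the given length (2 ns by
default) changes by at most the threshold (0.1 kcal/mol by default).
"Change" is the maximum pairwise spread within the window, which is
robust to oscillation; an endpoint-difference variant is available via
`mode = "endpoint"` because the criterion's plain-language statement
admits both readings. The time grid is used as-is; no interpolation.

## The synthetic fixture generator

`make_pair()` builds parent pairs with fully known ground truth: a core
template (benzene, pyridine, or naphthalene), `n_sites` substituent
positions, exactly `differing_sites` site groups at which the parents
differ, optionally a stereocentre directly at an attachment point and
optionally a ring fused to the core over two adjacent positions. The
substituent library holds small neutral single-attachment groups (F, Cl,
CH3, NH2, OCH3, CF3, phenyl, a chiral 1-hydroxyethyl in both
configurations) plus one two-attachment trimethylene bridge for fused
tests.

Differing pairings are drawn under a safety rule — the two substituents'
first atoms differ in element, or one side is hydrogen, or exactly one
side is a ring — applied across sites and parents, which guarantees the
planted template (plus shared substituents) *is* the true MCS; ring
substituents are additionally kept out of differing sites because a
dangling six-ring can tie with the benzene template for the MCS. This is
what makes the expected candidate count 2^k − 2 provable rather than
assumed. The generator is seeded and reproducible.

What these fixtures do **not** emulate: realistic medicinal-chemistry
diversity, charged or tautomeric substituents, macrocycles, and cores
whose MCS is genuinely ambiguous. Tests passing on fixtures demonstrate
the bookkeeping (counting, stereo, ring policy, reconstruction) is
correct; they do not certify behaviour on arbitrary real series, where
MCS ambiguity and exotic chemistry can trigger the flagging path — which
is exactly what the flag is for.

## Numerical and design choices

- **MCS settings** (`mcs_config()`): ring-matches-ring and
  complete-rings-only default to on (no partial rings, hence no ring
  breaks); stereo is not matched during the search (`match_chiral_tag =
  FALSE`), so core stereo disagreements surface as flags; minimum core 3
  atoms; 10 s search budget per pair, generous against the well-below-a-
  second typical case.
- **Tie-breaking.** Among maximum-size cores the search prefers fewer
  attachment sites, then the lexicographically smallest map. Equal-size
  alternatives are explored under a bounded budget (512 candidates), so
  heavily symmetric aromatic systems cannot stall the search; the
  maximality of the core size is never compromised, only the depth of
  tie enumeration.
- **Determinism.** For fixed inputs and configuration every stage —
  search order, assignment order (binary counting, A = 0, first group
  most significant), deduplication (first occurrence wins), ranking
  (ties by canonical form) — is deterministic; `generate_intermediates`
  on (B, A) yields the same candidate set as on (A, B).
- **Charges.** Parents with differing net formal charge are processed
  (the combination is often still useful) with a warning; charge-aware
  handling is out of scope.
- **Degenerate inputs.** Identical parents produce k = 0 and an empty
  candidate list with the parents still verified; molecules with no
  common substructure of at least `min_core_atoms` raise
  `core_too_small`; individual assembly failures (valence violations) are
  recorded per assignment in `failures`, never raised out of the
  orchestrator.

## Problem sizes used in the shipped checks

The test-suite and acceptance checks run on synthetic pairs of 8–25
heavy atoms: a 50-pair reconstruction suite spanning all three core
templates with stereo and fused variants, count-law sweeps up to k = 5
(30 candidates), and the canonical three-differing-site pair (benzene
core; F/CH3/OCH3 against Cl/H/NH2) whose six intermediates are the
package's headline check. These sizes keep the full suite under a minute
on one CPU while exercising every code path; the generator itself has no
intrinsic size limit beyond the MCS search budget.

## A worked example

```{r example, eval = FALSE}
A <- parse_smiles("Fc1cc(C)cc(OC)c1", "PA")[[1]]
B <- parse_smiles("Clc1cccc(N)c1",   "PB")[[1]]
iset <- generate_intermediates(A, B, pair_id = "demo")
iset
#> <intermediate_set> demo: k = 3, 6 candidates, parents reconstructed, 0 failures
rank_intermediates(iset, prune_config(metrics = c("lomap", "tanimoto")))
```

The six candidates are every proper mixture of the three differing
substituents; the ranked table reports each one's similarity to both
parents and the combined score used for ordering.
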