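# intergen

Chemical-intermediate generation for alchemical free-energy perturbation
(FEP) networks, in R.

## The problem

Relative FEP calculations transform one ligand into another through
nonphysical alchemical states. The transformation converges well only
when the two end states are similar; perturbation networks over a
congeneric series must therefore avoid edges between dissimilar ligands.
When such an edge is unavoidable, inserting a *chemical intermediate* — a
real molecule combining substituents of both end points — splits one
difficult perturbation A → B into two easier ones, A → I → B.

`intergen` automates this for medicinal and computational chemists
building perturbation networks:

- **Core identification** — the maximum common substructure (MCS) of a
  parent pair becomes the shared core (connected, ring-complete matching;
  deterministic tie-breaks).
- **R-group enumeration** — substituents are excised at the bonds
  crossing the core boundary and every cross-parent combination over the
  k differing substituent-site groups is assembled: 2^k − 2 candidates.
  Rings fused to the core travel as a single substituent, so no ring is
  ever broken.
- **Stereochemistry preservation** — tetrahedral parities are carried
  through assembly by positional bookkeeping (an incoming neighbour takes
  the excised one's place in the parity reference), never re-derived from
  geometry; the parents are re-assembled from their own R-groups as a
  self-check and the pair is flagged if they do not come back identical.
- **Pruning** — candidates are ranked by similarity to *both* parents:
  circular-fingerprint Tanimoto, a LOMAP-style MCS score
  `exp(-β (N_a + N_b − 2 N_mcs))`, and pluggable 3D shape scoring;
  per-parent scores combine by harmonic mean `2ab/(a+b)` (or sum /
  weighted sum), optionally after min–max normalization, with heavy-atom
  R-group filters.
- **Path analysis** — ΔΔG addition with root-sum-square uncertainty
  propagation, cycle-closure discrepancies, and a convergence-time
  criterion on ΔG time series (maximum change ≤ 0.1 kcal/mol over 2 ns
  by default).
- **Synthetic fixtures** — a seeded generator of parent pairs with known
  cores, differing-site counts, planted stereocentres and fused rings,
  so the whole pipeline is testable without external data.

## Worked example

Two benzene-core parents differing at three substituent positions
(parent A: F, CH3, OCH3; parent B: Cl, H, NH2):

```r
library(intergen)
A <- parse_smiles("Fc1cc(C)cc(OC)c1", "PA")[[1]]
B <- parse_smiles("Clc1cccc(N)c1",   "PB")[[1]]
iset <- generate_intermediates(A, B, pair_id = "demo")
iset
#> <intermediate_set> demo: k = 3, 6 candidates, parents reconstructed, 0 failures

rank_intermediates(iset, prune_config(metrics = c("lomap", "tanimoto")))
#>  candidate         canonical lomap_a lomap_b lomap_combined tanimoto_combined rank
#>     demoI0   Cc1cc(N)cc(c1)F   0.741   0.741          0.741             0.292    1
#>     demoI5    COc1cccc(c1)Cl   0.741   0.741          0.741             0.338    2
#>     demoI3 COc1cc(C)cc(c1)Cl   0.819   0.670          0.737             0.291    3
#>     demoI2      Nc1cccc(c1)F   0.670   0.819          0.737             0.279    4
#>     demoI4  Cc1cc(N)cc(c1)Cl   0.607   0.905          0.726             0.293    5
#>     demoI1     COc1cccc(c1)F   0.905   0.607          0.726             0.255    6

summarize_pair(iset, "lomap")
#> parent-parent LOMAP: 0.549   mean intermediate hm: 0.735   best: 0.741
```

Three differing sites yield the full 2^3 − 2 = 6 proper mixtures; the
parents themselves are reconstructed exactly (`parents reconstructed`),
and every candidate is more similar to both parents (harmonic-mean LOMAP
0.73–0.74) than the parents are to each other (0.55) — which is the
point of inserting an intermediate.

Whole series run pairwise with `run_series()`; a thin command-line
wrapper lives at `inst/cli/intergen` with subcommands `pair`, `series`,
`score`, `fixtures` and `analyze`, writing SDF candidates (scores as
properties), CSV score tables and JSON run reports.

## Scope

The package generates and ranks intermediates and analyses path
estimates. It does not run simulations: force fields, hybrid topologies,
lambda schedules and free-energy estimation belong to the MD stack
downstream. Network planning (which edges to include) and 3D-pose-guided
core identification are likewise out of scope. See the methods vignette
(`vignettes/intermediate-generation.Rmd`) for the model, its
assumptions, and known limitations.
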