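Package: intergen
Title: Chemical Intermediate Generation for Alchemical Free-Energy Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates chemical intermediate molecules between pairs of
    congeneric ligands for use in alchemical free-energy perturbation
    networks. Given two parent molecules, the maximum common substructure
    is identified and used as a shared core, per-site R-groups are excised
    and cross-combined with tetrahedral stereochemistry preserved, and the
    resulting candidates are sanitized, deduplicated and ranked by
    similarity to both parents (circular-fingerprint Tanimoto, an
    MCS-exponential LOMAP-style score, and pluggable 3D shape scoring).
    Also provides small analysis helpers for free-energy paths through an
    intermediate: uncertainty propagation, cycle-closure discrepancies and
    a convergence-time criterion on free-energy time series, plus a
    synthetic fixture generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
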