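# Shared fixtures and small oracles for the test suite.

smi <- function(s, name = "m") {
  m <- parse_smiles(s, name)[[1]]
  stopifnot(!is.null(m))
  m
}

# igraph view with element vertex colours and bond-order edge colours,
# used for independent subgraph checks.
mol_colored_graph <- function(mol) {
  g <- igraph::make_empty_graph(n = nrow(mol$atoms), directed = FALSE)
  if (nrow(mol$bonds) > 0L) {
    g <- igraph::add_edges(g, rbind(mol$bonds$a1, mol$bonds$a2))
  }
  list(g = g,
       vcol = as.integer(factor(mol$atoms$elem,
                                levels = c("C", "N", "O", "F", "Cl", "Br", "I", "S", "P", "B"))),
       ecol = mol$bonds$order)
}

# Independent check that `sub` (atoms/bonds data frames) embeds in `mol`
# respecting elements and bond orders.
embeds_in <- function(sub_atoms, sub_bonds, mol) {
  gs <- igraph::make_empty_graph(n = nrow(sub_atoms), directed = FALSE)
  if (nrow(sub_bonds) > 0L) {
    gs <- igraph::add_edges(gs, rbind(sub_bonds$a1, sub_bonds$a2))
  }
  gm <- mol_colored_graph(mol)
  lv <- c("C", "N", "O", "F", "Cl", "Br", "I", "S", "P", "B")
  # igraph's vf2 wrapper passes (target, pattern): color1/edge.color1
  # belong to the target graph
  n <- igraph::count_subgraph_isomorphisms(
    gs, gm$g, method = "vf2",
    vertex.color1 = gm$vcol,
    vertex.color2 = as.integer(factor(sub_atoms$elem, levels = lv)),
    edge.color1 = gm$ecol, edge.color2 = sub_bonds$order)
  n > 0
}

core_embeds_in_parents <- function(core, mol_a, mol_b) {
  embeds_in(core$atoms, core$bonds, mol_a) && embeds_in(core$atoms, core$bonds, mol_b)
}

# Brute-force candidate count oracle: assemble every assignment vector
# directly and count distinct sanitized products not equal to a parent.
brute_force_count <- function(mol_a, mol_b) {
  core <- locate_attachment_sites(find_core(mol_a, mol_b), mol_a, mol_b)
  part <- merge_partitions(group_fused_sites(core, mol_a, "A"),
                           group_fused_sites(core, mol_b, "B"))
  tab <- build_rgroup_table(mol_a, mol_b, core, part)
  k <- sum(tab$differing)
  if (k == 0L) return(0L)
  prods <- character(0)
  for (m in 0:(2^k - 1)) {
    bits <- as.integer(intToBits(m))[1:k]
    asn <- c("A", "B")[rev(bits) + 1L]
    res <- tryCatch(assemble_intermediate(tab, asn), error = function(e) NULL)
    if (!is.null(res)) prods <- c(prods, canonical_smiles(res))
  }
  parents <- canonical_smiles(list(mol_a, mol_b))
  length(setdiff(unique(prods), parents))
}

# RDKit (python) as an independent oracle for CIP labels: takes a vector
# of SMILES, returns a list of sorted label vectors.
rdkit_cip <- function(smiles) {
  sf <- tempfile(fileext = ".smi"); pf <- tempfile(fileext = ".py")
  on.exit(unlink(c(sf, pf)))
  writeLines(smiles, sf)
  writeLines(c(
    "from rdkit import Chem",
    "import sys",
    sprintf("lines = open(%s).read().splitlines()", deparse(sf)),
    "for s in lines:",
    "    m = Chem.MolFromSmiles(s)",
    "    if m is None:",
    "        print('?'); continue",
    "    Chem.AssignStereochemistry(m, cleanIt=True, force=True)",
    "    labs = sorted(a.GetPropsAsDict().get('_CIPCode') for a in m.GetAtoms() if a.HasProp('_CIPCode'))",
    "    print(','.join(labs))"), pf)
  out <- suppressWarnings(system2("python", pf, stdout = TRUE, stderr = FALSE))
  lapply(out, function(line) {
    v <- strsplit(line, ",", fixed = TRUE)[[1]]
    v[nzchar(v)]
  })
}
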