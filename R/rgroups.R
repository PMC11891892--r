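# R-group table construction, enumeration and stereochemistry-preserving
# reassembly. This is the heart of the generator: substituents are excised
# at the single bonds crossing from core to non-core, cross-combined over
# the differing site groups, and bonded back onto the core. Tetrahedral
# parity at atoms adjacent to a cut is restored positionally: the incoming
# neighbour takes the exact place of the outgoing one in the parity
# reference list (an implicit hydrogen stands in when a substituent is
# replaced by nothing), so the recorded stereochemistry is preserved
# without re-deriving it from geometry.

#' Build the R-group table for a parent pair
#'
#' For every site group of the merged partition, both parents' substituents
#' are excised by cutting the bonds crossing from core to non-core atoms.
#' A site where one parent carries only hydrogen yields an explicit
#' zero-atom "H" R-group so enumeration can place hydrogen against the
#' other parent's substituent.
#'
#' @param mol_a,mol_b parents.
#' @param core `core_scaffold` with attachment sites located.
#' @param partition merged site partition from [merge_partitions()].
#' @return An object of class `rgroup_table`: per site group one R-group
#'   from each parent plus a `differing` flag (canonical comparison
#'   including attachment labels and stereo).
#' @export
build_rgroup_table <- function(mol_a, mol_b, core, partition) {
  stopifnot(!is.null(core$crossings))
  # every parent ring that crosses the core boundary must do so within a
  # single site group, otherwise enumeration would cut it open
  for (p in c("A", "B")) {
    mol <- if (p == "A") mol_a else mol_b
    cr <- core$crossings[core$crossings$parent == p, , drop = FALSE]
    if (nrow(cr) == 0L) next
    grp_of_site <- site_group_index(partition)
    for (ring in perceive_rings(mol)) {
      hit <- cr$site[cr$parent_atom %in% ring & cr$nbr %in% ring]
      if (length(hit) > 0L && length(unique(grp_of_site[as.character(hit)])) > 1L) {
        intergen_error("ring_cut_required", sprintf(
          "ring through sites {%s} of parent %s spans more than one site group",
          paste(sort(unique(hit)), collapse = ","), p))
      }
    }
  }
  entries <- vector("list", length(partition))
  differing <- logical(length(partition))
  for (gi in seq_along(partition)) {
    grp <- partition[[gi]]
    rg_a <- extract_rgroup(mol_a, core, grp, "A")
    rg_b <- extract_rgroup(mol_b, core, grp, "B")
    frozen <- FALSE
    for (rg in list(rg_a, rg_b)) {
      if (any(rg$crossings$order > 1L)) frozen <- TRUE
    }
    same <- rgroups_identical(rg_a, rg_b, mol_a, mol_b)
    if (frozen && !same) {
      intergen_error("unsupported_bond", sprintf(
        "site group {%s}: crossing bond of order > 1 with differing substituents",
        paste(grp, collapse = ",")))
    }
    entries[[gi]] <- list(A = rg_a, B = rg_b)
    differing[gi] <- !same && !frozen
  }
  structure(list(core = core, site_groups = partition, entries = entries,
                 differing = differing,
                 mol_a = mol_a, mol_b = mol_b),
            class = "rgroup_table")
}

site_group_index <- function(partition) {
  out <- integer(0)
  for (gi in seq_along(partition)) {
    for (s in partition[[gi]]) out[as.character(s)] <- gi
  }
  out
}

# Excise one parent's substituent for a site group. Returns the fragment
# as parent atom indices plus its crossing bonds; zero atoms = implicit H.
extract_rgroup <- function(mol, core, grp, parent) {
  map <- if (parent == "A") core$map_a else core$map_b
  cr <- core$crossings[core$crossings$parent == parent &
                         core$crossings$site %in% grp, , drop = FALSE]
  atoms <- integer(0)
  if (nrow(cr) > 0L) {
    g <- mol_igraph(mol)
    noncore <- setdiff(seq_len(nrow(mol$atoms)), map)
    sub <- igraph::induced_subgraph(g, noncore)
    comp <- igraph::components(sub)$membership
    comp_of <- rep(NA_integer_, nrow(mol$atoms))
    comp_of[noncore] <- comp
    atoms <- sort(noncore[comp_of[noncore] %in% unique(comp_of[cr$nbr])])
  }
  list(parent = parent, sites = grp, atoms = atoms,
       crossings = cr[order(cr$site, cr$nbr), , drop = FALSE],
       heavy = length(atoms))
}

# Fragment as a standalone molecule-like graph with one labelled dummy
# atom per crossing bond (element "R<site>"), parities remapped so the
# dummy occupies the excised core neighbour's position. Used only for
# fragment comparison; dummies are not real elements.
fragment_graph <- function(mol, rg) {
  n_f <- length(rg$atoms)
  n_d <- nrow(rg$crossings)
  loc <- rep(NA_integer_, nrow(mol$atoms))
  loc[rg$atoms] <- seq_len(n_f)
  elem <- c(mol$atoms$elem[rg$atoms], paste0("R", rg$crossings$site))
  charge <- c(mol$atoms$charge[rg$atoms], rep(0L, n_d))
  parity <- c(mol$atoms$parity[rg$atoms], rep(0L, n_d))
  keep <- mol$bonds$a1 %in% rg$atoms & mol$bonds$a2 %in% rg$atoms
  bonds <- data.frame(a1 = loc[mol$bonds$a1[keep]], a2 = loc[mol$bonds$a2[keep]],
                      order = mol$bonds$order[keep])
  if (n_d > 0L) {
    bonds <- rbind(bonds, data.frame(a1 = loc[rg$crossings$nbr],
                                     a2 = n_f + seq_len(n_d),
                                     order = rg$crossings$order))
  }
  # remap parities of fragment atoms: core neighbour -> its dummy index
  adj <- mol_adjacency(mol)
  for (t in seq_len(n_f)) {
    if (parity[t] == 0L) next
    old <- adj[[rg$atoms[t]]]
    vals <- vapply(old, function(nb) {
      if (!is.na(loc[nb])) return(as.numeric(loc[nb]))
      d <- which(rg$crossings$nbr == rg$atoms[t] & rg$crossings$parent_atom == nb)
      if (length(d) == 1L) as.numeric(n_f + d) else NA_real_
    }, 0)
    if (length(old) < 4L) vals <- c(vals, Inf)
    parity[t] <- reorder_parity(parity[t], vals)
  }
  list(elem = elem, charge = charge, parity = parity, bonds = bonds,
       n_frag = n_f, n_dummy = n_d)
}

# Are two R-groups the same substituent? Checked by labelled-graph
# isomorphism (element, charge, bond order, attachment-site labels) plus
# parity consistency under at least one isomorphism.
rgroups_identical <- function(rg_a, rg_b, mol_a, mol_b) {
  if (rg_a$heavy != rg_b$heavy) return(FALSE)
  if (nrow(rg_a$crossings) != nrow(rg_b$crossings)) return(FALSE)
  if (rg_a$heavy == 0L) {
    return(identical(rg_a$crossings$site, rg_b$crossings$site))
  }
  fa <- fragment_graph(mol_a, rg_a)
  fb <- fragment_graph(mol_b, rg_b)
  key_a <- paste(fa$elem, fa$charge); key_b <- paste(fb$elem, fb$charge)
  if (!identical(sort(key_a), sort(key_b))) return(FALSE)
  col_levels <- unique(c(key_a, key_b))
  ga <- igraph::make_empty_graph(length(fa$elem), directed = FALSE)
  ga <- igraph::add_edges(ga, rbind(fa$bonds$a1, fa$bonds$a2))
  gb <- igraph::make_empty_graph(length(fb$elem), directed = FALSE)
  gb <- igraph::add_edges(gb, rbind(fb$bonds$a1, fb$bonds$a2))
  isos <- igraph::subgraph_isomorphisms(
    ga, gb, method = "vf2",
    vertex.color1 = match(key_a, col_levels), vertex.color2 = match(key_b, col_levels),
    edge.color1 = fa$bonds$order, edge.color2 = fb$bonds$order)
  if (length(isos) == 0L) return(FALSE)
  adj_a <- .frag_adj(fa); adj_b <- .frag_adj(fb)
  for (iso in isos) {
    sigma <- as.integer(iso)
    if (.iso_parity_ok(fa, fb, sigma, adj_a, adj_b)) return(TRUE)
  }
  FALSE
}

.frag_adj <- function(f) {
  n <- length(f$elem)
  adj <- vector("list", n)
  for (k in seq_len(nrow(f$bonds))) {
    i <- f$bonds$a1[k]; j <- f$bonds$a2[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, function(v) sort(v %||% integer(0)))
}

.iso_parity_ok <- function(fa, fb, sigma, adj_a, adj_b) {
  for (i in seq_along(fa$elem)) {
    pa <- fa$parity[i]; pb <- fb$parity[sigma[i]]
    if (pa == 0L && pb == 0L) next
    if ((pa == 0L) != (pb == 0L)) return(FALSE)
    old <- adj_a[[i]]
    vals <- as.numeric(sigma[old])
    if (length(old) < 4L) vals <- c(vals, Inf)
    if (reorder_parity(pa, vals) != pb) return(FALSE)
  }
  TRUE
}

#' Enumerate R-group assignments
#'
#' One assignment per element of \{A,B\}^k over the k differing site
#' groups, excluding the all-A and all-B vectors; non-differing groups are
#' fixed to the shared fragment. Ordered by binary counting with A = 0 and
#' the first differing group as the most significant digit.
#'
#' @param table an `rgroup_table`.
#' @return list of character vectors ("A"/"B") of length k.
#' @export
enumerate_assignments <- function(table) {
  k <- sum(table$differing)
  if (k < 1L) return(list())
  n <- 2L^k - 2L
  if (n <= 0L) return(list())
  lapply(seq_len(n), function(m) {
    bits <- integer(k)
    for (j in k:1) { bits[j] <- m %% 2L; m <- m %/% 2L }
    c("A", "B")[bits + 1L]
  })
}

# Full per-group choice vector: differing groups take the assignment,
# shared groups take parent A's (identical) fragment.
.full_choice <- function(table, assignment) {
  choice <- rep("A", length(table$site_groups))
  choice[which(table$differing)] <- assignment
  choice
}

#' Assemble an intermediate from a core and an R-group assignment
#'
#' Re-forms the crossing bonds between the chosen fragments and the core.
#' Every tetrahedral parity recorded in a source parent is restored by
#' positional substitution in its neighbour reference list; assembled
#' products are valence-checked and parities at atoms that are no longer
#' stereocentres are cleared.
#'
#' @param table an `rgroup_table`.
#' @param assignment character vector ("A"/"B") over the differing site
#'   groups, as produced by [enumerate_assignments()].
#' @param name name for the product molecule.
#' @return a `molecule` with attributes `origin` (per-site-group parent
#'   vector); raises an `assembly_failure` condition on valence or
#'   sanitization failure.
#' @export
assemble_intermediate <- function(table, assignment, name = "intermediate") {
  k <- sum(table$differing)
  if (length(assignment) != k) {
    intergen_error("assembly_failure",
                   sprintf("assignment length %d != %d differing site groups",
                           length(assignment), k))
  }
  choice <- .full_choice(table, assignment)
  core <- table$core
  mol_a <- table$mol_a; mol_b <- table$mol_b
  nc <- nrow(core$atoms)

  # assembled index maps per parent
  f_a <- rep(NA_integer_, nrow(mol_a$atoms))
  f_b <- rep(NA_integer_, nrow(mol_b$atoms))
  f_a[core$map_a] <- seq_len(nc)
  f_b[core$map_b] <- seq_len(nc)
  elem <- core$atoms$elem; charge <- core$atoms$charge
  parity <- integer(nc)                      # core parities resolved below
  bonds <- core$bonds[, c("a1", "a2", "order")]
  nxt <- nc
  for (gi in seq_along(table$site_groups)) {
    rg <- table$entries[[gi]][[choice[gi]]]
    mol <- if (choice[gi] == "A") mol_a else mol_b
    f <- if (choice[gi] == "A") f_a else f_b
    if (rg$heavy > 0L) {
      ids <- nxt + seq_along(rg$atoms)
      f[rg$atoms] <- ids
      nxt <- nxt + length(rg$atoms)
      elem <- c(elem, mol$atoms$elem[rg$atoms])
      charge <- c(charge, mol$atoms$charge[rg$atoms])
      parity <- c(parity, mol$atoms$parity[rg$atoms])   # remapped later
      keep <- mol$bonds$a1 %in% rg$atoms & mol$bonds$a2 %in% rg$atoms
      if (any(keep)) {
        bonds <- rbind(bonds, data.frame(a1 = f[mol$bonds$a1[keep]],
                                         a2 = f[mol$bonds$a2[keep]],
                                         order = mol$bonds$order[keep]))
      }
      cr <- rg$crossings
      if (nrow(cr) > 0L) {
        bonds <- rbind(bonds, data.frame(a1 = cr$core_atom, a2 = f[cr$nbr],
                                         order = cr$order))
      }
    }
    if (choice[gi] == "A") f_a <- f else f_b <- f
  }

  adj_a <- mol_adjacency(mol_a); adj_b <- mol_adjacency(mol_b)

  # new assembled id of the neighbour that replaces, in parent P's parity
  # reference of core atom `ci`, the excised P-side neighbour `nb`
  substitute_neighbour <- function(p, ci, nb, grp_index, choice) {
    cr_p <- table$entries[[grp_index]][[p]]$crossings
    row_p <- which(cr_p$core_atom == ci & cr_p$nbr == nb)
    q <- if (choice[grp_index] == "A") "A" else "B"
    cr_q <- table$entries[[grp_index]][[q]]$crossings
    cr_q <- cr_q[cr_q$core_atom == ci, , drop = FALSE]
    cr_p_here <- which(cr_p$core_atom == ci)
    pos <- match(row_p, cr_p_here)
    if (is.na(pos) || pos > nrow(cr_q)) return(Inf)   # replaced by implicit H
    fq <- if (q == "A") f_a else f_b
    as.numeric(fq[cr_q$nbr[pos]])
  }

  grp_of_site <- site_group_index(table$site_groups)
  core_parity_from <- function(p, ci) {
    mol <- if (p == "A") mol_a else mol_b
    adj <- if (p == "A") adj_a else adj_b
    map <- if (p == "A") core$map_a else core$map_b
    f <- if (p == "A") f_a else f_b
    pa <- map[ci]
    pr <- mol$atoms$parity[pa]
    if (pr == 0L) return(0L)
    nbrs <- adj[[pa]]
    vals <- numeric(0)
    for (nb in nbrs) {
      if (!is.na(f[nb])) { vals <- c(vals, as.numeric(f[nb])); next }
      cr <- core$crossings[core$crossings$parent == p &
                             core$crossings$parent_atom == pa &
                             core$crossings$nbr == nb, , drop = FALSE]
      if (nrow(cr) != 1L) return(0L)
      gi <- grp_of_site[[as.character(cr$site)]]
      vals <- c(vals, substitute_neighbour(p, ci, nb, gi, choice))
    }
    if (length(nbrs) < 4L) vals <- c(vals, Inf)
    # an added substituent where parent P had implicit H takes the H slot
    extra <- .extra_neighbours(p, ci, choice, table, f_a, f_b)
    if (length(extra) > 0L) {
      slots <- which(!is.finite(vals))
      if (length(extra) > length(slots)) return(0L)
      vals[slots[seq_along(extra)]] <- extra
    }
    reorder_parity(pr, vals)
  }

  for (ci in seq_len(nc)) {
    p <- core_parity_from("A", ci)
    if (p == 0L) p <- core_parity_from("B", ci)
    parity[ci] <- p
  }

  # fragment-atom parities: remap neighbour references into assembled ids
  for (gi in seq_along(table$site_groups)) {
    rg <- table$entries[[gi]][[choice[gi]]]
    if (rg$heavy == 0L) next
    mol <- if (choice[gi] == "A") mol_a else mol_b
    adj <- if (choice[gi] == "A") adj_a else adj_b
    f <- if (choice[gi] == "A") f_a else f_b
    for (x in rg$atoms) {
      if (mol$atoms$parity[x] == 0L) next
      nbrs <- adj[[x]]
      vals <- ifelse(is.na(f[nbrs]), NA_real_, as.numeric(f[nbrs]))
      if (length(nbrs) < 4L) vals <- c(vals, Inf)
      parity[f[x]] <- reorder_parity(mol$atoms$parity[x], vals)
    }
  }

  atoms <- data.frame(elem = elem, charge = charge, parity = parity,
                      stringsAsFactors = FALSE)
  out <- new_molecule(atoms, bonds, name = name)
  msg <- sanitize_check(out)
  if (!is.null(msg)) intergen_error("assembly_failure", msg)
  out <- validate_parities(out)
  attr(out, "origin") <- choice
  out
}

# Assembled ids of neighbours a chosen parent Q adds at core atom `ci`
# beyond what parent P had there (these occupy P's implicit-H positions).
.extra_neighbours <- function(p, ci, choice, table, f_a, f_b) {
  out <- numeric(0)
  for (gi in seq_along(table$site_groups)) {
    q <- choice[gi]
    if (q == p) next
    cr_q <- table$entries[[gi]][[q]]$crossings
    cr_q <- cr_q[cr_q$core_atom == ci, , drop = FALSE]
    cr_p <- table$entries[[gi]][[p]]$crossings
    n_p <- sum(cr_p$core_atom == ci)
    if (nrow(cr_q) > n_p) {
      fq <- if (q == "A") f_a else f_b
      out <- c(out, as.numeric(fq[cr_q$nbr[(n_p + 1L):nrow(cr_q)]]))
    }
  }
  out
}

#' Verify that the parents can be reconstructed from their own R-groups
#'
#' Assembles the all-A and all-B assignments and compares them with the
#' input parents by isomeric canonical form. A `FALSE` result flags a
#' problem in the decomposition for this pair (e.g. stereo information the
#' positional bookkeeping could not carry, or disagreeing core stereo).
#'
#' @param table an `rgroup_table`.
#' @return logical.
#' @export
verify_parent_reconstruction <- function(table) {
  k <- sum(table$differing)
  rec <- lapply(c("A", "B"), function(p) {
    tryCatch(assemble_intermediate(table, rep(p, k), name = p),
             error = function(e) NULL)
  })
  if (any(vapply(rec, is.null, TRUE))) return(FALSE)
  cans <- canonical_smiles(list(rec[[1]], rec[[2]], table$mol_a, table$mol_b))
  !anyNA(cans) && cans[1] == cans[3] && cans[2] == cans[4]
}

#' Generate all intermediates for a parent pair
#'
#' End-to-end workflow: find the shared core, locate and group attachment
#' sites, build the R-group table, enumerate cross-parent assignments,
#' assemble and sanitize each candidate, deduplicate by isomeric canonical
#' form, drop products identical to a parent, and verify that the parents
#' themselves are reconstructed.
#'
#' @param mol_a,mol_b parent molecules.
#' @param cfg an [mcs_config()].
#' @param pair_id identifier used in candidate names.
#' @return An object of class `intermediate_set`: `candidates` (list of
#'   molecules named `<pair_id>I0`, `I1`, ... with `origin` attributes),
#'   `k` (differing site groups), `parents_reconstructed`, `failures`
#'   (data.frame of failed assignments) and the underlying `table`.
#' @export
generate_intermediates <- function(mol_a, mol_b, cfg = mcs_config(),
                                   pair_id = "pair") {
  if (sum(mol_a$atoms$charge) != sum(mol_b$atoms$charge)) {
    intergen_warn(sprintf("parents %s and %s differ in net formal charge",
                          mol_a$name, mol_b$name))
  }
  core <- find_core(mol_a, mol_b, cfg)
  core <- locate_attachment_sites(core, mol_a, mol_b)
  part <- merge_partitions(group_fused_sites(core, mol_a, "A"),
                           group_fused_sites(core, mol_b, "B"))
  table <- build_rgroup_table(mol_a, mol_b, core, part)
  assignments <- enumerate_assignments(table)
  raw <- list(); fail <- list()
  for (i in seq_along(assignments)) {
    res <- tryCatch(
      assemble_intermediate(table, assignments[[i]],
                            name = sprintf("%s_tmp%d", pair_id, i)),
      error = function(e) e)
    if (inherits(res, "condition")) {
      fail[[length(fail) + 1L]] <- data.frame(
        assignment = paste(assignments[[i]], collapse = ""),
        reason = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      raw[[length(raw) + 1L]] <- res
    }
  }
  candidates <- list()
  if (length(raw) > 0L) {
    cans <- canonical_smiles(raw)
    parent_cans <- canonical_smiles(list(mol_a, mol_b))
    seen <- character(0)
    for (i in seq_along(raw)) {
      cs <- cans[i]
      if (is.na(cs)) {
        fail[[length(fail) + 1L]] <- data.frame(
          assignment = paste(attr(raw[[i]], "origin"), collapse = ""),
          reason = "canonicalization failed", stringsAsFactors = FALSE)
        next
      }
      if (cs %in% seen || cs %in% parent_cans) next
      seen <- c(seen, cs)
      m <- raw[[i]]
      m$name <- sprintf("%sI%d", pair_id, length(candidates))
      attr(m, "canonical") <- cs
      candidates[[length(candidates) + 1L]] <- m
    }
  }
  failures <- if (length(fail)) do.call(rbind, fail) else
    data.frame(assignment = character(0), reason = character(0))
  structure(list(pair_id = pair_id,
                 candidates = candidates,
                 k = sum(table$differing),
                 parents_reconstructed = verify_parent_reconstruction(table),
                 failures = failures,
                 table = table),
            class = "intermediate_set")
}

#' @export
print.intermediate_set <- function(x, ...) {
  cat(sprintf("<intermediate_set> %s: k = %d, %d candidates, parents %s, %d failures\n",
              x$pair_id, x$k, length(x$candidates),
              if (x$parents_reconstructed) "reconstructed" else "NOT reconstructed (flagged)",
              nrow(x$failures)))
  invisible(x)
}
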