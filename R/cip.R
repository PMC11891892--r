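# CIP R/S descriptors for tetrahedral stereocentres. Implements the
# standard atomic-number hierarchy over the hierarchical digraph
# (duplicate atoms for multiple bonds and ring closures, breadth-first
# sphere comparison). Stereo-dependent and isotope rules are not applied;
# for the drug-like molecules handled here the atomic-number hierarchy is
# decisive. Used to verify that assembled intermediates inherit their
# parents' stereocentre orientation.

.atomic_numbers <- c(H = 1L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L,
                     Si = 14L, P = 15L, S = 16L, Cl = 17L, Br = 35L,
                     I = 53L, Se = 34L)

.mol_ih_cache <- function(mol) {
  ih <- implicit_h_counts(mol)
  ih[is.na(ih)] <- 0L
  ih
}

# Compare two branches from a stereocentre by CIP spheres.
# Returns -1, 0, 1 (branch1 <, ==, > branch2).
.cip_compare <- function(mol, adj, bmap, root1, root2, center, max_depth = 10L) {
  mk <- function(root) {
    if (root == 0L) {   # implicit hydrogen branch
      list(list(atom = -1L, parent = NA_integer_, phantom = TRUE, path = integer(0)))
    } else {
      ord <- mol$bonds$order[bond_id(bmap, center, root)]
      out <- list(list(atom = root, parent = center, phantom = FALSE,
                       path = c(center, root)))
      out
    }
  }
  n1 <- mk(root1); n2 <- mk(root2)
  for (d in seq_len(max_depth)) {
    s1 <- .cip_sphere2(mol, adj, bmap, n1)
    s2 <- .cip_sphere2(mol, adj, bmap, n2)
    z1 <- s1$z; z2 <- s2$z
    len <- max(length(z1), length(z2))
    if (len > 0L) {
      z1 <- c(z1, rep(0L, len - length(z1)))
      z2 <- c(z2, rep(0L, len - length(z2)))
      cmp <- sign(z1 - z2)
      nz <- which(cmp != 0L)
      if (length(nz) > 0L) return(cmp[nz[1]])
    }
    n1 <- s1$nodes; n2 <- s2$nodes
    if (length(n1) == 0L && length(n2) == 0L) return(0L)
  }
  0L
}

# Sphere expansion used by .cip_compare: atomic numbers of the current
# node set (sorted descending), plus the next node set with duplicate
# atoms for multiple bonds, ring closures and hydrogens.
.cip_sphere2 <- function(mol, adj, bmap, nodes) {
  zval <- function(atom) {
    if (atom == -1L) return(1L)                     # hydrogen
    .atomic_numbers[[mol$atoms$elem[atom]]] %||% 0L
  }
  z <- vapply(nodes, function(nd) zval(nd$atom), 1L)
  nxt <- list()
  ih <- .mol_ih_cache(mol)
  for (nd in nodes) {
    if (nd$phantom || nd$atom == -1L) next
    a <- nd$atom
    # multiple-bond duplicate of the parent seen from this atom
    if (!is.na(nd$parent)) {
      ord <- mol$bonds$order[bond_id(bmap, a, nd$parent)]
      if (ord > 1L) {
        for (dup in seq_len(ord - 1L)) {
          nxt[[length(nxt) + 1L]] <- list(atom = nd$parent, parent = NA_integer_,
                                          phantom = TRUE, path = integer(0))
        }
      }
    }
    for (nb in adj[[a]]) {
      if (!is.na(nd$parent) && nb == nd$parent) next
      ord <- mol$bonds$order[bond_id(bmap, a, nb)]
      on_path <- nb %in% nd$path
      nxt[[length(nxt) + 1L]] <- list(atom = nb, parent = a,
                                      phantom = on_path,
                                      path = c(nd$path, nb))
      if (ord > 1L) {
        for (dup in seq_len(ord - 1L)) {
          nxt[[length(nxt) + 1L]] <- list(atom = nb, parent = NA_integer_,
                                          phantom = TRUE, path = integer(0))
        }
      }
    }
    for (h in seq_len(ih[a])) {
      nxt[[length(nxt) + 1L]] <- list(atom = -1L, parent = NA_integer_,
                                      phantom = TRUE, path = integer(0))
    }
  }
  list(z = sort(z, decreasing = TRUE), nodes = nxt)
}

#' CIP descriptors of a molecule's assigned stereocentres
#'
#' Assigns R/S labels to every atom carrying a tetrahedral parity, by
#' ranking the four substituent branches with the atomic-number CIP
#' hierarchy and reading the configured parity against that ranking.
#'
#' @param mol a `molecule`.
#' @return named character vector, `"R"`/`"S"` (or `NA` when two branches
#'   tie under the implemented rules), named by atom index.
#' @export
cip_descriptors <- function(mol) {
  centers <- which(mol$atoms$parity != 0L)
  if (length(centers) == 0L) {
    return(stats::setNames(character(0), character(0)))
  }
  adj <- mol_adjacency(mol)
  bmap <- bond_index_map(mol)
  out <- stats::setNames(rep(NA_character_, length(centers)),
                         as.character(centers))
  for (t in seq_along(centers)) {
    ctr <- centers[t]
    nbrs <- adj[[ctr]]                 # ascending; implicit H (0) ranked last
    branches <- c(nbrs, if (length(nbrs) < 4L) 0L)
    if (length(branches) != 4L) next
    # pairwise CIP comparison -> priority order (1 = highest)
    wins <- integer(4L)
    tied <- FALSE
    for (i in 1:3) for (j in (i + 1):4) {
      cmp <- .cip_compare(mol, adj, bmap, branches[i], branches[j], ctr)
      if (cmp == 0L) tied <- TRUE
      if (cmp > 0L) wins[i] <- wins[i] + 1L else if (cmp < 0L) wins[j] <- wins[j] + 1L
    }
    if (tied) next
    prio <- rank(-wins)               # 1 = highest priority
    # parity is defined against the branch order (ascending index, H
    # last); an even permutation to priority order preserves handedness
    s <- perm_sign(order(prio))
    p <- mol$atoms$parity[ctr]
    cw <- (p == 1L) == (s > 0L)       # calibrated against known references
    out[t] <- if (cw) "R" else "S"
  }
  out
}
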