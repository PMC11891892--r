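#' MCS search configuration
#'
#' Matching rules for the maximum common substructure search that defines
#' the shared core of a parent pair. Defaults keep rings whole: ring bonds
#' only match ring bonds and any matched ring atom must belong to a fully
#' matched ring, so the core can never force a ring break downstream.
#'
#' @param ring_matches_ring_only ring bonds may only match ring bonds.
#' @param complete_rings_only every matched ring atom/bond must belong to
#'   at least one ring that is matched in its entirety.
#' @param match_chiral_tag require stereocentre status (defined vs
#'   undefined parity) to agree between matched atoms.
#' @param timeout_s wall-clock budget for the search, seconds.
#' @param min_core_atoms smallest acceptable core.
#' @return a list of class `mcs_config`.
#' @export
mcs_config <- function(ring_matches_ring_only = TRUE,
                       complete_rings_only = TRUE,
                       match_chiral_tag = FALSE,
                       timeout_s = 10,
                       min_core_atoms = 3L) {
  stopifnot(timeout_s > 0, min_core_atoms >= 1L)
  structure(list(ring_matches_ring_only = isTRUE(ring_matches_ring_only),
                 complete_rings_only = isTRUE(complete_rings_only),
                 match_chiral_tag = isTRUE(match_chiral_tag),
                 timeout_s = timeout_s,
                 min_core_atoms = as.integer(min_core_atoms)),
            class = "mcs_config")
}

# Precomputed view of a molecule used during the search.
.mcs_view <- function(mol) {
  list(mol = mol,
       n = nrow(mol$atoms),
       elem = mol$atoms$elem,
       parity = mol$atoms$parity,
       adj = mol_adjacency(mol),
       bmap = bond_index_map(mol),
       bclass = bond_classes(mol),
       bring = ring_bond_flags(mol),
       rings = perceive_rings(mol))
}

.bond_key <- function(view, i, j, rmro) {
  k <- bond_id(view$bmap, i, j)
  if (is.na(k)) return(NA_character_)
  if (rmro) paste0(view$bclass[k], if (view$bring[k]) "R" else "") else view$bclass[k]
}

# Core bonds implied by a mapping: bonds present in both parents between
# mapped atoms with equal class. Returns a data.frame of core-local bonds.
.core_bonds <- function(va, vb, amap, bmap_atoms, rmro) {
  idx <- which(!is.na(amap))
  loc <- integer(va$n); loc[idx] <- seq_along(idx)
  res <- list()
  for (k in seq_len(nrow(va$mol$bonds))) {
    i <- va$mol$bonds$a1[k]; j <- va$mol$bonds$a2[k]
    if (is.na(amap[i]) || is.na(amap[j])) next
    ka <- .bond_key(va, i, j, rmro)
    kb <- .bond_key(vb, amap[i], amap[j], rmro)
    if (!is.na(kb) && identical(ka, kb)) {
      res[[length(res) + 1L]] <- c(loc[i], loc[j], va$mol$bonds$order[k])
    }
  }
  if (length(res) == 0L) {
    return(data.frame(a1 = integer(0), a2 = integer(0), order = integer(0)))
  }
  m <- do.call(rbind, res)
  data.frame(a1 = m[, 1], a2 = m[, 2], order = m[, 3])
}

# complete_rings_only validity of a mapping, checked in one parent.
.rings_complete <- function(view, mapped, core_bond_pairs) {
  in_map <- logical(view$n); in_map[mapped] <- TRUE
  if (length(view$rings) == 0L) return(TRUE)
  ring_ok <- vapply(view$rings, function(ring) {
    if (!all(in_map[ring])) return(FALSE)
    m <- length(ring)
    for (t in seq_len(m)) {
      u <- ring[t]; v <- ring[if (t == m) 1L else t + 1L]
      if (!(paste(min(u, v), max(u, v)) %in% core_bond_pairs)) return(FALSE)
    }
    TRUE
  }, TRUE)
  # every mapped ring atom must sit in some fully mapped ring
  ring_atoms <- unique(unlist(view$rings))
  for (a in intersect(ring_atoms, mapped)) {
    in_ok <- any(vapply(seq_along(view$rings), function(r)
      ring_ok[r] && a %in% view$rings[[r]], TRUE))
    if (!in_ok) return(FALSE)
  }
  TRUE
}

# Count attachment sites of a mapping (core atoms with a non-core
# neighbour in either parent) -- the tie-break criterion.
.site_count <- function(va, vb, amap) {
  mapped_a <- which(!is.na(amap))
  mapped_b <- amap[mapped_a]
  in_a <- logical(va$n); in_a[mapped_a] <- TRUE
  in_b <- logical(vb$n); in_b[mapped_b] <- TRUE
  n_sites <- 0L
  for (t in seq_along(mapped_a)) {
    a <- mapped_a[t]; b <- mapped_b[t]
    if (any(!in_a[va$adj[[a]]]) || any(!in_b[vb$adj[[b]]])) n_sites <- n_sites + 1L
  }
  n_sites
}

#' Find the shared core (maximum common substructure) of a parent pair
#'
#' Connected common-subgraph search by backtracking extension: a mapping
#' grows one compatible atom pair at a time, each new pair connected to the
#' current mapping by at least one bond matched in both parents. Among
#' mappings of maximal size that satisfy the ring constraints, ties are
#' broken deterministically: fewest attachment sites first, then the
#' lexicographically smallest index map.
#'
#' @param mol_a,mol_b parent molecules (sanitized, single component).
#' @param cfg an [mcs_config()].
#' @return An object of class `core_scaffold`: core atoms/bonds plus
#'   `map_a`/`map_b` (core atom -> parent atom index). Attachment sites are
#'   filled in by [locate_attachment_sites()].
#' @export
find_core <- function(mol_a, mol_b, cfg = mcs_config()) {
  for (m in list(mol_a, mol_b)) {
    msg <- sanitize_check(m)
    if (!is.null(msg)) intergen_error("invalid_molecule", paste0(m$name, ": ", msg))
  }
  va <- .mcs_view(mol_a); vb <- .mcs_view(mol_b)
  rmro <- cfg$ring_matches_ring_only
  t0 <- Sys.time()

  # integer bond-class matrices (0 = no bond) and atom compatibility
  keys_a <- vapply(seq_len(nrow(mol_a$bonds)), function(k)
    .bond_key(va, mol_a$bonds$a1[k], mol_a$bonds$a2[k], rmro), "")
  keys_b <- vapply(seq_len(nrow(mol_b$bonds)), function(k)
    .bond_key(vb, mol_b$bonds$a1[k], mol_b$bonds$a2[k], rmro), "")
  lev <- unique(c(keys_a, keys_b))
  bca <- matrix(0L, va$n, va$n); bcb <- matrix(0L, vb$n, vb$n)
  for (k in seq_along(keys_a)) {
    i <- mol_a$bonds$a1[k]; j <- mol_a$bonds$a2[k]
    bca[i, j] <- bca[j, i] <- match(keys_a[k], lev)
  }
  for (k in seq_along(keys_b)) {
    i <- mol_b$bonds$a1[k]; j <- mol_b$bonds$a2[k]
    bcb[i, j] <- bcb[j, i] <- match(keys_b[k], lev)
  }
  compat <- outer(va$elem, vb$elem, "==")
  if (cfg$match_chiral_tag) {
    compat <- compat & outer(va$parity != 0L, vb$parity != 0L, "==")
  }

  best <- NULL   # list(amap, n, sites, key)
  tie_budget <- 512L   # bounded exploration of equal-size mappings
  consider <- function(amap) {
    n <- sum(!is.na(amap))
    if (n < cfg$min_core_atoms) return(invisible())
    if (!is.null(best) && n < best$n) return(invisible())
    if (!is.null(best) && n == best$n) tie_budget <<- tie_budget - 1L
    if (cfg$complete_rings_only) {
      cb <- .core_bonds(va, vb, amap, NULL, rmro)
      mapped_a <- which(!is.na(amap))
      loc_to_a <- mapped_a
      pairs_a <- if (nrow(cb)) paste(pmin(loc_to_a[cb$a1], loc_to_a[cb$a2]),
                                     pmax(loc_to_a[cb$a1], loc_to_a[cb$a2])) else character(0)
      if (!.rings_complete(va, mapped_a, pairs_a)) return(invisible())
      mapped_b <- amap[mapped_a]
      pairs_b <- if (nrow(cb)) paste(pmin(amap[loc_to_a[cb$a1]], amap[loc_to_a[cb$a2]]),
                                     pmax(amap[loc_to_a[cb$a1]], amap[loc_to_a[cb$a2]])) else character(0)
      if (!.rings_complete(vb, mapped_b, pairs_b)) return(invisible())
    }
    sites <- .site_count(va, vb, amap)
    mapped_a <- which(!is.na(amap))
    key <- paste(rbind(mapped_a, amap[mapped_a]), collapse = ",")
    cand <- list(amap = amap, n = n, sites = sites, key = key)
    if (is.null(best) || n > best$n ||
        (n == best$n && (sites < best$sites ||
                         (sites == best$sites && key < best$key)))) {
      best <<- cand
    }
    invisible()
  }

  # Partition-based branch and bound (McSplit-style): vertices not yet
  # matched are kept in label classes -- an A-subset and a B-subset whose
  # members have identical bond-class patterns towards every matched pair.
  # Only same-class vertices can ever be matched, so
  #   bound = |matched| + sum over classes of min(|A side|, |B side|),
  # which prunes far more sharply than frontier counting, and symmetric
  # atoms collapse into one class instead of spawning equivalent branches.
  # Classes are split by each newly matched pair (bond class 0 = no bond,
  # giving induced common subgraphs); a class is `conn`ected once any of
  # its members has a matched neighbour, and only connected classes may be
  # branched on, which keeps the core a single fragment.
  timed_out <- FALSE
  node_count <- 0L

  recurse <- function(ma, mb, classes, from_match) {
    if (timed_out) return(invisible())
    node_count <<- node_count + 1L
    if (node_count %% 128L == 0L &&
        as.numeric(difftime(Sys.time(), t0, units = "secs")) > cfg$timeout_s) {
      timed_out <<- TRUE
      return(invisible())
    }
    n <- length(ma)
    if (from_match) {
      amap <- rep(NA_integer_, va$n); amap[ma] <- mb
      consider(amap)
    }
    if (length(classes) > 0L) {
      cls_min <- vapply(classes, function(cl) min(length(cl$a), length(cl$b)), 1L)
    } else cls_min <- integer(0)
    if (!is.null(best)) {
      bound <- n + sum(cls_min)
      if (bound < best$n) return(invisible())
      if (bound == best$n && tie_budget <= 0L) return(invisible())
    }
    eligible <- which(cls_min > 0L &
                        (n == 0L | vapply(classes, function(cl) cl$conn, TRUE)))
    if (length(eligible) == 0L) return(invisible())
    # branch on the largest eligible class; ties to the smallest A atom
    first_a <- vapply(classes[eligible], function(cl) min(cl$a), 1L)
    sel <- eligible[order(-cls_min[eligible], first_a)][1L]
    v <- min(classes[[sel]]$a)

    split_on <- function(classes, v, w) {
      out <- vector("list", 0L)
      for (cl in classes) {
        a <- cl$a[cl$a != v]; b <- cl$b[cl$b != w]
        if (length(a) == 0L || length(b) == 0L) next
        la <- bca[v, a]; lb <- bcb[w, b]
        for (val in unique(la)) {
          bsub <- b[lb == val]
          if (length(bsub) == 0L) next
          out[[length(out) + 1L]] <- list(a = a[la == val], b = bsub,
                                          conn = cl$conn || val > 0L)
        }
      }
      out
    }

    for (w in sort(classes[[sel]]$b)) {
      recurse(c(ma, v), c(mb, w), split_on(classes, v, w), TRUE)
      if (timed_out) return(invisible())
    }
    # exclude v entirely
    classes[[sel]]$a <- classes[[sel]]$a[classes[[sel]]$a != v]
    if (length(classes[[sel]]$a) == 0L) classes[[sel]] <- NULL
    recurse(ma, mb, classes, FALSE)
    invisible()
  }

  akey <- paste0(va$elem, if (cfg$match_chiral_tag) paste0("*", va$parity != 0L) else "")
  bkey <- paste0(vb$elem, if (cfg$match_chiral_tag) paste0("*", vb$parity != 0L) else "")
  classes0 <- list()
  for (key in intersect(unique(akey), unique(bkey))) {
    classes0[[length(classes0) + 1L]] <- list(a = which(akey == key),
                                              b = which(bkey == key),
                                              conn = FALSE)
  }
  recurse(integer(0), integer(0), classes0, FALSE)
  if (timed_out && is.null(best)) {
    intergen_error("mcs_timeout",
                   sprintf("MCS search exceeded %.1f s", cfg$timeout_s))
  }
  if (timed_out) {
    intergen_error("mcs_timeout",
                   sprintf("MCS search exceeded %.1f s (best so far %d atoms)",
                           cfg$timeout_s, best$n))
  }
  if (is.null(best)) {
    intergen_error("core_too_small",
                   sprintf("no common substructure with >= %d atoms under the configured constraints",
                           cfg$min_core_atoms))
  }

  mapped_a <- which(!is.na(best$amap))
  map_a <- mapped_a
  map_b <- best$amap[mapped_a]
  atoms <- mol_a$atoms[map_a, c("elem", "charge"), drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- .core_bonds(va, vb, best$amap, NULL, rmro)
  structure(list(atoms = atoms, bonds = bonds,
                 map_a = map_a, map_b = map_b,
                 name_a = mol_a$name, name_b = mol_b$name,
                 sites = NULL, crossings = NULL),
            class = "core_scaffold")
}

#' @export
print.core_scaffold <- function(x, ...) {
  cat(sprintf("<core_scaffold> %d atoms, %d bonds (%s | %s)%s\n",
              nrow(x$atoms), nrow(x$bonds), x$name_a, x$name_b,
              if (!is.null(x$sites)) sprintf(", %d attachment sites", nrow(x$sites)) else ""))
  invisible(x)
}

#' Locate attachment sites on a core
#'
#' A core atom is an attachment site when, in at least one parent, it has a
#' bonded neighbour outside the core. Each site records, per parent, the
#' bonds crossing from core to non-core at that atom.
#'
#' @param core a `core_scaffold` from [find_core()].
#' @param mol_a,mol_b the parents the core was derived from.
#' @return the core with `sites` (site label, core atom) and `crossings`
#'   (parent, site, core atom, parent-side atoms and bond order) filled in.
#' @export
locate_attachment_sites <- function(core, mol_a, mol_b) {
  cross <- list()
  for (p in c("A", "B")) {
    mol <- if (p == "A") mol_a else mol_b
    map <- if (p == "A") core$map_a else core$map_b
    in_core <- logical(nrow(mol$atoms)); in_core[map] <- TRUE
    adj <- mol_adjacency(mol)
    bmap <- bond_index_map(mol)
    for (ci in seq_along(map)) {
      for (nb in adj[[map[ci]]]) {
        if (!in_core[nb]) {
          k <- bond_id(bmap, map[ci], nb)
          cross[[length(cross) + 1L]] <- data.frame(
            parent = p, core_atom = ci, parent_atom = map[ci], nbr = nb,
            order = mol$bonds$order[k], stringsAsFactors = FALSE)
        }
      }
    }
  }
  cross <- if (length(cross)) do.call(rbind, cross) else
    data.frame(parent = character(0), core_atom = integer(0),
               parent_atom = integer(0), nbr = integer(0), order = integer(0))
  site_atoms <- sort(unique(cross$core_atom))
  core$sites <- data.frame(site = seq_along(site_atoms), core_atom = site_atoms)
  cross$site <- core$sites$site[match(cross$core_atom, core$sites$core_atom)]
  core$crossings <- cross[order(cross$parent, cross$site, cross$nbr), , drop = FALSE]
  rownames(core$crossings) <- NULL
  core
}

#' Group attachment sites frozen together by a fused ring
#'
#' In one parent, two sites belong to the same group when their crossing
#' bonds lead into the same connected set of non-core atoms -- which, with
#' a connected core, happens exactly when a ring runs through non-core
#' atoms between the two sites (a ring fused to the core). Grouped sites
#' are enumerated as a single substituent so no ring is ever broken.
#'
#' @param core a `core_scaffold` with sites located.
#' @param mol one of the two parents.
#' @param parent `"A"` or `"B"`: which parent `mol` is.
#' @return a partition: list of integer vectors of site labels (sites with
#'   no crossing bond in this parent form singleton groups).
#' @export
group_fused_sites <- function(core, mol, parent = c("A", "B")) {
  parent <- match.arg(parent)
  stopifnot(!is.null(core$sites))
  map <- if (parent == "A") core$map_a else core$map_b
  cr <- core$crossings[core$crossings$parent == parent, , drop = FALSE]
  n_sites <- nrow(core$sites)
  if (n_sites == 0L) return(list())
  if (nrow(cr) == 0L) return(as.list(core$sites$site))
  g <- mol_igraph(mol)
  noncore <- setdiff(seq_len(nrow(mol$atoms)), map)
  sub <- igraph::induced_subgraph(g, noncore)
  comp <- igraph::components(sub)$membership
  comp_of <- rep(NA_integer_, nrow(mol$atoms))
  comp_of[noncore] <- comp
  # union-find over sites keyed by shared non-core component
  parent_of <- seq_len(n_sites)
  find <- function(x) { while (parent_of[x] != x) x <- parent_of[x]; x }
  by_comp <- split(cr$site, comp_of[cr$nbr])
  for (ss in by_comp) {
    ss <- unique(ss)
    if (length(ss) > 1L) {
      r <- find(ss[1])
      for (s in ss[-1]) parent_of[find(s)] <- r
    }
  }
  roots <- vapply(seq_len(n_sites), find, 1L)
  unname(lapply(split(core$sites$site, roots), function(v) sort(unique(v))))
}

#' Merge two site partitions
#'
#' Union of the equivalence relations from each parent: a group frozen in
#' either parent stays frozen overall.
#'
#' @param p1,p2 partitions as returned by [group_fused_sites()].
#' @return merged partition (list of sorted site-label vectors), ordered by
#'   smallest member.
#' @export
merge_partitions <- function(p1, p2) {
  labels <- sort(unique(c(unlist(p1), unlist(p2))))
  if (length(labels) == 0L) return(list())
  idx <- seq_along(labels)
  parent_of <- idx
  find <- function(x) { while (parent_of[x] != x) x <- parent_of[x]; x }
  for (grp in c(p1, p2)) {
    pos <- match(grp, labels)
    if (length(pos) > 1L) {
      r <- find(pos[1])
      for (p in pos[-1]) parent_of[find(p)] <- r
    }
  }
  roots <- vapply(idx, find, 1L)
  out <- unname(lapply(split(labels, roots), function(v) sort(v)))
  out[order(vapply(out, min, 1L))]
}

# Serialize a core for debugging: SMILES-ish canonical string of the core
# graph plus a JSON site map.
#' @export
format.core_scaffold <- function(x, ...) {
  core_mol <- new_molecule(
    data.frame(elem = x$atoms$elem, charge = x$atoms$charge, parity = 0L),
    x$bonds, name = "core")
  smi <- tryCatch(canonical_smiles(core_mol), error = function(e) NA_character_)
  jsonlite::toJSON(list(core_smiles = smi, map_a = x$map_a, map_b = x$map_b,
                        sites = x$sites), auto_unbox = TRUE)
}
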