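#' Molecular graph records
#'
#' `intergen` represents a molecule as a hydrogen-suppressed coloured graph:
#' a data frame of heavy atoms (element, formal charge, tetrahedral parity)
#' and a data frame of bonds (kekulized order). Tetrahedral stereochemistry
#' is carried as the MDL V2000 atom parity (1 or 2, 0 = none/undefined),
#' defined relative to the atom's neighbours in ascending index order with
#' an implicit hydrogen ranked last. All parsing, stereo perception from
#' coordinates or wedges, and isomeric canonical SMILES generation are
#' delegated to OpenBabel (via ChemmineOB); the graph surgery performed
#' during intermediate generation only ever *permutes* parity references,
#' which keeps stereochemistry exact without re-deriving it.
#'
#' @param atoms data.frame with columns `elem` (character), `charge`
#'   (integer) and `parity` (integer 0/1/2).
#' @param bonds data.frame with columns `a1`, `a2` (atom indices) and
#'   `order` (1, 2 or 3; kekulized).
#' @param name molecule name.
#' @param coords optional numeric matrix (n x 3) of coordinates in Angstrom.
#' @return An object of class `molecule`.
#' @export
new_molecule <- function(atoms, bonds, name = "", coords = NULL) {
  atoms <- data.frame(
    elem = as.character(atoms$elem),
    charge = as.integer(atoms$charge %||% 0L),
    parity = as.integer(atoms$parity %||% 0L),
    stringsAsFactors = FALSE
  )
  if (nrow(bonds) > 0L) {
    a1 <- pmin(as.integer(bonds$a1), as.integer(bonds$a2))
    a2 <- pmax(as.integer(bonds$a1), as.integer(bonds$a2))
    bonds <- data.frame(a1 = a1, a2 = a2, order = as.integer(bonds$order))
    bonds <- bonds[order(bonds$a1, bonds$a2), , drop = FALSE]
    rownames(bonds) <- NULL
  } else {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  }
  if (!is.null(coords)) {
    coords <- matrix(as.numeric(coords), ncol = 3)
    stopifnot(nrow(coords) == nrow(atoms))
  }
  structure(list(name = as.character(name), atoms = atoms, bonds = bonds,
                 coords = coords),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s: %d heavy atoms, %d bonds, %d stereocentres\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              nrow(x$atoms), nrow(x$bonds), sum(x$atoms$parity != 0L)))
  invisible(x)
}

n_heavy_atoms <- function(mol) nrow(mol$atoms)

# Neighbour list: for atom i, integer vector of bonded atoms.
mol_adjacency <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, function(v) sort(v %||% integer(0)))
}

mol_igraph <- function(mol) {
  g <- igraph::make_empty_graph(n = nrow(mol$atoms), directed = FALSE)
  if (nrow(mol$bonds) > 0L) {
    g <- igraph::add_edges(g, rbind(mol$bonds$a1, mol$bonds$a2))
  }
  g
}

is_connected_mol <- function(mol) {
  nrow(mol$atoms) <= 1L || igraph::is_connected(mol_igraph(mol))
}

# ---- valence model -------------------------------------------------------

# Default valences for neutral atoms; vectors allow hypervalent S/P.
.default_valences <- list(
  H = 1L, B = 3L, C = 4L, N = 3L, O = 2L, F = 1L,
  Si = 4L, P = c(3L, 5L), S = c(2L, 4L, 6L), Cl = 1L,
  Br = 1L, I = 1L, Se = c(2L, 4L, 6L)
)

bond_order_sum <- function(mol) {
  n <- nrow(mol$atoms)
  s <- integer(n)
  for (k in seq_len(nrow(mol$bonds))) {
    s[mol$bonds$a1[k]] <- s[mol$bonds$a1[k]] + mol$bonds$order[k]
    s[mol$bonds$a2[k]] <- s[mol$bonds$a2[k]] + mol$bonds$order[k]
  }
  s
}

#' Implicit hydrogen counts
#'
#' Number of implicit hydrogens per heavy atom under the default valence
#' model (charge-adjusted), or `NA` where the valence model is violated.
#'
#' @param mol a `molecule`.
#' @return integer vector, one entry per atom.
#' @export
implicit_h_counts <- function(mol) {
  bos <- bond_order_sum(mol)
  n <- nrow(mol$atoms)
  out <- integer(n)
  for (i in seq_len(n)) {
    el <- mol$atoms$elem[i]
    dv <- .default_valences[[el]]
    if (is.null(dv)) { out[i] <- 0L; next }   # unknown element: no implicit H
    # Common charge adjustments: N+/O+ gain a bond, N-/O-/C- lose one.
    ch <- mol$atoms$charge[i]
    dv <- dv + if (el %in% c("N", "O", "P", "S")) ch else -abs(ch)
    dv <- dv[dv >= bos[i]]
    out[i] <- if (length(dv) == 0L) NA_integer_ else min(dv) - bos[i]
  }
  out
}

#' Sanity-check a molecule
#'
#' Valence check under the default valence model plus a single-component
#' connectivity check.
#'
#' @param mol a `molecule`.
#' @return `NULL` when the molecule is sound, otherwise a message string.
#' @export
sanitize_check <- function(mol) {
  ih <- implicit_h_counts(mol)
  if (anyNA(ih)) {
    bad <- which(is.na(ih))[1]
    return(sprintf("valence violation at atom %d (%s, bond order sum %d)",
                   bad, mol$atoms$elem[bad], bond_order_sum(mol)[bad]))
  }
  if (nrow(mol$atoms) > 0L && !is_connected_mol(mol)) {
    return("molecule is not a single connected component")
  }
  NULL
}

# ---- ring perception -----------------------------------------------------

# Logical per bond: bond lies in a ring (i.e. is not a bridge).
ring_bond_flags <- function(mol) {
  nb <- nrow(mol$bonds)
  if (nb == 0L) return(logical(0))
  g <- mol_igraph(mol)
  br <- igraph::bridges(g)
  flags <- rep(TRUE, nb)
  flags[as.integer(br)] <- FALSE
  flags
}

#' Perceive small rings
#'
#' Rings (up to `max_size` atoms) as a list of atom-index vectors: for
#' each ring bond the shortest cycles through it are collected, which on
#' drug-like graphs recovers the SSSR rings.
#'
#' @param mol a `molecule`.
#' @param max_size largest ring size reported.
#' @return list of integer vectors (atoms in cycle order).
#' @export
perceive_rings <- function(mol, max_size = 12L) {
  rb <- ring_bond_flags(mol)
  if (!any(rb)) return(list())
  g <- mol_igraph(mol)
  rings <- list()
  seen <- character(0)
  for (k in which(rb)) {
    u <- mol$bonds$a1[k]; v <- mol$bonds$a2[k]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(u, v)))
    sp <- igraph::all_shortest_paths(g2, from = u, to = v)$vpaths
    for (p in sp) {
      ring <- as.integer(p)
      if (length(ring) > max_size) next
      key <- paste(sort(ring), collapse = ",")
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        rings[[length(rings) + 1L]] <- ring   # ordered along the cycle
      }
    }
  }
  rings
}

bond_index_map <- function(mol) {
  if (nrow(mol$bonds) == 0L) return(new.env())
  e <- new.env(hash = TRUE, size = nrow(mol$bonds) * 2L)
  for (k in seq_len(nrow(mol$bonds))) {
    assign(paste(mol$bonds$a1[k], mol$bonds$a2[k]), k, envir = e)
  }
  e
}

bond_id <- function(bmap, i, j) {
  key <- paste(min(i, j), max(i, j))
  if (exists(key, envir = bmap, inherits = FALSE)) get(key, envir = bmap) else NA_integer_
}

#' Perceive aromatic atoms and bonds
#'
#' 5- and 6-membered rings whose Hueckel pi-electron count is 6: a ring
#' atom contributes 1 electron from a double bond inside the ring, 2 as a
#' heteroatom (N, O, S) or anionic carbon without one, and 0 when its only
#' double bond is exocyclic.
#'
#' @param mol a `molecule`.
#' @param rings precomputed rings (see [perceive_rings()]).
#' @return list with logical vectors `atoms` and `bonds`.
#' @export
perceive_aromatic <- function(mol, rings = perceive_rings(mol)) {
  na <- nrow(mol$atoms); nb <- nrow(mol$bonds)
  atom_ar <- logical(na); bond_ar <- logical(nb)
  if (length(rings) == 0L) return(list(atoms = atom_ar, bonds = bond_ar))
  bmap <- bond_index_map(mol)
  dbl_partner <- vector("list", na)
  for (k in seq_len(nb)) {
    if (mol$bonds$order[k] == 2L) {
      dbl_partner[[mol$bonds$a1[k]]] <- c(dbl_partner[[mol$bonds$a1[k]]], mol$bonds$a2[k])
      dbl_partner[[mol$bonds$a2[k]]] <- c(dbl_partner[[mol$bonds$a2[k]]], mol$bonds$a1[k])
    }
  }
  for (ring in rings) {
    if (!(length(ring) %in% c(5L, 6L))) next
    pi_e <- 0L; ok <- TRUE
    for (a in ring) {
      dp <- dbl_partner[[a]]
      if (length(dp) > 0L && any(dp %in% ring)) {
        pi_e <- pi_e + 1L
      } else if (length(dp) > 0L) {
        pi_e <- pi_e + 0L                   # exocyclic double bond
      } else if (mol$atoms$elem[a] %in% c("N", "O", "S") ||
                 (mol$atoms$elem[a] == "C" && mol$atoms$charge[a] < 0L)) {
        pi_e <- pi_e + 2L
      } else { ok <- FALSE; break }
    }
    if (ok && pi_e == 6L) {
      atom_ar[ring] <- TRUE
      m <- length(ring)
      for (t in seq_len(m)) {
        k <- bond_id(bmap, ring[t], ring[if (t == m) 1L else t + 1L])
        if (!is.na(k)) bond_ar[k] <- TRUE
      }
    }
  }
  list(atoms = atom_ar, bonds = bond_ar)
}

#' Bond matching classes
#'
#' Character class per bond used in substructure matching: the kekulized
#' order, with aromatic bonds collapsed into a single `"ar"` class so
#' differently kekulized aromatic rings still match.
#'
#' @param mol a `molecule`.
#' @return character vector, one entry per bond.
#' @export
bond_classes <- function(mol) {
  ar <- perceive_aromatic(mol)$bonds
  cls <- as.character(mol$bonds$order)
  cls[ar] <- "ar"
  cls
}

# ---- symmetry classes and stereocentre perception ------------------------

#' Atom symmetry classes
#'
#' Morgan-style iterative refinement of atom invariants. Atoms in
#' different classes are guaranteed non-equivalent; atoms sharing a class
#' are treated as topologically equivalent.
#'
#' @param mol a `molecule`.
#' @return integer class per atom.
#' @export
symmetry_classes <- function(mol) {
  n <- nrow(mol$atoms)
  if (n == 0L) return(integer(0))
  adj <- mol_adjacency(mol)
  ih <- implicit_h_counts(mol)
  ih[is.na(ih)] <- 0L
  bmap <- bond_index_map(mol)
  cls_key <- paste(mol$atoms$elem, mol$atoms$charge, lengths(adj), ih)
  cls <- as.integer(factor(cls_key))
  repeat {
    key <- vapply(seq_len(n), function(i) {
      nb <- adj[[i]]
      lab <- sort(vapply(nb, function(j)
        paste0(mol$bonds$order[bond_id(bmap, i, j)], ":", cls[j]), ""))
      paste(cls[i], paste(lab, collapse = "|"))
    }, "")
    new_cls <- as.integer(factor(key))
    if (max(new_cls) == max(cls)) break
    cls <- new_cls
  }
  cls
}

#' Perceive potential tetrahedral stereocentres
#'
#' Atoms with four distinct sigma substituents (counting at most one
#' implicit hydrogen), judged by the symmetry classes of their
#' neighbours.
#'
#' @param mol a `molecule`.
#' @return logical vector per atom.
#' @export
perceive_stereocenters <- function(mol) {
  n <- nrow(mol$atoms)
  out <- logical(n)
  if (n == 0L) return(out)
  adj <- mol_adjacency(mol)
  ih <- implicit_h_counts(mol)
  bos <- bond_order_sum(mol)
  cls <- symmetry_classes(mol)
  for (i in seq_len(n)) {
    deg <- length(adj[[i]])
    if (is.na(ih[i])) next
    if (bos[i] != deg) next                       # multiple bond present
    if (deg + ih[i] != 4L) next                   # not 4 sigma neighbours
    if (ih[i] > 1L) next
    if (anyDuplicated(cls[adj[[i]]])) next        # two equivalent branches
    out[i] <- TRUE
  }
  out
}

#' Clear parities on non-stereocentres
#'
#' Zeroes the tetrahedral parity of any atom that is not a perceived
#' stereocentre (e.g. after a recombination produced two identical
#' branches at a formerly chiral atom).
#'
#' @param mol a `molecule`.
#' @return the molecule with invalid parities cleared.
#' @export
validate_parities <- function(mol) {
  if (!any(mol$atoms$parity != 0L)) return(mol)
  sc <- perceive_stereocenters(mol)
  mol$atoms$parity[!sc] <- 0L
  mol
}

# ---- index surgery -------------------------------------------------------

#' Induced submolecule with parity bookkeeping
#'
#' Induced subgraph on `keep` (atom indices, in the order given -- so a
#' permutation of all atoms renumbers the molecule). A removed neighbour
#' of a kept stereocentre is replaced by an implicit hydrogen (ranked
#' last in the parity reference); losing more than one neighbour, or
#' ending up with two implicit hydrogens, clears the parity.
#'
#' @param mol a `molecule`.
#' @param keep integer atom indices to retain, in the desired order.
#' @param name name of the result.
#' @return a `molecule`.
#' @export
subset_molecule <- function(mol, keep, name = mol$name) {
  map <- rep(NA_integer_, nrow(mol$atoms))
  map[keep] <- seq_along(keep)
  atoms <- mol$atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  kb <- !is.na(map[mol$bonds$a1]) & !is.na(map[mol$bonds$a2])
  bonds <- mol$bonds[kb, , drop = FALSE]
  if (nrow(bonds) > 0L) {
    bonds$a1 <- map[bonds$a1]; bonds$a2 <- map[bonds$a2]
  }
  adj <- mol_adjacency(mol)
  for (t in seq_along(keep)) {
    if (atoms$parity[t] == 0L) next
    old <- adj[[keep[t]]]
    vals <- ifelse(is.na(map[old]), Inf, map[old])
    if (length(old) < 4L) vals <- c(vals, Inf)    # original implicit H, ranked last
    atoms$parity[t] <- reorder_parity(atoms$parity[t], vals)
  }
  coords <- if (!is.null(mol$coords)) mol$coords[keep, , drop = FALSE] else NULL
  new_molecule(atoms, bonds, name = name, coords = coords)
}

# ---- SDF bridge (ChemmineR objects, OpenBabel conversions) ---------------

.mdl_charge_codes <- c(`3` = 1L, `2` = 2L, `1` = 3L, `-1` = 5L, `-2` = 6L, `-3` = 7L)

charge_to_code <- function(ch) {
  if (ch == 0L) 0L else .mdl_charge_codes[[as.character(ch)]] %||% 0L
}

code_to_charge <- function(code) {
  switch(as.character(code), `1` = 3L, `2` = 2L, `3` = 1L,
         `5` = -1L, `6` = -2L, `7` = -3L, 0L)
}

#' Serialize a molecule as an SDF (V2000) record
#'
#' Stereochemistry is written into the V2000 atom-parity column; when no
#' coordinates are stored the record is written 0D, which OpenBabel reads
#' back with the parity column as the source of tetrahedral stereo. The
#' fixed-column MDL layout is emitted directly with `sprintf` (column
#' alignment matters: the parity field is read positionally).
#'
#' @param mol a `molecule`.
#' @param zero_coords write zero coordinates even when coordinates exist
#'   (used for canonicalization, where the parity column must win).
#' @param props named character vector written into the SDF data block.
#' @return a single string holding the `$$$$`-terminated record.
#' @export
sdf_text <- function(mol, zero_coords = is.null(mol$coords), props = character(0)) {
  n <- nrow(mol$atoms); nb <- nrow(mol$bonds)
  xyz <- if (!zero_coords && !is.null(mol$coords)) mol$coords else
    matrix(0, nrow = n, ncol = 3)
  chiral <- as.integer(any(mol$atoms$parity != 0L))
  lines <- c(
    if (nzchar(mol$name)) mol$name else "mol",
    sprintf("  intergen       %s", if (zero_coords || is.null(mol$coords)) "" else "3D"),
    "",
    sprintf("%3d%3d  0  0  %d  0  0  0  0  0999 V2000", n, nb, chiral))
  for (i in seq_len(n)) {
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0%3d%3d  0  0  0  0  0  0  0  0  0",
      xyz[i, 1], xyz[i, 2], xyz[i, 3], mol$atoms$elem[i],
      charge_to_code(mol$atoms$charge[i]), mol$atoms$parity[i]))
  }
  for (k in seq_len(nb)) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              mol$bonds$a1[k], mol$bonds$a2[k], mol$bonds$order[k]))
  }
  lines <- c(lines, "M  END")
  for (key in names(props)) {
    lines <- c(lines, sprintf(">  <%s>", key), as.character(props[[key]]), "")
  }
  paste(c(lines, "$$$$"), collapse = "\n")
}

# Parse a ChemmineR SDF object into a molecule.
from_sdf <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_[0-9]+$", "", rownames(ab))
  atoms <- data.frame(
    elem = elem,
    charge = vapply(ab[, "C6"], code_to_charge, 0L),
    parity = as.integer(ab[, "C7"]),
    stringsAsFactors = FALSE
  )
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0L) {
    data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  } else {
    data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  }
  coords <- ab[, 1:3, drop = FALSE]
  if (all(abs(coords) < 1e-9)) coords <- NULL
  nm <- ChemmineR::header(sdf)[["Molecule_Name"]] %||% ""
  new_molecule(atoms, bonds, name = nm, coords = coords)
}

# Run OpenBabel on SDF text; `opts` is a character vector of option names
# (e.g. "d" to delete hydrogens). Returns the converted text.
ob_convert <- function(text, from, to, opts = character(0)) {
  if (length(opts)) {
    ChemmineOB::convertFormat(from, to, source = text, options = data.frame(
      names = opts, args = rep("", length(opts)), stringsAsFactors = FALSE))
  } else {
    ChemmineOB::convertFormat(from, to, source = text)
  }
}

# Normalize one SDF record through OpenBabel: drop explicit hydrogens and
# let OpenBabel re-perceive stereo (from 3D coordinates, 2D wedges or an
# existing parity column) and write it back as a parity column.
normalize_sdf_record <- function(text) {
  out <- tryCatch(ob_convert(text, "SDF", "SDF", opts = "d"),
                  error = function(e) "")
  if (!nzchar(out) || !grepl("V2000", out, fixed = TRUE)) return(NULL)
  out
}

read_sdf_text <- function(text) {
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(text, tf)
  sdfset <- ChemmineR::read.SDFset(tf)
  lapply(seq_along(sdfset), function(i) from_sdf(sdfset[[i]]))
}

#' Parse molecules from an isomeric SMILES string
#'
#' @param smiles character vector of SMILES (one molecule each).
#' @param names optional molecule names.
#' @return list of `molecule` objects; unparseable entries are `NULL`.
#' @export
parse_smiles <- function(smiles, names = NULL) {
  if (is.null(names)) names <- sprintf("mol%d", seq_along(smiles))
  out <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    txt <- tryCatch(
      ob_convert(paste0(smiles[i], " ", names[i], "\n"), "SMI", "SDF", opts = "d"),
      error = function(e) "")
    if (!nzchar(txt) || !grepl("V2000", txt, fixed = TRUE)) next
    mol <- read_sdf_text(txt)[[1]]
    mol$coords <- NULL        # OpenBabel emits placeholder 2D coordinates
    out[[i]] <- mol
  }
  out
}

#' Isomeric canonical SMILES
#'
#' Canonical form of one or more molecules, computed by OpenBabel from a 0D
#' V2000 record whose parity column carries the tetrahedral stereo. The
#' result is invariant under atom renumbering and is the deduplication key
#' used throughout the package.
#'
#' @param mols a `molecule` or list of molecules.
#' @return character vector of canonical SMILES (`NA` on failure).
#' @export
canonical_smiles <- function(mols) {
  if (inherits(mols, "molecule")) mols <- list(mols)
  if (length(mols) == 0L) return(character(0))
  blocks <- vapply(seq_along(mols), function(i) {
    m <- mols[[i]]; m$name <- sprintf("ig%d", i)
    sdf_text(m, zero_coords = TRUE)
  }, "")
  out <- tryCatch(ob_convert(paste(blocks, collapse = "\n"), "SDF", "CAN"),
                  error = function(e) "")
  res <- rep(NA_character_, length(mols))
  if (nzchar(out)) {
    for (line in strsplit(out, "\n", fixed = TRUE)[[1]]) {
      parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(parts) >= 2L) {
        idx <- suppressWarnings(as.integer(sub("^ig", "", trimws(parts[2]))))
        if (!is.na(idx)) res[idx] <- trimws(parts[1])
      }
    }
  }
  res
}
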