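# Synthetic parent-pair generator. Builds pairs that share a known core
# template with a controlled number of differing substituent sites, so
# every stage of the generator (site discovery, fused grouping, stereo
# preservation, the 2^k - 2 count law) can be exercised without external
# data. Substituent pairings are restricted so that the planted core plus
# shared substituents IS the true maximum common substructure: at a
# differing site the two substituents must not be extendable into a larger
# common subgraph (first atoms differ in element, one side is bare
# hydrogen, or exactly one side is a ring, which the complete-rings-only
# matching rule keeps out of the core).

.core_templates <- function() {
  kek6 <- data.frame(a1 = 1:6, a2 = c(2:6, 1), order = c(2L, 1L, 2L, 1L, 2L, 1L))
  benzene <- new_molecule(
    data.frame(elem = rep("C", 6), charge = 0L, parity = 0L), kek6, "benzene")
  pyridine <- new_molecule(
    data.frame(elem = c("N", rep("C", 5)), charge = 0L, parity = 0L), kek6, "pyridine")
  # naphthalene: ring A = 1..6, ring B = 1-6-7-8-9-10, fused bond 1-6
  naph_bonds <- data.frame(
    a1 = c(1, 2, 3, 4, 5, 1, 6, 7, 8, 9, 10),
    a2 = c(2, 3, 4, 5, 6, 6, 7, 8, 9, 10, 1),
    order = c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L, 1L))
  bicyclic <- new_molecule(
    data.frame(elem = rep("C", 10), charge = 0L, parity = 0L), naph_bonds, "naphthalene")
  list(
    benzene = list(mol = benzene, positions = 1:6),
    pyridine = list(mol = pyridine, positions = 2:6),
    bicyclic = list(mol = bicyclic, positions = c(2:5, 7:10))
  )
}

# Substituent library. `attach` is the fragment atom bonded to the core;
# `first` its element ("" for bare H); `ring` whether the fragment is
# cyclic; two-attachment entries close a ring over two adjacent core atoms.
# Chiral entries set the attachment atom's parity (reference order: core
# atom, then internal atoms in definition order, implicit H last).
.substituent_library <- function() {
  frag <- function(elem, bonds = NULL, parity = NULL, ring = FALSE,
                   attach = 1L, attach2 = NULL, first = elem[1]) {
    atoms <- data.frame(elem = elem,
                        charge = rep(0L, length(elem)),
                        parity = rep(0L, length(elem)),
                        stringsAsFactors = FALSE)
    if (!is.null(parity)) atoms$parity[1] <- parity
    bonds <- bonds %||% data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
    list(atoms = atoms, bonds = bonds, attach = attach, attach2 = attach2,
         first = first, ring = ring)
  }
  chain <- function(n) data.frame(a1 = seq_len(n - 1), a2 = 2:n, order = 1L)
  list(
    H     = frag(character(0), first = ""),
    F     = frag("F"),
    Cl    = frag("Cl"),
    CH3   = frag("C"),
    NH2   = frag("N"),
    OCH3  = frag(c("O", "C"), chain(2), first = "O"),
    CF3   = frag(c("C", "F", "F", "F"),
                 data.frame(a1 = 1L, a2 = 2:4, order = 1L)),
    phenyl = frag(rep("C", 6),
                  data.frame(a1 = 1:6, a2 = c(2:6, 1), order = c(1L, 2L, 1L, 2L, 1L, 2L)),
                  ring = TRUE),
    chiralR = frag(c("C", "O", "C"),
                   data.frame(a1 = c(1L, 1L), a2 = c(2L, 3L), order = 1L),
                   parity = 1L),
    chiralS = frag(c("C", "O", "C"),
                   data.frame(a1 = c(1L, 1L), a2 = c(2L, 3L), order = 1L),
                   parity = 2L),
    fused   = frag(rep("C", 3), chain(3), attach = 1L, attach2 = 3L, ring = TRUE)
  )
}

# A differing pairing is safe (cannot extend the MCS) when one side is H,
# the first atoms differ, or exactly one side is a ring.
.subs_safe <- function(lib, a, b) {
  fa <- lib[[a]]; fb <- lib[[b]]
  if (fa$first == "" || fb$first == "") return(TRUE)
  if (fa$first != fb$first) return(TRUE)
  xor(isTRUE(fa$ring), isTRUE(fb$ring))
}

# Attach a single-valence fragment to `site_atom`; returns the molecule.
.attach_fragment <- function(mol, site_atom, fr, site_atom2 = NULL) {
  if (nrow(fr$atoms) == 0L) return(mol)
  off <- nrow(mol$atoms)
  atoms <- rbind(mol$atoms, fr$atoms)
  bonds <- mol$bonds
  if (nrow(fr$bonds) > 0L) {
    fb <- fr$bonds; fb$a1 <- fb$a1 + off; fb$a2 <- fb$a2 + off
    bonds <- rbind(bonds, fb)
  }
  bonds <- rbind(bonds, data.frame(a1 = site_atom, a2 = fr$attach + off, order = 1L))
  if (!is.null(fr$attach2)) {
    stopifnot(!is.null(site_atom2))
    bonds <- rbind(bonds, data.frame(a1 = site_atom2, a2 = fr$attach2 + off, order = 1L))
  }
  new_molecule(atoms, bonds, name = mol$name)
}

#' Fixture specification for a synthetic parent pair
#'
#' @param core_template `"benzene"`, `"pyridine"` or `"bicyclic"`
#'   (naphthalene).
#' @param n_sites number of substituent positions used on the core.
#' @param differing_sites k: number of site groups at which the parents
#'   differ (a fused-ring group counts once).
#' @param substituent_pool names from the built-in library (`H`, `F`,
#'   `Cl`, `CH3`, `NH2`, `OCH3`, `CF3`, `phenyl`, `chiralR`, `chiralS`).
#' @param with_stereocenter place a stereocentre directly at one differing
#'   attachment point.
#' @param with_fused_ring make one differing group a ring fused to the
#'   core over two adjacent positions.
#' @param seed RNG seed; the pair is reproducible for a fixed spec.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(core_template = "benzene", n_sites = 3L,
                         differing_sites = 2L,
                         substituent_pool = c("F", "Cl", "CH3", "NH2", "OCH3", "CF3", "phenyl"),
                         with_stereocenter = FALSE, with_fused_ring = FALSE,
                         seed = 1L) {
  stopifnot(differing_sites >= 0L, n_sites >= differing_sites)
  structure(list(core_template = core_template, n_sites = as.integer(n_sites),
                 differing_sites = as.integer(differing_sites),
                 substituent_pool = substituent_pool,
                 with_stereocenter = isTRUE(with_stereocenter),
                 with_fused_ring = isTRUE(with_fused_ring),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic parent pair
#'
#' Both parents share the chosen core template exactly; they differ at
#' exactly `differing_sites` site groups. Deterministic for a fixed spec.
#'
#' @param spec a [fixture_spec()].
#' @return list with `mol_a`, `mol_b` and `expected_k`.
#' @export
make_pair <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  templates <- .core_templates()
  if (!spec$core_template %in% names(templates)) {
    intergen_error("infeasible_spec",
                   sprintf("unknown core template '%s'", spec$core_template))
  }
  lib <- .substituent_library()
  pool <- intersect(spec$substituent_pool, setdiff(names(lib), c("H", "fused")))
  if (spec$with_stereocenter) pool <- union(pool, c("chiralR"))
  tmpl <- templates[[spec$core_template]]
  k <- spec$differing_sites
  n_single <- spec$n_sites - if (spec$with_fused_ring) 1L else 0L
  k_single <- k - if (spec$with_fused_ring) 1L else 0L
  if (spec$with_fused_ring && k < 1L) {
    intergen_error("infeasible_spec", "a fused-ring group requires differing_sites >= 1")
  }
  if (spec$with_stereocenter && k_single < 1L) {
    intergen_error("infeasible_spec",
                   "a stereocentre at an attachment point needs a non-fused differing site")
  }
  sample_vec <- function(x, n) x[sample.int(length(x), n)]

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  for (attempt in 1:50) {
    positions <- tmpl$positions
    fused_at <- NULL
    if (spec$with_fused_ring) {
      adj_pairs <- list()
      bset <- paste(pmin(tmpl$mol$bonds$a1, tmpl$mol$bonds$a2),
                    pmax(tmpl$mol$bonds$a1, tmpl$mol$bonds$a2))
      for (i in positions) for (j in positions) {
        if (i < j && paste(i, j) %in% bset) adj_pairs[[length(adj_pairs) + 1L]] <- c(i, j)
      }
      if (length(adj_pairs) == 0L) {
        intergen_error("infeasible_spec", "core template has no adjacent free positions")
      }
      fused_at <- adj_pairs[[sample.int(length(adj_pairs), 1L)]]
      positions <- setdiff(positions, fused_at)
    }
    if (n_single > length(positions)) {
      intergen_error("infeasible_spec", sprintf(
        "%d sites requested but only %d positions available", spec$n_sites,
        length(positions) + if (spec$with_fused_ring) 1L else 0L))
    }
    sites <- sort(sample_vec(positions, n_single))
    diff_sites <- if (k_single > 0L) sort(sample_vec(sites, k_single)) else integer(0)
    shared_sites <- setdiff(sites, diff_sites)

    subs_a <- list(); subs_b <- list()
    for (s in shared_sites) {
      nm <- sample_vec(pool, 1L)
      subs_a[[as.character(s)]] <- nm; subs_b[[as.character(s)]] <- nm
    }
    # differing sites: draw safe, globally-distinct pairings (H allowed on
    # B). Ring substituents are kept out of differing sites: a dangling
    # ring the size of the core template could tie with it for the MCS.
    used <- character(0)
    ok <- TRUE
    stereo_placed <- !spec$with_stereocenter
    acyclic_pool <- pool[!vapply(pool, function(nm) isTRUE(lib[[nm]]$ring), TRUE)]
    for (s in diff_sites) {
      cand_a <- setdiff(acyclic_pool, used)
      if (!stereo_placed) cand_a <- intersect(cand_a, c("chiralR", "chiralS"))
      cand_a <- sample_vec(cand_a, length(cand_a))
      placed <- FALSE
      for (a in cand_a) {
        cand_b <- setdiff(c(acyclic_pool, "H"), c(used, a))
        cand_b <- sample_vec(cand_b, length(cand_b))
        for (b in cand_b) {
          if (!.subs_safe(lib, a, b)) next
          # global safety: no cross-site extension between the parents
          other_a <- c(unlist(subs_a), a)
          other_b <- c(unlist(subs_b), b)
          if (all(vapply(other_a, function(x) .subs_safe(lib, x, b) ||
                           identical(x, b), TRUE)) &&
              all(vapply(other_b, function(x) .subs_safe(lib, a, x) ||
                           identical(a, x), TRUE))) {
            subs_a[[as.character(s)]] <- a
            subs_b[[as.character(s)]] <- b
            used <- c(used, a, if (b != "H") b)
            if (a %in% c("chiralR", "chiralS")) stereo_placed <- TRUE
            placed <- TRUE
            break
          }
        }
        if (placed) break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (!ok) next

    mol_a <- tmpl$mol; mol_b <- tmpl$mol
    for (s in sort(as.integer(names(subs_a)))) {
      mol_a <- .attach_fragment(mol_a, s, lib[[subs_a[[as.character(s)]]]])
    }
    for (s in sort(as.integer(names(subs_b)))) {
      mol_b <- .attach_fragment(mol_b, s, lib[[subs_b[[as.character(s)]]]])
    }
    if (spec$with_fused_ring) {
      mol_a <- .attach_fragment(mol_a, fused_at[1], lib$fused, fused_at[2])
      cand <- setdiff(acyclic_pool, c(used, "chiralR", "chiralS"))
      cand <- cand[vapply(cand, function(nm)
        all(vapply(c(unlist(subs_a), ""), function(x)
          x == "" || .subs_safe(lib, x, nm), TRUE)), TRUE)]
      if (length(cand) == 0L) next
      nm <- sample_vec(cand, 1L)
      mol_b <- .attach_fragment(mol_b, fused_at[1], lib[[nm]])
    }
    mol_a$name <- sprintf("%s_seed%d_A", spec$core_template, spec$seed)
    mol_b$name <- sprintf("%s_seed%d_B", spec$core_template, spec$seed)
    for (m in list(mol_a, mol_b)) {
      msg <- sanitize_check(m)
      if (!is.null(msg)) intergen_error("infeasible_spec", msg)
    }
    return(list(mol_a = mol_a, mol_b = mol_b, expected_k = k))
  }
  intergen_error("infeasible_spec",
                 "could not realize the requested number of differing sites from the pool")
}
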