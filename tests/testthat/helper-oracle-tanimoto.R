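# Independent circular-environment Tanimoto oracle: environments are
# rooted balls compared by labelled graph isomorphism (centre marked),
# with no reliance on the implementation's string identifiers.

.ball <- function(mol, center, r) {
  adj <- lapply(seq_len(nrow(mol$atoms)), function(i) {
    c(mol$bonds$a2[mol$bonds$a1 == i], mol$bonds$a1[mol$bonds$a2 == i])
  })
  d <- rep(Inf, nrow(mol$atoms)); d[center] <- 0
  frontier <- center
  for (step in seq_len(r)) {
    nxt <- setdiff(unique(unlist(adj[frontier])), which(is.finite(d)))
    d[nxt] <- step; frontier <- nxt
  }
  keep <- which(is.finite(d))
  ih <- implicit_h_counts(mol)
  deg <- lengths(adj)
  loc <- match(seq_len(nrow(mol$atoms)), keep)
  sel <- mol$bonds$a1 %in% keep & mol$bonds$a2 %in% keep
  bsel <- mol$bonds[sel, , drop = FALSE]
  g <- igraph::make_empty_graph(length(keep), directed = FALSE)
  if (nrow(bsel)) g <- igraph::add_edges(g, rbind(loc[bsel$a1], loc[bsel$a2]))
  vlab <- paste(mol$atoms$elem[keep], mol$atoms$charge[keep],
                deg[keep], ih[keep], keep == center)
  # same bond abstraction as the fingerprint: aromatic bonds are one class
  ecls <- match(bond_classes(mol)[sel], c("1", "2", "3", "ar"))
  list(g = g, v = vlab, e = ecls, r = r)
}

.ball_eq <- function(b1, b2) {
  if (b1$r != b2$r) return(FALSE)
  if (length(b1$v) != length(b2$v) || !identical(sort(b1$v), sort(b2$v))) return(FALSE)
  lev <- unique(c(b1$v, b2$v))
  igraph::isomorphic(b1$g, b2$g, method = "vf2",
                     vertex.color1 = match(b1$v, lev),
                     vertex.color2 = match(b2$v, lev),
                     edge.color1 = b1$e, edge.color2 = b2$e)
}

oracle_tanimoto <- function(mol_a, mol_b, radius = 2L) {
  mols <- list(mol_a, mol_b)
  balls <- list(); owner <- integer(0)
  for (mi in 1:2) for (r in 0:radius) for (a in seq_len(nrow(mols[[mi]]$atoms))) {
    balls[[length(balls) + 1L]] <- .ball(mols[[mi]], a, r)
    owner <- c(owner, mi)
  }
  classes <- integer(length(balls))
  nxtc <- 0L
  for (i in seq_along(balls)) {
    if (classes[i] > 0L) next
    nxtc <- nxtc + 1L; classes[i] <- nxtc
    for (j in seq_along(balls)) {
      if (j > i && classes[j] == 0L && .ball_eq(balls[[i]], balls[[j]])) {
        classes[j] <- nxtc
      }
    }
  }
  f1 <- unique(classes[owner == 1L]); f2 <- unique(classes[owner == 2L])
  length(intersect(f1, f2)) / length(union(f1, f2))
}
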