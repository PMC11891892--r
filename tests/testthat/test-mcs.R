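# Core identification: MCS search, attachment sites, fused-site grouping.

test_that("an asymmetric molecule against itself maps completely with no sites", {
  ala <- smi("N[C@@H](C)C(=O)O")
  core <- locate_attachment_sites(find_core(ala, ala), ala, ala)
  expect_identical(nrow(core$atoms), nrow(ala$atoms))
  expect_identical(nrow(core$sites), 0L)
  expect_identical(core$map_a, core$map_b)
})

test_that("toluene/ethylbenzene core is the phenyl plus one carbon", {
  tol <- smi("Cc1ccccc1", "toluene")
  etb <- smi("CCc1ccccc1", "ethylbenzene")
  core <- locate_attachment_sites(find_core(tol, etb), tol, etb)
  expect_identical(nrow(core$atoms), 7L)          # all of toluene
  expect_identical(nrow(core$sites), 1L)
  # the single site is the exocyclic carbon: its image in ethylbenzene
  # carries the extra methyl
  cr <- core$crossings
  expect_identical(unique(cr$parent), "B")
  expect_identical(core$atoms$elem[cr$core_atom], "C")
  expect_true(core_embeds_in_parents(core, tol, etb))
})

test_that("bond-order and ring constraints reject benzene/cyclohexane", {
  bz <- smi("c1ccccc1"); chx <- smi("C1CCCCC1")
  expect_error(find_core(bz, chx, mcs_config(min_core_atoms = 3L)),
               class = "core_too_small")
})

test_that("the core is symmetric in the argument order", {
  for (seed in 1:3) {
    p <- make_pair(fixture_spec(n_sites = 3, differing_sites = 2, seed = seed))
    c1 <- find_core(p$mol_a, p$mol_b)
    c2 <- find_core(p$mol_b, p$mol_a)
    expect_identical(nrow(c1$atoms), nrow(c2$atoms))
    expect_setequal(paste(c1$map_a, c1$map_b), paste(c2$map_b, c2$map_a))
  }
})

test_that("the core embeds in both parents and contains the planted template", {
  for (seed in 1:4) {
    p <- make_pair(fixture_spec(n_sites = 3, differing_sites = 2, seed = seed))
    core <- find_core(p$mol_a, p$mol_b)
    expect_true(core_embeds_in_parents(core, p$mol_a, p$mol_b))
    expect_true(all(1:6 %in% core$map_a))   # template atoms come first
  }
})

test_that("planted cores are exact on small fixtures (brute-force check)", {
  # parents built so template + shared substituent is the true MCS; verify
  # no larger common connected subgraph exists by exhaustive embedding of
  # every connected (n+1)-atom subgraph of parent A into parent B
  p <- make_pair(fixture_spec(n_sites = 2, differing_sites = 2, seed = 5))
  core <- find_core(p$mol_a, p$mol_b)
  n <- nrow(core$atoms)
  combos <- utils::combn(nrow(p$mol_a$atoms), n + 1L)
  bigger <- FALSE
  for (ci in seq_len(ncol(combos))) {
    keep <- combos[, ci]
    sub <- subset_molecule(p$mol_a, keep)
    if (nrow(sub$bonds) < n) next
    g <- igraph::make_empty_graph(n + 1L, directed = FALSE)
    g <- igraph::add_edges(g, rbind(sub$bonds$a1, sub$bonds$a2))
    if (!igraph::is_connected(g)) next
    if (embeds_in(sub$atoms, sub$bonds, p$mol_b)) { bigger <- TRUE; break }
  }
  expect_false(bigger)
})

test_that("fused rings group their attachment sites; partitions cover all sites", {
  xyl <- smi("Cc1ccccc1C", "oxylene")
  ind <- smi("c1ccc2c(c1)CCC2", "indane")
  core <- locate_attachment_sites(find_core(xyl, ind), xyl, ind)
  expect_identical(nrow(core$sites), 2L)          # two raw sites reported
  gA <- group_fused_sites(core, xyl, "A")
  gB <- group_fused_sites(core, ind, "B")
  expect_identical(lengths(gA), c(1L, 1L))        # methyls are independent
  expect_identical(lengths(gB), 2L)               # the ring freezes both
  merged <- merge_partitions(gA, gB)
  expect_identical(merged, list(c(1L, 2L)))
  # partition properties on a 3-site fused fixture: {fused pair} + singleton
  p <- make_pair(fixture_spec(n_sites = 3, differing_sites = 2,
                              with_fused_ring = TRUE, seed = 2))
  core <- locate_attachment_sites(find_core(p$mol_a, p$mol_b), p$mol_a, p$mol_b)
  part <- merge_partitions(group_fused_sites(core, p$mol_a, "A"),
                           group_fused_sites(core, p$mol_b, "B"))
  all_sites <- sort(unlist(part))
  expect_identical(all_sites, core$sites$site)        # cover, no duplicates
  expect_identical(sort(lengths(part)), c(1L, 2L))
})

test_that("the MCS search honours its timeout", {
  p <- make_pair(fixture_spec(n_sites = 4, differing_sites = 2, seed = 1))
  expect_error(find_core(p$mol_a, p$mol_b, mcs_config(timeout_s = 1e-4)),
               class = "mcs_timeout")
})
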