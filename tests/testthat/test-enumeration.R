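# R-group table, assignment enumeration, stereo-preserving assembly.

make_table <- function(mol_a, mol_b, cfg = mcs_config()) {
  core <- locate_attachment_sites(find_core(mol_a, mol_b, cfg), mol_a, mol_b)
  part <- merge_partitions(group_fused_sites(core, mol_a, "A"),
                           group_fused_sites(core, mol_b, "B"))
  build_rgroup_table(mol_a, mol_b, core, part)
}

test_that("identical parents give a table with no differing site groups", {
  m <- smi("Cc1ccc(F)cc1")
  tab <- make_table(m, m)
  expect_false(any(tab$differing))
  expect_length(enumerate_assignments(tab), 0L)
})

test_that("a pair with three differing substituent sites yields k = 3", {
  A <- smi("Fc1cc(C)cc(OC)c1", "A")
  B <- smi("Clc1cccc(N)c1", "B")
  tab <- make_table(A, B)
  expect_identical(sum(tab$differing), 3L)
  # hydrogen opposite a substituent becomes an explicit zero-atom R-group
  heavies <- vapply(tab$entries[tab$differing], function(e)
    min(e$A$heavy, e$B$heavy), 1L)
  expect_true(any(heavies == 0L))
})

test_that("assignment enumeration is 2^k - 2 in binary order with A = 0", {
  A <- smi("Fc1cc(C)cc(OC)c1", "A"); B <- smi("Clc1cccc(N)c1", "B")
  tab <- make_table(A, B)
  asn <- enumerate_assignments(tab)
  expect_length(asn, 6L)
  expect_identical(asn[[1]], c("A", "A", "B"))
  expect_identical(asn[[2]], c("A", "B", "A"))
  expect_identical(asn[[6]], c("B", "B", "A"))
  expect_false(any(vapply(asn, function(a) all(a == "A") || all(a == "B"), TRUE)))
})

test_that("all-parent assignments reconstruct the parents exactly", {
  for (seed in 1:3) {
    p <- make_pair(fixture_spec(n_sites = 3, differing_sites = 2,
                                with_stereocenter = TRUE, seed = seed))
    tab <- make_table(p$mol_a, p$mol_b)
    k <- sum(tab$differing)
    recA <- assemble_intermediate(tab, rep("A", k))
    recB <- assemble_intermediate(tab, rep("B", k))
    expect_identical(canonical_smiles(recA), canonical_smiles(p$mol_a))
    expect_identical(canonical_smiles(recB), canonical_smiles(p$mol_b))
    expect_true(verify_parent_reconstruction(tab))
  }
})

test_that("a stereocentre cut from the core keeps its configuration", {
  A <- smi("c1cc(ccc1[C@H](F)Cl)C", "A")      # R centre on the tolyl parent
  B <- smi("c1cc(ccc1N)OC", "B")
  iset <- generate_intermediates(A, B, pair_id = "c")
  expect_identical(iset$k, 2L)
  carrier <- Filter(function(m) any(m$atoms$parity != 0L), iset$candidates)
  expect_length(carrier, 1L)
  expect_identical(unname(cip_descriptors(carrier[[1]])), unname(cip_descriptors(A)))
})

test_that("disagreeing core stereochemistry flags the pair", {
  A <- smi("O[C@@H](C)c1ccc(F)cc1", "A")
  B <- smi("O[C@H](C)c1ccc(Cl)cc1", "B")      # opposite centre in the core
  iset <- generate_intermediates(A, B, pair_id = "flag")
  expect_false(iset$parents_reconstructed)
})

test_that("the candidate count law 2^k - 2 matches brute-force assembly", {
  for (k in 1:5) {
    p <- make_pair(fixture_spec(n_sites = 5, differing_sites = k, seed = 7))
    iset <- generate_intermediates(p$mol_a, p$mol_b, pair_id = "law")
    expect_identical(length(iset$candidates), as.integer(max(2^k - 2, 0)))
    expect_identical(length(iset$candidates), brute_force_count(p$mol_a, p$mol_b))
  }
})

test_that("every candidate contains the core and respects provenance", {
  p <- make_pair(fixture_spec(n_sites = 3, differing_sites = 3, seed = 4))
  core <- find_core(p$mol_a, p$mol_b)
  iset <- generate_intermediates(p$mol_a, p$mol_b, pair_id = "prov")
  n_core <- nrow(core$atoms)
  for (cand in iset$candidates) {
    expect_true(embeds_in(core$atoms, core$bonds, cand))
    origin <- attr(cand, "origin")
    expect_true(all(origin %in% c("A", "B")))
    # non-core atom count equals the sum of the chosen fragments' sizes
    sizes <- vapply(seq_along(origin), function(gi)
      iset$table$entries[[gi]][[origin[gi]]]$heavy, 1L)
    expect_identical(nrow(cand$atoms) - n_core, sum(sizes))
  }
})

test_that("fused substituents travel as one unit and rings stay whole", {
  p <- make_pair(fixture_spec(n_sites = 4, differing_sites = 2,
                              with_fused_ring = TRUE, seed = 3))
  iset <- generate_intermediates(p$mol_a, p$mol_b, pair_id = "fused")
  expect_identical(iset$k, 2L)
  expect_true(any(lengths(iset$table$site_groups) == 2L))
  ring_sizes_a <- sort(lengths(perceive_rings(p$mol_a)))
  for (cand in iset$candidates) {
    sizes <- lengths(perceive_rings(cand))
    fused_gi <- which(lengths(iset$table$site_groups) == 2L)
    if (attr(cand, "origin")[fused_gi] == "A") {
      expect_identical(sort(sizes), ring_sizes_a)   # 5-ring carried intact
    } else {
      expect_true(all(sizes %in% c(5L, 6L)))
      expect_false(5L %in% sizes)
    }
  }
})

test_that("generation is order-independent and dedupes by canonical form", {
  p <- make_pair(fixture_spec(n_sites = 3, differing_sites = 3, seed = 9))
  s1 <- sort(vapply(generate_intermediates(p$mol_a, p$mol_b)$candidates,
                    attr, "", "canonical"))
  s2 <- sort(vapply(generate_intermediates(p$mol_b, p$mol_a)$candidates,
                    attr, "", "canonical"))
  expect_identical(s1, s2)
  expect_false(anyDuplicated(s1) > 0L)
  parents <- canonical_smiles(list(p$mol_a, p$mol_b))
  expect_length(intersect(s1, parents), 0L)
})

test_that("a net formal charge difference between parents warns but proceeds", {
  A <- smi("CCc1ccccc1C(=O)O", "A")
  B <- smi("CCCc1ccccc1C(=O)[O-]", "B")
  expect_warning(iset <- generate_intermediates(A, B), "formal charge")
  expect_s3_class(iset, "intermediate_set")
})
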