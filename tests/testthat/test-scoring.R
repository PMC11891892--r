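# Similarity metrics, combiners, filtering and ranking.

test_that("score combiners match their closed forms", {
  hm <- prune_config(combiner = "harmonic_mean")
  expect_equal(combine_scores(0.2, 0.6, hm), 0.3)
  expect_equal(combine_scores(0.7, 0.7, hm), 0.7)
  expect_equal(combine_scores(0, 0, hm), 0)
  expect_equal(combine_scores(0.4, 0.5, prune_config(combiner = "sum")), 0.9)
  ws <- prune_config(combiner = "weighted_sum", weights = c(2, 1))
  expect_equal(combine_scores(0.3, 0.6, ws), 1.2)
  # harmonic mean is bounded by the inputs and by the arithmetic mean
  set.seed(21)
  for (i in 1:25) {
    s <- runif(2)
    h <- combine_scores(s[1], s[2], hm)
    expect_gte(h, min(s)); expect_lte(h, max(s))
    expect_lte(h, mean(s) + 1e-12)
  }
})

test_that("min-max normalization pins endpoints and zeroes constant columns", {
  x <- c(0.2, 0.5, 0.9)
  nx <- intergen:::minmax_normalize(x)
  expect_equal(range(nx), c(0, 1))
  expect_equal(order(nx), order(x))
  expect_equal(intergen:::minmax_normalize(rep(0.4, 3)), rep(0, 3))
})

test_that("circular-environment Tanimoto matches the isomorphism oracle", {
  eth <- smi("CCO"); pro <- smi("CCCO")
  expect_equal(tanimoto_score(eth, eth), 1.0)
  expect_equal(tanimoto_score(eth, pro), 1 / 3)            # 5 shared of 15
  expect_equal(tanimoto_score(eth, pro), oracle_tanimoto(eth, pro))
  expect_equal(tanimoto_score(smi("CC"), smi("OO")), 0)     # disjoint sets
  # further cross-checks against the independent oracle
  pairs <- list(c("Cc1ccccc1", "CCc1ccccc1"),
                c("c1ccncc1", "c1ccccc1"),
                c("CC(=O)O", "CC(=O)N"))
  for (p in pairs) {
    a <- smi(p[1]); b <- smi(p[2])
    expect_equal(tanimoto_score(a, b), oracle_tanimoto(a, b), info = p[1])
    expect_equal(tanimoto_score(a, b), tanimoto_score(b, a))
  }
})

test_that("the LOMAP-style score follows its exponential closed form", {
  tol <- smi("Cc1ccccc1"); etb <- smi("CCc1ccccc1")
  expect_equal(lomap_score(tol, tol), 1.0)
  # N_a + N_b - 2 N_mcs = 7 + 8 - 14 = 1
  expect_equal(lomap_score(tol, etb, beta = 0.1), exp(-0.1))
  expect_equal(lomap_score(tol, etb, beta = 0.3), exp(-0.3))
  # distance 10 at beta 0.1 gives exp(-1)
  a <- smi("CCCCCCc1ccccc1"); b <- smi("c1ccccc1CCCCCC")
  expect_equal(lomap_score(a, b), 1.0)              # identical constitution
  hex <- smi("CCCCCCCCCCCc1ccccc1")                 # 11-carbon chain
  expect_equal(lomap_score(smi("c1ccccc1"), hex, beta = 0.1), exp(-1.1))
  # monotone decay in the uncommon-atom count
  chain <- lapply(1:4, function(n)
    smi(paste0("c1ccccc1", paste(rep("C", n), collapse = ""))))
  scores <- vapply(chain, function(m) lomap_score(smi("c1ccccc1"), m), 0)
  expect_true(all(diff(scores) < 0))
})

test_that("shape scoring uses registered backends and demands coordinates", {
  m1 <- smi("CCO"); m1$coords <- matrix(c(0, 0, 0, 1.5, 0, 0, 2.2, 1.1, 0), 3, byrow = TRUE)
  m2 <- m1
  expect_equal(shape_color_score(m1, m2), 1.0)
  far <- m1; far$coords <- m1$coords + 50
  expect_equal(shape_color_score(m1, far), 0.0)
  shifted <- m1; shifted$coords <- m1$coords + c(0.6, 0, 0)
  s <- shape_color_score(m1, shifted)
  expect_true(s > 0 && s < 1)
  expect_error(shape_color_score(m1, m2, backend = "rocs"),
               class = "backend_unavailable")
  nocoord <- smi("CCO")
  expect_error(shape_color_score(nocoord, m1), class = "backend_unavailable")
  register_shape_backend("constant", function(a, b) 0.5)
  expect_equal(shape_color_score(m1, m2, backend = "constant"), 0.5)
})

test_that("the heavy-atom filter names the offending R-group", {
  expect_true(heavy_atom_filter(c(g1 = 1L, g2 = 5L))$keep)
  res <- heavy_atom_filter(c(g1 = 1L, g2 = 5L), max = 4L)
  expect_false(res$keep)
  expect_match(res$reason, "g2")
  res <- heavy_atom_filter(c(h = 0L), min = 1L)
  expect_false(res$keep)
  expect_match(res$reason, "h")
})

test_that("ranking orders by the first metric, breaks ties, and filters", {
  p <- make_pair(fixture_spec(n_sites = 3, differing_sites = 3, seed = 2))
  iset <- generate_intermediates(p$mol_a, p$mol_b, pair_id = "r")
  sc <- rank_intermediates(iset, prune_config(metrics = c("tanimoto", "lomap")))
  live <- sc[!sc$filtered, ]
  expect_identical(sort(live$rank), seq_len(nrow(live)))
  key <- live$tanimoto_combined[order(live$rank)]
  expect_true(all(diff(key) <= 1e-12))
  # stable under candidate-list permutation
  perm <- rev(seq_along(iset$candidates))
  iset2 <- iset; iset2$candidates <- iset$candidates[perm]
  sc2 <- rank_intermediates(iset2, prune_config(metrics = c("tanimoto", "lomap")))
  m <- merge(sc[, c("candidate", "rank")], sc2[, c("candidate", "rank")],
             by = "candidate")
  expect_identical(m$rank.x, m$rank.y)
  # normalization maps the best per-column candidate to 1
  scn <- rank_intermediates(iset, prune_config(metrics = "tanimoto", normalize = TRUE))
  expect_equal(max(scn$tanimoto_a), 1)
  expect_equal(max(scn$tanimoto_b), 1)
  expect_equal(min(scn$tanimoto_a), 0)
  # the implicit-H R-group is filtered out under a minimum size
  sc3 <- rank_intermediates(iset, prune_config(metrics = "tanimoto",
                                               heavy_atom_min = 1L))
  expect_true(any(sc3$filtered))
  expect_error(
    rank_intermediates(iset, prune_config(metrics = "tanimoto",
                                          heavy_atom_min = 100L)),
    class = "empty_after_filter")
})

test_that("pair summaries report the baseline, mean and best harmonic mean", {
  p <- make_pair(fixture_spec(n_sites = 3, differing_sites = 2, seed = 6))
  iset <- generate_intermediates(p$mol_a, p$mol_b, pair_id = "s")
  s <- summarize_pair(iset, metric = "tanimoto")
  hm <- vapply(iset$candidates, function(m) {
    a <- tanimoto_score(m, iset$table$mol_a)
    b <- tanimoto_score(m, iset$table$mol_b)
    2 * a * b / (a + b)
  }, 0)
  expect_equal(s$mean_hm, mean(hm))
  expect_equal(s$max_hm, max(hm))
  expect_equal(s$parent_pair_score,
               tanimoto_score(iset$table$mol_a, iset$table$mol_b))
  expect_gte(s$max_hm, s$mean_hm)
  agg <- summarize_series(list(s, s))
  expect_equal(agg$max, s$max_hm)
})
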