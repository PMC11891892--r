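# End-to-end pair/series runs, artifacts, report schema, CLI.

test_that("run_pair writes SDF, CSV and a schema-valid JSON report", {
  p <- make_pair(fixture_spec(n_sites = 3, differing_sites = 3, seed = 2))
  out <- file.path(tempdir(), "runpair")
  res <- run_pair(p$mol_a, p$mol_b, out_dir = out, set_id = "7")
  expect_identical(res$report$k, 3L)
  expect_identical(res$report$n_candidates, 6L)
  expect_true(res$report$parents_reconstructed)
  sdf <- file.path(out, "7_intermediates.sdf")
  csv <- file.path(out, "7_scores.csv")
  js <- file.path(out, "7_report.json")
  expect_true(all(file.exists(sdf, csv, js)))
  expect_true(isTRUE(validate_run_report(js)))
  # naming convention: intermediates <set>I<n> from 0
  expect_identical(vapply(res$set$candidates, function(m) m$name, "")[1:2],
                   c("7I0", "7I1"))
  # CLI round trip: scores stored as SDF properties match the table
  back <- read_molecules(sdf)
  expect_length(back, 6L)
  tab <- read.csv(csv)
  expect_identical(nrow(tab), 6L)
  m <- match(res$scores$candidate, tab$candidate)
  expect_equal(tab$tanimoto_combined[m], res$scores$tanimoto_combined)
  expect_equal(tab$rank[m], res$scores$rank)
  raw <- paste(readLines(sdf), collapse = "\n")
  expect_true(grepl(">  <tanimoto_combined>", raw, fixed = TRUE))
})

test_that("identical inputs give an empty, unflagged run", {
  m <- smi("Cc1ccc(F)cc1")
  out <- file.path(tempdir(), "runid")
  res <- run_pair(m, m, out_dir = out, set_id = "id")
  expect_identical(res$report$k, 0L)
  expect_identical(res$report$n_candidates, 0L)
  expect_true(res$report$parents_reconstructed)
  expect_true(file.exists(file.path(out, "id_report.json")))
})

test_that("series mode aggregates per-pair summaries and survives failures", {
  m <- smi("Cc1ccc(F)cc1")
  res <- run_series(list(m, m, m))
  expect_identical(nrow(res$summary), 3L)
  expect_true(all(res$summary$k == 0L))
  expect_true(all(res$summary$success))
  # a pair with no common core is recorded as a failure, the run continues
  mols <- list(smi("c1ccccc1", "bz"), smi("C1CCCCC1", "chx"), smi("Cc1ccccc1", "tol"))
  res2 <- run_series(mols)
  expect_identical(nrow(res2$summary), 3L)
  expect_true(any(!res2$summary$success | is.na(res2$summary$k)) ||
                any(!vapply(res2$results, is.list, TRUE)))
})

test_that("leave-one-out recovery on a two-site combinatorial family", {
  # family: benzene with {F,Cl} at one meta position x {C,N} at another;
  # removing one member, it reappears among the intermediates of the rest
  family <- c(FC = "Fc1cccc(C)c1", FN = "Fc1cccc(N)c1",
              ClC = "Clc1cccc(C)c1", ClN = "Clc1cccc(N)c1")
  mols <- lapply(seq_along(family), function(i) smi(family[[i]], names(family)[i]))
  removed <- canonical_smiles(mols[[4]])
  res <- run_series(mols[1:3])
  inter <- unlist(lapply(res$results, function(r)
    if (is.list(r)) vapply(r$set$candidates, attr, "", "canonical") else character(0)))
  expect_true(removed %in% inter)
})

test_that("the command-line interface runs the pair workflow", {
  cli <- system.file("cli", "intergen", package = "intergen")
  expect_true(nzchar(cli))
  p <- make_pair(fixture_spec(n_sites = 3, differing_sites = 2, seed = 5))
  dir <- file.path(tempdir(), "cliwork")
  dir.create(dir, showWarnings = FALSE)
  fa <- file.path(dir, "a.sdf"); fb <- file.path(dir, "b.sdf")
  write_molecules(list(p$mol_a), fa)
  write_molecules(list(p$mol_b), fb)
  out <- file.path(dir, "out")
  status <- system2("Rscript", c(cli, "pair", "-a", fa, "-b", fb, "-o", out,
                                 "--set-id", "9"),
                    stdout = TRUE, stderr = FALSE)
  expect_true(file.exists(file.path(out, "9_report.json")))
  rep <- jsonlite::read_json(file.path(out, "9_report.json"))
  expect_identical(rep$k, 2L)
  # fixtures + analyze subcommands
  status <- system2("Rscript", c(cli, "fixtures", "-o", dir, "--seed", "3"),
                    stdout = TRUE, stderr = FALSE)
  expect_true(file.exists(file.path(dir, "fixture_seed3.sdf")))
  legs <- file.path(dir, "legs.csv")
  write.csv(data.frame(label = c("A->I", "I->B"), ddg = c(0.4, 0.3),
                       sd = c(0.3, 0.4), n_replicates = 3L), legs, row.names = FALSE)
  out2 <- system2("Rscript", c(cli, "analyze", "--legs", legs),
                  stdout = TRUE, stderr = FALSE)
  expect_true(any(grepl("sd = 0.500", out2)))
})
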