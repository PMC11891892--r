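# Free-energy path analysis: propagation, cycle closure, convergence.

test_that("path estimates add free energies and propagate uncertainty", {
  l1 <- leg_estimate("A->I", 1.2, 0.3)
  l2 <- leg_estimate("I->B", -0.5, 0.4)
  p <- path_estimate(l1, l2)
  expect_equal(p$ddg, 0.7)
  expect_equal(p$sd, 0.5)                          # 3-4-5
  expect_equal(path_estimate(l1, leg_estimate("I->B", 0, 0))$sd, l1$sd)
  # associativity over a chain: sequential root-sum-square equals one pass
  set.seed(33)
  sds <- runif(6, 0, 1)
  legs <- lapply(sds, function(s) leg_estimate("x", 0.1, s))
  seq_path <- Reduce(path_estimate, legs[-1], legs[[1]])
  expect_equal(seq_path$sd, sqrt(sum(sds^2)))
  expect_gte(seq_path$sd, max(sds))
})

test_that("cycle closure reports the discrepancy with propagated sd", {
  d <- leg_estimate("A->B", -1.0, 0.2)
  expect_equal(cycle_closure(d, d)$discrepancy, 0)
  via <- leg_estimate("A->I->B", -0.3, 0.3)
  cc <- cycle_closure(d, via)
  expect_equal(cc$discrepancy, 0.7)
  expect_equal(cc$sd, sqrt(0.2^2 + 0.3^2))
  via2 <- leg_estimate("A->I->B", -0.83, 0.2)
  expect_equal(cycle_closure(d, via2)$discrepancy, 0.17)
})

# brute-force oracle, straight from the definition: the earliest full-
# window start t after which every pair of points at most `window` apart
# (spread mode), or every window's endpoints (endpoint mode), differ by
# at most `threshold`
brute_convergence <- function(times, values, threshold, window, mode = "spread") {
  eps <- 1e-9
  n <- length(times)
  for (i in which(times <= times[n] - window + eps)) {
    ok <- TRUE
    if (mode == "spread") {
      for (u in i:n) {
        if (!ok) break
        for (v in u:n) {
          if (times[v] - times[u] > window + eps) break
          if (abs(values[v] - values[u]) > threshold + eps) { ok <- FALSE; break }
        }
      }
    } else {
      for (u in i:n) {
        j <- which(times >= times[u] + window - eps)
        if (length(j) == 0L) break
        if (abs(values[j[1]] - values[u]) > threshold + eps) { ok <- FALSE; break }
      }
    }
    if (ok) return(times[i])
  }
  NA_real_
}

test_that("convergence time matches a brute-force window scan", {
  t <- seq(0, 7.5, by = 0.1)
  flat <- dg_series(t, rep(-3.2, length(t)))
  expect_equal(convergence_time(flat), 0)
  stepv <- ifelse(t < 3, 0, 1)                     # single 1 kcal/mol step at 3 ns
  s <- dg_series(t, stepv)
  expect_equal(convergence_time(s), 3.0)
  expect_equal(convergence_time(s), brute_convergence(t, stepv, 0.1, 2.0))
  drift <- dg_series(t, 0.1 * t)                   # 0.2 kcal/mol per window
  expect_true(is.na(convergence_time(drift)))
  expect_true(is.na(brute_convergence(t, 0.1 * t, 0.1, 2.0)))
  # random wiggles agree with the oracle in both modes
  set.seed(5)
  for (i in 1:10) {
    v <- cumsum(rnorm(length(t), sd = 0.05))
    s <- dg_series(t, v)
    expect_equal(convergence_time(s), brute_convergence(t, v, 0.1, 2.0))
    expect_equal(convergence_time(s, mode = "endpoint"),
                 brute_convergence(t, v, 0.1, 2.0, mode = "endpoint"))
  }
})

test_that("tightening the threshold never finds an earlier convergence", {
  t <- seq(0, 7.5, by = 0.1)
  set.seed(8)
  v <- cumsum(rnorm(length(t), sd = 0.04))
  s <- dg_series(t, v)
  times <- vapply(c(0.5, 0.3, 0.2, 0.1, 0.05), function(th) {
    ct <- convergence_time(s, threshold = th)
    if (is.na(ct)) 1e9 else ct          # not-converged sorts last
  }, 0)
  expect_true(all(diff(times) >= 0))
})

test_that("degenerate series are rejected with clear errors", {
  expect_error(convergence_time(dg_series(c(0, 0.1, 0.2), c(1, 1, 1)), window = 2),
               class = "window_too_long")
  expect_error(dg_series(c(0, 0.1, 0.15), c(1, 1, 1)), "uniformly")
  expect_error(leg_estimate("x", 0, -1), "sd")
})

test_that("leg estimates and dG series round-trip through CSV", {
  lf <- tempfile(fileext = ".csv")
  write.csv(data.frame(label = c("A->I", "I->B"), ddg = c(0.4, -0.1),
                       sd = c(0.3, 0.4), n_replicates = c(3L, 3L)),
            lf, row.names = FALSE)
  legs <- read_leg_estimates(lf)
  expect_length(legs, 2L)
  expect_equal(path_estimate(legs[[1]], legs[[2]])$sd, 0.5)
  sf <- tempfile(fileext = ".csv")
  t <- seq(0, 5, by = 0.1)
  write.csv(data.frame(time_ns = t, dg_kcal_mol = rep(1.5, length(t))),
            sf, row.names = FALSE)
  expect_equal(convergence_time(read_dg_series(sf)), 0)
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_leg_estimates(bad), class = "parse_error")
})
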