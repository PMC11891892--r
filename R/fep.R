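# Free-energy path analysis: uncertainty propagation over legs through an
# intermediate, cycle-closure discrepancies, and a convergence-time
# criterion on dG time series. These operate on estimates produced
# elsewhere (e.g. MBAR/BAR from replicate simulations); no free-energy
# estimation is performed here.

#' A free-energy leg estimate
#'
#' @param label leg label, e.g. `"A->I"`.
#' @param ddg free-energy difference, kcal/mol.
#' @param sd standard deviation over replicates, kcal/mol.
#' @param n_replicates number of independent replicates.
#' @return list of class `leg_estimate`.
#' @export
leg_estimate <- function(label, ddg, sd, n_replicates = 3L) {
  stopifnot(sd >= 0, n_replicates >= 1L)
  structure(list(label = label, ddg = ddg, sd = sd,
                 n_replicates = as.integer(n_replicates)),
            class = "leg_estimate")
}

#' Combine two legs into a path estimate
#'
#' For a path A -> I -> B through an intermediate: the free-energy
#' differences add and the standard deviation is the root of the summed
#' squares of the leg standard deviations.
#'
#' @param leg1,leg2 `leg_estimate` objects (A->I and I->B).
#' @return a `leg_estimate` for the combined path.
#' @export
path_estimate <- function(leg1, leg2) {
  leg_estimate(label = paste(leg1$label, leg2$label, sep = " + "),
               ddg = leg1$ddg + leg2$ddg,
               sd = sqrt(leg1$sd^2 + leg2$sd^2),
               n_replicates = min(leg1$n_replicates, leg2$n_replicates))
}

#' Cycle-closure discrepancy
#'
#' Free energies are path independent, so the difference between the
#' direct A -> B estimate and the A -> I -> B path should be zero within
#' uncertainty. Returns the discrepancy with its propagated standard
#' deviation.
#'
#' @param direct `leg_estimate` of the direct transformation.
#' @param via_intermediate `leg_estimate` of the path through the
#'   intermediate (see [path_estimate()]).
#' @return list with `discrepancy` and `sd`, kcal/mol.
#' @export
cycle_closure <- function(direct, via_intermediate) {
  list(discrepancy = via_intermediate$ddg - direct$ddg,
       sd = sqrt(via_intermediate$sd^2 + direct$sd^2))
}

#' A free-energy time series
#'
#' @param times times in ns, strictly increasing and uniformly spaced.
#' @param values dG estimates at each time, kcal/mol.
#' @return list of class `dg_series`.
#' @export
dg_series <- function(times, values) {
  stopifnot(length(times) == length(values), length(times) >= 2L)
  dt <- diff(times)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt)) {
    stop("times must be strictly increasing and uniformly spaced")
  }
  structure(list(times = as.numeric(times), values = as.numeric(values)),
            class = "dg_series")
}

#' Time until convergence of a dG time series
#'
#' The earliest time t after which the dG estimate stays converged: every
#' full window \[u, u + window\] with u >= t changes by no more than
#' `threshold`. By default "change" is the maximum pairwise spread inside
#' the window (robust to oscillation); with `mode = "endpoint"` only the
#' difference between each window's endpoints is examined.
#'
#' @param series a [dg_series()].
#' @param threshold maximum allowed change, kcal/mol.
#' @param window window length, ns.
#' @param mode `"spread"` (max pairwise difference) or `"endpoint"`.
#' @return the convergence time in ns, or `NA` (not converged) when no
#'   such t with a full window exists.
#' @export
convergence_time <- function(series, threshold = 0.1, window = 2.0,
                             mode = c("spread", "endpoint")) {
  mode <- match.arg(mode)
  t <- series$times; v <- series$values
  span <- t[length(t)] - t[1]
  if (span < window) {
    intergen_error("window_too_long", sprintf(
      "series spans %.3f ns, shorter than the %.3f ns window", span, window))
  }
  eps <- 1e-9
  starts <- which(t <= t[length(t)] - window + eps)
  violating <- vapply(starts, function(i) {
    j <- which(t >= t[i] + window - eps)[1]
    idx <- i:j
    change <- if (mode == "spread") diff(range(v[idx])) else abs(v[j] - v[i])
    change > threshold + eps
  }, TRUE)
  if (!any(violating)) return(t[1])
  last_bad <- max(which(violating))
  if (last_bad >= length(starts)) return(NA_real_)
  t[starts[last_bad] + 1L]
}

#' Read leg estimates from CSV
#'
#' Expected columns: `label`, `ddg`, `sd`, `n_replicates`.
#'
#' @param path CSV file.
#' @return list of `leg_estimate` objects.
#' @export
read_leg_estimates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "ddg", "sd", "n_replicates")
  if (!all(need %in% names(df))) {
    intergen_error("parse_error", sprintf(
      "%s: expected columns %s", path, paste(need, collapse = ", ")))
  }
  lapply(seq_len(nrow(df)), function(i)
    leg_estimate(df$label[i], df$ddg[i], df$sd[i], df$n_replicates[i]))
}

#' Read a dG time series from CSV
#'
#' Expected columns: `time_ns`, `dg_kcal_mol`.
#'
#' @param path CSV file.
#' @return a [dg_series()].
#' @export
read_dg_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_ns", "dg_kcal_mol")
  if (!all(need %in% names(df))) {
    intergen_error("parse_error", sprintf(
      "%s: expected columns %s", path, paste(need, collapse = ", ")))
  }
  dg_series(df$time_ns, df$dg_kcal_mol)
}
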