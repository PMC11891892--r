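# Similarity scoring and pruning of candidate intermediates.

#' Pruning configuration
#'
#' @param metrics character vector, subset of `tanimoto`, `lomap`,
#'   `shape_color`; ranking uses the first listed metric's combined score,
#'   the others are reported alongside.
#' @param combiner how the two per-parent scores are combined: `sum`,
#'   `weighted_sum` or `harmonic_mean`.
#' @param weights length-2 non-negative weights for `weighted_sum`.
#' @param normalize min-max normalize each metric's per-parent columns over
#'   the candidate pool before combining.
#' @param heavy_atom_min,heavy_atom_max optional bounds on the heavy-atom
#'   count of any enumerated R-group of a candidate.
#' @param lomap_beta decay constant of the LOMAP-style score (per heavy
#'   atom outside the MCS); 0.1 is the conventional LOMAP value.
#' @param shape_backend name of a registered 3D shape backend, or `NULL`.
#' @return list of class `prune_config`.
#' @export
prune_config <- function(metrics = c("tanimoto", "lomap"),
                         combiner = c("harmonic_mean", "sum", "weighted_sum"),
                         weights = c(1, 1),
                         normalize = FALSE,
                         heavy_atom_min = NULL, heavy_atom_max = NULL,
                         lomap_beta = 0.1,
                         shape_backend = NULL) {
  metrics <- match.arg(metrics, c("tanimoto", "lomap", "shape_color"),
                       several.ok = TRUE)
  combiner <- match.arg(combiner)
  stopifnot(length(weights) == 2L, all(weights >= 0), any(weights > 0),
            lomap_beta > 0)
  if (!is.null(heavy_atom_min) && !is.null(heavy_atom_max)) {
    stopifnot(heavy_atom_min <= heavy_atom_max)
  }
  structure(list(metrics = metrics, combiner = combiner, weights = weights,
                 normalize = isTRUE(normalize),
                 heavy_atom_min = heavy_atom_min, heavy_atom_max = heavy_atom_max,
                 lomap_beta = lomap_beta, shape_backend = shape_backend),
            class = "prune_config")
}

# ---- circular-environment Tanimoto ---------------------------------------

#' Circular atom environments
#'
#' ECFP-style environment identifiers: for every atom, a canonical string
#' for its neighbourhood at radius 0, 1, ... `radius`, built by iterated
#' concatenation of sorted (bond class, neighbour environment) labels. The
#' fingerprint of a molecule is the *set* of these identifiers (no bit
#' folding, so identifiers can be enumerated by hand for verification).
#'
#' @param mol a `molecule`.
#' @param radius maximum environment radius (bonds).
#' @return character vector of unique environment identifiers.
#' @export
circular_environments <- function(mol, radius = 2L) {
  n <- nrow(mol$atoms)
  if (n == 0L) return(character(0))
  adj <- mol_adjacency(mol)
  bmap <- bond_index_map(mol)
  bcls <- bond_classes(mol)
  ih <- implicit_h_counts(mol); ih[is.na(ih)] <- 0L
  env <- paste0(mol$atoms$elem, ";", mol$atoms$charge, ";",
                lengths(adj), ";", ih)
  ids <- paste0("0:", env)
  for (r in seq_len(radius)) {
    env <- vapply(seq_len(n), function(i) {
      nb <- adj[[i]]
      lab <- sort(vapply(nb, function(j)
        paste0(bcls[bond_id(bmap, i, j)], env[j]), ""))
      paste0(env[i], "(", paste(lab, collapse = ","), ")")
    }, "")
    ids <- c(ids, paste0(r, ":", env))
  }
  unique(ids)
}

#' Tanimoto similarity over circular environments
#'
#' \eqn{|F_c \cap F_p| / |F_c \cup F_p|} over the radius-2 environment
#' identifier sets of the two molecules. Symmetric and deterministic.
#'
#' @param mol_a,mol_b molecules to compare.
#' @param radius environment radius.
#' @return similarity in \[0, 1\].
#' @export
tanimoto_score <- function(mol_a, mol_b, radius = 2L) {
  fa <- circular_environments(mol_a, radius)
  fb <- circular_environments(mol_b, radius)
  u <- length(union(fa, fb))
  if (u == 0L) return(0)
  length(intersect(fa, fb)) / u
}

# ---- LOMAP-style MCS score -----------------------------------------------

#' LOMAP-style similarity score
#'
#' \eqn{\exp(-\beta (N_a + N_b - 2 N_{mcs}))} with heavy-atom counts and
#' the heavy-atom count of the pair's maximum common substructure: 1 for
#' MCS-identical molecules, decaying with every atom outside the shared
#' substructure. The rule-based LOMAP penalty multipliers (ring-size and
#' net-charge rules) are deliberately not applied; this is the
#' MCS-exponential distance only.
#'
#' @param mol_a,mol_b molecules to compare.
#' @param beta positive decay constant.
#' @param cfg MCS configuration used for the shared-substructure search.
#' @return score in (0, 1]; 0 (with a warning) when no common substructure
#'   of the configured minimum size exists.
#' @export
lomap_score <- function(mol_a, mol_b, beta = 0.1, cfg = mcs_config()) {
  n_mcs <- tryCatch(
    nrow(find_core(mol_a, mol_b, cfg)$atoms),
    intergen_error = function(e) {
      intergen_warn(sprintf("no common core for %s / %s; LOMAP score 0",
                            mol_a$name, mol_b$name))
      NA_integer_
    })
  if (is.na(n_mcs)) return(0)
  exp(-beta * (n_heavy_atoms(mol_a) + n_heavy_atoms(mol_b) - 2L * n_mcs))
}

# ---- 3D shape backends ---------------------------------------------------

.shape_backends <- new.env(parent = emptyenv())

#' Register a 3D shape/colour scoring backend
#'
#' Shape scoring (e.g. ROCS-style shape + chemical-feature overlay) is
#' delegated to pluggable backends: any function taking two molecules with
#' coordinates and returning a similarity in \[0, 1\].
#'
#' @param name backend name.
#' @param fun scoring function `function(mol_a, mol_b) -> numeric`.
#' @export
register_shape_backend <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  assign(name, fun, envir = .shape_backends)
  invisible(name)
}

#' 3D shape similarity via a registered backend
#'
#' @param mol_a,mol_b molecules with coordinates.
#' @param backend backend name (see [register_shape_backend()]).
#' @return similarity in \[0, 1\].
#' @export
shape_color_score <- function(mol_a, mol_b, backend = "grid_overlap") {
  if (!exists(backend, envir = .shape_backends, inherits = FALSE)) {
    intergen_error("backend_unavailable",
                   sprintf("no shape backend registered under '%s'", backend))
  }
  if (is.null(mol_a$coords) || is.null(mol_b$coords)) {
    intergen_error("backend_unavailable", "shape scoring requires 3D coordinates")
  }
  fun <- get(backend, envir = .shape_backends, inherits = FALSE)
  s <- fun(mol_a, mol_b)
  min(max(as.numeric(s), 0), 1)
}

.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, F = 1.47, Cl = 1.75,
                Br = 1.85, I = 1.98, S = 1.80, P = 1.80, B = 1.92)

# Naive voxel-overlap shape similarity: Tanimoto of the occupied-voxel
# sets of the two (pre-aligned) molecules on a common grid. A synthetic
# testing backend, not a reimplementation of any commercial shape score.
grid_overlap_score <- function(mol_a, mol_b, spacing = 0.5) {
  occupancy <- function(mol, lo, dims) {
    r <- .vdw_radii[mol$atoms$elem]; r[is.na(r)] <- 1.7
    occ <- array(FALSE, dims)
    for (i in seq_len(nrow(mol$coords))) {
      ctr <- mol$coords[i, ]
      rng <- lapply(1:3, function(d) {
        idx <- seq(floor((ctr[d] - r[i] - lo[d]) / spacing) + 1L,
                   ceiling((ctr[d] + r[i] - lo[d]) / spacing) + 1L)
        idx[idx >= 1L & idx <= dims[d]]
      })
      for (ix in rng[[1]]) for (iy in rng[[2]]) for (iz in rng[[3]]) {
        pt <- lo + (c(ix, iy, iz) - 0.5) * spacing
        if (sum((pt - ctr)^2) <= r[i]^2) occ[ix, iy, iz] <- TRUE
      }
    }
    occ
  }
  all_xyz <- rbind(mol_a$coords, mol_b$coords)
  lo <- apply(all_xyz, 2, min) - 2.2
  hi <- apply(all_xyz, 2, max) + 2.2
  dims <- pmax(ceiling((hi - lo) / spacing), 1L)
  oa <- occupancy(mol_a, lo, dims)
  ob <- occupancy(mol_b, lo, dims)
  u <- sum(oa | ob)
  if (u == 0L) return(0)
  sum(oa & ob) / u
}

# ---- filtering, combining, ranking ---------------------------------------

#' Heavy-atom filter on a candidate's R-groups
#'
#' @param rgroup_sizes named integer vector of heavy-atom counts, one per
#'   enumerated R-group of the candidate.
#' @param min,max optional inclusive bounds; `NULL` disables a bound.
#' @return list with `keep` (logical) and `reason` (string, `NA` if kept).
#' @export
heavy_atom_filter <- function(rgroup_sizes, min = NULL, max = NULL) {
  if (length(rgroup_sizes) > 0L) {
    labs <- names(rgroup_sizes) %||% as.character(seq_along(rgroup_sizes))
    for (i in seq_along(rgroup_sizes)) {
      if (!is.null(min) && rgroup_sizes[i] < min) {
        return(list(keep = FALSE, reason = sprintf(
          "R-group %s has %d heavy atoms < min %d", labs[i], rgroup_sizes[i], min)))
      }
      if (!is.null(max) && rgroup_sizes[i] > max) {
        return(list(keep = FALSE, reason = sprintf(
          "R-group %s has %d heavy atoms > max %d", labs[i], rgroup_sizes[i], max)))
      }
    }
  }
  list(keep = TRUE, reason = NA_character_)
}

#' Combine the two per-parent scores
#'
#' `sum`: \eqn{s_a + s_b}; `weighted_sum`: \eqn{w_a s_a + w_b s_b};
#' `harmonic_mean`: \eqn{2 s_a s_b / (s_a + s_b)}, defined as 0 when both
#' scores are 0. The harmonic mean penalizes imbalance: an intermediate
#' must resemble *both* parents to score well.
#'
#' @param s_a,s_b per-parent scores.
#' @param cfg a [prune_config()] (combiner and weights).
#' @return combined score.
#' @export
combine_scores <- function(s_a, s_b, cfg = prune_config()) {
  switch(cfg$combiner,
         sum = s_a + s_b,
         weighted_sum = cfg$weights[1] * s_a + cfg$weights[2] * s_b,
         harmonic_mean = ifelse(s_a + s_b == 0, 0, 2 * s_a * s_b / (s_a + s_b)))
}

# min-max normalize a column over the candidate pool; a constant column
# maps to all 0 (it carries no ranking information).
minmax_normalize <- function(x) {
  if (length(x) == 0L) return(x)
  rng <- range(x)
  if (diff(rng) == 0) return(rep(0, length(x)))
  (x - rng[1]) / diff(rng)
}

metric_score <- function(metric, mol, parent, cfg) {
  switch(metric,
         tanimoto = tanimoto_score(mol, parent),
         lomap = lomap_score(mol, parent, beta = cfg$lomap_beta),
         shape_color = shape_color_score(mol, parent,
                                         backend = cfg$shape_backend %||% "grid_overlap"))
}

# Heavy-atom counts of a candidate's enumerated R-groups, from provenance.
candidate_rgroup_sizes <- function(iset, cand) {
  origin <- attr(cand, "origin")
  tab <- iset$table
  idx <- which(tab$differing)
  sizes <- vapply(idx, function(gi) tab$entries[[gi]][[origin[gi]]]$heavy, 1L)
  names(sizes) <- vapply(idx, function(gi)
    paste0("{", paste(tab$site_groups[[gi]], collapse = ","), "}:", origin[gi]), "")
  sizes
}

#' Score, filter and rank an intermediate set
#'
#' Applies the heavy-atom R-group filter, computes every requested metric
#' against both parents, optionally min-max normalizes each metric's
#' per-parent columns over the candidate pool, combines the two scores,
#' and ranks the surviving candidates by the first metric's combined score
#' (descending; ties broken by canonical form).
#'
#' @param iset an `intermediate_set` from [generate_intermediates()].
#' @param cfg a [prune_config()].
#' @return a `score_table` data.frame: one row per candidate with columns
#'   `candidate`, `canonical`, per metric `<m>_a`, `<m>_b`, `<m>_combined`,
#'   plus `filtered`, `filter_reason` and `rank` (NA for filtered rows).
#' @export
rank_intermediates <- function(iset, cfg = prune_config()) {
  cands <- iset$candidates
  if (length(cands) == 0L) {
    intergen_error("empty_after_filter", "no candidates to rank")
  }
  mol_a <- iset$table$mol_a; mol_b <- iset$table$mol_b
  df <- data.frame(
    candidate = vapply(cands, function(m) m$name, ""),
    canonical = vapply(cands, function(m) attr(m, "canonical") %||%
                         canonical_smiles(m), ""),
    stringsAsFactors = FALSE)
  filt <- lapply(cands, function(m)
    heavy_atom_filter(candidate_rgroup_sizes(iset, m),
                      min = cfg$heavy_atom_min, max = cfg$heavy_atom_max))
  df$filtered <- !vapply(filt, `[[`, TRUE, "keep")
  df$filter_reason <- vapply(filt, `[[`, "", "reason")
  if (all(df$filtered)) {
    intergen_error("empty_after_filter",
                   "all candidates removed by the heavy-atom filter")
  }
  for (metric in cfg$metrics) {
    sa <- vapply(cands, function(m) metric_score(metric, m, mol_a, cfg), 0)
    sb <- vapply(cands, function(m) metric_score(metric, m, mol_b, cfg), 0)
    if (cfg$normalize) { sa <- minmax_normalize(sa); sb <- minmax_normalize(sb) }
    df[[paste0(metric, "_a")]] <- sa
    df[[paste0(metric, "_b")]] <- sb
    df[[paste0(metric, "_combined")]] <- combine_scores(sa, sb, cfg)
  }
  key <- df[[paste0(cfg$metrics[1], "_combined")]]
  df$rank <- NA_integer_
  live <- which(!df$filtered)
  ord <- live[order(-key[live], df$canonical[live])]
  df$rank[ord] <- seq_along(ord)
  class(df) <- c("score_table", class(df))
  df
}

#' Per-pair similarity summary
#'
#' For one metric: the parent-parent similarity (the baseline an
#' intermediate should beat), and the mean and maximum over candidates of
#' the harmonic mean of the candidate's similarity to the two parents.
#'
#' @param iset an `intermediate_set`.
#' @param metric one of `tanimoto`, `lomap`, `shape_color`.
#' @param cfg a [prune_config()] (for metric parameters).
#' @return list with `parent_pair_score`, `mean_hm`, `max_hm` (the latter
#'   two `NA` when the set has no candidates).
#' @export
summarize_pair <- function(iset, metric = "lomap", cfg = prune_config()) {
  mol_a <- iset$table$mol_a; mol_b <- iset$table$mol_b
  baseline <- metric_score(metric, mol_a, mol_b, cfg)
  if (length(iset$candidates) == 0L) {
    return(list(parent_pair_score = baseline, mean_hm = NA_real_, max_hm = NA_real_))
  }
  hm <- vapply(iset$candidates, function(m) {
    sa <- metric_score(metric, m, mol_a, cfg)
    sb <- metric_score(metric, m, mol_b, cfg)
    if (sa + sb == 0) 0 else 2 * sa * sb / (sa + sb)
  }, 0)
  list(parent_pair_score = baseline, mean_hm = mean(hm), max_hm = max(hm))
}

#' Series-level similarity summary
#'
#' Averages [summarize_pair()] results over the pairs of a series: the
#' mean parent-parent baseline, the mean of per-pair candidate means and
#' the mean of per-pair candidate maxima.
#'
#' @param summaries list of [summarize_pair()] results.
#' @return list with `parents`, `mean`, `max` (NAs from candidate-free
#'   pairs removed).
#' @export
summarize_series <- function(summaries) {
  g <- function(f) {
    v <- vapply(summaries, `[[`, 0, f)
    mean(v[!is.na(v)])
  }
  list(parents = g("parent_pair_score"), mean = g("mean_hm"), max = g("max_hm"))
}

#' Write a score table to CSV
#'
#' @param scores a `score_table`.
#' @param path output file.
#' @param pair_id pair identifier column value.
#' @export
write_score_table <- function(scores, path, pair_id = "") {
  out <- cbind(data.frame(pair_id = pair_id, stringsAsFactors = FALSE),
               as.data.frame(scores))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
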