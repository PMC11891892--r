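# File I/O and orchestration: read molecule files, run the generator and
# pruner for a pair or a whole congeneric series, and write SDF/CSV/JSON
# artifacts. Naming convention for outputs: parents <set>PA and <set>PB,
# intermediates <set>I0, <set>I1, ... in deterministic enumeration order.

#' Read molecules from an SDF or SMILES file
#'
#' SDF records are normalized through OpenBabel (explicit hydrogens
#' folded, stereo re-perceived from 3D coordinates, 2D wedges or an
#' existing parity column); SMILES files carry one molecule per line with
#' an optional whitespace-separated name. Unparseable records are skipped
#' with a warning; their indices are attached as attribute `failures`.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"sdf"` or `"smiles"`.
#' @return list of `molecule` objects (attribute `failures`: integer
#'   indices of skipped records).
#' @export
read_molecules <- function(path, format = c("auto", "sdf", "smiles")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    intergen_error("parse_error", sprintf("file not found: %s", path))
  }
  if (format == "auto") {
    format <- if (grepl("\\.(sdf|mol)$", path, ignore.case = TRUE)) "sdf" else "smiles"
  }
  mols <- list(); failures <- integer(0)
  if (format == "sdf") {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    recs <- strsplit(txt, "\\$\\$\\$\\$\\s*\n?")[[1]]
    recs <- recs[vapply(recs, function(r) grepl("V2000|V3000", r), TRUE)]
    for (i in seq_along(recs)) {
      norm <- normalize_sdf_record(paste0(recs[i], "\n$$$$\n"))
      m <- if (is.null(norm)) NULL else
        tryCatch(read_sdf_text(norm)[[1]], error = function(e) NULL)
      if (is.null(m)) failures <- c(failures, i) else mols[[length(mols) + 1L]] <- m
    }
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    for (i in seq_along(lines)) {
      parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      nm <- if (length(parts) > 1L) paste(parts[-1], collapse = " ") else
        sprintf("mol%d", i)
      m <- parse_smiles(parts[1], nm)[[1]]
      if (is.null(m)) failures <- c(failures, i) else mols[[length(mols) + 1L]] <- m
    }
  }
  if (length(failures) > 0L) {
    intergen_warn(sprintf("%s: skipped %d unparseable record(s): %s",
                          path, length(failures), paste(failures, collapse = ", ")))
  }
  if (length(mols) == 0L) intergen_warn(sprintf("%s: no molecules read", path))
  attr(mols, "failures") <- failures
  mols
}

#' Write molecules to an SDF file
#'
#' @param mols list of `molecule` objects.
#' @param path output file.
#' @param props optional list (one named character vector per molecule)
#'   written into each record's data block.
#' @export
write_molecules <- function(mols, path, props = NULL) {
  blocks <- vapply(seq_along(mols), function(i)
    sdf_text(mols[[i]], props = if (is.null(props)) character(0) else props[[i]]),
    "")
  writeLines(paste(blocks, collapse = "\n"), path)
  invisible(path)
}

#' Run the generator and pruner for one parent pair
#'
#' Executes the full workflow and writes three artifacts to `out_dir`:
#' `<set>_intermediates.sdf` (candidates with scores as SDF properties),
#' `<set>_scores.csv` (the ranked score table) and `<set>_report.json`
#' (counts, flags, timings and the configuration echo).
#'
#' @param mol_a,mol_b parent molecules (renamed to `<set>PA`/`<set>PB`).
#' @param out_dir output directory (created if missing); `NULL` skips
#'   writing.
#' @param set_id set identifier used in names and file prefixes.
#' @param mcs an [mcs_config()].
#' @param prune a [prune_config()].
#' @return (invisibly) list with the `intermediate_set`, the `score_table`
#'   (or `NULL` when there are no candidates) and the report list.
#' @export
run_pair <- function(mol_a, mol_b, out_dir = NULL, set_id = "1",
                     mcs = mcs_config(), prune = prune_config()) {
  t0 <- Sys.time()
  mol_a$name <- sprintf("%sPA", set_id)
  mol_b$name <- sprintf("%sPB", set_id)
  iset <- generate_intermediates(mol_a, mol_b, cfg = mcs, pair_id = set_id)
  scores <- NULL
  if (length(iset$candidates) > 0L) {
    scores <- rank_intermediates(iset, prune)
  }
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  report <- list(
    pair_id = set_id,
    parents = c(mol_a$name, mol_b$name),
    k = iset$k,
    n_candidates = length(iset$candidates),
    n_failures = nrow(iset$failures),
    parents_reconstructed = iset$parents_reconstructed,
    runtime_s = round(elapsed, 4),
    config = list(
      mcs = unclass(mcs),
      prune = unclass(prune)[c("metrics", "combiner", "weights", "normalize",
                               "heavy_atom_min", "heavy_atom_max", "lomap_beta")]
    )
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(scores)) {
      props <- lapply(seq_along(iset$candidates), function(i) {
        row <- scores[scores$candidate == iset$candidates[[i]]$name, , drop = FALSE]
        vals <- vapply(names(row)[-(1:2)], function(cn) as.character(row[[cn]]), "")
        names(vals) <- names(row)[-(1:2)]
        vals
      })
      write_molecules(iset$candidates, file.path(out_dir, sprintf("%s_intermediates.sdf", set_id)),
                      props = props)
      write_score_table(scores, file.path(out_dir, sprintf("%s_scores.csv", set_id)),
                        pair_id = set_id)
    } else {
      write_molecules(list(), file.path(out_dir, sprintf("%s_intermediates.sdf", set_id)))
    }
    jsonlite::write_json(report, file.path(out_dir, sprintf("%s_report.json", set_id)),
                         auto_unbox = TRUE, null = "null", digits = NA)
  }
  invisible(list(set = iset, scores = scores, report = report))
}

#' Run the generator over all pairs of a series
#'
#' Enumerates all unordered pairs of the input molecules (or a provided
#' pair list), runs [run_pair()] on each, and aggregates a per-pair
#' summary plus series-level similarity statistics (the parent-pair
#' baseline vs the mean and best intermediate harmonic-mean scores, per
#' metric). Per-pair failures are recorded and the run continues.
#'
#' @param mols list of `molecule` objects (>= 2).
#' @param out_dir output directory, or `NULL`.
#' @param pairs optional 2-column matrix of molecule indices.
#' @param mcs an [mcs_config()].
#' @param prune a [prune_config()].
#' @param metrics metrics to include in the series summary.
#' @return (invisibly) list with `summary` (per-pair data.frame),
#'   `series` (per-metric baseline/mean/max), `results` (per-pair
#'   [run_pair()] outputs or error messages).
#' @export
run_series <- function(mols, out_dir = NULL, pairs = NULL,
                       mcs = mcs_config(), prune = prune_config(),
                       metrics = c("lomap", "tanimoto")) {
  stopifnot(length(mols) >= 2L)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(length(mols), 2L))
  }
  rows <- list(); results <- list()
  sums <- stats::setNames(vector("list", length(metrics)), metrics)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    set_id <- sprintf("%d_%d", i, j)
    res <- tryCatch(
      run_pair(mols[[i]], mols[[j]], out_dir = out_dir, set_id = set_id,
               mcs = mcs, prune = prune),
      error = function(e) e)
    if (inherits(res, "condition")) {
      results[[set_id]] <- conditionMessage(res)
      rows[[r]] <- data.frame(pair = set_id, mol_a = mols[[i]]$name,
                              mol_b = mols[[j]]$name, k = NA_integer_,
                              n_intermediates = NA_integer_, success = FALSE,
                              best_combined = NA_real_, stringsAsFactors = FALSE)
      next
    }
    results[[set_id]] <- res
    best <- if (!is.null(res$scores)) {
      key <- paste0(prune$metrics[1], "_combined")
      live <- res$scores[!res$scores$filtered, , drop = FALSE]
      if (nrow(live)) max(live[[key]]) else NA_real_
    } else NA_real_
    rows[[r]] <- data.frame(pair = set_id, mol_a = mols[[i]]$name,
                            mol_b = mols[[j]]$name, k = res$set$k,
                            n_intermediates = length(res$set$candidates),
                            success = res$set$parents_reconstructed,
                            best_combined = best, stringsAsFactors = FALSE)
    for (m in metrics) {
      sums[[m]] <- c(sums[[m]], list(summarize_pair(res$set, m, prune)))
    }
  }
  summary <- do.call(rbind, rows)
  series <- lapply(sums, function(s) if (length(s)) summarize_series(s) else NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary, file.path(out_dir, "series_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(n_molecules = length(mols),
                              n_pairs = nrow(pairs),
                              n_success = sum(summary$success, na.rm = TRUE),
                              total_intermediates = sum(summary$n_intermediates, na.rm = TRUE),
                              series = series),
                         file.path(out_dir, "series_report.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
  }
  invisible(list(summary = summary, series = series, results = results))
}

#' Validate a pair run report against the shipped schema
#'
#' Lightweight structural validation: required fields present with the
#' expected JSON types, per `inst/schema/run_report.schema.json`.
#'
#' @param report a report list (as produced by [run_pair()]) or a path to
#'   a report JSON file.
#' @return TRUE, or a character vector of problems.
#' @export
validate_run_report <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  schema <- jsonlite::read_json(system.file("schema", "run_report.schema.json",
                                            package = "intergen"))
  problems <- character(0)
  for (field in names(schema$properties)) {
    req <- field %in% unlist(schema$required)
    if (!field %in% names(report)) {
      if (req) problems <- c(problems, sprintf("missing required field '%s'", field))
      next
    }
    type <- schema$properties[[field]]$type
    val <- report[[field]]
    ok <- switch(type,
                 string = is.character(val) || (is.list(val) && all(vapply(val, is.character, TRUE))),
                 integer = is.numeric(val),
                 number = is.numeric(val),
                 boolean = is.logical(val),
                 array = is.list(val) || length(val) > 1L,
                 object = is.list(val),
                 TRUE)
    if (!ok) problems <- c(problems, sprintf("field '%s' is not of type %s", field, type))
  }
  if (length(problems) == 0L) TRUE else problems
}
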