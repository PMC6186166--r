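#' Relative-to-full false discovery rate
#'
#' Treats the full-data (f = 1) reference run as ground truth: any
#' significant connection found at a lower fraction that the reference
#' did not find counts as a false positive. The rate is
#' `|S_f \ S_1| / |S_f|`, and 0 when `S_f` is empty (a message notes
#' the empty set). Reverser and progressor connections are compared
#' within their own direction class.
#'
#' @param s_f character vector: significant connections at (f, iteration).
#' @param s_1 character vector: the reference set at f = 1.
#' @return a value in [0, 1].
#' @export
#' @examples
#' relative_fdr(c("a", "b", "c", "d"), c("a", "b"))  # 0.5
relative_fdr <- function(s_f, s_1) {
  s_f <- unique(as.character(s_f)); s_1 <- unique(as.character(s_1))
  if (length(s_f) == 0) {
    message("empty significant set at this cell; relative FDR set to 0")
    return(0)
  }
  length(setdiff(s_f, s_1)) / length(s_f)
}

#' Per-connection detection frequency across iterations
#'
#' For one fraction, the frequency of a connection is the share of the K
#' thinning iterations in which it was called significant. Connections
#' never significant do not appear in the result.
#'
#' @param sets list of K character vectors (one per iteration).
#' @return named numeric vector in (0, 1], names = connection ids.
#' @export
connection_frequency <- function(sets) {
  if (length(sets) < 1)
    stop_connstab("connstab_domain_error", ">= 1 iteration required")
  K <- length(sets)
  tab <- table(unlist(lapply(sets, unique)))
  stats::setNames(as.numeric(tab) / K, names(tab))
}

#' Venn partition of per-fraction connection sets
#'
#' Splits the union of the chosen fractions' connection sets into the
#' `2^m - 1` disjoint Venn regions (m = number of fractions). Region
#' names list the member fractions joined by `&`. The regions are
#' pairwise disjoint and their union is the union of the input sets.
#'
#' @param sets_by_fraction named list: fraction (as character) -> set of
#'   connection ids. Each fraction's set should be its consensus set —
#'   connections at or above the consensus frequency threshold — with
#'   f = 1 contributing its single reference run.
#' @param fraction_subset fractions to include (default: all).
#' @return named list of regions.
#' @export
#' @examples
#' venn_partition(list(`0.5` = c("a", "b"), `1` = c("b", "c")))
venn_partition <- function(sets_by_fraction,
                           fraction_subset = names(sets_by_fraction)) {
  fraction_subset <- as.character(fraction_subset)
  if (!all(fraction_subset %in% names(sets_by_fraction)))
    stop_connstab("connstab_config_error",
                  "fraction_subset contains fractions not in the input")
  sets <- sets_by_fraction[fraction_subset]
  m <- length(sets)
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1)
  regions <- list()
  for (code in seq_len(2^m - 1)) {
    inc <- as.logical(bitwAnd(code, 2^(seq_len(m) - 1)))
    key <- paste(fraction_subset[inc], collapse = "&")
    in_region <- apply(membership, 1, function(r) all(r == inc))
    regions[[key]] <- universe[in_region]
  }
  regions
}

#' Top-k compound stability across fractions
#'
#' Ranks perturbagens at each fraction by most-negative aggregate score
#' (strongest candidate reverser first; ties broken by smaller q then
#' lexicographic id), truncates at k and reports pairwise overlap counts
#' and Jaccard indices between fractions.
#'
#' @param scores_by_fraction named list: fraction -> named numeric vector
#'   of perturbagen-level scores.
#' @param k list length (default 50); if fewer perturbagens are
#'   available the full list is used with a warning.
#' @param q_by_fraction optional matching list of q-values for
#'   tie-breaking.
#' @return list with `lists` (per-fraction ranked ids), `overlap` and
#'   `jaccard` (fraction x fraction matrices), and `k_used`.
#' @export
topk_stability <- function(scores_by_fraction, k = 50,
                           q_by_fraction = NULL) {
  if (k < 1)
    stop_connstab("connstab_config_error", "k must be >= 1")
  lists <- lapply(names(scores_by_fraction), function(f) {
    sc <- scores_by_fraction[[f]]
    qv <- if (!is.null(q_by_fraction)) q_by_fraction[[f]][names(sc)]
          else rep(0, length(sc))
    ord <- order(sc, qv, names(sc))
    ids <- names(sc)[ord]
    if (length(ids) < k)
      warning(sprintf("fraction %s: only %d perturbagens for top-%d; using all",
                      f, length(ids), k), call. = FALSE)
    utils::head(ids, k)
  })
  names(lists) <- names(scores_by_fraction)
  fr <- names(lists)
  overlap <- jac <- matrix(NA_real_, length(fr), length(fr),
                           dimnames = list(fr, fr))
  for (i in seq_along(fr)) for (j in seq_along(fr)) {
    a <- lists[[i]]; b <- lists[[j]]
    overlap[i, j] <- length(intersect(a, b))
    u <- length(union(a, b))
    jac[i, j] <- if (u == 0) 1 else overlap[i, j] / u
  }
  list(lists = lists, overlap = overlap, jaccard = jac,
       k_used = min(k, min(lengths(lists))))
}

#' Mean with percentile confidence interval
#'
#' Percentile interval (2.5/97.5 for the default level) over the K
#' iteration values, by the linear-interpolation percentile. A single
#' value yields the degenerate interval equal to that value.
#'
#' @param values numeric vector of per-iteration statistics (>= 1 value).
#' @param level confidence level in (0, 1).
#' @return named numeric `c(mean, lower, upper)`.
#' @export
summarize_ci <- function(values, level = 0.95) {
  if (length(values) == 0)
    stop_connstab("connstab_domain_error", "empty input")
  a <- (1 - level) / 2
  q <- stats::quantile(values, c(a, 1 - a), names = FALSE, type = 7)
  c(mean = mean(values), lower = q[1], upper = q[2])
}

# One grid cell: thin -> DE -> signature -> connectivity. Returns the
# cell's counts, significant sets per direction, and perturbagen-level
# scores/q. Degenerate cells (no normalizable gene or empty signature)
# come back with empty sets rather than aborting the grid.
pipeline_cell <- function(counts, library, f, iter, filter, conn_config,
                          master_seed) {
  cm <- thin_counts(counts, f,
                    child_seed(master_seed, sprintf("thin_f%g_i%d", f, iter)))
  de <- tryCatch(wald_de_test(cm),
                 connstab_normalization_error = function(e) NULL)
  empty_cell <- function(n_deg) list(
    f = f, iteration = iter, n_deg = n_deg, empty = TRUE,
    rev = character(0), prog = character(0),
    scores = NULL, q = NULL)
  if (is.null(de)) return(empty_cell(0L))
  n_deg <- sum(de$padj <= filter$alpha & abs(de$lfc) >= filter$lfc_min)
  sig <- suppressMessages(build_signature(
    de, filter, name = sprintf("sig_f%g_i%d", f, iter),
    provenance = list(f = f, iteration = iter)))
  if (is_empty_signature(sig)) return(empty_cell(n_deg))
  cc <- conn_config
  cc$seed <- child_seed(master_seed, sprintf("perm_f%g_i%d", f, iter))
  conn <- suppressWarnings(run_connectivity(sig, library, cc))
  sig_rows <- conn[conn$significant, , drop = FALSE]
  list(f = f, iteration = iter, n_deg = n_deg, empty = FALSE,
       rev = sig_rows$perturbagen[sig_rows$direction == "rev"],
       prog = sig_rows$perturbagen[sig_rows$direction == "prog"],
       scores = stats::setNames(conn$score, conn$perturbagen),
       q = stats::setNames(conn$q_value, conn$perturbagen))
}

cell_cache_path <- function(cache_dir, f, iter)
  file.path(cache_dir, sprintf("cell_f%g_i%d.json", f, iter))

save_cell <- function(cell, path) {
  # named vectors must become JSON objects, not bare arrays, or the
  # perturbagen names would be lost on reload
  for (nm in c("scores", "q"))
    if (!is.null(cell[[nm]])) cell[[nm]] <- as.list(cell[[nm]])
  jsonlite::write_json(cell, path, auto_unbox = TRUE, digits = NA)
}

load_cell <- function(path) {
  cell <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("rev", "prog"))
    cell[[nm]] <- as.character(cell[[nm]])
  for (nm in c("scores", "q"))
    if (!is.null(cell[[nm]])) cell[[nm]] <- unlist(cell[[nm]])
  cell
}

#' Run the fraction-by-iteration robustness grid
#'
#' The orchestrating operation: for every fraction `f < 1` in the grid it
#' runs K independent cells (binomial thinning of the full data, then
#' normalization, NB-Wald differential expression, signature filtering
#' and connectivity mapping), runs the full data once as the f = 1
#' reference, and assembles the stability statistics: per-fraction DEG
#' and significant-connection counts with percentile confidence
#' intervals, relative-to-full FDR per direction, per-connection
#' detection frequencies, a Venn partition of consensus reverser sets
#' across fractions, and top-k compound stability. Every stochastic step
#' uses a child seed derived from `master_seed`, so the whole summary is
#' a pure function of (inputs, configuration, master seed). With a
#' `cache_dir`, finished cells are persisted as JSON and skipped on
#' re-run.
#'
#' @param counts full-depth `CountMatrix`.
#' @param library `ReferenceLibrary` to query.
#' @param grid a [fraction_grid()].
#' @param filter a [signature_filter()].
#' @param conn_config a [connectivity_config()]; its `seed` is replaced
#'   by per-cell child seeds.
#' @param master_seed integer master seed.
#' @param k_top list length for top-k stability (default 50; capped at
#'   the number of perturbagens with a warning).
#' @param consensus_threshold frequency defining a fraction's consensus
#'   connection set for the Venn partition (default 0.5).
#' @param venn_fractions fractions for the Venn partition (default: all
#'   grid fractions).
#' @param cache_dir optional directory for resumable per-cell JSON.
#' @return an object of class `RobustnessSummary`; see Details.
#' @details The summary contains `per_cell` (one row per pipeline
#'   execution), `per_fraction` (means and CIs of DEG count, significant
#'   rev/prog counts and relative FDR), `frequency` (long data.frame of
#'   per-connection frequencies), `consensus` (per-direction consensus
#'   sets by fraction), `venn` (regions plus consistent/gained/lost
#'   views), `topk`, `reference` (the f = 1 significant sets) and the
#'   run configuration.
#' @export
run_grid <- function(counts, library, grid = fraction_grid(),
                     filter = signature_filter(),
                     conn_config = connectivity_config(),
                     master_seed = 1, k_top = 50,
                     consensus_threshold = 0.5,
                     venn_fractions = NULL, cache_dir = NULL) {
  stopifnot(inherits(grid, "FractionGrid"))
  if (!is.null(cache_dir) && !dir.exists(cache_dir))
    dir.create(cache_dir, recursive = TRUE)

  get_cell <- function(f, iter) {
    if (!is.null(cache_dir)) {
      path <- cell_cache_path(cache_dir, f, iter)
      if (file.exists(path)) return(load_cell(path))
    }
    cell <- pipeline_cell(counts, library, f, iter, filter, conn_config,
                          master_seed)
    if (!is.null(cache_dir)) save_cell(cell, cell_cache_path(cache_dir,
                                                             f, iter))
    cell
  }

  ref <- get_cell(1, 0L)
  if (ref$empty)
    stop_connstab("connstab_reference_error",
                  paste("the full-data (f = 1) signature is empty;",
                        "no reference set exists to compare against"))
  cells <- list(ref)
  for (f in grid$fractions[grid$fractions < 1])
    for (iter in seq_len(grid$iterations))
      cells[[length(cells) + 1L]] <- get_cell(f, iter)

  per_cell <- do.call(rbind, lapply(cells, function(cl) data.frame(
    f = cl$f, iteration = cl$iteration, n_deg = cl$n_deg,
    n_sig_rev = length(cl$rev), n_sig_prog = length(cl$prog),
    fdr_rev = suppressMessages(relative_fdr(cl$rev, ref$rev)),
    fdr_prog = suppressMessages(relative_fdr(cl$prog, ref$prog)))))

  fr_chr <- as.character(grid$fractions)
  stat_names <- c("n_deg", "n_sig_rev", "n_sig_prog", "fdr_rev",
                  "fdr_prog")
  per_fraction <- do.call(rbind, lapply(grid$fractions, function(f) {
    rows <- per_cell[per_cell$f == f, , drop = FALSE]
    out <- data.frame(f = f, K = nrow(rows))
    for (sn in stat_names) {
      ci <- summarize_ci(rows[[sn]])
      out[[paste0(sn, "_mean")]] <- ci[["mean"]]
      out[[paste0(sn, "_lower")]] <- ci[["lower"]]
      out[[paste0(sn, "_upper")]] <- ci[["upper"]]
    }
    out
  }))

  freq_rows <- list()
  consensus <- list(rev = list(), prog = list())
  scores_by_fraction <- list()
  q_by_fraction <- list()
  for (f in grid$fractions) {
    fc <- Filter(function(cl) cl$f == f, cells)
    for (dir in c("rev", "prog")) {
      fq <- connection_frequency(lapply(fc, `[[`, dir))
      consensus[[dir]][[as.character(f)]] <-
        names(fq)[fq >= consensus_threshold]
      if (length(fq) > 0)
        freq_rows[[length(freq_rows) + 1L]] <- data.frame(
          f = f, perturbagen = names(fq), direction = dir,
          frequency = as.numeric(fq), stringsAsFactors = FALSE)
    }
    sc_list <- Filter(Negate(is.null), lapply(fc, `[[`, "scores"))
    if (length(sc_list) > 0) {
      perts <- names(sc_list[[1]])
      sc_mat <- vapply(sc_list, function(s) s[perts],
                       numeric(length(perts)))
      if (length(perts) == 1) sc_mat <- matrix(sc_mat, nrow = 1)
      scores_by_fraction[[as.character(f)]] <-
        stats::setNames(rowMeans(sc_mat), perts)
      q_list <- Filter(Negate(is.null), lapply(fc, `[[`, "q"))
      q_mat <- vapply(q_list, function(s) s[perts], numeric(length(perts)))
      if (length(perts) == 1) q_mat <- matrix(q_mat, nrow = 1)
      q_by_fraction[[as.character(f)]] <-
        stats::setNames(rowMeans(q_mat), perts)
    }
  }
  frequency <- if (length(freq_rows) > 0) do.call(rbind, freq_rows)
               else data.frame(f = numeric(0), perturbagen = character(0),
                               direction = character(0),
                               frequency = numeric(0))

  if (is.null(venn_fractions)) venn_fractions <- grid$fractions
  venn_sets <- consensus$rev[as.character(venn_fractions)]
  venn <- list(
    regions = venn_partition(venn_sets),
    consistent = Reduce(intersect, venn_sets),
    gained = lapply(venn_sets[names(venn_sets) != "1"],
                    function(s) setdiff(s, ref$rev)),
    lost = lapply(venn_sets[names(venn_sets) != "1"],
                  function(s) setdiff(ref$rev, s)))

  topk <- suppressWarnings(topk_stability(scores_by_fraction, k = k_top,
                                          q_by_fraction = q_by_fraction))

  structure(list(
    per_cell = per_cell, per_fraction = per_fraction,
    frequency = frequency, consensus = consensus, venn = venn,
    topk = topk,
    reference = list(rev = ref$rev, prog = ref$prog),
    grid = grid, filter = filter, conn_config = conn_config,
    consensus_threshold = consensus_threshold,
    master_seed = master_seed), class = "RobustnessSummary")
}

#' @export
print.RobustnessSummary <- function(x, ...) {
  cat(sprintf(
    "RobustnessSummary: %d fractions x K = %d (+ reference), %d cells\n",
    length(x$grid$fractions), x$grid$iterations, nrow(x$per_cell)))
  cat(sprintf("reference (f = 1): %d rev, %d prog significant connections\n",
              length(x$reference$rev), length(x$reference$prog)))
  print(x$per_fraction[, c("f", "K", "n_deg_mean", "n_sig_rev_mean",
                           "fdr_rev_mean")], row.names = FALSE)
  invisible(x)
}

#' Serialize a robustness summary to canonical JSON
#'
#' A deterministic rendering used for reproducibility checks (identical
#' master seeds must give byte-identical files) and for downstream
#' report tooling.
#'
#' @param summary a `RobustnessSummary`.
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @return the JSON string (invisibly when written to `path`).
#' @export
summary_to_json <- function(summary, path = NULL) {
  obj <- unclass(summary)
  obj$grid <- unclass(obj$grid)
  obj$filter <- unclass(obj$filter)
  obj$conn_config <- unclass(obj$conn_config)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                           dataframe = "columns", null = "null",
                           pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
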