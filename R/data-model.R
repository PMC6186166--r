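#' Gene-level RNA-seq count matrix with a two-group contrast
#'
#' The container every pipeline stage consumes: a nonnegative integer
#' genes x samples matrix, a per-sample group label with exactly two
#' levels (the contrast is "second level vs first level"), and optional
#' gene lengths in bases for length-bias-aware enrichment.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). All entries must be
#'   nonnegative integers.
#' @param groups character or factor of length `ncol(counts)` giving each
#'   sample's group; exactly two distinct levels are allowed.
#' @param gene_lengths optional positive numeric vector named by gene id,
#'   covering every gene in `counts`; units are bases.
#' @return an object of class `CountMatrix`: a list with elements
#'   `counts`, `groups` (factor), and `gene_lengths` (or `NULL`).
#' @export
#' @examples
#' m <- matrix(rpois(12, 10), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' cm <- count_matrix(m, c("A", "A", "B", "B"))
#' dim(cm$counts)
count_matrix <- function(counts, groups, gene_lengths = NULL) {
  if (!is.matrix(counts))
    stop_connstab("connstab_format_error", "`counts` must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_connstab("connstab_format_error",
                  "`counts` needs gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop_connstab("connstab_format_error", "duplicate gene ids: %s",
                  paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                        collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop_connstab("connstab_format_error", "duplicate sample ids")
  bad <- which(!is.finite(counts) | counts < 0 | counts != floor(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_connstab("connstab_format_error",
                  "non-integer or negative count at gene %s, sample %s",
                  rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]])
  storage.mode(counts) <- "integer"
  if (length(groups) != ncol(counts))
    stop_connstab("connstab_consistency_error",
                  "`groups` length %d != %d samples", length(groups), ncol(counts))
  groups <- factor(as.character(groups))
  if (nlevels(groups) != 2)
    stop_connstab("connstab_contrast_error",
                  "exactly two group levels required, got: %s",
                  paste(levels(groups), collapse = ", "))
  if (!is.null(gene_lengths)) {
    if (is.null(names(gene_lengths)) ||
        !all(rownames(counts) %in% names(gene_lengths)))
      stop_connstab("connstab_consistency_error",
                    "`gene_lengths` must be named and cover every gene")
    gene_lengths <- gene_lengths[rownames(counts)]
    if (any(!is.finite(gene_lengths) | gene_lengths <= 0))
      stop_connstab("connstab_format_error", "gene lengths must be positive")
  }
  structure(list(counts = counts, groups = groups,
                 gene_lengths = gene_lengths),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s: %d", levels(x$groups), table(x$groups)),
                    collapse = ", ")))
  invisible(x)
}

# Both group levels need >= 2 samples before any dispersion / Wald step.
check_de_ready <- function(cm) {
  if (any(table(cm$groups) < 2))
    stop_connstab("connstab_contrast_error",
                  "each group needs >= 2 samples for differential expression")
  invisible(cm)
}

#' Up/down gene signature with provenance
#'
#' A signature is the pair of up- and down-regulated gene sets that
#' summarizes a two-group contrast, plus the provenance needed to trace it
#' back through the subsampling grid: the data fraction `f`, the iteration
#' index, and the filter thresholds that produced it.
#'
#' @param name signature name (used in GMT line names `<name>_UP`/`_DN`).
#' @param up,down character vectors of gene ids; must be disjoint.
#' @param scores optional named numeric vector of signed per-gene
#'   statistics (log2 fold changes) backing the signature.
#' @param provenance named list; `f` (fraction in (0,1], default 1) and
#'   `iteration` are always recorded.
#' @return an object of class `GeneSignature`.
#' @export
gene_signature <- function(name, up, down, scores = NULL,
                           provenance = list()) {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  bad <- intersect(up, down)
  if (length(bad) > 0)
    stop_connstab("connstab_integrity_error",
                  "genes in both up and down sets: %s",
                  paste(utils::head(bad, 5), collapse = ", "))
  if (is.null(provenance$f)) provenance$f <- 1
  if (provenance$f <= 0 || provenance$f > 1)
    stop_connstab("connstab_domain_error", "provenance$f must be in (0, 1]")
  if (is.null(provenance$iteration)) provenance$iteration <- 0L
  structure(list(name = as.character(name), up = up, down = down,
                 scores = scores, provenance = provenance),
            class = "GeneSignature")
}

#' Test whether a signature has no member genes
#'
#' Empty signatures are legal objects (a heavily thinned iteration may
#' yield one) but connectivity scoring refuses them.
#' @param signature a `GeneSignature`.
#' @return logical.
#' @export
is_empty_signature <- function(signature) {
  length(signature$up) + length(signature$down) == 0
}

#' @export
print.GeneSignature <- function(x, ...) {
  cat(sprintf("GeneSignature '%s': %d up, %d down (f = %g, iteration = %d)\n",
              x$name, length(x$up), length(x$down),
              x$provenance$f, as.integer(x$provenance$iteration)))
  invisible(x)
}

#' Perturbagen reference profile library
#'
#' Holds per-gene differential-expression scores (z-like, continuous) for
#' each perturbagen x cell-line profile over a shared gene universe, with
#' optional cell-line tags (e.g. "neuronal") used to restrict connectivity
#' queries to a cell-line subset.
#'
#' @param scores numeric matrix, genes (universe) x profiles; all entries
#'   finite. Rownames are the gene universe.
#' @param profile_info data.frame with columns `perturbagen` and
#'   `cell_line`, one row per column of `scores`; the pairs must be unique.
#' @param cell_line_tags optional named list mapping cell-line id to a
#'   character vector of tags.
#' @return an object of class `ReferenceLibrary`.
#' @export
reference_library <- function(scores, profile_info, cell_line_tags = list()) {
  if (!is.matrix(scores) || is.null(rownames(scores)))
    stop_connstab("connstab_format_error",
                  "`scores` must be a matrix with the gene universe as rownames")
  if (any(!is.finite(scores)))
    stop_connstab("connstab_format_error", "profile scores must be finite")
  if (anyDuplicated(rownames(scores)))
    stop_connstab("connstab_format_error", "duplicate genes in universe")
  if (nrow(profile_info) != ncol(scores))
    stop_connstab("connstab_consistency_error",
                  "profile_info rows (%d) != profile columns (%d)",
                  nrow(profile_info), ncol(scores))
  key <- paste(profile_info$perturbagen, profile_info$cell_line, sep = "\r")
  if (anyDuplicated(key))
    stop_connstab("connstab_format_error",
                  "duplicate (perturbagen, cell_line) profile pairs")
  colnames(scores) <- paste(profile_info$perturbagen,
                            profile_info$cell_line, sep = ":")
  structure(list(gene_universe = rownames(scores), scores = scores,
                 profile_info = as.data.frame(profile_info,
                                              stringsAsFactors = FALSE),
                 cell_line_tags = cell_line_tags),
            class = "ReferenceLibrary")
}

#' @export
print.ReferenceLibrary <- function(x, ...) {
  cat(sprintf(
    "ReferenceLibrary: %d genes, %d profiles (%d perturbagens x %d cell lines)\n",
    length(x$gene_universe), ncol(x$scores),
    length(unique(x$profile_info$perturbagen)),
    length(unique(x$profile_info$cell_line))))
  invisible(x)
}

# Keep only profiles whose cell line carries `tag`; NULL tag is a no-op.
filter_library <- function(library, tag = NULL) {
  if (is.null(tag)) return(library)
  keep_cl <- names(Filter(function(tg) tag %in% tg, library$cell_line_tags))
  keep <- library$profile_info$cell_line %in% keep_cl
  if (!any(keep))
    stop_connstab("connstab_config_error",
                  "no profiles remain after cell-line filter '%s'", tag)
  reference_library(library$scores[, keep, drop = FALSE],
                    library$profile_info[keep, , drop = FALSE],
                    library$cell_line_tags)
}

# Assemble the standard connection-result data.frame and enforce the
# direction convention: rev iff score < 0, prog iff score > 0, a zero
# score gets no direction and is never significant.
connection_result <- function(perturbagen, score, p_value, q_value,
                              alpha, cell_line = NA_character_) {
  direction <- ifelse(score < 0, "rev", ifelse(score > 0, "prog", NA))
  significant <- !is.na(direction) & q_value <= alpha
  out <- data.frame(perturbagen = perturbagen, cell_line = cell_line,
                    score = score, p_value = p_value, q_value = q_value,
                    direction = direction, significant = significant,
                    stringsAsFactors = FALSE)
  out <- out[order(out$score), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ConnectionResult", "data.frame")
  out
}
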