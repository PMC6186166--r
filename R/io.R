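#' Read a gene-level count matrix and sample groups from TSV
#'
#' The counts file is tab-separated with gene ids in the first column and
#' a header row of sample ids; the groups file maps sample id to group
#' label (two columns, no header required, header `sample<TAB>group`
#' tolerated). Validation is strict: non-integer or negative entries,
#' duplicate gene ids, samples without a group, or more than two group
#' levels all raise located errors rather than being coerced.
#'
#' @param path counts TSV path.
#' @param groups_path two-column TSV mapping sample id to group.
#' @return a [count_matrix()] whose sample order follows the counts header.
#' @export
read_counts <- function(path, groups_path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(tab) < 2)
    stop_connstab("connstab_format_error", "%s: need gene id + >=1 sample", path)
  gene_ids <- tab[[1]]
  if (anyDuplicated(gene_ids))
    stop_connstab("connstab_format_error", "%s: duplicate gene ids: %s", path,
                  paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  sample_ids <- colnames(tab)[-1]
  num <- suppressWarnings(
    vapply(tab[-1], as.numeric, numeric(nrow(tab))))
  num <- matrix(num, nrow = nrow(tab),
                dimnames = list(gene_ids, sample_ids))
  bad <- which(!is.finite(num) | num < 0 | num != floor(num), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_connstab("connstab_format_error",
                  "%s: non-integer or negative count '%s' at gene %s, sample %s",
                  path, tab[bad[1, 1], bad[1, 2] + 1L],
                  gene_ids[bad[1, 1]], sample_ids[bad[1, 2]])

  gr <- utils::read.delim(groups_path, header = FALSE, sep = "\t",
                          colClasses = "character")
  if (identical(tolower(gr[1, 1]), "sample")) gr <- gr[-1, , drop = FALSE]
  gmap <- stats::setNames(gr[[2]], gr[[1]])
  missing <- setdiff(sample_ids, names(gmap))
  if (length(missing) > 0)
    stop_connstab("connstab_consistency_error",
                  "samples in %s missing from %s: %s", path, groups_path,
                  paste(missing, collapse = ", "))
  groups <- gmap[sample_ids]
  if (length(unique(groups)) > 2)
    stop_connstab("connstab_contrast_error",
                  "%s: more than two group levels: %s", groups_path,
                  paste(sort(unique(groups)), collapse = ", "))
  count_matrix(num, groups)
}

#' Write a count matrix to TSV
#'
#' @param cm a `CountMatrix`.
#' @param path output TSV path; a sibling `<path>.groups.tsv` receives the
#'   sample-to-group map when `groups_path` is not given.
#' @param groups_path optional explicit path for the group map.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path,
                         groups_path = paste0(path, ".groups.tsv")) {
  df <- data.frame(gene = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = colnames(cm$counts), group = as.character(cm$groups)),
    groups_path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  invisible(path)
}

# Serialize provenance as "key=value" pairs for the GMT description field.
provenance_to_desc <- function(prov) {
  prov <- prov[vapply(prov, function(v) length(v) == 1 && is.atomic(v),
                      logical(1))]
  if (length(prov) == 0) return("na")
  paste(sprintf("%s=%s", names(prov), vapply(prov, format, character(1))),
        collapse = ";")
}

desc_to_provenance <- function(desc) {
  if (identical(desc, "na") || !nzchar(desc)) return(list())
  kv <- strsplit(strsplit(desc, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  out <- lapply(kv, function(p) if (length(p) == 2) p[2] else NA_character_)
  names(out) <- vapply(kv, `[`, character(1), 1)
  for (k in c("f", "iteration", "alpha", "lfc_min", "max_per_direction"))
    if (!is.null(out[[k]])) out[[k]] <- as.numeric(out[[k]])
  out
}

#' Write a gene signature as a two-line GMT file
#'
#' The dialect writes two tab-separated lines per signature, named
#' `<name>_UP` and `<name>_DN`, with the provenance serialized as
#' `key=value` pairs in the description field. An empty direction is a
#' valid member-less line.
#'
#' @param signature a `GeneSignature`.
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [read_signature_gmt()]
#' @export
write_signature_gmt <- function(signature, path) {
  desc <- provenance_to_desc(signature$provenance)
  lines <- c(
    paste(c(paste0(signature$name, "_UP"), desc, signature$up),
          collapse = "\t"),
    paste(c(paste0(signature$name, "_DN"), desc, signature$down),
          collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene signature from a two-line GMT file
#'
#' @param path GMT path as written by [write_signature_gmt()].
#' @return a `GeneSignature`; overlapping up/down sets raise an integrity
#'   error, a missing paired `_UP`/`_DN` line a format error.
#' @export
read_signature_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(fields, `[`, character(1), 1)
  up_i <- grep("_UP$", ids); dn_i <- grep("_DN$", ids)
  if (length(up_i) != 1 || length(dn_i) != 1)
    stop_connstab("connstab_format_error",
                  "%s: need exactly one _UP and one _DN line", path)
  name_up <- sub("_UP$", "", ids[up_i]); name_dn <- sub("_DN$", "", ids[dn_i])
  if (name_up != name_dn)
    stop_connstab("connstab_format_error",
                  "%s: _UP/_DN names differ ('%s' vs '%s')", path,
                  name_up, name_dn)
  member <- function(f) if (length(f) > 2) f[-(1:2)] else character(0)
  up <- member(fields[[up_i]]); dn <- member(fields[[dn_i]])
  gene_signature(name_up, up, dn,
                 provenance = desc_to_provenance(fields[[up_i]][2]))
}

#' Read/write a signature as a pair of GRP files
#'
#' GRP files hold one gene per line; the up and down sets live in paired
#' files `<base>_up.grp` and `<base>_dn.grp`.
#'
#' @param signature a `GeneSignature` (write only).
#' @param base path prefix for the pair.
#' @return the signature (read) or `base` invisibly (write).
#' @export
write_signature_grp <- function(signature, base) {
  writeLines(signature$up, paste0(base, "_up.grp"))
  writeLines(signature$down, paste0(base, "_dn.grp"))
  invisible(base)
}

#' @rdname write_signature_grp
#' @param name signature name to attach on read (default: basename).
#' @export
read_signature_grp <- function(base, name = basename(base)) {
  up_p <- paste0(base, "_up.grp"); dn_p <- paste0(base, "_dn.grp")
  if (!file.exists(up_p) || !file.exists(dn_p))
    stop_connstab("connstab_format_error",
                  "missing paired GRP file for base %s", base)
  rd <- function(p) { x <- readLines(p); x[nzchar(x)] }
  gene_signature(name, rd(up_p), rd(dn_p))
}

#' Read a perturbagen reference library
#'
#' Accepts either the long tab-separated format with columns
#' `perturbagen`, `cell_line`, `gene`, `score` (header required) or a GCT
#' 1.3 text file (first line `#1.3`) whose columns are profiles named
#' `perturbagen:cell_line`. The gene universe is the sorted union of genes
#' seen; a profile missing a gene gets score 0 and the total number of
#' imputed entries is reported in a warning.
#'
#' @param path library file path.
#' @param tags_path optional two-column TSV `cell_line<TAB>tag` (one tag
#'   per row; repeat a cell line for several tags).
#' @return a [reference_library()].
#' @export
read_reference_library <- function(path, tags_path = NULL) {
  first <- readLines(path, n = 1)
  lib <- if (identical(first, "#1.3")) read_library_gct(path)
         else read_library_long(path)
  if (!is.null(tags_path)) {
    tg <- utils::read.delim(tags_path, header = FALSE, sep = "\t",
                            colClasses = "character")
    lib$cell_line_tags <- split(tg[[2]], tg[[1]])
  }
  lib
}

read_library_long <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  need <- c("perturbagen", "cell_line", "gene", "score")
  if (!all(need %in% colnames(tab)))
    stop_connstab("connstab_format_error",
                  "%s: need columns %s", path, paste(need, collapse = ", "))
  score <- suppressWarnings(as.numeric(tab$score))
  if (anyNA(score)) {
    i <- which(is.na(score))[1]
    stop_connstab("connstab_format_error",
                  "%s: non-numeric score '%s' at line %d", path,
                  tab$score[i], i + 1L)
  }
  key <- paste(tab$perturbagen, tab$cell_line, tab$gene, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    stop_connstab("connstab_format_error",
                  "%s: duplicated (perturbagen, cell_line, gene) triple: (%s, %s, %s)",
                  path, tab$perturbagen[i], tab$cell_line[i], tab$gene[i])
  }
  universe <- sort(unique(tab$gene))
  pkey <- paste(tab$perturbagen, tab$cell_line, sep = "\r")
  profs <- unique(pkey)
  info <- do.call(rbind, strsplit(profs, "\r", fixed = TRUE))
  m <- matrix(0, nrow = length(universe), ncol = length(profs),
              dimnames = list(universe, NULL))
  m[cbind(match(tab$gene, universe), match(pkey, profs))] <- score
  n_imputed <- length(universe) * length(profs) - nrow(tab)
  if (n_imputed > 0)
    warning(sprintf("%s: %d missing (profile, gene) entries imputed as 0",
                    path, n_imputed), call. = FALSE)
  reference_library(m, data.frame(perturbagen = info[, 1],
                                  cell_line = info[, 2],
                                  stringsAsFactors = FALSE))
}

# GCT 1.3 text dialect: "#1.3", a dimensions line, then a header row
# ("id", metadata headers if any, profile names "pert:cell") and one row
# per gene. Row/column metadata blocks beyond the id column are skipped.
read_library_gct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || !identical(lines[1], "#1.3"))
    stop_connstab("connstab_format_error", "%s: not a GCT 1.3 file", path)
  dims <- as.integer(strsplit(lines[2], "\t", fixed = TRUE)[[1]])
  nr <- dims[1]; nc <- dims[2]
  nrm <- if (length(dims) >= 3) dims[3] else 0L
  ncm <- if (length(dims) >= 4) dims[4] else 0L
  header <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  prof_names <- header[(2 + nrm):(1 + nrm + nc)]
  body <- lines[(4 + ncm):(3 + ncm + nr)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  genes <- vapply(fields, `[`, character(1), 1)
  if (anyDuplicated(genes))
    stop_connstab("connstab_format_error", "%s: duplicate gene rows", path)
  vals <- vapply(fields, function(f) {
    v <- suppressWarnings(as.numeric(f[(2 + nrm):(1 + nrm + nc)]))
    if (anyNA(v))
      stop_connstab("connstab_format_error",
                    "%s: non-numeric score in row '%s'", path, f[1])
    v
  }, numeric(nc))
  m <- t(matrix(vals, nrow = nc, dimnames = list(prof_names, genes)))
  ord <- order(rownames(m))
  m <- m[ord, , drop = FALSE]
  info <- do.call(rbind, strsplit(prof_names, ":", fixed = TRUE))
  if (ncol(info) != 2)
    stop_connstab("connstab_format_error",
                  "%s: profile names must be 'perturbagen:cell_line'", path)
  reference_library(m, data.frame(perturbagen = info[, 1],
                                  cell_line = info[, 2],
                                  stringsAsFactors = FALSE))
}

#' Write a reference library in long TSV format
#'
#' @param library a `ReferenceLibrary`.
#' @param path output path.
#' @param tags_path optional path for the cell-line tag table.
#' @return `path`, invisibly.
#' @export
write_reference_library <- function(library, path, tags_path = NULL) {
  U <- library$gene_universe
  P <- ncol(library$scores)
  df <- data.frame(
    perturbagen = rep(library$profile_info$perturbagen, each = length(U)),
    cell_line = rep(library$profile_info$cell_line, each = length(U)),
    gene = rep(U, times = P),
    score = as.vector(library$scores),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(tags_path)) {
    tg <- library$cell_line_tags
    tdf <- data.frame(cell_line = rep(names(tg), lengths(tg)),
                      tag = unlist(tg, use.names = FALSE))
    utils::write.table(tdf, tags_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records the master seed, every derived child seed, the configuration
#' and the package version, so a grid run can be audited and reproduced.
#'
#' @param path output JSON path.
#' @param master_seed integer master seed of the run.
#' @param config named list of configuration values.
#' @param child_seeds named list/vector of derived seeds.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, master_seed, config = list(),
                           child_seeds = list()) {
  obj <- list(
    package = "connstab",
    version = as.character(utils::packageVersion("connstab")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    master_seed = master_seed,
    child_seeds = child_seeds,
    config = config)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
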