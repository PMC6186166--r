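#' Configuration for the synthetic-data generator
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' a two-group negative-binomial count matrix with a planted fraction of
#' differentially expressed (DE) genes and log-normal library-size
#' variation, and a perturbagen profile library containing planted
#' reversers (profiles opposing the disease signature), planted
#' progressors (mimicking it) and null perturbagens across several cell
#' lines. Defaults define the standard study conditions: 2,000 genes, 6+6
#' samples, 10% DE genes at |log2 fold change| = 2, a dispersion trend
#' `alpha(mu) = 0.05 + 2/mu` typical of bulk tumor RNA-seq, 100,000
#' reads expected per sample (about 50 reads per gene at full depth, so
#' the lower grid fractions are genuinely depth-starved) with 30%
#' coefficient of variation, and a
#' library of 40 perturbagens x 3 cell lines with 8 reversers and 8
#' progressors at planted effect `kappa = 3` (profile noise is standard
#' normal, so `kappa` is in noise-SD units).
#'
#' @param n_genes number of genes.
#' @param n_per_group samples per group (two groups, A and B).
#' @param pi_de fraction of genes planted DE, in (0, 1).
#' @param lfc_magnitude absolute planted log2 fold change.
#' @param dispersion_params `c(alpha0, alpha1)` for the trend
#'   `alpha(mu) = alpha0 + alpha1 / mu`, both >= 0.
#' @param depth_mean expected reads per sample.
#' @param depth_cv coefficient of variation of library size across samples.
#' @param n_perturbagens,n_cell_lines library dimensions.
#' @param kappa planted profile effect size (noise-SD units), > 0 for a
#'   non-degenerate plant.
#' @param n_reversers,n_progressors planted perturbagen counts; the rest
#'   are nulls.
#' @param n_neuronal number of cell lines tagged `"neuronal"`.
#' @param seed integer master seed for the generator.
#' @return an object of class `SimConfig` (validated named list).
#' @export
sim_config <- function(n_genes = 2000, n_per_group = 6, pi_de = 0.1,
                       lfc_magnitude = 2,
                       dispersion_params = c(0.05, 2),
                       depth_mean = 1e5, depth_cv = 0.3,
                       n_perturbagens = 40, n_cell_lines = 3,
                       kappa = 3, n_reversers = 8, n_progressors = 8,
                       n_neuronal = 1, seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_per_group = as.integer(n_per_group),
              pi_de = pi_de, lfc_magnitude = lfc_magnitude,
              dispersion_params = dispersion_params,
              depth_mean = depth_mean, depth_cv = depth_cv,
              n_perturbagens = as.integer(n_perturbagens),
              n_cell_lines = as.integer(n_cell_lines),
              kappa = kappa,
              n_reversers = as.integer(n_reversers),
              n_progressors = as.integer(n_progressors),
              n_neuronal = as.integer(n_neuronal),
              seed = as.integer(seed))
  if (cfg$n_genes < 1 || cfg$n_per_group < 1 || cfg$n_perturbagens < 1 ||
      cfg$n_cell_lines < 1)
    stop_connstab("connstab_config_error", "all counts must be >= 1")
  if (cfg$pi_de <= 0 || cfg$pi_de >= 1)
    stop_connstab("connstab_config_error", "pi_de must be in (0, 1)")
  if (round(cfg$pi_de * cfg$n_genes) < 1)
    stop_connstab("connstab_config_error",
                  "pi_de * n_genes < 1: no gene would be planted DE")
  if (cfg$kappa < 0)
    stop_connstab("connstab_config_error", "kappa must be >= 0")
  if (any(cfg$dispersion_params < 0) || length(cfg$dispersion_params) != 2)
    stop_connstab("connstab_config_error",
                  "dispersion_params must be two nonnegative values")
  if (cfg$n_reversers + cfg$n_progressors > cfg$n_perturbagens)
    stop_connstab("connstab_config_error",
                  "n_reversers + n_progressors > n_perturbagens")
  if (cfg$n_neuronal > cfg$n_cell_lines)
    stop_connstab("connstab_config_error", "n_neuronal > n_cell_lines")
  class(cfg) <- "SimConfig"
  cfg
}

#' Simulate a two-group negative-binomial count matrix with planted truth
#'
#' Counts are drawn `n_gj ~ NB(mu = s_j * q_g * 2^(x_j * beta_g),
#' dispersion = alpha(q_g))` with `x_j = 0` for group A and `1` for group
#' B. Baseline expression `q_g` is log-normal (wide dynamic range) and
#' rescaled so the expected total per sample equals `depth_mean`; library
#' factors `s_j` are log-normal with mean 1 and CV `depth_cv`. A fraction
#' `pi_de` of genes gets `beta_g = +/- lfc_magnitude` with random sign
#' (recorded in the truth); the rest have `beta_g = 0`. Deterministic
#' given `config$seed` (child seed tag `"counts"`).
#'
#' @param config a [sim_config()].
#' @return a list with elements `counts` (a `CountMatrix`) and `truth`
#'   (class `SimTruth`: `de_genes` is a named vector of true log2 fold
#'   changes over all genes, nonzero exactly at the planted genes).
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  ng <- config$n_genes; np <- config$n_per_group
  with_seed(child_seed(config$seed, "counts"), {
    q_raw <- stats::rlnorm(ng, meanlog = 0, sdlog = 1.5)
    q <- q_raw / sum(q_raw) * config$depth_mean
    sdlog_s <- sqrt(log(1 + config$depth_cv^2))
    s <- stats::rlnorm(2 * np, meanlog = -sdlog_s^2 / 2, sdlog = sdlog_s)
    n_de <- round(config$pi_de * ng)
    de_idx <- sample.int(ng, n_de)
    beta <- numeric(ng)
    beta[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
      config$lfc_magnitude
    x <- rep(c(0, 1), each = np)
    alpha <- config$dispersion_params[1] + config$dispersion_params[2] / q
    mu <- outer(q, s) * 2^(beta %o% x)
    counts <- matrix(0L, nrow = ng, ncol = 2 * np)
    for (j in seq_len(2 * np)) {
      counts[, j] <- ifelse(
        alpha < 1e-12,
        stats::rpois(ng, mu[, j]),
        stats::rnbinom(ng, mu = mu[, j], size = 1 / alpha))
    }
    gene_ids <- sprintf("g%04d", seq_len(ng))
    dimnames(counts) <- list(gene_ids,
                             sprintf("s%02d", seq_len(2 * np)))
    cm <- count_matrix(counts, rep(c("A", "B"), each = np))
    truth <- structure(
      list(de_genes = stats::setNames(beta, gene_ids),
           reverser_ids = character(0), progressor_ids = character(0),
           null_ids = character(0)),
      class = "SimTruth")
    list(counts = cm, truth = truth)
  })
}

#' Simulate a perturbagen reference library with planted connections
#'
#' Each profile is a vector of z-like per-gene scores over the count
#' matrix's gene universe. Reverser profiles score
#' `-kappa * sign(beta_g) + eps` on planted DE genes (so they oppose the
#' disease signature), progressors `+kappa * sign(beta_g) + eps`, nulls
#' pure `eps`, with `eps ~ N(0, 1)` drawn independently per profile. The
#' first `n_neuronal` cell lines are tagged `"neuronal"`. Deterministic
#' given `config$seed` (child seed tag `"library"`).
#'
#' @param truth `SimTruth` from [generate_counts()] (needs >= 1 planted
#'   gene).
#' @param config the same [sim_config()].
#' @return a list with elements `library` (a `ReferenceLibrary`) and
#'   `truth` (the input truth with `reverser_ids`, `progressor_ids` and
#'   `null_ids` filled in; the three sets partition the perturbagens).
#' @export
generate_reference_library <- function(truth, config) {
  stopifnot(inherits(config, "SimConfig"), inherits(truth, "SimTruth"))
  beta <- truth$de_genes
  if (!any(beta != 0))
    stop_connstab("connstab_config_error",
                  "truth has no planted DE gene; nothing to oppose or mimic")
  npert <- config$n_perturbagens; ncl <- config$n_cell_lines
  pert_ids <- sprintf("pert%02d", seq_len(npert))
  cl_ids <- sprintf("CL%d", seq_len(ncl))
  rev_ids <- pert_ids[seq_len(config$n_reversers)]
  prog_ids <- pert_ids[config$n_reversers + seq_len(config$n_progressors)]
  null_ids <- setdiff(pert_ids, c(rev_ids, prog_ids))
  plant <- stats::setNames(rep(0, npert), pert_ids)
  plant[rev_ids] <- -config$kappa
  plant[prog_ids] <- +config$kappa
  genes <- names(beta)
  sgn <- sign(beta)
  with_seed(child_seed(config$seed, "library"), {
    info <- data.frame(
      perturbagen = rep(pert_ids, each = ncl),
      cell_line = rep(cl_ids, times = npert),
      stringsAsFactors = FALSE)
    m <- matrix(stats::rnorm(length(genes) * nrow(info)),
                nrow = length(genes),
                dimnames = list(genes, NULL))
    m <- m + sgn %o% plant[info$perturbagen]
    tags <- stats::setNames(
      rep(list(character(0)), ncl), cl_ids)
    for (cl in cl_ids[seq_len(config$n_neuronal)]) tags[[cl]] <- "neuronal"
    lib <- reference_library(m, info, tags)
    truth$reverser_ids <- rev_ids
    truth$progressor_ids <- prog_ids
    truth$null_ids <- null_ids
    list(library = lib, truth = truth)
  })
}

#' Simulate gene-category annotation and gene lengths
#'
#' Emulates a Gene Ontology-style annotation: categories are gene sets
#' sampled without replacement, gene lengths are log-normal (median about
#' 1.5 kb). When `length_bias` is set and `de_genes` is supplied, lengths
#' are reassigned so that longer genes are more likely to be DE — the
#' selection bias the probability-weighting stage of the enrichment module
#' corrects for. Deterministic given `seed`.
#'
#' @param gene_ids character vector of gene ids.
#' @param n_categories number of categories.
#' @param size_range integer `c(min, max)` of category sizes; `max` must
#'   not exceed the number of genes.
#' @param length_bias logical; couple gene length with DE status.
#' @param seed integer seed.
#' @param de_genes optional character vector of DE gene ids (required when
#'   `length_bias = TRUE`).
#' @return a list with `categories` (named list category -> gene ids) and
#'   `gene_lengths` (named positive numeric, bases).
#' @export
generate_annotation <- function(gene_ids, n_categories = 50,
                                size_range = c(10, 50),
                                length_bias = FALSE, seed = 1,
                                de_genes = NULL) {
  if (length(size_range) != 2 || size_range[1] < 1 ||
      size_range[2] < size_range[1] || size_range[2] > length(gene_ids))
    stop_connstab("connstab_config_error",
                  "size_range must satisfy 1 <= min <= max <= n_genes")
  if (length_bias && is.null(de_genes))
    stop_connstab("connstab_config_error",
                  "length_bias = TRUE requires `de_genes`")
  with_seed(seed, {
    lens <- round(stats::rlnorm(length(gene_ids), meanlog = log(1500),
                                sdlog = 0.6))
    lens <- pmax(lens, 100)
    if (length_bias) {
      # hand the largest lengths preferentially to DE genes: DE genes draw
      # their lengths with probability proportional to the length itself
      is_de <- gene_ids %in% de_genes
      lens <- sort(lens)
      pool <- seq_along(lens)
      de_pick <- sample(pool, sum(is_de), prob = lens)
      out <- numeric(length(lens))
      out[is_de] <- lens[de_pick]
      out[!is_de] <- sample(lens[-de_pick])
      lens <- out
    }
    names(lens) <- gene_ids
    sizes <- sample(seq(size_range[1], size_range[2]), n_categories,
                    replace = TRUE)
    categories <- lapply(sizes, function(k) sample(gene_ids, k))
    names(categories) <- sprintf("CAT%04d", seq_len(n_categories))
    list(categories = categories, gene_lengths = lens)
  })
}
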