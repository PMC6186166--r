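#' Grid of subsampling fractions and iteration counts
#'
#' Defines the depth-reduction experiment: an ascending set of retention
#' fractions `f` in (0, 1] that must include 1 (the full-data reference),
#' and the number of independent thinning iterations `K` run at each
#' fraction below 1 (the reference run is executed exactly once). The
#' default grid covers two orders of magnitude of depth reduction with
#' `K = 25` iterations.
#'
#' @param fractions ascending distinct reals in (0, 1], containing 1.
#' @param iterations integer `K >= 1`.
#' @return an object of class `FractionGrid`.
#' @export
fraction_grid <- function(fractions = c(0.01, 0.1, 0.25, 0.5, 0.7, 0.8,
                                        0.9, 0.99, 1.0),
                          iterations = 25) {
  if (any(fractions <= 0) || any(fractions > 1))
    stop_connstab("connstab_domain_error", "fractions must be in (0, 1]")
  if (is.unsorted(fractions, strictly = TRUE))
    stop_connstab("connstab_config_error",
                  "fractions must be strictly ascending")
  if (!any(fractions == 1))
    stop_connstab("connstab_config_error",
                  "fractions must include 1.0 (the full-data reference)")
  if (iterations < 1)
    stop_connstab("connstab_config_error", "iterations must be >= 1")
  structure(list(fractions = fractions,
                 iterations = as.integer(iterations)),
            class = "FractionGrid")
}

#' Binomially thin a count matrix to fraction f
#'
#' Simulates a lower cDNA sequencing depth: each gene-level count `n` is
#' replaced by an independent `Binomial(n, f)` draw, the distribution of
#' the per-gene read count if every mapped read were retained
#' independently with probability `f`. Gene and sample order, group
#' labels and gene lengths are preserved. `f = 1` returns the input
#' unchanged without consuming random numbers. Deterministic given `seed`.
#'
#' @param counts a `CountMatrix`.
#' @param f retention fraction in (0, 1].
#' @param seed integer seed.
#' @return a `CountMatrix` of the same shape.
#' @export
#' @examples
#' sim <- generate_counts(sim_config(n_genes = 50, seed = 3))
#' thinned <- thin_counts(sim$counts, 0.5, seed = 11)
#' sum(thinned$counts) / sum(sim$counts)
thin_counts <- function(counts, f, seed) {
  stopifnot(inherits(counts, "CountMatrix"))
  if (length(f) != 1 || !is.finite(f) || f <= 0 || f > 1)
    stop_connstab("connstab_domain_error",
                  "f must be a single value in (0, 1], got %s", format(f))
  if (f == 1) return(counts)
  m <- counts$counts
  thinned <- with_seed(seed,
    matrix(stats::rbinom(length(m), as.vector(m), f),
           nrow = nrow(m), dimnames = dimnames(m)))
  count_matrix(thinned, counts$groups, counts$gene_lengths)
}
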