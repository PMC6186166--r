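#' Relative-log-expression (median-of-ratios) size factors
#'
#' For each sample j, `s_j` is the median over reference genes of
#' `n_gj / (prod_k n_gk)^(1/m)` — the ratio of the sample's count to the
#' gene's geometric mean across samples. Reference genes are those with
#' strictly positive counts in every sample. Factors are rescaled to
#' geometric mean 1, so they are identifiable up to that convention.
#'
#' @param counts a `CountMatrix` or a nonnegative numeric matrix.
#' @return named positive numeric vector of per-sample size factors with
#'   geometric mean 1 (within 1e-6).
#' @export
#' @examples
#' m <- matrix(c(2, 4, 8, 16, 4, 8), nrow = 3, byrow = TRUE,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' rle_size_factors(m)  # 1/sqrt(2), sqrt(2)
rle_size_factors <- function(counts) {
  m <- if (inherits(counts, "CountMatrix")) counts$counts else counts
  ref <- rowSums(m > 0) == ncol(m)
  if (!any(ref))
    stop_connstab("connstab_normalization_error",
                  paste("no gene has positive counts in every sample;",
                        "the median-of-ratios reference set is empty.",
                        "Filter samples or genes, or check for a sample",
                        "with zero library size."))
  logm <- log(m[ref, , drop = FALSE])
  log_geo <- rowMeans(logm)
  s <- exp(apply(logm - log_geo, 2, stats::median))
  s <- s / geometric_mean(s)
  stats::setNames(s, colnames(m))
}

#' Method-of-moments negative-binomial dispersion per gene
#'
#' On size-factor-normalized counts, the NB variance relation
#' `var = mu + alpha * mu^2` is inverted with the pooled within-group
#' variance (sum of within-group squared deviations over `n - 2` degrees
#' of freedom, so the group means are removed) and the grand mean:
#' `alpha_g = max(alpha_floor, (v_g - m_g) / m_g^2)`, with
#' `alpha_floor = 1e-8`. Genes with zero mean get the floor.
#'
#' @param counts a `CountMatrix` (both groups need >= 2 samples).
#' @param size_factors from [rle_size_factors()].
#' @return named nonnegative numeric vector of per-gene dispersions.
#' @export
estimate_dispersions <- function(counts, size_factors) {
  stopifnot(inherits(counts, "CountMatrix"))
  check_de_ready(counts)
  alpha_floor <- 1e-8
  y <- sweep(counts$counts, 2, size_factors, "/")
  g <- counts$groups
  n <- ncol(y)
  ss <- 0
  for (lev in levels(g)) {
    yl <- y[, g == lev, drop = FALSE]
    ss <- ss + rowSums((yl - rowMeans(yl))^2)
  }
  v <- ss / (n - 2)
  m <- rowMeans(y)
  alpha <- ifelse(m > 0, pmax(alpha_floor, (v - m) / m^2), alpha_floor)
  stats::setNames(alpha, rownames(y))
}

#' Negative-binomial Wald test for the two-group contrast
#'
#' The log2 fold change is `log2((mu_B + c0) / (mu_A + c0))` on group
#' means of normalized counts with pseudocount `c0 = 0.5`; its standard
#' error comes from the delta method under the NB variance relation,
#' `se^2 = [(1/n_A)(1/(mu_A + c0) + alpha) +
#' (1/n_B)(1/(mu_B + c0) + alpha)] / ln(2)^2`, and the two-sided p-value
#' from the standard normal on `lfc / se`. Genes with both group means
#' zero get `p = 1`, `lfc = 0` by convention. Adjusted p-values are
#' Benjamini-Hochberg ([bh_adjust()]).
#'
#' This stage is a documented NB-Wald approximation validated by
#' calibration tests, not a reimplementation of a shrinkage-based DE
#' engine; it is pluggable behind the `DEResult` interface.
#'
#' @param counts a `CountMatrix`.
#' @param size_factors from [rle_size_factors()]; computed if missing.
#' @param dispersions from [estimate_dispersions()]; computed if missing.
#' @return a `DEResult`: data.frame with columns `gene`, `base_mean`,
#'   `lfc`, `se`, `p_value`, `padj`, plus attributes `size_factors` and
#'   `dispersions`. The contrast is second group level vs first.
#' @export
wald_de_test <- function(counts,
                         size_factors = rle_size_factors(counts),
                         dispersions = estimate_dispersions(counts,
                                                            size_factors)) {
  stopifnot(inherits(counts, "CountMatrix"))
  check_de_ready(counts)
  c0 <- 0.5
  y <- sweep(counts$counts, 2, size_factors, "/")
  g <- counts$groups
  a <- levels(g)[1]; b <- levels(g)[2]
  ya <- y[, g == a, drop = FALSE]; yb <- y[, g == b, drop = FALSE]
  na <- ncol(ya); nb <- ncol(yb)
  mu_a <- rowMeans(ya); mu_b <- rowMeans(yb)
  lfc <- log2((mu_b + c0) / (mu_a + c0))
  se <- sqrt(((1 / na) * (1 / (mu_a + c0) + dispersions) +
              (1 / nb) * (1 / (mu_b + c0) + dispersions)) / log(2)^2)
  p <- 2 * stats::pnorm(-abs(lfc / se))
  both_zero <- mu_a == 0 & mu_b == 0
  lfc[both_zero] <- 0
  p[both_zero] <- 1
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  out <- data.frame(gene = rownames(y), base_mean = rowMeans(y),
                    lfc = lfc, se = se, p_value = p,
                    padj = bh_adjust(p), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "size_factors") <- size_factors
  attr(out, "dispersions") <- dispersions
  class(out) <- c("DEResult", "data.frame")
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment with the cumulative-minimum
#' enforcement, returned in input order. Inputs outside (0, 1] are a
#' domain error rather than being clamped.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return numeric vector of adjusted values, same order; always
#'   `>= p_values` elementwise.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values) | p_values <= 0 | p_values > 1))
    stop_connstab("connstab_domain_error", "p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Thresholds turning a DE table into a gene signature
#'
#' @param alpha adjusted-p cutoff, in (0, 1).
#' @param lfc_min minimum absolute log2 fold change, >= 0.
#' @param max_per_direction cap on each of the up and down sets, >= 1.
#' @return an object of class `SignatureFilter`.
#' @export
signature_filter <- function(alpha = 0.05, lfc_min = 1.0,
                             max_per_direction = 100) {
  if (alpha <= 0 || alpha >= 1)
    stop_connstab("connstab_config_error", "alpha must be in (0, 1)")
  if (lfc_min < 0)
    stop_connstab("connstab_config_error", "lfc_min must be >= 0")
  if (max_per_direction < 1)
    stop_connstab("connstab_config_error", "max_per_direction must be >= 1")
  structure(list(alpha = alpha, lfc_min = lfc_min,
                 max_per_direction = as.integer(max_per_direction)),
            class = "SignatureFilter")
}

#' Build a filtered up/down gene signature from a DE result
#'
#' Up genes satisfy `padj <= alpha` and `lfc >= lfc_min`; down genes
#' `padj <= alpha` and `lfc <= -lfc_min`. Each direction is truncated to
#' the `max_per_direction` smallest p-values, ties broken by larger
#' `|lfc|` then lexicographic gene id. An empty signature is returned
#' (not an error) and flagged; connectivity scoring refuses it later.
#'
#' @param de a `DEResult`.
#' @param filter a [signature_filter()].
#' @param name signature name.
#' @param provenance named list recorded on the signature; the filter
#'   thresholds are appended automatically.
#' @return a `GeneSignature` with the per-gene `lfc` of its members as
#'   `scores`.
#' @export
build_signature <- function(de, filter = signature_filter(),
                            name = "signature", provenance = list()) {
  stopifnot(inherits(de, "DEResult"), inherits(filter, "SignatureFilter"))
  pick <- function(dir_ok) {
    cand <- de[de$padj <= filter$alpha & dir_ok, , drop = FALSE]
    ord <- order(cand$p_value, -abs(cand$lfc), cand$gene)
    utils::head(cand$gene[ord], filter$max_per_direction)
  }
  up <- pick(de$lfc >= filter$lfc_min)
  down <- pick(de$lfc <= -filter$lfc_min)
  provenance$alpha <- filter$alpha
  provenance$lfc_min <- filter$lfc_min
  provenance$max_per_direction <- filter$max_per_direction
  sig <- gene_signature(name, up, down,
                        scores = stats::setNames(de$lfc, de$gene)[c(up, down)],
                        provenance = provenance)
  if (is_empty_signature(sig))
    message(sprintf("signature '%s' is empty at the chosen thresholds", name))
  sig
}
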