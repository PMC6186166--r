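#' Probability-weighting function for gene-length selection bias
#'
#' Longer transcripts accumulate more reads, so at a fixed expression
#' change a long gene is more likely to be called DE. The weighting
#' function estimates `P(DE | length)` by isotonic regression of the
#' per-decile DE fraction on length rank — genes are grouped into
#' equal-size length-rank bins (deciles by default, fewer for small
#' universes), the bin proportions are pool-adjacent-violators fitted,
#' and each gene inherits its bin's fitted value. Binning before the
#' isotonic fit keeps the curve from chasing the 0/1 noise of individual
#' genes while preserving exact monotonicity. Weights are clipped to
#' `[1e-6, 1 - 1e-6]` and renormalized so their mean equals the observed
#' DE fraction.
#'
#' @param de_flags 0/1 vector (or logical), one per gene; needs >= 10 DE
#'   and >= 10 non-DE genes and must not be constant.
#' @param gene_lengths positive numeric, same length/order.
#' @param n_bins number of length-rank bins (default 10; reduced when
#'   there are fewer than 10 genes per bin).
#' @return numeric weights in (0, 1), one per gene, in input order.
#' @export
fit_pwf <- function(de_flags, gene_lengths, n_bins = 10) {
  de_flags <- as.numeric(de_flags)
  if (length(de_flags) != length(gene_lengths))
    stop_connstab("connstab_consistency_error",
                  "de_flags and gene_lengths differ in length")
  if (!all(de_flags %in% c(0, 1)))
    stop_connstab("connstab_domain_error", "de_flags must be 0/1")
  if (length(unique(de_flags)) < 2)
    stop_connstab("connstab_degenerate_error",
                  "all genes share one DE status; no bias curve is fittable")
  if (sum(de_flags == 1) < 10 || sum(de_flags == 0) < 10)
    stop_connstab("connstab_domain_error",
                  ">= 10 DE and >= 10 non-DE genes required")
  n <- length(de_flags)
  n_bins <- max(2L, min(as.integer(n_bins), n %/% 10L))
  ord <- order(gene_lengths)
  bin <- cut(seq_len(n), breaks = n_bins, labels = FALSE)
  bin_mean <- as.numeric(tapply(de_flags[ord], bin, mean))
  yf <- stats::isoreg(seq_len(n_bins), bin_mean)$yf
  w <- numeric(n)
  w[ord] <- yf[bin]
  w <- pmin(pmax(w, 1e-6), 1 - 1e-6)
  w <- w * mean(de_flags) / mean(w)
  pmin(pmax(w, 1e-6), 1 - 1e-6)
}

# Wallenius noncentral hypergeometric mass function via its integral
# representation
#   P(X = x) = C(m1, x) C(m2, n - x) *
#              Int_0^1 (1 - t^(w/D))^x (1 - t^(1/D))^(n - x) dt,
#   D = w (m1 - x) + (m2 - (n - x)).
# With large D the mass of the raw integrand sits at unrepresentably
# small t, so the substitution t = s^D is applied first:
#   P(X = x) = C(m1, x) C(m2, n - x) * D *
#              Int_0^1 s^(D-1) (1 - s^w)^x (1 - s)^(n - x) ds,
# whose integrand peaks at interior s. It is evaluated in log space with
# a max shift so large configurations neither overflow nor underflow.
dwallenius <- function(x, m1, m2, n, w) {
  if (x < max(0, n - m2) || x > min(m1, n)) return(0)
  D <- w * (m1 - x) + (m2 - (n - x))
  if (D <= 0) return(1)  # only at x = m1, n - x = m2: all draws forced
  logf <- function(s) {
    out <- rep(-Inf, length(s))
    ok <- s > 0 & s < 1
    out[ok] <- (D - 1) * log(s[ok]) + x * log1p(-s[ok]^w) +
      (n - x) * log1p(-s[ok])
    out
  }
  shift <- max(logf(seq(1e-6, 1 - 1e-6, length.out = 513)))
  if (!is.finite(shift)) shift <- 0
  val <- stats::integrate(function(s) exp(logf(s) - shift), 0, 1,
                          abs.tol = 1e-10, rel.tol = 1e-10,
                          subdivisions = 1000L)$value
  exp(log(D) + lchoose(m1, x) + lchoose(m2, n - x) + shift + log(val))
}

#' Wallenius noncentral hypergeometric upper tail
#'
#' `P(X >= x)` for the number of category ("white") genes among `n` DE
#' genes drawn without replacement from a universe of `m1` category and
#' `m2` other genes with odds `w` favoring category genes. Evaluated by
#' numerical integration of the integral representation of the mass
#' function (absolute tolerance 1e-8 per term). At `w = 1` it reduces to
#' the central hypergeometric tail.
#'
#' @param x success-count threshold.
#' @param m1 category size; `m2` remaining universe size.
#' @param m2 see `m1`.
#' @param n number of draws (total DE genes).
#' @param w odds weight > 0.
#' @return tail probability in [0, 1].
#' @export
pwallenius_upper <- function(x, m1, m2, n, w) {
  if (w <= 0)
    stop_connstab("connstab_domain_error", "odds w must be > 0")
  lo <- max(0, n - m2); hi <- min(m1, n)
  if (x <= lo) return(1)
  if (x > hi) return(0)
  p <- sum(vapply(seq(x, hi), dwallenius, numeric(1),
                  m1 = m1, m2 = m2, n = n, w = w))
  min(max(p, 0), 1)
}

#' Length-bias-aware category over-representation test
#'
#' For each category the odds weight is the mean probability weight of
#' its genes divided by the mean weight outside it; the one-sided
#' (over-representation) p-value is the Wallenius noncentral
#' hypergeometric upper tail at the observed DE count with that weight.
#' Adjustment across categories is Benjamini-Hochberg. Categories of
#' size zero are skipped with a warning; with no DE genes in the
#' universe every p-value is 1.
#'
#' @param categories named list mapping category id to gene ids.
#' @param de_flags named 0/1 vector over the gene universe (names are
#'   gene ids).
#' @param weights per-gene weights from [fit_pwf()], same order as
#'   `de_flags`.
#' @return an `EnrichmentResult` data.frame with columns `category`,
#'   `size`, `n_de_in`, `odds`, `p_value`, `padj`.
#' @export
wallenius_enrichment <- function(categories, de_flags, weights) {
  genes <- names(de_flags)
  if (is.null(genes))
    stop_connstab("connstab_format_error", "de_flags must be named by gene")
  de_flags <- as.numeric(de_flags)
  N <- length(genes); n_de <- sum(de_flags)
  keep <- vapply(categories, function(g) length(intersect(g, genes)) > 0,
                 logical(1))
  if (any(!keep))
    warning(sprintf("%d empty categories skipped", sum(!keep)),
            call. = FALSE)
  categories <- categories[keep]
  res <- lapply(names(categories), function(cat) {
    inside <- genes %in% categories[[cat]]
    m1 <- sum(inside)
    x <- sum(de_flags[inside])
    w_in <- mean(weights[inside]); w_out <- mean(weights[!inside])
    w <- if (w_in > 0 && w_out > 0) w_in / w_out else 1
    p <- if (n_de == 0) 1 else pwallenius_upper(x, m1, N - m1, n_de, w)
    data.frame(category = cat, size = m1, n_de_in = x, odds = w,
               p_value = max(p, .Machine$double.xmin),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$padj <- bh_adjust(out$p_value)
  rownames(out) <- NULL
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}
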