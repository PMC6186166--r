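#' Configuration for connectivity scoring
#'
#' @param M permutation count for the signature null (>= 100; default
#'   10,000).
#' @param alpha_conn significance level applied to BH-adjusted q-values.
#' @param aggregation_level `"perturbagen"` (mean over a perturbagen's
#'   profiles, the default) or `"profile"`.
#' @param cell_line_filter optional cell-line tag (e.g. `"neuronal"`);
#'   when set, only profiles from tagged cell lines are scored.
#' @param seed integer seed for the permutation null.
#' @return an object of class `ConnectivityConfig`.
#' @export
connectivity_config <- function(M = 10000, alpha_conn = 0.05,
                                aggregation_level = c("perturbagen",
                                                      "profile"),
                                cell_line_filter = NULL, seed = 1) {
  if (M < 100)
    stop_connstab("connstab_config_error", "M must be >= 100")
  if (alpha_conn <= 0 || alpha_conn >= 1)
    stop_connstab("connstab_config_error", "alpha_conn must be in (0, 1)")
  structure(list(M = as.integer(M), alpha_conn = alpha_conn,
                 aggregation_level = match.arg(aggregation_level),
                 cell_line_filter = cell_line_filter,
                 seed = as.integer(seed)),
            class = "ConnectivityConfig")
}

# Intersect a signature with a gene universe; coverage error when nothing
# survives, since a score would be undefined.
signature_on_universe <- function(signature, universe) {
  if (is_empty_signature(signature))
    stop_connstab("connstab_coverage_error",
                  "signature '%s' is empty; nothing to score",
                  signature$name)
  up <- intersect(signature$up, universe)
  down <- intersect(signature$down, universe)
  if (length(up) + length(down) == 0)
    stop_connstab("connstab_coverage_error",
                  "signature '%s' has no gene in the library universe",
                  signature$name)
  list(up = up, down = down,
       dropped = length(signature$up) + length(signature$down) -
         length(up) - length(down))
}

#' Score one signature against one reference profile
#'
#' The raw score sums the profile's z-like scores over the signature's up
#' genes and subtracts the sum over its down genes; it is normalized by
#' the maximum raw score attainable by any signature of the same size on
#' this profile (the sum of the k largest `|z|`, k the number of
#' signature genes found in the universe). The result lies in [-1, 1]:
#' -1 is a perfect reversal, +1 a perfect mimic. Signature genes outside
#' the universe are dropped; their count is available via
#' `attr(, "dropped")`.
#'
#' @param signature a `GeneSignature`.
#' @param profile named numeric vector of per-gene scores (one library
#'   column, names = gene universe).
#' @return a single score in [-1, 1].
#' @export
#' @examples
#' z <- c(g1 = 3, g2 = -1, g3 = 2, g4 = -2)
#' sig <- gene_signature("s", up = "g1", down = "g4")
#' connection_score(sig, z)  # 1
connection_score <- function(signature, profile) {
  su <- signature_on_universe(signature, names(profile))
  k <- length(su$up) + length(su$down)
  raw <- sum(profile[su$up]) - sum(profile[su$down])
  max_raw <- sum(sort(abs(profile), decreasing = TRUE)[seq_len(k)])
  score <- if (max_raw > 0) raw / max_raw else 0
  attr(score, "dropped") <- su$dropped
  score
}

# Observed scores of a signature against every profile of a library.
# Returns the score vector plus the pieces the permutation null reuses.
score_profiles <- function(signature, library) {
  su <- signature_on_universe(signature, library$gene_universe)
  Z <- library$scores
  k <- length(su$up) + length(su$down)
  raw <- colSums(Z[su$up, , drop = FALSE]) -
    colSums(Z[su$down, , drop = FALSE])
  absZ <- abs(Z)
  max_raw <- apply(absZ, 2, function(col)
    sum(sort(col, decreasing = TRUE)[seq_len(k)]))
  score <- ifelse(max_raw > 0, raw / max_raw, 0)
  list(score = stats::setNames(score, colnames(Z)),
       k_up = length(su$up), k_down = length(su$down),
       max_raw = max_raw, dropped = su$dropped)
}

# Sparse M x |U| matrix of random signed signatures: each row has k_up
# entries +1 and k_down entries -1 at positions drawn uniformly without
# replacement. One draw is shared across every profile of a query
# (common random numbers).
random_sign_matrix <- function(n_universe, k_up, k_down, M, seed) {
  k <- k_up + k_down
  idx <- with_seed(seed,
    vapply(seq_len(M), function(i) sample.int(n_universe, k),
           integer(k)))
  Matrix::sparseMatrix(
    i = rep(seq_len(M), each = k),
    j = as.vector(idx),
    x = rep(c(rep(1, k_up), rep(-1, k_down)), M),
    dims = c(M, n_universe))
}

# Exhaustive signed-subset enumeration: every size-k subset of the
# universe crossed with every assignment of k_up plus-signs. Feasible
# when choose(|U|, k) * 2^k <= 1e6.
exhaustive_sign_matrix <- function(n_universe, k_up, k_down) {
  k <- k_up + k_down
  subsets <- utils::combn(n_universe, k)
  splits <- utils::combn(k, k_up)
  if (k_up == 0) splits <- matrix(integer(0), nrow = 0, ncol = 1)
  n_sub <- ncol(subsets); n_spl <- ncol(splits)
  M <- n_sub * n_spl
  sgn <- matrix(-1, nrow = k, ncol = n_spl)
  if (nrow(splits) > 0)
    for (s in seq_len(n_spl)) sgn[splits[, s], s] <- 1
  Matrix::sparseMatrix(
    i = rep(seq_len(M), each = k),
    j = as.vector(subsets[, rep(seq_len(n_sub), each = n_spl)]),
    x = as.vector(sgn[, rep(seq_len(n_spl), times = n_sub)]),
    dims = c(M, n_universe))
}

#' Permutation p-values for a signature against a library
#'
#' The null preserves the signature's up/down sizes: random signatures
#' draw the same number of up and down genes uniformly without
#' replacement from the library universe, and the identical set of M
#' random signatures is scored against every profile (common random
#' numbers, which stabilizes cross-perturbagen comparisons). The
#' per-profile p-value is the add-one estimator
#' `(1 + #\{|c_null| >= |c_obs|\}) / (M + 1)`, so `p >= 1/(M+1)` always.
#' When the signed-subset space is small
#' (`choose(|U|, k) * 2^k <= 1e6`) the null is enumerated exhaustively
#' and p is the exact proportion.
#'
#' @param signature a `GeneSignature`.
#' @param library a `ReferenceLibrary` (already cell-line-filtered if
#'   desired).
#' @param config a [connectivity_config()].
#' @return a list: `observed` (per-profile scores), `p_values`
#'   (per-profile), `null_scores` (null-by-profile score matrix, reused
#'   for perturbagen aggregation), `exhaustive` (logical), `k_up`,
#'   `k_down`.
#' @export
permutation_pvalues <- function(signature, library, config) {
  stopifnot(inherits(config, "ConnectivityConfig"))
  obs <- score_profiles(signature, library)
  nU <- length(library$gene_universe)
  k <- obs$k_up + obs$k_down
  exhaustive <- is.finite(choose(nU, k)) &&
    choose(nU, k) * 2^k <= 1e6
  S <- if (exhaustive)
    exhaustive_sign_matrix(nU, obs$k_up, obs$k_down)
  else
    random_sign_matrix(nU, obs$k_up, obs$k_down, config$M, config$seed)
  null_raw <- as.matrix(S %*% library$scores)
  null_scores <- sweep(null_raw, 2, ifelse(obs$max_raw > 0, obs$max_raw, 1),
                       "/")
  exceed <- colSums(abs(null_scores) >=
                      matrix(abs(obs$score), nrow = nrow(null_scores),
                             ncol = length(obs$score), byrow = TRUE))
  p <- if (exhaustive) exceed / nrow(null_scores)
       else (1 + exceed) / (nrow(null_scores) + 1)
  list(observed = obs$score, p_values = stats::setNames(p, names(obs$score)),
       null_scores = null_scores, exhaustive = exhaustive,
       k_up = obs$k_up, k_down = obs$k_down)
}

#' Aggregate profile scores to perturbagen level and classify connections
#'
#' At perturbagen level the connection score is the mean of the
#' perturbagen's profile scores and its p-value is the permutation
#' p-value of that mean under the shared null (the mean of the same null
#' draws across its profiles). BH adjustment runs across perturbagens; a
#' connection is significant when `q <= alpha_conn`. Direction is `rev`
#' for negative scores (candidate phenotype reversers) and `prog` for
#' positive ones; a zero score gets no direction and is never
#' significant. At `aggregation_level = "profile"` each profile is
#' reported separately with the same machinery.
#'
#' @param perm result of [permutation_pvalues()].
#' @param library the same `ReferenceLibrary` the p-values were computed
#'   on.
#' @param config the [connectivity_config()].
#' @return a `ConnectionResult` data.frame ranked by signed score
#'   (strongest reverser first).
#' @export
aggregate_and_classify <- function(perm, library, config) {
  info <- library$profile_info
  denom_p <- function(exceed, n_null)
    if (perm$exhaustive) exceed / n_null else (1 + exceed) / (n_null + 1)
  if (config$aggregation_level == "profile") {
    q <- bh_adjust(perm$p_values)
    return(connection_result(info$perturbagen, as.numeric(perm$observed),
                             as.numeric(perm$p_values), q,
                             config$alpha_conn,
                             cell_line = info$cell_line))
  }
  perts <- unique(info$perturbagen)
  score <- p <- numeric(length(perts))
  for (i in seq_along(perts)) {
    idx <- which(info$perturbagen == perts[i])
    obs_mean <- mean(perm$observed[idx])
    null_mean <- rowMeans(perm$null_scores[, idx, drop = FALSE])
    score[i] <- obs_mean
    p[i] <- denom_p(sum(abs(null_mean) >= abs(obs_mean)),
                    length(null_mean))
  }
  q <- bh_adjust(p)
  connection_result(perts, score, p, q, config$alpha_conn)
}

#' Run the full connectivity stage for one signature
#'
#' Applies the cell-line filter, computes observed scores and the shared
#' permutation null, aggregates to the configured level and classifies.
#'
#' @param signature a `GeneSignature`.
#' @param library a `ReferenceLibrary`.
#' @param config a [connectivity_config()].
#' @return a `ConnectionResult` data.frame.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 300, n_perturbagens = 10, n_reversers = 2,
#'                   n_progressors = 2, seed = 5)
#' sim <- generate_counts(cfg)
#' lib <- generate_reference_library(sim$truth, cfg)$library
#' de <- wald_de_test(sim$counts)
#' sig <- build_signature(de, signature_filter(max_per_direction = 20))
#' head(run_connectivity(sig, lib, connectivity_config(M = 200)))
run_connectivity <- function(signature, library,
                             config = connectivity_config()) {
  lib <- filter_library(library, config$cell_line_filter)
  perm <- permutation_pvalues(signature, lib, config)
  res <- aggregate_and_classify(perm, lib, config)
  lost <- setdiff(unique(library$profile_info$perturbagen),
                  unique(lib$profile_info$perturbagen))
  if (length(lost) > 0)
    warning(sprintf("%d perturbagens dropped (no profile after filter)",
                    length(lost)), call. = FALSE)
  res
}
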