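test_that("connection score matches the hand-evaluated examples", {
  z <- tiny_profile()  # g1: 3, g2: -1, g3: 2, g4: -2
  s1 <- gene_signature("s1", up = "g1", down = "g4")
  expect_equal(as.numeric(connection_score(s1, z)), 1)
  s2 <- gene_signature("s2", up = "g1", down = "g2")
  expect_equal(as.numeric(connection_score(s2, z)), 0.8)
})

test_that("score attains +/-1 at the extremal signatures and flips sign", {
  set.seed(21)
  z <- stats::setNames(rnorm(50), paste0("g", 1:50))
  top <- names(sort(abs(z), decreasing = TRUE))[1:10]
  best <- gene_signature("best", up = top[z[top] > 0],
                         down = top[z[top] < 0])
  expect_equal(as.numeric(connection_score(best, z)), 1)
  worst <- gene_signature("worst", up = best$down, down = best$up)
  expect_equal(as.numeric(connection_score(worst, z)), -1)

  # anti-symmetry for arbitrary signatures
  sig <- gene_signature("s", up = paste0("g", 1:5),
                        down = paste0("g", 6:9))
  flipped <- gene_signature("sf", up = sig$down, down = sig$up)
  expect_equal(as.numeric(connection_score(flipped, z)),
               -as.numeric(connection_score(sig, z)))
  # bounds hold for random signatures
  for (i in 1:20) {
    gs <- sample(names(z), 8)
    s <- gene_signature("r", up = gs[1:4], down = gs[5:8])
    expect_lte(abs(as.numeric(connection_score(s, z))), 1)
  }
})

test_that("score is invariant to positive rescaling of the profile", {
  set.seed(5)
  z <- stats::setNames(rnorm(30), paste0("g", 1:30))
  sig <- gene_signature("s", up = paste0("g", 1:3),
                        down = paste0("g", 10:12))
  expect_equal(as.numeric(connection_score(sig, 7.3 * z)),
               as.numeric(connection_score(sig, z)))
})

test_that("scoring refuses empty or non-overlapping signatures", {
  z <- tiny_profile()
  empty <- gene_signature("empty", character(0), character(0))
  expect_error(connection_score(empty, z),
               class = "connstab_coverage_error")
  alien <- gene_signature("alien", up = "x1", down = "x2")
  err <- expect_error(connection_score(alien, z),
                      class = "connstab_coverage_error")
  expect_match(conditionMessage(err), "alien")
  # genes outside the universe are dropped and counted
  part <- gene_signature("part", up = c("g1", "x9"), down = "g4")
  sc <- connection_score(part, z)
  expect_identical(attr(sc, "dropped"), 1L)
  expect_equal(as.numeric(sc), 1)
})

test_that("permutation p-values respect the add-one bound and the null center", {
  lib <- tiny_library(n_genes = 40, n_profiles = 4, seed = 2)
  sig <- gene_signature("s", up = paste0("g", 1:5),
                        down = paste0("g", 6:10))
  cfg <- connectivity_config(M = 500, seed = 7)
  perm <- permutation_pvalues(sig, lib, cfg)
  expect_false(perm$exhaustive)
  expect_true(all(perm$p_values >= 1 / 501))
  expect_true(all(perm$p_values <= 1))
  # determinism under the same seed
  perm2 <- permutation_pvalues(sig, lib, cfg)
  expect_identical(perm$p_values, perm2$p_values)
  expect_error(connectivity_config(M = 50),
               class = "connstab_config_error")
})

test_that("small universes switch to exhaustive enumeration that MC confirms", {
  lib <- tiny_library(n_genes = 8, n_profiles = 3, seed = 4)
  sig <- gene_signature("s", up = c("g1", "g3"), down = "g6")
  cfg <- connectivity_config(M = 200, seed = 1)
  perm <- permutation_pvalues(sig, lib, cfg)
  expect_true(perm$exhaustive)
  # C(8,3) subsets x C(3,2) up-assignments
  expect_identical(nrow(perm$null_scores), 56L * 3L)

  # Monte-Carlo at M = 200,000 must agree within 2 binomial SEs
  M <- 200000L
  S <- connstab:::random_sign_matrix(8, 2, 1, M, seed = 99)
  null_mc <- as.matrix(S %*% lib$scores)
  for (j in seq_len(ncol(lib$scores))) {
    obs <- perm$observed[j]
    k_abs <- sort(abs(lib$scores[, j]), decreasing = TRUE)
    max_raw <- sum(k_abs[1:3])
    p_mc <- (1 + sum(abs(null_mc[, j] / max_raw) >= abs(obs))) / (M + 1)
    se <- sqrt(perm$p_values[j] * (1 - perm$p_values[j]) / M)
    expect_lt(abs(p_mc - perm$p_values[j]), 2 * se + 2 / M)
  }
})

test_that("zero-signal queries come back non-significant", {
  # a signature orthogonal to a symmetric profile: score 0, p ~ 1
  z <- stats::setNames(c(rep(2, 5), rep(-2, 5), rep(0.01, 20)),
                       paste0("g", 1:30))
  lib <- reference_library(matrix(z, ncol = 1,
                                  dimnames = list(names(z), NULL)),
                           data.frame(perturbagen = "p1",
                                      cell_line = "CL1"))
  sig <- gene_signature("s", up = paste0("g", 1:2),
                        down = paste0("g", 4:5))  # raw = 2+2-2-2 = 0
  perm <- permutation_pvalues(sig, lib, connectivity_config(M = 300,
                                                            seed = 3))
  expect_equal(as.numeric(perm$observed), 0)
  expect_gt(perm$p_values[1], 0.95)
})

test_that("aggregation finds planted reversers and respects direction rules", {
  cfg <- sim_config(n_genes = 500, n_perturbagens = 12, n_reversers = 3,
                    n_progressors = 3, seed = 6)
  sim <- generate_counts(cfg)
  out <- generate_reference_library(sim$truth, cfg)
  de <- wald_de_test(sim$counts)
  sig <- build_signature(de, signature_filter(max_per_direction = 50))
  conn <- run_connectivity(sig, out$library,
                           connectivity_config(M = 1000, seed = 2))
  expect_s3_class(conn, "ConnectionResult")
  expect_true(all(abs(conn$score) <= 1))
  expect_true(all(conn$q_value >= conn$p_value - 1e-12))
  hits <- conn[conn$significant, ]
  expect_true(all(out$truth$reverser_ids %in%
                  hits$perturbagen[hits$direction == "rev"]))
  expect_true(all(out$truth$progressor_ids %in%
                  hits$perturbagen[hits$direction == "prog"]))
  # no progressor is ever called rev
  expect_length(intersect(out$truth$progressor_ids,
                          conn$perturbagen[conn$direction == "rev" &
                                           conn$significant]), 0)
  # ranked by signed score: strongest reverser first
  expect_true(!is.unsorted(conn$score))
})

test_that("profile-level aggregation reports each profile separately", {
  cfg <- sim_config(n_genes = 300, n_perturbagens = 6, n_reversers = 2,
                    n_progressors = 2, n_cell_lines = 2, seed = 14)
  sim <- generate_counts(cfg)
  lib <- generate_reference_library(sim$truth, cfg)$library
  de <- wald_de_test(sim$counts)
  sig <- build_signature(de, signature_filter(max_per_direction = 30))
  conn <- run_connectivity(sig, lib,
                           connectivity_config(M = 500, seed = 9,
                                               aggregation_level = "profile"))
  expect_identical(nrow(conn), 12L)
  expect_false(anyNA(conn$cell_line))
})

test_that("cell-line filtering restricts the perturbagen universe", {
  cfg <- sim_config(n_genes = 300, n_perturbagens = 8, n_reversers = 2,
                    n_progressors = 2, n_cell_lines = 3, n_neuronal = 1,
                    seed = 10)
  sim <- generate_counts(cfg)
  lib <- generate_reference_library(sim$truth, cfg)$library
  de <- wald_de_test(sim$counts)
  sig <- build_signature(de, signature_filter(max_per_direction = 30))
  all_cl <- run_connectivity(sig, lib,
                             connectivity_config(M = 300, seed = 4))
  neuro <- run_connectivity(sig, lib,
                            connectivity_config(M = 300, seed = 4,
                                                cell_line_filter = "neuronal"))
  expect_true(all(neuro$perturbagen %in% all_cl$perturbagen))
  # filtering to a missing tag is a config error
  expect_error(
    run_connectivity(sig, lib,
                     connectivity_config(M = 300,
                                         cell_line_filter = "hepatic")),
    class = "connstab_config_error")
})

test_that("pure-noise libraries stay calibrated at the configured level", {
  # kappa = 0: every perturbagen is null; the fraction called significant
  # at q <= 0.05 stays near or below alpha across seeds
  fractions <- vapply(1:20, function(s) {
    cfg <- sim_config(n_genes = 200, n_perturbagens = 15, n_reversers = 2,
                      n_progressors = 2, n_cell_lines = 2, kappa = 0,
                      seed = s)
    sim <- generate_counts(cfg)
    lib <- generate_reference_library(sim$truth, cfg)$library
    sig <- gene_signature("q", up = rownames(sim$counts$counts)[1:20],
                          down = rownames(sim$counts$counts)[21:40])
    conn <- run_connectivity(sig, lib,
                             connectivity_config(M = 400, seed = s + 100))
    mean(conn$significant)
  }, numeric(1))
  se <- sd(fractions) / sqrt(length(fractions))
  expect_lte(mean(fractions), 0.05 + 3 * max(se, 1e-3))
})
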