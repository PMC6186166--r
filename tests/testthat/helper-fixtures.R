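# Small deterministic objects shared across test files. Everything is
# built in code; nothing is read from disk except files the tests write
# themselves into tempdir().

tiny_count_matrix <- function() {
  m <- matrix(c(2L, 4L, 6L, 8L,
                8L, 16L, 24L, 32L,
                4L, 8L, 12L, 16L),
              nrow = 3, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  count_matrix(m, c("A", "A", "B", "B"))
}

# 4-gene universe with one profile, used for the hand-computable
# connectivity examples.
tiny_profile <- function() c(g1 = 3, g2 = -1, g3 = 2, g4 = -2)

tiny_library <- function(n_genes = 8, n_profiles = 3, seed = 1) {
  genes <- paste0("g", seq_len(n_genes))
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_profiles), nrow = n_genes,
              dimnames = list(genes, NULL))
  reference_library(
    m, data.frame(perturbagen = paste0("p", seq_len(n_profiles)),
                  cell_line = "CL1", stringsAsFactors = FALSE))
}

# Brute-force Benjamini-Hochberg: padj_i = min over {j : p_j >= p_i} of
# min(1, m * p_j / rank_j). Independent oracle for bh_adjust.
bh_brute_force <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "min")
  vapply(seq_len(m), function(i) {
    cand <- which(p >= p[i])
    min(1, min(m * p[cand] / rank(p, ties.method = "max")[cand]))
  }, numeric(1))
}

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
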