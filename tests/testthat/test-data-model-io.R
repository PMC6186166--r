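test_that("count matrix construction validates shape, values and groups", {
  cm <- tiny_count_matrix()
  expect_s3_class(cm, "CountMatrix")
  expect_identical(dim(cm$counts), c(3L, 4L))
  expect_identical(levels(cm$groups), c("A", "B"))

  m <- cm$counts
  m2 <- m; m2[2, 3] <- -1L
  expect_error(count_matrix(m2, cm$groups), class = "connstab_format_error")
  expect_error(count_matrix(m, c("A", "B", "C", "A")),
               class = "connstab_contrast_error")
  expect_error(count_matrix(m, c("A", "B")),
               class = "connstab_consistency_error")
  rownames(m2) <- c("g1", "g1", "g3")
  expect_error(count_matrix(abs(m2), cm$groups),
               class = "connstab_format_error")
  # lengths must cover every gene and be positive
  expect_error(count_matrix(m, cm$groups, gene_lengths = c(g1 = 100)),
               class = "connstab_consistency_error")
  cm_len <- count_matrix(m, cm$groups,
                         gene_lengths = c(g3 = 300, g1 = 100, g2 = 200))
  expect_identical(unname(cm_len$gene_lengths), c(100, 200, 300))
})

test_that("counts TSV round trip preserves the matrix and group labels", {
  cm <- tiny_count_matrix()
  path <- tempfile(fileext = ".tsv")
  write_counts(cm, path)
  back <- read_counts(path, paste0(path, ".groups.tsv"))
  expect_identical(back$counts, cm$counts)
  expect_identical(back$groups, cm$groups)
})

test_that("counts reader locates malformed entries and label problems", {
  counts_path <- write_tsv_lines(c(
    "gene\ts1\ts2\ts3\ts4",
    "g1\t1\t2\t3\t4",
    "g2\t5\t2.5\t7\t8",
    "g3\t9\t10\t11\t12"))
  groups_path <- write_tsv_lines(
    c("s1\tA", "s2\tA", "s3\tB", "s4\tB"))
  err <- expect_error(read_counts(counts_path, groups_path),
                      class = "connstab_format_error")
  expect_match(conditionMessage(err), "g2")
  expect_match(conditionMessage(err), "s2")
  expect_match(conditionMessage(err), "2.5", fixed = TRUE)

  ok_counts <- write_tsv_lines(c(
    "gene\ts1\ts2\ts3\ts4",
    "g1\t1\t2\t3\t4",
    "g2\t5\t6\t7\t8"))
  three_groups <- write_tsv_lines(
    c("s1\tA", "s2\tA", "s3\tB", "s4\tC"))
  expect_error(read_counts(ok_counts, three_groups),
               class = "connstab_contrast_error")
  incomplete <- write_tsv_lines(c("s1\tA", "s2\tA", "s3\tB"))
  expect_error(read_counts(ok_counts, incomplete),
               class = "connstab_consistency_error")
})

test_that("GMT write-read is a fixed point, including provenance and empties", {
  sig <- gene_signature("S", up = c("g1", "g2"), down = "g3",
                        provenance = list(f = 0.5, iteration = 3))
  path <- tempfile(fileext = ".gmt")
  write_signature_gmt(sig, path)
  back <- read_signature_gmt(path)
  expect_setequal(back$up, sig$up)
  expect_setequal(back$down, sig$down)
  expect_equal(back$provenance$f, 0.5)
  expect_equal(back$provenance$iteration, 3)
  # second cycle reproduces the file byte for byte
  path2 <- tempfile(fileext = ".gmt")
  write_signature_gmt(back, path2)
  expect_identical(readLines(path), readLines(path2))

  empty_dn <- gene_signature("E", up = c("g1"), down = character(0))
  p3 <- tempfile(fileext = ".gmt")
  write_signature_gmt(empty_dn, p3)
  back3 <- read_signature_gmt(p3)
  expect_identical(back3$down, character(0))
  expect_identical(back3$up, "g1")
})

test_that("GMT reader rejects overlapping or unpaired signatures", {
  overlap <- write_tsv_lines(c("S_UP\tna\tg1\tg5", "S_DN\tna\tg5"),
                             tempfile(fileext = ".gmt"))
  expect_error(read_signature_gmt(overlap),
               class = "connstab_integrity_error")
  unpaired <- write_tsv_lines("S_UP\tna\tg1", tempfile(fileext = ".gmt"))
  expect_error(read_signature_gmt(unpaired),
               class = "connstab_format_error")
})

test_that("GRP pair round trip and missing-file error", {
  sig <- gene_signature("S", up = c("g1", "g2"), down = c("g3", "g4"))
  base <- tempfile()
  write_signature_grp(sig, base)
  back <- read_signature_grp(base, name = "S")
  expect_setequal(back$up, sig$up)
  expect_setequal(back$down, sig$down)
  expect_error(read_signature_grp(tempfile()),
               class = "connstab_format_error")
})

test_that("long-format library reader builds the universe and imputes gaps", {
  lines <- c("perturbagen\tcell_line\tgene\tscore")
  for (p in c("p1", "p2")) for (cl in c("CL1", "CL2"))
    for (g in paste0("g", 1:5))
      lines <- c(lines, sprintf("%s\t%s\t%s\t%0.1f", p, cl, g,
                                nchar(p) + nchar(g) / 10))
  path <- write_tsv_lines(lines)
  lib <- read_reference_library(path)
  expect_s3_class(lib, "ReferenceLibrary")
  expect_identical(lib$gene_universe, paste0("g", 1:5))
  expect_identical(ncol(lib$scores), 4L)

  # drop one (profile, gene) entry: imputed as 0 with a counted warning
  path2 <- write_tsv_lines(lines[-which(grepl("^p2\tCL2\tg5", lines))])
  expect_warning(lib2 <- read_reference_library(path2), "1 missing")
  expect_identical(lib2$scores["g5", "p2:CL2"], 0)

  # duplicated triple is a format error
  path3 <- write_tsv_lines(c(lines, lines[2]))
  expect_error(read_reference_library(path3),
               class = "connstab_format_error")
  # non-numeric score is located
  bad <- lines; bad[3] <- "p1\tCL1\tg2\tabc"
  expect_error(read_reference_library(write_tsv_lines(bad)),
               class = "connstab_format_error")
})

test_that("cell-line tags attach from the tags table", {
  lines <- c("perturbagen\tcell_line\tgene\tscore",
             "p1\tCL1\tg1\t1", "p1\tCL2\tg1\t2")
  tags <- write_tsv_lines(c("CL2\tneuronal", "CL2\tcortex"))
  lib <- read_reference_library(write_tsv_lines(lines), tags_path = tags)
  expect_true("neuronal" %in% lib$cell_line_tags[["CL2"]])
  expect_null(lib$cell_line_tags[["CL1"]])
})

test_that("GCT 1.3 reader agrees with the long reader on the same library", {
  cfg <- sim_config(n_genes = 30, n_perturbagens = 4, n_cell_lines = 2,
                    n_reversers = 1, n_progressors = 1, seed = 8)
  sim <- generate_counts(cfg)
  lib <- generate_reference_library(sim$truth, cfg)$library
  long_path <- tempfile(fileext = ".tsv")
  write_reference_library(lib, long_path)
  from_long <- read_reference_library(long_path)

  gct_path <- tempfile(fileext = ".gct")
  ord <- order(rownames(lib$scores))
  m <- lib$scores[ord, , drop = FALSE]
  writeLines(c(
    "#1.3",
    sprintf("%d\t%d\t0\t0", nrow(m), ncol(m)),
    paste(c("id", colnames(m)), collapse = "\t"),
    vapply(seq_len(nrow(m)), function(i)
      paste(c(rownames(m)[i], format(m[i, ], digits = 17)),
            collapse = "\t"), character(1))), gct_path)
  from_gct <- read_reference_library(gct_path)
  expect_identical(from_gct$gene_universe, from_long$gene_universe)
  expect_equal(from_gct$scores, from_long$scores, tolerance = 1e-12)
})

test_that("run manifest records seeds and config as JSON", {
  path <- tempfile(fileext = ".json")
  write_manifest(path, master_seed = 17,
                 config = list(alpha = 0.05),
                 child_seeds = list(counts = child_seed(17, "counts")))
  man <- jsonlite::read_json(path)
  expect_identical(man$master_seed, 17L)
  expect_identical(man$child_seeds$counts, child_seed(17, "counts"))
  expect_equal(man$config$alpha, 0.05)
})

test_that("signature invariants: disjoint sets, recorded fraction, emptiness", {
  expect_error(gene_signature("S", up = c("g1", "g2"), down = c("g2")),
               class = "connstab_integrity_error")
  sig <- gene_signature("S", "g1", "g2")
  expect_equal(sig$provenance$f, 1)
  expect_false(is_empty_signature(sig))
  expect_true(is_empty_signature(gene_signature("E", character(0),
                                                character(0))))
  expect_error(gene_signature("S", "g1", "g2", provenance = list(f = 0)),
               class = "connstab_domain_error")
})
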