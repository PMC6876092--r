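# Expression input and the dual-threshold expressed-gene filter.

make_tiny_expr <- function() {
  genes <- c("G1", "G2", "G3")
  samples <- c("S1", "S2", "S3", "S4")
  tpm <- matrix(c(1, 1, 1, 1,
                  0, 0, 0, 0,
                  2, 0, 2, 0), nrow = 3, byrow = TRUE,
                dimnames = list(genes, samples))
  counts <- matrix(c(10, 10, 10, 10,
                     0, 0, 0, 0,
                     20, 0, 20, 0), nrow = 3, byrow = TRUE,
                   dimnames = list(genes, samples))
  list(tpm = tpm, counts = counts)
}

test_that("a GCT pair reads into aligned matrices of the right shape", {
  m <- make_tiny_expr()
  expr <- read_expression(write_lines_tmp(gct_lines(m$tpm), ".gct"),
                          write_lines_tmp(gct_lines(m$counts), ".gct"),
                          quiet = TRUE)
  expect_equal(dim(expr$tpm), c(3, 4))
  expect_equal(expr$gene_ids, c("G1", "G2", "G3"))
  expect_equal(expr$tpm["G3", "S3"], 2)
  expect_equal(expr$counts["G3", "S1"], 20)
})

test_that("the same data as GCT and as TSV give identical matrices", {
  m <- make_tiny_expr()
  tsv <- function(mat) c(paste(c("gene_id", colnames(mat)), collapse = "\t"),
                         vapply(seq_len(nrow(mat)), function(i)
                           paste(c(rownames(mat)[i], mat[i, ]),
                                 collapse = "\t"), character(1)))
  a <- read_expression(write_lines_tmp(gct_lines(m$tpm), ".gct"),
                       write_lines_tmp(gct_lines(m$counts), ".gct"))
  b <- read_expression(write_lines_tmp(tsv(m$tpm), ".tsv"),
                       write_lines_tmp(tsv(m$counts), ".tsv"))
  expect_equal(a$tpm, b$tpm)
  expect_equal(a$counts, b$counts)
})

test_that("layer disagreements and bad cells are rejected with context", {
  m <- make_tiny_expr()
  short <- m$counts[, 1:3]
  expect_error(
    read_expression(write_lines_tmp(gct_lines(m$tpm), ".gct"),
                    write_lines_tmp(gct_lines(short), ".gct")),
    "S4", class = "gotissue_alignment_error")

  bad <- gct_lines(m$tpm)
  bad[4] <- sub("\t1$", "\toops", bad[4])
  expect_error(
    read_expression(write_lines_tmp(bad, ".gct"),
                    write_lines_tmp(gct_lines(m$counts), ".gct")),
    "non-numeric", class = "gotissue_parse_error")

  neg <- m$tpm; neg[1, 1] <- -1
  expect_error(
    read_expression(write_lines_tmp(gct_lines(neg), ".gct"),
                    write_lines_tmp(gct_lines(m$counts), ".gct")),
    class = "gotissue_parse_error")

  frac <- m$counts; frac[1, 1] <- 1.5
  expect_error(
    read_expression(write_lines_tmp(gct_lines(m$tpm), ".gct"),
                    write_lines_tmp(gct_lines(frac), ".gct")),
    "whole numbers", class = "gotissue_parse_error")
})

test_that("version suffixes are stripped from gene ids on read", {
  m <- make_tiny_expr()
  rownames(m$tpm) <- rownames(m$counts) <- c("ENSG01.4", "ENSG02.1", "ENSG03.12")
  expr <- read_expression(write_lines_tmp(gct_lines(m$tpm), ".gct"),
                          write_lines_tmp(gct_lines(m$counts), ".gct"),
                          quiet = TRUE)
  expect_equal(expr$gene_ids, c("ENSG01", "ENSG02", "ENSG03"))
})

test_that("sample attributes map samples to trimmed tissue names", {
  f <- write_lines_tmp(c("SAMPID\tSMTSD",
                         "S1\tWhole Blood ", "S2\tWhole Blood",
                         "S3\tWhole Blood", "S4\tLiver", "S5\tLiver"))
  m <- read_sample_attributes(f)
  expect_length(m, 5)
  expect_equal(unname(unclass(m)["S1"]), "Whole Blood")

  expect_error(read_sample_attributes(f, tissue_column = "SMTS"),
               class = "gotissue_format_error")
  dup_ok <- write_lines_tmp(c("SAMPID\tSMTSD", "S1\tLiver", "S1\tLiver"))
  expect_length(read_sample_attributes(dup_ok), 1)
  dup_bad <- write_lines_tmp(c("SAMPID\tSMTSD", "S1\tLiver", "S1\tLung"))
  expect_error(read_sample_attributes(dup_bad),
               class = "gotissue_integrity_error")
})

# the two worked dual-threshold cases: a gene passing both prevalence
# criteria at exactly 40% of samples, and one passing TPM but failing counts
test_that("the dual-threshold filter applies both criteria with AND", {
  genes <- c("both_pass", "tpm_only", "count_only", "silent")
  samples <- paste0("S", 1:5)
  tpm <- matrix(c(0.2, 0.05, 0, 0.3, 0,
                  0.2, 0.2, 0.2, 0.2, 0.2,
                  0.01, 0.01, 0.01, 0.01, 0.01,
                  0, 0, 0, 0, 0), nrow = 4, byrow = TRUE,
                dimnames = list(genes, samples))
  counts <- matrix(c(7, 2, 0, 8, 0,
                     0, 0, 0, 0, 0,
                     10, 10, 10, 10, 10,
                     0, 0, 0, 0, 0), nrow = 4, byrow = TRUE,
                   dimnames = list(genes, samples))
  expr <- structure(list(tpm = tpm, counts = counts, gene_ids = genes,
                         sample_ids = samples), class = "expression_matrix")
  smap <- structure(setNames(rep("Liver", 5), samples),
                    class = "sample_tissue_map")
  bg <- select_expressed_genes(expr, smap, "Liver")
  expect_equal(bg$gene_ids, "both_pass")
  expect_equal(bg$n_samples, 5)

  # with both thresholds at zero every gene qualifies
  all_bg <- select_expressed_genes(expr, smap, "Liver",
                                   tpm_min = 0, count_min = 0)
  expect_setequal(all_bg$gene_ids, genes)
})

test_that("unknown tissues and fully absent samples are distinct errors", {
  m <- make_tiny_expr()
  expr <- structure(list(tpm = m$tpm, counts = m$counts,
                         gene_ids = rownames(m$tpm),
                         sample_ids = colnames(m$tpm)),
                    class = "expression_matrix")
  smap <- structure(c(S1 = "Liver", S2 = "Liver", SX = "Lung"),
                    class = "sample_tissue_map")
  expect_error(select_expressed_genes(expr, smap, "Heart"),
               class = "gotissue_lookup_error")
  expect_error(select_expressed_genes(expr, smap, "Lung"),
               class = "gotissue_alignment_error")
})

test_that("raising any threshold never enlarges the background", {
  spec <- fixture_spec(seed = 11, n_genes = 80, n_tissues = 1)
  fx <- make_expression(spec)
  expr <- read_expression(write_lines_tmp(fx$tpm_gct, ".gct"),
                          write_lines_tmp(fx$counts_gct, ".gct"))
  smap <- read_sample_attributes(write_lines_tmp(fx$attrs_tsv))
  base <- select_expressed_genes(expr, smap, "tissue01")
  for (args in list(list(tpm_min = 2), list(count_min = 300),
                    list(sample_fraction = 0.9))) {
    stricter <- do.call(select_expressed_genes,
                        c(list(expr, smap, "tissue01"), args))
    expect_true(all(stricter$gene_ids %in% base$gene_ids))
  }
})

test_that("the background is invariant under sample-column permutation", {
  spec <- fixture_spec(seed = 12, n_genes = 50, n_tissues = 1)
  fx <- make_expression(spec)
  expr <- read_expression(write_lines_tmp(fx$tpm_gct, ".gct"),
                          write_lines_tmp(fx$counts_gct, ".gct"))
  smap <- read_sample_attributes(write_lines_tmp(fx$attrs_tsv))
  perm <- sample(expr$sample_ids)
  shuffled <- structure(list(tpm = expr$tpm[, perm], counts = expr$counts[, perm],
                             gene_ids = expr$gene_ids, sample_ids = perm),
                        class = "expression_matrix")
  expect_equal(select_expressed_genes(expr, smap, "tissue01")$gene_ids,
               select_expressed_genes(shuffled, smap, "tissue01")$gene_ids)
})

test_that("planted expressed sets are recovered exactly per tissue", {
  for (seed in 1:6) {
    spec <- fixture_spec(seed = seed, n_genes = 60, n_tissues = 2,
                         samples_per_tissue = 5)
    fx <- make_expression(spec)
    expr <- read_expression(write_lines_tmp(fx$tpm_gct, ".gct"),
                            write_lines_tmp(fx$counts_gct, ".gct"))
    smap <- read_sample_attributes(write_lines_tmp(fx$attrs_tsv))
    for (ti in fx$tissues) {
      bg <- select_expressed_genes(expr, smap, ti)
      expect_setequal(bg$gene_ids, fx$expressed_expr[[ti]])
    }
  }
})

test_that("id mapping translates a background and drops unmapped genes", {
  bg <- structure(list(tissue = "Liver", gene_ids = c("E1", "E2", "E3"),
                       n_samples = 4,
                       thresholds = c(tpm_min = 0.1, count_min = 6,
                                      sample_fraction = 0.2)),
                  class = "tissue_background")
  map_file <- write_lines_tmp(c("E1\tP1", "E3\tP3"))
  mapped <- map_background_ids(bg, read_id_map(map_file), quiet = TRUE)
  expect_setequal(mapped$gene_ids, c("P1", "P3"))
})
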