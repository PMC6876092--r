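# The synthetic-fixture generators themselves.

test_that("fixture specs validate their counts", {
  expect_error(fixture_spec(n_terms = 2), class = "gotissue_generation_error")
  expect_error(fixture_spec(enrichment_strength = 1.2),
               class = "gotissue_generation_error")
  expect_error(fixture_spec(n_genes = 0), class = "gotissue_generation_error")
  expect_s3_class(fixture_spec(), "fixture_spec")
})

test_that("generated ontologies parse, stay acyclic and have one root", {
  for (seed in 1:25) {
    ont <- make_ontology(fixture_spec(seed = seed, n_terms = 15))
    g <- parse_obo(ont$obo)  # parse_obo errors on any cycle
    expect_length(g$id, 15)
    expect_equal(namespace_roots(g, "BP"), ont$root)
  }
  tiny <- make_ontology(fixture_spec(seed = 1, n_terms = 3))
  expect_length(parse_obo(tiny$obo)$id, 3)
})

test_that("generators are pure functions of the seed", {
  a <- make_ontology(fixture_spec(seed = 5))
  b <- make_ontology(fixture_spec(seed = 5))
  expect_identical(a$obo, b$obo)
  expect_false(identical(a$obo, make_ontology(fixture_spec(seed = 6))$obo))

  spec <- fixture_spec(seed = 5)
  expect_identical(make_annotations(spec)$gaf, make_annotations(spec)$gaf)
  expect_identical(make_expression(spec)$tpm_gct,
                   make_expression(spec)$tpm_gct)
  ont <- make_ontology(spec)
  ann <- make_annotations(spec, ont)
  bg <- sprintf("P%05d", 1:150)
  expect_identical(make_gene_list(spec, ont, ann, bg)$genes,
                   make_gene_list(spec, ont, ann, bg)$genes)
  # generators do not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(make_ontology(spec)); after <- runif(1)
  expect_identical(before, after)
})

test_that("emitted GAF parses back to exactly the ground-truth pairs", {
  spec <- fixture_spec(seed = 9, n_terms = 12, n_genes = 40)
  ont <- make_ontology(spec)
  ann <- make_annotations(spec, ont)
  expect_true(all(lengths(strsplit(
    grep("^[^!]", ann$gaf, value = TRUE), "\t")) >= 15))
  g <- parse_obo(ont$obo)
  parsed <- parse_gaf(ann$gaf, g, quiet = TRUE)
  got <- as.data.frame(parsed)[order(parsed$gene_id, parsed$term_id),
                               c("gene_id", "term_id")]
  rownames(got) <- NULL
  expect_equal(got, ann$direct)
})

test_that("expression bundles recover their designated sets per tissue", {
  spec <- fixture_spec(seed = 2, n_genes = 50, n_tissues = 2,
                       samples_per_tissue = 1)  # single-sample boundary
  fx <- make_expression(spec)
  expr <- read_expression(write_lines_tmp(fx$tpm_gct, ".gct"),
                          write_lines_tmp(fx$counts_gct, ".gct"))
  smap <- read_sample_attributes(write_lines_tmp(fx$attrs_tsv))
  for (ti in fx$tissues)
    expect_setequal(select_expressed_genes(expr, smap, ti)$gene_ids,
                    fx$expressed_expr[[ti]])
})

test_that("forced genes enter the designated set; disjoint sets stay disjoint", {
  spec <- fixture_spec(seed = 4, n_genes = 40, n_tissues = 2)
  forced <- c("P00001", "P00039")
  fx <- make_expression(spec, must_include = list(tissue02 = forced))
  expect_true(all(forced %in% fx$expressed[["tissue02"]]))

  # explicitly disjoint designations yield disjoint backgrounds
  half <- sprintf("P%05d", 1:20)
  other <- sprintf("P%05d", 21:40)
  fx_d <- make_expression(spec,
                          expressed_sets = list(tissue01 = half,
                                                tissue02 = other))
  expr <- read_expression(write_lines_tmp(fx_d$tpm_gct, ".gct"),
                          write_lines_tmp(fx_d$counts_gct, ".gct"))
  smap <- read_sample_attributes(write_lines_tmp(fx_d$attrs_tsv))
  bg1 <- select_expressed_genes(expr, smap, "tissue01")$gene_ids
  bg2 <- select_expressed_genes(expr, smap, "tissue02")$gene_ids
  expect_setequal(bg1, half)
  expect_setequal(bg2, other)
  expect_length(intersect(bg1, bg2), 0)
})

test_that("gene lists plant the requested signal fraction", {
  spec <- fixture_spec(seed = 8, enrichment_strength = 1, list_size = 10)
  ont <- make_ontology(spec)
  ann <- make_annotations(spec, ont)
  bg <- sprintf("P%05d", 1:200)
  gl <- make_gene_list(spec, ont, ann, bg)
  expect_false(is.na(gl$planted_term))
  expect_true(all(gl$genes %in% bg))

  null_spec <- fixture_spec(seed = 8, enrichment_strength = 0)
  gl0 <- make_gene_list(null_spec, ont, ann, bg)
  expect_true(is.na(gl0$planted_term))
  expect_length(gl0$genes, null_spec$list_size)

  # a planted term with too few background genes is a generation error
  tight <- fixture_spec(seed = 8, planted_term = ont$root)
  expect_error(make_gene_list(tight, ont, ann, bg[1:2]),
               class = "gotissue_generation_error")
})

test_that("null gene lists are calibrated: many small raw p, few discoveries", {
  # Under a true null, the minimum raw p across ~35 dependent tests falls
  # below 0.05 often (multiplicity: bounded between the one-test rate and
  # 1), while BH keeps the rate of any q <= 0.05 discovery low. Wide sanity
  # bands, not sharp quantiles.
  spec <- fixture_spec(seed = 50)
  ont <- make_ontology(spec)
  g <- parse_obo(ont$obo)
  ann <- make_annotations(spec, ont)
  annset <- build_annotation_set(parse_gaf(ann$gaf, g, quiet = TRUE),
                                 g, "BP")
  bg <- structure(list(tissue = "t",
                       gene_ids = sprintf("P%05d", 1:120), n_samples = 4,
                       thresholds = c(tpm_min = 0.1, count_min = 6,
                                      sample_fraction = 0.2)),
                  class = "tissue_background")
  minp <- minq <- numeric(200)
  for (i in 1:200) {
    gl <- make_gene_list(fixture_spec(seed = i, enrichment_strength = 0),
                         ont, ann, bg$gene_ids)
    r <- run_enrichment(gl$genes, bg, annset, g, quiet = TRUE)
    minp[i] <- min(r$table$p_value)
    minq[i] <- min(r$table$q_value)
  }
  expect_gte(mean(minp < 0.05), 0.05)  # at least the single-test rate
  expect_lte(mean(minp < 0.05), 0.95)  # but the null is not degenerate
  expect_lte(mean(minq <= 0.05), 0.25) # BH holds the familywise discovery rate
})

test_that("bundles are complete, self-consistent and parseable end-to-end", {
  spec <- fixture_spec(seed = 13)
  dir <- file.path(tempdir(), "bundle13")
  b <- make_fixture_bundle(spec, dir)
  expect_true(all(file.exists(unlist(b$paths))))

  g <- parse_obo(b$paths$obo)
  parsed <- parse_gaf(b$paths$gaf, g, quiet = TRUE)
  expect_gt(nrow(parsed), 0)
  expr <- read_expression(b$paths$tpm, b$paths$counts, quiet = TRUE)
  smap <- read_sample_attributes(b$paths$attrs)
  gt <- jsonlite::read_json(b$paths$ground_truth, simplifyVector = TRUE)
  bg <- select_expressed_genes(expr, smap, gt$planted_tissue)
  expect_setequal(bg$gene_ids, gt$expressed[[gt$planted_tissue]])
  genes <- read_gene_list(b$paths$gene_list)
  expect_true(all(genes %in% bg$gene_ids))
  expect_true(gt$planted_term %in% g$id)
})

test_that("split-id bundles exercise version stripping and the mapping table", {
  spec <- fixture_spec(seed = 21, split_ids = TRUE, n_genes = 60)
  dir <- file.path(tempdir(), "bundle21")
  b <- make_fixture_bundle(spec, dir)
  expect_true(file.exists(b$paths$id_map))
  expr <- read_expression(b$paths$tpm, b$paths$counts, quiet = TRUE)
  expect_true(all(grepl("^ENSG", expr$gene_ids)))
  expect_false(any(grepl("\\.", expr$gene_ids)))  # versions stripped
  smap <- read_sample_attributes(b$paths$attrs)
  gt <- jsonlite::read_json(b$paths$ground_truth, simplifyVector = TRUE)
  bg <- select_expressed_genes(expr, smap, gt$planted_tissue)
  mapped <- map_background_ids(bg, read_id_map(b$paths$id_map),
                               quiet = TRUE)
  expect_setequal(mapped$gene_ids, gt$expressed[[gt$planted_tissue]])
})
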