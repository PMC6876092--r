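# Synthetic fixture generators: mini ontologies (OBO), annotations (GAF),
# GTEx-style expression matrices (GCT) with planted expressed-gene sets, and
# input gene lists with planted enrichment signal. Every generator is a pure
# function of the spec (seeded RNG, global RNG state restored), so fixtures
# are reproducible byte for byte.

#' Describe a synthetic fixture bundle
#'
#' Collects the knobs of the fixture generators. Defaults describe a small
#' but structured study: a 40-term single-namespace DAG, 200 genes with 1-5
#' direct annotations each, and two tissues of 8 samples whose expressed-gene
#' sets cover different fractions of the genome (45% and 60%), emulating
#' tissues of different transcriptome breadth.
#'
#' @param seed integer seed; every generated byte is a function of it.
#' @param n_terms ontology size (>= 3).
#' @param n_genes gene-universe size.
#' @param n_tissues number of tissues.
#' @param samples_per_tissue samples per tissue.
#' @param planted_term GO accession to make enriched; `NULL` picks a term
#'   with a mid-sized annotated set automatically.
#' @param planted_tissue tissue whose background carries the signal genes;
#'   `NULL` uses the first tissue.
#' @param enrichment_strength fraction of the input gene list drawn from the
#'   planted term's genes, in \[0, 1\].
#' @param list_size input gene-list size.
#' @param extra_edge_prob probability that a non-root term gets a second
#'   parent (turns the random tree into a DAG).
#' @param expressed_fractions per-tissue fraction of genes designated
#'   expressed; `NULL` spreads tissues evenly over \[0.45, 0.60\].
#' @param split_ids emit Ensembl-like expression ids (with version
#'   suffixes) distinct from the UniProt-like annotation ids, plus a
#'   two-column mapping table, to exercise the id-bridging path.
#' @return a validated list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_terms = 40L, n_genes = 200L,
                         n_tissues = 2L, samples_per_tissue = 8L,
                         planted_term = NULL, planted_tissue = NULL,
                         enrichment_strength = 0.8, list_size = 25L,
                         extra_edge_prob = 0.15,
                         expressed_fractions = NULL,
                         split_ids = FALSE) {
  if (n_terms < 3L)
    gt_stop("n_terms must be at least 3", "generation")
  for (v in c(n_genes = n_genes, n_tissues = n_tissues,
              samples_per_tissue = samples_per_tissue,
              list_size = list_size))
    if (v < 1L) gt_stop("all fixture counts must be positive", "generation")
  if (enrichment_strength < 0 || enrichment_strength > 1)
    gt_stop("enrichment_strength must lie in [0, 1]", "generation")
  if (is.null(expressed_fractions)) {
    expressed_fractions <- if (n_tissues == 1L) 0.45 else
      0.45 + 0.15 * (seq_len(n_tissues) - 1) / (n_tissues - 1)
  }
  if (length(expressed_fractions) != n_tissues)
    gt_stop("expressed_fractions must have one entry per tissue",
            "generation")
  structure(list(seed = as.integer(seed), n_terms = as.integer(n_terms),
                 n_genes = as.integer(n_genes),
                 n_tissues = as.integer(n_tissues),
                 samples_per_tissue = as.integer(samples_per_tissue),
                 planted_term = planted_term,
                 planted_tissue = planted_tissue,
                 enrichment_strength = enrichment_strength,
                 list_size = as.integer(list_size),
                 extra_edge_prob = extra_edge_prob,
                 expressed_fractions = expressed_fractions,
                 split_ids = isTRUE(split_ids)),
            class = "fixture_spec")
}

#' @noRd
fixture_term_ids <- function(spec) sprintf("GO:%07d", seq_len(spec$n_terms))

#' @noRd
fixture_gene_ids <- function(spec) sprintf("P%05d", seq_len(spec$n_genes))

#' @noRd
fixture_tissues <- function(spec) sprintf("tissue%02d", seq_len(spec$n_tissues))

#' Generate a synthetic ontology
#'
#' Builds a rooted random tree over `n_terms` terms (term 1 is the root) and
#' adds extra parents with probability `extra_edge_prob`, yielding a
#' single-namespace DAG (acyclic because every edge points from a
#' higher-numbered term to a lower-numbered one). Emits valid OBO text plus
#' the exact edge list as ground truth for parser checks.
#'
#' @param spec a `fixture_spec`.
#' @return list with `obo` (character vector of lines), `edges`
#'   (data.frame `child`, `parent`, `relation`), `ids`, and `root`.
#' @export
make_ontology <- function(spec) {
  ids <- fixture_term_ids(spec)
  with_seed(spec$seed + 101L, {
    child <- character(0); parent <- character(0); rel <- character(0)
    for (i in 2:spec$n_terms) {
      p <- if (i == 2L) 1L else sample.int(i - 1L, 1L)
      child <- c(child, ids[i]); parent <- c(parent, ids[p])
      rel <- c(rel, "is_a")
      if (i >= 3L && stats::runif(1) < spec$extra_edge_prob) {
        p2 <- sample.int(i - 1L, 1L)
        if (p2 != p) {
          child <- c(child, ids[i]); parent <- c(parent, ids[p2])
          rel <- c(rel, sample(c("is_a", "part_of"), 1L))
        }
      }
    }
    edges <- data.frame(child = child, parent = parent, relation = rel,
                        stringsAsFactors = FALSE)
    obo <- c("format-version: 1.2", "ontology: synthetic-go", "")
    for (i in seq_along(ids)) {
      stanza <- c("[Term]",
                  paste0("id: ", ids[i]),
                  sprintf("name: synthetic term %03d", i),
                  "namespace: biological_process")
      e <- edges[edges$child == ids[i], , drop = FALSE]
      for (j in seq_len(nrow(e))) {
        stanza <- c(stanza, if (e$relation[j] == "is_a")
          paste0("is_a: ", e$parent[j])
        else paste0("relationship: part_of ", e$parent[j]))
      }
      obo <- c(obo, stanza, "")
    }
    list(obo = obo, edges = edges, ids = ids, root = ids[1])
  })
}

#' Generate synthetic GAF annotations
#'
#' Assigns each gene 1-5 direct annotations to uniformly random terms and
#' emits GAF 2.2 text (17 columns), returning the direct gene-term pairs as
#' ground truth so annotation propagation can be checked independently.
#'
#' @param spec a `fixture_spec`.
#' @param ontology output of [make_ontology()] (defaults to generating it).
#' @return list with `gaf` (character vector of lines) and `direct`
#'   (data.frame `gene_id`, `term_id`).
#' @export
make_annotations <- function(spec, ontology = make_ontology(spec)) {
  genes <- fixture_gene_ids(spec)
  with_seed(spec$seed + 202L, {
    gene_rep <- character(0); term_rep <- character(0)
    for (g in genes) {
      k <- sample.int(5L, 1L)
      t <- sample(ontology$ids, k)
      gene_rep <- c(gene_rep, rep(g, k)); term_rep <- c(term_rep, t)
    }
    direct <- unique(data.frame(gene_id = gene_rep, term_id = term_rep,
                                stringsAsFactors = FALSE))
    direct <- direct[order(direct$gene_id, direct$term_id), , drop = FALSE]
    rownames(direct) <- NULL
    rows <- sprintf(paste0("SYNDB\t%s\t%s\tinvolved_in\t%s\tSYN:0000001\t",
                           "IEA\t\tP\tsynthetic protein %s\t\tprotein\t",
                           "taxon:9606\t20260101\tSYNDB\t\t"),
                    direct$gene_id, direct$gene_id, direct$term_id,
                    direct$gene_id)
    list(gaf = c("!gaf-version: 2.2", "!generated-by: gotissue fixtures",
                 rows),
         direct = direct)
  })
}

# true-path propagation over a ground-truth edge list, independent of the
# annotation module (simple per-term ancestor walk)
#' @noRd
fixture_propagate <- function(direct, edges, ids) {
  parents <- split(edges$parent, factor(edges$child, levels = ids))
  anc <- function(t) {
    seen <- character(0); frontier <- parents[[t]]
    while (length(frontier)) {
      seen <- c(seen, frontier)
      frontier <- setdiff(unlist(parents[frontier], use.names = FALSE), seen)
    }
    unique(seen)
  }
  acc <- list()
  for (i in seq_len(nrow(direct))) {
    g <- direct$gene_id[i]; t <- direct$term_id[i]
    for (tt in c(t, anc(t)))
      acc[[tt]] <- c(acc[[tt]], g)
  }
  lapply(acc, function(g) sort(unique(g)))
}

#' Generate a synthetic expression bundle
#'
#' For each tissue, designates a known expressed-gene subset covering that
#' tissue's `expressed_fractions` share of the genome, then writes TPM and
#' read-count GCT 1.2 matrices in which designated genes sit well above the
#' default thresholds (TPM in \[1, 5\], counts in \[60, 600\]) in every
#' sample of their tissue, and all other gene/sample cells sit well below
#' (TPM < 0.01, counts 0). The margins are x10 / x0.1 of the default
#' cutoffs, so recovery by [select_expressed_genes()] is insensitive to
#' float formatting.
#'
#' @param spec a `fixture_spec`.
#' @param must_include optional named list (tissue -> gene ids) of genes
#'   forced into that tissue's expressed set (used to plant enrichment
#'   signal inside a background).
#' @param expressed_sets optional named list (tissue -> gene ids, annotation
#'   id space) that fully replaces the random designation, e.g. to build
#'   tissues with disjoint backgrounds.
#' @return list with `tpm_gct`, `counts_gct`, `attrs_tsv` (character
#'   vectors of lines), `expressed` (tissue -> annotation-space gene ids),
#'   `expressed_expr` (tissue -> expression-space ids, version-stripped),
#'   `id_map_tsv` (or `NULL` when ids are shared), `tissues`, `sample_ids`.
#' @export
make_expression <- function(spec, must_include = NULL,
                            expressed_sets = NULL) {
  genes <- fixture_gene_ids(spec)
  tissues <- fixture_tissues(spec)
  expr_ids <- if (spec$split_ids)
    sprintf("ENSG%011d", seq_len(spec$n_genes)) else genes
  # GCT rows carry a version suffix when ids are split, to exercise stripping
  expr_ids_versioned <- if (spec$split_ids) paste0(expr_ids, ".1") else expr_ids

  with_seed(spec$seed + 303L, {
    expressed_idx <- vector("list", spec$n_tissues)
    names(expressed_idx) <- tissues
    for (t in seq_len(spec$n_tissues)) {
      idx <- if (!is.null(expressed_sets) &&
                 tissues[t] %in% names(expressed_sets)) {
        match(expressed_sets[[tissues[t]]], genes)
      } else {
        size <- max(1L, round(spec$expressed_fractions[t] * spec$n_genes))
        sort(sample.int(spec$n_genes, size))
      }
      if (!is.null(must_include) && tissues[t] %in% names(must_include))
        idx <- union(idx, match(must_include[[tissues[t]]], genes))
      expressed_idx[[t]] <- sort(idx)
    }

    n_samp <- spec$n_tissues * spec$samples_per_tissue
    sample_ids <- unlist(lapply(tissues, function(ti)
      sprintf("SAMP-%s-%02d", ti, seq_len(spec$samples_per_tissue))))
    sample_tissue <- rep(tissues, each = spec$samples_per_tissue)

    tpm <- matrix(stats::runif(spec$n_genes * n_samp, 0, 0.01),
                  nrow = spec$n_genes,
                  dimnames = list(expr_ids, sample_ids))
    counts <- matrix(0L, nrow = spec$n_genes, ncol = n_samp,
                     dimnames = list(expr_ids, sample_ids))
    for (t in seq_len(spec$n_tissues)) {
      cols <- which(sample_tissue == tissues[t])
      idx <- expressed_idx[[t]]
      ncell <- length(idx) * length(cols)
      tpm[idx, cols] <- stats::runif(ncell, 1, 5)
      counts[idx, cols] <- sample(60:600, ncell, replace = TRUE)
    }

    gct <- function(mat, fmt) {
      vals <- apply(mat, 1, function(r) paste(sprintf(fmt, r),
                                              collapse = "\t"))
      c("#1.2",
        sprintf("%d\t%d", nrow(mat), ncol(mat)),
        paste(c("Name", "Description", colnames(mat)), collapse = "\t"),
        sprintf("%s\tna\t%s", expr_ids_versioned, vals))
    }
    attrs <- c("SAMPID\tSMTSD",
               sprintf("%s\t%s", sample_ids, sample_tissue))
    id_map_tsv <- if (spec$split_ids)
      sprintf("%s\t%s", expr_ids, genes) else NULL

    list(tpm_gct = gct(tpm, "%.6g"),
         counts_gct = gct(counts, "%d"),
         attrs_tsv = attrs,
         expressed = lapply(expressed_idx, function(i) genes[i]),
         expressed_expr = lapply(expressed_idx, function(i) expr_ids[i]),
         id_map_tsv = id_map_tsv,
         tissues = tissues, sample_ids = sample_ids)
  })
}

#' Choose a planted term with a mid-sized annotated set
#'
#' @noRd
pick_planted_term <- function(spec, propagated, background) {
  counts <- vapply(propagated,
                   function(g) length(intersect(g, background)), integer(1))
  cand <- names(counts)[counts >= 3L &
                        counts <= max(4L, floor(0.25 * length(background)))]
  if (length(cand) == 0L)
    gt_stop("no term has enough annotated genes inside the background",
            "generation")
  # deterministic: annotated-set size closest to 8, ties to lowest accession
  cand[order(abs(counts[cand] - 8L), cand)][1]
}

#' Generate an input gene list with planted enrichment
#'
#' Composes a gene list of `list_size` genes from the planted tissue's
#' background: a fraction `enrichment_strength` comes from the planted
#' term's annotated genes, the rest is drawn from background genes outside
#' that term. With `enrichment_strength = 0` the list is a uniform draw from
#' the background (a true null, used for calibration checks).
#'
#' @param spec a `fixture_spec`.
#' @param ontology output of [make_ontology()].
#' @param annotations output of [make_annotations()].
#' @param background character vector: the planted tissue's expressed genes
#'   (annotation id space).
#' @return list with `text` (character lines, `#` comment + one id per
#'   line), `genes`, and `planted_term` (the expected top hit, `NA` when
#'   `enrichment_strength = 0`).
#' @export
make_gene_list <- function(spec, ontology, annotations, background) {
  propagated <- fixture_propagate(annotations$direct, ontology$edges,
                                  ontology$ids)
  planted <- spec$planted_term
  if (is.null(planted) && spec$enrichment_strength > 0)
    planted <- pick_planted_term(spec, propagated, background)
  if (!is.null(planted)) {
    pool <- intersect(propagated[[planted]], background)
    if (length(pool) < 3L)
      gt_stop(sprintf(
        "planted term %s has %d gene(s) in the background; need >= 3",
        planted, length(pool)), "generation")
  }
  with_seed(spec$seed + 404L, {
    if (is.null(planted) || spec$enrichment_strength == 0) {
      genes <- sample(background, min(spec$list_size, length(background)))
      planted <- NA_character_
    } else {
      n_sig <- max(1L, round(spec$enrichment_strength * spec$list_size))
      sig <- sample(pool, min(n_sig, length(pool)))
      rest_pool <- setdiff(background, propagated[[planted]])
      rest <- sample(rest_pool,
                     min(spec$list_size - length(sig), length(rest_pool)))
      genes <- c(sig, rest)
    }
    list(text = c("# synthetic input gene list", genes),
         genes = genes, planted_term = planted)
  })
}

#' Write a two-tissue contrast bundle with disjoint backgrounds
#'
#' Builds the study design used to demonstrate the effect of the tissue
#' background on enrichment calls: two tissues whose expressed-gene sets are
#' fully disjoint (40% / 60% of the genome), and one input gene list usable
#' against either tissue — enrichment signal planted inside tissue01's
#' background plus a few tissue02 background genes. Running the same list
#' against each tissue then yields different universes N and (generically)
#' different significant-term sets, since the planted genes are dropped from
#' the tissue02 run as background outsiders.
#'
#' @param spec a `fixture_spec` with `n_tissues = 2`.
#' @param dir output directory (created if needed).
#' @return (invisibly) list with file `paths`, `planted_term`, and
#'   `backgrounds` (the two designated expressed-gene sets).
#' @export
make_contrast_bundle <- function(spec, dir) {
  if (spec$n_tissues != 2L)
    gt_stop("contrast bundles need exactly two tissues", "generation")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ont <- make_ontology(spec)
  ann <- make_annotations(spec, ont)
  genes <- fixture_gene_ids(spec)
  cut <- max(3L, floor(0.4 * spec$n_genes))
  bg1 <- genes[seq_len(cut)]
  bg2 <- genes[(cut + 1L):spec$n_genes]
  fx <- make_expression(spec,
                        expressed_sets = list(tissue01 = bg1,
                                              tissue02 = bg2))
  gl <- make_gene_list(spec, ont, ann, background = bg1)
  input <- c(gl$genes, bg2[seq_len(min(10L, length(bg2)))])

  paths <- list(obo = file.path(dir, "ontology.obo"),
                gaf = file.path(dir, "annotations.gaf"),
                tpm = file.path(dir, "tpm.gct"),
                counts = file.path(dir, "counts.gct"),
                attrs = file.path(dir, "sample_attributes.tsv"),
                gene_list = file.path(dir, "gene_list.txt"))
  writeLines(ont$obo, paths$obo)
  writeLines(ann$gaf, paths$gaf)
  writeLines(fx$tpm_gct, paths$tpm)
  writeLines(fx$counts_gct, paths$counts)
  writeLines(fx$attrs_tsv, paths$attrs)
  writeLines(input, paths$gene_list)
  invisible(list(paths = paths, planted_term = gl$planted_term,
                 backgrounds = list(tissue01 = bg1, tissue02 = bg2)))
}

#' Write a complete fixture bundle to disk
#'
#' Orchestrates all generators with coordinated ground truth: the planted
#' term is chosen from the annotation structure, its annotated genes are
#' forced into the planted tissue's expressed set, and the input gene list
#' is drawn to over-represent it. Writes `ontology.obo`, `annotations.gaf`,
#' `tpm.gct`, `counts.gct`, `sample_attributes.tsv`, `gene_list.txt`,
#' optionally `id_map.tsv`, and a `ground_truth.json` sidecar.
#'
#' @param spec a `fixture_spec`.
#' @param dir output directory (created if needed).
#' @return (invisibly) a list with the file `paths` and the `ground_truth`
#'   list (planted term/tissue, per-tissue expressed sets, edge count).
#' @export
make_fixture_bundle <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ont <- make_ontology(spec)
  ann <- make_annotations(spec, ont)
  propagated <- fixture_propagate(ann$direct, ont$edges, ont$ids)
  planted_tissue <- if (is.null(spec$planted_tissue))
    fixture_tissues(spec)[1] else spec$planted_tissue

  planted <- spec$planted_term
  if (is.null(planted) && spec$enrichment_strength > 0)
    planted <- pick_planted_term(spec, propagated, fixture_gene_ids(spec))
  must <- if (!is.null(planted))
    stats::setNames(list(propagated[[planted]]), planted_tissue) else NULL

  expr <- make_expression(spec, must_include = must)
  spec2 <- spec; spec2$planted_term <- planted
  gl <- make_gene_list(spec2, ont, ann,
                       background = expr$expressed[[planted_tissue]])

  paths <- list(
    obo = file.path(dir, "ontology.obo"),
    gaf = file.path(dir, "annotations.gaf"),
    tpm = file.path(dir, "tpm.gct"),
    counts = file.path(dir, "counts.gct"),
    attrs = file.path(dir, "sample_attributes.tsv"),
    gene_list = file.path(dir, "gene_list.txt"),
    ground_truth = file.path(dir, "ground_truth.json"))
  writeLines(ont$obo, paths$obo)
  writeLines(ann$gaf, paths$gaf)
  writeLines(expr$tpm_gct, paths$tpm)
  writeLines(expr$counts_gct, paths$counts)
  writeLines(expr$attrs_tsv, paths$attrs)
  writeLines(gl$text, paths$gene_list)
  if (!is.null(expr$id_map_tsv)) {
    paths$id_map <- file.path(dir, "id_map.tsv")
    writeLines(expr$id_map_tsv, paths$id_map)
  }
  ground_truth <- list(planted_term = gl$planted_term,
                       planted_tissue = planted_tissue,
                       root = ont$root,
                       n_edges = nrow(ont$edges),
                       expressed = expr$expressed,
                       input_genes = gl$genes)
  jsonlite::write_json(ground_truth, paths$ground_truth, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(paths = paths, ground_truth = ground_truth, spec = spec))
}
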