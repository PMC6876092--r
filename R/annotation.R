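# GAF parsing and true-path propagation of gene annotations.

#' Parse a GAF association file
#'
#' Reads GAF 2.1/2.2 (15 or 17 tab-separated columns, `!` comment lines) and
#' returns one association per row. Column 2 (DB Object ID, e.g. a UniProtKB
#' accession) is taken as the gene identifier. Rows are dropped when:
#' the qualifier contains `NOT` (they assert absence of function and must not
#' count toward enrichment), the term cannot be resolved in `graph` even via
#' `alt_id`, the resolved term is obsolete, or the evidence code is in
#' `exclude_evidence`. Dropped-row counts are reported via [message()].
#'
#' @param file path to a GAF file, or a character vector of GAF lines.
#' @param graph a `go_ontology` from [parse_obo()].
#' @param exclude_evidence optional character vector of evidence codes to
#'   discard (e.g. `"IEA"`). Default keeps everything.
#' @param taxon optional taxon id (e.g. `"9606"`); rows not matching
#'   `taxon:<id>` in column 13 are dropped.
#' @param quiet suppress the drop-count log lines.
#' @return a data.frame of class `go_annotations` with columns `gene_id`,
#'   `term_id` (canonical accession), `evidence_code`, `qualifier`,
#'   `namespace`.
#' @export
parse_gaf <- function(file, graph, exclude_evidence = NULL, taxon = NULL,
                      quiet = FALSE) {
  lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file))
    readLines(file, warn = FALSE) else unlist(strsplit(file, "\n", fixed = TRUE))
  is_comment <- startsWith(lines, "!")
  hdr <- lines[is_comment]
  ver <- grep("^!\\s*gaf-version:", hdr, value = TRUE)
  if (length(ver)) {
    v <- trimws(sub("^!\\s*gaf-version:", "", ver[1]))
    if (!grepl("^(1\\.|2\\.)", v))
      gt_stop(sprintf("unsupported gaf-version header: '%s'", v), "format")
  }
  data_idx <- which(!is_comment & nzchar(lines))
  if (length(data_idx) == 0L)
    return(empty_annotations())

  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 15L))
    gt_stop(sprintf("GAF line %d has %d fields (15 required)",
                    data_idx[which(nf < 15L)[1]], min(nf)), "parse")

  gene_id <- vapply(fields, `[[`, "", 2L)
  qualifier <- vapply(fields, `[[`, "", 4L)
  term_id <- vapply(fields, `[[`, "", 5L)
  evidence <- vapply(fields, `[[`, "", 7L)
  aspect <- vapply(fields, `[[`, "", 9L)
  taxon_f <- vapply(fields, `[[`, "", 13L)

  if (any(!nzchar(evidence)))
    gt_stop(sprintf("GAF line %d has an empty evidence code",
                    data_idx[which(!nzchar(evidence))[1]]), "parse")

  keep <- rep(TRUE, length(gene_id))
  is_not <- vapply(strsplit(qualifier, "|", fixed = TRUE),
                   function(q) "NOT" %in% q, logical(1))
  if (any(is_not)) {
    gt_log(sprintf("dropped %d NOT-qualified row(s)", sum(is_not)),
           quiet = quiet)
    keep <- keep & !is_not
  }
  if (!is.null(exclude_evidence)) {
    ev_drop <- evidence %in% exclude_evidence
    if (any(ev_drop & keep))
      gt_log(sprintf("dropped %d row(s) by evidence-code filter",
                     sum(ev_drop & keep)), quiet = quiet)
    keep <- keep & !ev_drop
  }
  if (!is.null(taxon)) {
    tx_keep <- grepl(paste0("(^|\\|)taxon:", taxon, "($|\\|)"), taxon_f)
    if (any(!tx_keep & keep))
      gt_log(sprintf("dropped %d row(s) by taxon filter",
                     sum(!tx_keep & keep)), quiet = quiet)
    keep <- keep & tx_keep
  }

  # canonicalize accessions through alt_id, then drop unknown/obsolete terms
  hit <- match(term_id, names(graph$alt_id))
  n_alt <- sum(!is.na(hit) & keep)
  if (n_alt)
    gt_log(sprintf("canonicalized %d alt_id accession(s)", n_alt),
           quiet = quiet)
  term_id[!is.na(hit)] <- unname(graph$alt_id[hit[!is.na(hit)]])
  known <- term_id %in% graph$id
  if (any(!known & keep))
    gt_log(sprintf("dropped %d row(s) with terms absent from the ontology",
                   sum(!known & keep)), quiet = quiet)
  keep <- keep & known
  obs <- keep & graph$obsolete[term_id]
  obs[is.na(obs)] <- FALSE
  if (any(obs)) {
    gt_log(sprintf("dropped %d row(s) on obsolete terms", sum(obs)),
           quiet = quiet)
    keep <- keep & !obs
  }

  out <- data.frame(gene_id = gene_id[keep],
                    term_id = term_id[keep],
                    evidence_code = evidence[keep],
                    qualifier = qualifier[keep],
                    namespace = unname(GO_ASPECT_MAP[aspect[keep]]),
                    stringsAsFactors = FALSE)
  class(out) <- c("go_annotations", "data.frame")
  out
}

#' @noRd
empty_annotations <- function() {
  out <- data.frame(gene_id = character(0), term_id = character(0),
                    evidence_code = character(0), qualifier = character(0),
                    namespace = character(0), stringsAsFactors = FALSE)
  class(out) <- c("go_annotations", "data.frame")
  out
}

#' Build term-to-gene maps with true-path propagation
#'
#' Restricts associations to one GO namespace, collapses duplicate
#' (gene, term) rows to a single membership, and (by default) propagates every
#' gene up the DAG so that a gene annotated to a term also counts for all of
#' that term's ancestors (the true-path rule). Per-term gene counts are
#' therefore monotone non-decreasing toward the root.
#'
#' @param annotations a `go_annotations` data.frame from [parse_gaf()].
#' @param graph the `go_ontology` the annotations refer to.
#' @param namespace GO category to restrict to (BP/CC/MF or full name).
#' @param propagate propagate annotations to ancestors (default `TRUE`).
#' @return an object of class `go_annotation_set`: list with `direct` and
#'   `propagated` (term -> character vector of gene ids), `gene_index`
#'   (gene -> term ids, the transpose of `propagated`), `namespace`, and
#'   `propagate`.
#' @export
build_annotation_set <- function(annotations, graph, namespace,
                                 propagate = TRUE) {
  namespace <- go_namespace(namespace)
  ann <- annotations[annotations$namespace == namespace &
                     annotations$term_id %in% graph$id, , drop = FALSE]
  ann <- unique(ann[, c("gene_id", "term_id")])

  direct <- lapply(split(ann$gene_id, ann$term_id), function(g) sort(unique(g)))

  if (propagate && length(direct)) {
    acc <- new.env(parent = emptyenv())
    for (t in names(direct)) {
      for (tt in c(t, go_ancestors(graph, t))) {
        prev <- if (exists(tt, envir = acc, inherits = FALSE))
          get(tt, envir = acc) else character(0)
        assign(tt, c(prev, direct[[t]]), envir = acc)
      }
    }
    propagated <- lapply(as.list(acc), function(g) sort(unique(g)))
    propagated <- propagated[order(names(propagated))]
  } else {
    propagated <- direct
  }

  gene_index <- if (length(propagated)) {
    terms_rep <- rep(names(propagated), lengths(propagated))
    genes_rep <- unlist(propagated, use.names = FALSE)
    lapply(split(terms_rep, genes_rep), function(t) sort(unique(t)))
  } else list()

  structure(list(direct = direct, propagated = propagated,
                 gene_index = gene_index, namespace = namespace,
                 propagate = propagate),
            class = "go_annotation_set")
}

#' @export
print.go_annotation_set <- function(x, ...) {
  cat(sprintf(paste0("go_annotation_set (%s): %d terms with direct",
                     " annotations, %d after propagation, %d genes\n"),
              x$namespace, length(x$direct), length(x$propagated),
              length(x$gene_index)))
  invisible(x)
}
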