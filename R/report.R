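# Result serialization: provenance-stamped TSV (round-trippable), a
# self-contained HTML table with AmiGO/NCBI links, Graphviz DOT lineage
# graphs, and the comparison summary. All writers are deterministic
# functions of their inputs: fixed sort orders, fixed float formatting
# (6 significant digits, scientific below 1e-4), and no timestamps in
# serialized output.

RESULT_COLUMNS <- c("term_id", "term_name", "namespace", "N", "M", "n", "k",
                    "p_value", "q_value", "hit_genes")

#' @noRd
provenance_lines <- function(meta) {
  th <- meta$thresholds
  c(sprintf("# tool\t%s %s", meta$tool, meta$version),
    sprintf("# tissue\t%s", meta$tissue),
    sprintf("# namespace\t%s", meta$namespace),
    sprintf("# N\t%d", meta$N),
    sprintf("# n\t%d", meta$n),
    sprintf("# n_input\t%d", meta$n_input),
    sprintf("# tpm_min\t%g", th[["tpm_min"]]),
    sprintf("# count_min\t%g", th[["count_min"]]),
    sprintf("# sample_fraction\t%g", th[["sample_fraction"]]),
    sprintf("# min_overlap\t%d", meta$min_overlap),
    sprintf("# propagate\t%s", if (isTRUE(meta$propagate)) "true" else "false"),
    sprintf("# dropped_genes\t%s",
            paste(meta$dropped_genes$gene_id, collapse = ";")),
    sprintf("# n_underflow\t%d", meta$n_underflow))
}

#' Write an enrichment result as provenance-stamped TSV
#'
#' Writes `#`-prefixed key-value provenance comments, a fixed header, and
#' one row per tested term in the result's order. The file is re-read by
#' [read_enrichment_tsv()] (the format [cmd_compare()] consumes). p- and
#' q-values are printed with 6 significant digits, scientific below 1e-4.
#'
#' @param result an `enrichment_result`.
#' @param file output path.
#' @export
write_enrichment_tsv <- function(result, file) {
  tab <- result$table
  rows <- sprintf("%s\t%s\t%s\t%d\t%d\t%d\t%d\t%s\t%s\t%s",
                  tab$term_id, tab$term_name, tab$namespace,
                  tab$N, tab$M, tab$n, tab$k,
                  format_pvalue(tab$p_value), format_pvalue(tab$q_value),
                  tab$hit_genes)
  writeLines(c(provenance_lines(result$meta),
               paste(RESULT_COLUMNS, collapse = "\t"), rows), file)
  invisible(file)
}

#' Read back an enrichment-result TSV
#'
#' Inverse of [write_enrichment_tsv()]: reconstructs the result table and
#' the provenance metadata needed downstream (tissue, namespace, N, n,
#' thresholds, dropped genes).
#'
#' @param file path to a TSV written by [write_enrichment_tsv()].
#' @return an `enrichment_result`.
#' @export
read_enrichment_tsv <- function(file) {
  lines <- readLines(file, warn = FALSE)
  prov <- lines[startsWith(lines, "# ")]
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L || !identical(strsplit(body[1], "\t")[[1]],
                                       RESULT_COLUMNS))
    gt_stop(sprintf("'%s' is not an enrichment-result TSV (bad header)",
                    file), "parse")
  kv <- strsplit(sub("^# ", "", prov), "\t", fixed = TRUE)
  meta_raw <- setNames(vapply(kv, function(x)
    if (length(x) > 1) x[2] else "", character(1)),
    vapply(kv, `[[`, "", 1))
  get_num <- function(key, default = NA_real_) {
    if (key %in% names(meta_raw)) as.numeric(meta_raw[[key]]) else default
  }
  dropped <- if (nzchar(meta_raw["dropped_genes"]) &&
                 !is.na(meta_raw["dropped_genes"]))
    strsplit(meta_raw[["dropped_genes"]], ";", fixed = TRUE)[[1]]
  else character(0)

  tab <- if (length(body) > 1L) {
    f <- strsplit(body[-1], "\t", fixed = TRUE)
    bad <- which(lengths(f) != length(RESULT_COLUMNS))
    if (length(bad))
      gt_stop(sprintf("'%s': malformed result row %d", file, bad[1]), "parse")
    data.frame(term_id = vapply(f, `[[`, "", 1),
               term_name = vapply(f, `[[`, "", 2),
               namespace = vapply(f, `[[`, "", 3),
               N = as.integer(vapply(f, `[[`, "", 4)),
               M = as.integer(vapply(f, `[[`, "", 5)),
               n = as.integer(vapply(f, `[[`, "", 6)),
               k = as.integer(vapply(f, `[[`, "", 7)),
               p_value = as.numeric(vapply(f, `[[`, "", 8)),
               q_value = as.numeric(vapply(f, `[[`, "", 9)),
               hit_genes = vapply(f, `[[`, "", 10),
               stringsAsFactors = FALSE)
  } else empty_result_table()

  meta <- list(tool = "gotissue",
               version = sub("^gotissue ", "", meta_raw["tool"]),
               tissue = unname(meta_raw["tissue"]),
               namespace = unname(meta_raw["namespace"]),
               N = as.integer(get_num("N")), n = as.integer(get_num("n")),
               n_input = as.integer(get_num("n_input")),
               thresholds = c(tpm_min = get_num("tpm_min"),
                              count_min = get_num("count_min"),
                              sample_fraction = get_num("sample_fraction")),
               min_overlap = as.integer(get_num("min_overlap", 1)),
               propagate = identical(unname(meta_raw["propagate"]), "true"),
               dropped_genes = data.frame(
                 gene_id = dropped,
                 reason = rep("not_in_background", length(dropped)),
                 stringsAsFactors = FALSE),
               n_underflow = as.integer(get_num("n_underflow", 0)),
               timestamp = NA_character_)
  structure(list(table = tab, meta = meta), class = "enrichment_result")
}

#' @noRd
html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write an enrichment result as a self-contained HTML table
#'
#' Produces a single HTML5 document with no external scripts. Each GO
#' accession links to its AmiGO term page and each hit gene links to an NCBI
#' gene-query URL built from the identifier.
#'
#' @param result an `enrichment_result`.
#' @param file output path.
#' @export
write_enrichment_html <- function(result, file) {
  tab <- result$table
  amigo <- function(id)
    sprintf('<a href="https://amigo.geneontology.org/amigo/term/%s">%s</a>',
            id, id)
  ncbi <- function(gene)
    sprintf('<a href="https://www.ncbi.nlm.nih.gov/gene/?term=%s">%s</a>',
            utils::URLencode(gene, reserved = TRUE), html_escape(gene))
  body_rows <- vapply(seq_len(nrow(tab)), function(i) {
    genes <- strsplit(tab$hit_genes[i], ";", fixed = TRUE)[[1]]
    paste0("<tr><td>", amigo(tab$term_id[i]), "</td><td>",
           html_escape(tab$term_name[i]), "</td><td>", tab$namespace[i],
           "</td><td>", tab$N[i], "</td><td>", tab$M[i], "</td><td>",
           tab$n[i], "</td><td>", tab$k[i], "</td><td>",
           format_pvalue(tab$p_value[i]), "</td><td>",
           format_pvalue(tab$q_value[i]), "</td><td>",
           paste(vapply(genes, ncbi, character(1)), collapse = "; "),
           "</td></tr>")
  }, character(1))
  doc <- c(
    "<!DOCTYPE html>", "<html lang=\"en\">", "<head>",
    "<meta charset=\"utf-8\"/>",
    sprintf("<title>GO enrichment: %s (%s)</title>",
            html_escape(result$meta$tissue), result$meta$namespace),
    "<style>table{border-collapse:collapse}td,th{border:1px solid #999;",
    "padding:2px 6px;font-family:sans-serif;font-size:90%}</style>",
    "</head>", "<body>",
    sprintf("<h1>GO enrichment in %s (%s)</h1>",
            html_escape(result$meta$tissue), result$meta$namespace),
    sprintf("<p>Background N = %d; effective input n = %d.</p>",
            result$meta$N, result$meta$n),
    "<table>",
    paste0("<tr>", paste0("<th>", RESULT_COLUMNS, "</th>", collapse = ""),
           "</tr>"),
    body_rows,
    "</table>", "</body>", "</html>")
  writeLines(doc, file)
  invisible(file)
}

#' @noRd
dot_quote <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

#' Write a GO-lineage graph in Graphviz DOT format
#'
#' Emits the lineage subgraph of the result's significant terms
#' (q <= `q_cutoff`): the significant terms plus all their ancestors up to
#' the namespace root. Significant nodes are drawn as filled boxes, ancestor
#' context nodes as plain ellipses; edges are labeled is_a / part_of. Node
#' and edge order is sorted by accession, so repeated runs yield
#' byte-identical DOT.
#'
#' @param graph the `go_ontology` the result was computed against.
#' @param result an `enrichment_result`.
#' @param file output path.
#' @param q_cutoff FDR threshold selecting the highlighted terms.
#' @export
write_lineage_dot <- function(graph, result, file, q_cutoff = 0.05) {
  sig <- significant_terms(result, q_cutoff)
  if (length(sig) == 0L) {
    gt_warn("no significant terms at this cutoff; writing an empty graph",
            "empty")
    writeLines(c("digraph go_lineage {", "}"), file)
    return(invisible(file))
  }
  sub <- lineage_subgraph(graph, sig)
  nodes <- sort(sub$id)
  node_lines <- vapply(nodes, function(id) {
    lab <- dot_quote(paste0(id, "\\n", sub$name[[id]]))
    if (id %in% sig)
      sprintf("  %s [label=%s, shape=box, style=filled, fillcolor=\"#9fc5e8\"];",
              dot_quote(id), lab)
    else
      sprintf("  %s [label=%s, shape=ellipse];", dot_quote(id), lab)
  }, character(1))
  e <- sub$edges[order(sub$edges$child, sub$edges$parent), , drop = FALSE]
  edge_lines <- sprintf("  %s -> %s [label=\"%s\"];",
                        vapply(e$child, dot_quote, character(1)),
                        vapply(e$parent, dot_quote, character(1)),
                        e$relation)
  writeLines(c("digraph go_lineage {",
               "  rankdir=BT;",
               node_lines, edge_lines, "}"), file)
  invisible(file)
}

#' Write a comparison summary
#'
#' Writes the three Venn partition counts on a machine-parseable comment
#' line (`# counts<TAB>left_only=..<TAB>shared=..<TAB>right_only=..`)
#' followed by the per-term membership table with both sides' statistics.
#'
#' @param cmp a `go_comparison` from [compare_results()].
#' @param file output path.
#' @export
write_comparison <- function(cmp, file) {
  d <- cmp$detail
  fmt <- function(x) ifelse(is.na(x), "NA", format_pvalue(x))
  fmt_i <- function(x) ifelse(is.na(x), "NA", as.character(x))
  rows <- sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s",
                  d$term_id, d$side,
                  fmt(d$left_p), fmt(d$left_q), fmt_i(d$left_k),
                  fmt_i(d$left_M),
                  fmt(d$right_p), fmt(d$right_q), fmt_i(d$right_k),
                  fmt_i(d$right_M))
  writeLines(c(
    sprintf("# left\t%s", cmp$left_label),
    sprintf("# right\t%s", cmp$right_label),
    sprintf("# q_cutoff\t%g", cmp$threshold),
    sprintf("# counts\tleft_only=%d\tshared=%d\tright_only=%d",
            length(cmp$left_only), length(cmp$shared),
            length(cmp$right_only)),
    paste(c("term_id", "side", "left_p", "left_q", "left_k", "left_M",
            "right_p", "right_q", "right_k", "right_M"), collapse = "\t"),
    rows), file)
  invisible(file)
}
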