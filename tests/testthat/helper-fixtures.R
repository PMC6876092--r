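# Hand-written mini-fixtures shared across tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

OBO_CHAIN <- c(
  "format-version: 1.2", "",
  "[Term]", "id: GO:0000001", "name: alpha",
  "namespace: biological_process", "",
  "[Term]", "id: GO:0000002", "name: beta",
  "namespace: biological_process", "is_a: GO:0000001 ! alpha", "",
  "[Term]", "id: GO:0000003", "name: gamma",
  "namespace: biological_process", "is_a: GO:0000002")

OBO_DIAMOND <- c(
  "format-version: 1.2", "",
  "[Term]", "id: GO:0000001", "name: a",
  "namespace: biological_process", "",
  "[Term]", "id: GO:0000002", "name: b",
  "namespace: biological_process", "is_a: GO:0000001", "",
  "[Term]", "id: GO:0000003", "name: c",
  "namespace: biological_process",
  "relationship: part_of GO:0000001", "",
  "[Term]", "id: GO:0000004", "name: d",
  "namespace: biological_process", "is_a: GO:0000002",
  "is_a: GO:0000003")

# one GAF 2.2 data row with sensible defaults
gaf_row <- function(gene, term, qualifier = "involved_in", evidence = "IEA",
                    aspect = "P", taxon = "taxon:9606") {
  paste(c("SYNDB", gene, gene, qualifier, term, "SYN:0000001", evidence,
          "", aspect, paste("protein", gene), "", "protein", taxon,
          "20260101", "SYNDB", "", ""), collapse = "\t")
}

gaf_text <- function(...) c("!gaf-version: 2.2", ...)

# a tiny paired GCT bundle: matrices in, lines out
gct_lines <- function(mat) {
  c("#1.2",
    sprintf("%d\t%d", nrow(mat), ncol(mat)),
    paste(c("Name", "Description", colnames(mat)), collapse = "\t"),
    vapply(seq_len(nrow(mat)), function(i)
      paste(c(rownames(mat)[i], "na", format(mat[i, ], trim = TRUE)),
            collapse = "\t"), character(1)))
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

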