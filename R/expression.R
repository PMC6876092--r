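# GTEx-style expression input and the dual-threshold expressed-gene filter.

# read one expression layer: GCT 1.2 ("#1.2" + dimensions line) or plain TSV
# with a leading gene-id column
#' @noRd
read_expression_layer <- function(file, what) {
  first <- readLines(file, n = 1L, warn = FALSE)
  if (identical(trimws(first), "#1.2")) {
    dims <- strsplit(readLines(file, n = 2L, warn = FALSE)[2], "\t")[[1]]
    df <- utils::read.delim(file, skip = 2L, header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 3L)
      gt_stop(sprintf("%s: GCT needs Name, Description and sample columns",
                      what), "parse")
    ids <- as.character(df[[1]])
    mat <- as.matrix(df[, -(1:2), drop = FALSE])
    if (nrow(mat) != as.integer(dims[1]) || ncol(mat) != as.integer(dims[2]))
      gt_stop(sprintf("%s: GCT dimensions line says %sx%s, found %dx%d",
                      what, dims[1], dims[2], nrow(mat), ncol(mat)), "parse")
  } else {
    df <- utils::read.delim(file, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    mat <- as.matrix(df[, -1, drop = FALSE])
  }
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(mat), nrow = nrow(mat)))) & !is.na(mat),
      arr.ind = TRUE)
    coord <- if (nrow(bad)) sprintf(" at gene %s, sample %s",
                                    ids[bad[1, 1]], colnames(mat)[bad[1, 2]])
             else ""
    gt_stop(sprintf("%s: non-numeric expression value%s", what, coord),
            "parse")
  }
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)
    gt_stop(sprintf("%s: missing value at gene %s, sample %s", what,
                    ids[bad[1, 1]], colnames(mat)[bad[1, 2]]), "parse")
  }
  rownames(mat) <- ids
  mat
}

#' Read a paired TPM / read-count expression matrix
#'
#' Reads two expression layers (TPM and unnormalized read counts) from GCT
#' 1.2 or plain TSV files, checks that they describe the same genes and
#' samples, and aligns the count matrix to the TPM matrix's row and column
#' order. Version-suffixed gene ids (trailing `.N`, Ensembl style) are
#' canonicalized by stripping the suffix.
#'
#' @param tpm_file path to the TPM layer (GCT or TSV).
#' @param counts_file path to the read-count layer (GCT or TSV).
#' @param quiet suppress log lines.
#' @return an object of class `expression_matrix`: list with numeric
#'   matrices `tpm` and `counts` (genes x samples, identical dimnames) and
#'   the vectors `gene_ids`, `sample_ids`.
#' @export
read_expression <- function(tpm_file, counts_file, quiet = FALSE) {
  tpm <- read_expression_layer(tpm_file, "TPM layer")
  counts <- read_expression_layer(counts_file, "count layer")

  strip_version <- function(m) {
    ids <- rownames(m)
    stripped <- sub("\\.[0-9]+$", "", ids)
    if (!identical(stripped, ids))
      gt_log(sprintf("stripped version suffixes from %d gene id(s)",
                     sum(stripped != ids)), quiet = quiet)
    rownames(m) <- stripped
    m
  }
  tpm <- strip_version(tpm); counts <- strip_version(counts)
  if (anyDuplicated(rownames(tpm)))
    gt_stop(sprintf("duplicate gene id after version stripping: %s",
                    rownames(tpm)[duplicated(rownames(tpm))][1]), "parse")

  mismatch <- function(a, b, what) {
    miss <- c(setdiff(a, b), setdiff(b, a))
    if (length(miss))
      gt_stop(sprintf("TPM and count layers disagree on %s: %s%s", what,
                      paste(utils::head(miss, 3), collapse = ", "),
                      if (length(miss) > 3) ", ..." else ""), "alignment")
  }
  mismatch(rownames(tpm), rownames(counts), "gene ids")
  mismatch(colnames(tpm), colnames(counts), "sample ids")
  counts <- counts[rownames(tpm), colnames(tpm), drop = FALSE]

  if (any(tpm < 0) || any(counts < 0))
    gt_stop("negative expression values are not allowed", "parse")
  if (any(abs(counts - round(counts)) > 1e-8))
    gt_stop("read counts must be whole numbers (unnormalized reads)", "parse")

  structure(list(tpm = tpm, counts = counts,
                 gene_ids = rownames(tpm), sample_ids = colnames(tpm)),
            class = "expression_matrix")
}

#' Read a sample-attributes table
#'
#' TSV mapping sample ids to tissue names, in the style of the GTEx sample
#' attributes file (`SAMPID` + `SMTSD` columns by default). Tissue strings
#' are whitespace-trimmed. Duplicate rows for a sample are accepted when they
#' agree; conflicting tissues for one sample are an integrity error.
#'
#' @param file path to the TSV.
#' @param tissue_column name of the tissue column (default `"SMTSD"`).
#' @param sample_column name of the sample-id column (default `"SAMPID"`).
#' @return named character vector of class `sample_tissue_map`
#'   (names = sample ids, values = tissue names).
#' @export
read_sample_attributes <- function(file, tissue_column = "SMTSD",
                                   sample_column = "SAMPID") {
  df <- utils::read.delim(file, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  for (col in c(sample_column, tissue_column))
    if (!col %in% names(df))
      gt_stop(sprintf("sample-attributes file lacks column '%s'", col),
              "format")
  ids <- trimws(as.character(df[[sample_column]]))
  tissues <- trimws(as.character(df[[tissue_column]]))
  pair <- !duplicated(paste0(ids, "\r", tissues))
  ids <- ids[pair]; tissues <- tissues[pair]
  if (anyDuplicated(ids))
    gt_stop(sprintf("sample %s maps to more than one tissue",
                    ids[duplicated(ids)][1]), "integrity")
  structure(setNames(tissues, ids), class = "sample_tissue_map")
}

#' Select the genes expressed in one tissue
#'
#' Applies the dual prevalence filter that defines the tissue background: a
#' gene is called expressed in the tissue iff, over that tissue's S samples,
#' BOTH (i) TPM >= `tpm_min` in at least `sample_fraction` of samples AND
#' (ii) read count >= `count_min` in at least `sample_fraction` of samples.
#' Defaults (TPM >= 0.1 and reads >= 6 in at least 20% of samples) follow the
#' GTEx expressed-gene convention. Fractions are compared as real numbers
#' (`>= sample_fraction`), not rounded sample counts.
#'
#' @param expr an `expression_matrix` from [read_expression()].
#' @param samples a `sample_tissue_map` from [read_sample_attributes()].
#' @param tissue tissue name to select.
#' @param tpm_min minimum TPM (default 0.1).
#' @param count_min minimum unnormalized read count (default 6).
#' @param sample_fraction minimum fraction of the tissue's samples that must
#'   pass each criterion (default 0.2).
#' @return an object of class `tissue_background`: list with `tissue`,
#'   `gene_ids` (the expressed set, i.e. the universe N of the enrichment
#'   test), `n_samples` and the `thresholds` actually applied.
#' @export
select_expressed_genes <- function(expr, samples, tissue,
                                   tpm_min = 0.1, count_min = 6,
                                   sample_fraction = 0.2) {
  if (tpm_min < 0 || count_min < 0)
    gt_stop("thresholds must be non-negative", "usage")
  if (!(sample_fraction > 0 && sample_fraction <= 1))
    gt_stop("sample_fraction must be in (0, 1]", "usage")
  tissue_samples <- names(samples)[unclass(samples) == tissue]
  if (length(tissue_samples) == 0L)
    gt_stop(sprintf("tissue '%s' has no samples in the attributes table",
                    tissue), "lookup")
  cols <- intersect(tissue_samples, expr$sample_ids)
  if (length(cols) == 0L)
    gt_stop(sprintf(
      "none of the %d sample(s) of tissue '%s' appear in the expression matrix",
      length(tissue_samples), tissue), "alignment")

  tpm_frac <- rowMeans(expr$tpm[, cols, drop = FALSE] >= tpm_min)
  cnt_frac <- rowMeans(expr$counts[, cols, drop = FALSE] >= count_min)
  keep <- tpm_frac >= sample_fraction & cnt_frac >= sample_fraction

  structure(list(tissue = tissue,
                 gene_ids = sort(expr$gene_ids[keep]),
                 n_samples = length(cols),
                 thresholds = c(tpm_min = tpm_min, count_min = count_min,
                                sample_fraction = sample_fraction)),
            class = "tissue_background")
}

#' Read a two-column gene-id mapping table
#'
#' TSV bridging expression gene ids (first column, e.g. Ensembl) to
#' annotation gene ids (second column, e.g. UniProtKB). A header line is
#' detected and skipped when its first field is not a gene id appearing
#' later; in practice supply a headerless two-column file.
#'
#' @param file path to the mapping TSV.
#' @return named character vector: names = expression ids, values =
#'   annotation ids.
#' @export
read_id_map <- function(file) {
  df <- utils::read.delim(file, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 2L)
    gt_stop("id-mapping table must have two tab-separated columns", "format")
  setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Translate a tissue background into annotation id space
#'
#' Applies an id-mapping table to the background's gene ids. Background genes
#' with no mapping entry are dropped from the universe with a logged count
#' (they cannot meet any annotation, so keeping them would inflate N).
#'
#' @param background a `tissue_background`.
#' @param id_map named character vector from [read_id_map()].
#' @param quiet suppress log lines.
#' @return the translated `tissue_background`.
#' @export
map_background_ids <- function(background, id_map, quiet = FALSE) {
  mapped <- id_map[background$gene_ids]
  n_drop <- sum(is.na(mapped))
  if (n_drop)
    gt_log(sprintf("dropped %d background gene(s) with no id mapping",
                   n_drop), quiet = quiet)
  background$gene_ids <- sort(unique(unname(mapped[!is.na(mapped)])))
  background$id_mapped <- TRUE
  background
}

#' Write a background gene list for audit
#'
#' One gene id per line, the exact universe the enrichment test used.
#'
#' @param background a `tissue_background`.
#' @param file output path.
#' @export
write_background <- function(background, file) {
  writeLines(background$gene_ids, file)
  invisible(file)
}

#' @export
print.tissue_background <- function(x, ...) {
  cat(sprintf(
    "tissue_background '%s': %d expressed genes over %d samples\n",
    x$tissue, length(x$gene_ids), x$n_samples))
  cat(sprintf("  thresholds: TPM >= %g and reads >= %g in >= %g%% of samples\n",
              x$thresholds["tpm_min"], x$thresholds["count_min"],
              100 * x$thresholds["sample_fraction"]))
  invisible(x)
}
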