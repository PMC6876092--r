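# The over-representation test: upper-tail hypergeometric p-values per GO
# term against the tissue background, with Benjamini-Hochberg FDR control
# across the tested term family.

#' Upper-tail hypergeometric p-value
#'
#' Probability of drawing at least `k` annotated genes when `n` genes are
#' sampled without replacement from a universe of `N` genes of which `M` are
#' annotated:
#' \deqn{P(X \ge k) = \sum_{x=k}^{\min(n,M)}
#'   \binom{M}{x}\binom{N-M}{n-x} / \binom{N}{n}.}
#' The sum is computed in log space (`lchoose` + log-sum-exp), so it is
#' numerically stable for large N. The upper summation limit is
#' `min(n, M)`: terms beyond it have a zero binomial factor. `k = 0` returns
#' exactly 1.
#'
#' @param N universe (background) size.
#' @param M number of background genes annotated to the term.
#' @param n number of genes drawn (effective input-list size).
#' @param k observed overlap between the input list and the term's genes.
#' @return the upper-tail probability, in (0, 1].
#' @examples
#' hypergeometric_pvalue(10, 4, 5, 3)  # 11/42
#' @export
hypergeometric_pvalue <- function(N, M, n, k) {
  for (v in c(N = N, M = M, n = n, k = k))
    if (length(v) != 1L || is.na(v) || v < 0 || v != round(v))
      gt_stop("N, M, n, k must be single non-negative integers", "domain")
  if (M > N) gt_stop("M <= N violated (more annotated genes than universe)",
                     "domain")
  if (n > N) gt_stop("n <= N violated (draw larger than universe)", "domain")
  if (k > min(n, M))
    gt_stop("k <= min(n, M) violated (overlap exceeds draw or annotation)",
            "domain")
  if (k == 0) return(1)
  x <- k:min(n, M)
  lw <- lchoose(M, x) + lchoose(N - M, n - x) - lchoose(N, n)
  m <- max(lw)
  min(1, exp(m + log(sum(exp(lw - m)))))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH FDR adjustment: with the p-values sorted ascending and m the
#' family size, the adjusted value at rank i is
#' `min over j >= i of p_(j) * m / j`, capped at 1. Values are returned in
#' the input order.
#'
#' @param p_values numeric vector of raw p-values, each in (0, 1].
#' @return numeric vector of adjusted values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L)
    gt_stop("p-value list must be non-empty", "domain")
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1))
    gt_stop("p-values must lie in (0, 1]", "domain")
  m <- length(p_values)
  o <- order(p_values)
  adj_sorted <- rev(cummin(rev(p_values[o] * m / seq_len(m))))
  adj_sorted <- pmin(adj_sorted, 1)
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

#' Read a user gene list
#'
#' Plain text, one gene identifier per line (the tool's input convention is
#' UniProtKB accessions). Lines starting with `#` and blank lines are
#' ignored; duplicates are collapsed.
#'
#' @param file path to the list, or a character vector of lines.
#' @return character vector of unique gene ids.
#' @export
read_gene_list <- function(file) {
  lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file))
    readLines(file, warn = FALSE) else unlist(strsplit(file, "\n", fixed = TRUE))
  lines <- trimws(lines)
  unique(lines[nzchar(lines) & !startsWith(lines, "#")])
}

#' Tissue-restricted GO over-representation test
#'
#' Runs the enrichment analysis of a gene list against a tissue-expressed
#' background:
#' \enumerate{
#'   \item the effective input set is the user list intersected with the
#'     background; genes outside the background are recorded in
#'     `dropped_genes` and n is the effective size (so k <= n <= N holds by
#'     construction);
#'   \item every term with at least one annotated background gene (M >= 1)
#'     and overlap k >= `min_overlap` is tested;
#'   \item p-values come from [hypergeometric_pvalue()] with N = background
#'     size;
#'   \item BH adjustment is applied across exactly the tested terms (the FDR
#'     family is one tissue, one namespace, one run).
#' }
#' Rows are sorted by ascending p-value, ties broken by GO accession, so
#' output is deterministic and diffable.
#'
#' @param genes character vector of input gene ids (duplicates collapsed).
#' @param background a `tissue_background`.
#' @param annotations a `go_annotation_set` (same id space as `background`;
#'   see [map_background_ids()] when expression and annotation ids differ).
#' @param graph the `go_ontology`, used to attach term names.
#' @param min_overlap smallest overlap k for a term to enter the tested
#'   family (default 1).
#' @param quiet suppress log lines.
#' @return an object of class `enrichment_result`: list with `table` (one
#'   row per tested term: `term_id`, `term_name`, `namespace`, `N`, `M`,
#'   `n`, `k`, `p_value`, `q_value`, `hit_genes` semicolon-joined) and
#'   `meta` (tissue, namespace, N, n, thresholds, `dropped_genes`,
#'   `n_underflow`, timestamp).
#' @export
run_enrichment <- function(genes, background, annotations, graph,
                           min_overlap = 1L, quiet = FALSE) {
  genes <- unique(genes)
  if (length(genes) == 0L)
    gt_stop("input gene list is empty", "usage")
  bg <- background$gene_ids
  if (length(bg) == 0L)
    gt_stop("tissue background is empty", "usage")

  effective <- intersect(genes, bg)
  dropped <- setdiff(genes, bg)
  dropped_genes <- data.frame(gene_id = dropped,
                              reason = rep("not_in_background",
                                           length(dropped)),
                              stringsAsFactors = FALSE)
  if (length(effective) == 0L)
    gt_stop(paste0("no input gene is in the tissue background; ",
                   "check that the gene list and expression matrix share an ",
                   "id space (an id-mapping table may be required)"), "usage")
  N <- length(bg)
  n <- length(effective)
  gt_log(sprintf("N = %d background genes; n = %d of %d input genes kept",
                 N, n, length(genes)), quiet = quiet)

  term_ids <- names(annotations$propagated)
  rows <- vector("list", length(term_ids))
  for (i in seq_along(term_ids)) {
    t <- term_ids[i]
    term_bg <- intersect(annotations$propagated[[t]], bg)
    M <- length(term_bg)
    if (M < 1L) next
    hits <- intersect(effective, term_bg)
    k <- length(hits)
    if (k < min_overlap) next
    rows[[i]] <- data.frame(term_id = t, M = M, k = k,
                            hit_genes = paste(sort(hits), collapse = ";"),
                            stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])

  meta <- list(tool = "gotissue",
               version = as.character(utils::packageVersion("gotissue")),
               tissue = background$tissue,
               namespace = annotations$namespace,
               N = N, n = n,
               n_input = length(genes),
               thresholds = background$thresholds,
               min_overlap = as.integer(min_overlap),
               propagate = annotations$propagate,
               dropped_genes = dropped_genes,
               n_underflow = 0L,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  if (is.null(rows) || nrow(rows) == 0L) {
    gt_warn("no term reaches the minimum overlap; result is empty", "empty")
    tab <- empty_result_table()
    return(structure(list(table = tab, meta = meta),
                     class = "enrichment_result"))
  }

  p <- vapply(seq_len(nrow(rows)),
              function(i) hypergeometric_pvalue(N, rows$M[i], n, rows$k[i]),
              numeric(1))
  under <- p < .Machine$double.xmin
  if (any(under)) {
    p[under] <- .Machine$double.xmin
    meta$n_underflow <- sum(under)
  }
  q <- bh_adjust(p)

  tab <- data.frame(term_id = rows$term_id,
                    term_name = unname(graph$name[rows$term_id]),
                    namespace = rep(annotations$namespace, nrow(rows)),
                    N = N, M = rows$M, n = n, k = rows$k,
                    p_value = p, q_value = q,
                    hit_genes = rows$hit_genes,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$p_value, tab$term_id), , drop = FALSE]
  rownames(tab) <- NULL
  gt_log(sprintf("tested %d terms; smallest q = %s", nrow(tab),
                 format_pvalue(min(tab$q_value))), quiet = quiet)
  structure(list(table = tab, meta = meta), class = "enrichment_result")
}

#' @noRd
empty_result_table <- function() {
  data.frame(term_id = character(0), term_name = character(0),
             namespace = character(0), N = integer(0), M = integer(0),
             n = integer(0), k = integer(0), p_value = numeric(0),
             q_value = numeric(0), hit_genes = character(0),
             stringsAsFactors = FALSE)
}

#' Significant terms of an enrichment result
#'
#' @param result an `enrichment_result`.
#' @param q_cutoff FDR threshold; terms with `q_value <= q_cutoff` are
#'   significant.
#' @return character vector of GO accessions.
#' @export
significant_terms <- function(result, q_cutoff = 0.05) {
  result$table$term_id[result$table$q_value <= q_cutoff]
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment_result: tissue '%s', %s; N = %d, n = %d, %d terms tested\n",
    x$meta$tissue, x$meta$namespace, x$meta$N, x$meta$n, nrow(x$table)))
  if (nrow(x$table)) {
    top <- utils::head(x$table[, c("term_id", "M", "k", "p_value", "q_value")],
                       5)
    top$p_value <- format_pvalue(top$p_value)
    top$q_value <- format_pvalue(top$q_value)
    print(top, row.names = FALSE)
  }
  invisible(x)
}
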