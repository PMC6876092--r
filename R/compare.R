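# Pairwise comparison of enrichment runs: the Venn-style three-way partition
# of their significant term sets.

#' Compare two enrichment results
#'
#' Thresholds both results at `q_cutoff` and partitions the union of their
#' significant terms into left-only, shared and right-only sets (the
#' three regions of a two-set Venn diagram). Shared terms keep both sides'
#' statistics side by side; values are never averaged. Both results must
#' come from the same GO namespace.
#'
#' @param left,right `enrichment_result` objects (e.g. two tissues, or a
#'   tissue-restricted run vs a whole-organism run).
#' @param q_cutoff FDR significance threshold applied to both sides
#'   (default 0.05).
#' @param left_label,right_label run identifiers; default to each run's
#'   tissue name.
#' @return an object of class `go_comparison`: list with `left_label`,
#'   `right_label`, `threshold`, the three accession sets `left_only`,
#'   `shared`, `right_only`, and `detail`, a data.frame with one row per
#'   term in the union carrying `side` and both sides' (p, q, k, M).
#' @export
compare_results <- function(left, right, q_cutoff = 0.05,
                            left_label = NULL, right_label = NULL) {
  if (!(q_cutoff > 0 && q_cutoff <= 1))
    gt_stop("q_cutoff must be in (0, 1]", "usage")
  if (!identical(left$meta$namespace, right$meta$namespace))
    gt_stop(sprintf("namespace mismatch: left is %s, right is %s",
                    left$meta$namespace, right$meta$namespace), "usage")
  if (is.null(left_label)) left_label <- left$meta$tissue
  if (is.null(right_label)) right_label <- right$meta$tissue

  lsig <- significant_terms(left, q_cutoff)
  rsig <- significant_terms(right, q_cutoff)
  if (length(lsig) == 0L || length(rsig) == 0L)
    gt_warn("at least one side has no significant terms at this cutoff",
            "empty")

  left_only <- sort(setdiff(lsig, rsig))
  shared <- sort(intersect(lsig, rsig))
  right_only <- sort(setdiff(rsig, lsig))

  all_terms <- c(left_only, shared, right_only)
  side <- c(rep("left_only", length(left_only)),
            rep("shared", length(shared)),
            rep("right_only", length(right_only)))
  pick <- function(res, terms, col) {
    idx <- match(terms, res$table$term_id)
    res$table[[col]][idx]
  }
  detail <- data.frame(term_id = all_terms, side = side,
                       left_p = pick(left, all_terms, "p_value"),
                       left_q = pick(left, all_terms, "q_value"),
                       left_k = pick(left, all_terms, "k"),
                       left_M = pick(left, all_terms, "M"),
                       right_p = pick(right, all_terms, "p_value"),
                       right_q = pick(right, all_terms, "q_value"),
                       right_k = pick(right, all_terms, "k"),
                       right_M = pick(right, all_terms, "M"),
                       stringsAsFactors = FALSE)
  detail <- detail[order(detail$term_id), , drop = FALSE]
  rownames(detail) <- NULL

  structure(list(left_label = left_label, right_label = right_label,
                 threshold = q_cutoff,
                 left_only = left_only, shared = shared,
                 right_only = right_only, detail = detail),
            class = "go_comparison")
}

#' @export
print.go_comparison <- function(x, ...) {
  cat(sprintf("go_comparison ('%s' vs '%s', q <= %g):\n",
              x$left_label, x$right_label, x$threshold))
  cat(sprintf("  left only: %d | shared: %d | right only: %d\n",
              length(x$left_only), length(x$shared), length(x$right_only)))
  invisible(x)
}
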