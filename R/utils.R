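# Internal helpers shared across modules: condition constructors, namespace
# normalization, logging, float formatting.

GO_NAMESPACES <- c("biological_process", "cellular_component",
                   "molecular_function")

# GAF aspect letter -> full namespace name
GO_ASPECT_MAP <- c(P = "biological_process",
                   C = "cellular_component",
                   F = "molecular_function")

# user-facing short codes
GO_SHORT_MAP <- c(BP = "biological_process",
                  CC = "cellular_component",
                  MF = "molecular_function")

#' @noRd
gt_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg,
                      class = c(paste0("gotissue_", class, "_error"),
                                "gotissue_error")))
}

#' @noRd
gt_warn <- function(msg, class = "generic") {
  warning(warningCondition(msg,
                           class = c(paste0("gotissue_", class, "_warning"),
                                     "gotissue_warning")))
}

#' @noRd
gt_log <- function(..., quiet = FALSE) {
  if (!isTRUE(quiet)) message("[gotissue] ", ...)
}

#' Normalize a GO namespace specifier
#'
#' Accepts short codes (`"BP"`, `"CC"`, `"MF"`), GAF aspect letters
#' (`"P"`, `"C"`, `"F"`) or full names, and returns the full namespace name.
#'
#' @param x character scalar naming a GO category.
#' @return one of `"biological_process"`, `"cellular_component"`,
#'   `"molecular_function"`.
#' @export
go_namespace <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    gt_stop("namespace must be a single character string", "usage")
  if (x %in% GO_NAMESPACES) return(x)
  up <- toupper(x)
  if (up %in% names(GO_SHORT_MAP)) return(unname(GO_SHORT_MAP[up]))
  if (up %in% names(GO_ASPECT_MAP)) return(unname(GO_ASPECT_MAP[up]))
  gt_stop(sprintf("unknown GO namespace '%s' (use BP, CC or MF)", x), "usage")
}

# fixed float formatting for p/q values: 6 significant digits, scientific
# notation below 1e-4 (what %.6g does), so serialized tables are diffable
#' @noRd
format_pvalue <- function(x) {
  vapply(x, function(v) sprintf("%.6g", v), character(1))
}

#' @noRd
is_go_accession <- function(x) {
  grepl("^GO:[0-9]{7}$", x)
}

# evaluate expr with a locally-seeded RNG, restoring global state after;
# makes every generator a pure function of its seed
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
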