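# OBO parsing and DAG queries over the Gene Ontology.
#
# The traversal graph uses is_a and part_of edges only (the standard
# convention for GO over-representation tools); regulates-family and other
# relationship types are ignored. Obsolete terms are parsed and flagged but
# never traversed. All queries are iterative, so graph depth is not limited
# by the recursion stack.

#' Parse an OBO ontology file into a GO DAG
#'
#' Reads an OBO 1.2/1.4 flat file and builds a directed acyclic graph of GO
#' terms. Only `[Term]` stanzas are interpreted; `[Typedef]` and other stanza
#' types are skipped. `is_a` and `relationship: part_of` lines become
#' child-to-parent traversal edges; every other relationship type is ignored.
#' Obsolete terms are kept (so their ids resolve) but carry no traversal
#' edges. `alt_id` lines populate a map from merged accessions to their
#' canonical term.
#'
#' Edges whose endpoints lie in different namespaces are dropped with a
#' warning, keeping the three GO categories (biological process, cellular
#' component, molecular function) independent.
#'
#' @param file path to an OBO file, or a character vector of OBO lines.
#' @return an object of class `go_ontology`: a list with elements
#'   `id`, `name`, `namespace`, `obsolete` (parallel vectors named by
#'   accession), `edges` (data.frame `child`, `parent`, `relation`),
#'   `parents` / `children` (adjacency lists) and `alt_id` (named character
#'   map alternate -> canonical).
#' @examples
#' obo <- c("format-version: 1.2", "",
#'   "[Term]", "id: GO:0000001", "name: root", "namespace: biological_process",
#'   "", "[Term]", "id: GO:0000002", "name: child",
#'   "namespace: biological_process", "is_a: GO:0000001 ! root")
#' g <- parse_obo(obo)
#' go_ancestors(g, "GO:0000002")
#' @export
parse_obo <- function(file) {
  lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file))
    readLines(file, warn = FALSE) else unlist(strsplit(file, "\n", fixed = TRUE))
  lines <- sub("\\s+$", "", lines)

  stanza_starts <- grep("^\\[", lines)
  if (length(stanza_starts) == 0L)
    gt_stop("no stanzas found: input is not an OBO document", "parse")

  # header (before first stanza) may set a default namespace
  header <- lines[seq_len(stanza_starts[1] - 1L)]
  default_ns <- sub("^default-namespace:\\s*", "",
                    grep("^default-namespace:", header, value = TRUE))
  default_ns <- if (length(default_ns)) default_ns[1] else NA_character_

  bounds <- c(stanza_starts, length(lines) + 1L)
  term_idx <- which(lines[stanza_starts] == "[Term]")
  if (length(term_idx) == 0L)
    gt_stop("OBO document contains no [Term] stanzas", "parse")

  n <- length(term_idx)
  ids <- character(n); names_ <- character(n); ns <- character(n)
  obsolete <- logical(n)
  edge_child <- character(0); edge_parent <- character(0)
  edge_rel <- character(0)
  alt_from <- character(0); alt_to <- character(0)

  for (j in seq_along(term_idx)) {
    s <- term_idx[j]
    body <- lines[seq(stanza_starts[s] + 1L, bounds[s + 1L] - 1L)]
    body <- body[nzchar(body)]
    # strip OBO trailing comments ("! ...")
    body <- sub("\\s*!.*$", "", body)

    get_vals <- function(key) {
      pat <- paste0("^", key, ":\\s*")
      sub(pat, "", grep(pat, body, value = TRUE))
    }
    id <- get_vals("id")
    if (length(id) != 1L || !nzchar(id))
      gt_stop(sprintf("[Term] stanza #%d is missing its id line", j), "parse")
    nm <- get_vals("name")
    nsj <- get_vals("namespace")
    if (length(nsj) == 0L) nsj <- default_ns
    if (length(nsj) != 1L || is.na(nsj) || !nsj %in% GO_NAMESPACES)
      gt_stop(sprintf(
        "stanza for %s has a missing or invalid namespace", id), "parse")
    obs <- any(grepl("^true$", get_vals("is_obsolete")))

    ids[j] <- id
    names_[j] <- if (length(nm)) nm[1] else ""
    ns[j] <- nsj
    obsolete[j] <- obs

    if (!obs) {
      isa <- get_vals("is_a")
      isa <- trimws(isa)
      rel <- get_vals("relationship")
      po <- trimws(sub("^part_of\\s+", "", grep("^part_of\\s", rel,
                                                value = TRUE)))
      tgt <- c(isa, po)
      if (length(tgt)) {
        edge_child <- c(edge_child, rep(id, length(tgt)))
        edge_parent <- c(edge_parent, tgt)
        edge_rel <- c(edge_rel, c(rep("is_a", length(isa)),
                                  rep("part_of", length(po))))
      }
    }
    av <- get_vals("alt_id")
    if (length(av)) {
      alt_from <- c(alt_from, av)
      alt_to <- c(alt_to, rep(id, length(av)))
    }
  }

  if (anyDuplicated(ids))
    gt_stop(sprintf("duplicate term id: %s",
                    ids[duplicated(ids)][1]), "parse")
  names(names_) <- ids; names(ns) <- ids; names(obsolete) <- ids
  alt_id <- structure(alt_to, names = alt_from)
  alt_id <- alt_id[!names(alt_id) %in% ids]

  # resolve edge targets through alt_id, then validate endpoints
  hit <- match(edge_parent, names(alt_id))
  edge_parent[!is.na(hit)] <- unname(alt_id[hit[!is.na(hit)]])
  unknown <- setdiff(edge_parent, ids)
  if (length(unknown))
    gt_stop(sprintf("edge target(s) not defined in this file: %s",
                    paste(utils::head(unknown, 3), collapse = ", ")), "parse")

  # drop edges into obsolete parents and cross-namespace edges
  keep <- !obsolete[edge_parent]
  cross <- ns[edge_child] != ns[edge_parent]
  if (any(cross & keep)) {
    gt_warn(sprintf("dropping %d cross-namespace edge(s)",
                    sum(cross & keep)), "parse")
    keep <- keep & !cross
  }
  edges <- data.frame(child = edge_child[keep], parent = edge_parent[keep],
                      relation = edge_rel[keep], stringsAsFactors = FALSE)
  edges <- unique(edges)
  edges <- edges[order(edges$child, edges$parent, edges$relation), ,
                 drop = FALSE]
  rownames(edges) <- NULL

  graph <- structure(list(
    id = ids, name = names_, namespace = ns, obsolete = obsolete,
    edges = edges,
    parents = split(edges$parent, factor(edges$child, levels = ids)),
    children = split(edges$child, factor(edges$parent, levels = ids)),
    alt_id = alt_id
  ), class = "go_ontology")

  cyc <- find_cycle(graph)
  if (!is.null(cyc))
    gt_stop(paste0("traversal edges contain a cycle: ",
                   paste(cyc, collapse = " -> ")), "integrity")
  graph
}

# Kahn's algorithm; returns NULL if acyclic, else one explicit cycle
#' @noRd
find_cycle <- function(graph) {
  indeg <- lengths(graph$children)   # edges parent<-child: in-degree as DAG sink
  # topological elimination over child->parent edges: eliminate nodes with no
  # remaining children
  remaining <- setNames(rep(TRUE, length(graph$id)), graph$id)
  deg <- lengths(graph$children)
  queue <- graph$id[deg == 0]
  parents <- graph$parents
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    remaining[v] <- FALSE
    for (p in parents[[v]]) {
      deg[p] <- deg[p] - 1L
      if (deg[p] == 0L) queue <- c(queue, p)
    }
  }
  if (!any(remaining)) return(NULL)
  # walk child links inside the residual set until a repeat gives a cycle
  start <- names(remaining)[remaining][1]
  path <- start; v <- start
  repeat {
    nxt <- intersect(graph$children[[v]], names(remaining)[remaining])[1]
    if (nxt %in% path)
      return(c(path[which(path == nxt):length(path)], nxt))
    path <- c(path, nxt); v <- nxt
  }
}

#' Resolve GO accessions to canonical term ids
#'
#' Canonicalizes ids through the `alt_id` map. Unknown ids raise a lookup
#' error; obsolete ids raise an obsolete-term error unless
#' `allow_obsolete = TRUE`.
#'
#' @param graph a `go_ontology`.
#' @param ids character vector of GO accessions.
#' @param allow_obsolete keep obsolete terms instead of erroring.
#' @return character vector of canonical accessions.
#' @export
resolve_term_id <- function(graph, ids, allow_obsolete = FALSE) {
  hit <- match(ids, names(graph$alt_id))
  ids[!is.na(hit)] <- unname(graph$alt_id[hit[!is.na(hit)]])
  unknown <- setdiff(ids, graph$id)
  if (length(unknown))
    gt_stop(sprintf("unknown GO term(s): %s",
                    paste(utils::head(unknown, 3), collapse = ", ")), "lookup")
  if (!allow_obsolete) {
    obs <- ids[graph$obsolete[ids]]
    if (length(obs))
      gt_stop(sprintf("term(s) are obsolete: %s",
                      paste(utils::head(obs, 3), collapse = ", ")), "obsolete")
  }
  ids
}

# iterative reachability over an adjacency list, excluding the start set
#' @noRd
reachable <- function(adj, start) {
  seen <- character(0)
  frontier <- unique(unlist(adj[start], use.names = FALSE))
  while (length(frontier)) {
    seen <- c(seen, frontier)
    frontier <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)),
                        seen)
  }
  unique(seen)
}

#' Ancestors of a GO term
#'
#' All terms reachable from `id` by repeatedly following is_a/part_of
#' child-to-parent edges; `id` itself is excluded.
#'
#' @inheritParams resolve_term_id
#' @param id a single GO accession (alternate ids are canonicalized).
#' @return character vector of ancestor accessions (unordered set).
#' @export
go_ancestors <- function(graph, id) {
  id <- resolve_term_id(graph, id)
  setdiff(reachable(graph$parents, id), id)
}

#' Descendants of a GO term
#'
#' All terms from which `id` is reachable along traversal edges; `id` itself
#' is excluded.
#'
#' @inheritParams go_ancestors
#' @return character vector of descendant accessions.
#' @export
go_descendants <- function(graph, id) {
  id <- resolve_term_id(graph, id)
  setdiff(reachable(graph$children, id), id)
}

#' Namespace root(s)
#'
#' Non-obsolete terms of a namespace with no traversal parents.
#'
#' @inheritParams resolve_term_id
#' @param namespace GO category (full name or BP/CC/MF).
#' @return character vector of root accessions (length 1 for a well-formed
#'   GO namespace).
#' @export
namespace_roots <- function(graph, namespace) {
  namespace <- go_namespace(namespace)
  cand <- graph$id[graph$namespace == namespace & !graph$obsolete]
  cand[lengths(graph$parents[cand]) == 0L]
}

#' Induced lineage subgraph
#'
#' The induced subgraph on `ids` together with all their ancestors. Edge
#' labels are preserved; the result contains the namespace root and is the
#' node set drawn by [write_lineage_dot()]. All ids must share one namespace.
#'
#' @inheritParams resolve_term_id
#' @param ids GO accessions to anchor the lineage view on.
#' @return a `go_ontology` restricted to `ids` and their ancestors.
#' @export
lineage_subgraph <- function(graph, ids) {
  ids <- unique(resolve_term_id(graph, ids))
  ns <- unique(graph$namespace[ids])
  if (length(ns) > 1L)
    gt_stop(paste0("lineage ids span multiple namespaces: ",
                   paste(ns, collapse = ", ")), "usage")
  nodes <- sort(union(ids, reachable(graph$parents, ids)))
  edges <- graph$edges[graph$edges$child %in% nodes &
                       graph$edges$parent %in% nodes, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(
    id = nodes,
    name = graph$name[nodes],
    namespace = graph$namespace[nodes],
    obsolete = graph$obsolete[nodes],
    edges = edges,
    parents = split(edges$parent, factor(edges$child, levels = nodes)),
    children = split(edges$child, factor(edges$parent, levels = nodes)),
    alt_id = graph$alt_id[graph$alt_id %in% nodes]
  ), class = "go_ontology")
}

#' @export
print.go_ontology <- function(x, ...) {
  cat(sprintf("go_ontology: %d terms (%d obsolete), %d edges\n",
              length(x$id), sum(x$obsolete), nrow(x$edges)))
  for (ns in intersect(GO_NAMESPACES, unique(x$namespace)))
    cat(sprintf("  %s: %d terms\n", ns, sum(x$namespace == ns)))
  invisible(x)
}
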