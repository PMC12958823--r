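#' Directed acyclic graphs over traits
#'
#' Minimal DAG container used for the trait-level causal network: a node list
#' and a 0/1 adjacency matrix with `amat[from, to] = 1` for a directed edge.
#' Acyclicity is enforced at construction and every structure-learning move.
#'
#' @param nodes character vector of node (trait) labels.
#' @param from,to equal-length character vectors of directed edges.
#' @return object of class `trait_dag`: list with `nodes`, `amat` and the
#'   cached topological order `topo`.
#' @examples
#' dag_from_edges(c("A", "B", "C"), from = c("A", "B"), to = c("B", "C"))
#' @export
dag_from_edges <- function(nodes, from = character(0), to = character(0)) {
  nodes <- as.character(nodes)
  stopifnot(!anyDuplicated(nodes), length(from) == length(to))
  amat <- matrix(0L, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  bad <- setdiff(c(from, to), nodes)
  if (length(bad)) stop("edge endpoints not in nodes: ", paste(bad, collapse = ", "))
  if (any(from == to)) stop("self-loops are not allowed")
  amat[cbind(from, to)] <- 1L
  topo <- dag_topo_order(amat)
  if (is.null(topo)) stop("edge set contains a directed cycle")
  structure(list(nodes = nodes, amat = amat, topo = topo), class = "trait_dag")
}

#' @rdname dag_from_edges
#' @export
empty_dag <- function(nodes) dag_from_edges(nodes)

# Topological order of an adjacency matrix, or NULL if cyclic.
dag_topo_order <- function(amat) {
  n <- nrow(amat)
  indeg <- colSums(amat)
  ord <- character(0)
  active <- rep(TRUE, n)
  for (step in seq_len(n)) {
    ready <- which(active & indeg == 0L)
    if (!length(ready)) return(NULL)
    i <- ready[1L]  # deterministic: first in node order
    ord <- c(ord, rownames(amat)[i])
    active[i] <- FALSE
    indeg <- indeg - amat[i, ]
  }
  ord
}

#' @export
print.trait_dag <- function(x, ...) {
  e <- dag_edges(x)
  cat("DAG:", length(x$nodes), "nodes,", nrow(e), "edges\n")
  if (nrow(e)) print(e)
  invisible(x)
}

#' Edge list of a DAG
#' @param dag a `trait_dag`.
#' @return data.frame with columns `from`, `to`.
#' @export
dag_edges <- function(dag) {
  idx <- which(dag$amat == 1L, arr.ind = TRUE)
  data.frame(from = rownames(dag$amat)[idx[, 1L]],
             to = colnames(dag$amat)[idx[, 2L]],
             stringsAsFactors = FALSE)[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

#' Number of edges in a DAG
#' @param dag a `trait_dag`.
#' @export
dag_n_edges <- function(dag) sum(dag$amat)

# Parents of node (index form used heavily by the scorers).
dag_parents <- function(dag, node) dag$nodes[dag$amat[, node] == 1L]

# TRUE if adding from -> to keeps the graph acyclic (i.e. no existing
# directed path to -> ... -> from).
dag_addition_ok <- function(amat, from, to) {
  if (from == to || amat[from, to] == 1L) return(FALSE)
  # BFS from `to` along directed edges; a hit on `from` would close a cycle
  seen <- colnames(amat) == to
  frontier <- to
  while (length(frontier)) {
    nxt <- colnames(amat)[colSums(amat[frontier, , drop = FALSE]) > 0 & !seen]
    if (from %in% nxt) return(FALSE)
    seen[colnames(amat) %in% nxt] <- TRUE
    frontier <- nxt
  }
  TRUE
}

dag_set_edge <- function(dag, from, to, value) {
  dag$amat[from, to] <- value
  dag$topo <- dag_topo_order(dag$amat)
  stopifnot(!is.null(dag$topo))
  dag
}

#' Write a DAG as a Graphviz DOT file or an edge-list CSV
#'
#' @param dag a `trait_dag`.
#' @param path output file path.
#' @param labels optional named numeric vector (`"from->to"`) of edge labels,
#'   e.g. structural coefficients or bootstrap strengths.
#' @export
write_dag_dot <- function(dag, path, labels = NULL) {
  e <- dag_edges(dag)
  lab <- ""
  if (nrow(e)) {
    key <- paste0(e$from, "->", e$to)
    lab <- vapply(seq_len(nrow(e)), function(i) {
      l <- if (!is.null(labels) && key[i] %in% names(labels))
        sprintf(" [label=\"%.3f\"]", labels[[key[i]]]) else ""
      sprintf("  \"%s\" -> \"%s\"%s;", e$from[i], e$to[i], l)
    }, "")
  }
  writeLines(c("digraph traits {",
               sprintf("  \"%s\";", dag$nodes),
               lab, "}"), path)
  invisible(path)
}

#' @rdname write_dag_dot
#' @export
write_dag_csv <- function(dag, path) {
  utils::write.csv(dag_edges(dag), path, row.names = FALSE)
  invisible(path)
}

#' Read a DAG from an edge-list CSV
#' @param path CSV with `from`/`to` columns.
#' @param nodes node set; default the union of endpoints.
#' @export
read_dag_csv <- function(path, nodes = NULL) {
  e <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("from", "to") %in% names(e)))
  if (is.null(nodes)) nodes <- unique(c(e$from, e$to))
  dag_from_edges(nodes, e$from, e$to)
}
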