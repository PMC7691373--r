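#' Construct a bipartite graph
#'
#' A bipartite graph holds two disjoint node sets `U` and `V` and a set of
#' undirected edges, each joining one `U` node and one `V` node. Node
#' identifiers are opaque strings; node order is first-seen and is preserved
#' everywhere so that downstream rankings are reproducible.
#'
#' @param edges a two-column `data.frame` or matrix; column 1 holds `U`-side
#'   identifiers, column 2 `V`-side identifiers. Duplicate rows are collapsed.
#' @param u_nodes,v_nodes optional character vectors fixing the node sets and
#'   their order; must cover every endpoint in `edges`. Nodes without edges
#'   are allowed (isolated nodes occur in sparse real data).
#' @return an object of class `bipartite_graph` with components `u`, `v`
#'   (ordered node identifiers) and `edges` (a `data.frame` with columns
#'   `u`, `v`).
#' @examples
#' g <- bipartite_graph(data.frame(u = c("A", "A", "B"), v = c("h", "i", "h")))
#' g
#' @export
bipartite_graph <- function(edges, u_nodes = NULL, v_nodes = NULL) {
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L)
    stop_arg("`edges` must have at least two columns (U side, V side)")
  eu <- as.character(edges[[1L]])
  ev <- as.character(edges[[2L]])
  if (anyNA(eu) || anyNA(ev) || any(eu == "") || any(ev == ""))
    stop_arg("edge endpoints must be non-missing, non-empty identifiers")
  keep <- !duplicated(paste(eu, ev, sep = "\r"))
  eu <- eu[keep]; ev <- ev[keep]

  u <- u_nodes %||% unique(eu)
  v <- v_nodes %||% unique(ev)
  u <- as.character(u); v <- as.character(v)
  if (anyDuplicated(u) || anyDuplicated(v))
    stop_arg("node sets must not contain duplicated identifiers")
  bad <- intersect(u, v)
  if (length(bad))
    stop_arg("graph is not bipartite: node(s) appear on both sides: ",
             paste(utils::head(bad, 5L), collapse = ", "))
  if (!all(eu %in% u)) stop_arg("edge endpoint(s) missing from `u_nodes`")
  if (!all(ev %in% v)) stop_arg("edge endpoint(s) missing from `v_nodes`")

  adj_u <- split(ev, factor(eu, levels = u))
  adj_v <- split(eu, factor(ev, levels = v))
  structure(
    list(u = u, v = v,
         edges = data.frame(u = eu, v = ev, stringsAsFactors = FALSE),
         adj_u = adj_u, adj_v = adj_v),
    class = "bipartite_graph")
}

#' @export
print.bipartite_graph <- function(x, ...) {
  cat("Bipartite graph: |U| =", length(x$u),
      " |V| =", length(x$v),
      " |E| =", nrow(x$edges), "\n")
  invisible(x)
}

#' @rdname bipartite_graph
#' @param g a `bipartite_graph`.
#' @export
u_nodes <- function(g) g$u

#' @rdname bipartite_graph
#' @export
v_nodes <- function(g) g$v

#' @rdname bipartite_graph
#' @export
n_edges <- function(g) nrow(g$edges)

#' Bipartite neighbourhood and degree
#'
#' `bipartite_neighbors()` returns the nodes adjacent to `node` in the
#' bipartite graph (always on the opposite side); `bipartite_degree()`
#' returns named degrees for one side or for all nodes.
#'
#' @param g a `bipartite_graph`.
#' @param node a node identifier from either side.
#' @return for `bipartite_neighbors()`, a character vector; for
#'   `bipartite_degree()`, a named integer vector.
#' @export
bipartite_neighbors <- function(g, node) {
  if (node %in% g$u) return(as.character(g$adj_u[[node]]))
  if (node %in% g$v) return(as.character(g$adj_v[[node]]))
  stop_arg("unknown node: ", node)
}

#' @rdname bipartite_neighbors
#' @param side `"u"`, `"v"` or `"both"`.
#' @export
bipartite_degree <- function(g, side = c("both", "u", "v")) {
  side <- match.arg(side)
  du <- lengths(g$adj_u)
  dv <- lengths(g$adj_v)
  switch(side, u = du, v = dv, both = c(du, dv))
}

# TRUE for each (u, v) pair that is an edge of g
is_edge <- function(g, u, v) {
  paste(u, v, sep = "\r") %in% paste(g$edges$u, g$edges$v, sep = "\r")
}

#' Read a bipartite edge list
#'
#' Reads a two-column edge list (one edge per line; column 1 = side `U`,
#' column 2 = side `V`). Lines starting with `#` are comments; the delimiter
#' is auto-detected among tab and comma unless given. Duplicate lines are
#' collapsed; node order is first-seen.
#'
#' @param path file path.
#' @param delimiter field separator; `NULL` (default) auto-detects.
#' @return a [bipartite_graph].
#' @export
read_bipartite_edgelist <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop_arg("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx))
    return(bipartite_graph(data.frame(u = character(), v = character())))
  body <- lines[idx]
  if (is.null(delimiter))
    delimiter <- if (grepl("\t", body[[1L]])) "\t" else ","
  parts <- strsplit(body, delimiter, fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L))
    stop_arg("malformed edge list: line ", idx[which(nf < 2L)[1L]],
             " has fewer than 2 fields")
  eu <- trimws(vapply(parts, `[[`, "", 1L))
  ev <- trimws(vapply(parts, `[[`, "", 2L))
  bipartite_graph(data.frame(u = eu, v = ev, stringsAsFactors = FALSE))
}

#' Write a bipartite edge list
#'
#' Inverse of [read_bipartite_edgelist()]: one edge per line, two columns.
#'
#' @param g a `bipartite_graph`.
#' @param path output file path.
#' @param delimiter field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_bipartite_edgelist <- function(g, path, delimiter = "\t") {
  writeLines(paste(g$edges$u, g$edges$v, sep = delimiter), path)
  invisible(path)
}
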