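#' Weighted one-mode projection
#'
#' Projects a bipartite graph onto one of its sides. Two same-side nodes are
#' joined iff they share at least one neighbour on the other side, and the
#' edge weight `WP(A, B)` is the number of shared neighbours. Every projected
#' edge is a "pattern": a same-side pair for which a similar connection
#' already exists in the bipartite graph. A simple (unweighted) projection is
#' recovered by ignoring the weights.
#'
#' @param g a [bipartite_graph].
#' @param side which side to project, `"u"` (default) or `"v"`.
#' @return an object of class `projected_graph` with components `nodes` (all
#'   nodes of the projected side, first-seen order, including nodes isolated
#'   in the projection), `side`, `edges` (a `data.frame` with columns `a`,
#'   `b`, `wp`; pairs canonicalised so `a < b` lexicographically), `adj`
#'   (adjacency list of the unweighted skeleton) and `ig` (the skeleton as an
#'   igraph object, used for distances and clustering coefficients).
#' @examples
#' g <- bipartite_graph(data.frame(u = c("A", "A", "B", "B"),
#'                                 v = c("x", "y", "x", "y")))
#' project_weighted(g)$edges  # WP(A,B) = 2
#' @export
project_weighted <- function(g, side = c("u", "v")) {
  side <- match.arg(side)
  if (!inherits(g, "bipartite_graph")) stop_arg("`g` must be a bipartite_graph")
  nodes <- if (side == "u") g$u else g$v
  other <- if (side == "u") g$v else g$u
  ei <- match(if (side == "u") g$edges$u else g$edges$v, nodes)
  ej <- match(if (side == "u") g$edges$v else g$edges$u, other)

  if (length(ei) && length(nodes)) {
    inc <- Matrix::sparseMatrix(i = ei, j = ej, x = 1,
                                dims = c(length(nodes), length(other)))
    w <- Matrix::tcrossprod(inc)
    tri <- Matrix::summary(w)
    tri <- tri[tri$i < tri$j & tri$x > 0, , drop = FALSE]
    a <- nodes[tri$i]; b <- nodes[tri$j]
    # canonical unordered pair: lexicographically sorted identifiers
    ed <- data.frame(a = pmin(a, b), b = pmax(a, b),
                     wp = as.integer(tri$x), stringsAsFactors = FALSE)
    ed <- ed[order(ed$a, ed$b), , drop = FALSE]
    rownames(ed) <- NULL
  } else {
    ed <- data.frame(a = character(), b = character(), wp = integer(),
                     stringsAsFactors = FALSE)
  }

  adj <- split(c(ed$b, ed$a), factor(c(ed$a, ed$b), levels = nodes))
  ig <- igraph::graph_from_data_frame(
    ed[, c("a", "b")], directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  wp <- ed$wp
  names(wp) <- pair_key(ed$a, ed$b)
  structure(list(nodes = nodes, side = side, edges = ed, adj = adj,
                 wp = wp, ig = ig),
            class = "projected_graph")
}

#' @export
print.projected_graph <- function(x, ...) {
  cat("Weighted one-mode projection (side ", toupper(x$side), "): ",
      length(x$nodes), " nodes, ", nrow(x$edges), " patterns\n", sep = "")
  invisible(x)
}

check_pg_node <- function(pg, z) {
  if (!z %in% pg$nodes) stop_arg("unknown node in projected graph: ", z)
}

#' Projected-graph neighbourhood, weight and degree
#'
#' Structural accessors on the unweighted skeleton of a projection:
#' neighbours, degree, and the shared-neighbour weight of a stored edge.
#'
#' @param pg a `projected_graph`.
#' @param node,a,b node identifiers.
#' @return `projected_neighbors()`: character vector; `projected_degree()`:
#'   named integer vector over all nodes; `projection_weight()`: the integer
#'   `WP(a, b)`, or 0 when the pair is not a pattern.
#' @export
projected_neighbors <- function(pg, node) {
  check_pg_node(pg, node)
  as.character(pg$adj[[node]])
}

#' @rdname projected_neighbors
#' @export
projected_degree <- function(pg) lengths(pg$adj)

#' @rdname projected_neighbors
#' @export
projection_weight <- function(pg, a, b) {
  w <- unname(pg$wp[pair_key(a, b)])
  ifelse(is.na(w), 0L, as.integer(w))
}

#' Local clustering coefficient
#'
#' Clustering coefficient of a node on the unweighted skeleton of the
#' projection: `2 t_z / (d_z (d_z - 1))` where `t_z` is the number of
#' triangles through `z` and `d_z` its degree. Nodes of degree below 2 admit
#' no triangle; their coefficient is defined as 0.
#'
#' @param pg a `projected_graph`.
#' @param z a node of `pg`.
#' @return a number in `[0, 1]`.
#' @export
clustering_coefficient <- function(pg, z) {
  check_pg_node(pg, z)
  unname(clustering_all(pg)[z])
}

# local clustering for every node at once (degree < 2 -> 0)
clustering_all <- function(pg) {
  cc <- suppressWarnings(
    igraph::transitivity(pg$ig, type = "local", isolates = "zero"))
  cc[is.na(cc)] <- 0
  names(cc) <- pg$nodes
  cc
}

#' Shortest distance in the projected graph
#'
#' Unweighted hop count between two nodes of the projection; `Inf` when they
#' lie in different components, 0 iff `a == b`.
#'
#' @param pg a `projected_graph`.
#' @param a,b nodes of `pg`.
#' @return a non-negative integer, or `Inf`.
#' @export
shortest_distance <- function(pg, a, b) {
  check_pg_node(pg, a); check_pg_node(pg, b)
  if (a == b) return(0)
  if (b %in% pg$adj[[a]]) return(1)
  as.numeric(igraph::distances(pg$ig, v = a, to = b)[1L, 1L])
}

# full distance matrix, used by the fitting routine
distance_matrix <- function(pg) {
  d <- igraph::distances(pg$ig)
  dimnames(d) <- list(pg$nodes, pg$nodes)
  d
}

#' Patterns covered by a cross-side node pair
#'
#' For a candidate pair `(a, i)` with `a` on the projected side and `i` on
#' the other side, the covered patterns are the projected edges `{a, C}` such
#' that `C` is both a projected neighbour of `a` and a bipartite neighbour of
#' `i`. Each covered pattern is existing evidence that the edge `(a, i)` may
#' form.
#'
#' @param g the [bipartite_graph] that `pg` projects.
#' @param pg the [project_weighted()] projection of `g`.
#' @param a a node of the projected side.
#' @param i a node of the opposite side.
#' @return a `data.frame` with columns `a`, `b`: one canonicalised unordered
#'   pair per covered pattern (zero rows when none is covered).
#' @export
patterns_covered <- function(g, pg, a, i) {
  proj_side <- if (pg$side == "u") g$u else g$v
  other_side <- if (pg$side == "u") g$v else g$u
  if (!a %in% proj_side)
    stop_arg("node ", a, " is not on the projected side")
  if (!i %in% other_side)
    stop_arg("node ", i, " is not on the side opposite the projection")
  nb_i <- if (pg$side == "u") g$adj_v[[i]] else g$adj_u[[i]]
  cov <- intersect(pg$adj[[a]], nb_i)
  if (!length(cov))
    return(data.frame(a = character(), b = character(),
                      stringsAsFactors = FALSE))
  data.frame(a = pmin(a, cov), b = pmax(a, cov), stringsAsFactors = FALSE)
}

#' Projected-graph I/O
#'
#' Writes a projection as a three-column TSV (`a`, `b`, `wp`) and reads it
#' back. Reading reconstructs the skeleton only from the listed edges, so
#' nodes isolated in the projection are not recovered.
#'
#' @param pg a `projected_graph`.
#' @param path file path.
#' @param side side label to attach on read.
#' @return `write_projected_edgelist()`: `path`, invisibly;
#'   `read_projected_edgelist()`: a `projected_graph`.
#' @export
write_projected_edgelist <- function(pg, path) {
  utils::write.table(pg$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_projected_edgelist
#' @export
read_projected_edgelist <- function(path, side = "u") {
  ed <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "integer"))
  names(ed) <- c("a", "b", "wp")
  nodes <- unique(c(rbind(ed$a, ed$b)))
  ed2 <- data.frame(a = pmin(ed$a, ed$b), b = pmax(ed$a, ed$b), wp = ed$wp,
                    stringsAsFactors = FALSE)
  ed2 <- ed2[order(ed2$a, ed2$b), , drop = FALSE]
  rownames(ed2) <- NULL
  adj <- split(c(ed2$b, ed2$a), factor(c(ed2$a, ed2$b), levels = nodes))
  ig <- igraph::graph_from_data_frame(
    ed2[, c("a", "b")], directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  wp <- ed2$wp
  names(wp) <- pair_key(ed2$a, ed2$b)
  structure(list(nodes = nodes, side = side, edges = ed2, adj = adj,
                 wp = wp, ig = ig),
            class = "projected_graph")
}
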