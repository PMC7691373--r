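#' Generate a synthetic bipartite graph
#'
#' Random bipartite graphs with controlled size and degree heterogeneity,
#' spanning the regimes of real two-mode data (tens to thousands of nodes,
#' average degrees from near 1 to the tens). Two degree models:
#'
#' * `"uniform"` — `n_edges` pairs drawn uniformly without replacement from
#'   `U x V`.
#' * `"preferential"` — edges added sequentially, endpoints drawn with
#'   probability proportional to (current degree + 1); produces the
#'   right-skewed, hub-dominated degree distributions typical of drug-target
#'   and user-item data.
#'
#' Isolated nodes are permitted (sparse real networks have them);
#' `min_degree_one = TRUE` first assigns every node one incident edge via a
#' random spanning assignment, then fills the remainder with the chosen
#' model.
#'
#' @param n_u,n_v side sizes.
#' @param n_edges number of distinct edges (`<= n_u * n_v`).
#' @param degree_model `"uniform"` or `"preferential"`.
#' @param seed integer RNG seed; identical seeds give identical graphs.
#' @param min_degree_one force minimum degree 1 on both sides (requires
#'   `n_edges >= max(n_u, n_v)`).
#' @return a [bipartite_graph] with node identifiers `u1..`, `v1..`.
#' @examples
#' g <- generate_bipartite(18, 14, 89, seed = 42)  # social-event scale
#' mean(bipartite_degree(g))                        # 2 * 89 / 32
#' @export
generate_bipartite <- function(n_u, n_v, n_edges,
                               degree_model = c("uniform", "preferential"),
                               seed = NULL, min_degree_one = FALSE) {
  degree_model <- match.arg(degree_model)
  if (n_u < 1 || n_v < 1) stop_arg("both sides need at least one node")
  if (n_edges < 0 || n_edges > n_u * n_v)
    stop_arg("`n_edges` must lie in [0, n_u * n_v]")
  if (min_degree_one && n_edges < max(n_u, n_v))
    stop_arg("min_degree_one needs n_edges >= max(n_u, n_v)")
  un <- paste0("u", seq_len(n_u))
  vn <- paste0("v", seq_len(n_v))
  with_seed(seed, {
    taken <- logical(n_u * n_v)  # index (i-1)*n_v + j
    ei <- integer(0); ej <- integer(0)
    add_edge <- function(i, j) {
      ei[[length(ei) + 1L]] <<- i
      ej[[length(ej) + 1L]] <<- j
      taken[(i - 1L) * n_v + j] <<- TRUE
    }
    if (min_degree_one) {
      # spanning assignment: pair every node of the larger side with a
      # cycle over the smaller side, in random order
      iu <- sample.int(n_u); jv <- sample.int(n_v)
      n0 <- max(n_u, n_v)
      for (t in seq_len(n0)) {
        i <- iu[(t - 1L) %% n_u + 1L]
        j <- jv[(t - 1L) %% n_v + 1L]
        if (!taken[(i - 1L) * n_v + j]) add_edge(i, j)
      }
    }
    remaining <- n_edges - length(ei)
    if (degree_model == "uniform") {
      free <- which(!taken)
      pick <- free[sample.int(length(free), remaining)]
      add_i <- (pick - 1L) %/% n_v + 1L
      add_j <- (pick - 1L) %% n_v + 1L
      ei <- c(ei, add_i); ej <- c(ej, add_j)
    } else {
      du <- tabulate(ei, n_u); dv <- tabulate(ej, n_v)
      while (remaining > 0L) {
        i <- sample.int(n_u, 1L, prob = du + 1)
        j <- sample.int(n_v, 1L, prob = dv + 1)
        if (!taken[(i - 1L) * n_v + j]) {
          add_edge(i, j)
          du[i] <- du[i] + 1L; dv[j] <- dv[j] + 1L
          remaining <- remaining - 1L
        }
      }
    }
    bipartite_graph(data.frame(u = un[ei], v = vn[ej],
                               stringsAsFactors = FALSE),
                    u_nodes = un, v_nodes = vn)
  })
}

#' Hold out a probe set of edges
#'
#' Removes a random fraction of the edges as the probe (test) set,
#' returning the training graph (same node sets, probe edges deleted) and
#' the probe edges. Training and probe partition the edge set.
#'
#' @param g a [bipartite_graph].
#' @param fraction probe fraction, strictly between 0 and 1 (0.1 gives the
#'   standard 90/10 split); `ceiling(fraction * |E|)` edges are held out.
#' @param seed integer RNG seed.
#' @return list with `train` (a `bipartite_graph`) and `probe`
#'   (`data.frame` of held-out edges).
#' @export
plant_probe <- function(g, fraction, seed = NULL) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop_arg("`fraction` must lie strictly between 0 and 1")
  m <- n_edges(g)
  n_hold <- ceiling(fraction * m)
  hold <- with_seed(seed, sample.int(m, n_hold))
  list(train = bipartite_graph(g$edges[-hold, , drop = FALSE],
                               u_nodes = g$u, v_nodes = g$v),
       probe = g$edges[hold, , drop = FALSE])
}
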