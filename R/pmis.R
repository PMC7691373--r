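#' Total pattern weights
#'
#' A pattern is an edge of the projected graph. Its total weight combines
#' three kinds of evidence that the underlying connection style repeats:
#' `W_t(A, B) = PE(A, B) + S_MI(A, B) + WP(A, B)` — potential energy,
#' mutual-information likelihood, and the shared-neighbour count. The three
#' components live on different scales (WP is an integer >= 1, PE is small,
#' MI is in bits) and are summed raw, exactly as the score is defined; all
#' three are kept in the output for transparency. `W_t` may be negative when
#' the MI term is strongly negative.
#'
#' @param g a [bipartite_graph].
#' @param pg the [project_weighted()] projection of `g`.
#' @param params a [pe_params()] object.
#' @param ctx an [mi_context()] built on `pg`; built on the fly when `NULL`.
#' @return a `data.frame` of class `pattern_weights` with one row per
#'   pattern and columns `a`, `b`, `pe`, `mi`, `wp`, `total`; the projection
#'   is attached as attribute `pg`.
#' @export
pattern_weights <- function(g, pg, params = pe_params(), ctx = NULL) {
  if (!inherits(g, "bipartite_graph")) stop_arg("`g` must be a bipartite_graph")
  if (!inherits(pg, "projected_graph")) stop_arg("`pg` must be a projected_graph")
  side_nodes <- if (pg$side == "u") g$u else g$v
  if (!identical(pg$nodes, side_nodes))
    stop_arg("`pg` is not the ", pg$side, "-side projection of `g` ",
             "(node sets disagree)")
  if (is.null(ctx)) ctx <- mi_context(pg)
  ed <- pg$edges
  n <- nrow(ed)
  cc <- clustering_all(pg)
  pe <- numeric(n); mi <- numeric(n)
  for (r in seq_len(n)) {
    a <- ed$a[r]; b <- ed$b[r]
    cn <- intersect(pg$adj[[a]], pg$adj[[b]])
    s <- if (length(cn)) sum(cc[cn]) else params$no_cn_constant
    # patterns are adjacent pairs: sd = 1
    pe[r] <- length(pg$adj[[a]]) * length(pg$adj[[b]]) * s
    mi[r] <- mi_score(ctx, a, b)
  }
  out <- data.frame(a = ed$a, b = ed$b, pe = pe, mi = mi,
                    wp = ed$wp, total = pe + mi + ed$wp,
                    stringsAsFactors = FALSE)
  attr(out, "pg") <- pg
  attr(out, "params") <- params
  class(out) <- c("pattern_weights", "data.frame")
  out
}

weights_lookup <- function(weights, col) {
  x <- weights[[col]]
  names(x) <- pair_key(weights$a, weights$b)
  x
}

#' PMIS score of a cross-side node pair
#'
#' The potential energy–mutual information similarity: the sum of the total
#' weights of all patterns covered by the pair `(a, i)` (see
#' [patterns_covered()]); 0 when no pattern is covered. Higher PMIS means a
#' likelier future edge.
#'
#' @param g a [bipartite_graph].
#' @param weights a [pattern_weights()] table (carries its projection).
#' @param a a node of the projected side.
#' @param i a node of the opposite side.
#' @return a real score.
#' @export
pmis_score <- function(g, weights, a, i) {
  pg <- attr(weights, "pg")
  cov <- patterns_covered(g, pg, a, i)
  if (!nrow(cov)) return(0)
  tot <- weights_lookup(weights, "total")
  sum(tot[pair_key(cov$a, cov$b)])
}

#' Rank candidate links by PMIS
#'
#' Scores cross-side candidate pairs and returns them sorted by descending
#' PMIS. By default every pair `(a, i)` absent from the bipartite edge set
#' is a candidate — the method scores all disconnected pairs, not a
#' pre-filtered candidate set. Alongside the PMIS total, the per-component
#' sums over covered patterns (`pe_sum`, `mi_sum`, `wp_sum`) are reported.
#' Ties are broken by first-seen node order (projected side, then opposite
#' side), making the ranking total and deterministic.
#'
#' @param g a [bipartite_graph].
#' @param weights a [pattern_weights()] table.
#' @param candidates optional two-column `data.frame` (projected-side node,
#'   opposite-side node); every row must be a non-edge of `g`.
#' @return a `data.frame` with columns `u`, `v`, `pmis`, `pe_sum`, `mi_sum`,
#'   `wp_sum` in ranked order. Columns `u`/`v` always refer to the original
#'   sides of `g`, whichever side was projected.
#' @export
rank_candidates <- function(g, weights, candidates = NULL) {
  pg <- attr(weights, "pg")
  proj_u <- pg$side == "u"
  proj_side <- if (proj_u) g$u else g$v
  other_side <- if (proj_u) g$v else g$u

  if (is.null(candidates)) {
    all_pairs <- expand.grid(a = proj_side, i = other_side,
                             KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    eu <- if (proj_u) g$edges$u else g$edges$v
    ev <- if (proj_u) g$edges$v else g$edges$u
    keep <- !(paste(all_pairs$a, all_pairs$i, sep = "\r") %in%
                paste(eu, ev, sep = "\r"))
    candidates <- all_pairs[keep, , drop = FALSE]
  } else {
    candidates <- data.frame(a = as.character(candidates[[1L]]),
                             i = as.character(candidates[[2L]]),
                             stringsAsFactors = FALSE)
    if (!all(candidates$a %in% proj_side))
      stop_arg("candidate column 1 must hold projected-side nodes")
    if (!all(candidates$i %in% other_side))
      stop_arg("candidate column 2 must hold nodes of the opposite side")
    uu <- if (proj_u) candidates$a else candidates$i
    vv <- if (proj_u) candidates$i else candidates$a
    if (any(is_edge(g, uu, vv)))
      stop_arg("candidate pair(s) already present as edges of the graph")
  }

  n <- nrow(candidates)
  tot <- weights_lookup(weights, "total")
  pe <- weights_lookup(weights, "pe")
  mi <- weights_lookup(weights, "mi")
  wp <- weights_lookup(weights, "wp")
  adj_other <- if (proj_u) g$adj_v else g$adj_u

  pmis <- pe_s <- mi_s <- wp_s <- numeric(n)
  for (r in seq_len(n)) {
    a <- candidates$a[r]
    cov <- intersect(pg$adj[[a]], adj_other[[candidates$i[r]]])
    if (length(cov)) {
      k <- pair_key(a, cov)
      pmis[r] <- sum(tot[k]); pe_s[r] <- sum(pe[k])
      mi_s[r] <- sum(mi[k]);  wp_s[r] <- sum(wp[k])
    }
  }

  out <- data.frame(
    u = if (proj_u) candidates$a else candidates$i,
    v = if (proj_u) candidates$i else candidates$a,
    pmis = pmis, pe_sum = pe_s, mi_sum = mi_s, wp_sum = wp_s,
    stringsAsFactors = FALSE)
  ord <- order(-out$pmis, match(out$u, g$u), match(out$v, g$v))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
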