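#' Mutual-information scoring context
#'
#' Precomputes everything the mutual-information likelihood score needs on a
#' projected graph: the total edge count `T_l`, node degrees, local
#' clustering coefficients, and the per-node mean mutual information
#' `I(L1; z)` for every node with at least two neighbours.
#'
#' The information quantities are self-informations `-log p` of link events.
#' The probability that two nodes of degrees `d_m`, `d_n` are *not* linked
#' in a graph with `T_l` edges is a hypergeometric-style product (no degree
#' correlation assumed), and the conditional link probability given a shared
#' neighbour `z` is `z`'s clustering coefficient. Probabilities are clamped
#' into `[eps, 1]` before logs so that zero clustering coefficients and
#' impossible links yield large finite information rather than infinities;
#' rankings are unaffected.
#'
#' @param pg a [project_weighted()] projection.
#' @param log_base base of all logarithms (default 2: information in bits;
#'   rankings are base-invariant).
#' @param eps probability clamp floor (default `1e-10`).
#' @return an object of class `mi_context`.
#' @export
mi_context <- function(pg, log_base = 2, eps = 1e-10) {
  if (!inherits(pg, "projected_graph")) stop_arg("`pg` must be a projected_graph")
  if (log_base <= 0 || log_base == 1) stop_arg("`log_base` must be positive and != 1")
  if (eps <= 0 || eps >= 1) stop_arg("`eps` must lie in (0, 1)")
  deg <- projected_degree(pg)
  tl <- nrow(pg$edges)
  cc <- clustering_all(pg)
  ctx <- structure(
    list(pg = pg, total_edges = tl, deg = deg, clustering = cc,
         log_base = log_base, eps = eps, node_mi = numeric(0)),
    class = "mi_context")
  eligible <- names(deg)[deg >= 2L]
  node_mi <- vapply(eligible, function(z) compute_node_mi(ctx, z), 0)
  names(node_mi) <- eligible
  ctx$node_mi <- node_mi
  ctx
}

#' @export
print.mi_context <- function(x, ...) {
  cat("MI context: T_l =", x$total_edges, "edges, log base", x$log_base,
      "-", length(x$node_mi), "nodes with cached I(L1; z)\n")
  invisible(x)
}

clamp_prob <- function(p, eps) pmin(pmax(p, eps), 1)

neg_log <- function(p, base, eps) -log(clamp_prob(p, eps), base = base)

#' No-link probability of a degree pair
#'
#' Probability that nodes of degrees `dm` and `dn` are not connected in a
#' graph with `T_l` edges, assuming no degree correlation:
#' `prod_{i=1..dn} (T_l - dm - i + 1) / (T_l - i + 1)`, i.e.
#' `C(T_l - dm, dn) / C(T_l, dn)`. Evaluated in log-space (log-gamma) so it
#' survives `T_l` in the tens of thousands; symmetric in `(dm, dn)`; 0 when
#' `dn > T_l - dm` (a link is then forced).
#'
#' @param ctx an [mi_context()] (supplies `T_l`).
#' @param dm,dn node degrees (vectors recycle).
#' @return probabilities in `[0, 1]`.
#' @export
prob_no_link <- function(ctx, dm, dn) {
  tl <- ctx$total_edges
  if (tl < 1L) stop_arg("no-link probability undefined on an edgeless graph (T_l = 0)")
  if (any(dm < 0) || any(dn < 0)) stop_arg("degrees must be non-negative")
  if (any(dm > tl) || any(dn > tl)) stop_arg("degree exceeds total edge count T_l")
  n <- max(length(dm), length(dn))
  dm <- rep_len(dm, n); dn <- rep_len(dn, n)
  # the ratio is symmetric in (dm, dn); canonicalise the pair so the
  # symmetry also holds bitwise in floating point
  lo <- pmin(dm, dn); dm <- pmax(dm, dn); dn <- lo
  out <- numeric(n)
  forced <- dn > tl - dm
  out[forced] <- 0
  if (any(!forced)) {
    i <- which(!forced)
    out[i] <- exp(lchoose(tl - dm[i], dn[i]) - lchoose(tl, dn[i]))
  }
  pmin(pmax(out, 0), 1)
}

#' Self-information of a link between a degree pair
#'
#' `-log p(L1)` with `p(L1) = 1 - p(L0)` from [prob_no_link()]; the smaller
#' this value, the likelier the link. Probabilities are clamped to the
#' context's `eps` floor, so degree pairs that cannot be linked (`p(L1) = 0`)
#' return the finite ceiling `-log(eps)` rather than infinity.
#'
#' @inheritParams prob_no_link
#' @return self-information in `log_base` units (bits by default).
#' @export
self_info_link <- function(ctx, dm, dn) {
  neg_log(1 - prob_no_link(ctx, dm, dn), ctx$log_base, ctx$eps)
}

# mean mutual information I(L1; z) over ordered neighbour pairs of z:
# (1 / (k (k-1))) * sum_{m != n in Gamma(z)} [ I(L1_mn) - I(L1_mn | z) ],
# where I(L1_mn | z) = -log C_z. The conditional term is constant in
# (m, n), and the ordered-pair mean equals the unordered-pair mean because
# every term is symmetric in (m, n).
compute_node_mi <- function(ctx, z) {
  nb <- ctx$pg$adj[[z]]
  k <- length(nb)
  d <- unname(ctx$deg[nb])
  p0 <- outer(d, d, function(x, y) prob_no_link(ctx, x, y))
  self <- neg_log(1 - p0, ctx$log_base, ctx$eps)
  mean_self <- sum(self[upper.tri(self)]) / (k * (k - 1) / 2)
  cond <- neg_log(ctx$clustering[[z]], ctx$log_base, ctx$eps)
  mean_self - cond
}

#' Mean mutual information of a node
#'
#' `I(L1; z)`: the mean, over ordered pairs of `z`'s neighbours, of the
#' reduction in link self-information obtained by knowing `z` is a common
#' neighbour. Defined only for nodes with two or more neighbours.
#'
#' @param ctx an [mi_context()].
#' @param z a node of the projected graph with degree at least 2.
#' @return information in `log_base` units.
#' @export
node_mutual_info <- function(ctx, z) {
  check_pg_node(ctx$pg, z)
  if (!z %in% names(ctx$node_mi))
    stop_arg("I(L1; z) is undefined for node ", z,
             " (fewer than 2 neighbours); skip it")
  unname(ctx$node_mi[z])
}

#' Mutual-information likelihood score of a node pair
#'
#' The MI similarity of projected nodes `x` and `y`:
#' `S_MI(x, y) = sum_{z in O_xy} I(L1; z) - I(L1_xy)`, where `O_xy` is the
#' set of common neighbours of `x` and `y` and `I(L1_xy)` comes from
#' [self_info_link()] on their degrees. Common neighbours are treated as
#' independent evidence (the sum). Higher scores mean a likelier link; the
#' score may be negative (a pair with no common neighbour scores
#' `-I(L1_xy)`).
#'
#' @param ctx an [mi_context()].
#' @param x,y distinct nodes of the projected graph.
#' @return a real score, symmetric in `(x, y)`.
#' @export
mi_score <- function(ctx, x, y) {
  check_pg_node(ctx$pg, x); check_pg_node(ctx$pg, y)
  if (x == y) stop_arg("mi_score requires two distinct nodes")
  o <- intersect(ctx$pg$adj[[x]], ctx$pg$adj[[y]])
  o <- o[ctx$deg[o] >= 2L]
  evid <- if (length(o)) sum(ctx$node_mi[o]) else 0
  evid - self_info_link(ctx, unname(ctx$deg[x]), unname(ctx$deg[y]))
}
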