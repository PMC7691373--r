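#' Fit a PMIL link-prediction model
#'
#' Fits the potential energy–mutual information link predictor to a
#' bipartite graph in three steps: (1) weighted one-mode projection of one
#' side, (2) potential energy and mutual-information scoring of every
#' pattern (projected edge), (3) total pattern weights
#' `W_t = PE + S_MI + WP`. The fitted object then ranks any cross-side
#' candidate pair by PMIS — the summed weight of the patterns the pair
#' covers — via [predict.pmil()].
#'
#' @param graph a [bipartite_graph] (or a two-column edge `data.frame`,
#'   which is coerced).
#' @param side side to project: `"auto"` (default; the smaller side, which
#'   keeps the cubic MI stage cheap), `"u"` or `"v"`.
#' @param no_cn_constant clustering-sum stand-in for pairs without common
#'   neighbours (see [pe_params()]).
#' @param log_base logarithm base of the information quantities (default 2,
#'   bits).
#' @param eps probability clamp floor for the MI terms (default `1e-10`).
#' @return an object of class `pmil`: a list with the input `graph`, the
#'   `projection`, the MI `context`, the `weights` table
#'   ([pattern_weights()]) and the call.
#' @examples
#' g <- generate_bipartite(n_u = 8, n_v = 6, n_edges = 18, seed = 1)
#' fit <- pmil(g)
#' head(predict(fit))
#' @seealso [predict.pmil()], [evaluate_predictor()], [score_candidates()]
#' @export
pmil <- function(graph, side = c("auto", "u", "v"), no_cn_constant = 0.1,
                 log_base = 2, eps = 1e-10) {
  side <- match.arg(side)
  if (!inherits(graph, "bipartite_graph")) graph <- bipartite_graph(graph)
  if (side == "auto")
    side <- if (length(graph$v) < length(graph$u)) "v" else "u"
  pg <- project_weighted(graph, side)
  params <- pe_params(no_cn_constant = no_cn_constant)
  ctx <- mi_context(pg, log_base = log_base, eps = eps)
  w <- pattern_weights(graph, pg, params = params, ctx = ctx)
  structure(list(graph = graph, side = side, projection = pg, context = ctx,
                 params = params, weights = w, call = match.call()),
            class = "pmil")
}

#' @export
print.pmil <- function(x, ...) {
  cat("PMIL link-prediction model\n")
  cat("  graph:      |U| =", length(x$graph$u), " |V| =", length(x$graph$v),
      " |E| =", nrow(x$graph$edges), "\n")
  cat("  projection:", toupper(x$side), "side,", nrow(x$weights),
      "patterns (T_l)\n")
  cat("  log base", x$context$log_base,
      " no-CN constant", x$params$no_cn_constant, "\n")
  invisible(x)
}

#' @export
summary.pmil <- function(object, ...) {
  w <- object$weights
  structure(list(
    n_u = length(object$graph$u), n_v = length(object$graph$v),
    n_edges = nrow(object$graph$edges), side = object$side,
    n_patterns = nrow(w),
    components = if (nrow(w))
      rbind(PE = summary(w$pe), MI = summary(w$mi),
            WP = summary(as.numeric(w$wp)), W_t = summary(w$total))
    else NULL,
    top_patterns = utils::head(w[order(-w$total), , drop = FALSE], 5L)),
    class = "summary.pmil")
}

#' @export
print.summary.pmil <- function(x, ...) {
  cat("PMIL model on a", x$n_u, "x", x$n_v, "bipartite graph (",
      x$n_edges, "edges );", toupper(x$side), "-side projection,",
      x$n_patterns, "patterns\n")
  if (!is.null(x$components)) {
    cat("\nPattern-weight components:\n")
    print(round(x$components, 4))
    cat("\nHeaviest patterns:\n")
    print(x$top_patterns, row.names = FALSE)
  }
  invisible(x)
}

#' Rank candidate links from a fitted PMIL model
#'
#' Scores candidate cross-side pairs by PMIS and returns the ranked score
#' table (see [rank_candidates()]). With `candidates = NULL` every non-edge
#' of the graph is scored.
#'
#' @param object a fitted [pmil] model.
#' @param candidates optional two-column `data.frame` of
#'   (projected-side, opposite-side) pairs; must be non-edges.
#' @param ... unused.
#' @return the ranked `data.frame` of [rank_candidates()].
#' @export
predict.pmil <- function(object, candidates = NULL, ...) {
  rank_candidates(object$graph, object$weights, candidates)
}

#' Diagnostic plots for a PMIL model
#'
#' Draws the distribution of total pattern weights and the relationship
#' between the mutual-information and potential-energy components (point
#' size proportional to the shared-neighbour count WP).
#'
#' @param x a fitted [pmil] model.
#' @param ... passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.pmil <- function(x, ...) {
  w <- x$weights
  if (!nrow(w)) {
    warning("no patterns to plot")
    return(invisible(x))
  }
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::hist(w$total, main = "Total pattern weight",
                 xlab = expression(W[t]), col = "grey80", border = "white",
                 ...)
  graphics::plot(w$pe, w$mi, cex = 0.5 + w$wp / max(w$wp),
                 xlab = "potential energy", ylab = "MI score (bits)",
                 main = "Pattern components")
  invisible(x)
}
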