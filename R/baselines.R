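#' Neighbourhood baseline scores for a cross-side pair
#'
#' Classic unipartite similarity indices adapted to bipartite inputs through
#' the same geometry the pattern machinery uses: the projected-side node `a`
#' contributes its projected neighbourhood `N_u(a)` and the opposite-side
#' node `i` its bipartite neighbourhood `N(i)` (both subsets of the
#' projected side), so the two sets are comparable. With
#' `CN = |N_u(a) ∩ N(i)|`:
#'
#' * `cn` — common neighbours, `CN`
#' * `jc` — Jaccard, `CN / |N_u(a) ∪ N(i)|`
#' * `pa` — preferential attachment, bipartite degree product
#'   `|N(a)| * |N(i)|`
#' * `cs` — cosine, `CN / sqrt(|N_u(a)| * |N(i)|)`
#'
#' Ratios with an empty denominator are 0. All scores are finite and
#' non-negative; `jc` and `cs` lie in `[0, 1]`.
#'
#' @param method one of `"cn"`, `"jc"`, `"pa"`, `"cs"`.
#' @param g a [bipartite_graph].
#' @param pg the projection of `g` (see [project_weighted()]).
#' @param a a node of the projected side.
#' @param i a node of the opposite side.
#' @return a single numeric score.
#' @export
baseline_score <- function(method = c("cn", "jc", "pa", "cs"), g, pg, a, i) {
  method <- match.arg(method)
  proj_side <- if (pg$side == "u") g$u else g$v
  other_side <- if (pg$side == "u") g$v else g$u
  if (!a %in% proj_side) stop_arg("node ", a, " is not on the projected side")
  if (!i %in% other_side) stop_arg("node ", i, " is not on the opposite side")
  na <- pg$adj[[a]]
  ni <- if (pg$side == "u") g$adj_v[[i]] else g$adj_u[[i]]
  cn <- length(intersect(na, ni))
  switch(method,
    cn = cn,
    jc = {
      un <- length(union(na, ni))
      if (un == 0L) 0 else cn / un
    },
    pa = length(bipartite_neighbors(g, a)) * length(ni),
    cs = {
      den <- length(na) * length(ni)
      if (den == 0L) 0 else cn / sqrt(den)
    })
}

#' Score all candidate pairs with any predictor
#'
#' Uniform front end over the PMIL model and the neighbourhood baselines:
#' builds whatever the chosen predictor needs on `g` and returns a ranked
#' score table. Used by the evaluation harness so every method runs under
#' the identical protocol.
#'
#' @param g a [bipartite_graph].
#' @param method `"pmil"` (default), `"cn"`, `"jc"`, `"pa"` or `"cs"`.
#' @param side projection side, as in [pmil()].
#' @param candidates optional two-column `data.frame` of
#'   (projected-side, opposite-side) pairs; defaults to all non-edges.
#' @param ... further arguments to [pmil()] (`no_cn_constant`, `log_base`,
#'   `eps`).
#' @return a `data.frame` with columns `u`, `v`, `score`, sorted by
#'   descending score with deterministic first-seen tie-breaking.
#' @export
score_candidates <- function(g, method = c("pmil", "cn", "jc", "pa", "cs"),
                             side = c("auto", "u", "v"), candidates = NULL,
                             ...) {
  method <- match.arg(method)
  side <- match.arg(side)
  if (method == "pmil") {
    fit <- pmil(g, side = side, ...)
    ranked <- predict(fit, candidates)
    out <- data.frame(u = ranked$u, v = ranked$v, score = ranked$pmis,
                      stringsAsFactors = FALSE)
    return(out)
  }
  if (side == "auto") side <- if (length(g$v) < length(g$u)) "v" else "u"
  pg <- project_weighted(g, side)
  proj_u <- side == "u"
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
  }
  sc <- vapply(seq_len(nrow(candidates)), function(r)
    baseline_score(method, g, pg, candidates$a[r], candidates$i[r]), 0)
  out <- data.frame(
    u = if (proj_u) candidates$a else candidates$i,
    v = if (proj_u) candidates$i else candidates$a,
    score = sc, stringsAsFactors = FALSE)
  ord <- order(-out$score, match(out$u, g$u), match(out$v, g$v))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
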