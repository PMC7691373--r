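#' K-fold edge split
#'
#' Partitions the edges of a bipartite graph into `k` folds of sizes
#' differing by at most one, uniformly at random and reproducibly from
#' `seed`. In cross-validation each fold in turn is the probe (test) set
#' and the remaining `k - 1` folds form the training graph.
#'
#' @param g a [bipartite_graph].
#' @param k number of folds (default 10: a 90/10 train/probe split).
#' @param seed integer RNG seed.
#' @return an object of class `split_plan`: list with `k`, `fold` (integer
#'   fold index per edge row of `g$edges`), `seed`.
#' @export
kfold_split <- function(g, k = 10, seed = 1) {
  m <- n_edges(g)
  if (k < 2) stop_arg("`k` must be at least 2")
  if (k > m) stop_arg("`k` (", k, ") exceeds the number of edges (", m, ")")
  fold <- with_seed(seed, sample(rep_len(seq_len(k), m)))
  structure(list(k = k, fold = fold, seed = seed), class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("Edge split:", x$k, "folds of sizes",
      paste(tabulate(x$fold, x$k), collapse = "/"),
      "(seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

#' Training graph and probe set of one fold
#'
#' @param g the full [bipartite_graph].
#' @param plan a [kfold_split()] plan for `g`.
#' @param fold fold index in `1..k` to hold out as the probe set.
#' @return list with `train` (a `bipartite_graph` on the full node sets,
#'   probe edges removed) and `probe` (`data.frame` of held-out edges).
#' @export
fold_graph <- function(g, plan, fold) {
  if (fold < 1 || fold > plan$k) stop_arg("fold index out of range")
  hold <- plan$fold == fold
  list(train = bipartite_graph(g$edges[!hold, , drop = FALSE],
                               u_nodes = g$u, v_nodes = g$v),
       probe = g$edges[hold, , drop = FALSE])
}

#' Sampling AUC over probe vs nonexistent links
#'
#' The probability that a randomly chosen missing link (a held-out probe
#' edge) scores higher than a randomly chosen nonexistent link, estimated
#' by `n_comparisons` independent draws with replacement:
#' `AUC = (N_h + 0.5 N_s) / N_t`, where `N_h` counts wins and `N_s` ties.
#' 1.0 is the ideal predictor; 0.5 is chance.
#'
#' @param scores_probe numeric scores of the probe (held-out) links.
#' @param scores_nonexistent numeric scores of nonexistent links.
#' @param n_comparisons number of sampled comparisons `N_t`.
#' @param seed integer RNG seed (`NULL` uses the current stream).
#' @return the AUC estimate in `[0, 1]`.
#' @export
auc_sampling <- function(scores_probe, scores_nonexistent,
                         n_comparisons = 10000, seed = NULL) {
  if (!length(scores_probe) || !length(scores_nonexistent))
    stop_arg("both score lists must be non-empty")
  if (n_comparisons < 1) stop_arg("`n_comparisons` must be at least 1")
  with_seed(seed, {
    sp <- scores_probe[sample.int(length(scores_probe), n_comparisons,
                                  replace = TRUE)]
    sn <- scores_nonexistent[sample.int(length(scores_nonexistent),
                                        n_comparisons, replace = TRUE)]
    (sum(sp > sn) + 0.5 * sum(sp == sn)) / n_comparisons
  })
}

#' Precision of the top of a ranking
#'
#' `L_r / L`, where `L_r` of the top-`L` ranked candidate pairs belong to
#' the probe set. `Precision@K` is the same quantity at `L = K` (commonly
#' 10, 20, 50). When the ranking holds fewer than `L` rows all rows are
#' used; an empty ranking scores 0.
#'
#' @param ranked a ranked score table with columns `u`, `v` (e.g. from
#'   [score_candidates()] or [predict.pmil()]).
#' @param probe_edges `data.frame` of held-out edges (columns `u`, `v`).
#' @param L cutoff.
#' @return precision in `[0, 1]`.
#' @export
precision_at_L <- function(ranked, probe_edges, L) {
  if (L < 1) stop_arg("`L` must be at least 1")
  if (!nrow(ranked)) return(0)
  L <- min(L, nrow(ranked))
  top <- ranked[seq_len(L), , drop = FALSE]
  hits <- sum(paste(top$u, top$v, sep = "\r") %in%
                paste(probe_edges[[1L]], probe_edges[[2L]], sep = "\r"))
  hits / L
}

#' Prediction power
#'
#' Deviation of a predictor's precision from the mean random predictor, in
#' orders of magnitude:
#' `PP = log10(precision_method / precision_random)` with
#' `precision_random = L / (|U| |V| - (E - L))`, `E` being the number of
#' training edges. 0 means no better than random; 1 means ten times better.
#'
#' @param precision_method the predictor's precision at cutoff `L`.
#' @param g the training [bipartite_graph] (supplies `|U|`, `|V|`, `E`).
#' @param L the cutoff used for the precision.
#' @return `PP`; `-Inf` when `precision_method` is 0.
#' @export
prediction_power <- function(precision_method, g, L) {
  if (precision_method < 0) stop_arg("precision must be non-negative")
  den <- length(g$u) * length(g$v) - (n_edges(g) - L)
  if (den <= 0) stop_arg("degenerate random-precision denominator")
  p_rand <- L / den
  if (p_rand <= 0) stop_arg("degenerate random-precision denominator")
  log10(precision_method / p_rand)
}

#' Cross-validated evaluation of a link predictor
#'
#' Runs the full edge-holdout protocol: `repeats` rounds of `k`-fold
#' splitting; per fold the predictor is fitted to the training graph, every
#' non-training pair is ranked, and four metrics are computed — sampling
#' AUC (probe vs nonexistent links), Precision at `L` (default: the probe
#' size), Prediction-Power at the same `L`, and Precision@K for each `K` in
#' `precision_at`. Nonexistent links are pairs absent from both the
#' training and the probe sets. All randomness (splits, AUC sampling)
#' descends from the single root `seed`.
#'
#' @param g a [bipartite_graph].
#' @param method predictor name, as in [score_candidates()].
#' @param k folds per round (default 10).
#' @param repeats independent k-fold rounds to average over (default 1).
#' @param n_comparisons AUC comparisons per fold (default 10,000).
#' @param L precision cutoff; `NULL` (default) uses the probe-set size.
#' @param precision_at integer vector of Precision@K cutoffs.
#' @param seed root RNG seed.
#' @param side projection side, as in [pmil()].
#' @param ... further predictor arguments (see [score_candidates()]).
#' @return an object of class `link_eval`: list with `folds` (one row of
#'   metrics per repeat x fold), `mean` (metric means over all folds) and
#'   the configuration.
#' @export
evaluate_predictor <- function(g, method = c("pmil", "cn", "jc", "pa", "cs"),
                               k = 10, repeats = 1, n_comparisons = 10000,
                               L = NULL, precision_at = c(10, 20, 50),
                               seed = 1, side = c("auto", "u", "v"), ...) {
  method <- match.arg(method)
  side <- match.arg(side)
  seeds <- matrix(derive_seeds(seed, 2L * repeats * k), ncol = 2L)
  rows <- vector("list", repeats * k)
  full_key <- paste(g$edges$u, g$edges$v, sep = "\r")
  idx <- 0L
  for (r in seq_len(repeats)) {
    plan <- kfold_split(g, k, seed = seeds[(r - 1L) * k + 1L, 1L])
    for (f in seq_len(k)) {
      idx <- idx + 1L
      fg <- fold_graph(g, plan, f)
      ranked <- score_candidates(fg$train, method, side, ...)
      rk <- paste(ranked$u, ranked$v, sep = "\r")
      probe_key <- paste(fg$probe$u, fg$probe$v, sep = "\r")
      probe_scores <- ranked$score[match(probe_key, rk)]
      nonexist_scores <- ranked$score[!(rk %in% full_key)]
      auc <- auc_sampling(probe_scores, nonexist_scores, n_comparisons,
                          seed = seeds[idx, 2L])
      Lf <- L %||% nrow(fg$probe)
      prec <- precision_at_L(ranked, fg$probe, Lf)
      pp <- prediction_power(prec, fg$train, Lf)
      pk <- vapply(precision_at, function(K)
        precision_at_L(ranked, fg$probe, K), 0)
      rows[[idx]] <- c(repeat_ = r, fold = f, auc = auc, precision = prec,
                       pp = pp, stats::setNames(pk, paste0("p_at_",
                                                           precision_at)))
    }
  }
  folds <- as.data.frame(do.call(rbind, rows))
  metric_cols <- setdiff(names(folds), c("repeat_", "fold"))
  structure(list(folds = folds, mean = colMeans(folds[metric_cols]),
                 method = method, k = k, repeats = repeats,
                 n_comparisons = n_comparisons, seed = seed),
            class = "link_eval")
}

#' @export
print.link_eval <- function(x, digits = 4, ...) {
  cat("Edge-holdout evaluation:", toupper(x$method), "-", x$repeats, "x",
      x$k, "folds,", x$n_comparisons, "AUC comparisons/fold (seed",
      paste0(x$seed, ")"), "\n")
  m <- x$mean
  m[!is.finite(m)] <- NA
  print(round(m, digits))
  invisible(x)
}
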