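# a small projected graph with T_l = 10 edges for degree-pair examples
pg10 <- local({
  ed <- data.frame(a = c("a", "a", "a", "b", "b", "c", "d", "e", "f", "g"),
                   b = c("b", "c", "d", "c", "e", "f", "g", "f", "g", "h"))
  g <- bipartite_graph(data.frame(u = c(ed$a, ed$b),
                                  v = paste0("w", rep(1:10, 2))))
  project_weighted(g, "u")
})

test_that("no-link probability: closed form, bounds, symmetry, monotonicity", {
  ctx <- mi_context(pg10)
  expect_equal(ctx$total_edges, 10)
  # C(7,2)/C(10,2) = 21/45, equal to the direct product (7/10)(6/9)
  expect_equal(prob_no_link(ctx, 3, 2), 21 / 45)
  expect_equal(prob_no_link(ctx, 3, 2), (7 / 10) * (6 / 9))
  # dm = 0 -> empty product
  expect_equal(prob_no_link(ctx, 0, 7), 1)
  # forced link
  expect_equal(prob_no_link(ctx, 9, 5), 0)
  # symmetry and bounds across the grid, against the product oracle
  for (dm in 0:10) for (dn in 0:10) {
    p <- prob_no_link(ctx, dm, dn)
    expect_equal(p, prob_no_link(ctx, dn, dm))
    expect_equal(p, o_prob_no_link(10, dm, dn), tolerance = 1e-12)
    expect_gte(p, 0); expect_lte(p, 1)
  }
  # decreasing in dm at fixed dn
  p_seq <- prob_no_link(ctx, 0:8, 2)
  expect_true(all(diff(p_seq) < 0))
  expect_error(prob_no_link(ctx, -1, 2), "non-negative")
})

test_that("link self-information: value, symmetry and clamped extremes", {
  ctx <- mi_context(pg10)
  expect_equal(self_info_link(ctx, 3, 2), -log2(24 / 45))
  expect_equal(self_info_link(ctx, 2, 3), self_info_link(ctx, 3, 2))
  # forced link: p(L1) = 1 -> zero information
  expect_equal(self_info_link(ctx, 9, 5), 0)
  # impossible link (both degrees 0): clamped ceiling, never an error
  expect_equal(self_info_link(ctx, 0, 0), -log2(1e-10))
})

test_that("node mutual information matches the literal transcription", {
  # 5-node graph, z of degree 3 with one triangle, T_l = 6
  ed <- data.frame(a = c("z", "z", "z", "m", "n", "q"),
                   b = c("m", "n", "p", "n", "q", "p"))
  g <- bipartite_graph(data.frame(u = c(ed$a, ed$b),
                                  v = paste0("w", 1:6)))
  pg <- project_weighted(g, "u")
  ctx <- mi_context(pg)
  adj <- o_adj(pg$edges, pg$nodes)
  deg <- sapply(adj, length)
  expect_equal(node_mutual_info(ctx, "z"), o_node_mi(adj, deg, 6, "z"),
               tolerance = 1e-12)
  # perfectly clustered node: conditional term vanishes, value is the
  # mean pairwise self-information
  tri_ed <- data.frame(a = c("a", "b", "c"), b = c("b", "c", "a"))
  tg <- bipartite_graph(data.frame(u = c(tri_ed$a, tri_ed$b),
                                   v = paste0("t", 1:3)))
  tpg <- project_weighted(tg, "u")
  tctx <- mi_context(tpg)
  expect_equal(node_mutual_info(tctx, "a"), self_info_link(tctx, 2, 2))
  # degree-1 node is undefined
  expect_error(node_mutual_info(ctx, "q2"), "unknown node")
  d1 <- mi_context(project_weighted(bipartite_graph(
    data.frame(u = c("a", "b", "b", "c"), v = c("x", "x", "y", "y"))), "u"))
  expect_error(node_mutual_info(d1, "a"), "undefined")
})

test_that("zero clustering hits the clamp floor but stays finite", {
  # path a - z - b: C_z = 0
  ed <- data.frame(a = c("a", "z"), b = c("z", "b"))
  g <- bipartite_graph(data.frame(u = c(ed$a, ed$b), v = c("w1", "w2")))
  pg <- project_weighted(g, "u")
  ctx <- mi_context(pg)
  v <- node_mutual_info(ctx, "z")
  expect_true(is.finite(v))
  # the conditional term is the clamp ceiling -log2(eps)
  expect_equal(v, self_info_link(ctx, 1, 1) + log2(1e-10))
})

test_that("MI score is symmetric and rewards common neighbours", {
  ctx <- mi_context(pg10)
  for (pair in list(c("a", "e"), c("c", "d"), c("f", "h"))) {
    expect_equal(mi_score(ctx, pair[1], pair[2]),
                 mi_score(ctx, pair[2], pair[1]))
  }
  # no common neighbour -> score is minus the pair self-information
  expect_equal(mi_score(ctx, "a", "h"),
               -self_info_link(ctx, unname(ctx$deg["a"]),
                               unname(ctx$deg["h"])))
  expect_error(mi_score(ctx, "a", "a"), "distinct")
})

test_that("MI score equals the brute-force transcription on random graphs", {
  for (seed in 1:10) {
    g <- random_bipartite(sample(4:12, 1), sample(4:12, 1),
                          sample(6:24, 1), seed = 300 + seed)
    pg <- project_weighted(g, "u")
    if (nrow(pg$edges) < 2) next
    ctx <- mi_context(pg)
    nodes <- names(ctx$deg)[ctx$deg >= 1]
    pairs <- utils::combn(nodes, 2)
    take <- seq_len(min(ncol(pairs), 10))
    for (jj in take) {
      x <- pairs[1, jj]; y <- pairs[2, jj]
      expect_equal(mi_score(ctx, x, y),
                   o_mi_score(pg$edges, pg$nodes, x, y),
                   tolerance = 1e-9)
    }
  }
})

test_that("MI score is invariant under node relabelling", {
  g <- random_bipartite(8, 6, 16, seed = 42)
  pg <- project_weighted(g, "u")
  ctx <- mi_context(pg)
  # relabel U nodes by a fixed permutation of fresh names
  map <- stats::setNames(paste0("R", rev(seq_along(g$u))), g$u)
  g2 <- bipartite_graph(data.frame(u = unname(map[g$edges$u]),
                                   v = g$edges$v),
                        u_nodes = unname(map[g$u]), v_nodes = g$v)
  ctx2 <- mi_context(project_weighted(g2, "u"))
  for (e in seq_len(min(nrow(pg$edges), 8))) {
    x <- pg$edges$a[e]; y <- pg$edges$b[e]
    expect_equal(mi_score(ctx, x, y),
                 mi_score(ctx2, unname(map[x]), unname(map[y])),
                 tolerance = 1e-12)
  }
})
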