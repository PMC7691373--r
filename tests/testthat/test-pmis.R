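test_that("pattern weights sum their three components exactly", {
  g <- random_bipartite(8, 6, 18, seed = 21)
  pg <- project_weighted(g, "u")
  w <- pattern_weights(g, pg)
  expect_equal(nrow(w), nrow(pg$edges))
  expect_identical(w$total, w$pe + w$mi + w$wp)
  # each component re-derived independently
  ctx <- mi_context(pg)
  for (r in seq_len(nrow(w))) {
    expect_equal(w$pe[r], potential_energy(pg, w$a[r], w$b[r]),
                 tolerance = 1e-12)
    expect_equal(w$mi[r], mi_score(ctx, w$a[r], w$b[r]), tolerance = 1e-12)
    expect_equal(w$wp[r], projection_weight(pg, w$a[r], w$b[r]))
  }
  # single-pattern graph
  g1 <- bipartite_graph(data.frame(u = c("A", "B"), v = c("x", "x")))
  expect_equal(nrow(pattern_weights(g1, project_weighted(g1, "u"))), 1)
  # mismatched graph/projection is refused
  g2 <- random_bipartite(5, 5, 8, seed = 22)
  expect_error(pattern_weights(g2, pg), "projection")
})

test_that("PMIS is the covered-pattern weight sum, zero when none", {
  g <- random_bipartite(10, 10, 30, seed = 23)
  pg <- project_weighted(g, "u")
  w <- pattern_weights(g, pg)
  tot <- w$total
  names(tot) <- paste(w$a, w$b)
  for (a in g$u) for (i in g$v) {
    if (is_edge(g, a, i)) next
    cov <- patterns_covered(g, pg, a, i)
    manual <- if (nrow(cov)) sum(tot[paste(cov$a, cov$b)]) else 0
    expect_equal(pmis_score(g, w, a, i), manual, tolerance = 1e-12)
  }
})

test_that("full pipeline matches the monolithic literal recomputation", {
  set.seed(99)
  for (seed in 1:6) {
    g <- random_bipartite(sample(5:12, 1), sample(5:12, 1),
                          sample(8:26, 1), seed = 500 + seed)
    pg <- project_weighted(g, "u")
    w <- pattern_weights(g, pg)
    cand_u <- sample(g$u, min(4, length(g$u)))
    cand_v <- sample(g$v, min(4, length(g$v)))
    for (a in cand_u) for (i in cand_v) {
      if (is_edge(g, a, i)) next
      expect_equal(pmis_score(g, w, a, i), o_pmis(g, a, i),
                   tolerance = 1e-9)
    }
  }
})

test_that("ranking covers all non-edges, sorts, and reports components", {
  g <- random_bipartite(7, 6, 15, seed = 24)
  w <- pattern_weights(g, project_weighted(g, "u"))
  tab <- rank_candidates(g, w)
  expect_equal(nrow(tab), 7 * 6 - 15)
  expect_true(all(diff(tab$pmis) <= 0))
  expect_false(any(is_edge(g, tab$u, tab$v)))
  expect_equal(tab$pmis, tab$pe_sum + tab$mi_sum + tab$wp_sum,
               tolerance = 1e-12)
  # empty candidate list and already-an-edge candidates
  empty <- rank_candidates(g, w, g$edges[0, ])
  expect_equal(nrow(empty), 0)
  expect_error(rank_candidates(g, w, g$edges[1, ]), "already present")
})

test_that("the unique pattern-covering pair ranks first", {
  # only (A, i) covers a pattern: N_u(A) = {B}, N(i) = {B}
  g <- bipartite_graph(data.frame(u = c("A", "B", "B", "C"),
                                  v = c("x", "x", "i", "y")))
  w <- pattern_weights(g, project_weighted(g, "u"))
  tab <- rank_candidates(g, w)
  expect_equal(unlist(tab[1, c("u", "v")], use.names = FALSE), c("A", "i"))
  expect_gt(tab$pmis[1], max(tab$pmis[-1]))
})

test_that("ranking is invariant under node relabelling", {
  g <- random_bipartite(8, 6, 18, seed = 25)
  w <- pattern_weights(g, project_weighted(g, "u"))
  tab <- rank_candidates(g, w)
  map_u <- stats::setNames(paste0("P", seq_along(g$u)), g$u)
  map_v <- stats::setNames(paste0("Q", seq_along(g$v)), g$v)
  g2 <- bipartite_graph(data.frame(u = unname(map_u[g$edges$u]),
                                   v = unname(map_v[g$edges$v])),
                        u_nodes = unname(map_u[g$u]),
                        v_nodes = unname(map_v[g$v]))
  w2 <- pattern_weights(g2, project_weighted(g2, "u"))
  tab2 <- rank_candidates(g2, w2)
  # scores permute with the labels: compare per-pair maps
  key1 <- paste(map_u[tab$u], map_v[tab$v])
  s2 <- tab2$pmis
  names(s2) <- paste(tab2$u, tab2$v)
  expect_equal(unname(s2[key1]), tab$pmis, tolerance = 1e-9)
})

test_that("PMIS is order-independent in edge storage", {
  g <- random_bipartite(8, 7, 20, seed = 26)
  w1 <- pattern_weights(g, project_weighted(g, "u"))
  ed <- g$edges[rev(seq_len(nrow(g$edges))), ]
  g2 <- bipartite_graph(ed, u_nodes = g$u, v_nodes = g$v)
  w2 <- pattern_weights(g2, project_weighted(g2, "u"))
  t1 <- rank_candidates(g, w1)
  t2 <- rank_candidates(g2, w2)
  s2 <- t2$pmis
  names(s2) <- paste(t2$u, t2$v)
  expect_equal(unname(s2[paste(t1$u, t1$v)]), t1$pmis, tolerance = 1e-12)
})

test_that("pmil() fit object exposes the pipeline and its methods work", {
  g <- generate_bipartite(10, 8, 24, seed = 27)
  fit <- pmil(g)
  expect_s3_class(fit, "pmil")
  expect_identical(fit$side, "v")  # auto projects the smaller side
  tab <- predict(fit)
  expect_equal(nrow(tab), 10 * 8 - 24)
  expect_output(print(fit), "PMIL link-prediction model")
  expect_output(print(summary(fit)), "patterns")
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path); plot(fit); grDevices::dev.off()
  expect_true(file.exists(path))
  # explicit side u matches the module-level route
  fit_u <- pmil(g, side = "u")
  w <- pattern_weights(g, project_weighted(g, "u"))
  expect_equal(predict(fit_u), rank_candidates(g, w))
})
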