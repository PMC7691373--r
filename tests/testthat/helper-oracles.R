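# Literal, unoptimised reference implementations used as independent
# oracles. They share no code with the package internals: plain loops,
# direct products, no caching, no log-gamma.

# adjacency list of an edge data.frame (a, b) over `nodes`
o_adj <- function(edges, nodes) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (r in seq_len(nrow(edges))) {
    a <- edges$a[r]; b <- edges$b[r]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# weighted projection by exhaustive pairwise intersection
o_projection <- function(g, side = "u") {
  nodes <- if (side == "u") g$u else g$v
  nb <- function(x) bipartite_neighbors(g, x)
  out <- data.frame(a = character(), b = character(), wp = integer())
  if (length(nodes) < 2) return(out)
  for (p in seq_len(length(nodes) - 1)) {
    for (q in seq(p + 1, length(nodes))) {
      w <- length(intersect(nb(nodes[p]), nb(nodes[q])))
      if (w > 0) {
        pr <- sort(c(nodes[p], nodes[q]))
        out <- rbind(out, data.frame(a = pr[1], b = pr[2], wp = w))
      }
    }
  }
  out[order(out$a, out$b), , drop = FALSE]
}

# triangle count through z by enumeration
o_triangles <- function(adj, z) {
  nb <- adj[[z]]
  t <- 0
  if (length(nb) >= 2) {
    for (p in seq_len(length(nb) - 1))
      for (q in seq(p + 1, length(nb)))
        if (nb[q] %in% adj[[nb[p]]]) t <- t + 1
  }
  t
}

o_clustering <- function(adj, z) {
  d <- length(adj[[z]])
  if (d < 2) return(0)
  2 * o_triangles(adj, z) / (d * (d - 1))
}

# BFS hop count
o_bfs <- function(adj, a, b) {
  if (a == b) return(0)
  seen <- a; frontier <- a; dist <- 0
  while (length(frontier)) {
    dist <- dist + 1
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    if (b %in% nxt) return(dist)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  Inf
}

o_clamp <- function(p, eps = 1e-10) min(max(p, eps), 1)

# no-link probability by the direct product, not log-gamma
o_prob_no_link <- function(tl, dm, dn) {
  p <- 1
  if (dn >= 1) for (i in seq_len(dn)) p <- p * (tl - dm - i + 1) / (tl - i + 1)
  min(max(p, 0), 1)
}

o_self_info <- function(tl, dm, dn, eps = 1e-10) {
  -log2(o_clamp(1 - o_prob_no_link(tl, dm, dn), eps))
}

# I(L1; z): ordered-pair mean of I(L1_mn) - I(L1_mn | z)
o_node_mi <- function(adj, deg, tl, z, eps = 1e-10) {
  nb <- adj[[z]]
  k <- length(nb)
  stopifnot(k >= 2)
  cond <- -log2(o_clamp(o_clustering(adj, z), eps))
  s <- 0
  for (m in nb) for (n in nb) if (m != n)
    s <- s + o_self_info(tl, deg[[m]], deg[[n]], eps) - cond
  s / (k * (k - 1))
}

# S_MI(x, y): literal transcription of the score
o_mi_score <- function(edges, nodes, x, y, eps = 1e-10) {
  adj <- o_adj(edges, nodes)
  deg <- sapply(adj, length)
  tl <- nrow(edges)
  o <- intersect(adj[[x]], adj[[y]])
  s <- 0
  for (z in o) if (deg[[z]] >= 2) s <- s + o_node_mi(adj, deg, tl, z, eps)
  s - o_self_info(tl, deg[[x]], deg[[y]], eps)
}

# PE(a, b) with BFS distance and enumerated clustering
o_potential_energy <- function(edges, nodes, a, b, no_cn = 0.1,
                               disconnected = 0) {
  adj <- o_adj(edges, nodes)
  da <- length(adj[[a]]); db <- length(adj[[b]])
  if (da == 0 || db == 0) return(0)
  cn <- intersect(adj[[a]], adj[[b]])
  s <- if (length(cn)) sum(sapply(cn, function(z) o_clustering(adj, z)))
       else no_cn
  sd_ab <- o_bfs(adj, a, b)
  if (!is.finite(sd_ab)) return(disconnected)
  da * db * s / sd_ab
}

# PMIS(a, i): monolithic recomputation of projection, weights and the
# covered-pattern sum for one candidate pair
o_pmis <- function(g, a, i, side = "u", no_cn = 0.1, eps = 1e-10) {
  proj <- o_projection(g, side)
  nodes <- if (side == "u") g$u else g$v
  adj <- o_adj(proj, nodes)
  nb_i <- bipartite_neighbors(g, i)
  cov <- intersect(adj[[a]], nb_i)
  s <- 0
  for (C in cov) {
    pe <- o_potential_energy(proj, nodes, a, C, no_cn)
    mi <- o_mi_score(proj, nodes, a, C, eps)
    wp <- proj$wp[(proj$a == min(a, C) & proj$b == max(a, C))]
    s <- s + pe + mi + wp
  }
  s
}

# exact rank AUC by exhaustive pair enumeration (Mann-Whitney form)
o_exact_auc <- function(probe, nonexist) {
  wins <- 0; ties <- 0
  for (p in probe) for (q in nonexist) {
    if (p > q) wins <- wins + 1
    else if (p == q) ties <- ties + 1
  }
  (wins + 0.5 * ties) / (length(probe) * length(nonexist))
}

# random bipartite graph helper for property tests; caps the edge count at
# the feasible maximum so random size draws never request too many
random_bipartite <- function(n_u, n_v, n_edges, seed) {
  generate_bipartite(n_u, n_v, min(n_edges, n_u * n_v),
                     degree_model = "uniform", seed = seed)
}
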