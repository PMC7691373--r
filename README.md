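# pmil — bipartite link prediction with potential energy and mutual information

`pmil` predicts missing links in bipartite networks — drug–target
interactions, user–item ratings, actor–event affiliations — where edges only
ever join two disjoint node sets U and V and the triangle-closure heuristics
of unipartite link prediction do not apply.

## Method

The predictor works in three steps on a bipartite graph G(U, V, E):

1. **Weighted one-mode projection.** Same-side nodes A, B are joined
   whenever they share a neighbour, with weight
   `WP(A,B) = |Γ(A) ∩ Γ(B)|`. Each projected edge is a *pattern* — a
   connection shape that already exists in the data.
2. **Pattern weighting.** Every pattern receives
   `W_t(A,B) = PE(A,B) + S^MI_AB + WP(A,B)`, combining
   * the *potential energy*
     `PE(A,B) = d_A d_B · (Σ_{z∈CN(A,B)} cl_z) · 1/sd(A,B)` — degree
     product × summed clustering coefficient of common neighbours × inverse
     shortest distance (a graph analogue of m·g·h; a constant 0.1 replaces
     the clustering sum when the pair has no common neighbour), and
   * the *mutual-information score*
     `S^MI_xy = Σ_{z∈O_xy} I(L¹;z) − I(L¹_xy)`, the reduction in link
     self-information contributed by the pair's common neighbours, with
     no-link probabilities `p(L⁰_mn) = C(T_l−d_m, d_n) / C(T_l, d_n)` and
     conditional link probabilities given by clustering coefficients.
3. **PMIS ranking.** A candidate cross-side pair (A, i) scores
   `PMIS(A,i) = Σ_{{A,B} ∈ Γ(A,i)} W_t(A,B)`, the summed weight of the
   patterns it covers; all non-edges are ranked by descending PMIS.

The package also ships bipartite adaptations of the common-neighbours,
Jaccard, preferential-attachment and cosine baselines, a K-fold edge-holdout
evaluation harness (sampling AUC, Precision, Prediction-Power, Precision@K),
and a synthetic bipartite-graph generator, so the whole pipeline runs and is
testable without any external data. See `vignette("pmil-methods")` for the
model's assumptions and design choices.

## Worked example

```r
library(pmil)

g <- generate_bipartite(n_u = 20, n_v = 20, n_edges = 120,
                        degree_model = "preferential", seed = 11)
fit <- pmil(g)
fit
#> PMIL link-prediction model
#>   graph:      |U| = 20  |V| = 20  |E| = 120
#>   projection: U side, 153 patterns (T_l)
#>   log base 2  no-CN constant 0.1

head(predict(fit), 5)
#>     u  v     pmis   pe_sum   mi_sum wp_sum
#> 1  u4 v2 56535.74 56478.30 19.44091     38
#> 2 u15 v7 50676.63 50610.29 17.33871     49
#> 3 u12 v7 49890.32 49827.42 16.89571     46
#> 4  u2 v7 44519.87 44452.60 14.27490     53
#> 5  u3 v6 39649.16 39580.40 12.75563     56
```

`predict()` ranks every absent U×V pair; `pmis` is the prediction score and
`pe_sum`, `mi_sum`, `wp_sum` show how much each signal contributed. Here the
top candidate `(u4, v2)` covers patterns worth 56,536 in total — hub nodes
on a dense preferential graph accumulate large degree products, which the PE
term rewards.

Cross-validated evaluation under 10-fold edge holdout:

```r
evaluate_predictor(g, method = "pmil", k = 10, n_comparisons = 5000, seed = 2)
#> Edge-holdout evaluation: PMIL - 1 x 10 folds, 5000 AUC comparisons/fold (seed 2)
#>       auc precision        pp   p_at_10   p_at_20   p_at_50
#>    0.8035    0.2417    0.7511    0.2800    0.1850    0.1240
```

A held-out true link outranks a random nonexistent one ~80% of the time;
precision at the probe size is 0.24, about 5.6× (`pp` ≈ 0.75 orders of
magnitude) better than a random predictor. The same call with
`method = "cn"` gives AUC 0.79 on this graph — the combined score edges out
its strongest component.

## Command line

A thin CLI over the same functions lives at `inst/cli/pmil.R`:

```sh
Rscript inst/cli/pmil.R generate --n-u 20 --n-v 20 --n-edges 120 \
    --model preferential --seed 1 --out graph.tsv
Rscript inst/cli/pmil.R score    --input graph.tsv --method pmil --seed 1 --out results/
Rscript inst/cli/pmil.R evaluate --input graph.tsv --k 10 --seed 1 --out results/
```

Inputs are two-column (tab or comma) edge lists, column 1 = side U; outputs
are TSV artifacts (`projected.tsv`, `pattern_weights.tsv`, `ranking.tsv`,
`evaluation.tsv/.json`) that round-trip through the package's readers.

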