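---
title: "Potential energy and mutual information for bipartite link prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Potential energy and mutual information for bipartite link prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmil)
```

## The problem

Many relational data sets in biology and beyond are *bipartite*: drugs and
the proteins they bind, users and the items they rate, people and the events
they attend. Edges only ever join the two sides. Observed networks are
snapshots — interactions may be missing because they have not happened yet or
because the assay never probed them — and link prediction asks which absent
cross-side pairs are most likely to be real. Classic unipartite indices such
as common neighbours rely on triangle closure, which cannot occur inside a
bipartite graph (any two same-side nodes are non-adjacent by construction),
so they cannot be applied directly.

`pmil` addresses this with a three-step pipeline: project one side to a
weighted unipartite graph, weight each projected edge by combining three
complementary signals, and rank candidate cross-side pairs by the total
weight of the projected edges that back them.

## The model

**Weighted projection.** For a bipartite graph $G(U, V, E)$, the $U$-side
projection joins $A, B \in U$ whenever they share at least one neighbour in
$V$, with weight $WP(A,B) = |\Gamma(A) \cap \Gamma(B)|$, the shared-neighbour
count. A simple (0/1) projection discards exactly the multiplicity
information that distinguishes, say, two drugs with one common target from
two drugs with ten; the weighted projection keeps it. Each projected edge is
a *pattern*: evidence that connections of that shape already exist.

**Potential energy.** By analogy with $mgh$, a node pair's potential energy
on the projection is

$$PE(A,B) = d_A d_B \cdot \Big(\sum_{z \in \Gamma(A)\cap\Gamma(B)} cl_z\Big)
\cdot \frac{1}{sd(A,B)},$$

the degree product (mass: hubs attract links), the summed local clustering
coefficient of the common neighbours (field strength: triadic cohesion), and
the inverse shortest distance (height: near pairs connect sooner). When the
pair has no common neighbour the middle factor is replaced by a small
positive constant (default `no_cn_constant = 0.1`), so degree and distance
still separate such pairs instead of collapsing them all to zero.

**Mutual information.** The MI score treats link formation as an event whose
self-information $-\log p$ is reduced by knowing the pair's common
neighbours:

$$S^{MI}_{xy} = \sum_{z \in O_{xy}} I(L^1;z) \;-\; I(L^1_{xy}),$$

where $I(L^1;z)$ is the mean mutual information between $z$ and the link
status of its neighbour pairs, estimated from $z$'s clustering coefficient
and the pairwise no-link probability
$p(L^0_{mn}) = \binom{T_l - d_m}{d_n} / \binom{T_l}{d_n}$ ($T_l$ = projected
edge count, no degree correlation assumed). Common neighbours are treated as
independent evidence, so their contributions add. The score is symmetric and
may be negative: a pair whose degrees make a link likely a priori but that
has no supporting neighbourhood is penalised.

**Pattern weight and PMIS.** Each pattern gets the raw sum
$W_t(A,B) = PE(A,B) + S^{MI}_{AB} + WP(A,B)$, deliberately without
normalisation — the three terms live on different scales (WP is an integer
$\ge 1$, PE is typically small, MI is in bits) and the combined score is
defined as their plain sum; the fitted object keeps all three components so
users can inspect the mix. The prediction score of a cross-side candidate
$(A, i)$ is

$$PMIS(A,i) = \sum_{\{A,B\} \in \Gamma(A,i)} W_t(A,B),$$

summed over the patterns $\{A, B\}$ with $B$ both a projected neighbour of
$A$ and a bipartite neighbour of $i$. Every disconnected pair is scored, not
just a pre-filtered candidate list. Higher PMIS means a likelier edge.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `side` | `"auto"` | side to project; `auto` picks the smaller side, which keeps the cubic MI stage on the cheaper projection |
| `no_cn_constant` | 0.1 | clustering-sum stand-in for pairs without common neighbours (dimensionless, must be > 0) |
| `log_base` | 2 | base of all information terms; bits by default. Rankings are invariant to the base, so this only changes the scale of the MI component |
| `eps` | 1e-10 | probability clamp floor (see below) |
| `disconnected_value` | 0 | PE of pairs in different components — the continuous limit of $1/sd \to 0$ |

## Numerical choices

* **Clamping.** A zero clustering coefficient makes the conditional
  self-information $-\log C_z$ infinite, and a forced or impossible link does
  the same to $-\log p(L^1)$. All probabilities are clamped into
  $[\varepsilon, 1]$ with $\varepsilon = 10^{-10}$ before logs. Every score
  is therefore finite, and the clamp is far below any probability a graph of
  realistic size produces, so orderings are preserved. Whether to clamp,
  skip or smooth these degenerate events is a genuinely open choice; we
  clamp and document it.
* **Log-space binomials.** $\binom{T_l-d_m}{d_n}/\binom{T_l}{d_n}$ is
  evaluated via log-gamma, so projected graphs with tens of thousands of
  edges do not overflow. The degree pair is canonicalised (sorted) first so
  the documented symmetry $p(L^0_{mn}) = p(L^0_{nm})$ holds bitwise, not
  just mathematically.
* **Degree < 2 nodes** admit no neighbour pair, so $I(L^1;z)$ is undefined
  for them; they are skipped in the evidence sum. (A common neighbour of a
  scored pair always has degree $\ge 2$, so this only matters for direct
  queries.) The clustering coefficient of such nodes is defined as 0.
* **Ordered vs unordered pairs.** The normaliser
  $|\Gamma(z)|(|\Gamma(z)|-1)$ counts ordered pairs; each unordered pair's
  symmetric term appears twice, so the ordered-pair mean equals the
  unordered-pair mean. The implementation uses the unordered form; the test
  oracle uses the literal ordered loop; they agree to machine precision.
* **Determinism.** Node order is first-seen everywhere; unordered pairs are
  keyed by lexicographically sorted identifiers; ranking ties break by
  first-seen node index. Two runs with the same input and seed are
  byte-identical.
* **Degenerate inputs.** Empty graphs project to empty graphs; isolated
  nodes carry degree 0 and PE 0; an edgeless projection has $T_l = 0$, where
  the no-link probability is undefined and queried as an error rather than a
  silent value.

## Evaluation protocol

`evaluate_predictor()` runs repeated K-fold edge holdout (default $K = 10$,
i.e. 90/10 splits). Per fold the predictor is fitted on the training graph
and all non-training pairs are ranked. Four metrics:

* **AUC**, in its sampling form: $N_t$ independent draws of one probe link
  and one nonexistent link, $AUC = (N_h + 0.5\,N_s)/N_t$. We default to
  $N_t = 10{,}000$ per fold and expose it; the exact rank AUC is the
  $N_t \to \infty$ limit, and the estimator is tested to converge to it.
  Nonexistent links are pairs absent from both training and probe sets.
* **Precision** at cutoff $L$, defaulting to the probe-set size — the
  standard choice when no cutoff is prescribed; exposed as a flag.
* **Prediction power** $\log_{10}(P_{method}/P_{random})$ with
  $P_{random} = L/(|U||V| - (E_{train} - L))$, $E_{train}$ the training edge
  count.
* **Precision@K** for $K \in \{10, 20, 50\}$ by default.

Probe edges stay in the ranked candidate pool (the standard protocol;
excluding them would make precision trivially 0 at full recall of the
training non-edges). Fold metrics are averaged arithmetically; `repeats`
independent K-fold rounds can be stacked, each deriving its own sub-seed
from the root seed.

## What the synthetic generator does and does not emulate

`generate_bipartite()` produces graphs spanning the size and density regimes
of the two-mode data sets this method targets — sides from tens to thousands
of nodes, average degree from ~1 to ~40 — under either a uniform edge model
or a preferential-attachment model whose right-skewed degree distributions
resemble hub-dominated drug-target and user-item data. Isolated nodes are
allowed by default, matching sparse real networks; `min_degree_one` forces a
spanning assignment first when a connected-ish fixture is wanted.

The generator does **not** reproduce community structure, degree
correlations, bipartite nestedness, or the measurement biases of any real
assay. Passing tests on these fixtures therefore demonstrates correctness of
the computation and above-chance recovery of planted structure, not
performance claims on any particular real data set.

## Design decisions taken where the design was open

* The MI and PE stages run on the **unweighted skeleton** of the projection;
  $WP$ enters only as the third summand of $W_t$. The information and
  energy formulas are stated for plain graphs, and mixing the multiplicity
  into degrees or distances would double-count it.
* Baselines (CN, JC, PA, CS) are adapted to bipartite inputs by comparing
  the projected neighbourhood $N_u(a)$ with the bipartite neighbourhood
  $N(i)$ — the same geometry the pattern-covered construction uses. This is
  our convention, stated here because unipartite indices admit several
  bipartite liftings.
* PE is computed between same-side (projected) pairs only; the candidate
  score consumes pattern weights, never a cross-side PE.
* $W_t$ is used as-is even when negative; the definition imposes no floor,
  and flooring would silently reorder candidates.

## Problem sizes

The package's test-and-demonstration scale is deliberate desk scale: oracle
equivalence on a hundred random graphs of up to 15+15 nodes, recovery
experiments on 20x20 graphs with 120 preferential edges and 10% holdout
across ten seeds, and 10,000-comparison AUC estimates. The implementation
itself is limited by the $O(|P|^3)$ MI stage on the projected side $P$, which
is why `side = "auto"` projects the smaller side.

## Worked example

```{r example}
set.seed(1)
g <- generate_bipartite(n_u = 20, n_v = 20, n_edges = 120,
                        degree_model = "preferential", seed = 11)
fit <- pmil(g)
fit
head(predict(fit))
```

```{r eval-example}
ev <- evaluate_predictor(g, method = "pmil", k = 10,
                         n_comparisons = 5000, seed = 2)
ev
```

## Known limitations

* Input bipartite edges are unweighted; interaction-probability weights are
  a natural extension the current score does not consume.
* The independence assumption behind the MI evidence sum ignores
  correlations among common neighbours; densely overlapping neighbourhoods
  are credited more than once.
* The all-pairs candidate scoring is quadratic in the side sizes and the MI
  stage cubic in the projected side; very large networks need candidate
  restriction, which the `candidates` argument supports but the package does
  not automate.
* Local-community (CAR-family), matrix-factorisation and random-walk
  predictors are outside the package's scope; the built-in baselines are the
  neighbourhood quartet.
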