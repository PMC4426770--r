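---
title: "Aligning uncertain biological networks: model, method, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning uncertain biological networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probnetalign)
```

## The problem

Protein–protein interaction data are noisy: an interaction detected by a
high-throughput assay exists with some confidence, not with certainty. A
natural representation is an *uncertain network* `g = (V, E, Pr_E)`: an
undirected graph whose edges each exist independently with a stated
probability `p_e` in `(0, 1]`. Such a network is a compact encoding of
`2^|E|` deterministic *implication graphs* (possible worlds), each occurring
with probability

```
Pr(g => G) = prod_{e in E'} p_e * prod_{e in E \ E'} (1 - p_e).
```

Global network alignment asks for a one-to-one correspondence between the
node sets of two networks that preserves interaction structure and, when
available, sequence similarity. `probnetalign` aligns two *fully* uncertain
networks; networks with all probabilities equal to 1 are handled by the
identical code path, so deterministic and half-probabilistic alignment are
special cases rather than separate algorithms.

## The model

### IsoRank recurrence and its random analogue

For deterministic networks the IsoRank similarity `R_ij` between node `i`
of network 1 and node `j` of network 2 satisfies the neighbor-support
recurrence `R = A R`, where the `(mn) x (mn)` support matrix has entries

```
A[i,j][u,v] = 1/(d_u d_v)  if (v_i, v_u) in E1 and (v_j, v_v) in E2
            = 1/mn         if d_u d_v = 0      (acnode / isolated pair)
            = 0            otherwise.
```

When edges are probabilistic, degrees `D_u`, `D_v` become independent
random variables and `A` becomes a random matrix. Rather than enumerate
worlds, the method computes the entrywise expectation `E(A)` and solves

```
R = alpha * E(A) R + (1 - alpha) * E,
```

where `E` (the blend vector) is the L1-normalized sequence-similarity
table and `alpha` balances topology against sequence. The default
`alpha = 0.6` is the established best value for this family of methods.

### Degree PGFs

The degree of a node with incident edge probabilities `p_e` is a sum of
independent Bernoulli variables, so its probability generating function is
the product `Q_v(z) = prod_{e in E_v} (1 - p_e + p_e z)`; coefficient `k`
is `P(D_v = k)`. For the worked two-edge example with probabilities 0.4
and 0.9:

```{r}
g <- uncertain_network(c("a", "a"), c("b", "c"), c(0.4, 0.9))
node_degree_pgf(g, "a")
```

The entries of `E(A)` need the degree distribution *conditioned on one
incident edge being present*, which is obtained by dividing the PGF by
that edge's factor `(1 - p_e + p_e z)` (synthetic division in ascending
powers) and shifting the degree by one: `P(D_v = k | e)` is coefficient
`k - 1` of the quotient. This replaces an `O(2^d)` enumeration with an
`O((d_u^max d_v^max)^2)` computation overall.

Numerical notes on the division:

* when `p_e = 1` the divisor is `z`; division is an index shift, valid
  because an always-present incident edge forces a vanishing constant
  term — this case is special-cased rather than divided;
* quotient coefficients within `1e-9` of `[0, 1]` are clamped; larger
  excursions raise an error rather than being silently clipped.

### The expected support matrix

For each pair of candidate edges `e1 = (v_i, v_u)`, `e2 = (v_j, v_v)` (in
all four orientation combinations, since edges are undirected) the
topological contribution to entry `([i,j],[u,v])` factorizes as

```
S = E[1/D_u | e1] * E[1/D_v | e2],
```

each factor a sum `sum_k P(D = k | e) / k` over the conditional
distribution. Two deliberate deviations from the printed form of the
method are governed by a single `mode` flag:

* **Edge-existence factor.** The printed expectation formula conditions on
  both enabling edges existing but never multiplies by the probability
  that they do. Without the factor `p_e1 * p_e2` the quantity is a
  conditional, not marginal, expectation, and it fails the defining
  possible-worlds oracle (the probability-weighted average of the
  deterministic support matrix over all joint implication worlds).
  Default mode `exact` applies the factor; `paper_literal` reproduces the
  printed form for fidelity studies.
* **Acnode probability.** The printed isolated-pair probability
  `P(D_u = 0) + P(D_v = 0)` double-counts the event that both degrees are
  zero (and can exceed 1, in which case it is clamped with a warning);
  `exact` mode applies inclusion–exclusion. The same flag governs both
  choices to avoid incoherent mixtures.

With these corrections, `E(A)` in exact mode is column-stochastic —
every possible world's support matrix is, and expectation preserves it —
which is what makes the blended power iteration a contraction.

The acnode term depends only on the column pair `(u, v)` and applies to
*every* row, a dense rank-one structure. It is stored implicitly as a
per-column additive weight and applied during matrix–vector products
(`sm_matvec()`), keeping the stored matrix sparse. Node pairs are
flattened row-major: `[i, j] -> (i - 1) * n + j`.

The ambiguity of whether an edge-adjacent pair should use conditional or
unconditional degree distributions in its acnode term is resolved in
favor of unconditional ones (the isolated-pair probability is defined on
the plain `D_u`, `D_v`).

### Iteration and extraction

`power_iterate()` starts from the uniform vector `R_0 = 1/mn` and repeats
`R <- alpha E(A) R + (1 - alpha) E` with L1 renormalization each step,
stopping when successive iterates differ by at most `eps` in L1
(defaults: `eps = 1e-6`, `max_iter = 1000`; the convergence constant is
only required to be "sufficiently small", so the default is a
conventional choice). In exact mode the renormalization is a no-op up to
roundoff; in literal mode it is load-bearing. The reported residual is
measured against the renormalized map, and on convergence satisfies
`||R - N(alpha E(A) R + (1-alpha) E)||_1 <= eps * (1 + alpha)`.
Non-convergence at `max_iter` returns a flagged result with a warning,
not an error.

`extract_alignment()` treats `R` as the weight matrix of the complete
bipartite graph on the two node sets and finds a maximum-weight matching
of cardinality `min(m, n)` with an `O(n^3)` Hungarian
(potential/shortest-augmenting-path) implementation. Design notes:

* rectangular instances are padded with zero-weight dummy nodes; with
  nonnegative weights the optimum over perfect matchings of the padded
  square equals the optimum over injections of the smaller side;
* the textbook potential feasibility condition is stated for the
  minimum-cost direction; maximum-weight matching needs the opposite
  inequality. The implementation solves min-cost on negated weights,
  which is equivalent and sidesteps the sign question;
* ties among weight-optimal matchings are broken deterministically toward
  the lexicographically smallest row-sorted pair list (needed for
  reproducible agreement scores). The refinement fixes pairs greedily and
  re-solves the remainder, an `O(mn)` extra Hungarian solves; it is
  applied when `m * n <= 400` and skipped above that, where the plain
  (still deterministic) Hungarian output is used.

## Evaluation metrics

* `agreement()`: fraction of aligned pairs shared by two alignments. The
  natural denominator is ambiguous; the default is the Jaccard form
  (intersection over union), which stays well defined for alignments of
  unequal cardinality, with `denominator = "size"` available.
* `goc()`: mean Jaccard overlap of GO term sets over aligned pairs. The
  quantity is stated to lie in `[0, 1]`, so the sum is normalized by the
  number of counted pairs; pairs with both term sets empty are skipped by
  default (`0/0` undefined), or counted as zero with
  `unannotated = "zero"`. Raw term sets are compared; GO graph semantics
  (ancestor closure, information content) are out of scope.
* `gnas()`: `alpha * |E| + (1 - alpha) * sum seq(u, v)`, with `|E|` the
  number of *conserved interactions* — aligned couples whose endpoints
  interact in both networks. For uncertain edges, `support` mode counts
  any positive-probability edge as present; `expected` mode sums
  `p1 * p2`, the expected conserved count over worlds (verified against
  the enumeration oracle in the tests).

## Synthetic data and oracles

The generator emulates the scale of the curated PPI benchmark networks
used for this problem family (tens of nodes, a comparable number of
interactions — e.g. a 14-node network with about 10 expected
interactions): Erdős–Rényi topology at a configurable density, edge
probabilities from a uniform, beta, or constant law (floored at `1e-6` to
stay on `(0, 1]`). `perturb_network()` produces a relabeled, shuffled
copy with edges toggled at a flip rate and probabilities jittered (the
jitter clamps rather than drops, so topology change is controlled solely
by the flip rate), returning the planted correspondence.
`generate_seqsim()` scores true pairs `signal + noise * U(0,1)` and
decoys `noise * U(0,1)`.

Defaults were chosen once as a realistic regime for this scale — density
0.15–0.3, probabilities in `U(0.5, 1)` (detected interactions are usually
more likely present than absent), flip rate 0.05, signal-to-noise 5–10 —
and are not tuned against test outcomes.

What a green planted-recovery test establishes: on networks of this
scale, with modest topological perturbation and informative sequence
similarity, the pipeline recovers the planted mapping. What it does not
establish: performance on scale-free or duplication–divergence
topologies, on networks orders of magnitude larger, or against curated
GO annotation — real PPI data have degree heterogeneity and correlated
noise the generator does not emulate.

Two brute-force oracles back the test suite: `oracle_expected_support()`
(possible-worlds average of the deterministic support matrix, capped at
10 total edges) and `oracle_max_matching()` (exhaustive injections,
capped at a 7-node smaller side). They share no code with the paths they
check.

## Degenerate inputs and edge cases

* probability-0 edges are dropped on load (they exist in no world);
  their endpoints remain as nodes;
* isolated nodes are legal and exercised — they are exactly the acnode
  branch;
* an all-zero or absent sequence-similarity table yields the uniform
  blend vector `1/mn`, so the blend term carries no information rather
  than zeroing the iteration;
* `alpha = 0` returns the normalized sequence vector exactly;
  `alpha = 1` is pure topology;
* two empty alignments agree vacuously (agreement 1); a GOC over pairs
  with no annotation at all is `NA` with a warning.

## Known limitations

* Edge probabilities are assumed independent; correlated uncertainty is
  out of scope.
* Node existence is certain; only interactions are probabilistic.
* One-to-one global alignment only — no many-to-many clusters, no local
  alignment, no multiple (>2) network alignment.
* The functional-coherence metric that maps terms onto a standardized
  GO-slim set requires an external resource and is intentionally absent.
* The dense `(mn) x (mn)` oracle and the lexicographic tie-break are for
  desk-scale instances; the sparse pipeline itself handles the benchmark
  scale (up to ~100-node networks) comfortably.
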