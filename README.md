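# probnetalign

Global alignment of **uncertain biological networks** — protein–protein
interaction graphs whose edges each exist independently with a stated
probability `p_e ∈ (0, 1]`. Such a network compactly encodes `2^|E|`
deterministic *implication graphs* (possible worlds). `probnetalign`
aligns two fully uncertain networks without enumerating worlds;
deterministic and half-probabilistic alignment fall out as the
all-probabilities-1 special case of the same code path.

Intended users: computational biologists comparing interaction networks
across species or conditions when interaction confidences should be
treated as probabilities rather than discarded or thresholded.

## Method in brief

The deterministic IsoRank recurrence scores node pairs by neighbor
support, `R = A R`, with

```
A[i,j][u,v] = 1/(d_u d_v)   if (v_i,v_u) ∈ E1 and (v_j,v_v) ∈ E2
            = 1/mn          if d_u d_v = 0   (isolated pair)
            = 0             otherwise.
```

With probabilistic edges the degrees `D_u`, `D_v` are random and so is
`A`. The package builds the entrywise expectation `E(A)` using
probability generating functions: the degree PGF of a node is
`Π_{e∈E_v}(1 − p_e + p_e z)`, and conditioning on one incident edge being
present divides out that factor. Entries factorize as
`p_e1 p_e2 · E[1/D_u | e1] · E[1/D_v | e2]` plus an isolated-pair term
`P(D_u D_v = 0)/mn`. The node-pair similarity vector solves

```
R = α E(A) R + (1 − α) E,       α = 0.6 by default,
```

by L1-normalized power iteration, where `E` is the normalized
sequence-similarity vector (e.g. BLAST bit scores). A one-to-one
alignment of cardinality `min(m, n)` is extracted by maximum-weight
bipartite matching (Hungarian method, deterministic lexicographic
tie-break). Alignment quality metrics: `agreement()` between two
alignments, `goc()` (GO-term Jaccard consistency), and `gnas()`
(`α·|conserved interactions| + (1−α)·Σ seq(u,v)`).

Exact-mode `E(A)` is validated in the test suite against a brute-force
possible-worlds oracle, and the matcher against exhaustive injection
enumeration. See `vignettes/uncertain-network-alignment.Rmd` for the full
model, the numerical choices, and the deliberate deviations from the
printed formulas (edge-existence factor, inclusion–exclusion acnode
probability) behind the `mode = "exact" | "paper_literal"` flag.

## Worked example

```r
library(probnetalign)

# the classic two-edge PGF example: incident probabilities 0.4 and 0.9
g <- uncertain_network(c("a", "a"), c("b", "c"), c(0.4, 0.9))
node_degree_pgf(g, "a")
#> [1] 0.06 0.58 0.36
```

`P(degree = 0) = 0.06`, `P(degree = 1) = 0.58`, `P(degree = 2) = 0.36` —
the coefficients of `(0.6 + 0.4z)(0.1 + 0.9z)`.

A full synthetic alignment with a planted correspondence:

```r
g1   <- generate_uncertain_network(
          generator_config(12, 0.3, prob_uniform(0.5, 1), seed = 42))
pert <- perturb_network(g1, edge_flip_rate = 0.05, prob_jitter = 0.1, seed = 43)
ss   <- generate_seqsim(pert$mapping, signal = 10, noise = 1, seed = 44)
res  <- align_networks(g1, pert$network, seqsim = ss)
res
#> <alignment result (exact mode, alpha = 0.6)>
#> <similarity vector 12 x 12: 16 iteration(s), residual 3.09e-07>
#> <alignment: 12 pair(s), total weight 0.369478>
#>    node1 node2      score
#> 1   n001  m012 0.03284209
#> 2   n002  m008 0.03064885
#> ...

gnas(res$alignment, g1, pert$network, seqsim = ss, conserved_mode = "expected")
#> GNAS = 53.8365 (alpha = 0.6, conserved = 6.42742 [expected], seq sum = 124.95)
```

Here the alignment recovers all 12 planted node pairs; the `score` column
is each pair's share of the converged similarity vector, `conserved` is
the expected number of aligned interaction pairs preserved across the two
networks, and `seq sum` the summed raw sequence similarity of the aligned
pairs.

## Command line

```sh
# installed wrapper script:
CLI=$(Rscript -e 'cat(system.file("cli", "probnetalign", package = "probnetalign"))')
Rscript "$CLI" simulate --out-prefix sim --n-nodes 12 --density 0.3 --seed 7
Rscript "$CLI" align --net1 sim_net1.tsv --net2 sim_net2.tsv \
        --seqsim sim_seqsim.tsv --alpha 0.6 --out sim_alignment.tsv
Rscript "$CLI" eval  --net1 sim_net1.tsv --net2 sim_net2.tsv \
        --alignment sim_alignment.tsv --annotations sim_annotations.tsv \
        --out sim_metrics.tsv
Rscript "$CLI" dump-degrees --net sim_net1.tsv
```

Network files are TSV edge lists `node_a<TAB>node_b<TAB>probability`
(probability column optional, default 1; `#` comment lines allowed). A
JSON file passed as `--config run.json` supplies flag defaults; explicit
flags override it. Every output starts with `#` header lines recording
the tool version, effective configuration, and input MD5 checksums.

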