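# Shared fixtures and brute-force oracles. All expected values asserted in
# the unit tests were either computed by these enumeration oracles or taken
# from tiny closed-form cases.

withr_local_tempfile <- function() tempfile(fileext = ".tsv")

# mirror of the package-internal trailing-zero normalization
poly_trim_for_test <- function(coef) {
  n <- length(coef)
  while (n > 1 && coef[n] == 0) n <- n - 1
  coef[seq_len(n)]
}

# the two-edge worked example: node "a" with incident probabilities 0.4, 0.9
worked_example_network <- function() {
  uncertain_network(c("a", "a"), c("b", "c"), c(0.4, 0.9))
}

# random small uncertain network (reproducible)
random_small_network <- function(seed, n = 4, density = 0.5,
                                 law = prob_uniform(0.2, 0.95)) {
  generate_uncertain_network(generator_config(n, density, law, seed = seed))
}

# degree distribution of v by enumerating all 2^|E_v| incident-edge subsets
enum_degree_distribution <- function(g, v) {
  vi <- match(v, g$nodes)
  rows <- which(g$edges$i == vi | g$edges$j == vi)
  p <- g$edges$p[rows]
  ne <- length(p)
  probs <- numeric(ne + 1)
  for (mask in seq_len(2^ne) - 1L) {
    present <- if (ne) bitwAnd(mask, bitwShiftL(1L, seq_len(ne) - 1L)) > 0
               else logical(0)
    probs[sum(present) + 1L] <- probs[sum(present) + 1L] +
      prod(ifelse(present, p, 1 - p))
  }
  probs
}

# conditional degree distribution of v given edge (v, other) is present:
# enumerate only worlds containing the edge and renormalize.
# Returns P(D_v = k | e) for k = 1..d_max.
enum_conditional_distribution <- function(g, v, other) {
  vi <- match(v, g$nodes)
  oi <- match(other, g$nodes)
  rows <- which(g$edges$i == vi | g$edges$j == vi)
  cond <- which(g$edges$i[rows] %in% c(vi, oi) &
                g$edges$j[rows] %in% c(vi, oi))
  stopifnot(length(cond) == 1)
  p <- g$edges$p[rows]
  ne <- length(p)
  probs <- numeric(ne)
  total <- 0
  for (mask in seq_len(2^ne) - 1L) {
    present <- bitwAnd(mask, bitwShiftL(1L, seq_len(ne) - 1L)) > 0
    if (!present[cond]) next
    w <- prod(ifelse(present, p, 1 - p))
    probs[sum(present)] <- probs[sum(present)] + w
    total <- total + w
  }
  probs / total
}

# deterministic conserved-interaction count of an alignment (for the GNAS
# possible-worlds oracle)
det_conserved_count <- function(a, G1, G2) {
  i1 <- match(a$pairs$node1, G1$nodes)
  i2 <- match(a$pairs$node2, G2$nodes)
  k1 <- paste(G1$edges$i, G1$edges$j)
  k2 <- paste(G2$edges$i, G2$edges$j)
  count <- 0
  K <- nrow(a$pairs)
  if (K < 2) return(0)
  for (k in seq_len(K - 1)) {
    for (l in (k + 1):K) {
      has1 <- paste(min(i1[k], i1[l]), max(i1[k], i1[l])) %in% k1
      has2 <- paste(min(i2[k], i2[l]), max(i2[k], i2[l])) %in% k2
      if (has1 && has2) count <- count + 1
    }
  }
  count
}

# fraction of the planted mapping recovered by an alignment
recovery_rate <- function(aln, mapping) {
  planted <- paste(mapping$node1, mapping$node2, sep = "\r")
  got <- paste(aln$pairs$node1, aln$pairs$node2, sep = "\r")
  mean(planted %in% got)
}
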