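# Synthetic uncertain networks with planted alignments, plus brute-force
# possible-worlds oracles used by the test suite. Generator scales follow
# the MINT-derived benchmark statistics (tens of nodes, comparable
# interaction counts); everything is bit-reproducible from a seed.

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generator configuration for synthetic uncertain networks
#'
#' @param n_nodes number of nodes (>= 2).
#' @param density expected fraction of present node pairs, in `(0, 1]`.
#' @param prob_law edge-probability law: one of
#'   `prob_uniform(lo, hi)`, `prob_beta(a, b)`, `prob_constant(p)`.
#'   Laws are clamped to a floor of `1e-6` so they stay supported on
#'   `(0, 1]`.
#' @param seed integer RNG seed.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_nodes, density, prob_law = prob_uniform(),
                             seed = 1L) {
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 2L) stop("`n_nodes` must be >= 2")
  if (!is.numeric(density) || density <= 0 || density > 1) {
    stop("`density` must lie in (0, 1]")
  }
  if (!inherits(prob_law, "prob_law")) stop("`prob_law` must be a prob_* law")
  structure(list(n_nodes = n_nodes, density = density, prob_law = prob_law,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' @rdname generator_config
#' @param lo,hi uniform law bounds in `(0, 1]`.
#' @export
prob_uniform <- function(lo = 0.5, hi = 1) {
  if (lo < 0 || hi > 1 || lo > hi) stop("need 0 <= lo <= hi <= 1")
  structure(list(kind = "uniform", lo = lo, hi = hi), class = "prob_law")
}

#' @rdname generator_config
#' @param a,b beta law shape parameters.
#' @export
prob_beta <- function(a = 2, b = 2) {
  if (a <= 0 || b <= 0) stop("beta shapes must be positive")
  structure(list(kind = "beta", a = a, b = b), class = "prob_law")
}

#' @rdname generator_config
#' @param p constant probability in `(0, 1]`.
#' @export
prob_constant <- function(p = 1) {
  if (p <= 0 || p > 1) stop("constant probability must lie in (0, 1]")
  structure(list(kind = "constant", p = p), class = "prob_law")
}

draw_probs <- function(law, k) {
  x <- switch(law$kind,
              uniform = stats::runif(k, law$lo, law$hi),
              beta = stats::rbeta(k, law$a, law$b),
              constant = rep(law$p, k),
              stop("unknown probability law: ", law$kind))
  pmin(pmax(x, 1e-6), 1)
}

#' Generate a synthetic uncertain network
#'
#' Erdos-Renyi topology: each of the `choose(n, 2)` node pairs is an edge
#' independently with probability `density`; each edge's existence
#' probability is drawn from the configured law. Fully reproducible from
#' the seed.
#'
#' @param config a [generator_config()].
#' @return an [uncertain_network()] with nodes `n01, n02, ...`.
#' @export
generate_uncertain_network <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    n <- config$n_nodes
    labels <- sprintf("n%03d", seq_len(n))
    pairs <- utils::combn(n, 2)
    present <- stats::runif(ncol(pairs)) < config$density
    k <- sum(present)
    p <- draw_probs(config$prob_law, k)
    uncertain_network(labels[pairs[1, present]], labels[pairs[2, present]],
                      p, nodes = labels)
  })
}

#' Perturb a network, planting a known node correspondence
#'
#' Returns a relabeled, node-shuffled copy in which each node pair's
#' edge/non-edge status is toggled independently with probability
#' `edge_flip_rate`, and surviving edge probabilities receive additive
#' uniform jitter of half-width `prob_jitter` (clamped to a floor of
#' `1e-6` rather than dropped, so topology change is controlled solely by
#' the flip rate). Newly created edges draw a fresh probability from
#' `U(0, 1)` (same floor). The true node correspondence is returned
#' alongside.
#'
#' @param g an [uncertain_network()].
#' @param edge_flip_rate toggle probability per node pair, in `[0, 1]`.
#' @param prob_jitter jitter half-width, in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return `list(network = <uncertain_network>, mapping = <data frame
#'   with columns node1 (label in g), node2 (label in the copy)>)`.
#' @export
perturb_network <- function(g, edge_flip_rate = 0, prob_jitter = 0, seed = 1L) {
  stopifnot(inherits(g, "uncertain_network"))
  if (edge_flip_rate < 0 || edge_flip_rate > 1) {
    stop("`edge_flip_rate` must lie in [0, 1]")
  }
  if (prob_jitter < 0 || prob_jitter > 1) stop("`prob_jitter` must lie in [0, 1]")
  with_seed(seed, {
    n <- n_nodes(g)
    perm <- sample(n)               # position in the copy of original node k
    new_labels <- sprintf("m%03d", seq_len(n))
    P <- matrix(0, n, n)            # probability matrix, 0 = absent
    if (n_edges(g)) P[cbind(g$edges$i, g$edges$j)] <- g$edges$p
    pairs <- utils::combn(n, 2)
    np <- ncol(pairs)
    flip <- stats::runif(np) < edge_flip_rate
    jit <- stats::runif(np, -prob_jitter, prob_jitter)
    fresh <- stats::runif(np)
    from <- character(0); to <- character(0); prob <- numeric(0)
    for (k in seq_len(np)) {
      i <- pairs[1, k]; j <- pairs[2, k]
      present <- P[i, j] > 0
      if (flip[k]) present <- !present
      if (!present) next
      p <- if (P[i, j] > 0 && !flip[k]) P[i, j] + jit[k] else fresh[k]
      p <- min(max(p, 1e-6), 1)
      from <- c(from, new_labels[perm[i]])
      to <- c(to, new_labels[perm[j]])
      prob <- c(prob, p)
    }
    list(network = uncertain_network(from, to, prob, nodes = new_labels),
         mapping = data.frame(node1 = g$nodes, node2 = new_labels[perm]))
  })
}

#' Generate synthetic sequence similarities for a planted mapping
#'
#' True (planted) pairs score `signal + noise * U(0, 1)`; every decoy
#' pair scores `noise * U(0, 1)`. With `noise = 0` the table exactly
#' indicates the mapping; with `signal = 0` it carries no information.
#'
#' @param mapping data frame with columns `node1`, `node2` (the planted
#'   correspondence, covering both node sets).
#' @param signal,noise nonnegative scalars.
#' @param seed integer RNG seed.
#' @return a data frame with columns `node1`, `node2`, `score`.
#' @export
generate_seqsim <- function(mapping, signal = 5, noise = 1, seed = 1L) {
  if (signal < 0 || noise < 0) stop("`signal` and `noise` must be nonnegative")
  with_seed(seed, {
    grid <- expand.grid(node1 = mapping$node1, node2 = mapping$node2,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    planted <- paste(mapping$node1, mapping$node2, sep = "\r")
    is_true <- paste(grid$node1, grid$node2, sep = "\r") %in% planted
    grid$score <- noise * stats::runif(nrow(grid)) + signal * is_true
    grid
  })
}

#' Generate synthetic GO-style annotations for a planted mapping
#'
#' Each planted pair shares a pool of terms: `terms_per_node` terms are
#' drawn for the network-1 node, and the partner inherits each with
#' probability `consistency` (replacing the rest with random terms).
#' Purely synthetic stand-in for curated GO annotation.
#'
#' @param mapping planted correspondence (columns `node1`, `node2`).
#' @param n_terms size of the term vocabulary.
#' @param terms_per_node terms drawn per node.
#' @param consistency probability a partner inherits each term.
#' @param seed integer RNG seed.
#' @return an [annotation_map()] covering the nodes of both networks.
#' @export
generate_annotations <- function(mapping, n_terms = 50, terms_per_node = 3,
                                 consistency = 0.8, seed = 1L) {
  with_seed(seed, {
    vocab <- sprintf("GO:%07d", seq_len(n_terms))
    out <- list()
    for (k in seq_len(nrow(mapping))) {
      t1 <- sample(vocab, min(terms_per_node, n_terms))
      inherit <- stats::runif(length(t1)) < consistency
      t2 <- ifelse(inherit, t1, sample(vocab, length(t1), replace = TRUE))
      out[[mapping$node1[k]]] <- t1
      out[[mapping$node2[k]]] <- unique(t2)
    }
    annotation_map(out)
  })
}

#' Possible-worlds oracle for the expected support matrix
#'
#' Exact `E(A)` as the probability-weighted average of the deterministic
#' support matrix over all `2^(|E1| + |E2|)` joint implication worlds.
#' Exponential; refused above the edge cap. This is the defining oracle
#' that [expected_support_matrix()] (exact mode) must reproduce.
#'
#' @param g1,g2 [uncertain_network()]s.
#' @param max_total_edges refuse instances with `|E1| + |E2|` above this
#'   (default 10).
#' @return a dense `(mn) x (mn)` matrix.
#' @export
oracle_expected_support <- function(g1, g2, max_total_edges = 10) {
  if (n_edges(g1) + n_edges(g2) > max_total_edges) {
    stop(sprintf("instance has %d + %d edges; oracle capped at %d total",
                 n_edges(g1), n_edges(g2), max_total_edges))
  }
  worlds1 <- enumerate_implication_graphs(g1)
  worlds2 <- enumerate_implication_graphs(g2)
  mn <- n_nodes(g1) * n_nodes(g2)
  acc <- matrix(0, mn, mn)
  for (w1 in worlds1) {
    for (w2 in worlds2) {
      wt <- w1$probability * w2$probability
      if (wt == 0) next
      acc <- acc + wt * as.matrix(deterministic_support_matrix(w1$network,
                                                               w2$network))
    }
  }
  acc
}

#' Exhaustive maximum-weight matching oracle
#'
#' Brute force over all injections of the smaller side into the larger.
#' Factorial; refused above the size cap.
#'
#' @param W numeric `m x n` weight matrix with `min(m, n) <= cap`.
#' @param cap maximum smaller-side size (default 7).
#' @return `list(rows, cols, weight)` of a maximizing injection.
#' @export
oracle_max_matching <- function(W, cap = 7) {
  W <- as.matrix(W)
  m <- nrow(W)
  n <- ncol(W)
  if (min(m, n) > cap) {
    stop(sprintf("smaller side has %d nodes; oracle capped at %d",
                 min(m, n), cap))
  }
  flip <- m > n
  A <- if (flip) t(W) else W       # rows are the smaller side
  nr <- nrow(A)
  nc <- ncol(A)
  best <- -Inf
  best_cols <- integer(0)
  cols <- integer(nr)
  used <- logical(nc)
  recurse <- function(row, acc) {
    if (row > nr) {
      if (acc > best) {
        best <<- acc
        best_cols <<- cols[seq_len(nr)]
      }
      return(invisible())
    }
    for (j in seq_len(nc)) {
      if (used[j]) next
      used[j] <<- TRUE
      cols[row] <<- j
      recurse(row + 1L, acc + A[row, j])
      used[j] <<- FALSE
    }
  }
  recurse(1L, 0)
  if (flip) list(rows = best_cols, cols = seq_len(nr), weight = best)
  else list(rows = seq_len(nr), cols = best_cols, weight = best)
}
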