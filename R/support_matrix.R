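# Expected support matrix E(A) of the random IsoRank matrix for two
# uncertain networks. Entry ([i,j],[u,v]) couples node pair (v_i, v_j) to
# the neighboring pair (v_u, v_v): in a possible world it is 1/(d_u d_v)
# when (v_i,v_u) and (v_j,v_v) are edges, 1/mn when d_u d_v = 0 (acnode),
# and 0 otherwise. The expectation factorizes through conditional degree
# PGFs, avoiding world enumeration.
#
# Storage: the topological part is a sparse (mn)x(mn) matrix; the acnode
# part depends only on the column pair (u,v) and is added to every row,
# i.e. it is the rank-one structure 1 %o% acnode. It is kept implicit and
# applied during matrix-vector products.

# row-major flattening of a node pair: ([i, j]) -> (i - 1) * n + j
flat_index <- function(i, j, n) (i - 1L) * n + j

new_support_matrix <- function(m, n, topo, acnode, mode, labels1, labels2) {
  structure(list(m = m, n = n, topo = topo, acnode = acnode, mode = mode,
                 labels1 = labels1, labels2 = labels2),
            class = "support_matrix")
}

#' Acnode (isolated-pair) probability
#'
#' Probability that the product of two independent node degrees is zero,
#' i.e. at least one of the nodes is isolated. `paper_literal` mode uses
#' the additive form `P(D_u = 0) + P(D_v = 0)` (clamped to 1 with a
#' warning if it exceeds 1); `exact` mode applies inclusion-exclusion
#' under independence.
#'
#' @param du,dv [degree_distribution()] objects (or bare probability
#'   vectors with `P(D = 0)` first).
#' @param mode `"exact"` (default) or `"paper_literal"`.
#' @return a probability in `[0, 1]`.
#' @export
acnode_probability <- function(du, dv, mode = c("exact", "paper_literal")) {
  mode <- match.arg(mode)
  p0u <- dd_p0(du)
  p0v <- dd_p0(dv)
  if (mode == "exact") {
    p0u + p0v - p0u * p0v
  } else {
    s <- p0u + p0v
    if (s > 1) {
      warning("literal acnode probability exceeds 1; clamped")
      s <- 1
    }
    s
  }
}

# sum_k coefficient[k] / k over the conditional degree distribution,
# i.e. E[1/D | e present] for the shifted quotient PGF q (q[t] is the
# probability that degree = t given the conditioning edge is present)
conditional_inverse_moment <- function(pgf, p) {
  q <- poly_divide_linear(pgf, p)
  sum(q / seq_along(q))
}

#' Expected support matrix of two uncertain networks
#'
#' For each candidate pair of edges `e1 = (v_i, v_u)` in network 1 and
#' `e2 = (v_j, v_v)` in network 2 (in all four orientation combinations
#' of the undirected edges), the topological contribution to entry
#' `([i,j],[u,v])` is
#' `S = sum_{k1,k2 >= 1} P(D_u = k1 | e1) P(D_v = k2 | e2) / (k1 k2)`,
#' computed from conditional degree PGFs. In `exact` mode `S` is
#' multiplied by `p_e1 p_e2` (the probability that the enabling edges
#' exist), making the matrix the true entrywise expectation over joint
#' possible worlds; `paper_literal` mode uses `S` unscaled, a conditional
#' rather than marginal expectation. Every entry additionally carries the
#' acnode term `acnode_probability(D_u, D_v, mode) / mn`, stored
#' implicitly per column pair (see [sm_matvec()]).
#'
#' In `exact` mode the full matrix is column-stochastic: every possible
#' world's support matrix is, and expectation preserves it.
#'
#' @param g1,g2 nonempty [uncertain_network()]s with `m` and `n` nodes.
#' @param mode `"exact"` (default) or `"paper_literal"`; governs both the
#'   edge-probability factor and the acnode probability.
#' @return an object of class `support_matrix` with fields `m`, `n`,
#'   `topo` (sparse `mn x mn` Matrix, row/column pairs flattened
#'   row-major as `(i-1)*n + j`), `acnode` (length-`mn` per-column
#'   additive weights, `1/mn` factor included), `mode`, and node labels.
#' @export
expected_support_matrix <- function(g1, g2, mode = c("exact", "paper_literal")) {
  mode <- match.arg(mode)
  m <- n_nodes(g1)
  n <- n_nodes(g2)
  if (m == 0L || n == 0L) stop("both networks must be nonempty")
  mn <- m * n
  pgf1 <- lapply(g1$nodes, function(v) node_degree_pgf(g1, v))
  pgf2 <- lapply(g2$nodes, function(v) node_degree_pgf(g2, v))
  p0_1 <- vapply(pgf1, `[`, numeric(1), 1L)
  p0_2 <- vapply(pgf2, `[`, numeric(1), 1L)
  if (mode == "exact") {
    P0 <- outer(p0_1, p0_2, function(a, b) a + b - a * b)
  } else {
    P0 <- outer(p0_1, p0_2, `+`)
    if (any(P0 > 1)) {
      warning("literal acnode probability exceeds 1 for some pair(s); clamped")
      P0[P0 > 1] <- 1
    }
  }
  acnode <- as.vector(t(P0)) / mn  # flat order (u-1)*n + v

  ne1 <- n_edges(g1)
  ne2 <- n_edges(g2)
  if (ne1 && ne2) {
    # E[1/D | edge present] at both endpoints of every edge
    h1a <- vapply(seq_len(ne1), function(k)
      conditional_inverse_moment(pgf1[[g1$edges$i[k]]], g1$edges$p[k]),
      numeric(1))
    h1b <- vapply(seq_len(ne1), function(k)
      conditional_inverse_moment(pgf1[[g1$edges$j[k]]], g1$edges$p[k]),
      numeric(1))
    h2a <- vapply(seq_len(ne2), function(k)
      conditional_inverse_moment(pgf2[[g2$edges$i[k]]], g2$edges$p[k]),
      numeric(1))
    h2b <- vapply(seq_len(ne2), function(k)
      conditional_inverse_moment(pgf2[[g2$edges$j[k]]], g2$edges$p[k]),
      numeric(1))

    e1 <- rep(seq_len(ne1), times = ne2)
    e2 <- rep(seq_len(ne2), each = ne1)
    fac <- if (mode == "exact") g1$edges$p[e1] * g2$edges$p[e2]
           else rep(1, length(e1))

    rows <- integer(0); cols <- integer(0); vals <- numeric(0)
    for (o1 in 1:2) {
      # orientation o1 = 1: row endpoint i = edge$i, column endpoint u = edge$j
      r1 <- if (o1 == 1) g1$edges$i[e1] else g1$edges$j[e1]
      c1 <- if (o1 == 1) g1$edges$j[e1] else g1$edges$i[e1]
      hc1 <- if (o1 == 1) h1b[e1] else h1a[e1]
      for (o2 in 1:2) {
        r2 <- if (o2 == 1) g2$edges$i[e2] else g2$edges$j[e2]
        c2 <- if (o2 == 1) g2$edges$j[e2] else g2$edges$i[e2]
        hc2 <- if (o2 == 1) h2b[e2] else h2a[e2]
        rows <- c(rows, flat_index(r1, r2, n))
        cols <- c(cols, flat_index(c1, c2, n))
        vals <- c(vals, (hc1 * hc2) * fac)
      }
    }
    topo <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                                 dims = c(mn, mn))
  } else {
    topo <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                 x = numeric(0), dims = c(mn, mn))
  }
  new_support_matrix(m, n, topo, acnode, mode, g1$nodes, g2$nodes)
}

#' Classical (deterministic) IsoRank support matrix
#'
#' The all-probabilities-1 reduction target: entry `([i,j],[u,v])` is
#' `1/(d_u d_v)` when `(v_i,v_u)` and `(v_j,v_v)` are edges, `1/mn` for
#' every row when `d_u` or `d_v` is zero, and 0 otherwise. Arithmetic is
#' ordered identically to the exact uncertain path (`(1/d_u) * (1/d_v)`)
#' so that the two coincide bitwise on deterministic input.
#'
#' @param G1,G2 `deterministic_network`s (all edge probabilities 1).
#' @return a `support_matrix` (see [expected_support_matrix()]).
#' @export
deterministic_support_matrix <- function(G1, G2) {
  if (!is_deterministic(G1) || !is_deterministic(G2)) {
    stop("both networks must be deterministic (all probabilities 1)")
  }
  m <- n_nodes(G1)
  n <- n_nodes(G2)
  if (m == 0L || n == 0L) stop("both networks must be nonempty")
  mn <- m * n
  d1 <- unname(node_degrees(G1))
  d2 <- unname(node_degrees(G2))
  acnode <- as.vector(t(outer(d1 == 0, d2 == 0, `|`))) / mn
  ne1 <- n_edges(G1)
  ne2 <- n_edges(G2)
  if (ne1 && ne2) {
    e1 <- rep(seq_len(ne1), times = ne2)
    e2 <- rep(seq_len(ne2), each = ne1)
    rows <- integer(0); cols <- integer(0); vals <- numeric(0)
    for (o1 in 1:2) {
      r1 <- if (o1 == 1) G1$edges$i[e1] else G1$edges$j[e1]
      c1 <- if (o1 == 1) G1$edges$j[e1] else G1$edges$i[e1]
      for (o2 in 1:2) {
        r2 <- if (o2 == 1) G2$edges$i[e2] else G2$edges$j[e2]
        c2 <- if (o2 == 1) G2$edges$j[e2] else G2$edges$i[e2]
        rows <- c(rows, flat_index(r1, r2, n))
        cols <- c(cols, flat_index(c1, c2, n))
        vals <- c(vals, (1 / d1[c1]) * (1 / d2[c2]))
      }
    }
    topo <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                                 dims = c(mn, mn))
  } else {
    topo <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                 x = numeric(0), dims = c(mn, mn))
  }
  new_support_matrix(m, n, topo, acnode, "deterministic",
                     G1$nodes, G2$nodes)
}

#' Apply a support matrix to a flattened similarity vector
#'
#' Computes `E(A) %*% r` without materializing the dense acnode rank-one
#' structure: `topo %*% r + sum(acnode * r)` added to every component.
#'
#' @param S a `support_matrix`.
#' @param r numeric vector of length `m * n` in row-major pair order.
#' @return numeric vector of length `m * n`.
#' @export
sm_matvec <- function(S, r) {
  stopifnot(length(r) == S$m * S$n)
  as.numeric(S$topo %*% r) + sum(S$acnode * r)
}

#' @export
as.matrix.support_matrix <- function(x, ...) {
  mn <- x$m * x$n
  as.matrix(Matrix::as.matrix(x$topo)) + matrix(x$acnode, mn, mn, byrow = TRUE)
}

#' @export
dim.support_matrix <- function(x) rep(x$m * x$n, 2L)

#' @export
print.support_matrix <- function(x, ...) {
  cat(sprintf(
    "<support matrix (%s mode): (%d x %d) pairs, %d stored topological entries>\n",
    x$mode, x$m, x$n, length(x$topo@x)))
  invisible(x)
}

#' Dump a support matrix for inspection
#'
#' Writes the stored topological entries in Matrix Market coordinate
#' format plus a sidecar TSV mapping flattened pair indices to node-label
#' pairs and the implicit per-column acnode weight. The full matrix is
#' `topo[r, c] + acnode[c]` for every `(r, c)`.
#'
#' @param S a `support_matrix`.
#' @param mtx_path Matrix Market output path.
#' @param map_path sidecar TSV output path.
#' @export
write_support_matrix <- function(S, mtx_path, map_path) {
  Matrix::writeMM(S$topo, mtx_path)
  idx <- seq_len(S$m * S$n)
  i <- (idx - 1L) %/% S$n + 1L
  j <- (idx - 1L) %% S$n + 1L
  utils::write.table(
    data.frame(flat_index = idx,
               node1 = S$labels1[i], node2 = S$labels2[j],
               acnode_weight = S$acnode),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mtx_path)
}
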