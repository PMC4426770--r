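# Probability-generating-function machinery for node degree distributions
# of uncertain networks. The degree of a node whose incident edges exist
# independently with probabilities p_e is a sum of independent Bernoulli
# variables; its PGF is the product of (1 - p_e + p_e z) over incident
# edges, so coefficient k is P(degree = k).

# drop trailing zero coefficients, keeping at least the constant term
poly_trim <- function(coef) {
  n <- length(coef)
  while (n > 1L && coef[n] == 0) n <- n - 1L
  coef[seq_len(n)]
}

#' Multiply two polynomials (coefficient convolution)
#'
#' Coefficients are in ascending powers: `a[k]` is the coefficient of
#' `z^(k-1)`. Trailing zeros are normalized away.
#'
#' @param a,b numeric coefficient vectors.
#' @return numeric coefficient vector of the product.
#' @examples
#' poly_multiply(c(0.6, 0.4), c(0.1, 0.9)) # 0.06 + 0.58 z + 0.36 z^2
#' @export
poly_multiply <- function(a, b) {
  a <- poly_trim(as.numeric(a))
  b <- poly_trim(as.numeric(b))
  out <- numeric(length(a) + length(b) - 1L)
  for (k in seq_along(a)) {
    idx <- k:(k + length(b) - 1L)
    out[idx] <- out[idx] + a[k] * b
  }
  poly_trim(out)
}

# Divide a PGF by the linear factor (1 - p + p z) of one incident edge.
# Synthetic division in ascending powers; exact mathematically because the
# factor divides the product. When p = 1 the divisor is z and division is
# an index shift, which requires a vanishing constant term (always true
# when an always-present edge is incident). Coefficients within 1e-9 of
# [0, 1] are clamped; larger excursions are a numerical-stability error.
poly_divide_linear <- function(coef, p) {
  coef <- as.numeric(coef)
  if (p <= 0 || p > 1) stop("divisor probability must lie in (0, 1]")
  if (p == 1) {
    if (abs(coef[1]) > 1e-9) {
      stop("constant term must vanish when dividing by z (p = 1)")
    }
    q <- if (length(coef) > 1L) coef[-1L] else numeric(0)
  } else {
    d0 <- 1 - p
    n <- length(coef) - 1L
    q <- numeric(max(n, 0L))
    carry <- 0
    for (k in seq_len(n)) {
      q[k] <- (coef[k] - carry) / d0
      carry <- q[k] * p
    }
  }
  if (!length(q)) q <- 1  # conditioning on the only incident edge
  lo <- q < 0
  hi <- q > 1
  if (any(q[lo] < -1e-9) || any(q[hi] > 1 + 1e-9)) {
    stop("PGF division numerically unstable: coefficient outside [0, 1] ",
         "by more than 1e-9")
  }
  q[lo] <- 0
  q[hi] <- 1
  poly_trim(q)
}

#' Degree-distribution PGF of a node
#'
#' Returns the probability generating function of the (random) degree of
#' node `v`: the product of `(1 - p_e + p_e z)` over the edges incident to
#' `v`. Coefficient `k+1` of the result is `P(D_v = k)`; the vector has
#' length `|E_v| + 1`. An isolated node has PGF `1` (degree 0 with
#' certainty).
#'
#' @param g an [uncertain_network()].
#' @param v node label.
#' @return numeric coefficient vector.
#' @examples
#' g <- uncertain_network(c("a", "a"), c("b", "c"), c(0.4, 0.9))
#' node_degree_pgf(g, "a") # c(0.06, 0.58, 0.36)
#' @export
node_degree_pgf <- function(g, v) {
  vi <- node_index(g, v)
  rows <- incident_edge_rows(g, vi)
  Reduce(poly_multiply,
         lapply(g$edges$p[rows], function(p) c(1 - p, p)),
         init = 1)
}

#' Conditional degree PGF given one incident edge is present
#'
#' Conditioning the degree of `v` on the presence of incident edge
#' `(v, other)` removes that edge's Bernoulli factor: the quotient
#' `Q_v(z) / (1 - p_e + p_e z)` is the PGF of the degree contribution of
#' the remaining incident edges. The conditional degree distribution is
#' shifted by one: `P(D_v = k | e present)` is coefficient `k` (1-based)
#' of the returned vector, for `k = 1..d_max`.
#'
#' @param g an [uncertain_network()].
#' @param v node label.
#' @param other label of the other endpoint of the conditioning edge,
#'   which must be incident to `v`.
#' @return numeric coefficient vector of the quotient PGF.
#' @export
conditional_degree_pgf <- function(g, v, other) {
  vi <- node_index(g, v)
  oi <- node_index(g, other)
  row <- which((g$edges$i == pmin(vi, oi)) & (g$edges$j == pmax(vi, oi)))
  if (!length(row)) {
    stop(sprintf("edge (%s, %s) is not in the network", v, other))
  }
  poly_divide_linear(node_degree_pgf(g, v), g$edges$p[row])
}

#' Degree distribution of a node
#'
#' Wraps the degree PGF coefficients as an explicit distribution
#' `P(D = k)` for `k = 0..d_max`, where `d_max` is the count of incident
#' edges.
#'
#' @inheritParams node_degree_pgf
#' @return an object of class `degree_distribution` with fields `probs`
#'   (length `d_max + 1`) and `d_max`.
#' @export
degree_distribution <- function(g, v) {
  vi <- node_index(g, v)
  d_max <- length(incident_edge_rows(g, vi))
  probs <- node_degree_pgf(g, v)
  # trailing-zero trimming cannot fire here (leading coefficient is
  # prod(p_e) > 0), but pad defensively so length == d_max + 1 holds
  probs <- c(probs, numeric(d_max + 1L - length(probs)))
  structure(list(probs = probs, d_max = d_max),
            class = "degree_distribution")
}

#' @export
print.degree_distribution <- function(x, ...) {
  cat("<degree distribution, d_max =", x$d_max, ">\n")
  print(stats::setNames(x$probs, 0:x$d_max))
  invisible(x)
}

# P(D = 0) from a degree_distribution or a bare probability vector
dd_p0 <- function(d) {
  if (inherits(d, "degree_distribution")) d$probs[1] else as.numeric(d)[1]
}
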