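# expected support matrix E(A): acnode probabilities, PGF-based entries,
# deterministic reduction, possible-worlds oracle equivalence

test_that("acnode probability: literal sum vs inclusion-exclusion", {
  du <- c(0.1, 0.9)
  dv <- c(0.2, 0.8)
  expect_equal(acnode_probability(du, dv, "paper_literal"), 0.3)
  # P(Du=0 or Dv=0) over the 4 joint outcomes: 0.1*0.2 + 0.1*0.8 + 0.9*0.2
  expect_equal(acnode_probability(du, dv, "exact"), 0.28)
  none <- c(0, 1)
  expect_equal(acnode_probability(none, none, "exact"), 0)
  expect_equal(acnode_probability(none, none, "paper_literal"), 0)
  # additive form can exceed 1 and is clamped with a warning
  expect_warning(
    s <- acnode_probability(c(0.7, 0.3), c(0.6, 0.4), "paper_literal"),
    "clamped")
  expect_equal(s, 1)
  expect_equal(acnode_probability(degree_distribution(
    worked_example_network(), "a"), c(1), "exact"), 1)
})

test_that("deterministic support matrix reproduces the degree arithmetic", {
  path <- deterministic_network(c("a", "b"), c("b", "c"))
  S <- deterministic_support_matrix(path, path)
  A <- as.matrix(S)
  n <- 3
  flat <- function(i, j) (i - 1) * n + j
  # entry ([a,a],[b,b]) = 1/(d_b * d_b) = 1/4
  expect_equal(A[flat(1, 1), flat(2, 2)], 1 / 4)
  # entry ([a,b],[b,a]) = 1/(d_b * d_a) = 1/2; ([a,b],[b,c]) likewise
  expect_equal(A[flat(1, 2), flat(2, 1)], 1 / 2)
  expect_equal(A[flat(1, 2), flat(2, 3)], 1 / 2)
  # non-adjacent, non-acnode pairs carry 0
  expect_equal(A[flat(1, 1), flat(3, 3)], 0)
  # the matrix is column-stochastic
  expect_equal(unname(colSums(A)), rep(1, n * n), tolerance = 1e-12)
})

test_that("isolated nodes trigger the uniform 1/mn column", {
  G1 <- deterministic_network("a", "b", nodes = c("a", "b", "u"))
  G2 <- deterministic_network("x", "y")
  S <- deterministic_support_matrix(G1, G2)
  A <- as.matrix(S)
  m <- 3; n <- 2
  # every entry of a column pair involving the isolated u is 1/mn
  for (v in 1:2) {
    col <- (3 - 1) * n + v
    expect_equal(unname(A[, col]), rep(1 / (m * n), m * n))
  }
})

test_that("columns agree with the direct neighbor-sum recurrence", {
  # (A r)[i,j] = sum_{u in N(i), v in N(j)} r[u,v] / (d_u d_v)  plus the
  # acnode term; evaluated directly on a 3-node example
  G <- deterministic_network(c("a", "b"), c("b", "c"))
  S <- deterministic_support_matrix(G, G)
  n <- 3
  d <- unname(node_degrees(G))
  adj <- list(2, c(1, 3), 2)
  set.seed(7)
  r <- runif(n * n)
  direct <- numeric(n * n)
  for (i in 1:n) {
    for (j in 1:n) {
      acc <- 0
      for (u in adj[[i]]) {
        for (v in adj[[j]]) {
          acc <- acc + r[(u - 1) * n + v] / (d[u] * d[v])
        }
      }
      direct[(i - 1) * n + j] <- acc
    }
  }
  expect_equal(sm_matvec(S, r), direct, tolerance = 1e-12)
})

test_that("single-edge networks give unit topological entries", {
  g1 <- uncertain_network("a", "b", 1)
  g2 <- uncertain_network("x", "y", 1)
  S <- expected_support_matrix(g1, g2)
  expect_equal(max(S$topo), 1)
  expect_equal(length(S$topo@x), 4)  # both orientations on both sides
})

test_that("exact-mode E(A) equals the joint possible-worlds oracle", {
  checked <- 0
  seed <- 0
  while (checked < 6) {
    seed <- seed + 1
    g1 <- random_small_network(seed, n = 4, density = 0.5)
    g2 <- random_small_network(seed + 100, n = 3, density = 0.6)
    if (n_edges(g1) + n_edges(g2) > 10 || !n_edges(g1) || !n_edges(g2)) next
    checked <- checked + 1
    S <- as.matrix(expected_support_matrix(g1, g2, mode = "exact"))
    O <- oracle_expected_support(g1, g2)
    expect_lt(max(abs(S - O)), 1e-9)
    # exact-mode entries are finite, nonnegative, at most 1, and columns
    # are stochastic (every world's matrix is)
    expect_true(all(is.finite(S)) && all(S >= 0) && all(S <= 1 + 1e-12))
    expect_equal(unname(colSums(S)), rep(1, ncol(S)), tolerance = 1e-9)
  }
})

test_that("paper_literal mode drops the enabling-edge factor", {
  g1 <- uncertain_network("a", "b", 0.5)
  g2 <- uncertain_network("x", "y", 0.5)
  Se <- expected_support_matrix(g1, g2, mode = "exact")
  Sl <- expected_support_matrix(g1, g2, mode = "paper_literal")
  # conditional P(D=1 | e) = 1 on both sides, so S = 1; exact scales by
  # p1 * p2 = 0.25, literal does not
  expect_equal(max(Se$topo), 0.25)
  expect_equal(max(Sl$topo), 1)
})

test_that("with all probabilities 1 every construction coincides exactly", {
  G1u <- uncertain_network(c("a", "a", "b"), c("b", "c", "c"), 1)
  G2u <- uncertain_network(c("x", "x"), c("y", "z"), 1)
  Sd <- deterministic_support_matrix(as_deterministic(G1u),
                                     as_deterministic(G2u))
  Se <- expected_support_matrix(G1u, G2u, mode = "exact")
  Sl <- expected_support_matrix(G1u, G2u, mode = "paper_literal")
  expect_identical(as.matrix(Se), as.matrix(Sd))
  expect_identical(as.matrix(Sl), as.matrix(Sd))
})

test_that("topological sparsity pattern is symmetric under pair swap", {
  g1 <- random_small_network(3, n = 4, density = 0.6)
  g2 <- random_small_network(4, n = 4, density = 0.6)
  S <- expected_support_matrix(g1, g2)
  pattern <- as.matrix(S$topo) != 0
  expect_identical(pattern, t(pattern))
})

test_that("matvec agrees with the densified matrix", {
  g1 <- random_small_network(5, n = 4, density = 0.5)
  g2 <- random_small_network(6, n = 3, density = 0.5)
  S <- expected_support_matrix(g1, g2)
  set.seed(1)
  r <- runif(n_nodes(g1) * n_nodes(g2))
  expect_equal(sm_matvec(S, r), as.numeric(as.matrix(S) %*% r),
               tolerance = 1e-12)
})

test_that("support matrix dump round-trips through Matrix Market", {
  g1 <- random_small_network(7, n = 3, density = 0.7)
  g2 <- random_small_network(8, n = 3, density = 0.7)
  S <- expected_support_matrix(g1, g2)
  mtx <- tempfile(fileext = ".mtx")
  map <- tempfile(fileext = ".tsv")
  write_support_matrix(S, mtx, map)
  back <- Matrix::readMM(mtx)
  expect_equal(as.matrix(Matrix::as.matrix(back)),
               as.matrix(Matrix::as.matrix(S$topo)), tolerance = 1e-12)
  side <- read.delim(map)
  expect_equal(nrow(side), n_nodes(g1) * n_nodes(g2))
  expect_equal(side$acnode_weight, S$acnode, tolerance = 1e-12)
})
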