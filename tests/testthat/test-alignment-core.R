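# similarity-vector iteration and one-to-one alignment extraction

test_that("iteration config validates its bounds", {
  expect_error(iteration_config(alpha = 1.5), "\\[0, 1\\]")
  expect_error(iteration_config(eps = 0), "positive")
  expect_error(iteration_config(max_iter = 0), ">= 1")
  cfg <- iteration_config()
  expect_equal(cfg$alpha, 0.6)
})

test_that("sequence-similarity normalization scales to unit mass", {
  g1 <- uncertain_network("a", "b", 1)
  g2 <- uncertain_network("x", "y", 1)
  ss <- data.frame(node1 = c("a", "b"), node2 = c("x", "y"),
                   score = c(3, 1))
  E <- normalize_seqsim(ss, g1, g2)
  expect_equal(E["a", "x"], 0.75)
  expect_equal(E["b", "y"], 0.25)
  expect_equal(E["a", "y"], 0)
  expect_equal(sum(E), 1, tolerance = 1e-12)
  # empty and all-zero tables fall back to the uniform vector
  expect_equal(unname(normalize_seqsim(NULL, g1, g2)),
               matrix(0.25, 2, 2))
  zero <- data.frame(node1 = "a", node2 = "x", score = 0)
  expect_equal(unname(normalize_seqsim(zero, g1, g2)), matrix(0.25, 2, 2))
  # invariance under positive rescaling
  ss10 <- transform(ss, score = score * 10)
  expect_equal(normalize_seqsim(ss10, g1, g2), E)
  expect_error(normalize_seqsim(transform(ss, score = -score), g1, g2),
               "nonnegative")
  expect_error(
    normalize_seqsim(data.frame(node1 = "q", node2 = "x", score = 1), g1, g2),
    "unknown node")
  # random tables always sum to 1
  set.seed(11)
  for (k in 1:5) {
    ssr <- data.frame(node1 = sample(c("a", "b"), 3, TRUE),
                      node2 = sample(c("x", "y"), 3, TRUE),
                      score = runif(3))
    expect_equal(sum(normalize_seqsim(ssr, g1, g2)), 1, tolerance = 1e-12)
  }
})

test_that("alpha = 0 returns the sequence vector exactly", {
  g1 <- random_small_network(1, n = 4, density = 0.5)
  g2 <- random_small_network(2, n = 4, density = 0.5)
  EA <- expected_support_matrix(g1, g2)
  ss <- data.frame(node1 = g1$nodes[1], node2 = g2$nodes[2], score = 2)
  E <- normalize_seqsim(ss, g1, g2)
  out <- power_iterate(EA, E, iteration_config(alpha = 0))
  expect_identical(out$R, E)
  expect_true(out$converged)
})

test_that("the fixed-point residual honors the convergence contract", {
  for (seed in c(3, 4, 5)) {
    g1 <- random_small_network(seed, n = 5, density = 0.5)
    g2 <- random_small_network(seed + 50, n = 4, density = 0.5)
    for (mode in c("exact", "paper_literal")) {
      EA <- suppressWarnings(expected_support_matrix(g1, g2, mode = mode))
      cfg <- iteration_config(alpha = 0.6, eps = 1e-8)
      out <- power_iterate(EA, normalize_seqsim(NULL, g1, g2), cfg)
      expect_true(out$converged)
      expect_lte(out$residual, cfg$eps * (1 + cfg$alpha))
      expect_equal(sum(out$R), 1, tolerance = 1e-12)
      expect_true(all(out$R >= 0))
    }
  }
})

test_that("non-convergence warns and flags instead of failing", {
  g1 <- random_small_network(9, n = 4, density = 0.6)
  g2 <- random_small_network(10, n = 4, density = 0.6)
  EA <- expected_support_matrix(g1, g2)
  expect_warning(
    out <- power_iterate(EA, normalize_seqsim(NULL, g1, g2),
                         iteration_config(eps = 1e-12, max_iter = 2)),
    "did not converge")
  expect_false(out$converged)
  expect_equal(out$iterations, 2)
})

test_that("self-alignment of a deterministic graph yields a symmetric R", {
  G <- deterministic_network(c("a", "b", "c"), c("b", "c", "d"))
  EA <- deterministic_support_matrix(G, G)
  out <- power_iterate(EA, normalize_seqsim(NULL, G, G),
                       iteration_config(eps = 1e-10))
  expect_equal(out$R, t(out$R), tolerance = 1e-9)
})

test_that("alignment extraction is optimal on hand-checked instances", {
  a <- extract_alignment(matrix(c(2, 1, 1, 2), 2, byrow = TRUE))
  expect_equal(a$pairs$node1, c("1", "2"))
  expect_equal(a$pairs$node2, c("1", "2"))
  expect_equal(a$total_weight, 4)
  # permutation matrix recovery
  set.seed(21)
  for (k in 1:5) {
    n <- sample(3:6, 1)
    perm <- sample(n)
    W <- matrix(0, n, n)
    W[cbind(seq_len(n), perm)] <- 1
    a <- extract_alignment(W)
    expect_equal(match(a$pairs$node2, as.character(seq_len(n))), perm)
    expect_equal(a$total_weight, n)
  }
})

test_that("matching equals the exhaustive-injection oracle on random instances", {
  set.seed(33)
  for (k in 1:40) {
    m <- sample(2:6, 1)
    n <- sample(2:6, 1)
    W <- matrix(round(runif(m * n), 3), m, n)
    a <- extract_alignment(W)
    o <- oracle_max_matching(W)
    expect_equal(a$total_weight, o$weight, tolerance = 1e-9)
    # one-to-one at full cardinality
    expect_equal(nrow(a$pairs), min(m, n))
    expect_false(anyDuplicated(a$pairs$node1) > 0)
    expect_false(anyDuplicated(a$pairs$node2) > 0)
  }
})

test_that("weight ties break to the lexicographically smallest pair list", {
  W <- matrix(1, 3, 3)
  a <- extract_alignment(W)
  expect_equal(a$pairs$node2, c("1", "2", "3"))
  # two optimal diagonals: {(1,1),(2,2)} and {(1,2),(2,1)} both weigh 2
  W2 <- matrix(c(1, 1, 1, 1), 2)
  a2 <- extract_alignment(W2)
  expect_equal(a2$pairs$node2, c("1", "2"))
  # rectangular: the unmatched row is the lexicographically latest option
  W3 <- matrix(1, 3, 2)
  a3 <- extract_alignment(W3)
  expect_equal(a3$pairs$node1, c("1", "2"))
})

test_that("full pipeline honors its contracts on identical triangles", {
  tri1 <- uncertain_network(c("a", "a", "b"), c("b", "c", "c"), 1)
  tri2 <- uncertain_network(c("x", "x", "y"), c("y", "z", "z"), 1)
  res <- align_networks(tri1, tri2)
  expect_equal(nrow(res$alignment$pairs), 3)
  expect_equal(res$alignment$total_weight,
               extract_alignment(res$similarity)$total_weight)
})

test_that("seqsim scale invariance carries through the whole pipeline", {
  g1 <- random_small_network(12, n = 5, density = 0.5)
  g2 <- random_small_network(13, n = 5, density = 0.5)
  ss <- data.frame(node1 = rep(g1$nodes[1:3], 2),
                   node2 = rep(g2$nodes[1:2], each = 3),
                   score = c(5, 1, 2, 0.5, 4, 3))
  r1 <- align_networks(g1, g2, seqsim = ss)
  r2 <- align_networks(g1, g2,
                       seqsim = transform(ss, score = score * 1000))
  expect_equal(r1$similarity$R, r2$similarity$R)
  expect_identical(r1$alignment$pairs[1:2], r2$alignment$pairs[1:2])
})

test_that("all-probability-1 input matches the deterministic code path bitwise", {
  g1 <- uncertain_network(c("a", "a", "b", "c"), c("b", "c", "c", "d"), 1)
  g2 <- uncertain_network(c("x", "x", "y"), c("y", "z", "z"), 1)
  Eu <- expected_support_matrix(g1, g2, mode = "exact")
  Ed <- deterministic_support_matrix(as_deterministic(g1),
                                     as_deterministic(g2))
  expect_identical(as.matrix(Eu), as.matrix(Ed))
  cfg <- iteration_config()
  Evec <- normalize_seqsim(NULL, g1, g2)
  ru <- power_iterate(Eu, Evec, cfg)
  rd <- power_iterate(Ed, Evec, cfg)
  expect_identical(ru$R, rd$R)
  expect_identical(extract_alignment(ru)$pairs, extract_alignment(rd)$pairs)
})

test_that("alignments round-trip through the TSV serializer", {
  g1 <- random_small_network(14, n = 4, density = 0.6)
  g2 <- random_small_network(15, n = 4, density = 0.6)
  res <- align_networks(g1, g2)
  path <- tempfile(fileext = ".tsv")
  write_alignment(res, path)
  back <- read_alignment(path)
  expect_equal(back$pairs$node1, res$alignment$pairs$node1)
  expect_equal(back$pairs$node2, res$alignment$pairs$node2)
  expect_equal(back$pairs$score, res$alignment$pairs$score,
               tolerance = 1e-9)
  # header records the run settings
  head <- readLines(path, n = 5)
  expect_true(any(grepl("alpha", head)))
})
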