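# Solve R = alpha E(A) R + (1 - alpha) E by power iteration and extract a
# one-to-one alignment by maximum-weight bipartite matching.

#' Iteration configuration
#'
#' @param alpha blend weight in `[0, 1]` between topological similarity
#'   (`alpha`) and sequence similarity (`1 - alpha`); default 0.6, the
#'   value established for IsoRank-family methods.
#' @param eps convergence threshold on the L1 difference of successive
#'   iterates; default `1e-6`.
#' @param max_iter iteration cap; default 1000.
#' @return an object of class `iteration_config`.
#' @export
iteration_config <- function(alpha = 0.6, eps = 1e-6, max_iter = 1000L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    stop("`alpha` must be a single number in [0, 1]")
  }
  if (!is.numeric(eps) || length(eps) != 1L || is.na(eps) || eps <= 0) {
    stop("`eps` must be a single positive number")
  }
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 1L) stop("`max_iter` must be >= 1")
  structure(list(alpha = alpha, eps = eps, max_iter = max_iter),
            class = "iteration_config")
}

#' Read a pairwise sequence-similarity table
#'
#' Three tab-separated columns: node in network 1, node in network 2,
#' nonnegative score (for instance a normalized BLAST bit score). Lines
#' starting with `#` are skipped. Pairs not listed default to score 0.
#'
#' @param path path to the file.
#' @return a data frame with columns `node1`, `node2`, `score`.
#' @export
read_seqsim <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rows <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(rows)) {
    return(data.frame(node1 = character(0), node2 = character(0),
                      score = numeric(0)))
  }
  fields <- strsplit(trimws(lines[rows]), "[\t ]+")
  bad <- which(lengths(fields) != 3L)
  if (length(bad)) {
    stop(sprintf("line %d: expected 3 columns (node1, node2, score)",
                 rows[bad[1]]))
  }
  score <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  if (anyNA(score)) {
    stop(sprintf("line %d: non-numeric score", rows[which(is.na(score))[1]]))
  }
  if (any(score < 0)) stop("sequence-similarity scores must be nonnegative")
  data.frame(node1 = vapply(fields, `[`, "", 1L),
             node2 = vapply(fields, `[`, "", 2L),
             score = score)
}

#' Normalize sequence similarities into the blend vector E
#'
#' Places the raw scores on the `m x n` node-pair grid of the two
#' networks and divides by the grand total so the vector sums to 1. An
#' empty or all-zero table maps to the uniform vector `1/mn` (sequence
#' information absent: the blend term becomes uninformative rather than
#' absorbing). Scaling all scores by a positive constant therefore leaves
#' the result unchanged.
#'
#' @param seqsim `NULL`, or a data frame with columns `node1`, `node2`,
#'   `score` (see [read_seqsim()]); scores must be nonnegative and pairs
#'   must name nodes of the respective networks.
#' @param g1,g2 the two networks being aligned.
#' @return an `m x n` numeric matrix summing to 1, with node labels as
#'   dimnames.
#' @export
normalize_seqsim <- function(seqsim, g1, g2) {
  m <- n_nodes(g1)
  n <- n_nodes(g2)
  E <- matrix(0, m, n, dimnames = list(g1$nodes, g2$nodes))
  if (!is.null(seqsim) && nrow(seqsim)) {
    if (any(seqsim$score < 0)) {
      stop("sequence-similarity scores must be nonnegative")
    }
    i <- match(seqsim$node1, g1$nodes)
    j <- match(seqsim$node2, g2$nodes)
    if (anyNA(i) || anyNA(j)) {
      k <- which(is.na(i) | is.na(j))[1]
      stop(sprintf("sequence-similarity pair (%s, %s) names unknown node(s)",
                   seqsim$node1[k], seqsim$node2[k]))
    }
    E[cbind(i, j)] <- E[cbind(i, j)] + seqsim$score
  }
  total <- sum(E)
  if (total > 0) E / total else matrix(1 / (m * n), m, n,
                                       dimnames = list(g1$nodes, g2$nodes))
}

#' Power iteration for the node-pair similarity vector
#'
#' Starting from the uniform vector `R_0 = 1/mn`, repeats
#' `R <- alpha * E(A) %*% R + (1 - alpha) * Evec`, renormalizing to L1
#' norm 1 each step, until the L1 difference between successive iterates
#' is at most `eps` or `max_iter` is reached. In exact mode `E(A)` is
#' column-stochastic, so the update is a contraction with factor `alpha`
#' and the renormalization is a no-op up to roundoff; in literal mode the
#' renormalization is load-bearing.
#'
#' @param EA a [expected_support_matrix()] / support_matrix object.
#' @param Evec `m x n` normalized sequence-similarity matrix (see
#'   [normalize_seqsim()]).
#' @param config an [iteration_config()].
#' @return an object of class `similarity_vector`: list with `R` (`m x n`
#'   matrix, L1 norm 1), `iterations`, `delta` (last step difference),
#'   `residual` (fixed-point residual of the renormalized map,
#'   `||R - N(alpha E(A) R + (1-alpha) E)||_1` with `N` the L1
#'   normalization; on convergence it is bounded by `eps * (1 + alpha)`),
#'   and `converged`. On
#'   non-convergence the result carries `converged = FALSE` and a
#'   warning, not an error.
#' @export
power_iterate <- function(EA, Evec, config = iteration_config()) {
  stopifnot(inherits(EA, "support_matrix"))
  m <- EA$m
  n <- EA$n
  if (!is.matrix(Evec) || nrow(Evec) != m || ncol(Evec) != n) {
    stop("`Evec` must be an m x n matrix matching the support matrix")
  }
  alpha <- config$alpha
  e <- as.vector(t(Evec))          # row-major flattening (i-1)*n + j
  r <- rep(1 / (m * n), m * n)
  delta <- Inf
  iter <- 0L
  converged <- FALSE
  while (iter < config$max_iter) {
    iter <- iter + 1L
    y <- alpha * sm_matvec(EA, r) + (1 - alpha) * e
    y <- y / sum(y)
    delta <- sum(abs(y - r))
    r <- y
    if (delta <= config$eps) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("power iteration did not converge in %d iterations (last delta %.3g)",
                    config$max_iter, delta))
  }
  # fixed-point residual of the *renormalized* map actually iterated
  z <- alpha * sm_matvec(EA, r) + (1 - alpha) * e
  residual <- sum(abs(r - z / sum(z)))
  R <- matrix(r, m, n, byrow = TRUE,
              dimnames = list(EA$labels1, EA$labels2))
  structure(list(R = R, iterations = iter, delta = delta,
                 residual = residual, converged = converged,
                 config = config),
            class = "similarity_vector")
}

#' @export
print.similarity_vector <- function(x, ...) {
  cat(sprintf("<similarity vector %d x %d: %d iteration(s), residual %.3g%s>\n",
              nrow(x$R), ncol(x$R), x$iterations, x$residual,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Extract a one-to-one alignment from a similarity vector
#'
#' Interprets the similarity grid as the weight matrix of the complete
#' bipartite graph on the two node sets and returns a maximum-weight
#' matching of cardinality `min(m, n)` (Hungarian method). Ties among
#' weight-optimal matchings are broken deterministically in favor of the
#' lexicographically smallest row-sorted pair list; the refinement
#' requires `m * n` re-solves and is applied when `m * n <= 400`
#' (plain Hungarian output, still deterministic, is used above that).
#'
#' @param R a `similarity_vector` from [power_iterate()], or a plain
#'   nonnegative `m x n` matrix (dimnames, if present, label the nodes).
#' @param lexicographic break weight ties lexicographically (default
#'   `TRUE`; silently skipped on instances larger than 400 cells).
#' @return an object of class `alignment`: list with `pairs` (data frame
#'   `node1`, `node2`, `score`), `total_weight`, and the two node
#'   universes.
#' @export
extract_alignment <- function(R, lexicographic = TRUE) {
  W <- if (inherits(R, "similarity_vector")) R$R else as.matrix(R)
  if (any(W < 0)) stop("similarity weights must be nonnegative")
  m <- nrow(W)
  n <- ncol(W)
  labels1 <- rownames(W)
  labels2 <- colnames(W)
  if (is.null(labels1)) labels1 <- as.character(seq_len(m))
  if (is.null(labels2)) labels2 <- as.character(seq_len(n))
  res <- if (lexicographic && m * n <= 400) lex_min_matching(W)
         else max_weight_matching(W)
  pairs <- data.frame(node1 = labels1[res$rows],
                      node2 = labels2[res$cols],
                      score = W[cbind(res$rows, res$cols)])
  structure(list(pairs = pairs, total_weight = res$weight,
                 labels1 = labels1, labels2 = labels2),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment: %d pair(s), total weight %.6g>\n",
              nrow(x$pairs), x$total_weight))
  if (nrow(x$pairs)) print(utils::head(x$pairs, 10))
  if (nrow(x$pairs) > 10) cat("...\n")
  invisible(x)
}

#' Align two uncertain networks
#'
#' Full pipeline: build the expected support matrix, normalize sequence
#' similarity, solve for the node-pair similarity vector by power
#' iteration, extract a maximum-weight one-to-one alignment. With all
#' edge probabilities 1 this reduces to deterministic IsoRank-style
#' alignment; with exactly one uncertain input it reproduces the
#' half-probabilistic setting.
#'
#' @param g1,g2 [uncertain_network()]s.
#' @param seqsim `NULL` (uniform blend vector) or a sequence-similarity
#'   data frame (see [read_seqsim()]).
#' @param config an [iteration_config()].
#' @param mode `"exact"` or `"paper_literal"` support-matrix mode.
#' @param lexicographic passed to [extract_alignment()].
#' @return an object of class `pna_result`: list with `alignment`,
#'   `similarity` (the [power_iterate()] result), `support` (the support
#'   matrix), and the effective settings.
#' @examples
#' g1 <- uncertain_network(c("a", "a", "b"), c("b", "c", "c"), c(.8, .6, .9))
#' g2 <- uncertain_network(c("x", "x", "y"), c("y", "z", "z"), c(.7, .6, .95))
#' res <- align_networks(g1, g2)
#' res$alignment$pairs
#' @export
align_networks <- function(g1, g2, seqsim = NULL,
                           config = iteration_config(),
                           mode = c("exact", "paper_literal"),
                           lexicographic = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(g1, "uncertain_network"),
            inherits(g2, "uncertain_network"),
            inherits(config, "iteration_config"))
  EA <- expected_support_matrix(g1, g2, mode = mode)
  Evec <- normalize_seqsim(seqsim, g1, g2)
  sim <- power_iterate(EA, Evec, config)
  aln <- extract_alignment(sim, lexicographic = lexicographic)
  structure(list(alignment = aln, similarity = sim, support = EA,
                 mode = mode, config = config),
            class = "pna_result")
}

#' @export
print.pna_result <- function(x, ...) {
  cat(sprintf("<alignment result (%s mode, alpha = %g)>\n",
              x$mode, x$config$alpha))
  print(x$similarity)
  print(x$alignment)
  invisible(x)
}

#' Write an alignment as TSV
#'
#' Columns `node1`, `node2`, `pair_score`; leading `#` comment lines
#' record the settings passed in `meta`.
#'
#' @param a an `alignment` (or `pna_result`).
#' @param path output path.
#' @param meta named list echoed into the header.
#' @export
write_alignment <- function(a, path, meta = list()) {
  if (inherits(a, "pna_result")) {
    meta <- c(list(alpha = a$config$alpha, eps = a$config$eps,
                   mode = a$mode,
                   iterations = a$similarity$iterations,
                   residual = a$similarity$residual), meta)
    a <- a$alignment
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k, format(meta[[k]])), con)
  }
  writeLines("# node1\tnode2\tpair_score", con)
  writeLines(sprintf("%s\t%s\t%.10g", a$pairs$node1, a$pairs$node2,
                     a$pairs$score), con)
  invisible(path)
}

#' Read an alignment TSV
#'
#' @param path file with columns node1, node2 and optionally a score;
#'   `#` lines are skipped.
#' @return an `alignment` object (universes default to the listed nodes).
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rows <- which(!grepl("^\\s*(#|$)", lines))
  fields <- strsplit(trimws(lines[rows]), "[\t ]+")
  if (any(lengths(fields) < 2L)) stop("alignment rows need at least 2 columns")
  node1 <- vapply(fields, `[`, "", 1L)
  node2 <- vapply(fields, `[`, "", 2L)
  score <- vapply(fields, function(f)
    if (length(f) >= 3) suppressWarnings(as.numeric(f[3])) else NA_real_,
    numeric(1))
  if (anyDuplicated(node1) || anyDuplicated(node2)) {
    stop("alignment is not one-to-one")
  }
  pairs <- data.frame(node1 = node1, node2 = node2, score = score)
  structure(list(pairs = pairs,
                 total_weight = if (anyNA(score)) NA_real_ else sum(score),
                 labels1 = node1, labels2 = node2),
            class = "alignment")
}
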