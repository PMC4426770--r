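# Alignment quality metrics: agreement between two alignments, GO
# consistency (GOC), and the global network alignment score (GNAS).

pair_keys <- function(a) paste(a$pairs$node1, a$pairs$node2, sep = "\r")

#' Agreement between two alignments
#'
#' Fraction of aligned pairs shared by two alignments of the same network
#' pair. The denominator is ambiguous when stated as "all alignments":
#' by default the union of the two pair sets is used (Jaccard; symmetric
#' and well defined for unequal cardinalities), with `"size"` dividing by
#' the (common) alignment size instead. 1 means the results agree
#' perfectly; 0 means they are completely different.
#'
#' @param a1,a2 `alignment` objects over the same node universes.
#' @param denominator `"union"` (default) or `"size"`.
#' @return a value in `[0, 1]`.
#' @export
agreement <- function(a1, a2, denominator = c("union", "size")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(a1, "alignment"), inherits(a2, "alignment"))
  if (!setequal(a1$labels1, a2$labels1) || !setequal(a1$labels2, a2$labels2)) {
    stop("alignments are over different node universes")
  }
  k1 <- pair_keys(a1)
  k2 <- pair_keys(a2)
  common <- length(intersect(k1, k2))
  denom <- switch(denominator,
                  union = length(union(k1, k2)),
                  size = max(length(k1), length(k2)))
  if (denom == 0) return(1)  # two empty alignments agree vacuously
  common / denom
}

#' Read a node-to-GO-term annotation table
#'
#' Two tab-separated columns `node<TAB>term` (minimal GAF-like dialect);
#' `#` lines skipped. A node may appear on several rows.
#'
#' @param path path to the file.
#' @return a named list of character term sets, class `annotation_map`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rows <- which(!grepl("^\\s*(#|$)", lines))
  fields <- strsplit(trimws(lines[rows]), "[\t ]+")
  if (any(lengths(fields) < 2L)) stop("annotation rows need 2 columns")
  node <- vapply(fields, `[`, "", 1L)
  term <- vapply(fields, `[`, "", 2L)
  annotation_map(split(term, node))
}

#' @rdname read_annotations
#' @param terms a named list mapping node label to a character vector of
#'   term identifiers (opaque strings; may be empty).
#' @export
annotation_map <- function(terms = list()) {
  structure(lapply(terms, function(x) unique(as.character(x))),
            class = "annotation_map")
}

#' GO consistency of an alignment
#'
#' Mean Jaccard overlap `|GO(u) n GO(v)| / |GO(u) u GO(v)|` of the GO
#' term sets of aligned node pairs. Stated to lie in `[0, 1]`, so the sum
#' is normalized by the number of counted pairs. Pairs with both term
#' sets empty are skipped by default (`0/0` is undefined); set
#' `unannotated = "zero"` to count them as 0 instead.
#'
#' @param a an `alignment`.
#' @param ann an [annotation_map()].
#' @param unannotated `"skip"` (default) or `"zero"`.
#' @return a value in `[0, 1]`, or `NA` if no pair is counted.
#' @export
goc <- function(a, ann, unannotated = c("skip", "zero")) {
  unannotated <- match.arg(unannotated)
  stopifnot(inherits(a, "alignment"))
  terms <- function(v) {
    t <- ann[[v]]
    if (is.null(t)) character(0) else t
  }
  jac <- vapply(seq_len(nrow(a$pairs)), function(k) {
    tu <- terms(a$pairs$node1[k])
    tv <- terms(a$pairs$node2[k])
    un <- length(union(tu, tv))
    if (un == 0) NA_real_ else length(intersect(tu, tv)) / un
  }, numeric(1))
  if (unannotated == "zero") jac[is.na(jac)] <- 0
  counted <- jac[!is.na(jac)]
  if (!length(counted)) {
    warning("no aligned pair has any annotation; GOC undefined")
    return(NA_real_)
  }
  mean(counted)
}

#' Global network alignment score
#'
#' `GNAS = alpha * |E| + (1 - alpha) * sum seq(u, v)` over aligned pairs,
#' where `|E|` counts conserved interactions: unordered pairs of aligned
#' couples `(u, v)`, `(u', v')` such that `(u, u')` is an edge of network
#' 1 and `(v, v')` an edge of network 2. For uncertain edges,
#' `conserved_mode = "support"` counts an edge as present when its
#' probability is positive; `"expected"` sums `p1 * p2` instead,
#' giving the expected conserved-interaction count over possible worlds.
#'
#' @param a an `alignment` over the nodes of `g1`, `g2`.
#' @param g1,g2 the aligned networks.
#' @param seqsim `NULL` or a raw (unnormalized) sequence-similarity data
#'   frame (see [read_seqsim()]); unknown pairs score 0.
#' @param alpha blend weight, default 0.6.
#' @param conserved_mode `"support"` (default) or `"expected"`.
#' @return a `metric_report` list: `gnas`, `conserved_edges`, `seq_sum`,
#'   plus the settings used.
#' @export
gnas <- function(a, g1, g2, seqsim = NULL, alpha = 0.6,
                 conserved_mode = c("support", "expected")) {
  conserved_mode <- match.arg(conserved_mode)
  stopifnot(inherits(a, "alignment"))
  if (alpha < 0 || alpha > 1) stop("`alpha` must lie in [0, 1]")
  i1 <- match(a$pairs$node1, g1$nodes)
  i2 <- match(a$pairs$node2, g2$nodes)
  if (anyNA(i1) || anyNA(i2)) {
    stop("alignment names nodes absent from the networks")
  }
  edge_prob <- function(g) {
    p <- g$edges$p
    names(p) <- paste(g$edges$i, g$edges$j)
    p
  }
  p1 <- edge_prob(g1)
  p2 <- edge_prob(g2)
  conserved <- 0
  K <- nrow(a$pairs)
  if (K >= 2) {
    for (k in seq_len(K - 1)) {
      for (l in (k + 1):K) {
        e1 <- p1[paste(min(i1[k], i1[l]), max(i1[k], i1[l]))]
        e2 <- p2[paste(min(i2[k], i2[l]), max(i2[k], i2[l]))]
        if (is.na(e1) || is.na(e2)) next
        conserved <- conserved +
          if (conserved_mode == "support") 1 else unname(e1 * e2)
      }
    }
  }
  seq_sum <- 0
  if (!is.null(seqsim) && nrow(seqsim)) {
    key <- paste(seqsim$node1, seqsim$node2, sep = "\r")
    hit <- match(paste(a$pairs$node1, a$pairs$node2, sep = "\r"), key)
    seq_sum <- sum(seqsim$score[hit[!is.na(hit)]])
  }
  structure(list(gnas = alpha * conserved + (1 - alpha) * seq_sum,
                 conserved_edges = conserved, seq_sum = seq_sum,
                 alpha = alpha, conserved_mode = conserved_mode),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("GNAS = %.6g (alpha = %g, conserved = %.6g [%s], seq sum = %.6g)\n",
              x$gnas, x$alpha, x$conserved_edges, x$conserved_mode,
              x$seq_sum))
  invisible(x)
}

#' Number of unordered network pairs
#'
#' How many pairwise alignment experiments a collection of `n` networks
#' yields: `choose(n, 2)`. (A 198-network collection gives 19,503.)
#'
#' @param n number of networks.
#' @return integer count.
#' @export
count_network_pairs <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 0) stop("`n` must be a nonnegative integer")
  n * (n - 1L) / 2
}
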