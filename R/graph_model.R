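# Data model and I/O for deterministic and uncertain (edge-probability)
# interaction networks, plus possible-worlds (implication graph) semantics.

new_uncertain_network <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "uncertain_network")
}

#' Construct an uncertain network
#'
#' An uncertain network is an undirected graph whose edges each exist
#' independently with a stated probability in (0, 1]. A network with all
#' probabilities equal to 1 is an ordinary deterministic network; see
#' [deterministic_network()].
#'
#' Edges are unordered: listing both `a b` and `b a` is a duplicate-edge
#' error, and self-loops are rejected. Node identity is the literal,
#' case-sensitive label string. Probability-0 edges are dropped with a
#' warning (an edge that can never exist belongs to no possible world).
#'
#' @param from,to character vectors of edge endpoints (node labels).
#' @param prob numeric vector of edge existence probabilities, recycled to
#'   the number of edges. Must lie in `[0, 1]`; zeros are dropped.
#' @param nodes optional character vector fixing the node set and order;
#'   defaults to first-appearance order of the endpoints. May include
#'   labels that touch no edge: isolated nodes (acnodes) are meaningful,
#'   they trigger the uniform `1/mn` branch of the support matrix.
#' @return An object of class `uncertain_network` with components
#'   `nodes` (character) and `edges` (data frame with integer endpoint
#'   indices `i < j` and probability `p`).
#' @examples
#' g <- uncertain_network(c("a", "a", "b"), c("b", "c", "c"), c(0.4, 0.9, 0.5))
#' n_nodes(g)
#' @export
uncertain_network <- function(from = character(), to = character(), prob = 1,
                              nodes = NULL) {
  from <- as.character(from)
  to <- as.character(to)
  if (length(from) != length(to)) {
    stop("`from` and `to` must have equal length")
  }
  prob <- rep_len(as.numeric(prob), length(from))
  if (anyNA(from) || anyNA(to)) stop("edge endpoints must not be missing")
  if (anyNA(prob)) stop("edge probabilities must be numeric and non-missing")
  if (any(prob < 0 | prob > 1)) {
    stop("edge probabilities must lie in [0, 1]")
  }
  zero <- prob == 0
  if (any(zero)) {
    warning(sprintf("dropped %d edge(s) with probability 0", sum(zero)))
  }
  if (is.null(nodes)) {
    nodes <- unique(as.character(rbind(from, to)))
  } else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) stop("node labels must be unique")
    absent <- setdiff(c(from, to), nodes)
    if (length(absent)) {
      stop("edge endpoints missing from `nodes`: ",
           paste(absent, collapse = ", "))
    }
  }
  from <- from[!zero]; to <- to[!zero]; prob <- prob[!zero]
  if (any(from == to)) stop("self-loops are not allowed")
  i <- match(from, nodes)
  j <- match(to, nodes)
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  if (anyDuplicated(paste(lo, hi))) {
    stop("duplicate edges (networks are undirected: 'a b' and 'b a' collide)")
  }
  edges <- data.frame(i = lo, j = hi, p = prob)
  if (nrow(edges)) {
    edges <- edges[order(edges$i, edges$j), , drop = FALSE]
    rownames(edges) <- NULL
  }
  new_uncertain_network(nodes, edges)
}

#' Construct a deterministic network
#'
#' A deterministic network is the special case of an [uncertain_network()]
#' in which every edge exists with probability exactly 1.
#'
#' @inheritParams uncertain_network
#' @return An object of classes `deterministic_network`, `uncertain_network`.
#' @export
deterministic_network <- function(from = character(), to = character(),
                                  nodes = NULL) {
  g <- uncertain_network(from, to, prob = 1, nodes = nodes)
  class(g) <- c("deterministic_network", class(g))
  g
}

#' @rdname deterministic_network
#' @param g an `uncertain_network`.
#' @export
is_deterministic <- function(g) {
  stopifnot(inherits(g, "uncertain_network"))
  all(g$edges$p == 1)
}

#' @rdname deterministic_network
#' @export
as_deterministic <- function(g) {
  if (!is_deterministic(g)) {
    stop("network has edges with probability < 1; not deterministic")
  }
  class(g) <- unique(c("deterministic_network", class(g)))
  g
}

#' @export
print.uncertain_network <- function(x, ...) {
  kind <- if (is_deterministic(x)) "deterministic" else "uncertain"
  cat(sprintf("<%s network: %d nodes, %d edges>\n",
              kind, n_nodes(x), n_edges(x)))
  invisible(x)
}

#' Network sizes and degrees
#'
#' `n_nodes()`/`n_edges()` count nodes and (probabilistic) edges;
#' `node_degrees()` returns the count of incident edges per node (for a
#' deterministic network this is the ordinary degree; for an uncertain
#' network it is the maximum possible degree `d^max`).
#'
#' @param g an `uncertain_network`.
#' @return integer vector or scalar.
#' @export
n_nodes <- function(g) length(g$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(g) nrow(g$edges)

#' @rdname n_nodes
#' @export
node_degrees <- function(g) {
  d <- tabulate(c(g$edges$i, g$edges$j), nbins = n_nodes(g))
  names(d) <- g$nodes
  d
}

# rows of g$edges incident to node index vi
incident_edge_rows <- function(g, vi) {
  which(g$edges$i == vi | g$edges$j == vi)
}

node_index <- function(g, v) {
  vi <- match(v, g$nodes)
  if (is.na(vi)) stop("unknown node: ", v)
  vi
}

#' Read a network edge list
#'
#' Parses a tab-separated edge list `node_a<TAB>node_b[<TAB>probability]`.
#' Lines starting with `#` and blank lines are skipped. Two-column rows
#' imply probability 1 (deterministic edge). Rows with probability 0 are
#' dropped and counted in a warning; their endpoints still enter the node
#' set in first-appearance order.
#'
#' @param path path to the file.
#' @return an [uncertain_network()].
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  data_rows <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(data_rows)) stop("empty network file: ", path)
  fields <- strsplit(trimws(lines[data_rows]), "[\t ]+")
  nf <- lengths(fields)
  bad <- which(nf < 2 | nf > 3)
  if (length(bad)) {
    stop(sprintf("line %d: expected 2 or 3 columns, found %d",
                 data_rows[bad[1]], nf[bad[1]]))
  }
  from <- vapply(fields, `[`, "", 1L)
  to <- vapply(fields, `[`, "", 2L)
  p_str <- vapply(fields, function(f) if (length(f) >= 3) f[3] else "1", "")
  p <- suppressWarnings(as.numeric(p_str))
  if (anyNA(p)) {
    k <- which(is.na(p))[1]
    stop(sprintf("line %d: non-numeric probability '%s'",
                 data_rows[k], p_str[k]))
  }
  out_of_range <- which(p < 0 | p > 1)
  if (length(out_of_range)) {
    k <- out_of_range[1]
    stop(sprintf("line %d: probability %s outside [0, 1]",
                 data_rows[k], p_str[k]))
  }
  # first-appearance node order, including endpoints of dropped p=0 rows
  nodes <- unique(as.character(rbind(from, to)))
  keep <- p > 0
  if (!all(keep)) {
    warning(sprintf("%s: dropped %d zero-probability edge(s)",
                    path, sum(!keep)))
  }
  uncertain_network(from[keep], to[keep], p[keep], nodes = nodes)
}

#' Write a network edge list
#'
#' Serializes in the dialect read by [read_network()]: a `#` header line,
#' then `node_a<TAB>node_b<TAB>probability` rows with probabilities at 6
#' significant digits.
#'
#' @param g an `uncertain_network`.
#' @param path output path.
#' @export
write_network <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# node_a\tnode_b\tprobability", con)
  if (n_edges(g)) {
    writeLines(sprintf("%s\t%s\t%s",
                       g$nodes[g$edges$i], g$nodes[g$edges$j],
                       format(signif(g$edges$p, 6), trim = TRUE)), con)
  }
  invisible(path)
}

#' Enumerate all implication graphs (possible worlds)
#'
#' An uncertain graph with `|E|` probabilistic edges contains `2^|E|`
#' deterministic implication graphs, each occurring with the product
#' probability of its present edges times the complement probabilities of
#' its absent edges. Probabilities over the full enumeration sum to 1.
#' This is an oracle-grade operation: output size is exponential, so the
#' edge count is capped.
#'
#' @param g an `uncertain_network`.
#' @param max_edges refuse inputs with more edges than this (default 20).
#' @return a list of `list(network = <deterministic_network>,
#'   probability = <numeric>)`, one element per world.
#' @export
enumerate_implication_graphs <- function(g, max_edges = 20) {
  ne <- n_edges(g)
  if (ne > max_edges) {
    stop(sprintf(
      "network has %d edges; enumerating 2^%d worlds exceeds max_edges = %d",
      ne, ne, max_edges))
  }
  p <- g$edges$p
  lapply(seq_len(2^ne) - 1L, function(mask) {
    present <- if (ne) bitwAnd(mask, bitwShiftL(1L, seq_len(ne) - 1L)) > 0
               else logical(0)
    world <- deterministic_network(
      g$nodes[g$edges$i[present]], g$nodes[g$edges$j[present]],
      nodes = g$nodes)
    list(network = world,
         probability = prod(ifelse(present, p, 1 - p)))
  })
}

#' Probability that an uncertain graph implies a deterministic graph
#'
#' For a deterministic graph `G` on the same node set whose edges are a
#' subset of the uncertain graph's edges, returns the probability of the
#' possible world in which exactly the edges of `G` are present:
#' the product of `p_e` over present edges times `1 - p_e` over absent
#' ones.
#'
#' @param g an `uncertain_network`.
#' @param G a `deterministic_network` with `nodes(G) == nodes(g)` (as a
#'   set) and `edges(G)` a subset of `edges(g)`; anything else errors
#'   rather than silently returning 0.
#' @return a probability in `[0, 1]`.
#' @export
implication_probability <- function(g, G) {
  stopifnot(inherits(g, "uncertain_network"))
  if (!is_deterministic(G)) stop("`G` must be a deterministic network")
  if (!setequal(g$nodes, G$nodes)) {
    stop("`G` must be defined on the same node set as `g`")
  }
  gkey <- paste(g$nodes[g$edges$i], g$nodes[g$edges$j], sep = "\r")
  # canonicalize G edge keys in g's label order
  Gi <- match(G$nodes[G$edges$i], g$nodes)
  Gj <- match(G$nodes[G$edges$j], g$nodes)
  Gkey <- paste(g$nodes[pmin(Gi, Gj)], g$nodes[pmax(Gi, Gj)], sep = "\r")
  if (!all(Gkey %in% gkey)) {
    stop("`G` contains an edge absent from `g`; implication probability ",
         "would be 0 by convention, refusing")
  }
  present <- gkey %in% Gkey
  prod(ifelse(present, g$edges$p, 1 - g$edges$p))
}
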