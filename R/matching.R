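# Maximum-weight bipartite matching (assignment) via the Hungarian
# potential / shortest-augmenting-path method, O(n^3). Rectangular
# instances are padded with zero-weight dummy nodes to a square; with
# nonnegative weights the maximum-weight perfect matching of the padded
# square restricted to real pairs attains the maximum over all injections
# of the smaller side.

# Minimum-cost assignment on a square cost matrix. Returns an integer
# vector p with p[j] = row assigned to column j. Classic potential-based
# formulation: maintains feasible potentials (u, v) and grows one
# augmenting path per row along tight edges.
hungarian_min <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  if (n == 0L) return(integer(0))
  u <- numeric(n)
  v <- numeric(n + 1L)          # index n + 1 is the virtual start column
  p <- integer(n + 1L)          # p[j] = row matched to column j (0 = none)
  way <- integer(n + 1L)
  cols <- seq_len(n)
  for (i in seq_len(n)) {
    p[n + 1L] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free <- !used[cols]
      cur <- cost[i0, free] - u[i0] - v[cols[free]]
      upd <- cur < minv[free]
      if (any(upd)) {
        fidx <- cols[free]
        minv[fidx[upd]] <- cur[upd]
        way[fidx[upd]] <- j0
      }
      free_idx <- cols[free]
      if (!length(free_idx)) stop("assignment infeasible")  # cannot happen
      j1 <- free_idx[which.min(minv[free_idx])]
      delta <- minv[j1]
      iu <- which(used)
      u[p[iu]] <- u[p[iu]] + delta
      v[iu] <- v[iu] - delta
      minv[free_idx] <- minv[free_idx] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  p[seq_len(n)]
}

# Maximum-weight matching of cardinality min(m, n) on a nonnegative
# rectangular weight matrix. Returns list(rows, cols, weight) with pairs
# ordered by row index.
max_weight_matching <- function(W) {
  m <- nrow(W)
  n <- ncol(W)
  if (m == 0L || n == 0L) return(list(rows = integer(0), cols = integer(0),
                                      weight = 0))
  N <- max(m, n)
  C <- matrix(0, N, N)
  C[seq_len(m), seq_len(n)] <- -W
  p <- hungarian_min(C)
  cols <- which(p[seq_len(n)] <= m)
  rows <- p[cols]
  # pad to full cardinality with zero-weight pairs if dummy swaps occurred
  need <- min(m, n) - length(rows)
  if (need > 0L) {
    free_r <- setdiff(seq_len(m), rows)[seq_len(need)]
    free_c <- setdiff(seq_len(n), cols)[seq_len(need)]
    rows <- c(rows, free_r)
    cols <- c(cols, free_c)
  }
  ord <- order(rows)
  rows <- rows[ord]
  cols <- cols[ord]
  list(rows = rows, cols = cols, weight = sum(W[cbind(rows, cols)]))
}

# Lexicographic refinement: among weight-optimal matchings, pick the one
# whose row-sorted pair list is lexicographically smallest. Greedy prefix
# fixing with Hungarian re-solves on the remainder; O(m n) solves, so it
# is reserved for modest instances (the caller gates on size).
lex_min_matching <- function(W, tol = 1e-9) {
  m <- nrow(W)
  n <- ncol(W)
  need <- min(m, n)
  base <- max_weight_matching(W)
  opt <- base$weight
  slack <- tol * max(1, abs(opt))
  sub_weight <- function(r, c) {
    if (!length(r) || !length(c)) 0
    else max_weight_matching(W[r, c, drop = FALSE])$weight
  }
  rows_sel <- integer(0)
  cols_sel <- integer(0)
  cols_avail <- seq_len(n)
  fixed <- 0
  for (i in seq_len(m)) {
    if (length(rows_sel) == need) break
    rest_rows <- seq_len(m)[seq_len(m) > i]
    chosen <- NA_integer_
    for (j in cols_avail) {
      rest <- sub_weight(rest_rows, setdiff(cols_avail, j))
      if (fixed + W[i, j] + rest >= opt - slack) {
        chosen <- j
        break
      }
    }
    if (is.na(chosen) && (m - i) < (need - length(rows_sel))) {
      # forced by cardinality; take the best-scoring available column
      chosen <- cols_avail[which.max(W[i, cols_avail])]
    }
    if (!is.na(chosen)) {
      rows_sel <- c(rows_sel, i)
      cols_sel <- c(cols_sel, chosen)
      cols_avail <- setdiff(cols_avail, chosen)
      fixed <- fixed + W[i, chosen]
    }
  }
  # defensive: top up cardinality with zero-weight pairs
  short <- need - length(rows_sel)
  if (short > 0L) {
    free_r <- setdiff(seq_len(m), rows_sel)[seq_len(short)]
    free_c <- cols_avail[seq_len(short)]
    rows_sel <- c(rows_sel, free_r)
    cols_sel <- c(cols_sel, free_c)
    ord <- order(rows_sel)
    rows_sel <- rows_sel[ord]
    cols_sel <- cols_sel[ord]
  }
  list(rows = rows_sel, cols = cols_sel,
       weight = sum(W[cbind(rows_sel, cols_sel)]))
}
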