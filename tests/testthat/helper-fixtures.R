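# Six-protein worked example: the network A-B, A-C, B-D, B-E, C-D, C-F,
# D-E, D-F, E-F, and its CD-distance matrix printed to four decimals.

fig_edges <- function() {
  list(from = c("A", "A", "B", "B", "C", "C", "D", "D", "E"),
       to   = c("B", "C", "D", "E", "D", "F", "E", "F", "F"))
}

fig_ppin <- function() {
  e <- fig_edges()
  ppin(e$from, e$to, quiet = TRUE)
}

fig_edge_file <- function(path = tempfile(fileext = ".tsv")) {
  e <- fig_edges()
  writeLines(c("# protein_a\tprotein_b", paste(e$from, e$to, sep = "\t")),
             path)
  path
}

# printed reference distances (4 decimals)
fig_printed_dist <- function() {
  vals <- c(
    0,      1.0000, 1.0000, 0.3333, 0.6000, 0.6000,
    1.0000, 0,      0.3333, 0.7143, 0.6667, 0.3333,
    1.0000, 0.3333, 0,      0.7143, 0.3333, 0.6667,
    0.3333, 0.7143, 0.7143, 0,      0.4286, 0.4286,
    0.6000, 0.6667, 0.3333, 0.4286, 0,      0.6667,
    0.6000, 0.3333, 0.6667, 0.4286, 0.6667, 0)
  matrix(vals, 6, 6, byrow = TRUE,
         dimnames = list(LETTERS[1:6], LETTERS[1:6]))
}

# independent CD-distance oracle: explicit set arithmetic per pair
cd_oracle <- function(graph) {
  nodes <- graph$nodes
  n <- length(nodes)
  D <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      a <- graph$adjacency[[nodes[i]]]
      b <- graph$adjacency[[nodes[j]]]
      u <- length(union(a, b)); x <- length(intersect(a, b))
      D[i, j] <- (u - x) / (u + x)
    }
  }
  D
}

# exhaustive shortest-Hamiltonian-path oracle (all orderings, with pruning)
hp_opt_enum <- function(D) {
  n <- nrow(D)
  best <- Inf
  rec <- function(rest, last, len) {
    if (len >= best) return(invisible(NULL))
    if (length(rest) == 0L) { best <<- len; return(invisible(NULL)) }
    for (v in rest) {
      step <- if (last == 0L) 0 else D[last, v]
      rec(setdiff(rest, v), v, len + step)
    }
  }
  rec(seq_len(n), 0L, 0)
  best
}

# bitmask dynamic-programming oracle for the same quantity, O(n^2 2^n)
hp_opt_dp <- function(D) {
  n <- nrow(D)
  if (n == 1L) return(0)
  full <- bitwShiftL(1L, n) - 1L
  dp <- matrix(Inf, full, n)
  for (v in seq_len(n)) dp[bitwShiftL(1L, v - 1L), v] <- 0
  for (mask in seq_len(full)) {
    for (v in seq_len(n)) {
      if (bitwAnd(mask, bitwShiftL(1L, v - 1L)) == 0L) next
      cur <- dp[mask, v]
      if (!is.finite(cur)) next
      for (w in seq_len(n)) {
        b <- bitwShiftL(1L, w - 1L)
        if (bitwAnd(mask, b) != 0L) next
        nm <- bitwOr(mask, b)
        nv <- cur + D[v, w]
        if (nv < dp[nm, w]) dp[nm, w] <- nv
      }
    }
  }
  min(dp[full, ])
}

random_symmetric_dist <- function(n, labels = sprintf("N%02d", seq_len(n))) {
  M <- matrix(stats::runif(n * n), n, n)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  dimnames(M) <- list(labels, labels)
  M
}

random_ppin <- function(n, p = 0.3) {
  repeat {
    A <- matrix(stats::runif(n * n) < p, n, n)
    A[lower.tri(A, diag = TRUE)] <- FALSE
    idx <- which(A, arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    labels <- sprintf("N%02d", seq_len(n))
    g <- ppin(labels[idx[, 1L]], labels[idx[, 2L]], quiet = TRUE)
    return(g)
  }
}

# two disjoint triangles with per-triangle GO term pools
two_triangle_instance <- function() {
  g <- ppin(c("A1", "A1", "A2", "B1", "B1", "B2"),
            c("A2", "A3", "A3", "B2", "B3", "B3"), quiet = TRUE)
  go <- go_annotations(list(
    A1 = c("GO:1", "GO:2"), A2 = c("GO:1", "GO:3"), A3 = c("GO:2", "GO:3"),
    B1 = c("GO:4", "GO:5"), B2 = c("GO:4", "GO:6"), B3 = c("GO:5", "GO:6")))
  truth <- c(A1 = "T1", A2 = "T1", A3 = "T1", B1 = "T2", B2 = "T2", B3 = "T2")
  list(graph = g, go = go, truth = truth)
}
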