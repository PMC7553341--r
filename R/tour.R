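#' Lin-Kernighan search parameters
#'
#' @param max_move_depth maximum number of links removed in one sequential
#'   K-opt move (K >= 2). Deeper moves can escape poorer local optima at
#'   higher cost; 5 is the usual sweet spot.
#' @param candidate_list_size per-protein candidate list size: added links
#'   are restricted to each protein's `candidate_list_size` nearest
#'   neighbours in CD-distance. A size of n-1 recovers unrestricted search.
#' @param runs number of optimisation runs; runs beyond the first restart
#'   from a seeded double-bridge perturbation of the best tour and the best
#'   result is kept.
#' @param seed integer seed for the perturbation stream (only consumed when
#'   `runs > 1`).
#' @return an object of class `lk_params`.
#' @export
lk_params <- function(max_move_depth = 5L, candidate_list_size = 5L,
                      runs = 1L, seed = 0L) {
  stopifnot(max_move_depth >= 2L, candidate_list_size >= 1L, runs >= 1L)
  structure(list(max_move_depth = as.integer(max_move_depth),
                 candidate_list_size = as.integer(candidate_list_size),
                 runs = as.integer(runs), seed = as.integer(seed)),
            class = "lk_params")
}

#' Length of a Hamiltonian path
#'
#' @param order character vector: a permutation of the proteins labelling
#'   `dist`.
#' @param dist a distance matrix from [cd_distance_matrix()].
#' @return the sum of distances over consecutive pairs (0 for one protein).
#' @export
tour_length <- function(order, dist) {
  labels <- rownames(dist)
  if (length(order) != length(labels) || !setequal(order, labels) ||
      anyDuplicated(order) > 0L) {
    stop("order is not a permutation of the distance-matrix labels",
         call. = FALSE)
  }
  n <- length(order)
  if (n < 2L) return(0)
  sum(dist[cbind(order[-n], order[-1L])])
}

new_tour <- function(order, dist) {
  structure(list(order = order, length = tour_length(order, dist)),
            class = "tour")
}

#' @export
print.tour <- function(x, ...) {
  cat(sprintf("<tour> %d proteins, length %.4f\n", length(x$order), x$length))
  invisible(x)
}

#' Nearest-neighbour initial tour
#'
#' Greedy Hamiltonian-path construction: starting from a dummy node at
#' distance 0 to every protein, repeatedly append the nearest unvisited
#' protein to the current end, then drop the dummy. Ties (including the
#' all-tie first step from the dummy) are broken towards the
#' lexicographically smallest protein identifier, so the construction is
#' deterministic.
#'
#' @param dist a distance matrix from [cd_distance_matrix()].
#' @return a `tour` object: `order` (character permutation) and `length`.
#' @export
nn_initial_tour <- function(dist) {
  labels <- rownames(dist)
  if (is.null(labels) || length(labels) == 0L) stop("empty distance matrix",
                                                    call. = FALSE)
  sorted <- sort(labels)
  D <- dist[sorted, sorted, drop = FALSE]
  n <- length(sorted)
  order_idx <- integer(n)
  visited <- rep(FALSE, n)
  cur <- 1L                      # dummy -> all at 0 -> lexicographic minimum
  order_idx[1L] <- cur; visited[cur] <- TRUE
  for (k in seq_len(n - 1L)) {
    d <- D[cur, ]
    d[visited] <- Inf
    cur <- which.min(d)          # stable: ties give the smallest label
    order_idx[k + 1L] <- cur; visited[cur] <- TRUE
  }
  new_tour(sorted[order_idx], dist)
}

#' Improve a tour with sequential K-opt (Lin-Kernighan) moves
#'
#' The Hamiltonian path is embedded as a cycle through a dummy node at
#' distance 0 to every protein, so the shortest cycle through the dummy
#' corresponds to the shortest path. Moves are built as alternating chains
#' of removed and added links following the classical criteria: sequential
#' exchange (the chain alternates around the ends of removed links),
#' positive gain (the cumulative gain stays > 0 at every step), disjunctive
#' (a link is never both added and removed in one move), candidate
#' restriction (added links come from each node's nearest-neighbour
#' candidate list), and feasibility (a move is applied only if the
#' resulting link set is a single Hamiltonian cycle, checked by
#' reconstruction). First-improvement moves are applied until no chain of
#' at most `max_move_depth` removed links improves the tour.
#'
#' @param tour a `tour` object (e.g. from [nn_initial_tour()]).
#' @param dist the distance matrix the tour lives on.
#' @param params an [lk_params] object.
#' @return a `tour` object with `length <= tour$length`.
#' @export
lk_improve <- function(tour, dist, params = lk_params()) {
  stopifnot(inherits(tour, "tour"), inherits(params, "lk_params"))
  labels <- rownames(dist)
  if (!setequal(tour$order, labels)) {
    stop("tour does not match the distance matrix labels", call. = FALSE)
  }
  n <- length(labels)
  if (n <= 2L) return(new_tour(tour$order, dist))
  sorted <- sort(labels)
  # augmented instance: index n+1 is the dummy node at distance 0 to all
  m <- n + 1L
  Daug <- matrix(0, m, m)
  Daug[seq_len(n), seq_len(n)] <- dist[sorted, sorted]
  cand <- lk_candidate_lists(Daug, params$candidate_list_size)
  ord0 <- c(match(tour$order, sorted), m)
  best <- lk_optimize_cycle(ord0, Daug, cand, params$max_move_depth)
  if (params$runs > 1L) {
    set.seed(params$seed)
    for (run in seq_len(params$runs - 1L)) {
      pert <- lk_double_bridge(best$ord)
      res <- lk_optimize_cycle(pert, Daug, cand, params$max_move_depth)
      if (res$length < best$length - 1e-12) best <- res
    }
  }
  path_idx <- lk_cut_at_dummy(best$ord, m)
  order <- sorted[path_idx]
  new_tour(order, dist)
}

#' Dump a tour as TSV
#'
#' Columns `rank`, `protein_id`, `dist_to_next` (empty for the last
#' protein); for debugging and stage inspection.
#'
#' @param tour a `tour` object.
#' @param dist the distance matrix the tour lives on.
#' @param path output path.
#' @export
write_tour <- function(tour, dist, path) {
  n <- length(tour$order)
  d_next <- c(if (n > 1L) dist[cbind(tour$order[-n], tour$order[-1L])], NA)
  df <- data.frame(rank = seq_len(n), protein_id = tour$order,
                   dist_to_next = round(d_next, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(NULL)
}

# ---- internal LK machinery (integer indices over the augmented matrix) ----

lk_candidate_lists <- function(D, size) {
  m <- nrow(D)
  lapply(seq_len(m), function(v) {
    others <- setdiff(seq_len(m), v)
    o <- order(D[v, others])            # stable: ties fall back to index order
    others[o][seq_len(min(size, length(others)))]
  })
}

lk_edge_key <- function(a, b, m) {
  ifelse(a < b, a * (m + 1) + b, b * (m + 1) + a)
}

# rebuild a cycle from (cycle edges - removed + added); NULL if infeasible
lk_reconstruct <- function(ord, removed, added, m) {
  n <- length(ord)
  nxt <- c(ord[-1L], ord[1L])
  cyc <- lk_edge_key(ord, nxt, m)
  new_keys <- c(setdiff(cyc, removed), added)
  if (length(new_keys) != n || anyDuplicated(new_keys) > 0L) return(NULL)
  i <- new_keys %/% (m + 1)
  j <- new_keys %% (m + 1)
  ends <- c(i, j)
  cnt <- tabulate(ends, m)
  if (any(cnt[ord] != 2L)) return(NULL)
  o <- order(ends)
  nb <- matrix(c(j, i)[o], nrow = 2L)   # column k = neighbours of node rank k
  node_of_col <- sort(ord)
  col_of <- integer(m); col_of[node_of_col] <- seq_len(n)
  out <- integer(n)
  cur <- ord[1L]; prev <- 0L
  for (k in seq_len(n)) {
    out[k] <- cur
    nbcur <- nb[, col_of[cur]]
    nxt1 <- if (nbcur[1L] == prev) nbcur[2L] else nbcur[1L]
    prev <- cur; cur <- nxt1
  }
  if (cur != ord[1L] || anyDuplicated(out) > 0L) return(NULL)
  out
}

lk_double_bridge <- function(ord) {
  n <- length(ord)
  if (n < 8L) return(ord)
  cuts <- sort(sample(2:(n - 1L), 3L))
  a <- ord[1:(cuts[1L] - 1L)]
  b <- ord[cuts[1L]:(cuts[2L] - 1L)]
  cc <- ord[cuts[2L]:(cuts[3L] - 1L)]
  d <- ord[cuts[3L]:n]
  c(a, cc, b, d)
}

lk_cut_at_dummy <- function(ord, dummy) {
  n <- length(ord)
  p <- which(ord == dummy)
  path <- ord[c(seq_len(n)[-seq_len(p)], seq_len(p - 1L))]
  # orientation is free on a cycle: fix it deterministically
  if (path[1L] > path[length(path)]) path <- rev(path)
  path
}

# depth-limited sequential-exchange search with don't-look bits;
# returns list(ord, length)
lk_optimize_cycle <- function(ord, D, cand, K) {
  m <- nrow(D)
  n <- length(ord)
  EPS <- 1e-12
  pos <- integer(m); pos[ord] <- seq_len(n)
  tour_next <- function(v) ord[pos[v] %% n + 1L]
  tour_prev <- function(v) ord[(pos[v] - 2L) %% n + 1L]
  is_tour_edge <- function(a, b) tour_next(a) == b || tour_prev(a) == b

  # recursive chain extension: t1 fixed move anchor, t_end is the free end
  chain <- function(t1, t_end, removed, added, gain, n_removed) {
    for (t3 in cand[[t_end]]) {
      if (t3 == t1 || t3 == t_end) next
      g_new <- gain - D[t_end, t3]
      if (g_new <= EPS) break               # candidates sorted by distance
      if (is_tour_edge(t_end, t3)) next     # adding a present link is void
      k_add <- lk_edge_key(t_end, t3, m)
      if (k_add %in% removed || k_add %in% added) next
      added2 <- c(added, k_add)
      for (t4 in c(tour_next(t3), tour_prev(t3))) {
        k_rem <- lk_edge_key(t3, t4, m)
        if (k_rem %in% added2 || k_rem %in% removed) next
        gain2 <- g_new + D[t3, t4]
        removed2 <- c(removed, k_rem)
        if (t4 != t1) {
          close_gain <- gain2 - D[t4, t1]
          if (close_gain > EPS) {
            k_close <- lk_edge_key(t4, t1, m)
            if (!(k_close %in% removed2) && !(k_close %in% added2)) {
              neword <- lk_reconstruct(ord, removed2, c(added2, k_close), m)
              if (!is.null(neword)) {
                return(list(ord = neword, gain = close_gain,
                            touched = c(removed2, added2, k_close)))
              }
            }
          }
        }
        if (n_removed + 1L < K) {
          res <- chain(t1, t4, removed2, added2, gain2, n_removed + 1L)
          if (!is.null(res)) return(res)
        }
      }
    }
    NULL
  }

  active <- rep(TRUE, m)
  repeat {
    improved_any <- FALSE
    for (t1 in ord) {
      if (!active[t1]) next
      found <- NULL
      for (t2 in c(tour_next(t1), tour_prev(t1))) {
        found <- chain(t1, t2, lk_edge_key(t1, t2, m), numeric(0),
                       D[t1, t2], 1L)
        if (!is.null(found)) break
      }
      if (is.null(found)) {
        active[t1] <- FALSE
      } else {
        ord <- found$ord
        pos[ord] <- seq_len(n)
        keys <- found$touched
        touched_nodes <- unique(c(keys %/% (m + 1), keys %% (m + 1)))
        active[touched_nodes] <- TRUE
        improved_any <- TRUE
      }
    }
    if (!improved_any) break
  }
  nxt <- c(ord[-1L], ord[1L])
  list(ord = ord, length = sum(D[cbind(ord, nxt)]))
}
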