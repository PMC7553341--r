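#' A set of protein modules plus an unassigned pool
#'
#' Modules are nonempty, pairwise-disjoint sets of protein identifiers;
#' `unassigned` holds proteins removed by filtering. At every pipeline
#' stage the union of all modules and the unassigned pool equals the input
#' protein set.
#'
#' @param modules list of character vectors (each nonempty, no overlaps).
#' @param unassigned character vector, disjoint from every module.
#' @return an object of class `module_set`.
#' @export
module_set <- function(modules = list(), unassigned = character(0)) {
  modules <- lapply(modules, function(x) sort(unique(as.character(x))))
  unassigned <- sort(unique(as.character(unassigned)))
  if (any(lengths(modules) == 0L)) stop("empty module", call. = FALSE)
  all_assigned <- unlist(modules, use.names = FALSE)
  if (anyDuplicated(all_assigned) > 0L) {
    stop("modules are not pairwise disjoint", call. = FALSE)
  }
  if (any(unassigned %in% all_assigned)) {
    stop("unassigned proteins overlap a module", call. = FALSE)
  }
  # deterministic ordering: by lexicographically smallest member
  if (length(modules) > 0L) {
    modules <- modules[order(vapply(modules, `[[`, character(1), 1L))]
  }
  structure(list(modules = modules, unassigned = unassigned),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("<module_set> %d module(s) (sizes: %s), %d unassigned\n",
              length(x$modules),
              paste(lengths(x$modules), collapse = ","),
              length(x$unassigned)))
  invisible(x)
}

#' All proteins covered by a module set
#' @param modules a [module_set].
#' @return sorted character vector of assigned plus unassigned proteins.
#' @export
module_set_proteins <- function(modules) {
  sort(c(unlist(modules$modules, use.names = FALSE), modules$unassigned))
}

#' Cut a tour into preliminary modules
#'
#' Proteins close together on the shortest path tend to belong to the same
#' functional module, so the path is cut at every consecutive pair whose
#' CD-distance exceeds `cut_threshold`; each maximal uncut segment becomes
#' one preliminary module.
#'
#' @param tour a `tour` object.
#' @param dist the distance matrix the tour lives on.
#' @param cut_threshold cut distance delta in `[0, 1]`; consecutive pairs
#'   with `d > cut_threshold` are severed. `NULL` selects the default: the
#'   empirical 75th percentile of the tour's consecutive distances.
#' @return a [module_set] with an empty unassigned pool.
#' @export
segment_tour <- function(tour, dist, cut_threshold = NULL) {
  stopifnot(inherits(tour, "tour"))
  ord <- tour$order
  n <- length(ord)
  if (n == 1L) return(module_set(list(ord)))
  d_step <- dist[cbind(ord[-n], ord[-1L])]
  if (is.null(cut_threshold)) {
    cut_threshold <- stats::quantile(d_step, 0.75, names = FALSE, type = 7)
  }
  stopifnot(cut_threshold >= 0, cut_threshold <= 1)
  cut_after <- which(d_step > cut_threshold)
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  module_set(mapply(function(s, e) ord[s:e], starts, ends, SIMPLIFY = FALSE))
}

#' Functional similarity of two proteins
#'
#' The Jaccard index of the proteins' GO term sets; 1 when the two
#' arguments denote the same protein. Two distinct proteins that are both
#' unannotated score 0 (the 0/0 form is defined as no evidence of shared
#' function).
#'
#' @param g_i,g_j character vectors of GO terms.
#' @param same_protein set `TRUE` when both term sets belong to one
#'   protein.
#' @return a similarity in `[0, 1]`.
#' @export
protein_similarity <- function(g_i, g_j, same_protein = FALSE) {
  if (isTRUE(same_protein)) return(1)
  g_i <- unique(g_i); g_j <- unique(g_j)
  u <- length(union(g_i, g_j))
  if (u == 0L) return(0)
  length(intersect(g_i, g_j)) / u
}

#' Functional similarity of two modules
#'
#' S(M_A, M_B) = sum over all cross pairs (i in M_A, j in M_B) of s(i, j),
#' divided by min(|M_A|, |M_B|). Because the numerator sums over all cross
#' pairs, the value can exceed 1.
#'
#' @param m_a,m_b disjoint nonempty character vectors of proteins.
#' @param go a `go_annotations` object.
#' @return a nonnegative real.
#' @export
module_similarity <- function(m_a, m_b, go) {
  stopifnot(length(m_a) > 0L, length(m_b) > 0L)
  if (length(intersect(m_a, m_b)) > 0L) {
    stop("modules overlap", call. = FALSE)
  }
  terms_a <- lapply(m_a, function(p) go_terms(go, p))
  terms_b <- lapply(m_b, function(p) go_terms(go, p))
  total <- 0
  for (ta in terms_a) {
    for (tb in terms_b) total <- total + protein_similarity(ta, tb)
  }
  total / min(length(m_a), length(m_b))
}

#' Merge functionally similar modules
#'
#' Greedy agglomeration: while any module pair has functional similarity
#' S(M_A, M_B) strictly greater than `theta`, merge the pair with the
#' largest S (ties broken towards the pair with the lexicographically
#' smallest member labels) and recompute similarities involving the merged
#' module. Terminates after at most (number of modules - 1) merges.
#'
#' @param modules a [module_set].
#' @param go a `go_annotations` object.
#' @param theta merge threshold (>= 0).
#' @return a [module_set]; the unassigned pool is passed through untouched.
#' @export
merge_by_function <- function(modules, go, theta) {
  stopifnot(inherits(modules, "module_set"), theta >= 0)
  mods <- modules$modules
  if (length(mods) < 2L) return(modules)
  nm <- length(mods)
  S <- matrix(0, nm, nm)
  for (a in seq_len(nm - 1L)) {
    for (b in (a + 1L):nm) {
      S[a, b] <- S[b, a] <- module_similarity(mods[[a]], mods[[b]], go)
    }
  }
  key <- vapply(mods, `[[`, character(1), 1L)  # smallest member (sorted sets)
  repeat {
    if (length(mods) < 2L) break
    smax <- max(S[upper.tri(S)])
    if (smax <= theta) break
    hits <- which(S == smax & upper.tri(S), arr.ind = TRUE)
    # deterministic tie-break: smallest member label of A, then of B
    pick <- hits[order(key[hits[, 1L]], key[hits[, 2L]])[1L], ]
    a <- pick[[1L]]; b <- pick[[2L]]
    merged <- sort(c(mods[[a]], mods[[b]]))
    mods[[a]] <- merged
    mods[[b]] <- NULL
    key <- vapply(mods, `[[`, character(1), 1L)
    S <- S[-b, -b, drop = FALSE]
    if (length(mods) >= 2L) {
      for (j in seq_along(mods)) {
        if (j == a) next
        S[a, j] <- S[j, a] <- module_similarity(mods[[a]], mods[[j]], go)
      }
    }
  }
  module_set(mods, unassigned = modules$unassigned)
}

#' Edge density of a module
#'
#' Ds = e / (N (N - 1) / 2) where N is the number of proteins in the
#' module and e the number of network interactions with both endpoints
#' inside it; 1 for a clique, 0 for an internally disconnected set.
#' Singleton modules return 0 by convention (no internal pair exists).
#'
#' @param module nonempty character vector of proteins.
#' @param graph the [ppin] the module lives in.
#' @return a density in `[0, 1]`.
#' @export
module_density <- function(module, graph) {
  stopifnot(length(module) > 0L)
  n <- length(unique(module))
  if (n == 1L) return(0)
  e <- ppin_internal_edges(graph, module)
  e / (n * (n - 1) / 2)
}

#' Filter modules by edge density
#'
#' Modules whose density falls below `density_min` are removed as whole
#' sets: their proteins move to the unassigned pool rather than being
#' silently dropped. Singletons (density 0 by convention) are kept only
#' when `keep_singletons` is set.
#'
#' @param modules a [module_set].
#' @param graph the [ppin] the modules live in.
#' @param density_min lower density bound in `[0, 1]`; 0 keeps every
#'   non-singleton module.
#' @param keep_singletons keep single-protein modules regardless of their
#'   conventional density of 0.
#' @return a [module_set].
#' @export
filter_by_density <- function(modules, graph, density_min = 0,
                              keep_singletons = FALSE) {
  stopifnot(inherits(modules, "module_set"),
            density_min >= 0, density_min <= 1)
  keep <- vapply(modules$modules, function(mod) {
    if (length(mod) == 1L) return(isTRUE(keep_singletons))
    module_density(mod, graph) >= density_min
  }, logical(1))
  dropped <- unlist(modules$modules[!keep], use.names = FALSE)
  module_set(modules$modules[keep],
             unassigned = c(modules$unassigned, dropped))
}
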