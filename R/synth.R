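#' Specification of a synthetic planted-module PPIN
#'
#' Describes a planted-partition (stochastic block model) interaction
#' network with per-module GO term pools, emulating a preprocessed PPI
#' dataset with functional annotation so the whole pipeline can be
#' exercised without external data.
#'
#' @param module_sizes integer vector of planted module sizes (each >= 1).
#' @param p_in probability of an edge between two proteins of the same
#'   module.
#' @param p_out probability of an edge between proteins of different
#'   modules.
#' @param terms_per_module size of each module's disjoint GO term pool.
#' @param terms_per_protein number of annotation terms drawn per protein.
#' @param annotation_noise per-term probability of drawing from a foreign
#'   module's pool instead of the protein's own.
#' @param seed integer seed; the generator is deterministic given the spec.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(module_sizes = c(20L, 20L, 20L, 20L, 20L),
                       p_in = 0.8, p_out = 0.05,
                       terms_per_module = 20L, terms_per_protein = 3L,
                       annotation_noise = 0.1, seed = 0L) {
  stopifnot(length(module_sizes) >= 1L, all(module_sizes >= 1L),
            p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1,
            terms_per_module >= 1L, terms_per_protein >= 0L,
            annotation_noise >= 0, annotation_noise <= 1)
  if (terms_per_protein > terms_per_module && annotation_noise == 0) {
    stop("infeasible: terms_per_protein exceeds the module pool with no noise",
         call. = FALSE)
  }
  structure(list(module_sizes = as.integer(module_sizes),
                 p_in = p_in, p_out = p_out,
                 terms_per_module = as.integer(terms_per_module),
                 terms_per_protein = as.integer(terms_per_protein),
                 annotation_noise = annotation_noise,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate a synthetic PPIN with planted modules
#'
#' Draws a planted-partition graph (each intra-module pair is an edge with
#' probability `p_in`, each inter-module pair with `p_out`), assigns each
#' module a disjoint pool of GO terms, and annotates each protein with
#' `terms_per_protein` terms from its own pool, each term independently
#' replaced with probability `annotation_noise` by a term from a uniformly
#' chosen foreign pool. Proteins left isolated by the edge draw are
#' re-wired to one random member of their own module (or, for a singleton
#' module, to a random foreign protein) so the graph satisfies the
#' degree >= 1 invariant while keeping the truth labelling total.
#'
#' @param spec a [synth_spec].
#' @return a list with elements `graph` (a [ppin]), `go`
#'   (a `go_annotations`), and `truth` (named character vector: protein ->
#'   planted module label).
#' @export
generate_ppin <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  sizes <- spec$module_sizes
  k <- length(sizes)
  n <- sum(sizes)
  if (n < 2L) stop("need at least two proteins to form an interaction",
                   call. = FALSE)
  block <- rep(seq_len(k), sizes)
  proteins <- sprintf("P%04d", seq_len(n))
  names(block) <- proteins
  pref <- matrix(spec$p_out, k, k)
  diag(pref) <- spec$p_in
  g <- igraph::sample_sbm(n, pref.matrix = pref, block.sizes = sizes)
  el <- igraph::as_edgelist(g, names = FALSE)
  from <- proteins[el[, 1L]]
  to <- proteins[el[, 2L]]
  # re-wire isolated proteins instead of dropping them
  deg <- igraph::degree(g)
  for (v in which(deg == 0L)) {
    mates <- setdiff(which(block == block[v]), v)
    if (length(mates) == 0L) mates <- setdiff(seq_len(n), v)
    u <- mates[sample.int(length(mates), 1L)]
    from <- c(from, proteins[v]); to <- c(to, proteins[u])
  }
  if (length(from) == 0L) {
    stop("generated graph has no edges; raise p_in or module sizes",
         call. = FALSE)
  }
  graph <- ppin(from, to, quiet = TRUE)

  pools <- lapply(seq_len(k), function(m) {
    sprintf("GO:%07d", (m - 1L) * spec$terms_per_module +
              seq_len(spec$terms_per_module))
  })
  ann <- vector("list", n)
  names(ann) <- proteins
  for (v in seq_len(n)) {
    terms <- character(spec$terms_per_protein)
    for (t in seq_len(spec$terms_per_protein)) {
      pool_id <- block[v]
      if (k > 1L && spec$annotation_noise > 0 &&
          stats::runif(1L) < spec$annotation_noise) {
        pool_id <- sample(setdiff(seq_len(k), block[v]), 1L)
      }
      terms[t] <- sample(pools[[pool_id]], 1L)
    }
    ann[[v]] <- unique(terms)
  }
  truth <- sprintf("T%d", block)
  names(truth) <- proteins

  list(graph = graph, go = go_annotations(ann), truth = truth)
}

#' Write a synthetic instance to disk
#'
#' Emits the edge-list TSV, the GO annotation TSV and a truth-label TSV
#' (`protein_id`, `module_label`) into `dir`.
#'
#' @param instance a list from [generate_ppin()].
#' @param dir output directory (created if missing).
#' @return invisibly, the three file paths.
#' @export
write_synth_instance <- function(instance, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  edges_path <- file.path(dir, "edges.tsv")
  go_path <- file.path(dir, "go.tsv")
  truth_path <- file.path(dir, "truth.tsv")
  g <- instance$graph
  rows <- unlist(lapply(g$nodes, function(p) {
    nb <- g$adjacency[[p]]
    nb <- nb[nb > p]                 # each undirected edge written once
    if (length(nb) > 0L) paste(p, nb, sep = "\t") else character(0)
  }))
  writeLines(c("# protein_a\tprotein_b", rows), edges_path)
  go <- instance$go
  go_rows <- unlist(lapply(names(go), function(p) paste(p, go[[p]], sep = "\t")))
  writeLines(c("# protein\tgo_term", go_rows), go_path)
  writeLines(c("protein_id\tmodule_label",
               paste(names(instance$truth), instance$truth, sep = "\t")),
             truth_path)
  invisible(c(edges = edges_path, go = go_path, truth = truth_path))
}
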