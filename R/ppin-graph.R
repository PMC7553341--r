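#' Protein-protein interaction network (PPIN)
#'
#' A `ppin` object is an undirected, simple graph over protein identifiers.
#' It stores a lexicographically ordered node vector, per-protein adjacency
#' sets (the open neighbourhood `Int(i)`: a protein is never a member of its
#' own adjacency list), and the edge count. Invariants enforced by the
#' constructor: symmetric adjacency, no self-loops, no duplicate edges, and
#' every node has degree >= 1.
#'
#' @param from,to character vectors of equal length giving the endpoints of
#'   each interaction record (possibly with duplicates, reversed duplicates
#'   and self-loops, which are cleaned away).
#' @param quiet suppress the message reporting dropped records.
#'
#' @return An object of class `ppin` with elements `nodes` (character),
#'   `adjacency` (named list of character vectors, lexicographically
#'   sorted), and `edge_count` (integer).
#' @export
ppin <- function(from, to, quiet = FALSE) {
  stopifnot(is.character(from), is.character(to), length(from) == length(to))
  n_in <- length(from)
  keep <- from != to
  n_loops <- sum(!keep)
  from <- from[keep]; to <- to[keep]
  if (length(from) == 0L) {
    stop("empty graph: no edges remain after cleaning", call. = FALSE)
  }
  # collapse duplicates and reversed duplicates through an igraph simplify
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  n_dup <- length(from) - igraph::ecount(g)
  # isolated nodes cannot arise from an edge list, but guard anyway
  deg <- igraph::degree(g)
  g <- igraph::delete_vertices(g, which(deg == 0L))
  if (igraph::vcount(g) == 0L) {
    stop("empty graph: no edges remain after cleaning", call. = FALSE)
  }
  nodes <- sort(igraph::V(g)$name)
  adj <- igraph::as_adj_list(g, mode = "all")
  adjacency <- lapply(adj, function(v) sort(igraph::V(g)$name[v]))
  names(adjacency) <- igraph::V(g)$name
  adjacency <- adjacency[nodes]
  if (!quiet && (n_loops > 0L || n_dup > 0L)) {
    message(sprintf("ppin: dropped %d self-loop and %d duplicate record(s) of %d",
                    n_loops, n_dup, n_in))
  }
  structure(
    list(nodes = nodes, adjacency = adjacency,
         edge_count = as.integer(igraph::ecount(g))),
    class = "ppin"
  )
}

#' @export
print.ppin <- function(x, ...) {
  cat(sprintf("<ppin> %d proteins, %d interactions\n",
              length(x$nodes), x$edge_count))
  invisible(x)
}

#' Number of proteins in a PPIN
#' @param graph a [ppin] object.
#' @return integer node count.
#' @export
ppin_size <- function(graph) length(graph$nodes)

#' Count interactions internal to a set of proteins
#'
#' @param graph a [ppin] object.
#' @param proteins character vector of protein identifiers.
#' @return integer: number of graph edges with both endpoints in `proteins`.
#' @export
ppin_internal_edges <- function(graph, proteins) {
  proteins <- unique(proteins)
  n_ends <- vapply(proteins, function(p) {
    sum(graph$adjacency[[p]] %in% proteins)
  }, integer(1))
  as.integer(sum(n_ends) / 2L)
}

#' Read a protein interaction edge list
#'
#' Supports a plain two-column tab-separated format (lines starting with `#`
#' are comments) and PSI-MITAB, of which only the two interactor-identifier
#' columns are used (the primary identifier before any `|` alternative).
#' The loaded graph is cleaned: self-interactions are dropped, duplicate and
#' reversed-duplicate records are collapsed, and proteins left without any
#' interaction are removed (a neighbourhood-overlap distance is undefined
#' for them and they cannot be placed on the interaction tour).
#'
#' @param path path to the interaction file.
#' @param dialect `"tsv"` (default) or `"mitab"`.
#' @param quiet suppress cleaning messages.
#' @return a [ppin] object.
#' @export
read_edge_list <- function(path, dialect = c("tsv", "mitab"), quiet = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  comment_char <- if (dialect == "tsv") "#" else "#"
  is_data <- !grepl("^\\s*$", lines) & !startsWith(lines, comment_char)
  if (dialect == "mitab") {
    # a MITAB header line starts with "ID(s) interactor A" or "#ID"
    is_data <- is_data & !grepl("^ID\\(s\\)", lines)
  }
  idx <- which(is_data)
  if (length(idx) == 0L) stop("no interaction records in ", path, call. = FALSE)
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nfield <- lengths(parts)
  bad <- which(nfield < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed interaction row at line %d of %s (need >= 2 tab-separated fields)",
                 idx[bad[1L]], path), call. = FALSE)
  }
  a <- vapply(parts, `[[`, character(1), 1L)
  b <- vapply(parts, `[[`, character(1), 2L)
  if (dialect == "mitab") {
    # keep the primary identifier of each interactor
    a <- vapply(strsplit(a, "|", fixed = TRUE), `[[`, character(1), 1L)
    b <- vapply(strsplit(b, "|", fixed = TRUE), `[[`, character(1), 1L)
  }
  a <- trimws(a); b <- trimws(b)
  if (any(a == "" | b == "")) {
    bad <- which(a == "" | b == "")[1L]
    stop(sprintf("malformed interaction row at line %d of %s (empty identifier)",
                 idx[bad], path), call. = FALSE)
  }
  ppin(a, b, quiet = quiet)
}

#' Read GO annotations for proteins
#'
#' Builds a mapping from protein identifier to a set of GO term identifiers.
#' Terms are opaque strings; duplicates collapse under set semantics, and a
#' protein absent from the file maps to the empty set on lookup.
#'
#' Dialects: `"tsv"` is two tab-separated columns (protein, term; `#`
#' comments), `"gaf"` is GAF 2.x (`!` comments; column 2 = object id,
#' column 5 = GO id).
#'
#' @param path path to the annotation file.
#' @param dialect `"tsv"` (default) or `"gaf"`.
#' @return an object of class `go_annotations`: a named list of character
#'   vectors (term sets), queried with [go_terms()].
#' @export
read_go_annotations <- function(path, dialect = c("tsv", "gaf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  comment_char <- if (dialect == "tsv") "#" else "!"
  is_data <- !grepl("^\\s*$", lines) & !startsWith(lines, comment_char)
  idx <- which(is_data)
  if (length(idx) == 0L) return(go_annotations(list()))
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nfield <- lengths(parts)
  min_fields <- if (dialect == "tsv") 2L else 5L
  bad <- which(nfield < min_fields)
  if (length(bad) > 0L) {
    stop(sprintf("malformed %s annotation row at line %d of %s (need >= %d tab-separated fields)",
                 dialect, idx[bad[1L]], path, min_fields), call. = FALSE)
  }
  if (dialect == "tsv") {
    prot <- vapply(parts, `[[`, character(1), 1L)
    term <- vapply(parts, `[[`, character(1), 2L)
  } else {
    prot <- vapply(parts, `[[`, character(1), 2L)
    term <- vapply(parts, `[[`, character(1), 5L)
  }
  prot <- trimws(prot); term <- trimws(term)
  if (any(prot == "" | term == "")) {
    bad <- which(prot == "" | term == "")[1L]
    stop(sprintf("malformed annotation row at line %d of %s (empty field)",
                 idx[bad], path), call. = FALSE)
  }
  go_annotations(lapply(split(term, prot), function(x) sort(unique(x))))
}

#' Construct a GO annotation map from a named list
#'
#' @param x named list: protein identifier -> character vector of GO terms.
#' @return a `go_annotations` object.
#' @export
go_annotations <- function(x = list()) {
  stopifnot(is.list(x))
  if (length(x) > 0L) {
    stopifnot(!is.null(names(x)), all(names(x) != ""))
    x <- lapply(x, function(v) sort(unique(as.character(v))))
    x <- x[sort(names(x))]
  }
  structure(x, class = "go_annotations")
}

#' @export
print.go_annotations <- function(x, ...) {
  cat(sprintf("<go_annotations> %d annotated protein(s), %d distinct term(s)\n",
              length(x), length(unique(unlist(x)))))
  invisible(x)
}

#' Look up the GO term set of a protein
#'
#' @param go a `go_annotations` object.
#' @param protein a protein identifier.
#' @return character vector of terms; `character(0)` for an unannotated
#'   protein.
#' @export
go_terms <- function(go, protein) {
  terms <- go[[protein]]
  if (is.null(terms)) character(0) else terms
}

#' Write a module set to TSV
#'
#' Two columns, `module_id` and `protein_id`. Modules are numbered `M1`,
#' `M2`, ... in order of their lexicographically smallest member; proteins
#' are sorted within each module; unassigned proteins follow with
#' `module_id` `"NA"`. The ordering is deterministic so identical module
#' sets produce byte-identical files.
#'
#' @param modules a [module_set] object.
#' @param path output file path.
#' @export
write_modules <- function(modules, path) {
  stopifnot(inherits(modules, "module_set"))
  mods <- lapply(modules$modules, sort)
  if (length(mods) > 0L) {
    mods <- mods[order(vapply(mods, `[[`, character(1), 1L))]
  }
  rows <- character(0)
  for (k in seq_along(mods)) {
    rows <- c(rows, paste(sprintf("M%d", k), mods[[k]], sep = "\t"))
  }
  rows <- c(rows, paste("NA", sort(modules$unassigned), sep = "\t"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("module_id\tprotein_id", rows), con)
  invisible(NULL)
}

#' Read a module set written by [write_modules()]
#'
#' @param path path to a modules TSV.
#' @return a [module_set] object.
#' @export
read_modules <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          na.strings = NULL)
  if (!identical(names(df), c("module_id", "protein_id"))) {
    stop("not a modules TSV (expected columns module_id, protein_id): ",
         path, call. = FALSE)
  }
  un <- df$protein_id[df$module_id == "NA"]
  asg <- df[df$module_id != "NA", , drop = FALSE]
  mods <- unname(split(asg$protein_id, asg$module_id))
  module_set(mods, unassigned = un)
}
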