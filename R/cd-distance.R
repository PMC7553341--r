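#' Czekanowski-Dice distance matrix of a PPIN
#'
#' For proteins i and j with open adjacency lists Int(i), Int(j) (a protein
#' is not a member of its own list), the CD-distance is
#'
#'   d_ij = (|Int(i) u Int(j)| - |Int(i) n Int(j)|) /
#'          (|Int(i) u Int(j)| + |Int(i) n Int(j)|)
#'
#' which is 0 when the two neighbourhoods are identical and 1 when they are
#' disjoint. With c_ij common neighbours and degrees k_i, k_j this reduces
#' to d_ij = 1 - 2 c_ij / (k_i + k_j), computed here for all pairs from the
#' adjacency matrix. Diagonal entries are stored as 0 by convention and are
#' never consumed downstream.
#'
#' @param graph a [ppin] object; must contain no isolated protein (the
#'   distance is a 0/0 form when both neighbourhoods are empty).
#' @return a symmetric numeric matrix with `dimnames` equal to
#'   `graph$nodes`, entries in `[0, 1]` off the diagonal.
#' @export
cd_distance_matrix <- function(graph) {
  stopifnot(inherits(graph, "ppin"))
  nodes <- graph$nodes
  n <- length(nodes)
  if (n == 0L) stop("empty graph", call. = FALSE)
  deg <- lengths(graph$adjacency)
  if (any(deg == 0L)) {
    stop("isolated protein(s) present: ",
         paste(nodes[deg == 0L], collapse = ", "), call. = FALSE)
  }
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(n)) A[i, graph$adjacency[[i]]] <- 1
  common <- A %*% t(A)        # c_ij: common neighbours (open neighbourhoods)
  degsum <- outer(deg, deg, "+")
  D <- 1 - 2 * common / degsum
  diag(D) <- 0
  # clamp tiny negative rounding at identical neighbourhoods
  D[D < 0] <- 0
  dimnames(D) <- list(nodes, nodes)
  D
}

#' Write a labelled distance matrix as TSV
#'
#' One header row of protein identifiers and one labelled row per protein;
#' intended for inspection and debugging.
#'
#' @param dist a matrix from [cd_distance_matrix()].
#' @param path output path.
#' @param digits number of decimal places to print.
#' @export
write_distance_matrix <- function(dist, path, digits = 4) {
  stopifnot(is.matrix(dist), !is.null(rownames(dist)))
  df <- as.data.frame(round(dist, digits))
  df <- cbind(protein = rownames(dist), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
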