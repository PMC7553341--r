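#' Cohesion of a module set
#'
#' Cohesion combines the functional similarity and the CD-distance of
#' intra-module protein pairs:
#'
#'   C_o = S + 1/D   (D != 0),   C_o = S   (D = 0)
#'
#' where S is the aggregate of s(i, j) and D the aggregate of d_ij over all
#' unordered pairs i, j lying in the same module. The aggregation defaults
#' to the plain mean over all intra-module pairs, chosen so that tighter,
#' more functionally homogeneous modules score higher; it is pluggable via
#' `aggregate` (e.g. to average per module first).
#'
#' A module set with no intra-module pair (all singletons) returns 0.
#'
#' @param modules a [module_set] with at least one module.
#' @param go a `go_annotations` object.
#' @param dist the CD-distance matrix.
#' @param aggregate function reducing a numeric vector of per-pair values
#'   to a scalar; default `mean`.
#' @return the cohesion score C_o.
#' @export
cohesion <- function(modules, go, dist, aggregate = mean) {
  stopifnot(inherits(modules, "module_set"))
  if (length(modules$modules) == 0L) stop("no modules", call. = FALSE)
  prs <- intra_pairs(modules)
  if (nrow(prs) == 0L) return(0)
  sd_ <- pair_values(prs, go, dist)
  S <- aggregate(sd_$s)
  D <- aggregate(sd_$d)
  if (D != 0) S + 1 / D else S
}

#' Separation of a module set
#'
#' Separation combines the CD-distance and the functional similarity of
#' cross-module protein pairs:
#'
#'   S_e = D + 1/S   (S != 0),   S_e = D   (S = 0)
#'
#' where D is the aggregate of d_ij and S the aggregate of s(i, j) over all
#' pairs i, j lying in different modules (mean by default, pluggable as in
#' [cohesion()]). Well-separated module sets — distant and functionally
#' unrelated across modules — score higher.
#'
#' @inheritParams cohesion
#' @param modules a [module_set] with at least two modules.
#' @return the separation score S_e.
#' @export
separation <- function(modules, go, dist, aggregate = mean) {
  stopifnot(inherits(modules, "module_set"))
  if (length(modules$modules) < 2L) {
    stop("separation needs at least two modules", call. = FALSE)
  }
  prs <- cross_pairs(modules)
  sd_ <- pair_values(prs, go, dist)
  D <- aggregate(sd_$d)
  S <- aggregate(sd_$s)
  if (S != 0) D + 1 / S else D
}

#' Score a module set
#'
#' Convenience wrapper computing cohesion, separation and their S/D
#' components in one pass.
#'
#' @inheritParams cohesion
#' @return a list of class `evaluation_result` with elements `cohesion`,
#'   `separation`, `intra_similarity`, `intra_distance`,
#'   `inter_similarity`, `inter_distance`, `n_modules`, `module_sizes`,
#'   `n_unassigned`. Separation entries are `NA` when fewer than two
#'   modules exist.
#' @export
evaluate_modules <- function(modules, go, dist, aggregate = mean) {
  stopifnot(inherits(modules, "module_set"))
  if (length(modules$modules) == 0L) stop("no modules", call. = FALSE)
  prs_in <- intra_pairs(modules)
  if (nrow(prs_in) > 0L) {
    sd_in <- pair_values(prs_in, go, dist)
    S_in <- aggregate(sd_in$s); D_in <- aggregate(sd_in$d)
    co <- if (D_in != 0) S_in + 1 / D_in else S_in
  } else {
    S_in <- 0; D_in <- 0; co <- 0
  }
  if (length(modules$modules) >= 2L) {
    sd_x <- pair_values(cross_pairs(modules), go, dist)
    S_x <- aggregate(sd_x$s); D_x <- aggregate(sd_x$d)
    se <- if (S_x != 0) D_x + 1 / S_x else D_x
  } else {
    S_x <- NA_real_; D_x <- NA_real_; se <- NA_real_
  }
  structure(list(cohesion = co, separation = se,
                 intra_similarity = S_in, intra_distance = D_in,
                 inter_similarity = S_x, inter_distance = D_x,
                 n_modules = length(modules$modules),
                 module_sizes = lengths(modules$modules),
                 n_unassigned = length(modules$unassigned)),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation> %d module(s); cohesion %.4f, separation %s\n",
              x$n_modules, x$cohesion,
              if (is.na(x$separation)) "NA" else sprintf("%.4f", x$separation)))
  invisible(x)
}

#' Adjusted Rand index against a reference labelling
#'
#' Compares the module assignment with a ground-truth labelling of the
#' same proteins (used for synthetic planted-module recovery checks).
#' Unassigned proteins are treated as one extra cluster of their own.
#'
#' @param predicted a [module_set].
#' @param truth named vector: protein identifier -> reference label.
#' @return the ARI in `[-1, 1]`; 1 for identical partitions.
#' @export
adjusted_rand_index <- function(predicted, truth) {
  stopifnot(inherits(predicted, "module_set"), !is.null(names(truth)))
  prots <- module_set_proteins(predicted)
  if (!setequal(prots, names(truth))) {
    stop("predicted modules and truth labels cover different proteins",
         call. = FALSE)
  }
  pred_lab <- character(length(prots)); names(pred_lab) <- prots
  for (k in seq_along(predicted$modules)) {
    pred_lab[predicted$modules[[k]]] <- sprintf("M%d", k)
  }
  pred_lab[predicted$unassigned] <- ".unassigned"
  mclust::adjustedRandIndex(pred_lab[prots], as.character(truth[prots]))
}

# ---- internal pair enumeration ----

intra_pairs <- function(modules) {
  out <- lapply(modules$modules, function(mod) {
    if (length(mod) < 2L) return(NULL)
    t(utils::combn(mod, 2L))
  })
  do.call(rbind, c(out, list(matrix(character(0), ncol = 2L))))
}

cross_pairs <- function(modules) {
  mods <- modules$modules
  out <- list(matrix(character(0), ncol = 2L))
  nm <- length(mods)
  for (a in seq_len(nm - 1L)) {
    for (b in (a + 1L):nm) {
      out[[length(out) + 1L]] <-
        as.matrix(expand.grid(mods[[a]], mods[[b]],
                              stringsAsFactors = FALSE))
    }
  }
  do.call(rbind, out)
}

pair_values <- function(pairs, go, dist) {
  s <- vapply(seq_len(nrow(pairs)), function(r) {
    protein_similarity(go_terms(go, pairs[r, 1L]), go_terms(go, pairs[r, 2L]))
  }, numeric(1))
  d <- dist[pairs]
  list(s = s, d = d)
}
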