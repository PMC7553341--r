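#' Pipeline configuration
#'
#' Collects every input path and tunable of the end-to-end module
#' detection pipeline. `cut_threshold = NULL` selects the adaptive default
#' (75th percentile of tour-edge distances, see [segment_tour()]).
#'
#' @param edges path to the interaction edge list.
#' @param go optional path to a GO annotation file (`NULL` = no
#'   annotations; every protein gets the empty term set and no merging
#'   occurs beyond the identity).
#' @param edge_dialect `"tsv"` or `"mitab"`.
#' @param go_dialect `"tsv"` or `"gaf"`.
#' @param cut_threshold tour segmentation cut delta, or `NULL` for the
#'   adaptive default.
#' @param merge_threshold GO-similarity merge threshold theta.
#' @param density_min lower module-density bound (0 disables filtering).
#' @param keep_singletons keep singleton modules through density
#'   filtering.
#' @param lk an [lk_params] object.
#' @param out_dir optional output directory for stage dumps, final
#'   modules, metrics JSON and the run manifest.
#' @param log_level `"info"` for per-stage progress messages, `"quiet"`
#'   for silence.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(edges, go = NULL,
                            edge_dialect = "tsv", go_dialect = "tsv",
                            cut_threshold = NULL, merge_threshold = 0.05,
                            density_min = 0, keep_singletons = FALSE,
                            lk = lk_params(), out_dir = NULL,
                            log_level = c("info", "quiet")) {
  structure(list(edges = edges, go = go,
                 edge_dialect = edge_dialect, go_dialect = go_dialect,
                 cut_threshold = cut_threshold,
                 merge_threshold = merge_threshold,
                 density_min = density_min,
                 keep_singletons = keep_singletons,
                 lk = lk, out_dir = out_dir,
                 log_level = match.arg(log_level)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat key-value file mirroring the [pipeline_config()] arguments, with
#' the LK parameters under `k_opt_depth`, `candidates`, `runs`, `seed`.
#' Values supplied in `...` override the file.
#'
#' @param path path to a YAML config file.
#' @param ... overrides, named as in [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  over <- list(...)
  raw[names(over)] <- over
  lk <- lk_params(
    max_move_depth = raw$k_opt_depth %||% 5L,
    candidate_list_size = raw$candidates %||% 5L,
    runs = raw$runs %||% 1L,
    seed = raw$seed %||% 0L)
  pipeline_config(
    edges = raw$edges, go = raw$go,
    edge_dialect = raw$edge_dialect %||% "tsv",
    go_dialect = raw$go_dialect %||% "tsv",
    cut_threshold = raw$cut_threshold,
    merge_threshold = raw$merge_threshold %||% 0.05,
    density_min = raw$density_min %||% 0,
    keep_singletons = isTRUE(raw$keep_singletons),
    lk = lk, out_dir = raw$out_dir,
    log_level = raw$log_level %||% "info")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a pipeline configuration
#'
#' Checks file existence and threshold ranges; stops with an informative
#' error on the first violation.
#'
#' @param config a `pipeline_config`.
#' @return the config, invisibly.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!file.exists(config$edges)) {
    stop("edges file not found: ", config$edges, call. = FALSE)
  }
  if (!is.null(config$go) && !file.exists(config$go)) {
    stop("GO annotation file not found: ", config$go, call. = FALSE)
  }
  if (!is.null(config$cut_threshold) &&
      (config$cut_threshold < 0 || config$cut_threshold > 1)) {
    stop("cut_threshold must lie in [0, 1]", call. = FALSE)
  }
  if (config$merge_threshold < 0) {
    stop("merge_threshold must be >= 0", call. = FALSE)
  }
  if (config$density_min < 0 || config$density_min > 1) {
    stop("density_min must lie in [0, 1]", call. = FALSE)
  }
  invisible(config)
}

#' Run the full module detection pipeline
#'
#' Stages: read inputs, build the CD-distance matrix, construct the
#' nearest-neighbour tour, improve it with sequential K-opt moves, cut the
#' tour into preliminary modules, merge functionally similar modules by GO
#' similarity, filter by edge density, and score the result. When
#' `config$out_dir` is set, stage dumps (distance matrix, tour, pre-merge
#' / post-merge / final modules), a metrics JSON and a run manifest
#' (parameters, seed, input checksums) are written there.
#'
#' @param config a `pipeline_config`.
#' @return a list with elements `modules` (final [module_set]),
#'   `evaluation` ([evaluate_modules()] output), `tour`, `dist`, `graph`,
#'   `go` and `manifest`.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  quiet <- identical(config$log_level, "quiet")
  say <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s': %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  graph <- with_stage("read", read_edge_list(config$edges,
                                             dialect = config$edge_dialect,
                                             quiet = quiet))
  say("read", "%d proteins, %d interactions", length(graph$nodes),
      graph$edge_count)
  go <- if (is.null(config$go)) go_annotations() else
    with_stage("read", read_go_annotations(config$go,
                                           dialect = config$go_dialect))
  dist <- with_stage("distance", cd_distance_matrix(graph))
  say("distance", "%dx%d CD-distance matrix", nrow(dist), ncol(dist))
  tour0 <- with_stage("tour", nn_initial_tour(dist))
  say("tour", "nearest-neighbour tour length %.4f", tour0$length)
  tour <- with_stage("tour", lk_improve(tour0, dist, config$lk))
  say("tour", "K-opt improved tour length %.4f", tour$length)
  pre <- with_stage("segment", segment_tour(tour, dist, config$cut_threshold))
  say("segment", "%d preliminary module(s)", length(pre$modules))
  merged <- with_stage("merge",
                       merge_by_function(pre, go, config$merge_threshold))
  say("merge", "%d module(s) after GO merging", length(merged$modules))
  final <- with_stage("filter",
                      filter_by_density(merged, graph, config$density_min,
                                        config$keep_singletons))
  say("filter", "%d module(s) kept, %d protein(s) unassigned",
      length(final$modules), length(final$unassigned))
  evaluation <- with_stage("score", evaluate_modules(final, go, dist))

  manifest <- list(
    edges = config$edges,
    edges_md5 = unname(tools::md5sum(config$edges)),
    go = config$go,
    go_md5 = if (!is.null(config$go)) unname(tools::md5sum(config$go)),
    edge_dialect = config$edge_dialect, go_dialect = config$go_dialect,
    cut_threshold = config$cut_threshold,
    merge_threshold = config$merge_threshold,
    density_min = config$density_min,
    keep_singletons = config$keep_singletons,
    k_opt_depth = config$lk$max_move_depth,
    candidates = config$lk$candidate_list_size,
    runs = config$lk$runs, seed = config$lk$seed,
    n_proteins = length(graph$nodes), n_interactions = graph$edge_count)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    od <- config$out_dir
    write_distance_matrix(dist, file.path(od, "distances.tsv"))
    write_tour(tour, dist, file.path(od, "tour.tsv"))
    write_modules(pre, file.path(od, "modules_premerge.tsv"))
    write_modules(merged, file.path(od, "modules_postmerge.tsv"))
    write_modules(final, file.path(od, "modules.tsv"))
    jsonlite::write_json(
      list(cohesion = evaluation$cohesion,
           separation = evaluation$separation,
           intra_similarity = evaluation$intra_similarity,
           intra_distance = evaluation$intra_distance,
           inter_similarity = evaluation$inter_similarity,
           inter_distance = evaluation$inter_distance,
           n_modules = evaluation$n_modules,
           module_sizes = as.integer(evaluation$module_sizes),
           n_unassigned = evaluation$n_unassigned),
      file.path(od, "metrics.json"), auto_unbox = TRUE, digits = NA,
      null = "null", na = "null")
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  list(modules = final, evaluation = evaluation, tour = tour, dist = dist,
       graph = graph, go = go, manifest = manifest)
}
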