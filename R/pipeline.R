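#' Reconstruction configuration
#'
#' The four parameters of the reconstruction: neighbourhood search radius
#' `r` (metres; just below the minimal branch gap to bridge), neighbour cap
#' `k` (`Inf` for unlimited), level-set width `d` (metres; just below the
#' minimal branch length to resolve), and smoothing window `w` (odd
#' positive integer), plus whether false-tip pruning runs and a seed
#' recorded for provenance.
#'
#' @param r search radius, metres; > 0.
#' @param d level-set width, metres; > 0.
#' @param k neighbour cap (positive integer or `Inf`).
#' @param w odd positive integer smoothing window.
#' @param prune run [prune_false_tips()]?
#' @param seed integer, recorded in output provenance.
#' @return object of class `reconstruction_config`.
#' @export
reconstruction_config <- function(r, d, k = Inf, w = 3L, prune = TRUE,
                                  seed = 1L) {
  stopifnot(r > 0, d > 0, is.infinite(k) || k >= 1,
            w >= 1, w %% 2 == 1)
  structure(list(r = r, d = d, k = k, w = as.integer(w),
                 prune = isTRUE(prune), seed = as.integer(seed)),
            class = "reconstruction_config")
}

#' Run the full reconstruction pipeline
#'
#' Chains all stages: neighbourhood graph (with optional repair spheres),
#' source detection, geodesic distances, level sets, branch-cut
#' segmentation, skeletonization, false-tip pruning, position smoothing and
#' radius estimation. Deterministic given the input cloud and
#' configuration. A warning is raised when the radius exceeds the
#' level width, since an edge could then skip a level boundary.
#'
#' @param cloud a [point_cloud()] (or a path readable by
#'   [read_point_cloud()]).
#' @param config a [reconstruction_config()].
#' @param repair_spheres list of `list(center = c(x, y, z), radius = r)`
#'   applied in order with [repair_connect_sphere()] before geodesics.
#' @param edits optional edit script applied to the finished skeleton with
#'   [apply_edit_script()].
#' @param verbose print per-stage counts as they are computed.
#' @return object of class `reconstruction`: list with `skeleton`, `report`
#'   (named list of per-stage counts), `graph`, `field`, `partition`,
#'   `config`.
#' @export
run_pipeline <- function(cloud, config, repair_spheres = list(),
                         edits = NULL, verbose = FALSE) {
  if (is.character(cloud)) cloud <- read_point_cloud(cloud)
  stopifnot(inherits(cloud, "point_cloud"),
            inherits(config, "reconstruction_config"))
  if (config$r > config$d)
    warning("r (", config$r, ") exceeds d (", config$d,
            "): an edge of N could skip a level boundary")
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  say("points: %d", n_points(cloud))
  graph <- stage("neighborhood",
                 build_neighborhood_graph(cloud, config$r, config$k))
  for (sp in repair_spheres)
    graph <- stage("repair", repair_connect_sphere(graph, sp$center,
                                                   sp$radius))
  n_comp <- length(connected_components(graph))
  say("edges: %d (components: %d)", nrow(graph$edges), n_comp)

  source <- stage("source", find_source(cloud))
  field <- stage("geodesics", shortest_paths(graph, source))
  say("reachable: %d, unreachable: %d",
      sum(!is.na(field$dist)), field$n_unreachable)

  levels <- stage("levelsets", assign_levels(field, config$d))
  partition <- stage("segmentation", segment_levels(graph, levels, field))
  say("levels: %d, branch cuts: %d",
      length(unique(partition$comps$level)), nrow(partition$comps))

  skel <- stage("skeleton", build_skeleton(partition, field, cloud))
  tips_before <- length(skeleton_tips(skel))
  n_pruned <- 0L
  if (config$prune) {
    skel <- stage("pruning", prune_false_tips(skel, field, partition))
    n_pruned <- attr(skel, "n_pruned")
  }
  skel <- stage("smoothing", smooth_skeleton(skel, config$w))
  skel <- stage("radii",
                estimate_radii(skel, field, partition, cloud, config$w))
  if (!is.null(edits)) skel <- stage("edits", apply_edit_script(skel, edits))
  say("nodes: %d, tips: %d (pruned %d)", nrow(skel$nodes),
      length(skeleton_tips(skel)), n_pruned)

  report <- list(n_points = n_points(cloud),
                 n_edges = nrow(graph$edges),
                 n_forced_edges = sum(graph$edges$forced),
                 n_components = n_comp,
                 n_unreachable = field$n_unreachable,
                 n_levels = length(unique(partition$comps$level)),
                 n_branch_cuts = nrow(partition$comps),
                 n_nodes = nrow(skel$nodes),
                 n_tips_before_prune = tips_before,
                 n_pruned = n_pruned,
                 n_tips = length(skeleton_tips(skel)))
  structure(list(skeleton = skel, report = report, graph = graph,
                 field = field, partition = partition, config = config),
            class = "reconstruction")
}

#' @export
print.reconstruction <- function(x, ...) {
  cat("<reconstruction>\n")
  for (nm in names(x$report)) cat(sprintf("  %-20s %d\n", nm, x$report[[nm]]))
  invisible(x)
}

#' Persist a reconstruction's skeleton with full provenance
#' @param recon a [run_pipeline()] result.
#' @param path JSON output file.
#' @export
write_reconstruction_json <- function(recon, path) {
  stopifnot(inherits(recon, "reconstruction"))
  cfg <- unclass(recon$config)
  cfg$k <- if (is.infinite(cfg$k)) "unlimited" else cfg$k
  write_skeleton_json(recon$skeleton, path,
                      provenance = list(config = cfg,
                                        seed = recon$config$seed,
                                        report = recon$report))
}

#' Dump the per-point level/component table
#' @param recon a [run_pipeline()] result.
#' @param path TSV output file.
#' @export
write_levels_tsv <- function(recon, path) {
  stopifnot(inherits(recon, "reconstruction"))
  df <- data.frame(id = recon$field$ids,
                   dist = recon$field$dist,
                   level = recon$partition$levels,
                   component = recon$partition$comp)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
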