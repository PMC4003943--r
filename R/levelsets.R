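#' Assign geodesic level indices (the level sets S)
#'
#' Bins reachable points into fixed-width intervals of geodesic distance:
#' `level(p) = floor(dist(p) / d)`. The width `d` should sit just below the
#' minimal branch length to be resolved: larger values merge fine features,
#' smaller values can fabricate false branches. Levels are full-width bins
#' ("extended" in the geodesic space), not thin rings, which stabilises the
#' segmentation of sparse clouds.
#'
#' @param field a [shortest_paths()] result.
#' @param d level-set width in metres; > 0.
#' @return integer vector of level indices per point (NA for unreachable
#'   points), with `d` attached as an attribute.
#' @export
assign_levels <- function(field, d) {
  stopifnot(inherits(field, "geodesic_field"))
  if (!is.numeric(d) || length(d) != 1L || d <= 0)
    stop("level width d must be a positive number")
  lev <- as.integer(floor(field$dist / d))
  attr(lev, "d") <- d
  lev
}

#' Segment each level into connected branch cuts
#'
#' Within one level, the intersection of a branch with the level forms a
#' "branch cut". Cuts are recovered as the connected components of the
#' neighbourhood graph restricted to that level's points (edges whose
#' endpoints share the level); no cross-level edges are considered and no
#' per-level graph is rebuilt. Components are ranked within their level by
#' minimum member geodesic distance when `field` is supplied (then by
#' smallest member id), so skeleton node ids are reproducible.
#'
#' @param graph the [build_neighborhood_graph()] the levels were derived
#'   from.
#' @param levels level index map from [assign_levels()].
#' @param field optional [shortest_paths()] result used for rank ordering.
#' @return object of class `level_partition`: list with `d`, `levels`
#'   (per-point level), `comp` (per-point component index, NA for
#'   unreachable), and `comps` (data.frame `comp`, `level`, `rank`, `size`).
#' @export
segment_levels <- function(graph, levels, field = NULL) {
  stopifnot(inherits(graph, "neighborhood_graph"))
  n <- nrow(graph$coords)
  if (length(levels) != n)
    stop("levels must be computed on the same cloud as graph")
  e <- graph$edges
  same <- !is.na(levels[e$i]) & !is.na(levels[e$j]) &
    levels[e$i] == levels[e$j]
  memb <- component_membership(graph, e[same, , drop = FALSE])
  memb[is.na(levels)] <- NA_integer_

  reach <- which(!is.na(memb))
  key <- memb[reach]
  comp_level <- tapply(levels[reach], key, `[`, 1L)
  comp_size <- tapply(reach, key, length)
  comp_minid <- tapply(graph$ids[reach], key, min)
  comp_mind <- if (!is.null(field))
    tapply(field$dist[reach], key, min) else comp_minid
  ord <- order(comp_level, comp_mind, comp_minid)
  old <- as.integer(names(comp_level))[ord]
  new_of_old <- integer(max(memb, na.rm = TRUE))
  new_of_old[old] <- seq_along(old)
  comp <- ifelse(is.na(memb), NA_integer_, new_of_old[memb])

  comps <- data.frame(comp = seq_along(old),
                      level = as.integer(comp_level[ord]),
                      size = as.integer(comp_size[ord]))
  comps$rank <- stats::ave(comps$comp, comps$level, FUN = seq_along)
  structure(list(d = attr(levels, "d"), levels = levels, comp = comp,
                 comps = comps[, c("comp", "level", "rank", "size")]),
            class = "level_partition")
}

#' @export
print.level_partition <- function(x, ...) {
  cat(sprintf(
    "<level_partition> d = %g m; %d levels, %d branch cuts, %d points\n",
    if (is.null(x$d)) NA else x$d, length(unique(x$comps$level)),
    nrow(x$comps), sum(!is.na(x$comp))))
  invisible(x)
}
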