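#' Find the trunk-base source point
#'
#' The source is the point with the lowest height coordinate (z); ties are
#' broken by the smallest point id.
#'
#' @param cloud a [point_cloud()].
#' @return the source point id.
#' @export
find_source <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (n_points(cloud) == 0L) stop("empty cloud has no source point")
  z <- cloud$coords[, 3]
  cand <- which(z == min(z))
  cloud$ids[cand[which.min(cloud$ids[cand])]]
}

#' Geodesic distances from the source (the graph G)
#'
#' Single-source shortest paths from the trunk-base source through the
#' neighbourhood graph, via Dijkstra's algorithm. The predecessor links
#' form the shortest-path tree G, a subgraph of N, which represents the
#' geodesic space of the scanned surface. Points in components not
#' containing the source are unreachable: they are flagged (distance and
#' predecessor `NA`), counted, and excluded from all downstream stages —
#' never silently dropped. Bridge such gaps explicitly with
#' [repair_connect_sphere()] rather than by inflating `r`.
#'
#' @param graph a [build_neighborhood_graph()] result.
#' @param source source point id, from [find_source()].
#' @return object of class `geodesic_field`: list with `source` (id),
#'   `ids`, `dist` (metres per point, NA if unreachable), `pred`
#'   (predecessor row index per point, NA for source/unreachable),
#'   `n_unreachable`.
#' @export
shortest_paths <- function(graph, source) {
  stopifnot(inherits(graph, "neighborhood_graph"))
  src_row <- id_to_row(graph$ids, source)
  n <- nrow(graph$coords)
  res <- cpp_dijkstra(n, graph$edges$i, graph$edges$j, graph$edges$length,
                      src_row)
  dist <- res$dist
  pred <- res$pred
  unreachable <- is.infinite(dist)
  dist[unreachable] <- NA_real_
  pred[unreachable] <- NA_integer_
  structure(list(source = source, ids = graph$ids, dist = dist, pred = pred,
                 n_unreachable = sum(unreachable)),
            class = "geodesic_field")
}

#' @export
print.geodesic_field <- function(x, ...) {
  cat(sprintf(
    "<geodesic_field> source id %d; %d reachable, %d unreachable%s\n",
    x$source, sum(!is.na(x$dist)), x$n_unreachable,
    if (x$n_unreachable > 0)
      " (consider repair_connect_sphere() to bridge gaps)" else ""))
  if (any(!is.na(x$dist)))
    cat(sprintf("  max geodesic distance %.3f m\n", max(x$dist, na.rm = TRUE)))
  invisible(x)
}
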