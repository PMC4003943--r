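#' Build the neighbourhood graph N
#'
#' Links every pair of points separated by at most the search radius `r`,
#' so that gaps wider than `r` are never bridged — the property that keeps
#' distinct fine branches apart. With a finite neighbour cap `k`, each
#' point keeps only its `k` nearest in-radius neighbours and the directed
#' selections are symmetrized by union (an edge exists if either endpoint
#' kept it), which preserves thin-branch connectivity.
#'
#' @param cloud a [point_cloud()].
#' @param r search radius in metres; > 0.
#' @param k neighbour cap; positive integer or `Inf` (default) for
#'   unlimited.
#' @return object of class `neighborhood_graph`: list with `ids`, `coords`,
#'   `edges` (data.frame `i`, `j`, `length`, `forced`; `i`/`j` are 1-based
#'   row indices into `coords`), `r`, `k`.
#' @export
build_neighborhood_graph <- function(cloud, r, k = Inf) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (n_points(cloud) == 0L) stop("cannot build a graph on an empty cloud")
  if (!is.numeric(r) || length(r) != 1L || r <= 0)
    stop("search radius r must be a positive number")
  if (!(is.infinite(k) || (k >= 1)))
    stop("neighbour cap k must be >= 1 or Inf")
  el <- cpp_radius_edges(cloud$coords, r, as.numeric(k))
  edges <- data.frame(i = el$i, j = el$j, length = el$length,
                      forced = logical(length(el$i)))
  structure(list(ids = cloud$ids, coords = cloud$coords, edges = edges,
                 r = r, k = k),
            class = "neighborhood_graph")
}

#' @export
print.neighborhood_graph <- function(x, ...) {
  cat(sprintf(
    "<neighborhood_graph> %d points, %d edges (r = %g m, k = %s)%s\n",
    nrow(x$coords), nrow(x$edges), x$r,
    if (is.infinite(x$k)) "unlimited" else format(x$k),
    if (any(x$edges$forced)) sprintf(", %d repair-forced",
                                     sum(x$edges$forced)) else ""))
  invisible(x)
}

# component membership vector (integer per row), optionally on an edge
# subset (used for per-level segmentation)
component_membership <- function(graph, edges = graph$edges) {
  n <- nrow(graph$coords)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges))
    g <- igraph::add_edges(g, rbind(edges$i, edges$j))
  igraph::components(g)$membership
}

#' Connected components of the neighbourhood graph
#'
#' @param graph a [build_neighborhood_graph()] result.
#' @return list of integer vectors of point ids, one per maximal connected
#'   set, sorted by decreasing size (ties: by smallest member id).
#' @export
connected_components <- function(graph) {
  stopifnot(inherits(graph, "neighborhood_graph"))
  memb <- component_membership(graph)
  comps <- split(graph$ids, memb)
  sizes <- lengths(comps)
  minid <- vapply(comps, min, numeric(1))
  comps <- comps[order(-sizes, minid)]
  names(comps) <- NULL
  comps
}

#' Force full connectivity inside a repair sphere
#'
#' The connectivity-repair operation: every pair of points enclosed by the
#' sphere becomes linked (many-to-many), bridging occlusion gaps that the
#' radius criterion cannot close without inflating `r` globally. Added
#' edges are flagged `forced` and carry their Euclidean length. The
#' operation is idempotent and never removes edges.
#'
#' @param graph a `neighborhood_graph`.
#' @param center sphere centre, length-3 numeric (metres).
#' @param radius sphere radius in metres; > 0.
#' @return the augmented `neighborhood_graph`.
#' @export
repair_connect_sphere <- function(graph, center, radius) {
  stopifnot(inherits(graph, "neighborhood_graph"),
            length(center) == 3L, radius > 0)
  d2 <- colSums((t(graph$coords) - center)^2)
  inside <- which(d2 < radius^2)
  if (length(inside) < 2L) {
    warning("repair sphere encloses ", length(inside),
            " point(s); graph unchanged")
    return(graph)
  }
  pairs <- t(utils::combn(inside, 2L))
  key_new <- paste(pairs[, 1], pairs[, 2])
  key_old <- paste(pmin(graph$edges$i, graph$edges$j),
                   pmax(graph$edges$i, graph$edges$j))
  add <- !(key_new %in% key_old)
  if (any(add)) {
    pi <- pairs[add, 1]; pj <- pairs[add, 2]
    len <- sqrt(rowSums((graph$coords[pi, , drop = FALSE] -
                         graph$coords[pj, , drop = FALSE])^2))
    graph$edges <- rbind(graph$edges,
                         data.frame(i = pi, j = pj, length = len,
                                    forced = TRUE))
  }
  graph
}
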