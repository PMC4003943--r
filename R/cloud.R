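#' Point cloud container
#'
#' A point cloud is the raw sample set P: stable integer point ids plus 3D
#' coordinates in metres, with z the height axis. Ids default to file order
#' starting at 0 and are preserved by all downstream operations.
#'
#' @param coords numeric matrix with 3 columns (x, y, z) in metres.
#' @param ids optional integer vector of unique point ids; defaults to
#'   `0:(n-1)`.
#' @return An object of class `point_cloud`: a list with elements `ids`
#'   (integer) and `coords` (n x 3 numeric matrix).
#' @examples
#' pc <- point_cloud(matrix(runif(30), ncol = 3))
#' n_points(pc)
#' @export
point_cloud <- function(coords, ids = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stop("coords must have exactly 3 columns (x, y, z)")
  storage.mode(coords) <- "double"
  if (!all(is.finite(coords)))
    stop("all coordinates must be finite")
  # an empty cloud may exist (e.g. after total occlusion) but every
  # downstream stage rejects it
  if (is.null(ids)) ids <- seq_len(nrow(coords)) - 1L
  ids <- as.integer(ids)
  if (length(ids) != nrow(coords))
    stop("length(ids) must equal nrow(coords)")
  if (anyDuplicated(ids))
    stop("point ids must be unique")
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(ids = ids, coords = coords), class = "point_cloud")
}

#' Number of points in a cloud
#' @param cloud a [point_cloud()].
#' @return integer count.
#' @export
n_points <- function(cloud) nrow(cloud$coords)

#' @export
print.point_cloud <- function(x, ...) {
  rng <- apply(x$coords, 2, range)
  cat(sprintf("<point_cloud> %d points\n", n_points(x)))
  cat(sprintf("  extent: x [%.3f, %.3f]  y [%.3f, %.3f]  z [%.3f, %.3f] m\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

# row index of a point id within the cloud/graph id vector
id_to_row <- function(ids, id) {
  r <- match(id, ids)
  if (anyNA(r)) stop("unknown point id(s): ", paste(id[is.na(r)], collapse = ", "))
  r
}

#' Mean nearest-neighbour distance
#'
#' The mean, over all points, of the distance to the closest other point.
#' For a Poisson-uniform sample of intensity lambda on a locally flat
#' surface this is approximately `1/(2*sqrt(lambda))`.
#'
#' @param cloud a [point_cloud()] with at least 2 points.
#' @return mean nearest-neighbour distance in metres.
#' @export
mean_nn_distance <- function(cloud) {
  if (n_points(cloud) < 2L) stop("need at least 2 points")
  mean(FNN::get.knn(cloud$coords, k = 1L)$nn.dist[, 1L])
}
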