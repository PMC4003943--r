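#' Export a skeleton as a truncated-cone mesh
#'
#' Every parent-child node pair becomes one frustum whose end radii are the
#' two node radii, tessellated with `sides` rectangles (split into
#' triangles). The mesh can be written as Wavefront OBJ or ASCII PLY.
#'
#' @param skeleton a `skeleton` with all radii set.
#' @param path optional output file; format from extension (`.obj` or
#'   `.ply`) unless `format` is given.
#' @param sides number of facets around each frustum (>= 3).
#' @param format `"obj"` or `"ply"`; only used when `path` is given.
#' @return invisibly, a list with `vertices` (matrix), `faces` (triangle
#'   index matrix, 1-based) and `frusta` (data.frame with endpoints and
#'   radii, one row per skeleton edge).
#' @export
export_mesh <- function(skeleton, path = NULL, sides = 12L,
                        format = c("auto", "obj", "ply")) {
  stopifnot(inherits(skeleton, "skeleton"), sides >= 3L)
  format <- match.arg(format)
  nd <- skeleton$nodes
  if (anyNA(nd$radius))
    stop("all node radii must be set before meshing (see estimate_radii)")
  edge <- which(!is.na(nd$parent))
  if (length(edge) == 0L) stop("skeleton has no edges to mesh")
  pidx <- match(nd$parent[edge], nd$id)
  frusta <- data.frame(
    x0 = nd$x[pidx], y0 = nd$y[pidx], z0 = nd$z[pidx],
    x1 = nd$x[edge], y1 = nd$y[edge], z1 = nd$z[edge],
    r0 = nd$radius[pidx], r1 = nd$radius[edge])

  verts <- list(); faces <- list(); off <- 0L
  phi <- 2 * pi * (seq_len(sides) - 1L) / sides
  for (f in seq_len(nrow(frusta))) {
    a <- c(frusta$x0[f], frusta$y0[f], frusta$z0[f])
    b <- c(frusta$x1[f], frusta$y1[f], frusta$z1[f])
    h <- b - a
    len <- sqrt(sum(h^2))
    if (len < 1e-12) next
    h <- h / len
    e <- perp_basis(h)
    ring <- cos(phi) %o% e[, 1] + sin(phi) %o% e[, 2]
    v0 <- matrix(a, sides, 3, byrow = TRUE) + frusta$r0[f] * ring
    v1 <- matrix(b, sides, 3, byrow = TRUE) + frusta$r1[f] * ring
    verts[[f]] <- rbind(v0, v1)
    nx <- c(2:sides, 1L)
    quad <- cbind(seq_len(sides), nx, sides + nx, sides + seq_len(sides)) + off
    faces[[f]] <- rbind(quad[, c(1, 2, 3)], quad[, c(1, 3, 4)])
    off <- off + 2L * sides
  }
  mesh <- list(vertices = do.call(rbind, verts),
               faces = do.call(rbind, faces), frusta = frusta)

  if (!is.null(path)) {
    if (format == "auto")
      format <- if (tolower(tools::file_ext(path)) == "ply") "ply" else "obj"
    if (format == "obj") {
      con <- file(path, "w")
      on.exit(close(con))
      writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                         mesh$vertices[, 2], mesh$vertices[, 3]), con)
      writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                         mesh$faces[, 3]), con)
    } else {
      con <- file(path, "w")
      on.exit(close(con))
      writeLines(c("ply", "format ascii 1.0",
                   sprintf("element vertex %d", nrow(mesh$vertices)),
                   "property double x", "property double y",
                   "property double z",
                   sprintf("element face %d", nrow(mesh$faces)),
                   "property list uchar int vertex_indices", "end_header"),
                 con)
      writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1],
                         mesh$vertices[, 2], mesh$vertices[, 3]), con)
      writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                         mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
    }
  }
  invisible(mesh)
}
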