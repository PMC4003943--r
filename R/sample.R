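#' Virtual-scanner sampling specification
#'
#' Parameters of the TLS-like surface sampler: a target density of points
#' per square metre of lateral frustum surface, and the scale (metres) of
#' the exponential outward perturbation emulating ranging error. A
#' `noise_scale` of 0 puts every point exactly on the surface.
#'
#' @param density points per m^2 of lateral surface; > 0.
#' @param noise_scale exponential perturbation scale in metres; >= 0.
#' @param seed integer seed for the sampling stream.
#' @return object of class `sampling_spec`.
#' @export
sampling_spec <- function(density = 2000, noise_scale = 0.001, seed = 1L) {
  stopifnot(density > 0, noise_scale >= 0)
  structure(list(density = density, noise_scale = noise_scale,
                 seed = as.integer(seed)),
            class = "sampling_spec")
}

# orthonormal pair spanning the plane perpendicular to unit vector h
perp_basis <- function(h) {
  ref <- if (abs(h[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- c(h[2] * ref[3] - h[3] * ref[2],
          h[3] * ref[1] - h[1] * ref[3],
          h[1] * ref[2] - h[2] * ref[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(h[2] * e1[3] - h[3] * e1[2],
          h[3] * e1[1] - h[1] * e1[3],
          h[1] * e1[2] - h[2] * e1[1])
  cbind(e1, e2)
}

#' Sample the surface of a synthetic tree into a point cloud
#'
#' Emulates a terrestrial laser scan of the model with no occlusion. For
#' each frustum the number of points is Poisson with mean
#' `density * lateral area`; the axial position is drawn with likelihood
#' proportional to the local circumference (inverse-CDF of the linear
#' radius profile), the azimuth uniformly on `[0, 2*pi)`; each point is then
#' displaced outward along the local surface normal by an
#' `Exponential(noise_scale)` draw. The two frustum caps are never sampled.
#'
#' @param model a [segment_model()].
#' @param spec a [sampling_spec()].
#' @return a [point_cloud()]; the number of removed/generated points per
#'   segment is available as `attr(, "segment")`.
#' @export
sample_surface <- function(model, spec) {
  stopifnot(inherits(model, "segment_model"), inherits(spec, "sampling_spec"))
  withr::with_seed(spec$seed, sample_surface_impl(model, spec))
}

sample_surface_impl <- function(model, spec) {
  areas <- segment_lateral_area(model)
  counts <- rpois(nrow(model), spec$density * areas)
  total <- sum(counts)
  if (total == 0L)
    stop("sampling produced no points; increase density")
  out <- matrix(0, nrow = total, ncol = 3)
  at <- 0L
  for (s in seq_len(nrow(model))) {
    n <- counts[s]
    if (n == 0L) next
    base <- c(model$x0[s], model$y0[s], model$z0[s])
    tip <- c(model$x1[s], model$y1[s], model$z1[s])
    len <- model$length[s]
    h <- (tip - base) / len
    r0 <- model$base_radius[s]; r1 <- model$top_radius[s]
    u <- runif(n)
    if (abs(r1 - r0) < 1e-12) {
      t <- u
    } else {
      # P(T <= t) ~ integral of r(t); invert the quadratic CDF
      t <- (-r0 + sqrt(r0^2 + u * (r1^2 - r0^2))) / (r1 - r0)
    }
    phi <- runif(n, 0, 2 * pi)
    e <- perp_basis(h)
    rt <- r0 + (r1 - r0) * t
    dir <- outer(cos(phi), e[, 1]) + outer(sin(phi), e[, 2])
    pts <- matrix(base, n, 3, byrow = TRUE) +
      (t * len) %o% h + rt * dir
    if (spec$noise_scale > 0) {
      # outward surface normal of the cone wall (tilted by the taper)
      m <- (r1 - r0) / len
      nrm <- dir - matrix(m * h, n, 3, byrow = TRUE)
      nrm <- nrm / sqrt(rowSums(nrm^2))
      pts <- pts + rexp(n, rate = 1 / spec$noise_scale) * nrm
    }
    out[at + seq_len(n), ] <- pts
    at <- at + n
  }
  cloud <- point_cloud(out)
  attr(cloud, "segment") <- rep(model$id, counts)
  attr(cloud, "provenance") <- list(sampling = unclass(spec))
  cloud
}

#' Remove points inside occlusion regions
#'
#' Emulates scan occlusion by deleting every point strictly inside any of
#' the given regions. A region is a list with `type = "sphere"` (`center`,
#' `radius`) or `type = "box"` (`min`, `max`).
#'
#' @param cloud a [point_cloud()].
#' @param regions list of region specifications (possibly empty).
#' @return the filtered [point_cloud()] (original ids kept); the number of
#'   deleted points is attached as `attr(, "n_removed")`.
#' @export
apply_occlusion <- function(cloud, regions) {
  stopifnot(inherits(cloud, "point_cloud"))
  inside <- rep(FALSE, n_points(cloud))
  for (reg in regions) {
    if (is.null(reg$type)) stop("occlusion region needs a 'type'")
    if (reg$type == "sphere") {
      stopifnot(length(reg$center) == 3L, reg$radius > 0)
      d2 <- colSums((t(cloud$coords) - reg$center)^2)
      inside <- inside | d2 < reg$radius^2
    } else if (reg$type == "box") {
      stopifnot(length(reg$min) == 3L, length(reg$max) == 3L)
      inside <- inside |
        (cloud$coords[, 1] > reg$min[1] & cloud$coords[, 1] < reg$max[1] &
         cloud$coords[, 2] > reg$min[2] & cloud$coords[, 2] < reg$max[2] &
         cloud$coords[, 3] > reg$min[3] & cloud$coords[, 3] < reg$max[3])
    } else {
      stop("unknown occlusion region type: ", reg$type)
    }
  }
  kept <- point_cloud(cloud$coords[!inside, , drop = FALSE],
                      ids = cloud$ids[!inside])
  attr(kept, "n_removed") <- sum(inside)
  kept
}
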