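#' Segment model container
#'
#' A synthetic tree is a rooted set of truncated-cone (frustum) segments.
#' Each row of `segments` holds one frustum: `id`, `parent` (NA for the
#' root), base and tip endpoints in metres, `base_radius` and `top_radius`
#' in metres, and `depth` (bracket-nesting level at emission).
#'
#' @param segments data.frame with columns `id`, `parent`, `x0`, `y0`, `z0`,
#'   `x1`, `y1`, `z1`, `base_radius`, `top_radius`, `depth`.
#' @return object of class `segment_model` (the validated data.frame with a
#'   `length` column added).
#' @export
segment_model <- function(segments) {
  req <- c("id", "parent", "x0", "y0", "z0", "x1", "y1", "z1",
           "base_radius", "top_radius", "depth")
  if (!all(req %in% names(segments)))
    stop("missing segment columns: ", paste(setdiff(req, names(segments)),
                                            collapse = ", "))
  segments <- as.data.frame(segments)[req]
  if (nrow(segments) == 0L) stop("segment model is empty")
  if (anyDuplicated(segments$id)) stop("segment ids must be unique")
  roots <- which(is.na(segments$parent))
  if (length(roots) != 1L) stop("segment model must have exactly one root")
  pidx <- match(segments$parent, segments$id)
  if (any(is.na(pidx) & !is.na(segments$parent)))
    stop("parent ids must exist")
  # tree check: every segment must reach the root by parent links
  depth_ok <- rep(FALSE, nrow(segments))
  depth_ok[roots] <- TRUE
  for (pass in seq_len(nrow(segments))) {
    newly <- !depth_ok & !is.na(pidx) & depth_ok[ifelse(is.na(pidx), roots, pidx)]
    if (!any(newly)) break
    depth_ok[newly] <- TRUE
  }
  if (!all(depth_ok)) stop("segment parent links contain a cycle")
  # endpoint continuity: child base must coincide with parent tip
  ch <- which(!is.na(pidx))
  if (length(ch)) {
    gap <- sqrt((segments$x0[ch] - segments$x1[pidx[ch]])^2 +
                (segments$y0[ch] - segments$y1[pidx[ch]])^2 +
                (segments$z0[ch] - segments$z1[pidx[ch]])^2)
    if (any(gap > 1e-9))
      stop("child base points must coincide with parent tip points")
  }
  segments$length <- sqrt((segments$x1 - segments$x0)^2 +
                          (segments$y1 - segments$y0)^2 +
                          (segments$z1 - segments$z0)^2)
  if (any(segments$length <= 0)) stop("all segment lengths must be positive")
  if (any(segments$base_radius <= 0) || any(segments$top_radius <= 0))
    stop("all radii must be positive")
  class(segments) <- c("segment_model", "data.frame")
  segments
}

#' @export
print.segment_model <- function(x, ...) {
  s <- summarize_structure(x)
  cat(sprintf("<segment_model> %d segments, %d tips, total length %.3f m\n",
              s$n_segments, s$n_tips, s$total_length))
  invisible(x)
}

# draw a positive value from N(mean, sd); bounded resampling
draw_positive <- function(mean, sd, what, max_tries = 100L) {
  for (t in seq_len(max_tries)) {
    v <- rnorm(1L, mean, sd)
    if (v > 0) return(v)
  }
  stop("could not draw a positive ", what, " from N(", mean, ", ", sd,
       "^2) in ", max_tries, " tries")
}

# rotate the (a, b) column pair of frame F by theta degrees in their plane:
# a' = cos a + sin b, b' = -sin a + cos b (right-handed about a x b)
rotate_pair <- function(frame, a, b, theta_deg) {
  th <- theta_deg * pi / 180
  va <- frame[, a]; vb <- frame[, b]
  frame[, a] <- cos(th) * va + sin(th) * vb
  frame[, b] <- -sin(th) * va + cos(th) * vb
  frame
}

#' Interpret an expanded symbol string as a tree of truncated cones
#'
#' Walks the symbol string with a 3D turtle. Each `F` emits one frustum
#' along the current heading; the root segment uses `initial_length` and
#' `initial_radius` and points along +z, and every other segment scales its
#' parent's length and base radius by fresh draws from the scaling
#' distributions (resampled while non-positive, at most 100 times). Each
#' rotation symbol turns the turtle frame by an independent draw from the
#' angle distribution. `[` pushes and `]` pops the full turtle state.
#'
#' A segment's top radius equals the base radius of its first child;
#' childless segments taper by `radius_scaling_mean`. All draws come from
#' one stream seeded with `spec$seed`, consumed in symbol-scan order, so
#' the same seed reproduces the model bit for bit. The branching structure
#' (segment and tip counts) is determined by the symbols alone.
#'
#' @param symbols symbol string, typically from [expand_grammar()].
#' @param spec the [grammar_spec()] carrying the geometry parameters.
#' @return a [segment_model()].
#' @export
interpret_turtle <- function(symbols, spec) {
  stopifnot(inherits(spec, "grammar_spec"))
  chars <- check_symbols(normalize_symbols(symbols), "symbols")
  withr::with_seed(spec$seed, interpret_turtle_impl(chars, spec))
}

interpret_turtle_impl <- function(chars, spec) {
  # turtle state
  pos <- c(0, 0, 0)
  frame <- cbind(H = c(0, 0, 1), L = c(1, 0, 0), U = c(0, 1, 0))
  len <- spec$initial_length
  rad <- spec$initial_radius
  parent <- NA_integer_
  stack <- list()
  depth <- 0L

  n_guess <- sum(chars == "F")
  if (n_guess == 0L) stop("symbol string emits no segments")
  seg <- vector("list", n_guess)
  nseg <- 0L

  ang <- function() rnorm(1L, spec$angle_mean, spec$angle_sd)
  for (ch in chars) {
    if (ch == "F") {
      if (nseg > 0L) {
        # non-root: scale the inherited size by fresh draws
        len <- len * draw_positive(spec$length_scaling_mean,
                                   spec$length_scaling_sd, "length scale")
        rad <- rad * draw_positive(spec$radius_scaling_mean,
                                   spec$radius_scaling_sd, "radius scale")
      }
      tip <- pos + len * frame[, "H"]
      nseg <- nseg + 1L
      seg[[nseg]] <- c(id = nseg, parent = parent, pos, tip, rad, depth)
      parent <- nseg
      pos <- tip
    } else if (ch == TURN_LEFT) {
      frame <- rotate_pair(frame, "H", "L", ang())
    } else if (ch == TURN_RIGHT) {
      frame <- rotate_pair(frame, "H", "L", -ang())
    } else if (ch == PITCH_UP) {
      frame <- rotate_pair(frame, "H", "U", ang())
    } else if (ch == PITCH_DOWN) {
      frame <- rotate_pair(frame, "H", "U", -ang())
    } else if (ch == "+") {
      frame <- rotate_pair(frame, "L", "U", ang())
    } else if (ch == "-") {
      frame <- rotate_pair(frame, "L", "U", -ang())
    } else if (ch == "[") {
      stack[[length(stack) + 1L]] <- list(pos = pos, frame = frame,
                                          len = len, rad = rad,
                                          parent = parent)
      depth <- depth + 1L
    } else if (ch == "]") {
      if (length(stack) == 0L) stop("pop from empty turtle stack")
      st <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      pos <- st$pos; frame <- st$frame
      len <- st$len; rad <- st$rad; parent <- st$parent
      depth <- depth - 1L
    }
    # nonterminal letters have no geometric effect
  }

  m <- do.call(rbind, seg[seq_len(nseg)])
  df <- data.frame(id = as.integer(m[, 1]), parent = as.integer(m[, 2]),
                   x0 = m[, 3], y0 = m[, 4], z0 = m[, 5],
                   x1 = m[, 6], y1 = m[, 7], z1 = m[, 8],
                   base_radius = m[, 9], top_radius = NA_real_,
                   depth = as.integer(m[, 10]))
  # continuous frusta: top radius = first child's base radius; tip
  # segments taper by the mean radius scaling
  first_child <- vapply(df$id, function(i) {
    ch <- df$id[!is.na(df$parent) & df$parent == i]
    if (length(ch)) min(ch) else NA_integer_
  }, integer(1))
  df$top_radius <- ifelse(is.na(first_child),
                          df$base_radius * spec$radius_scaling_mean,
                          df$base_radius[match(first_child, df$id)])
  segment_model(df)
}

#' Generate a synthetic tree from a grammar
#'
#' Convenience wrapper: [expand_grammar()] followed by [interpret_turtle()].
#'
#' @param spec a [grammar_spec()].
#' @return a [segment_model()].
#' @export
generate_tree <- function(spec) interpret_turtle(expand_grammar(spec), spec)

# lateral (side) surface area of each frustum: pi * (r0 + r1) * slant
segment_lateral_area <- function(model) {
  slant <- sqrt(model$length^2 + (model$base_radius - model$top_radius)^2)
  pi * (model$base_radius + model$top_radius) * slant
}

segment_is_tip <- function(model) {
  !(model$id %in% model$parent[!is.na(model$parent)])
}

#' Structural summary of a segment model
#'
#' Exact structural measures used for validation: tip and segment counts,
#' minimum segment length, total length, bounding-box extents and total
#' lateral (side) surface area of the frusta.
#'
#' @param model a [segment_model()].
#' @return object of class `structure_summary`, a list with fields
#'   `n_tips`, `n_segments`, `min_segment_length`, `total_length`,
#'   `bounding_box` (x/y/z extents, m), `lateral_surface_area` (m^2).
#' @export
summarize_structure <- function(model) {
  stopifnot(inherits(model, "segment_model"))
  if (nrow(model) == 0L) stop("empty model")
  pts <- rbind(as.matrix(model[, c("x0", "y0", "z0")], rownames.force = FALSE),
               as.matrix(model[, c("x1", "y1", "z1")], rownames.force = FALSE))
  structure(list(
    n_tips = sum(segment_is_tip(model)),
    n_segments = nrow(model),
    min_segment_length = min(model$length),
    total_length = sum(model$length),
    bounding_box = unname(apply(pts, 2, function(v) diff(range(v)))),
    lateral_surface_area = sum(segment_lateral_area(model))
  ), class = "structure_summary")
}

#' @export
print.structure_summary <- function(x, ...) {
  cat(sprintf(paste0("<structure_summary> %d segments, %d tips\n",
                     "  total length %.3f m; smallest segment %.3f m\n",
                     "  bounding box %.2f x %.2f x %.2f m; lateral area %.3f m^2\n"),
              x$n_segments, x$n_tips, x$total_length, x$min_segment_length,
              x$bounding_box[1], x$bounding_box[2], x$bounding_box[3],
              x$lateral_surface_area))
  invisible(x)
}
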