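# ---- skeleton container -----------------------------------------------------

new_skeleton <- function(nodes, members, journal = list()) {
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, members = members, journal = journal),
            class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf(
    "<skeleton> %d nodes, %d roots, %d tips, %d levels\n",
    nrow(x$nodes), length(skeleton_roots(x)), length(skeleton_tips(x)),
    length(unique(x$nodes$level[!is.na(x$nodes$level)]))))
  invisible(x)
}

# children ids per node id (named list)
skeleton_children <- function(skel) {
  nd <- skel$nodes
  kids <- split(nd$id[!is.na(nd$parent)], nd$parent[!is.na(nd$parent)])
  out <- setNames(vector("list", nrow(nd)), nd$id)
  out[names(kids)] <- kids
  out
}

#' Root node ids of a skeleton
#' @param skel a `skeleton`.
#' @return integer vector of node ids with no parent.
#' @export
skeleton_roots <- function(skel) skel$nodes$id[is.na(skel$nodes$parent)]

#' Tip node ids of a skeleton
#' @param skel a `skeleton`.
#' @return integer vector of node ids with no children.
#' @export
skeleton_tips <- function(skel) {
  nd <- skel$nodes
  nd$id[!(nd$id %in% nd$parent[!is.na(nd$parent)])]
}

node_row <- function(skel, id) {
  r <- match(id, skel$nodes$id)
  if (anyNA(r)) stop("unknown skeleton node id(s): ",
                     paste(id[is.na(r)], collapse = ", "))
  r
}

# validate the tree property; used by the editing operations
check_skeleton <- function(skel) {
  nd <- skel$nodes
  if (anyDuplicated(nd$id)) stop("duplicate node ids")
  pr <- nd$parent[!is.na(nd$parent)]
  if (!all(pr %in% nd$id)) stop("parent links must reference existing nodes")
  # cycle check by repeated parent hops
  idx <- match(nd$parent, nd$id)
  reached <- is.na(nd$parent)
  for (pass in seq_len(nrow(nd))) {
    newly <- !reached & reached[ifelse(is.na(idx), 1L, idx)] & !is.na(idx)
    if (!any(newly)) break
    reached[newly] <- TRUE
  }
  if (!all(reached)) stop("parent links contain a cycle")
  invisible(skel)
}

# ---- construction -----------------------------------------------------------

# first ancestor (through the shortest-path tree) lying on a strictly lower
# level, for every reachable point; NA for the source and level-0 points
down_pointers <- function(field, levels) {
  n <- length(field$dist)
  dp <- rep(NA_integer_, n)
  ord <- order(field$dist, na.last = NA)  # increasing distance, reachable only
  for (v in ord) {
    p <- field$pred[v]
    if (is.na(p)) next
    dp[v] <- if (levels[p] < levels[v]) p else dp[p]
  }
  dp
}

#' Build the skeleton K from segmented level sets
#'
#' Every branch cut (level component) becomes one skeleton node placed at
#' the arithmetic centroid of its member points. A node at level i is
#' linked downward to the unique level i-1 node whose component receives
#' the majority of the predecessor-chain entry points of its members (ties
#' resolve to the component with the nearest centroid), enforcing the rule
#' that a node cannot be linked to more than one node a level below.
#' Components whose members have no path into a lower level are emitted as
#' orphan roots with a warning.
#'
#' @param partition a [segment_levels()] result.
#' @param field the [shortest_paths()] field used to build the partition.
#' @param cloud the underlying [point_cloud()].
#' @return object of class `skeleton`: `nodes` (data.frame `id`, `x`, `y`,
#'   `z`, `level`, `parent`, `radius`, `comp`, `n_members`) plus the member
#'   point rows of every node.
#' @export
build_skeleton <- function(partition, field, cloud) {
  stopifnot(inherits(partition, "level_partition"),
            inherits(field, "geodesic_field"),
            inherits(cloud, "point_cloud"))
  comp <- partition$comp
  comps <- partition$comps
  reach <- which(!is.na(comp))
  if (length(reach) == 0L) stop("partition contains no reachable points")

  members <- split(reach, comp[reach])
  members <- members[as.character(comps$comp)]
  cent <- do.call(rbind, lapply(members, function(rows)
    colMeans(cloud$coords[rows, , drop = FALSE])))

  dp <- down_pointers(field, partition$levels)
  parent <- rep(NA_integer_, nrow(comps))
  src_row <- id_to_row(field$ids, field$source)
  src_comp <- comp[src_row]
  orphans <- 0L
  for (ci in seq_len(nrow(comps))) {
    if (comps$comp[ci] == src_comp) next  # the root component
    votes <- comp[dp[members[[ci]]]]
    votes <- votes[!is.na(votes)]
    if (length(votes) == 0L) {
      orphans <- orphans + 1L
      next
    }
    tab <- table(votes)
    best <- as.integer(names(tab)[tab == max(tab)])
    if (length(best) > 1L) {
      d2 <- rowSums((cent[best, , drop = FALSE] -
                     matrix(cent[ci, ], length(best), 3, byrow = TRUE))^2)
      best <- best[which.min(d2)]
    }
    parent[ci] <- best[1L]
  }
  if (orphans > 0L)
    warning(orphans, " component(s) have no geodesic path to a lower level;",
            " emitted as orphan roots")

  nodes <- data.frame(id = comps$comp,
                      x = cent[, 1], y = cent[, 2], z = cent[, 3],
                      level = comps$level, parent = parent,
                      radius = NA_real_, comp = comps$comp,
                      n_members = comps$size)
  new_skeleton(nodes, setNames(members, comps$comp))
}

# ---- false-tip pruning ------------------------------------------------------

#' Prune false tips
#'
#' A tip node is false when segmentation instability split a through-branch
#' sideways: operationally, when one of its member points is the
#' shortest-path predecessor of a point at a higher geodesic level (which
#' necessarily lies outside the tip's own component). Such tips are removed
#' together with their single-child ancestors up to — but excluding — the
#' nearest branching node; the root is never removed. The test is repeated
#' until no false tip remains, so the operation is idempotent and only ever
#' removes nodes.
#'
#' @param skeleton a [build_skeleton()] result.
#' @param field,partition the structures the skeleton was built from.
#' @return the pruned `skeleton`; the number of removed nodes is attached
#'   as `attr(, "n_pruned")`.
#' @export
prune_false_tips <- function(skeleton, field, partition) {
  stopifnot(inherits(skeleton, "skeleton"))
  levels <- partition$levels
  # rows whose point is predecessor of some strictly higher-level point
  has_up_child <- rep(FALSE, length(field$dist))
  q <- which(!is.na(field$pred))
  up <- q[levels[q] > levels[field$pred[q]]]
  has_up_child[field$pred[up]] <- TRUE

  n_pruned <- 0L
  repeat {
    kids <- skeleton_children(skeleton)
    nkid <- lengths(kids)[match(skeleton$nodes$id, skeleton$nodes$id)]
    names(nkid) <- skeleton$nodes$id
    tips <- skeleton_tips(skeleton)
    roots <- skeleton_roots(skeleton)
    false_tips <- tips[vapply(as.character(tips), function(t)
      any(has_up_child[skeleton$members[[t]]]), logical(1))]
    false_tips <- setdiff(false_tips, roots)
    if (length(false_tips) == 0L) break
    drop <- integer(0)
    for (t in false_tips) {
      node <- t
      repeat {
        drop <- c(drop, node)
        p <- skeleton$nodes$parent[node_row(skeleton, node)]
        if (is.na(p) || p %in% roots || nkid[[as.character(p)]] >= 2L) break
        node <- p
      }
    }
    drop <- unique(drop)
    keep <- !(skeleton$nodes$id %in% drop)
    skeleton$members <- skeleton$members[keep]
    skeleton$nodes <- skeleton$nodes[keep, , drop = FALSE]
    rownames(skeleton$nodes) <- NULL
    n_pruned <- n_pruned + length(drop)
  }
  attr(skeleton, "n_pruned") <- n_pruned
  skeleton
}

# ---- smoothing --------------------------------------------------------------

# maximal non-branching chains as vectors of node ids, including the anchor
# (root / tip / branching) nodes at both ends
skeleton_chains <- function(skel) {
  kids <- skeleton_children(skel)
  nkid <- lengths(kids)
  is_anchor <- setNames(is.na(skel$nodes$parent) | nkid[as.character(skel$nodes$id)] != 1L,
                        skel$nodes$id)
  # also anchor nodes whose parent is absent handled above (roots)
  chains <- list()
  for (a in skel$nodes$id[is_anchor[as.character(skel$nodes$id)]]) {
    for (c0 in kids[[as.character(a)]]) {
      path <- c(a)
      node <- c0
      while (!is_anchor[[as.character(node)]]) {
        path <- c(path, node)
        node <- kids[[as.character(node)]][1L]
      }
      chains[[length(chains) + 1L]] <- c(path, node)
    }
  }
  chains
}

# centred moving average of the rows of m with window truncated
# symmetrically near the ends; end rows are anchored (returned unchanged)
moving_average_interior <- function(m, w) {
  L <- nrow(m)
  out <- m
  if (L < 3L || w < 3L) return(out)
  h0 <- (w - 1L) %/% 2L
  for (i in 2L:(L - 1L)) {
    h <- min(h0, i - 1L, L - i)
    out[i, ] <- colMeans(m[(i - h):(i + h), , drop = FALSE])
  }
  out
}

#' Smooth skeleton node positions
#'
#' Applies a centred moving average of odd length `w` along every maximal
#' non-branching chain, from the tip of each branch to the base of the
#' trunk. Junction nodes, tips and the root are anchored at their original
#' positions, and the window is truncated symmetrically near chain ends, so
#' branch insertion points and total extent are preserved. Topology, levels
#' and radii are untouched; `w = 1` is the identity.
#'
#' @param skeleton a `skeleton`.
#' @param w odd positive integer window length.
#' @return the smoothed `skeleton`.
#' @export
smooth_skeleton <- function(skeleton, w) {
  stopifnot(inherits(skeleton, "skeleton"))
  if (!is.numeric(w) || length(w) != 1L || w < 1 || w %% 2 != 1)
    stop("smoothing window w must be an odd positive integer")
  if (w == 1) return(skeleton)
  pos <- as.matrix(skeleton$nodes[, c("x", "y", "z")])
  new_pos <- pos
  for (chain in skeleton_chains(skeleton)) {
    rows <- node_row(skeleton, chain)
    sm <- moving_average_interior(pos[rows, , drop = FALSE], w)
    interior <- seq_along(rows)[-c(1L, length(rows))]
    new_pos[rows[interior], ] <- sm[interior, , drop = FALSE]
  }
  skeleton$nodes[, c("x", "y", "z")] <- new_pos
  skeleton
}

# ---- radius estimation ------------------------------------------------------

#' Estimate node radii from level-boundary crossing points
#'
#' For every node, the "starting points" are its member points whose
#' shortest-path predecessor lies in the previous level — the first
#' crossings of the level boundary, which wrap the branch in an approximate
#' circle perpendicular to the local branch direction. The node's base
#' radius is the mean perpendicular distance of these points to the axis
#' line through the node along the direction from its parent (the root
#' axis is taken as +z). Nodes with fewer than 3 starting points inherit
#' the nearest ancestor's radius (a root with no resolvable radius takes
#' its first descendant's). Radii are finally smoothed with the same
#' moving-average window used for positions.
#'
#' @param skeleton a `skeleton` (positions already smoothed, if desired).
#' @param field,partition,cloud the structures the skeleton was built from.
#' @param w odd positive integer smoothing window (as in
#'   [smooth_skeleton()]).
#' @return the `skeleton` with `nodes$radius` set.
#' @export
estimate_radii <- function(skeleton, field, partition, cloud, w = 1) {
  stopifnot(inherits(skeleton, "skeleton"))
  if (!is.numeric(w) || length(w) != 1L || w < 1 || w %% 2 != 1)
    stop("smoothing window w must be an odd positive integer")
  levels <- partition$levels
  is_start <- !is.na(field$pred) &
    levels[pmax(field$pred, 1L)] == levels - 1L
  is_start[is.na(is_start)] <- FALSE

  nd <- skeleton$nodes
  raw <- rep(NA_real_, nrow(nd))
  ord <- order(nd$level, nd$id)
  for (ri in ord) {
    rows <- skeleton$members[[ri]]
    sp <- rows[is_start[rows]]
    if (length(sp) < 3L) next
    npos <- c(nd$x[ri], nd$y[ri], nd$z[ri])
    pid <- nd$parent[ri]
    axis <- if (is.na(pid)) c(0, 0, 1) else {
      pr <- node_row(skeleton, pid)
      npos - c(nd$x[pr], nd$y[pr], nd$z[pr])
    }
    nrm <- sqrt(sum(axis^2))
    if (nrm < 1e-12) axis <- c(0, 0, 1) else axis <- axis / nrm
    v <- cloud$coords[sp, , drop = FALSE] -
      matrix(npos, length(sp), 3, byrow = TRUE)
    proj <- as.numeric(v %*% axis)
    perp <- v - proj %o% axis
    raw[ri] <- mean(sqrt(rowSums(perp^2)))
  }

  # inherit the nearest ancestor's radius where unresolved
  filled <- raw
  for (ri in ord) {
    if (!is.na(filled[ri])) next
    pid <- nd$parent[ri]
    if (!is.na(pid)) filled[ri] <- filled[node_row(skeleton, pid)]
  }
  # roots with nothing above them inherit downward from the first child
  for (ri in which(is.na(filled) & is.na(nd$parent))) {
    node <- nd$id[ri]
    kids <- skeleton_children(skeleton)
    while (is.na(filled[node_row(skeleton, node)])) {
      ch <- kids[[as.character(node)]]
      ch_ok <- ch[!is.na(filled[node_row(skeleton, ch)])]
      if (length(ch_ok)) {
        filled[ri] <- filled[node_row(skeleton, min(ch_ok))]
        break
      }
      if (length(ch) == 0L) break
      node <- min(ch)
    }
    # then propagate down the usual way
    for (rj in ord) {
      if (is.na(filled[rj]) && !is.na(nd$parent[rj]))
        filled[rj] <- filled[node_row(skeleton, nd$parent[rj])]
    }
  }
  if (anyNA(filled))
    stop("could not resolve a radius for ",
         sum(is.na(filled)), " node(s): too few starting points anywhere")

  skeleton$nodes$radius <- filled
  if (w > 1) {
    rad <- matrix(skeleton$nodes$radius, ncol = 1)
    new_rad <- rad
    for (chain in skeleton_chains(skeleton)) {
      rows <- node_row(skeleton, chain)
      sm <- moving_average_interior(rad[rows, , drop = FALSE], w)
      interior <- seq_along(rows)[-c(1L, length(rows))]
      new_rad[rows[interior], ] <- sm[interior, , drop = FALSE]
    }
    skeleton$nodes$radius <- as.numeric(new_rad)
  }
  skeleton
}
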