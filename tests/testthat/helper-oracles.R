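# Independent oracles and fixture builders used across the suite. All
# fixtures are generated in code; nothing is read from disk.

# Rodrigues rotation matrix: rotate by theta degrees about unit axis
rodrigues <- function(axis, theta_deg) {
  th <- theta_deg * pi / 180
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# all-pairs shortest paths by Floyd-Warshall on a dense weight matrix
floyd_warshall <- function(W) {
  n <- nrow(W)
  D <- W
  diag(D) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
  D
}

# brute-force radius edge list (i < j, distance <= r)
brute_force_edges <- function(coords, r) {
  D <- as.matrix(dist(coords))
  idx <- which(upper.tri(D) & D <= r, arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2], length = D[idx])
}

# hand-assemble a neighborhood_graph from coordinates and an edge list
# (for Dijkstra tests on arbitrary weighted graphs)
make_graph_fixture <- function(coords, edges) {
  structure(list(ids = seq_len(nrow(coords)) - 1L, coords = as.matrix(coords),
                 edges = data.frame(i = edges$i, j = edges$j,
                                    length = edges$length,
                                    forced = FALSE),
                 r = max(edges$length), k = Inf),
            class = "neighborhood_graph")
}

# single vertical cylinder segment model: base at origin, along +z
cylinder_model <- function(length = 1, radius = 0.1, top_radius = radius) {
  segment_model(data.frame(id = 1L, parent = NA_integer_,
                           x0 = 0, y0 = 0, z0 = 0, x1 = 0, y1 = 0,
                           z1 = length, base_radius = radius,
                           top_radius = top_radius, depth = 0L))
}

# deterministic Y: trunk 1 m, two arms of 0.75 m at +/- `angle` degrees
y_model <- function(angle = 45, scaling = 0.75) {
  g <- grammar_spec("F[<F][>F]", rules = list(), iterations = 0L,
                    angle_mean = angle, angle_sd = 0,
                    initial_length = 1, length_scaling_mean = scaling,
                    initial_radius = 0.1, radius_scaling_mean = scaling,
                    seed = 1L)
  generate_tree(g)
}

# hand-built skeleton from a nodes data.frame (id, x, y, z, level, parent,
# radius); members empty
toy_skeleton <- function(nodes) {
  nodes$comp <- NA_integer_
  if (is.null(nodes$radius)) nodes$radius <- NA_real_
  if (is.null(nodes$n_members)) nodes$n_members <- 0L
  treeskel:::new_skeleton(
    nodes[, c("id", "x", "y", "z", "level", "parent", "radius", "comp",
              "n_members")],
    setNames(rep(list(integer(0)), nrow(nodes)), nodes$id))
}

# toy geodesic field / level partition built directly from vectors
# (synthetic stand-ins for the real structures; used to exercise
# build_skeleton and prune_false_tips on exactly-known inputs)
toy_field <- function(dist, pred, source_row = 1L) {
  structure(list(source = source_row - 1L,
                 ids = seq_along(dist) - 1L,
                 dist = dist, pred = pred,
                 n_unreachable = sum(is.na(dist))),
            class = "geodesic_field")
}

toy_partition <- function(levels, comp, d = 1) {
  ord <- !duplicated(comp) & !is.na(comp)
  comps <- data.frame(comp = comp[ord], level = levels[ord])
  comps <- comps[order(comps$comp), ]
  comps$size <- as.integer(table(comp)[as.character(comps$comp)])
  comps$rank <- stats::ave(comps$comp, comps$level, FUN = seq_along)
  lv <- levels
  attr(lv, "d") <- d
  structure(list(d = d, levels = lv, comp = comp,
                 comps = comps[, c("comp", "level", "rank", "size")]),
            class = "level_partition")
}

# reconstruction on a sampled cloud of one vertical cylinder
cylinder_pipeline <- function(length = 2, radius = 0.1, density = 3000,
                              noise = 0, d = 0.2, r = 0.05, w = 1,
                              seed = 7L) {
  m <- cylinder_model(length, radius)
  cl <- sample_surface(m, sampling_spec(density, noise, seed))
  run_pipeline(cl, reconstruction_config(r = r, d = d, w = w, prune = TRUE))
}
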