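test_that("a sampled cylinder reduces to a centred path skeleton", {
  rec <- cylinder_pipeline(length = 2, radius = 0.1, d = 0.2, w = 1)
  skel <- rec$skeleton
  nd <- skel$nodes
  # a path: one root, one tip, no branching
  expect_length(skeleton_roots(skel), 1L)
  expect_length(skeleton_tips(skel), 1L)
  kids <- table(nd$parent)
  expect_true(all(kids == 1L))
  # interior nodes sit on the axis (the first levels are lopsided because
  # the geodesic ball around the source is a one-sided patch, and the top
  # rim is sparse)
  interior <- nd$level >= 3 & nd$level < max(nd$level)
  expect_true(all(abs(nd$x[interior]) < 0.02))
  expect_true(all(abs(nd$y[interior]) < 0.02))
  # node count ~ geodesic length / d
  expect_equal(nrow(nd), 11, tolerance = 0.1)
})

test_that("radius recovery on a noise-free cylinder is within 5%", {
  rec <- cylinder_pipeline(length = 2, radius = 0.1, d = 0.2, w = 1)
  nd <- rec$skeleton$nodes
  interior <- nd$level >= 3 & nd$level < max(nd$level)
  expect_true(all(abs(nd$radius[interior] - 0.1) / 0.1 < 0.05))
  expect_lt(abs(median(nd$radius) - 0.1) / 0.1, 0.05)
})

test_that("the Y yields two tips above one branching node", {
  m <- y_model(angle = 60)
  cl <- sample_surface(m, sampling_spec(3000, 0, seed = 41))
  rec <- suppressWarnings(run_pipeline(
    cl, reconstruction_config(r = 0.04, d = 0.15, w = 3)))
  skel <- rec$skeleton
  expect_length(skeleton_tips(skel), 2L)
  nkid <- table(skel$nodes$parent)
  expect_identical(sum(nkid == 2L), 1L)  # exactly one junction
})

test_that("majority vote links a cut to the lower cut feeding it", {
  # hand-built: source(1) - 2 - {4 main | 5 spur} - {6,7,8} at the top;
  # 6,7 descend through 4, 8 descends through the spur 5
  dist <- c(0, 1.2, 2.2, 2.4, 3.2, 3.3, 3.4)
  pred <- c(NA, 1L, 2L, 2L, 3L, 3L, 4L)
  lev <- as.integer(floor(dist / 1))
  comp <- c(1L, 2L, 3L, 4L, 5L, 5L, 5L)  # cut 4 is the hand-split spur
  f <- toy_field(dist, pred)
  p <- toy_partition(lev, comp, d = 1)
  cloud <- point_cloud(cbind(seq_along(dist), 0, dist))
  skel <- build_skeleton(p, f, cloud)
  nd <- skel$nodes
  expect_identical(nd$parent, c(NA, 1L, 2L, 2L, 3L))
  # centroid of cut 5 = mean of points 5,6,7
  expect_equal(nd$x[5], mean(c(5, 6, 7)))
  # level-0 root holds the source
  expect_identical(nd$level[is.na(nd$parent)], 0L)
})

test_that("false tips are pruned back to the branching node, idempotently", {
  dist <- c(0, 1.2, 2.2, 2.4, 3.2, 3.3, 3.4)
  pred <- c(NA, 1L, 2L, 2L, 3L, 3L, 4L)
  lev <- as.integer(floor(dist / 1))
  comp <- c(1L, 2L, 3L, 4L, 5L, 5L, 5L)
  f <- toy_field(dist, pred)
  p <- toy_partition(lev, comp, d = 1)
  cloud <- point_cloud(cbind(seq_along(dist), 0, dist))
  skel <- build_skeleton(p, f, cloud)

  # the spur (node 4, members {point 4}) is a tip, and point 4 is the
  # predecessor of point 7 at a higher level outside the spur: false tip
  expect_setequal(skeleton_tips(skel), c(4L, 5L))
  pruned <- prune_false_tips(skel, f, p)
  expect_identical(attr(pruned, "n_pruned"), 1L)
  expect_setequal(pruned$nodes$id, c(1L, 2L, 3L, 5L))

  # idempotent: a second pass removes nothing
  again <- prune_false_tips(pruned, f, p)
  expect_identical(again$nodes, pruned$nodes)

  # a skeleton with no false tips is untouched; the root survives always
  expect_identical(prune_false_tips(pruned, f, p)$nodes$id,
                   pruned$nodes$id)
  expect_true(1L %in% again$nodes$id)
})

test_that("smoothing averages interior chain nodes only", {
  nodes <- data.frame(id = 1:3, x = c(0, 1, 2), y = c(0, 1, 0), z = 0,
                      level = 0:2, parent = c(NA, 1L, 2L))
  skel <- toy_skeleton(nodes)
  sm <- smooth_skeleton(skel, 3)
  expect_equal(unlist(sm$nodes[2, c("x", "y", "z")]), c(1, 1 / 3, 0),
               ignore_attr = TRUE)
  # root and tip anchored
  expect_equal(unlist(sm$nodes[1, c("x", "y", "z")]), c(0, 0, 0),
               ignore_attr = TRUE)
  expect_equal(unlist(sm$nodes[3, c("x", "y", "z")]), c(2, 0, 0),
               ignore_attr = TRUE)
  # w = 1 is the identity
  expect_identical(smooth_skeleton(skel, 1), skel)
  expect_error(smooth_skeleton(skel, 2), "odd")

  # junctions are anchored too: on a Y of chains the centre keeps its spot
  yn <- data.frame(id = 1:5, x = c(0, 0, 0, -1, 1), y = 0,
                   z = c(0, 1, 2, 3, 3), level = c(0:2, 3L, 3L),
                   parent = c(NA, 1L, 2L, 3L, 3L))
  ys <- toy_skeleton(yn)
  sm2 <- smooth_skeleton(ys, 5)
  expect_equal(unlist(sm2$nodes[3, c("x", "y", "z")]), c(0, 0, 2),
               ignore_attr = TRUE)
  # topology never changes
  expect_identical(sm2$nodes$parent, ys$nodes$parent)
})

test_that("radius falls back to the parent with < 3 starting points", {
  # cylinder pipeline, then strip a node's members to force the fallback
  rec <- cylinder_pipeline(length = 2, radius = 0.1, d = 0.2, w = 1)
  skel <- rec$skeleton
  mid <- skel$nodes$id[skel$nodes$level == 5][1]
  ri <- match(mid, skel$nodes$id)
  skel$members[[ri]] <- skel$members[[ri]][integer(0)]
  skel$nodes$radius <- NA_real_
  out <- estimate_radii(skel, rec$field, rec$partition,
                        point_cloud(rec$graph$coords), w = 1)
  pr <- match(out$nodes$parent[ri], out$nodes$id)
  expect_identical(out$nodes$radius[ri], out$nodes$radius[pr])
})

test_that("edit operations preserve the tree and journal replays", {
  rec <- cylinder_pipeline(length = 1, radius = 0.1, d = 0.2, w = 1)
  skel <- rec$skeleton
  n0 <- skel$nodes

  tips0 <- skeleton_tips(skel)
  tip <- tips0[1]
  ed <- add_node(skel, position = c(0.05, 0, 1.1), radius = 0.01,
                 parent = tip)
  new_id <- attr(ed, "new_id")
  # the old tip now has a child; the new node is a tip
  expect_setequal(skeleton_tips(ed), c(setdiff(tips0, tip), new_id))
  back <- delete_node(ed, new_id)
  expect_identical(back$nodes, n0)  # add then delete restores the nodes

  moved <- move_node(skel, tip, c(9, 9, 9))
  expect_equal(unlist(moved$nodes[match(tip, moved$nodes$id),
                                  c("x", "y", "z")]),
               c(9, 9, 9), ignore_attr = TRUE)
  withr <- set_radius(skel, tip, 0.5)
  expect_equal(withr$nodes$radius[match(tip, withr$nodes$id)], 0.5)

  # the journal replays to the same result
  replayed <- apply_edit_script(skel, ed$journal)
  expect_identical(replayed$nodes, ed$nodes)
})

test_that("connect joins orphan roots and refuses cycles", {
  nodes <- data.frame(id = 1:4, x = c(0, 0, 5, 5), y = 0,
                      z = c(0, 1, 0, 1), level = c(0L, 1L, 0L, 1L),
                      parent = c(NA, 1L, NA, 3L))
  skel <- toy_skeleton(nodes)
  expect_length(skeleton_roots(skel), 2L)
  joined <- connect_node(skel, child = 3L, parent = 2L)
  expect_length(skeleton_roots(joined), 1L)
  expect_error(connect_node(joined, child = 3L, parent = 4L),
               "already has a parent")
  # making the root a child of its own descendant must fail
  expect_error(connect_node(joined, child = 1L, parent = 4L), "cycle")
})

test_that("mesh export produces one frustum per edge with the right area", {
  rec <- cylinder_pipeline(length = 2, radius = 0.1, d = 0.2, w = 1)
  mesh <- export_mesh(rec$skeleton, sides = 48L)
  nd <- rec$skeleton$nodes
  expect_identical(nrow(mesh$frusta), nrow(nd) - 1L)  # node count - roots

  # lateral area of the meshed cylinder ~ 2*pi*r*L over the skeleton span
  tri_area <- function(V, F) {
    a <- V[F[, 2], ] - V[F[, 1], ]; b <- V[F[, 3], ] - V[F[, 1], ]
    cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                a[, 1] * b[, 2] - a[, 2] * b[, 1])
    sum(sqrt(rowSums(cr^2))) / 2
  }
  area <- tri_area(mesh$vertices, mesh$faces)
  span <- sum(sqrt(diff(nd$x[order(nd$level)])^2 +
                   diff(nd$y[order(nd$level)])^2 +
                   diff(nd$z[order(nd$level)])^2))
  expect_equal(area, 2 * pi * 0.1 * span, tolerance = 0.02)

  two <- toy_skeleton(data.frame(id = 1:2, x = 0, y = 0, z = c(0, 1),
                                 level = 0:1, parent = c(NA, 1L),
                                 radius = 0.1))
  expect_identical(nrow(export_mesh(two)$frusta), 1L)
  none <- toy_skeleton(data.frame(id = 1:2, x = 0, y = 0, z = c(0, 1),
                                  level = 0:1, parent = c(NA, 1L)))
  expect_error(export_mesh(none), "radii must be set")
})
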