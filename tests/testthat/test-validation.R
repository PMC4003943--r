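# fabricate an axis_decomposition from (order, length) rows, for the
# arithmetic fixtures taken from printed validation tables
fake_axes <- function(orders, lengths = rep(1, length(orders))) {
  out <- data.frame(axis = seq_along(orders), order = orders,
                    length = lengths, n_edges = 1L,
                    parent_axis = NA_integer_)
  class(out) <- c("axis_decomposition", "data.frame")
  out
}

test_that("an unbranched chain is a single order-1 axis", {
  m <- cylinder_model(2, 0.1)
  ax <- assign_axis_orders(m)
  expect_identical(nrow(ax), 1L)
  expect_identical(ax$order, 1L)
  expect_equal(ax$length, 2)
})

test_that("the main axis follows the larger subtree; ties break by id", {
  # unequal Y: long arm must continue the order-1 axis
  df <- data.frame(id = 1:3, parent = c(NA, 1L, 1L),
                   x0 = 0, y0 = 0, z0 = c(0, 1, 1),
                   x1 = c(0, 1, -1), y1 = 0, z1 = c(1, 2.5, 1.6),
                   base_radius = c(0.1, 0.07, 0.07),
                   top_radius = c(0.07, 0.05, 0.05), depth = c(0L, 1L, 1L))
  m <- segment_model(df)
  ax <- assign_axis_orders(m)
  edge_axis <- attr(ax, "edge_axis")
  main <- ax$axis[ax$order == 1L]
  expect_identical(unname(edge_axis[c("1", "2")]), rep(main, 2L))
  expect_identical(sum(ax$order == 2L), 1L)
  expect_equal(ax$length[ax$order == 1L],
               1 + sqrt(1 + 1.5^2), tolerance = 1e-12)

  # exact tie in subtree length and radius: smaller id wins
  sym <- df
  sym$x1 <- c(0, 1, -1); sym$z1 <- c(1, 2, 2)
  m2 <- segment_model(sym)
  ax2 <- assign_axis_orders(m2)
  expect_identical(unname(attr(ax2, "edge_axis")[c("1", "2")]),
                   rep(ax2$axis[ax2$order == 1L], 2L))
})

test_that("axes partition the edges and lengths exactly", {
  m <- generate_tree(sapling_grammar(seed = 3))
  ax <- assign_axis_orders(m)
  ea <- attr(ax, "edge_axis")
  expect_identical(length(ea), nrow(m))          # each edge in one axis
  expect_identical(sum(ax$n_edges), nrow(m))
  expect_equal(sum(ax$length), sum(m$length), tolerance = 1e-9)
  expect_identical(sum(ax$order == 1L), 1L)      # exactly one main stem
  expect_gte(min(ax$order), 1L)
})

test_that("comparing a decomposition with itself reports zero error", {
  ax <- assign_axis_orders(generate_tree(sapling_grammar(seed = 5)))
  rep0 <- compare_decompositions(ax, ax)
  expect_true(all(rep0$axis_error_pct == 0))
  expect_true(all(rep0$length_error_pct == 0))
  expect_true(all(rep0$pct_detected == 100))
  # totals equal the sums over orders
  tot <- rep0[rep0$order == "total", ]
  expect_identical(tot$M, sum(rep0$M[rep0$order != "total"]))
})

test_that("printed validation-table arithmetic is reproduced", {
  # sapling E1: 7 measured vs 4 reconstructed axes -> 42.9% error
  r <- compare_decompositions(fake_axes(rep(1, 7)), fake_axes(rep(1, 4)))
  tot <- r[r$order == "total", ]
  expect_equal(round(tot$axis_error_pct, 1), 42.9)

  # elm cumulative length 43.87 m measured vs 36.96 m reconstructed:
  # 84.25% detected by the |M - R|/M convention (printed as "85%")
  r2 <- compare_decompositions(fake_axes(1, 43.87), fake_axes(1, 36.96))
  tot2 <- r2[r2$order == "total", ]
  expect_equal(tot2$pct_length_detected, 36.96 / 43.87 * 100,
               tolerance = 1e-12)
  expect_lt(abs(tot2$pct_length_detected - 85), 1)

  # sapling E1 cumulative length 79.5 vs 72.3 -> 9.1% error
  r3 <- compare_decompositions(fake_axes(1, 79.5), fake_axes(1, 72.3))
  expect_equal(round(r3$length_error_pct[r3$order == "total"], 1), 9.1)

  # the printed mean errors are means of the printed per-tree values
  expect_equal(round(mean(c(42.9, 25.0, 18.8, 15.8)), 1), 25.6)
  expect_equal(round(mean(c(9.1, 4.3, 4.6, 2.2)), 2), 5.05)  # printed 5.1
  expect_equal(round(mean(c(0.0, 21.4, 16.0, 11.8)), 1), 12.3)
  expect_equal(round(mean(c(0.6, 3.2, 2.3, 1.0)), 3), 1.775) # printed 1.8
})

test_that("spurious orders are flagged, forests are ordered per tree", {
  r <- compare_decompositions(fake_axes(c(1, 2)), fake_axes(c(1, 2, 3)))
  expect_true(r$spurious[r$order == "3"])
  expect_true(is.na(r$pct_detected[r$order == "3"]))

  two <- toy_skeleton(data.frame(id = 1:4, x = c(0, 0, 5, 5), y = 0,
                                 z = c(0, 1, 0, 1), level = c(0L, 1L, 0L, 1L),
                                 parent = c(NA, 1L, NA, 3L)))
  expect_warning(ax <- assign_axis_orders(two), "forest")
  expect_true(attr(ax, "multi_root"))
  expect_identical(sum(ax$order == 1L), 2L)
})

test_that("skeletons and ground-truth models validate against each other", {
  m <- y_model(angle = 60)
  cl <- sample_surface(m, sampling_spec(3000, 0, seed = 51))
  rec <- suppressWarnings(run_pipeline(
    cl, reconstruction_config(r = 0.04, d = 0.15, w = 3)))
  report <- compare_decompositions(assign_axis_orders(m),
                                   assign_axis_orders(rec$skeleton))
  tot <- report[report$order == "total", ]
  expect_equal(tot$M, 2)  # trunk axis + one lateral
  expect_equal(tot$R, 2)
  # reconstructed length close to the true 2.5 m (skeleton spans between
  # cut centroids, so the extremities lose up to ~d)
  expect_equal(tot$R_length, tot$M_length, tolerance = 0.15)
})
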