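spec0 <- function(...) {
  # deterministic geometry: all SDs zero
  grammar_spec(axiom = "F", rules = list(), iterations = 0L,
               angle_mean = 30, angle_sd = 0,
               initial_length = 1, length_scaling_mean = 0.75,
               length_scaling_sd = 0, initial_radius = 0.1,
               radius_scaling_mean = 0.75, radius_scaling_sd = 0,
               seed = 1L, ...)
}

test_that("a lone F is one unit segment along +z", {
  m <- interpret_turtle("F", spec0())
  expect_equal(nrow(m), 1L)
  expect_equal(unlist(m[1, c("x0", "y0", "z0")]), c(x0 = 0, y0 = 0, z0 = 0))
  expect_equal(unlist(m[1, c("x1", "y1", "z1")]), c(x1 = 0, y1 = 0, z1 = 1))
  expect_equal(m$base_radius, 0.1)
  expect_equal(m$top_radius, 0.075)  # childless: taper by the mean scaling
})

test_that("Y-shape child tips match the rotation-matrix oracle", {
  m <- interpret_turtle("F[<F][>F]", spec0())
  expect_equal(nrow(m), 3L)
  expect_equal(m$parent, c(NA, 1L, 1L))
  expect_equal(m$length[2:3], c(0.75, 0.75))

  # yaw rotates the heading about the turtle's up vector (0, 1, 0);
  # left is +30 degrees, right is -30
  tip <- function(theta) c(0, 0, 1) + rodrigues(c(0, 1, 0), theta) %*%
    c(0, 0, 0.75)
  expect_equal(unlist(m[2, c("x1", "y1", "z1")]), tip(30)[, 1],
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unlist(m[3, c("x1", "y1", "z1")]), tip(-30)[, 1],
               ignore_attr = TRUE, tolerance = 1e-12)

  # both children make 30 degrees with the trunk axis
  for (i in 2:3) {
    v <- c(m$x1[i] - m$x0[i], m$y1[i] - m$y0[i], m$z1[i] - m$z0[i])
    ang <- acos(sum(v * c(0, 0, 1)) / sqrt(sum(v^2))) * 180 / pi
    expect_equal(ang, 30, tolerance = 1e-9)
  }

  # top radius = first child's base radius on the trunk
  expect_equal(m$top_radius[1], m$base_radius[2])
  expect_equal(m$base_radius[2], 0.075)
})

test_that("pitch and roll follow the turtle frame conventions", {
  # pitch up rotates the heading about the left vector: tip moves into +y
  m <- interpret_turtle("^F", spec0())
  expect_equal(unlist(m[1, c("x1", "y1", "z1")]),
               (rodrigues(c(1, 0, 0), -30) %*% c(0, 0, 1))[, 1],
               ignore_attr = TRUE, tolerance = 1e-12)
  # roll alone does not move the heading
  m2 <- interpret_turtle("+F", spec0())
  expect_equal(unlist(m2[1, c("x1", "y1", "z1")]), c(0, 0, 1),
               ignore_attr = TRUE, tolerance = 1e-12)
  # a 90-degree roll moves a subsequent yaw into the pitch plane:
  # roll(90) then yaw-left(90) lands the heading where pitch-up(90) does
  g <- spec0(); g$angle_mean <- 90
  m3 <- interpret_turtle("+<F", g)
  m4 <- interpret_turtle("^F", g)
  expect_equal(unlist(m3[1, c("x1", "y1", "z1")]),
               unlist(m4[1, c("x1", "y1", "z1")]), tolerance = 1e-12)
})

test_that("bracket stack isolates branch state", {
  m <- interpret_turtle("F[<F[<F]]F", spec0())
  # the outer F after the bracket continues from segment 1's tip, along +z
  expect_equal(m$parent, c(NA, 1L, 2L, 1L))
  last <- which(m$depth == 0L & m$id != 1L)
  expect_equal(unlist(m[last, c("x1", "y1", "z1")]),
               c(0, 0, 1 + 0.75), ignore_attr = TRUE, tolerance = 1e-12)
  # an unmatched pop is caught by the bracket-balance check up front
  expect_error(interpret_turtle("F]", spec0()), "unbalanced")
})

test_that("same seed gives a bit-identical model; structure is seed-free", {
  g <- sapling_grammar(seed = 7L)
  g$iterations <- 4L
  m1 <- generate_tree(g)
  m2 <- generate_tree(g)
  expect_identical(m1, m2)
  g2 <- g; g2$seed <- 8L
  m3 <- generate_tree(g2)
  expect_identical(nrow(m3), nrow(m1))
  expect_identical(summarize_structure(m3)$n_tips,
                   summarize_structure(m1)$n_tips)
  expect_false(isTRUE(all.equal(m1$x1, m3$x1)))
})

test_that("structure summary matches arithmetic on the Y-shape", {
  m <- y_model(angle = 30, scaling = 0.75)
  s <- summarize_structure(m)
  expect_identical(s$n_segments, 3L)
  expect_identical(s$n_tips, 2L)
  expect_equal(s$total_length, 1 + 2 * 0.75)
  expect_equal(s$min_segment_length, 0.75)
  # frustum lateral areas: pi * (r0 + r1) * slant, summed
  slant <- sqrt(m$length^2 + (m$base_radius - m$top_radius)^2)
  expect_equal(s$lateral_surface_area,
               sum(pi * (m$base_radius + m$top_radius) * slant))
})

test_that("single-segment summary is exact", {
  s <- summarize_structure(cylinder_model(1, 0.1, 0.075))
  expect_identical(s$n_tips, 1L)
  expect_identical(s$n_segments, 1L)
  expect_equal(s$total_length, 1)
})

test_that("invalid models are rejected", {
  df <- as.data.frame(cylinder_model(1, 0.1))
  bad <- rbind(df, within(df, { id <- 2L; parent <- 3L }))
  expect_error(segment_model(bad), "parent ids must exist")
  zero <- within(df, { x1 <- x0; y1 <- y0; z1 <- z0 })
  expect_error(segment_model(zero), "lengths must be positive")
})
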