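test_that("curve evaluation matches the helix-plus-polynomial form", {
  # straight-line degenerate
  c0 <- space_curve(t_range = c(0, 10))
  expect_equal(curve_points(c0, 5)[1, ], c(0, 0, 5))
  # pure helix: a=2, omega=pi/10, phi=0
  h <- space_curve(helix_radius_nm = 2, helix_pitch_rad_per_nm = pi / 10,
                   t_range = c(0, 10))
  expect_equal(curve_points(h, 0)[1, ], c(2, 0, 0))
  expect_equal(curve_points(h, 10)[1, ], c(-2, 0, 10), tolerance = 1e-12)
  # polynomial: x(t) = 1 + 0.5 t
  p <- space_curve(poly_x = c(1, 0.5), t_range = c(0, 10))
  expect_equal(curve_points(p, 4)[1, ], c(3, 0, 4))
  # out-of-range values clamp with a warning
  expect_warning(curve_points(c0, 99), "clamped")
})

test_that("tangents are analytic, unit length, and ignore constant offsets", {
  c0 <- space_curve(t_range = c(0, 10))
  expect_equal(curve_tangent(c0, c(0, 5, 10)),
               matrix(rep(c(0, 0, 1), each = 3), 3, 3))
  h <- space_curve(helix_radius_nm = 1, helix_pitch_rad_per_nm = 1,
                   t_range = c(0, 10))
  expect_equal(curve_tangent(h, 0)[1, ], c(0, 1 / sqrt(2), 1 / sqrt(2)))
  p1 <- space_curve(poly_x = c(0, 0.3, 0.01), t_range = c(0, 10))
  p2 <- space_curve(poly_x = c(5, 0.3, 0.01), t_range = c(0, 10))
  expect_equal(curve_tangent(p1, c(1, 7)), curve_tangent(p2, c(1, 7)))
})

test_that("curve_length: exact for lines, closed-form for helices, refinement-stable", {
  expect_equal(curve_length(space_curve(t_range = c(0, 20))), 20)
  # helix arclength over parameter length Lz is Lz * sqrt(1 + a^2 w^2)
  h <- space_curve(helix_radius_nm = 2, helix_pitch_rad_per_nm = 0.5,
                   t_range = c(0, 30))
  expect_equal(curve_length(h), 30 * sqrt(1 + 1), tolerance = 1e-8)
  wig <- space_curve(poly_x = c(0, 0.2, 0.01), poly_y = c(1, -0.1, 0.005),
                     helix_radius_nm = 1, helix_pitch_rad_per_nm = 0.8,
                     t_range = c(0, 40))
  l1 <- curve_length(wig, n = 128)
  l2 <- curve_length(wig, n = 256)
  expect_lt(abs(l2 - l1) / l2, 1e-4)
})

test_that("curve_min_distance matches closed-form and brute-force oracles", {
  a <- space_curve(t_range = c(0, 20))
  b <- space_curve(poly_x = 10, t_range = c(0, 20))
  d <- curve_min_distance(a, b, sampling_nm = 0.5)
  expect_equal(d$min, 10, tolerance = 1e-9)
  expect_equal(d$mean_min, 10, tolerance = 1e-9)
  # skew perpendicular lines offset along the common perpendicular
  s1 <- space_curve(t_range = c(-10, 10))
  s2 <- transform_curve(space_curve(t_range = c(-10, 10)),
                        rotation_about_axis(2, 90), c(0, 3, 0))
  expect_equal(curve_min_distance(s1, s2, 0.5)$min, 3, tolerance = 1e-6)
  # self distance zero
  expect_equal(curve_min_distance(a, a, 0.5)$min, 0)
  # randomized curve pairs against the dense brute-force oracle, and
  # monotone non-increasing minimum under sampling refinement
  set.seed(21)
  for (k in 1:20) {
    c1 <- space_curve(helix_radius_nm = runif(1, 0, 2),
                      helix_pitch_rad_per_nm = runif(1, 0.1, 0.8),
                      poly_x = c(runif(1, -5, 5), runif(1, -0.5, 0.5)),
                      poly_y = c(runif(1, -5, 5), runif(1, -0.5, 0.5)),
                      t_range = c(0, 25))
    c2 <- transform_curve(
      space_curve(poly_x = c(runif(1, -5, 5), runif(1, -0.5, 0.5)),
                  poly_y = runif(1, -5, 5), t_range = c(0, 25)),
      rotation_about_axis(sample(1:3, 1), runif(1, -60, 60)),
      runif(3, -3, 3))
    for (s in c(2, 1)) {
      got <- curve_min_distance(c1, c2, sampling_nm = s)$min
      expect_lt(abs(got - brute_min_distance(c1, c2)), 2 * s)
    }
    d2 <- curve_min_distance(c1, c2, sampling_nm = 2, polish = FALSE)$min
    d1 <- curve_min_distance(c1, c2, sampling_nm = 1, polish = FALSE)$min
    expect_lte(d1, d2 + 1e-9)
  }
})

test_that("distances and lengths are invariant under rigid motion", {
  set.seed(22)
  c1 <- space_curve(helix_radius_nm = 1.5, helix_pitch_rad_per_nm = 0.4,
                    poly_x = c(2, 0.1), t_range = c(0, 30))
  c2 <- space_curve(poly_x = 8, poly_y = c(1, -0.2), t_range = c(0, 30))
  R <- rotation_about_axis(1, 37) %*% rotation_about_axis(3, -12)
  tr <- c(4, -7, 2)
  d0 <- curve_min_distance(c1, c2, 0.5)
  d1 <- curve_min_distance(transform_curve(c1, R, tr),
                           transform_curve(c2, R, tr), 0.5)
  expect_equal(d1$min, d0$min, tolerance = 1e-8)
  expect_equal(d1$mean_min, d0$mean_min, tolerance = 1e-8)
  expect_equal(curve_length(transform_curve(c1, R, tr)), curve_length(c1))
  # tangents rotate correspondingly
  expect_equal(curve_tangent(transform_curve(c1, R, tr), 3)[1, ],
               as.vector(R %*% curve_tangent(c1, 3)[1, ]))
})
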