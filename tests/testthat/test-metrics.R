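make_line <- function(x, y, t_range = c(0, 30), pose = axial_T_pose()) {
  space_curve(poly_x = x, poly_y = y, t_range = t_range, pose = pose)
}

test_that("nearest-neighbour distances: lattice rows, crossing contact, permutation invariance", {
  cs <- list(make_line(0, 0), make_line(10, 0), make_line(20, 0))
  nn <- nearest_neighbor_distances(cs, sampling_nm = 1)
  expect_equal(nn$nn_distance_nm, c(10, 10, 10), tolerance = 1e-9)
  expect_equal(mean(nn$nn_distance_nm), 10, tolerance = 1e-9)
  expect_error(nearest_neighbor_distances(cs[1]), "two curves")
  # a crossing pair at contact reads near zero under the closest-approach
  # statistic
  cr1 <- space_curve(poly_y = c(0, 1), t_range = c(-15, 15))
  cr2 <- space_curve(poly_x = 0.5, poly_y = c(0, -1), t_range = c(-15, 15))
  nnx <- nearest_neighbor_distances(list(cr1, cr2), sampling_nm = 0.5)
  expect_lt(nnx$nn_min_distance_nm[1], 0.9)
  # permutation invariance
  perm <- c(3, 1, 2)
  nnp <- nearest_neighbor_distances(cs[perm], sampling_nm = 1)
  expect_equal(sort(nnp$nn_distance_nm), sort(nn$nn_distance_nm))
  # rigid-motion invariance
  R <- rotation_about_axis(2, 33); tr <- c(5, -2, 8)
  nnr <- nearest_neighbor_distances(
    lapply(cs, transform_curve, R = R, t = tr), sampling_nm = 1)
  expect_equal(nnr$nn_distance_nm, nn$nn_distance_nm, tolerance = 1e-8)
})

test_that("orientation angles follow the anatomical conventions", {
  # straight line along L: all angles zero
  axial_L <- space_curve(t_range = c(0, 30))  # local z -> dim3 = L
  a <- orientation_angles(axial_L, axes = c("T", "N", "L"))
  expect_equal(a$longitudinal_deg, 0)
  expect_equal(a$tangential_deg, 0)
  # direction (0, cos6, sin6) in (L, T, N): tangential +6 degrees
  d <- c(cos(pi / 30), sin(pi / 30))  # (T, N) components, 6 degrees
  tilted <- make_line(c(0, d[2] / d[1]), 0)  # slope in N per nm of T
  at <- orientation_angles(tilted, axes = c("T", "N", "L"))
  expect_equal(at$tangential_deg, 6, tolerance = 1e-6)
  expect_equal(at$longitudinal_deg, 90, tolerance = 1e-6)
  # 45 degrees between T and N, perpendicular to L
  c45 <- make_line(c(0, 1), 0)
  a45 <- orientation_angles(c45, axes = c("T", "N", "L"))
  expect_equal(a45$tangential_deg, 45, tolerance = 1e-6)
  expect_equal(a45$longitudinal_deg, 90, tolerance = 1e-6)
})

test_that("angle_summary: degenerate SD, planted-Gaussian SD recovery, sign symmetry", {
  same <- replicate(4, make_line(0, 0), simplify = FALSE)
  expect_equal(angle_summary(same)$sd_longitudinal_deg, 0)
  # planted longitudinal angles ~ Gaussian(90, 10), n = 200
  set.seed(71)
  lam <- stats::rnorm(200, 0, 10)  # in-plane deviation; longitudinal = 90 - lam
  curves <- lapply(lam, function(l)
    make_line(c(0, 0), c(0, tan(pi * l / 180))))
  s <- angle_summary(curves)
  expect_equal(s$mean_longitudinal_deg, 90, tolerance = 1.5)
  expect_equal(s$sd_longitudinal_deg, 10, tolerance = 1.5)
  # +6 / -6 pair: signed median 0, median magnitude 6
  pm <- list(make_line(c(0, tan(pi / 30)), 0),
             make_line(c(0, -tan(pi / 30)), 0))
  sp <- angle_summary(pm)
  expect_equal(sp$median_tangential_deg, 0, tolerance = 1e-9)
  expect_equal(sp$median_abs_tangential_deg, 6, tolerance = 1e-6)
  expect_identical(c(sp$n_positive, sp$n_negative), c(1L, 1L))
})

test_that("bundle detection: components, thresholds, monotonicity, planted fraction", {
  # all curves farther than contact: no bundles
  far <- list(make_line(0, 0), make_line(10, 0), make_line(20, 0))
  b0 <- detect_bundles(far, contact_nm = 4)
  expect_identical(b0$bundle_fraction_percent, 0)
  # three mutually touching curves form one bundle of size 3
  tight <- list(make_line(0, 0), make_line(3, 0), make_line(6, 0))
  b3 <- detect_bundles(tight, contact_nm = 3.5)
  expect_length(b3$bundles, 1)
  expect_identical(sort(b3$bundles[[1]]), 1:3)
  expect_identical(b3$bundle_fraction_percent, 100)
  # monotone non-decreasing in the contact threshold
  sc <- make_scene("bundled", n_fibrils = 10, spacing_nm = 10,
                   bundle_fraction = 0.4, bundle_size = 2, seed = 72)
  fr <- vapply(c(2, 4, 6, 11), function(ct)
    detect_bundles(sc$truth_curves, contact_nm = ct)$bundle_fraction_percent,
    numeric(1))
  expect_true(all(diff(fr) >= 0))
  # planted 40% at the default contact threshold
  expect_equal(detect_bundles(sc$truth_curves,
                              contact_nm = 4.4)$bundle_fraction_percent, 40)
})

test_that("grid maps aggregate consistently (count-weighted conservation)", {
  set.seed(73)
  curves <- lapply(1:12, function(i)
    make_line(c(runif(1, 2, 38), runif(1, -0.2, 0.2)),
              runif(1, 2, 38), t_range = c(0, 40)))
  mt <- compute_metrics(curves)
  # one cell covering everything: cell mean = global mean
  g1 <- grid_maps(mt, curves, extent_nm = c(45, 45), cell_side_nm = 50)
  expect_equal(g1$mean_tangential[1, 1],
               mean(mt$per_curve$angle_tangential_deg))
  # general grid: count-weighted cell means equal global means
  g <- grid_maps(mt, curves, extent_nm = c(45, 45), cell_side_nm = 12)
  for (field in c("mean_tangential", "mean_nn")) {
    m <- g[[field]]
    w <- g$count
    glob <- switch(field,
                   mean_tangential = mean(mt$per_curve$angle_tangential_deg),
                   mean_nn = mean(mt$per_curve$nn_distance_nm))
    expect_equal(sum(m * w, na.rm = TRUE) / sum(w), glob, tolerance = 1e-10)
  }
  expect_identical(sum(g$count), 12)
})

test_that("planted mid-band spacing decrease shows up in the grid map", {
  sc <- make_scene("tilted", n_fibrils = 8, spacing_nm = 11,
                   spacing_mid_nm = 9.7, seed = 74,
                   box_nm = c(57.6, 57.6, 57.6))
  mt <- compute_metrics(sc$truth_curves)
  g <- grid_maps(mt, sc$truth_curves, extent_nm = c(57.6, 57.6),
                 cell_side_nm = 12)
  col_nn <- apply(g$mean_nn, 2, mean, na.rm = TRUE)
  col_nn <- col_nn[!is.nan(col_nn)]
  expect_equal(min(col_nn), 9.7, tolerance = 0.2)
  expect_lt(min(col_nn), col_nn[1])
  expect_lt(min(col_nn), col_nn[length(col_nn)])
})

test_that("assignment solver matches brute-force enumeration", {
  set.seed(75)
  for (k in 1:10) {
    n <- sample(2:6, 1)
    C <- matrix(runif(n * n), n, n)
    a <- solve_assignment(C)
    expect_equal(sum(C[cbind(seq_len(n), a)]), brute_assignment_cost(C),
                 tolerance = 1e-12)
  }
  # rectangular: 3 rows, 5 columns
  C <- matrix(runif(15), 3, 5)
  a <- solve_assignment(C)
  expect_false(anyNA(a))
  expect_identical(anyDuplicated(a), 0L)
})

test_that("recovery_report: identity, partial sets, order invariance", {
  truth <- lapply(seq(0, 40, 10), function(x) make_line(x, 0))
  rec <- recovery_report(truth, truth)
  expect_identical(rec$n_matched, 5L)
  expect_equal(rec$matches$rmsd_nm, rep(0, 5), tolerance = 1e-9)
  rec2 <- recovery_report(truth, truth[1:4])
  expect_identical(rec2$n_matched, 4L)
  expect_identical(rec2$n_missed, 1L)
  # permuted truth gives the same set of matched pairs
  perm <- c(4, 2, 5, 1, 3)
  rec3 <- recovery_report(truth[perm], truth[1:4])
  expect_identical(rec3$n_matched, 4L)
  expect_equal(sort(perm[rec3$matches$truth]), sort(rec2$matches$truth))
})
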