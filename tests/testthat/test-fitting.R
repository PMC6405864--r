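test_that("curve_cost: uniform volumes, centred-tube preference, intensity linearity", {
  cfg <- fit_config()
  vk <- density_volume(array(3.7, c(20, 20, 20)), 1)
  cv <- space_curve(poly_x = 10, poly_y = 10, t_range = c(0, 19),
                    pose = axial_T_pose())
  expect_equal(curve_cost(cv, vk, cfg), -3.7)
  tube <- straight_tube_volume(x0 = 28.8, y0 = 28.8)
  on_truth <- curve_cost(tube$curve, tube$volume, cfg)
  shifted <- tube$curve
  shifted$poly_x <- shifted$poly_x + 5
  expect_lt(on_truth, curve_cost(shifted, tube$volume, cfg))
  v2 <- tube$volume; v2$data <- 2 * v2$data
  expect_equal(curve_cost(tube$curve, v2, cfg), 2 * on_truth,
               tolerance = 1e-12)
  outside <- tube$curve
  outside$poly_x <- outside$poly_x + 500
  expect_error(curve_cost(outside, tube$volume, cfg), "outside")
})

test_that("seed_candidates finds planted tubes and returns nothing on featureless input", {
  cfg <- fit_config()
  sc <- make_scene("parallel", n_fibrils = 3, spacing_nm = 12, seed = 61)
  v <- render_scene(sc)
  seeds <- seed_candidates(v, cfg)
  expect_gte(length(seeds), 3)
  # each true fibril has a seed within 2 voxels (1.8 nm)
  for (tr in sc$truth_curves) {
    dmin <- min(vapply(seeds, function(s)
      curve_min_distance(tr, s, sampling_nm = 1,
                         polish = FALSE)$mean_min, numeric(1)))
    expect_lt(dmin, 1.8)
  }
  expect_identical(seed_candidates(density_volume(array(1, c(24, 24, 24)),
                                                  0.9), cfg),
                   list())
  # determinism
  s2 <- seed_candidates(v, cfg)
  expect_equal(lapply(seeds, attr, "params"), lapply(s2, attr, "params"))
})

test_that("fit_single recovers a noiseless tube to sub-voxel accuracy and honours its contracts", {
  tube <- straight_tube_volume(x0 = 26.1, y0 = 31.5, slope_x = 0.1,
                               slope_y = -0.05)
  cfg <- fit_config(rng_seed = 7)
  seeds <- seed_candidates(tube$volume, cfg)
  fit <- fit_single(tube$volume, seeds[[1]], cfg)
  rec <- recovery_report(list(tube$curve), list(fit))
  expect_equal(rec$n_matched, 1L)
  expect_lt(rec$matches$rmsd_nm / 0.9, 0.5)  # < 0.5 voxel
  # optimizer contracts
  expect_lte(fit$cost, fit$pso_cost)
  expect_lte(fit$cost, curve_cost(seeds[[1]], tube$volume, cfg))
  expect_true(all(diff(fit$history) <= 1e-12))
  # determinism: identical seed and rng give identical results
  fit2 <- fit_single(tube$volume, seeds[[1]], cfg)
  expect_identical(fit$params, fit2$params)
  expect_identical(fit$cost, fit2$cost)
})

test_that("fixed parameters stay pinned through swarm and simplex", {
  tube <- straight_tube_volume(x0 = 30, y0 = 25, slope_x = 0.2)
  cfg <- fit_config(poly_degree = 1, fixed_params = c(cy1 = 0),
                    rng_seed = 3)
  seeds <- seed_candidates(tube$volume, cfg)
  fit <- fit_single(tube$volume, seeds[[1]], cfg)
  expect_identical(unname(fit$params["cy1"]), 0)
})

test_that("a helical fibril is recovered when the helix term is enabled", {
  hx <- space_curve(helix_radius_nm = 2, helix_pitch_rad_per_nm = 0.35,
                    helix_phase_rad = 0.8, poly_x = 28.8, poly_y = 28.8,
                    t_range = c(0, 56.7), pose = axial_T_pose())
  sc <- make_scene("parallel", n_fibrils = 1, seed = 9)
  sc$truth_curves <- list(hx)
  v <- render_scene(sc, shape_vox = c(64, 64, 64), voxel_size_nm = 0.9)
  cfg <- fit_config(fit_helix = TRUE, poly_degree = 1,
                    helix_omega_range = c(0.2, 0.5),
                    pso_iterations = 120, n_particles = 60,
                    init_spread = 0.3, rng_seed = 2)
  seeds <- seed_candidates(v, cfg)
  fit <- fit_single(v, seeds[[1]], cfg)
  rec <- recovery_report(list(hx), list(fit))
  expect_lt(rec$matches$rmsd_nm / 0.9, 0.5)
  expect_equal(unname(fit$params["a"]), 2, tolerance = 0.15)
  expect_equal(unname(fit$params["omega"]), 0.35, tolerance = 0.1)
})

test_that("fit_all extracts every planted fibril once and nothing from uniform volumes", {
  sc <- make_scene("parallel", n_fibrils = 5, spacing_nm = 11,
                   noise_sigma = 0.25, seed = 63)
  v <- gaussian_denoise(apply_noise(render_scene(sc), sc), 0.9)
  cfg <- fit_config(rng_seed = 5)
  fits <- fit_all(v, cfg)
  rec <- recovery_report(sc$truth_curves, fits)
  expect_identical(rec$n_matched, 5L)
  expect_identical(rec$n_spurious, 0L)
  expect_lt(max(rec$matches$rmsd_nm) / 0.9, 1)
  # accepted fits are mutually non-duplicate
  curves <- lapply(fits, `[[`, "curve")
  for (i in seq_along(curves)[-1]) for (j in seq_len(i - 1)) {
    expect_gt(curve_min_distance(curves[[i]], curves[[j]], 1,
                                 polish = FALSE)$mean_min,
              cfg$mask_radius_nm / 2)
  }
  expect_identical(fit_all(density_volume(array(0.5, c(24, 24, 24)), 0.9),
                           cfg),
                   list())
})
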