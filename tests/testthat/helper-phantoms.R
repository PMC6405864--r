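# Shared fixtures, all generated in code.

# Canonical pose whose local z runs along the first grid axis (the
# tangential direction under the default tagging), x -> dim2, y -> dim3.
axial_T_pose <- function() list(R = cbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0)),
                                t = c(0, 0, 0))

# A straight tube running along dim1 at (x, y) nm in the (dim2, dim3)
# plane, with optional slopes, rendered at 0.9 nm voxels.
straight_tube_volume <- function(x0 = 28.8, y0 = 28.8, slope_x = 0,
                                 slope_y = 0, shape = c(64, 64, 64),
                                 noise_sigma = 0, seed = 1,
                                 voxel = 0.9) {
  tmax <- (shape[1] - 1) * voxel
  cv <- space_curve(poly_x = c(x0, slope_x), poly_y = c(y0, slope_y),
                    t_range = c(0, tmax), pose = axial_T_pose())
  sc <- make_scene("parallel", n_fibrils = 1, seed = seed,
                   noise_sigma = noise_sigma,
                   box_nm = shape * voxel)
  sc$truth_curves <- list(cv)
  v <- render_scene(sc, shape_vox = shape, voxel_size_nm = voxel)
  if (noise_sigma > 0) v <- apply_noise(v, sc)
  list(volume = v, curve = cv, scene = sc)
}

# Gaussian-blob phantom for interpolation/rotation checks.
blob_volume <- function(n = 32, voxel = 1) {
  idx <- as.matrix(expand.grid(seq_len(n), seq_len(n), seq_len(n)))
  arr <- array(exp(-rowSums(sweep(idx, 2, c(0.4, 0.55, 0.5) * n)^2) /
                     (0.03 * n^2)), c(n, n, n))
  density_volume(arr, voxel)
}

# Dense brute-force curve distance oracle (no polishing, very fine
# sampling), independent of curve_min_distance's internals.
brute_min_distance <- function(c1, c2, step = 0.05) {
  t1 <- seq(c1$t_range[1], c1$t_range[2], by = step)
  t2 <- seq(c2$t_range[1], c2$t_range[2], by = step)
  p1 <- curve_points(c1, t1)
  p2 <- curve_points(c2, t2)
  d2 <- outer(rowSums(p1^2), rowSums(p2^2), "+") - 2 * p1 %*% t(p2)
  sqrt(max(min(d2), 0))
}

# Brute-force optimal assignment by permutation enumeration (small n).
brute_assignment_cost <- function(C) {
  n <- nrow(C)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  min(vapply(perms(seq_len(n)), function(p)
    sum(C[cbind(seq_len(n), p)]), numeric(1)))
}
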