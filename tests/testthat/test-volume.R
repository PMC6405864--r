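test_that("MRC round trip preserves data and header voxel size", {
  set.seed(11)
  v <- density_volume(array(rnorm(18 * 20 * 22), c(18, 20, 22)), 0.45)
  p <- withr::local_tempfile(fileext = ".mrc")
  write_volume(v, p)
  v2 <- read_volume(p)
  # header pixel spacing 4.5 Angstrom reads back as 0.45 nm
  expect_equal(v2$voxel_size_nm, rep(0.45, 3), tolerance = 1e-6)
  # mode-2 storage is float32: first trip is exact to single precision,
  # the second round trip is bit-exact
  expect_lt(max(abs(v2$data - v$data)), 1e-6)
  write_volume(v2, p)
  v3 <- read_volume(p)
  expect_identical(v3$data, v2$data)
})

test_that("TIFF stacks require an explicit voxel size", {
  v <- density_volume(array(runif(8 * 9 * 4), c(8, 9, 4)), 0.9)
  p <- withr::local_tempfile(fileext = ".tif")
  write_volume(v, p)
  expect_error(read_volume(p), "voxel size")
  v2 <- read_volume(p, voxel_size_nm = 0.9)
  expect_lt(max(abs(v2$data - v$data)), 1e-6)
})

test_that("gaussian_denoise: identity at sigma 0, closed-form impulse peak, smoothing and linearity", {
  imp <- array(0, c(33, 33, 33)); imp[17, 17, 17] <- 1
  vi <- density_volume(imp, 1)
  expect_identical(gaussian_denoise(vi, 0)$data, vi$data)
  g <- gaussian_denoise(vi, 2)
  # separable 3D Gaussian peak value (2*pi*sigma^2)^(-3/2), sigma = 2 vox
  expect_equal(max(g$data), (2 * pi * 4)^(-3 / 2), tolerance = 0.01)
  expect_equal(sum(g$data), 1, tolerance = 1e-3)  # intensity conserved
  set.seed(12)
  w <- density_volume(array(rnorm(24^3), c(24, 24, 24)), 1)
  expect_lt(stats::var(as.vector(gaussian_denoise(w, 1.5)$data)),
            stats::var(as.vector(w$data)))
  # linearity: filter(a V1 + b V2) = a filter(V1) + b filter(V2)
  v1 <- density_volume(array(rnorm(16^3), c(16, 16, 16)), 1)
  v2 <- density_volume(array(rnorm(16^3), c(16, 16, 16)), 1)
  lhs <- gaussian_denoise(density_volume(2 * v1$data - 3 * v2$data, 1), 1.2)
  rhs <- 2 * gaussian_denoise(v1, 1.2)$data - 3 * gaussian_denoise(v2, 1.2)$data
  expect_lt(max(abs(lhs$data - rhs)), 1e-10)
})

test_that("crop_middle_slab follows the floor(extent/2) centering convention", {
  v <- density_volume(array(seq_len(10 * 10 * 100), c(10, 10, 100)), 1,
                      axes = c("T", "N", "L"))
  sl <- crop_middle_slab(v, 20, axis = "L")
  # extent 100, thickness 20 -> half-open [40, 60)
  expect_identical(dim(sl$data), c(10L, 10L, 20L))
  expect_identical(sl$data[, , 1], v$data[, , 41])
  expect_identical(sl$data[, , 20], v$data[, , 60])
  expect_equal(sl$origin_nm[3], 40)
  # full extent is a no-op
  expect_identical(crop_middle_slab(v, 100, axis = "L")$data, v$data)
  expect_error(crop_middle_slab(v, 101, axis = "L"), "exceeds")
})

test_that("tile_grid arithmetic: counts, stride flooring, historical grids", {
  # 121.5 nm plane at 0.45 nm/vox = 270 vox; side 40.5 nm = 90 vox -> 3 per axis
  expect_length(tile_grid(270, 90, 0), 3)
  # 1D extent 81 vox, side 40.5 (floored to 40), overlap 0.5 -> stride
  # 20.25 floored per origin: {0, 20, 40}
  expect_identical(tile_grid(81, 40.5, 0.5), c(0L, 20L, 40L))
  # the three recorded tomogram grid configurations reproduce the
  # published subvolume counts 13, 44 and 261
  counts <- c(
    length(tile_grid(630, 90, 0.5)) * length(tile_grid(134, 90, 0.5)),
    length(tile_grid(540, 90, 0.5)) * length(tile_grid(225, 90, 0.5)),
    length(tile_grid(1350, 90, 0.5)) * length(tile_grid(450, 90, 0.5)))
  expect_identical(counts, c(13L, 44L, 261L))
  expect_error(tile_grid(50, 90, 0), "larger")
})

test_that("extract_subvolumes tiles the plane and commutes with intensity rescaling", {
  set.seed(13)
  v <- density_volume(array(rnorm(27 * 27 * 10), c(27, 27, 10)), 1.5,
                      axes = c("T", "L", "N"))
  tiles <- extract_subvolumes(v, side = 13.5, overlap = 0, side_unit = "nm")
  expect_length(tiles, 9)  # 27 vox / 9 vox side = 3 per axis
  # disjoint non-overlapping footprints covering the full plane
  origins <- t(vapply(tiles, function(x) x$spec$origin_vox, integer(3)))
  expect_identical(sort(unique(origins[, 1])), c(0L, 9L, 18L))
  # rescaling intensities never changes tile geometry
  v2 <- v; v2$data <- 3 * v$data + 7
  tiles2 <- extract_subvolumes(v2, side = 13.5, overlap = 0)
  expect_identical(lapply(tiles, function(x) x$spec),
                   lapply(tiles2, function(x) x$spec))
  expect_equal(tiles2[[5]]$volume$data, 3 * tiles[[5]]$volume$data + 7)
})

test_that("rotate_to_axis: identity pass-through, exact 90-degree path, inverse consistency", {
  set.seed(14)
  v <- density_volume(array(rnorm(12 * 14 * 16), c(12, 14, 16)), 1)
  expect_identical(rotate_to_axis(v, diag(3))$data, v$data)
  R90 <- rotation_about_axis(3, 90)
  vr <- rotate_to_axis(v, R90)
  expect_identical(dim(vr$data), c(14L, 12L, 16L))
  expect_identical(rotate_to_axis(vr, t(R90))$data, v$data)
  expect_error(rotate_to_axis(v, diag(c(1, 1, -1))), "proper")
  # general rotation then its inverse stays highly correlated on a
  # smooth phantom
  vb <- blob_volume(32)
  Rg <- rotation_about_axis(1, 30) %*% rotation_about_axis(2, 20)
  v2 <- rotate_to_axis(rotate_to_axis(vb, Rg), t(Rg))
  expect_gt(stats::cor(as.vector(v2$data), as.vector(vb$data)), 0.99)
})
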