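#' @keywords internal
"_PACKAGE"

# Degrees <-> radians
deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Trilinear interpolation of a 3D array at fractional voxel coordinates
#'
#' Coordinates are 0-based voxel-centre coordinates: the centre of voxel
#' `[i, j, k]` (1-based R indexing) sits at `(i-1, j-1, k-1)`. Points
#' outside the grid return `outside`.
#'
#' @param arr 3D numeric array.
#' @param pts numeric matrix, n x 3, 0-based voxel coordinates.
#' @param outside value returned for points outside the grid.
#' @return numeric vector of length `nrow(pts)`.
#' @keywords internal
interp_trilinear <- function(arr, pts, outside = NA_real_) {
  d <- dim(arr)
  x <- pts[, 1L]; y <- pts[, 2L]; z <- pts[, 3L]
  inside <- x >= 0 & x <= d[1L] - 1 & y >= 0 & y <= d[2L] - 1 &
    z >= 0 & z <= d[3L] - 1
  out <- rep(outside, length(x))
  if (!any(inside)) return(out)
  x <- x[inside]; y <- y[inside]; z <- z[inside]
  x0 <- pmin(floor(x), d[1L] - 2); x0[d[1L] == 1] <- 0
  y0 <- pmin(floor(y), d[2L] - 2); y0[d[2L] == 1] <- 0
  z0 <- pmin(floor(z), d[3L] - 2); z0[d[3L] == 1] <- 0
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  # collapse degenerate axes (extent 1)
  if (d[1L] == 1) { x0 <- rep(0, length(x)); fx <- rep(0, length(x)) }
  if (d[2L] == 1) { y0 <- rep(0, length(y)); fy <- rep(0, length(y)) }
  if (d[3L] == 1) { z0 <- rep(0, length(z)); fz <- rep(0, length(z)) }
  sx <- 1L; sy <- d[1L]; sz <- d[1L] * d[2L]
  base <- 1 + x0 * sx + y0 * sy + z0 * sz
  dx <- if (d[1L] > 1) sx else 0L
  dy <- if (d[2L] > 1) sy else 0L
  dz <- if (d[3L] > 1) sz else 0L
  v000 <- arr[base];                v100 <- arr[base + dx]
  v010 <- arr[base + dy];           v110 <- arr[base + dx + dy]
  v001 <- arr[base + dz];           v101 <- arr[base + dx + dz]
  v011 <- arr[base + dy + dz];      v111 <- arr[base + dx + dy + dz]
  val <-
    v000 * (1 - fx) * (1 - fy) * (1 - fz) +
    v100 * fx       * (1 - fy) * (1 - fz) +
    v010 * (1 - fx) * fy       * (1 - fz) +
    v110 * fx       * fy       * (1 - fz) +
    v001 * (1 - fx) * (1 - fy) * fz +
    v101 * fx       * (1 - fy) * fz +
    v011 * (1 - fx) * fy       * fz +
    v111 * fx       * fy       * fz
  out[inside] <- val
  out
}

# Evaluate code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, code)
}

# Derive a child seed from a parent seed and a stream label, staying in
# 32-bit integer range.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Normalize rows of a matrix of 3-vectors.
normalize_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  m / n
}

# Check a 3x3 matrix is a proper rotation.
is_proper_rotation <- function(R, tol = 1e-8) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

# Rotation matrix about one of the coordinate axes (1, 2 or 3), angle in
# degrees.
rotation_about_axis <- function(axis, angle_deg) {
  th <- deg2rad(angle_deg)
  c2 <- cos(th); s2 <- sin(th)
  R <- diag(3)
  idx <- setdiff(1:3, axis)
  R[idx[1], idx[1]] <- c2; R[idx[1], idx[2]] <- -s2
  R[idx[2], idx[1]] <- s2; R[idx[2], idx[2]] <- c2
  R
}
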