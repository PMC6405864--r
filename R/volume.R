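#' Tomographic density volume
#'
#' The basic container every stage of the pipeline consumes: a 3D scalar
#' grid (higher values = denser material) with a physical voxel size in
#' nanometres, an anatomical axis tagging, and the position of voxel
#' (0,0,0) in scene coordinates.
#'
#' Coordinate convention: voxel-centred, 0-based indices; the position of
#' voxel index `i` (0-based) along an axis is `i * voxel_size_nm + origin_nm`.
#'
#' The `axes` tag maps grid dimensions to the anatomical directions of the
#' wood cell wall: `"L"` (longitudinal, along the fibre), `"T"`
#' (tangential, in the wall plane) and `"N"` (radial/normal, through the
#' wall thickness; the beam/thin-section direction). Re-tagging axes never
#' touches intensities.
#'
#' @param data numeric 3D array of densities.
#' @param voxel_size_nm positive voxel edge length(s) in nm; scalar or
#'   length-3 (one per grid dimension).
#' @param axes character(3), a permutation of `c("T","N","L")` giving the
#'   anatomical tag of each grid dimension.
#' @param origin_nm numeric(3), scene position of voxel (0,0,0) in nm.
#' @return an object of class `density_volume`.
#' @export
density_volume <- function(data, voxel_size_nm,
                           axes = c("T", "N", "L"),
                           origin_nm = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(dim(data) < 1L)) stop("all three extents must be >= 1 voxel")
  voxel_size_nm <- rep_len(as.numeric(voxel_size_nm), 3L)
  if (any(!is.finite(voxel_size_nm)) || any(voxel_size_nm <= 0))
    stop("voxel_size_nm must be positive on every axis")
  axes <- as.character(axes)
  if (!setequal(axes, c("T", "N", "L")) || length(axes) != 3L)
    stop("`axes` must be a permutation of c(\"T\",\"N\",\"L\")")
  structure(
    list(data = data, voxel_size_nm = voxel_size_nm, axes = axes,
         origin_nm = rep_len(as.numeric(origin_nm), 3L)),
    class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  cat(sprintf("<density_volume> %s voxels, %s nm/voxel, axes (%s)\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxel_size_nm, 4), collapse = ", "),
              paste(x$axes, collapse = ",")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.density_volume <- function(x) dim(x$data)

# Map an axis tag ("L"/"T"/"N") or dimension index to a dimension index.
axis_dim <- function(v, axis) {
  if (is.numeric(axis)) {
    axis <- as.integer(axis)
    if (axis < 1L || axis > 3L) stop("axis index out of range")
    return(axis)
  }
  i <- match(axis, v$axes)
  if (is.na(i)) stop(sprintf("no axis tagged '%s' in volume", axis))
  i
}

#' Read a tomographic volume from MRC or a multipage TIFF stack
#'
#' MRC2014 headers carry the pixel spacing; for TIFF stacks (no standard
#' voxel-size metadata) `voxel_size_nm` must be supplied explicitly.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"mrc"` or `"tiff"`.
#' @param voxel_size_nm voxel size in nm; overrides/los supplies header
#'   information. Required for TIFF.
#' @param axes anatomical axis tags (see [density_volume()]).
#' @return a [density_volume()].
#' @export
read_volume <- function(path, format = c("auto", "mrc", "tiff"),
                        voxel_size_nm = NULL,
                        axes = c("T", "N", "L")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mrc = , rec = , map = "mrc",
                     tif = , tiff = "tiff",
                     stop("cannot infer format from extension: ", ext))
  }
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "mrc") {
    m <- read_mrc(path)
    vs <- if (!is.null(voxel_size_nm)) rep_len(voxel_size_nm, 3L)
          else m$voxel_size_nm
    if (is.null(vs) || any(!is.finite(vs)) || any(vs <= 0))
      stop("MRC header has no usable pixel spacing; ",
           "supply `voxel_size_nm` explicitly")
    if (max(vs) - min(vs) > 1e-9 * max(vs) && length(axes) != 3L)
      stop("anisotropic voxel size requires an explicit `axes` mapping")
    density_volume(m$data, vs, axes = axes)
  } else {
    if (is.null(voxel_size_nm))
      stop("TIFF stacks carry no voxel size; `voxel_size_nm` is required")
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    d <- dim(pages[[1L]])
    arr <- array(0, c(d[1L], d[2L], length(pages)))
    for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
    density_volume(arr, voxel_size_nm, axes = axes)
  }
}

#' Write a volume to MRC (mode 2 float) or a multipage 32-bit float TIFF
#'
#' @param v a [density_volume()].
#' @param path output path; format inferred from the extension unless
#'   `format` is given.
#' @param format `"auto"`, `"mrc"` or `"tiff"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, format = c("auto", "mrc", "tiff")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mrc = , rec = , map = "mrc",
                     tif = , tiff = "tiff",
                     stop("cannot infer format from extension: ", ext))
  }
  if (format == "mrc") {
    write_mrc(v$data, path, voxel_size_nm = v$voxel_size_nm)
  } else {
    d <- dim(v$data)
    pages <- lapply(seq_len(d[3L]), function(k) v$data[, , k])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  }
  invisible(path)
}

# 1D Gaussian kernel, radius 4 sigma, normalised.
gauss_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-0.5 * ((-r):r / sigma_vox)^2)
  k / sum(k)
}

# Convolve a 3D array along one axis with reflective (mirror) boundaries.
conv_axis_reflect <- function(arr, axis, kernel) {
  d <- dim(arr)
  n <- d[axis]
  r <- (length(kernel) - 1L) %/% 2L
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = n)
  # reflective index: 1,2,...,n reflected at both ends (no edge repeat)
  refl <- function(i) {
    i <- abs(i - 1L)
    p <- i %% (2L * (n - 1L))
    ifelse(p >= n, 2L * (n - 1L) - p, p) + 1L
  }
  if (n == 1L) refl <- function(i) rep(1L, length(i))
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (j in seq_along(kernel)) {
    off <- j - r - 1L
    out <- out + kernel[j] * m[refl(seq_len(n) + off), , drop = FALSE]
  }
  aperm(array(out, d[perm]), order(perm))
}

#' Gaussian denoising of a density volume
#'
#' Separable Gaussian convolution with reflective boundary handling, so
#' total intensity is conserved. `sigma_nm = 0` returns the input
#' unchanged. The filter is linear and shift-equivariant.
#'
#' @param v a [density_volume()].
#' @param sigma_nm Gaussian standard deviation in nm (>= 0).
#' @return the filtered [density_volume()].
#' @export
gaussian_denoise <- function(v, sigma_nm) {
  if (!is.finite(sigma_nm) || sigma_nm < 0) stop("sigma_nm must be >= 0")
  if (sigma_nm == 0) return(v)
  arr <- v$data
  for (ax in 1:3) {
    s_vox <- sigma_nm / v$voxel_size_nm[ax]
    if (s_vox > 1e-12 && dim(arr)[ax] > 1L)
      arr <- conv_axis_reflect(arr, ax, gauss_kernel(s_vox))
  }
  out <- v
  out$data <- arr
  out
}

#' Crop a centred slab from a volume
#'
#' Emulates restricting analysis to the middle part of a tomogram along
#' the section-thickness direction. The centre voxel index follows the
#' `floor(extent/2)` convention and the slab is the half-open index range
#' `[centre - floor(t/2), centre + ceiling(t/2))` in voxels.
#'
#' @param v a [density_volume()].
#' @param thickness_nm slab thickness in nm (converted to voxels by
#'   rounding); must not exceed the extent along `axis`.
#' @param axis axis tag (`"N"` by default semantics of a thin section) or
#'   dimension index.
#' @return the cropped [density_volume()] (origin updated).
#' @export
crop_middle_slab <- function(v, thickness_nm, axis = "N") {
  ax <- axis_dim(v, axis)
  n <- dim(v$data)[ax]
  t_vox <- as.integer(round(thickness_nm / v$voxel_size_nm[ax]))
  if (t_vox < 1L) stop("thickness is below one voxel")
  if (t_vox > n) stop("slab thickness exceeds the volume extent")
  ctr <- n %/% 2L
  lo <- ctr - t_vox %/% 2L
  lo <- max(0L, min(lo, n - t_vox))
  idx <- seq.int(lo + 1L, lo + t_vox)
  sel <- list(seq_len(dim(v$data)[1L]), seq_len(dim(v$data)[2L]),
              seq_len(dim(v$data)[3L]))
  sel[[ax]] <- idx
  out <- v
  out$data <- v$data[sel[[1L]], sel[[2L]], sel[[3L]], drop = FALSE]
  out$origin_nm[ax] <- v$origin_nm[ax] + lo * v$voxel_size_nm[ax]
  out
}

#' Deterministic 1D tile origins for a square subvolume grid
#'
#' Tiles an extent with windows of a given side and fractional overlap.
#' The stride is `side * (1 - overlap)`; fractional strides are floored
#' to whole voxels (documented rounding rule). Tiles are emitted while
#' they fit entirely inside the extent.
#'
#' @param extent_vox integer extent in voxels.
#' @param side_vox window side in voxels (floored if fractional).
#' @param overlap overlap fraction in `[0, 1)`.
#' @return integer vector of 0-based tile origins.
#' @export
tile_grid <- function(extent_vox, side_vox, overlap = 0) {
  side <- as.integer(floor(side_vox))
  if (side < 3L) stop("tile side must be >= 3 voxels")
  if (side > extent_vox) stop("tile side larger than the extent")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  stride <- side * (1 - overlap)
  origins <- integer(0)
  i <- 0
  repeat {
    o <- as.integer(floor(i * stride))
    if (o + side > extent_vox) break
    origins <- c(origins, o)
    i <- i + 1
  }
  unique(origins)
}

#' Extract a grid of square subvolumes from a plane of the volume
#'
#' Tiles the chosen plane with squares of the given side (full depth on
#' the third axis). The side is interpreted in nm by default; the unit of
#' the historical "40.5" grid side is ambiguous, so `side_unit = "voxel"`
#' is supported as well. Overlapping tiles are permitted.
#'
#' @param v a [density_volume()].
#' @param side tile side length, in `side_unit`.
#' @param overlap overlap fraction in `[0, 1)`.
#' @param plane character(2) axis tags (or integer dims) spanning the
#'   tiled plane; default the two non-"N" axes.
#' @param side_unit `"nm"` (default) or `"voxel"`.
#' @return list of records, each with `spec` (a list: `origin_vox`
#'   0-based, `extent_vox`, `label`) and `volume` (a [density_volume()]).
#' @export
extract_subvolumes <- function(v, side, overlap = 0, plane = NULL,
                               side_unit = c("nm", "voxel")) {
  side_unit <- match.arg(side_unit)
  if (is.null(plane)) plane <- setdiff(v$axes, "N")
  dims <- vapply(plane, function(a) axis_dim(v, a), integer(1))
  if (length(unique(dims)) != 2L) stop("`plane` must name two distinct axes")
  d <- dim(v$data)
  side_vox <- vapply(dims, function(ax) {
    if (side_unit == "nm") floor(side / v$voxel_size_nm[ax]) else floor(side)
  }, numeric(1))
  o1 <- tile_grid(d[dims[1L]], side_vox[1L], overlap)
  o2 <- tile_grid(d[dims[2L]], side_vox[2L], overlap)
  third <- setdiff(1:3, dims)
  out <- vector("list", length(o1) * length(o2))
  k <- 1L
  for (b in o2) for (a in o1) {
    origin <- integer(3); extent <- d
    origin[dims[1L]] <- a; origin[dims[2L]] <- b; origin[third] <- 0L
    extent[dims[1L]] <- side_vox[1L]; extent[dims[2L]] <- side_vox[2L]
    sel <- lapply(1:3, function(i) seq.int(origin[i] + 1L, origin[i] + extent[i]))
    sub <- v
    sub$data <- v$data[sel[[1L]], sel[[2L]], sel[[3L]], drop = FALSE]
    sub$origin_nm <- v$origin_nm + origin * v$voxel_size_nm
    out[[k]] <- list(
      spec = list(origin_vox = origin, extent_vox = extent,
                  label = sprintf("tile_%03d", k)),
      volume = sub)
    k <- k + 1L
  }
  out
}

# TRUE if R is a signed permutation matrix (axis-aligned rotation).
is_signed_permutation <- function(R, tol = 1e-9) {
  all(abs(abs(R) * (abs(R) - 1)) < tol) &&
    all(abs(colSums(abs(R)) - 1) < tol) && all(abs(rowSums(abs(R)) - 1) < tol)
}

#' Rotate a volume by a rigid rotation, resampling on the original grid
#'
#' Used to approximately align fibrils with one of the grid axes before
#' fitting. Axis-aligned 90-degree rotations (signed permutation
#' matrices) are applied exactly by transposition/flipping; general
#' rotations are resampled with trilinear interpolation about the volume
#' centre, with out-of-field voxels filled with the volume median.
#' The identity is a bit-exact pass-through.
#'
#' @param v a [density_volume()].
#' @param rotation proper 3x3 rotation matrix (determinant +1) mapping
#'   source directions to target directions.
#' @return the rotated [density_volume()].
#' @export
rotate_to_axis <- function(v, rotation) {
  if (!is_proper_rotation(rotation))
    stop("`rotation` must be a proper rotation matrix (det = +1)")
  if (max(abs(rotation - diag(3))) < 1e-12) return(v)
  d <- dim(v$data)
  if (is_signed_permutation(rotation)) {
    Rr <- round(rotation)
    # For y = R x, output dim i draws from the input dim j with R[i, j] != 0;
    # aperm wants, for each output dim, that source dim.
    src_of_out <- apply(abs(Rr), 1L, which.max)
    arr <- aperm(v$data, src_of_out)
    for (i in 1:3) {
      if (Rr[i, src_of_out[i]] < 0) {
        idx <- list(seq_len(dim(arr)[1L]), seq_len(dim(arr)[2L]),
                    seq_len(dim(arr)[3L]))
        idx[[i]] <- rev(idx[[i]])
        arr <- arr[idx[[1L]], idx[[2L]], idx[[3L]], drop = FALSE]
      }
    }
    out <- v
    out$data <- arr
    out$voxel_size_nm <- v$voxel_size_nm[src_of_out]
    return(out)
  }
  # general rotation: inverse mapping about the centre, in nm coordinates
  ctr <- (d - 1) / 2
  idx <- as.matrix(expand.grid(x = seq_len(d[1L]) - 1,
                               y = seq_len(d[2L]) - 1,
                               z = seq_len(d[3L]) - 1))
  p_nm <- sweep(idx, 2L, ctr) * rep(v$voxel_size_nm, each = nrow(idx))
  src_nm <- p_nm %*% rotation  # = t(R^-1 %*% t(p)) since R^-1 = t(R)
  src_vox <- sweep(src_nm / rep(v$voxel_size_nm, each = nrow(idx)), 2L,
                   ctr, "+")
  fill <- stats::median(v$data)
  vals <- interp_trilinear(v$data, src_vox, outside = fill)
  out <- v
  out$data <- array(vals, d)
  out
}
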