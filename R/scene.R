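#' Synthetic phantom scenes with known fibril geometry
#'
#' Generates ground-truth fibril arrangements emulating the organisations
#' seen in the transition layer of the wood secondary cell wall:
#' parallel lattices, two families crossing at a symmetric angle to the
#' tangential plane, and bundles of 2-3 fibrils at near-contact
#' distance. Scenes are the oracle for every recovery experiment: the
#' same curves that are rendered into a phantom volume are available as
#' exact truth for the metrics module.
#'
#' Fibrils run nominally along the tangential (T) axis; lattice
#' positions live in the (L, N) plane. The direction of a fibril with
#' signed tangential-plane angle `tau` and in-plane deviation `lambda`
#' (from the T axis, toward L) is
#' `d = (cos(tau) sin(lambda), cos(tau) cos(lambda), sin(tau))` in
#' (L, T, N) components, so the angle with the longitudinal axis is
#' `90 - lambda` degrees and the signed angle with the tangential plane
#' is `tau`.
#'
#' @param arrangement `"parallel"`, `"crossed"`, `"bundled"` or
#'   `"tilted"` (parallel with alternating-sign tangential tilt and an
#'   optional mid-band spacing decrease).
#' @param n_fibrils number of fibrils (>= 1).
#' @param spacing_nm lattice spacing between neighbouring fibrils, nm.
#' @param tangential_deg magnitude of the signed angle with the
#'   tangential plane; applied as alternating +/- for `"tilted"`, as
#'   +/- family angles for `"crossed"`, 0-able for others.
#' @param longitudinal_jitter_deg SD of Gaussian in-plane angular
#'   jitter (deviation of the longitudinal angle from 90 degrees).
#' @param spacing_jitter_nm SD of Gaussian jitter on lattice positions.
#' @param bundle_fraction fraction of fibrils placed in bundles
#'   (`"bundled"` only).
#' @param bundle_size fibrils per bundle, 2 or 3.
#' @param contact_nm centre-to-centre distance of bundled / crossing
#'   fibrils; default `2 * tube_radius_nm` (touching tubes).
#' @param spacing_mid_nm optional reduced spacing in the middle band of
#'   the lattice (emulates a denser mid-layer); default `NULL` = uniform.
#' @param box_nm extents of the scene box in (dim1, dim2, dim3) = (T, N, L)
#'   order, nm.
#' @param tube_radius_nm fibril half-thickness, nm. Elementary fibrils
#'   are a few nm thick; the default radius is 1.75 nm.
#' @param fibril_intensity,matrix_intensity rendered densities of the
#'   fibril phase and the embedding matrix (fibrils are the denser
#'   phase, so `fibril_intensity > matrix_intensity`).
#' @param noise_sigma SD of additive Gaussian noise applied by
#'   [apply_noise()].
#' @param wedge optional missing-wedge model, a list with
#'   `tilt_min_deg`, `tilt_max_deg` (and unused `tilt_step_deg` kept for
#'   provenance); default the single-axis geometry -63..+63 degrees in
#'   3-degree steps.
#' @param seed integer RNG seed; identical seed + parameters give a
#'   bit-identical scene and volume.
#' @return an object of class `synthetic_scene` with `truth_curves`,
#'   the generation parameters, and `axes = c("T","N","L")`.
#' @export
make_scene <- function(arrangement = c("parallel", "crossed", "bundled",
                                       "tilted"),
                       n_fibrils = 9L,
                       spacing_nm = 10,
                       tangential_deg = 0,
                       longitudinal_jitter_deg = 0,
                       spacing_jitter_nm = 0,
                       bundle_fraction = 0,
                       bundle_size = 2L,
                       contact_nm = NULL,
                       spacing_mid_nm = NULL,
                       box_nm = c(57.6, 57.6, 43.2),
                       tube_radius_nm = 1.75,
                       fibril_intensity = 1,
                       matrix_intensity = 0,
                       noise_sigma = 0,
                       wedge = NULL,
                       seed = 1L) {
  arrangement <- match.arg(arrangement)
  n_fibrils <- as.integer(n_fibrils)
  if (n_fibrils < 1L) stop("n_fibrils must be >= 1")
  if (bundle_fraction < 0 || bundle_fraction > 1)
    stop("bundle_fraction must be in [0, 1]")
  if (!bundle_size %in% c(2L, 3L)) stop("bundle_size must be 2 or 3")
  if (spacing_nm <= 2 * tube_radius_nm)
    stop("spacing must exceed the fibril diameter")
  if (fibril_intensity <= matrix_intensity)
    stop("fibril_intensity must exceed matrix_intensity")
  if (is.null(contact_nm)) contact_nm <- 2 * tube_radius_nm

  # (T, N, L) box extents; fibrils run along T
  Tb <- box_nm[1L]; Nb <- box_nm[2L]; Lb <- box_nm[3L]
  margin <- tube_radius_nm * 2

  with_seed(derive_seed(seed, "scene"), {
    placements <- switch(
      arrangement,
      parallel = place_lattice(n_fibrils, spacing_nm, NULL, Lb, Nb, margin),
      tilted   = place_lattice(n_fibrils, spacing_nm, spacing_mid_nm,
                               Lb, Nb, margin),
      crossed  = place_crossed(n_fibrils, spacing_nm, contact_nm,
                               Lb, Nb, margin),
      bundled  = place_bundled(n_fibrils, spacing_nm, bundle_fraction,
                               bundle_size, contact_nm, Lb, Nb, margin))
    if (spacing_jitter_nm > 0) {
      placements$L <- placements$L +
        stats::rnorm(nrow(placements), 0, spacing_jitter_nm)
      placements$N <- placements$N +
        stats::rnorm(nrow(placements), 0, spacing_jitter_nm)
    }
    tau <- switch(arrangement,
      parallel = rep(tangential_deg, nrow(placements)),
      bundled  = rep(tangential_deg, nrow(placements)),
      tilted   = tangential_deg *
        rep_len(c(1, -1), nrow(placements)),
      crossed  = tangential_deg * placements$family_sign)
    lam <- if (longitudinal_jitter_deg > 0)
      stats::rnorm(nrow(placements), 0, longitudinal_jitter_deg)
    else rep(0, nrow(placements))

    curves <- vector("list", nrow(placements))
    for (i in seq_len(nrow(placements))) {
      curves[[i]] <- oriented_fibril(
        L0 = placements$L[i], N0 = placements$N[i],
        tau_deg = tau[i], lambda_deg = lam[i],
        t_extent = Tb, box_nm = box_nm)
    }
    structure(
      list(truth_curves = curves,
           arrangement = arrangement,
           n_fibrils = length(curves),
           spacing_nm = spacing_nm,
           spacing_mid_nm = spacing_mid_nm,
           tangential_deg = tangential_deg,
           longitudinal_jitter_deg = longitudinal_jitter_deg,
           spacing_jitter_nm = spacing_jitter_nm,
           bundle_fraction = bundle_fraction,
           bundle_size = bundle_size,
           contact_nm = contact_nm,
           n_bundled = sum(placements$bundled),
           bundled_flag = placements$bundled,
           box_nm = box_nm,
           tube_radius_nm = tube_radius_nm,
           fibril_intensity = fibril_intensity,
           matrix_intensity = matrix_intensity,
           noise_sigma = noise_sigma,
           wedge = wedge,
           axes = c("T", "N", "L"),
           seed = as.integer(seed)),
      class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %s, %d fibrils, spacing %.3g nm, seed %d\n",
              x$arrangement, x$n_fibrils, x$spacing_nm, x$seed))
  invisible(x)
}

# --- placement helpers (positions in the (L, N) plane, fibrils along T) ---

# near-square lattice; optional reduced spacing in the middle band along L
place_lattice <- function(n, spacing, spacing_mid, Lb, Nb, margin) {
  ncol_ <- max(1L, floor((Lb - 2 * margin) / spacing) + 1L)
  ncol_ <- min(ncol_, n)
  nrow_ <- ceiling(n / ncol_)
  gaps <- rep(spacing, ncol_ - 1L)
  if (!is.null(spacing_mid) && ncol_ >= 3L) {
    mid <- (length(gaps) + 1L) %/% 2L
    gaps[mid] <- spacing_mid
  }
  Lpos <- cumsum(c(0, gaps))
  Lpos <- Lpos - mean(Lpos) + Lb / 2
  Npos <- (seq_len(nrow_) - (nrow_ + 1) / 2) * spacing + Nb / 2
  grid <- expand.grid(L = Lpos, N = Npos)[seq_len(n), , drop = FALSE]
  grid$bundled <- FALSE
  grid$family_sign <- 1
  grid
}

# Two crossing families at near-contact distance. The two directions
# differ only in the sign of their tangential tilt, so their common
# perpendicular is the longitudinal axis: offsetting the second family
# by `contact` along L makes every crossing pair pass at exactly that
# distance.
place_crossed <- function(n, spacing, contact, Lb, Nb, margin) {
  nA <- ceiling(n / 2); nB <- n - nA
  Lpos <- function(k) (seq_len(k) - (k + 1) / 2) * spacing + Lb / 2
  data.frame(
    L = c(Lpos(nA) - contact / 2, Lpos(nB) + contact / 2),
    N = rep(Nb / 2, n),
    bundled = FALSE,
    family_sign = c(rep(1, nA), rep(-1, nB)))
}

# lattice with a fraction of fibrils doubled/tripled into contact bundles
place_bundled <- function(n, spacing, fraction, size, contact, Lb, Nb,
                          margin) {
  n_bundles <- round(n * fraction / size)
  n_bundled <- n_bundles * size
  n_hosts <- n - n_bundled + n_bundles  # lattice sites used
  base <- place_lattice(n_hosts, spacing, NULL, Lb, Nb, margin)
  out <- base[0, ]
  bi <- 0L
  for (i in seq_len(n_hosts)) {
    if (bi < n_bundles) {
      bi <- bi + 1L
      offs <- (seq_len(size) - (size + 1) / 2) * contact
      add <- data.frame(L = base$L[i], N = base$N[i] + offs,
                        bundled = TRUE, family_sign = 1)
      out <- rbind(out, add)
    } else {
      out <- rbind(out, data.frame(L = base$L[i], N = base$N[i],
                                   bundled = FALSE, family_sign = 1))
    }
  }
  rownames(out) <- NULL
  out
}

# straight fibril through (L0, N0) with signed tangential angle tau and
# in-plane deviation lambda, running along T across the box
oriented_fibril <- function(L0, N0, tau_deg, lambda_deg, t_extent, box_nm) {
  tau <- deg2rad(tau_deg); lam <- deg2rad(lambda_deg)
  # direction in volume (dim1, dim2, dim3) = (T, N, L)
  d <- c(cos(tau) * cos(lam), sin(tau), cos(tau) * sin(lam))
  # local z -> d; build an orthonormal frame (x, y, z)
  z <- d / sqrt(sum(d^2))
  x <- c(-z[2L], z[1L], 0)
  if (sqrt(sum(x^2)) < 1e-8) x <- c(1, 0, 0)
  x <- x / sqrt(sum(x^2))
  y <- c(z[2L] * x[3L] - z[3L] * x[2L],
         z[3L] * x[1L] - z[1L] * x[3L],
         z[1L] * x[2L] - z[2L] * x[1L])
  R <- cbind(x, y, z)
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  centre <- c(box_nm[1L] / 2, N0, L0)
  half <- t_extent / 2 - 0.5
  space_curve(t_range = c(-half, half),
              pose = list(R = R, t = centre))
}

#' Render a synthetic scene into a density volume
#'
#' Each fibril is rendered as a soft tube: the intensity at distance `d`
#' from the nearest centerline is
#' `matrix + (fibril - matrix) * profile(d / r)` with a raised-cosine
#' profile (`profile(0) = 1`, monotone decreasing, `profile(u) = 0` for
#' `u >= 1.5`), so the cost landscape seen by the optimizer is smooth.
#' Rendering is deterministic for fixed inputs and monotone in the
#' intensity parameters.
#'
#' @param scene a [make_scene()] object.
#' @param shape_vox integer triple, volume extents in voxels
#'   (dim order (T, N, L)); default covers `box_nm`.
#' @param voxel_size_nm voxel size, nm (default 0.9, a 2x-binned
#'   tomographic pixel).
#' @return a [density_volume()] (no noise, no wedge; see
#'   [apply_noise()] and [apply_missing_wedge()]).
#' @export
render_scene <- function(scene, shape_vox = NULL, voxel_size_nm = 0.9) {
  if (voxel_size_nm <= 0) stop("voxel size must be positive")
  if (is.null(shape_vox)) shape_vox <- round(scene$box_nm / voxel_size_nm)
  shape_vox <- as.integer(shape_vox)
  r <- scene$tube_radius_nm
  dist <- array(Inf, shape_vox)
  step <- voxel_size_nm / 3
  rad_vox <- ceiling(1.5 * r / voxel_size_nm) + 1L
  for (cv in scene$truth_curves) {
    s <- sample_curve(cv, step)
    pts_vox <- s$points / voxel_size_nm  # origin 0, voxel-centred
    for (k in seq_len(nrow(pts_vox))) {
      p <- pts_vox[k, ]
      lo <- pmax(floor(p) - rad_vox, 0)
      hi <- pmin(ceiling(p) + rad_vox, shape_vox - 1L)
      if (any(hi < lo)) next
      ix <- seq.int(lo[1L], hi[1L]); iy <- seq.int(lo[2L], hi[2L])
      iz <- seq.int(lo[3L], hi[3L])
      dx2 <- (ix - p[1L])^2; dy2 <- (iy - p[2L])^2; dz2 <- (iz - p[3L])^2
      d2 <- outer(outer(dx2, dy2, "+"), dz2, "+") * voxel_size_nm^2
      sub <- dist[ix + 1L, iy + 1L, iz + 1L, drop = FALSE]
      upd <- d2 < sub^2
      sub[upd] <- sqrt(d2[upd])
      dist[ix + 1L, iy + 1L, iz + 1L] <- sub
    }
  }
  u <- dist / r
  prof <- array(0, shape_vox)
  inside <- u < 1.5
  prof[inside] <- cos(pi * u[inside] / 3)^2
  arr <- scene$matrix_intensity +
    (scene$fibril_intensity - scene$matrix_intensity) * prof
  density_volume(arr, voxel_size_nm, axes = scene$axes)
}

#' Add seeded noise to a rendered phantom
#'
#' Additive Gaussian noise with the scene's `noise_sigma` (optionally
#' Poisson-scaled counting noise). The realisation is fully determined
#' by the scene seed. A signal-to-noise report (fibril-matrix contrast
#' over sigma) is attached as attribute `"snr"`.
#'
#' @param v a rendered [density_volume()].
#' @param scene the [make_scene()] object (for `noise_sigma` and seed).
#' @param poisson_scale optional counts-per-intensity-unit for Poisson
#'   noise before the Gaussian stage (`NULL` = off).
#' @return noisy [density_volume()].
#' @export
apply_noise <- function(v, scene, poisson_scale = NULL) {
  sigma <- scene$noise_sigma
  out <- v
  with_seed(derive_seed(scene$seed, "noise"), {
    if (!is.null(poisson_scale) && poisson_scale > 0) {
      lam <- pmax(out$data, 0) * poisson_scale
      out$data <- array(stats::rpois(length(lam), lam) / poisson_scale,
                        dim(out$data))
    }
    if (sigma > 0) {
      out$data <- out$data +
        array(stats::rnorm(length(out$data), 0, sigma), dim(out$data))
    }
  })
  contrast <- scene$fibril_intensity - scene$matrix_intensity
  attr(out, "snr") <- if (sigma > 0) contrast / sigma else Inf
  out
}

#' Emulate limited-tilt (missing-wedge) anisotropy
#'
#' Single-axis tomography samples projections over a limited tilt range
#' (here -63 to +63 degrees by default), leaving a wedge of Fourier
#' space unmeasured and elongating features along the beam axis. The
#' default implementation is a binary Fourier wedge mask: a spatial
#' frequency is kept iff the angle of its (in-plane, beam) component
#' pair relative to the specimen plane is within the tilt range. The
#' mask is idempotent, and a +/-90 degree range is an identity within
#' float tolerance.
#'
#' @param v a [density_volume()].
#' @param wedge list with `tilt_min_deg`, `tilt_max_deg` (degrees);
#'   default `list(tilt_min_deg = -63, tilt_max_deg = 63)`.
#' @param beam_axis axis tag of the beam direction (default `"N"`).
#' @param tilt_axis axis tag of the tilt axis (default `"T"`).
#' @return degraded [density_volume()].
#' @export
apply_missing_wedge <- function(v,
                                wedge = list(tilt_min_deg = -63,
                                             tilt_max_deg = 63),
                                beam_axis = "N", tilt_axis = "T") {
  if (wedge$tilt_min_deg >= wedge$tilt_max_deg)
    stop("degenerate wedge: tilt_min must be < tilt_max")
  bdim <- axis_dim(v, beam_axis)
  tdim <- axis_dim(v, tilt_axis)
  if (bdim == tdim) stop("beam and tilt axes must differ")
  pdim <- setdiff(1:3, c(bdim, tdim))  # in-plane axis swept by tilting
  d <- dim(v$data)
  freq_1d <- function(n) {
    k <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1))
    k / n
  }
  kb <- freq_1d(d[bdim]); kp <- freq_1d(d[pdim])
  # angle from the specimen plane of the (kp, kb) frequency component pair
  kb_full <- switch(bdim, array(kb, d),
                    array(rep(kb, each = d[1L]), d),
                    array(rep(kb, each = d[1L] * d[2L]), d))
  kp_full <- switch(pdim, array(kp, d),
                    array(rep(kp, each = d[1L]), d),
                    array(rep(kp, each = d[1L] * d[2L]), d))
  ang <- atan2(abs(kb_full), abs(kp_full))
  tmax <- deg2rad(max(abs(wedge$tilt_min_deg), abs(wedge$tilt_max_deg)))
  keep <- ang <= tmax + 1e-12
  F <- stats::fft(v$data)
  F[!keep] <- 0
  out <- v
  out$data <- array(Re(stats::fft(F, inverse = TRUE)) / length(F), d)
  out
}

#' Point-response anisotropy of a missing-wedge model
#'
#' Applies the wedge mask to a smoothed point impulse at the centre of a
#' cubic volume and returns the ratio of full-width-at-half-maximum
#' along the beam axis to that along the in-plane axis (sub-voxel, by
#' linear interpolation of the half-maximum crossings). A limited tilt
#' range gives a ratio above 1 (elongation along the beam); a full
#' +/-90-degree range gives exactly 1.
#'
#' @param wedge wedge model list (see [apply_missing_wedge()]).
#' @param n cubic volume side, voxels.
#' @param voxel_size_nm voxel size, nm.
#' @param sigma_nm pre-smoothing of the impulse so the half-maximum is
#'   resolvable on the grid.
#' @return list with `fwhm_beam_vox`, `fwhm_inplane_vox`, `ratio`.
#' @export
wedge_psf_anisotropy <- function(wedge, n = 48L, voxel_size_nm = 0.9,
                                 sigma_nm = 1.8) {
  n <- as.integer(n)
  ctr <- n %/% 2L + 1L
  imp <- array(0, c(n, n, n)); imp[ctr, ctr, ctr] <- 1
  v <- gaussian_denoise(density_volume(imp, voxel_size_nm), sigma_nm)
  w <- apply_missing_wedge(v, wedge)
  fwhm <- function(prof) {
    prof <- prof / max(prof)
    above <- which(prof >= 0.5)
    lo <- min(above); hi <- max(above)
    f1 <- if (lo > 1L) lo - 1 + (0.5 - prof[lo - 1L]) /
      (prof[lo] - prof[lo - 1L]) else lo
    f2 <- if (hi < length(prof)) hi + (prof[hi] - 0.5) /
      (prof[hi] - prof[hi + 1L]) else hi
    f2 - f1
  }
  beam <- fwhm(w$data[ctr, , ctr])     # N axis under default tagging
  inpl <- fwhm(w$data[ctr, ctr, ])     # L axis
  list(fwhm_beam_vox = beam, fwhm_inplane_vox = inpl,
       ratio = beam / inpl)
}

#' Convenience: scene -> rendered, noisy, wedge-degraded volume
#'
#' @param scene a [make_scene()] object.
#' @param voxel_size_nm voxel size, nm.
#' @param shape_vox optional volume shape in voxels.
#' @return a [density_volume()].
#' @export
scene_volume <- function(scene, voxel_size_nm = 0.9, shape_vox = NULL) {
  v <- render_scene(scene, shape_vox = shape_vox,
                    voxel_size_nm = voxel_size_nm)
  v <- apply_noise(v, scene)
  if (!is.null(scene$wedge)) v <- apply_missing_wedge(v, scene$wedge)
  v
}
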