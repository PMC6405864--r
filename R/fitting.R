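#' Configuration for model-based fibril fitting
#'
#' Controls the cost function, the particle-swarm global stage, the
#' Nelder-Mead simplex refinement, and the iterative multi-fibril
#' extraction. All randomness in a fit is driven by `rng_seed`, so a
#' fixed seed gives a deterministic run.
#'
#' @param n_particles swarm size.
#' @param pso_iterations swarm iterations.
#' @param inertia,cognitive,social standard PSO constriction weights.
#' @param simplex_tol,simplex_maxit Nelder-Mead relative tolerance and
#'   iteration cap for the refinement stage.
#' @param poly_degree degree of the polynomial deviation terms (1-5).
#'   Kept low so the polynomial cannot imitate the helix.
#' @param fit_helix also optimize the helicoidal term (radius, angular
#'   rate, phase)? Off by default: straight-tube phantoms and
#'   nearly-straight fibrils are fitted by the polynomial alone, and a
#'   degenerate helix (radius ~ 0) leaves its phase unidentifiable.
#' @param helix_radius_max_nm,helix_omega_range bounds of the helix
#'   parameters when `fit_helix = TRUE`.
#' @param slope_max bound on the linear coefficients (lateral drift per
#'   nm along the fit axis); 1.5 admits fibrils up to ~56 degrees from
#'   the fit axis.
#' @param curvature_max bound on the quadratic (and scaled cubic)
#'   coefficients, 1/nm.
#' @param n_cost_samples centerline samples used by [curve_cost()].
#' @param tube_sigma_nm radius of the cross-section averaging ring in
#'   the cost function, nm.
#' @param max_fibrils_per_subvolume cap on fibrils extracted by
#'   [fit_all()].
#' @param mask_radius_nm radius of the soft suppression mask applied
#'   around each accepted fibril before re-seeding.
#' @param accept_threshold minimum cost improvement over the background
#'   level, in multiples of the volume's robust noise scale.
#' @param fit_axis axis tag the curve parameter runs along (the axis
#'   fibrils were approximately aligned with).
#' @param seed_slice_step_vox slice spacing used by [seed_candidates()].
#' @param seed_peak_frac relative peak threshold for seeding (fraction
#'   of the robust intensity amplitude above background).
#' @param init_spread particle initialisation spread as a fraction of
#'   each parameter's bound range.
#' @param fixed_params optional named numeric vector pinning selected
#'   packed parameters (e.g. `c(cy1 = 0)`) to constants during
#'   optimization — useful for restricted fits and oracle comparisons.
#' @param rng_seed integer seed.
#' @return an object of class `fit_config`.
#' @export
fit_config <- function(n_particles = 24L,
                       pso_iterations = 40L,
                       inertia = 0.7298,
                       cognitive = 1.49618,
                       social = 1.49618,
                       simplex_tol = 1e-7,
                       simplex_maxit = 400L,
                       poly_degree = 2L,
                       fit_helix = FALSE,
                       helix_radius_max_nm = 3,
                       helix_omega_range = c(0.05, 1.0),
                       slope_max = 1.5,
                       curvature_max = 0.02,
                       n_cost_samples = 48L,
                       tube_sigma_nm = 1.2,
                       max_fibrils_per_subvolume = 15L,
                       mask_radius_nm = 3.5,
                       accept_threshold = 3,
                       fit_axis = "T",
                       seed_slice_step_vox = 4L,
                       seed_peak_frac = 0.35,
                       init_spread = 0.15,
                       fixed_params = NULL,
                       rng_seed = 1L) {
  stopifnot(n_particles >= 1L, pso_iterations >= 1L,
            poly_degree >= 1L, poly_degree <= 5L,
            n_cost_samples >= 2L, max_fibrils_per_subvolume >= 1L)
  structure(as.list(environment()), class = "fit_config")
}

# --- parameter vector <-> curve -----------------------------------------

# Bounds (and names) of the packed parameter vector for a volume.
# Layout: cx0..cxD, cy0..cyD [, a, omega, phi]
param_bounds <- function(v, cfg) {
  zdim <- axis_dim(v, cfg$fit_axis)
  od <- setdiff(1:3, zdim)
  ext <- (dim(v$data) - 1) * v$voxel_size_nm
  D <- cfg$poly_degree
  hi_coef <- cfg$curvature_max / c(1, 10, 100, 1000)[seq_len(max(0, D - 1))]
  lower <- c(0, -cfg$slope_max, -hi_coef)
  upper <- c(ext[od[1L]], cfg$slope_max, hi_coef)
  lower <- lower[seq_len(D + 1L)]; upper <- upper[seq_len(D + 1L)]
  lo <- c(lower, lower); hi <- c(upper, upper)
  lo[D + 2L] <- 0; hi[D + 2L] <- ext[od[2L]]
  nms <- c(paste0("cx", 0:D), paste0("cy", 0:D))
  if (cfg$fit_helix) {
    lo <- c(lo, 0, cfg$helix_omega_range[1L], -pi)
    hi <- c(hi, cfg$helix_radius_max_nm, cfg$helix_omega_range[2L], pi)
    nms <- c(nms, "a", "omega", "phi")
  }
  names(lo) <- nms; names(hi) <- nms
  list(lower = lo, upper = hi, zdim = zdim, odims = od,
       t_max = ext[zdim])
}

# Build the canonical fit pose: local z along the fit axis, local x and
# y along the remaining two grid axes (in index order).
fit_pose <- function(bounds) {
  R <- matrix(0, 3, 3)
  R[bounds$odims[1L], 1L] <- 1
  R[bounds$odims[2L], 2L] <- 1
  R[bounds$zdim, 3L] <- 1
  if (det(R) < 0) R[bounds$odims[2L], 2L] <- -1  # keep it proper
  R
}

params_to_curve <- function(par, bounds, cfg) {
  D <- cfg$poly_degree
  px <- par[seq_len(D + 1L)]
  py <- par[D + 1L + seq_len(D + 1L)]
  if (cfg$fit_helix) {
    a <- par[[2L * (D + 1L) + 1L]]
    w <- par[[2L * (D + 1L) + 2L]]
    ph <- par[[2L * (D + 1L) + 3L]]
  } else { a <- 0; w <- 0; ph <- 0 }
  R <- fit_pose(bounds)
  negy <- R[bounds$odims[2L], 2L] < 0
  if (negy) py <- -py
  space_curve(helix_radius_nm = a, helix_pitch_rad_per_nm = w,
              helix_phase_rad = ph, poly_x = px, poly_y = py,
              t_range = c(0, bounds$t_max),
              pose = list(R = R, t = c(0, 0, 0)))
}

# Least-squares projection of an arbitrary curve onto the packed
# parameterization (used to turn seeds into start vectors).
curve_to_params <- function(curve, bounds, cfg) {
  D <- cfg$poly_degree
  t <- seq(0, bounds$t_max, length.out = 64L)
  # sample the curve over the volume's z extent by inverting its own
  # parameter against the fit axis coordinate
  ts <- seq(curve$t_range[1L], curve$t_range[2L], length.out = 256L)
  pts <- curve_points(curve, ts)
  zc <- pts[, bounds$zdim]
  ord <- order(zc)
  x <- stats::approx(zc[ord], pts[ord, bounds$odims[1L]], xout = t,
                     rule = 2)$y
  y <- stats::approx(zc[ord], pts[ord, bounds$odims[2L]], xout = t,
                     rule = 2)$y
  basis <- outer(t, 0:D, "^")
  px <- stats::lm.fit(basis, x)$coefficients
  py <- stats::lm.fit(basis, y)$coefficients
  par <- c(px, py)
  if (cfg$fit_helix) par <- c(par, 1e-3, mean(cfg$helix_omega_range), 0)
  par[is.na(par)] <- 0
  names(par) <- names(bounds$lower)
  clamp_params(par, bounds)
}

clamp_params <- function(par, bounds) {
  pmin(pmax(par, bounds$lower), bounds$upper)
}

# --- cost function ------------------------------------------------------

# Robust background and noise-scale estimates for a volume.
volume_background <- function(v) stats::median(v$data)

volume_noise_scale <- function(v) {
  s <- stats::mad(as.vector(v$data))
  rng <- diff(range(v$data))
  max(s, 0.02 * rng, .Machine$double.eps)
}

#' Density cost of a space curve in a volume
#'
#' Negative mean of the density interpolated along the curve, each
#' centerline sample averaged over a small ring normal to the local
#' tangent (radius `tube_sigma_nm`, Gaussian weights), so the cost is
#' minimised when the curve runs along the centre of a dense tube.
#' Samples falling outside the volume contribute the robust background
#' estimate, so a curve is never rewarded for escaping the box. Linear
#' in the volume intensities and fully deterministic.
#'
#' @param curve a [space_curve()] in the volume's nm frame.
#' @param v a [density_volume()].
#' @param cfg a [fit_config()].
#' @param background background density for out-of-volume samples;
#'   default the volume median.
#' @return scalar cost (lower = denser = better).
#' @export
curve_cost <- function(curve, v, cfg = fit_config(), background = NULL) {
  if (is.null(background)) background <- volume_background(v)
  n <- cfg$n_cost_samples
  t <- seq(curve$t_range[1L], curve$t_range[2L], length.out = n)
  P <- curve_points(curve, t)
  Tg <- curve_tangent(curve, t)
  # ring offsets: two orthogonal normals per sample
  ref <- matrix(rep(c(1, 0, 0), each = n), n, 3L)
  swap <- abs(Tg[, 1L]) > 0.9
  ref[swap, ] <- matrix(rep(c(0, 1, 0), each = sum(swap)), ncol = 3L)
  n1 <- cbind(Tg[, 2L] * ref[, 3L] - Tg[, 3L] * ref[, 2L],
              Tg[, 3L] * ref[, 1L] - Tg[, 1L] * ref[, 3L],
              Tg[, 1L] * ref[, 2L] - Tg[, 2L] * ref[, 1L])
  n1 <- normalize_rows(n1)
  n2 <- cbind(Tg[, 2L] * n1[, 3L] - Tg[, 3L] * n1[, 2L],
              Tg[, 3L] * n1[, 1L] - Tg[, 1L] * n1[, 3L],
              Tg[, 1L] * n1[, 2L] - Tg[, 2L] * n1[, 1L])
  r <- cfg$tube_sigma_nm
  pts <- rbind(P, P + r * n1, P - r * n1, P + r * n2, P - r * n2)
  wts <- c(rep(1, n), rep(exp(-0.5), 4L * n))
  vox <- sweep(pts, 2L, v$origin_nm) / rep(v$voxel_size_nm,
                                           each = nrow(pts))
  vals <- interp_trilinear(v$data, vox, outside = NA_real_)
  if (all(is.na(vals[seq_len(n)])))
    stop("curve lies entirely outside the volume")
  vals[is.na(vals)] <- background
  -sum(vals * wts) / sum(wts)
}

# --- seeding ------------------------------------------------------------

# 2D local maxima of a matrix above a threshold (strict 8-neighbour).
peaks_2d <- function(m, thr) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3L || nc < 3L) return(cbind(i = integer(0), j = integer(0)))
  ctr <- m[2:(nr - 1L), 2:(nc - 1L)]
  ok <- ctr >= thr
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    ok <- ok & ctr > m[2:(nr - 1L) + di, 2:(nc - 1L) + dj]
  }
  w <- which(ok, arr.ind = TRUE)
  cbind(i = w[, 1L] + 1L, j = w[, 2L] + 1L)
}

smooth_2d <- function(m, sigma_vox = 1) {
  a <- array(m, c(dim(m), 1L))
  k <- gauss_kernel(sigma_vox)
  a <- conv_axis_reflect(a, 1L, k)
  a <- conv_axis_reflect(a, 2L, k)
  a[, , 1L]
}

#' Straight-line fibril seeds from transverse density maxima
#'
#' Takes slices perpendicular to the fit axis, detects local density
#' maxima in each (after light smoothing), and links maxima across
#' slices by nearest-neighbour tracking from the middle slice outward.
#' Tracks covering at least half the slices are least-squares fitted
#' with straight lines and ranked by the mean density along the seed.
#' A featureless (uniform) volume yields no maxima and an empty list.
#'
#' @param v a (denoised) [density_volume()].
#' @param cfg a [fit_config()].
#' @return list of [space_curve()] seeds, ranked best first, each with
#'   attributes `"params"` (packed start vector) and `"score"`.
#' @export
seed_candidates <- function(v, cfg = fit_config()) {
  bounds <- param_bounds(v, cfg)
  zdim <- bounds$zdim; od <- bounds$odims
  d <- dim(v$data)
  nz <- d[zdim]
  step <- max(2L, as.integer(cfg$seed_slice_step_vox))
  zidx <- unique(c(seq(1L, nz, by = step), nz))
  slice_of <- function(k) {
    sel <- list(seq_len(d[1L]), seq_len(d[2L]), seq_len(d[3L]))
    sel[[zdim]] <- k
    sl <- v$data[sel[[1L]], sel[[2L]], sel[[3L]]]
    m <- array(sl, d[od])
    smooth_2d(m, 1)
  }
  slices <- lapply(zidx, slice_of)
  bg <- stats::median(v$data)
  amp <- stats::quantile(unlist(lapply(slices, max)), 0.9, names = FALSE) - bg
  if (!is.finite(amp) || amp <= 0) return(list())
  thr <- bg + cfg$seed_peak_frac * amp
  pk <- lapply(slices, peaks_2d, thr = thr)
  mid <- which.min(abs(zidx - stats::median(zidx)))
  if (nrow(pk[[mid]]) == 0L) return(list())
  link_radius <- cfg$slope_max * step + 2.5
  n_slices <- length(zidx)
  tracks <- list()
  for (s in seq_len(nrow(pk[[mid]]))) {
    pos <- matrix(NA_real_, n_slices, 2L)
    pos[mid, ] <- pk[[mid]][s, ]
    for (dir in c(1L, -1L)) {
      cur <- pk[[mid]][s, ]
      vel <- c(0, 0)
      ks <- if (dir == 1L) seq(mid + 1L, n_slices) else seq(mid - 1L, 1L)
      if (mid + dir < 1L || mid + dir > n_slices) next
      misses <- 0L
      for (k in ks) {
        pred <- cur + vel
        cand <- pk[[k]]
        if (nrow(cand) > 0L) {
          dd <- sqrt((cand[, 1L] - pred[1L])^2 + (cand[, 2L] - pred[2L])^2)
          jbest <- which.min(dd)
        } else jbest <- integer(0)
        if (length(jbest) && dd[jbest] <= link_radius) {
          vel <- (cand[jbest, ] - cur) / 1
          cur <- cand[jbest, ]
          pos[k, ] <- cur
          misses <- 0L
        } else {
          cur <- pred
          misses <- misses + 1L
          if (misses >= 2L) break
        }
      }
    }
    hit <- !is.na(pos[, 1L])
    if (sum(hit) < max(3L, floor(0.5 * n_slices))) next
    z_nm <- (zidx[hit] - 1L) * v$voxel_size_nm[zdim]
    x_nm <- (pos[hit, 1L] - 1L) * v$voxel_size_nm[od[1L]]
    y_nm <- (pos[hit, 2L] - 1L) * v$voxel_size_nm[od[2L]]
    fx <- stats::lm.fit(cbind(1, z_nm), x_nm)$coefficients
    fy <- stats::lm.fit(cbind(1, z_nm), y_nm)$coefficients
    tracks[[length(tracks) + 1L]] <- c(fx, fy)
  }
  if (!length(tracks)) return(list())
  D <- cfg$poly_degree
  seeds <- lapply(tracks, function(tr) {
    par <- numeric(length(bounds$lower))
    names(par) <- names(bounds$lower)
    par[c("cx0", "cx1")] <- tr[1:2]
    par[c("cy0", "cy1")] <- tr[3:4]
    if (cfg$fit_helix) {
      par["a"] <- 1e-3
      par["omega"] <- mean(cfg$helix_omega_range)
    }
    par <- clamp_params(par, bounds)
    cv <- params_to_curve(par, bounds, cfg)
    attr(cv, "params") <- par
    cv
  })
  scores <- vapply(seeds, function(s)
    -curve_cost(s, v, cfg, background = bg), numeric(1))
  ord <- order(scores, decreasing = TRUE)
  seeds <- seeds[ord]; scores <- scores[ord]
  # de-duplicate seeds closer than half the mask radius
  keep <- logical(length(seeds))
  for (i in seq_along(seeds)) {
    dup <- FALSE
    if (any(keep)) {
      for (j in which(keep)) {
        md <- curve_min_distance(seeds[[i]], seeds[[j]], sampling_nm = 2,
                                 polish = FALSE)$mean_min
        if (md < cfg$mask_radius_nm / 2) { dup <- TRUE; break }
      }
    }
    keep[i] <- !dup
  }
  seeds <- seeds[keep]
  for (i in seq_along(seeds)) attr(seeds[[i]], "score") <- scores[keep][i]
  seeds
}

# --- single-fibril fit --------------------------------------------------

#' Fit one space curve to tomographic density
#'
#' Global particle-swarm search over the bounded parameter box
#' (particles initialised around the seed), followed by Nelder-Mead
#' simplex refinement of the swarm's best. The returned cost never
#' exceeds the swarm-stage cost, and the recorded history (best cost so
#' far, per iteration) is non-increasing.
#'
#' @param v a [density_volume()].
#' @param seed a [space_curve()] start (e.g. from [seed_candidates()]),
#'   or a packed parameter vector.
#' @param cfg a [fit_config()].
#' @param rng_label string mixed into the seed so successive fits in one
#'   run draw distinct, reproducible streams.
#' @return an object of class `fit_result`: `curve`, `params`, `cost`,
#'   `pso_cost`, `history`, `converged`, `improvement`,
#'   `background_cost`.
#' @export
fit_single <- function(v, seed, cfg = fit_config(), rng_label = "fit") {
  bounds <- param_bounds(v, cfg)
  bg <- volume_background(v)
  if (inherits(seed, "space_curve")) {
    par0 <- attr(seed, "params")
    if (is.null(par0)) par0 <- curve_to_params(seed, bounds, cfg)
  } else {
    par0 <- clamp_params(as.numeric(seed), bounds)
    names(par0) <- names(bounds$lower)
  }
  fixed <- cfg$fixed_params
  fixed_idx <- match(names(fixed), names(bounds$lower))
  if (anyNA(fixed_idx)) stop("unknown parameter name in fixed_params")
  pin <- function(p) {
    if (length(fixed_idx)) p[fixed_idx] <- fixed
    p
  }
  par0 <- pin(par0)
  D <- length(par0)
  rng <- bounds$upper - bounds$lower
  if (!is.null(fixed)) rng[names(fixed)] <- 0
  fn <- function(p) {
    # a particle whose curve leaves the volume entirely just scores the
    # background level (no reward, no crash)
    tryCatch(
      curve_cost(params_to_curve(clamp_params(pin(p), bounds), bounds, cfg),
                 v, cfg, background = bg),
      error = function(e) -bg)
  }
  res <- with_seed(derive_seed(cfg$rng_seed, rng_label), {
    np <- cfg$n_particles
    X <- matrix(rep(par0, each = np), np, D)
    if (np > 1L) {
      jit <- matrix(stats::runif(np * D, -1, 1), np, D) *
        rep(rng * cfg$init_spread, each = np)
      jit[1L, ] <- 0  # particle 1 is the seed itself
      X <- X + jit
      X <- pmin(pmax(X, rep(bounds$lower, each = np)),
                rep(bounds$upper, each = np))
    }
    V <- matrix(stats::runif(np * D, -1, 1), np, D) *
      rep(rng * cfg$init_spread / 4, each = np)
    cost <- apply(X, 1L, fn)
    Pb <- X; Pbc <- cost
    g <- which.min(cost)
    Gb <- X[g, ]; Gbc <- cost[g]
    history <- numeric(cfg$pso_iterations)
    for (it in seq_len(cfg$pso_iterations)) {
      r1 <- matrix(stats::runif(np * D), np, D)
      r2 <- matrix(stats::runif(np * D), np, D)
      V <- cfg$inertia * V +
        cfg$cognitive * r1 * (Pb - X) +
        cfg$social * r2 * (matrix(rep(Gb, each = np), np, D) - X)
      X <- X + V
      X <- pmin(pmax(X, rep(bounds$lower, each = np)),
                rep(bounds$upper, each = np))
      cost <- apply(X, 1L, fn)
      upd <- cost < Pbc
      Pb[upd, ] <- X[upd, ]; Pbc[upd] <- cost[upd]
      g <- which.min(Pbc)
      if (Pbc[g] < Gbc) { Gb <- Pb[g, ]; Gbc <- Pbc[g] }
      history[it] <- Gbc
    }
    list(Gb = Gb, Gbc = Gbc, history = history)
  })
  pso_cost <- res$Gbc
  op <- stats::optim(res$Gb, fn, method = "Nelder-Mead",
                     control = list(maxit = cfg$simplex_maxit,
                                    reltol = cfg$simplex_tol))
  if (op$value <= pso_cost) {
    final_par <- clamp_params(pin(op$par), bounds)
    final_cost <- op$value
  } else {
    final_par <- pin(res$Gb)
    final_cost <- pso_cost
  }
  names(final_par) <- names(bounds$lower)
  background_cost <- -bg
  improvement <- background_cost - final_cost
  noise_scale <- volume_noise_scale(v)
  structure(
    list(curve = params_to_curve(final_par, bounds, cfg),
         params = final_par,
         cost = final_cost,
         pso_cost = pso_cost,
         history = res$history,
         converged = improvement > cfg$accept_threshold * noise_scale,
         improvement = improvement,
         background_cost = background_cost,
         noise_scale = noise_scale,
         subvolume_label = ""),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> cost %.5g (swarm %.5g), improvement %.3g, converged: %s\n",
    x$cost, x$pso_cost, x$improvement, x$converged))
  invisible(x)
}

# Soft-suppress the density around a fitted curve (towards background),
# so re-seeding finds the remaining fibrils.
suppress_curve <- function(v, curve, mask_radius_nm, background) {
  d <- dim(v$data)
  step <- min(v$voxel_size_nm) / 2
  s <- sample_curve(curve, step)
  pts_vox <- sweep(s$points, 2L, v$origin_nm) /
    rep(v$voxel_size_nm, each = nrow(s$points))
  rad_vox <- ceiling(1.5 * mask_radius_nm / min(v$voxel_size_nm)) + 1L
  w <- array(0, d)
  for (k in seq_len(nrow(pts_vox))) {
    p <- pts_vox[k, ]
    lo <- pmax(floor(p) - rad_vox, 0)
    hi <- pmin(ceiling(p) + rad_vox, d - 1L)
    if (any(hi < lo)) next
    ix <- seq.int(lo[1L], hi[1L]); iy <- seq.int(lo[2L], hi[2L])
    iz <- seq.int(lo[3L], hi[3L])
    dx2 <- ((ix - p[1L]) * v$voxel_size_nm[1L])^2
    dy2 <- ((iy - p[2L]) * v$voxel_size_nm[2L])^2
    dz2 <- ((iz - p[3L]) * v$voxel_size_nm[3L])^2
    dd <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
    u <- dd / mask_radius_nm
    wk <- ifelse(u < 1.5, cos(pi * u / 3)^2, 0)
    sub <- w[ix + 1L, iy + 1L, iz + 1L, drop = FALSE]
    w[ix + 1L, iy + 1L, iz + 1L] <- pmax(sub, wk)
  }
  out <- v
  out$data <- v$data - (v$data - background) * w
  out
}

#' Iteratively extract all fibrils from a subvolume
#'
#' Greedy peel: fit the best-ranked seed, accept it if its cost
#' improvement over background passes the threshold and it does not
#' duplicate an already-accepted fibril, softly suppress its density,
#' re-seed, and repeat until the threshold fails, seeds are exhausted or
#' the fibril cap is reached.
#'
#' @param v a (denoised) [density_volume()].
#' @param cfg a [fit_config()].
#' @param label free-text subvolume label carried into results.
#' @return list of accepted [fit_single()] results (possibly empty).
#' @export
fit_all <- function(v, cfg = fit_config(), label = "") {
  bg <- volume_background(v)
  work <- v
  accepted <- list()
  for (round in seq_len(cfg$max_fibrils_per_subvolume + 3L)) {
    if (length(accepted) >= cfg$max_fibrils_per_subvolume) break
    seeds <- seed_candidates(work, cfg)
    if (!length(seeds)) break
    # drop seeds that sit on an already-accepted fibril
    if (length(accepted)) {
      ok <- vapply(seeds, function(s) {
        all(vapply(accepted, function(a)
          curve_min_distance(s, a$curve, sampling_nm = 2,
                             polish = FALSE)$mean_min >
            cfg$mask_radius_nm / 2, logical(1)))
      }, logical(1))
      seeds <- seeds[ok]
      if (!length(seeds)) break
    }
    fit <- fit_single(work, seeds[[1L]], cfg,
                      rng_label = paste0("fit", round))
    fit$subvolume_label <- label
    if (!fit$converged) break
    dup <- FALSE
    for (a in accepted) {
      if (curve_min_distance(fit$curve, a$curve, sampling_nm = 2,
                             polish = FALSE)$mean_min <=
          cfg$mask_radius_nm / 2) { dup <- TRUE; break }
    }
    if (!dup) accepted[[length(accepted) + 1L]] <- fit
    work <- suppress_curve(work, fit$curve, cfg$mask_radius_nm, bg)
  }
  accepted
}
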