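#' Orientation angles of a space curve
#'
#' The curve's mean unit tangent (average of analytic tangents at
#' quadrature nodes, renormalized) is compared with the anatomical
#' planes and axis of the cell wall. The tangent is canonicalized so
#' its largest-magnitude component is positive (a centerline has no
#' intrinsic direction). Reported angles:
#'
#' * `tangential_deg` — signed angle with the tangential (L-T) plane;
#'   the sign is the side of the plane (the N component's sign).
#' * `transverse_deg` — unsigned angle with the transverse plane
#'   (the plane perpendicular to L).
#' * `longitudinal_deg` — angle with the longitudinal axis, in
#'   `[0, 180)`; a fibril perpendicular to the fibre axis reads 90.
#'
#' @param curve a [space_curve()].
#' @param axes character(3) anatomical tags of the volume dimensions
#'   (see [density_volume()]).
#' @param n_nodes quadrature nodes for the mean tangent.
#' @return named list with the three angles (degrees) and the mean
#'   tangent (`tangent`, volume-frame components).
#' @export
orientation_angles <- function(curve, axes = c("T", "N", "L"),
                               n_nodes = 33L) {
  t <- seq(curve$t_range[1L], curve$t_range[2L], length.out = n_nodes)
  tg <- curve_tangent(curve, t)
  m <- colMeans(tg)
  m <- m / sqrt(sum(m^2))
  dom <- which.max(abs(m))
  if (m[dom] < 0) m <- -m
  comp <- function(tag) m[match(tag, axes)]
  dL <- comp("L"); dT <- comp("T"); dN <- comp("N")
  clamp1 <- function(x) pmin(pmax(x, -1), 1)
  list(tangential_deg = rad2deg(asin(clamp1(dN))),
       transverse_deg = rad2deg(asin(abs(clamp1(dL)))),
       longitudinal_deg = rad2deg(acos(clamp1(dL))),
       tangent = m)
}

#' Pairwise and nearest-neighbour distances for a curve set
#'
#' The pair distance is the symmetric mean-of-minima from
#' [curve_min_distance()]; the nearest neighbour of a curve is the
#' other curve minimising that pair distance. The contact matrix of
#' plain minima is kept for bundle detection.
#'
#' @param curves list of [space_curve()] (length >= 2).
#' @param sampling_nm arc sampling for distance evaluation.
#' @return data.frame with `curve`, `nn_distance_nm` / `nn_partner`
#'   (mean-of-minima functional, the statistic for parallel spacing) and
#'   `nn_min_distance_nm` / `nn_min_partner` (plain closest approach,
#'   the statistic under which crossing fibrils read as near-contact);
#'   attributes `"pair_mean"` and `"pair_min"` hold the full symmetric
#'   matrices.
#' @export
nearest_neighbor_distances <- function(curves, sampling_nm = 1) {
  n <- length(curves)
  if (n < 2L) stop("need at least two curves")
  M <- matrix(0, n, n); Mn <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    d <- curve_min_distance(curves[[i]], curves[[j]],
                            sampling_nm = sampling_nm)
    M[i, j] <- M[j, i] <- d$mean_min
    Mn[i, j] <- Mn[j, i] <- d$min
  }
  diag(M) <- Inf; diag(Mn) <- Inf
  nn <- apply(M, 1L, which.min)
  nnm <- apply(Mn, 1L, which.min)
  out <- data.frame(curve = seq_len(n),
                    nn_distance_nm = M[cbind(seq_len(n), nn)],
                    nn_partner = nn,
                    nn_min_distance_nm = Mn[cbind(seq_len(n), nnm)],
                    nn_min_partner = nnm)
  diag(M) <- 0; diag(Mn) <- 0
  attr(out, "pair_mean") <- M
  attr(out, "pair_min") <- Mn
  out
}

#' Summary statistics of fibril orientation angles
#'
#' Reports the median signed tangential-plane angle, the median of its
#' magnitudes (tilt magnitudes of either sign), counts per sign, and
#' the standard deviation of the longitudinal angles. The longitudinal
#' SD switches to a circular (axial) estimate when the spread exceeds
#' 30 degrees, where the linear formula would be biased by wrap-around.
#'
#' @param curves list of [space_curve()], or a list of angle lists from
#'   [orientation_angles()].
#' @param axes anatomical axis tags.
#' @return named list of summary statistics (degrees).
#' @export
angle_summary <- function(curves, axes = c("T", "N", "L")) {
  angs <- lapply(curves, function(x) {
    if (inherits(x, "space_curve")) orientation_angles(x, axes) else x
  })
  tang <- vapply(angs, `[[`, numeric(1), "tangential_deg")
  long <- vapply(angs, `[[`, numeric(1), "longitudinal_deg")
  spread <- diff(range(long))
  sd_long <- if (length(long) < 2L) 0
  else if (spread <= 30) stats::sd(long)
  else {
    th <- deg2rad(long) * 2  # axial doubling
    R <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
    rad2deg(sqrt(-2 * log(max(R, 1e-12)))) / 2
  }
  list(median_tangential_deg = stats::median(tang),
       median_abs_tangential_deg = stats::median(abs(tang)),
       mean_tangential_deg = mean(tang),
       n_positive = sum(tang > 0),
       n_negative = sum(tang < 0),
       mean_longitudinal_deg = mean(long),
       sd_longitudinal_deg = sd_long,
       n_curves = length(tang))
}

#' Detect fibril bundles from sustained near-contact proximity
#'
#' Two fibrils are linked when their distance profile stays within
#' `contact_nm` over at least `min_overlap_fraction` of the samples (in
#' both directions); bundles are the connected components of size >= 2
#' of the resulting graph. The bundled fraction is
#' `100 * bundled / total` percent, and is monotone non-decreasing in
#' `contact_nm`.
#'
#' @param curves list of [space_curve()].
#' @param contact_nm contact distance threshold, nm. The default used
#'   throughout the package is twice the tube radius plus one voxel.
#' @param min_overlap_fraction minimum fraction of samples within
#'   contact for a link.
#' @param sampling_nm arc sampling.
#' @return list with `bundle_id` (integer per curve, NA if unbundled),
#'   `bundles` (list of member index vectors), `bundle_fraction_percent`
#'   and the `contact_nm` used.
#' @export
detect_bundles <- function(curves, contact_nm = 4.4,
                           min_overlap_fraction = 0.5,
                           sampling_nm = 1) {
  if (contact_nm <= 0) stop("contact_nm must be positive")
  n <- length(curves)
  bundle_id <- rep(NA_integer_, n)
  if (n < 2L)
    return(list(bundle_id = bundle_id, bundles = list(),
                bundle_fraction_percent = 0, contact_nm = contact_nm))
  edges <- matrix(integer(0), ncol = 2L)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    d12 <- curve_min_distance(curves[[i]], curves[[j]],
                              sampling_nm = sampling_nm, polish = FALSE)
    d21 <- curve_min_distance(curves[[j]], curves[[i]],
                              sampling_nm = sampling_nm, polish = FALSE)
    f <- min(mean(d12$profile <= contact_nm),
             mean(d21$profile <= contact_nm))
    if (f >= min_overlap_fraction) edges <- rbind(edges, c(i, j))
  }
  if (nrow(edges)) {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    comp <- igraph::components(g)
    sizes <- tabulate(comp$membership)
    k <- 0L
    for (cid in which(sizes >= 2L)) {
      k <- k + 1L
      bundle_id[comp$membership == cid] <- k
    }
  }
  bundles <- split(which(!is.na(bundle_id)), bundle_id[!is.na(bundle_id)])
  list(bundle_id = bundle_id,
       bundles = unname(bundles),
       bundle_fraction_percent = 100 * sum(!is.na(bundle_id)) / n,
       contact_nm = contact_nm)
}

#' All per-curve and summary fibril descriptors
#'
#' One call computing the package's quantitative descriptors for a
#' fitted (or ground-truth) curve set: nearest-neighbour distances,
#' orientation angles, bundle membership, and their summaries.
#'
#' @param curves list of [space_curve()].
#' @param axes anatomical axis tags of the host volume.
#' @param sampling_nm arc sampling for distances.
#' @param contact_nm bundle contact threshold, nm.
#' @param min_overlap_fraction see [detect_bundles()].
#' @return object of class `fibril_metrics`: `per_curve` data.frame
#'   (angles, nn distance/partner, bundle id) and `summary` list
#'   (means/medians/SDs, bundle fraction, curve count).
#' @export
compute_metrics <- function(curves, axes = c("T", "N", "L"),
                            sampling_nm = 1, contact_nm = 4.4,
                            min_overlap_fraction = 0.5) {
  n <- length(curves)
  angs <- lapply(curves, orientation_angles, axes = axes)
  per <- data.frame(
    curve = seq_len(n),
    angle_tangential_deg = vapply(angs, `[[`, numeric(1), "tangential_deg"),
    angle_transverse_deg = vapply(angs, `[[`, numeric(1), "transverse_deg"),
    angle_longitudinal_deg = vapply(angs, `[[`, numeric(1),
                                    "longitudinal_deg"))
  if (n >= 2L) {
    nn <- nearest_neighbor_distances(curves, sampling_nm = sampling_nm)
    per$nn_distance_nm <- nn$nn_distance_nm
    per$nn_partner <- nn$nn_partner
    per$nn_min_distance_nm <- nn$nn_min_distance_nm
    per$nn_min_partner <- nn$nn_min_partner
    pair_mean <- attr(nn, "pair_mean")
  } else {
    per$nn_distance_nm <- NA_real_
    per$nn_partner <- NA_integer_
    per$nn_min_distance_nm <- NA_real_
    per$nn_min_partner <- NA_integer_
    pair_mean <- matrix(0, n, n)
  }
  bl <- detect_bundles(curves, contact_nm = contact_nm,
                       min_overlap_fraction = min_overlap_fraction,
                       sampling_nm = sampling_nm)
  per$bundle_id <- bl$bundle_id
  asum <- angle_summary(angs, axes)
  # mean nn over curves and over distinct nearest-neighbour pairs (the
  # historical "average nearest neighbour distance" could be either)
  mean_nn_pairs <- if (n >= 2L) {
    pair_ids <- unique(t(apply(cbind(per$curve, per$nn_partner), 1L, sort)))
    mean(pair_mean[pair_ids])
  } else NA_real_
  summary <- c(asum[setdiff(names(asum), "n_curves")],
    list(mean_nn_distance_nm = mean(per$nn_distance_nm),
         median_nn_distance_nm = stats::median(per$nn_distance_nm),
         sd_nn_distance_nm = stats::sd(per$nn_distance_nm),
         mean_nn_min_distance_nm = mean(per$nn_min_distance_nm),
         mean_nn_distance_pairs_nm = mean_nn_pairs,
         bundle_fraction_percent = bl$bundle_fraction_percent,
         contact_nm = bl$contact_nm,
         n_curves = n))
  structure(list(per_curve = per, summary = summary, bundles = bl$bundles),
            class = "fibril_metrics")
}

#' @export
print.fibril_metrics <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<fibril_metrics> %d curves | mean nn %.2f nm | median tangential %+.1f deg (|.| %.1f) | bundled %.1f%%\n",
    s$n_curves, s$mean_nn_distance_nm, s$median_tangential_deg,
    s$median_abs_tangential_deg, s$bundle_fraction_percent))
  invisible(x)
}

#' Spatial grid maps of fibril descriptors
#'
#' Assigns each curve to the grid cell containing its midpoint on the
#' chosen plane and aggregates per-cell means of the tangential and
#' transverse angles and the nearest-neighbour distance. The
#' count-weighted mean of cell values equals the global mean of the
#' assigned curves (conservation invariant).
#'
#' @param metrics a [compute_metrics()] result.
#' @param curves the curve list the metrics were computed on.
#' @param extent_nm numeric(2) plane extents, nm.
#' @param cell_side_nm grid cell side, nm (the classical analysis used
#'   squares of side 40.5 on the tomogram plane; the unit there is
#'   ambiguous, so the side is a free parameter here).
#' @param plane_dims integer(2), volume dims spanning the map plane
#'   (default `c(1, 3)`, the in-plane axes under the default tagging).
#' @return object of class `grid_map`: list of matrices
#'   (`mean_tangential`, `mean_transverse`, `mean_nn`, `count`) plus
#'   the cell geometry.
#' @export
grid_maps <- function(metrics, curves, extent_nm, cell_side_nm,
                      plane_dims = c(1L, 3L)) {
  if (cell_side_nm <= 0) stop("cell_side_nm must be positive")
  mids <- t(vapply(curves, function(cv)
    curve_points(cv, mean(cv$t_range))[1L, ], numeric(3)))
  u <- mids[, plane_dims[1L]]; w <- mids[, plane_dims[2L]]
  n1 <- max(1L, ceiling(extent_nm[1L] / cell_side_nm))
  n2 <- max(1L, ceiling(extent_nm[2L] / cell_side_nm))
  ci <- pmin(pmax(floor(u / cell_side_nm), 0), n1 - 1L) + 1L
  cj <- pmin(pmax(floor(w / cell_side_nm), 0), n2 - 1L) + 1L
  agg <- function(vals) {
    m <- matrix(NA_real_, n1, n2)
    s <- tapply(vals, list(factor(ci, 1:n1), factor(cj, 1:n2)), mean)
    m[] <- as.numeric(s)
    m
  }
  count <- matrix(0, n1, n2)
  tab <- table(factor(ci, 1:n1), factor(cj, 1:n2))
  count[] <- as.numeric(tab)
  structure(
    list(mean_tangential = agg(metrics$per_curve$angle_tangential_deg),
         mean_transverse = agg(metrics$per_curve$angle_transverse_deg),
         mean_nn = agg(metrics$per_curve$nn_distance_nm),
         count = count,
         cell_side_nm = cell_side_nm,
         plane_dims = plane_dims),
    class = "grid_map")
}

#' Match fitted fibrils against ground truth
#'
#' Optimal one-to-one assignment (Hungarian algorithm) between truth
#' and fitted curves minimising the summed symmetric mean curve
#' distance; assignments farther than `match_tol_nm` count as missed /
#' spurious rather than matched. Per-match centerline RMSD is the root
#' mean square of per-sample distances from the truth curve to the
#' fitted one.
#'
#' @param truth_curves list of ground-truth [space_curve()] (e.g.
#'   `scene$truth_curves`).
#' @param fits list of [fit_single()] results or of [space_curve()].
#' @param sampling_nm arc sampling.
#' @param match_tol_nm maximum pair distance for a valid match.
#' @return list with `matches` (data.frame: truth, fit, distance_nm,
#'   rmsd_nm, d_tangential_deg), `n_truth`, `n_fits`, `n_matched`,
#'   `n_missed`, `n_spurious`, `match_fraction`.
#' @export
recovery_report <- function(truth_curves, fits, sampling_nm = 0.5,
                            match_tol_nm = 3) {
  fit_curves <- lapply(fits, function(f)
    if (inherits(f, "fit_result")) f$curve else f)
  nt <- length(truth_curves); nf <- length(fit_curves)
  if (nt == 0L || nf == 0L)
    return(list(matches = data.frame(), n_truth = nt, n_fits = nf,
                n_matched = 0L, n_missed = nt, n_spurious = nf,
                match_fraction = 0))
  C <- matrix(0, nt, nf)
  for (i in seq_len(nt)) for (j in seq_len(nf)) {
    C[i, j] <- curve_min_distance(truth_curves[[i]], fit_curves[[j]],
                                  sampling_nm = sampling_nm,
                                  polish = FALSE)$mean_min
  }
  assign <- solve_assignment(C)
  rows <- list()
  for (i in seq_len(nt)) {
    j <- assign[i]
    if (is.na(j) || C[i, j] > match_tol_nm) next
    ts <- seq(truth_curves[[i]]$t_range[1L], truth_curves[[i]]$t_range[2L],
              length.out = 64L)
    tp <- curve_points(truth_curves[[i]], ts)
    fs <- sample_curve(fit_curves[[j]], sampling_nm)
    prof <- points_to_polyline_distance(tp, fs$points)
    at <- orientation_angles(truth_curves[[i]])
    af <- orientation_angles(fit_curves[[j]])
    rows[[length(rows) + 1L]] <- data.frame(
      truth = i, fit = j, distance_nm = C[i, j],
      rmsd_nm = sqrt(mean(prof^2)),
      d_tangential_deg = af$tangential_deg - at$tangential_deg)
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(truth = integer(0), fit = integer(0),
               distance_nm = numeric(0), rmsd_nm = numeric(0),
               d_tangential_deg = numeric(0))
  list(matches = matches,
       n_truth = nt, n_fits = nf,
       n_matched = nrow(matches),
       n_missed = nt - nrow(matches),
       n_spurious = nf - nrow(matches),
       match_fraction = nrow(matches) / nt)
}
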