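# Synthetic streamline phantoms: bundles sampled around parametric 3-D
# curves inside a small image grid, scalar volumes with planted
# along-tract profiles, waypoint/endpoint ROIs, probability maps,
# distractor streamlines, group profile tables, and learning-curve data.
# Every generator is a pure function of its seed.

#' Default phantom grid
#'
#' 60 x 60 x 60 voxels at 2 mm isotropic; voxel (0,0,0) centered at world
#' (0,0,0) mm, so the field of view spans 0..118 mm per axis.
#' @return list(dim, affine).
#' @keywords internal
phantom_grid <- function(shape = c(60L, 60L, 60L), voxel = 2) {
  affine <- diag(c(voxel, voxel, voxel, 1))
  list(dim = as.integer(shape), affine = affine)
}

# orthonormal frame normal to a tangent vector
normal_frame <- function(tangent) {
  t1 <- tangent / sqrt(sum(tangent^2))
  up <- if (abs(t1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  n1 <- up - sum(up * t1) * t1
  n1 <- n1 / sqrt(sum(n1^2))
  n2 <- c(t1[2] * n1[3] - t1[3] * n1[2],
          t1[3] * n1[1] - t1[1] * n1[3],
          t1[1] * n1[2] - t1[2] * n1[1])
  cbind(n1, n2)
}

#' Sample a bundle of streamlines around a parametric curve
#'
#' Each streamline is the curve evaluated at 100 parameter values, offset
#' by a per-streamline transverse displacement drawn from
#' Normal(0, spread^2) in the curve's normal plane, plus per-point
#' isotropic Gaussian noise. About half the streamlines are emitted in
#' reversed point order to stress orientation handling downstream.
#'
#' @param curve function mapping t in \[0, 1\] to a 3-vector (world mm).
#' @param n_streamlines number of streamlines (>= 1).
#' @param spread SD (mm) of the per-streamline transverse offset.
#' @param noise SD (mm) of per-point isotropic noise.
#' @param seed integer seed.
#' @param n_points points per streamline.
#' @param flip_prob probability a streamline is emitted reversed
#'   (default 0.5).
#' @return list of streamline matrices.
#' @export
make_bundle <- function(curve, n_streamlines, spread, noise, seed,
                        n_points = 100L, flip_prob = 0.5) {
  if (spread < 0 || noise < 0) stop("spread and noise must be >= 0")
  stopifnot(n_streamlines >= 1)
  tt <- seq(0, 1, length.out = n_points)
  base <- t(vapply(tt, curve, numeric(3)))
  # per-point normal frames from finite-difference tangents
  tangents <- rbind(base[2, ] - base[1, ],
                    base[-1, , drop = FALSE] - base[-n_points, , drop = FALSE])
  with_seed(seed, {
    lapply(seq_len(n_streamlines), function(s) {
      off <- stats::rnorm(2, sd = spread)
      pts <- base
      for (i in seq_len(n_points)) {
        fr <- normal_frame(tangents[i, ])
        pts[i, ] <- pts[i, ] + fr %*% off
      }
      if (noise > 0)
        pts <- pts + matrix(stats::rnorm(3 * n_points, sd = noise),
                            n_points, 3)
      if (stats::runif(1) < flip_prob) pts <- pts[n_points:1, , drop = FALSE]
      pts
    })
  })
}

# smoothed random-walk distractor streamlines filling the FOV
make_distractors <- function(n, grid, seed, n_points = 60L) {
  lo <- 6; hi <- (grid$dim - 1) * grid$affine[1, 1] - 6
  with_seed(seed, {
    lapply(seq_len(n), function(s) {
      start <- stats::runif(3, lo, hi[1])
      steps <- matrix(stats::rnorm(3 * (n_points - 1), sd = 2.5),
                      n_points - 1, 3)
      pts <- apply(rbind(start, steps), 2, cumsum)
      # light smoothing (edge NAs filled with the nearest smoothed value),
      # then clamp into the FOV
      for (k in 1:3) {
        sm <- as.numeric(stats::filter(pts[, k], rep(1 / 5, 5), sides = 2))
        valid <- which(!is.na(sm))
        sm[seq_len(valid[1] - 1)] <- sm[valid[1]]
        sm[seq(valid[length(valid)] + 1, length.out = length(sm) -
                 valid[length(valid)])] <- sm[valid[length(valid)]]
        pts[, k] <- pmin(pmax(sm, lo), hi[1])
      }
      pts
    })
  })
}

# spherical ROI mask around a world point
sphere_mask <- function(center, radius, grid, name = "roi") {
  dims <- grid$dim
  idx <- as.matrix(expand.grid(i = 0:(dims[1] - 1), j = 0:(dims[2] - 1),
                               k = 0:(dims[3] - 1)))
  centers <- voxel_to_world(idx, grid$affine)
  d2 <- rowSums(sweep(centers, 2, center)^2)
  data <- array(as.numeric(d2 <= radius^2), dim = dims)
  mask_volume(data, grid$affine, "roi", name)
}

#' Build a complete synthetic phantom
#'
#' Generates bundles around the supplied curves, paints scalar volumes so
#' voxels within a tube around bundle b's curve at parameter t hold the
#' planted profile value p_b(t), places waypoint ROIs at t = 0.25 and 0.75
#' and endpoint ROIs at t = 0 and 1, builds a smoothed-occupancy
#' probability map per bundle, adds distractor streamlines, and returns
#' the ground-truth labels.
#'
#' @param bundles list of bundle specs: each a list with `name`, `curve`
#'   (function \[0,1\] -> world mm), `n_streamlines`, `spread` (mm),
#'   `noise` (mm), and `profiles` (named list of functions t -> scalar
#'   value, one per metric).
#' @param n_distractors number of distractor streamlines.
#' @param seed integer seed.
#' @param grid phantom grid (default 60^3 voxels at 2 mm).
#' @param background background scalar value (default 0.1).
#' @param roi_radius ROI sphere radius in mm (default 6).
#' @return list with `tractogram`, `scalars` (named list of
#'   `scalar_volume`), `rois` (per bundle: `start`, `end`, `way1`, `way2`),
#'   `prob_maps` (per bundle), `truth` (character vector: bundle name or
#'   `"distractor"` per streamline), and `grid`.
#' @export
make_phantom <- function(bundles, n_distractors = 100L, seed = 1L,
                         grid = phantom_grid(), background = 0.1,
                         roi_radius = 6) {
  # pairwise curve separation warning
  if (length(bundles) >= 2L) {
    spreads <- vapply(bundles, `[[`, numeric(1), "spread")
    for (a in seq_along(bundles)) for (b in seq_along(bundles)) {
      if (a >= b) next
      ta <- seq(0, 1, length.out = 50)
      pa <- t(vapply(ta, bundles[[a]]$curve, numeric(3)))
      pb <- t(vapply(ta, bundles[[b]]$curve, numeric(3)))
      sep <- sqrt(max(min(outer(rowSums(pa^2), rowSums(pb^2), "+") -
                            2 * pa %*% t(pb)), 0))
      if (sep < 3 * max(spreads))
        warning(sprintf(
          "bundles '%s' and '%s' are closer than 3x the maximal spread; exact recognition not guaranteed",
          bundles[[a]]$name, bundles[[b]]$name), call. = FALSE)
    }
  }
  streamlines <- list()
  truth <- character(0)
  rois <- list()
  prob_maps <- list()
  metric_names <- unique(unlist(lapply(bundles, function(b)
    names(b$profiles))))
  scal_data <- lapply(metric_names, function(m)
    array(background, dim = grid$dim))
  names(scal_data) <- metric_names
  scal_dist <- lapply(metric_names, function(m) array(Inf, dim = grid$dim))
  names(scal_dist) <- metric_names
  voxel <- grid$affine[1, 1]
  for (bi in seq_along(bundles)) {
    b <- bundles[[bi]]
    sls <- make_bundle(b$curve, b$n_streamlines, b$spread, b$noise,
                       seed = seed + bi)
    streamlines <- c(streamlines, sls)
    truth <- c(truth, rep(b$name, b$n_streamlines))
    # ROIs at curve parameters
    rois[[b$name]] <- list(
      start = sphere_mask(b$curve(0), roi_radius, grid,
                          paste0(b$name, "_start")),
      end = sphere_mask(b$curve(1), roi_radius, grid,
                        paste0(b$name, "_end")),
      way1 = sphere_mask(b$curve(0.25), roi_radius, grid,
                         paste0(b$name, "_way1")),
      way2 = sphere_mask(b$curve(0.75), roi_radius, grid,
                         paste0(b$name, "_way2")))
    # paint planted profiles: nearest curve parameter within the tube
    tube <- 2 * max(b$spread, voxel)
    tt <- seq(0, 1, length.out = 400)
    cpts <- t(vapply(tt, b$curve, numeric(3)))
    r_vox <- ceiling(tube / voxel)
    for (ci in seq_along(tt)) {
      v0 <- round(world_to_voxel(cpts[ci, , drop = FALSE], grid$affine))
      rng <- lapply(1:3, function(k)
        max(0, v0[k] - r_vox):min(grid$dim[k] - 1, v0[k] + r_vox))
      box <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
      centers <- voxel_to_world(box, grid$affine)
      d <- sqrt(rowSums(sweep(centers, 2, cpts[ci, ])^2))
      keep <- d <= tube
      if (!any(keep)) next
      lin <- box[keep, 1] + grid$dim[1] *
        (box[keep, 2] + grid$dim[2] * box[keep, 3]) + 1
      for (m in names(b$profiles)) {
        closer <- d[keep] < scal_dist[[m]][lin]
        if (any(closer)) {
          scal_dist[[m]][lin[closer]] <- d[keep][closer]
          scal_data[[m]][lin[closer]] <- b$profiles[[m]](tt[ci])
        }
      }
    }
    # probability map: smoothed streamline occupancy
    occ <- array(0, dim = grid$dim)
    for (sl in sls) {
      v <- round_half_away(world_to_voxel(resample_streamline(sl, 100L),
                                          grid$affine))
      ok <- v[, 1] >= 0 & v[, 1] < grid$dim[1] &
            v[, 2] >= 0 & v[, 2] < grid$dim[2] &
            v[, 3] >= 0 & v[, 3] < grid$dim[3]
      lin <- v[ok, 1] + grid$dim[1] * (v[ok, 2] + grid$dim[2] * v[ok, 3]) + 1
      occ[lin] <- occ[lin] + 1
    }
    occ <- box_smooth3(occ)
    if (max(occ) > 0) occ <- occ / max(occ)
    prob_maps[[b$name]] <- mask_volume(occ, grid$affine, "prob",
                                       paste0(b$name, "_prob"))
  }
  if (n_distractors > 0L) {
    dstr <- make_distractors(n_distractors, grid, seed = seed + 1000L)
    streamlines <- c(streamlines, dstr)
    truth <- c(truth, rep("distractor", n_distractors))
  }
  tg <- tractogram(streamlines, grid$affine, grid$dim)
  scalars <- lapply(metric_names, function(m)
    scalar_volume(scal_data[[m]], grid$affine, m))
  names(scalars) <- metric_names
  list(tractogram = tg, scalars = scalars, rois = rois,
       prob_maps = prob_maps, truth = truth, grid = grid)
}

# 3^3 box mean filter (edge-truncated)
box_smooth3 <- function(a) {
  dims <- dim(a)
  out <- array(0, dims)
  cnt <- array(0, dims)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    xs <- max(1, 1 + dx):min(dims[1], dims[1] + dx)
    ys <- max(1, 1 + dy):min(dims[2], dims[2] + dy)
    zs <- max(1, 1 + dz):min(dims[3], dims[3] + dz)
    out[xs - dx, ys - dy, zs - dz] <- out[xs - dx, ys - dy, zs - dz] +
      a[xs, ys, zs]
    cnt[xs - dx, ys - dy, zs - dz] <- cnt[xs - dx, ys - dy, zs - dz] + 1
  }
  out / cnt
}

#' Default two-bundle phantom specification
#'
#' Two well-separated arcs inside the default grid, 60 streamlines each,
#' spread 1.5 mm, per-point noise 0.2 mm, with planted FA profiles
#' (`0.3 + 0.2 sin(pi t)` for the first bundle, a linear ramp for the
#' second).
#'
#' @return list of bundle specs suitable for [make_phantom()].
#' @export
default_phantom_bundles <- function() {
  arc1 <- function(t) c(30 + 25 * cos(pi * (1 - t)), 40 + 25 * sin(pi * (1 - t)), 40)
  arc2 <- function(t) c(30 + 25 * cos(pi * (1 - t)), 40 + 25 * sin(pi * (1 - t)), 80)
  list(
    list(name = "arc_low", curve = arc1, n_streamlines = 60L, spread = 1.5,
         noise = 0.2,
         profiles = list(FA = function(t) 0.3 + 0.2 * sin(pi * t))),
    list(name = "arc_high", curve = arc2, n_streamlines = 60L, spread = 1.5,
         noise = 0.2,
         profiles = list(FA = function(t) 0.25 + 0.3 * t)))
}

#' Waypoint/endpoint definitions for a phantom
#'
#' Builds a `bundle_definitions` from the ROIs the phantom generator
#' placed: both waypoints as inclusion ROIs (tolerance `tol`), plus start
#' and end ROIs.
#'
#' @param phantom result of [make_phantom()].
#' @param tol inclusion tolerance in mm (default 2).
#' @return a `bundle_definitions`.
#' @export
phantom_definitions <- function(phantom, tol = 2) {
  defs <- lapply(phantom$rois, function(r) {
    bundle_criteria(
      include = list(list(mask = r$way1, tol = tol),
                     list(mask = r$way2, tol = tol)),
      start = r$start, end = r$end)
  })
  bundle_definitions(defs)
}

#' Simulate a two-group tidy profile dataset
#'
#' Per subject, a smooth random base profile (low-order Fourier basis with
#' random coefficients) plus node-wise Gaussian noise; subjects of group 2
#' are shifted by `effect_size_sd * noise_sd` at the `effect_nodes`.
#' Age and sex covariates are drawn independently of group.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param n_nodes profile nodes (default 100).
#' @param effect_nodes integer node ids (0-based) carrying the planted
#'   group effect; may be empty for a global null.
#' @param effect_size_sd effect size in units of the node noise SD.
#' @param noise_sd node-wise noise SD.
#' @param seed integer seed.
#' @param tract_name,metric labels for the tidy rows.
#' @return list with `table` (tidy data.frame) and `covariates`
#'   (`subject_id, group, age, sex`).
#' @export
make_group_dataset <- function(n_per_group, n_nodes = 100L,
                               effect_nodes = integer(0),
                               effect_size_sd = 0, noise_sd = 0.05,
                               seed = 1L, tract_name = "CST_R",
                               metric = "FA") {
  if (n_per_group < 2L) stop("n_per_group must be >= 2")
  if (length(effect_nodes) &&
      (min(effect_nodes) < 0 || max(effect_nodes) > n_nodes - 1))
    stop("effect_nodes must lie in 0..n_nodes-1")
  with_seed(seed, {
    n_sub <- 2L * n_per_group
    subject_id <- sprintf("sub-%03d", seq_len(n_sub))
    group <- rep(c("control", "patient"), each = n_per_group)
    age <- stats::runif(n_sub, 20, 70)
    sex <- sample(c("F", "M"), n_sub, replace = TRUE)
    t_nodes <- seq(0, 1, length.out = n_nodes)
    rows <- vector("list", n_sub)
    for (s in seq_len(n_sub)) {
      coefs <- stats::rnorm(3, sd = c(0.05, 0.03, 0.02))
      base <- 0.45 + coefs[1] * sin(pi * t_nodes) +
        coefs[2] * cos(pi * t_nodes) + coefs[3] * sin(2 * pi * t_nodes)
      vals <- base + stats::rnorm(n_nodes, sd = noise_sd)
      if (group[s] == "patient" && length(effect_nodes))
        vals[effect_nodes + 1L] <- vals[effect_nodes + 1L] +
          effect_size_sd * noise_sd
      rows[[s]] <- data.frame(subject_id = subject_id[s],
                              tract_name = tract_name,
                              node_id = seq_len(n_nodes) - 1L,
                              metric = metric, value = vals,
                              stringsAsFactors = FALSE)
    }
    list(table = do.call(rbind, rows),
         covariates = data.frame(subject_id = subject_id, group = group,
                                 age = age, sex = sex,
                                 stringsAsFactors = FALSE))
  })
}

#' Simulate learning-curve data
#'
#' Scores follow the exponential learning-curve model evaluated at the
#' given sizes, plus Gaussian noise.
#'
#' @param alpha asymptotic score (must exceed `beta`).
#' @param beta score at the smallest size.
#' @param kappa rate parameter (> 0).
#' @param x_min smallest training size used by the model.
#' @param sizes training sizes (default: the canonical grid
#'   100, 175, 350, 700, 1000, 1453).
#' @param noise_sd score noise SD.
#' @param seed integer seed.
#' @return data.frame with columns `size`, `score`.
#' @export
make_learning_data <- function(alpha, beta, kappa, x_min = min(sizes),
                               sizes = c(100, 175, 350, 700, 1000, 1453),
                               noise_sd = 0, seed = 1L) {
  if (alpha <= beta) stop("alpha must exceed beta")
  if (kappa <= 0) stop("kappa must be positive")
  scores <- learning_curve(sizes, alpha, beta, kappa, x_min)
  if (noise_sd > 0)
    scores <- with_seed(seed, scores + stats::rnorm(length(sizes),
                                                    sd = noise_sd))
  data.frame(size = sizes, score = scores)
}
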