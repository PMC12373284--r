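# Set-level bundle cleaning: iterative Mahalanobis outlier removal and
# QuickBundles-threshold cleaning.

#' Parameters for Mahalanobis bundle cleaning
#'
#' Defaults follow the established tractometry cleaning settings: 100
#' cleaning nodes, distance threshold 3 (Mahalanobis units), length
#' threshold 4 (z-score units), at most 5 rounds, and never fewer than 20
#' retained streamlines.
#'
#' @param n_points nodes for cleaning-space resampling.
#' @param distance_threshold mean node-wise Mahalanobis distance above which
#'   a streamline is removed.
#' @param length_threshold absolute length z-score above which a streamline
#'   is removed.
#' @param clean_rounds maximum removal rounds.
#' @param min_sl minimum number of retained streamlines; a removal that
#'   would drop the bundle below this is skipped and cleaning stops.
#' @return an object of class `cleaning_params`.
#' @export
cleaning_params <- function(n_points = 100L, distance_threshold = 3,
                            length_threshold = 4, clean_rounds = 5L,
                            min_sl = 20L) {
  stopifnot(n_points >= 2, distance_threshold > 0, length_threshold > 0,
            clean_rounds >= 1, min_sl >= 1)
  structure(list(n_points = as.integer(n_points),
                 distance_threshold = distance_threshold,
                 length_threshold = length_threshold,
                 clean_rounds = as.integer(clean_rounds),
                 min_sl = as.integer(min_sl)),
            class = "cleaning_params")
}

# Flip-align every streamline of a resampled S x n x 3 array to the first
# one (minimize direct mean distance vs flipped); returns the array.
flip_align_array <- function(arr) {
  n <- dim(arr)[2]
  ref <- arr[1, , ]
  for (s in seq_len(dim(arr)[1])[-1]) {
    direct <- mean(sqrt(rowSums((arr[s, , ] - ref)^2)))
    flipped <- mean(sqrt(rowSums((arr[s, n:1, ] - ref)^2)))
    if (flipped < direct) arr[s, , ] <- arr[s, n:1, ]
  }
  arr
}

# Per-node 3x3 covariance of an S x 3 point cloud with ridge
# regularization proportional to the bundle spread, so exactly collinear
# clouds stay invertible. Population (1/n) normalization keeps node
# statistics exactly invariant under duplication of the bundle.
ridge_cov <- function(pts, ridge) {
  n <- nrow(pts)
  cv <- stats::cov(pts) * (n - 1) / n
  cv + diag(3) * ridge
}

# Mean over nodes of the node-wise Mahalanobis distance of every
# streamline; arr is S x n x 3 (flip-aligned).
mean_node_mahalanobis <- function(arr) {
  S <- dim(arr)[1]
  n <- dim(arr)[2]
  # scalar bundle spread^2: mean over nodes of the total node variance
  spread2 <- mean(vapply(seq_len(n), function(j)
    sum(diag(stats::cov(arr[, j, ]))), numeric(1)))
  ridge <- 1e-6 * spread2 + 1e-12
  d <- matrix(0, S, n)
  for (j in seq_len(n)) {
    pts <- arr[, j, ]
    mu <- colMeans(pts)
    cv <- ridge_cov(pts, ridge)
    d[, j] <- sqrt(stats::mahalanobis(pts, mu, cv))
  }
  rowMeans(d)
}

#' Mahalanobis bundle cleaning
#'
#' Iteratively removes streamlines that are unusually long or far from the
#' rest of the bundle. Per round, each streamline gets (a) a length
#' z-score against the current bundle and (b) the mean over nodes of its
#' node-wise Mahalanobis distance from the node-wise mean under the
#' node-wise (ridge-regularized) 3x3 covariance. Streamlines exceeding
#' either threshold are removed; iteration stops when nothing is removed,
#' `clean_rounds` is reached, or a removal would drop the bundle below
#' `min_sl` (that round is skipped).
#'
#' @param bundle nonempty list of streamlines (consistent orientation is
#'   established internally by flip-aligning to the first streamline).
#' @param params a `cleaning_params`.
#' @return integer indices (into the input order) of retained streamlines.
#' @export
mahalanobis_clean <- function(bundle, params = cleaning_params()) {
  if (!length(bundle)) stop("mahalanobis_clean: empty bundle")
  stopifnot(inherits(params, "cleaning_params"))
  kept <- seq_along(bundle)
  if (length(bundle) <= params$min_sl) {
    message(sprintf(
      "bundle of size %d at or below min_sl = %d: returned unchanged",
      length(bundle), params$min_sl))
    return(kept)
  }
  arr <- flip_align_array(bundle_array(bundle, params$n_points))
  lens <- vapply(bundle, streamline_length, numeric(1))
  for (round in seq_len(params$clean_rounds)) {
    cur <- arr[kept, , , drop = FALSE]
    if (length(kept) < 2L) break
    lz <- (lens[kept] - mean(lens[kept]))
    sdl <- stats::sd(lens[kept])
    lz <- if (sdl > 0) abs(lz / sdl) else rep(0, length(kept))
    md <- mean_node_mahalanobis(cur)
    bad <- md > params$distance_threshold | lz > params$length_threshold
    if (!any(bad)) break
    if (length(kept) - sum(bad) < params$min_sl) {
      message(sprintf(
        "skipping removal of %d streamline(s): would drop below min_sl = %d",
        sum(bad), params$min_sl))
      break
    }
    kept <- kept[!bad]
  }
  kept
}

#' QuickBundles-threshold cleaning
#'
#' Greedy single-pass clustering under the MDF distance with 12 comparison
#' points: streamlines are scanned in order and assigned to the first
#' cluster whose running centroid lies within `thresh_mm`, else a new
#' cluster is opened. Centroids are running means of resampled streamlines
#' flip-aligned to the centroid. The largest cluster is retained (ties go
#' to the earliest-created cluster).
#'
#' @param bundle nonempty list of streamlines.
#' @param thresh_mm positive clustering threshold in mm.
#' @param n_points resampling resolution for the MDF comparisons.
#' @return integer indices (input order) of the retained (largest) cluster.
#' @export
qb_threshold_clean <- function(bundle, thresh_mm, n_points = 12L) {
  if (!length(bundle)) stop("qb_threshold_clean: empty bundle")
  if (thresh_mm <= 0) stop("qb_threshold_clean: thresh_mm must be positive")
  n <- as.integer(n_points)
  arr <- bundle_array(bundle, n)
  centroids <- list()
  counts <- integer(0)
  members <- list()
  for (s in seq_along(bundle)) {
    pts <- arr[s, , ]
    placed <- FALSE
    for (k in seq_along(centroids)) {
      direct <- mean(sqrt(rowSums((pts - centroids[[k]])^2)))
      flipped <- mean(sqrt(rowSums((pts[n:1, ] - centroids[[k]])^2)))
      if (min(direct, flipped) <= thresh_mm) {
        aligned <- if (flipped < direct) pts[n:1, ] else pts
        centroids[[k]] <- (centroids[[k]] * counts[k] + aligned) /
          (counts[k] + 1)
        counts[k] <- counts[k] + 1L
        members[[k]] <- c(members[[k]], s)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroids[[length(centroids) + 1L]] <- pts
      counts <- c(counts, 1L)
      members[[length(members) + 1L]] <- s
    }
  }
  members[[which.max(counts)]]
}
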