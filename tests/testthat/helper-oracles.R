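# Independent oracles and small fixture builders used across tests.

# Explicit segment-walk arc-length resampler: for each target arc-length
# position, find the containing segment by a linear scan and interpolate
# within it. Shares no code with resample_streamline.
oracle_resample <- function(sl, n) {
  seg_len <- sqrt(rowSums(diff(sl)^2))
  cum <- c(0, cumsum(seg_len))
  L <- cum[length(cum)]
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    s <- (i - 1) * L / (n - 1)
    j <- 1L
    while (j < length(seg_len) && cum[j + 1] < s) j <- j + 1L
    frac <- if (seg_len[j] > 0) (s - cum[j]) / seg_len[j] else 0
    out[i, ] <- sl[j, ] + frac * (sl[j + 1, ] - sl[j, ])
  }
  out
}

# Per-point-loop MDF oracle.
oracle_mdf <- function(a, b, n) {
  ra <- oracle_resample(a, n)
  rb <- oracle_resample(b, n)
  direct <- 0; flipped <- 0
  for (i in seq_len(n)) {
    direct <- direct + sqrt(sum((ra[i, ] - rb[i, ])^2)) / n
    flipped <- flipped + sqrt(sum((ra[i, ] - rb[n + 1 - i, ])^2)) / n
  }
  min(direct, flipped)
}

# Brute-force min distance over all mask-voxel centers, including the
# inside test, mirroring the documented contract with plain loops.
oracle_min_distance <- function(points, mask) {
  idx <- which(mask$data != 0, arr.ind = TRUE) - 1
  inv <- solve(mask$affine)
  best <- Inf
  for (p in seq_len(nrow(points))) {
    v <- (inv %*% c(points[p, ], 1))[1:3]
    nearest <- sign(v) * floor(abs(v) + 0.5)
    for (r in seq_len(nrow(idx))) {
      if (all(nearest == idx[r, ])) return(0)
      center <- (mask$affine %*% c(idx[r, ], 1))[1:3]
      best <- min(best, sqrt(sum((points[p, ] - center)^2)))
    }
  }
  best
}

# Definitional BH step-up scan over all cutoffs.
oracle_bh <- function(pvals, alpha) {
  m <- length(pvals)
  ord <- order(pvals)
  k_best <- 0L
  for (k in seq_len(m)) {
    if (pvals[ord[k]] <= k * alpha / m) k_best <- k
  }
  rejected <- logical(m)
  if (k_best > 0) rejected[ord[seq_len(k_best)]] <- TRUE
  rejected
}

# Normal-equations OLS for one response vector.
oracle_ols <- function(X, y) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  resid <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(sigma2 * solve(t(X) %*% X)))
  list(beta = drop(beta), se = se, df = df)
}

# A random smooth polyline for property tests.
random_polyline <- function(n_pts, seed) {
  set.seed(seed)
  start <- runif(3, 10, 30)
  steps <- matrix(rnorm(3 * (n_pts - 1), sd = 3), n_pts - 1, 3)
  apply(rbind(start, steps), 2, cumsum)
}

# Straight-bundle fixture along +x at a given (y, z).
straight_bundle <- function(n_sl, y = 40, z = 40, spread = 1, noise = 0.2,
                            seed = 1) {
  make_bundle(function(t) c(20 + 60 * t, y, z), n_sl, spread, noise, seed)
}

# Small identity-affine test volume grid.
unit_grid_volume <- function(dims, fill = 0, name = "test") {
  scalar_volume(array(fill, dim = dims), diag(4), name)
}
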