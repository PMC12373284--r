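#' @keywords internal
"_PACKAGE"

# A streamline is a numeric matrix with 3 columns (x, y, z), world mm, RAS.
# Rows are ordered points along the trajectory.

#' Validate a streamline
#'
#' Checks that `sl` is a numeric matrix with 3 columns, at least 2 rows and
#' all-finite coordinates. Returns the matrix (with dimnames dropped)
#' invisibly so it can be used in pipelines.
#'
#' @param sl candidate streamline (n x 3 numeric matrix, world mm, RAS).
#' @return the validated matrix.
#' @keywords internal
as_streamline <- function(sl) {
  if (is.data.frame(sl)) sl <- as.matrix(sl)
  if (!is.matrix(sl) || !is.numeric(sl) || ncol(sl) != 3L)
    stop("a streamline must be a numeric matrix with 3 columns (x, y, z)")
  if (nrow(sl) < 2L)
    stop("degenerate streamline: fewer than 2 points")
  if (!all(is.finite(sl)))
    stop("streamline contains non-finite coordinates")
  dimnames(sl) <- NULL
  sl
}

#' Total streamline length
#'
#' Sum of Euclidean distances between consecutive points, in mm.
#'
#' @param sl streamline matrix (n x 3, world mm).
#' @return length in mm (scalar, >= 0).
#' @examples
#' streamline_length(rbind(c(0, 0, 0), c(3, 4, 0)))  # 5
#' @export
streamline_length <- function(sl) {
  sl <- as_streamline(sl)
  d <- diff(sl)
  sum(sqrt(rowSums(d * d)))
}

#' Reverse the point order of a streamline
#'
#' @param sl streamline matrix.
#' @return the streamline with rows in reverse order.
#' @export
flip_streamline <- function(sl) {
  sl <- as_streamline(sl)
  sl[rev(seq_len(nrow(sl))), , drop = FALSE]
}

#' Resample a streamline to a fixed number of equidistant points
#'
#' Points are placed on the piecewise-linear input curve at arc-length
#' positions \eqn{i L/(n-1)}, \eqn{i = 0, \ldots, n-1}, where L is the total
#' length. The first and last output points equal the input endpoints
#' exactly. Linear interpolation on the polyline, no smoothing.
#'
#' @param sl streamline matrix (>= 2 points).
#' @param n number of output points (default 100).
#' @return an n x 3 matrix.
#' @export
resample_streamline <- function(sl, n = 100L) {
  sl <- as_streamline(sl)
  if (!is.numeric(n) || length(n) != 1L || n < 2L)
    stop("n must be a single integer >= 2")
  n <- as.integer(n)
  seg <- diff(sl)
  s <- c(0, cumsum(sqrt(rowSums(seg * seg))))
  L <- s[length(s)]
  if (L <= 0)
    stop("degenerate streamline: zero total length")
  target <- seq(0, L, length.out = n)
  out <- matrix(0, n, 3L)
  for (k in 1:3) {
    out[, k] <- stats::approx(s, sl[, k], xout = target,
                              ties = "ordered", rule = 2)$y
  }
  out[1L, ] <- sl[1L, ]
  out[n, ] <- sl[nrow(sl), ]
  out
}

#' Minimum direct-flip (MDF) distance between two streamlines
#'
#' Both streamlines are resampled to `n` points; the distance is the smaller
#' of the mean pointwise Euclidean distance computed directly and after
#' reversing one streamline. Symmetric, non-negative, zero for identical
#' point sets up to a flip.
#'
#' @param a,b streamline matrices.
#' @param n number of comparison points (default 20).
#' @return distance in mm.
#' @export
mdf_distance <- function(a, b, n = 20L) {
  ra <- resample_streamline(a, n)
  rb <- resample_streamline(b, n)
  direct <- mean(sqrt(rowSums((ra - rb)^2)))
  flipped <- mean(sqrt(rowSums((ra - rb[rev(seq_len(n)), , drop = FALSE])^2)))
  min(direct, flipped)
}

#' Does a streamline cross the mid-sagittal plane?
#'
#' The midline is the plane x = 0 of world RAS space. A crossing requires a
#' strict sign change: the x coordinates must contain both a strictly
#' negative and a strictly positive value. Touching x = 0 does not count.
#'
#' @param sl streamline matrix (world mm, RAS).
#' @return logical scalar.
#' @export
crosses_midline <- function(sl) {
  sl <- as_streamline(sl)
  any(sl[, 1L] < 0) && any(sl[, 1L] > 0)
}

#' Fraction of a streamline's movement along each axis
#'
#' Movement is summed per segment: for axis a, the fraction is
#' \eqn{\sum_i |\Delta_{a,i}| / \sum_a \sum_i |\Delta_{a,i}|} over consecutive
#' point differences. The three fractions sum to 1.
#'
#' @param sl streamline matrix.
#' @return named numeric vector `c("L/R" = ., "P/A" = ., "I/S" = .)`
#'   corresponding to the x, y and z axes.
#' @export
primary_axis_fraction <- function(sl) {
  sl <- as_streamline(sl)
  d <- abs(diff(sl))
  tot <- colSums(d)
  denom <- sum(tot)
  if (denom <= 0)
    stop("degenerate streamline: zero total movement")
  stats::setNames(tot / denom, c("L/R", "P/A", "I/S"))
}

# Resample every streamline of a bundle to n points; returns an S x n x 3
# array (S streamlines).
bundle_array <- function(bundle, n = 100L) {
  stopifnot(length(bundle) >= 1L)
  arr <- array(0, dim = c(length(bundle), n, 3L))
  for (s in seq_along(bundle)) arr[s, , ] <- resample_streamline(bundle[[s]], n)
  arr
}
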