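# Volume containers. A scalar_volume is a list(data, affine, name); a
# mask_volume is a list(data, affine, kind) with kind "roi" (binary) or
# "prob" (values in [0,1]). The affine maps 0-based voxel indices to world
# mm of voxel centers (NIfTI convention).

#' Construct a scalar volume
#'
#' @param data 3-D numeric array of finite values.
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices map to
#'   world mm of voxel centers).
#' @param name metric label, e.g. "FA", "MD", "MK".
#' @return an object of class `scalar_volume`.
#' @export
scalar_volume <- function(data, affine, name = "scalar") {
  check_affine(affine)
  if (length(dim(data)) != 3L) stop("data must be a 3-D array")
  if (!all(is.finite(data))) stop("scalar volume contains non-finite values")
  structure(list(data = data, affine = affine, name = name),
            class = "scalar_volume")
}

#' Construct a mask volume (binary ROI or probability map)
#'
#' ROI masks are binarized (non-zero becomes 1); probability maps must lie
#' in \[0, 1\].
#'
#' @param data 3-D numeric array.
#' @param affine 4x4 voxel-to-world matrix.
#' @param kind `"roi"` (binary) or `"prob"` (probability map).
#' @param name optional label used in error messages.
#' @return an object of class `mask_volume`.
#' @export
mask_volume <- function(data, affine, kind = c("roi", "prob"), name = "mask") {
  kind <- match.arg(kind)
  check_affine(affine)
  if (length(dim(data)) != 3L) stop("data must be a 3-D array")
  if (kind == "roi") {
    data <- (data != 0) * 1
  } else if (any(data < 0 | data > 1)) {
    stop("probability map values must lie in [0, 1]")
  }
  structure(list(data = data, affine = affine, kind = kind, name = name),
            class = "mask_volume")
}

check_affine <- function(affine) {
  if (!is.matrix(affine) || !identical(dim(affine), c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  det3 <- det(affine[1:3, 1:3])
  if (!is.finite(det3) || abs(det3) < .Machine$double.eps)
    stop("affine is not invertible")
  invisible(affine)
}

# world mm (m x 3) -> continuous 0-based voxel coordinates (m x 3)
world_to_voxel <- function(points, affine) {
  points <- rbind(t(points), 1)
  v <- solve(affine) %*% points
  t(v[1:3, , drop = FALSE])
}

# 0-based voxel coordinates -> world mm
voxel_to_world <- function(vox, affine) {
  v <- rbind(t(vox), 1)
  w <- affine %*% v
  t(w[1:3, , drop = FALSE])
}

# round half away from zero, per element
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Sample a volume at world-mm points
#'
#' Points are mapped through the inverse affine and interpolated in voxel
#' space. Points falling outside the grid receive the fill value 0; their
#' count is attached as the `"n_outside"` attribute.
#'
#' @param vol a `scalar_volume` or `mask_volume`.
#' @param points m x 3 matrix of world-mm coordinates.
#' @param mode `"trilinear"` or `"nearest"`.
#' @return numeric vector of m sampled values with attribute `n_outside`.
#' @export
sample_volume <- function(vol, points, mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  dims <- dim(vol$data)
  v <- world_to_voxel(points, vol$affine)
  inside <- v[, 1] >= 0 & v[, 1] <= dims[1] - 1 &
            v[, 2] >= 0 & v[, 2] <= dims[2] - 1 &
            v[, 3] >= 0 & v[, 3] <= dims[3] - 1
  out <- numeric(nrow(v))
  if (any(inside)) {
    vi <- v[inside, , drop = FALSE]
    if (mode == "nearest") {
      idx <- round_half_away(vi) + 1  # to 1-based
      out[inside] <- vol$data[cbind(idx[, 1], idx[, 2], idx[, 3])]
    } else {
      i0 <- pmax(pmin(floor(vi), rep(dims - 1, each = nrow(vi)) - 1), 0)
      i1 <- pmin(i0 + 1, rep(dims - 1, each = nrow(vi)))
      f <- vi - i0
      acc <- numeric(nrow(vi))
      for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
        w <- (if (dx) f[, 1] else 1 - f[, 1]) *
             (if (dy) f[, 2] else 1 - f[, 2]) *
             (if (dz) f[, 3] else 1 - f[, 3])
        ix <- if (dx) i1[, 1] else i0[, 1]
        iy <- if (dy) i1[, 2] else i0[, 2]
        iz <- if (dz) i1[, 3] else i0[, 3]
        acc <- acc + w * vol$data[cbind(ix + 1, iy + 1, iz + 1)]
      }
      out[inside] <- acc
    }
  }
  attr(out, "n_outside") <- sum(!inside)
  out
}

# 1-based array indices of nonzero mask voxels, as an m x 3 matrix
mask_voxel_indices <- function(mask) {
  which(mask$data != 0, arr.ind = TRUE)
}

#' Minimum distance from a set of points to a binary mask
#'
#' Distance in world mm to the nearest mask-voxel center. A point whose
#' nearest integer voxel index (round half away from zero per axis, after
#' inverse affine) is itself a mask voxel is inside the mask: distance 0.
#'
#' @param points m x 3 world-mm matrix (typically the points of one
#'   streamline).
#' @param mask a `mask_volume`.
#' @return minimum distance in mm (0 if any point is inside).
#' @export
min_distance_to_mask <- function(points, mask) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  idx1 <- mask_voxel_indices(mask)
  if (nrow(idx1) == 0L)
    stop(sprintf("mask '%s' is empty", mask$name))
  dims <- dim(mask$data)
  v <- world_to_voxel(points, mask$affine)
  near <- round_half_away(v)
  ok <- near[, 1] >= 0 & near[, 1] < dims[1] &
        near[, 2] >= 0 & near[, 2] < dims[2] &
        near[, 3] >= 0 & near[, 3] < dims[3]
  if (any(ok)) {
    lin <- (near[ok, 1]) + dims[1] * (near[ok, 2] + dims[2] * near[ok, 3]) + 1
    if (any(mask$data[lin] != 0)) return(0)
  }
  centers <- voxel_to_world(idx1 - 1, mask$affine)
  # chunked min over the points x centers cross-distance
  best <- Inf
  step <- max(1L, floor(2e6 / nrow(centers)))
  for (start in seq(1L, nrow(points), by = step)) {
    p <- points[start:min(start + step - 1L, nrow(points)), , drop = FALSE]
    d2 <- outer(rowSums(p^2), rowSums(centers^2), "+") -
      2 * p %*% t(centers)
    best <- min(best, min(d2))
  }
  sqrt(max(best, 0))
}

#' Is each point inside a binary mask?
#'
#' Nearest-voxel membership: a point is inside iff its nearest integer voxel
#' index after inverse affine is a mask voxel.
#'
#' @param points m x 3 world-mm matrix.
#' @param mask a `mask_volume`.
#' @return logical vector of length m.
#' @export
points_in_mask <- function(points, mask) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  dims <- dim(mask$data)
  near <- round_half_away(world_to_voxel(points, mask$affine))
  ok <- near[, 1] >= 0 & near[, 1] < dims[1] &
        near[, 2] >= 0 & near[, 2] < dims[2] &
        near[, 3] >= 0 & near[, 3] < dims[3]
  res <- logical(nrow(points))
  if (any(ok)) {
    lin <- (near[ok, 1]) + dims[1] * (near[ok, 2] + dims[2] * near[ok, 3]) + 1
    res[ok] <- mask$data[lin] != 0
  }
  res
}

#' Read a NIfTI file as a scalar volume
#'
#' @param path path to a .nii or .nii.gz file.
#' @param name metric label; defaults to the file stem.
#' @return a `scalar_volume`.
#' @export
read_scalar_volume <- function(path, name = NULL) {
  img <- RNifti::readNifti(path)
  if (is.null(name))
    name <- sub("\\.nii(\\.gz)?$", "", basename(path))
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  scalar_volume(as.array(img)[, , , drop = TRUE], aff, name)
}

#' Read a NIfTI file as a mask volume
#'
#' @inheritParams read_scalar_volume
#' @param kind `"roi"` or `"prob"`.
#' @return a `mask_volume`.
#' @export
read_mask_volume <- function(path, kind = c("roi", "prob"), name = NULL) {
  kind <- match.arg(kind)
  img <- RNifti::readNifti(path)
  if (is.null(name))
    name <- sub("\\.nii(\\.gz)?$", "", basename(path))
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  mask_volume(as.array(img)[, , , drop = TRUE], aff, kind, name)
}

#' Write a volume to NIfTI
#'
#' @param vol a `scalar_volume` or `mask_volume`.
#' @param path destination .nii or .nii.gz path.
#' @return the path, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  # store the geometry in the sform only: RNifti's qform replacement does
  # not fold scale factors into pixdim, and a zeroed qform at equal code
  # precedence would shadow the sform after a disk round-trip
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
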