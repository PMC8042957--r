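# Longitudinal reslicing: estimate the implant long axis, then sample 2D
# grayscale planes containing that axis at chosen rotation angles.

#' Estimate the implant long axis from a volume
#'
#' The axis is the principal direction (largest-spread eigenvector of the
#' coordinate covariance) of all voxels at or above the implant intensity
#' threshold, through their centroid. This replaces the manual marker-based
#' alignment used when reslicing interactively. The direction is
#' sign-normalized so its z (stack) component is positive; for an axis
#' perpendicular to the stack direction, the first nonzero component is
#' made positive.
#'
#' @param v A \linkS4class{CTVolume}.
#' @param implantThreshold Intensity at or above which a voxel counts as
#'   implant (default 200 on the 8-bit scale; titanium reconstructs far
#'   brighter than bone).
#' @return An \linkS4class{ImplantAxis} (point and direction in voxel
#'   units, (x, y, z) order).
#' @export
estimateAxis <- function(v, implantThreshold = 200) {
  stopifnot(is(v, "CTVolume"))
  idx <- which(voxels(v) >= implantThreshold, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    stop("no implant found: no voxels at or above intensity ",
         implantThreshold)
  }
  # arr.ind columns follow array order (z, y, x); geometry uses (x, y, z)
  pts <- cbind(idx[, 3], idx[, 2], idx[, 1]) - 1
  ctr <- colMeans(pts)
  cv <- stats::cov(pts)
  eg <- eigen(cv, symmetric = TRUE)
  dir <- eg$vectors[, 1]
  dir <- dir / sqrt(sum(dir^2))
  if (dir[3] < 0) dir <- -dir
  if (dir[3] == 0) {
    nz <- which(dir != 0)[1]
    if (length(nz) && dir[nz] < 0) dir <- -dir
  }
  new("ImplantAxis", point = as.numeric(ctr), direction = as.numeric(dir))
}

# Radial basis for a plane at `angleDeg` about axis direction d: e1 is the
# +x direction made perpendicular to d (the 0-degree reference), e2 = d x e1.
.radialBasis <- function(d) {
  ref <- c(1, 0, 0)
  if (abs(sum(ref * d)) > 1 - 1e-9) ref <- c(0, 1, 0)
  e1 <- ref - sum(ref * d) * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Extract a longitudinal grayscale slice through the implant axis
#'
#' Samples the volume on a regular grid in the plane containing the
#' implant axis at rotation \code{angleDeg} about it (0 degrees = the +x
#' radial direction; \code{angleOffsetDeg} maps an external angular
#' reference, e.g. a histology plane, onto volume coordinates). Pixels are
#' obtained by trilinear interpolation of the grayscale volume at
#' voxel-size spacing -- interpolation happens before any thresholding.
#' Rows span the implant bounding box along the axis plus a 10% margin
#' (row 1 at the implant top); columns span the whole volume radially,
#' with the nominal angle on the positive side. Samples outside the
#' volume take intensity 0. When the axis direction is grid-aligned the
#' sampling origin is snapped to the voxel lattice, so orthogonal slices
#' reproduce coordinate planes exactly.
#'
#' @param v A \linkS4class{CTVolume}.
#' @param axis An \linkS4class{ImplantAxis}.
#' @param angleDeg Plane angle in [0, 360).
#' @param angleOffsetDeg Constant added to \code{angleDeg} when forming
#'   the radial direction (default 0).
#' @param implantThreshold Threshold used to find the implant bounding box
#'   along the axis.
#' @return A \linkS4class{CTSlice}.
#' @export
extractLongitudinalSlice <- function(v, axis, angleDeg, angleOffsetDeg = 0,
                                     implantThreshold = 200) {
  stopifnot(is(v, "CTVolume"), is(axis, "ImplantAxis"))
  if (!is.numeric(angleDeg) || length(angleDeg) != 1L || is.na(angleDeg) ||
      angleDeg < 0 || angleDeg >= 360) {
    stop("angleDeg must lie in [0, 360)")
  }
  d <- axis@direction
  p0 <- axis@point
  # exact trigonometry at multiples of 90 so orthogonal planes stay on grid
  th <- (angleDeg + angleOffsetDeg) / 180
  b <- .radialBasis(d)
  radial <- cospi(th) * b$e1 + sinpi(th) * b$e2

  snapped <- max(abs(abs(d) - c(0, 0, 1))) < 1e-9 ||
             max(abs(abs(d) - c(0, 1, 0))) < 1e-9 ||
             max(abs(abs(d) - c(1, 0, 0))) < 1e-9
  if (snapped) p0 <- round(p0)

  vox <- voxels(v)
  idx <- which(vox >= implantThreshold, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("no implant voxels above threshold; cannot set slice extent")
  pts <- cbind(idx[, 3], idx[, 2], idx[, 1]) - 1
  s <- as.numeric((pts - matrix(p0, nrow(pts), 3, byrow = TRUE)) %*% d)
  sLo <- floor(min(s) - 0.1 * diff(range(s)))
  sHi <- ceiling(max(s) + 0.1 * diff(range(s)))
  sGrid <- sLo:sHi

  dm <- dim(vox)
  corners <- as.matrix(expand.grid(x = c(0, dm[3] - 1), y = c(0, dm[2] - 1),
                                   z = c(0, dm[1] - 1)))
  tMax <- ceiling(max(abs((corners - matrix(p0, 8, 3, byrow = TRUE)) %*%
                            radial)))
  tGrid <- (-tMax):tMax

  grid <- expand.grid(srow = sGrid, tcol = tGrid)
  P <- matrix(p0, nrow(grid), 3, byrow = TRUE) +
    outer(grid$srow, d) + outer(grid$tcol, radial)
  val <- .trilinear(vox, P, outside = 0)
  px <- matrix(val, nrow = length(sGrid), ncol = length(tGrid))

  new("CTSlice", pixels = px, pixelSizeUm = voxelSize(v),
      angleDeg = angleDeg,
      origin = p0 + sLo * d - tMax * radial,
      basisAxial = d, basisRadial = radial)
}
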