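# Synthetic implant-in-bone phantom generator with analytic ground truth.
#
# The implant is modeled as an axis-aligned threaded cylinder: a core
# cylinder plus annular thread rings at pitch spacing (crest thickness =
# half the pitch). Rings rather than a true helix make the thread profile
# identical in every longitudinal plane, so the per-plane ground-truth BIC
# is exact. Bone fills a surrounding shell; where the contact map says
# "no contact", a gap of 3 background voxels separates bone from the
# implant surface so that the prescribed pattern survives discretization.

.CREST_FRACTION <- 0.5   # crest axial thickness as a fraction of pitch
.CONTACT_GAP_VX <- 3     # background gap (voxels) at no-contact surface
.GRANULE_ZONE_UM <- 400  # granules occupy this shell around the implant

# Geometry of a phantom in voxel units; returns $error instead of failing
# so PhantomConfig validity can report it.
.phantomGeometry <- function(cfg) {
  vs <- cfg@voxelSizeUm
  rOut <- (cfg@implantDiameterUm / 2) / vs
  rCore <- rOut - cfg@threadDepthUm / vs
  pitch <- cfg@threadPitchUm / vs
  crest <- pitch * .CREST_FRACTION
  boneR <- cfg@boneOuterRadiusUm / vs
  Lr <- round(cfg@implantLengthUm / vs)          # core extent in voxel rows
  if (pitch < 2 || crest < 1 || rCore < 2) {
    return(list(error = "thread geometry too fine for this voxel size"))
  }
  nRings <- floor((Lr - crest) / pitch) + 1
  nGrooves <- nRings - 1
  shape <- cfg@volumeShape
  if (any(is.na(shape))) {
    margin <- 12L
    nxy <- 2L * (ceiling(boneR) + 7L)
    shape <- c(Lr + 2L * margin, nxy, nxy)      # (z, y, x)
  }
  shape <- as.integer(shape)
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  cx <- floor(nx / 2); cy <- floor(ny / 2)      # 0-based center indices
  z0 <- floor((nz - Lr) / 2)
  fit <- cx - rOut >= 2 && nx - 1 - cx - rOut >= 2 &&
         cy - rOut >= 2 && ny - 1 - cy - rOut >= 2 &&
         z0 >= 2 && z0 + Lr - 1 <= nz - 3
  if (!fit) {
    return(list(error = "implant does not fit in the volume with a 2-voxel margin"))
  }
  ringTop <- z0 + (seq_len(nRings) - 1) * pitch
  list(vs = vs, rOut = rOut, rCore = rCore, pitch = pitch, crest = crest,
       boneR = boneR, Lr = Lr, nRings = nRings, nGrooves = nGrooves,
       shape = shape, cx = cx, cy = cy, z0 = z0,
       ringTop = ringTop, ringBot = ringTop + crest - 1,
       gap = .CONTACT_GAP_VX)
}

# Euclidean voxel-center distance from (rho, z) to the implant voxel set.
# `rho` may be a matrix (one z slab at a time); z is scalar (voxel rows).
.distToImplant <- function(rho, z, geo) {
  dzc <- max(0, geo$z0 - z, z - (geo$z0 + geo$Lr - 1))
  dCore <- sqrt(pmax(rho - geo$rCore, 0)^2 + dzc^2)
  az <- min(pmax(0, pmax(geo$ringTop - z, z - geo$ringBot)))
  dRing <- sqrt(pmax(rho - geo$rOut, 0)^2 + az^2)
  pmin(dCore, dRing)
}

# Groove cell index for axial position z (voxel rows); crest rows are split
# at their midline between the two adjacent grooves.
.grooveOfZ <- function(z, geo) {
  g <- floor((z - geo$z0 - geo$crest / 2) / geo$pitch) + 1
  pmin(pmax(g, 1), geo$nGrooves)
}

#' Construct and validate a phantom configuration
#'
#' Defaults describe the emulated study conditions: a 4 mm diameter,
#' 8.5 mm long threaded implant at 20 um isotropic resolution, with class
#' intensity means background 20, bone 75 (the center of the 60-90 bone
#' threshold window) and implant 230. Thread pitch (800 um) and depth
#' (320 um) are generator choices typical of a dental implant; the thread
#' is modeled as annular rings so every longitudinal plane sees the same
#' profile. Artifact parameters (noise, halo, granules) are applied only
#' by \code{\link{addArtifacts}}.
#'
#' @param implantDiameterUm,implantLengthUm Implant outer diameter and
#'   length (micrometres).
#' @param threadDepthUm,threadPitchUm Thread groove depth and crest pitch.
#' @param boneOuterRadiusUm Outer radius of the bone shell.
#' @param volumeShape Integer (z, y, x) dimensions, or NA to derive from
#'   the geometry.
#' @param voxelSizeUm Isotropic voxel size.
#' @param intensityMeans Named vector (background, bone, implant).
#' @param noiseSd Gaussian noise SD used by \code{addArtifacts}.
#' @param haloWidthVoxels,haloIntensity Residual beam-hardening halo: shell
#'   width around the implant and the brightness floor applied inside it.
#' @param granuleCount,granuleRadiusUm Ceramic granule confound (0 = none).
#' @param seed Seed for granule placement and noise.
#' @return A validated \linkS4class{PhantomConfig}.
#' @examples
#' cfg <- phantomConfig(voxelSizeUm = 80)
#' cfg
#' @export
phantomConfig <- function(implantDiameterUm = 4000,
                          implantLengthUm = 8500,
                          threadDepthUm = 320,
                          threadPitchUm = 800,
                          boneOuterRadiusUm = 2600,
                          volumeShape = NA,
                          voxelSizeUm = 20,
                          intensityMeans = c(background = 20, bone = 75,
                                             implant = 230),
                          noiseSd = 5,
                          haloWidthVoxels = 1,
                          haloIntensity = 75,
                          granuleCount = 0,
                          granuleRadiusUm = 30,
                          seed = 1) {
  new("PhantomConfig",
      implantDiameterUm = implantDiameterUm,
      implantLengthUm = implantLengthUm,
      threadDepthUm = threadDepthUm,
      threadPitchUm = threadPitchUm,
      boneOuterRadiusUm = boneOuterRadiusUm,
      volumeShape = as.numeric(volumeShape),
      voxelSizeUm = voxelSizeUm,
      intensityMeans = intensityMeans,
      noiseSd = noiseSd,
      haloWidthVoxels = haloWidthVoxels,
      haloIntensity = haloIntensity,
      granuleCount = granuleCount,
      granuleRadiusUm = granuleRadiusUm,
      seed = seed)
}

setMethod("show", "PhantomConfig", function(object) {
  geo <- .phantomGeometry(object)
  cat(sprintf(
    "PhantomConfig: implant %g x %g mm, pitch %g um, voxel %g um\n",
    object@implantDiameterUm / 1000, object@implantLengthUm / 1000,
    object@threadPitchUm, object@voxelSizeUm))
  cat(sprintf("  volume %d x %d x %d (z,y,x); %d thread rings, %d grooves per side\n",
              geo$shape[1], geo$shape[2], geo$shape[3], geo$nRings,
              geo$nGrooves))
})

#' Sample a random contact map with a prescribed global contact fraction
#'
#' For each groove ring, \code{round(targetFraction * granularity)} of the
#' angular sectors are marked as contact, chosen by a seeded random
#' permutation. The permutation is drawn once per groove and truncated, so
#' for a fixed seed the contact set is nested in the target fraction:
#' raising the target never removes contact anywhere (monotonicity).
#'
#' @param targetFraction Desired global contact fraction in [0, 1]; the
#'   realized fraction is within half a sector width of the target.
#' @param granularity Number of angular sectors (>= 4); default 36
#'   (10-degree sectors).
#' @param nGrooves Number of groove rings (default 10, matching the
#'   default implant geometry).
#' @param seed Integer seed; the map is reproducible for a fixed seed.
#' @return A \linkS4class{ContactMap}.
#' @examples
#' cm <- sampleContactMap(0.5, granularity = 36, seed = 7)
#' rowSums(contactMatrix(cm))  # 18 contact sectors per groove ring
#' @export
sampleContactMap <- function(targetFraction, granularity = 36, nGrooves = 10,
                             seed = 1) {
  if (!is.numeric(targetFraction) || length(targetFraction) != 1L ||
      is.na(targetFraction) || targetFraction < 0 || targetFraction > 1) {
    stop("targetFraction must lie in [0, 1]")
  }
  if (granularity < 4) stop("granularity must be >= 4")
  k <- round(targetFraction * granularity)
  contact <- .withSeed(seed, {
    t(vapply(seq_len(nGrooves), function(g) {
      perm <- sample.int(granularity)
      s <- logical(granularity)
      if (k > 0) s[perm[seq_len(k)]] <- TRUE
      s
    }, logical(granularity)))
  })
  new("ContactMap", contact = contact)
}

# Analytic ground truth from the contact map alone. All grooves share the
# same profile arc length (annular-ring thread), so pooling over grooves
# reduces to an unweighted mean of the per-cell indicators.
.analyticTruth <- function(cm, geo, angles, groovesPerSide, angleOffsetDeg) {
  contact <- contactMatrix(cm)
  nSec <- ncol(contact)
  sw <- 360 / nSec
  sectorOf <- function(a) floor((a %% 360) / sw) + 1
  gps <- groovesPerSide
  if (gps > nrow(contact)) {
    stop("groovesPerSide exceeds the grooves of the contact map")
  }
  rows <- list()
  perPlane <- numeric(length(angles))
  for (i in seq_along(angles)) {
    th <- angles[i] + angleOffsetDeg
    sR <- sectorOf(th); sL <- sectorOf(th + 180)
    g <- seq_len(gps)
    bicR <- 100 * as.numeric(contact[g, sR])
    bicL <- 100 * as.numeric(contact[g, sL])
    rows[[i]] <- data.frame(
      angle_deg = angles[i],
      side = rep(c("right", "left"), each = gps),
      groove = c(g, g),
      bic_percent = c(bicR, bicL))
    perPlane[i] <- mean(c(bicR, bicL))
  }
  list(perGroove = do.call(rbind, rows),
       perPlane = data.frame(angle_deg = angles, bic_percent = perPlane),
       meanBIC = mean(perPlane))
}

#' Analytic ground-truth BIC of a contact map
#'
#' Computes the per-groove, per-plane, and multi-angle mean BIC that a
#' noise-free, artifact-free phantom built from \code{cm} carries, without
#' building the volume. Per-plane values pool the upper
#' \code{groovesPerSide} grooves of both sides (all grooves share the same
#' profile arc length under the annular-ring thread model).
#'
#' @param cm A \linkS4class{ContactMap}.
#' @param cfg A \linkS4class{PhantomConfig} (fixes the groove geometry).
#' @param angles Plane angles in degrees.
#' @param groovesPerSide Number of upper grooves per side entering the
#'   per-plane value (default 4).
#' @param angleOffsetDeg Offset added to all angles before sector lookup.
#' @return A \linkS4class{PhantomTruth}.
#' @export
groundTruthBIC <- function(cm, cfg, angles = c(0, 45, 90, 135),
                           groovesPerSide = 4, angleOffsetDeg = 0) {
  geo <- .phantomGeometry(cfg)
  if (nrow(contactMatrix(cm)) != geo$nGrooves) {
    stop("contact map has ", nrow(contactMatrix(cm)),
         " grooves but the geometry provides ", geo$nGrooves)
  }
  tr <- .analyticTruth(cm, geo, angles, groovesPerSide, angleOffsetDeg)
  new("PhantomTruth", perGroove = tr$perGroove, perPlane = tr$perPlane,
      meanBIC = tr$meanBIC, contactMap = cm, config = cfg)
}

#' Build a noise-free phantom volume with its analytic ground truth
#'
#' Rasterizes the threaded implant and the bone shell prescribed by the
#' contact map into a grayscale \linkS4class{CTVolume}. Bone touches the
#' thread profile exactly where the map says contact; elsewhere a
#' 3-voxel background gap separates bone from the implant surface.
#' Artifacts (noise, halo, granules) are added separately by
#' \code{\link{addArtifacts}}. The build is fully deterministic.
#'
#' @param cfg A \linkS4class{PhantomConfig}.
#' @param cm A \linkS4class{ContactMap} over the geometry's groove count.
#' @param angles,groovesPerSide,angleOffsetDeg Passed to
#'   \code{\link{groundTruthBIC}} for the bundled truth record.
#' @return List with elements \code{volume} (\linkS4class{CTVolume}) and
#'   \code{truth} (\linkS4class{PhantomTruth}).
#' @examples
#' cfg <- phantomConfig(voxelSizeUm = 80)
#' cm <- sampleContactMap(1, seed = 1)
#' ph <- buildPhantom(cfg, cm)
#' truthPerPlane(ph$truth)
#' @export
buildPhantom <- function(cfg, cm, angles = c(0, 45, 90, 135),
                         groovesPerSide = 4, angleOffsetDeg = 0) {
  stopifnot(is(cfg, "PhantomConfig"), is(cm, "ContactMap"))
  geo <- .phantomGeometry(cfg)
  if (!is.null(geo$error)) stop(geo$error)
  contact <- contactMatrix(cm)
  if (nrow(contact) != geo$nGrooves) {
    stop("contact map has ", nrow(contact),
         " grooves but the geometry provides ", geo$nGrooves)
  }
  im <- cfg@intensityMeans
  nz <- geo$shape[1]; ny <- geo$shape[2]; nx <- geo$shape[3]
  yv <- seq_len(ny) - 1 - geo$cy
  xv <- seq_len(nx) - 1 - geo$cx
  rho <- sqrt(outer(yv^2, xv^2, "+"))
  phi <- (atan2(matrix(yv, ny, nx), matrix(xv, ny, nx, byrow = TRUE)) *
            180 / pi) %% 360
  nSec <- ncol(contact)
  sector <- pmin(floor(phi / (360 / nSec)) + 1, nSec)

  vox <- array(im[["background"]], c(nz, ny, nx))
  zCore <- geo$z0:(geo$z0 + geo$Lr - 1)
  for (z in zCore) {
    k <- floor((z - geo$z0) / geo$pitch) + 1
    isRing <- k >= 1 && k <= geo$nRings &&
      (z - geo$z0) - (k - 1) * geo$pitch <= geo$crest - 1 + 1e-9
    surfR <- if (isRing) geo$rOut else geo$rCore
    implantM <- rho <= surfR + 1e-9
    d <- .distToImplant(rho, z, geo)
    g <- .grooveOfZ(z, geo)
    contactM <- matrix(contact[g, ][sector], ny, nx)
    boneM <- !implantM & rho <= geo$boneR & (contactM | d >= geo$gap - 1e-9)
    slab <- matrix(im[["background"]], ny, nx)
    slab[boneM] <- im[["bone"]]
    slab[implantM] <- im[["implant"]]
    vox[z + 1, , ] <- slab
  }
  tr <- .analyticTruth(cm, geo, angles, groovesPerSide, angleOffsetDeg)
  truth <- new("PhantomTruth", perGroove = tr$perGroove,
               perPlane = tr$perPlane, meanBIC = tr$meanBIC,
               contactMap = cm, config = cfg)
  list(volume = CTVolume(vox, cfg@voxelSizeUm), truth = truth)
}

#' Add residual scan artifacts to a phantom volume
#'
#' Applies, in order: (1) a beam-hardening halo -- every non-implant voxel
#' within \code{haloWidthVoxels} (chessboard distance) of the implant has
#' its intensity raised to at least \code{haloIntensity}, emulating the
#' bright rim that survives reconstruction-time corrections; (2) ceramic
#' granules -- \code{granuleCount} spheres of radius
#' \code{granuleRadiusUm} at bone intensity, placed at seeded random
#' positions within 400 um of the implant surface (the defect region where
#' the ceramic carrier resides), deliberately indistinguishable from bone
#' under the default thresholds; (3) additive Gaussian noise of SD
#' \code{noiseSd}, clipped to [0, 255] and quantized to the 8-bit grid.
#' With all three parameters at zero the volume is returned unchanged.
#'
#' @param v A \linkS4class{CTVolume} (typically from
#'   \code{\link{buildPhantom}}).
#' @param cfg The \linkS4class{PhantomConfig}; fields
#'   \code{haloWidthVoxels}, \code{haloIntensity}, \code{granuleCount},
#'   \code{granuleRadiusUm}, \code{noiseSd} and \code{seed} are used.
#' @return A new \linkS4class{CTVolume} with artifacts applied.
#' @export
addArtifacts <- function(v, cfg) {
  stopifnot(is(v, "CTVolume"), is(cfg, "PhantomConfig"))
  if (cfg@haloWidthVoxels == 0 && cfg@granuleCount == 0 && cfg@noiseSd == 0) {
    return(v)
  }
  geo <- .phantomGeometry(cfg)
  im <- cfg@intensityMeans
  vox <- voxels(v)
  implantM <- vox >= (im[["bone"]] + im[["implant"]]) / 2

  if (cfg@haloWidthVoxels > 0) {
    shell <- .dilateChessboard(implantM, as.integer(cfg@haloWidthVoxels)) &
      !implantM
    vox[shell] <- pmax(vox[shell], cfg@haloIntensity)
  }

  .withSeed(cfg@seed, {
    if (cfg@granuleCount > 0) {
      vox <- .placeGranules(vox, implantM, cfg, geo)
    }
    if (cfg@noiseSd > 0) {
      vox <- vox + rnorm(length(vox), 0, cfg@noiseSd)
      vox <- round(pmin(pmax(vox, 0), 255))
    }
  })
  CTVolume(vox, voxelSize(v))
}

# Rejection-sample granule centers in the peri-implant shell and rasterize
# them at bone intensity (never overwriting implant voxels).
.placeGranules <- function(vox, implantM, cfg, geo) {
  zone <- .GRANULE_ZONE_UM / geo$vs
  rg <- cfg@granuleRadiusUm / geo$vs
  n <- as.integer(cfg@granuleCount)
  centers <- matrix(0, 0, 3)
  guard <- 0L
  while (nrow(centers) < n && guard < 200L) {
    m <- 4L * (n - nrow(centers)) + 64L
    z <- runif(m, geo$z0, geo$z0 + geo$Lr - 1)
    rho <- sqrt(runif(m, geo$rCore^2, (geo$rOut + zone)^2))
    ang <- runif(m, 0, 2 * pi)
    d <- vapply(seq_len(m), function(i) {
      .distToImplant(rho[i], z[i], geo)
    }, numeric(1))
    ok <- d > 0.25 & d <= zone & rho <= geo$boneR
    if (any(ok)) {
      pts <- cbind(geo$cx + rho[ok] * cos(ang[ok]),
                   geo$cy + rho[ok] * sin(ang[ok]), z[ok])
      centers <- rbind(centers, pts)
    }
    guard <- guard + 1L
  }
  centers <- centers[seq_len(min(n, nrow(centers))), , drop = FALSE]
  dims <- dim(vox)
  rr <- max(rg, 0.5)
  boneI <- cfg@intensityMeans[["bone"]]
  for (i in seq_len(nrow(centers))) {
    cxg <- centers[i, 1]; cyg <- centers[i, 2]; czg <- centers[i, 3]
    zr <- max(0, floor(czg - rr)):min(dims[1] - 1, ceiling(czg + rr))
    yr <- max(0, floor(cyg - rr)):min(dims[2] - 1, ceiling(cyg + rr))
    xr <- max(0, floor(cxg - rr)):min(dims[3] - 1, ceiling(cxg + rr))
    for (zz in zr) for (yy in yr) for (xx in xr) {
      if ((xx - cxg)^2 + (yy - cyg)^2 + (zz - czg)^2 <= rr^2 &&
          !implantM[zz + 1, yy + 1, xx + 1]) {
        vox[zz + 1, yy + 1, xx + 1] <- max(vox[zz + 1, yy + 1, xx + 1], boneI)
      }
    }
  }
  vox
}

#' Rasterize the bare implant, optionally tilted, for axis validation
#'
#' Builds a volume containing only the threaded implant (no bone), with
#' its long axis tilted by \code{tiltDeg} about the volume's y axis
#' through the implant center. Useful for validating
#' \code{\link{estimateAxis}} against a known construction: the true
#' direction is \code{(sin(tilt), 0, cos(tilt))} and the true centroid is
#' the implant center used here (the volume center in x/y, the midpoint
#' of the implant extent in z).
#'
#' @param cfg A \linkS4class{PhantomConfig}.
#' @param tiltDeg Tilt angle about the y axis, degrees.
#' @return List: \code{volume} (\linkS4class{CTVolume}), \code{center}
#'   (x, y, z voxel units) and \code{direction} (unit vector) of the
#'   constructed axis.
#' @export
implantOnlyVolume <- function(cfg, tiltDeg = 0) {
  stopifnot(is(cfg, "PhantomConfig"))
  geo <- .phantomGeometry(cfg)
  if (!is.null(geo$error)) stop(geo$error)
  im <- cfg@intensityMeans
  nz <- geo$shape[1]; ny <- geo$shape[2]; nx <- geo$shape[3]
  zc <- geo$z0 + (geo$Lr - 1) / 2
  ct <- cospi(tiltDeg / 180); st <- sinpi(tiltDeg / 180)
  xv <- seq_len(nx) - 1 - geo$cx
  y2 <- (seq_len(ny) - 1 - geo$cy)^2
  vox <- array(im[["background"]], c(nz, ny, nx))
  for (z in seq_len(nz) - 1) {
    # implant-frame coordinates of this slab (rotation about y through
    # the implant center); xi, zi vary along x only
    xi <- ct * xv - st * (z - zc)
    zi <- st * xv + ct * (z - zc) + zc
    k <- floor((zi - geo$z0) / geo$pitch) + 1
    isRing <- k >= 1 & k <= geo$nRings &
      (zi - geo$z0) - (k - 1) * geo$pitch <= geo$crest - 1 + 1e-9
    inCore <- zi >= geo$z0 & zi <= geo$z0 + geo$Lr - 1
    surfR <- ifelse(isRing, geo$rOut, geo$rCore)
    surfR[!inCore] <- -1
    rho <- sqrt(outer(y2, xi^2, "+"))
    implantM <- rho <= matrix(surfR + 1e-9, ny, nx, byrow = TRUE)
    if (any(implantM)) {
      slab <- matrix(im[["background"]], ny, nx)
      slab[implantM] <- im[["implant"]]
      vox[z + 1, , ] <- slab
    }
  }
  list(volume = CTVolume(vox, cfg@voxelSizeUm),
       center = c(geo$cx, geo$cy, zc),
       direction = c(st, 0, ct))
}
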