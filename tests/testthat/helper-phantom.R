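# Shared fixtures: coarse-voxel phantoms (80 um) keep unit tests fast while
# preserving the full thread geometry (10 grooves, 4+ voxel thread depth).
# Heavier acceptance checks rebuild at 40 um.

testPhantomConfig <- function(...) {
  args <- utils::modifyList(
    list(voxelSizeUm = 80, noiseSd = 0, haloWidthVoxels = 0,
         granuleCount = 0),
    list(...))
  do.call(phantomConfig, args)
}

# Memoised standard phantoms so several test files can reuse one build.
.fixtures <- new.env(parent = emptyenv())

cachedPhantom <- function(fraction, seed = 7) {
  key <- sprintf("ph_%g_%d", fraction, seed)
  if (is.null(.fixtures[[key]])) {
    cfg <- testPhantomConfig()
    cm <- sampleContactMap(fraction, granularity = 36, seed = seed)
    .fixtures[[key]] <- c(buildPhantom(cfg, cm), list(cfg = cfg, cm = cm))
  }
  .fixtures[[key]]
}

# Run the measurement pipeline on one plane of a volume.
measurePlane <- function(v, axis, angle, excl = 1, pooling = "pooled") {
  sl <- extractLongitudinalSlice(v, axis, angle)
  li <- classifySlice(sl)
  pr <- traceImplantProfile(li)
  gr <- selectGrooves(pr, measurementConfig(exclusion_layers = excl,
                                            pooling = pooling))
  measureBIC(li, gr, measurementConfig(exclusion_layers = excl,
                                       pooling = pooling))
}

# --- Independent oracles -------------------------------------------------

# Geometry recomputed from config fields alone (kept separate from the
# package's internal geometry code on purpose).
oracleGeometry <- function(cfg, shp) {
  vs <- cfg@voxelSizeUm
  rOut <- cfg@implantDiameterUm / 2 / vs
  rCore <- rOut - cfg@threadDepthUm / vs
  pitch <- cfg@threadPitchUm / vs
  crest <- pitch / 2
  Lr <- round(cfg@implantLengthUm / vs)
  nRings <- floor((Lr - crest) / pitch) + 1
  list(vs = vs, rOut = rOut, rCore = rCore, pitch = pitch, crest = crest,
       Lr = Lr, nRings = nRings, nGrooves = nRings - 1,
       cx = floor(shp[3] / 2), cy = floor(shp[2] / 2),
       z0 = floor((shp[1] - Lr) / 2))
}

# Brute-force voxel walk: sample the continuous thread profile within one
# voxel-aligned longitudinal plane (angle 0 or 90) and call an arc point
# "contact" if any bone-intensity voxel center of that plane lies within
# `touchTol` pixels of it. The search stays in-plane: contact is defined
# per plane, and neighboring angular sectors may legitimately differ.
# Works on noise-free, artifact-free volumes and is independent of the
# contact map and of the package's probing/exclusion logic.
oracleVoxelWalkBIC <- function(volume, cfg, angleDeg, groovesPerSide = 4,
                               touchTol = 2.0) {
  stopifnot(angleDeg %in% c(0, 90))
  vox <- voxels(volume)
  geo <- oracleGeometry(cfg, dim(vox))
  boneI <- cfg@intensityMeans[["bone"]]
  # plane through the axis: rows = z, cols = signed radial position
  plane <- if (angleDeg == 0) vox[, geo$cy + 1, ] else vox[, , geo$cx + 1]
  ctr <- if (angleDeg == 0) geo$cx else geo$cy
  isBoneNear <- function(t, z) {   # t = signed radial coord, z in voxel rows
    cr <- max(1, floor(ctr + t - touchTol) + 1):
          min(ncol(plane), ceiling(ctr + t + touchTol) + 1)
    zr <- max(1, floor(z - touchTol) + 1):
          min(nrow(plane), ceiling(z + touchTol) + 1)
    for (zz in zr) for (cc in cr) {
      if (plane[zz, cc] == boneI &&
          (cc - 1 - ctr - t)^2 + (zz - 1 - z)^2 <= touchTol^2) {
        return(TRUE)
      }
    }
    FALSE
  }
  hits <- total <- 0
  for (sgn in c(1, -1)) {
    for (k in seq_len(groovesPerSide)) {
      za <- geo$z0 + (k - 1) * geo$pitch + geo$crest   # groove top row
      zb <- geo$z0 + k * geo$pitch - 1                 # groove bottom row
      pts <- rbind(
        cbind(rho = geo$rCore, z = seq(za, zb, by = 0.5)),            # valley
        cbind(rho = seq(geo$rCore, geo$rOut, by = 0.5), z = za - 0.5),# upper flank
        cbind(rho = seq(geo$rCore, geo$rOut, by = 0.5), z = zb + 0.5))# lower flank
      for (i in seq_len(nrow(pts))) {
        hits <- hits + isBoneNear(sgn * pts[i, "rho"], pts[i, "z"])
        total <- total + 1
      }
    }
  }
  100 * hits / total
}

# Edge-crossing oracle for the lateral boundary length of an implant mask:
# all 4-neighbor implant/non-implant pixel-edge crossings minus the top and
# bottom end faces.
oracleLateralEdgeCount <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  vert <- sum(xor(mask[, -1], mask[, -nc]))
  horiz <- sum(xor(mask[-1, ], mask[-nr, ]))
  rows <- which(rowSums(mask) > 0)
  horiz + vert - sum(mask[min(rows), ]) - sum(mask[max(rows), ])
}
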