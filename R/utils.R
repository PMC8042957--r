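# Internal helpers shared across modules.

# Run expr under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never perturb the
# user's stream.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Round half away from zero to `digits` decimals (the convention of the
# printed statistical tables; base round() rounds half to even).
.roundHalfAway <- function(x, digits = 2L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# 8-connected component labeling of a logical matrix. EBImage::bwlabel is
# 4-connected; merge its labels across diagonal contacts with union-find.
.label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(a, b) {
    ra <- findRoot(a); rb <- findRoot(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbor pairs: (r, c) vs (r+1, c+1) and (r+1, c) vs (r, c+1)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]
  a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]
  pairs <- rbind(
    cbind(as.vector(a1), as.vector(b1)),
    cbind(as.vector(a2), as.vector(b2))
  )
  pairs <- unique(pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                        pairs[, 1] != pairs[, 2], , drop = FALSE])
  if (nrow(pairs)) {
    for (i in seq_len(nrow(pairs))) unite(pairs[i, 1], pairs[i, 2])
    roots <- vapply(seq_len(n), findRoot, integer(1))
    relab <- match(roots, sort(unique(roots)))
    nz <- lab > 0L
    lab[nz] <- relab[lab[nz]]
  }
  lab
}

# Trilinear interpolation of a [z, y, x] array at points given as an
# n x 3 matrix of (x, y, z) 0-based voxel-center coordinates. Samples
# outside the volume take the value `outside`.
.trilinear <- function(vox, pts, outside = 0) {
  d <- dim(vox)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  out <- numeric(nrow(pts))
  corner <- function(dx, dy, dz) {
    xi <- x0 + dx; yi <- y0 + dy; zi <- z0 + dz
    w <- (if (dx) fx else 1 - fx) *
         (if (dy) fy else 1 - fy) *
         (if (dz) fz else 1 - fz)
    ok <- xi >= 0 & xi < nx & yi >= 0 & yi < ny & zi >= 0 & zi < nz & w > 0
    val <- rep(outside, length(xi))
    if (any(ok)) {
      lin <- (zi[ok] + 1) + yi[ok] * nz + xi[ok] * nz * ny
      val[ok] <- vox[lin]
    }
    w * val
  }
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    out <- out + corner(dx, dy, dz)
  }
  out
}

# Chessboard (Chebyshev) dilation of a logical array by `width` voxels,
# computed separably axis by axis (a box structuring element).
.dilateChessboard <- function(mask, width) {
  if (width <= 0) return(mask)
  d <- dim(mask)
  for (axis in seq_along(d)) {
    acc <- mask
    for (off in seq_len(width)) {
      acc <- acc | .shiftArray(mask, axis, off) | .shiftArray(mask, axis, -off)
    }
    mask <- acc
  }
  mask
}

# Shift a 2D or 3D logical array by `off` along `axis`, padding with FALSE.
.shiftArray <- function(a, axis, off) {
  d <- dim(a)
  n <- d[axis]
  if (abs(off) >= n) return(array(FALSE, d))
  src <- if (off > 0) seq_len(n - off) else seq(1 - off, n)
  dst <- if (off > 0) seq(1 + off, n) else seq_len(n + off)
  out <- array(FALSE, d)
  idxO <- lapply(d, seq_len); idxS <- idxO
  idxO[[axis]] <- dst; idxS[[axis]] <- src
  out <- do.call(`[<-`, c(list(out), idxO,
                          list(value = do.call(`[`, c(list(a), idxS)))))
  out
}
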