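mkSlice <- function(px) {
  new("CTSlice", pixels = px, pixelSizeUm = 20, angleDeg = 0,
      origin = c(0, 0, 0), basisAxial = c(0, 0, 1), basisRadial = c(1, 0, 0))
}

test_that("thresholding follows the inclusive bone window and implant cut", {
  px <- matrix(c(59, 60, 75, 90, 91, 199, 200, 230, 0), 3, 3)
  lab <- labelMatrix(classifySlice(mkSlice(px)))
  codes <- labelCodes()
  expect_equal(as.vector(lab),
               as.vector(codes[c(1, 2, 2, 2, 1, 1, 3, 3, 1)]),
               ignore_attr = TRUE)
})

test_that("labels always partition the image", {
  set.seed(4)
  px <- matrix(runif(900, 0, 255), 30, 30)
  lab <- labelMatrix(classifySlice(mkSlice(px)))
  tab <- table(factor(lab, levels = labelCodes()))
  expect_equal(sum(tab), 900)
})

test_that("speckle cleanup removes small bone components and is idempotent", {
  px <- matrix(0, 12, 12)
  px[2:5, 2:5] <- 75          # 16-px bone block: kept
  px[8, 8] <- 75              # isolated speckle: dropped
  px[10, 10] <- 75; px[11, 11] <- 75  # diagonal pair: 8-connected, size 2
  cfg <- segmentationConfig(min_component_px = 3)
  l1 <- classifySlice(mkSlice(px), cfg)
  expect_equal(sum(labelMatrix(l1) == labelCodes()[["BONE"]]), 16)
  # re-applying the cleanup to the already-clean result changes nothing
  px2 <- matrix(0, 12, 12)
  px2[labelMatrix(l1) == labelCodes()[["BONE"]]] <- 75
  l2 <- classifySlice(mkSlice(px2), cfg)
  expect_identical(labelMatrix(l2), labelMatrix(l1))
})

test_that("a noise-free phantom slice segments to the constructed geometry", {
  ph <- cachedPhantom(0.5)
  ax <- estimateAxis(ph$volume)
  sl <- extractLongitudinalSlice(ph$volume, ax, 0)
  lab <- labelMatrix(classifySlice(sl))
  # expected implant cross-section from the construction parameters
  geo <- oracleGeometry(ph$cfg, dim(voxels(ph$volume)))
  org <- sl@origin
  nu <- nrow(lab); nt <- ncol(lab)
  zPos <- org[3] + seq_len(nu) - 1
  xPos <- org[1] + seq_len(nt) - 1
  rho <- abs(outer(rep(1, nu), xPos) - geo$cx)
  zRel <- zPos - geo$z0
  k <- floor(zRel / geo$pitch) + 1
  isRing <- k >= 1 & k <= geo$nRings & zRel - (k - 1) * geo$pitch <= geo$crest - 1
  inCore <- zRel >= 0 & zRel <= geo$Lr - 1
  surf <- ifelse(isRing, geo$rOut, geo$rCore)
  surf[!inCore] <- -1
  expected <- rho <= outer(surf, rep(1, nt)) + 1e-9
  expect_identical(lab == labelCodes()[["IMPLANT"]], expected)
})
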