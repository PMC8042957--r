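test_that("contact map hits the target fraction within one sector and is seeded", {
  cm <- sampleContactMap(0.5, granularity = 36, nGrooves = 10, seed = 7)
  expect_equal(unname(rowSums(contactMatrix(cm))), rep(18, 10))
  cm2 <- sampleContactMap(0.5, granularity = 36, nGrooves = 10, seed = 7)
  expect_identical(contactMatrix(cm), contactMatrix(cm2))

  expect_true(all(contactMatrix(sampleContactMap(1, seed = 1))))
  expect_false(any(contactMatrix(sampleContactMap(0, seed = 1))))
  expect_error(sampleContactMap(1.2), "\\[0, 1\\]")
  expect_error(sampleContactMap(0.5, granularity = 3), ">= 4")

  # realized fraction within half a sector width of the target
  for (f in c(0.13, 0.61, 0.87)) {
    cm3 <- sampleContactMap(f, granularity = 36, seed = 3)
    expect_lt(abs(mean(contactMatrix(cm3)) - f), 0.5 / 36 + 1e-12)
  }
})

test_that("contact sampling is nested: raising the target never removes contact", {
  prev <- matrix(FALSE, 10, 36)
  for (f in seq(0, 1, by = 0.1)) {
    cur <- contactMatrix(sampleContactMap(f, granularity = 36, seed = 11))
    expect_true(all(cur[prev]))
    prev <- cur
  }
})

test_that("ground truth spans [0,100], is consistent, and matches boundaries", {
  ph1 <- cachedPhantom(1)
  expect_equal(truthPerPlane(ph1$truth)$bic_percent, rep(100, 4))
  ph0 <- cachedPhantom(0)
  expect_equal(truthPerPlane(ph0$truth)$bic_percent, rep(0, 4))

  ph <- cachedPhantom(0.5)
  tr <- ph$truth
  expect_true(all(truthPerGroove(tr)$bic_percent >= 0 &
                  truthPerGroove(tr)$bic_percent <= 100))
  expect_equal(meanBICPercent(tr), mean(truthPerPlane(tr)$bic_percent))
})

test_that("raising the target fraction never lowers the ground-truth mean", {
  cfg <- testPhantomConfig()
  vals <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(f) {
    meanBICPercent(groundTruthBIC(sampleContactMap(f, seed = 5), cfg))
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("a 180-degree-symmetric contact map gives equal BIC at theta and theta+180", {
  base <- contactMatrix(sampleContactMap(0.5, granularity = 36, seed = 9))
  sym <- base | base[, c(19:36, 1:18)]   # impose rotational symmetry
  cm <- new("ContactMap", contact = sym)
  cfg <- testPhantomConfig()
  tr <- groundTruthBIC(cm, cfg, angles = c(10, 190, 65, 245))
  pp <- truthPerPlane(tr)$bic_percent
  expect_equal(pp[1], pp[2])
  expect_equal(pp[3], pp[4])
})

test_that("analytic ground truth agrees with the brute-force voxel walk", {
  for (f in c(0.25, 0.75)) {
    ph <- cachedPhantom(f)
    for (a in c(0, 90)) {
      walk <- oracleVoxelWalkBIC(ph$volume, ph$cfg, a)
      truth <- truthPerPlane(ph$truth)
      expect_lt(abs(walk - truth$bic_percent[truth$angle_deg == a]), 2)
    }
  }
})

test_that("artifact application is the identity at zero settings and is seeded", {
  ph <- cachedPhantom(0.5)
  cfg0 <- testPhantomConfig()   # all artifact knobs zero
  expect_identical(voxels(addArtifacts(ph$volume, cfg0)), voxels(ph$volume))

  cfgN <- testPhantomConfig(noiseSd = 5, seed = 42)
  a1 <- addArtifacts(ph$volume, cfgN)
  a2 <- addArtifacts(ph$volume, cfgN)
  expect_identical(voxels(a1), voxels(a2))
  expect_false(identical(voxels(a1), voxels(ph$volume)))
})

test_that("a one-voxel halo pushes the interface shell into the bone window", {
  ph <- cachedPhantom(0)   # no contact: every shell voxel starts as background
  cfgH <- testPhantomConfig(haloWidthVoxels = 1, haloIntensity = 75)
  vh <- addArtifacts(ph$volume, cfgH)
  ax <- estimateAxis(ph$volume)
  li <- classifySlice(extractLongitudinalSlice(vh, ax, 0))
  lab <- labelMatrix(li)
  mask <- lab == labelCodes()[["IMPLANT"]]
  shell <- microBIC:::.dilateChessboard(mask, 1L) & !mask
  # restrict to rows with implant (the lateral shell, not beyond the ends)
  rows <- range(which(rowSums(mask) > 0))
  shell[seq_len(rows[1] - 1), ] <- FALSE
  shell[(rows[2] + 1):nrow(shell), ] <- FALSE
  expect_true(all(lab[shell] == labelCodes()[["BONE"]]))
})

test_that("the build rejects geometry that cannot fit", {
  expect_error(phantomConfig(voxelSizeUm = 80, volumeShape = c(130, 40, 40)),
               "fit")
  expect_error(phantomConfig(voxelSizeUm = 80,
                             intensityMeans = c(background = 75, bone = 20,
                                                implant = 230)),
               "ordered")
})
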