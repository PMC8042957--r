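mkLabel <- function(lab) {
  new("LabelSlice", labels = lab, pixelSizeUm = 20, angleDeg = 0)
}

test_that("profile tracing matches rectangle geometry and the edge-count oracle", {
  lab <- matrix(0L, 30, 20)
  lab[6:25, 6:15] <- labelCodes()[["IMPLANT"]]   # 20 rows x 10 cols
  pr <- traceImplantProfile(mkLabel(lab))
  e <- pr@elements
  expect_equal(sum(e$side == "left"), 20)
  expect_equal(sum(e$side == "right"), 20)
  expect_equal(nrow(e), oracleLateralEdgeCount(lab == 2))
})

test_that("phantom profile length equals the brute-force edge-crossing count", {
  ph <- cachedPhantom(0.5)
  ax <- estimateAxis(ph$volume)
  li <- classifySlice(extractLongitudinalSlice(ph$volume, ax, 0))
  pr <- traceImplantProfile(li)
  expect_equal(nrow(pr@elements),
               oracleLateralEdgeCount(labelMatrix(li) == labelCodes()[["IMPLANT"]]))
})

test_that("profile tracing rejects empty and fragmented implants", {
  lab <- matrix(0L, 10, 10)
  expect_error(traceImplantProfile(mkLabel(lab)), "no implant")
  lab[2:3, 2:3] <- 2L; lab[7:8, 7:8] <- 2L
  expect_error(traceImplantProfile(mkLabel(lab)), "found 2")
})

test_that("groove selection returns the upper four grooves per side", {
  ph <- cachedPhantom(0.5)
  ax <- estimateAxis(ph$volume)
  li <- classifySlice(extractLongitudinalSlice(ph$volume, ax, 0))
  gr <- selectGrooves(traceImplantProfile(li))
  expect_length(gr, 8)
  for (sd in c("left", "right")) {
    sel <- Filter(function(g) g@side == sd, gr)
    expect_equal(vapply(sel, function(g) g@indexFromTop, integer(1)), 1:4)
  }
  # grooves indexed from the top: element rows increase with groove index
  rsel <- Filter(function(g) g@side == "right", gr)
  tops <- vapply(rsel, function(g) min(g@elements$row), numeric(1))
  expect_true(all(diff(tops) > 0))
})

test_that("groove selection errors on too few grooves unless allowed", {
  lab <- matrix(0L, 40, 40)
  lab[5:35, 15:22] <- 2L          # core
  lab[c(5:8, 15:18, 25:28), 12:25] <- 2L  # 3 crests -> 2 grooves
  li <- mkLabel(lab)
  pr <- traceImplantProfile(li)
  expect_error(selectGrooves(pr), "found 2 .* required 4")
  w <- capture_warnings(
    gr <- selectGrooves(pr, measurementConfig(allow_fewer_grooves = TRUE)))
  expect_match(w, "found 2", all = TRUE)
  expect_length(gr, 4)  # 2 grooves x 2 sides
  # a threadless implant has no crest pair at all
  flat <- matrix(0L, 30, 20); flat[5:25, 8:12] <- 2L
  expect_error(selectGrooves(traceImplantProfile(mkLabel(flat))), "crest")
})

test_that("measured BIC hits the boundary cases and stays in range", {
  ph1 <- cachedPhantom(1)
  ax <- estimateAxis(ph1$volume)
  r1 <- measurePlane(ph1$volume, ax, 0)
  expect_equal(perSliceBIC(r1), 100)
  ph0 <- cachedPhantom(0)
  r0 <- measurePlane(ph0$volume, estimateAxis(ph0$volume), 0)
  expect_equal(perSliceBIC(r0), 0)
  ph <- cachedPhantom(0.5)
  r <- measurePlane(ph$volume, estimateAxis(ph$volume), 45)
  g <- perGrooveBIC(r)
  expect_true(all(g$bic_percent >= 0 & g$bic_percent <= 100))
  expect_true(all(g$contact_px <= g$total_px))
})

test_that("per-slice pooling rules are consistent with the per-groove table", {
  ph <- cachedPhantom(0.5)
  ax <- estimateAxis(ph$volume)
  rp <- measurePlane(ph$volume, ax, 0, pooling = "pooled")
  rg <- measurePlane(ph$volume, ax, 0, pooling = "groove-mean")
  g <- perGrooveBIC(rp)
  expect_equal(perSliceBIC(rp), 100 * sum(g$contact_px) / sum(g$total_px))
  expect_equal(perSliceBIC(rg), mean(perGrooveBIC(rg)$bic_percent))
})

test_that("measured BIC is monotone in the phantom contact fraction", {
  cfg <- testPhantomConfig()
  vals <- vapply(c(0.2, 0.5, 0.8), function(f) {
    ph <- buildPhantom(cfg, sampleContactMap(f, seed = 21))
    perSliceBIC(measurePlane(ph$volume, estimateAxis(ph$volume), 0))
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("multi-angle mean is the arithmetic mean of distinct-angle slices", {
  mk <- function(bic, ang) {
    new("BICResult",
        perGroove = data.frame(side = "left", groove = 1L,
                               contact_px = bic, total_px = 100,
                               bic_percent = bic),
        perSliceBIC = bic, angleDeg = ang, pooling = "pooled")
  }
  res <- meanBIC(list(mk(40, 0), mk(50, 45), mk(60, 90), mk(70, 135)))
  expect_equal(meanBICPercent(res), 55)
  expect_equal(unname(perAngleBIC(res)), c(40, 50, 60, 70))
  expect_equal(meanBICPercent(meanBIC(list(mk(81.3, 0)))), 81.3)
  expect_equal(meanBICPercent(meanBIC(list(mk(62, 0), mk(62, 45),
                                           mk(62, 90), mk(62, 135)))), 62)
  expect_error(meanBIC(list()), "at least one")
  expect_error(meanBIC(list(mk(40, 0), mk(50, 0))), "distinct")
})
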