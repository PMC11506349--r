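test_that("adaptive threshold handles degenerate and analytic inputs", {
  expect_false(any(segmentAdaptive(matrix(100, 120L, 120L))))
  expect_error(segmentAdaptive(matrix(0, 50L, 50L), blockSize = 50L), "odd")
  # dark disk on a bright field: recovered within perimeter quantization
  img <- matrix(200, 200L, 200L)
  ctr <- 100.5; rad <- 20
  d2 <- outer((seq_len(200) - ctr)^2, (seq_len(200) - ctr)^2, `+`)
  img[d2 <= rad^2] <- 80
  mask <- segmentAdaptive(img, blockSize = 51L)
  trueArea <- sum(d2 <= rad^2)
  expect_lt(abs(sum(mask) - trueArea), 2 * pi * rad)
  expect_gte(maskIoUForTest(mask, d2 <= rad^2), 0.9)
})

test_that("adaptive threshold is invariant to affine intensity rescaling", {
  img <- getBand(fixtureField("normal", 301L)$stack, 520)
  m1 <- segmentAdaptive(img)
  m2 <- segmentAdaptive(2.5 * img + 40)
  expect_identical(m1, m2)
})

test_that("520 nm adaptive segmentation recovers the collagen class", {
  f <- fixtureField("normal", 301L)
  mask <- segmentAdaptive(getBand(f$stack, 520))
  truth <- classLayer(f$truth, "matrix")
  expect_gte(maskIoUForTest(mask, truth), 0.7)
})

test_that("forest training is deterministic and validates its input", {
  f <- fixtureField("well", 301L)
  expect_error(
    trainNucleusRF(list(f$stack),
                   list(ClassMask(matrix(0L, 400L, 400L)))),
    "single class")
  m1 <- fixtureModel()
  sub <- SpectralStack(lapply(bands(f$stack), function(b) b[1:150, 1:150]),
                       wavelengths(f$stack))
  tr <- lapply(c("normal", "well"), function(g) fixtureField(g, seed = 990L))
  mA <- trainNucleusRF(lapply(tr, `[[`, "stack"), lapply(tr, `[[`, "truth"),
                       nTrees = 25L, seed = 77L)
  mB <- trainNucleusRF(lapply(tr, `[[`, "stack"), lapply(tr, `[[`, "truth"),
                       nTrees = 25L, seed = 77L)
  expect_equal(predictNucleusProb(sub, mA), predictNucleusProb(sub, mB))
})

test_that("nucleus segmentation reaches resubstitution and held-out accuracy", {
  model <- fixtureModel()
  # resubstitution on a training field
  trF <- fixtureField("well", 990L)
  pred <- segmentNuclei(trF$stack, model)
  truth <- classLayer(trF$truth, "nucleus")
  expect_gte(mean(pred == truth), 0.95)
  # held-out field, new seed
  f <- fixtureField("well", 301L)
  predH <- segmentNuclei(f$stack, model)
  truthH <- classLayer(f$truth, "nucleus")
  expect_gte(maskIoUForTest(predH, truthH), 0.7)
  # forest beats the adaptive threshold on the nucleus class
  adap <- segmentAdaptive(getBand(f$stack, 630))
  expect_gt(maskIoUForTest(predH, truthH), maskIoUForTest(adap, truthH))
})

test_that("nucleus segmentation handles empty fields and extreme thresholds", {
  model <- fixtureModel()
  f <- fixtureField("well", 301L)
  expect_false(any(segmentNuclei(f$stack, model, probThreshold = 1)))
  # background-only field: a scene with all object rates zeroed
  p <- gradeParams("normal")
  p$nucleusDensity <- 0; p$dropletRate <- 0
  empty <- simulateFields("normal", 1L, fieldShape = c(400L, 400L),
                          params = p, seed = 13L)[[1L]]
  expect_false(any(segmentNuclei(empty$stack, model)))
  # missing band is reported by wavelength
  noRed <- SpectralStack(list(getBand(f$stack, 520), getBand(f$stack, 600)),
                         c(520, 600))
  expect_error(segmentNuclei(noRed, model), "630")
})

test_that("instance splitting separates touching objects", {
  mk <- function(centers, rad = 10) {
    m <- matrix(FALSE, 80L, 80L)
    for (ct in centers) {
      d2 <- outer((seq_len(80) - ct[1L])^2, (seq_len(80) - ct[2L])^2, `+`)
      m <- m | (d2 <= rad^2)
    }
    m
  }
  # two disjoint disks
  two <- mk(list(c(20, 20), c(60, 60)))
  inst <- splitInstances(two)
  expect_equal(nInstances(inst), 2L)
  areas <- nucleusAreas(inst, 1)$area_um2
  expect_equal(sort(areas), rep(sum(mk(list(c(20, 20)))), 2L),
               tolerance = 0.01)
  # two disks fused through a narrow neck
  fused <- mk(list(c(40, 28), c(40, 46)), rad = 10)
  expect_equal(nInstances(splitInstances(fused)), 2L)
  # empty mask
  expect_equal(nInstances(splitInstances(matrix(FALSE, 10L, 10L))), 0L)
})

test_that("pseudo-color composition follows the grade-aware lookup", {
  h <- 60L; w <- 60L
  mkDisk <- function(r0, c0, rad) {
    outer((seq_len(h) - r0)^2, (seq_len(w) - c0)^2, `+`) <= rad^2
  }
  masks <- list(matrix = matrix(TRUE, h, w) & !mkDisk(30, 30, 8),
                bright600 = mkDisk(30, 30, 8),
                pit = matrix(FALSE, h, w),
                nucleus = mkDisk(15, 15, 4))
  # normal grade: the one droplet renders yellow
  rgbN <- composePseudocolor(masks, "normal")
  yellow <- rgbN[, , 1] == 1 & abs(rgbN[, , 2] - 0.85) < 1e-9 & rgbN[, , 3] < 0.2
  expect_equal(nInstances(splitInstances(yellow)), 1L)
  # tumor grade: red pearls, no yellow anywhere
  rgbW <- composePseudocolor(masks, "well")
  expect_false(any(rgbW[, , 1] == 1 & abs(rgbW[, , 2] - 0.85) < 1e-9))
  red <- abs(rgbW[, , 1] - 0.85) < 1e-9 & rgbW[, , 2] < 0.2
  expect_true(any(red))
  # empty masks give an all-white image
  emptyMasks <- lapply(masks, function(m) m & FALSE)
  expect_true(all(composePseudocolor(emptyMasks, "well") == 1))
  # overlap priority: nucleus wins over bright600 where both are set
  masks2 <- masks; masks2$nucleus <- mkDisk(30, 30, 3)
  rgbP <- composePseudocolor(masks2, "well")
  expect_true(all(abs(rgbP[30, 30, ] - c(0.15, 0.2, 0.8)) < 1e-9))
  bad <- masks; bad$nucleus <- matrix(FALSE, 10L, 10L)
  expect_error(composePseudocolor(bad, "well"), "shape")
})

test_that("every pixel receives exactly one pseudo-color", {
  f <- fixtureField("well", 301L)
  rgb <- composePseudocolor(f$truth, "well")
  lut <- c("1/1/1", "0.75/0.75/0.75", "0.85/0.08/0.08",
           "1/0.65/0.8", "0.15/0.2/0.8")
  flat <- matrix(rgb, ncol = 3L)
  keys <- unique(paste(flat[, 1L], flat[, 2L], flat[, 3L], sep = "/"))
  expect_true(all(keys %in% lut))
})
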