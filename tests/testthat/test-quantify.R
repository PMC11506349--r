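# helpers to build small synthetic masks/stacks for window QC rules
.uniformMaskStack <- function(h, w, labels, i630 = 0.5 * 255) {
  stack <- SpectralStack(list(matrix(i630, h, w), matrix(i630, h, w),
                              matrix(i630, h, w)),
                         wavelengths = c(520, 600, 630))
  list(stack = stack, mask = ClassMask(labels))
}

test_that("window QC selects non-overlapping tissue windows on a phantom", {
  f <- fixtureField("well", 301L, shape = c(600L, 600L))
  mask <- segmentField(f$stack, fixtureModel(), "well")
  wins <- suppressWarnings(selectWindows(f$stack, mask))
  expect_gte(nrow(wins), 1L)
  expect_lte(nrow(wins), 5L)
  if (nrow(wins) > 1L) {
    for (i in seq_len(nrow(wins) - 1L)) {
      for (j in (i + 1L):nrow(wins))
        expect_true(abs(wins$row0[i] - wins$row0[j]) >= 200 ||
                    abs(wins$col0[i] - wins$col0[j]) >= 200)
    }
  }
  expect_true(all(wins$pearl_frac < 0.05))
  expect_true(all(wins$mean_intensity >= 0.1 & wins$mean_intensity <= 0.9))
  # selection is deterministic: rerun gives identical windows
  expect_identical(wins, suppressWarnings(selectWindows(f$stack, mask)))
})

test_that("an all-background mosaic yields no windows, with a warning", {
  u <- .uniformMaskStack(300L, 300L, matrix(0L, 300L, 300L))
  expect_warning(wins <- selectWindows(u$stack, u$mask), "0 of 5")
  expect_equal(nrow(wins), 0L)
})

test_that("a window dominated by keratin pearl is rejected", {
  lab <- matrix(1L, 200L, 200L)
  lab[1:80, ] <- 2L           # 40% bright600 coverage
  u <- .uniformMaskStack(200L, 200L, lab)
  expect_warning(wins <- selectWindows(u$stack, u$mask), "0 of 5")
  expect_equal(nrow(wins), 0L)
  # same geometry without the pearl passes
  u2 <- .uniformMaskStack(200L, 200L, matrix(1L, 200L, 200L))
  wins2 <- suppressWarnings(selectWindows(u2$stack, u2$mask, nWindows = 1L))
  expect_equal(nrow(wins2), 1L)
})

test_that("nc ratio follows its definition including edge cases", {
  nuc <- matrix(FALSE, 20L, 25L); nuc[1:10, 1:10] <- TRUE   # 100 px
  tis <- matrix(FALSE, 20L, 25L); tis[1:20, 1:20] <- TRUE   # 400 px
  expect_equal(ncRatio(nuc, tis), 100 / 300)
  expect_equal(ncRatio(nuc & FALSE, tis), 0)
  expect_error(ncRatio(nuc, tis & FALSE), "empty")
  expect_identical(ncRatio(tis, tis), Inf)
  expect_equal(ncRatio(nuc, tis, mode = "window"), 100 / 500)
})

test_that("nucleus areas convert pixel counts through the calibration", {
  lab <- matrix(0L, 30L, 30L); lab[1:8, 1:10] <- 1L   # 80 px instance
  inst <- InstanceMask(lab)
  tab <- nucleusAreas(inst, 0.5)
  expect_equal(tab$area_um2, 20)
  empty <- nucleusAreas(splitInstances(matrix(FALSE, 5L, 5L)), 0.5)
  expect_equal(nrow(empty), 0L)
})

test_that("measured nucleus areas recover the scene ground truth", {
  f <- fixtureField("well", 301L)
  inst <- splitInstances(segmentNuclei(f$stack, fixtureModel()))
  tab <- nucleusAreas(inst, pixelSize(f$scene))
  sc <- f$scene@nuclei
  # match each true nucleus to the instance under its centroid
  lab <- labels2d(inst)
  ids <- mapply(function(r, c) lab[round(r), round(c)], sc$row, sc$col)
  ok <- ids > 0
  expect_gte(mean(ok), 0.9)
  errs <- abs(tab$area_um2[ids[ok]] - sc$area_um2[ok])
  expect_lte(median(errs), 2)
})

test_that("atypia fractions are monotone and scale-consistent", {
  tab <- data.frame(instance = 1:3, area_um2 = c(5, 15, 25),
                    centroid_row = 0, centroid_col = 0)
  fb <- fractionBelow(tab)
  expect_equal(unname(fb$fractions[["20"]]), 2 / 3)
  expect_true(all(diff(fb$fractions) >= 0))
  expect_equal(fb$below20, c(TRUE, TRUE, FALSE))
  expect_error(fractionBelow(tab[0, ]), "empty")
  # invariance: rescaling pixel size with co-transformed thresholds
  lab <- matrix(0L, 40L, 40L); lab[1:6, 1:6] <- 1L; lab[20:29, 20:29] <- 2L
  inst <- InstanceMask(lab)
  f1 <- fractionBelow(nucleusAreas(inst, 0.5), thresholds = c(10, 20))
  f2 <- fractionBelow(nucleusAreas(inst, 1.0), thresholds = 4 * c(10, 20))
  expect_equal(unname(f1$fractions), unname(f2$fractions))
})

test_that("keratin pearl statistics respect the minimum-area rule", {
  empty <- keratinPearlStats(splitInstances(matrix(FALSE, 10L, 10L)), 0.5)
  expect_equal(empty$count, 0L)
  expect_equal(empty$total_um2, 0)
  # two disks of 500 and 800 um^2 at 1 um/px (areas = pixel counts)
  lab <- matrix(0L, 120L, 120L)
  d1 <- outer((1:120 - 30)^2, (1:120 - 30)^2, `+`) <= (sqrt(500 / pi))^2
  d2 <- outer((1:120 - 90)^2, (1:120 - 90)^2, `+`) <= (sqrt(800 / pi))^2
  lab[d1] <- 1L; lab[d2] <- 2L
  ps <- keratinPearlStats(InstanceMask(lab, 2L), 1, minAreaUm2 = 100)
  expect_equal(ps$count, 2L)
  expect_equal(ps$total_um2, sum(d1) + sum(d2))
  expect_equal(ps$total_um2, 1300, tolerance = 0.03)
  # the smaller disk is excluded by a higher cutoff
  expect_equal(keratinPearlStats(InstanceMask(lab, 2L), 1,
                                 minAreaUm2 = 600)$count, 1L)
})

test_that("recovered pearls are more abundant in well- than poorly-differentiated fields", {
  model <- fixtureModel()
  counts <- list(poorly = numeric(0), well = numeric(0))
  for (g in c("poorly", "well")) {
    for (s in 1:5) {
      f <- simulateFields(g, 1L, fieldShape = c(400L, 400L),
                          seed = 6000L + 13L * s)[[1L]]
      mask <- segmentField(f$stack, model, g)
      ps <- keratinPearlStats(
        splitInstances(classLayer(mask, "bright600"),
                       classOf = histoClassCodes()[["bright600"]]),
        pixelSize(f$stack))
      counts[[g]] <- c(counts[[g]], ps$count)
    }
  }
  expect_gt(mean(counts$well), mean(counts$poorly))
})

test_that("atypia overlay colors nuclei by the 20 um^2 threshold", {
  lab <- matrix(0L, 40L, 40L)
  lab[1:4, 1:4] <- 1L      # 16 px = 4 um^2 at 0.5 um/px -> blue
  lab[20:30, 20:30] <- 2L  # 121 px = 30.25 um^2 -> red
  rgb <- atypiaOverlay(InstanceMask(lab), 0.5)
  expect_equal(rgb[2, 2, ], c(0.15, 0.2, 0.85))
  expect_equal(rgb[25, 25, ], c(0.85, 0.1, 0.1))
  expect_equal(rgb[40, 1, ], c(1, 1, 1))
})
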