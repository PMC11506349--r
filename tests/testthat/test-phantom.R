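test_that("stain spectra reproduce the published H&E absorption structure", {
  sp <- fixtureSpectra()
  wl <- sp@wavelengths
  # hematoxylin peaks at 560 nm on the band grid
  expect_equal(wl[which.max(sp@epsH)], 560)
  # eosin support ends before 680 nm
  expect_equal(sp@epsE[wl == 680], 0)
  # eosin: strong at 520, weak but positive at 630 (evaluated mixture)
  e520 <- sp@epsE[wl == 520]; e630 <- sp@epsE[wl == 630]
  expect_gt(e520, e630)
  expect_gt(e630, 0)
  # direct evaluation of the declared Gaussian mixture as oracle
  mix <- function(w) 0.6 * exp(-(w - 518)^2 / (2 * 35^2)) +
                     0.6 * exp(-(w - 528)^2 / (2 * 35^2))
  expect_equal(e520, mix(520), tolerance = 1e-12)
  expect_equal(e630, mix(630), tolerance = 1e-12)
  # hematoxylin positive over its 400-600 nm support
  expect_true(all(sp@epsH[wl >= 400 & wl <= 600] > 0))
  expect_error(makeStainSpectra(numeric(0)), "empty")
  expect_error(makeStainSpectra(c(350, 500)), "400-700")
})

test_that("scene sampling is deterministic and respects grade anatomy", {
  s1 <- sampleScene("well", fieldShape = c(400L, 400L), seed = 7L)
  s2 <- sampleScene("well", fieldShape = c(400L, 400L), seed = 7L)
  expect_identical(s1@nuclei, s2@nuclei)
  expect_identical(labels2d(s1@truthMask), labels2d(s2@truthMask))
  # droplets only in normal tissue, pearls only in tumor, pits only in well
  sn <- fixtureField("normal", 301L)$scene
  expect_identical(nrow(sn@pearls), 0L)
  expect_identical(nrow(sn@pits), 0L)
  sp <- fixtureField("poorly", 302L)$scene
  expect_identical(nrow(sp@droplets), 0L)
  codes <- histoClassCodes()
  if (nrow(sn@droplets) > 0)
    expect_true(any(labels2d(sn@truthMask) == codes[["bright600"]]))
})

test_that("ground-truth nucleus areas match the sampled areas to quantization", {
  sc <- fixtureField("well", 301L)$scene
  ps <- pixelSize(sc)
  # continuous ellipse area pi*a*b in um^2 equals the lognormal draw
  expect_lt(max(abs(pi * sc@nuclei$a_px * sc@nuclei$b_px * ps^2 -
                    sc@nuclei$area_um2)), 1 * ps^2)
  # rasterized pixel count agrees within boundary quantization
  lab <- labels2d(sc@truthMask)
  inst <- splitInstances(lab == histoClassCodes()[["nucleus"]])
  expect_equal(nInstances(inst), nrow(sc@nuclei), tolerance = 0.05)
})

test_that("pearl counts follow the configured Poisson rate", {
  counts <- vapply(1:20, function(s)
    nrow(sampleScene("well", fieldShape = c(400L, 400L), seed = 4000L + s)@pearls),
    numeric(1L))
  rate <- gradeParams("well")$pearlRate
  # Poisson mean over 20 replicates: 3 sigma band
  expect_lt(abs(mean(counts) - rate), 3 * sqrt(rate / 20))
})

test_that("rendering follows Beer-Lambert with vignette and noise model", {
  sc <- fixtureField("well", 301L)$scene
  sp <- fixtureSpectra()
  noiseless <- renderStack(sc, sp, vignetteStrength = 0, noiseSigma = 0,
                           nFrames = 1L, seed = 1L)[[1L]]
  # zero-absorbance background pixel reads I0 = 0.9 * max gray in every band
  lab <- labels2d(sc@truthMask)
  bg <- which(lab == 0L, arr.ind = TRUE)[1L, ]
  for (b in seq_len(nbands(noiseless)))
    expect_equal(bands(noiseless)[[b]][bg[1L], bg[2L]], 0.9 * 255)
  # nucleus center darker than a matrix pixel at 630 nm
  nuc <- sc@nuclei[1L, ]
  i630 <- getBand(noiseless, 630)
  mx <- which(lab == 1L, arr.ind = TRUE)[1L, ]
  expect_lt(i630[round(nuc$row), round(nuc$col)], i630[mx[1L], mx[2L]])
  expect_error(renderStack(sc, sp, nFrames = 0L), "nFrames")
})

test_that("rendered intensity is monotone decreasing in stain concentration", {
  sc <- sampleScene("well", fieldShape = c(400L, 400L), seed = 31L)
  sp <- fixtureSpectra()
  base <- renderStack(sc, sp, vignetteStrength = 0.2, noiseSigma = 0,
                      nFrames = 1L, seed = 1L)[[1L]]
  scUp <- sc
  scUp@stainH <- sc@stainH + 0.3
  up <- renderStack(scUp, sp, vignetteStrength = 0.2, noiseSigma = 0,
                    nFrames = 1L, seed = 1L)[[1L]]
  for (b in seq_len(nbands(base)))
    expect_true(all(bands(up)[[b]] <= bands(base)[[b]] + 1e-9))
})

test_that("tilesets expose exact overlap geometry and ground-truth offsets", {
  sc <- sampleScene("well", fieldShape = c(400L, 700L), seed = 41L)
  sp <- fixtureSpectra()
  ts <- makeTileset(sc, sp, nTiles = 2L, overlapFraction = 0.3,
                    tileWidth = 400L, noiseSigma = 0, nFrames = 1L, seed = 1L)
  expect_equal(ts[[2L]]$offset[["x"]], 280)   # (1 - 0.3) * 400
  # overlapping strips are pixel-identical before noise
  a <- getBand(ts[[1L]]$frames[[1L]], 630)[, 281:400]
  b <- getBand(ts[[2L]]$frames[[1L]], 630)[, 1:120]
  expect_equal(a, b)
  one <- makeTileset(sc, sp, nTiles = 1L, overlapFraction = 0.3,
                     tileWidth = 400L, noiseSigma = 0, nFrames = 1L, seed = 1L)
  expect_length(one, 1L)
  expect_equal(one[[1L]]$offset[["x"]], 0)
  expect_error(makeTileset(sc, sp, nTiles = 2L, overlapFraction = 0.05),
               "overlapFraction")
})
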