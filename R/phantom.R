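# Synthetic 13-band H&E phantom generator.  Scenes are built from geometric
# primitives (nucleus ellipses, keratin-pearl disks with concentric rings,
# lipid droplets, squamous pits) on a textured eosinophilic matrix, carry a
# pixel-level ground-truth ClassMask, and are rendered to spectral stacks
# through Beer-Lambert absorption with per-field vignetting and per-frame
# sensor noise.

#' Default band centers of the 13-LED acquisition
#'
#' Thirteen narrow-band centers spanning 420-680 nm that include the three
#' working bands of the staging analysis (520, 600 and 630 nm).  The
#' exact LED centers of any given instrument may differ; all functions
#' accept arbitrary strictly increasing center lists.
#'
#' @return Numeric vector of 13 wavelengths in nm.
#' @export
defaultBandCenters <- function() {
  c(420, 440, 460, 480, 500, 520, 540, 560, 580, 600, 630, 660, 680)
}

#' Absorbance spectra of hematoxylin and eosin at given band centers
#'
#' Hematoxylin is modelled as a Gaussian absorbance curve centered at
#' 560 nm (width 60 nm, unit amplitude) whose red shoulder keeps nuclei
#' absorbing out to 630 nm; eosin as an equal-weight mixture of Gaussians
#' at 518 and 528 nm (width 35 nm, amplitude 0.6 each).  Outside the dyes'
#' support (400-600 nm for hematoxylin, 450-650 nm for eosin) values below
#' 1e-3 are truncated to zero.  Absolute amplitudes are arbitrary; only
#' relative band contrast matters for segmentation.
#'
#' @param wavelengths Numeric vector of band centers in nm (400-700).
#' @return A [StainSpectra-class].
#' @examples
#' sp <- makeStainSpectra(defaultBandCenters())
#' sp@wavelengths[which.max(sp@epsH)]  # 560
#' @export
makeStainSpectra <- function(wavelengths) {
  if (length(wavelengths) == 0L)
    stop("wavelength list must not be empty", call. = FALSE)
  if (any(wavelengths < 400 | wavelengths > 700))
    stop("wavelengths must lie within 400-700 nm", call. = FALSE)
  w <- as.numeric(wavelengths)
  epsH <- exp(-(w - 560)^2 / (2 * 60^2))
  epsH[(w < 400 | w > 600) & epsH < 1e-3] <- 0
  epsE <- 0.6 * exp(-(w - 518)^2 / (2 * 35^2)) +
          0.6 * exp(-(w - 528)^2 / (2 * 35^2))
  epsE[(w < 450 | w > 650) & epsE < 1e-3] <- 0
  new("StainSpectra", wavelengths = w, epsH = epsH, epsE = epsE)
}

#' Default generator parameters for one tissue grade
#'
#' Encodes the qualitative histology of each grade: normal dermis has
#' sparse small fibroblast nuclei among collagen fibers with occasional
#' large lipid droplets; poorly differentiated cSCC has densely packed,
#' large, pleomorphic nuclei and almost no keratinization; well
#' differentiated cSCC has moderately dense smaller nuclei, frequent
#' keratin pearls and squamous pits.  Tumor nucleus densities follow
#' typical carcinoma cellularity (packed epithelial sheets) so that the
#' three grades' window-level statistics are separated by construction.
#'
#' @param grade "normal", "poorly" or "well".
#' @return Named list of generator parameters: `nucleusDensity`
#'   (nuclei/mm^2), `nucleusAreaLogMean`/`nucleusAreaLogSd` (lognormal of
#'   nuclear area, um^2), `nucleusAspectRange`, `pearlRate`,
#'   `pearlRadiusUm`, `dropletRate`, `dropletRadiusUm`, `pitRate`,
#'   `pitRadiusUm` (rates per field, radii in um), `matrixCoverage`,
#'   `matrixTextureScale` (px), stain concentrations (`cNucleusH`,
#'   `cNucleusE`, `cMatrixE`, `cPearlE`), `illumVignetteStrength`,
#'   `noiseSigma` (gray levels) and `framesPerField`.
#' @export
gradeParams <- function(grade = c("normal", "poorly", "well")) {
  grade <- match.arg(grade)
  base <- list(
    grade = grade,
    nucleusAspectRange = c(1.1, 1.9),
    pearlRate = 0, pearlRadiusUm = c(10, 20),
    dropletRate = 0, dropletRadiusUm = c(6, 12),
    pitRate = 0, pitRadiusUm = c(5, 9),
    cNucleusH = 1.0, cNucleusE = 0.15,
    cMatrixE = 0.35, cPearlE = 2.0,
    illumVignetteStrength = 0.3,
    noiseSigma = 2,
    framesPerField = 5
  )
  spec <- switch(grade,
    normal = list(nucleusDensity = 50,
                  nucleusAreaLogMean = log(15), nucleusAreaLogSd = 0.25,
                  nucleusAspectRange = c(1.4, 2.4),
                  dropletRate = 3,
                  matrixCoverage = 0.75, matrixTextureScale = 5),
    poorly = list(nucleusDensity = 4000,
                  nucleusAreaLogMean = log(32), nucleusAreaLogSd = 0.45,
                  pearlRate = 0.5,
                  matrixCoverage = 0.88, matrixTextureScale = 8),
    well   = list(nucleusDensity = 2500,
                  nucleusAreaLogMean = log(14), nucleusAreaLogSd = 0.30,
                  pearlRate = 4, pitRate = 2,
                  matrixCoverage = 0.85, matrixTextureScale = 8)
  )
  utils::modifyList(base, spec)
}

# rasterize a filled ellipse; returns integer indices into an h x w matrix
.ellipseIndices <- function(h, w, r0, c0, a, b, theta) {
  rr <- max(1L, floor(r0 - a)):min(h, ceiling(r0 + a))
  cc <- max(1L, floor(c0 - a)):min(w, ceiling(c0 + a))
  dr <- rep(rr - r0, times = length(cc))
  dc <- rep(cc - c0, each = length(rr))
  u <- (dc * cos(theta) + dr * sin(theta)) / a
  v <- (-dc * sin(theta) + dr * cos(theta)) / b
  inside <- u * u + v * v <= 1
  r <- rep(rr, times = length(cc))[inside]
  c <- rep(cc, each = length(rr))[inside]
  (c - 1L) * h + r
}

.diskIndices <- function(h, w, r0, c0, rad) {
  .ellipseIndices(h, w, r0, c0, rad, rad, 0)
}

# non-overlap placement by rejection sampling; returns data.frame of centers
.placeObjects <- function(n, h, w, radii, occupiedR, occupiedC, occupiedRad,
                          maxTries = 100L, allowContact = FALSE) {
  outR <- numeric(0); outC <- numeric(0); keep <- integer(0)
  for (i in seq_len(n)) {
    rad <- radii[i]
    placed <- FALSE
    for (t in seq_len(maxTries)) {
      r0 <- stats::runif(1, 1 + rad, h - rad)
      c0 <- stats::runif(1, 1 + rad, w - rad)
      if (!allowContact) {
        allR <- c(occupiedR, outR); allC <- c(occupiedC, outC)
        allRad <- c(occupiedRad, radii[keep])
        if (length(allR)) {
          d2 <- (allR - r0)^2 + (allC - c0)^2
          if (any(d2 < (allRad + rad)^2)) next
        }
      }
      outR <- c(outR, r0); outC <- c(outC, c0); keep <- c(keep, i)
      placed <- TRUE
      break
    }
    if (!placed) next
  }
  list(r = outR, c = outC, keep = keep)
}

#' Sample the geometric ground truth of one phantom field
#'
#' Object counts are Poisson draws of the grade's rates, nuclear areas are
#' lognormal, and all objects are placed without overlap by rejection
#' sampling (at most 100 tries per object; objects that do not fit are
#' dropped with a warning).  The returned scene carries per-pixel stain
#' concentration maps (hematoxylin high in nuclei; eosin moderate in the
#' matrix, high in pearl rings, absent in droplets, pits and background)
#' and a ground-truth [ClassMask-class].
#'
#' @param grade Tissue grade ("normal", "poorly", "well").
#' @param params Generator parameters; defaults to `gradeParams(grade)`.
#' @param fieldShape Field size `c(rows, cols)` in px, at least 400 x 400.
#' @param pixelSize Pixel size in um/px.
#' @param seed Integer seed; the same seed reproduces the scene exactly.
#' @param allowContact If TRUE nuclei may touch (used to exercise the
#'   watershed instance splitter); ground-truth instances then overlap.
#' @return A [PhantomScene-class].
#' @export
sampleScene <- function(grade = c("normal", "poorly", "well"),
                        params = gradeParams(grade),
                        fieldShape = c(600L, 600L),
                        pixelSize = 0.5, seed = 1L,
                        allowContact = FALSE) {
  grade <- match.arg(grade)
  if (any(fieldShape < 400L))
    stop("fieldShape must be at least 400 x 400 px", call. = FALSE)
  h <- as.integer(fieldShape[1L]); w <- as.integer(fieldShape[2L])
  withr::with_seed(seed, {
    # textured eosinophilic matrix (collagen fibers / epidermis)
    noise <- matrix(stats::rnorm(h * w), h, w)
    tex <- EBImage::gblur(noise, sigma = params$matrixTextureScale,
                          boundary = "replicate")
    thr <- stats::quantile(tex, 1 - params$matrixCoverage)
    matrixMask <- tex > thr
    texU <- (tex - min(tex)) / (max(tex) - min(tex))

    areaMm2 <- h * w * pixelSize^2 / 1e6
    labels <- matrix(0L, h, w)
    labels[matrixMask] <- 1L
    stainH <- matrix(0, h, w)
    stainE <- matrix(0, h, w)
    stainE[matrixMask] <- params$cMatrixE * (0.8 + 0.4 * texU[matrixMask])

    codes <- histoClassCodes()
    occR <- numeric(0); occC <- numeric(0); occRad <- numeric(0)
    dropped <- 0L

    # keratin pearls (tumor grades)
    nPearls <- if (grade == "normal") 0L else stats::rpois(1L, params$pearlRate)
    pearls <- data.frame(row = numeric(0), col = numeric(0),
                         radius_px = numeric(0))
    if (nPearls > 0L) {
      rad <- stats::runif(nPearls, params$pearlRadiusUm[1L],
                          params$pearlRadiusUm[2L]) / pixelSize
      pl <- .placeObjects(nPearls, h, w, rad, occR, occC, occRad)
      dropped <- dropped + nPearls - length(pl$keep)
      rad <- rad[pl$keep]
      pearls <- data.frame(row = pl$r, col = pl$c, radius_px = rad)
      for (i in seq_len(nrow(pearls))) {
        idx <- .diskIndices(h, w, pearls$row[i], pearls$col[i],
                            pearls$radius_px[i])
        rr <- ((idx - 1L) %% h) + 1L
        cc <- ((idx - 1L) %/% h) + 1L
        d <- sqrt((rr - pearls$row[i])^2 + (cc - pearls$col[i])^2)
        ring <- 0.8 + 0.2 * cos(2 * pi * d / 6)   # concentric keratin rings
        labels[idx] <- codes[["bright600"]]
        stainE[idx] <- params$cPearlE * ring
        stainH[idx] <- 0
      }
      occR <- c(occR, pearls$row); occC <- c(occC, pearls$col)
      occRad <- c(occRad, pearls$radius_px)
    }

    # lipid droplets (normal tissue): unstained clear disks
    nDrop <- if (grade == "normal") stats::rpois(1L, params$dropletRate) else 0L
    droplets <- data.frame(row = numeric(0), col = numeric(0),
                           radius_px = numeric(0))
    if (nDrop > 0L) {
      rad <- stats::runif(nDrop, params$dropletRadiusUm[1L],
                          params$dropletRadiusUm[2L]) / pixelSize
      pl <- .placeObjects(nDrop, h, w, rad, occR, occC, occRad)
      dropped <- dropped + nDrop - length(pl$keep)
      rad <- rad[pl$keep]
      droplets <- data.frame(row = pl$r, col = pl$c, radius_px = rad)
      for (i in seq_len(nrow(droplets))) {
        idx <- .diskIndices(h, w, droplets$row[i], droplets$col[i],
                            droplets$radius_px[i])
        labels[idx] <- codes[["bright600"]]
        stainE[idx] <- 0; stainH[idx] <- 0
      }
      occR <- c(occR, droplets$row); occC <- c(occC, droplets$col)
      occRad <- c(occRad, droplets$radius_px)
    }

    # squamous pits (well grade): clear holes in the epidermis
    nPits <- if (grade == "well") stats::rpois(1L, params$pitRate) else 0L
    pits <- data.frame(row = numeric(0), col = numeric(0),
                       radius_px = numeric(0))
    if (nPits > 0L) {
      rad <- stats::runif(nPits, params$pitRadiusUm[1L],
                          params$pitRadiusUm[2L]) / pixelSize
      pl <- .placeObjects(nPits, h, w, rad, occR, occC, occRad)
      dropped <- dropped + nPits - length(pl$keep)
      rad <- rad[pl$keep]
      pits <- data.frame(row = pl$r, col = pl$c, radius_px = rad)
      for (i in seq_len(nrow(pits))) {
        idx <- .diskIndices(h, w, pits$row[i], pits$col[i], pits$radius_px[i])
        labels[idx] <- codes[["pit"]]
        stainE[idx] <- 0; stainH[idx] <- 0
      }
      occR <- c(occR, pits$row); occC <- c(occC, pits$col)
      occRad <- c(occRad, pits$radius_px)
    }

    # nuclei: lognormal areas, non-overlapping ellipses
    nNuc <- stats::rpois(1L, params$nucleusDensity * areaMm2)
    nuclei <- data.frame(row = numeric(0), col = numeric(0),
                         a_px = numeric(0), b_px = numeric(0),
                         theta = numeric(0), area_um2 = numeric(0))
    if (nNuc > 0L) {
      areaUm2 <- stats::rlnorm(nNuc, params$nucleusAreaLogMean,
                               params$nucleusAreaLogSd)
      aspect <- stats::runif(nNuc, params$nucleusAspectRange[1L],
                             params$nucleusAspectRange[2L])
      areaPx <- areaUm2 / pixelSize^2
      aPx <- sqrt(areaPx * aspect / pi)
      bPx <- aPx / aspect
      theta <- stats::runif(nNuc, 0, pi)
      pl <- .placeObjects(nNuc, h, w, aPx, occR, occC, occRad,
                          allowContact = allowContact)
      dropped <- dropped + nNuc - length(pl$keep)
      k <- pl$keep
      nuclei <- data.frame(row = pl$r, col = pl$c, a_px = aPx[k],
                           b_px = bPx[k], theta = theta[k],
                           area_um2 = areaUm2[k])
      for (i in seq_len(nrow(nuclei))) {
        idx <- .ellipseIndices(h, w, nuclei$row[i], nuclei$col[i],
                               nuclei$a_px[i], nuclei$b_px[i],
                               nuclei$theta[i])
        labels[idx] <- codes[["nucleus"]]
        stainH[idx] <- params$cNucleusH
        stainE[idx] <- params$cNucleusE
      }
    }
    if (dropped > 0L)
      warning(sprintf("%d object(s) could not be placed without overlap and were dropped",
                      dropped), call. = FALSE)

    new("PhantomScene", grade = grade, nuclei = nuclei, pearls = pearls,
        droplets = droplets, pits = pits, stainH = stainH, stainE = stainE,
        truthMask = ClassMask(labels), pixelSize = pixelSize)
  })
}

# noiseless Beer-Lambert signal per band, including vignette
.renderSignal <- function(scene, spectra, vignetteStrength, maxGray) {
  h <- nrow(scene@stainH); w <- ncol(scene@stainH)
  i0 <- 0.9 * maxGray
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  r2 <- outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, `+`)
  V <- 1 - vignetteStrength * r2 / max(r2)
  lapply(seq_along(spectra@wavelengths), function(b) {
    A <- scene@stainH * spectra@epsH[b] + scene@stainE * spectra@epsE[b]
    i0 * V * 10^(-A)
  })
}

#' Render a phantom scene to repeated spectral-stack frames
#'
#' Per band the noiseless signal follows Beer-Lambert transmission,
#' `I(x,y) = I0 * V(x,y) * 10^-(cH*epsH + cE*epsE)` with `I0` at 90% of
#' the gray range and `V` a radial vignette equal to 1 at the field center
#' and `1 - strength` at the corners.  Each of the `nFrames` acquisition
#' frames adds independent Gaussian sensor noise (sd `noiseSigma` gray
#' levels, clipped to the valid range); frames differ only in noise.
#'
#' @param scene A [PhantomScene-class].
#' @param spectra A [StainSpectra-class] sampled at the stack wavelengths.
#' @param vignetteStrength Relative corner falloff in 0..1.
#' @param noiseSigma Gaussian noise sd in gray levels.
#' @param nFrames Number of frames (>= 1).
#' @param seed Noise seed.
#' @param bitDepth Sensor bit depth.
#' @param fieldId Field identifier prefix for the frames.
#' @return List of `nFrames` [SpectralStack-class] objects.
#' @export
renderStack <- function(scene, spectra, vignetteStrength = 0.3,
                        noiseSigma = 2, nFrames = 5L, seed = 1L,
                        bitDepth = 8L, fieldId = "phantom") {
  stopifnot(is(scene, "PhantomScene"), is(spectra, "StainSpectra"))
  if (nFrames < 1L) stop("nFrames must be >= 1", call. = FALSE)
  maxGray <- 2^bitDepth - 1
  signal <- .renderSignal(scene, spectra, vignetteStrength, maxGray)
  h <- nrow(scene@stainH); w <- ncol(scene@stainH)
  withr::with_seed(seed, {
    lapply(seq_len(nFrames), function(f) {
      bandsF <- lapply(signal, function(s) {
        if (noiseSigma > 0)
          s <- s + matrix(stats::rnorm(h * w, 0, noiseSigma), h, w)
        pmin(pmax(s, 0), maxGray)
      })
      SpectralStack(bandsF, spectra@wavelengths,
                    pixelSize = scene@pixelSize, bitDepth = bitDepth,
                    fieldId = sprintf("%s_frame%02d", fieldId, f))
    })
  })
}

#' Cut a rendered field into an overlapping strip of tiles
#'
#' The whole scene is rendered once (so overlapping strips of adjacent
#' tiles are pixel-identical before noise) and cropped into a 1 x nTiles
#' horizontal strip; independent per-tile, per-frame sensor noise is added
#' afterwards.  True integer tile offsets are returned as the registration
#' ground truth.
#'
#' @inheritParams renderStack
#' @param nTiles Number of tiles in the strip.
#' @param overlapFraction Fraction of tile width shared by adjacent tiles
#'   (0.15-0.6).
#' @param tileWidth Tile width in px; defaults to the scene height
#'   (square tiles).
#' @return List with one element per tile:
#'   `list(frames = <list of SpectralStack>, offset = c(x, y))`, the
#'   offset being the tile origin in scene coordinates (x = column).
#' @export
makeTileset <- function(scene, spectra, nTiles, overlapFraction = 0.3,
                        tileWidth = NULL, vignetteStrength = 0,
                        noiseSigma = 2, nFrames = 5L, seed = 1L,
                        bitDepth = 8L) {
  if (overlapFraction < 0.15 || overlapFraction > 0.6)
    stop("overlapFraction must be within [0.15, 0.6]", call. = FALSE)
  stopifnot(nTiles >= 1L)
  h <- nrow(scene@stainH); w <- ncol(scene@stainH)
  if (is.null(tileWidth)) tileWidth <- h
  step <- round((1 - overlapFraction) * tileWidth)
  need <- (nTiles - 1L) * step + tileWidth
  if (need > w)
    stop(sprintf("scene is %d px wide but %d tiles of width %d at overlap %.2f need %d px",
                 w, nTiles, tileWidth, overlapFraction, need), call. = FALSE)
  maxGray <- 2^bitDepth - 1
  signal <- .renderSignal(scene, spectra, vignetteStrength, maxGray)
  lapply(seq_len(nTiles), function(i) {
    x0 <- (i - 1L) * step
    cols <- (x0 + 1L):(x0 + tileWidth)
    tileSignal <- lapply(signal, function(s) s[, cols, drop = FALSE])
    frames <- withr::with_seed(splitSeed(seed, sprintf("tile%02d", i)), {
      lapply(seq_len(nFrames), function(f) {
        bandsF <- lapply(tileSignal, function(s) {
          if (noiseSigma > 0)
            s <- s + matrix(stats::rnorm(length(s), 0, noiseSigma),
                            nrow(s), ncol(s))
          pmin(pmax(s, 0), maxGray)
        })
        SpectralStack(bandsF, spectra@wavelengths,
                      pixelSize = scene@pixelSize, bitDepth = bitDepth,
                      fieldId = sprintf("tile%02d_frame%02d", i, f))
      })
    })
    list(frames = frames, offset = c(x = x0, y = 0))
  })
}

#' Crop the ground-truth mask of a scene to a tile of [makeTileset()]
#' @param scene A [PhantomScene-class].
#' @param offset Tile offset `c(x, y)` as returned by [makeTileset()].
#' @param tileWidth Tile width in px.
#' @return A [ClassMask-class] for the tile.
#' @export
cropTruth <- function(scene, offset, tileWidth) {
  lab <- labels2d(scene@truthMask)
  cols <- (offset[["x"]] + 1L):(offset[["x"]] + tileWidth)
  ClassMask(lab[, cols, drop = FALSE], classCodes = scene@truthMask@classCodes)
}
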