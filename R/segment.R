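# Band-specific segmentation: adaptive thresholding for the 520 nm
# (collagen / diseased epidermis) and 600 nm (droplets / keratin pearls)
# bands, random-forest pixel classification for nuclei on the 630 nm band,
# watershed instance splitting and pseudo-color composition.

#' Adaptive local-mean threshold segmentation of one band
#'
#' A pixel is foreground when its intensity differs from the local mean
#' over a `blockSize` x `blockSize` neighborhood by more than
#' `offsetFrac` of the image's intensity range -- darker than the local
#' mean for `polarity = "dark"` (stained, absorbing structures), brighter
#' for `"bright"` (unstained vacuoles such as lipid droplets).  The raw
#' mask is cleaned by a morphological opening (disk radius 1) and removal
#' of components smaller than `minArea` px.  Expressing the offset as a
#' fraction of the range makes the mask invariant to affine intensity
#' rescaling.
#'
#' @param img Numeric band matrix.
#' @param blockSize Odd neighborhood side in px (>= 3).
#' @param offsetFrac Offset as a fraction of the image intensity range.
#' @param minArea Minimum component area in px.
#' @param polarity "dark" (default) or "bright".
#' @return Logical foreground mask.
#' @export
segmentAdaptive <- function(img, blockSize = 51L, offsetFrac = 0.02,
                            minArea = 30L, polarity = c("dark", "bright")) {
  polarity <- match.arg(polarity)
  if (blockSize %% 2 == 0) stop("blockSize must be odd", call. = FALSE)
  if (blockSize < 3) stop("blockSize must be >= 3", call. = FALSE)
  rng <- max(img) - min(img)
  if (rng <= 0) return(matrix(FALSE, nrow(img), ncol(img)))
  lm <- boxMean(img, blockSize)
  fg <- if (polarity == "dark") img < lm - offsetFrac * rng
        else img > lm + offsetFrac * rng
  opened <- EBImage::opening(fg * 1, EBImage::makeBrush(3L, "disc")) > 0.5
  .dropSmallComponents(opened, minArea)
}

# keep connected components whose mean intensity is below maxRel times the
# image median (strongly absorbing objects such as keratin)
.keepDarkComponents <- function(mask, img, maxRel) {
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask)
  K <- max(lab)
  inside <- lab > 0L
  meanI <- rowsum(img[inside], lab[inside]) /
    tabulate(lab[inside], nbins = K)
  keepId <- which(meanI < maxRel * stats::median(img))
  matrix(lab %in% keepId, nrow(mask), ncol(mask))
}

# keep connected components that are large and round (isoperimetric
# circularity 4*pi*A/P^2 above a cutoff)
.keepRoundComponents <- function(mask, minArea, minCircularity) {
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask)
  sh <- EBImage::computeFeatures.shape(lab)
  circ <- 4 * pi * sh[, "s.area"] / pmax(sh[, "s.perimeter"], 1)^2
  keepId <- which(sh[, "s.area"] >= minArea & circ >= minCircularity)
  matrix(lab %in% keepId, nrow(mask), ncol(mask))
}

.dropSmallComponents <- function(mask, minArea) {
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  keepId <- which(sizes >= minArea)
  matrix(lab %in% keepId, nrow(mask), ncol(mask))
}

#' Pixel feature matrix for nucleus classification
#'
#' Fixed, versioned feature order (models are only applied to matrices
#' built by this function): raw 630 nm intensity; Gaussian-smoothed 630 nm
#' at sigma 1, 2 and 4 px; gradient magnitude at sigma 2; local standard
#' deviation over 5x5; raw 520 and 600 nm intensities.  All intensities
#' are normalized to the 0..1 gray range.
#'
#' @param stack A [SpectralStack-class] containing 520, 600 and 630 nm
#'   bands.
#' @return Numeric matrix, one row per pixel (column-major order), with
#'   named feature columns.
#' @export
pixelFeatures <- function(stack) {
  mv <- maxValue(stack)
  i630 <- getBand(stack, 630) / mv
  i520 <- getBand(stack, 520) / mv
  i600 <- getBand(stack, 600) / mv
  f <- cbind(
    i630   = as.vector(i630),
    g1_630 = as.vector(EBImage::gblur(i630, 1, boundary = "replicate")),
    g2_630 = as.vector(EBImage::gblur(i630, 2, boundary = "replicate")),
    g4_630 = as.vector(EBImage::gblur(i630, 4, boundary = "replicate")),
    grad_630 = as.vector(gradientMagnitude(i630, 2)),
    sd5_630  = as.vector(localSd(i630, 5L)),
    i520   = as.vector(i520),
    i600   = as.vector(i600)
  )
  f
}

#' Train the random-forest nucleus pixel classifier
#'
#' Pixels of the supplied annotated fields are labelled nucleus /
#' non-nucleus from their ground-truth masks, subsampled to at most
#' `maxPerClass` per class (balanced), and a probability random forest is
#' grown (default 100 trees, depth <= 12).  Training is deterministic for
#' a given seed and data.
#'
#' @param stacks List of [SpectralStack-class] training fields.
#' @param truthMasks List of matching [ClassMask-class] annotations.
#' @param nTrees Number of trees.
#' @param maxDepth Maximum tree depth.
#' @param maxPerClass Maximum training pixels per class.
#' @param seed Training seed.
#' @return A [NucleusModel-class].
#' @export
trainNucleusRF <- function(stacks, truthMasks, nTrees = 100L, maxDepth = 12L,
                           maxPerClass = 50000L, seed = 1L) {
  stopifnot(length(stacks) == length(truthMasks), length(stacks) >= 1L)
  feats <- list(); labs <- list()
  for (i in seq_along(stacks)) {
    feats[[i]] <- pixelFeatures(stacks[[i]])
    labs[[i]] <- as.vector(classLayer(truthMasks[[i]], "nucleus"))
  }
  X <- do.call(rbind, feats)
  y <- unlist(labs)
  if (length(unique(y)) < 2L)
    stop("training data contain a single class; need nucleus and non-nucleus pixels",
         call. = FALSE)
  withr::with_seed(splitSeed(seed, "rf-subsample"), {
    iPos <- which(y); iNeg <- which(!y)
    if (length(iPos) > maxPerClass) iPos <- sample(iPos, maxPerClass)
    if (length(iNeg) > maxPerClass) iNeg <- sample(iNeg, maxPerClass)
    sel <- c(iPos, iNeg)
  })
  df <- as.data.frame(X[sel, , drop = FALSE])
  df$.nucleus <- factor(ifelse(y[sel], "nucleus", "other"),
                        levels = c("other", "nucleus"))
  forest <- ranger::ranger(
    dependent.variable.name = ".nucleus", data = df,
    num.trees = nTrees, max.depth = maxDepth, probability = TRUE,
    seed = splitSeed(seed, "rf-train"), num.threads = 1L)
  new("NucleusModel", forest = forest,
      featureNames = colnames(X), seed = as.integer(seed),
      trainInfo = list(nFields = length(stacks),
                       nPos = length(iPos), nNeg = length(iNeg),
                       nTrees = nTrees, maxDepth = maxDepth,
                       package = as.character(utils::packageVersion("msiStage"))))
}

#' Per-pixel nucleus probability map
#' @param stack A [SpectralStack-class] with 520/600/630 nm bands.
#' @param model A [NucleusModel-class].
#' @return Numeric matrix of nucleus probabilities in 0..1.
#' @export
predictNucleusProb <- function(stack, model) {
  X <- pixelFeatures(stack)
  if (!identical(colnames(X), model@featureNames))
    stop("feature specification of the stack does not match the model",
         call. = FALSE)
  p <- stats::predict(model@forest, as.data.frame(X),
                      num.threads = 1L)$predictions[, "nucleus"]
  matrix(p, nrow(getBand(stack, 630)), ncol(getBand(stack, 630)))
}

#' Segment nuclei on the 630 nm band with a trained forest
#'
#' The probability map is thresholded (strictly above `probThreshold`),
#' holes are filled and components below `minNucleusArea` px removed.
#'
#' @inheritParams predictNucleusProb
#' @param probThreshold Probability cut in 0..1.
#' @param minNucleusArea Minimum nucleus area in px.
#' @return Logical nucleus mask.
#' @export
segmentNuclei <- function(stack, model, probThreshold = 0.5,
                          minNucleusArea = 30L) {
  prob <- predictNucleusProb(stack, model)
  mask <- prob > probThreshold
  if (any(mask)) mask <- EBImage::fillHull(mask * 1) > 0.5
  .dropSmallComponents(mask, minNucleusArea)
}

#' Split a binary mask into object instances
#'
#' Distance-transform watershed with an h-maxima style tolerance (default
#' 2 px) separates touching objects; masks without internal distance
#' maxima degrade gracefully to connected components.
#'
#' @param mask Logical mask.
#' @param h Watershed tolerance (minimum marker dynamic) in px.
#' @param classOf Class code to attach to the instances.
#' @return An [InstanceMask-class] with contiguous ids 1..K.
#' @export
splitInstances <- function(mask, h = 2,
                           classOf = histoClassCodes()[["nucleus"]]) {
  if (!any(mask)) {
    return(InstanceMask(matrix(0L, nrow(mask), ncol(mask)), classOf))
  }
  d <- EBImage::distmap(mask * 1)
  lab <- EBImage::watershed(d, tolerance = h, ext = 1L)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  ids <- sort(setdiff(unique(as.vector(lab)), 0L))
  if (length(ids) && !identical(ids, seq_along(ids))) {
    remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  InstanceMask(lab, classOf)
}

#' Detect squamous pits as interior holes of the tissue mask
#'
#' Pits are operationalized as enclosed holes of the segmented tissue
#' (diseased epidermis) at least `minPitArea` px in size; used for the
#' well-differentiated grade only.
#'
#' @param tissueMask Logical mask of segmented tissue.
#' @param minPitArea Minimum hole area in px.
#' @return Logical pit mask.
#' @export
detectPits <- function(tissueMask, minPitArea = 200L) {
  if (!any(tissueMask)) return(tissueMask & FALSE)
  filled <- EBImage::fillHull(tissueMask * 1) > 0.5
  holes <- filled & !tissueMask
  .dropSmallComponents(holes, minPitArea)
}

.pseudoLUT <- function(gradeLabel) {
  list(
    background = c(1, 1, 1),
    matrix = c(0.75, 0.75, 0.75),
    bright600 = if (gradeLabel == "normal") c(1, 0.85, 0.1)
                else c(0.85, 0.08, 0.08),
    pit = c(1, 0.65, 0.8),
    nucleus = c(0.15, 0.2, 0.8)
  )
}

#' Compose a pseudo-color image from per-class masks
#'
#' Fixed lookup: nuclei blue, eosinophilic matrix gray, squamous pits
#' pink, background white; the 600 nm class renders yellow for normal
#' tissue (lipid droplets) and red for tumor grades (keratin pearls).
#' Overlaps resolve by priority nucleus > bright600 > pit > matrix, so
#' every pixel receives exactly one color.
#'
#' @param masks A [ClassMask-class], or a named list of logical masks with
#'   any of `matrix`, `bright600`, `pit`, `nucleus`.
#' @param gradeLabel Grade of the slide ("normal", "poorly", "well");
#'   selects the droplet/pearl color semantics.
#' @return `h x w x 3` RGB array in 0..1.
#' @export
composePseudocolor <- function(masks, gradeLabel = c("normal", "poorly", "well")) {
  gradeLabel <- match.arg(gradeLabel)
  if (is(masks, "ClassMask")) {
    masks <- list(matrix = classLayer(masks, "matrix"),
                  bright600 = classLayer(masks, "bright600"),
                  pit = classLayer(masks, "pit"),
                  nucleus = classLayer(masks, "nucleus"))
  }
  dims <- lapply(masks, dim)
  if (length(unique(dims)) != 1L)
    stop("masks are not co-registered (shape mismatch)", call. = FALSE)
  d <- dims[[1L]]
  lut <- .pseudoLUT(gradeLabel)
  rgb <- array(1, c(d, 3L))   # background white
  # ascending priority: matrix < pit < bright600 < nucleus
  for (cls in c("matrix", "pit", "bright600", "nucleus")) {
    m <- masks[[cls]]
    if (is.null(m) || !any(m)) next
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[m] <- lut[[cls]][ch]
      rgb[, , ch] <- plane
    }
  }
  rgb
}

#' Full band-specific segmentation of one field
#'
#' Runs the three band-specific segmentations and assembles one semantic
#' [ClassMask-class]: adaptive dark-object threshold at 520 nm (collagen
#' fibers / diseased epidermis), adaptive threshold at 600 nm (keratin
#' pearls for tumor grades; bright unstained lipid droplets for normal
#' tissue), random-forest nucleus segmentation at 630 nm, and -- for the
#' well-differentiated grade -- squamous pits as enclosed tissue holes.
#' Overlaps resolve by priority nucleus > bright600 > pit > matrix.
#'
#' @param stack Preprocessed [SpectralStack-class] field or mosaic.
#' @param model A [NucleusModel-class].
#' @param grade Grade label of the slide.
#' @param blockSize,offsetFrac,minArea Adaptive threshold parameters.
#' @param probThreshold,minNucleusArea Nucleus segmentation parameters.
#' @param minPitArea Minimum squamous-pit area in px.
#' @return A [ClassMask-class].
#' @export
segmentField <- function(stack, model, grade = c("normal", "poorly", "well"),
                         blockSize = 51L, offsetFrac = 0.02, minArea = 30L,
                         probThreshold = 0.5, minNucleusArea = 30L,
                         minPitArea = 200L) {
  grade <- match.arg(grade)
  m520 <- segmentAdaptive(getBand(stack, 520), blockSize, offsetFrac, minArea)
  m600 <- segmentAdaptive(getBand(stack, 600), blockSize, offsetFrac, minArea,
                          polarity = if (grade == "normal") "bright" else "dark")
  if (grade != "normal") {
    # keratin pearls are concentric whorls larger than the threshold block:
    # the local-mean rule recovers the rings but can miss the center, so
    # close small gaps and fill the interior to one solid object per pearl;
    # keratin is eosin-dense, so drop components that are not substantially
    # darker than the field's matrix level (mild texture fluctuations)
    m600 <- EBImage::closing(m600 * 1, EBImage::makeBrush(9L, "disc")) > 0.5
    m600 <- EBImage::fillHull(m600 * 1) > 0.5
    m600 <- .keepDarkComponents(m600, getBand(stack, 600), maxRel = 0.85)
  } else {
    # lipid droplets are large round unstained vacuoles enclosed by tissue;
    # restrict the bright mask to the filled collagen interior and drop
    # irregular inter-fiber gaps by a circularity criterion
    interior <- EBImage::fillHull(m520 * 1) > 0.5
    m600 <- .keepRoundComponents(m600 & interior, minArea = 300L,
                                 minCircularity = 0.5)
  }
  nuc <- segmentNuclei(stack, model, probThreshold, minNucleusArea)
  codes <- histoClassCodes()
  labels <- matrix(codes[["background"]], nrow(m520), ncol(m520))
  labels[m520] <- codes[["matrix"]]
  if (grade == "well") {
    tissue <- m520 | m600 | nuc
    pits <- detectPits(tissue, minPitArea)
    labels[pits] <- codes[["pit"]]
  }
  labels[m600] <- codes[["bright600"]]
  labels[nuc] <- codes[["nucleus"]]
  ClassMask(labels)
}
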