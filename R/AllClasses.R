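#' @import methods
NULL

#' SpectralStack: one field of view of a multispectral acquisition
#'
#' Container for a set of co-registered single-band grayscale images of the
#' same microscope field, acquired under narrow-band LED illumination.  Band
#' images are numeric matrices in gray-level units (0 .. 2^bitDepth - 1) and
#' are kept in floating point until written to disk.
#'
#' @slot bands List of numeric matrices, one per band, identical dimensions.
#' @slot wavelengths Numeric vector of band center wavelengths in nm,
#'   strictly increasing, one per band.
#' @slot pixelSize Physical pixel size in micrometres per pixel.
#' @slot bitDepth Integer bit depth of the sensor (8 or 16).
#' @slot fieldId Character identifier of the field of view.
#' @export
setClass("SpectralStack",
  representation(
    bands = "list",
    wavelengths = "numeric",
    pixelSize = "numeric",
    bitDepth = "integer",
    fieldId = "character"
  )
)

setValidity("SpectralStack", function(object) {
  msgs <- character()
  b <- object@bands
  if (length(b) < 1L) msgs <- c(msgs, "stack must contain at least one band")
  if (!all(vapply(b, is.matrix, logical(1L))))
    msgs <- c(msgs, "all bands must be matrices")
  if (length(b) >= 1L) {
    d <- dim(b[[1L]])
    if (!all(vapply(b, function(x) identical(dim(x), d), logical(1L))))
      msgs <- c(msgs, "all bands must share identical height x width")
  }
  if (length(b) != length(object@wavelengths))
    msgs <- c(msgs, "number of bands must equal number of wavelengths")
  if (length(object@wavelengths) > 1L &&
      any(diff(object@wavelengths) <= 0))
    msgs <- c(msgs, "wavelengths must be strictly increasing")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msgs <- c(msgs, "pixelSize must be a positive scalar (um/px)")
  if (!(object@bitDepth %in% c(8L, 16L)))
    msgs <- c(msgs, "bitDepth must be 8 or 16")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SpectralStack
#'
#' @param bands List of numeric band matrices (ascending wavelength order).
#' @param wavelengths Numeric vector of band centers (nm).
#' @param pixelSize Pixel size in um/px (default 0.5).
#' @param bitDepth Sensor bit depth, 8 or 16.
#' @param fieldId Field identifier string.
#' @return A [SpectralStack-class] object.
#' @examples
#' s <- SpectralStack(list(matrix(0, 4, 4), matrix(1, 4, 4)),
#'                    wavelengths = c(520, 630))
#' nbands(s)
#' @export
SpectralStack <- function(bands, wavelengths, pixelSize = 0.5,
                          bitDepth = 8L, fieldId = "") {
  if (length(bands) != length(wavelengths))
    stop("number of bands must equal number of wavelengths", call. = FALSE)
  ord <- order(wavelengths)
  new("SpectralStack",
      bands = bands[ord],
      wavelengths = as.numeric(wavelengths[ord]),
      pixelSize = as.numeric(pixelSize),
      bitDepth = as.integer(bitDepth),
      fieldId = as.character(fieldId))
}

#' Histological class codes of the per-pixel semantic mask
#'
#' Fixed mapping between integer labels and the five semantic classes the
#' band-specific segmentation produces: background, eosinophilic matrix
#' (collagen fibers in dermis / diseased epidermis; the 520 nm class),
#' bright600 (lipid droplet or keratin pearl; the 600 nm class), nucleus
#' (the 630 nm class) and squamous pit.
#'
#' @return Named integer vector of class codes.
#' @export
histoClassCodes <- function() {
  c(background = 0L, matrix = 1L, bright600 = 2L, nucleus = 3L, pit = 4L)
}

#' ClassMask: per-pixel semantic labels for one field
#'
#' @slot labels Integer matrix of class labels.
#' @slot classCodes Named integer vector mapping class names to label
#'   values (see [histoClassCodes()]).
#' @export
setClass("ClassMask",
  representation(labels = "matrix", classCodes = "integer"))

setValidity("ClassMask", function(object) {
  msgs <- character()
  if (is.null(names(object@classCodes)) || any(names(object@classCodes) == ""))
    msgs <- c(msgs, "classCodes must be a fully named integer vector")
  lv <- unique(as.vector(object@labels))
  if (!all(lv %in% object@classCodes))
    msgs <- c(msgs, "every label value must appear in classCodes")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ClassMask
#' @param labels Integer matrix of per-pixel labels.
#' @param classCodes Named integer vector of permitted codes.
#' @return A [ClassMask-class] object.
#' @export
ClassMask <- function(labels, classCodes = histoClassCodes()) {
  storage.mode(labels) <- "integer"
  new("ClassMask", labels = labels, classCodes = classCodes)
}

#' InstanceMask: labelled connected objects of one semantic class
#'
#' @param x,object An `InstanceMask`.
#' @slot labels Integer matrix; 0 = background, k >= 1 = instance id.
#'   Instance ids are contiguous 1..K.
#' @slot classOf Integer class code (from [histoClassCodes()]) the
#'   instances belong to.
#' @export
setClass("InstanceMask",
  representation(labels = "matrix", classOf = "integer"))

setValidity("InstanceMask", function(object) {
  ids <- setdiff(unique(as.vector(object@labels)), 0L)
  if (length(ids) && !identical(sort(ids), seq_len(max(ids))))
    return("instance ids must be contiguous 1..K")
  TRUE
})

#' Construct an InstanceMask
#' @param labels Integer label matrix (0 background, 1..K instances).
#' @param classOf Class code of the instances.
#' @return An [InstanceMask-class] object.
#' @export
InstanceMask <- function(labels, classOf = histoClassCodes()[["nucleus"]]) {
  storage.mode(labels) <- "integer"
  new("InstanceMask", labels = labels, classOf = as.integer(classOf))
}

#' StainSpectra: absorbance coefficients of hematoxylin and eosin
#'
#' Unitless optical-density-per-unit-concentration curves for the two H&E
#' dyes evaluated at the stack's band centers.  Hematoxylin peaks near
#' 560 nm with support over 400-600 nm (and a long red shoulder that keeps
#' nuclei absorbing at 630 nm); eosin peaks near 518/528 nm with support
#' over 450-650 nm.
#'
#' @slot wavelengths Band centers (nm).
#' @slot epsH Hematoxylin absorbance coefficients at those wavelengths.
#' @slot epsE Eosin absorbance coefficients at those wavelengths.
#' @export
setClass("StainSpectra",
  representation(wavelengths = "numeric", epsH = "numeric", epsE = "numeric"))

setValidity("StainSpectra", function(object) {
  if (length(object@wavelengths) != length(object@epsH) ||
      length(object@wavelengths) != length(object@epsE))
    return("wavelengths, epsH and epsE must have equal length")
  if (any(object@epsH < 0) || any(object@epsE < 0))
    return("absorbance coefficients must be non-negative")
  TRUE
})

#' PhantomScene: geometric ground truth of one synthetic tissue field
#'
#' @param object A `PhantomScene`.
#' @slot grade One of "normal", "poorly", "well".
#' @slot nuclei data.frame of nucleus ellipses (center, axes, orientation,
#'   area in um^2).
#' @slot pearls data.frame of keratin-pearl disks (center, radius).
#' @slot droplets data.frame of lipid-droplet disks.
#' @slot pits data.frame of squamous-pit disks (well grade only).
#' @slot stainH Matrix of hematoxylin concentration per pixel.
#' @slot stainE Matrix of eosin concentration per pixel.
#' @slot truthMask [ClassMask-class] with the ground-truth labels.
#' @slot pixelSize Pixel size in um/px.
#' @export
setClass("PhantomScene",
  representation(
    grade = "character",
    nuclei = "data.frame",
    pearls = "data.frame",
    droplets = "data.frame",
    pits = "data.frame",
    stainH = "matrix",
    stainE = "matrix",
    truthMask = "ClassMask",
    pixelSize = "numeric"
  )
)

setValidity("PhantomScene", function(object) {
  msgs <- character()
  if (!(object@grade %in% c("normal", "poorly", "well")))
    msgs <- c(msgs, "grade must be one of normal/poorly/well")
  if (!identical(dim(object@stainH), dim(object@stainE)))
    msgs <- c(msgs, "stain maps must share dimensions")
  if (nrow(object@pearls) > 0 && object@grade == "normal")
    msgs <- c(msgs, "pearls are only present in tumor grades")
  if (nrow(object@droplets) > 0 && object@grade != "normal")
    msgs <- c(msgs, "droplets are only present in normal tissue")
  if (nrow(object@pits) > 0 && object@grade != "well")
    msgs <- c(msgs, "pits are only present in the well-differentiated grade")
  if (length(msgs)) msgs else TRUE
})

#' PairwiseTransform: robust registration of one tile pair
#'
#' @param object A `PairwiseTransform`.
#' @slot model "translation", "similarity" or "affine".
#' @slot matrix 2x3 matrix mapping source (x, y, 1) to target (x, y),
#'   x = column, y = row.
#' @slot nInliers Number of RANSAC inliers supporting the model.
#' @slot inlierRMS Root-mean-square residual of the inliers in pixels.
#' @export
setClass("PairwiseTransform",
  representation(model = "character", matrix = "matrix",
                 nInliers = "integer", inlierRMS = "numeric"))

setValidity("PairwiseTransform", function(object) {
  msgs <- character()
  if (!(object@model %in% c("translation", "similarity", "affine")))
    msgs <- c(msgs, "unknown transform model")
  if (!identical(dim(object@matrix), c(2L, 3L)))
    msgs <- c(msgs, "matrix must be 2x3")
  minIn <- if (object@model == "translation") 2L else 4L
  if (object@nInliers < minIn)
    msgs <- c(msgs, sprintf("need >= %d inliers for model '%s'",
                            minIn, object@model))
  if (length(msgs)) msgs else TRUE
})

#' NucleusModel: trained random-forest pixel classifier for the 630 nm band
#'
#' @slot forest Fitted `ranger` probability forest.
#' @slot featureNames Ordered character vector of the pixel features the
#'   forest was trained on (fixed order; models are only applied to feature
#'   matrices with this exact column order).
#' @slot seed Integer training seed.
#' @slot trainInfo List with training provenance (fields used, class
#'   counts, package version).
#' @export
setClass("NucleusModel",
  representation(forest = "ANY", featureNames = "character",
                 seed = "integer", trainInfo = "list"))

# ---- accessors ---------------------------------------------------------

#' @describeIn SpectralStack List of band matrices.
#' @param x,object A `SpectralStack`.
#' @export
setGeneric("bands", function(x) standardGeneric("bands"))
#' @rdname SpectralStack-class
#' @export
setMethod("bands", "SpectralStack", function(x) x@bands)

#' @describeIn SpectralStack Band center wavelengths (nm).
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))
#' @rdname SpectralStack-class
#' @export
setMethod("wavelengths", "SpectralStack", function(x) x@wavelengths)

#' @describeIn SpectralStack Pixel size in um/px.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname SpectralStack-class
#' @export
setMethod("pixelSize", "SpectralStack", function(x) x@pixelSize)
#' @rdname SpectralStack-class
#' @export
setMethod("pixelSize", "PhantomScene", function(x) x@pixelSize)

#' @describeIn SpectralStack Sensor bit depth.
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))
#' @rdname SpectralStack-class
#' @export
setMethod("bitDepth", "SpectralStack", function(x) x@bitDepth)

#' @describeIn SpectralStack Field identifier.
#' @export
setGeneric("fieldId", function(x) standardGeneric("fieldId"))
#' @rdname SpectralStack-class
#' @export
setMethod("fieldId", "SpectralStack", function(x) x@fieldId)

#' @describeIn SpectralStack Number of bands.
#' @export
setGeneric("nbands", function(x) standardGeneric("nbands"))
#' @rdname SpectralStack-class
#' @export
setMethod("nbands", "SpectralStack", function(x) length(x@bands))

#' @describeIn SpectralStack Largest representable gray level.
#' @export
setGeneric("maxValue", function(x) standardGeneric("maxValue"))
#' @rdname SpectralStack-class
#' @export
setMethod("maxValue", "SpectralStack", function(x) 2^x@bitDepth - 1)

#' @rdname SpectralStack-class
#' @export
setMethod("dim", "SpectralStack", function(x) dim(x@bands[[1L]]))

#' Extract one band image by its center wavelength
#'
#' @param x A [SpectralStack-class].
#' @param wavelength Band center in nm; must match one of
#'   `wavelengths(x)` exactly.
#' @return The band's numeric matrix.
#' @export
getBand <- function(x, wavelength) {
  i <- match(wavelength, x@wavelengths)
  if (is.na(i))
    stop(sprintf("stack has no band at %g nm (bands: %s)", wavelength,
                 paste(x@wavelengths, collapse = ", ")), call. = FALSE)
  x@bands[[i]]
}

#' @describeIn ClassMask Integer label matrix.
#' @param x,object A `ClassMask`.
#' @export
setGeneric("labels2d", function(x) standardGeneric("labels2d"))
#' @rdname ClassMask-class
#' @export
setMethod("labels2d", "ClassMask", function(x) x@labels)
#' @rdname InstanceMask-class
#' @export
setMethod("labels2d", "InstanceMask", function(x) x@labels)

#' @describeIn ClassMask Named class-code vector.
#' @export
setGeneric("classCodes", function(x) standardGeneric("classCodes"))
#' @rdname ClassMask-class
#' @export
setMethod("classCodes", "ClassMask", function(x) x@classCodes)

#' Logical mask of one semantic class
#' @param mask A [ClassMask-class].
#' @param class Class name (one of `names(classCodes(mask))`).
#' @return Logical matrix.
#' @export
classLayer <- function(mask, class) {
  codes <- mask@classCodes
  if (!(class %in% names(codes)))
    stop(sprintf("unknown class '%s'", class), call. = FALSE)
  mask@labels == codes[[class]]
}

#' @describeIn InstanceMask Number of instances.
#' @export
setGeneric("nInstances", function(x) standardGeneric("nInstances"))
#' @rdname InstanceMask-class
#' @export
setMethod("nInstances", "InstanceMask", function(x) max(0L, max(x@labels)))

#' @rdname SpectralStack-class
#' @export
setMethod("show", "SpectralStack", function(object) {
  d <- dim(object)
  cat(sprintf("SpectralStack '%s': %d bands (%g-%g nm), %d x %d px, %g um/px, %d-bit\n",
              object@fieldId, length(object@bands),
              min(object@wavelengths), max(object@wavelengths),
              d[1L], d[2L], object@pixelSize, object@bitDepth))
})

#' @rdname ClassMask-class
#' @export
setMethod("show", "ClassMask", function(object) {
  tab <- table(factor(object@labels, levels = object@classCodes,
                      labels = names(object@classCodes)))
  cat("ClassMask", paste(dim(object@labels), collapse = " x "), "px\n")
  print(tab)
})

#' @rdname PhantomScene-class
#' @export
setMethod("show", "PhantomScene", function(object) {
  cat(sprintf("PhantomScene grade=%s: %d nuclei, %d pearls, %d droplets, %d pits (%s px)\n",
              object@grade, nrow(object@nuclei), nrow(object@pearls),
              nrow(object@droplets), nrow(object@pits),
              paste(dim(object@stainH), collapse = " x ")))
})

#' @rdname PairwiseTransform-class
#' @export
setMethod("show", "PairwiseTransform", function(object) {
  cat(sprintf("PairwiseTransform (%s): tx=%.2f ty=%.2f, %d inliers, RMS %.3f px\n",
              object@model, object@matrix[1, 3], object@matrix[2, 3],
              object@nInliers, object@inlierRMS))
})
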