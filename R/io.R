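# Reading and writing of spectral stacks (multi-page TIFF or per-band file
# directories with sidecar JSON metadata), label masks and measurement
# tables.  Stacks are stored losslessly: gray levels are integers in
# 0..2^bitDepth-1 and survive a write/read round trip bit-exactly.

.sidecarPath <- function(path) sub("\\.[A-Za-z]+$", "", path) |> paste0(".json")

#' Write a spectral stack to a multi-page TIFF with JSON sidecar
#'
#' Band images are rounded to integer gray levels and written as one TIFF
#' page per band (ascending wavelength).  Wavelengths, pixel size, bit
#' depth and field id go to a sidecar JSON file next to the TIFF.
#'
#' @param stack A [SpectralStack-class].
#' @param path Output file, extension `.tif`/`.tiff`.
#' @return `path`, invisibly.
#' @seealso [readStack()]
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "SpectralStack"))
  validObject(stack)
  mv <- maxValue(stack)
  pages <- lapply(stack@bands, function(b) {
    b <- pmin(pmax(round(b), 0), mv)
    b / mv
  })
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = stack@bitDepth,
                            compression = "none", reduce = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop(sprintf("cannot write stack to '%s'", path), call. = FALSE)
  meta <- list(wavelengths_nm = stack@wavelengths,
               pixel_size_um = stack@pixelSize,
               bit_depth = stack@bitDepth,
               field_id = stack@fieldId)
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a spectral stack from a multi-page TIFF or per-band directory
#'
#' Two layouts are accepted: a multi-page TIFF written by [writeStack()]
#' (wavelengths recovered from the sidecar JSON) or a directory of
#' per-band files named `band_<wavelength>nm.tif` / `.png`.  Bands are
#' returned sorted by ascending wavelength with intensities unchanged.
#'
#' @param path TIFF file or directory of band files.
#' @param pixelSize Pixel size in um/px; overrides sidecar metadata when
#'   given (directories without sidecar require it or use the 0.5 default).
#' @param expectedWavelengths Optional numeric vector; an error names any
#'   wavelength whose band file is missing.
#' @return A [SpectralStack-class].
#' @export
readStack <- function(path, pixelSize = NULL, expectedWavelengths = NULL) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "^band_[0-9]+nm\\.(tif|tiff|png)$",
                        full.names = TRUE)
    if (length(files) == 0L)
      stop(sprintf("no band files 'band_<wavelength>nm.*' found in '%s'", path),
           call. = FALSE)
    wl <- as.numeric(sub("^band_([0-9]+)nm\\..*$", "\\1", basename(files)))
    if (!is.null(expectedWavelengths)) {
      missing <- setdiff(expectedWavelengths, wl)
      if (length(missing))
        stop(sprintf("missing band file(s) for wavelength(s): %s nm",
                     paste(missing, collapse = ", ")), call. = FALSE)
    }
    ord <- order(wl)
    files <- files[ord]; wl <- wl[ord]
    imgs <- lapply(files, .readGrayImage)
    bd <- max(vapply(imgs, attr, numeric(1L), "bitDepth"))
    bands <- lapply(imgs, function(x) round(unclass(x) * (2^bd - 1)))
    meta <- list()
    sc <- file.path(path, "stack.json")
    if (file.exists(sc)) meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  } else {
    if (!file.exists(path)) stop(sprintf("'%s' does not exist", path), call. = FALSE)
    pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    meta <- list()
    if (file.exists(.sidecarPath(path)))
      meta <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
    bd <- if (!is.null(meta$bit_depth)) as.integer(meta$bit_depth) else 8L
    bands <- lapply(pages, function(p) {
      if (length(dim(p)) == 3L) p <- p[, , 1L]
      round(p * (2^bd - 1))
    })
    wl <- if (!is.null(meta$wavelengths_nm)) as.numeric(meta$wavelengths_nm)
          else if (length(bands) == 13L) defaultBandCenters()
          else seq(420, by = 20, length.out = length(bands))
    if (length(wl) != length(bands))
      stop(sprintf("stack has %d bands but metadata lists %d wavelengths",
                   length(bands), length(wl)), call. = FALSE)
    if (!is.null(expectedWavelengths)) {
      missing <- setdiff(expectedWavelengths, wl)
      if (length(missing))
        stop(sprintf("missing band(s) at wavelength(s): %s nm",
                     paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  if (length(bands) < 2L)
    stop("expected >= 2 bands", call. = FALSE)
  d <- dim(bands[[1L]])
  if (!all(vapply(bands, function(b) identical(dim(b), d), logical(1L))))
    stop("band images have mismatched shapes", call. = FALSE)
  ps <- if (!is.null(pixelSize)) pixelSize
        else if (!is.null(meta$pixel_size_um)) as.numeric(meta$pixel_size_um)
        else 0.5
  bdFinal <- if (exists("bd", inherits = FALSE)) bd else 8L
  SpectralStack(bands, wl, pixelSize = ps, bitDepth = bdFinal,
                fieldId = if (!is.null(meta$field_id)) meta$field_id
                          else basename(path))
}

.readGrayImage <- function(f) {
  if (grepl("\\.png$", f, ignore.case = TRUE)) {
    img <- png::readPNG(f)
    bd <- 8L
  } else {
    img <- tiff::readTIFF(f)
    bd <- 8L
  }
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  structure(img, bitDepth = bd)
}

#' Write a label mask as an 8-bit PNG
#'
#' @param mask A [ClassMask-class] or [InstanceMask-class] (labels must be
#'   < 256).
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
writeMask <- function(mask, path) {
  lab <- labels2d(mask)
  if (max(lab) > 255L) stop("mask labels exceed 8-bit range", call. = FALSE)
  png::writePNG(lab / 255, path)
  invisible(path)
}

#' Read a label mask written by [writeMask()]
#' @param path PNG path.
#' @param classCodes Class codes to attach; defaults to [histoClassCodes()].
#' @return A [ClassMask-class].
#' @export
readMask <- function(path, classCodes = histoClassCodes()) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  ClassMask(matrix(as.integer(round(img * 255)), nrow(img), ncol(img)),
            classCodes = classCodes)
}

.gradeLevels <- c("normal", "poorly", "well")

#' Validate a measurement table
#'
#' A measurement table has one row per (slide, window-or-field, metric)
#' with columns `slide_id`, `field_or_window_id`, `grade_label`,
#' `metric_name`, `value`.  Grade labels come from the closed set
#' normal/poorly/well and values must be finite.
#'
#' @param table data.frame to validate.
#' @return The table, invisibly, or an error.
#' @export
validateMeasurements <- function(table) {
  need <- c("slide_id", "field_or_window_id", "grade_label",
            "metric_name", "value")
  if (!all(need %in% names(table)))
    stop(sprintf("measurement table must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  if (!all(table$grade_label %in% .gradeLevels))
    stop("grade_label must be one of normal/poorly/well", call. = FALSE)
  if (nrow(table) > 0 && !all(is.finite(table$value)))
    stop("measurement values must be finite", call. = FALSE)
  invisible(table)
}

#' Write a measurement table to CSV in stable order
#'
#' Rows are sorted by slide, window/field id, then metric so that repeated
#' runs produce byte-identical files.
#'
#' @param table Measurement data.frame (see [validateMeasurements()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeMeasurements <- function(table, path) {
  validateMeasurements(table)
  ord <- order(table$slide_id, table$field_or_window_id, table$metric_name)
  utils::write.csv(table[ord, c("slide_id", "field_or_window_id",
                                "grade_label", "metric_name", "value"),
                         drop = FALSE],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a measurement table written by [writeMeasurements()]
#' @param path CSV path.
#' @return Validated measurement data.frame.
#' @export
readMeasurements <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(slide_id = "character",
                                        field_or_window_id = "character",
                                        grade_label = "character",
                                        metric_name = "character",
                                        value = "numeric"))
  validateMeasurements(tab)
  tab
}
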