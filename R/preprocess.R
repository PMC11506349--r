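# Acquisition preprocessing: averaging of repeated frames and correction of
# uneven illumination with a two-dimensional per-pixel gamma map.

#' Average repeated acquisition frames of one field
#'
#' Per-pixel, per-band arithmetic mean of `n` frames of the same field,
#' which reduces independent sensor noise by a factor `sqrt(n)`.  The
#' result is kept in floating representation until written to disk.
#'
#' @param frames List of at least two [SpectralStack-class] frames with
#'   identical geometry and wavelengths.
#' @return A [SpectralStack-class] of the mean frame.
#' @export
averageFrames <- function(frames) {
  if (!is.list(frames) || length(frames) < 2L)
    stop("need at least 2 frames to average", call. = FALSE)
  ref <- frames[[1L]]
  for (f in frames[-1L]) {
    if (!identical(dim(f), dim(ref)) ||
        !identical(wavelengths(f), wavelengths(ref)))
      stop("frames have mismatched geometry or wavelengths", call. = FALSE)
  }
  n <- length(frames)
  meanBands <- lapply(seq_len(nbands(ref)), function(b) {
    acc <- frames[[1L]]@bands[[b]]
    for (f in frames[-1L]) acc <- acc + f@bands[[b]]
    acc / n
  })
  SpectralStack(meanBands, wavelengths(ref), pixelSize = pixelSize(ref),
                bitDepth = bitDepth(ref),
                fieldId = sub("_frame[0-9]+$", "", fieldId(ref)))
}

#' Correct uneven illumination with a 2-D per-pixel gamma map
#'
#' The illumination field `L` is estimated as a wide Gaussian blur of the
#' normalized image (sigma defaulting to `max(H, W) / 8`).  Each pixel is
#' then re-exposed through its own gamma, `O = I_norm ^ gamma(x, y)` with
#' `gamma = log(m) / log(L)` and `m = mean(L)`: pixels under an
#' illumination deficit (`L < m`) are brightened, pixels under excess
#' darkened, and a flat field maps exactly to its mean.  A uniform image
#' has `gamma = 1` everywhere and is returned unchanged; the output is
#' rescaled to the input range.
#'
#' @param img Single 2-D band image (numeric matrix, max > 0).
#' @param sigma Illumination-estimate blur in px.
#' @return Corrected image, same dimensions and range as the input.
#' @export
correctIllumination <- function(img, sigma = max(dim(img)) / 8) {
  stopifnot(is.matrix(img))
  mx <- max(img)
  if (mx <= 0) stop("constant-zero image cannot be corrected", call. = FALSE)
  iNorm <- img / mx
  # the illumination field is smooth: estimate it on a decimated image
  f <- max(1L, floor(sigma / 10))
  if (f > 1L) {
    small <- EBImage::resize(iNorm, w = ceiling(nrow(iNorm) / f),
                             h = ceiling(ncol(iNorm) / f))
    Ls <- EBImage::gblur(small, sigma = sigma / f, boundary = "replicate")
    L <- EBImage::resize(Ls, w = nrow(iNorm), h = ncol(iNorm))
  } else {
    L <- EBImage::gblur(iNorm, sigma = sigma, boundary = "replicate")
  }
  eps <- 1e-4
  L <- pmin(pmax(L, eps), 1 - eps)
  m <- mean(L)
  gam <- log(m) / log(L)
  out <- iNorm^gam
  out * mx
}

#' Average frames and correct illumination in every band
#'
#' Convenience wrapper applying [averageFrames()] then
#' [correctIllumination()] band by band, matching the acquisition order of
#' the imaging protocol (averaging first; the two steps differ only at
#' second order for small noise).
#'
#' @param frames List of [SpectralStack-class] frames.
#' @param correct If FALSE skip the illumination correction.
#' @param sigma Illumination-estimate blur in px.
#' @return A preprocessed [SpectralStack-class].
#' @export
preprocessField <- function(frames, correct = TRUE,
                            sigma = max(dim(frames[[1L]])) / 8) {
  avg <- averageFrames(frames)
  if (!correct) return(avg)
  corrected <- lapply(avg@bands, correctIllumination, sigma = sigma)
  SpectralStack(corrected, wavelengths(avg), pixelSize = pixelSize(avg),
                bitDepth = bitDepth(avg), fieldId = fieldId(avg))
}
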