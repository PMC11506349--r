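# Staging statistics: sliding-window nucleo/cytoplasmic ratio with
# exposure / centroid / pearl quality control, per-nucleus areas and
# atypia fractions below fixed thresholds, and keratin-pearl morphometry.

# integral-image window sums on a stride grid; returns matrix of sums for
# every window origin (rows x cols of the origin grid)
.windowSums <- function(x, window, rows0, cols0) {
  S <- apply(x, 2L, cumsum)
  S <- t(apply(S, 1L, cumsum))
  S <- rbind(0, cbind(0, S))
  r1 <- rows0; r2 <- rows0 + window - 1L
  c1 <- cols0; c2 <- cols0 + window - 1L
  outer(seq_along(r1), seq_along(c1), function(i, j)
    S[cbind(r2[i] + 1L, c2[j] + 1L)] - S[cbind(r1[i], c2[j] + 1L)] -
      S[cbind(r2[i] + 1L, c1[j])] + S[cbind(r1[i], c1[j])])
}

#' Select quality-controlled analysis windows on a mosaic
#'
#' A `window` x `window` box slides over the mosaic on a `stride` grid.
#' A window passes quality control when (a) its mean 630 nm intensity
#' lies within the exposure band (`exposure` as fractions of the gray
#' range), (b) the centroid of its tissue foreground falls inside the
#' central `centralFrac` part of the window (excluding under-exposed
#' areas and nucleus/keratin-pearl junctions), and (c) keratin-pearl
#' (600 nm class) pixels cover less than `maxPearlFrac` of the window.
#' Among passing windows, `nWindows` pairwise non-overlapping ones are
#' chosen greedily by descending tissue coverage, ties broken in
#' row-major scan order.  If fewer than `nWindows` pass, all passing
#' windows are returned with a warning.
#'
#' @param stack Mosaic [SpectralStack-class] (needs the 630 nm band).
#' @param mask Matching [ClassMask-class] from [segmentField()].
#' @param grade Grade label of the slide.  Keratin pearls exist only in
#'   tumor tissue, so rule (c) applies the bright600 class for "poorly"
#'   and "well"; for "normal" slides (where that class holds lipid
#'   droplets) the rule is vacuous.
#' @param nWindows Number of windows to select.
#' @param window Window side in px.
#' @param stride Search stride in px.
#' @param exposure Exposure band `c(lo, hi)` as fractions of gray range.
#' @param centralFrac Centroid tolerance as a fraction of window size.
#' @param maxPearlFrac Maximum fraction of bright600 pixels per window.
#' @return data.frame of selected windows (`row0`, `col0`, `size`,
#'   `mean_intensity`, `coverage`, `pearl_frac`, `centroid_off`), with
#'   attribute `nPassed` (total passing windows).
#' @export
selectWindows <- function(stack, mask, grade = c("well", "poorly", "normal"),
                          nWindows = 5L, window = 200L,
                          stride = 50L, exposure = c(0.1, 0.9),
                          centralFrac = 0.5, maxPearlFrac = 0.05) {
  grade <- match.arg(grade)
  d <- dim(stack)
  if (any(d < window))
    stop("mosaic is smaller than the analysis window", call. = FALSE)
  lab <- labels2d(mask)
  if (!identical(dim(lab), d))
    stop("mask does not match the mosaic", call. = FALSE)
  i630 <- getBand(stack, 630) / maxValue(stack)
  codes <- classCodes(mask)
  tissue <- (lab != codes[["background"]]) * 1
  pearl <- if (grade == "normal") matrix(0, d[1L], d[2L])
           else (lab == codes[["bright600"]]) * 1
  rows0 <- seq(1L, d[1L] - window + 1L, by = stride)
  cols0 <- seq(1L, d[2L] - window + 1L, by = stride)
  nPix <- window^2
  sumI <- .windowSums(i630, window, rows0, cols0)
  sumT <- .windowSums(tissue, window, rows0, cols0)
  sumP <- .windowSums(pearl, window, rows0, cols0)
  rowIdx <- matrix(rep(seq_len(d[1L]), d[2L]), d[1L], d[2L])
  colIdx <- matrix(rep(seq_len(d[2L]), each = d[1L]), d[1L], d[2L])
  sumTR <- .windowSums(tissue * rowIdx, window, rows0, cols0)
  sumTC <- .windowSums(tissue * colIdx, window, rows0, cols0)

  meanI <- sumI / nPix
  coverage <- sumT / nPix
  pearlFrac <- sumP / nPix
  centR <- sumTR / pmax(sumT, 1) - outer(rows0 + (window - 1) / 2,
                                         rep(1, length(cols0)))
  centC <- sumTC / pmax(sumT, 1) - outer(rep(1, length(rows0)),
                                         cols0 + (window - 1) / 2)
  half <- centralFrac * window / 2
  passed <- meanI >= exposure[1L] & meanI <= exposure[2L] &
    sumT > 0 & abs(centR) <= half & abs(centC) <= half &
    pearlFrac < maxPearlFrac

  cand <- which(passed, arr.ind = TRUE)
  out <- data.frame(row0 = integer(0), col0 = integer(0), size = integer(0),
                    mean_intensity = numeric(0), coverage = numeric(0),
                    pearl_frac = numeric(0), centroid_off = numeric(0))
  nPassed <- nrow(cand)
  if (nPassed > 0L) {
    scan <- (cand[, 1L] - 1L) * length(cols0) + cand[, 2L]  # row-major ties
    ord <- order(-coverage[cand], scan)
    selR <- integer(0); selC <- integer(0)
    for (k in ord) {
      r0 <- rows0[cand[k, 1L]]; c0 <- cols0[cand[k, 2L]]
      if (length(selR)) {
        ov <- abs(selR - r0) < window & abs(selC - c0) < window
        if (any(ov)) next
      }
      selR <- c(selR, r0); selC <- c(selC, c0)
      out <- rbind(out, data.frame(
        row0 = r0, col0 = c0, size = window,
        mean_intensity = meanI[cand[k, 1L], cand[k, 2L]],
        coverage = coverage[cand[k, 1L], cand[k, 2L]],
        pearl_frac = pearlFrac[cand[k, 1L], cand[k, 2L]],
        centroid_off = sqrt(centR[cand[k, 1L], cand[k, 2L]]^2 +
                            centC[cand[k, 1L], cand[k, 2L]]^2)))
      if (nrow(out) == nWindows) break
    }
  }
  if (nrow(out) < nWindows)
    warning(sprintf("only %d of %d requested windows passed quality control",
                    nrow(out), nWindows), call. = FALSE)
  attr(out, "nPassed") <- nPassed
  out
}

#' Nucleo/cytoplasmic ratio of one window
#'
#' Ratio of nucleus pixels to cytoplasm pixels, the cytoplasm being the
#' tissue foreground minus the nuclei (`mode = "cyto"`, default) or the
#' whole window area (`mode = "window"`, the nuclear area proportion).
#'
#' @param nucleusMask Logical nucleus mask of the window.
#' @param tissueMask Logical tissue mask (treated as including nuclei).
#' @param mode "cyto" or "window".
#' @return Non-negative scalar; `Inf` when the cytoplasm is empty.
#' @export
ncRatio <- function(nucleusMask, tissueMask, mode = c("cyto", "window")) {
  mode <- match.arg(mode)
  stopifnot(identical(dim(nucleusMask), dim(tissueMask)))
  if (!any(tissueMask)) stop("tissue mask is empty", call. = FALSE)
  tissueMask <- tissueMask | nucleusMask
  nNuc <- sum(nucleusMask)
  if (mode == "window") return(nNuc / length(nucleusMask))
  nCyto <- sum(tissueMask) - nNuc
  if (nCyto == 0L) return(Inf)
  nNuc / nCyto
}

#' Per-nucleus areas in physical units
#'
#' @param instances An [InstanceMask-class] from [splitInstances()].
#' @param pixelSize Pixel size in um/px.
#' @return data.frame with `instance`, `area_um2`, `centroid_row`,
#'   `centroid_col`; empty for an empty mask.
#' @export
nucleusAreas <- function(instances, pixelSize) {
  .assertScalarNumeric(pixelSize, "pixelSize", positive = TRUE)
  lab <- labels2d(instances)
  K <- nInstances(instances)
  if (K == 0L)
    return(data.frame(instance = integer(0), area_um2 = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0)))
  px <- tabulate(lab[lab > 0L], nbins = K)
  rowIdx <- matrix(rep(seq_len(nrow(lab)), ncol(lab)), nrow(lab))
  colIdx <- matrix(rep(seq_len(ncol(lab)), each = nrow(lab)), nrow(lab))
  inside <- lab > 0L
  sr <- rowsum(rowIdx[inside], lab[inside])
  sc <- rowsum(colIdx[inside], lab[inside])
  data.frame(instance = seq_len(K),
             area_um2 = px * pixelSize^2,
             centroid_row = as.vector(sr) / px,
             centroid_col = as.vector(sc) / px)
}

#' Fraction of nuclei below area thresholds (nuclear atypia)
#'
#' For each threshold, the fraction of nuclei with area strictly below it;
#' a per-nucleus flag at the 20 um^2 staging threshold is included for
#' overlay rendering (blue below, red at or above).
#'
#' @param table data.frame from [nucleusAreas()] (non-empty).
#' @param thresholds Area thresholds in um^2.
#' @return List with `fractions` (named by threshold) and `below20`
#'   (logical per nucleus).
#' @export
fractionBelow <- function(table, thresholds = c(10, 20, 30, 40)) {
  if (nrow(table) == 0L) stop("nucleus table is empty", call. = FALSE)
  fr <- vapply(thresholds, function(t) mean(table$area_um2 < t), numeric(1L))
  names(fr) <- as.character(thresholds)
  list(fractions = fr, below20 = table$area_um2 < 20)
}

#' Keratin-pearl counts and areas
#'
#' Instances of the 600 nm class at least `minAreaUm2` in area are counted
#' as keratin pearls (smaller specks are ignored).
#'
#' @param instances [InstanceMask-class] of the bright600 class.
#' @param pixelSize Pixel size in um/px.
#' @param minAreaUm2 Minimum pearl area in um^2.
#' @return List with `count`, `areas_um2`, `total_um2`.
#' @export
keratinPearlStats <- function(instances, pixelSize, minAreaUm2 = 100) {
  lab <- labels2d(instances)
  K <- nInstances(instances)
  if (K == 0L) return(list(count = 0L, areas_um2 = numeric(0), total_um2 = 0))
  areas <- tabulate(lab[lab > 0L], nbins = K) * pixelSize^2
  areas <- areas[areas >= minAreaUm2]
  list(count = length(areas), areas_um2 = areas, total_um2 = sum(areas))
}

#' Blue/red nuclear-atypia overlay
#'
#' Renders nuclei below the staging threshold in blue and the rest in red
#' on a white background (the overlay style of the atypia analysis).
#'
#' @param instances [InstanceMask-class] of nuclei.
#' @param pixelSize Pixel size in um/px.
#' @param threshold Area threshold in um^2.
#' @return `h x w x 3` RGB array.
#' @export
atypiaOverlay <- function(instances, pixelSize, threshold = 20) {
  lab <- labels2d(instances)
  rgb <- array(1, c(dim(lab), 3L))
  K <- nInstances(instances)
  if (K == 0L) return(rgb)
  areas <- tabulate(lab[lab > 0L], nbins = K) * pixelSize^2
  small <- areas < threshold
  blue <- c(0.15, 0.2, 0.85); red <- c(0.85, 0.1, 0.1)
  inside <- lab > 0L
  colSel <- ifelse(small[lab[inside]], 1, 0)
  for (ch in 1:3) {
    plane <- rgb[, , ch]
    plane[inside] <- colSel * blue[ch] + (1 - colSel) * red[ch]
    rgb[, , ch] <- plane
  }
  rgb
}
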