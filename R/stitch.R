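# Mosaic construction: scale-space corner features with normalized patch
# descriptors, Lowe-ratio matching, RANSAC registration (translation /
# similarity / affine) and feather-blended composition with edge cropping.
# Registration is estimated once on a reference band (default 630 nm,
# highest nuclear contrast) and the same per-tile transform is applied to
# all bands so the spectral cube stays co-registered.

#' Detect corner keypoints in a band image
#'
#' Harris corner response on a lightly smoothed image, followed by 5x5
#' non-maximum suppression; the strongest `maxKeypoints` responses away
#' from the border are kept.
#'
#' @param img Numeric band matrix.
#' @param maxKeypoints Maximum number of keypoints returned.
#' @param sigma Gradient smoothing scale in px.
#' @param border Margin in px excluded from detection (descriptor support).
#' @return data.frame with columns `x` (col), `y` (row), `response`.
#' @export
detectKeypoints <- function(img, maxKeypoints = 500L, sigma = 1.5,
                            border = 12L) {
  rng <- max(img) - min(img)
  if (rng <= 0) return(data.frame(x = numeric(0), y = numeric(0),
                                  response = numeric(0)))
  g <- EBImage::gblur(img / rng, sigma = sigma, boundary = "replicate")
  h <- nrow(g); w <- ncol(g)
  dy <- (g[c(2:h, h), ] - g[c(1, 1:(h - 1)), ]) / 2
  dx <- (g[, c(2:w, w)] - g[, c(1, 1:(w - 1))]) / 2
  sxx <- EBImage::gblur(dx * dx, sigma = 2, boundary = "replicate")
  syy <- EBImage::gblur(dy * dy, sigma = 2, boundary = "replicate")
  sxy <- EBImage::gblur(dx * dy, sigma = 2, boundary = "replicate")
  R <- (sxx * syy - sxy * sxy) - 0.05 * (sxx + syy)^2
  # 5x5 grayscale dilation = local max filter
  mx <- EBImage::dilate(R, EBImage::makeBrush(5, "box"))
  peak <- (R >= mx) & (R > 1e-8)
  peak[seq_len(border), ] <- FALSE
  peak[(h - border + 1L):h, ] <- FALSE
  peak[, seq_len(border)] <- FALSE
  peak[, (w - border + 1L):w] <- FALSE
  idx <- which(peak)
  if (length(idx) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), response = numeric(0)))
  rr <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  resp <- R[idx]
  ord <- order(resp, decreasing = TRUE)
  keep <- ord[seq_len(min(maxKeypoints, length(ord)))]
  data.frame(x = cc[keep], y = rr[keep], response = resp[keep])
}

# z-normalized square patch descriptors; rows = keypoints
.describeKeypoints <- function(img, kp, patch = 15L) {
  r <- (patch - 1L) / 2L
  n <- nrow(kp)
  D <- matrix(NA_real_, n, patch * patch)
  for (i in seq_len(n)) {
    p <- img[(kp$y[i] - r):(kp$y[i] + r), (kp$x[i] - r):(kp$x[i] + r)]
    s <- stats::sd(p)
    if (s < 1e-9) next
    D[i, ] <- (as.vector(p) - mean(p)) / s
  }
  ok <- !is.na(D[, 1L])
  list(desc = D[ok, , drop = FALSE], kp = kp[ok, , drop = FALSE])
}

#' Detect and match keypoints between two overlapping tiles
#'
#' Corner keypoints with normalized intensity-patch descriptors are
#' matched by nearest descriptor distance, filtered with the Lowe ratio
#' test (best distance < `ratio` x second-best).
#'
#' @param imgA,imgB Band matrices of the two tiles (same bit depth).
#' @param ratio Lowe ratio-test threshold.
#' @param maxKeypoints Keypoints per image.
#' @param minMatches Minimum surviving matches; fewer is an error
#'   ("insufficient overlap/texture").
#' @return data.frame of matched coordinates `xa, ya, xb, yb, dist`.
#' @export
detectAndMatch <- function(imgA, imgB, ratio = 0.75, maxKeypoints = 500L,
                           minMatches = 8L) {
  da <- .describeKeypoints(imgA, detectKeypoints(imgA, maxKeypoints))
  db <- .describeKeypoints(imgB, detectKeypoints(imgB, maxKeypoints))
  if (nrow(da$kp) == 0L || nrow(db$kp) < 2L)
    stop("insufficient overlap/texture: too few keypoints", call. = FALSE)
  # squared euclidean distances between descriptor sets
  a2 <- rowSums(da$desc^2)
  b2 <- rowSums(db$desc^2)
  D2 <- outer(a2, b2, `+`) - 2 * tcrossprod(da$desc, db$desc)
  D2 <- pmax(D2, 0)
  best <- apply(D2, 1L, function(r) {
    o <- order(r)[1:2]
    c(o[1L], sqrt(r[o[1L]]), sqrt(r[o[2L]]))
  })
  keep <- best[2L, ] < ratio * best[3L, ]
  if (sum(keep) < minMatches)
    stop(sprintf("insufficient overlap/texture: %d matches (need >= %d)",
                 sum(keep), minMatches), call. = FALSE)
  j <- best[1L, keep]
  data.frame(xa = da$kp$x[keep], ya = da$kp$y[keep],
             xb = db$kp$x[j], yb = db$kp$y[j],
             dist = best[2L, keep])
}

.fitTranslation <- function(pa, pb) {
  t <- colMeans(pb - pa)
  matrix(c(1, 0, 0, 1, t[1L], t[2L]), 2L, 3L)
}

# Umeyama least-squares similarity (rotation + isotropic scale + translation)
.fitSimilarity <- function(pa, pb) {
  ma <- colMeans(pa); mb <- colMeans(pb)
  qa <- sweep(pa, 2L, ma); qb <- sweep(pb, 2L, mb)
  va <- sum(qa^2) / nrow(pa)
  if (va < 1e-9) return(.fitTranslation(pa, pb))
  S <- crossprod(qb, qa) / nrow(pa)
  sv <- svd(S)
  d <- sign(det(sv$u %*% t(sv$v)))
  Dm <- diag(c(1, d))
  R <- sv$u %*% Dm %*% t(sv$v)
  s <- sum(diag(Dm) * sv$d) / va
  t <- mb - s * R %*% ma
  cbind(s * R, t)
}

.fitAffine <- function(pa, pb) {
  X <- cbind(pa, 1)
  cf <- qr.solve(X, pb)   # 3 x 2
  t(cf)                   # 2 x 3
}

.transformResiduals <- function(M, pa, pb) {
  pred <- cbind(pa, 1) %*% t(M)
  sqrt(rowSums((pred - pb)^2))
}

#' Estimate a robust pairwise transform from matched points
#'
#' RANSAC (up to `maxIter` minimal samples, inlier threshold
#' `ransacThreshold` px) followed by a least-squares refit on the inliers.
#' The returned matrix maps source coordinates (first image of the match
#' set) into target coordinates.
#'
#' @param matches data.frame from [detectAndMatch()].
#' @param model "translation", "similarity" (default; translation +
#'   rotation + isotropic scale) or "affine".
#' @param ransacThreshold Inlier residual threshold in px.
#' @param maxIter Maximum RANSAC iterations.
#' @param seed Integer seed for the RANSAC sampler.
#' @return A [PairwiseTransform-class].
#' @export
estimateTransform <- function(matches,
                              model = c("similarity", "translation", "affine"),
                              ransacThreshold = 2, maxIter = 2000L,
                              seed = 1L) {
  model <- match.arg(model)
  pa <- as.matrix(matches[, c("xa", "ya")])
  pb <- as.matrix(matches[, c("xb", "yb")])
  n <- nrow(pa)
  k <- switch(model, translation = 1L, similarity = 2L, affine = 3L)
  if (n < k) stop("too few matches for the requested model", call. = FALSE)
  fit <- switch(model, translation = .fitTranslation,
                similarity = .fitSimilarity, affine = .fitAffine)
  minInliers <- if (model == "translation") 2L else 4L
  withr::with_seed(seed, {
    bestIn <- logical(n); bestCount <- -1L; bestRms <- Inf
    iters <- min(maxIter, max(1L, choose(n, k) * 2L))
    for (it in seq_len(iters)) {
      s <- sample.int(n, k)
      if (k > 1L && any(duplicated(pa[s, , drop = FALSE]))) next
      M <- try(fit(pa[s, , drop = FALSE], pb[s, , drop = FALSE]),
               silent = TRUE)
      if (inherits(M, "try-error")) next
      res <- .transformResiduals(M, pa, pb)
      inl <- res <= ransacThreshold
      cnt <- sum(inl)
      rms <- if (cnt) sqrt(mean(res[inl]^2)) else Inf
      if (cnt > bestCount || (cnt == bestCount && rms < bestRms)) {
        bestCount <- cnt; bestIn <- inl; bestRms <- rms
      }
    }
    if (bestCount < max(minInliers, k))
      stop(sprintf("RANSAC failed: best model has %d inliers (need >= %d)",
                   max(bestCount, 0L), minInliers), call. = FALSE)
    M <- fit(pa[bestIn, , drop = FALSE], pb[bestIn, , drop = FALSE])
    res <- .transformResiduals(M, pa, pb)
    inl <- res <= ransacThreshold
    if (sum(inl) >= max(minInliers, k)) {
      M <- fit(pa[inl, , drop = FALSE], pb[inl, , drop = FALSE])
      res <- .transformResiduals(M, pa, pb)
      inl <- res <= ransacThreshold
    } else inl <- bestIn
    new("PairwiseTransform", model = model, matrix = M,
        nInliers = as.integer(sum(inl)),
        inlierRMS = sqrt(mean(res[inl]^2)))
  })
}

# distance-to-edge feather weight map for a h x w tile
.featherWeights <- function(h, w) {
  outer(pmin(seq_len(h), h + 1L - seq_len(h)),
        pmin(seq_len(w), w + 1L - seq_len(w)), pmin)
}

#' Compose a mosaic from tiles and their transforms
#'
#' Every band of every tile is warped with the tile's single transform
#' (mapping tile coordinates into the anchor frame of the first tile),
#' overlaps are fused by distance-to-edge linear feathering, and the
#' mosaic is cropped to the maximal axis-aligned interior region free of
#' unfilled pixels.
#'
#' @param tiles List of [SpectralStack-class] tiles.
#' @param transforms List of [PairwiseTransform-class] (or bare 2x3
#'   matrices), one per tile, mapping each tile into the first tile's
#'   frame; the first entry is the identity.
#' @return A [SpectralStack-class] mosaic.
#' @export
composeMosaic <- function(tiles, transforms) {
  stopifnot(length(tiles) == length(transforms), length(tiles) >= 1L)
  Ms <- lapply(transforms, function(t)
    if (is(t, "PairwiseTransform")) t@matrix else t)
  if (length(tiles) == 1L) return(tiles[[1L]])
  ref <- tiles[[1L]]
  nb <- nbands(ref)
  # warped corner bounds over all tiles
  corners <- do.call(rbind, lapply(seq_along(tiles), function(i) {
    d <- dim(tiles[[i]])
    cs <- rbind(c(1, 1), c(d[2L], 1), c(1, d[1L]), c(d[2L], d[1L]))
    cbind(cs, 1) %*% t(Ms[[i]])
  }))
  x0 <- floor(min(corners[, 1L])); y0 <- floor(min(corners[, 2L]))
  x1 <- ceiling(max(corners[, 1L])); y1 <- ceiling(max(corners[, 2L]))
  W <- x1 - x0 + 1L; H <- y1 - y0 + 1L
  shift <- matrix(c(0, 0, 0, 0, 1 - x0, 1 - y0), 2L, 3L)
  acc <- replicate(nb, matrix(0, H, W), simplify = FALSE)
  wsum <- matrix(0, H, W)
  for (i in seq_along(tiles)) {
    d <- dim(tiles[[i]])
    M <- Ms[[i]]
    M[, 3L] <- M[, 3L] + shift[, 3L]
    wts <- warpBilinear(.featherWeights(d[1L], d[2L]), M, c(H, W))
    wts[is.na(wts)] <- 0
    for (b in seq_len(nb)) {
      v <- warpBilinear(tiles[[i]]@bands[[b]], M, c(H, W))
      v[is.na(v)] <- 0
      acc[[b]] <- acc[[b]] + v * wts
    }
    wsum <- wsum + wts
  }
  filled <- wsum > 0
  # shrink to the maximal interior rectangle free of unfilled pixels by
  # repeatedly trimming the boundary line with the most unfilled pixels
  r1 <- 1L; r2 <- H; c1 <- 1L; c2 <- W
  repeat {
    if (r1 > r2 || c1 > c2)
      stop("tiles do not form a filled mosaic", call. = FALSE)
    sub <- filled[r1:r2, c1:c2, drop = FALSE]
    if (all(sub)) break
    holes <- c(top = sum(!sub[1L, ]), bottom = sum(!sub[nrow(sub), ]),
               left = sum(!sub[, 1L]), right = sum(!sub[, ncol(sub)]))
    side <- names(which.max(holes))
    if (holes[[side]] == 0L) {
      # unfilled pixels strictly interior: cannot crop them away
      stop("tiles do not form a filled mosaic", call. = FALSE)
    }
    switch(side, top = r1 <- r1 + 1L, bottom = r2 <- r2 - 1L,
           left = c1 <- c1 + 1L, right = c2 <- c2 - 1L)
  }
  rows <- r1:r2; cols <- c1:c2
  bandsOut <- lapply(acc, function(a)
    (a / pmax(wsum, .Machine$double.eps))[rows, cols, drop = FALSE])
  SpectralStack(bandsOut, wavelengths(ref), pixelSize = pixelSize(ref),
                bitDepth = bitDepth(ref), fieldId = "mosaic")
}

#' Stitch an ordered strip of tiles into one mosaic
#'
#' Consecutive tiles are matched on the reference band, each pairwise
#' transform is estimated robustly and chained to the first tile's frame,
#' and all bands are fused with [composeMosaic()].
#'
#' @param tiles List of preprocessed [SpectralStack-class] tiles in strip
#'   order.
#' @param refWavelength Band used for matching (nm); 630 by default
#'   (highest nuclear contrast).
#' @param fallbackWavelengths Bands tried in order when the reference band
#'   lacks texture (e.g. acellular dermis is featureless at 630 nm but
#'   rich in collagen contrast at 520 nm).
#' @param model Transform model passed to [estimateTransform()].
#' @param ransacThreshold RANSAC inlier threshold in px.
#' @param seed RANSAC seed.
#' @return List with `mosaic` ([SpectralStack-class]) and `transforms`.
#' @export
stitchStrip <- function(tiles, refWavelength = 630,
                        fallbackWavelengths = 520,
                        model = "similarity", ransacThreshold = 2,
                        seed = 1L) {
  stopifnot(length(tiles) >= 1L)
  transforms <- vector("list", length(tiles))
  transforms[[1L]] <- new("PairwiseTransform", model = "translation",
                          matrix = matrix(c(1, 0, 0, 1, 0, 0), 2L, 3L),
                          nInliers = 2L, inlierRMS = 0)
  if (length(tiles) > 1L) {
    Mprev <- rbind(transforms[[1L]]@matrix, c(0, 0, 1))
    for (i in 2:length(tiles)) {
      m <- NULL
      for (wl in c(refWavelength, fallbackWavelengths)) {
        m <- try(detectAndMatch(getBand(tiles[[i]], wl),
                                getBand(tiles[[i - 1L]], wl)),
                 silent = TRUE)
        if (!inherits(m, "try-error")) break
      }
      if (inherits(m, "try-error"))
        stop(sprintf("tile graph disconnected: tiles %s unreachable (pair %d-%d failed: %s)",
                     paste(i:length(tiles), collapse = ","), i - 1L, i,
                     attr(m, "condition")$message), call. = FALSE)
      tp <- estimateTransform(m, model = model,
                              ransacThreshold = ransacThreshold,
                              seed = splitSeed(seed, sprintf("ransac%02d", i)))
      Mcur <- Mprev %*% rbind(tp@matrix, c(0, 0, 1))
      transforms[[i]] <- new("PairwiseTransform", model = tp@model,
                             matrix = Mcur[1:2, , drop = FALSE],
                             nInliers = tp@nInliers, inlierRMS = tp@inlierRMS)
      Mprev <- Mcur
    }
  }
  list(mosaic = composeMosaic(tiles, transforms), transforms = transforms)
}
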