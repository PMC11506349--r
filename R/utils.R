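# Internal numerics shared across modules: seed substreams, integral-image
# statistics, gradients and bilinear warping. All image matrices are indexed
# [row, col] and kept in double precision until written to disk.

#' Derive a reproducible sub-seed from a root seed and a stage label
#'
#' Every stochastic stage of the pipeline (scene sampling, sensor noise,
#' RANSAC, forest training, ...) draws its seed from one root seed plus a
#' human-readable label, so changing the randomness of one stage never
#' shifts another stage's stream.
#'
#' @param seed Integer root seed.
#' @param label Character scalar naming the substream.
#' @return A positive integer seed below 2^31.
#' @export
splitSeed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (v in utf8ToInt(label)) h <- (h * 131 + v) %% 1000003
  s <- abs(as.numeric(seed)) %% 65011 + 1
  as.integer((s * 32717 + h * 1009) %% 2147483563) + 1L
}

# Column-wise then row-wise cumulative sums give an integral image; zero
# padding plus a matching count image yields exact local means at borders.
.integralMean <- function(x, k) {
  stopifnot(k >= 1, k %% 2 == 1)
  h <- nrow(x); w <- ncol(x); r <- (k - 1L) / 2L
  cs <- function(m) {
    m <- apply(m, 2L, cumsum)
    t(apply(m, 1L, cumsum))
  }
  pad <- matrix(0, h + 2L * r, w + 2L * r)
  pad[(r + 1L):(r + h), (r + 1L):(r + w)] <- x
  cnt <- matrix(0, h + 2L * r, w + 2L * r)
  cnt[(r + 1L):(r + h), (r + 1L):(r + w)] <- 1
  S <- cs(pad); C <- cs(cnt)
  i1 <- seq_len(h); i2 <- i1 + 2L * r
  j1 <- seq_len(w); j2 <- j1 + 2L * r
  box <- function(M) {
    M2 <- rbind(0, cbind(0, M))
    M2[i2 + 1L, j2 + 1L] - M2[i1, j2 + 1L] - M2[i2 + 1L, j1] + M2[i1, j1]
  }
  box(S) / box(C)
}

#' Local mean of an image over a square neighborhood
#' @param x Numeric matrix.
#' @param k Odd window side in pixels.
#' @return Matrix of local means (borders use the valid sub-window).
#' @keywords internal
boxMean <- function(x, k) .integralMean(x, k)

#' Local standard deviation over a square neighborhood
#' @inheritParams boxMean
#' @keywords internal
localSd <- function(x, k) {
  m <- boxMean(x, k)
  sqrt(pmax(boxMean(x * x, k) - m * m, 0))
}

# Gaussian-derivative gradient magnitude (central differences on a blurred
# image); sigma in pixels.
gradientMagnitude <- function(x, sigma = 2) {
  g <- EBImage::gblur(x, sigma = sigma, boundary = "replicate")
  h <- nrow(g); w <- ncol(g)
  dr <- (g[c(2:h, h), ] - g[c(1, 1:(h - 1)), ]) / 2
  dc <- (g[, c(2:w, w)] - g[, c(1, 1:(w - 1))]) / 2
  sqrt(dr * dr + dc * dc)
}

# Inverse bilinear warp. M is a 2x3 matrix mapping source (x, y, 1) -> target
# (x, y) with x = column, y = row. Pixels sampling outside the source are NA.
warpBilinear <- function(img, M, outDim) {
  A <- rbind(M, c(0, 0, 1))
  Ainv <- solve(A)
  h <- outDim[1L]; w <- outDim[2L]
  xt <- rep(seq_len(w), each = h)
  yt <- rep(seq_len(h), times = w)
  xs <- Ainv[1, 1] * xt + Ainv[1, 2] * yt + Ainv[1, 3]
  ys <- Ainv[2, 1] * xt + Ainv[2, 2] * yt + Ainv[2, 3]
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  hs <- nrow(img); ws <- ncol(img)
  ok <- x0 >= 1 & y0 >= 1 & x0 + 1 <= ws & y0 + 1 <= hs
  out <- rep(NA_real_, h * w)
  if (any(ok)) {
    x0k <- x0[ok]; y0k <- y0[ok]; fxk <- fx[ok]; fyk <- fy[ok]
    idx <- function(r, c) (c - 1L) * hs + r
    v00 <- img[idx(y0k, x0k)]
    v01 <- img[idx(y0k, x0k + 1)]
    v10 <- img[idx(y0k + 1, x0k)]
    v11 <- img[idx(y0k + 1, x0k + 1)]
    out[ok] <- (1 - fyk) * ((1 - fxk) * v00 + fxk * v01) +
      fyk * ((1 - fxk) * v10 + fxk * v11)
  }
  matrix(out, h, w)
}

# intersection-over-union of two logical masks
maskIoU <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

.assertScalarNumeric <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}
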