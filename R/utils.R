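#' @keywords internal
"_PACKAGE"

## Internal raster helpers shared by the edge, weight-map and metric code.
## Images are plain numeric matrices, row-major top-left origin.

.assertImage <- function(img, minDim = 1L, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("'%s' must be a numeric matrix", arg), call. = FALSE)
  if (any(!is.finite(img)))
    stop(sprintf("'%s' contains non-finite values", arg), call. = FALSE)
  if (nrow(img) < minDim || ncol(img) < minDim)
    stop(sprintf("'%s' must be at least %dx%d", arg, minDim, minDim),
         call. = FALSE)
  invisible(img)
}

.assertSameShape <- function(...) {
  ms <- list(...)
  d <- dim(ms[[1L]])
  for (m in ms[-1L])
    if (!identical(dim(m), d))
      stop("rasters must share one shape", call. = FALSE)
  invisible(d)
}

## Replicate (edge-value) padding by `p` pixels on every side.
.padReplicate <- function(img, p) {
  h <- nrow(img); w <- ncol(img)
  ri <- c(rep.int(1L, p), seq_len(h), rep.int(h, p))
  ci <- c(rep.int(1L, p), seq_len(w), rep.int(w, p))
  img[ri, ci, drop = FALSE]
}

## Correlation (not flipped convolution) of an image with a small square
## kernel, replicate padding, output same shape as input.
.correlate <- function(img, kern) {
  k <- nrow(kern)
  stopifnot(k == ncol(kern), k %% 2L == 1L)
  p <- (k - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  P <- .padReplicate(img, p)
  out <- matrix(0, h, w)
  for (di in seq_len(k)) for (dj in seq_len(k)) {
    kv <- kern[di, dj]
    if (kv != 0)
      out <- out + kv * P[(di):(di + h - 1L), (dj):(dj + w - 1L), drop = FALSE]
  }
  out
}

## Separable filtering with a 1-D kernel along rows then columns
## (replicate padding); used by the SSIM Gaussian window.
.filterSeparable <- function(img, k1d) {
  k <- length(k1d)
  p <- (k - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  P <- .padReplicate(img, p)
  tmp <- matrix(0, h, w + 2L * p)
  for (i in seq_len(k))
    tmp <- tmp + k1d[i] * P[i:(i + h - 1L), , drop = FALSE]
  out <- matrix(0, h, w)
  for (j in seq_len(k))
    out <- out + k1d[j] * tmp[, j:(j + w - 1L), drop = FALSE]
  out
}

## Sum over `W` consecutive rows; output has nrow(M) - W + 1 rows.
.movingSumRows <- function(M, W) {
  cs <- apply(M, 2L, cumsum)
  cs <- rbind(0, cs)
  n <- nrow(cs)
  cs[(W + 1L):n, , drop = FALSE] - cs[1L:(n - W), , drop = FALSE]
}

.movingSumCols <- function(M, W) t(.movingSumRows(t(M), W))

## Monic polynomial coefficients (descending powers) with the given roots.
.polyFromRoots <- function(roots) {
  p <- 1
  for (r in roots) p <- c(p, 0) - c(0, r * p)
  p
}

## Evaluate a polynomial (descending coefficients) at (possibly complex) x.
.polyval <- function(coef, x) {
  y <- x * 0
  for (c0 in coef) y <- y * x + c0
  y
}
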