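## Fusion-quality metrics (entropy, mutual information, feature mutual
## information, Qabf edge preservation, SSIM) and multi-objective search
## indicators (IGD, hypervolume).

.quantize256 <- function(img) {
  x <- pmin(pmax(img, 0), 1)
  as.integer(floor(x * 255 + 0.5))
}

.entropyFromCounts <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Shannon entropy of an image
#'
#' Intensities are quantized to 256 uniform levels on `[0, 1]`;
#' `ENT = -sum P log2 P` with `0 log 0 := 0`. Ranges over `[0, 8]` bits.
#'
#' @param img Numeric matrix with values (nominally) in `[0, 1]`.
#' @return Entropy in bits.
#' @export
imageEntropy <- function(img) {
  .assertImage(img)
  q <- .quantize256(img)
  .entropyFromCounts(tabulate(q + 1L, nbins = 256L))
}

#' Mutual information between two images
#'
#' `MI = H(a) + H(b) - H(a, b)` on the 256 x 256 joint histogram of the
#' quantized intensities; symmetric and nonnegative, with
#' `MI(x, x) = ENT(x)`.
#'
#' @param a,b Numeric matrices of one shape.
#' @return Mutual information in bits.
#' @export
mutualInformation <- function(a, b) {
  .assertSameShape(a, b)
  qa <- .quantize256(a); qb <- .quantize256(b)
  ha <- .entropyFromCounts(tabulate(qa + 1L, nbins = 256L))
  hb <- .entropyFromCounts(tabulate(qb + 1L, nbins = 256L))
  hab <- .entropyFromCounts(tabulate(qa * 256L + qb + 1L, nbins = 65536L))
  max(ha + hb - hab, 0)
}

.gradientMagnitude <- function(img) {
  ks <- compassKernels()
  gx <- .correlate(img, ks$E0)
  gy <- .correlate(img, ks$E90)
  sqrt(gx * gx + gy * gy)
}

#' Feature mutual information (FMI)
#'
#' Mutual dependence between fused and source images measured on gradient
#' (feature) representations: each image's Sobel gradient magnitude is
#' rescaled to `[0, 1]`, and the normalized mutual information
#' `2 MI / (H_1 + H_2)` between fused and source features is averaged over
#' the two sources. Constant-gradient (featureless) inputs score 0.
#'
#' @param fused Fused image.
#' @param src1,src2 Source images, same shape.
#' @return Value in `[0, 1]`.
#' @export
fmi <- function(fused, src1, src2) {
  .assertSameShape(fused, src1, src2)
  gf <- .gradientMagnitude(fused)
  vals <- vapply(list(src1, src2), function(s) {
    gs <- .gradientMagnitude(s)
    mf <- max(gf); ms <- max(gs)
    if (mf <= 0 || ms <= 0) return(0)
    a <- gf / mf; b <- gs / ms
    ha <- imageEntropy(a); hb <- imageEntropy(b)
    if (ha + hb <= 0) return(0)
    2 * mutualInformation(a, b) / (ha + hb)
  }, 0)
  mean(vals)
}

#' Qabf edge-preservation metric
#'
#' Edge-information transfer from the sources to the fused image in the
#' Xydeas-Petrovic style: per-pixel Sobel gradient strength and orientation
#' are compared between each source and the fused image, mapped through
#' sigmoid preservation models
#' (strength: `Gg / (1 + exp(kg (G - sg)))` with `Gg = 0.9994`,
#' `kg = -15`, `sg = 0.5`; orientation: `Ga = 0.9879`, `ka = -22`,
#' `sa = 0.8`), normalized so exact preservation scores 1, and averaged
#' with the source gradient strengths as weights.
#'
#' @inheritParams fmi
#' @return Value in `[0, 1]`; 0 when both sources carry no gradient.
#' @export
qabf <- function(fused, src1, src2) {
  .assertSameShape(fused, src1, src2)
  ks <- compassKernels()
  grad <- function(img) {
    gx <- .correlate(img, ks$E0)
    gy <- .correlate(img, ks$E90)
    list(g = sqrt(gx * gx + gy * gy), a = atan2(gy, gx))
  }
  Gg <- 0.9994; kg <- -15; sg <- 0.5
  Ga <- 0.9879; ka <- -22; sa <- 0.8
  qMax <- (Gg / (1 + exp(kg * (1 - sg)))) * (Ga / (1 + exp(ka * (1 - sa))))
  f <- grad(fused)
  perSource <- function(s) {
    x <- grad(s)
    hi <- pmax(x$g, f$g)
    G <- ifelse(hi > 0, pmin(x$g, f$g) / pmax(hi, 1e-300), 0)
    da <- abs(x$a - f$a)
    da <- pmin(da, 2 * pi - da)          # wrap to [0, pi]
    A <- 1 - da / (pi / 2)
    Qg <- Gg / (1 + exp(kg * (G - sg)))
    Qa <- Ga / (1 + exp(ka * (A - sa)))
    pmin(Qg * Qa / qMax, 1)
  }
  g1 <- .gradientMagnitude(src1)
  g2 <- .gradientMagnitude(src2)
  wsum <- sum(g1) + sum(g2)
  if (wsum <= 0) return(0)
  (sum(perSource(src1) * g1) + sum(perSource(src2) * g2)) / wsum
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM over an 11 x 11 Gaussian window (`sigma = 1.5`), with
#' `C1 = 0.01^2`, `C2 = 0.03^2` for unit dynamic range.
#'
#' @param f,i Numeric matrices of one shape with intensities in `[0, 1]`.
#' @return Value in `[-1, 1]`; exactly 1 for identical images.
#' @export
ssimIndex <- function(f, i) {
  .assertSameShape(f, i)
  k <- stats::dnorm(seq(-5, 5), sd = 1.5)
  k <- k / sum(k)
  C1 <- 0.01^2; C2 <- 0.03^2
  muF <- .filterSeparable(f, k)
  muI <- .filterSeparable(i, k)
  sF <- .filterSeparable(f * f, k) - muF * muF
  sI <- .filterSeparable(i * i, k) - muI * muI
  sFI <- .filterSeparable(f * i, k) - muF * muI
  num <- (2 * muF * muI + C1) * (2 * sFI + C2)
  den <- (muF^2 + muI^2 + C1) * (sF + sI + C2)
  mean(num / den)
}

#' Inverted generational distance (IGD)
#'
#' Mean, over the reference front `pstar`, of the Euclidean distance to the
#' nearest member of the approximation set `A`. Zero iff every reference
#' point is matched exactly; lower is better.
#'
#' @param A Numeric matrix, one objective vector per row (approximation).
#' @param pstar Numeric matrix, one reference-front point per row.
#' @return Nonnegative scalar.
#' @export
igd <- function(A, pstar) {
  if (!is.matrix(A)) A <- matrix(A, nrow = 1L)
  if (!is.matrix(pstar)) pstar <- matrix(pstar, nrow = 1L)
  if (nrow(A) == 0L || nrow(pstar) == 0L)
    stop("empty point set", call. = FALSE)
  if (ncol(A) != ncol(pstar))
    stop("dimension mismatch", call. = FALSE)
  dmin <- vapply(seq_len(nrow(pstar)), function(i) {
    d2 <- colSums((t(A) - pstar[i, ])^2)
    sqrt(min(d2))
  }, 0)
  mean(dmin)
}

#' Hypervolume indicator
#'
#' Lebesgue measure of the objective-space region dominated by `A` and
#' bounded above by the reference point `ref`. Points not strictly
#' dominating `ref` are ignored. Two objectives use an exact sweep;
#' three or four use inclusion-exclusion over the nondominated points.
#'
#' @param A Numeric matrix of objective vectors (rows), all minimized.
#' @param ref Reference point, same dimension.
#' @return Nonnegative scalar (0, with a warning, when no point dominates
#'   `ref`).
#' @export
hypervolume <- function(A, ref) {
  if (!is.matrix(A)) A <- matrix(A, nrow = 1L)
  m <- ncol(A)
  if (length(ref) != m) stop("dimension mismatch", call. = FALSE)
  keep <- apply(A, 1L, function(p) all(p < ref))
  A <- A[keep, , drop = FALSE]
  if (nrow(A) == 0L) {
    warning("no point strictly dominates the reference point",
            call. = FALSE)
    return(0)
  }
  A <- nondominatedFilter(A)
  if (m == 2L) {
    o <- order(A[, 1L], A[, 2L])
    A <- A[o, , drop = FALSE]
    n <- nrow(A)
    nxt <- c(A[-1L, 1L], ref[1L])
    sum((nxt - A[, 1L]) * (ref[2L] - A[, 2L]))
  } else if (m <= 4L) {
    ## inclusion-exclusion over boxes [p, ref]
    n <- nrow(A)
    total <- 0
    for (sz in seq_len(n)) {
      combs <- utils::combn(n, sz)
      sgn <- (-1)^(sz + 1)
      for (ci in seq_len(ncol(combs))) {
        corner <- apply(A[combs[, ci], , drop = FALSE], 2L, max)
        total <- total + sgn * prod(ref - corner)
      }
    }
    total
  } else stop("hypervolume supports at most 4 objectives", call. = FALSE)
}

#' All fused-image quality metrics at once
#'
#' @inheritParams fmi
#' @return Named list: `ent`, `mi1`, `mi2`, `fmi`, `qabf`, `ssim1`,
#'   `ssim2`.
#' @export
metricReport <- function(fused, src1, src2) {
  list(ent = imageEntropy(fused),
       mi1 = mutualInformation(fused, src1),
       mi2 = mutualInformation(fused, src2),
       fmi = fmi(fused, src1, src2),
       qabf = qabf(fused, src1, src2),
       ssim1 = ssimIndex(fused, src1),
       ssim2 = ssimIndex(fused, src2))
}
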