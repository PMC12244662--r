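## Gradient-compass edge extraction: eight-direction Sobel filtering,
## maximum edge-strength maps, and modality-exclusive detail images.

#' Eight-direction Sobel compass kernels
#'
#' Builds the classical 3x3 Sobel kernel bank rotated in 45-degree steps.
#' `E0` responds to vertical edges (horizontal intensity gradient); each
#' subsequent kernel is the previous one with its outer ring of coefficients
#' rotated by one position, so `E(theta+180) == -E(theta)`.
#'
#' @return A named list of eight 3x3 integer matrices
#'   (`E0`, `E45`, ..., `E315`).
#' @examples
#' ks <- compassKernels()
#' stopifnot(all(ks$E180 == -ks$E0), all(vapply(ks, sum, 0) == 0))
#' @export
compassKernels <- function() {
  e0 <- matrix(c(-1, 0, 1,
                 -2, 0, 2,
                 -1, 0, 1), 3L, 3L, byrow = TRUE)
  ## ring positions clockwise from the top-left corner
  ring <- rbind(c(1, 1), c(1, 2), c(1, 3), c(2, 3),
                c(3, 3), c(3, 2), c(3, 1), c(2, 1))
  ringVals <- e0[ring]
  ks <- vector("list", 8L)
  angles <- seq(0L, 315L, by = 45L)
  names(ks) <- paste0("E", angles)
  for (i in seq_along(angles)) {
    k <- matrix(0, 3L, 3L)
    ## rotate the ring clockwise by (i-1) positions: 45 degrees per step
    shifted <- ringVals[((seq_len(8L) - 1L - (i - 1L)) %% 8L) + 1L]
    k[ring] <- shifted
    ks[[i]] <- k
  }
  ks
}

#' Compass filter responses
#'
#' Correlates an image with each of the eight compass kernels (replicate
#' border padding), returning the signed directional derivative responses.
#'
#' @param img Numeric matrix, at least 3x3.
#' @param kernels Kernel bank from [compassKernels()].
#' @return Named list of eight signed response matrices, same shape as `img`.
#' @export
compassResponses <- function(img, kernels = compassKernels()) {
  .assertImage(img, minDim = 3L)
  lapply(kernels, function(k) .correlate(img, k))
}

#' Maximum edge-strength map
#'
#' Per-pixel maximum absolute compass response over the four non-redundant
#' directions (0, 45, 90, 135 degrees). Because opposite-angle kernels are
#' negations, this equals the maximum over all eight signed responses.
#'
#' @inheritParams compassResponses
#' @return Nonnegative numeric matrix, same shape as `img`.
#' @export
edgeStrengthMap <- function(img, kernels = compassKernels()) {
  .assertImage(img, minDim = 3L)
  out <- abs(.correlate(img, kernels$E0))
  for (nm in c("E45", "E90", "E135"))
    out <- pmax(out, abs(.correlate(img, kernels[[nm]])))
  out
}

#' Detail images
#'
#' Each source's maximum edge-strength map is subtracted from the *other*
#' source, isolating the content one modality carries that the other's edge
#' structure does not explain: `DI1 = I2 - EI1`, `DI2 = I1 - EI2`. Values
#' stay signed; no clamping.
#'
#' @param i1,i2 Co-registered source images (numeric matrices, one shape).
#' @param e1,e2 Edge-strength maps of `i1` and `i2` (same shape).
#' @return List with signed matrices `di1` and `di2`.
#' @export
detailImages <- function(i1, i2, e1, e2) {
  .assertSameShape(i1, i2, e1, e2)
  list(di1 = i2 - e1, di2 = i1 - e2)
}
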