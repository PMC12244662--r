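## Oustaloup recursive approximation of the fractional differentiator s^alpha
## and degree-5 polynomial fits of its coefficients as functions of alpha.
##
## The rational approximation of order 2N+1 places 2N+1 real negative zeros
## and poles geometrically over a frequency band [wb, wh]:
##   w_z,k = wb * (wh/wb)^((2k - 1 - alpha) / (2(2N+1)))
##   w_p,k = wb * (wh/wb)^((2k - 1 + alpha) / (2(2N+1)))     k = 1..2N+1
## The scalar gain is normalized so the magnitude at the geometric center
## frequency w_c = sqrt(wb*wh) equals w_c^alpha exactly.

#' Oustaloup rational-approximation coefficients
#'
#' Numerator and denominator polynomial coefficients (descending powers) of
#' the order-`2N+1` rational approximation of `s^alpha` over `band`.
#'
#' @param alpha Fractional order in `(0, 1]`.
#' @param N Half-order constant; the rational function has degree `2N + 1`
#'   (default 2, i.e. degree 5).
#' @param band Frequency band `c(wb, wh)` in rad/s, `0 < wb < wh`
#'   (default `c(0.01, 100)`).
#' @return List with numeric vectors `b` (numerator) and `a` (denominator),
#'   each of length `2N + 2`, plus `zeros`, `poles`, `gain`.
#' @export
oustaloupCoefficients <- function(alpha, N = 2L, band = c(0.01, 100)) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]", call. = FALSE)
  wb <- band[1L]; wh <- band[2L]
  if (!(wb > 0 && wh > wb)) stop("need 0 < wb < wh", call. = FALSE)
  K <- 2L * as.integer(N) + 1L
  k <- seq_len(K)
  r <- wh / wb
  wz <- wb * r^((2 * k - 1 - alpha) / (2 * K))
  wp <- wb * r^((2 * k - 1 + alpha) / (2 * K))
  b <- .polyFromRoots(-wz)   # zeros at -wz
  a <- .polyFromRoots(-wp)
  wc <- sqrt(wb * wh)
  g0 <- Mod(.polyval(b, 1i * wc) / .polyval(a, 1i * wc))
  gain <- wc^alpha / g0
  list(b = gain * b, a = a, zeros = -wz, poles = -wp, gain = gain)
}

#' Evaluate an Oustaloup transfer function at frequencies
#'
#' @param model Output of [oustaloupCoefficients()].
#' @param omega Numeric vector of angular frequencies (rad/s).
#' @return Complex vector `G(i*omega)`.
#' @export
oustaloupResponse <- function(model, omega) {
  .polyval(model$b, 1i * omega) / .polyval(model$a, 1i * omega)
}

#' Degree-5 polynomial fits of Oustaloup coefficients over the order
#'
#' Samples `M - 1` orders uniformly over `alphaRange`, computes the
#' numerator/denominator coefficients at each, and least-squares fits each
#' coefficient as a degree-5 polynomial in `alpha`. This turns the
#' per-order Oustaloup construction into closed-form coefficient curves
#' `FB_k(alpha)`, `FA_k(alpha)`.
#'
#' @param alphaRange Order interval to sample, default `c(0.6, 1.0)`.
#' @param N Half-order constant (default 2).
#' @param M Sampling constant: `M - 1` orders are sampled (default 20,
#'   i.e. 19 samples; at least 7 so the degree-5 fit is determined).
#' @param band Frequency band, as in [oustaloupCoefficients()].
#' @return List with `phiB`, `phiA`: `6 x (2N+2)` matrices of fit
#'   coefficients (rows are powers `alpha^5 .. alpha^0`), plus the sampled
#'   `alphas` and the raw coefficient matrices `B`, `A`
#'   (`(M-1) x (2N+2)`).
#' @export
fitCoefficientPolynomials <- function(alphaRange = c(0.6, 1.0), N = 2L,
                                      M = 20L, band = c(0.01, 100)) {
  M <- as.integer(M)
  if (M - 1L < 6L)
    stop("M - 1 sampled orders must be >= 6 for a degree-5 fit",
         call. = FALSE)
  alphas <- seq(alphaRange[1L], alphaRange[2L], length.out = M - 1L)
  nc <- 2L * as.integer(N) + 2L
  B <- A <- matrix(0, M - 1L, nc)
  for (i in seq_along(alphas)) {
    m <- oustaloupCoefficients(alphas[i], N = N, band = band)
    B[i, ] <- m$b
    A[i, ] <- m$a
  }
  V <- outer(alphas, 5:0, `^`)  # Vandermonde, descending powers
  phiB <- qr.solve(V, B)
  phiA <- qr.solve(V, A)
  list(phiB = phiB, phiA = phiA, alphas = alphas, B = B, A = A,
       N = as.integer(N), M = M, band = band)
}

#' Evaluate fitted coefficient polynomials at an order
#'
#' @param fit Output of [fitCoefficientPolynomials()].
#' @param alpha Order at which to evaluate.
#' @return List with numeric vectors `b` and `a`.
#' @export
evalCoefficientPolynomials <- function(fit, alpha) {
  v <- alpha^(5:0)
  list(b = drop(v %*% fit$phiB), a = drop(v %*% fit$phiA))
}

#' Memory weights from the discretized Oustaloup filter
#'
#' Adapter from the frequency-domain machinery to the velocity-memory form
#' used by the optimizer: the rational approximation of `s^(alpha-1)` (the
#' fractional *integrator deficit* acting on the velocity) is discretized by
#' the bilinear transform and its first `depth` impulse-response samples are
#' taken as effective weights on the recent velocities. The default
#' optimizer path uses the exact GL weights ([glCoefficients()]); this
#' adapter exists so the frequency-domain construction is usable end-to-end.
#'
#' @param alpha Fractional order in `(0, 1)`.
#' @param depth Number of memory weights.
#' @param N,band As in [oustaloupCoefficients()].
#' @param fs Sampling rate for the bilinear transform (default 2 Hz).
#' @return Numeric vector of `depth` finite weights.
#' @export
oustaloupMemoryWeights <- function(alpha, depth = 4L, N = 2L,
                                   band = c(0.01, 100), fs = 2) {
  m <- oustaloupCoefficients(alpha, N = N, band = band)
  dz <- signal::as.Arma(signal::bilinear(m$zeros, m$poles, m$gain,
                                         T = 1 / fs))
  imp <- c(1, numeric(depth - 1L))
  h <- as.numeric(signal::filter(dz$b, dz$a, imp))
  if (any(!is.finite(h))) stop("discretized filter is unstable",
                               call. = FALSE)
  ## normalize so the weights sum like the GL partial sums (scale-free memory)
  s <- sum(abs(h))
  if (s > 0) h <- h * sum(glCoefficients(alpha, depth)) / s
  h
}
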