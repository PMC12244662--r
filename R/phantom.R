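## Seeded synthetic CT-like / MR-like phantom pairs.
##
## Both modalities share one head geometry (an elliptical skull ring around
## a brain region), so the pair is co-registered by construction, while the
## tissue contrast is modality-exclusive: the CT-like image shows a bright
## skull, flat soft tissue, and high-intensity bone inserts; the MR-like
## image shows a dark skull, a smoothly textured soft-tissue interior, and
## bright lesions. Gaussian noise is added and clipped to [0, 1].

#' Generate a registered CT-like / MR-like phantom pair
#'
#' @param size Image side length (square), `>= 32`; default 256.
#' @param seed Integer seed; the pair is a deterministic function of the
#'   arguments.
#' @param noiseSigma Additive Gaussian noise standard deviation
#'   (default 0.01).
#' @param skullThickness Ring thickness in pixels (default `size/32`).
#' @param lesionCount Number of bright MR lesions (default 3).
#' @param textureScale Smoothing length of the MR soft-tissue texture in
#'   pixels (default `size/16`).
#' @return A [PhantomPair-class] with masks `ring`, `brain`, `lesions`,
#'   `inserts`.
#' @export
generatePhantomPair <- function(size = 256L, seed = 1L, noiseSigma = 0.01,
                                skullThickness = max(3L, round(size / 32)),
                                lesionCount = 3L,
                                textureScale = max(2, size / 16)) {
  size <- as.integer(size)
  if (is.na(size) || size < 32L)
    stop("phantom size must be at least 32", call. = FALSE)
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed,
                                  envir = globalenv())
  })
  set.seed(seed)

  cx <- (size + 1) / 2; cy <- (size + 1) / 2
  a <- 0.42 * size; b <- 0.36 * size       # outer skull semi-axes
  xs <- matrix(seq_len(size), size, size)            # row coordinate
  ys <- matrix(seq_len(size), size, size, byrow = TRUE)
  rr <- sqrt(((xs - cx) / a)^2 + ((ys - cy) / b)^2)  # elliptical radius
  thick <- skullThickness / min(a, b)
  ring <- rr <= 1 & rr > 1 - thick
  brain <- rr <= 1 - thick

  blob <- function(px, py, radius) {
    sqrt((xs - px)^2 + (ys - py)^2) <= radius
  }

  ## CT: flat soft tissue, bright skull, bone inserts near the skull base
  ct <- matrix(0.02, size, size)
  ct[brain] <- 0.35
  ct[ring] <- 0.95
  inserts <- matrix(FALSE, size, size)
  nIns <- 2L
  for (k in seq_len(nIns)) {
    ang <- stats::runif(1, pi * 0.6, pi * 1.4)
    r0 <- 0.75 + stats::runif(1, -0.05, 0.05)
    m <- blob(cx + r0 * a * cos(ang) * 0.9, cy + r0 * b * sin(ang) * 0.9,
              stats::runif(1, 0.02, 0.035) * size) & brain
    inserts <- inserts | m
  }
  ct[inserts] <- 1.0

  ## MR: dark skull, textured interior, bright lesions
  mr <- matrix(0.05, size, size)
  tex <- matrix(stats::rnorm(size * size), size, size)
  g <- stats::dnorm(seq(-3, 3, length.out = max(3L,
                                                2L * round(textureScale) + 1L)))
  g <- g / sum(g)
  tex <- .filterSeparable(tex, g)
  tex <- (tex - min(tex)) / (max(tex) - min(tex))    # [0, 1]
  mr[brain] <- 0.3 + 0.5 * tex[brain]
  mr[ring] <- 0.05
  lesions <- matrix(FALSE, size, size)
  if (lesionCount > 0L) for (k in seq_len(lesionCount)) {
    ang <- stats::runif(1, 0, 2 * pi)
    r0 <- stats::runif(1, 0.2, 0.6)
    m <- blob(cx + r0 * a * cos(ang), cy + r0 * b * sin(ang),
              stats::runif(1, 0.03, 0.05) * size) & brain
    lesions <- lesions | m
  }
  mr[lesions] <- 0.92

  if (noiseSigma > 0) {
    ct <- ct + stats::rnorm(size * size, sd = noiseSigma)
    mr <- mr + stats::rnorm(size * size, sd = noiseSigma)
  }
  ct <- pmin(pmax(ct, 0), 1)
  mr <- pmin(pmax(mr, 0), 1)

  new("PhantomPair", ct = ct, mr = mr,
      masks = list(ring = ring, brain = brain, lesions = lesions,
                   inserts = inserts),
      seed = as.numeric(seed))
}

#' Analytic bi-objective reference front
#'
#' True Pareto front of the classic one-dimensional bi-objective problem
#' `f1 = x^2`, `f2 = (x - 2)^2` (front traced by `x` in `[0, 2]`), used as
#' a well-defined toy instance for convergence testing.
#'
#' @param problemId Currently only `"sch"`.
#' @param nPoints Number of uniformly parameter-sampled front points.
#' @return Matrix with `nPoints` rows and columns `f1`, `f2`.
#' @export
analyticFront <- function(problemId = "sch", nPoints = 100L) {
  problemId <- match.arg(problemId, "sch")
  t <- seq(0, 2, length.out = nPoints)
  cbind(f1 = t^2, f2 = (t - 2)^2)
}

#' The toy bi-objective evaluator matching [analyticFront()]
#'
#' @return A function mapping a length-1 decision vector to `c(f1, f2)`.
#' @export
toyProblem <- function() function(x) c(x[1L]^2, (x[1L] - 2)^2)
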