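## End-to-end fusion: decode a 6-parameter decision vector into weight-map
## settings, evaluate the (quality, cost) bi-objective, and merge pixels.
##
## Decision vector x = (wIdx1, wIdx2, g1, g2, gamma1, gamma2):
##   wIdx in [0, 3] rounds to an index into window sides {3, 5, 7, 9};
##   gains g in [0.1, 10] and exponents gamma in [0.25, 4] reshape the
##   covariance weight maps: wt_i = g_i * pixelWeightMap(DI_i, W_i)^gamma_i.

.windowSides <- c(3L, 5L, 7L, 9L)

.decisionLower <- c(0, 0, 0.1, 0.1, 0.25, 0.25)
.decisionUpper <- c(3, 3, 10, 10, 4, 4)

#' Decode a fusion decision vector
#'
#' @param x Length-6 numeric vector; components outside the box are
#'   clipped with a warning.
#' @return List with `W1`, `W2` (window sides), `g1`, `g2` (gains),
#'   `gamma1`, `gamma2` (exponents).
#' @export
decodeDecision <- function(x) {
  if (length(x) != 6L) stop("decision vector must have length 6",
                            call. = FALSE)
  if (any(x < .decisionLower | x > .decisionUpper)) {
    warning("decision vector clipped to bounds", call. = FALSE)
    x <- pmin(pmax(x, .decisionLower), .decisionUpper)
  }
  list(W1 = .windowSides[round(x[1L]) + 1L],
       W2 = .windowSides[round(x[2L]) + 1L],
       g1 = x[3L], g2 = x[4L], gamma1 = x[5L], gamma2 = x[6L])
}

#' Weighted pixel merge
#'
#' `F = (I1 wt1 + I2 wt2) / (wt1 + wt2 + eps)`; where both weights vanish
#' the arithmetic mean of the sources is used. Every fused pixel is a
#' convex combination of the two source pixels.
#'
#' @param i1,i2 Source images (one shape).
#' @param wt1,wt2 Nonnegative weight maps (same shape).
#' @param eps Denominator guard (default `1e-12`).
#' @return Fused image, same shape.
#' @export
fusePixels <- function(i1, i2, wt1, wt2, eps = 1e-12) {
  .assertSameShape(i1, i2, wt1, wt2)
  if (any(wt1 < 0) || any(wt2 < 0))
    stop("weights must be nonnegative", call. = FALSE)
  s <- wt1 + wt2
  out <- (i1 * wt1 + i2 * wt2) / (s + eps)
  zero <- s < eps
  if (any(zero)) out[zero] <- (i1[zero] + i2[zero]) / 2
  out
}

#' Quality objective (Fitness1)
#'
#' `Fitness1 = 1 - (ENT/8 + FMI + Qabf)`, minimized. The entropy is
#' divided by its 8-bit cap so the three terms share the `[0, 1]` scale.
#'
#' @param fused Fused image.
#' @param i1,i2 Source images.
#' @return Scalar in `[-2, 1]`; lower is better.
#' @export
fitness1 <- function(fused, i1, i2) {
  1 - (imageEntropy(fused) / 8 + fmi(fused, i1, i2) + qabf(fused, i1, i2))
}

#' Cost objective
#'
#' The cost to be minimized (maximizing `Fitness2 ~ 1/Time`). The default
#' `"proxy"` model is the deterministic operation-count surrogate
#' `(W1^2 + W2^2) * H * W`; `"wallclock"` returns measured seconds from a
#' supplied timer value.
#'
#' @param W1,W2 Window sides used for the two weight maps.
#' @param dim Image dimensions `c(H, W)`.
#' @param model `"proxy"` or `"wallclock"`.
#' @param seconds Measured seconds (wallclock model only).
#' @return Positive scalar cost.
#' @export
fusionCost <- function(W1, W2, dim, model = c("proxy", "wallclock"),
                       seconds = NULL) {
  model <- match.arg(model)
  if (model == "proxy") (W1^2 + W2^2) * dim[1L] * dim[2L]
  else {
    if (is.null(seconds) || seconds <= 0)
      stop("wallclock model needs positive measured seconds", call. = FALSE)
    seconds
  }
}

## Precompute everything a candidate evaluation needs for one image pair.
.fusionContext <- function(i1, i2) {
  .assertSameShape(i1, i2)
  .assertImage(i1, minDim = 3L); .assertImage(i2, minDim = 3L)
  ks <- compassKernels()
  e1 <- edgeStrengthMap(i1, ks)
  e2 <- edgeStrengthMap(i2, ks)
  di <- detailImages(i1, i2, e1, e2)
  maps1 <- lapply(.windowSides, function(W) pixelWeightMap(di$di1, W))
  maps2 <- lapply(.windowSides, function(W) pixelWeightMap(di$di2, W))
  names(maps1) <- names(maps2) <- as.character(.windowSides)
  list(i1 = i1, i2 = i2, di1 = di$di1, di2 = di$di2,
       maps1 = maps1, maps2 = maps2, dim = dim(i1))
}

.candidateWeights <- function(ctx, dec) {
  wt1 <- dec$g1 * ctx$maps1[[as.character(dec$W1)]]^dec$gamma1
  wt2 <- dec$g2 * ctx$maps2[[as.character(dec$W2)]]^dec$gamma2
  list(wt1 = wt1, wt2 = wt2)
}

.evaluateCandidate <- function(ctx, x, costModel = "proxy") {
  dec <- decodeDecision(x)
  w <- .candidateWeights(ctx, dec)
  t0 <- proc.time()[["elapsed"]]
  fused <- fusePixels(ctx$i1, ctx$i2, w$wt1, w$wt2)
  f1 <- fitness1(fused, ctx$i1, ctx$i2)
  dt <- proc.time()[["elapsed"]] - t0
  cost <- if (costModel == "proxy")
    fusionCost(dec$W1, dec$W2, ctx$dim)
  else fusionCost(dec$W1, dec$W2, ctx$dim, model = "wallclock",
                  seconds = max(dt, 1e-6))
  c(f1, cost)
}

#' Optimized multimodal image fusion
#'
#' Runs the full pipeline on a co-registered pair: gradient-compass edge
#' extraction, detail images, covariance weight maps for all candidate
#' window sides, then a VF-MODPSO search over the 6-parameter weight-map
#' reshaping against the (Fitness1, cost) bi-objective. One particle is
#' warm-started at the baseline configuration (`W = 3`, unit gains and
#' exponents). The returned solution is the knee-point archive member
#' (closest to the ideal point in normalized objective space).
#'
#' @param i1,i2 Source images (numeric matrices in `[0, 1]`, one shape).
#' @param cfg An [optimizerConfig()] for the 6-dimensional decision space;
#'   `NULL` builds one from `popSize`, `maxIter` and `seed`.
#' @param popSize,maxIter,seed Convenience settings used when `cfg` is
#'   `NULL`.
#' @param costModel `"proxy"` (deterministic operation count, default) or
#'   `"wallclock"`.
#' @return A [FusionResult-class].
#' @export
fuseImages <- function(i1, i2, cfg = NULL, popSize = 12L, maxIter = 8L,
                       seed = 1L, costModel = c("proxy", "wallclock")) {
  costModel <- match.arg(costModel)
  ctx <- .fusionContext(i1, i2)
  baseline <- c(0, 0, 1, 1, 1, 1)
  costMax <- fusionCost(9L, 9L, ctx$dim)
  if (is.null(cfg))
    cfg <- optimizerConfig(lower = .decisionLower, upper = .decisionUpper,
                           popSize = popSize, maxIter = maxIter,
                           seed = seed, warmStart = baseline,
                           objectiveScale = c(1, costMax),
                           hvWindow = 0L, diversityThreshold = 0)
  if (is.null(cfg$warmStart)) cfg$warmStart <- matrix(baseline, 1L)
  if (is.null(cfg$objectiveScale)) cfg$objectiveScale <- c(1, costMax)
  problem <- function(x) .evaluateCandidate(ctx, x, costModel)
  run <- runVFMODPSO(problem, cfg)

  Fo <- archiveObjectives(run$archive)
  ## knee point: minimum distance to the ideal in [0,1]-normalized space
  N <- Fo
  for (j in seq_len(ncol(Fo))) {
    rng <- diff(range(Fo[, j]))
    N[, j] <- if (rng > 1e-12) (Fo[, j] - min(Fo[, j])) / rng else 0
  }
  knee <- which.min(rowSums(N * N))
  x <- archivePositions(run$archive)[knee, ]
  dec <- decodeDecision(x)
  w <- .candidateWeights(ctx, dec)
  fused <- fusePixels(ctx$i1, ctx$i2, w$wt1, w$wt2)
  new("FusionResult", fused = fused, wt1 = w$wt1, wt2 = w$wt2,
      decision = as.numeric(x), objectives = as.numeric(Fo[knee, ]),
      metrics = metricReport(fused, i1, i2), archive = run$archive,
      trace = run$trace)
}
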