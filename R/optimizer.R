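## Multi-objective Darwinian particle swarm optimization with a bounded
## Pareto archive, and its variable-order fractional variant.
##
## All objectives are minimized. The velocity update is
##   v <- memory(history, alpha) + rho1*r1*(gbest - x)
##        + rho2*r2*(localbest - x) + rho3*r3*(neighbest - x)
## where memory() is the truncated Grünwald-Letnikov series (unit inertia at
## alpha = 1, depth 1). Darwinian rules delete stagnating particles and
## spawn replacements with probability given by the selection coefficient.

#' Pareto dominance
#'
#' `a` dominates `b` iff `a <= b` in every component and `a < b` in at
#' least one (all-minimize orientation).
#'
#' @param a,b Numeric objective vectors of equal length.
#' @return Logical scalar.
#' @export
dominates <- function(a, b) {
  if (length(a) != length(b))
    stop("objective vectors must have equal length", call. = FALSE)
  all(a <= b) && any(a < b)
}

#' Nondominated subset
#'
#' Returns exactly the rows of `points` not dominated by any other row;
#' duplicated rows are kept once.
#'
#' @param points Numeric matrix, one objective vector per row.
#' @return Matrix of the nondominated rows.
#' @export
nondominatedFilter <- function(points) {
  if (!is.matrix(points)) points <- matrix(points, nrow = 1L)
  n <- nrow(points)
  if (n == 0L) stop("empty point set", call. = FALSE)
  keep <- .nondominatedIdx(points)
  pts <- points[keep, , drop = FALSE]
  pts[!duplicated(pts), , drop = FALSE]
}

.nondominatedIdx <- function(F) {
  n <- nrow(F)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    for (j in seq_len(n)) {
      if (i == j) next
      if (dominates(F[j, ], F[i, ])) { keep[i] <- FALSE; break }
    }
  }
  keep
}

#' Darwinian selection coefficient
#'
#' `SCc(Nkill) = SCcMax * (1 - 1 / (Nkill + 1))`: zero when no particle has
#' ever been removed, approaching `SCcMax` from below as removals grow.
#'
#' @param nKill Number of particles removed so far (`>= 0`).
#' @param sccMax Maximum attainable coefficient, in `(0, 1]`.
#' @return The selection coefficient, in `[0, sccMax)`.
#' @export
selectionCoefficient <- function(nKill, sccMax = 0.9) {
  if (any(nKill < 0)) stop("nKill must be nonnegative", call. = FALSE)
  if (sccMax <= 0 || sccMax > 1) stop("sccMax must be in (0, 1]",
                                      call. = FALSE)
  sccMax * (1 - 1 / (nKill + 1))
}

## NSGA-II crowding distance of each row of F (larger = less crowded).
.crowdingDistance <- function(F) {
  n <- nrow(F)
  if (n <= 2L) return(rep(Inf, n))
  d <- numeric(n)
  for (j in seq_len(ncol(F))) {
    o <- order(F[, j])
    rng <- F[o[n], j] - F[o[1L], j]
    d[o[c(1L, n)]] <- Inf
    if (rng > 0)
      d[o[2:(n - 1L)]] <- d[o[2:(n - 1L)]] +
        (F[o[3:n], j] - F[o[1:(n - 2L)], j]) / rng
  }
  d
}

## Internal archive: list(P = positions, F = objectives, cap).
.archNew <- function(cap, d, m)
  list(P = matrix(numeric(0), 0L, d), F = matrix(numeric(0), 0L, m),
       cap = cap)

## Insert a candidate; returns list(arch, inserted).
.archAdd <- function(arch, x, f) {
  n <- nrow(arch$F)
  if (n > 0L) {
    for (i in seq_len(n))
      if (dominates(arch$F[i, ], f) || all(arch$F[i, ] == f))
        return(list(arch = arch, inserted = FALSE))
    dominated <- vapply(seq_len(n), function(i) dominates(f, arch$F[i, ]),
                        TRUE)
    if (any(dominated)) {
      arch$P <- arch$P[!dominated, , drop = FALSE]
      arch$F <- arch$F[!dominated, , drop = FALSE]
    }
  }
  arch$P <- rbind(arch$P, x)
  arch$F <- rbind(arch$F, f)
  if (nrow(arch$F) > arch$cap) {
    cd <- .crowdingDistance(arch$F)
    drop1 <- which.min(cd)
    arch$P <- arch$P[-drop1, , drop = FALSE]
    arch$F <- arch$F[-drop1, , drop = FALSE]
  }
  list(arch = arch, inserted = TRUE)
}

#' Insert a candidate solution into a Pareto archive
#'
#' The candidate enters iff no stored entry dominates it; entries it
#' dominates are removed; if the archive then exceeds capacity the most
#' crowded entry (smallest crowding distance) is dropped.
#'
#' @param archive A [ParetoArchive-class].
#' @param position Decision vector of the candidate.
#' @param objective Its objective vector (all-minimized).
#' @return The updated [ParetoArchive-class].
#' @export
updateArchive <- function(archive, position, objective) {
  a <- list(P = archive@positions, F = archive@objectives,
            cap = archive@capacity)
  a <- .archAdd(a, position, objective)$arch
  new("ParetoArchive", positions = a$P, objectives = a$F,
      capacity = archive@capacity)
}

## Mean pairwise Euclidean distance of archive objectives after
## normalization by the per-objective range (the diversity statistic the
## termination threshold is compared with).
.archiveDiversity <- function(F) {
  n <- nrow(F)
  if (n < 2L) return(Inf)
  N <- F
  for (j in seq_len(ncol(F))) {
    rng <- diff(range(F[, j]))
    N[, j] <- if (rng > 1e-12) (F[, j] - min(F[, j])) / rng else 0
  }
  mean(stats::dist(N))
}

#' Optimizer configuration
#'
#' Collects every tunable of the swarm search. Defaults follow the study
#' configuration where one is stated (1000 iterations, hypervolume
#' convergence threshold 0.01, diversity threshold 0.2, time limit 3600 s)
#' and conventional PSO/archive practice elsewhere.
#'
#' @param lower,upper Numeric box bounds of the decision space.
#' @param popSize Initial swarm size (default 50).
#' @param maxIter Maximum iterations (default 1000).
#' @param rho Length-3 acceleration weights for the global, local and
#'   neighbourhood attractors (default `c(0.8, 0.8, 0.8)`).
#' @param archiveCapacity Global archive capacity (default `popSize`).
#' @param pbestCapacity Personal archive capacity (default 5).
#' @param vmaxFrac Velocity clamp as a fraction of the box width
#'   (default 0.2).
#' @param depth Fractional memory depth (default 4).
#' @param alphaLo,alphaHi Variable-order range (default `[0.6, 1]`).
#' @param stagnationMax Iterations without personal-best improvement before
#'   a particle is deleted (default 5).
#' @param sccMax Maximum Darwinian selection coefficient (default 0.9).
#' @param minPop,maxPop Population bounds under Darwinian rules
#'   (defaults 10 and 60).
#' @param hvThreshold Stop when hypervolume improvement over `hvWindow`
#'   iterations falls below this (default 0.01; 0 disables).
#' @param hvWindow Window length for the hypervolume stop (default 50).
#' @param diversityThreshold Stop when normalized mean pairwise archive
#'   distance falls below this (default 0.2; 0 disables).
#' @param hvRef Reference point for the hypervolume trace, applied to
#'   objectives divided by `objectiveScale` (default `c(2, 2)`).
#' @param objectiveScale Per-objective divisors used for the hypervolume
#'   trace, diversity statistic and leader scalarization (default all 1).
#' @param timeLimit Wall-clock budget in seconds (default 3600).
#' @param seed Integer RNG seed; `NULL` leaves the RNG state alone.
#' @param warmStart Optional matrix (or vector) of decision vectors placed
#'   into the initial population.
#' @return A list of class `"optimizerConfig"`.
#' @export
optimizerConfig <- function(lower, upper, popSize = 50L, maxIter = 1000L,
                            rho = c(0.8, 0.8, 0.8),
                            archiveCapacity = popSize, pbestCapacity = 5L,
                            vmaxFrac = 0.2, depth = 4L,
                            alphaLo = 0.6, alphaHi = 1.0,
                            stagnationMax = 5L, sccMax = 0.9,
                            minPop = 10L, maxPop = 60L,
                            hvThreshold = 0.01, hvWindow = 50L,
                            diversityThreshold = 0.2, hvRef = c(2, 2),
                            objectiveScale = NULL, timeLimit = 3600,
                            seed = NULL, warmStart = NULL) {
  stopifnot(length(lower) == length(upper), all(upper > lower),
            all(rho > 0), maxIter >= 0, popSize >= 1)
  if (!is.null(warmStart) && !is.matrix(warmStart))
    warmStart <- matrix(warmStart, nrow = 1L)
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper),
                 popSize = as.integer(popSize), maxIter = as.integer(maxIter),
                 rho = rho, archiveCapacity = as.integer(archiveCapacity),
                 pbestCapacity = as.integer(pbestCapacity),
                 vmaxFrac = vmaxFrac, depth = as.integer(depth),
                 alphaLo = alphaLo, alphaHi = alphaHi,
                 stagnationMax = as.integer(stagnationMax), sccMax = sccMax,
                 minPop = as.integer(minPop), maxPop = as.integer(maxPop),
                 hvThreshold = hvThreshold, hvWindow = as.integer(hvWindow),
                 diversityThreshold = diversityThreshold, hvRef = hvRef,
                 objectiveScale = objectiveScale, timeLimit = timeLimit,
                 seed = seed, warmStart = warmStart),
            class = "optimizerConfig")
}

.evalRows <- function(problem, X, lower, upper, m = NULL) {
  n <- nrow(X); D <- ncol(X)
  F <- NULL
  for (i in seq_len(n)) {
    f <- problem(X[i, ])
    tries <- 0L
    while (any(!is.finite(f)) && tries < 20L) {
      warning("non-finite objective; particle resampled", call. = FALSE)
      X[i, ] <- lower + stats::runif(D) * (upper - lower)
      f <- problem(X[i, ])
      tries <- tries + 1L
    }
    if (any(!is.finite(f)))
      stop("evaluator persistently returned non-finite objectives",
           call. = FALSE)
    if (is.null(F)) F <- matrix(0, n, length(f))
    F[i, ] <- f
  }
  list(X = X, F = F)
}

.runEngine <- function(problem, cfg, fractional, darwinian) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  lower <- cfg$lower; upper <- cfg$upper
  D <- length(lower)
  depth <- if (fractional) cfg$depth else 1L
  aLo <- if (fractional) cfg$alphaLo else 1
  aHi <- if (fractional) cfg$alphaHi else 1
  vmax <- cfg$vmaxFrac * (upper - lower)
  npop <- cfg$popSize

  X <- sweep(sweep(matrix(stats::runif(npop * D), npop, D),
                   2L, upper - lower, "*"), 2L, lower, "+")
  if (!is.null(cfg$warmStart)) {
    k <- min(nrow(cfg$warmStart), npop)
    X[seq_len(k), ] <- cfg$warmStart[seq_len(k), , drop = FALSE]
  }
  V <- matrix(0, npop, D)
  vhist <- list(V)
  ev <- .evalRows(problem, X, lower, upper)
  X <- ev$X; Fobj <- ev$F
  m <- ncol(Fobj)
  scale <- if (is.null(cfg$objectiveScale)) rep(1, m) else cfg$objectiveScale

  gbest <- .archNew(cfg$archiveCapacity, D, m)
  pbest <- vector("list", npop)
  for (i in seq_len(npop)) {
    pbest[[i]] <- .archAdd(.archNew(cfg$pbestCapacity, D, m),
                           X[i, ], Fobj[i, ])$arch
    gbest <- .archAdd(gbest, X[i, ], Fobj[i, ])$arch
  }
  stagn <- integer(npop)
  nKill <- 0L
  nEval <- npop

  trace <- data.frame(iteration = integer(0), hv = numeric(0),
                      archiveSize = integer(0), nKill = integer(0),
                      alpha = numeric(0))
  t0 <- proc.time()[["elapsed"]]

  t <- 0L
  while (t < cfg$maxIter) {
    t <- t + 1L
    alpha <- alphaSchedule(t, cfg$maxIter, aLo, aHi)
    cs <- glCoefficients(alpha, depth)

    ## leaders: global from archive by binary crowding tournament
    nA <- nrow(gbest$F)
    cd <- .crowdingDistance(gbest$F)
    c1 <- sample.int(nA, npop, replace = TRUE)
    c2 <- sample.int(nA, npop, replace = TRUE)
    gsel <- ifelse(cd[c1] >= cd[c2], c1, c2)
    G <- gbest$P[gsel, , drop = FALSE]

    ## local best: uniform draw from the personal archive
    Lb <- matrix(0, npop, D)
    for (i in seq_len(npop)) {
      np <- nrow(pbest[[i]]$P)
      k <- if (np == 1L) 1L else sample.int(np, 1L)
      Lb[i, ] <- pbest[[i]]$P[k, ]
    }

    ## neighbourhood best: ring of radius 1, scalarized-min member
    ## (the scalarized argmin is always nondominated within the trio)
    sc <- rowSums(sweep(Fobj, 2L, scale, "/"))
    left <- c(npop, seq_len(npop - 1L))
    right <- c(seq_len(npop)[-1L], 1L)
    trio <- cbind(sc[left], sc, sc[right])
    pick <- max.col(-trio, ties.method = "first")
    nsel <- cbind(left, seq_len(npop), right)[cbind(seq_len(npop), pick)]
    Nb <- X[nsel, , drop = FALSE]

    R1 <- matrix(stats::runif(npop * D), npop, D)
    R2 <- matrix(stats::runif(npop * D), npop, D)
    R3 <- matrix(stats::runif(npop * D), npop, D)

    mem <- cs[1L] * vhist[[1L]]
    kmax <- min(depth, length(vhist))
    if (kmax > 1L)
      for (k in 2L:kmax)
        mem <- mem + cs[k] * vhist[[k]]
    V <- mem + cfg$rho[1L] * R1 * (G - X) + cfg$rho[2L] * R2 * (Lb - X) +
      cfg$rho[3L] * R3 * (Nb - X)
    V <- pmin(pmax(V, matrix(-vmax, npop, D, byrow = TRUE)),
              matrix(vmax, npop, D, byrow = TRUE))
    Xn <- X + V
    loMat <- matrix(lower, npop, D, byrow = TRUE)
    hiMat <- matrix(upper, npop, D, byrow = TRUE)
    clipped <- Xn < loMat | Xn > hiMat
    V[clipped] <- -V[clipped]          # reflect on clipped components
    Xn <- pmin(pmax(Xn, loMat), hiMat)
    X <- Xn
    vhist <- c(list(V), vhist)
    if (length(vhist) > depth) vhist <- vhist[seq_len(depth)]

    ev <- .evalRows(problem, X, lower, upper)
    X <- ev$X; Fobj <- ev$F
    nEval <- nEval + npop

    for (i in seq_len(npop)) {
      res <- .archAdd(pbest[[i]], X[i, ], Fobj[i, ])
      pbest[[i]] <- res$arch
      stagn[i] <- if (res$inserted) 0L else stagn[i] + 1L
      gbest <- .archAdd(gbest, X[i, ], Fobj[i, ])$arch
    }

    hv <- hypervolume(sweep(gbest$F, 2L, scale, "/"), cfg$hvRef)
    trace <- rbind(trace,
                   data.frame(iteration = t, hv = hv,
                              archiveSize = nrow(gbest$F), nKill = nKill,
                              alpha = alpha))

    if (darwinian) {
      stale <- which(stagn >= cfg$stagnationMax)
      nDel <- min(length(stale), npop - cfg$minPop)
      if (nDel > 0L) {
        drop1 <- stale[order(-stagn[stale])][seq_len(nDel)]
        keep <- setdiff(seq_len(npop), drop1)
        X <- X[keep, , drop = FALSE]
        V <- V[keep, , drop = FALSE]
        Fobj <- Fobj[keep, , drop = FALSE]
        vhist <- lapply(vhist, function(M) M[keep, , drop = FALSE])
        pbest <- pbest[keep]
        stagn <- stagn[keep]
        npop <- length(keep)
        nKill <- nKill + nDel
      }
      if (npop < cfg$maxPop &&
          stats::runif(1L) < selectionCoefficient(nKill, cfg$sccMax)) {
        xn <- lower + stats::runif(D) * (upper - lower)
        fn <- problem(xn)
        if (all(is.finite(fn))) {
          nEval <- nEval + 1L
          X <- rbind(X, xn)
          V <- rbind(V, rep(0, D))
          Fobj <- rbind(Fobj, fn)
          vhist <- lapply(vhist, function(M) rbind(M, rep(0, D)))
          pbest <- c(pbest, list(.archAdd(.archNew(cfg$pbestCapacity, D, m),
                                          xn, fn)$arch))
          stagn <- c(stagn, 0L)
          npop <- npop + 1L
          gbest <- .archAdd(gbest, xn, fn)$arch
        }
      }
    }

    if (cfg$hvThreshold > 0 && cfg$hvWindow > 0L && t > cfg$hvWindow &&
        hv - trace$hv[t - cfg$hvWindow] < cfg$hvThreshold) break
    if (cfg$diversityThreshold > 0 && nrow(gbest$F) >= 3L &&
        .archiveDiversity(sweep(gbest$F, 2L, scale, "/")) <
          cfg$diversityThreshold) break
    if (proc.time()[["elapsed"]] - t0 > cfg$timeLimit) break
  }

  arch <- new("ParetoArchive", positions = gbest$P, objectives = gbest$F,
              capacity = as.numeric(cfg$archiveCapacity))
  list(archive = arch, trace = trace, nKill = nKill, nEval = nEval,
       iterations = t)
}

#' Run multi-objective PSO (MODPSO)
#'
#' The archive-guided multi-objective swarm search with unit inertia and no
#' Darwinian particle turnover: initialize, select leaders from the global
#' and personal Pareto archives, update velocities and positions, update
#' the archives, and stop on iteration count, hypervolume stagnation,
#' archive diversity collapse, or the time limit.
#'
#' @param problem Function mapping a decision vector to a numeric objective
#'   vector (all components minimized).
#' @param cfg An [optimizerConfig()].
#' @return List with `archive` (a [ParetoArchive-class]), `trace`
#'   (per-iteration hypervolume log), `nKill`, `nEval`, `iterations`.
#' @export
runMODPSO <- function(problem, cfg)
  .runEngine(problem, cfg, fractional = FALSE, darwinian = FALSE)

#' Run variable-order fractional MODPSO (VF-MODPSO)
#'
#' As [runMODPSO()] but the inertia term is the variable-order fractional
#' memory over the last `cfg$depth` velocities (order decreasing linearly
#' from `alphaHi` to `alphaLo`) and Darwinian deletion/spawning is active.
#' With `alphaLo = alphaHi = 1`, `depth = 1` and `darwinian = FALSE` the
#' trajectory is bit-identical to [runMODPSO()] under the same seed.
#'
#' @inheritParams runMODPSO
#' @param darwinian Enable particle deletion/spawning (default `TRUE`).
#' @return As [runMODPSO()].
#' @export
runVFMODPSO <- function(problem, cfg, darwinian = TRUE)
  .runEngine(problem, cfg, fractional = TRUE, darwinian = darwinian)
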