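test_that("dominance is the strict Pareto partial order", {
  expect_true(dominates(c(0.1, 5), c(0.2, 5)))
  expect_false(dominates(c(1, 2), c(2, 1)))
  expect_false(dominates(c(2, 1), c(1, 2)))
  expect_false(dominates(c(1, 2), c(1, 2)))
  expect_error(dominates(c(1, 2), c(1, 2, 3)), "equal length")
  set.seed(8)
  for (rep in 1:200) {
    a <- runif(3); b <- runif(3); c0 <- runif(3)
    expect_false(dominates(a, a))                       # irreflexive
    if (dominates(a, b)) expect_false(dominates(b, a))  # asymmetric
    if (dominates(a, b) && dominates(b, c0))
      expect_true(dominates(a, c0))                     # transitive
  }
})

test_that("nondominated filter agrees with the brute-force oracle", {
  F <- rbind(c(0, 1), c(1, 0), c(1, 1))
  expect_equal(nondominatedFilter(F), rbind(c(0, 1), c(1, 0)))
  expect_equal(nondominatedFilter(matrix(c(3, 4), 1)), matrix(c(3, 4), 1))
  set.seed(21)
  for (rep in 1:5) {
    F <- matrix(runif(400), 200, 2)
    nd <- nondominatedFilter(F)
    oracle <- F[nondomOracle(F), , drop = FALSE]
    expect_equal(nd[order(nd[, 1]), ], oracle[order(oracle[, 1]), ])
  }
  expect_error(nondominatedFilter(matrix(numeric(0), 0, 2)), "empty")
})

test_that("selection coefficient follows its closed form", {
  expect_equal(selectionCoefficient(0), 0)
  expect_equal(selectionCoefficient(1, 0.9), 0.45)
  expect_lt(selectionCoefficient(1e6, 0.9), 0.9)
  expect_gt(selectionCoefficient(1e6, 0.9), 0.9 - 1e-5)
  ns <- 0:20
  expect_true(all(diff(selectionCoefficient(ns, 0.7)) > 0))
  expect_error(selectionCoefficient(-1), "nonnegative")
})

test_that("archive updates keep mutual nondomination and capacity", {
  arch <- paretoArchive(capacity = 5, d = 2, m = 2)
  arch <- updateArchive(arch, c(0, 0), c(1, 1))
  expect_equal(length(arch), 1L)
  # dominated candidate leaves the archive unchanged
  arch2 <- updateArchive(arch, c(9, 9), c(2, 2))
  expect_identical(archiveObjectives(arch2), archiveObjectives(arch))
  # candidate dominating everything collapses the archive onto itself
  arch3 <- updateArchive(arch, c(5, 5), c(0.5, 0.5))
  expect_equal(length(arch3), 1L)
  expect_equal(unname(archiveObjectives(arch3)[1, ]), c(0.5, 0.5))
  # random stream at large capacity equals the nondominated filter
  set.seed(13)
  pts <- matrix(runif(160), 80, 2)
  big <- paretoArchive(capacity = 1000, d = 2, m = 2)
  for (i in seq_len(nrow(pts)))
    big <- updateArchive(big, pts[i, ], pts[i, ])
  got <- archiveObjectives(big)
  want <- nondominatedFilter(pts)
  expect_equal(got[order(got[, 1]), ], want[order(want[, 1]), ],
               ignore_attr = TRUE)
  # bounded capacity stays within bounds and mutually nondominated
  small <- paretoArchive(capacity = 6, d = 2, m = 2)
  for (i in seq_len(nrow(pts)))
    small <- updateArchive(small, pts[i, ], pts[i, ])
  expect_lte(length(small), 6L)
  expect_true(validObject(small))
})

test_that("degenerate and seeded runs behave contractually", {
  cfg0 <- optimizerConfig(lower = -2, upper = 4, popSize = 15,
                          maxIter = 0, seed = 42)
  r0 <- runMODPSO(toyProblem(), cfg0)
  # maxIter = 0: archive is the nondominated subset of the initial swarm
  expect_true(all(nondomOracle(archiveObjectives(r0$archive))))
  expect_equal(nrow(r0$trace), 0L)
  # identical config and seed reproduce the run log exactly
  cfg <- optimizerConfig(lower = -2, upper = 4, popSize = 20,
                         maxIter = 25, seed = 7,
                         hvThreshold = 0, diversityThreshold = 0)
  a <- runVFMODPSO(toyProblem(), cfg)
  b <- runVFMODPSO(toyProblem(), cfg)
  expect_identical(a$trace, b$trace)
  expect_identical(archiveObjectives(a$archive),
                   archiveObjectives(b$archive))
})

test_that("the unit-order depth-1 fractional run reduces to MODPSO", {
  cfg <- optimizerConfig(lower = -2, upper = 4, popSize = 20,
                         maxIter = 30, seed = 17, alphaLo = 1,
                         alphaHi = 1, depth = 1,
                         hvThreshold = 0, diversityThreshold = 0)
  a <- runMODPSO(toyProblem(), cfg)
  b <- runVFMODPSO(toyProblem(), cfg, darwinian = FALSE)
  expect_identical(a$trace, b$trace)
  expect_identical(archivePositions(a$archive),
                   archivePositions(b$archive))
})

test_that("Darwinian turnover counts kills monotonically and spawns", {
  # a constant objective stalls every personal archive, forcing deletions
  cfg <- optimizerConfig(lower = 0, upper = 1, popSize = 12,
                         maxIter = 25, seed = 2, minPop = 4,
                         hvThreshold = 0, diversityThreshold = 0,
                         hvRef = c(3, 3))
  r <- runVFMODPSO(function(x) c(1, 1), cfg)
  expect_gt(r$nKill, 0)
  expect_true(all(diff(r$trace$nKill) >= 0))
  # a healthy run on the toy problem never decreases nKill either
  cfg2 <- optimizerConfig(lower = -2, upper = 4, popSize = 20,
                          maxIter = 40, seed = 5,
                          hvThreshold = 0, diversityThreshold = 0)
  r2 <- runVFMODPSO(toyProblem(), cfg2)
  expect_true(all(diff(r2$trace$nKill) >= 0))
})

test_that("non-finite evaluations are logged and the particle resampled", {
  flaky <- function(x)
    if (x[1] > 1) c(NaN, 1) else c(x[1]^2, (x[1] - 2)^2)
  cfg <- optimizerConfig(lower = -2, upper = 4, popSize = 10,
                         maxIter = 5, seed = 3,
                         hvThreshold = 0, diversityThreshold = 0)
  w <- capture_warnings(r <- runMODPSO(flaky, cfg))
  expect_true(any(grepl("resampled", w)))
  expect_true(all(is.finite(archiveObjectives(r$archive))))
})
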