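test_that("entropy hits its distributional landmarks", {
  expect_equal(imageEntropy(matrix(0.5, 16, 16)), 0)
  two <- matrix(rep(c(0, 1), 128), 16, 16)
  expect_equal(imageEntropy(two), 1.0)
  all256 <- matrix(rep(0:255, 4) / 255, 32, 32)
  expect_equal(imageEntropy(all256), 8.0)
  expect_error(imageEntropy(matrix(numeric(0), 0, 0)), "at least")
})

test_that("mutual information is symmetric, bounded, near zero under independence", {
  set.seed(1)
  a <- randomImage(64, 64)
  b <- randomImage(64, 64)
  expect_equal(mutualInformation(a, a), imageEntropy(a), tolerance = 1e-12)
  expect_equal(mutualInformation(a, b), mutualInformation(b, a),
               tolerance = 1e-12)
  # independence: use coarsely quantized noise so the plug-in histogram
  # estimator bias ((K-1)^2 / (2 N ln 2)) is well below the tolerance
  lv <- function() matrix(sample(0:15, 128 * 128, TRUE) / 15, 128, 128)
  ind <- mutualInformation(lv(), lv())
  expect_gte(ind, 0)
  expect_lt(ind, 0.05)
  expect_lte(mutualInformation(a, b),
             min(imageEntropy(a), imageEntropy(b)) + 1e-12)
  expect_error(mutualInformation(a, matrix(0, 3, 3)), "share one shape")
})

test_that("feature mutual information is 1 on self-fusion, near 0 on noise", {
  img <- ctImage(generatePhantomPair(64, seed = 2, noiseSigma = 0))
  expect_equal(fmi(img, img, img), 1.0, tolerance = 1e-12)
  expect_equal(fmi(img, img, img),
               fmi(img, img, img))                 # swap-invariant trivially
  set.seed(4)
  noisyF <- randomImage(256, 256)
  s1 <- randomImage(256, 256); s2 <- randomImage(256, 256)
  expect_lt(fmi(noisyF, s1, s2), 0.1)
  expect_equal(fmi(matrix(0.3, 16, 16), s1[1:16, 1:16], s2[1:16, 1:16]), 0)
})

test_that("Qabf rewards preserved edges and punishes erased ones", {
  img <- ctImage(generatePhantomPair(64, seed = 3, noiseSigma = 0))
  expect_gte(qabf(img, img, img), 0.99)
  flat <- matrix(mean(img), nrow(img), ncol(img))
  expect_lt(qabf(flat, img, img), 0.05)
  set.seed(6)
  for (rep in 1:5) {
    q <- qabf(randomImage(32, 32), randomImage(32, 32), randomImage(32, 32))
    expect_gte(q, 0)
    expect_lte(q, 1)
  }
  expect_lt(qabf(img, flat, flat), 1e-4)   # gradient-free sources
  expect_equal(qabf(img, matrix(0.5, 64, 64), matrix(0.5, 64, 64)), 0)
})

test_that("SSIM is 1 on identity, negative on inversion, decreasing in noise", {
  img <- mrImage(generatePhantomPair(64, seed = 5, noiseSigma = 0))
  expect_equal(ssimIndex(img, img), 1.0, tolerance = 1e-12)
  bin <- matrix(rep(c(0, 1), each = 32, times = 32), 64, 64)
  expect_lt(ssimIndex(1 - bin, bin), 0)
  set.seed(7)
  sims <- vapply(c(0.02, 0.1, 0.3), function(s) {
    mean(vapply(1:3, function(k) {
      noisy <- pmin(pmax(img + matrix(rnorm(64 * 64, sd = s), 64), 0), 1)
      ssimIndex(noisy, img)
    }, 0))
  }, 0)
  expect_true(all(diff(sims) < 0))
})

test_that("IGD matches hand values and is monotone under front coverage", {
  Pstar <- rbind(c(0, 1), c(1, 0))
  expect_equal(igd(Pstar, Pstar), 0)
  expect_equal(igd(matrix(c(0, 0), 1), Pstar), 1.0)
  set.seed(8)
  A <- matrix(runif(20), 10, 2)
  base <- igd(A, Pstar)
  expect_lte(igd(rbind(A, c(0, 1)), Pstar), base)
  expect_error(igd(matrix(numeric(0), 0, 2), Pstar), "empty")
})

test_that("2-D hypervolume sweep is exact and agrees with oracles", {
  expect_equal(hypervolume(matrix(c(1, 1), 1), c(2, 2)), 1.0)
  expect_equal(hypervolume(rbind(c(0, 1), c(1, 0)), c(2, 2)), 3.0)
  expect_warning(h0 <- hypervolume(matrix(c(3, 3), 1), c(2, 2)),
                 "reference")
  expect_equal(h0, 0)
  set.seed(9)
  for (rep in 1:10) {
    A <- matrix(runif(2 * sample(3:10, 1)), ncol = 2)
    ref <- c(2, 2)
    expect_equal(hypervolume(A, ref), hvInclusionExclusion(A, ref),
                 tolerance = 1e-12)
  }
  # monotone under adding a nondominated point; translation-invariant
  A <- rbind(c(0.2, 0.8), c(0.5, 0.5))
  expect_gte(hypervolume(rbind(A, c(0.8, 0.1)), c(2, 2)),
             hypervolume(A, c(2, 2)))
  expect_equal(hypervolume(A + 0.7, c(2.7, 2.7)),
               hypervolume(A, c(2, 2)), tolerance = 1e-12)
})
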