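test_that("GL coefficients match the recurrence limits and gamma oracle", {
  expect_equal(glCoefficients(1, 4), c(1, 0, 0, 0))
  expect_equal(glCoefficients(0.5, 4), c(0.5, 0.125, 0.0625, 0.0390625))
  # direct gamma-ratio form: c_k = alpha * gamma(k - alpha) /
  #   (gamma(k + 1) * gamma(1 - alpha)) for alpha in (0, 1)
  set.seed(3)
  for (alpha in runif(10, 0.05, 0.95)) {
    cs <- glCoefficients(alpha, 10)
    ck <- vapply(1:10, function(k)
      alpha * gamma(k - alpha) / (gamma(k + 1) * gamma(1 - alpha)), 0)
    expect_equal(cs, ck, tolerance = 1e-12)
    expect_true(all(cs > 0))
    expect_true(all(diff(cs) < 0))
    expect_true(all(cumsum(cs) <= 1 + 1e-12))
  }
  expect_error(glCoefficients(0, 3), "positive")
  expect_error(glCoefficients(0.5, 0), "positive integer")
})

test_that("alpha schedule is linear with the right endpoints", {
  expect_equal(alphaSchedule(0, 100), 1.0)
  expect_equal(alphaSchedule(100, 100), 0.6)
  expect_equal(alphaSchedule(50, 100), 0.8)
  expect_equal(alphaSchedule(7, 30, alphaLo = 0.9, alphaHi = 0.9), 0.9)
  a <- vapply(0:20, alphaSchedule, 0, T = 20)
  expect_true(all(diff(a) <= 0))
  expect_error(alphaSchedule(-1, 10), "outside")
  expect_error(alphaSchedule(11, 10), "outside")
})

test_that("fractional velocity term reduces correctly and honors depth", {
  expect_equal(fractionalVelocityTerm(list(c(2, -1)), 1, 4), c(2, -1))
  expect_equal(fractionalVelocityTerm(list(c(1, 0), c(0, 2)), 0.5, 2),
               c(0.5, 0.25))
  expect_equal(fractionalVelocityTerm(list(c(0, 0), c(0, 0)), 0.7, 4),
               c(0, 0))
  # matrix-form history, most recent row first
  expect_equal(fractionalVelocityTerm(rbind(c(1, 0), c(0, 2)), 0.5, 2),
               c(0.5, 0.25))
  expect_error(fractionalVelocityTerm(list(), 0.5), "at least one")
})

test_that("Oustaloup approximation has the ladder structure and band fit", {
  band <- c(0.01, 100)
  for (alpha in c(0.3, 0.5, 0.7, 0.9)) {
    m <- oustaloupCoefficients(alpha, N = 2, band = band)
    expect_length(m$b, 6L)
    expect_length(m$a, 6L)
    # real negative, interlacing zeros/poles
    expect_true(all(m$zeros < 0) && all(m$poles < 0))
    zp <- sort(c(abs(m$zeros), abs(m$poles)))
    expect_equal(zp, sort(c(rbind(sort(abs(m$zeros)), sort(abs(m$poles))))))
    # exact magnitude at the geometric center frequency
    wc <- sqrt(prod(band))
    expect_equal(Mod(oustaloupResponse(m, wc)), wc^alpha,
                 tolerance = 1e-6)
    # within 5% over the inner half (log scale) of the band
    lw <- log10(band)
    om <- 10^seq(mean(lw) - diff(lw) / 4, mean(lw) + diff(lw) / 4,
                 length.out = 40)
    expect_lt(max(abs(Mod(oustaloupResponse(m, om)) - om^alpha) /
                    om^alpha), 0.05)
  }
  # alpha -> 0: unity gain everywhere in the band
  m0 <- oustaloupCoefficients(1e-9)
  om <- 10^seq(-1, 1, length.out = 10)
  expect_equal(Mod(oustaloupResponse(m0, om)), rep(1, 10),
               tolerance = 1e-6)
  expect_error(oustaloupCoefficients(1.5), "alpha")
  expect_error(oustaloupCoefficients(0.5, band = c(10, 1)), "wb < wh")
})

test_that("degree-5 coefficient polynomials refit the sampled curves", {
  fit <- fitCoefficientPolynomials(c(0.6, 1.0), N = 2, M = 20)
  V <- outer(fit$alphas, 5:0, `^`)
  for (k in seq_len(ncol(fit$A))) {
    relA <- max(abs(V %*% fit$phiA[, k] - fit$A[, k])) /
      max(abs(fit$A[, k]))
    relB <- max(abs(V %*% fit$phiB[, k] - fit$B[, k])) /
      max(abs(fit$B[, k]))
    expect_lt(relA, 1e-3)
    expect_lt(relB, 1e-3)
  }
  # the leading (monic) coefficient is constant in alpha: only the
  # intercept survives the fit
  expect_equal(unname(fit$phiA[6L, 1L]), 1, tolerance = 1e-8)
  expect_lt(max(abs(fit$phiA[1:5, 1L])), 1e-6)
  # evaluation between samples stays between neighbouring sampled values
  # for monotone curves (check the constant-in-alpha pole product too)
  ev <- evalCoefficientPolynomials(fit, 0.73)
  a1 <- fit$A[fit$alphas < 0.73, 2L]
  a2 <- fit$A[fit$alphas > 0.73, 2L]
  expect_true(ev$a[2L] >= min(max(a1), min(a2)) - 1e-6 &&
                ev$a[2L] <= max(max(a1), min(a2)) + 1e-6)
  expect_error(fitCoefficientPolynomials(M = 6), "degree-5")
})

test_that("discretized-filter memory weights are finite and scaled", {
  for (alpha in c(0.4, 0.7, 0.9)) {
    w <- oustaloupMemoryWeights(alpha, depth = 4)
    expect_length(w, 4L)
    expect_true(all(is.finite(w)))
    expect_equal(sum(abs(w)), sum(glCoefficients(alpha, 4)),
                 tolerance = 1e-10)
  }
})
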