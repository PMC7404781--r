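test_that("training score distance obeys the exact moment identity", {
  for (seed in 1:3) {
    s <- rankRSet(n = 40, r = 8, seed = seed)
    # add noise so every requested component is present
    m <- intensities(s) + matrix(rnorm(length(intensities(s)), 0, 0.01),
                                 nrow = 40)
    s <- makeSet(m, wn = wavenumbers(s))
    for (k in c(2, 5)) {
      fit <- fitDDSIMCA(s, k, alpha = 0.05)
      h <- fit@trainDistances$h
      expect_lt(abs(mean(h) - k * (40 - 1) / 40), 1e-8)
    }
  }
})

test_that("exact low-rank training data trigger the degenerate-residual path", {
  s <- rankRSet(n = 30, r = 3, seed = 21)
  expect_message(fit <- fitDDSIMCA(s, 3, alpha = 0.05), "subspace")
  expect_true(fit@degenerateV)
  expect_lt(max(fit@trainDistances$v), 1e-8 * mean(rowSums(
    scale(intensities(s), scale = FALSE)^2)))
  # in-subspace test samples are judged by the score distance only
  cls <- classifySamples(fit, s)
  expect_true(all(is.finite(cls$c)))
  # far out-of-subspace sample is an outlier
  out <- intensities(s)[1, , drop = FALSE] +
    10 * sd(intensities(s)) * rep(c(1, -1), length.out = length(wavenumbers(s)))
  cls2 <- classifySamples(fit, makeSet(out, wn = wavenumbers(s)))
  expect_equal(cls2$category, "outlier")
})

test_that("classification is self-consistent, order-invariant and centered", {
  s <- rankRSet(n = 50, r = 6, seed = 22)
  m <- intensities(s) + matrix(rnorm(50 * length(wavenumbers(s)), 0, 0.02), 50)
  s <- makeSet(m, wn = wavenumbers(s))
  fit <- fitDDSIMCA(s, 4, alpha = 0.01)
  cls <- classifySamples(fit, s)
  expect_equal(cls$h, fit@trainDistances$h, tolerance = 1e-10)
  expect_equal(cls$v, fit@trainDistances$v, tolerance = 1e-10)
  # the training mean spectrum sits at the center of the class
  ctr <- makeSet(matrix(colMeans(m), 1), wn = wavenumbers(s))
  c0 <- classifySamples(fit, ctr)
  expect_equal(c0$h, 0, tolerance = 1e-12)
  expect_equal(c0$v, 0, tolerance = 1e-12)
  expect_equal(c0$category, "regular")
  # sample order does not matter
  perm <- sample(50)
  clsP <- classifySamples(fit, s[, perm])
  expect_equal(clsP$h, cls$h[perm], tolerance = 1e-12)
  # shifting all spectra by a constant vector and refitting leaves distances
  shift <- rnorm(length(wavenumbers(s)))
  fit2 <- fitDDSIMCA(makeSet(sweep(m, 2, shift, "+"), wn = wavenumbers(s)),
                     4, alpha = 0.01)
  expect_equal(fit2@trainDistances$h, fit@trainDistances$h, tolerance = 1e-6)
  expect_equal(fit2@trainDistances$v, fit@trainDistances$v, tolerance = 1e-6)
  # total distance is monotone in h and v
  expect_true(fit@Nh / fit@h0 > 0 && fit@Nv / fit@v0 > 0)
  # axis mismatch is refused
  expect_error(classifySamples(fit, makeSet(m, wn = wavenumbers(s) + 2)),
               "axis mismatch")
})

test_that("thresholds are ordered and gamma is multiplicity-adjusted", {
  s <- rankRSet(n = 100, r = 6, seed = 23)
  m <- intensities(s) + matrix(rnorm(100 * length(wavenumbers(s)), 0, 0.02), 100)
  fit <- fitDDSIMCA(makeSet(m, wn = wavenumbers(s)), 4,
                    alpha = 0.01, gamma = 0.01)
  expect_gt(fit@cOut, fit@cCrit)
  gammaAdj <- 1 - (1 - 0.01)^(1 / 100)
  expect_equal(fit@cOut, qchisq(1 - gammaAdj, fit@Nh + fit@Nv))
  expect_error(fitDDSIMCA(makeSet(m, wn = wavenumbers(s)), 100), "rank error")
})

test_that("moment estimator recovers chi-square degrees of freedom", {
  set.seed(24)
  h0 <- 3.7
  for (N in c(4, 12)) {
    h <- h0 * rchisq(50000, N) / N
    expect_lt(abs(estimateChiSqDoF(h) - N) / N, 0.1)
    expect_lt(abs(estimateChiSqDoF(h, "robust") - N) / N, 0.15)
  }
  expect_error(estimateChiSqDoF(rep(2, 10)), "degenerate")
})

test_that("PC selection follows the one-SE parsimony rule", {
  # singleton candidate set: no choice to make
  s <- rankRSet(n = 40, r = 5, seed = 25)
  m <- intensities(s) + matrix(rnorm(40 * length(wavenumbers(s)), 0, 0.02), 40)
  s <- makeSet(m, wn = wavenumbers(s))
  sel1 <- selectNumPCs(s, kCandidates = 1, alpha = 0.05, folds = 4, seed = 1)
  expect_equal(sel1$chosen_k, 1)
  # noiseless rank-3 data: candidates at and above the rank collapse onto
  # it, so the cross-validated acceptance curve is constant from k = 3
  s3 <- rankRSet(n = 60, r = 3, seed = 26)
  sel <- suppressMessages(selectNumPCs(s3, kCandidates = 1:6, alpha = 0.1,
                                       folds = 5, seed = 2))
  rates <- sel$curve$acceptance
  expect_equal(rates[3:6], rep(rates[3], 4), tolerance = 1e-12)
  expect_lte(sel$chosen_k, 3)
  # the chosen k honors the one-SE rule
  mx <- max(rates, na.rm = TRUE)
  se <- sqrt(mx * (1 - mx) / 60)
  expect_gte(rates[sel$chosen_k], mx - se)
})

test_that("extreme plot matches its defining counts and limits", {
  s <- rankRSet(n = 80, r = 5, seed = 27)
  m <- intensities(s) + matrix(rnorm(80 * length(wavenumbers(s)), 0, 0.02), 80)
  fit <- fitDDSIMCA(makeSet(m, wn = wavenumbers(s)), 3, alpha = 0.01)
  ep <- extremePlotData(fit, alphaGrid = c(1e-9, 0.01, 0.1, 0.5, 1 - 1e-12))
  expect_equal(ep$observed[1], 0)              # alpha -> 0: nothing extreme
  expect_equal(ep$observed[5], 80)             # alpha -> 1: everything
  expect_true(all(diff(ep$observed) >= 0))     # monotone in alpha
  expect_equal(ep$expected, 80 * ep$alpha)
  expect_true(all(ep$lower <= ep$upper))
  # recompute one grid point from the stored training distances
  expect_equal(ep$observed[2],
               sum(fit@trainDistances$c > qchisq(0.99, fit@Nh + fit@Nv)))
})
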