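test_that("SNV gives exact row standardization and clean errors", {
  s <- makeSet(matrix(c(1, 2, 3), 1, 3))
  expect_equal(unname(intensities(snv(s))[1, ]), c(-1, 0, 1))
  const <- makeSet(matrix(5, 1, 3), ids = "flat")
  expect_error(snv(const), "zero-variance.*flat")
  set.seed(11)
  r <- snv(makeSet(matrix(rnorm(20 * 100), 20, 100)))
  m <- intensities(r)
  expect_lt(max(abs(rowMeans(m))), 1e-12)
  expect_lt(max(abs(apply(m, 1, sd) - 1)), 1e-12)
})

test_that("SNV is invariant to positive affine changes of each spectrum", {
  set.seed(12)
  m <- matrix(rnorm(5 * 60), 5, 60)
  a <- runif(5, 0.5, 3); b <- rnorm(5)
  s1 <- snv(makeSet(m))
  s2 <- snv(makeSet(m * a + b))
  expect_lt(max(abs(intensities(s1) - intensities(s2))), 1e-10)
})

test_that("MSC inverts affine scatter exactly and matches an OLS oracle", {
  set.seed(13)
  ref <- exp(-0.5 * ((1:80 - 40) / 10)^2) + 0.3
  s <- makeSet(rbind(2 * ref + 3, ref), wn = 1:80 * 4 + 646)
  out <- intensities(msc(s, reference = ref))
  expect_lt(max(abs(out[1, ] - ref)), 1e-10)   # exact affine case
  expect_lt(max(abs(out[2, ] - ref)), 1e-10)   # identity case
  # noisy rows: after correction, OLS of row on ref has slope 1, intercept 0
  n <- 15
  bs <- runif(n, 0.5, 2); as <- rnorm(n, 0, 0.5)
  m <- t(vapply(1:n, function(i) bs[i] * ref + as[i] + rnorm(80, 0, 1e-6),
                numeric(80)))
  corr <- intensities(msc(makeSet(m, wn = 1:80 * 4 + 646), reference = ref))
  for (i in 1:n) {
    cf <- coef(lm(corr[i, ] ~ ref))
    expect_lt(abs(cf[2] - 1), 1e-4)
    expect_lt(abs(cf[1]), 1e-4)
  }
  # default reference is the set mean
  expect_equal(intensities(msc(makeSet(m, wn = 1:80 * 4 + 646))),
               intensities(msc(makeSet(m, wn = 1:80 * 4 + 646),
                               reference = colMeans(m))))
})

test_that("normalization modes and their degenerate inputs", {
  expect_equal(unname(intensities(normalizeSpectra(makeSet(matrix(c(2, 4), 1)), "max"))[1, ]),
               c(0.5, 1))
  expect_equal(unname(intensities(normalizeSpectra(makeSet(matrix(c(1, 3), 1)), "area"))[1, ]),
               c(0.25, 0.75))
  set.seed(14)
  m <- matrix(rnorm(6 * 40), 6, 40)
  out <- intensities(normalizeSpectra(makeSet(m), "area"))
  expect_lt(max(abs(rowSums(abs(out)) - 1)), 1e-12)
  expect_error(normalizeSpectra(makeSet(matrix(0, 1, 4), ids = "z"), "area"), "z")
})

test_that("Savitzky-Golay reproduces polynomial derivatives exactly", {
  wn <- seq(1000, 1200, by = 4)
  y <- wn^2
  s <- makeSet(matrix(y, 1), wn = wn)
  d1 <- intensities(savitzkyGolay(s, window = 7, polyorder = 2, deriv = 1))[1, ]
  expect_lt(max(abs(d1 - 2 * wn)), 1e-6)      # derivative of w^2, incl. edges
  d0 <- intensities(savitzkyGolay(s, window = 7, polyorder = 2, deriv = 0))[1, ]
  expect_lt(max(abs(d0 - y)), 1e-6)           # quadratic reproduced by quadratic fit
  const <- makeSet(matrix(1, 1, length(wn)), wn = wn)
  expect_lt(max(abs(intensities(savitzkyGolay(const, 7, 2, 1)))), 1e-12)
  # deriv 0 with polyorder = window - 1 interpolates: identity
  set.seed(15)
  r <- makeSet(matrix(rnorm(2 * 30), 2, 30), wn = seq(650, by = 4, length.out = 30))
  ident <- savitzkyGolay(r, window = 5, polyorder = 4, deriv = 0)
  expect_lt(max(abs(intensities(ident) - intensities(r))), 1e-8)
})

test_that("Savitzky-Golay matches a brute-force local least-squares oracle", {
  set.seed(16)
  wn <- seq(650, by = 4, length.out = 60)
  cases <- expand.grid(window = c(5, 9), polyorder = 2:3, deriv = 0:2)
  cases <- cases[cases$deriv <= cases$polyorder, ]
  oracle <- function(y, window, polyorder, deriv) {
    p <- length(y); half <- (window - 1) %/% 2
    out <- numeric(p)
    for (j in seq_len(p)) {
      idx <- if (j <= half) 1:window
             else if (j > p - half) (p - window + 1):p
             else (j - half):(j + half)
      fit <- lm(y[idx] ~ poly(wn[idx] - wn[j], degree = polyorder, raw = TRUE))
      out[j] <- factorial(deriv) *
        coef(fit)[deriv + 1] * (if (deriv == 0) 1 else 1)
    }
    out
  }
  m <- matrix(rnorm(8 * 60), 8, 60)
  s <- makeSet(m, wn = wn)
  for (ci in seq_len(nrow(cases))) {
    got <- intensities(savitzkyGolay(s, cases$window[ci], cases$polyorder[ci],
                                     cases$deriv[ci]))
    for (i in 1:8)
      expect_lt(max(abs(got[i, ] - oracle(m[i, ], cases$window[ci],
                                          cases$polyorder[ci], cases$deriv[ci]))),
                1e-8)
  }
})

test_that("Savitzky-Golay interior agrees with signal::sgolayfilt", {
  skip_if_not_installed("signal")
  set.seed(17)
  wn <- seq(650, by = 4, length.out = 80)
  y <- rnorm(80)
  s <- makeSet(matrix(y, 1), wn = wn)
  for (w in c(7, 11)) {
    half <- (w - 1) %/% 2
    ours <- intensities(savitzkyGolay(s, w, 3, 0))[1, ]
    ref <- signal::sgolayfilt(y, p = 3, n = w)
    interior <- (half + 1):(80 - half)
    expect_lt(max(abs(ours[interior] - ref[interior])), 1e-8)
  }
})

test_that("preprocessing preserves shape and metadata and validates config", {
  std <- generateStudy(studyDesign("mir", "apricot", "separable", seed = 5))
  v <- std$validation2
  for (f in list(snv, function(x) normalizeSpectra(x, "area"),
                 function(x) savitzkyGolay(x, 9, 2, 1), msc)) {
    out <- f(v)
    expect_equal(dim(intensities(out)), dim(intensities(v)))
    expect_identical(sampleMeta(out), sampleMeta(v))
  }
  expect_error(preprocessConfig("savgol", window = 4), "odd")
  expect_error(preprocessConfig("savgol", window = 3, polyorder = 3), "polyorder")
  expect_error(preprocessConfig("savgol", window = 5, polyorder = 2,
                                deriv_order = 3), "deriv_order")
  cfg <- preprocessConfig("snv")
  expect_identical(names(cfg), c("method", "normalize_mode", "window",
                                 "polyorder", "deriv_order", "msc_reference"))
  # non-uniform axis must be rejected with advice
  bad <- makeSet(matrix(rnorm(10), 1), wn = c(1:9, 11) * 4)
  expect_error(savitzkyGolay(bad, 5, 2, 1), "uniform")
})
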