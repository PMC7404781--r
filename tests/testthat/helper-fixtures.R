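# shared fixtures, all generated in code

# minimal SpectrumSet from a samples x wavenumbers matrix
makeSet <- function(m, wn = seq_len(ncol(m)) * 4 + 646, ids = NULL, meta = NULL) {
  SpectrumSet(m, wavenumbers = wn, sampleIds = ids, meta = meta)
}

# target-class data of exact rank r: Gaussian factor scores times fixed
# smooth spectral profiles, plus a constant mean spectrum
rankRSet <- function(n, r, seed, gridStep = 20, scoreSd = NULL) {
  set.seed(seed)
  grid <- seq(650, 4000, by = gridStep)
  prof <- t(vapply(seq_len(r), function(i)
    exp(-0.5 * ((grid - (800 + 400 * i)) / (30 + 5 * i))^2), numeric(length(grid))))
  if (is.null(scoreSd)) scoreSd <- seq(r, 1)
  S <- matrix(rnorm(n * r), n, r) %*% diag(scoreSd, r)
  mu <- exp(-0.5 * ((grid - 2900) / 300)^2)
  m <- S %*% prof + rep(1, n) %*% t(mu)
  makeSet(m, wn = grid)
}

# closure-constrained mixtures: 4 mass fractions summing to 1 times fixed
# component profiles -> the unit response is exactly representable at 4 LVs
closureMixSet <- function(n, seed, gridStep = 20) {
  set.seed(seed)
  grid <- seq(650, 4000, by = gridStep)
  prof <- rbind(exp(-0.5 * ((grid - 1045) / 40)^2),
                exp(-0.5 * ((grid - 1745) / 30)^2) + 0.3 * exp(-0.5 * ((grid - 1160) / 50)^2),
                1.2 * exp(-0.5 * ((grid - 2925) / 60)^2),
                0.5 * exp(-0.5 * ((grid - 1530) / 35)^2) + 0.6 * exp(-0.5 * ((grid - 3290) / 120)^2))
  S <- matrix(runif(n * 4, 0.2, 1), n, 4)
  S <- S / rowSums(S)
  makeSet(S %*% prof, wn = grid)
}

# rebuild the endmembers + artifact model exactly as generateStudy does,
# so independently rendered samples share the study's noise basis
studyGeneratorPieces <- function(design) {
  set.seed(design$seed)
  em <- makeEndmembers(design$region, design$seed)
  art <- makeArtifactModel(em, compSd = design$compSd, noiseSd = design$noiseSd,
                           wnSd = design$wnSd, scatterSd = design$scatterSd,
                           offsetSd = design$offsetSd, slopeSd = design$slopeSd,
                           varietyShift = design$varietyShift,
                           nBasis = design$nBasis)
  list(em = em, art = art)
}

# render n pure samples (alternating varieties) with a given generator
renderPureSet <- function(pieces, n, seed) {
  set.seed(seed)
  m <- t(vapply(seq_len(n), function(i)
    renderSample(pieces$em, 0, 1 + i %% 2, artifacts = pieces$art),
    numeric(length(pieces$em$grid))))
  makeSet(m, wn = pieces$em$grid)
}
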