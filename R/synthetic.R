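# Synthetic almond / apricot / peanut powder spectra.
#
# Endmembers are sums of Gaussian bands on a fixed wavenumber grid.  The
# three materials share one band table (the same functional groups appear
# in all three powders) and differ in band amplitudes - apricot and peanut
# carry coherent macronutrient contrasts versus almond (more carbohydrate,
# less lipid and protein) plus small band-position shifts in the
# fingerprint region, while peanut is a seed-jittered copy of apricot, so
# the two adulterants resemble each other far more than either resembles
# almond.  Within-class variability is generated by four bounded
# "composition" factors (lipid, protein, carbohydrate, moisture) that move
# band groups coherently, a fixed per-variety amplitude signature, and
# measurement artifacts: multiplicative scatter, additive offset, a linear
# baseline tilt, a smooth correlated-noise component confined to a fixed
# low-dimensional basis, and white detector noise.

.MIR_BANDS <- list(
  centers = c(1045, 1160, 1240, 1380, 1460, 1530, 1650, 1745, 2854, 2925, 3010, 3290),
  widths  = c(  30,   25,   28,   22,   20,   25,   30,   25,   18,   22,   15,  120),
  almond  = c(0.55, 0.30, 0.28, 0.22, 0.35, 0.30, 0.40, 0.70, 0.60, 0.80, 0.15, 0.25),
  apricot_base = c(0.95, 0.52, 0.45, 0.36, 0.55, 0.16, 0.22, 0.40, 0.36, 0.50, 0.08, 0.42),
  center_shift = c( -15,  -10,   10,   12,   -6,   12,  -10,   -8,   -3,   -4,   -3,   20),
  width_adu    = c(  40,   30,   24,   26,   18,   28,   26,   22,   18,   22,   15,  140),
  # macronutrient factor loadings: lipid, protein, carbohydrate, moisture
  fac_load = rbind(c(0,0,0,0,0,0,0,1,1,1,0,0),
                   c(0,0,0,0,0,1,1,0,0,0,0,0),
                   c(1,1,1,1,1,0,0,0,0,0,0,0),
                   c(0,0,0,0,0,0,0,0,0,0,0,1)),
  variety_sig = c(1,-1,1,1,-1,1,-1,1,-1,1,1,-1),
  grid = c(650, 4000, 4))

.NIR_BANDS <- list(
  centers = c(4330, 4536, 4744, 4987, 5174, 5376, 6250, 6929, 8550),
  widths  = c(  50,   55,   60,   65,   60,   70,  140,  160,  350),
  almond  = c(0.45, 0.60, 0.25, 0.40, 0.50, 0.35, 0.30, 0.45, 0.20),
  apricot_base = c(0.30, 0.42, 0.35, 0.62, 0.70, 0.50, 0.45, 0.30, 0.28),
  center_shift = c( -20,  -15,   18,   20,  -12,   15,   25,  -20,   30),
  width_adu    = c(  60,   50,   55,   75,   55,   80,  160,  150,  380),
  fac_load = rbind(c(1,1,0,0,0,0,0,0,1),
                   c(0,0,0,0,0,0,0,1,0),
                   c(0,0,1,1,1,1,0,0,0),
                   c(0,0,0,0,0,0,1,0,0)),
  variety_sig = c(1,-1,1,-1,1,1,-1,1,-1),
  grid = c(4000, 10000, 8))

# adulterant amplitude contrast multiplier (applied to apricot_base - almond)
.ADU_CONTRAST <- 1.8

#' Synthetic powder endmembers
#'
#' Builds the three endmember specifications (almond, apricot, peanut) for a
#' spectral region.  Band placement follows the qualitative landscape of
#' powdered-nut spectra (ester carbonyl, amide, C-H and carbohydrate C-O
#' bands in the mid-IR; overtone/combination bands in the NIR).  Apricot
#' and peanut differ from almond by coherent macronutrient amplitude
#' contrasts plus fingerprint band shifts; peanut is derived from apricot
#' by a small seed-deterministic amplitude and position jitter, making the
#' two adulterants spectrally similar to each other and distinct from
#' almond.
#'
#' @param region "mir" (650-4000 cm^-1, step 4) or
#'   "nir" (4000-10000 cm^-1, step 8).
#' @param seed integer; the same seed always yields identical endmembers.
#' @return An object of class \code{"EndmemberSet"}: the grid and one
#'   spec (centers, widths, amplitudes) per material, plus the factor
#'   loadings and variety signature shared by the study generator.
#' @export
makeEndmembers <- function(region = c("mir", "nir"), seed = 1) {
  region <- match.arg(region)
  B <- if (region == "mir") .MIR_BANDS else .NIR_BANDS
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  nb <- length(B$centers)
  aprAmp <- B$almond + .ADU_CONTRAST * (B$apricot_base - B$almond)
  aprAmp <- pmax(aprAmp, 0.02)
  aprCen <- B$centers + B$center_shift
  peaAmp <- pmax(aprAmp * (1 + stats::rnorm(nb, 0, 0.05)), 0.02)
  peaCen <- aprCen + stats::rnorm(nb, 0, 2)
  grid <- seq(B$grid[1], B$grid[2], by = B$grid[3])
  structure(list(
    region = region, grid = grid, seed = seed,
    almond  = list(material = "almond",  name = "almond",
                   centers = B$centers, widths = B$widths, amplitudes = B$almond),
    apricot = list(material = "apricot", name = "apricot",
                   centers = aprCen, widths = B$width_adu, amplitudes = aprAmp),
    peanut  = list(material = "peanut",  name = "peanut",
                   centers = peaCen, widths = B$width_adu, amplitudes = peaAmp),
    fac_load = B$fac_load, variety_sig = B$variety_sig),
    class = "EndmemberSet")
}

#' Render one endmember on its grid
#'
#' @param endmembers an \code{\link{makeEndmembers}} result.
#' @param material "almond", "apricot" or "peanut".
#' @param variety 1 or 2 (almond only: variety 2 applies the fixed
#'   amplitude signature scaled by \code{varietyShift}).
#' @param varietyShift amplitude perturbation scale of the second variety.
#' @return Numeric spectrum on \code{endmembers$grid}.
#' @export
renderEndmember <- function(endmembers, material = "almond", variety = 1,
                            varietyShift = 0.04) {
  sp <- endmembers[[material]]
  amp <- sp$amplitudes
  if (material == "almond" && variety == 2)
    amp <- amp * (1 + varietyShift * endmembers$variety_sig)
  g <- endmembers$grid
  s <- numeric(length(g))
  for (i in seq_along(sp$centers))
    s <- s + amp[i] * exp(-0.5 * ((g - sp$centers[i]) / sp$widths[i])^2)
  s
}

# bounded uniform draw with mean 0 and standard deviation sd
.runifSd <- function(n, sd) stats::runif(n, -sqrt(3) * sd, sqrt(3) * sd)

#' Artifact model for the synthetic study
#'
#' Draws the fixed smooth correlated-noise basis (Gaussian-kernel-smoothed
#' white noise, unit RMS, correlation length ~ 30 grid points) and bundles
#' the artifact scales.  All per-sample artifact coefficients are bounded
#' uniform draws with the stated standard deviations.
#'
#' @param endmembers an \code{\link{makeEndmembers}} result (for the grid).
#' @param compSd sd of the four macronutrient composition factors
#'   (relative band-amplitude units).
#' @param noiseSd sd of each smooth-noise basis coefficient.
#' @param wnSd sd of white detector noise (absorbance units).
#' @param scatterSd sd of the multiplicative scatter factor around 1.
#' @param offsetSd sd of the additive offset.
#' @param slopeSd sd of the linear baseline tilt.
#' @param varietyShift amplitude perturbation scale of variety 2.
#' @param nBasis number of smooth-noise basis functions.
#' @return list of scales plus the \code{p x nBasis} noise basis, consumed
#'   by \code{\link{renderSample}}.
#' @export
makeArtifactModel <- function(endmembers, compSd = 0.03, noiseSd = 0.0025,
                              wnSd = 5e-4, scatterSd = 0.05, offsetSd = 0.03,
                              slopeSd = 0.03, varietyShift = 0.04, nBasis = 12) {
  p <- length(endmembers$grid)
  kern <- stats::dnorm(seq(-90, 90), 0, 30)
  kern <- kern / sum(kern)
  kn <- sqrt(sum(kern^2))
  basis <- vapply(seq_len(nBasis), function(i) {
    w <- stats::rnorm(p + 180)
    v <- stats::filter(w, kern, sides = 2)[91:(p + 90)] / kn
    as.numeric(v / sqrt(mean(v^2)))
  }, numeric(p))
  list(compSd = compSd, noiseSd = noiseSd, wnSd = wnSd, scatterSd = scatterSd,
       offsetSd = offsetSd, slopeSd = slopeSd, varietyShift = varietyShift,
       basis = basis)
}

#' Render one synthetic sample spectrum
#'
#' The sample is the mass-fraction mixture
#' \eqn{(1-c)\,\mathrm{almond}_{variety} + c\,\mathrm{adulterant}} with the
#' composition factors perturbing each constituent's band amplitudes,
#' wrapped in measurement artifacts:
#' \eqn{s = b\,\mathrm{mix} + \mathrm{offset} + \mathrm{slope}\,u +
#' B\zeta + \epsilon} where \eqn{u} is the 0-1 scaled axis, \eqn{B} the
#' smooth-noise basis and \eqn{\epsilon} white noise.  With
#' \code{artifacts = NULL} the render is the exact noiseless mixture, so
#' rendering at concentration c equals the convex combination of the
#' renders at 0 and 100.
#'
#' Randomness is taken from the current R RNG stream; seed the stream (or
#' use \code{\link{generateStudy}}) for reproducibility.
#'
#' @param endmembers an \code{\link{makeEndmembers}} result.
#' @param concentration adulterant mass percent in [0, 100].
#' @param variety almond variety, 1 or 2.
#' @param adulterant "apricot" or "peanut".
#' @param artifacts a \code{\link{makeArtifactModel}} result, or NULL for
#'   the exact noiseless mixture.
#' @return Numeric spectrum on \code{endmembers$grid}.
#' @export
renderSample <- function(endmembers, concentration, variety = 1,
                         adulterant = c("apricot", "peanut"),
                         artifacts = NULL) {
  adulterant <- match.arg(adulterant)
  if (!is.finite(concentration) || concentration < 0 || concentration > 100)
    stop("concentration must lie in [0, 100]")
  g <- endmembers$grid
  vs <- if (is.null(artifacts)) 0.04 else artifacts$varietyShift
  if (is.null(artifacts)) {
    base <- renderEndmember(endmembers, "almond", variety, vs)
    adu <- if (concentration > 0)
      renderEndmember(endmembers, adulterant, varietyShift = vs)
    else 0
    f <- concentration / 100
    return((1 - f) * base + f * adu)
  }
  fl <- endmembers$fac_load
  perturb <- function(sp, amp) {
    z <- .runifSd(nrow(fl), artifacts$compSd)
    amp * (1 + drop(t(fl) %*% z))
  }
  gauss <- function(sp, amp) {
    s <- numeric(length(g))
    for (i in seq_along(sp$centers))
      s <- s + amp[i] * exp(-0.5 * ((g - sp$centers[i]) / sp$widths[i])^2)
    s
  }
  almAmp <- endmembers$almond$amplitudes
  if (variety == 2) almAmp <- almAmp * (1 + vs * endmembers$variety_sig)
  base <- gauss(endmembers$almond, perturb(endmembers$almond, almAmp))
  if (concentration > 0) {
    sp <- endmembers[[adulterant]]
    adu <- gauss(sp, perturb(sp, sp$amplitudes))
    f <- concentration / 100
    mix <- (1 - f) * base + f * adu
  } else mix <- base
  u <- (g - min(g)) / diff(range(g))
  zeta <- .runifSd(ncol(artifacts$basis), artifacts$noiseSd)
  (1 + .runifSd(1, artifacts$scatterSd)) * mix +
    .runifSd(1, artifacts$offsetSd) +
    .runifSd(1, artifacts$slopeSd) * u +
    drop(artifacts$basis %*% zeta) +
    stats::rnorm(length(g), 0, artifacts$wnSd)
}

#' Study design for the synthetic adulteration experiment
#'
#' Encodes the package's reference sample plan: 100 pure calibration
#' samples (50 per almond variety); validation set 1 of the first variety
#' (10 pure + adulterant at 5-50\% in 5\% steps, 10 replicates per level,
#' 110 total); validation set 2 of the second variety (10 pure + 7, 15,
#' 22, 30\%, 10 replicates per level, 50 total).  Two noise presets are
#' shipped: \code{"separable"} (clean measurement; every level at or above
#' 15\% is detectable) and \code{"hard"} (noisier measurement and wider
#' natural variability; the 5\% and 7\% levels are only partially
#' detected).
#'
#' @param region "mir" or "nir".
#' @param adulterant "apricot" or "peanut".
#' @param preset "separable" or "hard".
#' @param nPureVal pure samples per validation set (10 by default;
#'   some NIR-style analyses use 15).
#' @param nCalPerVariety pure calibration samples per variety (50).
#' @param reps replicates per adulteration level (10).
#' @param seed study RNG seed.
#' @param ... overrides of individual artifact scales (compSd, noiseSd,
#'   wnSd, scatterSd, offsetSd, slopeSd, varietyShift, nBasis).
#' @return list of class \code{"StudyDesign"}.
#' @export
studyDesign <- function(region = c("mir", "nir"),
                        adulterant = c("apricot", "peanut"),
                        preset = c("separable", "hard"),
                        nPureVal = 10, nCalPerVariety = 50, reps = 10,
                        seed = 1, ...) {
  region <- match.arg(region)
  adulterant <- match.arg(adulterant)
  preset <- match.arg(preset)
  art <- if (preset == "separable")
    list(compSd = 0.03, noiseSd = 0.0025, wnSd = 5e-4, scatterSd = 0.05,
         offsetSd = 0.03, slopeSd = 0.03, varietyShift = 0.04, nBasis = 12)
  else
    list(compSd = 0.045, noiseSd = 0.004, wnSd = 1e-3, scatterSd = 0.05,
         offsetSd = 0.03, slopeSd = 0.03, varietyShift = 0.04, nBasis = 12)
  over <- list(...)
  bad <- setdiff(names(over), names(art))
  if (length(bad)) stop(sprintf("unknown design override(s): %s",
                                paste(bad, collapse = ", ")))
  art[names(over)] <- over
  structure(c(list(region = region, adulterant = adulterant, preset = preset,
                   nPureVal = as.integer(nPureVal),
                   nCalPerVariety = as.integer(nCalPerVariety),
                   reps = as.integer(reps),
                   validation1_levels = seq(5, 50, by = 5),
                   validation2_levels = c(7, 15, 22, 30),
                   seed = as.integer(seed)),
              art),
            class = "StudyDesign")
}

#' Generate the synthetic study data sets
#'
#' Renders the calibration set and both validation sets of a
#' \code{\link{studyDesign}}.  The calibration set depends only on the
#' region, preset and seed (not on the adulterant), so the runs for the two
#' adulterants share one calibration model.  Output is bit-reproducible
#' for a given design.
#'
#' @param design a \code{\link{studyDesign}}.
#' @return list with \code{calibration}, \code{validation1},
#'   \code{validation2} (\linkS4class{SpectrumSet}s with full metadata) and
#'   the \code{endmembers} used.
#' @export
generateStudy <- function(design) {
  stopifnot(inherits(design, "StudyDesign"))
  if (design$nCalPerVariety < 1 || design$reps < 1 || design$nPureVal < 0)
    stop("design totals inconsistent")
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(design$seed)
  em <- makeEndmembers(design$region, design$seed)
  art <- makeArtifactModel(em, compSd = design$compSd,
                           noiseSd = design$noiseSd, wnSd = design$wnSd,
                           scatterSd = design$scatterSd,
                           offsetSd = design$offsetSd,
                           slopeSd = design$slopeSd,
                           varietyShift = design$varietyShift,
                           nBasis = design$nBasis)
  renderSet <- function(conc, variety, role, prefix) {
    n <- length(conc)
    m <- t(vapply(seq_len(n), function(i)
      renderSample(em, conc[i], variety[i], design$adulterant, art),
      numeric(length(em$grid))))
    ids <- sprintf("%s_%03d", prefix, seq_len(n))
    meta <- data.frame(
      class_label = ifelse(conc > 0, "adulterated", "pure"),
      adulterant = ifelse(conc > 0, design$adulterant, "none"),
      concentration = conc, variety = variety, set_role = role,
      row.names = ids)
    SpectrumSet(m, wavenumbers = em$grid, sampleIds = ids, meta = meta)
  }
  nc <- design$nCalPerVariety
  cal <- renderSet(rep(0, 2 * nc), rep(c(1L, 2L), each = nc),
                   "calibration", "cal")
  v1conc <- c(rep(0, design$nPureVal),
              rep(design$validation1_levels, each = design$reps))
  v1 <- renderSet(v1conc, rep(1L, length(v1conc)), "validation1", "val1")
  v2conc <- c(rep(0, design$nPureVal),
              rep(design$validation2_levels, each = design$reps))
  v2 <- renderSet(v2conc, rep(2L, length(v2conc)), "validation2", "val2")
  list(calibration = cal, validation1 = v1, validation2 = v2,
       endmembers = em)
}
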