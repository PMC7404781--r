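#' Standard normal variate transform
#'
#' Centers and scales every spectrum to mean 0 and unit standard deviation
#' (n-1 denominator), removing additive offsets and multiplicative scatter.
#'
#' @param x a \linkS4class{SpectrumSet} whose spectra have at least two
#'   points and nonzero standard deviation.
#' @return A \linkS4class{SpectrumSet} of SNV-transformed spectra.
#' @export
snv <- function(x) {
  m <- intensities(x)
  if (ncol(m) < 2) stop("SNV requires spectra with at least 2 points")
  mu <- rowMeans(m)
  sdv <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
  bad <- sdv == 0 | !is.finite(sdv)
  if (any(bad))
    stop(sprintf("zero-variance spectrum (SNV undefined) for sample(s): %s",
                 paste(rownames(m)[bad], collapse = ", ")))
  .replaceIntensities(x, (m - mu) / sdv)
}

#' Multiplicative scatter correction
#'
#' Regresses each spectrum on a reference by ordinary least squares,
#' \eqn{x \approx a + b \cdot ref}, and returns \eqn{(x - a)/b}.
#'
#' @param x a \linkS4class{SpectrumSet}.
#' @param reference reference spectrum (numeric vector on the same axis);
#'   by default the column mean of \code{x} ("train mean").  When correcting
#'   new data against a calibration set, pass the calibration mean.
#' @return A \linkS4class{SpectrumSet} of corrected spectra.
#' @export
msc <- function(x, reference = NULL) {
  m <- intensities(x)
  if (is.null(reference)) reference <- colMeans(m)
  if (length(reference) != ncol(m))
    stop("reference must have the same number of points as the spectra")
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  if (denom == 0) stop("reference spectrum is constant")
  b <- as.vector(m %*% rc) / denom          # OLS slope per sample
  a <- rowMeans(m) - b * mean(reference)
  bad <- abs(b) < 1e-12
  if (any(bad))
    stop(sprintf("MSC correction failed (|slope| < 1e-12) for sample(s): %s",
                 paste(rownames(m)[bad], collapse = ", ")))
  .replaceIntensities(x, (m - a) / b)
}

#' Normalize spectra by maximum or total area
#'
#' @param x a \linkS4class{SpectrumSet}.
#' @param mode \code{"max"} divides each spectrum by its maximum;
#'   \code{"area"} divides by the sum of absolute values.
#' @return A \linkS4class{SpectrumSet}.
#' @export
normalizeSpectra <- function(x, mode = c("max", "area")) {
  mode <- match.arg(mode)
  m <- intensities(x)
  s <- if (mode == "max") apply(m, 1, max) else rowSums(abs(m))
  bad <- s == 0 | !is.finite(s)
  if (any(bad))
    stop(sprintf("cannot normalize all-zero spectrum for sample(s): %s",
                 paste(rownames(m)[bad], collapse = ", ")))
  .replaceIntensities(x, m / s)
}

# least-squares polynomial smoother row for one window:
# returns w such that w %*% y = d-th derivative of the fitted polynomial at x0
.savgolRow <- function(xw, x0, polyorder, deriv) {
  G <- outer(xw - x0, 0:polyorder, "^")
  # row 'deriv+1' of the pseudo-inverse picks the deriv-th poly coefficient
  cf <- solve(crossprod(G), t(G))[deriv + 1, ]
  factorial(deriv) * cf
}

#' Savitzky-Golay smoothing and derivatives
#'
#' Replaces every point with the \code{deriv}-th derivative of a local
#' least-squares polynomial of degree \code{polyorder} fitted over a
#' centered window of \code{window} points.  The polynomial is fitted in
#' physical axis units, so derivatives are scaled per cm^-1 and the output
#' is grid-independent.  At the edges the fit uses a full-width one-sided
#' window evaluated at the edge point, keeping the axis length constant.
#'
#' @param x a \linkS4class{SpectrumSet} on a uniform grid (relative step
#'   tolerance 1e-9).
#' @param window odd window size in points, \code{>= 3} and
#'   \code{> polyorder}.
#' @param polyorder polynomial degree.
#' @param deriv derivative order (0, 1 or 2); 0 gives plain smoothing.
#' @return A \linkS4class{SpectrumSet} of filtered spectra.
#' @export
savitzkyGolay <- function(x, window, polyorder, deriv = 0) {
  if (window %% 2 != 1 || window < 3) stop("window must be an odd integer >= 3")
  if (polyorder >= window) stop("window must be larger than polyorder")
  if (!deriv %in% 0:2) stop("deriv must be 0, 1 or 2")
  if (deriv > polyorder) stop("deriv must not exceed polyorder")
  wn <- wavenumbers(x)
  p <- length(wn)
  if (window > p) stop("window is larger than the axis")
  d <- diff(wn)
  if (max(abs(d - d[1])) > 1e-9 * abs(d[1]))
    stop("axis step is not uniform; resample onto a uniform grid first")
  half <- (window - 1) %/% 2
  L <- matrix(0, p, p)
  # interior rows share one coefficient vector (uniform grid)
  wrel <- (-half:half) * d[1]
  wInt <- .savgolRow(wrel, 0, polyorder, deriv)
  for (j in seq_len(p)) {
    if (j <= half) idx <- 1:window
    else if (j > p - half) idx <- (p - window + 1):p
    else { L[j, (j - half):(j + half)] <- wInt; next }
    L[j, idx] <- .savgolRow(wn[idx], wn[j], polyorder, deriv)
  }
  m <- intensities(x)
  .replaceIntensities(x, m %*% t(L))
}

#' Build a preprocessing configuration
#'
#' @param method one of "none", "normalize", "smooth", "msc", "snv",
#'   "savgol".  "smooth" is Savitzky-Golay with \code{deriv_order = 0}.
#' @param normalize_mode "max" or "area" (normalize only).
#' @param window,polyorder,deriv_order Savitzky-Golay settings; the window
#'   must be odd, at least 3 and larger than \code{polyorder}, and
#'   \code{deriv_order <= polyorder}.
#' @param msc_reference "train_mean" or a numeric reference spectrum.
#' @return A validated list of class \code{"PreprocessConfig"}; the keys
#'   match the pipeline YAML schema exactly.
#' @export
preprocessConfig <- function(method = c("none", "normalize", "smooth", "msc",
                                        "snv", "savgol"),
                             normalize_mode = c("max", "area"),
                             window = 11, polyorder = 2, deriv_order = 0,
                             msc_reference = "train_mean") {
  method <- match.arg(method)
  normalize_mode <- match.arg(normalize_mode)
  if (method %in% c("smooth", "savgol")) {
    if (window %% 2 != 1 || window < 3) stop("window must be an odd integer >= 3")
    if (window <= polyorder) stop("window must exceed polyorder")
    if (method == "smooth") deriv_order <- 0
    if (!deriv_order %in% 0:2) stop("deriv_order must be 0, 1 or 2")
    if (deriv_order > polyorder) stop("deriv_order must not exceed polyorder")
  }
  structure(list(method = method, normalize_mode = normalize_mode,
                 window = as.integer(window), polyorder = as.integer(polyorder),
                 deriv_order = as.integer(deriv_order),
                 msc_reference = msc_reference),
            class = "PreprocessConfig")
}

#' Apply a preprocessing configuration
#'
#' @param x a \linkS4class{SpectrumSet}.
#' @param config a \code{\link{preprocessConfig}} (or equivalent list).
#' @param reference reference spectrum for MSC when
#'   \code{msc_reference = "train_mean"} was resolved on a calibration set;
#'   defaults to the mean of \code{x}.
#' @return The transformed \linkS4class{SpectrumSet}.
#' @export
applyPreprocess <- function(x, config, reference = NULL) {
  switch(config$method,
    none = x,
    snv = snv(x),
    msc = {
      ref <- if (is.numeric(config$msc_reference)) config$msc_reference
             else reference
      msc(x, ref)
    },
    normalize = normalizeSpectra(x, config$normalize_mode),
    smooth = savitzkyGolay(x, config$window, config$polyorder, 0),
    savgol = savitzkyGolay(x, config$window, config$polyorder,
                           config$deriv_order),
    stop(sprintf("unknown preprocessing method '%s'", config$method)))
}
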