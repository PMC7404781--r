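#' OCPLSModel: one-class partial least squares model
#'
#' PLS1 regression of the constant unit response y = 1 on the (uncentered)
#' target-class spectra.  Class membership of a new sample is judged by two
#' statistics: Hotelling's T-squared of its latent-variable scores (centered
#' and standardized by the training score moments) against an F-distribution
#' bound, and the absolute centered residual (ACR) of its predicted response
#' against a Gaussian two-sided bound.  A sample is accepted only when both
#' statistics are within their limits; the four quadrants (regular, good
#' leverage, response outlier, bad leverage) diagnose the kind of deviation.
#'
#' @slot weights p x A PLS weight vectors (W).
#' @slot loadings p x A X-loadings (P).
#' @slot projection W (P'W)^{-1}; new scores are X \%*\% projection.
#' @slot yloadings response loadings q (length A).
#' @slot coefficients regression vector b for the raw spectra.
#' @slot scoreCenter,scoreSD training score means and standard deviations.
#' @slot ncomp number of latent variables A.
#' @slot t2Limit Hotelling acceptance bound.
#' @slot residualCenter mean training predicted-response residual.
#' @slot residualSD standard deviation of training residuals.
#' @slot acrLimit bound on the absolute centered residual.
#' @slot alpha nominal type-I error of each of the two tests.
#' @slot nTrain training sample count.
#' @slot wavenumber training axis.
#' @exportClass OCPLSModel
setClass("OCPLSModel",
  representation(weights = "matrix", loadings = "matrix",
                 projection = "matrix", yloadings = "numeric",
                 coefficients = "numeric",
                 scoreCenter = "numeric", scoreSD = "numeric",
                 ncomp = "integer", t2Limit = "numeric",
                 residualCenter = "numeric", residualSD = "numeric",
                 acrLimit = "numeric", alpha = "numeric",
                 nTrain = "integer", wavenumber = "numeric"))

setValidity("OCPLSModel", function(object) {
  msg <- character(0)
  if (object@ncomp < 1) msg <- c(msg, "ncomp must be >= 1")
  if (object@t2Limit <= 0) msg <- c(msg, "t2Limit must be positive")
  if (object@acrLimit <= 0) msg <- c(msg, "acrLimit must be positive")
  if (any(object@scoreSD <= 0)) msg <- c(msg, "score variances must be positive")
  if (length(msg)) msg else TRUE
})

# NIPALS PLS1 of y on X (no centering: a constant response has zero
# covariance with column-centered predictors, so the weights would vanish).
# With partial = TRUE extraction stops quietly when the rank is exhausted
# and the components found so far are returned (used by MCCV, whose
# candidate grid may exceed the data rank).
.pls1 <- function(X, y, ncomp, tol = 1e-12, partial = FALSE) {
  n <- nrow(X); p <- ncol(X)
  E <- X; f <- y
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  q <- numeric(ncomp); Tm <- matrix(0, n, ncomp)
  A <- 0L
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (!is.finite(nw) || nw < tol) {
      if (partial && A >= 1L) break
      stop(sprintf("fit error: NIPALS weight collapsed at latent variable %d (rank exhausted)", a))
    }
    w <- w / nw
    tt <- drop(E %*% w)
    ss <- sum(tt^2)
    if (!is.finite(ss) || ss < tol) {
      if (partial && A >= 1L) break
      stop(sprintf("fit error: zero score variance at latent variable %d", a))
    }
    pa <- drop(crossprod(E, tt)) / ss
    qa <- sum(f * tt) / ss
    E <- E - tcrossprod(tt, pa)
    f <- f - tt * qa
    W[, a] <- w; P[, a] <- pa; q[a] <- qa; Tm[, a] <- tt
    A <- a
  }
  W <- W[, seq_len(A), drop = FALSE]
  P <- P[, seq_len(A), drop = FALSE]
  q <- q[seq_len(A)]
  Tm <- Tm[, seq_len(A), drop = FALSE]
  R <- W %*% solve(crossprod(P, W))
  list(W = W, P = P, q = q, scores = Tm, projection = R,
       coef = drop(R %*% q), ncomp = A)
}

#' Fit a one-class PLS model
#'
#' @param x \linkS4class{SpectrumSet} of target-class training spectra.
#' @param ncomp number of latent variables A (1 <= A < n).
#' @param alpha nominal type-I error of each acceptance test (study
#'   default 0.01).  The T-squared limit is
#'   \eqn{A(n^2-1)/(n(n-A)) F_{1-\alpha}(A, n-A)}; the ACR limit is
#'   \eqn{z_{1-\alpha/2}\,\mathrm{sd}(r)} on the centered training
#'   residuals \eqn{r_i = \hat{y}_i - 1}.
#' @return An \linkS4class{OCPLSModel}.
#' @export
fitOCPLS <- function(x, ncomp, alpha = 0.01) {
  stopifnot(alpha > 0, alpha < 1)
  m <- intensities(x)
  n <- nrow(m)
  if (ncomp >= n) stop("rank error: ncomp must be smaller than the number of training samples")
  if (ncomp < 1) stop("ncomp must be >= 1")
  fit <- .pls1(m, rep(1, n), as.integer(ncomp))
  A <- fit$ncomp
  scCenter <- colMeans(fit$scores)
  scSD <- apply(fit$scores, 2, stats::sd)
  r <- drop(m %*% fit$coef) - 1
  rc <- mean(r)
  rs <- stats::sd(r)
  if (!is.finite(rs) || rs <= 0)
    stop("degenerate training residuals (zero spread); ACR limit undefined")
  model <- new("OCPLSModel",
    weights = fit$W, loadings = fit$P, projection = fit$projection,
    yloadings = fit$q, coefficients = fit$coef,
    scoreCenter = scCenter, scoreSD = scSD, ncomp = A,
    t2Limit = A * (n^2 - 1) / (n * (n - A)) * stats::qf(1 - alpha, A, n - A),
    residualCenter = rc, residualSD = rs,
    acrLimit = stats::qnorm(1 - alpha / 2) * rs,
    alpha = alpha, nTrain = as.integer(n), wavenumber = wavenumbers(x))
  validObject(model)
  model
}

.ocplsStats <- function(model, m) {
  Tn <- m %*% model@projection
  t2 <- rowSums(sweep(sweep(Tn, 2, model@scoreCenter), 2, model@scoreSD, "/")^2)
  acr <- abs(drop(m %*% model@coefficients) - 1 - model@residualCenter)
  list(t2 = t2, acr = acr)
}

#' @rdname classifySamples
#' @export
setMethod("classifySamples", "OCPLSModel", function(object, newdata) {
  stopifnot(is(newdata, "SpectrumSet"))
  wn <- wavenumbers(newdata)
  if (length(wn) != length(object@wavenumber) ||
      any(wn != object@wavenumber))
    stop("axis mismatch: new data must be on exactly the training wavenumber axis")
  m <- intensities(newdata)
  st <- .ocplsStats(object, m)
  hiT <- st$t2 > object@t2Limit
  hiA <- st$acr > object@acrLimit
  quadrant <- ifelse(!hiT & !hiA, "regular",
                     ifelse(hiT & !hiA, "good_leverage",
                            ifelse(!hiT & hiA, "response_outlier", "bad_leverage")))
  data.frame(sample_id = rownames(m), t2 = st$t2, acr = st$acr,
             quadrant = quadrant, accepted = !hiT & !hiA,
             stringsAsFactors = FALSE, row.names = NULL)
})

setMethod("show", "OCPLSModel", function(object) {
  cat(sprintf("OCPLSModel: %d LV(s), n_train = %d\n", object@ncomp, object@nTrain))
  cat(sprintf("  T2 limit = %.3f, ACR limit = %.4g (alpha = %g)\n",
              object@t2Limit, object@acrLimit, object@alpha))
  invisible(NULL)
})

#' Monte-Carlo cross-validation for the number of latent variables
#'
#' Repeatedly splits the training set at random, fits the unit-response PLS
#' on the kept part, predicts the held-out responses and pools the
#' residuals against 1 over all repetitions.  The standard deviation of the
#' pooled residuals is reported per candidate LV count; the chosen A is the
#' smallest count whose residual sd is within \code{tolerance} of the
#' minimum (parsimony rule).
#'
#' @param x \linkS4class{SpectrumSet} of target-class training spectra.
#' @param maxLVs largest candidate LV count (must be smaller than the
#'   retained part of every split).
#' @param splits number of Monte-Carlo repetitions (>= 10).
#' @param holdoutFraction fraction of samples held out per split.
#' @param seed RNG seed; results are reproducible for a given seed.
#' @param tolerance relative slack of the parsimony rule (default 0.05).
#' @return list with \code{chosen_A}, \code{curve} (data.frame of lv and
#'   residual_sd), and the settings used.
#' @export
mccvSelectLVs <- function(x, maxLVs = 10, splits = 100, holdoutFraction = 0.2,
                          seed = 1, tolerance = 0.05) {
  n <- ncol(x)
  if (splits < 10) stop("at least 10 Monte-Carlo splits are required")
  if (holdoutFraction <= 0 || holdoutFraction >= 1)
    stop("holdoutFraction must be in (0, 1)")
  nHold <- max(1, round(n * holdoutFraction))
  if (nHold >= n) stop("split error: holdout leaves no training samples")
  if (maxLVs >= n - nHold)
    stop("split error: maxLVs must be smaller than the retained sample count")
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  m <- intensities(x)
  res <- vector("list", maxLVs)
  for (s in seq_len(splits)) {
    hold <- sample.int(n, nHold)
    fit <- try(.pls1(m[-hold, , drop = FALSE], rep(1, n - nHold), maxLVs,
                     partial = TRUE), silent = TRUE)
    if (inherits(fit, "try-error")) next
    Xh <- m[hold, , drop = FALSE]
    for (A in seq_len(fit$ncomp)) {
      b <- fit$projection[, seq_len(A), drop = FALSE] %*% fit$q[seq_len(A)]
      res[[A]] <- c(res[[A]], drop(Xh %*% b) - 1)
    }
  }
  sds <- vapply(res, function(r) if (is.null(r)) NA_real_ else stats::sd(r),
                numeric(1))
  if (all(is.na(sds))) stop("split error: no successful Monte-Carlo fits")
  chosen <- which(sds <= min(sds, na.rm = TRUE) * (1 + tolerance))[1]
  list(chosen_A = as.integer(chosen),
       curve = data.frame(lv = seq_len(maxLVs), residual_sd = sds),
       splits = splits, holdout_fraction = holdoutFraction, seed = seed,
       tolerance = tolerance)
}
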