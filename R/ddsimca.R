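#' DDSIMCAModel: data-driven SIMCA class model
#'
#' A one-class PCA model of the target class.  For a training sample i the
#' score distance is \eqn{h_i = \sum_{a \le k} t_{ia}^2/\lambda_a} and the
#' orthogonal distance \eqn{v_i} is the residual sum of squares outside the
#' k-component subspace.  Both are assigned scaled chi-square distributions
#' with data-estimated degrees of freedom \eqn{N_h, N_v}; the total distance
#' \eqn{c = N_h h/h_0 + N_v v/v_0} is compared with
#' \eqn{\chi^2_{1-\alpha}(N_h + N_v)} (acceptance) and with the
#' multiplicity-adjusted outlier quantile at significance \eqn{\gamma}.
#'
#' @slot center mean training spectrum.
#' @slot loadings p x k orthonormal PCA loadings.
#' @slot eigenvalues k score variances (n-1 denominator).
#' @slot ncomp number of principal components k (after rank truncation).
#' @slot h0,v0 scaling centers (training means of h and v).
#' @slot Nh,Nv estimated degrees of freedom.
#' @slot alpha,gamma type-I error of acceptance; outlier significance.
#' @slot cCrit,cOut acceptance and outlier thresholds on the total distance.
#' @slot nTrain number of training samples.
#' @slot wavenumber training axis (classification requires an exact match).
#' @slot dofMethod "moments" or "robust".
#' @slot degenerateV TRUE when the training data lie in the model subspace
#'   (all v = 0); acceptance then uses the score distance alone and any
#'   sample with v above \code{vTol} is an outlier.
#' @slot vTol numerical tolerance used for the degenerate-subspace check.
#' @slot trainDistances data.frame of training h, v, c.
#' @exportClass DDSIMCAModel
setClass("DDSIMCAModel",
  representation(center = "numeric", loadings = "matrix",
                 eigenvalues = "numeric", ncomp = "integer",
                 h0 = "numeric", v0 = "numeric", Nh = "numeric", Nv = "numeric",
                 alpha = "numeric", gamma = "numeric",
                 cCrit = "numeric", cOut = "numeric", nTrain = "integer",
                 wavenumber = "numeric", dofMethod = "character",
                 degenerateV = "logical", vTol = "numeric",
                 trainDistances = "data.frame"))

setValidity("DDSIMCAModel", function(object) {
  msg <- character(0)
  k <- object@ncomp
  if (k < 1) msg <- c(msg, "ncomp must be >= 1")
  if (ncol(object@loadings) != k) msg <- c(msg, "loadings/ncomp mismatch")
  if (object@Nh <= 0) msg <- c(msg, "Nh must be positive")
  if (!object@degenerateV && object@Nv <= 0) msg <- c(msg, "Nv must be positive")
  G <- crossprod(object@loadings)
  if (max(abs(G - diag(k))) > 1e-10)
    msg <- c(msg, "loadings are not orthonormal")
  if (length(msg)) msg else TRUE
})

#' Chi-square degrees of freedom by the method of moments (or robustly)
#'
#' For x distributed as \eqn{x_0 \chi^2(N)/N} the method of moments gives
#' \eqn{N = 2\,\mathrm{mean}(x)^2/\mathrm{var}(x)}.  The robust variant
#' matches the interquartile-range-to-median ratio of a scaled chi-square,
#' which tolerates contaminated training sets.
#'
#' @param x positive sample (score or orthogonal distances).
#' @param method "moments" (classical) or "robust".
#' @return Estimated degrees of freedom (positive real).
#' @export
estimateChiSqDoF <- function(x, method = c("moments", "robust")) {
  method <- match.arg(method)
  if (method == "moments") {
    v <- stats::var(x)
    if (!is.finite(v) || v <= 0)
      stop("degenerate distances (zero variance); try method = 'robust'")
    return(2 * mean(x)^2 / v)
  }
  med <- stats::median(x)
  iqr <- stats::IQR(x)
  if (med <= 0 || iqr <= 0)
    stop("degenerate distances; cannot estimate degrees of freedom")
  target <- iqr / med
  f <- function(logN) {
    N <- exp(logN)
    (stats::qchisq(0.75, N) - stats::qchisq(0.25, N)) / stats::qchisq(0.5, N) - target
  }
  lo <- log(0.05); hi <- log(2000)
  if (f(lo) * f(hi) > 0) return(2 * mean(x)^2 / max(stats::var(x), 1e-300))
  exp(stats::uniroot(f, c(lo, hi), tol = 1e-8)$root)
}

.ddDistances <- function(model, m) {
  Xc <- sweep(m, 2, model@center)
  Tk <- Xc %*% model@loadings
  h <- rowSums(sweep(Tk^2, 2, model@eigenvalues, "/"))
  v <- pmax(rowSums(Xc^2) - rowSums(Tk^2), 0)
  list(h = h, v = v)
}

.ddTotal <- function(model, h, v) {
  if (model@degenerateV) {
    cc <- model@Nh * h / model@h0
    cc[v > model@vTol] <- Inf
    cc
  } else {
    model@Nh * h / model@h0 + model@Nv * v / model@v0
  }
}

#' Fit a data-driven SIMCA model
#'
#' PCA on the column-centered training matrix; chi-square acceptance at
#' significance \code{alpha} and an outlier boundary at \code{gamma},
#' adjusted for multiplicity over the training set
#' (\eqn{\gamma_{adj} = 1 - (1-\gamma)^{1/n}}).  Components whose
#' eigenvalue falls below 1e-12 of the leading one are dropped, so
#' \code{ncomp} may be reduced to the numerical rank.  When the training
#' data lie exactly in the model subspace (all orthogonal distances zero)
#' the fit reports the degeneracy and acceptance is governed by the score
#' distance alone.
#'
#' @param x \linkS4class{SpectrumSet} of target-class training spectra.
#' @param ncomp number of principal components (k < number of samples).
#' @param alpha type-I error for the acceptance boundary (study default 0.01).
#' @param gamma significance of the outlier boundary (study default 0.01).
#' @param dofMethod degrees-of-freedom estimator, see
#'   \code{\link{estimateChiSqDoF}}.
#' @param roundDoF round the estimated degrees of freedom to integers
#'   (clipped to [1, 250]) for parity with toolbox conventions.
#' @return A \linkS4class{DDSIMCAModel}.
#' @export
fitDDSIMCA <- function(x, ncomp, alpha = 0.01, gamma = 0.01,
                       dofMethod = c("moments", "robust"), roundDoF = FALSE) {
  dofMethod <- match.arg(dofMethod)
  stopifnot(alpha > 0, alpha < 1, gamma > 0, gamma < 1)
  m <- intensities(x)
  n <- nrow(m); p <- ncol(m)
  if (ncomp >= n) stop("rank error: ncomp must be smaller than the number of training samples")
  if (ncomp < 1) stop("ncomp must be >= 1")
  ctr <- colMeans(m)
  Xc <- sweep(m, 2, ctr)
  sv <- svd(Xc, nu = 0)
  d2 <- sv$d^2
  rank <- sum(d2 > d2[1] * 1e-12)
  k <- min(as.integer(ncomp), rank)
  P <- sv$v[, seq_len(k), drop = FALSE]
  Tk <- Xc %*% P
  lam <- colSums(Tk^2) / (n - 1)
  h <- rowSums(sweep(Tk^2, 2, lam, "/"))
  tot <- rowSums(Xc^2)
  v <- pmax(tot - rowSums(Tk^2), 0)
  h0 <- mean(h)
  v0 <- mean(v)
  vTol <- max(1e-8 * mean(tot), 10 * max(v))
  degen <- v0 <= 1e-12 * mean(tot)
  Nh <- estimateChiSqDoF(h, dofMethod)
  Nv <- if (degen) 0 else estimateChiSqDoF(v, dofMethod)
  if (roundDoF) {
    Nh <- min(max(round(Nh), 1), 250)
    if (!degen) Nv <- min(max(round(Nv), 1), 250)
  }
  if (degen) {
    message(sprintf(
      "training data lie in the %d-component subspace (all orthogonal distances ~ 0); acceptance uses the score distance only", k))
    v0 <- 0
  }
  Ntot <- Nh + Nv
  gammaAdj <- 1 - (1 - gamma)^(1 / n)
  model <- new("DDSIMCAModel",
    center = ctr, loadings = P, eigenvalues = lam, ncomp = k,
    h0 = h0, v0 = v0, Nh = Nh, Nv = Nv, alpha = alpha, gamma = gamma,
    cCrit = stats::qchisq(1 - alpha, Ntot),
    cOut = stats::qchisq(1 - gammaAdj, Ntot),
    nTrain = as.integer(n), wavenumber = wavenumbers(x),
    dofMethod = dofMethod, degenerateV = degen, vTol = vTol,
    trainDistances = data.frame(sample_id = rownames(m), h = h, v = v,
                                stringsAsFactors = FALSE))
  model@trainDistances$c <- .ddTotal(model, h, v)
  validObject(model)
  model
}

#' @rdname classifySamples
#' @export
setMethod("classifySamples", "DDSIMCAModel", function(object, newdata) {
  stopifnot(is(newdata, "SpectrumSet"))
  wn <- wavenumbers(newdata)
  if (length(wn) != length(object@wavenumber) ||
      any(wn != object@wavenumber))
    stop("axis mismatch: new data must be on exactly the training wavenumber axis")
  m <- intensities(newdata)
  d <- .ddDistances(object, m)
  cc <- .ddTotal(object, d$h, d$v)
  category <- ifelse(cc <= object@cCrit, "regular",
                     ifelse(cc <= object@cOut, "extreme", "outlier"))
  data.frame(sample_id = rownames(m), h = d$h, v = d$v, c = cc,
             category = category, accepted = cc <= object@cCrit,
             stringsAsFactors = FALSE, row.names = NULL)
})

setMethod("show", "DDSIMCAModel", function(object) {
  cat(sprintf("DDSIMCAModel: %d PC(s), n_train = %d\n",
              object@ncomp, object@nTrain))
  cat(sprintf("  h0 = %.4g, v0 = %.4g, Nh = %.3g, Nv = %.3g%s\n",
              object@h0, object@v0, object@Nh, object@Nv,
              if (object@degenerateV) " (degenerate residual)" else ""))
  cat(sprintf("  alpha = %g (c_crit = %.3f), gamma = %g (c_out = %.3f)\n",
              object@alpha, object@cCrit, object@gamma, object@cOut))
  invisible(NULL)
})

#' Choose the number of principal components by target-class sensitivity
#'
#' Cross-validates the target-class acceptance rate for each candidate k
#' and picks the smallest k whose cross-validated acceptance is within one
#' binomial standard error of the maximum.  Candidates above the numerical
#' rank of the data collapse onto the rank (the acceptance curve is then
#' constant there).
#'
#' @param x \linkS4class{SpectrumSet} of target-class training spectra.
#' @param kCandidates candidate numbers of components (default 1:10).
#' @param alpha,gamma,dofMethod passed to \code{\link{fitDDSIMCA}}.
#' @param folds number of cross-validation folds (>= 2).
#' @param seed RNG seed for the fold assignment.
#' @return list with \code{chosen_k} and \code{curve}
#'   (data.frame of k and cross-validated acceptance rate).
#' @export
selectNumPCs <- function(x, kCandidates = 1:10, alpha = 0.01, gamma = 0.01,
                         dofMethod = "moments", folds = 5, seed = 1) {
  n <- ncol(x)
  if (folds < 2) stop("at least 2 folds are required")
  if (n < folds) stop("more folds than samples")
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  fold <- sample(rep(seq_len(folds), length.out = n))
  rates <- vapply(kCandidates, function(k) {
    acc <- 0; tried <- 0
    for (f in seq_len(folds)) {
      tr <- x[, fold != f]
      te <- x[, fold == f]
      mod <- try(suppressMessages(
        fitDDSIMCA(tr, min(k, ncol(tr) - 1), alpha, gamma, dofMethod)),
        silent = TRUE)
      if (inherits(mod, "try-error")) next
      acc <- acc + sum(classifySamples(mod, te)$accepted)
      tried <- tried + ncol(te)
    }
    if (tried == 0) NA_real_ else acc / tried
  }, numeric(1))
  if (all(is.na(rates))) stop("selection error: all candidate models degenerate")
  mx <- max(rates, na.rm = TRUE)
  se <- sqrt(mx * (1 - mx) / n)
  chosen <- kCandidates[which(!is.na(rates) & rates >= mx - se)[1]]
  list(chosen_k = chosen,
       curve = data.frame(k = kCandidates, acceptance = rates))
}

#' @rdname extremePlotData
#' @export
setMethod("extremePlotData", "DDSIMCAModel", function(object, alphaGrid = NULL) {
  if (is.null(alphaGrid))
    alphaGrid <- 10^seq(log10(0.0005), log10(0.5), length.out = 25)
  n <- object@nTrain
  Ntot <- object@Nh + object@Nv
  cc <- object@trainDistances$c
  observed <- vapply(alphaGrid, function(a)
    sum(cc > stats::qchisq(1 - a, Ntot)), numeric(1))
  data.frame(alpha = alphaGrid,
             expected = n * alphaGrid,
             observed = observed,
             lower = stats::qbinom(0.025, n, alphaGrid),
             upper = stats::qbinom(0.975, n, alphaGrid))
})

# save/restore global RNG state so seeded helpers do not disturb the caller
.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed.restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
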