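#' Write a fitted one-class model to JSON
#'
#' @param model a \linkS4class{DDSIMCAModel} or \linkS4class{OCPLSModel}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeModelJSON <- function(model, path) {
  obj <- if (is(model, "DDSIMCAModel")) list(
    type = "ddsimca",
    mean = model@center, loadings = model@loadings,
    eigenvalues = model@eigenvalues, k = model@ncomp,
    h0 = model@h0, v0 = model@v0, N_h = model@Nh, N_v = model@Nv,
    alpha = model@alpha, gamma = model@gamma,
    c_crit = model@cCrit, c_out = model@cOut, n_train = model@nTrain,
    wavenumber = model@wavenumber, dof_method = model@dofMethod,
    degenerate_v = model@degenerateV, v_tol = model@vTol,
    train_distances = model@trainDistances)
  else if (is(model, "OCPLSModel")) list(
    type = "ocpls",
    weights = model@weights, loadings = model@loadings,
    projection = model@projection, yloadings = model@yloadings,
    regression_coefficients = model@coefficients,
    score_center = model@scoreCenter, score_sd = model@scoreSD,
    A = model@ncomp, t2_limit = model@t2Limit,
    residual_center = model@residualCenter, residual_sd = model@residualSD,
    acr_limit = model@acrLimit, alpha = model@alpha,
    n_train = model@nTrain, wavenumber = model@wavenumber)
  else stop("unsupported model class")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fitted one-class model from JSON
#'
#' @param path path written by \code{\link{writeModelJSON}}.
#' @return The reconstructed model object.
#' @export
readModelJSON <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(o$type, "ddsimca")) {
    m <- new("DDSIMCAModel",
      center = as.numeric(o$mean), loadings = as.matrix(o$loadings),
      eigenvalues = as.numeric(o$eigenvalues), ncomp = as.integer(o$k),
      h0 = o$h0, v0 = o$v0, Nh = o$N_h, Nv = o$N_v,
      alpha = o$alpha, gamma = o$gamma, cCrit = o$c_crit, cOut = o$c_out,
      nTrain = as.integer(o$n_train), wavenumber = as.numeric(o$wavenumber),
      dofMethod = o$dof_method, degenerateV = o$degenerate_v, vTol = o$v_tol,
      trainDistances = as.data.frame(o$train_distances))
  } else if (identical(o$type, "ocpls")) {
    m <- new("OCPLSModel",
      weights = as.matrix(o$weights), loadings = as.matrix(o$loadings),
      projection = as.matrix(o$projection),
      yloadings = as.numeric(o$yloadings),
      coefficients = as.numeric(o$regression_coefficients),
      scoreCenter = as.numeric(o$score_center),
      scoreSD = as.numeric(o$score_sd), ncomp = as.integer(o$A),
      t2Limit = o$t2_limit, residualCenter = o$residual_center,
      residualSD = o$residual_sd, acrLimit = o$acr_limit, alpha = o$alpha,
      nTrain = as.integer(o$n_train), wavenumber = as.numeric(o$wavenumber))
  } else stop("unrecognized model JSON")
  validObject(m)
  m
}
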