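#' @import methods
NULL

#' Wavenumber axis of a spectral object
#'
#' @param x a \linkS4class{SpectrumSet} or fitted model object.
#' @return Numeric vector of wavenumbers in cm^-1, in storage order
#'   (ascending or descending as read).
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' Intensity matrix of a SpectrumSet
#'
#' @param x a \linkS4class{SpectrumSet}.
#' @return Numeric matrix with one row per sample and one column per
#'   wavenumber (chemometric orientation), with sample ids as rownames and
#'   wavenumbers as colnames.
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' Per-sample metadata of a SpectrumSet
#'
#' @param x a \linkS4class{SpectrumSet}.
#' @return A \code{data.frame} with one row per sample (class_label,
#'   adulterant, concentration, variety, set_role).
#' @export
setGeneric("sampleMeta", function(x) standardGeneric("sampleMeta"))

#' Restrict a SpectrumSet to a wavenumber region
#'
#' Keeps the columns whose wavenumber lies in the closed interval
#' \code{[low, high]}; column order and metadata are preserved.
#'
#' @param x a \linkS4class{SpectrumSet}.
#' @param low,high region bounds in cm^-1 with \code{low < high}.
#' @return A \linkS4class{SpectrumSet} restricted to the region.
#' @export
setGeneric("selectRegion", function(x, low, high) standardGeneric("selectRegion"))

#' Classify samples against a fitted one-class model
#'
#' @param object a fitted \linkS4class{DDSIMCAModel} or
#'   \linkS4class{OCPLSModel}.
#' @param newdata a \linkS4class{SpectrumSet} on exactly the training
#'   wavenumber axis.
#' @return A \code{data.frame} with one row per sample: the model's distance
#'   statistics, the assigned category/quadrant and the accept decision.
#' @export
setGeneric("classifySamples", function(object, newdata) standardGeneric("classifySamples"))

#' Extreme-plot data for a DD-SIMCA training set
#'
#' @param object a fitted \linkS4class{DDSIMCAModel}.
#' @param alphaGrid significance levels at which to compare observed and
#'   expected numbers of extreme training samples (default: log-spaced grid).
#' @return A \code{data.frame} with columns \code{alpha}, \code{expected},
#'   \code{observed}, \code{lower}, \code{upper} (95\% binomial envelope).
#' @export
setGeneric("extremePlotData", function(object, alphaGrid = NULL) standardGeneric("extremePlotData"))
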