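#' SpectrumSet: aligned spectra with per-sample metadata
#'
#' A \code{SpectrumSet} holds a set of spectra measured on a common
#' wavenumber grid together with the study metadata of each sample.  It
#' extends \linkS4class{SummarizedExperiment}: rows are wavenumbers
#' (\code{rowData(x)$wavenumber}, cm^-1, strictly monotone in either
#' direction), columns are samples, and the single assay
#' \code{"intensity"} stores absorbance/reflectance values.  The
#' chemometric samples-by-wavenumbers orientation is available through
#' \code{\link{intensities}}.
#'
#' Metadata columns (colData): \code{class_label} ("pure"/"adulterated"),
#' \code{adulterant} ("none"/"apricot"/"peanut"), \code{concentration}
#' (mass percent, 0-100), \code{variety} (1 or 2), \code{set_role}
#' ("calibration"/"validation1"/"validation2").  A sample is pure iff its
#' concentration is 0 iff its adulterant is "none".
#'
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass SpectrumSet
setClass("SpectrumSet", contains = "SummarizedExperiment")

.META_COLS <- c("class_label", "adulterant", "concentration", "variety", "set_role")

setValidity("SpectrumSet", function(object) {
  msg <- character(0)
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  wn <- SummarizedExperiment::rowData(object)$wavenumber
  if (is.null(wn)) {
    msg <- c(msg, "rowData column 'wavenumber' is required")
  } else {
    if (anyNA(wn) || !is.numeric(wn))
      msg <- c(msg, "wavenumbers must be numeric and non-missing")
    if (length(wn) > 1) {
      d <- diff(wn)
      if (!(all(d > 0) || all(d < 0)))
        msg <- c(msg, "wavenumber axis must be strictly monotone")
    }
  }
  if (length(msg) == 0) {
    a <- SummarizedExperiment::assay(object, "intensity")
    if (anyNA(a)) msg <- c(msg, "intensity matrix contains missing values")
    ids <- colnames(object)
    if (is.null(ids) && ncol(object) > 0)
      msg <- c(msg, "sample ids (colnames) are required")
    if (anyDuplicated(ids))
      msg <- c(msg, sprintf("duplicate sample id(s): %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    cd <- SummarizedExperiment::colData(object)
    if (all(.META_COLS %in% colnames(cd)) && nrow(cd) > 0) {
      cl <- cd$class_label; co <- cd$concentration; ad <- cd$adulterant
      if (!all(cl %in% c("pure", "adulterated")))
        msg <- c(msg, "class_label must be 'pure' or 'adulterated'")
      if (any(co < 0 | co > 100))
        msg <- c(msg, "concentration must lie in [0, 100]")
      bad <- (cl == "pure") != (co == 0) | (cl == "pure") != (ad == "none")
      if (any(bad))
        msg <- c(msg, sprintf(
          "pure <=> concentration 0 <=> adulterant 'none' violated for: %s",
          paste(rownames(cd)[bad], collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SpectrumSet
#'
#' @param intensities numeric matrix, samples in rows, wavenumbers in
#'   columns (chemometric orientation).
#' @param wavenumbers numeric vector of length \code{ncol(intensities)},
#'   strictly monotone (ascending or descending), in cm^-1.
#' @param sampleIds character vector of unique sample labels; defaults to
#'   rownames of \code{intensities} or \code{"s1"..."sn"}.
#' @param meta \code{data.frame} with one row per sample; missing metadata
#'   columns are filled with pure-calibration defaults.
#' @return A \linkS4class{SpectrumSet}.
#' @examples
#' s <- SpectrumSet(matrix(rnorm(6), 2, 3), wavenumbers = c(1000, 1004, 1008))
#' wavenumbers(s)
#' @export
SpectrumSet <- function(intensities, wavenumbers, sampleIds = NULL, meta = NULL) {
  if (!is.matrix(intensities)) intensities <- as.matrix(intensities)
  n <- nrow(intensities); p <- ncol(intensities)
  if (length(wavenumbers) != p)
    stop("length(wavenumbers) must equal ncol(intensities)")
  if (is.null(sampleIds))
    sampleIds <- if (!is.null(rownames(intensities))) rownames(intensities)
                 else if (n > 0) paste0("s", seq_len(n)) else character(0)
  if (is.null(meta)) meta <- data.frame(row.names = sampleIds)
  meta <- as.data.frame(meta)
  if (n > 0) {
    if (is.null(meta$class_label))   meta$class_label   <- "pure"
    if (is.null(meta$adulterant))    meta$adulterant    <- "none"
    if (is.null(meta$concentration)) meta$concentration <- 0
    if (is.null(meta$variety))       meta$variety       <- 1L
    if (is.null(meta$set_role))      meta$set_role      <- "calibration"
  } else {
    for (cc in .META_COLS) if (is.null(meta[[cc]]))
      meta[[cc]] <- if (cc == "concentration") numeric(0)
                    else if (cc == "variety") integer(0) else character(0)
  }
  if (nrow(meta) != n) stop("metadata row count must equal the sample count")
  a <- t(intensities)
  dimnames(a) <- list(NULL, sampleIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = a),
    rowData = S4Vectors::DataFrame(wavenumber = as.numeric(wavenumbers)),
    colData = S4Vectors::DataFrame(meta, row.names = sampleIds))
  new("SpectrumSet", se)
}

#' @rdname wavenumbers
#' @export
setMethod("wavenumbers", "SpectrumSet", function(x)
  as.numeric(SummarizedExperiment::rowData(x)$wavenumber))

#' @rdname intensities
#' @export
setMethod("intensities", "SpectrumSet", function(x) {
  m <- t(SummarizedExperiment::assay(x, "intensity"))
  dimnames(m) <- list(colnames(x), format(wavenumbers(x), trim = TRUE))
  m
})

#' @rdname sampleMeta
#' @export
setMethod("sampleMeta", "SpectrumSet", function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
})

#' Direction of the wavenumber axis
#'
#' @param x a \linkS4class{SpectrumSet}.
#' @return "ascending" or "descending".
#' @export
axisDirection <- function(x) {
  wn <- wavenumbers(x)
  if (length(wn) < 2 || wn[2] > wn[1]) "ascending" else "descending"
}

#' @rdname selectRegion
#' @export
setMethod("selectRegion", "SpectrumSet", function(x, low, high) {
  if (!is.finite(low) || !is.finite(high) || low >= high)
    stop("'low' must be smaller than 'high'")
  wn <- wavenumbers(x)
  keep <- wn >= low & wn <= high
  if (!any(keep))
    stop(sprintf("region [%g, %g] does not overlap the axis [%g, %g]",
                 low, high, min(wn), max(wn)))
  x[keep, ]
})

setMethod("show", "SpectrumSet", function(object) {
  wn <- wavenumbers(object)
  cat(sprintf("SpectrumSet: %d sample(s) x %d wavenumber(s)\n",
              ncol(object), nrow(object)))
  if (length(wn))
    cat(sprintf("  axis: %g .. %g cm-1 (%s)\n", wn[1], wn[length(wn)],
                axisDirection(object)))
  cd <- SummarizedExperiment::colData(object)
  if ("class_label" %in% colnames(cd) && nrow(cd) > 0) {
    tb <- table(cd$class_label)
    cat("  classes:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(NULL)
})

# replace the intensity matrix (samples x wavenumbers), keeping everything else
.replaceIntensities <- function(x, m) {
  a <- t(m)
  dimnames(a) <- dimnames(SummarizedExperiment::assay(x, "intensity"))
  SummarizedExperiment::assay(x, "intensity") <- a
  x
}
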