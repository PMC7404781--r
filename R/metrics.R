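#' Truncate a percentage to two decimals
#'
#' Report-layer formatting used throughout the package: percentages are
#' truncated (rounded toward zero) at the requested number of decimals,
#' e.g. 50/55 = 90.9090... prints as 90.90.
#'
#' @param x numeric percentage(s).
#' @param digits decimal places kept (default 2).
#' @return Truncated value(s).
#' @export
percentTruncate <- function(x, digits = 2) {
  trunc(x * 10^digits) / 10^digits
}

#' Confusion-matrix summary for one-class screening
#'
#' A pure sample is correctly classified when it is accepted by the class
#' model; an adulterated sample when it is rejected.  Total accuracy is
#' 100 * correct / total under either naming convention.  Under
#' \code{"results_adulterated_positive"} (default, matching the numbers the
#' study tables print) sensitivity is the detected fraction of adulterated
#' samples and specificity the accepted fraction of pure samples; the
#' \code{"eq12_pure_positive"} convention swaps the two names.
#'
#' @param truth character vector of "pure"/"adulterated".
#' @param accepted logical vector: accepted by the class model.
#' @param convention metric naming convention (see above).
#' @return A one-row \code{data.frame}: counts
#'   (\code{n_pure, n_adulterated, pure_accepted, adulterated_rejected}),
#'   percentages (\code{sensitivity, specificity, accuracy}, full
#'   precision), and the convention used.
#' @export
confusionSummary <- function(truth, accepted,
                             convention = c("results_adulterated_positive",
                                            "eq12_pure_positive")) {
  convention <- match.arg(convention)
  if (length(truth) == 0) stop("empty input")
  if (length(truth) != length(accepted)) stop("inputs must have equal length")
  if (!all(truth %in% c("pure", "adulterated")))
    stop(sprintf("unknown label(s): %s",
                 paste(unique(setdiff(truth, c("pure", "adulterated"))), collapse = ", ")))
  accepted <- as.logical(accepted)
  if (anyNA(accepted)) stop("accepted must be TRUE/FALSE")
  nPure <- sum(truth == "pure")
  nAdu <- sum(truth == "adulterated")
  pureAcc <- sum(truth == "pure" & accepted)
  aduRej <- sum(truth == "adulterated" & !accepted)
  accuracy <- 100 * (pureAcc + aduRej) / (nPure + nAdu)
  rPure <- if (nPure > 0) 100 * pureAcc / nPure else NA_real_
  rAdu <- if (nAdu > 0) 100 * aduRej / nAdu else NA_real_
  if (convention == "results_adulterated_positive") {
    sens <- rAdu; spec <- rPure
  } else {
    sens <- rPure; spec <- rAdu
  }
  data.frame(n_pure = nPure, n_adulterated = nAdu,
             pure_accepted = pureAcc, adulterated_rejected = aduRej,
             sensitivity = sens, specificity = spec, accuracy = accuracy,
             convention = convention, stringsAsFactors = FALSE)
}

#' Rejection rate by adulteration level
#'
#' @param concentration numeric vector of adulterant concentrations (percent
#'   mass; 0 for pure samples).
#' @param accepted logical vector of accept decisions.
#' @return \code{data.frame} with one row per unique concentration:
#'   \code{concentration, n, rejected, rate}.
#' @export
perLevelDetection <- function(concentration, accepted) {
  if (length(concentration) != length(accepted))
    stop("inputs must have equal length")
  lev <- sort(unique(concentration))
  out <- data.frame(
    concentration = lev,
    n = vapply(lev, function(l) sum(concentration == l), numeric(1)),
    rejected = vapply(lev, function(l)
      sum(concentration == l & !accepted), numeric(1)))
  out$rate <- out$rejected / out$n
  out
}
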