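#' Read a SpectrumSet from wide-format CSV
#'
#' The interchange format is one row per sample: columns
#' \code{sample_id, class_label, adulterant, concentration, variety,
#' set_role} followed by one numeric column per wavenumber, whose header is
#' the wavenumber value in cm^-1.  UTF-8, '.' decimal separator.
#'
#' @param path path to a CSV file written by \code{\link{writeSpectraCSV}}
#'   (or following the same layout).
#' @return A \linkS4class{SpectrumSet}; axis monotonicity is validated and
#'   its direction preserved as read.
#' @export
readSpectraCSV <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fill = FALSE, colClasses = "character")
  need <- c("sample_id", .META_COLS)
  if (!all(need %in% colnames(df)[seq_along(need)]))
    stop(sprintf("format error: first columns must be %s",
                 paste(need, collapse = ", ")))
  wncols <- setdiff(colnames(df), need)
  wn <- suppressWarnings(as.numeric(wncols))
  if (anyNA(wn))
    stop(sprintf("format error: non-numeric wavenumber header(s): %s",
                 paste(wncols[is.na(wn)][1:min(3, sum(is.na(wn)))], collapse = ", ")))
  ids <- df$sample_id
  if (anyDuplicated(ids))
    stop(sprintf("validation error: duplicate sample id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  m <- matrix(NA_real_, nrow(df), length(wncols))
  for (j in seq_along(wncols)) {
    v <- suppressWarnings(as.numeric(df[[wncols[j]]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop(sprintf("parse error: non-numeric intensity at row %d, column '%s'",
                   bad, wncols[j]))
    }
    m[, j] <- v
  }
  conc <- suppressWarnings(as.numeric(df$concentration))
  if (anyNA(conc)) stop("parse error: non-numeric concentration")
  meta <- data.frame(class_label = df$class_label,
                     adulterant = df$adulterant,
                     concentration = conc,
                     variety = as.integer(df$variety),
                     set_role = df$set_role,
                     row.names = ids)
  SpectrumSet(m, wavenumbers = wn, sampleIds = ids, meta = meta)
}

# exact-round-trip numeric formatting
.fmtNum <- function(x) sprintf("%.17g", x)

#' Write a SpectrumSet to wide-format CSV
#'
#' Writes the fixed column order \code{sample_id, class_label, adulterant,
#' concentration, variety, set_role}, then one column per wavenumber.
#' Numeric values are printed with 17 significant digits so that
#' \code{\link{readSpectraCSV}} reproduces them exactly; the output is
#' byte-stable for identical input.
#'
#' @param x a \linkS4class{SpectrumSet}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSpectraCSV <- function(x, path) {
  stopifnot(is(x, "SpectrumSet"))
  validObject(x)
  wn <- wavenumbers(x)
  m <- intensities(x)
  meta <- sampleMeta(x)
  header <- c("sample_id", .META_COLS, .fmtNum(wn))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  if (nrow(m) > 0) {
    body <- vapply(seq_len(nrow(m)), function(i) {
      paste(c(rownames(m)[i],
              meta$class_label[i], meta$adulterant[i],
              .fmtNum(meta$concentration[i]), meta$variety[i], meta$set_role[i],
              .fmtNum(m[i, ])), collapse = ",")
    }, character(1))
    writeLines(body, con)
  }
  invisible(path)
}
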