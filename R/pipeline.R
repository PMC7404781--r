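#' Configuration for an end-to-end screening run
#'
#' @param classifier exactly one of "ddsimca" or "ocpls".
#' @param data either a list of CSV paths (\code{calibration},
#'   \code{validation1}, \code{validation2}) or NULL to generate synthetic
#'   data from \code{preset}/\code{region}.
#' @param preset,region,nPureVal synthetic-data settings (see
#'   \code{\link{studyDesign}}); used when \code{data} is NULL.  Both
#'   adulterants are generated, giving four validation sets.
#' @param regionBounds optional \code{c(low, high)} wavenumber window
#'   applied before preprocessing (e.g. \code{c(650, 3700)} for MIR runs,
#'   discarding the information-free upper MIR range).
#' @param preprocess a \code{\link{preprocessConfig}} (default SNV, the
#'   standard pretreatment for reflectance powder spectra).
#' @param ncomp number of PCs (ddsimca) or LVs (ocpls), or "auto" to select
#'   by cross-validated sensitivity (ddsimca) / MCCV (ocpls).
#' @param alpha,gamma significance levels (gamma is ddsimca-only).
#' @param dofMethod ddsimca degrees-of-freedom estimator.
#' @param mccv list of MCCV settings (maxLVs, splits, holdoutFraction,
#'   tolerance) used when \code{ncomp = "auto"} with ocpls.
#' @param outlierRefit drop training samples flagged as outliers (ddsimca)
#'   or outside the acceptance limits (ocpls) and refit once before
#'   validation; default TRUE.
#' @param convention metric naming convention, see
#'   \code{\link{confusionSummary}}.
#' @param outputDir directory for run artifacts (created if needed), or
#'   NULL to keep results in memory only.
#' @param seed study seed (synthetic generation and any selection CV).
#' @return list of class \code{"RunConfig"}.
#' @export
runConfig <- function(classifier = c("ddsimca", "ocpls"), data = NULL,
                      preset = "separable", region = "mir", nPureVal = 10,
                      regionBounds = NULL,
                      preprocess = preprocessConfig("snv"),
                      ncomp = 4, alpha = 0.01, gamma = 0.01,
                      dofMethod = "moments",
                      mccv = list(maxLVs = 10, splits = 100,
                                  holdoutFraction = 0.2, tolerance = 0.05),
                      outlierRefit = TRUE,
                      convention = "results_adulterated_positive",
                      outputDir = NULL, seed = 1) {
  if (length(classifier) != 1 || !classifier %in% c("ddsimca", "ocpls"))
    stop("validation error: exactly one classifier ('ddsimca' or 'ocpls') per run")
  if (!is.null(data)) {
    need <- c("calibration", "validation1", "validation2")
    if (!all(need %in% names(data)))
      stop("data paths must name calibration, validation1 and validation2")
    missing <- unlist(data[need])[!file.exists(unlist(data[need]))]
    if (length(missing))
      stop(sprintf("referenced path(s) do not exist: %s",
                   paste(missing, collapse = ", ")))
  }
  structure(list(classifier = classifier, data = data, preset = preset,
                 region = region, nPureVal = nPureVal,
                 regionBounds = regionBounds, preprocess = preprocess,
                 ncomp = ncomp, alpha = alpha, gamma = gamma,
                 dofMethod = dofMethod, mccv = mccv,
                 outlierRefit = outlierRefit, convention = convention,
                 outputDir = outputDir, seed = as.integer(seed)),
            class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' Keys mirror the arguments of \code{\link{runConfig}}; the
#' \code{preprocess} block uses the keys \code{method, normalize_mode,
#' window, polyorder, deriv_order, msc_reference}.
#'
#' @param path YAML file.
#' @return list of class \code{"RunConfig"}.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  pp <- if (is.null(y$preprocess)) preprocessConfig("snv")
        else do.call(preprocessConfig, y$preprocess)
  args <- y[setdiff(names(y), "preprocess")]
  args$preprocess <- pp
  if (!is.null(args$regionBounds)) args$regionBounds <- as.numeric(args$regionBounds)
  do.call(runConfig, args)
}

.logLine <- function(log, fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  if (!is.null(log)) cat(line, "\n", file = log, append = TRUE)
  message(line)
}

#' Run the adulteration-screening study end to end
#'
#' Generates (or loads) the calibration and validation sets, restricts the
#' region, preprocesses, fits the configured one-class model on the pure
#' calibration samples (optionally refitting once after outlier removal),
#' classifies every validation set, and assembles confusion summaries and
#' per-level detection tables.  With synthetic data the four validation
#' sets are the two adulterants crossed with the two almond varieties,
#' sharing a single calibration model.  Deterministic for a fixed
#' configuration and seed.
#'
#' @param config a \code{\link{runConfig}} (or path to a YAML file).
#' @return list of class \code{"RunReport"}: \code{model},
#'   \code{classifications} (per-set data.frames), \code{metrics}
#'   (per-set confusion summaries), \code{per_level} detection tables,
#'   \code{model_summary}, and provenance (config echo, seed, version,
#'   timestamp).  When \code{outputDir} is set, the model JSON,
#'   classification CSVs, metrics CSV, report JSON and a log file are
#'   written there.
#' @export
runStudy <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(inherits(config, "RunConfig"))
  outDir <- config$outputDir
  log <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    log <- file.path(outDir, "run.log")
    cat("", file = log)
  }
  stage <- function(name, expr) {
    r <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    r
  }

  # --- data -----------------------------------------------------------
  sets <- stage("load", {
    if (!is.null(config$data)) {
      list(calibration = readSpectraCSV(config$data$calibration),
           validation = list(
             validation1 = readSpectraCSV(config$data$validation1),
             validation2 = readSpectraCSV(config$data$validation2)))
    } else {
      s1 <- generateStudy(studyDesign(config$region, "apricot", config$preset,
                                      nPureVal = config$nPureVal,
                                      seed = config$seed))
      s2 <- generateStudy(studyDesign(config$region, "peanut", config$preset,
                                      nPureVal = config$nPureVal,
                                      seed = config$seed))
      list(calibration = s1$calibration,
           validation = list(val1_apricot = s1$validation1,
                             val2_apricot = s1$validation2,
                             val1_peanut = s2$validation1,
                             val2_peanut = s2$validation2))
    }
  })
  .logLine(log, "loaded calibration (%d) and %d validation set(s)",
           ncol(sets$calibration), length(sets$validation))

  # --- region ---------------------------------------------------------
  if (!is.null(config$regionBounds)) {
    b <- config$regionBounds
    sets$calibration <- stage("region", selectRegion(sets$calibration, b[1], b[2]))
    sets$validation <- lapply(sets$validation, selectRegion, low = b[1], high = b[2])
    .logLine(log, "region restricted to [%g, %g] cm-1 (%d points)",
             b[1], b[2], nrow(sets$calibration))
  }

  # --- preprocessing --------------------------------------------------
  calRef <- colMeans(intensities(sets$calibration))
  cal <- stage("preprocess", applyPreprocess(sets$calibration, config$preprocess,
                                             reference = calRef))
  vals <- lapply(sets$validation, applyPreprocess, config = config$preprocess,
                 reference = calRef)
  .logLine(log, "preprocessing: %s", config$preprocess$method)

  # --- model selection and fit ---------------------------------------
  selection <- NULL
  ncomp <- config$ncomp
  if (identical(ncomp, "auto")) {
    if (config$classifier == "ddsimca") {
      selection <- stage("select", selectNumPCs(
        cal, 1:10, config$alpha, config$gamma, config$dofMethod,
        folds = 5, seed = config$seed))
      ncomp <- selection$chosen_k
      .logLine(log, "selected %d PC(s) by cross-validated sensitivity", ncomp)
    } else {
      selection <- stage("select", mccvSelectLVs(
        cal, maxLVs = config$mccv$maxLVs, splits = config$mccv$splits,
        holdoutFraction = config$mccv$holdoutFraction, seed = config$seed,
        tolerance = config$mccv$tolerance))
      ncomp <- selection$chosen_A
      .logLine(log, "MCCV selected %d LV(s)", ncomp)
    }
  }
  fitOne <- function(train) {
    if (config$classifier == "ddsimca")
      fitDDSIMCA(train, ncomp, config$alpha, config$gamma, config$dofMethod)
    else fitOCPLS(train, ncomp, config$alpha)
  }
  model <- stage("fit", fitOne(cal))
  if (config$outlierRefit) {
    trainCls <- classifySamples(model, cal)
    drop <- if (config$classifier == "ddsimca")
      trainCls$category == "outlier" else !trainCls$accepted
    if (any(drop)) {
      .logLine(log, "outlier refit: removing %d training sample(s): %s",
               sum(drop), paste(trainCls$sample_id[drop], collapse = ", "))
      cal <- cal[, !drop]
      model <- stage("refit", fitOne(cal))
    }
  }

  # --- classification and metrics ------------------------------------
  classifications <- lapply(vals, function(v)
    stage("classify", classifySamples(model, v)))
  metrics <- list(); perLevel <- list()
  for (nm in names(vals)) {
    md <- sampleMeta(vals[[nm]])
    cls <- classifications[[nm]]
    metrics[[nm]] <- confusionSummary(md$class_label, cls$accepted,
                                      config$convention)
    perLevel[[nm]] <- perLevelDetection(md$concentration, cls$accepted)
    .logLine(log, "%s: accuracy %.2f%% (sens %.2f, spec %.2f)", nm,
             percentTruncate(metrics[[nm]]$accuracy),
             percentTruncate(metrics[[nm]]$sensitivity),
             percentTruncate(metrics[[nm]]$specificity))
  }

  modelSummary <- if (config$classifier == "ddsimca")
    list(classifier = "ddsimca", ncomp = model@ncomp, Nh = model@Nh,
         Nv = model@Nv, h0 = model@h0, v0 = model@v0,
         c_crit = model@cCrit, c_out = model@cOut, n_train = model@nTrain)
  else
    list(classifier = "ocpls", ncomp = model@ncomp, t2_limit = model@t2Limit,
         acr_limit = model@acrLimit, residual_center = model@residualCenter,
         residual_sd = model@residualSD, n_train = model@nTrain)

  report <- structure(list(
    model = model, calibration = cal, validation = vals,
    classifications = classifications, metrics = metrics,
    per_level = perLevel, selection = selection,
    model_summary = modelSummary,
    provenance = list(config = config[setdiff(names(config), "data")],
                      seed = config$seed,
                      package_version = as.character(utils::packageVersion("OneClassSpectra")),
                      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
    class = "RunReport")

  # --- artifacts ------------------------------------------------------
  if (!is.null(outDir)) {
    writeModelJSON(model, file.path(outDir, "model.json"))
    for (nm in names(classifications))
      utils::write.csv(classifications[[nm]],
                       file.path(outDir, sprintf("classification_%s.csv", nm)),
                       row.names = FALSE)
    mt <- do.call(rbind, lapply(names(metrics), function(nm)
      cbind(group = nm, metrics[[nm]])))
    utils::write.csv(mt, file.path(outDir, "metrics.csv"), row.names = FALSE)
    pl <- do.call(rbind, lapply(names(perLevel), function(nm)
      cbind(group = nm, perLevel[[nm]])))
    utils::write.csv(pl, file.path(outDir, "per_level.csv"), row.names = FALSE)
    jsonlite::write_json(list(metrics = mt, model_summary = modelSummary,
                              provenance = report$provenance),
                         file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    .logLine(log, "artifacts written to %s", outDir)
  }
  report
}

#' Export plot-ready tables for a completed run
#'
#' For a DD-SIMCA run: the per-sample (h, v, c) coordinates per validation
#' set, the acceptance-boundary curve (points satisfying
#' \eqn{N_h h/h_0 + N_v v/v_0 = c_{crit}}) and outlier-boundary curve, and
#' the calibration extreme-plot table.  For an OCPLS run: the per-sample
#' (t2, acr) coordinates and the two limit lines.
#'
#' @param runDir directory written by \code{\link{runStudy}}.
#' @return Invisibly, the paths of the CSV files written into
#'   \code{runDir}.
#' @export
exportPlotData <- function(runDir) {
  modelPath <- file.path(runDir, "model.json")
  if (!file.exists(modelPath)) stop("missing run artifact: model.json")
  model <- readModelJSON(modelPath)
  clsFiles <- list.files(runDir, "^classification_.*\\.csv$", full.names = TRUE)
  if (!length(clsFiles)) stop("missing run artifacts: classification CSVs")
  paths <- character(0)
  if (is(model, "DDSIMCAModel")) {
    hMax <- model@h0 * stats::qchisq(0.999, model@Nh) / max(model@Nh, 1e-9)
    hGrid <- seq(0, hMax, length.out = 200)
    curve <- function(cLevel) {
      v <- if (model@degenerateV) rep(0, length(hGrid))
           else (cLevel - model@Nh * hGrid / model@h0) * model@v0 / model@Nv
      d <- data.frame(h = hGrid, v = v, c = cLevel)
      d[d$v >= 0, ]
    }
    p <- file.path(runDir, "acceptance_curve.csv")
    utils::write.csv(rbind(cbind(boundary = "acceptance", curve(model@cCrit)),
                           cbind(boundary = "outlier", curve(model@cOut))),
                     p, row.names = FALSE)
    paths <- c(paths, p)
    p <- file.path(runDir, "extreme_plot.csv")
    utils::write.csv(extremePlotData(model), p, row.names = FALSE)
    paths <- c(paths, p)
  } else {
    p <- file.path(runDir, "limits.csv")
    utils::write.csv(data.frame(statistic = c("t2", "acr"),
                                limit = c(model@t2Limit, model@acrLimit)),
                     p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
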