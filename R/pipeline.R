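# Umbrella pipeline driver: one validated configuration runs either the
# qSIP chain (fraction table -> EAF tables) or the DOM chain (peak lists ->
# assignments, class summary, ordination), writing all outputs plus a
# provenance record.

QSIP_KEYS <- c("pipeline", "fractions", "pairing", "calibration",
               "bootstrap", "seed", "out_dir")
DOM_KEYS <- c("pipeline", "peaks", "tol_ppm", "min_oxygen", "calibrants",
              "detection_rel", "seed", "out_dir")

.validateConfig <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (is.null(config$pipeline) ||
      !config$pipeline %in% c("qsip", "dom"))
    stop("config error: 'pipeline' must be 'qsip' or 'dom'")
  allowed <- if (config$pipeline == "qsip") QSIP_KEYS else DOM_KEYS
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$out_dir))
    stop("config error: 'out_dir' is required")
  if (is.null(config$seed)) config$seed <- 1L
  config
}

.writeProvenance <- function(config, outDir) {
  prov <- list(package = "qsipdom",
               version = as.character(utils::packageVersion("qsipdom")),
               seed = config$seed,
               config = config)
  yaml::write_yaml(prov, file.path(outDir, "provenance.yaml"))
}

#' Run an end-to-end pipeline from a configuration
#'
#' The configuration (a named list or path to a YAML file) selects one of
#' two pipelines.  Unknown keys are rejected before any computation, and a
#' provenance record (config echo, package version, seed) is written next
#' to the outputs, so identical config + seed reproduce identical files.
#'
#' \describe{
#'   \item{qsip}{keys: `fractions` (fraction-table path), `pairing`
#'     (`"replicate"` or `"mean-control"`), `calibration`, `bootstrap`
#'     (resample count, 0 to disable), `seed`, `out_dir`.  Writes one
#'     `eaf_<sample>_<marker>.csv` per sample/marker pairing.}
#'   \item{dom}{keys: `peaks` (one or more peak-list paths), `tol_ppm`,
#'     `min_oxygen`, `calibrants` (optional path to a file with a `formula`
#'     column of strings), `detection_rel`, `seed`, `out_dir`.  Writes
#'     per-sample `assignments_<sample>.csv`, `class_summary.csv`,
#'     `weighted_ratios.csv`, and with two or more samples
#'     `bray_curtis.csv`, `pcoa_coordinates.csv`, `pcoa_eigenvalues.csv`.}
#' }
#'
#' @param config named list or YAML file path.
#' @return Invisibly, a character vector of output file paths.
#' @export
runPipeline <- function(config) {
  config <- .validateConfig(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- if (config$pipeline == "qsip") .runQsip(config)
             else .runDom(config)
  .writeProvenance(config, config$out_dir)
  invisible(c(outputs, file.path(config$out_dir, "provenance.yaml")))
}

.runQsip <- function(config) {
  if (is.null(config$fractions))
    stop("config error: 'fractions' is required for the qsip pipeline")
  profiles <- readFractionTable(config$fractions)
  meta <- data.frame(
    sample = vapply(profiles, sampleId, ""),
    marker = vapply(profiles, markerGene, ""),
    label = vapply(profiles, labelState, ""))
  outputs <- character()
  for (key in unique(paste(meta$sample, meta$marker, sep = "|"))) {
    sel <- paste(meta$sample, meta$marker, sep = "|") == key
    lab <- profiles[sel & meta$label == "labeled"]
    ctl <- profiles[sel & meta$label == "unlabeled"]
    if (!length(lab) || !length(ctl))
      stop("sample/marker ", key, " lacks a labeled or unlabeled profile")
    res <- eafFromProfiles(
      unname(lab), unname(ctl),
      pairing = config$pairing %||% "replicate",
      calibration = config$calibration %||% "hungate",
      bootstrap = config$bootstrap %||% 0,
      seed = config$seed)
    path <- file.path(config$out_dir,
                      paste0("eaf_", gsub("[^A-Za-z0-9]", "_", key), ".csv"))
    writeEafResult(res, path)
    outputs <- c(outputs, path)
  }
  outputs
}

.runDom <- function(config) {
  if (is.null(config$peaks))
    stop("config error: 'peaks' is required for the dom pipeline")
  calibrants <- NULL
  if (!is.null(config$calibrants)) {
    cal <- read.csv(config$calibrants, stringsAsFactors = FALSE)
    if (is.null(cal$formula))
      stop("parse error: calibrant file needs a 'formula' column")
    calibrants <- parseFormula(cal$formula)
  }
  samples <- list()
  outputs <- character()
  for (path in config$peaks) {
    id <- sub("\\.[^.]*$", "", basename(path))
    peaks <- readPeakList(path)
    if (!is.null(calibrants))
      peaks <- internalCalibrate(peaks, calibrants)$peaks
    peaks <- applyDetectionLimit(peaks, config$detection_rel %||% 0)
    ds <- assignFormulas(peaks, sampleId = id,
                         tolPpm = config$tol_ppm %||% 0.5,
                         minOxygen = config$min_oxygen %||% 1)
    samples[[id]] <- ds
    out <- file.path(config$out_dir, paste0("assignments_", id, ".csv"))
    writeAssignments(ds, out)
    outputs <- c(outputs, out)
  }

  classTab <- do.call(rbind, lapply(samples, function(s) {
    a <- assignments(s)
    shares <- tapply(a$rel_intensity, a$compound_class, sum, default = 0)
    data.frame(sample_id = sampleId(s), compound_class = names(shares),
               rel_intensity = round(as.numeric(shares), 6))
  }))
  classPath <- file.path(config$out_dir, "class_summary.csv")
  write.csv(classTab, classPath, row.names = FALSE, quote = TRUE)

  ratioTab <- do.call(rbind, lapply(samples, function(s)
    data.frame(sample_id = sampleId(s),
               as.data.frame(t(round(weightedRatios(s), 6))))))
  ratioPath <- file.path(config$out_dir, "weighted_ratios.csv")
  write.csv(ratioTab, ratioPath, row.names = FALSE, quote = FALSE)
  outputs <- c(outputs, classPath, ratioPath)

  if (length(samples) >= 2) {
    dset <- domSet(unname(samples))
    d <- brayCurtis(dset)
    bcPath <- file.path(config$out_dir, "bray_curtis.csv")
    writeDissimilarity(d, bcPath)
    ord <- principalCoordinates(d)
    coPath <- file.path(config$out_dir, "pcoa_coordinates.csv")
    eigPath <- file.path(config$out_dir, "pcoa_eigenvalues.csv")
    writeOrdination(ord, coPath, eigPath)
    outputs <- c(outputs, bcPath, coPath, eigPath)
  }
  outputs
}

`%||%` <- function(a, b) if (is.null(a)) b else a
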