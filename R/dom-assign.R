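# Peak-list operations: detection limit, internal calibration, formula
# assignment, intensity normalization, weighted molar ratios, DomSet assembly.

#' Apply a relative detection limit to a peak list
#'
#' Removes peaks whose intensity falls below `relThreshold` times the
#' base-peak (maximum) intensity.  Working on the relative scale makes the
#' cut comparable between samples of different absolute signal.  Peak order
#' is preserved and the operation is idempotent.
#'
#' @param peaks `data.frame` with columns `mz` and `intensity`.
#' @param relThreshold fraction of base-peak intensity in \[0, 1).
#' @return The filtered `data.frame`.
#' @export
applyDetectionLimit <- function(peaks, relThreshold) {
  stopifnot(relThreshold >= 0, relThreshold < 1)
  if (nrow(peaks) == 0) return(peaks)
  keep <- peaks$intensity >= relThreshold * max(peaks$intensity)
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Internally calibrate a peak list against known formulas
#'
#' Matches each calibrant's expected \[M-H\]- m/z to the nearest observed
#' peak within `windowPpm`, fits a linear model of ppm error versus m/z to
#' the matches, and removes the fitted error from every peak.  A least
#' squares fit can only shrink the calibrants' RMS error.  With fewer than
#' `minMatches` matched calibrants the calibration fails: peaks are passed
#' through unchanged with a warning.
#'
#' @param peaks `data.frame` with columns `mz`, `intensity`.
#' @param calibrants `data.frame` of element counts (`c`, `h`, `o`, `n`,
#'   `s`, `p`), e.g. a marine-DOM calibration list from [parseFormula()].
#' @param windowPpm coarse matching window, default 3 ppm.
#' @param minMatches minimum matched calibrants, default 5.
#' @return List with `peaks` (m/z corrected, column `calibrated` set),
#'   and `diagnostics`: `calibrated` flag, `nMatched`, `rmsPre` and
#'   `rmsPost` (ppm, over matched calibrants), and the fit `coefficients`.
#' @export
internalCalibrate <- function(peaks, calibrants, windowPpm = 3,
                              minMatches = 5) {
  expected <- monoisotopicMass(calibrants) - PROTON_MASS
  idx <- vapply(expected, function(m) {
    i <- which.min(abs(peaks$mz - m))
    err <- (peaks$mz[i] - m) / m * 1e6
    if (abs(err) <= windowPpm) i else NA_integer_
  }, integer(1))
  ok <- !is.na(idx)
  failed <- list(peaks = transform(peaks, calibrated = FALSE),
                 diagnostics = list(calibrated = FALSE,
                                    nMatched = sum(ok)))
  if (sum(ok) < minMatches) {
    warning(sprintf(
      "calibration failed: %d matched calibrant(s), need %d; ",
      sum(ok), minMatches), "peaks passed through uncalibrated")
    return(failed)
  }
  obs <- peaks$mz[idx[ok]]
  errPpm <- (obs - expected[ok]) / expected[ok] * 1e6
  fit <- lm(errPpm ~ obs)
  corrected <- peaks$mz /
    (1 + predict(fit, newdata = data.frame(obs = peaks$mz)) * 1e-6)
  post <- (corrected[idx[ok]] - expected[ok]) / expected[ok] * 1e6
  out <- peaks
  out$mz <- as.numeric(corrected)
  out$calibrated <- TRUE
  list(peaks = out,
       diagnostics = list(calibrated = TRUE, nMatched = sum(ok),
                          rmsPre = sqrt(mean(errPpm^2)),
                          rmsPost = sqrt(mean(post^2)),
                          coefficients = coef(fit)))
}

#' Assign molecular formulas to a negative-mode peak list
#'
#' Converts each m/z to a neutral mass (\[M-H\]- assumed), enumerates
#' candidate CHNOSP formulas within `tolPpm` (see [enumerateFormulas()]),
#' and keeps the candidate with the smallest absolute mass error.  Peaks
#' with two or more candidates in tolerance are flagged `ambiguous` (and
#' optionally dropped); peaks with no candidate are dropped.  Derived
#' quantities (molar ratios, `ai_mod`, DBE, compound class) are attached per
#' retained formula.  If the same best formula arises from several peaks,
#' intensities are summed and the smallest-error peak kept.
#'
#' @param peaks `data.frame` with columns `mz`, `intensity`.
#' @param sampleId sample identifier.
#' @param tolPpm assignment tolerance in ppm, default 0.5.
#' @param minOxygen minimum oxygen count (0 or 1), default 1.
#' @param dropAmbiguous drop peaks with multiple candidates, default FALSE.
#' @param habitat optional habitat label (see [assignHabitat()]).
#' @param normalize normalize intensities after assignment, default TRUE.
#' @return A [DomSample-class].
#' @examples
#' sim <- simulatePeakList(spectrumSimConfig(nFormulas = 20, ppmSD = 0,
#'                                           nNoisePeaks = 0, seed = 7))
#' ds <- assignFormulas(sim$peaks, sampleId = "sim")
#' head(assignments(ds))
#' @export
assignFormulas <- function(peaks, sampleId, tolPpm = 0.5, minOxygen = 1,
                           dropAmbiguous = FALSE, habitat = NA_character_,
                           normalize = TRUE) {
  stopifnot(all(peaks$intensity > 0))
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    cand <- enumerateFormulas(neutralMass(peaks$mz[i]), tolPpm = tolPpm,
                              minOxygen = minOxygen)
    if (nrow(cand) == 0) return(NULL)
    best <- cand[1, ]
    data.frame(mz = peaks$mz[i], intensity = peaks$intensity[i],
               c = best$c, h = best$h, o = best$o, n = best$n,
               s = best$s, p = best$p, error_ppm = best$error_ppm,
               dbe = best$dbe, n_candidates = nrow(cand),
               ambiguous = nrow(cand) >= 2)
  })
  a <- do.call(rbind, rows)
  if (is.null(a))
    a <- data.frame(mz = numeric(), intensity = numeric(), c = integer(),
                    h = integer(), o = integer(), n = integer(),
                    s = integer(), p = integer(), error_ppm = numeric(),
                    dbe = numeric(), n_candidates = integer(),
                    ambiguous = logical())
  if (dropAmbiguous && nrow(a) > 0)
    a <- a[!a$ambiguous, , drop = FALSE]

  if (nrow(a) > 0) {
    key <- formulaKey(a$c, a$h, a$o, a$n, a$s, a$p)
    if (anyDuplicated(key)) {
      totals <- tapply(a$intensity, key, sum)
      a <- a[order(abs(a$error_ppm)), , drop = FALSE]
      a <- a[!duplicated(formulaKey(a$c, a$h, a$o, a$n, a$s, a$p)), ,
             drop = FALSE]
      a$intensity <- as.numeric(
        totals[formulaKey(a$c, a$h, a$o, a$n, a$s, a$p)])
    }
    a <- a[order(a$mz), , drop = FALSE]
    a$neutral_mass <- neutralMass(a$mz)
    a$hc <- a$h / a$c
    a$oc <- a$o / a$c
    a$nc <- a$n / a$c
    a$sc <- a$s / a$c
    a$pc <- a$p / a$c
    a$ai_mod <- aiMod(a$c, a$h, a$o, a$n, a$s, a$p)
    a$compound_class <- classifyFormula(a$c, a$h, a$o, a$n, a$s, a$p)
  } else {
    a$neutral_mass <- numeric()
    a$hc <- a$oc <- a$nc <- a$sc <- a$pc <- numeric()
    a$ai_mod <- numeric()
    a$compound_class <- factor(character(), levels = DOM_CLASSES)
  }
  a$rel_intensity <- rep(NA_real_, nrow(a))
  rownames(a) <- NULL
  out <- new("DomSample", sampleId = as.character(sampleId),
             habitat = as.character(habitat), assignments = a)
  if (normalize && nrow(a) > 0) normalizeIntensities(out) else out
}

#' @rdname normalizeIntensities
#' @export
setMethod("normalizeIntensities", "DomSample", function(x) {
  a <- x@assignments
  if (nrow(a) == 0 || sum(a$intensity) <= 0)
    stop("empty sample: no assigned formulas with positive intensity")
  a$rel_intensity <- a$intensity / sum(a$intensity)
  x@assignments <- a
  x
})

#' @rdname weightedRatios
#' @export
setMethod("weightedRatios", "DomSample", function(x) {
  a <- x@assignments
  if (nrow(a) == 0) stop("empty sample: no assigned formulas")
  if (anyNA(a$rel_intensity))
    stop("sample is not normalized; call normalizeIntensities() first")
  w <- a$rel_intensity
  c(hc = sum(w * a$hc), oc = sum(w * a$oc), nc = sum(w * a$nc),
    sc = sum(w * a$sc), pc = sum(w * a$pc))
})

#' Assemble DomSamples into a DomSet
#'
#' Builds the formulas-by-samples relative-intensity container used for
#' dissimilarity analysis.  Rows are the union of formulas across samples;
#' a formula absent from a sample contributes zero (no imputation).
#'
#' @param samples list of normalized [DomSample-class] objects.
#' @return A [DomSet-class].
#' @export
domSet <- function(samples) {
  stopifnot(length(samples) >= 1)
  ids <- vapply(samples, sampleId, "")
  if (anyDuplicated(ids)) stop("duplicate sample ids")
  tabs <- lapply(samples, assignments)
  if (any(vapply(tabs, function(a) anyNA(a$rel_intensity), TRUE)))
    stop("all samples must be normalized")
  keys <- lapply(tabs, function(a) formulaKey(a$c, a$h, a$o, a$n, a$s, a$p))
  allKeys <- sort(unique(unlist(keys)))
  m <- matrix(0, nrow = length(allKeys), ncol = length(samples),
              dimnames = list(allKeys, ids))
  for (j in seq_along(samples))
    m[keys[[j]], j] <- tabs[[j]]$rel_intensity

  meta <- do.call(rbind, lapply(tabs, function(a)
    a[c("c", "h", "o", "n", "s", "p", "hc", "oc", "nc", "sc", "pc",
        "ai_mod", "dbe", "compound_class")]))
  meta <- meta[!duplicated(unlist(keys)), , drop = FALSE]
  rownames(meta) <- unlist(keys)[!duplicated(unlist(keys))]
  meta <- meta[allKeys, , drop = FALSE]

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(relIntensity = m),
    rowData = S4Vectors::DataFrame(meta),
    colData = S4Vectors::DataFrame(
      habitat = vapply(samples, function(s) s@habitat, ""),
      row.names = ids))
  new("DomSet", se)
}

#' Samples-by-formulas relative intensity matrix
#'
#' @param x a [DomSet-class].
#' @return Numeric matrix with samples as rows (each summing to 1).
#' @export
relIntensityMatrix <- function(x) {
  stopifnot(is(x, "DomSet"))
  t(SummarizedExperiment::assay(x, "relIntensity"))
}
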