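#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

# ---- GradientProfile --------------------------------------------------------

#' GradientProfile: one density-gradient qPCR curve
#'
#' Holds the per-fraction buoyant densities and marker-gene copy numbers of a
#' single CsCl gradient from one incubation (one sample, one marker, labeled
#' or unlabeled control).
#'
#' @slot sampleId character scalar identifying the incubation.
#' @slot marker marker gene quantified, `"18S"` (fungal) or `"16S"`
#'   (prokaryotic).
#' @slot label `"labeled"` or `"unlabeled"`.
#' @slot isotope isotope used for labeling; only `"13C"` is supported.
#' @slot replicateId replicate identifier (character scalar).
#' @slot fractions `data.frame` with columns `fraction_index` (unique
#'   integers), `density` (g/mL, within 1.60-1.85), `copies` (non-negative),
#'   and `below_detection` (logical; flagged fractions contribute zero copies
#'   to the weighted mean density).
#'
#' @seealso [GradientProfile()], [weightedMeanDensity()], [eafFromProfiles()]
#' @name GradientProfile-class
#' @rdname GradientProfile-class
#' @exportClass GradientProfile
setClass("GradientProfile",
  slots = c(
    sampleId = "character",
    marker = "character",
    label = "character",
    isotope = "character",
    replicateId = "character",
    fractions = "data.frame"
  )
)

setValidity("GradientProfile", function(object) {
  fr <- object@fractions
  need <- c("fraction_index", "density", "copies", "below_detection")
  if (!all(need %in% names(fr)))
    return(paste("fractions must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(fr$fraction_index))
    return("fraction indices must be unique within a profile")
  if (any(fr$density < 1.60 | fr$density > 1.85))
    return("buoyant densities must lie in [1.60, 1.85] g/mL")
  if (any(fr$copies < 0))
    return("copies must be non-negative")
  ord <- order(fr$fraction_index)
  d <- fr$density[ord]
  if (length(d) > 1 && !(all(diff(d) > 0) || all(diff(d) < 0)))
    return("densities must be strictly monotone when sorted by fraction index")
  if (!object@label %in% c("labeled", "unlabeled"))
    return("label must be 'labeled' or 'unlabeled'")
  if (!identical(object@isotope, "13C"))
    return("only 13C labeling is supported")
  TRUE
})

#' Construct a GradientProfile
#'
#' @param sampleId sample identifier.
#' @param marker marker gene, e.g. `"18S"` or `"16S"`.
#' @param label `"labeled"` or `"unlabeled"`.
#' @param fractions `data.frame` with columns `fraction_index`, `density`
#'   (g/mL), `copies`, and optionally `below_detection` (defaults to `FALSE`).
#' @param replicateId replicate identifier, default `"r1"`.
#' @param isotope isotope label, only `"13C"`.
#'
#' @return A [GradientProfile-class] object with fractions sorted by index.
#' @examples
#' gp <- GradientProfile("s1", "18S", "unlabeled",
#'   data.frame(fraction_index = 1:3,
#'              density = c(1.68, 1.70, 1.72),
#'              copies = c(10, 80, 10)))
#' weightedMeanDensity(gp)
#' @export
GradientProfile <- function(sampleId, marker, label, fractions,
                            replicateId = "r1", isotope = "13C") {
  if (is.null(fractions$below_detection))
    fractions$below_detection <- FALSE
  fractions$fraction_index <- as.integer(fractions$fraction_index)
  fractions <- fractions[order(fractions$fraction_index),
                         c("fraction_index", "density", "copies",
                           "below_detection"),
                         drop = FALSE]
  rownames(fractions) <- NULL
  new("GradientProfile",
      sampleId = as.character(sampleId), marker = as.character(marker),
      label = label, isotope = isotope,
      replicateId = as.character(replicateId), fractions = fractions)
}

# ---- StandardCurve ----------------------------------------------------------

#' StandardCurve: qPCR calibration line
#'
#' A qPCR standard curve, Cq = slope * log10(copies) + intercept, fitted to a
#' dilution series.  Amplification efficiency is `10^(-1/slope) - 1`; a curve
#' is considered valid when efficiency lies in \[0.90, 1.10\] and
#' R-squared exceeds 0.9.
#'
#' @slot slope Cq change per log10(copies); negative for a working assay.
#' @slot intercept Cq at one copy.
#' @slot rSquared coefficient of determination of the fit.
#'
#' @seealso [StandardCurve()], [quantifyFromCq()]
#' @name StandardCurve-class
#' @rdname StandardCurve-class
#' @exportClass StandardCurve
setClass("StandardCurve",
  slots = c(slope = "numeric", intercept = "numeric", rSquared = "numeric")
)

setValidity("StandardCurve", function(object) {
  if (length(object@slope) != 1 || length(object@intercept) != 1 ||
      length(object@rSquared) != 1)
    return("slope, intercept and rSquared must be scalars")
  if (object@slope >= 0)
    return("standard-curve slope must be negative (Cq decreases with copies)")
  if (object@rSquared < 0 || object@rSquared > 1)
    return("rSquared must lie in [0, 1]")
  TRUE
})

#' Construct a StandardCurve
#'
#' @param slope Cq per log10(copies), negative.
#' @param intercept Cq at one copy.
#' @param rSquared R-squared of the dilution-series fit.
#' @return A [StandardCurve-class] object.
#' @examples
#' sc <- StandardCurve(slope = -3.3219, intercept = 38, rSquared = 0.999)
#' efficiency(sc)     # 1.00 (100%)
#' isValidCurve(sc)
#' @export
StandardCurve <- function(slope, intercept, rSquared) {
  new("StandardCurve", slope = slope, intercept = intercept,
      rSquared = rSquared)
}

# ---- EafResult --------------------------------------------------------------

#' EafResult: excess atom fraction estimates for one marker
#'
#' Per-pair intermediates and EAF values from a labeled/unlabeled gradient
#' comparison, plus a summary across pairs.  Negative per-pair EAF values
#' (measurement noise) are retained; the summary also reports a
#' zero-clipped mean.
#'
#' @slot pairs `data.frame` with one row per labeled/unlabeled pairing:
#'   `replicateId`, `W_light`, `W_lab`, `dW` (g/mL), `G` (GC fraction),
#'   `M_light`, `M_lab`, `M_heavymax` (g/mol per nucleotide), `eaf`,
#'   `atom_pct` (eaf * 100).
#' @slot summary named list: `mean`, `sd`, `mean_clipped` (negatives set to
#'   zero before averaging), `n`, and optionally `ci` (bootstrap interval).
#' @slot marker marker gene.
#' @slot calibration GC-density calibration used, `"hungate"` or
#'   `"schildkraut"`.
#'
#' @seealso [eafFromProfiles()]
#' @name EafResult-class
#' @rdname EafResult-class
#' @exportClass EafResult
setClass("EafResult",
  slots = c(pairs = "data.frame", summary = "list",
            marker = "character", calibration = "character")
)

# ---- DomSample --------------------------------------------------------------

#' DomSample: a formula-assigned FT-ICR-MS sample
#'
#' One DOM sample after peak assignment: each retained peak carries its best
#' molecular formula, signed mass error, derived ratios, modified aromaticity
#' index, compound class, and (after [normalizeIntensities()]) a relative
#' intensity that sums to one over assigned formulas.
#'
#' @slot sampleId sample identifier.
#' @slot habitat habitat category or `NA` (see [assignHabitat()]).
#' @slot assignments `data.frame` with columns `mz`, `intensity`, `c`, `h`,
#'   `o`, `n`, `s`, `p`, `error_ppm`, `n_candidates`, `ambiguous`,
#'   `neutral_mass`, `hc`, `oc`, `nc`, `sc`, `pc`, `ai_mod`, `dbe`,
#'   `compound_class`, `rel_intensity`.
#'
#' @seealso [assignFormulas()], [weightedRatios()]
#' @name DomSample-class
#' @rdname DomSample-class
#' @exportClass DomSample
setClass("DomSample",
  slots = c(sampleId = "character", habitat = "character",
            assignments = "data.frame")
)

setValidity("DomSample", function(object) {
  a <- object@assignments
  if (nrow(a) == 0) return(TRUE)
  key <- formulaKey(a$c, a$h, a$o, a$n, a$s, a$p)
  if (anyDuplicated(key))
    return("each molecular formula may appear at most once per sample")
  if (any(a$intensity <= 0))
    return("intensities must be positive")
  TRUE
})

# ---- DomSet -----------------------------------------------------------------

#' DomSet: multi-sample DOM relative-intensity container
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose rows are molecular
#' formulas (rowData holds element counts, molar ratios, `ai_mod` and
#' `compound_class`) and whose columns are samples (colData holds habitat
#' metadata).  The `"relIntensity"` assay stores per-sample relative
#' intensities; formulas absent from a sample are zero and each column sums
#' to one.
#'
#' @seealso [domSet()], [brayCurtis()], [principalCoordinates()]
#' @name DomSet-class
#' @rdname DomSet-class
#' @exportClass DomSet
setClass("DomSet", contains = "SummarizedExperiment")

setValidity("DomSet", function(object) {
  if (!"relIntensity" %in% SummarizedExperiment::assayNames(object))
    return("DomSet requires a 'relIntensity' assay")
  x <- SummarizedExperiment::assay(object, "relIntensity")
  if (any(x < 0)) return("relative intensities must be non-negative")
  cs <- colSums(x)
  if (any(abs(cs - 1) > 1e-9))
    return("each sample's relative intensities must sum to 1 (+/- 1e-9)")
  TRUE
})
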