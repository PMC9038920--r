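#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("markerGene", function(x) standardGeneric("markerGene"))

#' @rdname accessors
#' @export
setGeneric("labelState", function(x) standardGeneric("labelState"))

#' @rdname accessors
#' @export
setGeneric("replicateId", function(x) standardGeneric("replicateId"))

#' @rdname accessors
#' @export
setGeneric("fractions", function(x) standardGeneric("fractions"))

#' @rdname accessors
#' @export
setGeneric("efficiency", function(x) standardGeneric("efficiency"))

#' @rdname accessors
#' @export
setGeneric("isValidCurve", function(x) standardGeneric("isValidCurve"))

#' @rdname accessors
#' @export
setGeneric("eafPairs", function(x) standardGeneric("eafPairs"))

#' @rdname accessors
#' @export
setGeneric("eafSummary", function(x) standardGeneric("eafSummary"))

#' @rdname accessors
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))

#' Weighted mean buoyant density of a gradient profile
#'
#' @param x a [GradientProfile-class] or a `data.frame` with `density` and
#'   `copies` columns (optional `below_detection`).
#' @param ... unused.
#' @return Weighted mean density in g/mL.
#' @export
setGeneric("weightedMeanDensity",
           function(x, ...) standardGeneric("weightedMeanDensity"))

#' Intensity-weighted mean molar ratios of a DOM sample
#'
#' @param x a [DomSample-class] with normalized intensities.
#' @param ... unused.
#' @return Named numeric vector with elements `hc`, `oc`, `nc`, `sc`, `pc`.
#' @export
setGeneric("weightedRatios",
           function(x, ...) standardGeneric("weightedRatios"))

#' Normalize peak intensities to relative intensities
#'
#' @param x a [DomSample-class].
#' @param ... unused.
#' @return Object of the same class with `rel_intensity` summing to 1.
#' @export
setGeneric("normalizeIntensities",
           function(x, ...) standardGeneric("normalizeIntensities"))

#' Bray-Curtis dissimilarity between samples
#'
#' @param x a samples-by-formulas numeric matrix with rows summing to one,
#'   or a [DomSet-class].
#' @param ... passed on; `percent = TRUE` scales entries by 100.
#' @return A symmetric `matrix` of pairwise dissimilarities with zero
#'   diagonal and entries in \[0, 1\] (or \[0, 100\] with `percent = TRUE`).
#' @export
setGeneric("brayCurtis", function(x, ...) standardGeneric("brayCurtis"))
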