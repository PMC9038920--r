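#' Accessors for qsipdom classes
#'
#' Small accessors returning slot contents: sample identifier, marker gene,
#' label state, replicate id, the per-fraction table, qPCR curve efficiency
#' and validity, EAF per-pair table and summary, and DOM peak assignments.
#'
#' @param x an object.
#' @return The corresponding slot contents (see each class page).
#' @name accessors
NULL

#' @rdname accessors
setMethod("sampleId", "GradientProfile", function(x) x@sampleId)
#' @rdname accessors
setMethod("sampleId", "DomSample", function(x) x@sampleId)
#' @rdname accessors
setMethod("markerGene", "GradientProfile", function(x) x@marker)
#' @rdname accessors
setMethod("labelState", "GradientProfile", function(x) x@label)
#' @rdname accessors
setMethod("replicateId", "GradientProfile", function(x) x@replicateId)
#' @rdname accessors
setMethod("fractions", "GradientProfile", function(x) x@fractions)

#' @rdname accessors
setMethod("efficiency", "StandardCurve",
          function(x) 10^(-1 / x@slope) - 1)

#' @rdname accessors
setMethod("isValidCurve", "StandardCurve", function(x) {
  e <- efficiency(x)
  e >= 0.90 && e <= 1.10 && x@rSquared > 0.9
})

#' @rdname accessors
setMethod("eafPairs", "EafResult", function(x) x@pairs)
#' @rdname accessors
setMethod("eafSummary", "EafResult", function(x) x@summary)

#' @rdname accessors
setMethod("assignments", "DomSample", function(x) x@assignments)

setMethod("show", "GradientProfile", function(object) {
  fr <- object@fractions
  nq <- sum(fr$copies > 0 & !fr$below_detection)
  cat("GradientProfile:", object@sampleId,
      sprintf("[%s, %s, rep %s]\n", object@marker, object@label,
              object@replicateId))
  cat(sprintf("  %d fractions (%d quantified), density %.4f-%.4f g/mL\n",
              nrow(fr), nq, min(fr$density), max(fr$density)))
})

setMethod("show", "StandardCurve", function(object) {
  cat(sprintf(
    "StandardCurve: slope %.4f, intercept %.2f, R2 %.3f, efficiency %.1f%%%s\n",
    object@slope, object@intercept, object@rSquared,
    100 * efficiency(object),
    if (isValidCurve(object)) "" else " (INVALID)"))
})

setMethod("show", "EafResult", function(object) {
  s <- object@summary
  cat(sprintf("EafResult [%s, %s calibration]: %d pair(s)\n",
              object@marker, object@calibration, nrow(object@pairs)))
  cat(sprintf("  EAF mean %.4f (sd %s), clipped mean %.4f, atom%% %.2f\n",
              s$mean, if (is.na(s$sd)) "NA" else sprintf("%.4f", s$sd),
              s$mean_clipped, 100 * s$mean))
  if (!is.null(s$ci))
    cat(sprintf("  bootstrap 95%% CI: [%.4f, %.4f]\n", s$ci[1], s$ci[2]))
})

setMethod("show", "DomSample", function(object) {
  a <- object@assignments
  cat(sprintf("DomSample: %s (habitat: %s)\n", object@sampleId,
              object@habitat))
  cat(sprintf("  %d assigned formulas%s\n", nrow(a),
              if (nrow(a) && !all(is.na(a$rel_intensity)))
                ", intensities normalized" else ""))
})
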