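# qSIP chain: weighted mean buoyant density -> GC content -> per-nucleotide
# molecular weights -> excess atom fraction 13C.

.wmd <- function(density, copies, below_detection, minQuantified) {
  copies[below_detection] <- 0
  keep <- copies > 0
  if (!any(keep))
    stop("invalid profile: all copies are zero or below detection")
  if (sum(keep) < minQuantified)
    stop(sprintf(
      "invalid profile: %d quantified fraction(s), need at least %d",
      sum(keep), minQuantified))
  sum(density[keep] * copies[keep]) / sum(copies[keep])
}

#' @rdname weightedMeanDensity
#' @param minQuantified minimum number of fractions with positive copies
#'   required for a valid weighted mean.  Defaults to 3: gradients with one
#'   or two quantified fractions give spuriously precise band positions and
#'   are rejected.
#' @export
setMethod("weightedMeanDensity", "GradientProfile",
  function(x, minQuantified = 3) {
    fr <- x@fractions
    .wmd(fr$density, fr$copies, fr$below_detection, minQuantified)
  })

#' @rdname weightedMeanDensity
#' @export
setMethod("weightedMeanDensity", "data.frame",
  function(x, minQuantified = 3) {
    bd <- if (is.null(x$below_detection)) rep(FALSE, nrow(x)) else
      x$below_detection
    .wmd(x$density, x$copies, bd, minQuantified)
  })

#' Buoyant density of DNA from GC content
#'
#' Linear GC-to-density relation for DNA banding in a CsCl gradient.  The
#' `"schildkraut"` calibration (`rho = 1.660 + 0.098 * GC`) is the classic
#' forward prediction of band position from genome GC content; the
#' `"hungate"` calibration (`rho = 1.646057 + 0.083506 * G`) is the one
#' embedded in the qSIP EAF equation chain.  The two are deliberately not
#' interchangeable; see [gcFromDensity()] for the inverse.
#'
#' @param gc GC content as a fraction in \[0, 1\] (vectorized).
#' @param calibration `"schildkraut"` (default) or `"hungate"`.
#' @return Buoyant density in g/mL.
#' @examples
#' densityFromGC(0.315)   # ~1.69 g/mL, a low-GC yeast genome
#' @export
densityFromGC <- function(gc, calibration = c("schildkraut", "hungate")) {
  calibration <- match.arg(calibration)
  if (any(gc < 0 | gc > 1))
    stop("GC content must lie in [0, 1]")
  cal <- GC_DENSITY[[calibration]]
  unname(cal["intercept"] + cal["slope"] * gc)
}

#' GC content from the weighted mean density of an unlabeled gradient
#'
#' Inverts the linear GC-density calibration.  Values outside \[0, 1\] by at
#' most `tol` (measurement noise) are clamped with a warning; values further
#' out raise an error because the density is chemically implausible.
#'
#' @param wLight weighted mean density of the unlabeled profile, g/mL.
#' @param calibration `"hungate"` (default; the EAF-chain calibration) or
#'   `"schildkraut"`.
#' @param tol clamping tolerance on the GC scale, default 0.05.
#' @return GC content fraction in \[0, 1\].
#' @export
gcFromDensity <- function(wLight, calibration = c("hungate", "schildkraut"),
                          tol = 0.05) {
  calibration <- match.arg(calibration)
  cal <- GC_DENSITY[[calibration]]
  g <- unname((wLight - cal["intercept"]) / cal["slope"])
  if (any(g < -tol | g > 1 + tol))
    stop(sprintf(
      "implausible density: implied GC %s outside [%.2f, %.2f]",
      paste(sprintf("%.3f", g[g < -tol | g > 1 + tol]), collapse = ", "),
      -tol, 1 + tol))
  if (any(g < -1e-9 | g > 1 + 1e-9))
    warning("implied GC outside [0, 1] by <= ", tol, "; clamping")
  pmin(pmax(g, 0), 1)
}

#' Mean molecular weight per nucleotide of unlabeled DNA
#'
#' `M_light = 0.496 * G + 307.691` g/mol, the GC-dependent mean nucleotide
#' weight of DNA at natural isotopic abundance.
#'
#' @param gc GC content fraction in \[0, 1\].
#' @return g/mol per nucleotide.
#' @export
lightMolecularWeight <- function(gc) {
  if (any(gc < 0 | gc > 1)) stop("GC content must lie in [0, 1]")
  unname(MW_LIGHT["slope"] * gc + MW_LIGHT["intercept"])
}

#' Mean molecular weight per nucleotide of labeled DNA
#'
#' The density shift of the labeled gradient is attributed entirely to added
#' mass: `M_lab = (dW / W_light + 1) * M_light`, i.e.
#' `M_light * W_lab / W_light`.
#'
#' @param wLab weighted mean density of the labeled profile, g/mL.
#' @param wLight weighted mean density of the unlabeled profile, g/mL (> 0).
#' @param mLight unlabeled molecular weight, g/mol per nucleotide.
#' @return g/mol per nucleotide.
#' @export
labeledMolecularWeight <- function(wLab, wLight, mLight) {
  if (any(wLight <= 0)) stop("wLight must be positive")
  mLight * (wLab / wLight)
}

#' Maximum molecular weight of fully 13C-labeled DNA
#'
#' `M_heavymax = M_light + (9.974564 - 0.4987282 * G)` g/mol: the mass gain
#' when every carbon atom is 13C, which depends on GC content through the
#' carbon count per nucleotide.
#'
#' @param gc GC content fraction in \[0, 1\].
#' @param mLight unlabeled molecular weight, g/mol per nucleotide.
#' @return g/mol per nucleotide.
#' @export
maxHeavyMolecularWeight <- function(gc, mLight) {
  if (any(gc < 0 | gc > 1)) stop("GC content must lie in [0, 1]")
  unname(mLight + MW_HEAVY_GAIN["intercept"] + MW_HEAVY_GAIN["slope"] * gc)
}

#' Excess atom fraction 13C
#'
#' `EAF = (M_lab - M_light) / (M_heavymax - M_light) * (1 - 0.01111233)`:
#' the fraction of carbon atoms in the marker's DNA that are 13C in excess
#' of natural abundance.  An EAF of 0.3 means 30% of the carbon atoms in the
#' targeted gene are labeled.  Small negative values (noise) are returned
#' unclipped.
#'
#' @param mLab,mLight,mHeavymax molecular weights, g/mol per nucleotide;
#'   `mHeavymax` must exceed `mLight`.
#' @return EAF as a fraction, at most `1 - NAT13C`.
#' @export
excessAtomFraction <- function(mLab, mLight, mHeavymax) {
  if (any(mHeavymax <= mLight))
    stop("degenerate chemistry: mHeavymax must exceed mLight")
  (mLab - mLight) / (mHeavymax - mLight) * (1 - NAT13C)
}

#' Express an EAF as atom percent
#'
#' @param eaf excess atom fraction.
#' @return The same quantity on the percent scale (`eaf * 100`).
#' @export
eafToAtomPercent <- function(eaf) 100 * eaf

.eafChain <- function(wLight, wLab, calibration, replicateId) {
  g <- gcFromDensity(wLight, calibration = calibration)
  mLight <- lightMolecularWeight(g)
  mLab <- labeledMolecularWeight(wLab, wLight, mLight)
  mHeavy <- maxHeavyMolecularWeight(g, mLight)
  eaf <- excessAtomFraction(mLab, mLight, mHeavy)
  data.frame(replicateId = replicateId, W_light = wLight, W_lab = wLab,
             dW = wLab - wLight, G = g, M_light = mLight, M_lab = mLab,
             M_heavymax = mHeavy, eaf = eaf, atom_pct = 100 * eaf,
             stringsAsFactors = FALSE)
}

#' Excess atom fraction from paired gradient profiles
#'
#' Runs the full qSIP chain on paired labeled/unlabeled [GradientProfile]s:
#' weighted mean densities, GC content from the unlabeled band position,
#' molecular weights, and EAF per pair, with a mean/SD summary.  Negative
#' per-pair EAFs are retained in `eafPairs()`; the summary also carries a
#' zero-clipped mean.
#'
#' @param labeled a [GradientProfile-class] or list of them (the 13C
#'   incubations).
#' @param unlabeled a [GradientProfile-class] or list of them (controls).
#' @param pairing `"replicate"` matches labeled and unlabeled profiles
#'   one-to-one by `replicateId`; `"mean-control"` pairs every labeled
#'   profile against the mean weighted density of all controls.
#' @param calibration GC-density calibration used to infer GC from the
#'   unlabeled band position; `"hungate"` (default) or `"schildkraut"`.
#' @param bootstrap number of seeded bootstrap resamples of replicate pairs
#'   for a 95% confidence interval on the mean EAF; 0 (default) disables.
#' @param seed integer seed for the bootstrap.
#' @param minQuantified passed to [weightedMeanDensity()].
#' @return An [EafResult-class].
#' @examples
#' sim <- simulateGradientPair(gradientSimConfig(taxonGC = 0.5,
#'                                               trueEAF = 0.3, qpcrCV = 0))
#' res <- eafFromProfiles(sim$labeled, sim$unlabeled)
#' eafSummary(res)$mean
#' @export
eafFromProfiles <- function(labeled, unlabeled,
                            pairing = c("replicate", "mean-control"),
                            calibration = c("hungate", "schildkraut"),
                            bootstrap = 0, seed = 1L, minQuantified = 3) {
  pairing <- match.arg(pairing)
  calibration <- match.arg(calibration)
  if (is(labeled, "GradientProfile")) labeled <- list(labeled)
  if (is(unlabeled, "GradientProfile")) unlabeled <- list(unlabeled)
  stopifnot(length(labeled) >= 1, length(unlabeled) >= 1)
  markers <- unique(c(vapply(labeled, markerGene, ""),
                      vapply(unlabeled, markerGene, "")))
  if (length(markers) != 1)
    stop("pairing error: profiles mix markers (", paste(markers,
         collapse = ", "), ")")
  if (any(vapply(labeled, labelState, "") != "labeled") ||
      any(vapply(unlabeled, labelState, "") != "unlabeled"))
    stop("pairing error: 'labeled' must hold labeled profiles and ",
         "'unlabeled' the controls")

  wLab <- vapply(labeled, weightedMeanDensity, 0,
                 minQuantified = minQuantified)
  wLight <- vapply(unlabeled, weightedMeanDensity, 0,
                   minQuantified = minQuantified)

  if (pairing == "replicate") {
    repLab <- vapply(labeled, replicateId, "")
    repCtl <- vapply(unlabeled, replicateId, "")
    idx <- match(repLab, repCtl)
    if (anyNA(idx) || anyDuplicated(repLab) || anyDuplicated(repCtl))
      stop("pairing error: replicate ids must match one-to-one")
    pairs <- .eafChain(wLight[idx], wLab, calibration, repLab)
  } else {
    pairs <- .eafChain(rep(mean(wLight), length(wLab)), wLab, calibration,
                       vapply(labeled, replicateId, ""))
  }

  eafs <- pairs$eaf
  summ <- list(mean = mean(eafs),
               sd = if (length(eafs) > 1) sd(eafs) else NA_real_,
               mean_clipped = mean(pmax(eafs, 0)),
               n = length(eafs))
  if (bootstrap > 0) {
    set.seed(seed)
    bm <- vapply(seq_len(bootstrap), function(i)
      mean(eafs[sample.int(length(eafs), replace = TRUE)]), 0)
    summ$ci <- unname(quantile(bm, c(0.025, 0.975)))
  }
  new("EafResult", pairs = pairs, summary = summ,
      marker = markers, calibration = calibration)
}

#' Copies from a qPCR quantification cycle
#'
#' Converts Cq values to copy numbers through a [StandardCurve-class]:
#' `copies = 10^((cq - intercept) / slope)`.  Cq values beyond the
#' no-template-control threshold (default 35 cycles) are flagged
#' `below_detection`.
#'
#' @param cq numeric vector of quantification cycles.
#' @param curve a valid [StandardCurve-class].
#' @param detectionCq Cq above which a reaction is considered below the
#'   detection limit, default 35.
#' @return `data.frame` with columns `cq`, `copies`, `below_detection`.
#' @export
quantifyFromCq <- function(cq, curve, detectionCq = 35) {
  if (!isValidCurve(curve))
    stop("rejected: standard curve outside validity bounds ",
         "(efficiency 90-110%, R2 > 0.9)")
  data.frame(cq = cq,
             copies = 10^((cq - curve@intercept) / curve@slope),
             below_detection = cq > detectionCq)
}
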