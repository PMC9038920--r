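# Seeded simulators: SIP gradient pairs with known EAF, FT-ICR-MS peak
# lists with known formulas, and grouped DOM sample matrices.

#' Configuration for the gradient-pair simulator
#'
#' Defaults mirror the study conditions: 15 fractions spanning
#' 1.66-1.78 g/mL (gradients started at 1.70 g/mL), a Gaussian DNA band
#' (isoconcentration approximation) of width 0.006 g/mL, and multiplicative
#' lognormal qPCR noise with 20% coefficient of variation.
#'
#' @param nFractions number of gradient fractions, >= 5; default 15.
#' @param densitySpan range of fraction densities, g/mL; default
#'   `c(1.66, 1.78)`.
#' @param bandSD Gaussian band standard deviation, g/mL; default 0.006.
#' @param taxonGC GC content of the banding DNA, fraction.
#' @param trueEAF ground-truth excess atom fraction, in
#'   \[0, 1 - NAT13C\].
#' @param totalCopies total marker copies distributed over the gradient.
#' @param qpcrCV coefficient of variation of lognormal qPCR noise;
#'   0 disables.
#' @param detectionFloor copies below this are flagged below detection.
#' @param calibration GC-density calibration for the forward model,
#'   `"hungate"` (default, matching [eafFromProfiles()]) or
#'   `"schildkraut"`.
#' @param sampleId sample identifier for the simulated profiles.
#' @param seed integer seed.
#' @return Validated configuration list.
#' @export
gradientSimConfig <- function(nFractions = 15, densitySpan = c(1.66, 1.78),
                              bandSD = 0.006, taxonGC = 0.5, trueEAF = 0,
                              totalCopies = 1e6, qpcrCV = 0.20,
                              detectionFloor = 0,
                              calibration = c("hungate", "schildkraut"),
                              sampleId = "sim", seed = 1L) {
  calibration <- match.arg(calibration)
  stopifnot(nFractions >= 5, bandSD > 0, length(densitySpan) == 2,
            densitySpan[1] < densitySpan[2],
            taxonGC >= 0, taxonGC <= 1,
            trueEAF >= 0, trueEAF <= 1 - NAT13C,
            totalCopies > 0, qpcrCV >= 0, detectionFloor >= 0)
  list(nFractions = as.integer(nFractions), densitySpan = densitySpan,
       bandSD = bandSD, taxonGC = taxonGC, trueEAF = trueEAF,
       totalCopies = totalCopies, qpcrCV = qpcrCV,
       detectionFloor = detectionFloor, calibration = calibration,
       sampleId = sampleId, seed = as.integer(seed))
}

# copies per fraction: Gaussian band integrated over each fraction's density
# interval, renormalized over the gradient span so totals are conserved
.bandCopies <- function(centers, mu, sd, total) {
  mids <- (centers[-1] + centers[-length(centers)]) / 2
  step <- diff(centers)
  lo <- c(centers[1] - step[1] / 2, mids)
  hi <- c(mids, centers[length(centers)] + step[length(step)] / 2)
  w <- pnorm(hi, mu, sd) - pnorm(lo, mu, sd)
  total * w / sum(w)
}

#' Simulate a labeled/unlabeled gradient pair with known EAF
#'
#' Forward model inverting the EAF chain: the unlabeled band centers at the
#' density implied by `taxonGC` (via the configured calibration); the
#' labeled band center is obtained by converting `trueEAF` to a labeled
#' molecular weight and back to a density.  Copies per fraction are the
#' Gaussian band mass integrated over each fraction's density interval,
#' scaled to `totalCopies` (conserved exactly before noising), then
#' multiplied by lognormal noise of unit mean and flagged below the
#' detection floor.
#'
#' @param config a [gradientSimConfig()] list.
#' @return List with elements `labeled` and `unlabeled`
#'   ([GradientProfile-class]) and `truth` (true EAF, GC, band centers,
#'   molecular weights, seed).
#' @export
simulateGradientPair <- function(config = gradientSimConfig()) {
  set.seed(config$seed)
  g <- config$taxonGC
  wLight <- densityFromGC(g, calibration = config$calibration)
  mLight <- lightMolecularWeight(g)
  mHeavy <- maxHeavyMolecularWeight(g, mLight)
  mLab <- mLight + config$trueEAF / (1 - NAT13C) * (mHeavy - mLight)
  wLab <- wLight * mLab / mLight
  span <- config$densitySpan
  if (wLight < span[1] || wLight > span[2] ||
      wLab < span[1] || wLab > span[2])
    stop(sprintf(
      "config error: band center(s) %.4f / %.4f g/mL outside span [%.2f, %.2f]",
      wLight, wLab, span[1], span[2]))

  centers <- seq(span[1], span[2], length.out = config$nFractions)
  mk <- function(mu, label) {
    copies <- .bandCopies(centers, mu, config$bandSD, config$totalCopies)
    if (config$qpcrCV > 0) {
      sdlog <- sqrt(log(1 + config$qpcrCV^2))
      copies <- copies * rlnorm(length(copies), -sdlog^2 / 2, sdlog)
    }
    GradientProfile(config$sampleId, "18S", label,
      data.frame(fraction_index = seq_along(centers), density = centers,
                 copies = copies,
                 below_detection = copies < config$detectionFloor))
  }
  list(labeled = mk(wLab, "labeled"),
       unlabeled = mk(wLight, "unlabeled"),
       truth = list(trueEAF = config$trueEAF, gc = g,
                    W_light = wLight, W_lab = wLab,
                    M_light = mLight, M_lab = mLab, M_heavymax = mHeavy,
                    seed = config$seed, calibration = config$calibration))
}

#' Configuration for the peak-list simulator
#'
#' Formulas are sampled from the CHNOSP constraint space restricted to
#' H/C and O/C bands typical of marine DOM, with masses inside the
#' acquisition window.  Observed m/z values carry Gaussian ppm-scale error;
#' intensities are lognormal; noise peaks carry no truth formula.
#'
#' @param nFormulas number of true formula peaks.
#' @param mzWindow m/z acquisition window, Da; default `c(95, 1000)`.
#' @param hcRange,ocRange H/C and O/C sampling bands.
#' @param nRange,sRange,pRange heteroatom count ranges.
#' @param minOxygen minimum oxygen count, default 1.
#' @param ppmSD standard deviation of mass error, ppm; default 0.2.
#' @param intensityMeanlog,intensitySDlog lognormal intensity parameters.
#' @param nNoisePeaks number of unassignable noise peaks; default 50.
#' @param seed integer seed.
#' @return Validated configuration list.
#' @export
spectrumSimConfig <- function(nFormulas = 500, mzWindow = MASS_WINDOW,
                              hcRange = c(0.5, 2.2), ocRange = c(0, 1.2),
                              nRange = c(0L, 4L), sRange = c(0L, 2L),
                              pRange = c(0L, 1L), minOxygen = 1,
                              ppmSD = 0.2, intensityMeanlog = log(1e7),
                              intensitySDlog = 1, nNoisePeaks = 50,
                              seed = 1L) {
  stopifnot(nFormulas >= 1, mzWindow[1] < mzWindow[2],
            hcRange[1] <= hcRange[2], ocRange[1] <= ocRange[2],
            ppmSD >= 0, nNoisePeaks >= 0,
            nRange[2] <= ELEMENT_LIMITS$n[2],
            sRange[2] <= ELEMENT_LIMITS$s[2],
            pRange[2] <= ELEMENT_LIMITS$p[2])
  if (mzWindow[2] + PROTON_MASS <
      monoisotopicMass(1, 1, minOxygen) + 1e-9)
    stop("config error: infeasible constraint ranges for the mass window")
  list(nFormulas = as.integer(nFormulas), mzWindow = mzWindow,
       hcRange = hcRange, ocRange = ocRange, nRange = nRange,
       sRange = sRange, pRange = pRange, minOxygen = minOxygen,
       ppmSD = ppmSD, intensityMeanlog = intensityMeanlog,
       intensitySDlog = intensitySDlog,
       nNoisePeaks = as.integer(nNoisePeaks), seed = as.integer(seed))
}

# rejection-sample distinct valid formulas with neutral mass - proton
# inside the m/z window
.sampleFormulas <- function(cfg) {
  want <- cfg$nFormulas
  got <- data.frame()
  keys <- character()
  massLo <- cfg$mzWindow[1] + PROTON_MASS
  massHi <- cfg$mzWindow[2] + PROTON_MASS
  cMax <- min(ELEMENT_LIMITS$c[2], floor(massHi / 12))
  tries <- 0
  while (nrow(got) < want) {
    tries <- tries + 1
    if (tries > 2000 * want)
      stop("config error: infeasible constraint ranges (sampler starved)")
    c_ <- sample(3:cMax, 1)
    n_ <- sample(cfg$nRange[1]:cfg$nRange[2], 1,
                 prob = 0.5^(0:(cfg$nRange[2] - cfg$nRange[1])))
    s_ <- sample(cfg$sRange[1]:cfg$sRange[2], 1,
                 prob = 0.6^(0:(cfg$sRange[2] - cfg$sRange[1])))
    p_ <- sample(cfg$pRange[1]:cfg$pRange[2], 1,
                 prob = 0.8^(0:(cfg$pRange[2] - cfg$pRange[1])))
    h_ <- round(c_ * runif(1, cfg$hcRange[1], cfg$hcRange[2]))
    if ((h_ + n_ + p_) %% 2 == 1) h_ <- h_ + 1  # integer DBE (nitrogen rule)
    o_ <- round(c_ * runif(1, cfg$ocRange[1], cfg$ocRange[2]))
    o_ <- max(o_, cfg$minOxygen)
    if (h_ < 1 || h_ > min(ELEMENT_LIMITS$h[2], 2 * c_ + 2 + n_)) next
    if (o_ > ELEMENT_LIMITS$o[2]) next
    if (doubleBondEquivalents(c_, h_, o_, n_, s_, p_) < 0) next
    m <- monoisotopicMass(c_, h_, o_, n_, s_, p_)
    if (m < massLo || m > massHi) next
    k <- formulaKey(c_, h_, o_, n_, s_, p_)
    if (k %in% keys) next
    keys <- c(keys, k)
    got <- rbind(got, data.frame(c = c_, h = h_, o = o_, n = n_, s = s_,
                                 p = p_, mass = m))
  }
  got
}

#' Simulate an FT-ICR-MS peak list with known formulas
#'
#' @param config a [spectrumSimConfig()] list.
#' @return List with `peaks` (`data.frame`: `mz`, `intensity`, ordered by
#'   m/z) and `truth` (`data.frame`: one row per peak with `is_noise` flag
#'   and the generating element counts for signal peaks; plus the seed as
#'   an attribute).
#' @export
simulatePeakList <- function(config = spectrumSimConfig()) {
  set.seed(config$seed)
  f <- .sampleFormulas(config)
  eps <- rnorm(nrow(f), 0, config$ppmSD * 1e-6)
  mzSignal <- (f$mass - PROTON_MASS) * (1 + eps)
  intSignal <- rlnorm(nrow(f), config$intensityMeanlog,
                      config$intensitySDlog)
  truth <- data.frame(mz = mzSignal, is_noise = FALSE,
                      c = f$c, h = f$h, o = f$o, n = f$n, s = f$s, p = f$p)
  if (config$nNoisePeaks > 0) {
    mzNoise <- runif(config$nNoisePeaks, config$mzWindow[1],
                     config$mzWindow[2])
    intNoise <- rlnorm(config$nNoisePeaks, config$intensityMeanlog - 2,
                       config$intensitySDlog)
    truth <- rbind(truth,
                   data.frame(mz = mzNoise, is_noise = TRUE, c = NA, h = NA,
                              o = NA, n = NA, s = NA, p = NA))
    mzSignal <- c(mzSignal, mzNoise)
    intSignal <- c(intSignal, intNoise)
  }
  ord <- order(mzSignal)
  peaks <- data.frame(mz = mzSignal[ord], intensity = intSignal[ord])
  truth <- truth[ord, , drop = FALSE]
  rownames(truth) <- NULL
  attr(truth, "seed") <- config$seed
  list(peaks = peaks, truth = truth)
}

#' Simulate grouped DOM samples with class-level intensity shifts
#'
#' Emulates a habitat contrast (e.g., water column versus sediment pore
#' water, where nitrogen-containing unsaturated formulas are relatively
#' enriched in the sediments): all groups share one pool of formulas with a
#' common base intensity profile; each group multiplies the intensities of
#' chosen compound classes by stated factors, each sample adds lognormal
#' noise, and rows are renormalized.
#'
#' @param nPerGroup samples per group, >= 2.
#' @param groups named list (>= 2 entries) of named numeric vectors giving
#'   multiplicative intensity shifts per compound class (names from
#'   [DOM_CLASSES]); an empty vector means no shift.  The default contrasts
#'   a `water` group (no shift) with a `sediment` group where
#'   "Unsaturated with N" is enriched threefold and "Highly unsaturated
#'   O-poor" halved.
#' @param nFormulas size of the shared formula pool, default 150.
#' @param sampleSDlog lognormal per-sample noise (sdlog), default 0.3.
#' @param seed integer seed.
#' @return List with `set` (a [DomSet-class]; colData holds the group as
#'   `habitat`) and `truth` (group labels, shift table, seed).
#' @export
simulateDomGroups <- function(nPerGroup = 3,
                              groups = list(
                                water = c(),
                                sediment = c("Unsaturated with N" = 3,
                                             "Highly unsaturated O-poor" = 0.5)),
                              nFormulas = 150, sampleSDlog = 0.3,
                              seed = 1L) {
  if (length(groups) < 2) stop("config error: need at least 2 groups")
  if (nPerGroup < 2) stop("config error: need at least 2 samples per group")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be named")
  set.seed(seed)
  cfg <- spectrumSimConfig(nFormulas = nFormulas, mzWindow = c(95, 650),
                           nNoisePeaks = 0, seed = seed)
  pool <- .sampleFormulas(cfg)
  cls <- as.character(classifyFormula(pool$c, pool$h, pool$o, pool$n,
                                      pool$s, pool$p))
  base <- rlnorm(nFormulas, log(1e6), 1)
  if (max(base) / sum(base) > 0.99)
    warning("degenerate composition: nearly all intensity on one formula")

  samples <- list()
  for (gName in names(groups)) {
    shift <- groups[[gName]]
    bad <- setdiff(names(shift), DOM_CLASSES)
    if (length(bad))
      stop("unknown compound class in shifts: ", paste(bad, collapse = ", "))
    mult <- rep(1, nFormulas)
    for (cl in names(shift)) mult[cls == cl] <- shift[[cl]]
    for (i in seq_len(nPerGroup)) {
      intensity <- base * mult * rlnorm(nFormulas, 0, sampleSDlog)
      a <- data.frame(
        mz = pool$mass - PROTON_MASS, intensity = intensity,
        c = pool$c, h = pool$h, o = pool$o, n = pool$n, s = pool$s,
        p = pool$p, error_ppm = 0, dbe = doubleBondEquivalents(pool),
        n_candidates = 1L, ambiguous = FALSE, neutral_mass = pool$mass,
        hc = pool$h / pool$c, oc = pool$o / pool$c, nc = pool$n / pool$c,
        sc = pool$s / pool$c, pc = pool$p / pool$c,
        ai_mod = aiMod(pool), compound_class = classifyFormula(pool),
        rel_intensity = NA_real_)
      ds <- new("DomSample", sampleId = sprintf("%s_%02d", gName, i),
                habitat = gName, assignments = a)
      samples[[length(samples) + 1]] <- normalizeIntensities(ds)
    }
  }
  list(set = domSet(samples),
       truth = list(groups = rep(names(groups), each = nPerGroup),
                    shifts = groups, nFormulas = nFormulas, seed = seed))
}
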