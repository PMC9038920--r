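# Physical constants shared across the qSIP and DOM chains.

#' Natural abundance of 13C
#'
#' Fraction of carbon atoms that are 13C at natural abundance.  The excess
#' atom fraction of a fully labeled molecule saturates at `1 - NAT13C`.
#'
#' @format Length-one numeric.
#' @export
NAT13C <- 0.01111233

# Exact monoisotopic masses (Da) of the light isotopes used in formula
# assignment; 12C is exactly 12 by definition of the unified mass scale.
ISOTOPE_MASS <- c(
  c = 12,
  h = 1.00782503,
  o = 15.99491462,
  n = 14.00307401,
  s = 31.97207069,
  p = 30.97376151
)

#' Mass of a proton in Da
#'
#' Used to convert between the m/z of a singly deprotonated ion and the
#' neutral monoisotopic mass.
#'
#' @format Length-one numeric.
#' @export
PROTON_MASS <- 1.00727646

# GC -> buoyant density calibrations (g/mL).
#
# "schildkraut": rho = 1.660 + 0.098 * GC, the classic CsCl relation; used
# for forward predictions of band position from genome GC content.
#
# "hungate": W_light = 1.646057 + 0.083506 * G, the calibration embedded in
# the qSIP EAF equation chain; inverted as G = (W_light - 1.646057)/0.083506.
GC_DENSITY <- list(
  schildkraut = c(intercept = 1.660, slope = 0.098),
  hungate     = c(intercept = 1.646057, slope = 0.083506)
)

# Per-nucleotide molecular weight coefficients of the EAF chain (g/mol):
# M_light = 0.496 * G + 307.691
# M_heavymax - M_light = -0.4987282 * G + 9.974564   (full 13C labeling)
MW_LIGHT <- c(intercept = 307.691, slope = 0.496)
MW_HEAVY_GAIN <- c(intercept = 9.974564, slope = -0.4987282)

# Element-count constraint space for DOM formula assignment.
ELEMENT_LIMITS <- list(
  c = c(1L, 100L),
  h = c(1L, 250L),
  o = c(0L, 100L),
  n = c(0L, 4L),
  s = c(0L, 2L),
  p = c(0L, 1L)
)

# FT-ICR-MS acquisition window, Da.
MASS_WINDOW <- c(95, 1000)
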